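# CSV I/O for kinetic series. The transwell CSV holds time/receiver_conc;
# geometry goes to a JSON sidecar so the record is self-describing.

#' Write / read a transwell experiment (CSV + JSON sidecar)
#'
#' @param exp A [transwell_experiment()].
#' @param path CSV path; the sidecar is written to `<path>.json`.
#' @return `write_transwell_csv()` returns `path` invisibly;
#'   `read_transwell_csv()` a [transwell_experiment()].
#' @export
write_transwell_csv <- function(exp, path) {
  stopifnot(inherits(exp, "transwell_experiment"))
  utils::write.csv(
    data.frame(time = exp$data$time_min, receiver_conc = exp$data$receiver_conc),
    path,
    row.names = FALSE
  )
  jsonlite::write_json(
    list(
      donor_conc0 = exp$donor_conc0, donor_volume_ml = exp$donor_volume,
      receiver_volume_ml = exp$receiver_volume, area_cm2 = exp$area,
      direction = exp$direction, teer = exp$teer
    ),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' @rdname write_transwell_csv
#' @export
read_transwell_csv <- function(path) {
  d <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  transwell_experiment(
    times = d$time, receiver_conc = d$receiver_conc,
    donor_conc0 = meta$donor_conc0, donor_volume = meta$donor_volume_ml,
    receiver_volume = meta$receiver_volume_ml, area = meta$area_cm2,
    direction = meta$direction, teer = meta$teer
  )
}

#' Write / read a ThT trace as CSV
#'
#' Columns `time`, `intensity`, with a header row.
#'
#' @param trace A [tht_trace()].
#' @param path CSV path.
#' @return `write_tht_csv()` returns `path` invisibly; `read_tht_csv()` a
#'   [tht_trace()].
#' @export
write_tht_csv <- function(trace, path) {
  stopifnot(inherits(trace, "tht_trace"))
  utils::write.csv(
    data.frame(time = trace$time_h, intensity = trace$intensity),
    path,
    row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_tht_csv
#' @export
read_tht_csv <- function(path) {
  d <- utils::read.csv(path)
  tht_trace(d$time, d$intensity)
}
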