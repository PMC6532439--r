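#' Background-level an AFM height map
#'
#' Subtracts the least-squares constant (`order = 0`) or plane (`order = 1`)
#' from the image, the usual first step before thresholding raw AFM
#' topographs. No clipping is applied to the residual heights.
#'
#' @param map A [height_map()].
#' @param order 0 for constant (mean) removal, 1 for plane removal.
#' @return The levelled [height_map()].
#' @export
level_map <- function(map, order = 1L) {
  stopifnot(inherits(map, "height_map"), order %in% c(0L, 1L))
  h <- map$heights
  if (order == 0L) {
    h <- h - mean(h)
  } else {
    d <- dim(h)
    ri <- rep(seq_len(d[1]), times = d[2])
    ci <- rep(seq_len(d[2]), each = d[1])
    fit <- stats::lm.fit(cbind(1, ri, ci), as.vector(h))
    h <- matrix(fit$residuals, d[1], d[2])
  }
  out <- map
  out$heights <- h
  out
}

#' Pixel fraction above a fixed height threshold
#'
#' The aggregate fibrillation index: the percentage of image pixels whose
#' height is strictly greater than a fixed threshold (default 1.5 nm). The
#' count of such pixels is proportional to the total deposited fibril
#' length, so the percentage tracks fibril growth or disassembly.
#'
#' @param map A [height_map()].
#' @param threshold Height threshold in nm (>= 0); default 1.5.
#' @return A one-row tibble: `threshold`, `n_above`, `n_total`,
#'   `percent_above`.
#' @examples
#' hm <- height_map(matrix(c(0, 2, 0, 3), 2), pixel_size = 1)
#' pixel_fraction_above(hm, 1.5)$percent_above # 50
#' @export
pixel_fraction_above <- function(map, threshold = 1.5) {
  stopifnot(inherits(map, "height_map"))
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold < 0) {
    stop("`threshold` must be a single non-negative number (nm)",
      call. = FALSE
    )
  }
  n_total <- length(map$heights)
  n_above <- sum(map$heights > threshold)
  tibble::tibble(
    threshold = threshold,
    n_above = n_above,
    n_total = n_total,
    percent_above = 100 * n_above / n_total
  )
}

#' Fibrillation time course from replicate AFM images
#'
#' Applies [pixel_fraction_above()] to a set of height maps carrying
#' acquisition times, averages replicates per time point (arithmetic mean,
#' SD as the replicate dispersion), and returns the series sorted by time.
#'
#' @param maps List of [height_map()] objects; each must have a non-`NULL`
#'   `time` (hours). Several maps may share a time (replicate images).
#' @param threshold Height threshold in nm; default 1.5.
#' @return A tibble of class `fibrillation_timecourse` with columns
#'   `time_h`, `percent_above`, `sd`, `n_maps` (and `normalized` after
#'   [normalize_timecourse()]).
#' @export
fibrillation_timecourse <- function(maps, threshold = 1.5) {
  stopifnot(is.list(maps), length(maps) >= 1)
  times <- vapply(maps, function(m) {
    stopifnot(inherits(m, "height_map"))
    if (is.null(m$time)) {
      stop("every map needs a `time` (hours)", call. = FALSE)
    }
    m$time
  }, numeric(1))
  pct <- vapply(
    maps, function(m) pixel_fraction_above(m, threshold)$percent_above,
    numeric(1)
  )
  out <- tibble::tibble(time_h = times, percent_above = pct) |>
    dplyr::group_by(.data$time_h) |>
    dplyr::summarise(
      sd = if (dplyr::n() > 1) stats::sd(.data$percent_above) else 0,
      n_maps = dplyr::n(),
      percent_above = mean(.data$percent_above),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$time_h) |>
    dplyr::select("time_h", "percent_above", "sd", "n_maps")
  class(out) <- c("fibrillation_timecourse", class(out))
  attr(out, "threshold") <- threshold
  out
}

#' Normalize a fibrillation time course to its starting point
#'
#' Divides each time point's mean percentage by the value at the first
#' (earliest) time, so every series starts at 1; used when comparing
#' disaggregation kinetics across samples.
#'
#' @param tc A [fibrillation_timecourse()] result.
#' @return The same tibble with a `normalized` column (`normalized[1] == 1`).
#' @export
normalize_timecourse <- function(tc) {
  stopifnot(inherits(tc, "fibrillation_timecourse"))
  p0 <- tc$percent_above[1]
  if (!is.finite(p0) || p0 <= 0) {
    stop("cannot normalize: percent_above at the first time point is not > 0",
      call. = FALSE
    )
  }
  tc$normalized <- tc$percent_above / p0
  tc
}

#' Plot a fibrillation time course
#'
#' @param object A [fibrillation_timecourse()] result.
#' @param normalized Plot the normalized series if present.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fibrillation_timecourse <- function(object, normalized = FALSE, ...) {
  if (normalized && !"normalized" %in% names(object)) {
    object <- normalize_timecourse(object)
  }
  y <- if (normalized) "normalized" else "percent_above"
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$time_h, .data[[y]])) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "incubation time (h)",
      y = if (normalized) {
        "pixel fraction above threshold (normalized)"
      } else {
        "% pixels above threshold"
      }
    )
  if (!normalized) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$percent_above - .data$sd,
        ymax = .data$percent_above + .data$sd
      ),
      width = 0
    )
  }
  p
}
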