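#' AFM height map
#'
#' Container for an atomic-force-microscopy topography image: a rectangular
#' grid of surface heights in nanometres together with the lateral pixel size.
#' All AFM analytics in the package ([pixel_fraction_above()],
#' [height_distribution()], ...) consume this object.
#'
#' @param heights Numeric matrix of heights (nm). Rows/columns are image
#'   pixels; values must be finite.
#' @param pixel_size Lateral size of one pixel (nm), a single positive number.
#' @param label Optional character label (e.g. sample name).
#' @param time Optional acquisition time in hours, used by
#'   [fibrillation_timecourse()].
#'
#' @return An object of class `height_map`: a list with elements `heights`,
#'   `pixel_size`, `label`, `time`.
#' @examples
#' hm <- height_map(matrix(0, 16, 16), pixel_size = 4)
#' dim(hm$heights)
#' @export
height_map <- function(heights, pixel_size, label = NULL, time = NULL) {
  heights <- as.matrix(heights)
  if (length(heights) == 0L) {
    stop("`heights` must be a non-empty matrix", call. = FALSE)
  }
  if (!is.numeric(heights) || !all(is.finite(heights))) {
    stop("`heights` must be numeric and finite", call. = FALSE)
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0) {
    stop("`pixel_size` must be a single positive number (nm)", call. = FALSE)
  }
  structure(
    list(
      heights = unname(heights),
      pixel_size = as.numeric(pixel_size),
      label = label,
      time = if (!is.null(time)) as.numeric(time) else NULL
    ),
    class = "height_map"
  )
}

#' @export
print.height_map <- function(x, ...) {
  d <- dim(x$heights)
  cat(sprintf(
    "<height_map> %d x %d pixels, %.3g nm/pixel (%.3g x %.3g nm)\n",
    d[1], d[2], x$pixel_size, d[1] * x$pixel_size, d[2] * x$pixel_size
  ))
  if (!is.null(x$label)) cat("  label:", x$label, "\n")
  if (!is.null(x$time)) cat("  time :", x$time, "h\n")
  cat(sprintf(
    "  heights: min %.3g, max %.3g nm\n",
    min(x$heights), max(x$heights)
  ))
  invisible(x)
}

#' @export
as_tibble.height_map <- function(x, ...) {
  d <- dim(x$heights)
  tibble::tibble(
    x_nm = rep((seq_len(d[2]) - 0.5) * x$pixel_size, each = d[1]),
    y_nm = rep((seq_len(d[1]) - 0.5) * x$pixel_size, times = d[2]),
    height_nm = as.vector(x$heights)
  )
}

#' Write / read a height map as a plain-text matrix with a JSON sidecar
#'
#' The grid is stored as a tab-separated numeric matrix (`<path>`); metadata
#' (`pixel_size_nm`, optional `label`, `time_h`, `seed`) goes to
#' `<path>.json`.
#'
#' @param map A [height_map()].
#' @param path Output path for the TSV matrix.
#' @param seed Optional integer recorded in the sidecar for provenance.
#' @return `write_height_map()` returns `path` invisibly; `read_height_map()`
#'   returns a [height_map()].
#' @export
write_height_map <- function(map, path, seed = NULL) {
  stopifnot(inherits(map, "height_map"))
  utils::write.table(map$heights, path,
    sep = "\t", row.names = FALSE,
    col.names = FALSE
  )
  meta <- list(
    pixel_size_nm = map$pixel_size,
    field_size_nm = nrow(map$heights) * map$pixel_size
  )
  if (!is.null(map$label)) meta$label <- map$label
  if (!is.null(map$time)) meta$time_h <- map$time
  if (!is.null(seed)) meta$seed <- seed
  jsonlite::write_json(meta, paste0(path, ".json"),
    auto_unbox = TRUE,
    digits = NA
  )
  invisible(path)
}

#' @rdname write_height_map
#' @export
read_height_map <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  height_map(m,
    pixel_size = meta$pixel_size_nm,
    label = meta$label %||% NULL,
    time = meta$time_h %||% NULL
  )
}

#' @importFrom rlang %||%
NULL

#' Plot a height map
#'
#' @param object A [height_map()].
#' @param ... Unused.
#' @return A ggplot raster of the topography with nm axes.
#' @export
autoplot.height_map <- function(object, ...) {
  df <- as_tibble.height_map(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$x_nm, .data$y_nm,
    fill = .data$height_nm
  )) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "height (nm)") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "x (nm)", y = "y (nm)",
      title = object$label %||% "AFM height map"
    )
}
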