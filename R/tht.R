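#' Thioflavin-T fluorescence trace
#'
#' A ThT fluorescence time series; ThT emission reports beta-sheet amyloid
#' content, so a decaying trace tracks fibril disassembly.
#'
#' @param times Sampling times (h), strictly increasing from 0.
#' @param intensity Fluorescence intensities (a.u., >= 0).
#' @param label Optional sample label.
#' @return A tibble of class `tht_trace` with columns `time_h`, `intensity`
#'   (and `normalized` after [normalize_tht()]).
#' @export
tht_trace <- function(times, intensity, label = NULL) {
  stopifnot(length(times) == length(intensity), all(intensity >= 0))
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  out <- tibble::tibble(time_h = times, intensity = intensity)
  class(out) <- c("tht_trace", class(out))
  attr(out, "label") <- label
  out
}

#' Simulate a ThT fluorescence trace
#'
#' Monotone decay models for fibril disassembly kinetics, sampled at
#' `sample_times` with optional multiplicative Gaussian noise:
#'
#' * `"none"` - constant at `baseline_intensity`;
#' * `"exponential"` - `baseline * (plateau + (1 - plateau) exp(-k t))`;
#' * `"sigmoidal"` - `baseline * (plateau + (1 - plateau) / (1 +
#'   exp(k (t - t_half))))`, `t_half` the midpoint of the sampled span.
#'
#' @param baseline_intensity Intensity at t = 0 (a.u., > 0).
#' @param decay_model One of `"none"`, `"exponential"`, `"sigmoidal"`.
#' @param decay_rate Decay rate k (1/h).
#' @param plateau_fraction Long-time intensity as a fraction of baseline,
#'   in `[0, 1]`.
#' @param sample_times Sampling times (h), increasing from 0.
#' @param noise_cv Multiplicative noise CV (fraction); 0 disables.
#' @param seed Integer RNG seed.
#' @return A [tht_trace()] with a `truth` attribute.
#' @export
gen_tht_trace <- function(baseline_intensity,
                          decay_model = c("none", "exponential", "sigmoidal"),
                          decay_rate = 0.1, plateau_fraction = 0,
                          sample_times = seq(0, 24, by = 2),
                          noise_cv = 0, seed = 1L) {
  decay_model <- match.arg(decay_model)
  stopifnot(
    baseline_intensity > 0, plateau_fraction >= 0, plateau_fraction <= 1,
    decay_rate >= 0, noise_cv >= 0, sample_times[1] == 0
  )
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  t <- sample_times
  shape <- switch(decay_model,
    none = rep(1, length(t)),
    exponential = plateau_fraction +
      (1 - plateau_fraction) * exp(-decay_rate * t),
    sigmoidal = {
      t_half <- max(t) / 2
      plateau_fraction + (1 - plateau_fraction) /
        (1 + exp(decay_rate * (t - t_half)))
    }
  )
  y <- baseline_intensity * shape
  if (noise_cv > 0) {
    y <- pmax(y * (1 + stats::rnorm(length(y), sd = noise_cv)), 0)
  }
  out <- tht_trace(t, y)
  attr(out, "truth") <- list(
    baseline_intensity = baseline_intensity, decay_model = decay_model,
    decay_rate = decay_rate, plateau_fraction = plateau_fraction,
    noise_cv = noise_cv, seed = seed, intensity_clean = baseline_intensity * shape
  )
  out
}

#' Normalize a ThT trace to its zero-time intensity
#'
#' @param trace A [tht_trace()].
#' @return The trace with a `normalized` column (`normalized[1] == 1`).
#' @export
normalize_tht <- function(trace) {
  stopifnot(inherits(trace, "tht_trace"))
  i0 <- trace$intensity[1]
  if (!is.finite(i0) || i0 <= 0) {
    stop("cannot normalize: zero-time intensity is not > 0", call. = FALSE)
  }
  trace$normalized <- trace$intensity / i0
  trace
}

#' Percent reduction of ThT signal at a given time
#'
#' `100 * (1 - normalized intensity)` at the sampled time nearest `t`
#' (ties toward the earlier sample); e.g. a normalized value of 0.6 at 18 h
#' is a 40% reduction in beta-sheet content.
#'
#' @param trace A [tht_trace()].
#' @param t Time (h).
#' @return Percent reduction relative to the zero-time intensity.
#' @export
percent_reduction <- function(trace, t) {
  trace <- normalize_tht(trace)
  i <- which.min(abs(trace$time_h - t))
  100 * (1 - trace$normalized[i])
}

#' Earliest time the normalized ThT signal falls to a fraction
#'
#' Scans the sampled series for the first time the normalized intensity is
#' at or below `fraction` (e.g. 0.1 for near-complete disruption of the
#' beta-sheet signal).
#'
#' @param trace A [tht_trace()].
#' @param fraction Target normalized level in `[0, 1]`.
#' @return The earliest sampled time (h), or `NA` with a `"not reached"`
#'   message attribute when the series never reaches the level.
#' @export
time_to_fraction <- function(trace, fraction) {
  stopifnot(fraction >= 0, fraction <= 1)
  trace <- normalize_tht(trace)
  i <- which(trace$normalized <= fraction)
  if (length(i) == 0) {
    out <- NA_real_
    attr(out, "status") <- "not reached"
    return(out)
  }
  trace$time_h[min(i)]
}

#' Plot a ThT trace
#'
#' @param object A [tht_trace()].
#' @param ... Unused.
#' @return A ggplot of the normalized intensity over time.
#' @export
autoplot.tht_trace <- function(object, ...) {
  object <- normalize_tht(object)
  ggplot2::ggplot(object, ggplot2::aes(.data$time_h, .data$normalized)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "time (h)", y = "ThT intensity (normalized)")
}
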