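#' Transwell experiment record
#'
#' Donor/receiver geometry and the receiver concentration time series of a
#' two-compartment transwell assay (endothelial monolayer on a porous
#' insert). Direction "efflux" means basolateral donor, apical receiver; the
#' TEER value is carried as metadata only and never enters any computation.
#'
#' @param times Sampling times (min), strictly increasing from 0.
#' @param receiver_conc Receiver-compartment concentrations (amount/mL) at
#'   `times`; any consistent amount unit works.
#' @param donor_conc0 Initial donor concentration (amount/mL, > 0).
#' @param donor_volume,receiver_volume Compartment volumes (mL). Defaults:
#'   0.5 mL apical, 1 mL basolateral arranged per `direction`.
#' @param area Membrane area (cm^2); default 1.12.
#' @param direction `"efflux"` (basolateral to apical) or `"influx"`
#'   (apical to basolateral).
#' @param teer Optional TEER metadata (Ohm cm^2).
#' @return An object of class `transwell_experiment`.
#' @export
transwell_experiment <- function(times, receiver_conc, donor_conc0,
                                 donor_volume = 0.5, receiver_volume = 1.0,
                                 area = 1.12, direction = c(
                                   "efflux",
                                   "influx"
                                 ),
                                 teer = NULL) {
  direction <- match.arg(direction)
  stopifnot(
    length(times) == length(receiver_conc),
    donor_conc0 > 0, donor_volume > 0, receiver_volume > 0, area > 0,
    all(receiver_conc >= 0)
  )
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  structure(
    list(
      data = tibble::tibble(time_min = times, receiver_conc = receiver_conc),
      donor_conc0 = donor_conc0, donor_volume = donor_volume,
      receiver_volume = receiver_volume, area = area,
      direction = direction, teer = teer
    ),
    class = "transwell_experiment"
  )
}

#' @export
print.transwell_experiment <- function(x, ...) {
  cat(sprintf(
    "<transwell_experiment> %s, %d samples over %.3g min; A = %.3g cm^2, Vd = %.3g mL, Vr = %.3g mL\n",
    x$direction, nrow(x$data), max(x$data$time_min), x$area,
    x$donor_volume, x$receiver_volume
  ))
  invisible(x)
}

#' @export
as_tibble.transwell_experiment <- function(x, ...) x$data

#' Simulate a two-compartment transwell time series
#'
#' Passive linear exchange across the membrane,
#' `dQ_r/dt = P A (C_d - C_r)`, integrated exactly: the concentration
#' difference relaxes as `exp(-k t)` with
#' `k = P A (1/V_d + 1/V_r)`, so
#' `C_r(t) = C_eq (1 - exp(-k t))` with `C_eq = C_d0 V_d / (V_d + V_r)`.
#' Mass is conserved exactly with noise off. Sampled receiver
#' concentrations optionally get multiplicative Gaussian noise of
#' coefficient of variation `noise_cv`, truncated at zero.
#'
#' @param true_permeability Membrane permeability P (cm/min).
#' @param donor_conc0 Initial donor concentration (amount/mL).
#' @param sample_times Sampling times (min), increasing from 0; default
#'   0-180 min every 30 min.
#' @inheritParams transwell_experiment
#' @param noise_cv Coefficient of variation of the sampling noise
#'   (fraction); 0 disables.
#' @param seed Integer RNG seed.
#' @return A `transwell_experiment` with a `truth` attribute holding the
#'   generating parameters and the noise-free donor/receiver series.
#' @export
gen_transwell_series <- function(true_permeability, donor_conc0,
                                 sample_times = seq(0, 180, by = 30),
                                 donor_volume = 0.5, receiver_volume = 1.0,
                                 area = 1.12,
                                 direction = c("efflux", "influx"),
                                 noise_cv = 0, seed = 1L) {
  direction <- match.arg(direction)
  stopifnot(
    true_permeability >= 0, donor_conc0 > 0, noise_cv >= 0,
    sample_times[1] == 0
  )
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  q0 <- donor_conc0 * donor_volume
  k <- true_permeability * area * (1 / donor_volume + 1 / receiver_volume)
  c_eq <- q0 / (donor_volume + receiver_volume)
  cr <- c_eq * (1 - exp(-k * sample_times))
  cd <- (q0 - cr * receiver_volume) / donor_volume
  cr_obs <- cr
  if (noise_cv > 0) {
    cr_obs <- pmax(
      cr * (1 + stats::rnorm(length(cr), sd = noise_cv)), 0
    )
  }
  out <- transwell_experiment(
    times = sample_times, receiver_conc = cr_obs,
    donor_conc0 = donor_conc0, donor_volume = donor_volume,
    receiver_volume = receiver_volume, area = area, direction = direction
  )
  attr(out, "truth") <- list(
    true_permeability = true_permeability, noise_cv = noise_cv, seed = seed,
    receiver_conc_clean = cr, donor_conc_clean = cd
  )
  out
}

#' Apparent endothelial permeability from a transwell series
#'
#' Standard apparent-permeability estimate: the cumulative receiver amount
#' `Q(t) = C_r(t) V_r` is regressed linearly on time over the initial
#' sink-condition window (points where the receiver amount is below
#' `sink_fraction` of the initial donor amount, where transfer is
#' effectively linear), and
#' `EP = slope / (area * donor_conc0)` in cm/min.
#'
#' A negative fitted slope is reported as `EP = 0` with `flagged = TRUE`
#' (never silently clipped without notice).
#'
#' @param exp A [transwell_experiment()].
#' @param sink_fraction Sink-condition cutoff as a fraction of the initial
#'   donor amount; default 0.1.
#' @return A one-row tibble of class `permeability_result`: `EP` (cm/min),
#'   `slope`, `fit_intercept`, `r_squared`, `n_points_used`, `flagged`.
#' @export
endothelial_permeability <- function(exp, sink_fraction = 0.1) {
  stopifnot(inherits(exp, "transwell_experiment"))
  d <- exp$data
  if (nrow(d) < 2) stop("need at least 2 time points", call. = FALSE)
  q <- d$receiver_conc * exp$receiver_volume
  q0 <- exp$donor_conc0 * exp$donor_volume
  use <- q < sink_fraction * q0
  if (sum(use) < 2) {
    stop("fewer than 2 points satisfy the sink condition", call. = FALSE)
  }
  fit <- stats::lm(q[use] ~ d$time_min[use])
  slope <- unname(stats::coef(fit)[2])
  ssr <- sum(stats::residuals(fit)^2)
  sst <- sum((q[use] - mean(q[use]))^2)
  out <- tibble::tibble(
    EP = max(slope, 0) / (exp$area * exp$donor_conc0),
    slope = slope,
    fit_intercept = unname(stats::coef(fit)[1]),
    r_squared = if (sst > 0) 1 - ssr / sst else NA_real_,
    n_points_used = sum(use),
    flagged = slope < 0
  )
  class(out) <- c("permeability_result", class(out))
  out
}

#' Percent passage across the monolayer
#'
#' Share of the initially loaded donor amount found in the receiver
#' compartment at time `t`:
#' `100 * C_r(t) V_r / (C_d0 V_d)`. Evaluated at the sampled time nearest
#' `t` (ties toward the earlier sample).
#'
#' @param exp A [transwell_experiment()].
#' @param t Time (min) at which to evaluate; default the last sample.
#' @return Percent passage (0-100 for a passive system).
#' @export
percent_passage <- function(exp, t = NULL) {
  stopifnot(inherits(exp, "transwell_experiment"))
  d <- exp$data
  i <- if (is.null(t)) {
    nrow(d)
  } else {
    which.min(abs(d$time_min - t)) # which.min -> earlier sample on tie
  }
  100 * d$receiver_conc[i] * exp$receiver_volume /
    (exp$donor_conc0 * exp$donor_volume)
}
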