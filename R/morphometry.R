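#' Normalized height distribution of an AFM field
#'
#' Bins the per-pixel heights falling inside an analysis range (default
#' 4-25 nm, which excludes the substrate background) and normalizes the
#' result to a probability density over the counted pixels, the form used to
#' discriminate spherical from discoidal particle populations.
#'
#' @param map A [height_map()].
#' @param range Analysis interval in nm, length 2; default `c(4, 25)`.
#' @param n_bins Number of equal-width bins; default 84 (0.25 nm bins over
#'   the default range).
#' @return A list of class `height_distribution`: `bins` (tibble with
#'   `bin_lo`, `bin_hi`, `mid`, `density`), `range`, `bin_width`,
#'   `n_pixels_counted`. Densities integrate to 1.
#' @export
height_distribution <- function(map, range = c(4, 25), n_bins = 84L) {
  stopifnot(inherits(map, "height_map"), length(range) == 2, n_bins >= 2)
  range <- sort(as.numeric(range))
  h <- as.vector(map$heights)
  h <- h[h >= range[1] & h <= range[2]]
  if (length(h) == 0) {
    stop("no pixels inside the analysis range; empty height distribution",
      call. = FALSE
    )
  }
  edges <- seq(range[1], range[2], length.out = n_bins + 1)
  counts <- graphics::hist(h, breaks = edges, plot = FALSE)$counts
  w <- diff(edges)[1]
  structure(
    list(
      bins = tibble::tibble(
        bin_lo = edges[-(n_bins + 1)],
        bin_hi = edges[-1],
        mid = (edges[-1] + edges[-(n_bins + 1)]) / 2,
        density = counts / (sum(counts) * w)
      ),
      range = range,
      bin_width = w,
      n_pixels_counted = length(h)
    ),
    class = "height_distribution"
  )
}

#' @export
print.height_distribution <- function(x, ...) {
  cat(sprintf(
    "<height_distribution> %d bins over %.3g-%.3g nm, %d pixels counted\n",
    nrow(x$bins), x$range[1], x$range[2], x$n_pixels_counted
  ))
  invisible(x)
}

#' @export
tidy.height_distribution <- function(x, ...) x$bins

#' Theoretical AFM height density for a tangent sphere
#'
#' For a sphere of diameter D resting on the substrate and imaged by a
#' zero-width tip, the upper-surface height at lateral offset r from the
#' centre is `R + sqrt(R^2 - r^2)` (R = D/2), so equal-area pixel sampling
#' yields the triangular density `P(h) proportional to (h - R)` on
#' `[R, D]`. `sphere_model_density()` returns that density convolved with a
#' Gaussian of sd `broadening_sd` (instrumental broadening), renormalized;
#' the convolution has the closed form used here, so `broadening_sd = 0`
#' recovers the sharp triangular density.
#'
#' @param h Heights at which to evaluate (nm).
#' @param diameter Sphere diameter D (nm).
#' @param broadening_sd Gaussian broadening sd (nm, >= 0).
#' @return Density values at `h` (1/nm), integrating to 1 over the real line.
#' @examples
#' integrate(sphere_model_density, 5, 15, diameter = 12.7,
#'           broadening_sd = 0.3)
#' @export
sphere_model_density <- function(h, diameter, broadening_sd = 0) {
  stopifnot(diameter > 0, broadening_sd >= 0)
  R <- diameter / 2
  norm <- (diameter - R)^2 / 2 # integral of (h - R) over [R, D]
  if (broadening_sd == 0) {
    return(ifelse(h >= R & h <= diameter, (h - R) / norm, 0))
  }
  s <- broadening_sd
  # int_R^D (u - R) * dnorm(h - u, 0, s) du, by parts
  a <- R - h
  b <- diameter - h
  val <- (h - R) * (stats::pnorm(b / s) - stats::pnorm(a / s)) +
    s^2 * (stats::dnorm(a, 0, s) - stats::dnorm(b, 0, s))
  pmax(val, 0) / norm
}

#' Fit the spherical-particle model to a height distribution
#'
#' Least-squares fit of [sphere_model_density()] (diameter and Gaussian
#' broadening free) to the binned density, giving the characteristic
#' particle diameter 2R_S of a spherical population.
#'
#' @param dist A [height_distribution()].
#' @return A list of class `sphere_fit`: `diameter_2Rs` (nm),
#'   `broadening_sd` (nm), `goodness` (residual sum of squares over bins).
#' @export
fit_sphere <- function(dist) {
  stopifnot(inherits(dist, "height_distribution"))
  occ <- dist$bins[dist$bins$density > 0, ]
  if (nrow(occ) < 3) {
    stop("too few occupied bins to fit a sphere model", call. = FALSE)
  }
  # start from the upper edge of the occupied support (density peaks at h = D)
  d0 <- max(occ$mid)
  s0 <- max(2 * dist$bin_width, 0.2)
  fit <- minpack.lm::nls.lm(
    par = list(logd = log(d0), logs = log(s0)),
    fn = function(p) {
      dist$bins$density -
        sphere_model_density(dist$bins$mid, exp(p$logd), exp(p$logs))
    },
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  if (fit$info %in% c(0L, 5L)) {
    stop("sphere fit failed to converge: ", fit$message, call. = FALSE)
  }
  est <- exp(unlist(fit$par))
  structure(
    list(
      diameter_2Rs = unname(est[1]),
      broadening_sd = unname(est[2]),
      goodness = sum(fit$fvec^2)
    ),
    class = "sphere_fit"
  )
}

#' @export
print.sphere_fit <- function(x, ...) {
  cat(sprintf(
    "<sphere_fit> 2R_S = %.2f nm (broadening %.2f nm, RSS %.3g)\n",
    x$diameter_2Rs, x$broadening_sd, x$goodness
  ))
  invisible(x)
}

#' @export
tidy.sphere_fit <- function(x, ...) {
  tibble::tibble(
    term = c("diameter_2Rs", "broadening_sd"),
    estimate = c(x$diameter_2Rs, x$broadening_sd)
  )
}

#' @export
glance.sphere_fit <- function(x, ...) {
  tibble::tibble(
    diameter_2Rs = x$diameter_2Rs, broadening_sd = x$broadening_sd,
    goodness = x$goodness
  )
}

#' Fit the discoidal-particle model to a height distribution
#'
#' A flat disc population ideally contributes a delta function at the disc
#' height hD; instrumental broadening turns it into a Gaussian peak. The fit
#' locates the mode (ties broken toward the lowest bin), refines hD and the
#' broadening by least squares with a Gaussian peak, and regresses a
#' straight line over the upper tail of occupied bins above the mode (the
#' descending flank used descriptively for disc populations).
#'
#' @param dist A [height_distribution()].
#' @param tail_fraction Fraction of occupied bins above the mode used for
#'   the tail regression; default 0.25.
#' @return A list of class `disc_fit`: `height_hD` (nm), `broadening_sd`
#'   (nm), `goodness` (RSS), `tail_slope`, `tail_intercept` (both `NA` with
#'   `tail_defined = FALSE` when the support above the mode is degenerate).
#' @export
fit_disc <- function(dist, tail_fraction = 0.25) {
  stopifnot(
    inherits(dist, "height_distribution"),
    tail_fraction > 0, tail_fraction <= 1
  )
  bins <- dist$bins
  occ <- bins[bins$density > 0, ]
  if (nrow(occ) == 0) stop("empty height distribution", call. = FALSE)
  mode_mid <- bins$mid[which.max(bins$density)] # which.max -> lowest bin on tie
  s0 <- max(dist$bin_width, 0.05)
  fit <- minpack.lm::nls.lm(
    par = list(mu = mode_mid, logs = log(s0), loga = 0),
    fn = function(p) {
      bins$density - exp(p$loga) * stats::dnorm(bins$mid, p$mu, exp(p$logs))
    },
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  hD <- if (fit$info %in% c(0L, 5L)) mode_mid else fit$par$mu
  broad <- if (fit$info %in% c(0L, 5L)) s0 else exp(fit$par$logs)
  rss <- sum(fit$fvec^2)

  tail_bins <- occ[occ$mid > hD, ]
  # at least two bins are needed for a line; degenerate only if unavailable
  n_tail <- min(nrow(tail_bins), max(2L, ceiling(tail_fraction * nrow(tail_bins))))
  tail_bins <- utils::tail(tail_bins, n_tail)
  if (nrow(tail_bins) >= 2) {
    tl <- stats::lm(density ~ mid, data = tail_bins)
    slope <- unname(stats::coef(tl)[2])
    intercept <- unname(stats::coef(tl)[1])
    defined <- TRUE
  } else {
    slope <- NA_real_
    intercept <- NA_real_
    defined <- FALSE
  }
  structure(
    list(
      height_hD = hD, broadening_sd = broad, goodness = rss,
      tail_slope = slope, tail_intercept = intercept,
      tail_defined = defined
    ),
    class = "disc_fit"
  )
}

#' @export
print.disc_fit <- function(x, ...) {
  cat(sprintf(
    "<disc_fit> hD = %.2f nm (broadening %.2f nm, RSS %.3g)\n",
    x$height_hD, x$broadening_sd, x$goodness
  ))
  if (!x$tail_defined) cat("  tail regression undefined (degenerate support)\n")
  invisible(x)
}

#' @export
tidy.disc_fit <- function(x, ...) {
  tibble::tibble(
    term = c("height_hD", "broadening_sd", "tail_slope", "tail_intercept"),
    estimate = c(x$height_hD, x$broadening_sd, x$tail_slope, x$tail_intercept)
  )
}

#' @export
glance.disc_fit <- function(x, ...) {
  tibble::tibble(
    height_hD = x$height_hD, broadening_sd = x$broadening_sd,
    goodness = x$goodness, tail_defined = x$tail_defined
  )
}

#' Classify a particle population as spherical or discoidal
#'
#' Fits both the sphere and the disc height-distribution models and keeps
#' the one with the lower residual sum of squares. The margin (RSS of the
#' losing model over RSS of the winning model) quantifies confidence;
#' margins below `margin_threshold` are flagged uncertain.
#'
#' @param dist A [height_distribution()].
#' @param margin_threshold Minimum RSS ratio for a confident call; default 2.
#' @return A one-row tibble: `model` ("sphere" or "disc"), `size_nm` (the
#'   winning model's characteristic size), `broadening_nm`, `residual`,
#'   `margin`, `uncertain`.
#' @export
classify_population <- function(dist, margin_threshold = 2) {
  # a model that cannot even be fitted (e.g. a pure delta for the sphere
  # model) concedes with infinite residual
  sf <- tryCatch(fit_sphere(dist), error = function(e) list(goodness = Inf))
  df <- tryCatch(fit_disc(dist), error = function(e) list(goodness = Inf))
  if (!is.finite(sf$goodness) && !is.finite(df$goodness)) {
    stop("neither the sphere nor the disc model could be fitted",
      call. = FALSE
    )
  }
  sphere_wins <- sf$goodness < df$goodness
  margin <- if (sphere_wins) {
    df$goodness / sf$goodness
  } else {
    sf$goodness / df$goodness
  }
  tibble::tibble(
    model = if (sphere_wins) "sphere" else "disc",
    size_nm = if (sphere_wins) sf$diameter_2Rs else df$height_hD,
    broadening_nm = if (sphere_wins) sf$broadening_sd else df$broadening_sd,
    residual = min(sf$goodness, df$goodness),
    margin = margin,
    uncertain = margin < margin_threshold
  )
}

#' Lipid-to-protein molar ratio of an HDL preparation
#'
#' Converts a lipid:protein weight ratio into a molar stoichiometry:
#' `molar_ratio = weight_ratio * mw_protein / mw_lipid`. For a discoidal
#' preparation at a 2.5:1 POPC:apoA-I weight ratio (POPC 760.1 g/mol,
#' apoA-I 28 kDa) this gives ~92 lipids per protein.
#'
#' @param weight_ratio Lipid mass per protein mass (dimensionless, > 0).
#' @param mw_lipid Lipid molecular mass (g/mol, > 0).
#' @param mw_protein Protein molecular mass (g/mol, > 0).
#' @return Moles of lipid per mole of protein.
#' @examples
#' round(lipidation_molar_ratio(2.5, 760.1, 28000)) # 92
#' @export
lipidation_molar_ratio <- function(weight_ratio, mw_lipid, mw_protein) {
  if (any(c(weight_ratio, mw_lipid, mw_protein) <= 0)) {
    stop("all inputs must be > 0", call. = FALSE)
  }
  weight_ratio * mw_protein / mw_lipid
}

#' Plot a height distribution with optional model fits
#'
#' @param object A [height_distribution()].
#' @param sphere,disc Optional fit objects to overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.height_distribution <- function(object, sphere = NULL, disc = NULL,
                                         ...) {
  p <- ggplot2::ggplot(object$bins, ggplot2::aes(.data$mid, .data$density)) +
    ggplot2::geom_col(width = object$bin_width, fill = "grey70") +
    ggplot2::labs(x = "height (nm)", y = "density (1/nm)")
  grid <- seq(object$range[1], object$range[2], length.out = 400)
  if (!is.null(sphere)) {
    p <- p + ggplot2::geom_line(
      data = tibble::tibble(
        mid = grid,
        density = sphere_model_density(
          grid, sphere$diameter_2Rs, sphere$broadening_sd
        )
      ),
      colour = "red"
    )
  }
  if (!is.null(disc)) {
    p <- p + ggplot2::geom_line(
      data = tibble::tibble(
        mid = grid,
        density = stats::dnorm(grid, disc$height_hD, disc$broadening_sd)
      ),
      colour = "darkgreen"
    )
  }
  p
}
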