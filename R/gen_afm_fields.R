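# Synthetic AFM fields with known ground truth.
#
# All three generators share the same conventions: the field is a square grid
# of `field_size / pixel_size` pixels, heights start from a zero substrate,
# i.i.d. Gaussian noise of sd `noise_sd` is added per pixel at the end, and
# the RNG is fully determined by `seed` (bit-reproducible output).

grid_axis <- function(field_size, pixel_size) {
  n <- floor(field_size / pixel_size)
  if (n < 1) stop("field smaller than one pixel", call. = FALSE)
  (seq_len(n) - 0.5) * pixel_size
}

# rejection-sample particle centres at least `min_dist` apart and at least
# `margin` from the field edge
place_centres <- function(n, field_size, min_dist, margin, max_tries = NULL) {
  max_tries <- max_tries %||% (500L * n)
  centres <- matrix(numeric(0), ncol = 2)
  tries <- 0L
  while (nrow(centres) < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop(sprintf(
        "could not place %d non-overlapping particles in a %.4g nm field",
        n, field_size
      ), call. = FALSE)
    }
    p <- stats::runif(2, min = margin, max = field_size - margin)
    if (nrow(centres) == 0 ||
      all(sqrt(rowSums(sweep(centres, 2, p)^2)) >= min_dist)) {
      centres <- rbind(centres, p)
    }
  }
  unname(centres)
}

add_pixel_noise <- function(heights, noise_sd) {
  if (noise_sd > 0) {
    heights <- heights +
      matrix(stats::rnorm(length(heights), sd = noise_sd), nrow(heights))
  }
  heights
}

#' Simulate an AFM field of spherical particles
#'
#' Renders `n_particles` spheres of a common diameter, each tangent to the
#' substrate plane, as seen by an idealised zero-width tip: the recorded
#' height at lateral offset `r` from a particle centre is
#' `R + sqrt(R^2 - r^2)` for `r <= R` (the upper hemisphere surface), where
#' `R = diameter / 2`. Centres are placed uniformly at random, at least one
#' diameter apart (no overlap) and one radius from the field edge.
#'
#' This emulates AFM topographs of mature spherical HDL; tip-radius
#' convolution is deliberately not modelled (see the methods vignette).
#'
#' @param n_particles Number of spheres (may be 0).
#' @param diameter Sphere diameter (nm); the true maximum height.
#' @param field_size Side of the square field (nm); must exceed `diameter`.
#' @param pixel_size Lateral pixel size (nm).
#' @param noise_sd Per-pixel additive Gaussian noise sd (nm); 0 disables.
#' @param seed Integer RNG seed; identical inputs give bit-identical maps.
#' @param label Optional label attached to the output map.
#'
#' @return A [height_map()] with attribute `truth`, a list of the generating
#'   parameters and the particle centres, so estimators can be scored.
#' @examples
#' hm <- gen_sphere_field(5, diameter = 12.7, field_size = 500,
#'                        pixel_size = 2, noise_sd = 0, seed = 1)
#' max(hm$heights) # ~ 12.7
#' @export
gen_sphere_field <- function(n_particles, diameter, field_size, pixel_size,
                             noise_sd = 0, seed = 1L, label = NULL) {
  stopifnot(n_particles >= 0, diameter > 0, pixel_size > 0, noise_sd >= 0)
  if (diameter >= field_size) {
    stop("`diameter` must be smaller than `field_size`", call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  ax <- grid_axis(field_size, pixel_size)
  heights <- matrix(0, length(ax), length(ax))
  R <- diameter / 2
  centres <- if (n_particles > 0) {
    place_centres(n_particles, field_size, min_dist = diameter, margin = R)
  } else {
    matrix(numeric(0), ncol = 2)
  }
  for (i in seq_len(nrow(centres))) {
    dx2 <- outer((ax - centres[i, 1])^2, (ax - centres[i, 2])^2, "+")
    inside <- dx2 <= R^2
    h <- R + sqrt(pmax(R^2 - dx2, 0))
    heights[inside] <- pmax(heights[inside], h[inside])
  }
  heights <- add_pixel_noise(heights, noise_sd)
  out <- height_map(heights, pixel_size, label = label)
  attr(out, "truth") <- list(
    model = "sphere", n_particles = n_particles, diameter = diameter,
    noise_sd = noise_sd, seed = seed, centres = centres
  )
  out
}

#' Simulate an AFM field of flat discs
#'
#' Discs are rendered as flat plateaus of height `disc_height` over circular
#' footprints of diameter `disc_diameter` (pixel centres inside the footprint
#' take the full height). Placement and noise conventions as in
#' [gen_sphere_field()]. Emulates discoidal HDL lying flat on the substrate.
#'
#' @inheritParams gen_sphere_field
#' @param disc_height Plateau height (nm); the true surface height.
#' @param disc_diameter Footprint diameter (nm).
#' @return A [height_map()] with a `truth` attribute.
#' @export
gen_disc_field <- function(n_particles, disc_height, disc_diameter,
                           field_size, pixel_size, noise_sd = 0, seed = 1L,
                           label = NULL) {
  stopifnot(
    n_particles >= 0, disc_height > 0, disc_diameter > 0,
    pixel_size > 0, noise_sd >= 0
  )
  if (disc_diameter >= field_size) {
    stop("`disc_diameter` must be smaller than `field_size`", call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  ax <- grid_axis(field_size, pixel_size)
  heights <- matrix(0, length(ax), length(ax))
  R <- disc_diameter / 2
  centres <- if (n_particles > 0) {
    place_centres(n_particles, field_size,
      min_dist = disc_diameter,
      margin = R
    )
  } else {
    matrix(numeric(0), ncol = 2)
  }
  for (i in seq_len(nrow(centres))) {
    dx2 <- outer((ax - centres[i, 1])^2, (ax - centres[i, 2])^2, "+")
    heights[dx2 <= R^2] <- disc_height
  }
  heights <- add_pixel_noise(heights, noise_sd)
  out <- height_map(heights, pixel_size, label = label)
  attr(out, "truth") <- list(
    model = "disc", n_particles = n_particles, disc_height = disc_height,
    disc_diameter = disc_diameter, noise_sd = noise_sd, seed = seed,
    centres = centres
  )
  out
}

#' Simulate an AFM field of semiflexible fibrils
#'
#' Each fibril is a discretised worm-like chain: starting from a random
#' position and direction, the path advances in steps of one pixel while the
#' tangent angle diffuses with variance `step / persistence_length` per step.
#' The path reflects off the field boundary so it stays inside. Visited
#' pixels are set to `fibril_height`; paths may cross. Emulates unbranched
#' amyloid fibrils of constant apparent height and growing contour length.
#'
#' @inheritParams gen_sphere_field
#' @param n_fibrils Number of fibrils (may be 0).
#' @param contour_length Contour length of each fibril (nm).
#' @param persistence_length Worm-like-chain persistence length (nm).
#' @param fibril_height Apparent fibril height (nm).
#' @return A [height_map()] with a `truth` attribute that includes the number
#'   of distinct pixels covered by fibril paths (`n_path_pixels`).
#' @export
gen_fibril_field <- function(n_fibrils, contour_length, persistence_length,
                             fibril_height, field_size, pixel_size,
                             noise_sd = 0, seed = 1L, label = NULL,
                             time = NULL) {
  stopifnot(
    n_fibrils >= 0, contour_length > 0, persistence_length > 0,
    fibril_height > 0, pixel_size > 0, noise_sd >= 0
  )
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  ax <- grid_axis(field_size, pixel_size)
  n <- length(ax)
  heights <- matrix(0, n, n)
  covered <- matrix(FALSE, n, n)
  step <- pixel_size
  n_steps <- max(1L, round(contour_length / step))
  ang_sd <- sqrt(step / persistence_length)

  for (f in seq_len(n_fibrils)) {
    pos <- stats::runif(2, min = 0.05 * field_size, max = 0.95 * field_size)
    theta <- stats::runif(1, 0, 2 * pi)
    for (s in seq_len(n_steps)) {
      i <- pmin(pmax(ceiling(pos[1] / pixel_size), 1L), n)
      j <- pmin(pmax(ceiling(pos[2] / pixel_size), 1L), n)
      covered[i, j] <- TRUE
      theta <- theta + stats::rnorm(1, sd = ang_sd)
      prop <- pos + step * c(cos(theta), sin(theta))
      # reflect at boundaries to keep the path inside the field
      for (k in 1:2) {
        if (prop[k] < 0) {
          prop[k] <- -prop[k]
          theta <- if (k == 1) pi - theta else -theta
        } else if (prop[k] > field_size) {
          prop[k] <- 2 * field_size - prop[k]
          theta <- if (k == 1) pi - theta else -theta
        }
      }
      pos <- prop
    }
  }
  heights[covered] <- fibril_height
  heights <- add_pixel_noise(heights, noise_sd)
  out <- height_map(heights, pixel_size, label = label, time = time)
  attr(out, "truth") <- list(
    model = "fibril", n_fibrils = n_fibrils, contour_length = contour_length,
    persistence_length = persistence_length, fibril_height = fibril_height,
    noise_sd = noise_sd, seed = seed, n_path_pixels = sum(covered)
  )
  out
}

# save/restore the global RNG state so generators are pure in `seed`
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) {
    assign(".Random.seed", old, envir = globalenv())
  }
}
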