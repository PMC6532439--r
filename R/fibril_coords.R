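#' Fibril coordinate model
#'
#' Ordered C-alpha coordinates of a stacked cross-beta fibril: a set of
#' chains, each carrying the same residue numbers, plus the fibril axis.
#' Coordinates are in nanometres throughout the package.
#'
#' @param atoms Data frame with columns `chain`, `resno`, `x`, `y`, `z`
#'   (nm), one row per C-alpha atom.
#' @param axis Unit fibril-axis vector (length 3), or `NULL` to estimate it
#'   as the normalised mean displacement between consecutive-chain centroids.
#'
#' @return An object of class `fibril_coords`: list with `atoms` (tibble,
#'   sorted by chain then residue), `chains` (chain labels in order), `resno`
#'   (shared residue numbers) and `axis`.
#' @export
fibril_coords <- function(atoms, axis = NULL) {
  atoms <- tibble::as_tibble(atoms)
  need <- c("chain", "resno", "x", "y", "z")
  if (!all(need %in% names(atoms))) {
    stop(
      "`atoms` needs columns ", paste(need, collapse = ", "),
      call. = FALSE
    )
  }
  atoms$chain <- as.character(atoms$chain)
  chains <- unique(atoms$chain)
  resno <- sort(unique(atoms$resno))
  per_chain <- split(atoms$resno, atoms$chain)
  same <- vapply(
    per_chain, function(r) identical(sort(r), resno), logical(1)
  )
  if (!all(same)) {
    stop("all chains must carry the same residue numbers", call. = FALSE)
  }
  atoms <- atoms[order(match(atoms$chain, chains), atoms$resno), ]
  obj <- structure(
    list(atoms = atoms, chains = chains, resno = resno, axis = NULL),
    class = "fibril_coords"
  )
  if (is.null(axis)) {
    axis <- if (length(chains) >= 2) estimate_axis(obj) else c(0, 0, 1)
  }
  axis <- axis / sqrt(sum(axis^2))
  obj$axis <- as.numeric(axis)
  obj
}

#' @export
print.fibril_coords <- function(x, ...) {
  cat(sprintf(
    "<fibril_coords> %d chains (%s) x %d residues (%d-%d)\n",
    length(x$chains), paste(x$chains, collapse = ""),
    length(x$resno), min(x$resno), max(x$resno)
  ))
  cat(sprintf(
    "  axis: (%.3f, %.3f, %.3f)\n", x$axis[1], x$axis[2], x$axis[3]
  ))
  invisible(x)
}

#' @export
as_tibble.fibril_coords <- function(x, ...) x$atoms

# n_res x 3 coordinate matrix of one chain, rows in residue order
chain_matrix <- function(f, chain) {
  a <- f$atoms[f$atoms$chain == chain, ]
  as.matrix(a[order(a$resno), c("x", "y", "z")])
}

# all-atom coordinate matrix (chains stacked in order)
coords_matrix <- function(f) {
  as.matrix(f$atoms[, c("x", "y", "z")])
}

# normalised mean displacement between consecutive-chain centroids
estimate_axis <- function(f) {
  cent <- t(vapply(
    f$chains, function(ch) colMeans(chain_matrix(f, ch)), numeric(3)
  ))
  d <- colMeans(diff(cent))
  n <- sqrt(sum(d^2))
  if (n < 1e-12) {
    stop("degenerate chain centroids; supply `axis` explicitly",
      call. = FALSE
    )
  }
  d / n
}

#' Generate an ideal cross-beta fibril stack
#'
#' Builds a synthetic fibril of `n_chains` identical peptide chains stacked
#' along the z axis: chain 1 is a straight extended C-alpha template
#' (0.35 nm spacing, centred on the axis) for the requested residue range;
#' chain *k* is chain 1 rotated by `(k-1) * twist_deg_per_chain` about z and
#' translated by `(k-1) * rise_per_chain` along z. An optional isotropic
#' Gaussian perturbation of sd `distortion_sd` is applied per atom to mimic
#' structural disorder. The construction axis (z) is recorded in the output.
#'
#' Defaults mirror the amyloid cross-beta geometry commonly used for
#' Abeta(17-42) pentamer models: 5 chains, residues 17-42, 0.48 nm
#' inter-chain rise.
#'
#' @param n_chains Number of chains (>= 2).
#' @param residues Integer vector of residue numbers (default `17:42`).
#' @param rise_per_chain Translation between consecutive chains along z (nm).
#' @param twist_deg_per_chain Rotation between consecutive chains about z
#'   (degrees).
#' @param distortion_sd Per-atom Gaussian perturbation sd (nm); 0 gives the
#'   exact ideal geometry.
#' @param seed Integer RNG seed (used only when `distortion_sd > 0`).
#' @return A [fibril_coords()] whose `axis` is `c(0, 0, 1)`, with a `truth`
#'   attribute recording the generating parameters.
#' @examples
#' f <- gen_ideal_fibril()
#' order_parameter(f) # 1 for the undistorted stack
#' @export
gen_ideal_fibril <- function(n_chains = 5, residues = 17:42,
                             rise_per_chain = 0.48, twist_deg_per_chain = 0,
                             distortion_sd = 0, seed = 1L) {
  stopifnot(n_chains >= 2, length(residues) >= 1, distortion_sd >= 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  nr <- length(residues)
  # extended template, xy-centroid on the axis so twist preserves centroids
  template <- cbind(
    x = (seq_len(nr) - (nr + 1) / 2) * 0.35,
    y = 0,
    z = 0
  )
  chains <- LETTERS[seq_len(n_chains)]
  atoms <- purrr::map_dfr(seq_len(n_chains), function(k) {
    th <- (k - 1) * twist_deg_per_chain * pi / 180
    rot <- matrix(
      c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3
    )
    xyz <- template %*% t(rot)
    xyz[, 3] <- xyz[, 3] + (k - 1) * rise_per_chain
    tibble::tibble(
      chain = chains[k], resno = residues,
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
    )
  })
  if (distortion_sd > 0) {
    atoms[c("x", "y", "z")] <- atoms[c("x", "y", "z")] +
      matrix(stats::rnorm(3 * nrow(atoms), sd = distortion_sd), ncol = 3)
  }
  out <- fibril_coords(atoms, axis = c(0, 0, 1))
  attr(out, "truth") <- list(
    n_chains = n_chains, residues = residues,
    rise_per_chain = rise_per_chain,
    twist_deg_per_chain = twist_deg_per_chain,
    distortion_sd = distortion_sd, seed = seed
  )
  out
}

#' Fibril trajectory
#'
#' Time-ordered snapshots of a fibril coordinate model, as produced by
#' [gen_fibril_trajectory()] or read from a multi-MODEL structure file.
#'
#' @param frames List of [fibril_coords()], all structurally congruent.
#' @param times Strictly increasing frame times (ns).
#' @return An object of class `fibril_trajectory`.
#' @export
fibril_trajectory <- function(frames, times = seq_along(frames) - 1) {
  stopifnot(length(frames) >= 1, length(times) == length(frames))
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  ref <- frames[[1]]
  ok <- vapply(frames, function(f) {
    identical(f$chains, ref$chains) && identical(f$resno, ref$resno)
  }, logical(1))
  if (!all(ok)) {
    stop("all frames must share the same chains and residues", call. = FALSE)
  }
  structure(
    list(frames = frames, times = as.numeric(times)),
    class = "fibril_trajectory"
  )
}

#' @export
print.fibril_trajectory <- function(x, ...) {
  cat(sprintf(
    "<fibril_trajectory> %d frames, t = %.3g..%.3g ns; %d chains x %d residues\n",
    length(x$frames), min(x$times), max(x$times),
    length(x$frames[[1]]$chains), length(x$frames[[1]]$resno)
  ))
  invisible(x)
}

#' Generate a synthetic fibril trajectory
#'
#' Draws `n_frames` snapshots of the ideal fibril of [gen_ideal_fibril()],
#' frame *t* perturbed with per-atom Gaussian sd `distortion_schedule[t]`.
#' A stand-in for molecular-dynamics snapshots when testing trajectory
#' statistics (order-parameter time series, PCA, RMSD).
#'
#' @inheritParams gen_ideal_fibril
#' @param n_frames Number of snapshots.
#' @param distortion_schedule Numeric vector (recycled to `n_frames`) of
#'   per-frame distortion sds (nm).
#' @param times Frame times (ns); default `0, 1, 2, ...`.
#' @return A [fibril_trajectory()] with a `truth` attribute.
#' @export
gen_fibril_trajectory <- function(n_frames, distortion_schedule = 0,
                                  times = seq_len(n_frames) - 1,
                                  n_chains = 5, residues = 17:42,
                                  rise_per_chain = 0.48,
                                  twist_deg_per_chain = 0, seed = 1L) {
  stopifnot(n_frames >= 1)
  sched <- rep_len(distortion_schedule, n_frames)
  frames <- purrr::map(seq_len(n_frames), function(t) {
    gen_ideal_fibril(
      n_chains = n_chains, residues = residues,
      rise_per_chain = rise_per_chain,
      twist_deg_per_chain = twist_deg_per_chain,
      distortion_sd = sched[t],
      # offset keeps frames independent yet reproducible and < 2^31
      seed = (seed + 7919L * t) %% .Machine$integer.max
    )
  })
  out <- fibril_trajectory(frames, times)
  attr(out, "truth") <- list(
    distortion_schedule = sched, seed = seed
  )
  out
}
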