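#' Fibril order parameter
#'
#' Quantifies how well a stacked fibril is aligned along its axis. For each
#' residue number r, `v_r` is the vector joining the C-alpha of the first
#' chain to the corresponding C-alpha (same residue number) of the last
#' chain; the order parameter is the mean signed cosine between `v_r` and
#' the fibril axis z:
#'
#' \deqn{ordP = \frac{1}{N_r} \sum_r
#'   \frac{\langle v_r, z\rangle}{\|v_r\|\,\|z\|} = \frac{1}{N_r}\sum_r
#'   \cos\alpha_r}
#'
#' Values near 1 indicate the amyloid-like aligned stack; values below 1
#' indicate a distorted structure (negative values are representable since
#' the cosine is signed).
#'
#' @param f A [fibril_coords()].
#' @param first_chain,last_chain Chains whose corresponding C-alpha atoms
#'   define `v_r`; default the first and last chains in order (A and E for a
#'   pentamer).
#' @param axis Fibril axis; default the axis recorded in `f` (the
#'   construction axis for generated fibrils, else the consecutive-chain
#'   centroid estimate).
#' @return The order parameter, a number in \eqn{[-1, 1]}.
#' @examples
#' order_parameter(gen_ideal_fibril(distortion_sd = 0)) # exactly 1
#' @export
order_parameter <- function(f, first_chain = NULL, last_chain = NULL,
                            axis = NULL) {
  stopifnot(inherits(f, "fibril_coords"))
  first_chain <- first_chain %||% f$chains[1]
  last_chain <- last_chain %||% f$chains[length(f$chains)]
  for (ch in c(first_chain, last_chain)) {
    if (!ch %in% f$chains) stop("chain ", ch, " not present", call. = FALSE)
  }
  z <- axis %||% f$axis
  z <- z / sqrt(sum(z^2))
  v <- chain_matrix(f, last_chain) - chain_matrix(f, first_chain)
  nv <- sqrt(rowSums(v^2))
  if (any(nv < 1e-12)) {
    stop("coincident C-alpha atoms between the two chains", call. = FALSE)
  }
  mean((v %*% z) / nv)
}

#' Order-parameter time series with equilibrium summary
#'
#' Computes [order_parameter()] for every frame and summarises the trailing
#' equilibrium window (default the last 20% of frames, mirroring the
#' last-20-of-100-ns convention for converged trajectories) as mean +/- SEM
#' over the window's frames (frame-to-frame correlation is ignored; see the
#' methods vignette).
#'
#' @param traj A [fibril_trajectory()].
#' @param window Trailing fraction of frames treated as equilibrated,
#'   in (0, 1]; default 0.2.
#' @inheritParams order_parameter
#' @return A list of class `ordp_result`: `per_frame` (tibble with `time`,
#'   `ordp`, `in_window`), `equilibrium_mean`, `equilibrium_sem`.
#' @export
ordp_equilibrium <- function(traj, window = 0.2, first_chain = NULL,
                             last_chain = NULL, axis = NULL) {
  stopifnot(inherits(traj, "fibril_trajectory"), window > 0, window <= 1)
  ordp <- vapply(
    traj$frames, order_parameter, numeric(1),
    first_chain = first_chain, last_chain = last_chain, axis = axis
  )
  n <- length(ordp)
  n_win <- max(1L, ceiling(window * n))
  in_window <- seq_len(n) > n - n_win
  eq <- ordp[in_window]
  structure(
    list(
      per_frame = tibble::tibble(
        time = traj$times, ordp = ordp, in_window = in_window
      ),
      equilibrium_mean = mean(eq),
      equilibrium_sem = if (length(eq) > 1) {
        stats::sd(eq) / sqrt(length(eq))
      } else {
        0
      }
    ),
    class = "ordp_result"
  )
}

#' @export
print.ordp_result <- function(x, ...) {
  cat(sprintf(
    "<ordp_result> %d frames; equilibrium ordP = %.4f +/- %.4f (SEM, %d frames)\n",
    nrow(x$per_frame), x$equilibrium_mean, x$equilibrium_sem,
    sum(x$per_frame$in_window)
  ))
  invisible(x)
}

#' @export
tidy.ordp_result <- function(x, ...) x$per_frame

#' @export
glance.ordp_result <- function(x, ...) {
  tibble::tibble(
    equilibrium_mean = x$equilibrium_mean,
    equilibrium_sem = x$equilibrium_sem,
    n_frames = nrow(x$per_frame),
    n_window = sum(x$per_frame$in_window)
  )
}

# frame rank check: Kabsch needs a non-collinear point set
check_not_collinear <- function(xyz) {
  c0 <- sweep(xyz, 2, colMeans(xyz))
  if (sum(svd(c0, nu = 0, nv = 0)$d > 1e-9) < 2) {
    stop("degenerate (collinear) configuration; cannot superpose",
      call. = FALSE
    )
  }
}

# superpose `mobile` onto `fixed` (both n x 3, nm) via bio3d's Kabsch fit
superpose_onto <- function(mobile, fixed) {
  inds <- seq_len(3 * nrow(fixed))
  fit <- bio3d::fit.xyz(
    fixed = as.vector(t(fixed)), mobile = as.vector(t(mobile)),
    fixed.inds = inds, mobile.inds = inds
  )
  matrix(fit, ncol = 3, byrow = TRUE)
}

replace_coords <- function(f, xyz) {
  f$atoms$x <- xyz[, 1]
  f$atoms$y <- xyz[, 2]
  f$atoms$z <- xyz[, 3]
  f
}

#' Rigid-body superposition of trajectory frames
#'
#' Least-squares (Kabsch) superposition of every frame's C-alpha set onto a
#' reference frame: optimal rotation plus translation, no scaling, the
#' transformation that minimises RMSD.
#'
#' @param traj A [fibril_trajectory()].
#' @param reference Index of the reference frame (default 1).
#' @return The aligned [fibril_trajectory()].
#' @export
kabsch_align <- function(traj, reference = 1L) {
  stopifnot(inherits(traj, "fibril_trajectory"))
  ref <- coords_matrix(traj$frames[[reference]])
  check_not_collinear(ref)
  frames <- lapply(traj$frames, function(f) {
    replace_coords(f, superpose_onto(coords_matrix(f), ref))
  })
  out <- fibril_trajectory(frames, traj$times)
  out
}

#' Root-mean-square deviation between two structures
#'
#' RMSD over corresponding C-alpha atoms, by default after optimal rigid
#' superposition of `frame` onto `reference`.
#'
#' @param frame,reference [fibril_coords()] with identical chains/residues.
#' @param align Superpose before measuring (default `TRUE`); `FALSE` gives
#'   the raw coordinate RMSD.
#' @return RMSD in nm.
#' @export
rmsd <- function(frame, reference, align = TRUE) {
  stopifnot(inherits(frame, "fibril_coords"), inherits(reference, "fibril_coords"))
  a <- coords_matrix(frame)
  b <- coords_matrix(reference)
  stopifnot(nrow(a) == nrow(b))
  if (align) {
    check_not_collinear(b)
    a <- superpose_onto(a, b)
  }
  sqrt(mean(rowSums((a - b)^2)))
}

#' Essential-dynamics PCA of a fibril trajectory
#'
#' Principal component analysis of the 3N C-alpha Cartesian coordinates over
#' a trailing window of frames: the population covariance matrix of the
#' coordinate vectors is diagonalised, yielding collective-motion
#' eigenvectors; the first eigenvalue measures the amplitude of the dominant
#' collective fluctuation (nm^2) and grows as the structure gets floppier.
#'
#' @param traj A [fibril_trajectory()].
#' @param window Trailing fraction of frames analysed, in (0, 1];
#'   default 1 (all frames).
#' @param align Superpose each window frame onto the window-mean structure
#'   before computing the covariance (default `TRUE`). Set `FALSE` to work
#'   on the raw coordinates, e.g. when the frames are already superposed.
#' @return A list of class `fibril_pca`: `eigenvalues` (nm^2, descending),
#'   `first_eigenvalue`, `variance_fraction_pc1`, `mean_structure`
#'   (a [fibril_coords()]), `projections` (tibble: frame, time, pc, score).
#' @export
pca_trajectory <- function(traj, window = 1, align = TRUE) {
  stopifnot(inherits(traj, "fibril_trajectory"), window > 0, window <= 1)
  n <- length(traj$frames)
  n_win <- max(1L, ceiling(window * n))
  if (n_win < 2) stop("need at least 2 frames in the window", call. = FALSE)
  idx <- seq.int(n - n_win + 1L, n)
  mats <- lapply(traj$frames[idx], coords_matrix)
  if (align) {
    # two-pass: mean of frames aligned to the first, then align to that mean
    ref <- mats[[1]]
    check_not_collinear(ref)
    for (pass in 1:2) {
      aligned <- lapply(mats, superpose_onto, fixed = ref)
      ref <- Reduce(`+`, aligned) / length(aligned)
    }
    mats <- aligned
  }
  X <- do.call(rbind, lapply(mats, function(m) as.vector(t(m))))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  covm <- crossprod(Xc) / nrow(Xc) # population covariance
  ev <- eigen(covm, symmetric = TRUE)
  lambda <- pmax(ev$values, 0)
  scores <- Xc %*% ev$vectors
  n_show <- min(5L, ncol(scores))
  proj <- tidyr::expand_grid(
    frame = idx, pc = seq_len(n_show)
  )
  proj$time <- traj$times[proj$frame]
  proj$score <- scores[cbind(match(proj$frame, idx), proj$pc)]
  mean_f <- replace_coords(
    traj$frames[[idx[1]]], matrix(mu, ncol = 3, byrow = TRUE)
  )
  structure(
    list(
      eigenvalues = lambda,
      first_eigenvalue = lambda[1],
      variance_fraction_pc1 = if (sum(lambda) > 0) lambda[1] / sum(lambda) else 0,
      mean_structure = mean_f,
      projections = proj[, c("frame", "time", "pc", "score")]
    ),
    class = "fibril_pca"
  )
}

#' @export
print.fibril_pca <- function(x, ...) {
  cat(sprintf(
    "<fibril_pca> PC1 eigenvalue %.4g nm^2 (%.1f%% of variance), %d modes\n",
    x$first_eigenvalue, 100 * x$variance_fraction_pc1,
    sum(x$eigenvalues > 0)
  ))
  invisible(x)
}

#' @export
tidy.fibril_pca <- function(x, ...) {
  tibble::tibble(
    pc = seq_along(x$eigenvalues),
    eigenvalue = x$eigenvalues,
    variance_fraction = if (sum(x$eigenvalues) > 0) {
      x$eigenvalues / sum(x$eigenvalues)
    } else {
      rep(0, length(x$eigenvalues))
    }
  )
}

#' @export
glance.fibril_pca <- function(x, ...) {
  tibble::tibble(
    first_eigenvalue = x$first_eigenvalue,
    variance_fraction_pc1 = x$variance_fraction_pc1,
    total_variance = sum(x$eigenvalues)
  )
}
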