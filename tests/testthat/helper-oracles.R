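# Independent brute-force oracles. These deliberately avoid the package's
# code paths (no bio3d, no eigen-on-covariance shortcuts shared with the
# implementation) so agreement is a genuine cross-check.

# order parameter by an explicit per-residue loop
oracle_ordp <- function(f, first_chain = NULL, last_chain = NULL,
                        axis = NULL) {
  chains <- f$chains
  first_chain <- if (is.null(first_chain)) chains[1] else first_chain
  last_chain <- if (is.null(last_chain)) chains[length(chains)] else last_chain
  z <- if (is.null(axis)) f$axis else axis
  z <- z / sqrt(sum(z^2))
  a <- f$atoms[f$atoms$chain == first_chain, ]
  b <- f$atoms[f$atoms$chain == last_chain, ]
  a <- a[order(a$resno), ]
  b <- b[order(b$resno), ]
  total <- 0
  for (i in seq_len(nrow(a))) {
    v <- c(b$x[i] - a$x[i], b$y[i] - a$y[i], b$z[i] - a$z[i])
    total <- total + sum(v * z) / sqrt(sum(v^2))
  }
  total / nrow(a)
}

# hand-written Kabsch superposition (SVD with reflection guard)
oracle_kabsch <- function(mobile, fixed) {
  cm <- colMeans(mobile)
  cf <- colMeans(fixed)
  m0 <- sweep(mobile, 2, cm)
  f0 <- sweep(fixed, 2, cf)
  s <- svd(t(m0) %*% f0)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(m0 %*% t(rot), 2, cf, "+")
}

# RMSD by explicit accumulation
oracle_rmsd <- function(a, b) {
  total <- 0
  for (i in seq_len(nrow(a))) {
    total <- total + sum((a[i, ] - b[i, ])^2)
  }
  sqrt(total / nrow(a))
}

# PCA eigenvalues via SVD of the centred frame matrix (population scaling)
oracle_pca_eigenvalues <- function(frame_matrix) {
  xc <- sweep(frame_matrix, 2, colMeans(frame_matrix))
  sv <- svd(xc, nu = 0, nv = 0)$d
  ev <- sv^2 / nrow(frame_matrix)
  c(ev, rep(0, ncol(frame_matrix) - length(ev)))
}

# random congruent fibril_coords for oracle comparisons
random_fibril <- function(n_chains = 5, n_res = 26, seed = 1) {
  set.seed(seed)
  atoms <- tibble::tibble(
    chain = rep(LETTERS[seq_len(n_chains)], each = n_res),
    resno = rep(seq(17, length.out = n_res), n_chains),
    x = rnorm(n_chains * n_res),
    y = rnorm(n_chains * n_res),
    z = rnorm(n_chains * n_res)
  )
  fibril_coords(atoms, axis = c(0, 0, 1))
}

# coordinates of one chain as a matrix (duplicated here on purpose)
oracle_chain_matrix <- function(f, chain) {
  a <- f$atoms[f$atoms$chain == chain, ]
  a <- a[order(a$resno), ]
  as.matrix(a[, c("x", "y", "z")])
}

expect_rel_equal <- function(actual, expected, rel_tol) {
  denom <- pmax(abs(expected), 1e-300)
  expect_lt(max(abs(actual - expected) / denom), rel_tol)
}
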