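shifted_stack <- function(shift, n_chains = 3, n_res = 8) {
  # chains displaced by multiples of `shift` from a common random template
  set.seed(99)
  template <- matrix(rnorm(3 * n_res), ncol = 3)
  atoms <- do.call(rbind, lapply(seq_len(n_chains), function(k) {
    xyz <- sweep(template, 2, (k - 1) * shift, "+")
    tibble::tibble(
      chain = LETTERS[k], resno = seq_len(n_res),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
    )
  }))
  fibril_coords(atoms, axis = c(0, 0, 1))
}

test_that("order parameter reproduces exact geometric cases", {
  expect_equal(order_parameter(shifted_stack(c(0, 0, 0.48))), 1)
  expect_equal(order_parameter(shifted_stack(c(0.48, 0, 0))), 0)
  # stack displaced at 60 degrees from the axis -> cos(60) = 0.5
  d60 <- 0.48 * c(sin(pi / 3), 0, cos(pi / 3))
  expect_equal(order_parameter(shifted_stack(d60)), 0.5, tolerance = 1e-12)
})

test_that("order parameter equals the brute-force oracle on random systems", {
  for (s in 1:5) {
    f <- random_fibril(seed = s)
    expect_rel_equal(order_parameter(f), oracle_ordp(f), 1e-10)
    expect_rel_equal(
      order_parameter(f, "B", "D"), oracle_ordp(f, "B", "D"), 1e-10
    )
  }
})

test_that("order parameter is bounded and rigid-motion invariant", {
  for (s in 1:10) {
    f <- random_fibril(seed = 100 + s)
    o <- order_parameter(f)
    expect_gte(o, -1)
    expect_lte(o, 1)
    # joint rotation of coordinates and axis, plus a translation
    th <- s
    rot <- matrix(c(
      cos(th), sin(th), 0,
      -sin(th), cos(th), 0,
      0, 0, 1
    ), 3, 3) %*% matrix(c(
      1, 0, 0,
      0, cos(2 * th), sin(2 * th),
      0, -sin(2 * th), cos(2 * th)
    ), 3, 3)
    xyz <- as.matrix(f$atoms[, c("x", "y", "z")]) %*% t(rot)
    g <- fibril_coords(
      tibble::tibble(
        chain = f$atoms$chain, resno = f$atoms$resno,
        x = xyz[, 1] + 5, y = xyz[, 2] - 3, z = xyz[, 3] + 1
      ),
      axis = as.numeric(rot %*% f$axis)
    )
    expect_equal(order_parameter(g), o, tolerance = 1e-10)
  }
})

test_that("coincident atoms between the compared chains are an error", {
  f <- shifted_stack(c(0, 0, 0)) # chains are exact copies
  expect_error(order_parameter(f), "oincident")
})

test_that("equilibrium ordP summarises the trailing window", {
  tr <- gen_fibril_trajectory(10, distortion_schedule = 0, seed = 1)
  r <- ordp_equilibrium(tr)
  expect_identical(sum(r$per_frame$in_window), 2L) # last 20% of 10 frames
  expect_identical(r$equilibrium_sem, 0)
  expect_equal(r$equilibrium_mean, 1)
  full <- ordp_equilibrium(tr, window = 1)
  expect_true(all(full$per_frame$in_window))
})

test_that("equilibrium ordP agrees with a Monte-Carlo oracle", {
  s <- 0.25
  r <- ordp_equilibrium(
    gen_fibril_trajectory(40, distortion_schedule = s, seed = 2),
    window = 1
  )
  # independent draws through the oracle ordP
  mc <- sapply(1:60, function(k) {
    oracle_ordp(gen_ideal_fibril(distortion_sd = s, seed = 5000 + k))
  })
  sem <- sqrt(r$equilibrium_sem^2 + var(mc) / length(mc))
  expect_lt(abs(r$equilibrium_mean - mean(mc)), 2 * sem + 1e-6)
})

test_that("Kabsch superposition is optimal, idempotent and exact on rigid copies", {
  f <- gen_ideal_fibril(distortion_sd = 0.2, seed = 3)
  th <- 0.7
  rot <- matrix(c(
    cos(th), sin(th), 0,
    -sin(th), cos(th), 0,
    0, 0, 1
  ), 3, 3)
  xyz <- as.matrix(f$atoms[, c("x", "y", "z")]) %*% t(rot)
  g <- fibril_coords(
    tibble::tibble(
      chain = f$atoms$chain, resno = f$atoms$resno,
      x = xyz[, 1] + 2, y = xyz[, 2] + 4, z = xyz[, 3] - 1
    ),
    axis = f$axis
  )
  expect_lt(rmsd(g, f), 1e-9)

  tr <- fibril_trajectory(list(f, g))
  al <- kabsch_align(tr)
  al2 <- kabsch_align(al)
  expect_equal(
    al2$frames[[2]]$atoms, al$frames[[2]]$atoms,
    tolerance = 1e-9
  )

  # alignment never increases RMSD on random frames
  for (s in 1:5) {
    a <- random_fibril(seed = 300 + s)
    b <- random_fibril(seed = 400 + s)
    expect_lte(rmsd(a, b), rmsd(a, b, align = FALSE) + 1e-12)
  }
})

test_that("collinear configurations cannot be superposed", {
  atoms <- tibble::tibble(
    chain = rep(c("A", "B"), each = 5), resno = rep(1:5, 2),
    x = 0, y = 0, z = c(1:5, 6:10) * 0.35
  )
  f <- fibril_coords(atoms, axis = c(0, 0, 1))
  expect_error(rmsd(f, f), "collinear")
})

test_that("RMSD matches hand formulas and the brute-force oracle", {
  f <- random_fibril(seed = 7)
  expect_identical(rmsd(f, f, align = FALSE), 0)
  g <- f
  n <- nrow(g$atoms)
  d <- 0.9
  g$atoms$x[1] <- g$atoms$x[1] + d
  expect_equal(rmsd(g, f, align = FALSE), sqrt(d^2 / n), tolerance = 1e-12)
  for (s in 1:5) {
    a <- random_fibril(seed = 500 + s)
    b <- random_fibril(seed = 600 + s)
    m_a <- as.matrix(a$atoms[, c("x", "y", "z")])
    m_b <- as.matrix(b$atoms[, c("x", "y", "z")])
    expect_rel_equal(rmsd(a, b, align = FALSE), oracle_rmsd(m_a, m_b), 1e-10)
    # aligned route against the independent Kabsch oracle
    expect_rel_equal(
      rmsd(a, b), oracle_rmsd(oracle_kabsch(m_a, m_b), m_b), 1e-8
    )
  }
})

test_that("trajectory PCA matches hand-computed and oracle eigenvalues", {
  # constant trajectory: no variance at all
  tr0 <- gen_fibril_trajectory(5, distortion_schedule = 0, seed = 1)
  p0 <- pca_trajectory(tr0)
  expect_lt(max(p0$eigenvalues), 1e-18)

  # two frames, one atom displaced by d along x: population covariance has
  # the single eigenvalue d^2 / 4
  f <- gen_ideal_fibril(seed = 2)
  g <- f
  d <- 0.6
  g$atoms$x[5] <- g$atoms$x[5] + d
  p2 <- pca_trajectory(fibril_trajectory(list(f, g)), align = FALSE)
  expect_equal(p2$first_eigenvalue, d^2 / 4, tolerance = 1e-12)
  expect_lt(p2$eigenvalues[2], 1e-18)

  # random trajectories: eigenvalues equal the SVD oracle; the spectrum sums
  # to the covariance trace
  tr <- gen_fibril_trajectory(8, distortion_schedule = 0.3, seed = 5)
  p <- pca_trajectory(tr, align = FALSE)
  X <- do.call(rbind, lapply(tr$frames, function(fr) {
    as.vector(t(as.matrix(fr$atoms[, c("x", "y", "z")])))
  }))
  ev_oracle <- oracle_pca_eigenvalues(X)
  k <- sum(ev_oracle > 1e-12)
  expect_rel_equal(p$eigenvalues[1:k], ev_oracle[1:k], 1e-10)
  xc <- sweep(X, 2, colMeans(X))
  expect_rel_equal(sum(p$eigenvalues), sum(xc^2) / nrow(X), 1e-9)

  expect_error(
    pca_trajectory(fibril_trajectory(list(f))), "2 frames"
  )
})

test_that("fibril axis defaults to the consecutive-centroid direction", {
  f <- gen_ideal_fibril(distortion_sd = 0)
  bare <- fibril_coords(f$atoms) # no recorded axis
  expect_equal(bare$axis, c(0, 0, 1), tolerance = 1e-12)
  expect_equal(order_parameter(bare), 1)
})
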