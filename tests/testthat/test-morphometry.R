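test_that("height distributions are normalized densities over the range", {
  dm <- gen_disc_field(5, 12.9, 13, 200, 1, noise_sd = 0, seed = 2)
  hd <- height_distribution(dm)
  # identical noiseless discs occupy the single bin containing 12.9 nm
  occ <- hd$bins[hd$bins$density > 0, ]
  expect_identical(nrow(occ), 1L)
  expect_true(occ$bin_lo <= 12.9 && 12.9 <= occ$bin_hi)
  expect_equal(sum(hd$bins$density * hd$bin_width), 1, tolerance = 1e-9)
  # a flat map has nothing inside the 4-25 nm range
  expect_error(
    height_distribution(height_map(matrix(0, 10, 10), 1)),
    "range"
  )
})

test_that("sphere-field heights follow the analytic tangent-sphere law", {
  # P(h) ~ (h - R) on [R, 2R]; check Kolmogorov distance of the empirical CDF
  hm <- gen_sphere_field(80, 12.7, 1000, 1, noise_sd = 0, seed = 6)
  h <- hm$heights[hm$heights > 0]
  expect_gt(length(h), 1e4)
  R <- 12.7 / 2
  analytic_cdf <- function(x) pmin(pmax((x - R)^2 / R^2, 0), 1)
  ks <- suppressWarnings(ks.test(h, analytic_cdf))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("sphere model density has the right support, mode and mass", {
  h <- seq(0, 20, by = 0.01)
  d0 <- sphere_model_density(h, diameter = 12.7, broadening_sd = 0)
  expect_true(all(d0[h < 12.7 / 2 | h > 12.7] == 0))
  on_support <- d0[h >= 12.7 / 2 & h <= 12.7]
  expect_true(all(diff(on_support) >= 0)) # density increases toward h = D
  # sharp form integrated over its support; broadened over the real line
  expect_equal(
    integrate(sphere_model_density, 12.7 / 2, 12.7,
      diameter = 12.7, broadening_sd = 0
    )$value,
    1,
    tolerance = 1e-8
  )
  for (s in c(0.2, 0.5)) {
    mass <- integrate(sphere_model_density, -5, 25,
      diameter = 12.7,
      broadening_sd = s, subdivisions = 500
    )$value
    expect_equal(mass, 1, tolerance = 1e-6)
  }
  # broadened and sharp forms agree in the small-broadening limit away from
  # the support edges (convolution halves the density exactly at h = D)
  interior <- h > 12.7 / 2 + 0.01 & h < 12.7 - 0.01
  expect_equal(
    sphere_model_density(h[interior], 12.7, 1e-6), d0[interior],
    tolerance = 1e-4
  )
})

test_that("sphere and disc fits recover the simulated particle sizes", {
  sm <- gen_sphere_field(40, 12.7, 800, 2, noise_sd = 0.2, seed = 8)
  sf <- fit_sphere(height_distribution(sm))
  expect_lt(abs(sf$diameter_2Rs - 12.7), 0.3)

  dm <- gen_disc_field(100, 12.9, 13, 500, 2, noise_sd = 0.2, seed = 8)
  df <- fit_disc(height_distribution(dm))
  expect_lt(abs(df$height_hD - 12.9), 0.2)
  expect_true(df$tail_defined)
})

test_that("a pure delta distribution flags the tail regression undefined", {
  dm <- gen_disc_field(5, 12.9, 13, 200, 2, noise_sd = 0, seed = 2)
  df <- fit_disc(height_distribution(dm))
  expect_false(df$tail_defined)
  expect_true(is.na(df$tail_slope))
})

test_that("broadened delta peaks are located within a bin width", {
  # oracle: the mode of the analytic Gaussian is its mean
  dm <- gen_disc_field(150, 10.5, 13, 600, 2, noise_sd = 0.4, seed = 13)
  hd <- height_distribution(dm)
  df <- fit_disc(hd)
  expect_lt(abs(df$height_hD - 10.5), hd$bin_width)
})

test_that("population classification picks the generating model", {
  sm <- gen_sphere_field(40, 12.7, 800, 2, noise_sd = 0, seed = 5)
  cs <- classify_population(height_distribution(sm))
  expect_identical(cs$model, "sphere")
  expect_false(cs$uncertain)

  dm <- gen_disc_field(100, 12.9, 13, 500, 2, noise_sd = 0, seed = 5)
  cd <- classify_population(height_distribution(dm))
  expect_identical(cd$model, "disc")
  expect_false(cd$uncertain)
  expect_gt(cd$margin, 2) # classification margin beyond 2x residual ratio
})

test_that("size recovery stays within two bin widths across seeds", {
  errs <- sapply(1:10, function(s) {
    dm <- gen_disc_field(100, 12.9, 13, 500, 2, noise_sd = 0.3, seed = s)
    hd <- height_distribution(dm)
    abs(fit_disc(hd)$height_hD - 12.9)
  })
  hd_bw <- height_distribution(
    gen_disc_field(5, 12.9, 13, 200, 2, seed = 1)
  )$bin_width
  expect_lte(median(errs), 2 * hd_bw)
})

test_that("lipidation stoichiometry converts weight to molar ratios", {
  # 2.5:1 POPC:apoA-I by weight, 760.1 and 28000 g/mol -> 92 lipids/protein
  expect_identical(round(lipidation_molar_ratio(2.5, 760.1, 28000)), 92)
  expect_identical(lipidation_molar_ratio(1, 777, 777), 1)
  # DMPC at a 0.4 weight ratio (hand arithmetic: 0.4 * 28000 / 677.9)
  expect_equal(lipidation_molar_ratio(0.4, 677.9, 28000), 16.5, tolerance = 0.05)
  # exactly linear in the weight ratio
  w <- c(0.5, 1, 2, 4)
  r <- lipidation_molar_ratio(w, 760.1, 28000)
  expect_equal(r, w * lipidation_molar_ratio(1, 760.1, 28000), tolerance = 1e-12)
  expect_error(lipidation_molar_ratio(0, 760, 28000), "> 0")
})
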