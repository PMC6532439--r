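grouped <- function(means, n_per, sd = 1, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    group = rep(paste0("g", seq_along(means)), each = n_per),
    value = rnorm(n_per * length(means), rep(means, each = n_per), sd)
  )
}

test_that("one-way ANOVA has the classical degrees of freedom", {
  d <- grouped(c(0, 1, 2, 3), n_per = 9, seed = 2)
  res <- anova_oneway(d)
  expect_identical(res$df_between, 3L)
  expect_identical(res$df_within, 32L)
  expect_gte(res$F, 0)
})

test_that("ANOVA matches the hand-computed sum-of-squares oracle", {
  for (s in 1:5) {
    d <- grouped(c(0, 0.5, 1.5), n_per = 6, seed = 10 + s)
    res <- anova_oneway(d)
    # explicit between/within decomposition
    gm <- tapply(d$value, d$group, mean)
    ns <- tapply(d$value, d$group, length)
    grand <- mean(d$value)
    ss_b <- sum(ns * (gm - grand)^2)
    ss_w <- sum((d$value - gm[d$group])^2)
    f_oracle <- (ss_b / (length(gm) - 1)) / (ss_w / (nrow(d) - length(gm)))
    p_oracle <- pf(f_oracle, length(gm) - 1, nrow(d) - length(gm),
      lower.tail = FALSE
    )
    expect_equal(res$F, unname(f_oracle), tolerance = 1e-10)
    expect_equal(res$p, unname(p_oracle), tolerance = 1e-10)
  }
})

test_that("with two groups F equals the squared pooled t statistic", {
  d <- grouped(c(0, 1), n_per = 7, seed = 4)
  res <- anova_oneway(d)
  a <- d$value[d$group == "g1"]
  b <- d$value[d$group == "g2"]
  t_stat <- unname(t.test(a, b, var.equal = TRUE)$statistic)
  expect_equal(res$F, t_stat^2, tolerance = 1e-10)
})

test_that("ANOVA F is invariant under shifting and scaling the data", {
  d <- grouped(c(0, 1, 3), n_per = 5, seed = 6)
  f0 <- anova_oneway(d)$F
  shifted <- dplyr::mutate(d, value = value + 100)
  scaled <- dplyr::mutate(d, value = value * 7)
  expect_equal(anova_oneway(shifted)$F, f0, tolerance = 1e-9)
  expect_equal(anova_oneway(scaled)$F, f0, tolerance = 1e-9)
})

test_that("degenerate grouped data is rejected", {
  flatd <- tibble::tibble(
    group = rep(c("a", "b"), each = 3), value = rep(c(5, 9), each = 3)
  )
  expect_error(anova_oneway(flatd), "variance")
  expect_error(
    anova_oneway(tibble::tibble(group = "a", value = 1:5)), "2 groups"
  )
})

test_that("ANOVA holds its nominal type-I error rate", {
  n_sim <- 3000
  set.seed(77)
  rejections <- sum(replicate(n_sim, {
    d <- tibble::tibble(
      group = rep(c("a", "b", "c", "d"), each = 5), value = rnorm(20)
    )
    anova_oneway(d)$p < 0.05
  }))
  rate <- rejections / n_sim
  mc_band <- 3.5 * sqrt(0.05 * 0.95 / n_sim)
  expect_lt(abs(rate - 0.05), mc_band)
})

test_that("Tukey HSD flags only genuinely separated groups", {
  same <- tibble::tibble(
    group = rep(c("a", "b", "c"), each = 4),
    value = rep(c(1.2, 0.8, 1.1, 0.9), 3)
  )
  expect_true(all(!tukey_hsd(same)$significant))

  # one group 10 SD away from the rest
  d <- grouped(c(0, 0, 10), n_per = 6, sd = 1, seed = 8)
  tk <- tukey_hsd(d)
  with_g3 <- grepl("g3", tk$pair)
  expect_true(all(tk$significant[with_g3]))
  expect_true(all(!tk$significant[!with_g3]))
})

test_that("Tukey adjusted p never undercuts the unadjusted pairwise p", {
  for (s in 1:5) {
    d <- grouped(c(0, 0.7, 1.1, 0.2), n_per = 5, seed = 20 + s)
    tk <- tukey_hsd(d)
    fit <- aov(value ~ factor(group), data = d)
    mse <- anova(fit)$`Mean Sq`[2]
    dfw <- anova(fit)$Df[2]
    ns <- table(d$group)
    for (i in seq_len(nrow(tk))) {
      gg <- strsplit(tk$pair[i], "-", fixed = TRUE)[[1]]
      se <- sqrt(mse * (1 / ns[[gg[1]]] + 1 / ns[[gg[2]]]))
      p_raw <- 2 * pt(-abs(tk$diff[i]) / se, dfw)
      expect_gte(tk$p_adj[i] + 1e-12, p_raw)
    }
  }
})

test_that("Tukey output is symmetric in group relabeling", {
  d <- grouped(c(0, 1, 2), n_per = 5, seed = 12)
  tk1 <- tukey_hsd(d)
  relabeled <- dplyr::mutate(
    d,
    group = c(g1 = "g3", g2 = "g2", g3 = "g1")[group]
  )
  tk2 <- tukey_hsd(relabeled)
  expect_equal(unname(sort(abs(tk1$diff))), unname(sort(abs(tk2$diff))),
    tolerance = 1e-12
  )
  expect_equal(unname(sort(tk1$p_adj)), unname(sort(tk2$p_adj)),
    tolerance = 1e-9
  )
})

test_that("one-tailed pooled t behaves at its anchors", {
  a <- c(1.1, 0.9, 1.0, 1.2)
  expect_equal(t_test_one_tailed(a, a, "greater")$p_value, 0.5,
    tolerance = 1e-12
  )
  b <- c(0.1, 0.2, 0.05, 0.15)
  pg <- t_test_one_tailed(a, b, "greater")$p_value
  pl <- t_test_one_tailed(a, b, "less")$p_value
  expect_equal(pg + pl, 1, tolerance = 1e-12)

  # textbook arithmetic: pooled variance, se, t, df by hand
  x <- c(1, 2, 3)
  y <- c(2, 4, 6)
  sp2 <- (2 * var(x) + 2 * var(y)) / 4
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (2 / 3))
  res <- t_test_one_tailed(x, y, "less")
  expect_equal(res$statistic, t_hand, tolerance = 1e-12)
  expect_identical(res$df, 4)
  expect_equal(res$p_value, pt(t_hand, 4), tolerance = 1e-12)
})
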