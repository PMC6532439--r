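#' One-way ANOVA on grouped observations
#'
#' Classical fixed-effects one-way analysis of variance: the ratio of
#' between-group to within-group mean squares is referred to the F
#' distribution with (k - 1, N - k) degrees of freedom. Typical use: EP
#' values from three independent transwell experiments run in triplicate
#' across treatment groups (k = 4 groups of 9 gives df = 3, 32).
#'
#' @param data Data frame with one observation per row.
#' @param value,group Column names (strings) of the observation and the
#'   group label; defaults `"value"`, `"group"`.
#' @return A list of class `anova_result`: `F`, `df_between`, `df_within`,
#'   `p`, `group_means` (tibble), plus the underlying `stats::aov` fit.
#' @examples
#' d <- data.frame(group = rep(c("a", "b"), each = 5),
#'                 value = c(rnorm(5), rnorm(5, 2)))
#' anova_oneway(d)$p
#' @export
anova_oneway <- function(data, value = "value", group = "group") {
  d <- check_grouped(data, value, group, min_per_group = 2)
  if (all(tapply(d$value, d$group, stats::var) == 0)) {
    stop("zero within-group variance; ANOVA is undefined", call. = FALSE)
  }
  fit <- stats::aov(value ~ group, data = d)
  tab <- stats::anova(fit)
  structure(
    list(
      F = tab$`F value`[1],
      df_between = tab$Df[1],
      df_within = tab$Df[2],
      p = tab$`Pr(>F)`[1],
      group_means = d |>
        dplyr::group_by(.data$group) |>
        dplyr::summarise(
          mean = mean(.data$value), sd = stats::sd(.data$value),
          n = dplyr::n(), .groups = "drop"
        ),
      fit = fit
    ),
    class = "anova_result"
  )
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf(
    "<anova_result> F(%d,%d) = %.4g, p = %.4g\n",
    x$df_between, x$df_within, x$F, x$p
  ))
  invisible(x)
}

#' @export
tidy.anova_result <- function(x, ...) x$group_means

#' @export
glance.anova_result <- function(x, ...) {
  tibble::tibble(
    statistic = x$F, df_between = x$df_between, df_within = x$df_within,
    p_value = x$p
  )
}

#' Tukey HSD post hoc comparisons
#'
#' All pairwise group comparisons with the studentized-range correction
#' (Tukey-Kramer for unbalanced groups), using the pooled within-group mean
#' square from the one-way ANOVA.
#'
#' @inheritParams anova_oneway
#' @param alpha Family-wise significance level; default 0.05.
#' @return A tibble of class `tukey_result`: `pair`, `diff` (mean
#'   difference), `q` (studentized-range statistic), `p_adj`, `significant`.
#' @export
tukey_hsd <- function(data, value = "value", group = "group", alpha = 0.05) {
  d <- check_grouped(data, value, group, min_per_group = 2)
  fit <- stats::aov(value ~ group, data = d)
  tk <- stats::TukeyHSD(fit)$group
  ms_within <- stats::anova(fit)$`Mean Sq`[2]
  ns <- table(d$group)
  pairs <- rownames(tk)
  halves <- strsplit(pairs, "-", fixed = TRUE)
  se_q <- vapply(halves, function(gg) {
    sqrt(ms_within / 2 * (1 / ns[[gg[1]]] + 1 / ns[[gg[2]]]))
  }, numeric(1))
  out <- tibble::tibble(
    pair = pairs,
    diff = tk[, "diff"],
    q = abs(tk[, "diff"]) / se_q,
    p_adj = tk[, "p adj"],
    significant = tk[, "p adj"] < alpha
  )
  class(out) <- c("tukey_result", class(out))
  attr(out, "alpha") <- alpha
  out
}

#' One-tailed two-sample Student's t-test
#'
#' Pooled-variance (classical Student) two-sample t-test with a one-sided
#' alternative, the test used when comparing equilibrium trajectory metrics
#' between two simulated systems.
#'
#' @param a,b Numeric observation vectors.
#' @param direction `"greater"` tests mean(a) > mean(b), `"less"` the
#'   reverse.
#' @return A one-row tibble: `statistic` (t), `df`, `p_value`, `mean_a`,
#'   `mean_b`, `direction`.
#' @examples
#' t_test_one_tailed(c(5, 6, 7), c(1, 2, 3), "greater")
#' @export
t_test_one_tailed <- function(a, b, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  stopifnot(length(a) >= 2, length(b) >= 2)
  ht <- stats::t.test(a, b, var.equal = TRUE, alternative = direction)
  tibble::tibble(
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value,
    mean_a = mean(a),
    mean_b = mean(b),
    direction = direction
  )
}

check_grouped <- function(data, value, group, min_per_group = 2) {
  stopifnot(is.data.frame(data))
  if (!value %in% names(data) || !group %in% names(data)) {
    stop(sprintf("`data` needs columns '%s' and '%s'", value, group),
      call. = FALSE
    )
  }
  d <- data.frame(
    value = as.numeric(data[[value]]),
    group = factor(data[[group]])
  )
  if (nlevels(d$group) < 2) {
    stop("need at least 2 groups", call. = FALSE)
  }
  if (any(table(d$group) < min_per_group)) {
    stop("each group needs at least ", min_per_group, " observations",
      call. = FALSE
    )
  }
  d
}
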