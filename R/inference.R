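stat_result <- function(comparison, statistic_name, statistic, df = NA_real_,
                        p_raw, p_adjusted = NA_real_,
                        effect_size_d = NA_real_, n1, n2) {
  tibble::tibble(
    comparison = comparison,
    statistic_name = statistic_name,
    statistic = statistic,
    df = df,
    p_raw = p_raw,
    p_adjusted = p_adjusted,
    effect_size_d = effect_size_d,
    n1 = as.integer(n1),
    n2 = as.integer(n2)
  )
}

#' Two-independent-sample z-test for proportions
#'
#' Pooled-variance z-test without continuity correction:
#' `z = (p1 - p2) / sqrt(pbar (1 - pbar) (1/n1 + 1/n2))` with the pooled
#' proportion `pbar = (x1 + x2) / (n1 + n2)`. Used for head-assay response
#' proportions. A warning (not an error) is issued when expected successes or
#' failures in either group fall below 5, where the normal approximation is
#' doubtful.
#'
#' @param p1,p2 Observed sample proportions.
#' @param n1,n2 Group sizes.
#' @param sides 1 or 2 (two-sided by default).
#' @param comparison Length-2 character vector of group labels.
#' @return A one-row tibble: `comparison`, `statistic_name` (`"z"`),
#'   `statistic`, `df` (NA), `p_raw`, `p_adjusted` (NA, filled by family-wise
#'   adjustment downstream), `effect_size_d` (NA), `n1`, `n2`.
#' @examples
#' two_sample_z_test(0.8, 40, 0.2, 40)
#' @export
two_sample_z_test <- function(p1, n1, p2, n2, sides = 2,
                              comparison = c("group1", "group2")) {
  stopifnot(sides %in% c(1, 2))
  if (p1 < 0 || p1 > 1 || p2 < 0 || p2 > 1) abort("proportions must lie in [0, 1]")
  pbar <- (p1 * n1 + p2 * n2) / (n1 + n2)
  if (pbar <= 0 || pbar >= 1) {
    abort("degenerate pooled proportion (0 or 1): the z statistic is undefined")
  }
  expected <- c(n1 * pbar, n1 * (1 - pbar), n2 * pbar, n2 * (1 - pbar))
  if (any(expected < 5)) {
    warn("expected successes/failures below 5; normal approximation is unreliable")
  }
  z <- (p1 - p2) / sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2))
  p <- if (sides == 2) 2 * pnorm(-abs(z)) else pnorm(-abs(z))
  stat_result(paste(comparison, collapse = " vs "), "z", z,
              p_raw = p, n1 = n1, n2 = n2)
}

#' Pooled two-sample t-test
#'
#' Classical equal-variance two-sample t-test with `df = n1 + n2 - 2`
#' (delegates to [stats::t.test()] with `var.equal = TRUE`), reporting
#' Cohen's d alongside. Degenerate inputs with zero pooled variance return
#' `t = 0, p = 1` when the means agree and an infinite statistic with `p = 0`
#' when they differ.
#'
#' @param x,y Numeric vectors (each of length >= 2).
#' @inheritParams two_sample_z_test
#' @return A one-row tibble in the same shape as [two_sample_z_test()], with
#'   `statistic_name = "t"`, `df`, and `effect_size_d` populated.
#' @examples
#' two_sample_t_test(c(1, 2, 3), c(4, 5, 6))
#' @export
two_sample_t_test <- function(x, y, sides = 2,
                              comparison = c("group1", "group2")) {
  stopifnot(sides %in% c(1, 2))
  if (length(x) < 2 || length(y) < 2) abort("each group needs >= 2 observations")
  n1 <- length(x); n2 <- length(y)
  df <- n1 + n2 - 2
  label <- paste(comparison, collapse = " vs ")

  pooled_var <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / df
  if (pooled_var == 0) {
    if (mean(x) == mean(y)) {
      return(stat_result(label, "t", 0, df = df, p_raw = 1,
                         effect_size_d = 0, n1 = n1, n2 = n2))
    }
    return(stat_result(label, "t", sign(mean(x) - mean(y)) * Inf, df = df,
                       p_raw = 0, effect_size_d = sign(mean(x) - mean(y)) * Inf,
                       n1 = n1, n2 = n2))
  }

  fit <- t.test(x, y, var.equal = TRUE)
  # one-sided: p in the direction of the observed difference
  p <- if (sides == 2) fit$p.value else fit$p.value / 2
  stat_result(label, "t", unname(fit$statistic), df = df, p_raw = p,
              effect_size_d = cohens_d(x, y), n1 = n1, n2 = n2)
}

#' One-way ANOVA with Tukey HSD post-hoc comparisons
#'
#' Fits a one-way ANOVA across three or more groups (via [stats::aov()]) and
#' performs all pairwise Tukey honest-significant-difference comparisons with
#' family-wise-adjusted p-values (via [stats::TukeyHSD()]). The returned table
#' has the overall F-test as its first row (comparison `"overall"`) followed
#' by one row per pair with the studentized-range statistic
#' `q = |diff| / sqrt((MSE / 2) (1/ni + 1/nj))`.
#'
#' @param data Data frame with one observation per row.
#' @param value Name of the numeric response column (string).
#' @param group Name of the grouping column (string).
#' @return A tibble of test results, one row for the F test plus one per
#'   group pair; `p_adjusted` on pair rows is the Tukey family-wise p.
#' @examples
#' d <- data.frame(y = c(1, 2, 1.5, 5, 6, 5.5, 9, 10, 9.5),
#'                 g = rep(c("a", "b", "c"), each = 3))
#' one_way_anova_tukey(d, "y", "g")
#' @export
one_way_anova_tukey <- function(data, value = "backing_time_s",
                                group = "treatment") {
  data <- as.data.frame(data)
  check_columns(data, c(value, group), "data")
  data[[group]] <- factor(data[[group]])
  sizes <- table(data[[group]])
  if (length(sizes) < 3) abort("ANOVA requires at least 3 groups")
  if (any(sizes < 2)) {
    abort(paste0("group(s) with fewer than 2 observations: ",
                 paste(names(sizes)[sizes < 2], collapse = ", ")))
  }

  fit <- aov(stats::reformulate(group, value), data = data)
  anova_tab <- summary(fit)[[1]]
  mse <- anova_tab["Residuals", "Mean Sq"]
  df_resid <- anova_tab["Residuals", "Df"]
  f_row <- stat_result("overall", "F", anova_tab[1, "F value"],
                       df = anova_tab[1, "Df"],
                       p_raw = anova_tab[1, "Pr(>F)"],
                       n1 = nrow(data), n2 = nrow(data))

  hsd <- TukeyHSD(fit)[[group]]
  pairs <- strsplit(rownames(hsd), "-", fixed = TRUE)
  pair_rows <- purrr::map_dfr(seq_len(nrow(hsd)), function(i) {
    a <- pairs[[i]][1]; b <- pairs[[i]][2]
    ni <- sizes[[a]]; nj <- sizes[[b]]
    q <- abs(hsd[i, "diff"]) / sqrt((mse / 2) * (1 / ni + 1 / nj))
    stat_result(paste(a, "vs", b), "q", q, df = df_resid,
                p_raw = hsd[i, "p adj"], p_adjusted = hsd[i, "p adj"],
                n1 = ni, n2 = nj)
  })
  dplyr::bind_rows(f_row, pair_rows)
}

#' Hochberg step-up p-value adjustment
#'
#' Adjusts a family of p-values with the Hochberg step-up procedure
#' (delegating to [stats::p.adjust()]): with raw p sorted ascending
#' `p(1) <= ... <= p(m)`, `adj(m) = p(m)` and
#' `adj(i) = min(adj(i+1), (m - i + 1) p(i))`, capped at 1 and returned in the
#' input order. Adjusted p-values are never smaller than the raw ones, so the
#' procedure can only conservatively increase them.
#'
#' @param p_values Numeric vector of raw p-values in \[0, 1\].
#' @return Numeric vector of adjusted p-values, same length and order.
#' @examples
#' hochberg_adjust(c(0.01, 0.04, 0.03))
#' @export
hochberg_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "hochberg")
}

#' Cohen's d for two independent samples
#'
#' `d = (mean(x) - mean(y)) / s_pooled` with
#' `s_pooled = sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))`. The sign
#' of the mean difference is preserved.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @return A single numeric effect size.
#' @examples
#' cohens_d(rnorm(20, 1), rnorm(20, 0))
#' @export
cohens_d <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) abort("each group needs >= 2 observations")
  sp <- sqrt(((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2))
  if (sp == 0) abort("zero pooled standard deviation: d is undefined")
  (mean(x) - mean(y)) / sp
}

#' Power of the pooled two-sample t-test at a given effect size
#'
#' Exact power from the noncentral t distribution with noncentrality
#' `d sqrt(n/2)` and `2n - 2` degrees of freedom (equal group sizes).
#'
#' @param n Per-group sample size (>= 2).
#' @param d Cohen's d effect size.
#' @param alpha Significance level.
#' @param sides 1 or 2.
#' @return Power as a probability.
#' @examples
#' power_two_sample_t(26, 0.8) # ~0.81
#' @export
power_two_sample_t <- function(n, d, alpha = 0.05, sides = 2) {
  stopifnot(n >= 2, sides %in% c(1, 2))
  df <- 2 * n - 2
  ncp <- d * sqrt(n / 2)
  if (sides == 2) {
    crit <- qt(1 - alpha / 2, df)
    pt(crit, df, ncp, lower.tail = FALSE) + pt(-crit, df, ncp)
  } else {
    pt(qt(1 - alpha, df), df, ncp, lower.tail = FALSE)
  }
}

#' Per-group sample size for a two-sample t-test
#'
#' Smallest integer per-group n at which the pooled two-sample t-test reaches
#' the target power for a given Cohen's d, solved iteratively against the
#' noncentral-t power function [power_two_sample_t()]. At d = 0.8 (a large
#' effect), alpha = 0.05, power = 0.8, two-sided, this gives 26 animals per
#' group.
#'
#' @param d Cohen's d (> 0).
#' @param alpha Significance level in (0, 1).
#' @param power Target power in (0, 1).
#' @param sides 1 or 2.
#' @return A one-row tibble with `n_per_group`, `power_achieved` (power at
#'   the returned n), `d`, `alpha`, `power_target`, `sides`.
#' @examples
#' sample_size_t(d = 0.8) # n_per_group = 26
#' @export
sample_size_t <- function(d, alpha = 0.05, power = 0.8, sides = 2) {
  if (d <= 0) abort("`d` must be positive (the target power is unreachable otherwise)")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    abort("`alpha` and `power` must lie in (0, 1)")
  }
  n <- 2
  while (power_two_sample_t(n, d, alpha, sides) < power) {
    n <- n + 1
    if (n > 1e7) abort("sample-size search did not converge")
  }
  tibble::tibble(
    n_per_group = as.integer(n),
    power_achieved = power_two_sample_t(n, d, alpha, sides),
    d = d, alpha = alpha, power_target = power, sides = as.integer(sides)
  )
}

#' Per-group sample size for comparing two proportions
#'
#' Uses Cohen's arcsine effect size
#' `h = |2 arcsin(sqrt(p2)) - 2 arcsin(sqrt(p1))|` and the two-sample
#' normal-approximation formula
#' `n = round(2 (z_{1-alpha/2} + z_{power})^2 / h^2)`. For pilot proportions
#' 0.3 and 0.8 at alpha = 0.05 and power = 0.8 this gives h = 1.055 and 14
#' animals per group.
#'
#' @param p1,p2 Proportions in (0, 1), `p1 != p2`.
#' @inheritParams sample_size_t
#' @return A one-row tibble with `h`, `n_per_group`, `p1`, `p2`, `alpha`,
#'   `power_target`.
#' @examples
#' sample_size_two_prop(0.3, 0.8) # h ~= 1.055, n_per_group = 14
#' @export
sample_size_two_prop <- function(p1, p2, alpha = 0.05, power = 0.8) {
  if (p1 <= 0 || p1 >= 1 || p2 <= 0 || p2 >= 1) {
    abort("proportions must lie strictly inside (0, 1)")
  }
  if (p1 == p2) abort("`p1` and `p2` must differ")
  h <- abs(2 * asin(sqrt(p2)) - 2 * asin(sqrt(p1)))
  n <- round(2 * (qnorm(1 - alpha / 2) + qnorm(power))^2 / h^2)
  tibble::tibble(
    h = h, n_per_group = as.integer(n),
    p1 = p1, p2 = p2, alpha = alpha, power_target = power
  )
}

#' Significance codes at the 0.05 / 0.01 / 0.001 thresholds
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of `"***"`, `"**"`, `"*"` or `"ns"`.
#' @export
signif_code <- function(p) {
  dplyr::case_when(
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns"
  )
}
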