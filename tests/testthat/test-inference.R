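test_that("z-test matches the pooled formula and its symmetries", {
  res <- two_sample_z_test(0.8, 40, 0.2, 40)
  expect_equal(res$statistic, 0.6 / sqrt(0.5 * 0.5 * (2 / 40)),
               tolerance = 1e-12)
  expect_equal(res$statistic, 5.367, tolerance = 1e-3)

  eq <- two_sample_z_test(0.5, 30, 0.5, 30)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_raw, 1)

  swapped <- two_sample_z_test(0.2, 40, 0.8, 40)
  expect_equal(swapped$statistic, -res$statistic)
  expect_equal(swapped$p_raw, res$p_raw)

  # independent route: chi-square test without continuity correction
  pt <- suppressWarnings(stats::prop.test(c(32, 8), c(40, 40), correct = FALSE))
  expect_equal(res$statistic^2, unname(pt$statistic), tolerance = 1e-10)
  expect_equal(res$p_raw, pt$p.value, tolerance = 1e-10)

  expect_error(two_sample_z_test(0, 40, 0, 40), "degenerate")
  expect_warning(two_sample_z_test(0.5, 5, 0.3, 5), "normal approximation")
})

test_that("pooled t-test reproduces the hand-computed example", {
  res <- two_sample_t_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(res$statistic, -3.674, tolerance = 1e-3)
  expect_equal(res$p_raw, 0.0214, tolerance = 1e-2)
  expect_equal(res$df, 4)
  expect_equal(res$effect_size_d, -3)

  # identity and scale invariance
  x <- c(2, 4, 9, 3)
  expect_equal(two_sample_t_test(x, x)$statistic, 0)
  expect_equal(two_sample_t_test(x, x)$p_raw, 1)
  y <- c(1, 5, 2, 8)
  expect_equal(two_sample_t_test(3.7 * x, 3.7 * y)$statistic,
               two_sample_t_test(x, y)$statistic, tolerance = 1e-12)
})

test_that("degenerate zero-variance t inputs hit the documented sentinels", {
  same <- two_sample_t_test(c(2, 2, 2), c(2, 2))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_raw, 1)
  diff <- two_sample_t_test(c(3, 3), c(1, 1, 1))
  expect_equal(diff$statistic, Inf)
  expect_equal(diff$p_raw, 0)
})

test_that("ANOVA+Tukey separates forced groups and matches TukeyHSD", {
  d <- data.frame(
    y = c(0.01, -0.01, 0.02, 0, 10.01, 9.99),
    g = rep(c("a", "b", "c"), each = 2)
  )
  res <- one_way_anova_tukey(d, "y", "g")
  expect_equal(res$comparison[1], "overall")
  pair <- function(a, b) res[res$comparison %in%
                               c(paste(a, "vs", b), paste(b, "vs", a)), ]
  expect_gt(pair("a", "b")$p_adjusted, 0.05)
  expect_lt(pair("a", "c")$p_adjusted, 0.001)
  expect_lt(pair("b", "c")$p_adjusted, 0.001)

  # identical groups: F ~ 0, adjusted p ~ 1
  d0 <- data.frame(y = rep(c(1, 2), 3), g = rep(c("a", "b", "c"), each = 2))
  res0 <- one_way_anova_tukey(d0, "y", "g")
  expect_equal(res0$statistic[1], 0, tolerance = 1e-12)
  expect_true(all(res0$p_adjusted[-1] > 0.999))

  expect_error(one_way_anova_tukey(d[1:4, ], "y", "g"), "3 groups")
  expect_error(
    one_way_anova_tukey(data.frame(y = c(1, 2, 3, 4, 5),
                                   g = c("a", "a", "b", "b", "c")), "y", "g"),
    "fewer than 2")
})

test_that("hochberg adjustment matches the step-up oracle on grids", {
  expect_equal(hochberg_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.04, 0.04))
  expect_equal(hochberg_adjust(0.37), 0.37) # m = 1: unchanged (= Bonferroni)
  expect_error(hochberg_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  grid <- seq(0, 1, by = 0.01)
  for (p in grid) expect_identical(hochberg_adjust(p), hochberg_oracle(p))
  withr::with_seed(123, {
    for (m in 2:5) {
      for (rep in 1:200) {
        p <- sample(grid, m, replace = TRUE)
        adj <- hochberg_adjust(p)
        expect_equal(adj, hochberg_oracle(p))
        expect_true(all(adj >= p))
        expect_true(!is.unsorted(adj[order(p)]))
      }
    }
  })
})

test_that("cohens_d follows the pooled-sd definition and its invariances", {
  x <- c(9, 11, 10, 10); y <- c(4, 6, 5, 5)
  sp <- sqrt((3 * var(x) + 3 * var(y)) / 6)
  expect_equal(cohens_d(x, y), 5 / sp, tolerance = 1e-12)
  expect_equal(cohens_d(x, x), 0)
  expect_equal(cohens_d(x + 100, y + 100), cohens_d(x, y), tolerance = 1e-12)
  expect_equal(cohens_d(y, x), -cohens_d(x, y), tolerance = 1e-12)
  expect_error(cohens_d(c(1, 1), c(1, 1)), "pooled")
})

test_that("noncentral-t sample size solver agrees with power.t.test", {
  res <- sample_size_t(0.8)
  expect_equal(res$n_per_group, 26L)
  # independent oracle for the power curve
  expect_equal(power_two_sample_t(26, 0.8),
               stats::power.t.test(n = 26, delta = 0.8)$power,
               tolerance = 1e-5)
  # monotonicity: doubling d strictly decreases n
  expect_lt(sample_size_t(1.6)$n_per_group, 26L)

  hi <- sample_size_t(0.8, power = 0.99)
  expect_gte(power_two_sample_t(hi$n_per_group, 0.8), 0.99)
  expect_lt(power_two_sample_t(hi$n_per_group - 1, 0.8), 0.99)
  expect_equal(hi$n_per_group,
               ceiling(stats::power.t.test(delta = 0.8, power = 0.99)$n))

  expect_error(sample_size_t(0), "positive")
})

test_that("arcsine-h two-proportion sample size reproduces its definition", {
  res <- sample_size_two_prop(0.3, 0.8)
  expect_equal(res$h, 2 * asin(sqrt(0.8)) - 2 * asin(sqrt(0.3)),
               tolerance = 1e-12)
  expect_equal(res$h, 1.0550, tolerance = 1e-4)
  expect_equal(res$n_per_group, 14L)
  # arcsine symmetry: (p1, p2) -> (1 - p2, 1 - p1) preserves h
  expect_equal(sample_size_two_prop(0.2, 0.7)$h,
               sample_size_two_prop(0.3, 0.8)$h, tolerance = 1e-12)
  expect_error(sample_size_two_prop(0.5, 0.5), "differ")
})

test_that("significance codes follow the 0.05/0.01/0.001 convention", {
  expect_equal(signif_code(c(0.0005, 0.005, 0.03, 0.2)),
               c("***", "**", "*", "ns"))
})
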