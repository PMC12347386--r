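test_that("summaries report sample SD and z-based 95% CI", {
  x <- sample_with_moments(21, 7.08, 0.10)
  s <- summarize_values(x)
  expect_equal(s$n, 21)
  expect_equal(s$mean, 7.08, tolerance = 1e-12)
  expect_equal(s$sd, 0.10, tolerance = 1e-12)
  expect_equal(round(c(s$ci_low, s$ci_high), 2), c(7.04, 7.12))

  y <- sample_with_moments(21, 7.02, 0.09)
  sy <- summarize_values(y)
  expect_equal(round(c(sy$ci_low, sy$ci_high), 2), c(6.98, 7.06))

  const <- summarize_values(rep(3.2, 10))
  expect_equal(const$sd, 0)
  expect_equal(const$ci_low, const$mean)
  expect_equal(const$ci_high, const$mean)
  expect_error(summarize_values(1), "at least 2")

  # permutation invariance in patient order
  set.seed(4)
  expect_equal(summarize_values(sample(x)), s)
})

test_that("skewness follows the adjusted Fisher-Pearson formula", {
  expect_equal(sample_skewness(c(-1, 0, 1)), 0)
  # independent direct-moment computation for (0, 0, 1)
  v <- c(0, 0, 1)
  m2 <- mean((v - mean(v))^2)
  m3 <- mean((v - mean(v))^3)
  expect_equal(sample_skewness(v), (m3 / m2^1.5) * sqrt(3 * 2) / 1)
  expect_gt(sample_skewness(v), 0)
  set.seed(8)
  z <- rnorm(25)
  expect_equal(sample_skewness(-z), -sample_skewness(z))
  expect_error(sample_skewness(rep(1, 5)), "constant")
})

test_that("Shapiro-Wilk battery flags normal and skewed samples correctly", {
  expect_equal(sw_critical_value(21), 0.908)
  expect_error(sw_critical_value(2), "3..50")
  expect_error(sw_critical_value(21, alpha = 0.01), "tabulated")

  grid <- qnorm(ppoints(21)) # an exact normal quantile grid
  res <- shapiro_wilk(grid)
  expect_gt(res$w_stat, 0.95)
  expect_gt(res$p_value, 0.05)
  expect_true(res$is_normal)
  expect_false(res$reject_h0)
  expect_equal(res$w_critical, 0.908)

  skewed <- exp(2 * grid) # strongly right-skewed
  res2 <- shapiro_wilk(skewed)
  expect_true(res2$reject_h0)
  expect_gt(res2$skew, 1)

  # W is location- and scale-invariant
  expect_equal(shapiro_wilk(5 - 3 * grid)$w_stat, res$w_stat, tolerance = 1e-10)
  expect_error(shapiro_wilk(rep(1, 10)), "constant")
})

test_that("signed-rank test matches enumeration, wilcox.test, and frozen cases", {
  # 3 pairs, all differences positive: W = 0, exact two-sided p = 2/8
  r <- wilcoxon_signed_rank(c(5, 6, 7), c(4, 5, 6))
  expect_equal(r$w_signed_rank, 0)
  expect_equal(r$p_value, 0.25)
  expect_equal(r$method, "exact")

  expect_error(wilcoxon_signed_rank(1:5, 1:5), "degenerate")

  # exact distribution equals brute-force enumeration, with and without ties
  for (seed in 1:10) {
    set.seed(seed)
    m <- sample(4:12, 1)
    d <- round(rnorm(m), if (seed %% 2) 0 else 2) # rounding induces ties/zeros
    if (all(d == 0)) d[1] <- 1
    ours <- wilcoxon_signed_rank(d, rep(0, m))
    expect_equal(ours$p_value, brute_wilcoxon_p(d), tolerance = 1e-12)
  }

  # agreement with the reference implementation in the untied exact case
  set.seed(42)
  x <- rnorm(12)
  y <- rnorm(12)
  ours <- wilcoxon_signed_rank(x, y)
  ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  expect_equal(min(sum(rank(abs(x - y))[x > y]), sum(rank(abs(x - y))[x < y])),
               ours$w_signed_rank)

  # effect size definition r = |z| / sqrt(m)
  expect_equal(ours$effect_size_r, abs(ours$z) / sqrt(ours$n_used))

  # a uniform 0.2 Gy shift plus small noise across 21 pairs is significant
  set.seed(7)
  a <- rnorm(21, 7.0, 0.1)
  b <- a - 0.2 + rnorm(21, 0, 0.05)
  expect_true(wilcoxon_signed_rank(a, b)$significant)

  # statistic bounds: 0 <= W <= m(m+1)/2
  expect_gte(ours$w_signed_rank, 0)
  expect_lte(ours$w_signed_rank, 12 * 13 / 2)
})

test_that("large-sample path falls back to a tie-corrected normal approximation", {
  set.seed(11)
  x <- rnorm(40, 1, 1)
  r <- wilcoxon_signed_rank(x, rep(0, 40))
  expect_equal(r$method, "normal-approximation")
  ref <- stats::wilcox.test(x, rep(0, 40), paired = TRUE, exact = FALSE,
                            correct = TRUE)
  expect_equal(r$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("comparison tables pair arms, emit one row per index, and catch errors", {
  set.seed(21)
  n <- 12
  ids <- sprintf("P%02d", 1:n)
  panels <- tibble::tibble(
    patient_id = rep(ids, 2),
    arm = rep(c("IC_OFF", "IC_ON"), each = n),
    D50 = c(rnorm(n, 7.1, 0.1), rnorm(n, 6.9, 0.15)),
    gEUD = c(rnorm(n, 7.0, 0.1), rnorm(n, 6.8, 0.15))
  )
  tbl <- build_comparison_tables(panels)
  expect_equal(nrow(tbl), 2)
  expect_equal(tbl$index, c("D50", "gEUD"))
  expect_true(all(tbl$ci_low_off <= tbl$mean_off))
  expect_true(all(tbl$mean_off <= tbl$ci_high_off))
  expect_equal(tbl$w_critical, rep(sw_critical_value(n), 2))
  txt <- format_comparison_table(tbl)
  expect_length(txt, 2 + nrow(tbl))

  # identical arms: paired test is degenerate, not significant
  same <- panels
  same$D50[same$arm == "IC_ON"] <- same$D50[same$arm == "IC_OFF"]
  same$gEUD[same$arm == "IC_ON"] <- same$gEUD[same$arm == "IC_OFF"]
  tbl2 <- build_comparison_tables(same)
  expect_true(all(tbl2$test_method == "degenerate"))
  expect_false(any(tbl2$significant))

  # unpaired patients are reported by id
  broken <- panels[-1, ]
  expect_error(build_comparison_tables(broken), "P01")
})
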