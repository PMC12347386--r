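#' Mean, SD and z-based 95% confidence interval
#'
#' Summarizes a vector of per-patient index values as mean, sample SD
#' (denominator n - 1), and the normal-approximation 95% confidence
#' interval of the mean, `mean +/- 1.96 * SD / sqrt(n)`. The z interval
#' (rather than t) is the convention used throughout the cohort tables this
#' package reproduces.
#'
#' @param values numeric vector, length >= 2.
#' @return a one-row tibble `n, mean, sd, ci_low, ci_high`.
#' @export
#' @examples
#' summarize_values(rnorm(21, 7.08, 0.10))
summarize_values <- function(values) {
  values <- as.numeric(values)
  if (anyNA(values)) stop("missing values in sample", call. = FALSE)
  n <- length(values)
  if (n < 2) stop("need at least 2 values", call. = FALSE)
  m <- mean(values)
  s <- stats::sd(values)
  half <- 1.96 * s / sqrt(n)
  tibble::tibble(n = n, mean = m, sd = s, ci_low = m - half, ci_high = m + half)
}

## Classic small-sample Shapiro-Wilk critical values of W at alpha = 0.05,
## n = 3..50. A sample is flagged non-normal when its W falls below the entry.
.sw_critical_05 <- c(
  0.767, 0.748, 0.762, 0.788, 0.803, 0.818, 0.829, 0.842, # n = 3..10
  0.850, 0.859, 0.866, 0.874, 0.881, 0.887, 0.892, 0.897, # n = 11..18
  0.901, 0.905, 0.908, 0.911, 0.914, 0.916, 0.918, 0.920, # n = 19..26
  0.923, 0.924, 0.926, 0.927, 0.929, 0.930, 0.931, 0.933, # n = 27..34
  0.934, 0.935, 0.936, 0.938, 0.939, 0.940, 0.941, 0.942, # n = 35..42
  0.943, 0.944, 0.945, 0.945, 0.946, 0.947, 0.947, 0.947  # n = 43..50
)

#' Shapiro-Wilk critical value of W
#'
#' Reference value of the W statistic from the classic small-sample table;
#' W below this value rejects normality at the given level.
#'
#' @param n sample size, 3..50.
#' @param alpha significance level; only 0.05 is tabulated.
#' @return the critical W.
#' @export
#' @examples
#' sw_critical_value(21) # 0.908
sw_critical_value <- function(n, alpha = 0.05) {
  if (alpha != 0.05) stop("only alpha = 0.05 is tabulated", call. = FALSE)
  if (n < 3 || n > 50) stop("`n` must be in 3..50", call. = FALSE)
  .sw_critical_05[n - 2L]
}

#' Adjusted Fisher-Pearson sample skewness
#'
#' The standardized third moment with the small-sample adjustment
#' `G1 = b1 * sqrt(n (n-1)) / (n - 2)` where `b1 = m3 / m2^(3/2)`.
#'
#' @param values numeric vector, length >= 3, non-constant.
#' @return sample skewness (dimensionless).
#' @export
sample_skewness <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 3) stop("need at least 3 values", call. = FALSE)
  m <- mean(values)
  m2 <- mean((values - m)^2)
  if (m2 == 0) stop("skewness undefined for a constant sample", call. = FALSE)
  m3 <- mean((values - m)^3)
  b1 <- m3 / m2^1.5
  b1 * sqrt(n * (n - 1)) / (n - 2)
}

#' Shapiro-Wilk normality test with critical-value reference
#'
#' Runs the Shapiro-Wilk test (Royston's approximation, suitable for the
#' small cohorts this battery targets), looks up the tabulated critical W at
#' alpha = 0.05, and reports sample skewness alongside. `reject_h0` is
#' driven by the p-value (< 0.05); `is_normal` is its negation. The
#' `effect_size` column quantifies the departure from normality as
#' `|qnorm(p)| / sqrt(n)` — one of several conventions in use, since no
#' standardized definition exists for this battery.
#'
#' @param values numeric vector, 3 <= n <= 50, non-constant.
#' @return a one-row tibble `n, w_stat, w_critical, skew, effect_size,
#'   p_value, reject_h0, is_normal`.
#' @export
shapiro_wilk <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 3 || n > 50) stop("`values` must have 3..50 observations", call. = FALSE)
  if (stats::sd(values) == 0) {
    stop("Shapiro-Wilk W undefined for a constant sample", call. = FALSE)
  }
  sw <- stats::shapiro.test(values)
  p <- sw$p.value
  tibble::tibble(
    n = n,
    w_stat = unname(sw$statistic),
    w_critical = sw_critical_value(n),
    skew = sample_skewness(values),
    effect_size = abs(stats::qnorm(max(p, 1e-300))) / sqrt(n),
    p_value = p,
    reject_h0 = p < 0.05,
    is_normal = p >= 0.05
  )
}

## exact null distribution of 2*W+ over doubled (possibly mid-) ranks,
## identical to enumerating all 2^m sign assignments
signed_rank_distribution <- function(r2) {
  N <- sum(r2)
  f <- numeric(N + 1)
  f[1] <- 1
  for (r in r2) {
    if (r == 0) { f <- 2 * f; next }
    f <- f + c(rep(0, r), f[seq_len(N + 1 - r)])
  }
  f # counts over 2*W+ = 0..N; sums to 2^m
}

#' Exact Wilcoxon signed-rank test for paired samples
#'
#' The nonparametric paired comparison used to contrast matched plan arms.
#' Zero differences are dropped before ranking (classic treatment), ties
#' receive midranks, and the reported statistic is the smaller of the
#' positive and negative rank sums. For m <= 25 remaining pairs the
#' two-sided p-value is exact — computed from the full null distribution of
#' the rank sum over all 2^m sign assignments (tie-aware); beyond that a
#' normal approximation with tie-corrected variance and continuity
#' correction is used. The effect size is `r = |z| / sqrt(m)` with
#' `z = (W+ - m(m+1)/4) / sqrt(sum(rank^2) / 4)`.
#'
#' @param x,y paired numeric vectors of equal length.
#' @param exact_limit largest m for which the exact distribution is used.
#' @return a one-row tibble `n_pairs, n_used, w_signed_rank, z, p_value,
#'   effect_size_r, significant, method`.
#' @export
#' @examples
#' wilcoxon_signed_rank(c(5, 6, 7), c(4, 5, 6)) # W = 0, exact p = 0.25
wilcoxon_signed_rank <- function(x, y, exact_limit = 25) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) stop("`x` and `y` must have equal length", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values in paired samples", call. = FALSE)
  d <- x - y
  d <- d[d != 0]
  m <- length(d)
  if (m == 0) {
    stop("all paired differences are zero; signed-rank test degenerate",
         call. = FALSE)
  }
  rk <- rank(abs(d))
  w_pos <- sum(rk[d > 0])
  w_neg <- sum(rk[d < 0])
  w <- min(w_pos, w_neg)
  mu <- m * (m + 1) / 4
  sigma <- sqrt(sum(rk^2) / 4) # exact tie-aware null variance of W+
  z <- (w_pos - mu) / sigma
  if (m <= exact_limit) {
    r2 <- as.integer(round(2 * rk))
    f <- signed_rank_distribution(r2)
    total <- sum(f)
    w2 <- as.integer(round(2 * w_pos))
    pl <- sum(f[seq_len(w2 + 1L)]) / total
    pg <- sum(f[(w2 + 1L):length(f)]) / total
    p <- min(1, 2 * min(pl, pg))
    method <- "exact"
  } else {
    p <- 2 * stats::pnorm(-(abs(w_pos - mu) - 0.5) / sigma)
    p <- min(1, max(p, .Machine$double.xmin))
    method <- "normal-approximation"
  }
  tibble::tibble(
    n_pairs = length(x), n_used = m, w_signed_rank = w, z = z,
    p_value = p, effect_size_r = abs(z) / sqrt(m),
    significant = p < 0.05, method = method
  )
}

#' Paired-cohort comparison tables
#'
#' Builds the per-index comparison of two matched plan arms: for every index
#' column in `panels` it reports each arm's mean, SD and 95% CI
#' ([summarize_values()]), the Shapiro-Wilk normality battery per arm
#' ([shapiro_wilk()]), and the paired Wilcoxon signed-rank comparison
#' ([wilcoxon_signed_rank()]). Patients present in only one arm raise an
#' error listing their ids. Indices with missing values (e.g. GI without
#' isodose volumes) are compared on complete pairs.
#'
#' @param panels tibble with columns `patient_id`, `arm` (`IC_OFF` /
#'   `IC_ON`) and one numeric column per index.
#' @param indices character vector of index columns; default all numeric
#'   columns except the keys.
#' @return a tibble with one row per index: arm summaries (suffixes `_off`,
#'   `_on`), normality results (`w_off`, `p_norm_off`, `normal_off`,
#'   `skew_off`, ... and `_on`), and paired-test columns (`w_signed_rank`,
#'   `p_value`, `effect_size_r`, `significant`).
#' @export
build_comparison_tables <- function(panels, indices = NULL) {
  stopifnot(is.data.frame(panels), all(c("patient_id", "arm") %in% names(panels)))
  if (is.null(indices)) {
    indices <- names(panels)[vapply(panels, is.numeric, logical(1))]
    indices <- setdiff(indices, c("patient_id"))
  }
  off <- panels[panels$arm == "IC_OFF", , drop = FALSE]
  on <- panels[panels$arm == "IC_ON", , drop = FALSE]
  unpaired <- c(setdiff(off$patient_id, on$patient_id),
                setdiff(on$patient_id, off$patient_id))
  if (length(unpaired)) {
    stop(sprintf("unpaired patients in cohort: %s",
                 paste(sort(unique(unpaired)), collapse = ", ")), call. = FALSE)
  }
  off <- off[order(off$patient_id), , drop = FALSE]
  on <- on[order(on$patient_id), , drop = FALSE]

  rows <- lapply(indices, function(idx) {
    xo <- off[[idx]]
    xn <- on[[idx]]
    ok <- !is.na(xo) & !is.na(xn)
    xo <- xo[ok]
    xn <- xn[ok]
    so <- summarize_values(xo)
    sn <- summarize_values(xn)
    no <- shapiro_wilk(xo)
    nn <- shapiro_wilk(xn)
    wt <- tryCatch(wilcoxon_signed_rank(xo, xn), error = function(e) {
      tibble::tibble(n_pairs = length(xo), n_used = 0L, w_signed_rank = NA_real_,
                     z = NA_real_, p_value = NA_real_, effect_size_r = NA_real_,
                     significant = FALSE, method = "degenerate")
    })
    tibble::tibble(
      index = idx, n = so$n,
      mean_off = so$mean, sd_off = so$sd, ci_low_off = so$ci_low, ci_high_off = so$ci_high,
      mean_on = sn$mean, sd_on = sn$sd, ci_low_on = sn$ci_low, ci_high_on = sn$ci_high,
      w_off = no$w_stat, skew_off = no$skew, p_norm_off = no$p_value,
      normal_off = no$is_normal,
      w_on = nn$w_stat, skew_on = nn$skew, p_norm_on = nn$p_value,
      normal_on = nn$is_normal,
      w_critical = no$w_critical,
      w_signed_rank = wt$w_signed_rank, z = wt$z, p_value = wt$p_value,
      effect_size_r = wt$effect_size_r, significant = wt$significant,
      test_method = wt$method
    )
  })
  do.call(rbind, rows)
}

#' Render a comparison table as fixed-precision text
#'
#' Plain-text rendering of [build_comparison_tables()] output in the usual
#' journal layout: `mean +/- SD (95% CI)` per arm at 2 decimals and the
#' paired p-value at 4 decimals.
#'
#' @param comparison output of [build_comparison_tables()].
#' @return a character vector of lines.
#' @export
format_comparison_table <- function(comparison) {
  fmt_arm <- function(m, s, lo, hi) {
    sprintf("%.2f +/- %.2f (%.2f-%.2f)", m, s, lo, hi)
  }
  header <- sprintf("%-16s %-28s %-28s %8s", "Index", "IC-off", "IC-on", "p")
  body <- vapply(seq_len(nrow(comparison)), function(i) {
    r <- comparison[i, ]
    sprintf("%-16s %-28s %-28s %8.4f", r$index,
            fmt_arm(r$mean_off, r$sd_off, r$ci_low_off, r$ci_high_off),
            fmt_arm(r$mean_on, r$sd_on, r$ci_low_on, r$ci_high_on),
            r$p_value)
  }, character(1))
  c(header, strrep("-", nchar(header)), body)
}
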