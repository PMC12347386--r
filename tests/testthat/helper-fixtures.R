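# shared fixtures and independent oracles

two_bin_curve <- function() dvh_curve(c(0, 7, 8), c(1, 0.5, 0))

# random valid cumulative DVH: strictly increasing grid from 0, cum from 1
random_cum_curve <- function(seed, k = 8, residual = FALSE) {
  set.seed(seed)
  d <- c(0, cumsum(runif(k - 1, 0.2, 2)))
  drops <- runif(k - 1)
  v <- c(1, 1 - cumsum(drops) / sum(drops) * if (residual) runif(1, 0.5, 0.9) else 1)
  v <- pmax(v, 0)
  dvh_curve(d, v)
}

random_diff_dvh <- function(seed, k = 6, dose_range = c(2, 10)) {
  set.seed(seed)
  D <- sort(runif(k, dose_range[1], dose_range[2]))
  v <- runif(k)
  v <- v / sum(v)
  v <- v + (1 - sum(v)) / k # exact renormalisation
  dvh_diff(D, v / sum(v))
}

# sample with exact mean and SD (affine-adjusted normal quantile grid)
sample_with_moments <- function(n, mean, sd) {
  x <- qnorm(ppoints(n))
  x <- (x - base::mean(x)) / stats::sd(x)
  mean + sd * x
}

# brute-force exact two-sided signed-rank p over all 2^m sign assignments
brute_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  m <- length(d)
  rk <- rank(abs(d))
  w_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  w_all <- as.vector(signs %*% rk)
  pl <- mean(w_all <= w_obs + 1e-9)
  pg <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(pl, pg))
}

# independent scalar root-finder oracle for the LQ EUD
eud_root_oracle <- function(diff, alpha, alpha_beta, n_fractions = 1) {
  beta <- alpha / alpha_beta
  S <- sum(diff$partial_volume *
             exp(-alpha * diff$bin_dose - beta * diff$bin_dose^2 / n_fractions))
  f <- function(E) alpha * E + beta * E^2 / n_fractions + log(S)
  upper <- max(diff$bin_dose) * 2 + 10
  stats::uniroot(f, c(0, upper), tol = 1e-13)$root
}

# same oracle with the survival sum factored around its largest term, so it
# stays usable at doses where the naive sum underflows
eud_root_oracle_log <- function(diff, alpha, alpha_beta, n_fractions = 1) {
  beta <- alpha / alpha_beta
  expo <- log(diff$partial_volume) -
    alpha * diff$bin_dose - beta * diff$bin_dose^2 / n_fractions
  m <- max(expo)
  logS <- m + log(sum(exp(expo - m)))
  f <- function(E) alpha * E + beta * E^2 / n_fractions + logS
  stats::uniroot(f, c(0, max(diff$bin_dose) * 2 + 10), tol = 1e-10)$root
}

# calibration is the slow step; share one calibrated config across files
.cal_cache <- new.env(parent = emptyenv())
calibrated_default_config <- function(seed = 1) {
  key <- paste0("seed", seed)
  if (is.null(.cal_cache[[key]])) {
    .cal_cache[[key]] <- calibrate_cohort(cohort_config(seed = seed))$config
  }
  .cal_cache[[key]]
}
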