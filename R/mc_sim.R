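#' Configuration of the Monte Carlo resampling study
#'
#' The resampling study draws `n_samples` independent values per (index,
#' arm) from a normal distribution parameterized by the cohort mean and SD
#' of that index — the standard way of propagating cohort summary
#' uncertainty into full index distributions when patient-level data are
#' not available. Streams are seeded per (index, arm) from the master seed
#' via [stream_seed()], so adding indices never perturbs existing streams.
#'
#' @param baseline tibble with columns `index`, `arm`, `mean`, `sd`;
#'   default [ho_cohort_baseline()].
#' @param n_samples draws per distribution, default 10000.
#' @param seed master integer seed.
#' @param bin_width histogram bin width (index units); `NULL` (default)
#'   uses Sturges breaks.
#' @return a list of class `mc_config`.
#' @export
mc_config <- function(baseline = ho_cohort_baseline(), n_samples = 10000,
                      seed = 1, bin_width = NULL) {
  stopifnot(is.data.frame(baseline),
            all(c("index", "arm", "mean", "sd") %in% names(baseline)))
  if (n_samples < 1) stop("`n_samples` must be >= 1", call. = FALSE)
  bad <- baseline$index[is.na(baseline$mean) | is.na(baseline$sd)]
  if (length(bad)) {
    stop(sprintf("baseline incomplete for index: %s",
                 paste(unique(bad), collapse = ", ")), call. = FALSE)
  }
  if (any(baseline$sd < 0)) stop("baseline sd must be >= 0", call. = FALSE)
  structure(list(baseline = tibble::as_tibble(baseline),
                 n_samples = as.integer(n_samples), seed = as.integer(seed),
                 bin_width = bin_width),
            class = "mc_config")
}

#' Draw normal samples for one index
#'
#' `n` independent draws from `N(mean, sd^2)`; the same seed reproduces the
#' samples bit-for-bit. `sd = 0` returns the mean repeated.
#'
#' @param mean,sd distribution parameters (`sd >= 0`).
#' @param n number of draws.
#' @param seed integer seed for this stream.
#' @return numeric vector of length `n`.
#' @export
draw_index_samples <- function(mean, sd, n, seed) {
  stop_if_not_scalar_number(mean, "mean")
  stop_if_not_scalar_number(sd, "sd")
  if (sd < 0) stop("`sd` must be >= 0", call. = FALSE)
  set.seed(as.integer(seed))
  stats::rnorm(n, mean = mean, sd = sd)
}

#' Run the Monte Carlo resampling study
#'
#' One simulated distribution per (index, arm) row of the baseline:
#' samples, summary statistics ([summarize_values()]) and a histogram whose
#' counts sum to `n_samples`.
#'
#' @param config an [mc_config()].
#' @return a list of `mc_distribution` objects, each with fields `index`,
#'   `arm`, `samples`, `summary`, `breaks`, `counts`, `seed`.
#' @export
run_mc_study <- function(config) {
  stopifnot(inherits(config, "mc_config"))
  bl <- config$baseline
  lapply(seq_len(nrow(bl)), function(i) {
    row <- bl[i, ]
    s <- stream_seed(config$seed, "mc", row$index, row$arm)
    samples <- draw_index_samples(row$mean, row$sd, config$n_samples, s)
    if (is.null(config$bin_width)) {
      h <- graphics::hist(samples, breaks = "Sturges", plot = FALSE)
    } else {
      bw <- config$bin_width
      lo <- floor(min(samples) / bw) * bw
      hi <- ceiling(max(samples) / bw) * bw
      if (hi <= lo) hi <- lo + bw
      h <- graphics::hist(samples, breaks = seq(lo, hi, by = bw), plot = FALSE)
    }
    structure(
      list(index = row$index, arm = row$arm, samples = samples,
           summary = summarize_values(samples),
           breaks = h$breaks, counts = h$counts, seed = s),
      class = "mc_distribution"
    )
  })
}

#' @export
print.mc_distribution <- function(x, ...) {
  cat(sprintf("<mc_distribution> %s / %s: n = %d, mean %.4g, sd %.4g\n",
              x$index, x$arm, length(x$samples), x$summary$mean, x$summary$sd))
  invisible(x)
}

#' Fraction of simulated values below a threshold
#'
#' The proportion of Monte Carlo draws strictly below `threshold` — e.g.
#' the simulated probability that an index falls short of the 7 Gy
#' prophylactic dose goal.
#'
#' @param dist an `mc_distribution` (or plain numeric vector).
#' @param threshold finite numeric threshold.
#' @return proportion in `[0, 1]`.
#' @export
fraction_below <- function(dist, threshold) {
  stop_if_not_scalar_number(threshold, "threshold")
  samples <- if (inherits(dist, "mc_distribution")) dist$samples else as.numeric(dist)
  mean(samples < threshold)
}

#' Tabulate a Monte Carlo study
#'
#' @param dists list returned by [run_mc_study()].
#' @return a tibble with one row per distribution: `index, arm, n, mean,
#'   sd, ci_low, ci_high`.
#' @export
mc_summary_table <- function(dists) {
  rows <- lapply(dists, function(d) {
    tibble::tibble(index = d$index, arm = d$arm, n = d$summary$n,
                   mean = d$summary$mean, sd = d$summary$sd,
                   ci_low = d$summary$ci_low, ci_high = d$summary$ci_high)
  })
  do.call(rbind, rows)
}

#' Export Monte Carlo histograms as a long table
#'
#' @param dists list returned by [run_mc_study()].
#' @return a tibble `index, arm, bin_low, bin_high, count` (counts per
#'   distribution sum to the number of draws).
#' @export
mc_histogram_table <- function(dists) {
  rows <- lapply(dists, function(d) {
    k <- length(d$counts)
    tibble::tibble(index = d$index, arm = d$arm,
                   bin_low = d$breaks[seq_len(k)],
                   bin_high = d$breaks[seq_len(k) + 1L],
                   count = d$counts)
  })
  do.call(rbind, rows)
}
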