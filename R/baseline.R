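#' Reference cohort summaries for hip HO prophylaxis plans
#'
#' Per-index, per-arm mean and SD from a published 21-patient paired cohort
#' of single-fraction (7 Gy) prophylactic hip irradiation plans, evaluated
#' with the dose engine's inhomogeneity correction off (`IC_OFF`,
#' water-equivalent density) and on (`IC_ON`). These summaries serve two
#' roles in the package: they are the default baseline that parameterizes
#' the Monte Carlo resampling study ([run_mc_study()]), and the calibration
#' targets of the synthetic cohort generator ([calibrate_cohort()]).
#'
#' The 14 indices are the dosimetric panel (`D2`, `D50`, `D90`, `D95`,
#' `D98` in Gy; `HI`, `GI` dimensionless) and the radiobiological panel
#' (`gEUD`, `EUD_LQ_ab3`, `EUD_LQ_ab10` and the four EQD2 conversions, all
#' in Gy).
#'
#' @return a tibble with columns `index`, `arm`, `mean`, `sd` (28 rows).
#' @export
#' @examples
#' ho_cohort_baseline()
ho_cohort_baseline <- function() {
  idx <- c("D2", "D50", "D90", "D95", "D98", "HI", "GI",
           "gEUD", "EUD_LQ_ab3", "EUD_LQ_ab10",
           "EQD2_ab3_gEUD", "EQD2_ab10_gEUD", "EQD2_ab3_LQ", "EQD2_ab10_LQ")
  off_mean <- c(7.30, 7.08, 6.80, 6.72, 6.60, 0.10, 1.58,
                7.02, 7.01, 7.00, 14.07, 9.96, 14.05, 9.92)
  off_sd <- c(0.22, 0.10, 0.14, 0.18, 0.22, 0.05, 0.60,
              0.09, 0.09, 0.09, 0.31, 0.18, 0.31, 0.19)
  on_mean <- c(7.31, 6.87, 6.38, 6.20, 6.07, 0.18, 2.84,
               6.80, 6.79, 6.75, 13.35, 9.53, 13.30, 9.44)
  on_sd <- c(0.16, 0.19, 0.32, 0.38, 0.39, 0.05, 1.32,
             0.21, 0.21, 0.23, 0.70, 0.41, 0.71, 0.45)
  tibble::tibble(
    index = rep(idx, 2),
    arm = rep(c("IC_OFF", "IC_ON"), each = length(idx)),
    mean = c(off_mean, on_mean),
    sd = c(off_sd, on_sd)
  )
}
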