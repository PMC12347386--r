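#' Radiobiological model parameters
#'
#' Bundles the parameters of the EUD/EQD2 models: the gEUD volume-effect
#' exponent `a` (a = 1 gives the arithmetic mean dose), the linear-quadratic
#' sensitivity `alpha` (Gy^-1), the `alpha/beta` ratio (Gy; ~3 for
#' late-responding, ~10 for early-responding tissue), and the fraction
#' number `n_fractions`. `beta` is derived as `alpha / alpha_beta`.
#'
#' The absolute `alpha` only matters for heterogeneous dose distributions:
#' for a uniform DVH the LQ EUD equals the delivered dose for every
#' admissible `(alpha, beta, n)`. The default 0.3 Gy^-1 is a conventional
#' soft-tissue value.
#'
#' @param a gEUD exponent, non-zero; default 1.
#' @param alpha LQ alpha in Gy^-1, positive; default 0.3.
#' @param alpha_beta alpha/beta ratio in Gy, positive.
#' @param n_fractions number of fractions, >= 1; default 1.
#' @return a list of class `radiobio_params`.
#' @export
radiobio_params <- function(a = 1, alpha = 0.3, alpha_beta = 3, n_fractions = 1) {
  if (a == 0) stop("`a` must be non-zero", call. = FALSE)
  if (alpha <= 0) stop("`alpha` must be positive", call. = FALSE)
  if (alpha_beta <= 0) stop("`alpha_beta` must be positive", call. = FALSE)
  if (n_fractions < 1) stop("`n_fractions` must be >= 1", call. = FALSE)
  structure(list(a = a, alpha = alpha, alpha_beta = alpha_beta,
                 beta = alpha / alpha_beta, n_fractions = n_fractions),
            class = "radiobio_params")
}

#' Generalized equivalent uniform dose (gEUD)
#'
#' The weighted power mean of order `a` of the differential DVH,
#' `gEUD = (sum_i v_i D_i^a)^(1/a)`. For `a = 1` this is exactly the mean
#' dose; large positive `a` emphasizes hot spots (serial tissue), large
#' negative `a` cold spots (tumor coverage).
#'
#' @param diff a [dvh_diff()].
#' @param a non-zero exponent.
#' @return gEUD in Gy.
#' @export
#' @examples
#' geud(dvh_diff(c(6, 8), c(0.5, 0.5)), a = 1) # 7
#' geud(dvh_diff(c(6, 8), c(0.5, 0.5)), a = 2) # sqrt(50)
geud <- function(diff, a = 1) {
  stopifnot(inherits(diff, "dvh_diff"))
  stop_if_not_scalar_number(a, "a")
  if (a == 0) stop("`a` must be non-zero", call. = FALSE)
  D <- diff$bin_dose
  v <- diff$partial_volume
  if (any(D < 0)) stop("negative bin dose", call. = FALSE)
  keep <- v > 0
  D <- D[keep]
  v <- v[keep]
  if (a == 1) return(sum(v * D))
  if (any(D == 0) && a < 0) return(0) # cold-spot limit of the power mean
  M <- max(D)
  if (M == 0) return(0)
  M * sum(v * (D / M)^a)^(1 / a)
}

#' Linear-quadratic equivalent uniform dose
#'
#' The uniform dose that yields the same LQ clonogen survival as the
#' heterogeneous distribution. With survival fraction
#' `S = sum_i v_i exp(-alpha D_i - beta D_i^2 / n)`, the EUD is the
#' non-negative root of `alpha E + (beta / n) E^2 = -log S`, evaluated in
#' closed form as `E = 2 L / (sqrt(alpha^2 + 4 beta L / n) + alpha)` with
#' `L = -log S`. The survival sum is accumulated in the log domain, so the
#' result stays finite at large doses whenever any partial volume is
#' positive. A uniform DVH at dose D returns exactly D.
#'
#' @param diff a [dvh_diff()].
#' @param params a [radiobio_params()].
#' @return EUD in Gy.
#' @export
eud_lq <- function(diff, params) {
  stopifnot(inherits(diff, "dvh_diff"), inherits(params, "radiobio_params"))
  D <- diff$bin_dose
  v <- diff$partial_volume
  if (any(D < 0)) stop("negative bin dose", call. = FALSE)
  keep <- v > 0
  D <- D[keep]
  v <- v[keep]
  al <- params$alpha
  be <- params$beta
  n <- params$n_fractions
  log_surv <- log_sum_exp(log(v) - al * D - be * D^2 / n)
  L <- -log_surv
  if (L <= 0) return(0) # all dose bins at 0 Gy
  2 * L / (sqrt(al^2 + 4 * be * L / n) + al)
}

#' Equivalent dose in 2 Gy fractions (EQD2)
#'
#' Standard LQ isoeffect conversion
#' `EQD2 = D * (d + alpha/beta) / (2 + alpha/beta)` for total dose `D`
#' delivered at `d` Gy per fraction. `d = 2` is a fixed point.
#'
#' @param total_dose_gy total physical (or equivalent uniform) dose, Gy.
#' @param dose_per_fraction_gy dose per fraction, Gy.
#' @param alpha_beta alpha/beta ratio, Gy.
#' @return EQD2 in Gy.
#' @export
#' @examples
#' eqd2(7.02, 7.02, 3)  # 14.07
#' eqd2(7.02, 7.02, 10) # 9.96
eqd2 <- function(total_dose_gy, dose_per_fraction_gy, alpha_beta) {
  stop_if_not_scalar_number(total_dose_gy, "total_dose_gy")
  stop_if_not_scalar_number(dose_per_fraction_gy, "dose_per_fraction_gy")
  stop_if_not_scalar_number(alpha_beta, "alpha_beta")
  if (total_dose_gy <= 0 || dose_per_fraction_gy <= 0 || alpha_beta <= 0) {
    stop("all arguments must be positive", call. = FALSE)
  }
  total_dose_gy * (dose_per_fraction_gy + alpha_beta) / (2 + alpha_beta)
}

#' Radiobiological index panel for one plan
#'
#' Computes, from the plan's target DVH: gEUD (exponent `a`), the LQ EUD at
#' each `alpha/beta` scenario, and the EQD2 of each EUD. The dose per
#' fraction entering each EQD2 conversion is the corresponding EUD divided
#' by the number of fractions (a single 7 Gy fraction gives d = EUD).
#'
#' @param plan a [plan_record()].
#' @param a gEUD exponent, default 1 (mean dose).
#' @param alpha LQ alpha, Gy^-1, default 0.3.
#' @param alpha_beta alpha/beta scenarios in Gy, default `c(3, 10)`.
#' @return a one-row tibble with columns `patient_id, arm, geud,
#'   eud_lq_ab3, eud_lq_ab10, eqd2_ab3_geud, eqd2_ab10_geud, eqd2_ab3_lq,
#'   eqd2_ab10_lq` (column suffixes follow the supplied scenarios).
#' @export
compute_radbio_panel <- function(plan, a = 1, alpha = 0.3, alpha_beta = c(3, 10)) {
  stopifnot(inherits(plan, "plan_record"))
  diff <- cumulative_to_differential(plan$target_dvh)
  nfx <- plan$n_fractions
  g <- geud(diff, a = a)
  out <- tibble::tibble(patient_id = plan$patient_id, arm = plan$arm, geud = g)
  for (ab in alpha_beta) {
    e <- eud_lq(diff, radiobio_params(a = a, alpha = alpha, alpha_beta = ab,
                                      n_fractions = nfx))
    out[[sprintf("eud_lq_ab%g", ab)]] <- e
  }
  for (ab in alpha_beta) {
    out[[sprintf("eqd2_ab%g_geud", ab)]] <- eqd2(g, g / nfx, ab)
  }
  for (ab in alpha_beta) {
    e <- out[[sprintf("eud_lq_ab%g", ab)]]
    out[[sprintf("eqd2_ab%g_lq", ab)]] <- eqd2(e, e / nfx, ab)
  }
  out
}
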