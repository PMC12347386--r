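#' Dose covering the hottest q% of the volume (D_q%)
#'
#' Reads the coverage dose off the cumulative DVH: the dose at which the
#' cumulative volume first falls to `q`% of the structure, linearly
#' interpolated between grid points. On flat segments the lowest dose
#' achieving the volume is returned. If the curve ends with residual volume
#' above `q`% (the hottest q% all sits at or beyond the last grid dose),
#' the maximum recorded dose is returned.
#'
#' @param curve a [dvh_curve()].
#' @param q volume percentage in (0, 100].
#' @return dose in Gy.
#' @export
#' @examples
#' cv <- dvh_curve(c(0, 7, 8), c(1, 0.5, 0))
#' dose_at_volume(cv, 50) # 7
#' dose_at_volume(cv, 2)  # 7.96
dose_at_volume <- function(curve, q) {
  stop_if_not_scalar_number(q, "q")
  if (q <= 0 || q > 100) stop("`q` must be in (0, 100]", call. = FALSE)
  curve <- validate_dvh_curve(curve)
  d <- curve$dose_gy
  v <- curve$cum_volume
  qf <- q / 100
  idx <- which(v <= qf)
  if (!length(idx)) return(d[length(d)]) # residual volume exceeds q%
  i <- idx[1]
  if (i == 1L) return(d[1])
  if (v[i - 1L] == v[i]) return(d[i]) # defensive; cummin makes this rare
  d[i - 1L] + (v[i - 1L] - qf) / (v[i - 1L] - v[i]) * (d[i] - d[i - 1L])
}

#' ICRU 83 homogeneity index
#'
#' `HI = (D2% - D98%) / D50%`: the near-maximum to near-minimum dose spread
#' normalized by the median dose. 0 for a perfectly uniform target dose;
#' larger values mean more internal dose variability.
#'
#' @param d2,d98,d50 coverage doses in Gy, with `d50 > 0` and `d2 >= d98`.
#' @return dimensionless HI.
#' @export
#' @examples
#' homogeneity_index(7.30, 6.60, 7.08) # ~0.10
homogeneity_index <- function(d2, d98, d50) {
  stop_if_not_scalar_number(d2, "d2")
  stop_if_not_scalar_number(d98, "d98")
  stop_if_not_scalar_number(d50, "d50")
  if (d50 <= 0) stop("`d50` must be positive", call. = FALSE)
  if (d2 < d98) stop("`d2` must be >= `d98`", call. = FALSE)
  (d2 - d98) / d50
}

#' ICRU 91 gradient index
#'
#' `GI = V50% / V100%`: the ratio of the volume enclosed by the 50%
#' prescription isodose to that enclosed by the 100% isodose. Values close
#' to 1 indicate a steep dose fall-off around the target.
#'
#' @param v50,v100 isodose volumes in cc, `v100 > 0`.
#' @return dimensionless GI.
#' @export
gradient_index <- function(v50, v100) {
  stop_if_not_scalar_number(v50, "v50")
  stop_if_not_scalar_number(v100, "v100")
  if (v100 <= 0) stop("`v100` must be positive", call. = FALSE)
  v50 / v100
}

#' Dosimetric index panel for one plan
#'
#' Computes the coverage doses D2%, D50%, D90%, D95%, D98% from the target
#' DVH, the homogeneity index from D2/D98/D50, and the gradient index from
#' the plan's isodose volumes (`NA` when the volumes are absent).
#'
#' @param plan a [plan_record()].
#' @return a one-row tibble with columns `patient_id, arm, d2, d50, d90,
#'   d95, d98, hi, gi`.
#' @export
compute_dosimetric_panel <- function(plan) {
  stopifnot(inherits(plan, "plan_record"))
  cv <- plan$target_dvh
  d2 <- dose_at_volume(cv, 2)
  d50 <- dose_at_volume(cv, 50)
  d90 <- dose_at_volume(cv, 90)
  d95 <- dose_at_volume(cv, 95)
  d98 <- dose_at_volume(cv, 98)
  gi <- if (!is.na(plan$v50_cc) && !is.na(plan$v100_cc)) {
    gradient_index(plan$v50_cc, plan$v100_cc)
  } else {
    NA_real_
  }
  tibble::tibble(
    patient_id = plan$patient_id, arm = plan$arm,
    d2 = d2, d50 = d50, d90 = d90, d95 = d95, d98 = d98,
    hi = homogeneity_index(d2, d98, d50), gi = gi
  )
}
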