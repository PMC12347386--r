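#' Cumulative dose-volume histogram for one structure
#'
#' A cumulative DVH gives, for each dose level, the fraction of the structure
#' volume receiving at least that dose. Curves are stored on a strictly
#' increasing dose grid starting at 0 Gy with `cum_volume[1] = 1`; volumes
#' supplied in percent (detected when the maximum exceeds 1.5 under
#' `volume_unit = "auto"`) are rescaled to fractions. A curve whose grid does
#' not start at 0 Gy is extended with a leading point at (0 Gy, 1).
#'
#' @param dose_gy numeric vector of doses, Gy, strictly increasing.
#' @param volume numeric vector of cumulative volumes, fraction of total
#'   volume (or percent, see `volume_unit`), non-increasing.
#' @param structure label of the contoured structure.
#' @param total_volume_cc optional absolute structure volume in cc.
#' @param volume_unit `"auto"` (default), `"fraction"` or `"percent"`.
#' @return an object of class `dvh_curve` with fields `structure`,
#'   `dose_gy`, `cum_volume`, `total_volume_cc`.
#' @export
#' @examples
#' dvh_curve(c(0, 7, 8), c(100, 50, 0)) # percent auto-detected
dvh_curve <- function(dose_gy, volume, structure = "target",
                      total_volume_cc = NULL,
                      volume_unit = c("auto", "fraction", "percent")) {
  volume_unit <- match.arg(volume_unit)
  if (length(dose_gy) != length(volume) || !length(dose_gy)) {
    stop("`dose_gy` and `volume` must be non-empty vectors of equal length",
         call. = FALSE)
  }
  if (anyNA(dose_gy) || anyNA(volume)) stop("DVH contains missing values", call. = FALSE)
  if (volume_unit == "percent" ||
      (volume_unit == "auto" && max(volume) > 1.5)) {
    volume <- volume / 100
  }
  if (dose_gy[1] > 0) {
    dose_gy <- c(0, dose_gy)
    volume <- c(1, volume)
  }
  x <- structure(
    list(structure = structure, dose_gy = as.numeric(dose_gy),
         cum_volume = as.numeric(volume),
         total_volume_cc = total_volume_cc),
    class = "dvh_curve"
  )
  validate_dvh_curve(x)
}

#' Validate a cumulative DVH curve
#'
#' Checks the `dvh_curve` invariants: strictly increasing dose grid starting
#' at 0 Gy, `cum_volume[1] = 1`, non-increasing cumulative volume (increases
#' up to `tol` are clamped; larger increases raise an error naming the row),
#' and a non-negative final volume.
#'
#' @param x a `dvh_curve`.
#' @param tol tolerance for cumulative-volume increases, default `1e-6`.
#' @return `x`, invisibly cleaned (tiny increases clamped).
#' @export
validate_dvh_curve <- function(x, tol = 1e-6) {
  d <- x$dose_gy
  v <- x$cum_volume
  if (d[1] != 0) stop("dose grid must start at 0 Gy", call. = FALSE)
  dd <- diff(d)
  if (any(dd <= 0)) {
    row <- which(dd <= 0)[1] + 1L
    stop(sprintf("non-monotone dose grid at row %d (dose %.6g after %.6g)",
                 row, d[row], d[row - 1L]), call. = FALSE)
  }
  if (abs(v[1] - 1) > tol) {
    stop(sprintf("cum_volume[1] must be 1, got %.6g", v[1]), call. = FALSE)
  }
  v[1] <- 1
  dv <- diff(v)
  if (any(dv > tol)) {
    row <- which(dv > tol)[1] + 1L
    stop(sprintf(
      "cumulative volume increases at row %d (%.6g -> %.6g); not a cumulative DVH",
      row, v[row - 1L], v[row]), call. = FALSE)
  }
  v <- cummin(v) # clamp sub-tolerance wiggles
  if (v[length(v)] < 0) stop("negative cumulative volume", call. = FALSE)
  x$cum_volume <- v
  invisible(x)
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat(sprintf("<dvh_curve> %s: %d grid points, 0-%.3g Gy, residual volume %.3g\n",
              x$structure, length(x$dose_gy), max(x$dose_gy),
              x$cum_volume[length(x$cum_volume)]))
  invisible(x)
}

#' Differential dose-volume histogram
#'
#' Bins `(bin_dose[i], partial_volume[i])` where `partial_volume[i]` is the
#' fraction of the structure receiving approximately `bin_dose[i]`; partial
#' volumes are non-negative and sum to 1 (within 1e-9). This is the substrate
#' of the gEUD power mean and the LQ cell-survival EUD.
#'
#' @param bin_dose numeric, Gy, non-decreasing bin centers.
#' @param partial_volume numeric, non-negative, summing to 1.
#' @return an object of class `dvh_diff`.
#' @export
dvh_diff <- function(bin_dose, partial_volume) {
  if (length(bin_dose) != length(partial_volume) || !length(bin_dose)) {
    stop("`bin_dose` and `partial_volume` must be non-empty and equal length",
         call. = FALSE)
  }
  if (any(partial_volume < 0)) stop("negative partial volume", call. = FALSE)
  if (any(diff(bin_dose) < 0)) stop("bin_dose must be non-decreasing", call. = FALSE)
  if (abs(sum(partial_volume) - 1) > 1e-9) {
    stop(sprintf("partial volumes sum to %.12g, expected 1", sum(partial_volume)),
         call. = FALSE)
  }
  structure(list(bin_dose = as.numeric(bin_dose),
                 partial_volume = as.numeric(partial_volume)),
            class = "dvh_diff")
}

#' @export
print.dvh_diff <- function(x, ...) {
  cat(sprintf("<dvh_diff> %d bins, %.3g-%.3g Gy\n", length(x$bin_dose),
              min(x$bin_dose), max(x$bin_dose)))
  invisible(x)
}

#' Convert a cumulative DVH to differential form
#'
#' Differences consecutive cumulative volumes: bin `i` carries
#' `cum_volume[i] - cum_volume[i+1]` at the midpoint of the bracketing grid
#' doses. Residual volume still present at the last grid point is absorbed
#' into a terminal point-mass bin at that dose, so partial volumes always sum
#' to exactly 1. Zero-weight interior bins are dropped.
#'
#' @param curve a `dvh_curve`.
#' @return a `dvh_diff`.
#' @export
#' @examples
#' cumulative_to_differential(dvh_curve(c(0, 7, 8), c(1, 0.5, 0)))
cumulative_to_differential <- function(curve) {
  curve <- validate_dvh_curve(curve)
  d <- curve$dose_gy
  v <- curve$cum_volume
  m <- length(d)
  if (m == 1L) return(dvh_diff(d, 1)) # all volume at the single grid dose
  w <- v[-m] - v[-1]
  mid <- (d[-m] + d[-1]) / 2
  keep <- w > 0
  bins_d <- mid[keep]
  bins_w <- w[keep]
  resid <- v[m]
  if (resid > 1e-12) {
    bins_d <- c(bins_d, d[m])
    bins_w <- c(bins_w, resid)
  }
  if (!length(bins_d)) { # fully degenerate: all volume below first positive dose
    bins_d <- d[m]
    bins_w <- 1
  }
  ## renormalise away accumulated rounding so the sum is exactly 1
  bins_w <- bins_w / sum(bins_w)
  dvh_diff(bins_d, bins_w)
}

#' Convert a differential DVH to cumulative form
#'
#' Reconstructs the bin edges by the midpoint-inverse recursion
#' `e[i+1] = 2 * bin_dose[i] - e[i]` starting from `e[1] = 0`, and sets the
#' cumulative volume at each edge to the tail sum of the partial volumes.
#' A bin whose dose coincides with the current edge is treated as a terminal
#' point mass (the residual volume at the last edge). This makes the
#' conversion the exact inverse of [cumulative_to_differential()] on any
#' cumulative curve whose grid starts at 0 Gy.
#'
#' @param diff a `dvh_diff`.
#' @return a `dvh_curve`.
#' @export
#' @examples
#' differential_to_cumulative(dvh_diff(c(3.5, 7.5), c(0.5, 0.5)))
differential_to_cumulative <- function(diff) {
  D <- diff$bin_dose
  w <- diff$partial_volume
  k <- length(D)
  edges <- 0
  cum <- 1
  e <- 0
  remaining <- 1
  for (i in seq_len(k)) {
    if (D[i] <= e + 1e-12) {
      ## point mass sitting on the current edge: only valid as terminal bin
      if (i != k) {
        stop(sprintf(
          "bin %d (dose %.6g) is inconsistent with reconstructed edge %.6g",
          i, D[i], e), call. = FALSE)
      }
      break
    }
    e_next <- 2 * D[i] - e
    remaining <- remaining - w[i]
    edges <- c(edges, e_next)
    cum <- c(cum, max(remaining, 0))
    e <- e_next
  }
  out <- structure(
    list(structure = "target", dose_gy = edges, cum_volume = cum,
         total_volume_cc = NULL),
    class = "dvh_curve"
  )
  validate_dvh_curve(out, tol = 1e-9)
}

## ---------------------------------------------------------------------------
## text dialect: optional '# structure: NAME' block headers, a 'dose_gy<sep>volume'
## header line, then two numeric columns (separator auto-detected among
## tab/comma/whitespace). Volumes in percent are auto-detected per curve.

#' Read DVH curves from a plain-text table
#'
#' Parses the package's two-column text dialect: an optional
#' `# structure: NAME` line per block, a header line, then `dose, volume`
#' rows (tab, comma or whitespace separated). Volume columns whose maximum
#' exceeds 1.5 are interpreted as percent and rescaled to fractions; curves
#' not starting at 0 Gy are extended with full volume at 0 Gy. Errors name
#' the offending file row.
#'
#' @param path path to the text file.
#' @param sep column separator, or `"auto"` (default) to detect.
#' @return a list of [dvh_curve()] objects.
#' @export
read_dvh_file <- function(path, sep = "auto") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop(sprintf("empty DVH file: %s", path), call. = FALSE)

  blocks <- list()
  cur_label <- NULL
  cur_rows <- integer(0)
  flush <- function() {
    if (length(cur_rows)) {
      blocks[[length(blocks) + 1L]] <<- list(label = cur_label, rows = cur_rows)
    }
    cur_rows <<- integer(0)
  }
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line)) next
    if (startsWith(line, "#")) {
      m <- regmatches(line, regexec("^#\\s*structure\\s*:\\s*(.+)$", line))[[1]]
      if (length(m) == 2L) {
        flush()
        cur_label <- trimws(m[2])
      }
      next
    }
    cur_rows <- c(cur_rows, i)
  }
  flush()
  if (!length(blocks)) stop(sprintf("no data rows in %s", path), call. = FALSE)

  parse_block <- function(block, idx) {
    label <- block$label %||% if (length(blocks) == 1L) "target" else
      sprintf("structure_%d", idx)
    rows <- block$rows
    first <- lines[rows[1]]
    use_sep <- sep
    if (use_sep == "auto") {
      use_sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else "[[:space:]]+"
    }
    split_row <- function(line) {
      parts <- strsplit(trimws(line), use_sep)[[1]]
      parts[nzchar(parts)]
    }
    ## header row is any first row that does not parse as two numbers
    first_parts <- suppressWarnings(as.numeric(split_row(first)))
    data_rows <- if (anyNA(first_parts)) rows[-1] else rows
    if (!length(data_rows)) stop(sprintf("no data rows in %s", path), call. = FALSE)
    dose <- numeric(length(data_rows))
    vol <- numeric(length(data_rows))
    for (j in seq_along(data_rows)) {
      parts <- suppressWarnings(as.numeric(split_row(lines[data_rows[j]])))
      if (length(parts) < 2L || anyNA(parts[1:2])) {
        stop(sprintf("cannot parse row %d of %s as (dose, volume)",
                     data_rows[j], path), call. = FALSE)
      }
      dose[j] <- parts[1]
      vol[j] <- parts[2]
    }
    dd <- diff(dose)
    if (any(dd <= 0)) {
      bad <- data_rows[which(dd <= 0)[1] + 1L]
      stop(sprintf("non-monotone dose grid at row %d of %s", bad, path),
           call. = FALSE)
    }
    is_percent <- max(vol) > 1.5
    frac <- if (is_percent) vol / 100 else vol
    dv <- diff(frac)
    if (any(dv > 1e-6)) {
      bad <- data_rows[which(dv > 1e-6)[1] + 1L]
      stop(sprintf("cumulative volume increases at row %d of %s", bad, path),
           call. = FALSE)
    }
    dvh_curve(dose, frac, structure = label, volume_unit = "fraction")
  }
  lapply(seq_along(blocks), function(i) parse_block(blocks[[i]], i))
}

#' Write DVH curves to the package text dialect
#'
#' Volumes are written as fractions at 17 significant digits so that
#' [read_dvh_file()] reproduces the curve bit-for-bit on the same grid.
#'
#' @param curves a `dvh_curve` or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dvh_file <- function(curves, path) {
  if (inherits(curves, "dvh_curve")) curves <- list(curves)
  out <- character(0)
  for (cv in curves) {
    out <- c(out,
             sprintf("# structure: %s", cv$structure),
             "dose_gy\tvolume",
             sprintf("%.17g\t%.17g", cv$dose_gy, cv$cum_volume))
  }
  writeLines(out, path)
  invisible(path)
}

#' Treatment-plan record
#'
#' One evaluated plan: a patient id, the plan arm (`IC_OFF` for the
#' homogeneous, water-equivalent density calculation or `IC_ON` for the
#' inhomogeneity-corrected recalculation), the prescription (default a
#' single 7 Gy fraction), the target cumulative DVH, and the absolute
#' volumes enclosed by the 100% and 50% prescription isodoses (needed for
#' the gradient index; may be `NA`).
#'
#' @param patient_id patient identifier.
#' @param arm `"IC_OFF"` or `"IC_ON"`.
#' @param target_dvh a [dvh_curve()].
#' @param prescription_dose_gy prescription dose in Gy, default 7.
#' @param n_fractions number of fractions, default 1.
#' @param v100_cc,v50_cc volumes of the 100% / 50% isodose, cc (optional).
#' @return an object of class `plan_record`.
#' @export
plan_record <- function(patient_id, arm, target_dvh,
                        prescription_dose_gy = 7, n_fractions = 1,
                        v100_cc = NA_real_, v50_cc = NA_real_) {
  arm <- match.arg(arm, c("IC_OFF", "IC_ON"))
  stopifnot(inherits(target_dvh, "dvh_curve"))
  if (n_fractions < 1) stop("n_fractions must be >= 1", call. = FALSE)
  if (!is.na(v100_cc) && !is.na(v50_cc)) {
    if (!(v100_cc > 0)) stop("v100_cc must be positive", call. = FALSE)
    if (v50_cc < v100_cc) {
      stop("v50_cc must be >= v100_cc (the 50% isodose encloses the 100%)",
           call. = FALSE)
    }
  }
  structure(
    list(patient_id = as.character(patient_id), arm = arm,
         prescription_dose_gy = prescription_dose_gy,
         n_fractions = as.integer(n_fractions),
         target_dvh = validate_dvh_curve(target_dvh),
         v100_cc = as.numeric(v100_cc), v50_cc = as.numeric(v50_cc)),
    class = "plan_record"
  )
}

#' @export
print.plan_record <- function(x, ...) {
  cat(sprintf("<plan_record> patient %s, %s, %g Gy x %d\n", x$patient_id,
              x$arm, x$prescription_dose_gy, x$n_fractions))
  invisible(x)
}

#' Read or write a paired-cohort manifest
#'
#' The manifest is a CSV with one row per patient mapping the patient id to
#' the IC-off and IC-on DVH files and their isodose volumes: columns
#' `patient_id, ic_off_path, ic_on_path, ic_off_v100_cc, ic_off_v50_cc,
#' ic_on_v100_cc, ic_on_v50_cc`. Paths are interpreted relative to the
#' manifest's directory.
#'
#' @param path manifest CSV path.
#' @return `read_cohort_manifest`: a tibble; `load_cohort`: a list of
#'   [plan_record()]s (two per patient).
#' @export
read_cohort_manifest <- function(path) {
  if (!file.exists(path)) stop(sprintf("manifest not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "ic_off_path", "ic_on_path", "ic_off_v100_cc",
            "ic_off_v50_cc", "ic_on_v100_cc", "ic_on_v50_cc")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop(sprintf("manifest missing columns: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' @rdname read_cohort_manifest
#' @export
load_cohort <- function(path) {
  manifest <- read_cohort_manifest(path)
  base <- dirname(path)
  plans <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    for (arm in c("IC_OFF", "IC_ON")) {
      pre <- if (arm == "IC_OFF") "ic_off" else "ic_on"
      fp <- file.path(base, row[[paste0(pre, "_path")]])
      curves <- read_dvh_file(fp)
      plans[[length(plans) + 1L]] <- plan_record(
        patient_id = row$patient_id, arm = arm, target_dvh = curves[[1]],
        v100_cc = row[[paste0(pre, "_v100_cc")]],
        v50_cc = row[[paste0(pre, "_v50_cc")]]
      )
    }
  }
  plans
}
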