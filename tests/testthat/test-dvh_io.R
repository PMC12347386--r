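test_that("reading a DVH file rescales percent volumes and validates monotonicity", {
  f <- withr::local_tempfile(fileext = ".dvh")
  writeLines(c("dose_gy,volume", "0,100", "7,50", "8,0"), f)
  curves <- read_dvh_file(f)
  expect_length(curves, 1)
  expect_equal(curves[[1]]$cum_volume, c(1, 0.5, 0))
  expect_equal(curves[[1]]$dose_gy, c(0, 7, 8))

  # degenerate single-row curve: all volume at >= 0 Gy
  writeLines(c("0,100"), f)
  cv <- read_dvh_file(f)[[1]]
  expect_equal(cv$cum_volume, 1)

  # non-monotone dose grid names the offending file row
  writeLines(c("0,100", "5,60", "4,70"), f)
  expect_error(read_dvh_file(f), "row 3")

  # increasing cumulative volume names the offending file row
  writeLines(c("dose_gy\tvolume", "0\t100", "5\t60", "6\t70"), f)
  expect_error(read_dvh_file(f), "row 4")
})

test_that("curve constructor extends to 0 Gy and rejects invalid inputs", {
  cv <- dvh_curve(c(1, 7), c(100, 50))
  expect_equal(cv$dose_gy[1], 0)
  expect_equal(cv$cum_volume[1], 1)
  expect_error(dvh_curve(c(0, 5, 5), c(1, 0.5, 0.2)), "non-monotone")
  expect_error(dvh_curve(c(0, 5, 6), c(1, 0.5, 0.7)), "increases")
})

test_that("cumulative-to-differential uses midpoint bins and a terminal residual bin", {
  d <- cumulative_to_differential(two_bin_curve())
  expect_equal(d$bin_dose, c(3.5, 7.5))
  expect_equal(d$partial_volume, c(0.5, 0.5))
  expect_equal(sum(d$partial_volume), 1)

  # uniform box: one effective bin of weight ~1 near 7 Gy
  box <- dvh_curve(c(0, 7, 7.01), c(1, 1, 0))
  db <- cumulative_to_differential(box)
  expect_equal(sum(db$partial_volume), 1)
  expect_equal(db$bin_dose[which.max(db$partial_volume)], 7.005)
  expect_gt(max(db$partial_volume), 0.999)

  # residual volume at the last grid point becomes a terminal point mass
  res <- dvh_curve(c(0, 7, 8), c(1, 0.5, 0.2))
  dr <- cumulative_to_differential(res)
  expect_equal(dr$bin_dose, c(3.5, 7.5, 8))
  expect_equal(dr$partial_volume, c(0.5, 0.3, 0.2))
})

test_that("differential-to-cumulative reconstructs tail sums on recovered edges", {
  cv <- differential_to_cumulative(dvh_diff(c(3.5, 7.5), c(0.5, 0.5)))
  expect_equal(cv$dose_gy, c(0, 7, 8))
  expect_equal(cv$cum_volume, c(1, 0.5, 0))
})

test_that("round trips conserve volume and invert each other within 1e-9", {
  for (seed in 1:15) {
    cv <- random_cum_curve(seed, residual = seed %% 3 == 0)
    d <- cumulative_to_differential(cv)
    expect_equal(sum(d$partial_volume), 1, tolerance = 1e-12)
    back <- differential_to_cumulative(d)
    # exact inverse on the positive-drop support of the original curve
    keep <- c(TRUE, diff(cv$cum_volume) < 0)
    if (cv$cum_volume[length(cv$cum_volume)] > 1e-12) {
      keep[length(keep)] <- TRUE
    }
    expect_equal(back$dose_gy, cv$dose_gy[keep], tolerance = 1e-9)
    expect_equal(back$cum_volume, cv$cum_volume[keep], tolerance = 1e-9)
    # and differentiating again conserves every partial volume
    d2 <- cumulative_to_differential(back)
    expect_equal(d2$partial_volume, d$partial_volume, tolerance = 1e-9)
    expect_equal(d2$bin_dose, d$bin_dose, tolerance = 1e-9)
  }
})

test_that("writer output re-reads bit-for-bit on the same grid", {
  f <- withr::local_tempfile(fileext = ".dvh")
  cv <- random_cum_curve(99, k = 12)
  write_dvh_file(cv, f)
  back <- read_dvh_file(f)[[1]]
  expect_identical(back$dose_gy, cv$dose_gy)
  expect_identical(back$cum_volume, cv$cum_volume)
  expect_identical(back$structure, cv$structure)

  # multi-structure files keep block labels
  write_dvh_file(list(cv, two_bin_curve()), f)
  both <- read_dvh_file(f)
  expect_length(both, 2)
  expect_identical(both[[2]]$cum_volume, two_bin_curve()$cum_volume)
})

test_that("plan records enforce isodose-volume and fraction invariants", {
  cv <- two_bin_curve()
  expect_error(plan_record("p1", "IC_OFF", cv, v100_cc = 100, v50_cc = 50),
               "v50_cc")
  expect_error(plan_record("p1", "IC_OFF", cv, n_fractions = 0), "n_fractions")
  p <- plan_record("p1", "IC_ON", cv, v100_cc = 50, v50_cc = 100)
  expect_s3_class(p, "plan_record")
  expect_equal(p$prescription_dose_gy, 7)
  expect_equal(p$n_fractions, 1L)
})
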