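test_that("gEUD is the weighted power mean of the differential DVH", {
  single <- dvh_diff(7, 1)
  for (a in c(-5, -1, 0.5, 1, 2, 8)) expect_equal(geud(single, a), 7)
  half <- dvh_diff(c(6, 8), c(0.5, 0.5))
  expect_equal(geud(half, 1), 7)
  expect_equal(geud(half, 2), sqrt(50))
  expect_error(geud(half, 0), "non-zero")
})

test_that("gEUD is non-decreasing in the exponent and bounded by dose extremes", {
  as <- setdiff(-5:5, 0)
  for (seed in 1:12) {
    d <- random_diff_dvh(seed)
    g <- vapply(as, function(a) geud(d, a), numeric(1))
    expect_true(all(diff(g) >= -1e-10)) # power-mean inequality
    expect_true(all(g >= min(d$bin_dose) - 1e-10))
    expect_true(all(g <= max(d$bin_dose) + 1e-10))
  }
})

test_that("LQ EUD closed form agrees with a root-finder oracle", {
  prm <- radiobio_params(alpha = 0.3, alpha_beta = 3, n_fractions = 1)
  # uniform-dose identity for a grid of parameter scenarios
  for (al in c(0.1, 0.3, 0.5)) {
    for (ab in c(3, 10)) {
      for (nf in c(1, 5)) {
        p <- radiobio_params(alpha = al, alpha_beta = ab, n_fractions = nf)
        expect_equal(eud_lq(dvh_diff(7, 1), p), 7, tolerance = 1e-12)
      }
    }
  }
  # frozen two-bin example against the independent scalar root
  half <- dvh_diff(c(6, 8), c(0.5, 0.5))
  expect_equal(eud_lq(half, prm), eud_root_oracle(half, 0.3, 3), tolerance = 1e-9)
  # random DVHs, both alpha/beta scenarios
  for (seed in 1:100) {
    d <- random_diff_dvh(seed)
    for (ab in c(3, 10)) {
      p <- radiobio_params(alpha = 0.3, alpha_beta = ab)
      expect_equal(eud_lq(d, p), eud_root_oracle(d, 0.3, ab), tolerance = 1e-9)
    }
  }
})

test_that("LQ EUD respects bounds, bin permutation, and cold-spot dominance", {
  p <- radiobio_params(alpha = 0.3, alpha_beta = 3)
  for (seed in 1:12) {
    d <- random_diff_dvh(seed)
    e <- eud_lq(d, p)
    expect_gte(e, min(d$bin_dose) - 1e-9)
    expect_lte(e, max(d$bin_dose) + 1e-9)
    # survival is convex over the [2, 10] Gy support, so EUD <= mean dose
    expect_lte(e, geud(d, 1) + 1e-9)
    # splitting every bin into two half-weight copies leaves EUD unchanged
    dd <- c(d$bin_dose, d$bin_dose)
    vv <- c(d$partial_volume, d$partial_volume) / 2
    o <- order(dd)
    merged <- dvh_diff(dd[o], vv[o])
    expect_equal(eud_lq(merged, p), e, tolerance = 1e-12)
  }
})

test_that("LQ EUD survival sum is accumulated in the log domain", {
  # doses large enough that every survival term underflows a naive sum
  d <- dvh_diff(c(3000, 4000), c(0.5, 0.5))
  p <- radiobio_params(alpha = 0.3, alpha_beta = 3)
  e <- eud_lq(d, p)
  expect_true(is.finite(e))
  expect_equal(e, eud_root_oracle_log(d, 0.3, 3), tolerance = 1e-6)
  # all-zero dose edge: no kill, EUD 0
  expect_equal(eud_lq(dvh_diff(0, 1), p), 0)
})

test_that("EQD2 conversion reproduces single-fraction isoeffect doses", {
  expect_equal(round(eqd2(7.02, 7.02, 3), 2), 14.07)
  expect_equal(round(eqd2(7.02, 7.02, 10), 2), 9.96)
  expect_equal(eqd2(2, 2, 3.7), 2) # 2 Gy per fraction is the fixed point
  expect_error(eqd2(-1, 2, 3), "positive")
  # linear in total dose at fixed d; strictly increasing in d
  expect_equal(eqd2(14, 7, 3), 2 * eqd2(7, 7, 3))
  expect_gt(eqd2(7, 8, 3), eqd2(7, 7, 3))
})

test_that("radiobiological panel composes its component operations", {
  box <- dvh_curve(c(0, 7, 7.0001), c(1, 1, 0))
  plan <- plan_record("u", "IC_OFF", box)
  panel <- compute_radbio_panel(plan)
  expect_equal(panel$geud, 7, tolerance = 1e-3)
  expect_equal(panel$eud_lq_ab3, 7, tolerance = 1e-3)
  expect_equal(panel$eqd2_ab3_geud, 7 * 10 / 5, tolerance = 2e-3)

  plan2 <- plan_record("t", "IC_ON", two_bin_curve())
  p2 <- compute_radbio_panel(plan2)
  diff <- cumulative_to_differential(plan2$target_dvh)
  expect_equal(p2$geud, geud(diff, 1))
  expect_equal(p2$eud_lq_ab10,
               eud_lq(diff, radiobio_params(alpha = 0.3, alpha_beta = 10)))
  expect_equal(p2$eqd2_ab3_lq, eqd2(p2$eud_lq_ab3, p2$eud_lq_ab3, 3))
  expect_equal(p2$eqd2_ab10_geud, eqd2(p2$geud, p2$geud, 10))
})
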