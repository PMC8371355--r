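test_that("worked AKI scenarios reproduce the printed tangent slopes", {
  s_low <- dcr_dgfr(worked_low(), 24)
  s_high <- dcr_dgfr(worked_high(), 24)
  expect_equal(s_low$value, -0.009722536, tolerance = 5e-7)
  expect_equal(s_high$value, -0.217521268, tolerance = 5e-8)
  expect_identical(s_low$branch, "general")
  # the steeper slope belongs to the higher starting creatinine
  expect_gt(abs(s_high$value), abs(s_low$value))
})

test_that("the GFR sensitivity is exactly zero at t = 0, on every branch", {
  p_gen <- worked_low()
  p_dv0 <- kinetic_params(2, 90, 40, 42, 0)
  p_both <- kinetic_params(2, 90, 0, 42, 0)
  p_neg <- kinetic_params(2, 90, 0.25 / 0.06, 42, -0.25)  # gfr = -dv_dt
  for (p in list(p_gen, p_dv0, p_both, p_neg)) {
    expect_identical(dcr_dgfr(p, 0)$value, 0)
  }
})

test_that("branch dispatch matches the singular locus", {
  expect_identical(dcr_dgfr(kinetic_params(1, 90, 40, 42, 0), 24)$branch,
                   "limit-dv0")
  expect_identical(dcr_dgfr(kinetic_params(1, 90, 0, 42, 0), 24)$branch,
                   "limit-both-zero")
  p_neg <- kinetic_params(1, 90, 0.25, 42, -0.25, gfr_unit = "L/h")
  expect_identical(dcr_dgfr(p_neg, 24)$branch, "limit-gfr-eq-neg-dv")
  expect_identical(dcr_dgfr(worked_low(), 24)$branch, "general")
})

test_that("degenerate limit matches hand arithmetic", {
  # gfr = dv = 0: -(t/v0)(gen t / (2 v0) + cr0), canonical units
  p <- kinetic_params(1, 90, 0, 42, 0)
  hand <- -(24 / 42) * (5.4 * 24 / 84 + 1)      # -1.45306...
  expect_equal(dcr_dgfr_limit_both_zero(p, 24, units = "L/h")$value, hand,
               tolerance = 1e-12)
  expect_equal(dcr_dgfr(p, 24)$value, hand * 0.06, tolerance = 1e-12)
  expect_lt(hand, 0)
})

test_that("gfr = -dv_dt limit matches an independent symbolic evaluation", {
  # frozen from a computer-algebra limit of the general derivative at
  # cr0=1, gen=5.4 mg/dL.L/h, dv=-0.25 L/h, v0=42, t=24
  p <- kinetic_params(1, 5.4, 0.25, 42, -0.25,
                      gfr_unit = "L/h", gen_unit = "mg/dL.L/h")
  expect_equal(dcr_dgfr_limit_gfr_eq_neg_dv(p, 24, units = "L/h")$value,
               -1.643139785649128, tolerance = 1e-12)
})

test_that("stable-volume limit at steady state reduces to -Gen/G^2 form", {
  p <- kinetic_params(2, 90, 45, 42, 0)
  p$cr0 <- p$gen / p$gfr_k   # start exactly at steady state
  g <- p$gfr_k
  t <- 24
  expected <- -(1 - exp(-g * t / p$v0)) * p$gen / g^2
  expect_equal(dcr_dgfr_limit_dv0(p, t, units = "L/h")$value, expected,
               tolerance = 1e-12)
  expect_lt(expected, 0)
})

test_that("limit functions refuse parameters belonging to another branch", {
  p00 <- kinetic_params(1, 90, 0, 42, 0)
  expect_error(dcr_dgfr_limit_dv0(p00, 24), "both-zero")
  expect_error(dcr_dgfr_limit_gfr_eq_neg_dv(p00, 24), "both-zero")
})

test_that("general derivative is continuous into all three limit branches", {
  # the general product-rule expression, evaluated 1e-9 off each singular
  # locus, must agree with the analytic limit evaluated on the locus
  general <- kgfr:::.dcr_dgfr_general
  d <- draw_valid_params(60, seed = 5)
  off <- 1e-9
  for (i in seq_len(nrow(d))) {
    t <- d$t[i]
    # locus 1: dv_dt = 0
    p <- params_row(d, i)
    p$dv_dt <- 0
    lim <- dcr_dgfr_limit_dv0(p, t, units = "L/h")$value
    for (s in c(off, -off)) {
      expect_lt(rel_err(general(p$cr0, p$gen, p$gfr_k, s, p$v0, t), lim), 1e-6)
    }
    # locus 2: gfr = -dv_dt (clinically reachable side: dv_dt < 0)
    p2 <- params_row(d, i)
    p2$dv_dt <- -min(abs(p2$dv_dt) + 0.05, 0.3)
    p2$gfr_k <- -p2$dv_dt
    lim2 <- dcr_dgfr_limit_gfr_eq_neg_dv(p2, t, units = "L/h")$value
    g_off <- -p2$dv_dt + off
    expect_lt(rel_err(general(p2$cr0, p2$gen, g_off, p2$dv_dt, p2$v0, t),
                      lim2), 1e-6)
    # locus 3: both zero
    p3 <- params_row(d, i)
    lim3 <- dcr_dgfr_limit_both_zero(
      kinetic_params(p3$cr0, p3$gen, 0, p3$v0, 0, gen_unit = "mg/dL.L/h"),
      t, units = "L/h")$value
    expect_lt(rel_err(general(p3$cr0, p3$gen, off, off, p3$v0, t), lim3), 1e-6)
  }
})

test_that("analytic GFR sensitivity agrees with the finite-difference oracle", {
  for (p in list(worked_low(), worked_high())) {
    fd <- finite_difference("gfr_k", p, 24, h = 1e-4)
    expect_lt(rel_err(dcr_dgfr(p, 24, units = "L/h")$value, fd), 1e-5)
  }
  d <- draw_valid_params(100, seed = 23)
  for (i in seq_len(nrow(d))) {
    p <- params_row(d, i)
    fd <- finite_difference("gfr_k", p, d$t[i], h = 1e-4)
    expect_lt(rel_err(dcr_dgfr(p, d$t[i], units = "L/h")$value, fd), 1e-5)
  }
})

test_that("finite difference is symmetric and converges at O(h^2)", {
  p <- worked_high()
  exact <- dcr_dgfr(p, 24, units = "L/h")$value
  h <- c(4e-3, 2e-3, 1e-3)
  errs <- vapply(h, function(hh) {
    abs(finite_difference("gfr_k", p, 24, h = hh) - exact)
  }, numeric(1))
  ratios <- errs[-length(errs)] / errs[-1]
  expect_true(all(ratios > 3.5 & ratios < 4.5))
})

test_that("volume-rate sensitivity matches its oracle and vanishes at t=0", {
  p_fig1 <- kinetic_params(1, 90, 10, 42, 0.25)
  expect_equal(dcr_dvolrate(p_fig1, 0)$value, 0)
  # frozen from independent symbolic differentiation at this point
  expect_equal(dcr_dvolrate(p_fig1, 24)$value, -1.3060992742475905,
               tolerance = 1e-10)
  fd <- finite_difference("dv_dt", p_fig1, 24, h = 1e-5)
  expect_lt(rel_err(dcr_dvolrate(p_fig1, 24)$value, fd), 1e-6)
  d <- draw_valid_params(60, seed = 31)
  for (i in seq_len(nrow(d))) {
    p <- params_row(d, i)
    if (abs(p$dv_dt) < 1e-3 || abs(p$gfr_k + p$dv_dt) < 1e-3) next
    fd <- finite_difference("dv_dt", p, d$t[i], h = 1e-6)
    expect_lt(rel_err(dcr_dvolrate(p, d$t[i])$value, fd), 1e-4)
  }
})

test_that("volume-rate sensitivity refuses the un-derived singular loci", {
  expect_error(dcr_dvolrate(kinetic_params(1, 90, 40, 42, 0), 24),
               "unsupported branch")
  p_sing <- kinetic_params(1, 90, 0.25, 42, -0.25, gfr_unit = "L/h")
  expect_error(dcr_dvolrate(p_sing, 24), "unsupported branch")
})

test_that("the GFR sensitivity is negative on every valid draw with t > 0", {
  scan <- sign_scan(n = 20000, seed = 101)
  expect_identical(scan$n_nonnegative, 0L)
  expect_lt(scan$worst_case$value, 0)
  # every formula branch participates in the scan
  expect_setequal(names(scan$branch_counts),
                  c("general", "limit-dv0", "limit-both-zero",
                    "limit-gfr-eq-neg-dv"))
})

test_that("sign scans are reproducible under a fixed seed", {
  a <- sign_scan(n = 2000, seed = 9)
  b <- sign_scan(n = 2000, seed = 9)
  expect_identical(a$worst_case$value, b$worst_case$value)
  c <- sign_scan(n = 2000, seed = 10)
  expect_false(identical(a$worst_case$value, c$worst_case$value))
})

test_that("long stable-volume horizons reproduce the chronic tangent", {
  # as t grows with dv_dt = 0 the kinetic tangent approaches the CKD
  # reciprocal slope -Gen/GFR^2
  for (gfr in c(90, 45, 10)) {
    p <- kinetic_params(1, 90, gfr, 42, 0)
    t_long <- 40 * p$v0 / p$gfr_k
    kin <- dcr_dgfr(p, t_long)$value
    expect_equal(kin, ckd_slope(90, gfr), tolerance = 1e-6)
  }
})
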