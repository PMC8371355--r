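test_that("inversion recovers the generating GFR from a noiseless pair", {
  p <- kinetic_params(1, 90, 40, 42, 0)
  crt <- creatinine_at(p, 24)
  est <- invert_gfr(1, crt, 24, v0 = 42, dv_dt = 0, gen = 90)
  expect_true(est$converged)
  expect_equal(est$gfr_k_hat, 40, tolerance = 1e-8)
  expect_lt(est$residual, 1e-8)
})

test_that("round-trip recovery holds across randomized scenarios", {
  d <- draw_valid_params(200, seed = 77)
  d$gfr <- pmin(d$gfr, 120)    # stay inside the default bracket with margin
  worst <- 0
  for (i in seq_len(nrow(d))) {
    p <- params_row(d, i)
    crt <- creatinine_at(p, d$t[i])
    est <- invert_gfr(d$cr0[i], crt, d$t[i], v0 = d$v0[i], dv_dt = d$dv[i],
                      gen = d$gen[i], tol = 1e-10)
    expect_true(est$converged)
    worst <- max(worst, abs(est$gfr_k_hat - d$gfr[i]))
  }
  expect_lt(worst, 1e-6)
})

test_that("a steady-state observation returns its implied GFR", {
  # crt = cr0 = gen/(gfr + dv): the interval's fixed point
  gen <- 90; gfr <- 60; dv <- 0.25
  cr_ss <- gen / (gfr + dv / 0.06)
  est <- invert_gfr(cr_ss, cr_ss, 24, v0 = 42, dv_dt = dv, gen = gen)
  expect_true(est$converged)
  expect_equal(est$gfr_k_hat, gfr, tolerance = 1e-6)
})

test_that("observations outside the attainable band are flagged, not clamped", {
  p0 <- kinetic_params(1, 90, 0, 42, 0)
  cr_max <- creatinine_at(p0, 24)     # zero clearance: ceiling
  est_hi <- invert_gfr(1, cr_max + 0.5, 24, v0 = 42, dv_dt = 0, gen = 90)
  expect_false(est_hi$converged)
  expect_true(is.na(est_hi$gfr_k_hat))
  expect_match(est_hi$note, "above attainable")
  est_lo <- invert_gfr(5, 0.01, 24, v0 = 42, dv_dt = 0, gen = 90)
  expect_false(est_lo$converged)
  expect_match(est_lo$note, "below attainable")
  expect_error(invert_gfr(1, 1.5, dt = -2, v0 = 42, gen = 90), "positive duration")
})

test_that("the forward map is strictly decreasing in GFR on the bracket", {
  # monotone residual: bisection cannot find a second root
  for (i in seq_len(20)) {
    d <- draw_valid_params(1, seed = 300 + i)
    gfr_grid <- seq(0, 300, length.out = 61)
    cr <- vapply(gfr_grid, function(g) {
      creatinine_at(kinetic_params(d$cr0, d$gen, g, d$v0, d$dv), d$t)
    }, numeric(1))
    expect_true(all(diff(cr) < 0))
  }
})

test_that("series inversion recovers a piecewise GFR course", {
  # renal recovery: 40 mL/min over the first day, 44 over the second
  seg <- data.frame(duration_h = c(24, 24), gfr_k_ml_min = c(40, 44),
                    dv_dt_l_h = c(0, 0))
  spec <- scenario_spec(seg, cr0 = 1.0, gen = 90, v0 = 42, cv = 0,
                        sampling_interval_h = 24)
  series <- generate_series(spec)
  est <- invert_series(series, v0 = 42, gen = 90)
  expect_equal(nrow(est), 2)
  expect_true(all(est$converged))
  expect_equal(est$gfr_k_ml_min, c(40, 44), tolerance = 1e-4)
})

test_that("volume is carried across intervals via the fluid balance", {
  seg <- data.frame(duration_h = c(24, 24), gfr_k_ml_min = c(10, 30),
                    dv_dt_l_h = c(0.25, -0.1))
  spec <- scenario_spec(seg, cr0 = 1.0, gen = 90, v0 = 42, cv = 0,
                        sampling_interval_h = 24)
  series <- generate_series(spec)
  expect_equal(series$net_fluid_l, c(0, 6, -2.4))
  est <- invert_series(series, v0 = 42, gen = 90)
  expect_equal(est$v0_l, c(42, 48))     # end volume becomes next start
  expect_equal(est$dv_dt_l_h, c(0.25, -0.1))
  expect_equal(est$gfr_k_ml_min, c(10, 30), tolerance = 1e-4)
})

test_that("one wild measurement flags only its own interval", {
  seg <- data.frame(duration_h = c(24, 24, 24),
                    gfr_k_ml_min = c(40, 40, 40), dv_dt_l_h = 0)
  series <- generate_series(scenario_spec(seg, cr0 = 1.0, gen = 90, v0 = 42,
                                          cv = 0, sampling_interval_h = 24))
  series$creatinine_mg_dl[3] <- 25     # above any attainable value
  est <- invert_series(series, v0 = 42, gen = 90)
  # the interval ending at the wild value is flagged; its neighbours still
  # produce estimates (the following one from the wild starting point)
  expect_false(est$converged[2])
  expect_true(est$converged[1] && est$converged[3])
  expect_equal(est$gfr_k_ml_min[1], 40, tolerance = 1e-4)
  expect_match(est$note[2], "above attainable")
})

test_that("two identical steady-state creatinines give gen/cr - dv", {
  cr <- 2.5; dv <- 0.12; gen <- 90
  series <- data.frame(time_h = c(0, 24), creatinine_mg_dl = c(cr, cr),
                       net_fluid_l = c(0, dv * 24))
  est <- invert_series(series, v0 = 42, gen = gen)
  expect_equal(est$gfr_k_ml_min, gen / cr - dv / 0.06, tolerance = 1e-6)
})

test_that("CKD reciprocal and its tangent match the chronic picture", {
  expect_identical(ckd_cr(90, 90), 1)
  expect_identical(ckd_cr(90, 10), 9)
  expect_equal(ckd_cr(72, 72), 1)     # gen = gfr always gives 1 mg/dL
  expect_equal(ckd_slope(90, 90), -1 / 90)
  expect_equal(ckd_slope(90, 10), -0.9)
  expect_error(ckd_cr(90, 0), "positive")
  expect_error(ckd_slope(90, -5), "positive")
  # slope is the derivative of the curve
  for (g in c(15, 60, 110)) {
    fd <- (ckd_cr(90, g + 1e-5) - ckd_cr(90, g - 1e-5)) / 2e-5
    expect_equal(ckd_slope(90, g), fd, tolerance = 1e-7)
  }
  expect_true(all(ckd_slope(90, seq(1, 150, by = 1)) < 0))
})

test_that("recovery error shrinks as measurement noise shrinks", {
  seg <- data.frame(duration_h = 24, gfr_k_ml_min = 40, dv_dt_l_h = 0)
  err_at_cv <- function(cv) {
    errs <- vapply(1:40, function(k) {
      spec <- scenario_spec(seg, cr0 = 2, gen = 90, v0 = 42, cv = cv,
                            sampling_interval_h = 24, seed = 1000 + k)
      est <- invert_series(generate_series(spec), v0 = 42, gen = 90)
      if (est$converged[1]) abs(est$gfr_k_ml_min[1] - 40) else NA_real_
    }, numeric(1))
    stats::median(errs, na.rm = TRUE)
  }
  e_hi <- err_at_cv(0.08)
  e_lo <- err_at_cv(0.01)
  e_zero <- err_at_cv(0)
  expect_lt(e_lo, e_hi)
  expect_lt(e_zero, 1e-6)
})
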