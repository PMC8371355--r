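# Inversion: given a creatinine pair bracketing a clinical interval, find
# the kinetic GFR whose forward model reproduces the observed endpoint.
# The GFR sensitivity is strictly negative for t > 0, so the forward map
# GFR -> Cr_t is strictly decreasing and has at most one root: bracketing
# root-finding is safe and cannot pick a spurious solution.

#' Estimate the kinetic GFR from one creatinine pair
#'
#' Solves `creatinine_at(params(gfr), dt) = crt` for the kinetic GFR by
#' bracketed root-finding on `[0, gfr_max]` mL/min. Because the creatinine
#' is strictly decreasing in GFR, the attainable observations lie between
#' `creatinine_at(gfr_max)` and `creatinine_at(0)`; an observation outside
#' that band yields `converged = FALSE` with a diagnostic note instead of a
#' clamped estimate, so model misfit stays visible.
#'
#' @param cr0 Creatinine at the start of the interval, mg/dL.
#' @param crt Creatinine at the end of the interval, mg/dL.
#' @param dt Interval length, h (> 0).
#' @param v0 Volume of distribution at interval start, L.
#' @param dv_dt Net volume-change rate over the interval, L/h.
#' @param gen Creatinine generation rate, mg/dL·mL/min.
#' @param gfr_max Upper bracket, mL/min (default 300 — physiologic ceiling
#'   with a wide margin).
#' @param tol Root tolerance, mL/min (default 1e-8).
#' @return A `kgfr_interval` object: `interval` (`c(0, dt)` h), `gfr_k_hat`
#'   (mL/min, `NA` if not attainable), `converged`, `residual` (mg/dL),
#'   `note`.
#' @examples
#' p <- kinetic_params(1, 90, 40, 42, 0)
#' crt <- creatinine_at(p, 24)
#' invert_gfr(1, crt, 24, v0 = 42, dv_dt = 0, gen = 90)$gfr_k_hat  # ~40
#' @export
invert_gfr <- function(cr0, crt, dt, v0, dv_dt = 0, gen,
                       gfr_max = 300, tol = 1e-8) {
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) {
    stop("dt must be a positive duration in hours")
  }
  base <- kinetic_params(cr0 = cr0, gen = gen, gfr_k = 0, v0 = v0,
                         dv_dt = dv_dt)
  .assert_valid(base, dt)
  if (!(crt > 0)) stop("observed creatinine must be positive (rule A)")
  fwd <- function(g_ml_min) {
    p <- base
    p$gfr_k <- g_ml_min * ML_MIN_TO_L_H
    .creatinine_core(p$cr0, p$gen, p$gfr_k, p$dv_dt, p$v0, dt)
  }
  cr_hi <- fwd(0)        # no clearance: highest attainable creatinine
  cr_lo <- fwd(gfr_max)  # maximal clearance: lowest attainable
  result <- function(gfr, converged, residual, note) {
    structure(list(interval = c(0, dt), gfr_k_hat = gfr,
                   converged = converged, residual = residual, note = note),
              class = "kgfr_interval")
  }
  if (crt > cr_hi) {
    return(result(NA_real_, FALSE, crt - cr_hi, sprintf(
      "observed %.4g mg/dL above attainable maximum %.4g (would need GFR < 0)",
      crt, cr_hi)))
  }
  if (crt < cr_lo) {
    return(result(NA_real_, FALSE, cr_lo - crt, sprintf(
      "observed %.4g mg/dL below attainable minimum %.4g (would need GFR > %g mL/min)",
      crt, cr_lo, gfr_max)))
  }
  f <- function(g) fwd(g) - crt
  root <- stats::uniroot(f, interval = c(0, gfr_max),
                         f.lower = cr_hi - crt, f.upper = cr_lo - crt,
                         tol = tol)$root
  result(root, TRUE, abs(fwd(root) - crt), "ok")
}

#' @export
print.kgfr_interval <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("Kinetic GFR over (%g, %g] h: %.4f mL/min (residual %.2g mg/dL)\n",
                x$interval[1], x$interval[2], x$gfr_k_hat, x$residual))
  } else {
    cat(sprintf("Kinetic GFR over (%g, %g] h: not attainable — %s\n",
                x$interval[1], x$interval[2], x$note))
  }
  invisible(x)
}

#' Estimate the kinetic GFR for each interval of a measurement series
#'
#' Applies [invert_gfr()] to every consecutive pair of a serial-creatinine
#' series. Each interval uses the earlier measurement as its `cr0` and its
#' own time zero; the interval's volume-change rate is the net fluid
#' balance over the interval divided by its length (0 when no balance is
#' recorded), and the volume of distribution is carried forward as the
#' previous interval's end volume. A non-attainable observation flags its
#' own interval and leaves the others untouched.
#'
#' @param series Data frame with columns `time_h` (strictly increasing) and
#'   `creatinine_mg_dl` (> 0), optionally `net_fluid_l` — the net fluid
#'   balance (L) accrued over the interval *ending* at that row (the first
#'   row's value is ignored).
#' @param v0 Volume of distribution at the first measurement, L.
#' @param gen Creatinine generation rate, mg/dL·mL/min.
#' @param ... Passed to [invert_gfr()] (`gfr_max`, `tol`).
#' @return Data frame of class `kgfr_intervals`: one row per interval with
#'   `interval_start_h`, `interval_end_h`, `v0_l`, `dv_dt_l_h`,
#'   `gfr_k_ml_min`, `converged`, `residual_mg_dl`, `note`.
#' @export
invert_series <- function(series, v0, gen, ...) {
  series <- as.data.frame(series)
  need <- c("time_h", "creatinine_mg_dl")
  if (!all(need %in% names(series))) {
    stop("series needs columns: ", paste(need, collapse = ", "))
  }
  tt <- series$time_h
  cr <- series$creatinine_mg_dl
  if (length(tt) < 2L) stop("need at least two measurements")
  if (any(diff(tt) <= 0)) stop("measurement times must be strictly increasing")
  if (any(cr <= 0)) stop("creatinine measurements must be positive (rule A)")
  bal <- if ("net_fluid_l" %in% names(series)) series$net_fluid_l else
    rep(0, length(tt))
  bal[is.na(bal)] <- 0
  m <- length(tt) - 1L
  out <- data.frame(
    interval_start_h = tt[-length(tt)], interval_end_h = tt[-1],
    v0_l = NA_real_, dv_dt_l_h = NA_real_, gfr_k_ml_min = NA_real_,
    converged = FALSE, residual_mg_dl = NA_real_, note = NA_character_,
    stringsAsFactors = FALSE
  )
  v <- v0
  for (i in seq_len(m)) {
    dt <- tt[i + 1] - tt[i]
    dv <- bal[i + 1] / dt
    est <- invert_gfr(cr0 = cr[i], crt = cr[i + 1], dt = dt, v0 = v,
                      dv_dt = dv, gen = gen, ...)
    out$v0_l[i] <- v
    out$dv_dt_l_h[i] <- dv
    out$gfr_k_ml_min[i] <- est$gfr_k_hat
    out$converged[i] <- est$converged
    out$residual_mg_dl[i] <- est$residual
    out$note[i] <- est$note
    v <- v + dv * dt   # end volume carried into the next interval
  }
  class(out) <- c("kgfr_intervals", "data.frame")
  out
}

#' Steady-state (CKD) creatinine as a function of GFR
#'
#' In slowly progressive chronic kidney disease the creatinine tracks its
#' steady state, so concentration is generation over clearance — a
#' reciprocal curve: `Cr = Gen / GFR`.
#'
#' @param gen Generation rate, mg/dL·mL/min.
#' @param gfr GFR, mL/min (> 0); vectorised.
#' @return Creatinine, mg/dL.
#' @examples
#' ckd_cr(90, c(90, 10))  # 1, 9
#' @export
ckd_cr <- function(gen, gfr) {
  if (any(gfr <= 0)) stop("GFR must be positive on the CKD curve")
  gen / gfr
}

#' Tangent slope of the CKD reciprocal curve
#'
#' `d(Gen/GFR)/dGFR = -Gen/GFR^2`: shallow at high GFR (low creatinine),
#' steep at low GFR (high creatinine), always negative.
#'
#' @inheritParams ckd_cr
#' @return Slope, mg/dL per mL/min.
#' @examples
#' ckd_slope(90, c(90, 10))  # -1/90, -0.9
#' @export
ckd_slope <- function(gen, gfr) {
  if (any(gfr <= 0)) stop("GFR must be positive on the CKD curve")
  -gen / gfr^2
}
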