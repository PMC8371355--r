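# Forward model.  The creatinine amount balance
#   d/dt (Cr_t * V_t) = Gen - GFR_K * Cr_t,   V_t = V0 + (dV/dt) * t
# has the closed-form solution
#   Cr_t = Cr0 + [1 - (V0/V_t)^(1 + G/D)] * (Gen/(G + D) - Cr0)
# with G = GFR_K and D = dV/dt (both L/h).  The power term is evaluated in
# log space via log1p/expm1, which keeps the expression accurate all the
# way into the removable singularities at D = 0 and G + D = 0; exact
# evaluation AT those loci uses the analytic limit forms.

# below this (L/h) a rate is treated as sitting on its singular locus
BRANCH_EPS <- 1e-8

#' Volume of distribution at time t
#'
#' `V_t = V0 + (dV/dt) * t`. Errors if the result is not positive (the
#' volume rules of the model forbid draining the compartment).
#'
#' @param params A [kinetic_params] object.
#' @param t Time(s) since the start of the interval, h.
#' @return Volume(s), L.
#' @export
volume_at <- function(params, t) {
  stopifnot(inherits(params, "kinetic_params"), all(t >= 0))
  v <- params$v0 + params$dv_dt * t
  if (any(v <= 0)) {
    stop("volume of distribution becomes non-positive within the horizon ",
         "(rules B/E): v0 = ", params$v0, " L, dv_dt = ", params$dv_dt,
         " L/h", call. = FALSE)
  }
  v
}

#' Steady-state serum creatinine
#'
#' The concentration at which creatinine excretion (plus dilution by volume
#' gain) balances generation: `Gen / (GFR_K + dV/dt)`. With a stable volume
#' this is the familiar chronic (CKD) value `Gen/GFR`. Only defined when
#' `GFR_K + dV/dt > 0`; otherwise the creatinine grows without bound and a
#' `kgfr_no_steady_state` error is signalled.
#'
#' @param params A [kinetic_params] object.
#' @return Steady-state creatinine, mg/dL.
#' @export
steady_state_cr <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  s <- params$gfr_k + params$dv_dt
  if (s <= 0) {
    stop(structure(
      class = c("kgfr_no_steady_state", "error", "condition"),
      list(message = sprintf(
        "no steady state: gfr_k + dv_dt = %g L/h <= 0 (creatinine grows without bound)", s),
        call = sys.call(-1))))
  }
  params$gen / s
}

# scalar core of the closed form; canonical units, t >= 0
.creatinine_core <- function(cr0, gen, g, d, v0, t) {
  if (t == 0) return(cr0)
  if (abs(d) < BRANCH_EPS) {
    if (abs(g) < BRANCH_EPS) {
      return(cr0 + gen * t / v0)            # no clearance, fixed volume
    }
    e <- expm1(-g * t / v0)                  # e^{-gt/v0} - 1
    return(cr0 + (cr0 - gen / g) * e)        # exponential relaxation
  }
  s <- g + d
  L <- -log1p(d * t / v0)                    # ln(V0 / V_t), exact near d ~ 0
  if (abs(s) < BRANCH_EPS) {
    return(cr0 - gen * L / d)                # limit of the general form
  }
  u <- (s / d) * L                           # (1 + g/d) * ln(V0/V_t)
  cr0 - expm1(u) * (gen / s - cr0)
}

#' Serum creatinine at time t (closed form)
#'
#' Evaluates the closed-form solution of the kinetic model. When the
#' volume-change rate sits on (or within `1e-8` L/h of) a singular locus the
#' analytic limit form is used instead: the exponential one-compartment
#' solution for `dV/dt = 0`, its linear-accumulation limit for
#' `GFR_K = dV/dt = 0`, and a logarithmic form for `GFR_K = -dV/dt`.
#' The function is continuous in all parameters across these branches.
#'
#' @param params A [kinetic_params] object.
#' @param t Time(s) since interval start, h (vectorised).
#' @param mode Validation mode passed to [validate_params()].
#' @return Creatinine concentration(s), mg/dL.
#' @examples
#' p <- kinetic_params(cr0 = 1, gen = 90, gfr_k = 90, v0 = 42, dv_dt = 0.25)
#' creatinine_at(p, 24)  # ~0.96 mg/dL
#' @export
creatinine_at <- function(params, t, mode = "strict-clinical") {
  stopifnot(inherits(params, "kinetic_params"), is.numeric(t), all(t >= 0))
  .assert_valid(params, max(t), mode)
  vapply(t, function(ti) {
    .creatinine_core(params$cr0, params$gen, params$gfr_k, params$dv_dt,
                     params$v0, ti)
  }, numeric(1))
}

#' Right-hand side of the creatinine balance ODE
#'
#' `dCr/dt = (Gen - GFR_K * Cr - Cr * dV/dt) / V_t`, the amount balance
#' rearranged for concentration. Zero exactly at the steady state.
#'
#' @param params A [kinetic_params] object.
#' @param t Time, h.
#' @param cr Creatinine concentration at `t`, mg/dL.
#' @return Rate of change of concentration, mg/dL per h.
#' @export
ode_rhs <- function(params, t, cr) {
  v <- volume_at(params, t)
  (params$gen - params$gfr_k * cr - cr * params$dv_dt) / v
}

#' Numerically integrate the creatinine ODE
#'
#' Independent check on the closed form: integrates [ode_rhs()] from `cr0`
#' with `deSolve`'s adaptive `lsoda` at tight tolerances. Intended as a
#' verification oracle, not the production path.
#'
#' @param params A [kinetic_params] object.
#' @param times Sorted time grid starting at 0, h.
#' @param rtol,atol Integrator tolerances.
#' @return A `kgfr_trajectory` data frame with columns `time_h`,
#'   `creatinine_mg_dl`, `volume_l`.
#' @export
simulate_numeric <- function(params, times, rtol = 1e-10, atol = 1e-12) {
  stopifnot(is.numeric(times), length(times) >= 2L,
            !is.unsorted(times), times[1] == 0)
  .assert_valid(params, max(times))
  rhs <- function(t, y, parms) list(ode_rhs(params, t, y[[1]]))
  sol <- deSolve::ode(y = c(cr = params$cr0), times = times, func = rhs,
                      parms = NULL, method = "lsoda",
                      rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    stop("ODE oracle integration failed", call. = FALSE)
  }
  trajectory(times = times, creatinine = sol[, "cr"],
             volume = volume_at(params, times), cr0 = params$cr0)
}

#' Closed-form creatinine trajectory on a time grid
#'
#' @param params A [kinetic_params] object.
#' @param times Sorted time grid starting at 0, h.
#' @return A `kgfr_trajectory` data frame (`time_h`, `creatinine_mg_dl`,
#'   `volume_l`).
#' @export
simulate_trajectory <- function(params, times) {
  stopifnot(is.numeric(times), !is.unsorted(times), times[1] == 0)
  trajectory(times = times, creatinine = creatinine_at(params, times),
             volume = volume_at(params, times), cr0 = params$cr0)
}

# trajectory container with its invariants
trajectory <- function(times, creatinine, volume, cr0) {
  stopifnot(length(times) == length(creatinine),
            length(times) == length(volume))
  if (any(volume <= 0)) stop("trajectory volume must stay positive")
  if (any(creatinine <= 0)) stop("trajectory creatinine must stay positive")
  if (abs(creatinine[1] - cr0) > 1e-9 * max(1, cr0)) {
    stop("trajectory must start at cr0")
  }
  out <- data.frame(time_h = times, creatinine_mg_dl = creatinine,
                    volume_l = volume)
  class(out) <- c("kgfr_trajectory", "data.frame")
  out
}

#' @export
plot.kgfr_trajectory <- function(x, ...) {
  graphics::plot(x$time_h, x$creatinine_mg_dl, type = "l",
                 xlab = "time (h)", ylab = "serum creatinine (mg/dL)", ...)
  invisible(x)
}
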