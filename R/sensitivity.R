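# Analytic sensitivities of the closed-form creatinine to the kinetic GFR
# and to the volume-change rate.
#
# With G = GFR_K, D = dV/dt, s = G + D, L = ln(V0/V_t) and u = (s/D)*L,
# the product-rule derivative dCr_t/dG is
#     -(L/D) e^u (Gen/s - Cr0)  -  (1 - e^u) Gen/s^2 ,
# which we evaluate in the algebraically identical form
#     (Gen*L/(D*s)) * f(u)  +  (L/D) * Cr0 * e^u,
#     f(u) = (expm1(u) - u e^u)/u  (Taylor series for small |u|).
# The naive two-term form loses ~10 digits within 1e-9 of the s = 0 locus
# (two ~1e9 terms cancel); the f(u) form is uniformly accurate, so the
# general branch remains continuous with the three limit branches below.

# f(u) = (e^u - 1 - u e^u)/u = -u/2 - u^2/3 - u^4*... ; sum_{k>=2} u^{k-1}(1-k)/k!
.f_u <- function(u) {
  if (abs(u) < 1e-4) {
    -u / 2 - u^2 / 3 - u^3 / 8 - u^4 / 30
  } else {
    (expm1(u) - u * exp(u)) / u
  }
}

# the general product-rule expression in its stable form; requires d != 0
# and g + d != 0 exactly, but is accurate arbitrarily close to both loci
.dcr_dgfr_general <- function(cr0, gen, g, d, v0, t) {
  s <- g + d
  L <- -log1p(d * t / v0)
  u <- (s / d) * L
  gen * L / (d * s) * .f_u(u) + (L / d) * cr0 * exp(u)
}

# scalar derivative core in canonical units (mg/dL per L/h) with branch tag
.dcr_dgfr_core <- function(cr0, gen, g, d, v0, t) {
  if (abs(d) < BRANCH_EPS) {
    if (abs(g) < BRANCH_EPS) {
      value <- -(t / v0) * (gen * t / (2 * v0) + cr0)
      return(list(value = value, branch = "limit-both-zero"))
    }
    e <- exp(-g * t / v0)
    value <- e * (t / v0) * (gen / g - cr0) - (-expm1(-g * t / v0)) * gen / g^2
    return(list(value = value, branch = "limit-dv0"))
  }
  s <- g + d
  if (abs(s) < BRANCH_EPS) {
    L <- -log1p(d * t / v0)
    value <- -(1 / d) * L * (gen / (2 * d) * L - cr0)
    return(list(value = value, branch = "limit-gfr-eq-neg-dv"))
  }
  list(value = .dcr_dgfr_general(cr0, gen, g, d, v0, t), branch = "general")
}

.new_sensitivity <- function(value, branch, params, t, wrt, unit) {
  structure(
    list(value = value, branch = branch, params = params, t = t,
         wrt = wrt, unit = unit),
    class = "kgfr_sensitivity"
  )
}

#' @export
print.kgfr_sensitivity <- function(x, ...) {
  cat(sprintf("d[Cr]/d%s at t = %g h: %.9g %s  [branch: %s]\n",
              x$wrt, x$t, x$value, x$unit, x$branch))
  invisible(x)
}

#' Sensitivity of serum creatinine to the kinetic GFR
#'
#' Analytic partial derivative of the closed-form creatinine at time `t`
#' with respect to the kinetic GFR, holding every other variable (including
#' time) constant. Three removable singularities are handled by dispatching
#' to their analytic limit forms: `dV/dt = 0` ([dcr_dgfr_limit_dv0()]),
#' `GFR_K = -dV/dt` ([dcr_dgfr_limit_gfr_eq_neg_dv()]) and
#' `GFR_K = dV/dt = 0` ([dcr_dgfr_limit_both_zero()]). On the clinically
#' valid parameter space the value is strictly negative for `t > 0` and
#' zero at `t = 0`: raising the GFR can only lower the creatinine.
#'
#' @param params A [kinetic_params] object.
#' @param t Time since interval start, h.
#' @param units Reporting unit for the slope: `"mL/min"` (default, the
#'   clinical convention mg/dL per mL/min; internal L/h value times 0.06)
#'   or `"L/h"`.
#' @param mode Validation mode (see [validate_params()]).
#' @return A `kgfr_sensitivity` object: `value`, `branch` (which formula
#'   produced it), `params`, `t`, `unit`.
#' @examples
#' p <- kinetic_params(cr0 = 1, gen = 90, gfr_k = 90, v0 = 42, dv_dt = 0.25)
#' dcr_dgfr(p, 24)$value  # -0.009722536
#' @export
dcr_dgfr <- function(params, t, units = c("mL/min", "L/h"),
                     mode = "strict-clinical") {
  units <- match.arg(units)
  stopifnot(inherits(params, "kinetic_params"),
            is.numeric(t), length(t) == 1L, t >= 0)
  .assert_valid(params, t, mode)
  core <- .dcr_dgfr_core(params$cr0, params$gen, params$gfr_k,
                         params$dv_dt, params$v0, t)
  value <- core$value
  unit <- "mg/dL per L/h"
  if (units == "mL/min") {
    value <- value * ML_MIN_TO_L_H
    unit <- "mg/dL per mL/min"
  }
  .new_sensitivity(value, core$branch, params, t, "GFR_K", unit)
}

#' GFR sensitivity: stable-volume limit
#'
#' The `dV/dt -> 0` limit of [dcr_dgfr()] — clinically the most important
#' special case (stable volume, or no intake/output information):
#' `e^{-Gt/V0} (t/V0)(Gen/G - Cr0) - (1 - e^{-Gt/V0}) Gen/G^2`.
#' Requires `GFR_K > 0`; the doubly-degenerate `GFR_K = 0` case is the
#' business of [dcr_dgfr_limit_both_zero()].
#'
#' @inheritParams dcr_dgfr
#' @return A `kgfr_sensitivity` object (branch `"limit-dv0"`).
#' @export
dcr_dgfr_limit_dv0 <- function(params, t, units = c("mL/min", "L/h")) {
  units <- match.arg(units)
  stopifnot(inherits(params, "kinetic_params"), t >= 0)
  if (abs(params$gfr_k) < BRANCH_EPS) {
    stop("gfr_k = 0 with dv_dt = 0 routes to the both-zero limit; ",
         "use dcr_dgfr_limit_both_zero()", call. = FALSE)
  }
  g <- params$gfr_k; v0 <- params$v0; gen <- params$gen; cr0 <- params$cr0
  value <- exp(-g * t / v0) * (t / v0) * (gen / g - cr0) -
    (-expm1(-g * t / v0)) * gen / g^2
  if (units == "mL/min") {
    .new_sensitivity(value * ML_MIN_TO_L_H, "limit-dv0", params, t,
                     "GFR_K", "mg/dL per mL/min")
  } else {
    .new_sensitivity(value, "limit-dv0", params, t, "GFR_K", "mg/dL per L/h")
  }
}

#' GFR sensitivity: limit at GFR_K = -dV/dt
#'
#' The limit of [dcr_dgfr()] as `GFR_K -> -dV/dt` (where the steady-state
#' denominator vanishes):
#' `-(1/D) ln(V0/V_t) [ Gen/(2D) ln(V0/V_t) - Cr0 ]`, `D = dV/dt`.
#' With `dV/dt > 0` this locus needs a negative GFR (extended-math mode);
#' with `dV/dt < 0` it is clinically reachable at `GFR_K = |dV/dt|`.
#' Requires `dV/dt != 0`; the doubly-degenerate case routes to
#' [dcr_dgfr_limit_both_zero()].
#'
#' @inheritParams dcr_dgfr
#' @return A `kgfr_sensitivity` object (branch `"limit-gfr-eq-neg-dv"`).
#' @export
dcr_dgfr_limit_gfr_eq_neg_dv <- function(params, t, units = c("mL/min", "L/h")) {
  units <- match.arg(units)
  stopifnot(inherits(params, "kinetic_params"), t >= 0)
  d <- params$dv_dt
  if (abs(d) < BRANCH_EPS) {
    stop("dv_dt = 0 routes to the both-zero limit; ",
         "use dcr_dgfr_limit_both_zero()", call. = FALSE)
  }
  L <- -log1p(d * t / params$v0)
  value <- -(1 / d) * L * (params$gen / (2 * d) * L - params$cr0)
  if (units == "mL/min") value <- value * ML_MIN_TO_L_H
  .new_sensitivity(value, "limit-gfr-eq-neg-dv", params, t, "GFR_K",
                   if (units == "mL/min") "mg/dL per mL/min" else "mg/dL per L/h")
}

#' GFR sensitivity: limit at GFR_K = dV/dt = 0
#'
#' The doubly-degenerate limit of [dcr_dgfr()]:
#' `-(t/V0) [ Gen t/(2 V0) + Cr0 ]` — manifestly non-positive, zero only
#' at `t = 0`.
#'
#' @inheritParams dcr_dgfr
#' @return A `kgfr_sensitivity` object (branch `"limit-both-zero"`).
#' @export
dcr_dgfr_limit_both_zero <- function(params, t, units = c("mL/min", "L/h")) {
  units <- match.arg(units)
  stopifnot(inherits(params, "kinetic_params"), t >= 0)
  value <- -(t / params$v0) *
    (params$gen * t / (2 * params$v0) + params$cr0)
  if (units == "mL/min") value <- value * ML_MIN_TO_L_H
  .new_sensitivity(value, "limit-both-zero", params, t, "GFR_K",
                   if (units == "mL/min") "mg/dL per mL/min" else "mg/dL per L/h")
}

#' Sensitivity of serum creatinine to the volume-change rate
#'
#' Analytic partial derivative of the closed-form creatinine with respect
#' to `dV/dt`. Unlike the GFR derivative its sign is unconstrained: volume
#' loss concentrates, volume gain dilutes, but the time-evolution term can
#' pull either way. No limit forms are provided at the singular loci
#' `dV/dt = 0` and `GFR_K + dV/dt = 0`; input within `1e-8` L/h of either
#' is refused rather than approximated.
#'
#' @param params A [kinetic_params] object.
#' @param t Time since interval start, h.
#' @param mode Validation mode (see [validate_params()]).
#' @return A `kgfr_sensitivity` object; `value` in mg/dL per (L/h).
#' @export
dcr_dvolrate <- function(params, t, mode = "strict-clinical") {
  stopifnot(inherits(params, "kinetic_params"),
            is.numeric(t), length(t) == 1L, t >= 0)
  .assert_valid(params, t, mode)
  g <- params$gfr_k; d <- params$dv_dt
  s <- g + d
  if (abs(d) < BRANCH_EPS || abs(s) < BRANCH_EPS) {
    stop("unsupported branch: dcr_dvolrate has no limit form at dv_dt = 0 ",
         "or gfr_k + dv_dt = 0; supply parameters away from these loci",
         call. = FALSE)
  }
  v0 <- params$v0
  vt <- volume_at(params, t)
  L <- -log1p(d * t / v0)                 # ln(V0/V_t)
  x <- exp((1 + g / d) * L)               # (V0/V_t)^(1 + G/D)
  b <- params$gen / s - params$cr0
  value <- x * (g / d^2 * L + (1 + g / d) * t / vt) * b +
    (1 - x) * (-params$gen / s^2)
  .new_sensitivity(value, "general", params, t, "dV/dt", "mg/dL per L/h")
}

#' Central finite-difference slope of the forward model
#'
#' Verification oracle for the analytic sensitivities: central difference
#' `(f(x+h) - f(x-h)) / (2h)` of [creatinine_at()] in the chosen parameter,
#' in canonical units (slope per L/h). If a perturbed parameter set is
#' invalid the step is shrunk tenfold and retried once.
#'
#' @param target `"gfr_k"` or `"dv_dt"`: which parameter to perturb.
#' @param params A [kinetic_params] object.
#' @param t Time, h.
#' @param h Step size, L/h (default `1e-4`).
#' @param mode Validation mode for the perturbed evaluations.
#' @return Slope in mg/dL per (L/h).
#' @export
finite_difference <- function(target = c("gfr_k", "dv_dt"), params, t,
                              h = 1e-4, mode = "strict-clinical") {
  target <- match.arg(target)
  eval_at <- function(step) {
    p_hi <- params; p_hi[[target]] <- params[[target]] + step
    p_lo <- params; p_lo[[target]] <- params[[target]] - step
    (creatinine_at(p_hi, t, mode = "extended-math") -
       creatinine_at(p_lo, t, mode = "extended-math")) / (2 * step)
  }
  ok <- function(step) {
    p_hi <- params; p_hi[[target]] <- params[[target]] + step
    p_lo <- params; p_lo[[target]] <- params[[target]] - step
    # rule C is irrelevant to the difference quotient; check the rest
    validate_params(p_hi, t, "extended-math")$valid &&
      validate_params(p_lo, t, "extended-math")$valid
  }
  if (!ok(h)) {
    h <- h / 10
    if (!ok(h)) stop("finite-difference oracle: perturbed parameters invalid ",
                     "even after shrinking the step", call. = FALSE)
  }
  eval_at(h)
}

#' Numerical sign scan of the GFR sensitivity
#'
#' Draws `n` parameter sets uniformly from clinically valid ranges (seeded)
#' and evaluates [dcr_dgfr()] at each, counting how many derivatives come
#' out non-negative. The model's central monotonicity property asserts the
#' count is zero for `t > 0`. A small fraction of draws is pinned onto each
#' singular locus so all four formula branches are exercised: every 100th
#' draw sets `dv_dt = 0`, every 500th additionally `gfr_k = 0`, and every
#' 250th (when the drawn `dv_dt` is negative) sets `gfr_k = -dv_dt`.
#'
#' @param ranges Named list of `c(lo, hi)` ranges: `cr0` (mg/dL), `gen`
#'   (mg/dL·mL/min), `gfr_k` (mL/min), `v0` (L), `t` (h), and `dv_dt_hi`
#'   (L/h upper bound; the lower bound is `-v0/t * (1 - 1e-6)`, just inside
#'   the volume-exhaustion rule). Defaults cover the clinically plausible
#'   space.
#' @param n Number of draws.
#' @param seed RNG seed.
#' @return A `kgfr_sign_scan` object: counts, the worst (largest) observed
#'   derivative with its parameters, branch tallies, the ranges and seed.
#' @examples
#' sign_scan(n = 1000, seed = 1)$n_nonnegative  # 0
#' @export
sign_scan <- function(ranges = NULL, n = 10000, seed = 1) {
  defaults <- list(cr0 = c(0.2, 15), gen = c(20, 150), gfr_k = c(0, 120),
                   v0 = c(20, 60), t = c(0, 72), dv_dt_hi = 0.5)
  if (is.null(ranges)) ranges <- list()
  ranges <- utils::modifyList(defaults, ranges)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  runifr <- function(r, m) stats::runif(m, r[1], r[2])
  cr0 <- runifr(ranges$cr0, n)
  gen <- runifr(ranges$gen, n) * ML_MIN_TO_L_H
  gfr <- runifr(ranges$gfr_k, n) * ML_MIN_TO_L_H
  v0 <- runifr(ranges$v0, n)
  tt <- runifr(ranges$t, n)
  tt[tt == 0] <- ranges$t[2] / 2            # t > 0 strictly
  lo <- -v0 / tt * (1 - 1e-6)
  dv <- lo + stats::runif(n) * (ranges$dv_dt_hi - lo)
  # pin some draws onto the singular loci so every branch is visited
  i100 <- seq_len(n) %% 100L == 0L
  dv[i100] <- 0
  i500 <- seq_len(n) %% 500L == 0L
  gfr[i500] <- 0
  dv[i500] <- 0
  i250 <- (seq_len(n) %% 250L == 0L) & !i100 & !i500 & dv < 0
  gfr[i250] <- -dv[i250]
  values <- numeric(n)
  branches <- character(n)
  for (i in seq_len(n)) {
    core <- .dcr_dgfr_core(cr0[i], gen[i], gfr[i], dv[i], v0[i], tt[i])
    values[i] <- core$value
    branches[i] <- core$branch
  }
  bad <- values >= 0
  worst_i <- which.max(values)
  structure(
    list(
      n_samples = n,
      n_nonnegative = sum(bad),
      worst_case = list(
        params = kinetic_params(cr0[worst_i], gen[worst_i], gfr[worst_i],
                                v0[worst_i], dv[worst_i],
                                gfr_unit = "L/h", gen_unit = "mg/dL.L/h"),
        t = tt[worst_i],
        value = values[worst_i] * ML_MIN_TO_L_H
      ),
      branch_counts = table(branches),
      ranges = ranges,
      seed = seed
    ),
    class = "kgfr_sign_scan"
  )
}

#' @export
print.kgfr_sign_scan <- function(x, ...) {
  cat(sprintf("Sign scan of d[Cr]/dGFR_K: %d draws (seed %d)\n",
              x$n_samples, x$seed))
  cat(sprintf("  non-negative derivatives: %d\n", x$n_nonnegative))
  cat(sprintf("  largest derivative: %.6g mg/dL per mL/min at t = %.2f h\n",
              x$worst_case$value, x$worst_case$t))
  cat("  branches visited:",
      paste(sprintf("%s=%d", names(x$branch_counts), x$branch_counts),
            collapse = ", "), "\n")
  invisible(x)
}
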