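# The modelling front door: fit per-interval kinetic GFRs to a serial
# creatinine series and return a classed object with the usual accessors.

#' Fit kinetic GFR estimates to a serial creatinine series
#'
#' The model-fitting entry point. Each consecutive pair of measurements
#' defines a clinical interval; within each interval the one-compartment
#' kinetic model is inverted for the constant kinetic GFR that carries the
#' creatinine from the interval's first to its second measurement, given
#' the generation rate, the (carried-forward) volume of distribution and
#' the interval's net fluid balance. Strict monotonicity of the forward
#' model in GFR makes each interval's estimate unique.
#'
#' @param data Data frame with columns `time_h`, `creatinine_mg_dl` and
#'   optionally `net_fluid_l` (net balance over the interval ending at that
#'   row).
#' @param v0 Volume of distribution at the first measurement, L (default
#'   42, total body water of a typical adult).
#' @param gen Creatinine generation rate, mg/dL·mL/min (default 90, i.e. a
#'   steady-state creatinine of 1.0 mg/dL at a GFR of 90 mL/min).
#' @param ... Passed to [invert_gfr()] (`gfr_max`, `tol`).
#' @return An object of class `kgfr`: list with `estimates` (the
#'   [invert_series()] table), `data`, `v0`, `gen`, `call`.
#' @examples
#' p <- kinetic_params(1, 90, 40, 42, 0)
#' obs <- data.frame(time_h = c(0, 24), creatinine_mg_dl = creatinine_at(p, c(0, 24)))
#' fit <- kgfr(obs, v0 = 42, gen = 90)
#' coef(fit)
#' @export
kgfr <- function(data, v0 = 42, gen = 90, ...) {
  est <- invert_series(data, v0 = v0, gen = gen, ...)
  structure(
    list(estimates = est, data = as.data.frame(data), v0 = v0, gen = gen,
         call = match.call()),
    class = "kgfr"
  )
}

#' @export
print.kgfr <- function(x, digits = 4, ...) {
  cat("Kinetic GFR fit\n")
  cat("Call: ", deparse(x$call), "\n\n")
  est <- x$estimates
  lab <- sprintf("(%g, %g] h", est$interval_start_h, est$interval_end_h)
  gfr <- ifelse(est$converged,
                formatC(est$gfr_k_ml_min, digits = digits, format = "f"),
                "not attainable")
  cat(paste(format(lab, width = 14), gfr, "mL/min", collapse = "\n"), "\n")
  invisible(x)
}

#' @export
coef.kgfr <- function(object, ...) {
  est <- object$estimates
  stats::setNames(est$gfr_k_ml_min,
                  sprintf("gfr_%g_%gh", est$interval_start_h,
                          est$interval_end_h))
}

# per-interval parameter set i of a fit (canonical units)
.interval_params <- function(object, i) {
  est <- object$estimates
  kinetic_params(
    cr0 = object$data$creatinine_mg_dl[i],
    gen = object$gen,
    gfr_k = est$gfr_k_ml_min[i],
    v0 = est$v0_l[i],
    dv_dt = est$dv_dt_l_h[i],
    gen_unit = "mg/dL.mL/min", gfr_unit = "mL/min"
  )
}

#' Predict the fitted creatinine trajectory
#'
#' Evaluates the piecewise forward model — each interval run with its
#' estimated GFR from the interval's observed starting creatinine — at
#' arbitrary times. Times beyond the last measurement extrapolate the last
#' interval's parameters; non-attainable intervals yield `NA`.
#'
#' @param object A [kgfr] fit.
#' @param times Times, h (default: the measurement times).
#' @param ... Unused.
#' @return Numeric vector of creatinine, mg/dL.
#' @export
predict.kgfr <- function(object, times = object$data$time_h, ...) {
  est <- object$estimates
  starts <- est$interval_start_h
  ends <- est$interval_end_h
  vapply(times, function(tm) {
    if (tm <= starts[1]) return(object$data$creatinine_mg_dl[1])
    i <- findInterval(tm, starts, rightmost.closed = FALSE)
    i <- min(i, length(starts))          # extrapolate with the last interval
    if (!est$converged[i]) return(NA_real_)
    p <- .interval_params(object, i)
    creatinine_at(p, tm - starts[i])
  }, numeric(1))
}

#' @export
fitted.kgfr <- function(object, ...) {
  predict.kgfr(object)
}

#' @export
residuals.kgfr <- function(object, ...) {
  object$data$creatinine_mg_dl - fitted.kgfr(object)
}

#' @export
summary.kgfr <- function(object, ...) {
  est <- object$estimates
  ss <- ifelse(est$gfr_k_ml_min > 0,
               object$gen / (est$gfr_k_ml_min + est$dv_dt_l_h / ML_MIN_TO_L_H),
               NA_real_)
  structure(
    list(call = object$call, estimates = est, steady_state_mg_dl = ss,
         gen = object$gen, v0 = object$v0,
         residuals = residuals.kgfr(object),
         n_intervals = nrow(est), n_flagged = sum(!est$converged)),
    class = "summary.kgfr"
  )
}

#' @export
print.summary.kgfr <- function(x, digits = 4, ...) {
  cat("Kinetic GFR fit\n")
  cat("Call: ", deparse(x$call), "\n")
  cat(sprintf("Gen = %g mg/dL.mL/min, initial V0 = %g L\n\n", x$gen, x$v0))
  est <- x$estimates
  tab <- data.frame(
    interval = sprintf("(%g, %g]", est$interval_start_h, est$interval_end_h),
    gfr_ml_min = round(est$gfr_k_ml_min, digits),
    v0_l = round(est$v0_l, 2),
    dv_dt_l_h = round(est$dv_dt_l_h, 4),
    steady_state = round(x$steady_state_mg_dl, digits),
    converged = est$converged
  )
  print(tab, row.names = FALSE)
  if (x$n_flagged > 0) {
    cat(sprintf("\n%d interval(s) not attainable by the model:\n", x$n_flagged))
    for (i in which(!est$converged)) cat("  -", est$note[i], "\n")
  }
  invisible(x)
}

#' @export
plot.kgfr <- function(x, n_grid = 200, ...) {
  d <- x$data
  tmax <- max(d$time_h)
  grid <- seq(min(d$time_h), tmax, length.out = n_grid)
  pred <- predict.kgfr(x, grid)
  graphics::plot(d$time_h, d$creatinine_mg_dl, pch = 19,
                 xlab = "time (h)", ylab = "serum creatinine (mg/dL)",
                 ylim = range(c(d$creatinine_mg_dl, pred), na.rm = TRUE), ...)
  graphics::lines(grid, pred, col = "steelblue", lwd = 2)
  graphics::legend("topleft", bty = "n",
                   legend = c("observed", "fitted kinetic model"),
                   pch = c(19, NA), lty = c(NA, 1),
                   col = c("black", "steelblue"))
  invisible(x)
}

#' Simulate new noisy series from a fitted kinetic model
#'
#' Draws observation series from the fitted piecewise trajectory with
#' multiplicative lognormal measurement noise, at the original measurement
#' times.
#'
#' @param object A [kgfr] fit (all intervals converged).
#' @param nsim Number of series.
#' @param seed Optional RNG seed.
#' @param cv Coefficient of variation of the assay noise (default 0.05).
#' @param ... Unused.
#' @return Data frame: one column `time_h` plus `sim_1 ... sim_nsim`.
#' @export
simulate.kgfr <- function(object, nsim = 1, seed = NULL, cv = 0.05, ...) {
  if (any(!object$estimates$converged)) {
    stop("cannot simulate from a fit with non-attainable intervals")
  }
  if (!is.null(seed)) set.seed(seed)
  truth <- fitted.kgfr(object)
  sigma <- log(1 + cv)
  n <- length(truth)
  sims <- vapply(seq_len(nsim),
                 function(k) truth * exp(stats::rnorm(n, 0, sigma)),
                 numeric(n))
  out <- data.frame(time_h = object$data$time_h, sims)
  names(out) <- c("time_h", paste0("sim_", seq_len(nsim)))
  out
}
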