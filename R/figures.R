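# Diagnostic figures: the creatinine-vs-GFR curves with their computed
# tangents, the derivative-vs-GFR curves, and the CKD reciprocal.

.tangent_line <- function(x0, y0, slope, halfwidth, ...) {
  xs <- c(x0 - halfwidth, x0 + halfwidth)
  graphics::lines(xs, y0 + slope * (xs - x0), lty = 2, ...)
}

#' Regenerate the package's diagnostic figures
#'
#' Writes four plots to `out_dir`:
#' \enumerate{
#'   \item creatinine at 24 h versus kinetic GFR for the AKI vignette
#'     (Cr0 = 1, Gen = 90, V0 = 42 L, dV/dt = 0.25 L/h), with computed
#'     tangents at GFR = 10 and (extended-math) GFR = -90 mL/min;
#'   \item the GFR sensitivity versus GFR for that parameter set and for an
#'     extreme-but-allowable set (Cr0 = 9, V0 = 30 L, dV/dt = -0.25 L/h,
#'     Gen = 40), both everywhere below zero;
#'   \item the CKD reciprocal Gen/GFR with its tangents at GFR = 90 and 10;
#'   \item the low- versus high-Cr0 AKI curves with tangents at GFR = 90
#'     and 10 mL/min.
#' }
#'
#' @param out_dir Output directory (created if absent).
#' @param format `"png"` or `"pdf"`.
#' @param t Evaluation time, h (default 24).
#' @return Invisibly, the paths of the written files.
#' @export
regenerate_figures <- function(out_dir, format = c("png", "pdf"), t = 24) {
  format <- match.arg(format)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  open_dev <- function(name) {
    path <- file.path(out_dir, paste0(name, ".", format))
    if (format == "png") {
      grDevices::png(path, width = 900, height = 650, res = 110)
    } else {
      grDevices::pdf(path, width = 8, height = 6)
    }
    path
  }
  paths <- character(0)
  pset <- function(cr0, gen, gfr, v0, dv) {
    kinetic_params(cr0, gen, gfr, v0, dv)
  }
  cr_curve <- function(cr0, gen, v0, dv, grid) {
    vapply(grid, function(g) {
      creatinine_at(pset(cr0, gen, g, v0, dv), t, mode = "extended-math")
    }, numeric(1))
  }
  slope_at <- function(cr0, gen, v0, dv, g) {
    dcr_dgfr(pset(cr0, gen, g, v0, dv), t, mode = "extended-math")$value
  }

  # 1: Cr_t vs GFR with tangents at 10 and -90 mL/min
  paths <- c(paths, open_dev("cr_vs_gfr_tangents"))
  grid <- seq(-120, 150, by = 1)
  y <- cr_curve(1.0, 90, 42, 0.25, grid)
  graphics::plot(grid, y, type = "l", col = "red", lwd = 2,
                 xlab = "kinetic GFR (mL/min)",
                 ylab = sprintf("creatinine at %g h (mg/dL)", t),
                 main = "Creatinine vs kinetic GFR, with computed tangents")
  for (g0 in c(10, -90)) {
    y0 <- cr_curve(1.0, 90, 42, 0.25, g0)
    .tangent_line(g0, y0, slope_at(1.0, 90, 42, 0.25, g0), 40)
    graphics::points(g0, y0, pch = 19,
                     col = if (g0 > 0) "orange" else "darkgreen")
  }
  grDevices::dev.off()

  # 2: derivative vs GFR for two parameter sets, both strictly negative
  paths <- c(paths, open_dev("dcr_dgfr_vs_gfr"))
  grid2 <- seq(0, 150, by = 0.5)
  d1 <- vapply(grid2, function(g) slope_at(1.0, 90, 42, 0.25, g), numeric(1))
  d2 <- vapply(grid2, function(g) slope_at(9.0, 40, 30, -0.25, g), numeric(1))
  graphics::plot(grid2, d1, type = "l", col = "red", lwd = 2,
                 ylim = range(c(d1, d2, 0)),
                 xlab = "kinetic GFR (mL/min)",
                 ylab = "dCr/dGFR (mg/dL per mL/min)",
                 main = "GFR sensitivity stays below zero")
  graphics::lines(grid2, d2, col = "blue", lwd = 2)
  graphics::abline(h = 0, lty = 3)
  graphics::legend("bottomright", bty = "n", lwd = 2, col = c("red", "blue"),
                   legend = c("Cr0=1, Gen=90, V0=42, dV/dt=+0.25",
                              "Cr0=9, Gen=40, V0=30, dV/dt=-0.25"))
  grDevices::dev.off()

  # 3: CKD reciprocal with tangents
  paths <- c(paths, open_dev("ckd_reciprocal"))
  gfr_grid <- seq(5, 150, by = 0.5)
  graphics::plot(gfr_grid, ckd_cr(90, gfr_grid), type = "l", col = "red",
                 lwd = 2, xlab = "GFR (mL/min)",
                 ylab = "steady-state creatinine (mg/dL)",
                 main = "CKD: creatinine = Gen/GFR")
  for (g0 in c(90, 10)) {
    .tangent_line(g0, ckd_cr(90, g0), ckd_slope(90, g0), 30,
                  col = if (g0 == 90) "darkgreen" else "blue")
    graphics::points(g0, ckd_cr(90, g0), pch = 19,
                     col = if (g0 == 90) "darkgreen" else "blue")
  }
  grDevices::dev.off()

  # 4: low vs high starting creatinine, tangents at 90 and 10 mL/min
  paths <- c(paths, open_dev("aki_low_vs_high_cr0"))
  grid4 <- seq(1, 150, by = 0.5)
  y_lo <- cr_curve(1.0, 90, 42, 0.25, grid4)
  y_hi <- cr_curve(9.0, 90, 42, 0.25, grid4)
  graphics::plot(grid4, y_hi, type = "l", col = "red", lwd = 2,
                 xlab = "kinetic GFR (mL/min)",
                 ylab = sprintf("creatinine at %g h (mg/dL)", t),
                 main = "Tangent steepness: low vs high starting creatinine")
  graphics::lines(grid4, y_lo, col = "blue", lwd = 2)
  y0 <- cr_curve(1.0, 90, 42, 0.25, 90)
  .tangent_line(90, y0, slope_at(1.0, 90, 42, 0.25, 90), 40, col = "darkgreen")
  graphics::points(90, y0, pch = 19, col = "blue")
  y0 <- cr_curve(9.0, 90, 42, 0.25, 10)
  .tangent_line(10, y0, slope_at(9.0, 90, 42, 0.25, 10), 40, col = "black")
  graphics::points(10, y0, pch = 19, col = "red")
  grDevices::dev.off()

  invisible(paths)
}
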