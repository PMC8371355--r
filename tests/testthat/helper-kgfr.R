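# Shared fixtures: seeded draws of clinically valid parameter sets.
# Clinical-unit columns (gfr/gen per mL/min) are converted by kinetic_params.

draw_valid_params <- function(n, seed, t_min = 1, t_max = 72) {
  set.seed(seed)
  cr0 <- runif(n, 0.3, 12)
  gen <- runif(n, 30, 140)        # mg/dL.mL/min
  gfr <- runif(n, 2, 120)         # mL/min
  v0 <- runif(n, 25, 55)
  t <- runif(n, t_min, t_max)
  lo <- -v0 / t * 0.9             # safely inside the volume-exhaustion rule
  dv <- lo + runif(n) * (0.5 - lo)
  data.frame(cr0 = cr0, gen = gen, gfr = gfr, v0 = v0, t = t, dv = dv)
}

params_row <- function(d, i) {
  kinetic_params(cr0 = d$cr0[i], gen = d$gen[i], gfr_k = d$gfr[i],
                 v0 = d$v0[i], dv_dt = d$dv[i])
}

# the two worked AKI scenarios used throughout (low and high starting Cr)
worked_low <- function() kinetic_params(1.0, 90, 90, 42, 0.25)
worked_high <- function() kinetic_params(9.0, 90, 10, 42, 0.25)

rel_err <- function(a, b) abs(a - b) / pmax(abs(b), .Machine$double.eps)
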