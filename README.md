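# kgfr — creatinine kinetics and the kinetic glomerular filtration rate

Serum creatinine is the workhorse marker of kidney function, but it only
tracks the glomerular filtration rate (GFR) faithfully at steady state. In
acute kidney injury the creatinine is still moving, and the *kinetic GFR*
framework infers the underlying filtration rate from that moving
creatinine. `kgfr` implements the one-compartment kinetic model behind that
framework for nephrologists, intensivists and modellers: forward
simulation, analytic sensitivity analysis, and inversion of serial
creatinine measurements into per-interval kinetic GFR estimates.

## The model

Creatinine mass balance over its volume of distribution (total body water,
allowed to change at a constant net rate from fluid inputs/outputs):

```
d/dt ( Cr_t · V_t ) = Gen − GFR_K · Cr_t ,      V_t = V0 + (ΔV/Δt) · t
```

with `Cr_t` the serum creatinine (mg/dL), `Gen` the constant muscle
generation rate, `GFR_K` the kinetic GFR and `V0` the initial volume. This
linear first-order ODE has the closed form

```
Cr_t = Cr0 + [ 1 − (V0 / V_t)^(1 + GFR_K/(ΔV/Δt)) ] · ( Gen/(GFR_K + ΔV/Δt) − Cr0 )
```

— the initial creatinine plus a time-evolved fraction of the spread
between it and the eventual steady state `Gen/(GFR_K + ΔV/Δt)`.

The package provides, all in exported functions:

* **Forward model** — `creatinine_at()`, `steady_state_cr()`,
  `volume_at()`, `simulate_trajectory()`, plus an independent numerical
  ODE oracle `simulate_numeric()` (deSolve).
* **Analytic sensitivities** — `dcr_dgfr()` (∂Cr/∂GFR_K, with the three
  removable-singularity limit branches at `ΔV/Δt = 0`,
  `GFR_K = −ΔV/Δt` and `GFR_K = ΔV/Δt = 0` handled analytically) and
  `dcr_dvolrate()` (∂Cr/∂(ΔV/Δt)), verified against a central
  finite-difference oracle.
* **The sign property** — `sign_scan()` draws parameters from the whole
  clinically valid space and confirms numerically that ∂Cr/∂GFR_K is
  negative for every `t > 0`: the GFR can only ever move the creatinine in
  the opposite direction.
* **Inversion** — `kgfr()` fits per-interval kinetic GFRs to a serial
  creatinine series (unique by monotonicity); `invert_gfr()` is the
  single-interval primitive; `ckd_cr()`/`ckd_slope()` give the chronic
  steady-state reciprocal `Gen/GFR` and its tangent `−Gen/GFR²`.
* **Synthetic data and figures** — `scenario_spec()`/`generate_series()`
  (seeded lognormal measurement noise), `regenerate_figures()`.

Units at the user interface are clinical (mg/dL, mL/min, L, h); internally
all rates are L/h (1 mL/min = 0.06 L/h).

## Worked example

A patient with baseline creatinine 1.0 mg/dL (Gen = 90 mg/dL·mL/min,
V0 = 42 L) suffers a GFR drop to 10 mL/min while receiving net
+0.25 L/h of fluid:

```r
library(kgfr)
p <- kinetic_params(cr0 = 1.0, gen = 90, gfr_k = 10, v0 = 42, dv_dt = 0.25)
creatinine_at(p, 24)    # 2.953 mg/dL after one day
steady_state_cr(p)      # heading for 6.353 mg/dL if nothing changes
dcr_dgfr(p, 24)
#> d[Cr]/dGFR_K at t = 24 h: -0.0546996797 mg/dL per mL/min  [branch: general]
```

The negative slope says each additional mL/min of filtration at the 24-h
mark would have lowered that day's creatinine by ~0.055 mg/dL.

Estimating the kinetic GFR from measurements (here a noiseless synthetic
recovery, 40 then 44 mL/min):

```r
seg <- data.frame(duration_h = c(24, 24), gfr_k_ml_min = c(40, 44),
                  dv_dt_l_h = c(0.25, 0))
series <- generate_series(scenario_spec(seg, cr0 = 1.0, gen = 90, v0 = 42,
                                        cv = 0, sampling_interval_h = 24))
fit <- kgfr(series, v0 = 42, gen = 90)
summary(fit)
#>  interval gfr_ml_min v0_l dv_dt_l_h steady_state converged
#>   (0, 24]         40   42      0.25       2.0377      TRUE
#>  (24, 48]         44   48      0.00       2.0455      TRUE
```

Note the creatinine *rose* (1.00 → 1.79 → 1.98 mg/dL) while the kinetic
GFR *improved* (40 → 44): both measurements still sit below their steady
states, so the creatinine keeps climbing even as filtration recovers. That
is a time effect, not a contradiction of the negative partial derivative,
which holds time fixed.

The global sign property:

```r
sign_scan(n = 20000, seed = 1)
#> Sign scan of d[Cr]/dGFR_K: 20000 draws (seed 1)
#>   non-negative derivatives: 0
#>   largest derivative: -3.79301e-06 mg/dL per mL/min at t = 0.01 h
#>   branches visited: general=19771, limit-both-zero=40, limit-dv0=160, limit-gfr-eq-neg-dv=29
```

## Command line

A thin CLI over the same functions is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","kgfr.R",package="kgfr"))')" \
  simulate --cr0 1 --gen 90 --gfr 10 --v0 42 --dvdt 0.25 --hours 48 --out traj.csv
```

Subcommands: `simulate`, `sensitivity`, `scan`, `invert`, `generate`,
`figures`. Exit status 2 flags a parameter-validation failure; `--config
file.json` supplies unit-tagged parameters.

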