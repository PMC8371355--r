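---
title: "Creatinine kinetics: model, sensitivities and inversion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Creatinine kinetics: model, sensitivities and inversion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kgfr)
```

# The model and its assumptions

The package models serum creatinine as a single well-mixed compartment —
total body water — fed by a constant muscle generation rate `Gen` and
cleared by glomerular filtration at rate `GFR_K · Cr_t`. The compartment
volume changes at a constant net rate `ΔV/Δt` from fluid inputs and
outputs:

$$\frac{d}{dt}\big(Cr_t V_t\big) = Gen - GFR_K\,Cr_t,
\qquad V_t = V_0 + \frac{\Delta V}{\Delta t}\,t.$$

The closed-form solution evaluated by `creatinine_at()` is

$$Cr_t = Cr_0 + \Big[1 - \big(V_0/V_t\big)^{\,1 + GFR_K/(\Delta V/\Delta t)}\Big]
\Big(\frac{Gen}{GFR_K + \Delta V/\Delta t} - Cr_0\Big),$$

the initial creatinine plus a time-evolved fraction of the spread to the
steady state $Gen/(GFR_K + \Delta V/\Delta t)$. The assumptions to keep in
mind:

* one compartment, instantaneously mixed — no tubular secretion, no
  multi-compartment redistribution;
* `Gen`, `GFR_K` and `ΔV/Δt` constant *within* a clinical interval; a
  changing clinical course is represented piecewise, with each interval
  restarting the clock (`t = 0`) at its first measurement;
* volume changes linearly and must stay positive throughout.

With a stable volume the approach to steady state is exponential with
time constant $V_0/GFR_K$; with net fluid gain it is algebraic,
$(1 + \tfrac{\Delta V}{\Delta t}t/V_0)^{-(GFR_K+\Delta V/\Delta t)/(\Delta V/\Delta t)}$
— slower, which is why the long-horizon tests treat the two cases
differently.

# Parameters, units and validity rules

| parameter | unit (interface) | unit (internal) | default / typical |
|---|---|---|---|
| `cr0` | mg/dL | mg/dL | measured |
| `gen` | mg/dL·mL/min | mg/dL·L/h | 90 (= 1.0 mg/dL at GFR 90) |
| `gfr_k` | mL/min | L/h | estimated |
| `v0` | L | L | 42 (total body water) |
| `dv_dt` | L/h | L/h | net I/O balance ÷ duration |

All internal rates are L/h; the single conversion 1 mL/min = 0.06 L/h is
applied once at the boundary (`kinetic_params()`, `to_canonical()`), so no
formula ever mixes unit systems. Slopes with respect to GFR are *reported*
in mg/dL per mL/min, the unit clinicians quote, by multiplying the
canonical per-L/h value by 0.06.

`validate_params()` enforces the clinical constraints as data rather than
exceptions, reporting *every* violated rule: creatinine positive (A),
volume positive (B), GFR non-negative (C), generation positive (D), and
`ΔV/Δt > -V0/t` so the compartment is never drained within the horizon
(E). Two modes exist because the mathematics is well defined beyond the
clinic: `"extended-math"` drops rule C so tangents can be examined at
negative GFR (useful when plotting the full creatinine-vs-GFR curve);
everything clinical uses `"strict-clinical"`. Rule E has no upper bound in
theory; values above 10 L/h (configurable) draw an advisory note only,
since such rates are implausible rather than impossible.

# Sensitivities and the removable singularities

`dcr_dgfr()` evaluates the product-rule derivative of the closed form with
respect to `GFR_K`. The raw expression divides by `ΔV/Δt` and by
`GFR_K + ΔV/Δt`, so three loci need analytic limits, each implemented as
its own branch and reported in the result's `branch` field:

* `ΔV/Δt = 0` (`dcr_dgfr_limit_dv0()`) — clinically the most common case:
  $e^{-Gt/V_0}\tfrac{t}{V_0}(\tfrac{Gen}{G}-Cr_0) -
  (1-e^{-Gt/V_0})\tfrac{Gen}{G^2}$;
* `GFR_K = -ΔV/Δt` (`dcr_dgfr_limit_gfr_eq_neg_dv()`) —
  $-\tfrac{1}{D}\ln\tfrac{V_0}{V_t}\big(\tfrac{Gen}{2D}\ln\tfrac{V_0}{V_t}-Cr_0\big)$,
  re-derived independently by series expansion during development and
  cross-checked against the general form; clinically reachable when
  `ΔV/Δt < 0`, otherwise only in extended-math mode;
* both zero (`dcr_dgfr_limit_both_zero()`) —
  $-\tfrac{t}{V_0}(\tfrac{Gen\,t}{2V_0}+Cr_0)$, manifestly non-positive.

**Numerical design.** A branch is taken when the relevant rate is within
`1e-8` L/h of its locus. Away from the loci the general formula is
evaluated in a reformulated, algebraically identical form: with
$L=\ln(V_0/V_t)$ computed as `-log1p(D t / V0)`, $s = G + D$ and
$u = sL/D$,

$$\frac{\partial Cr_t}{\partial GFR_K}
 = \frac{Gen\,L}{D\,s}\,f(u) + \frac{L}{D}\,Cr_0\,e^{u},
\qquad f(u)=\frac{e^u - 1 - u e^u}{u},$$

with $f$ switched to its Taylor series below $|u| < 10^{-4}$. The naive
two-term product-rule evaluation cancels two terms of order $10^9$ near
the $s=0$ locus and loses ~10 significant digits there; the reformulation
keeps the general branch accurate to machine precision arbitrarily close
to every locus, which the continuity tests verify at offsets of `1e-9`.
The same `log1p`/`expm1` treatment is used in the forward model, whose
power term $(V_0/V_t)^{1+G/D}$ is always computed in log space (exponents
above 20 occur at ordinary parameters).

`dcr_dvolrate()` gives the volume-rate sensitivity, whose sign is *not*
constrained (volume loss concentrates, gain dilutes, but the time-evolution
term can pull either way). No limit forms are derived for it; input within
`1e-8` L/h of its singular loci is refused explicitly rather than silently
approximated.

`finite_difference()` is the verification oracle for both derivatives: a
central difference on the forward model, `O(h²)` by construction, with one
automatic tenfold step shrink if a perturbed parameter set falls outside
the validity rules.

# The sign property

The model's central qualitative claim is that $\partial Cr_t/\partial
GFR_K < 0$ everywhere on the clinically valid space for `t > 0` — the GFR
can only move the creatinine in the opposite direction. The package does
not attempt a symbolic proof; `sign_scan()` is the numerical embodiment:
`n` seeded uniform draws over `cr0 ∈ [0.2, 15]` mg/dL, `gen ∈ [20, 150]`
mg/dL·mL/min, `gfr_k ∈ [0, 120]` mL/min, `v0 ∈ [20, 60]` L, `t ∈ (0, 72]`
h and `dv_dt` from just above the rule-E bound `-v0/t` up to `+0.5` L/h,
with a small fraction of draws pinned exactly onto each singular locus so
all four formula branches are exercised (1% at `ΔV/Δt = 0`, 0.2% at the
doubly degenerate point, ~0.4% at `GFR_K = -ΔV/Δt` on its clinically
reachable side). The scan reports the count of non-negative derivatives
(zero, under every seed tried) and the worst case observed. A scan is
evidence over the sampled ranges, not a proof: it cannot speak to
parameters outside them, though the monotone structure of every branch
gives no reason to expect surprises there.

# Inversion

Because the forward map `GFR_K → Cr_t` is strictly decreasing, a creatinine
pair `(cr0, crt, Δt)` determines at most one kinetic GFR. `invert_gfr()`
brackets on `[0, 300]` mL/min (a physiologic ceiling with wide margin) and
solves with `stats::uniroot` to `1e-8` mL/min; round-trip tests recover
generating GFRs to better than `1e-6` mL/min. Observations outside the
attainable band `[Cr(300), Cr(0)]` return `converged = FALSE` with a
diagnostic note — deliberately *not* clamped to a boundary estimate, so
model misfit (lab error, a real `GFR > 300`, wrong `Gen`) stays visible.

`invert_series()` / the `kgfr()` fit apply this per consecutive pair:
each interval restarts `t = 0` at its first measurement, uses the net
recorded fluid balance over the interval divided by its length as
`ΔV/Δt`, and carries the end-of-interval volume forward as the next
interval's `V0` (the model itself is silent on volume carry-over between
intervals; carrying the end volume is the choice consistent with a single
continuous patient). A flagged interval does not abort its neighbours.

# Synthetic data

`generate_series()` emulates serial creatinines from a known programmed
GFR course: piecewise-constant `GFR_K` and `ΔV/Δt` segments, creatinine
and volume carried continuously across joins, sampled on a regular grid.
Measurement error is multiplicative lognormal,
`obs = truth · exp(N(0, σ²))` with `σ = log(1 + CV)` and `CV = 0.05` by
default — creatinine assay error scales with level, and ~5% is a
realistic day-to-day analytic plus biologic variability for a chemistry
analyte. The truth never depends on the seed; the same seed reproduces
the same observations exactly.

What the generator does *not* emulate — and hence what passing round-trip
tests do and do not show: real GFR varies continuously rather than in
steps; `Gen` can fall in critical illness (sepsis) while the model holds
it constant; fluid balance is recorded with error; creatinine has
non-renal elimination at high levels. Recovery of the programmed GFR from
synthetic data therefore validates the *inversion machinery*, not the
clinical accuracy of the one-compartment model itself.

# Numerical choices, degenerate inputs, limitations

* Branch threshold `1e-8` L/h: far below any clinically meaningful rate
  (≪ 1 mL/day of fluid), far above the scale where the stable general
  form loses accuracy.
* `t = 0` returns `cr0` exactly and every GFR derivative is exactly zero
  there — the one point where the sign property is an equality.
* Problem sizes: the verification suites use 1000 randomized scenarios
  for the ODE-oracle and inversion round trips and a 100,000-draw sign
  scan — large enough to cover all branches and parameter corners many
  times over while keeping the whole suite under a minute per property.
* The steady state requires `GFR_K + ΔV/Δt > 0`; otherwise creatinine
  grows without bound and `steady_state_cr()` signals a classed error
  (`kgfr_no_steady_state`) rather than returning a negative
  concentration.
* Known limitations: constant `Gen` (a step change can be emulated by
  splitting intervals and changing `gen` between fits); no derivatives
  with respect to `Cr0`, `Gen`, `V0` or `t`; no eGFR equations or urine
  clearance — this package is strictly the kinetic compartment model.

# A worked contrast: chronic versus acute

```{r ckd-aki}
# chronic (steady-state) picture: reciprocal curve, tangents -Gen/GFR^2
ckd_cr(90, c(90, 10))
ckd_slope(90, c(90, 10))

# acute picture at the 24-h mark, same generation rate
low  <- kinetic_params(1.0, 90, 90, 42, 0.25)
high <- kinetic_params(9.0, 90, 10, 42, 0.25)
creatinine_at(low, 24); creatinine_at(high, 24)
dcr_dgfr(low, 24)$value; dcr_dgfr(high, 24)$value
```

The acute tangents reproduce the chronic pattern — shallow at low
creatinine, steep at high creatinine — but blunted: at 24 h only part of
the steady-state spread has evolved. As the horizon grows with stable
volume, `dcr_dgfr` converges to the chronic tangent `-Gen/GFR²` exactly,
which the test suite checks at 40 volume-turnover times.
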