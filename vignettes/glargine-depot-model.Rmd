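---
title: "A mechanistic depot-absorption model for insulin glargine 100 and 300 U/mL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A mechanistic depot-absorption model for insulin glargine 100 and 300 U/mL}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glarginepk)
```

## The problem

Insulin glargine is the only widely used basal insulin whose retardation
principle is subcutaneous precipitation: the injected pH-4 solution is
isoelectric at tissue pH and forms an amorphous depot, and the plasma
profile is governed by how fast that depot redissolves. The two marketed
strengths, Gla-100 (100 U/mL) and Gla-300 (300 U/mL), deliver the same
molecule and the same units per dose, but Gla-300 does so in one third of
the volume. Since redissolution happens at the depot surface, geometry
alone predicts a `(1/3)^(2/3) ≈ 0.48`-fold redissolution rate for Gla-300 —
the mechanism this package makes quantitative.

## Model structure and assumptions

The state is the amount (monomer-equivalent pmol) in eight pools: injected
soluble glargine `S`, precipitate `P`, dissolved hexamer `H`, dimer `D`,
monomer `M` in SC tissue, plasma `A`, and two accounting sinks (`L_deg`,
cumulative SC degradation; `L_cl`, cumulative clearance) that close the mass
balance exactly.

* **Formation.** `dS/dt = -k_FP·S`. A fraction `pw` of the precipitating
  flux stays in solution and joins the hexamer pool directly — the "small
  immediately absorbed" portion; the rest builds `P`.
* **Redissolution** is Nernst–Brunner, i.e. proportional to the depot
  surface area. Assuming a single body of volume `V = P / C_Formulation`,
  `SA = f_vol·(36π)^(1/3)·V^(2/3)`, where `f_vol` (3.6) corrects for the
  depot spreading along septal spaces rather than staying spherical. The
  per-area rate mixes the precipitate and soluble rates by the surface
  solution fraction: `J = [(1-pw)·k_pre + pw·k_sol]·SA(P)`.
* **Dissociation and loss.** First-order hexamer→dimer→monomer kinetics
  (`k_HD`, `k_DH`, `k_DM`) with non-specific degradation of every species.
  The hexamer loss rate is `1.948e-5 / V_Injection` (volume in mL), the
  dimer rate 4.57× that, the monomer rate fixed at 2.9e-3 /min. The volume
  dependence is the bioavailability mechanism: a Gla-300 injection has a
  third of the volume, hence 3× the hexamer/dimer loss rates.
* **Disposition.** Monomers are absorbed at `k_abs`; clearance is weakly
  saturable, `CL(C) = k_Clearance/(1 + α·C)` with `α·C < 1%` at therapeutic
  concentrations. `V_Plasma = 0.1421 L/kg × body mass`.

Deliberately out of scope: conversion to the M1 metabolite (identical for
both products and therefore irrelevant to their comparison), glucose
pharmacodynamics, and between-subject variability — the model describes an
average subject.

## Parameters, units, and the choices behind them

All computation is in pmol, minutes and mm; doses convert at 1 U = 6 nmol
(consistent with every clinically quoted U↔nmol pair, e.g. 0.4 U/kg =
2.4 nmol/kg). Three choices deserve explanation:

* **Area unit of `k_pre`/`k_sol`.** The dissolution constants (0.28 and
  0.34 pmol·min⁻¹ per unit area) are interpreted per mm². Read per cm²
  literally, a 32 U Gla-100 depot would take roughly half a year to
  redissolve, irreconcilable with the observed 24–36 h single-dose
  profiles; per mm² yields depletion in ~42 h (Gla-100) and ~88 h (Gla-300),
  matching the known time course. Equivalently, the rates can be read as
  28 and 34 pmol·min⁻¹·cm⁻² with areas in cm².
* **`pw` (surface solution fraction), default 0.1.** No published value
  exists. It is deliberately non-critical: because `k_pre ≈ k_sol`, the
  effective release coefficient changes by only ~6% as `pw` spans [0, 0.3],
  and steady-state daily exposure — which depends on bioavailability, not
  release speed — moves by under 0.5% (asserted by test). It is exposed as
  a configurable parameter.
* **Absorption acts on monomers only.** A single absorption constant is
  parameterized, sourced from monomer-model literature; dimer absorption
  has no constant and is omitted.

## Numerical treatment

The system is integrated with `deSolve::lsoda` (relative tolerance 1e-8,
absolute 1e-6 pmol). The depot term `P^(2/3)` reaches zero in finite time
with unbounded curvature; the right-hand side evaluates it on `max(P, 0)`,
which leaves `P` parked at zero after depletion (the formation term is the
only inflow). Mass conservation — the state components plus sinks summing
to the dose — holds to ~1e-14 relative in practice and is asserted at 1e-6
at every output time. AUCs use the trapezoid rule on a 1-minute output grid;
refining the grid changes 24-h AUCs by well under 0.01%.

Closed forms serve as independent oracles: the depletion time of a pure
depot, `t = 3·P0^(1/3)/(k_pre·a)` with `a = f_vol(36π)^(1/3)/C^(2/3)`
(cube-root scaling: 8× the dose, 2× the time), and the bioavailability of
the first-order SC network by first-step analysis,
`F = k_HD·k_DM·f_M / [(k_HD+λ_H)(k_DM+k_DH+λ_D) − k_HD·k_DH]` with
`f_M = k_abs/(k_abs+λ_M)`, which is exactly 1 when all losses vanish and
matches the simulated cleared fraction to ~1e-4.

## Multi-dose simulation

Steady state is constructed by **superposition**: once-daily single-dose
profiles are summed with 24-h shifts, which is exact for a linear system
and the construction used in the source analyses. The clearance saturation
makes the system only weakly nonlinear; a "full" mode that integrates one
depot per injection against a shared plasma compartment differs from
superposition by ≤0.01% with linear clearance and ≤1% with the default
`α` at 0.4 U/kg, which bounds the approximation error.

Two reconstruction choices in the regimen analyses were genuinely open:

* **Steady-state criterion.** The day a regimen "reaches steady state" is
  defined as the first day whose trailing 24-h AUC is within 5% of the
  day-6 value. Five percent reproduces the published day counts (2 days for
  Gla-100, 3 for Gla-300) and is of the order of assay noise; the tolerance
  is an explicit argument of `time_to_steady_state()`.
* **Flexible-interval scenarios** are encoded as per-dose shifts from the
  24-h raster after six establishing doses: one dose 3 h early (intervals
  21, 27 h); one late, one early (27, 18, 27 h); one early, one late
  (21, 30, 21 h). In all three, the max-to-min ratio of trailing 24-h AUC
  over the perturbed window is strictly smaller for Gla-300 (0.432 U/kg)
  than Gla-100 (0.4 U/kg).

The default product-switch pairing (Gla-100 0.4 U/kg ↔ Gla-300 0.432 U/kg)
uses the ~8% Gla-300 dose increase that `harmonizing_dose_scale()` finds by
bisection to equalize steady-state daily exposure; the closed-form
bioavailability ratio predicts ~9%, the difference coming from clearance
saturation and the dose-dependence of the loss rates (a larger Gla-300 dose
has a larger volume and hence slightly better bioavailability).

## Calibration

`fit_profile()` reproduces the estimation procedure as a contract: bounded
Levenberg–Marquardt least squares (`minpack.lm::nls.lm`) on the residuals at
fixed clock times (6, 8, 12, 16, 20, 24, 28 h post dose), restarted from
multiple seeded log-uniform initial points within the bounds, with the full
per-start trace retained. The fittable subset comprises the depot parameters
(`k_FP`, `k_pre`, `k_sol`), the dissociation rates (`k_HD`, `k_DM`) and the
hexamer loss numerator. Identical spec, data and seed give bit-identical
results. On noiseless synthetic data single-parameter fits recover the truth
to better than 1% and a joint three-parameter fit to better than 5%; under
10% multiplicative noise `k_pre` is recovered within 10% across seeds.

## What the synthetic data do and do not show

The original mean concentration curves from the euglycemic clamp studies are
not published as machine-readable tables, so the calibration and validation
machinery is exercised against synthetic profiles: the model's own output at
a stated parameter set, sampled at clamp-like times (half-hourly over 36 h
by default), with seeded multiplicative log-normal noise (mean-corrected, so
the expected factor is 1; concentration data are positive and
right-skewed). Passing recovery tests therefore demonstrates that the
estimation machinery is correct and well conditioned — not that the model is
structurally adequate for real clamp data, which would require the original
measurements. All randomness flows from explicit integer seeds, and
generation restores the caller's RNG stream.

## Problem sizes used in the shipped checks

The shipped tests and the acceptance script run single doses over 6-day
horizons on a 1-minute grid, 6–12-dose regimens, a 50-shell spatial run over
36 h, multi-start fits with 2–3 starts, and 200-replicate noise
calibrations; the full suite completes in well under a minute on one core.

## Known limitations

* The depot is a single coherent body; fragmentation or multi-site
  injection splitting is not modeled (`f_vol` absorbs shape effects only).
* Bioavailability differences rest entirely on the volume-dependent loss
  rates; at high Gla-300 doses the model likely underestimates local loss,
  and it has no covariates beyond body mass.
* The spatial variant exists to represent diffusion explicitly; with
  first-order local kinetics it cannot change plasma output, so `D_H`,
  `D_D` and `V_SC` are unidentifiable from plasma data alone.
* M1 metabolite kinetics and glucose dynamics are out of scope.
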