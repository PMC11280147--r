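---
title: "Estimating per-lung pulmonary vascular resistance in Glenn physiology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating per-lung pulmonary vascular resistance in Glenn physiology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glennpvr)
```

## The problem

In the staged palliation of single-ventricle heart disease, the Glenn
operation routes superior vena cava (SVC) blood directly into the left and
right pulmonary arteries. How blood then distributes between the lungs is
governed by each lung's pulmonary vascular resistance (PVR), and per-lung
PVR is the key input for simulating candidate Fontan completions. It is not
measured clinically: catheterization (CATH) reports a single Fick-based
total PVR, while cardiac MRI (CMR) reports branch flows. This package
estimates per-lung PVR from those routine data.

All computation is done in BSA-indexed units — flows in L/min/m²,
resistances in WU·m², pressures in mmHg — so that an indexed resistance
times an indexed flow is a pressure and patients of different sizes are
comparable. Absolute/indexed conversion helpers (`index_flow()`,
`deindex_flow()`) exist but the pipeline never needs them, because the
bundled cohort is indexed throughout.

## The 0D circuit

`glenn_circuit()` models the pathway as a purely resistive network: inlet →
series resistor `r_svc` (which also absorbs the pulmonary-artery junction's
resistance) → junction node → two branches, each a proximal vessel resistor
in series with an outlet resistor ending at a constant distal pressure.
Every element obeys ΔP = R·Q. There is deliberately no compliance: with no
storage elements the circuit is memoryless, one simulated cycle *is* the
periodic steady state, and each timestep reduces to Kirchhoff's current law
at the junction, solved in closed form by `solve_timestep()`.

Two design points were genuinely open and were settled as follows:

* **Where the junction resistor sits.** It is folded into the series inlet
  resistor, upstream of the split, so it loads both lungs equally. This
  preserves the reporting definition of per-lung PVR as
  (P̄_SVC − p_dist)/Q̄_branch, making the reported value independent of how
  resistance is split along the pathway (verified by the decomposition
  tests).
* **The distal pressure.** Both branches default to the patient's mean
  left-atrial pressure, the downstream pressure of the pulmonary circuit,
  matching the direct computed-PVR formula (P_SVC − P_LA)/Q.

Proximal vessel resistances default to zero — all resistance in the outlet
resistors — with `poiseuille_resistance()` available to set them from vessel
geometry (8μL/(πr⁴), converted from dyn·s·cm⁻⁵ to Wood units; default blood
viscosity 0.04 poise). Because the reported PVR is decomposition-invariant,
this default does not bias the estimates.

Every closed-form solve is cross-checkable against `nodal_oracle()`, an
independent path that assembles the full 6-unknown linear system (node
pressures and branch flows; Ohm's law per resistor, current conservation at
the junction) and solves it generically. The test suite sweeps randomized
circuits and requires agreement to 1e-10 and mass conservation
Q_L + Q_R = Q_in to 1e-12 relative at every timestep.

## Waveforms and discretization

A `flow_waveform()` is one cardiac cycle sampled on the endpoint-exclusive
uniform grid t = 0, Δt, …, (n−1)·Δt with n = l/Δt, interpreted periodically.
The endpoint-exclusive convention matters: a full sinusoidal period then
averages *exactly* to its mean, so synthetic waveforms honour their
prescribed cycle-averaged flow to machine precision. Cycle averages are the
plain sample mean (`time_average()`), the same (1/n)Σ discretization the
calibration cost uses. Defaults are Δt = 0.001 s and cycle length 0.8 s
(~75 bpm, typical for the 2–5-year-olds the method targets); both are
scenario parameters, not constants. `resample_linear()` re-grids a cycle by
piecewise-linear interpolation with periodic wrap on the final segment, so
measured waveforms on any grid can be aligned with the simulation grid.

## Calibration

`optimize_pvr()` tunes the two outlet resistances to match a
`clinical_target()` — observed branch flow waveforms plus the mean SVC
pressure — by minimizing `waveform_cost()`:

* per-branch mean squared flow error over the cycle, each normalized by the
  mean observed branch flow, plus the squared mean-pressure error normalized
  by the observed mean pressure. The cost is implemented literally in this
  form, with heterogeneous units (flow and pressure) and no
  re-normalization; the constant pressure term is added once, which a unit
  test confirms equals carrying it under the (1/n) sum.
* The optimizer is the standard Nelder-Mead simplex (reflection 1,
  expansion 2, contraction 0.5, shrink 0.5), implemented in-package so that
  convergence can be declared on an *absolute* 1e-4 tolerance applied to
  both the simplex parameter spread and the function-value spread, with an
  evaluation count and a `converged` flag in the result. Candidate points
  with a non-positive resistance receive a finite penalty (1e6) instead of
  being simulated, keeping the method a plain unconstrained simplex. The
  default evaluation budget is 2000; typical fits converge in 60–90
  evaluations, and an exhausted budget returns the best point flagged
  `converged = FALSE` rather than an error.
* Every patient starts from the same point: `initial_guess()` returns the
  cohort mean of the directly computed per-lung PVR, less any proximal
  series resistance, floored at 0.1 WU·m².

The simulator is a pluggable backend: `"closed_form"` (default), `"nodal"`
(the oracle path, used in tests to show backend-agnosticism to 1e-8), or any
user function mapping an outlet-resistance pair to a simulation — the
contract a 3D CFD runner would implement. Implementing such a runner is out
of scope here.

## The synthetic-data generator

Real phase-contrast waveforms for the bundled cohort are not available, so
recovery studies use `make_synthetic_patient()`: a ground-truth circuit is
simulated on a raised-sinusoid inlet
mean·(1 + pulsatility·sin(2πt/l + phase)), and the branch flows — plus
seeded zero-mean Gaussian noise scaled to a fraction of each branch's mean
flow — become the "observed" data. The inlet is treated as exactly known
(it is the model's boundary condition, not a fitted quantity), so noise is
applied to branch flows only. Scenario defaults mirror the bundled cohort:
inlet mean 1.97 L/min/m², distal pressure 4.4 mmHg, outlet resistances near
the cohort-mean computed PVR (6.2 and 5.3 WU·m²), pulsatility 0.3.
`make_synthetic_cohort()` draws per-patient ground truths from normal
distributions matched to the cohort's spread, truncated away from
non-physiologic values.

What passing recovery tests do and do not show: they demonstrate that the
calibration identifies the outlet resistances of data generated *by the
same model family* — a well-posedness and correctness check, including
robustness to observation noise. They cannot show that the resistive model
captures real pulmonary beds (no compliance, rigid assumptions, sinusoidal
rather than measured waveform shapes), and with only cycle-averaged
quantities entering the cost's optimum, the waveform shape is deliberately
uninformative about the fitted parameters.

```{r recovery-example}
sp <- make_synthetic_patient(
  synthetic_scenario(r_lpa_outlet = 9.2, r_rpa_outlet = 5.3, seed = 1))
fit <- optimize_pvr(sp$truth, sp$inlet, sp$target,
                    init = initial_guess(load_patient_table("bundled")))
glance(fit)
```

## The direct baseline and agreement statistics

`computed_pvr()` is the non-iterative reference: (P_SVC − P_LA)/Q per lung,
with the total as the parallel combination r_l·r_r/(r_l + r_r) — chosen
because both lungs share the same driving gradient, which makes it
algebraically identical to gradient-over-summed-flow and bounded above by
the smaller lung resistance.

The comparison toolkit implements the conventions used throughout
method-agreement work on such cohorts:

* `paired_compare()` gates on Shapiro-Wilk normality of the paired
  differences at 0.05: paired t-test if normal, Wilcoxon signed-rank
  otherwise, reporting which test fired.
* `icc_agreement()` is ICC(2,1) — two-way random effects, absolute
  agreement, single measure — with the Shrout-Fleiss F-based confidence
  interval. The absolute-agreement variant was fixed by checking it against
  an independent two-way-ANOVA implementation on the bundled cohort, and
  the test suite pins both the point estimate and the interval to those
  independently computed reference values, so a silent switch of variant
  would be caught.
* `bland_altman()` uses bias ± 1.96·SD of the differences (sample SD), and
  `percent_difference()` is defined per pair relative to a stated reference,
  then averaged — matching the sign and magnitude behaviour of cohort
  comparison tables better than a ratio of means.

## Numerical choices and degenerate inputs

* Resistances must be non-negative; a circuit with both branch totals zero
  is singular and rejected. Exactly one zero-total branch is legal but
  degenerate (it pins the junction to its distal pressure) and is flagged
  on the result.
* Negative transpulmonary gradients produce a warning, not an error — they
  occur in noisy clinical data and the sign is informative.
* Zero branch flow is a hard domain error for PVR (division by the flow),
  but cohort-level commands flag the offending patient and continue.
* Cohort summaries use the sample (n−1) standard deviation, verified to
  match the bundled table's printed summary row.
* The bundled table is printed to two decimals (integer pressures), which
  quantizes any statistic derived from it at about the third decimal; the
  package reports full-precision values computed from the table as shipped.

## Problem sizes

Defaults used by the test suite and the reproduction script: 0.8 s cycles at
Δt = 0.001 s (800 timesteps), 10-patient synthetic recovery cohorts, 10
noise replicates at 2% flow noise, and 1000 randomized circuits for the
solver cross-check. Because each simulation is a single vectorized
closed-form solve, a full 16-patient calibration run takes a few seconds.

## Known limitations

* The resistive model omits compliance and inertance by design (to mirror a
  rigid-wall reference model and avoid resistance/compliance
  identifiability problems); it cannot reproduce waveform phase lags.
* Only two parameters are calibrated; proximal resistances must come from
  geometry (Poiseuille) or an external source.
* The direct and calibrated estimates share their input data, so their
  mutual agreement is a consistency check, not an independent validation;
  the only independent clinical anchor, Fick-based CATH total PVR, is known
  to disagree with CMR-flow-based estimates, and the package's agreement
  statistics quantify rather than resolve that discrepancy.
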