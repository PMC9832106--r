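---
title: "Global sensitivity analysis of a post-hepatectomy hemodynamics model"
author: "hepasens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Global sensitivity analysis of a post-hepatectomy hemodynamics model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Partial hepatectomy — the surgical removal of part of the liver — can
precipitate post-operative portal hypertension and liver failure when the
remnant liver cannot accommodate the unchanged portal inflow.  A
lumped-parameter (0D) model of the whole circulation with a hepatic
sub-circuit can predict the hemodynamic response to a resection: portal
pressure `P_pv`, the portocaval gradient `PCG` (portal minus caval
pressure), mean arterial pressure `MAP`, cardiac output `CO`, and the
hepatic arterial and portal flows `Q_ha`, `Q_pv`, each taken as the mean
over a cardiac cycle before and after the virtual resection.

`hepasens` implements that model together with the three analysis layers
built on top of it:

1. variance-based global sensitivity analysis (Sobol indices, Saltelli
   pick–freeze designs) of ten varied inputs — four heart-elastance
   parameters, five vascular resistances, and the resected liver-mass
   fraction `hpx`;
2. a *physiologically filtered* polynomial-chaos surrogate whose
   orthonormal bases are built on the filtered sample itself (discrete
   Stieltjes recurrences), giving Sobol indices analytically from the
   coefficients;
3. a weighted calibration of heart elastances to patient measurement
   targets, in an original (four elastances) and a reduced
   (left-ventricle-only, admissible-region-constrained) variant.

## The circulation model

The closed loop has ten volume states: right atrium, right ventricle, a
pulmonary compartment, left atrium, left ventricle, systemic arteries, a
portal/splanchnic venous compartment, two liver lobes, and the vena
cava.  Heart chambers are time-varying elastances
$E(t) = E_b + E_a\,e(t)$ with a piecewise-cosine activation $e(t)\in[0,1]$
(ventricular window 0.36 s, atrial kick 0.18 s ending just before
systole; heart period fixed at 60/70 s since no chronotropic parameter
is varied).  Valves are ideal diodes regularized by a smooth positive
part $(\Delta P + \sqrt{\Delta P^2+\varepsilon^2})/2$ with
$\varepsilon = 0.05$ mmHg, which removes the stiffness a hard switch
would introduce.  The systemic artery feeds three parallel branches: the
"other organs" resistance `R_OO` to the vena cava, the digestive branch
`R_DO` into the portal compartment and on through the lobar portal
resistances into the liver, and the hepatic artery `R_ha` directly into
the lobes; the lobes drain through `R_hv` to the vena cava.

The ten varied inputs and all fixed constants are documented in
`?parameter_vector` and `?default_config`.  The fixed constants (total
blood volume 5000 mL, arterial compliance 1.6 mL/mmHg, venous reservoir
compliance 80 mL/mmHg, right-ventricular and left-atrial elastances,
valve and venous-return resistances) were placed once so that the
central cohort parameters reproduce a typical resting adult:
MAP ≈ 92 mmHg, CO ≈ 5 L/min, P_pv ≈ 10 mmHg, PCG ≈ 6 mmHg, portal flow
≈ 20% and arterial hepatic flow ≈ 5% of CO.

**Virtual hepatectomy.**  The resected fraction `hpx` of total liver
mass is removed right lobe first (default mass split 0.6/0.4,
configurable), the remainder from the left lobe; each lobe's portal,
arterial and venous resistances scale inversely with its remaining mass
fraction, a fully resected lobe leaves the network, and all
extra-hepatic parameters are untouched.  The post-resection run restarts
from the terminal pre-resection state, modelling an instantaneous
intra-operative change.  Only resistances are rescaled; whether lobe
compliance should shrink as well is left to the configuration (we keep
it fixed, since the stored lobar volume represents the remnant
vasculature's reserve, and rescaling it has no visible effect on the
cycle-averaged outputs at the default compliances).

**Numerics.**  The core integrates with a fixed-step classical RK4
scheme in compiled code (`dt = 2e-4` s, aligned to the period).  With
the regularized valves the smallest time constant is
$R_\mathrm{valve}/E_\mathrm{max}\approx 2$ ms, an order of magnitude
above the step, so the scheme is stable and accurate; a fixed step also
makes every run bit-identical for identical inputs, which the test suite
asserts.  Because every flow enters one state positively and another
negatively, total blood volume is conserved to round-off (checked to
1e-6 relative).  A run is accepted as periodic when all six
cycle-averaged outputs change by less than 1e-3 (relative) between
consecutive cycles, within at most 80 cycles; cohort drivers warm-start
from the periodic state of the cohort-median patient, roughly halving
the cycles needed.

## Input distributions and the synthetic cohort

The sensitivity study samples the ten inputs independently (a
requirement of the Sobol estimator).  Marginals can be estimated from a
cohort table by a boundary-corrected kernel density estimate
(`fit_kde`: Gaussian kernel, Silverman bandwidth, reflection at the
support bounds, unit mass on the bounds — choices we fixed ourselves,
as standard and reproducible) or specified as truncated parametric
families (`trunc_family`).  The packaged default cohort
(`default_cohort_spec`) uses the family per input that a best-fit
selection over {logistic, uniform, exponential, normal, cauchy}
(`best_fit_family`, ML + BIC) would report for such data: logistic
amplitudes, uniform atrial baseline, exponential LV amplitude, normal LV
baseline, and truncated Cauchy for the hepatic resistances and `hpx`.
Locations and scales were placed once so that the simulated
pre-resection outputs fall predominantly (≈ 85–90%) inside the
physiological box below while still exercising hypo- and hyperdynamic
extremes; they are part of the study conditions and are not tuned
thereafter.  Heavy-tailed families are truncated exactly by cdf
inversion, so no draw ever leaves its stated support.

What the generator deliberately does *not* emulate: between-input
correlations of a real cohort (inputs are sampled independently),
within-patient measurement uncertainty, and peroperative events such as
blood loss or vasodilation.  Passing tests therefore demonstrate the
correctness and internal consistency of the pipeline under realistic
marginal variability, not agreement with any specific clinical
population.

## Sobol indices

`build_saltelli_design` draws the paired matrices $A$, $B$ and the
hybrids $AB_j$ from a scrambled Sobol' sequence in dimension $2d$
(Gray-code construction with the published Joe–Kuo direction numbers,
random digital shift keyed by the seed), mapped through the marginal
inverse cdfs — first and total indices for all $d$ inputs at
$(d+2)N$ model evaluations.  `estimate_sobol` uses the modern default
estimators of this family: Saltelli-2010 for first order,
$S_j = \overline{Y_B(Y_{AB_j}-Y_A)}/\widehat{\mathrm{var}}(Y)$, and
Jansen for the total,
$S^{tot}_j = \overline{(Y_A-Y_{AB_j})^2}/(2\widehat{\mathrm{var}}(Y))$.
Small negative estimates are Monte-Carlo noise and are reported
unclipped.  `convergence_error` (max-over-inputs index change between
two base sizes), `confidence_intervals` (percentile intervals over
independently seeded repeats) and `classify_sensitivity` summarize the
results; the classification thresholds (sensitive $S\ge 0.2$; fairly
sensitive $0.05\le S<0.2$ with $|S^{tot}-S|<0.05$; insensitive
$S^{tot}<0.05$) operationalize the usual qualitative legend of such
tables and are configurable.

## The physiologically filtered PCE

Raw input sampling produces some patients no anesthesiologist would
recognize.  The physiological filter (`filter_bounds`: MAP 50–130 mmHg,
CO 3–10 L/min, P_pv 3–20 mmHg, PCG 1–14 mmHg; closed intervals, since
clinical bounds are inclusive by convention) discards those input–output
couples on the *pre-resection* outputs only.  Filtering breaks the
pick–freeze pairing, so Sobol indices after filtering are never
recomputed by pick–freeze on the retained subset; instead a degree-4
total-order polynomial chaos expansion is fitted to the retained couples
and its coefficients give the indices analytically
(first order: squared coefficients of multi-indices involving only input
$j$; total: any power of $j$; normalized by the Parseval variance).

The orthonormal marginal bases are built on the retained sample itself
by the discrete Stieltjes procedure — numerically stabler than
Gram–Schmidt on the Vandermonde columns — with a full-reorthogonalization
refinement pass triggered if the empirical Gram matrix deviates from
identity by more than 5e-2 anywhere (at degree 4 the plain recurrence
already meets the tolerance).  The filtered sample makes the inputs
mildly dependent, but the basis is still built per-marginal and
tensorized; this follows the construction the method prescribes, and the
resulting Gram deviation is part of what the validation measures.
Multi-indices are ordered graded-lexicographically, zero index first,
giving `choose(d+q, q)` = 1001 terms at d = 10, q = 4; least squares is
solved by rank-revealing QR with a 1e-8·trace ridge fallback above
condition 1e10 (heavy-tailed filtered samples can ill-condition
high-degree terms; in practice the condition number stays near 100).
Fidelity is scored by the predictive squared correlation coefficient
$Q^2$ on retained test couples enforced (structurally, via row
fingerprints) to be disjoint from the training rows.  We filter the test
draws with the same box as the training couples, so the score measures
fidelity on the physiological region the surrogate is actually used on.

The retained couples, with provenance (seed, bounds, counts), form the
virtual population (`assemble_population`, `write_population`), and
`filtered_input_summary` exports per-input ranges plus pairwise
occupancy grids for (Ea_LV, Eb_LV) and (Eb_LV, R_OO) — the two couples
whose joint distribution the filter visibly carves — which double as the
admissible region of the reduced calibration.

## Calibration

`weighted_error` implements the weighted relative error
$\mathrm{Err}_{L^2} = \sqrt{\sum_i w_i\,((Y^{target}_i -
Y^{sim}_i)/Y^{target}_i)^2}$ over the six outputs with clinical
confidence weights 1 (PCG, MAP, CO), 2/3 (P_pv) and 1/3 (the flows,
which are themselves derived as 20%/5% of CO).  The calibration pipeline
first fixes the five resistances algebraically from the patient's own
measurements (`derive_resistances`; caval pressure from P_pv − PCG, one
third of the gradient assigned to the portal inflow resistance — the
model's nominal split).  The measurements also pin the caval pressure
and the cardiac output *jointly*, which no single population value of
the venous constants can honor: a hypodynamic patient with a preserved
caval pressure needs a damming venous-return resistance, a hyperdynamic
one free venous return and a fuller reservoir.  Two venous quantities
are therefore derived per patient before any optimization: the
venous-return resistance from the right-ventricular preload the target
stroke volume requires ($P_{ra} = E_{b,RV}(SV + \text{ESV margin})$),
and the blood volume by a short damped fixed point matching the
simulated caval pressure (four extra model runs, counted in the
evaluation budget).  The optimizer then searches only heart elastances
with a
derivative-free Nelder–Mead simplex (restart on non-convergence,
evaluation budget 300, relative tolerance 1e-4): four elastances in the
original strategy, only the left-ventricular pair in the reduced one,
with proposals outside the filtered admissible region rejected by a
penalty barrier.  `R_OO` itself stays fixed at its measurement-derived
value and only participates in the region membership test — freeing it
would reintroduce a third dimension the strategy exists to avoid.
`compare_strategies` runs both variants over the nine representative
virtual patients (`virtual_patients`: baseline / hypodynamic /
hyperdynamic circulation at low, intermediate and high
portal-hypertension risk) under matched budgets.

## Problem sizes used by the tests and the acceptance script

The package's own validation runs at desk scale, chosen so the full
suite completes in minutes while every estimate stays well inside its
tolerance: the study artifacts use a 5,500-patient synthetic cohort
(≈ 4,800 retained; 4,200 training and ≥ 1,200 test couples for the
degree-4 surrogate); benchmark estimators run at $N = 2^{14}$;
estimator-convergence between $N = 10^4$ and $2\times 10^4$ is measured
on the validated surrogate of the circulation model (the same check at
the full model needs ≈ 3.6·10⁵ simulations — the surrogate reproduces
the model at $Q^2 > 0.995$, well below the 0.017 error being measured);
the acceptance script rebuilds the admissible region from a
2,000-patient cohort.  Scaling any of these up is a matter of the `N`
arguments.

## Known limitations

* The model is topology-faithful, not coefficient-faithful, to any
  particular published 0D circulation; conclusions are about parameter
  roles, not absolute hemodynamic predictions.
* No baroreflex, no 1D wave propagation, no liver regeneration, no
  peroperative events; within-patient uncertainty is out of scope.
* The filtered sample induces input dependence that the tensorized
  per-marginal basis ignores (by construction of the method).
* Pairwise occupancy grids are a coarse (20×20) representation of the
  admissible region; isolated empty cells inside it act as spurious
  barriers, which the calibration tolerates via its restart.
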