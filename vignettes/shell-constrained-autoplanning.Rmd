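---
title: "Two-step automated radiosurgery planning with dose-spillage shells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step automated radiosurgery planning with dose-spillage shells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(shellplan)
```

## The planning problem

Radiosurgery of a benign vestibular schwannoma delivers a single fraction of
12 Gy, prescribed at the 80% isodose line (so the in-target maximum is
12 / 0.8 = 15 Gy), with the goal that at least 98% of the target volume
(PTV = GTV, no margin) receives the full prescription. Because these
patients have long life expectancies, the *dose bath* — the low-to-
intermediate dose spread through normal tissue — and *dose spikes* —
fingers of high dose leaking from the target along beam directions — matter
beyond the classical organ-at-risk (OAR) limits.

`shellplan` implements, at desk scale on synthetic phantoms, a two-step
automated planning workflow for a non-coplanar robotic unit with cone
collimators:

1. **Pre-optimization** (`solve_lexicographic()`): a prioritized
   ("wish-list") optimizer minimizes the maximum dose on thin shells at 1,
   3 and 5 cm from the target, after securing coverage and under hard
   target/OAR limits. Each priority is one linear program over nonnegative
   beam weights; earlier achievements are frozen (with a small relaxation
   `delta`) as constraints for later phases, so the returned plan is
   Pareto-prioritized.
2. **Constraint transfer** (`plan_with_shell_constraints()`): the shell
   maxima achieved in step (i) are extracted as individualized per-patient
   constraints (integer cGy) and imposed as hard limits in a re-planning
   run whose objectives are coverage and MU economy — emulating the
   clinical pattern where a pre-optimizer writes the template for the
   vendor's treatment planning system.

The package also runs the *fixed-constraint* experiment
(`run_cohort_experiment()`): per-shell population means of the
individualized constraints are imposed on every patient ("fAUTO" arm), to
show that a one-size-fits-all template breaks coverage for part of the
population while individualized constraints do not.

## Synthetic phantoms: what they emulate, and what they do not

`generate_phantom()` builds one "patient" from a handful of parameters: an
ellipsoidal head (default semi-axes 75 × 90 × 80 mm), a vertical brainstem
cylinder (radius 6 mm) near the midline, a randomly oriented ellipsoidal
target at a lateral posterior-fossa-like position with a prescribed surface
gap to the brainstem, a small cochlea sphere lateral to the target, and two
thin nerve tubes abutting the target surface. `generate_cohort()` draws
target volumes log-uniformly on 1.0–7.3 cc (the range of the reference
clinical population, mean 2.9 cc) and brainstem gaps uniformly on 0–3 mm,
with per-phantom seeds derived from one cohort seed.

Geometry notes:

* Only isotropic voxels are supported (default 2 mm; the cohort experiment
  uses 4 mm). Voxel centres sit at `origin + index * spacing` with 0-based
  indices.
* The voxelized target volume is calibrated to the requested volume by
  bisection on a global scale factor of the ellipsoid semi-axes; the
  brainstem gap is then tuned by whole-voxel lateral shifts, which leave
  the calibrated voxel count unchanged. Volumes are guaranteed within 10%
  at spacings of 2 mm and below; a volume that cannot be voxelized to at
  least ~10 voxels fails with the minimum usable spacing in the message.
* The structure set is reduced to the OARs that shape the optimization
  geometry (brainstem, cochlea, two nerve tubes). Optic structures, eyes
  and pituitary receive near-zero dose in this lateralized geometry and
  are omitted.

What passing tests on these phantoms shows is that the *workflow* behaves
as designed — coverage is certified, shells are minimized in priority
order, individualized constraints transfer feasibly, fixed constraints
break heterogeneous patients. It does not validate the dose engine against
measured beam data, handle CT heterogeneity, or reproduce any clinical
cohort's absolute numbers.

## Beam model and influence matrix

Candidate beams live on a 179-node Fibonacci cap (polar angle up to 120°)
at `max(head radii) + standoff` from the head centre; the default standoff
(710 mm) places nodes at about the source-axis distance (SAD, 800 mm), so
nominal cone diameters apply at the target. Each beam is an analytic cone
kernel in a homogeneous water-equivalent body:

* inverse-square falloff `(SAD / distance)^2`;
* exponential attenuation `exp(-mu * (depth - ref_depth))` with depth the
  in-body path length from the ray's entry point, located by bisection
  against the voxelized body (the phantom bodies are convex);
* a flat core out to the geometric field radius with an error-function
  penumbra of width `sigma` beyond it. Calibration: an on-axis voxel at
  the reference depth (15 mm) and at SAD from the source receives exactly
  `output_cgy_per_mu` (1 cGy/MU) per MU.

Defaults (`beam_kernel_params()`): attenuation 0.005/mm (≈ 6 MV), sigma
2 mm. These are documented model choices, not vendor or published values.
Collimator diameters follow an Iris-style discrete set
{10, 12.5, 15, 20, 25, 30, 35, 40} mm. Per patient the experiment uses the
smallest diameter whose flat core covers the whole target from any
direction (centroid aiming) plus diameters near the target's
equivalent-sphere diameter; without the covering cone, elongated targets
keep a cold tip that no weighting can fix. `build_influence_matrix()`
assembles the sparse voxel-by-beam matrix in cGy/MU, dropping per-column
entries below `truncation_rel` (default 1e-5) of the column maximum.

## Shells

A shell at distance *d* is the band of voxels whose exact Euclidean
distance to the target (voxel-centre to voxel-centre, computed by a
separable exact distance transform in C++) lies in `[d, d + thickness)`,
clipped to the body and excluding the target. Default thickness is
`max(3 mm, voxel spacing)`; shells are thin bands, not full expansions,
because near-maximum dose on a band is the clinical "shell" construct.
Bands that would overlap are rejected; bands fully clipped away by the
body are flagged empty.

## The optimization machinery

Percentile quantities are handled by convex tail means: the coverage
surrogate is the mean of the coldest `ceiling(0.02 n)` target voxels
(`tail_mean_low()`), linearized with CVaR-style auxiliary variables so
every phase stays a linear program. The surrogate is *sound*: if the
coldest-2% mean is at least 12 Gy then at most `ceiling(0.02 n) - 1`
voxels can be below 12 Gy, hence exact V12Gy ≥ 98% — asserted in the test
suite on random dose vectors. Exact D2%/V12Gy are always recomputed by
sorting during evaluation.

Phases are solved by a safeguarded Mehrotra predictor-corrector
interior-point method written for this package (no LP solver ships with
the environment's R stack): eliminating slack and bound blocks reduces
each Newton step to an n × n positive-definite system over beams plus
auxiliaries, assembled in C++ from the fixed sparsity of the constraint
matrix. Planning LPs are heavily degenerate; three safeguards matter in
practice and are cross-checked in tests against an independent dense
simplex (`pracma::linprog`) and exhaustive lattice search:

* the centering parameter is capped below 1 and a pure centering step
  replaces any step that would inflate complementarity;
* an iterate whose primal residual and complementarity gap are at solver
  precision is accepted as optimal even when degenerate duals keep the
  dual residual large;
* if a phase still fails numerically, the previous phase's solution — a
  feasible witness for the current constraint set by construction — is
  kept, sacrificing only that phase's objective.

Numerical conventions: frozen bounds carry a 1e-6 relative slack so later
feasible sets stay full-dimensional; a "sufficient" objective whose goal
is met within 1e-6 is fixed at the goal; weights below 1e-6 of the maximum
are zeroed when a plan is assembled (beam and node counts refer to the
remaining support). The relaxation `delta` defaults to 1.03.

## Constraint transfer and rescaling

`extract_shell_dmax()` reports per-shell maxima rounded to the nearest
integer cGy. During re-planning an integer constraint `c` is interpreted
at its rounding granularity, `dose <= c + 0.5 cGy`; this keeps the plan
the constraints were extracted from feasible (nearest rounding can round
the witness's own maximum down by up to 0.5 cGy). All evaluated plans are
rescaled to exactly 98% coverage by the order statistic
(`rescale_to_coverage()`); an upscale is allowed only if the plan's hard
constraints survive it, otherwise the plan is flagged "not achieved" — the
mechanism by which too-tight fixed constraints surface as unacceptable
coverage. The scale factor is nudged by machine epsilon when the product
with the k-th order statistic would land one ulp below the prescription,
which otherwise silently drops every voxel tied at the boundary.

Evaluation conventions (`plan_report()`): V_D uses a closed threshold
(dose ≥ D); D2% is the `ceiling(0.02 n)`-th hottest voxel, no
interpolation; the conformity index is reported in both common variants
(plain volume ratio and inverse-overlap), since ratio-type indices near 1
do not identify which definition a clinical report used; the prescription
isodose volume is taken within the body. Dose grids are in Gy; shell
constraints in cGy; delivery time is a linear surrogate
(`delivery_model()`) with documented non-clinical coefficients.

## The cohort experiment and its fixed conditions

`run_cohort_experiment()` runs, per patient: shell construction →
influence matrix → step (i) → constraint extraction → AUTO re-plan →
weighted-sum baseline; then forms population-mean constraints and re-plans
every patient under them (fAUTO). The baseline planner is a deliberately
simpler single-pass weighted sum (coverage reward 100/Gy, shell penalties
1/Gy, MU penalty 1e-4/MU) standing in for conventional coverage-first
planning; it shares the hard target/OAR bounds but has no prioritization
and no hard shell limits.

The study conditions are fixed once: 20 phantoms, cohort seed 7, 4 mm
voxels, 179 nodes, two collimators per patient, centroid aiming, shells at
1/3/5 cm for optimization and 1/2/3/5/7 cm for evaluation. These sizes
keep the full experiment at a few minutes on one CPU while leaving each
target 15–115 voxels. The paired comparison (`cohort_table()`,
`compare_arms()`) reports per-metric mean ± SD, exact two-sided Wilcoxon
signed-rank p values (full enumeration over sign assignments, mid-ranked
ties, zeros dropped; the convention choices are documented because
clinical reports rarely state them), and the per-patient percent-difference
panel `(reference - comparison) / reference * 100`. No multiple-testing
correction is applied; p values are reported raw.

## Known limitations

* The dose engine is an analytic kernel in homogeneous water; no
  heterogeneity, scatter or measured beam data.
* Bodies must be convex for the entry-point bisection; the supplied
  phantoms are.
* The baseline emulates "manual planning" only in spirit; nothing is
  claimed about any vendor optimizer's internals.
* The fixed-constraint arm's failure pattern depends on cohort
  heterogeneity; with a homogeneous cohort fAUTO and AUTO coincide (this
  degenerate case is itself a test).
* Exact Wilcoxon enumeration is used up to n = 20 pairs; beyond that the
  tie-corrected normal approximation with continuity correction applies.

## A worked call

```{r example}
ph <- generate_phantom(phantom_spec(ptv_volume_cc = 2.9, voxel_mm = 4,
                                    rng_seed = 11))
shells <- build_shell_set(ph$masks$PTV, ph$masks$body, ph$spacing_mm,
                          c(1, 3, 5), 4)
nodes <- generate_node_set(179, ph)
infl <- build_influence_matrix(nodes, c(15, 20, 25), beam_kernel_params(), ph)
st <- gather_structures(ph, shells)
sol <- solve_lexicographic(infl, default_vs_wishlist(), st)
sol$report
extract_shell_dmax(sol$plan, infl, shells)
```
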