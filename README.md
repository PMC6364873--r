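# shellplan

Automated inverse planning for non-coplanar robotic radiosurgery of
vestibular schwannoma, at desk scale on synthetic head phantoms — built
around the question of how far the *dose bath* (low-to-intermediate dose
spread through normal tissue) and *dose spikes* (high-dose fingers leaking
from the target) can be pushed down without giving up target coverage,
organ-at-risk (OAR) sparing, or treatment time.

The package implements a two-step workflow:

1. **Prioritized pre-optimization.** A "wish-list" drives a lexicographic
   ε-constraint optimization of nonnegative beam weights `w` acting through
   a sparse dose-influence matrix (`d = A w`). Hard constraints: target
   Dmax ≤ 12/0.8 = 15 Gy (single-fraction 12 Gy prescribed at the 80%
   isodose) and OAR Dmax bounds. Priorities: coverage — via the convex
   coldest-2%-tail surrogate, CVaR-linearized so every phase is an LP, and
   *sufficient* at 12 Gy (the surrogate provably certifies exact
   V12Gy ≥ 98%) — then minimization of the maximum dose on thin shells at
   1, 3 and 5 cm from the target (built by exact Euclidean distance
   transform), then total MU. Each phase freezes earlier achievements as
   constraints (relaxation δ = 1.03).
2. **Constraint transfer.** The achieved shell maxima become
   individualized hard constraints (integer cGy) for a re-planning run with
   coverage and MU-economy objectives ("AUTO"). Averaging the
   individualized constraints over the cohort and re-planning everyone
   under the fixed set ("fAUTO") shows that population templates break
   coverage for part of a heterogeneous population.

Everything around the optimizer is first-class: a seeded synthetic phantom
generator emulating the clinical population (target volumes 1.0–7.3 cc
adjacent to brainstem/cochlea/nerve surrogates), an analytic cone-beam dose
kernel with 179-node non-coplanar geometry, DVH metrics (D2%, V_D,
conformity indices, exact coverage rescaling), and paired cohort statistics
(exact Wilcoxon signed-rank by full enumeration, percent-difference
panels). Phases are solved by a safeguarded primal-dual interior-point LP
solver written for the package and cross-checked in tests against an
independent simplex implementation and exhaustive lattice search.

Intended users: medical-physics researchers prototyping prioritized
planning and constraint-transfer strategies, and anyone who wants a fully
scripted, reproducible sandbox for shell-based dose-spillage control.

## A worked example

```r
library(shellplan)

ph <- generate_phantom(phantom_spec(ptv_volume_cc = 2.9, voxel_mm = 4,
                                    rng_seed = 11))
shells <- build_shell_set(ph$masks$PTV, ph$masks$body, ph$spacing_mm,
                          c(1, 3, 5), 4)
nodes  <- generate_node_set(179, ph)
infl   <- build_influence_matrix(nodes, c(15, 20, 25), beam_kernel_params(), ph)
sol    <- solve_lexicographic(infl, default_vs_wishlist(),
                              gather_structures(ph, shells))
sol$report
#> # A tibble: 5 x 8
#>   priority structure metric        direction achieved    bound status iterations
#> 1        1 PTV       tail_mean_low max         12       12.0   goal_reached  24
#> 2        2 shell_1cm Dmax          min          1.93     1.99  optimal       24
#> 3        3 shell_3cm Dmax          min          0.668    0.688 optimal       36
#> 4        4 shell_5cm Dmax          min          0.458    0.471 optimal       41
#> 5        5 MU        total_mu      min       2078.    2140.    optimal       58

extract_shell_dmax(sol$plan, infl, shells)
#> # A tibble: 3 x 2
#>   distance_cm dmax_cgy
#> 1           1      199
#> 2           3       69
#> 3           5       47

sol$plan
#> <vs_plan> optimal: 136 beams on 128 nodes, 2078 MU, est. 40.3 min
```

Reading: the coverage surrogate reached its 12 Gy goal (so ≥ 98% of the
target receives the prescription), after which the maximum dose on the
1/3/5 cm shells was pushed to 1.93/0.67/0.46 Gy in priority order, and
finally total MU was minimized. The extracted 199/69/47 cGy triple is this
patient's individualized shell-constraint set for the step-(ii) re-plan
(`plan_with_shell_constraints()`). The full cohort experiment is one call:

```r
cohort <- generate_cohort(20, phantom_spec(voxel_mm = 4), seed = 7)
res <- run_cohort_experiment(cohort, experiment_config())
glance(res)
compare_arms(res, "baseline", "auto")
```

`tidy()`/`glance()` methods cover plans and experiment results;
`autoplot()` draws DVHs and percent-difference panels. A thin command-line
front end (`inst/cli/shellplan`) wraps phantom/cohort generation, shell
building, planning, evaluation and the experiment.

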