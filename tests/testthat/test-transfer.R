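test_that("population-mean constraints average per-distance in integer cGy", {
  mk <- function(v) structure(tibble::tibble(distance_cm = c(1, 3, 5),
                                             dmax_cgy = v),
                              class = c("vs_shell_constraints",
                                        class(tibble::tibble())))
  one <- mk(c(400, 150, 100))
  expect_equal(population_mean_constraints(list(one))$dmax_cgy,
               c(400, 150, 100))
  two <- population_mean_constraints(list(mk(c(100, 50, 25)),
                                          mk(c(300, 150, 75))))
  expect_equal(two$dmax_cgy, c(200, 100, 50))
  bad <- structure(tibble::tibble(distance_cm = c(1, 2), dmax_cgy = c(1, 1)),
                   class = c("vs_shell_constraints", class(tibble::tibble())))
  expect_error(population_mean_constraints(list(one, bad)), "mismatched")
})

test_that("individualized constraints are feasible for their own patient", {
  ctx <- mini_context()
  cons <- extract_shell_dmax(ctx$sol$plan, ctx$infl, ctx$sh_opt)
  re <- plan_with_shell_constraints(ctx$infl, prescription(), ctx$oar,
                                    cons, ctx$st)
  expect_true(re$feasible)
  expect_equal(re$plan$status, "optimal")
  # the coverage goal is met: the step-(i) plan is a feasible witness
  expect_gte(re$coverage_surrogate_gy, 12 - 1e-4)
  # the re-plan respects the imposed shell maxima (at cGy granularity)
  dose_cgy <- 100 * dose_grid(ctx$infl, re$plan)
  for (r in seq_len(nrow(cons))) {
    m <- ctx$st[[paste0("shell_", shellplan:::format_distance(cons$distance_cm[r]))]]
    expect_lte(max(dose_cgy[m]), (cons$dmax_cgy[r] + 0.5) * (1 + 1e-6))
  }
  # no-regression: hard OAR bounds are still honoured
  dg <- dose_grid(ctx$infl, re$plan)
  for (nm in names(ctx$oar)) {
    m <- ctx$ph$masks[[nm]]
    if (any(m)) expect_lte(max(dg[m]), ctx$oar[[nm]] * (1 + 1e-6))
  }
})

test_that("halved constraints degrade coverage; loosened ones stay feasible", {
  ctx <- mini_context()
  cons <- extract_shell_dmax(ctx$sol$plan, ctx$infl, ctx$sh_opt)
  tight <- cons
  tight$dmax_cgy <- pmax(1, round(cons$dmax_cgy * 0.5))
  t_re <- plan_with_shell_constraints(ctx$infl, prescription(), ctx$oar,
                                      tight, ctx$st)
  expect_true(!t_re$feasible || t_re$coverage_surrogate_gy < 12 - 1e-6)
  loose <- cons
  loose$dmax_cgy <- cons$dmax_cgy * 10
  l_re <- plan_with_shell_constraints(ctx$infl, prescription(), ctx$oar,
                                      loose, ctx$st)
  expect_true(l_re$feasible)
  expect_gte(l_re$coverage_surrogate_gy, 12 - 1e-4)
  expect_error(plan_with_shell_constraints(
    ctx$infl, prescription(), ctx$oar,
    tibble::tibble(distance_cm = 1, dmax_cgy = -5), ctx$st), "positive")
})

test_that("the cohort experiment returns a complete per-patient record", {
  co <- generate_cohort(3, phantom_spec(voxel_mm = 4,
                                        head_radii_mm = c(55, 65, 60)),
                        seed = 12)
  cfg <- experiment_config(node_count = 60, opt_distances_cm = c(1, 2, 3),
                           shell_thickness_mm = 4)
  res <- suppressWarnings(run_cohort_experiment(co, cfg))
  expect_s3_class(res, "vs_transfer_result")
  expect_equal(nrow(res$patients), 3)
  expect_true(all(is.na(res$patients$error)))
  expect_length(res$constraints, 3)
  expect_equal(res$fixed_constraints$distance_cm, c(1, 2, 3))
  # fixed constraints are the rounded mean of the individual sets
  expect_equal(res$fixed_constraints$dmax_cgy,
               round(Reduce(`+`, lapply(res$constraints, `[[`, "dmax_cgy")) / 3))
  for (arm in c("auto", "fauto", "baseline"))
    expect_length(res$metrics[[arm]], 3)
  expect_true(all(res$patients$auto_coverage_pct >= 98 - 1e-6))
  g <- glance(res)
  expect_equal(g$n_patients, 3L)
  cmp <- compare_arms(res, "baseline", "auto")
  expect_s3_class(cmp, "vs_cohort_comparison")
  expect_true(all(c("metric", "p_value", "significant") %in% names(cmp$table)))
})

test_that("identical patients make the fixed arm match the individualized arm", {
  ph <- generate_phantom(phantom_spec(voxel_mm = 4,
                                      head_radii_mm = c(55, 65, 60),
                                      rng_seed = 9))
  co <- structure(list(ph, ph), class = c("vs_cohort", "list"))
  cfg <- experiment_config(node_count = 60, opt_distances_cm = c(1, 2, 3),
                           shell_thickness_mm = 4)
  res <- suppressWarnings(run_cohort_experiment(co, cfg))
  # mean of identical constraint sets is the set itself
  expect_equal(res$fixed_constraints$dmax_cgy, res$constraints[[1]]$dmax_cgy)
  expect_equal(res$patients$fauto_coverage_pct,
               res$patients$auto_coverage_pct, tolerance = 1e-6)
})
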