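# Lexicographic planner on analytic toys and a coarse end-to-end context.

test_that("a decoupled two-beam system reaches the exact lexicographic optimum", {
  infl <- toy_influence(diag(2)) # beam j doses voxel j at 1 Gy/MU
  masks <- toy_masks(2, PTV = 1, shell_1cm = 2)
  constraints <- tibble::tibble(structure = "PTV", metric = "Dmax",
                                alpha = NA_real_, bound_gy = 12, sense = "le")
  objectives <- tibble::tibble(
    priority = 1:3,
    structure = c("PTV", "shell_1cm", "MU"),
    metric = c("tail_mean_low", "Dmax", "total_mu"),
    alpha = c(0.02, NA, NA),
    direction = c("max", "min", "min"),
    goal_gy = c(12, NA, NA),
    sufficient = c(TRUE, FALSE, FALSE))
  wl <- wishlist(constraints, objectives)
  sol <- solve_lexicographic(infl, wl, masks)
  expect_equal(unname(sol$plan$weights), c(12, 0), tolerance = 1e-4)
  shell_phase <- sol$report[sol$report$structure == "shell_1cm", ]
  expect_lt(shell_phase$achieved, 1e-6)
  expect_equal(sol$report$status[1], "goal_reached")
  # no hard constraint violated beyond 1e-6 relative
  dose <- drop(as.matrix(infl$A %*% sol$plan$weights)) / 100
  expect_lte(max(dose[1]), 12 * (1 + 1e-6))
})

test_that("scaling the influence columns rescales weights, not doses", {
  set.seed(21)
  A <- matrix(runif(8, 0.2, 1), 4, 2)
  masks <- toy_masks(4, PTV = 1:2, shell_1cm = 3:4)
  constraints <- tibble::tibble(structure = "PTV", metric = "Dmax",
                                alpha = NA_real_, bound_gy = 15, sense = "le")
  objectives <- tibble::tibble(
    priority = 1:2, structure = c("PTV", "shell_1cm"),
    metric = c("tail_mean_low", "Dmax"), alpha = c(0.02, NA),
    direction = c("max", "min"), goal_gy = c(12, NA),
    sufficient = c(TRUE, FALSE))
  wl <- wishlist(constraints, objectives)
  s1 <- solve_lexicographic(toy_influence(A), wl, masks)
  s2 <- solve_lexicographic(toy_influence(3 * A), wl, masks)
  expect_equal(unname(s2$plan$weights), unname(s1$plan$weights) / 3,
               tolerance = 1e-4)
  d1 <- drop(as.matrix(toy_influence(A)$A %*% s1$plan$weights))
  d2 <- drop(as.matrix(toy_influence(3 * A)$A %*% s2$plan$weights))
  expect_equal(d1, d2, tolerance = 1e-4)
})

test_that("later-phase optima are nonincreasing in the relaxation delta", {
  set.seed(31)
  A <- matrix(runif(12, 0.1, 1), 4, 3)
  masks <- toy_masks(4, PTV = 1:2, shell_1cm = 3:4)
  constraints <- tibble::tibble(structure = "PTV", metric = "Dmax",
                                alpha = NA_real_, bound_gy = 15, sense = "le")
  objectives <- tibble::tibble(
    priority = 1:2, structure = c("PTV", "shell_1cm"),
    metric = c("tail_mean_low", "Dmax"), alpha = c(0.9, NA),
    direction = c("max", "min"), goal_gy = c(NA, NA),
    sufficient = c(FALSE, FALSE)) # phase 1 is a pure maximization here
  ach <- vapply(c(1.0, 1.05, 1.2), function(d) {
    wl <- wishlist(constraints, objectives, delta = d)
    sol <- solve_lexicographic(toy_influence(A), wl, masks)
    sol$report$achieved[2]
  }, double(1))
  expect_true(all(diff(ach) <= 1e-6)) # looser earlier bound, lower shell max
})

test_that("an end-to-end coarse plan satisfies all hard bounds", {
  ctx <- mini_context()
  plan <- ctx$sol$plan
  expect_equal(plan$status, "optimal")
  dose <- dose_grid(ctx$infl, plan)
  expect_lte(max(dose[ctx$ph$masks$PTV]), 15 * (1 + 1e-6))
  for (nm in names(ctx$oar)) {
    m <- ctx$ph$masks[[nm]]
    if (any(m)) expect_lte(max(dose[m]), ctx$oar[[nm]] * (1 + 1e-6))
  }
  # the coverage surrogate certifies exact coverage on the same voxels
  expect_gte(tail_mean_low(dose[ctx$ph$masks$PTV], 0.02), 12 - 1e-4)
  # extracted constraints are nonincreasing with distance
  cons <- extract_shell_dmax(plan, ctx$infl, ctx$sh_opt)
  expect_true(all(diff(cons$dmax_cgy) <= 0))
})

test_that("sparsification reaches a fixed point and cannot improve objectives", {
  infl <- toy_influence(cbind(diag(2), c(0.01, 0.01)))
  masks <- toy_masks(2, PTV = 1, shell_1cm = 2)
  constraints <- tibble::tibble(structure = "PTV", metric = "Dmax",
                                alpha = NA_real_, bound_gy = 12, sense = "le")
  objectives <- tibble::tibble(
    priority = 1:3, structure = c("PTV", "shell_1cm", "MU"),
    metric = c("tail_mean_low", "Dmax", "total_mu"),
    alpha = c(0.02, NA, NA), direction = c("max", "min", "min"),
    goal_gy = c(12, NA, NA), sufficient = c(TRUE, FALSE, FALSE))
  wl <- wishlist(constraints, objectives)
  sol <- solve_lexicographic(infl, wl, masks)
  # the useless third beam carries no weight and is dropped
  sp <- sparsify(sol$plan, infl, wl, masks, max_beams = 1)
  expect_true(sp$sparsify_converged)
  expect_lte(sp$beam_count, 1)
  shell_before <- sol$report$achieved[2]
  shell_after <- sp$report$achieved[2]
  expect_gte(shell_after, shell_before - 1e-6) # restricted set cannot improve
  # a plan already under the cap is returned unchanged
  sp2 <- sparsify(sp, infl, wl, masks, max_beams = 5)
  expect_identical(sp2$weights, sp$weights)
})

test_that("the delivery-time surrogate is linear and monotone", {
  model <- delivery_model()
  empty <- structure(list(node_count = 0, beam_count = 0, total_mu = 0),
                     class = "vs_plan")
  expect_equal(estimate_delivery(empty, model), model$setup_min)
  p1 <- structure(list(node_count = 56, beam_count = 162, total_mu = 4899),
                  class = "vs_plan")
  p2 <- p1; p2$total_mu <- 2 * p1$total_mu
  expect_equal(estimate_delivery(p2, model) - estimate_delivery(p1, model),
               p1$total_mu / model$mu_per_min)
  expect_gt(estimate_delivery(p1, model), model$setup_min)
})

test_that("shell Dmax extraction matches a brute-force maximum", {
  n <- 9
  shells <- structure(list(
    distances_cm = c(1, 3, 5), thickness_mm = 3,
    masks = toy_masks(n, a = 1:3, b = 4:6, c = 7:9), empty = rep(FALSE, 3)),
    class = "vs_shell_set")
  # uniform 1 Gy everywhere
  infl_u <- toy_influence(matrix(1, n, 1))
  plan_u <- structure(list(weights = c(b1 = 1)), class = "vs_plan")
  expect_warning(cons_u <- extract_shell_dmax(plan_u, infl_u, shells), NA)
  expect_equal(cons_u$dmax_cgy, c(100, 100, 100))
  # random dose field vs direct scan
  set.seed(5)
  A <- matrix(runif(n * 3), n, 3)
  A[1:3, ] <- A[1:3, ] + 2 # keep the closest band hottest
  w <- runif(3, 1, 5)
  infl_r <- toy_influence(A)
  plan_r <- structure(list(weights = w), class = "vs_plan")
  cons_r <- suppressWarnings(
    extract_shell_dmax(plan_r, infl_r, shells, round_cgy = FALSE))
  dose_cgy <- drop(A %*% w) * 100
  expect_equal(cons_r$dmax_cgy,
               c(max(dose_cgy[1:3]), max(dose_cgy[4:6]), max(dose_cgy[7:9])))
  # a dose field increasing with distance triggers the invariant warning
  A2 <- matrix(c(rep(0.1, 3), rep(0.5, 3), rep(1, 3)), n, 1)
  plan_i <- structure(list(weights = 10), class = "vs_plan")
  expect_warning(extract_shell_dmax(plan_i, toy_influence(A2), shells),
                 "nonincreasing")
})
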