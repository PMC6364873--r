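# Step (ii) of the two-step workflow and the fixed-constraint study:
# re-planning under individualized shell Dmax constraints (AUTO), population
# -mean fixed constraints (fAUTO), and the full cohort experiment with a
# weighted-sum baseline planner standing in for conventional single-pass
# planning.

#' Re-plan under hard shell Dmax constraints
#'
#' The step-(ii) planner: the per-shell maximum doses (in cGy) are imposed
#' as hard constraints alongside the target and organ-at-risk Dmax bounds;
#' the objective stack is coverage (sufficient at the prescription dose)
#' followed by total-MU economy. Infeasible constraint sets return status
#' `infeasible`; nothing is silently relaxed. An integer-cGy constraint `c`
#' is interpreted at its rounding granularity, `dose <= c + 0.5 cGy`, so
#' the plan the constraints were extracted from always remains feasible
#' under nearest-integer rounding.
#'
#' @param infl A `vs_influence`.
#' @param rx A [prescription()].
#' @param oar_dmax_gy Named hard organ-at-risk Dmax bounds (Gy).
#' @param shell_constraints A `vs_shell_constraints` (cGy per distance).
#' @param structures Named mask list containing the target, OARs and
#'   `shell_<d>cm` masks for every constrained distance.
#' @param delta Relaxation factor for the objective stack.
#' @return List: `plan` (`vs_plan`), `report`, `coverage_surrogate_gy`
#'   (achieved coldest-tail mean), `feasible`.
#' @export
plan_with_shell_constraints <- function(infl, rx, oar_dmax_gy,
                                        shell_constraints, structures,
                                        delta = 1.03) {
  stopifnot(inherits(shell_constraints, "vs_shell_constraints") ||
              is.data.frame(shell_constraints))
  if (any(shell_constraints$dmax_cgy <= 0))
    abort("shell constraints must be positive")
  constraints <- tibble(
    structure = c("PTV", names(oar_dmax_gy),
                  paste0("shell_", format_distance(shell_constraints$distance_cm))),
    metric = "Dmax",
    alpha = NA_real_,
    bound_gy = c(rx$ptv_max_gy, unname(oar_dmax_gy),
                 cgy_to_gy(shell_constraints$dmax_cgy + 0.5)),
    sense = "le"
  )
  objectives <- tibble(
    priority = 1:2,
    structure = c("PTV", "MU"),
    metric = c("tail_mean_low", "total_mu"),
    alpha = c(1 - rx$coverage_fraction, NA_real_),
    direction = c("max", "min"),
    goal_gy = c(rx$dose_gy, NA_real_),
    sufficient = c(TRUE, FALSE)
  )
  wl <- wishlist(constraints, objectives, delta)
  sol <- solve_lexicographic(infl, wl, structures)
  cov_row <- sol$report[sol$report$metric == "tail_mean_low", ]
  list(plan = sol$plan, report = sol$report,
       coverage_surrogate_gy = if (nrow(cov_row)) cov_row$achieved[1] else NA_real_,
       feasible = sol$plan$status != "infeasible")
}

#' Population-mean shell constraints
#'
#' The fixed-constraint arm: per-distance arithmetic mean of the per-patient
#' shell Dmax values, rounded to the nearest integer cGy.
#'
#' @param sets List of `vs_shell_constraints` with matching distance lists.
#' @return A `vs_shell_constraints`.
#' @export
population_mean_constraints <- function(sets) {
  if (length(sets) < 1L) abort("need at least one constraint set")
  d0 <- sets[[1L]]$distance_cm
  for (s in sets)
    if (!isTRUE(all.equal(s$distance_cm, d0)))
      abort("constraint sets have mismatched distance lists")
  vals <- round(Reduce(`+`, lapply(sets, function(s) s$dmax_cgy)) / length(sets))
  structure(tibble(distance_cm = d0, dmax_cgy = vals),
            class = c("vs_shell_constraints", class(tibble())))
}

#' Weighted-sum baseline planner
#'
#' A deliberately simpler single-pass planner emulating conventional
#' coverage-first planning: one LP minimizing
#' `-w_cov * coverage_surrogate + w_shell * sum(shell Dmax) + w_mu * MU`
#' under the target and organ-at-risk hard Dmax bounds (no hard shell
#' constraints and no prioritization).
#'
#' @inheritParams plan_with_shell_constraints
#' @param shells A `vs_shell_set` whose distances are penalized.
#' @param weights Penalty weights: `coverage` (per Gy of the coverage
#'   surrogate), `shell` (per Gy of each shell maximum), `mu` (per MU).
#' @return A `vs_plan`.
#' @export
baseline_plan <- function(infl, rx, oar_dmax_gy, shells, structures,
                          weights = c(coverage = 100, shell = 1, mu = 1e-4)) {
  nb <- ncol(infl$A)
  env <- new_lp_model(nb)
  hard <- tibble(structure = c("PTV", names(oar_dmax_gy)),
                 bound_gy = c(rx$ptv_max_gy, unname(oar_dmax_gy)))
  for (r in seq_len(nrow(hard)))
    add_constraint_rows(env, infl, structures, hard$structure[r], "Dmax",
                        NA_real_, hard$bound_gy[r], "le", nb)
  tp_ptv <- dose_triplets(structure_rows(infl, structures, "PTV"))
  au <- add_tail_low_aux(env, tp_ptv, 1 - rx$coverage_fraction)
  t_shell <- integer(0)
  for (nm in paste0("shell_", format_distance(shells$distances_cm))) {
    tp <- dose_triplets(nonzero_rows(structure_rows(infl, structures, nm)))
    t <- lp_add_vars(env, 1L)
    lp_add_rows(env, c(tp$i, seq_len(tp$nrow)), c(tp$j, rep(t, tp$nrow)),
                c(tp$x, rep(-1, tp$nrow)), rep(0, tp$nrow),
                "baseline shell epigraph", screen = TRUE)
    t_shell <- c(t_shell, t)
  }
  lp <- lp_assemble(env)
  cv <- rep(0, env$nvar)
  cv[seq_len(nb)] <- weights[["mu"]]
  cv[au$zeta] <- -weights[["coverage"]]
  cv[au$s] <- weights[["coverage"]] / au$k
  cv[t_shell] <- weights[["shell"]]
  res <- solve_lp(cv, lp$A, lp$b)
  if (!res$status %in% c("optimal", "maxit", "stalled") || res$pinf > 1e-6)
    abort(sprintf("baseline planner failed: status %s", res$status))
  new_plan(res$x[seq_len(nb)], infl, list(weights = weights), "optimal",
           report = NULL)
}

#' Configuration for the cohort experiment
#'
#' Bundles the geometry, dose-model, wish-list and baseline settings of
#' [run_cohort_experiment()]. `NULL` shell thickness means
#' `max(3, voxel spacing)` mm.
#'
#' @param rx A [prescription()].
#' @param oar_dmax_gy Named hard OAR Dmax bounds (Gy).
#' @param opt_distances_cm Shell distances optimized and constrained.
#' @param eval_distances_cm Shell distances evaluated in reports.
#' @param shell_thickness_mm Shell band thickness (mm) or NULL.
#' @param node_count,cap_angle_deg,standoff_mm Node-set geometry.
#' @param kernel A [beam_kernel_params()].
#' @param n_collimators Number of cone diameters per patient (matched to
#'   the target's equivalent diameter).
#' @param aim_k Extra random target-interior aim points per node/cone.
#' @param truncation_rel Influence-matrix truncation threshold.
#' @param delta Wish-list relaxation factor.
#' @param baseline_weights Weighted-sum baseline penalties.
#' @param seed Experiment seed (drives aim sampling per patient).
#' @export
experiment_config <- function(rx = prescription(),
                              oar_dmax_gy = c(brainstem = 12, cochlea = 12,
                                              trigeminal_nerve = 15,
                                              facial_nerve = 15),
                              opt_distances_cm = c(1, 3, 5),
                              eval_distances_cm = c(1, 2, 3, 5, 7),
                              shell_thickness_mm = NULL,
                              node_count = 179, cap_angle_deg = 120,
                              standoff_mm = 710,
                              kernel = beam_kernel_params(),
                              n_collimators = 2L, aim_k = 0L,
                              truncation_rel = 1e-5, delta = 1.03,
                              baseline_weights = c(coverage = 100, shell = 1,
                                                   mu = 1e-4),
                              seed = 1L) {
  structure(as.list(environment()), class = "vs_experiment_config")
}

# Per-patient cone diameters: the smallest collimator whose flat core covers
# the whole target from any direction (centroid aiming), plus diameters
# around the equivalent sphere diameter for conformity.
pick_collimators <- function(phantom, n = 3L) {
  ptv_idx <- which(phantom$masks$PTV)
  xyz <- voxel_coords(phantom$dim, rep(phantom$spacing_mm, 3L),
                      phantom$origin, ptv_idx)
  ctr <- colMeans(xyz)
  r_cover <- sqrt(max(rowSums(sweep(xyz, 2L, ctr, "-")^2))) +
    phantom$spacing_mm / 2
  vol_cc <- length(ptv_idx) * phantom$spacing_mm^3 / 1000
  d_eq <- 2 * (3 * vol_cc * 1000 / (4 * pi))^(1 / 3)
  set <- collimator_set()
  covering <- set[set >= 2 * r_cover]
  d_large <- if (length(covering)) min(covering) else max(set)
  by_eq <- set[order(abs(set - d_eq), -set)]
  out <- unique(c(d_large, by_eq))
  sort(out[seq_len(min(n, length(out)))])
}

#' Run the individualized vs fixed shell-constraint cohort experiment
#'
#' For every phantom: build shells and the influence matrix, run the
#' prioritized pre-optimization (step i), extract its individualized shell
#' Dmax constraints, re-plan under them (AUTO, step ii), and solve the
#' weighted-sum baseline. The per-patient constraints are then averaged
#' into one fixed set under which every patient is re-planned again
#' (fAUTO). All plans are rescaled to the coverage target where hard
#' constraints permit, then evaluated with [plan_report()].
#'
#' @param cohort A list of `vs_phantom` (e.g. [generate_cohort()]).
#' @param config An [experiment_config()].
#' @param keep_plans Keep the `vs_plan` objects in the result.
#' @param verbose Print per-patient progress.
#' @return A `vs_transfer_result`: `patients` summary tibble,
#'   `constraints` (per-patient `vs_shell_constraints`),
#'   `fixed_constraints`, `metrics` (per-arm lists of `vs_plan_metrics`),
#'   and optionally `plans`.
#' @export
run_cohort_experiment <- function(cohort, config = experiment_config(),
                                  keep_plans = FALSE, verbose = FALSE) {
  stopifnot(length(cohort) >= 2L)
  n <- length(cohort)
  cfg <- config
  ctx <- vector("list", n)
  say <- function(...) if (verbose) message(sprintf(...))

  for (i in seq_len(n)) {
    ctx[[i]] <- tryCatch({
      ph <- cohort[[i]]
      thick <- cfg$shell_thickness_mm %||% max(3, ph$spacing_mm)
      sh_opt <- build_shell_set(ph$masks$PTV, ph$masks$body, ph$spacing_mm,
                                cfg$opt_distances_cm, thick)
      sh_eval <- build_shell_set(ph$masks$PTV, ph$masks$body, ph$spacing_mm,
                                 cfg$eval_distances_cm, thick)
      structures <- gather_structures(ph, sh_opt, sh_eval)
      nodes <- generate_node_set(cfg$node_count, ph, cfg$cap_angle_deg,
                                 cfg$standoff_mm)
      colls <- pick_collimators(ph, cfg$n_collimators)
      infl <- build_influence_matrix(nodes, colls, cfg$kernel, ph,
                                     aim_k = cfg$aim_k,
                                     aim_seed = derive_seed(cfg$seed, i),
                                     truncation_rel = cfg$truncation_rel)
      wl <- default_vs_wishlist(cfg$rx, cfg$oar_dmax_gy,
                                cfg$opt_distances_cm, cfg$delta)
      say("patient %d: step-i solve (%d beams)", i, ncol(infl$A))
      sol <- solve_lexicographic(infl, wl, structures)
      cons <- extract_shell_dmax(sol$plan, infl, sh_opt)
      say("patient %d: AUTO re-plan", i)
      auto <- plan_with_shell_constraints(infl, cfg$rx, cfg$oar_dmax_gy,
                                          cons, structures, cfg$delta)
      base <- baseline_plan(infl, cfg$rx, cfg$oar_dmax_gy, sh_opt, structures,
                            cfg$baseline_weights)
      list(phantom = ph, structures = structures, shells_eval = sh_eval,
           infl = infl, preplan = sol$plan, constraints = cons,
           auto = auto, baseline = base, error = NA_character_)
    }, error = function(e) list(error = conditionMessage(e)))
  }

  ok <- vapply(ctx, function(x) is.na(x$error), logical(1))
  if (!any(ok))
    abort(sprintf("every patient failed; first error: %s", ctx[[1L]]$error))
  fixed <- population_mean_constraints(lapply(ctx[ok], `[[`, "constraints"))

  arms <- c("auto", "fauto", "baseline")
  metrics <- setNames(lapply(arms, function(a) vector("list", n)), arms)
  plans <- if (keep_plans) metrics else NULL
  pat_rows <- vector("list", n)
  for (i in seq_len(n)) {
    if (!ok[i]) {
      pat_rows[[i]] <- tibble(patient = i, ptv_cc = NA_real_,
                              error = ctx[[i]]$error)
      next
    }
    cx <- ctx[[i]]
    say("patient %d: fAUTO re-plan", i)
    fauto <- tryCatch(
      plan_with_shell_constraints(cx$infl, cfg$rx, cfg$oar_dmax_gy, fixed,
                                  cx$structures, cfg$delta),
      error = function(e) NULL)
    arm_plans <- list(auto = cx$auto$plan,
                      fauto = if (!is.null(fauto)) fauto$plan else NULL,
                      baseline = cx$baseline)
    arm_cons <- list(auto = cx$constraints, fauto = fixed, baseline = NULL)
    row <- list(patient = i,
                ptv_cc = structure_volume_cc(cx$phantom, "PTV"),
                gap_mm = cx$phantom$spec$ptv_brainstem_gap_mm,
                error = NA_character_)
    for (a in arms) {
      pl <- arm_plans[[a]]
      if (is.null(pl)) {
        row[[paste0(a, "_coverage_pct")]] <- NA_real_
        row[[paste0(a, "_acceptable")]] <- FALSE
        next
      }
      arm_res <- tryCatch({
        dose <- dose_grid(cx$infl, pl)
        rs <- rescale_to_coverage(
          dose, cx$phantom$masks$PTV, cfg$rx,
          hard_check = make_hard_check(dose, cx, cfg, arm_cons[[a]]))
        covg <- coverage(rs$dose, cx$phantom$masks$PTV, cfg$rx)
        list(metrics = plan_report(rs$dose, cx$phantom, cx$shells_eval,
                                   pl, cfg$rx),
             coverage = covg, factor = rs$factor,
             acceptable = rs$achieved &&
               covg >= 100 * cfg$rx$coverage_fraction - 1e-9)
      }, error = function(e) list(metrics = NULL, coverage = NA_real_,
                                  factor = NA_real_, acceptable = FALSE,
                                  error = conditionMessage(e)))
      metrics[[a]][[i]] <- arm_res$metrics
      if (keep_plans) plans[[a]][[i]] <- pl
      row[[paste0(a, "_coverage_pct")]] <- arm_res$coverage
      row[[paste0(a, "_rescale_factor")]] <- arm_res$factor
      row[[paste0(a, "_acceptable")]] <- arm_res$acceptable
    }
    pat_rows[[i]] <- as_tibble(row)
  }
  structure(
    list(patients = dplyr::bind_rows(pat_rows),
         constraints = lapply(ctx, function(x) x$constraints),
         fixed_constraints = fixed,
         metrics = metrics,
         plans = plans,
         config = cfg),
    class = "vs_transfer_result"
  )
}

# closure testing whether upscaling by `s` keeps the arm's hard constraints
make_hard_check <- function(dose, cx, cfg, cons) {
  ph <- cx$phantom
  ptv_max <- max(dose[ph$masks$PTV])
  oar_max <- vapply(names(cfg$oar_dmax_gy), function(nm) {
    m <- ph$masks[[nm]]
    if (is.null(m) || !any(m)) 0 else max(dose[m])
  }, double(1))
  shell_max <- if (is.null(cons)) NULL else
    vapply(seq_len(nrow(cons)), function(r) {
      m <- cx$structures[[paste0("shell_", format_distance(cons$distance_cm[r]))]]
      if (is.null(m) || !any(m)) 0 else max(dose[m])
    }, double(1))
  function(s) {
    tol <- 1e-4
    ok <- s * ptv_max <= cfg$rx$ptv_max_gy * (1 + tol) &&
      all(s * oar_max <= cfg$oar_dmax_gy * (1 + tol))
    if (!is.null(shell_max))
      ok <- ok && all(s * shell_max <= cgy_to_gy(cons$dmax_cgy + 0.5) * (1 + tol))
    ok
  }
}

#' @export
print.vs_transfer_result <- function(x, ...) {
  ok <- is.na(x$patients$error)
  cat(sprintf("<vs_transfer_result> %d patients (%d failed)\n",
              nrow(x$patients), sum(!ok)))
  cat(sprintf("  AUTO acceptable:  %d/%d\n",
              sum(x$patients$auto_acceptable[ok]), sum(ok)))
  cat(sprintf("  fAUTO acceptable: %d/%d\n",
              sum(x$patients$fauto_acceptable[ok]), sum(ok)))
  cat("  fixed constraints (cGy):",
      paste(x$fixed_constraints$dmax_cgy, collapse = " / "), "\n")
  invisible(x)
}

#' Paired comparison of two experiment arms
#'
#' @param result A `vs_transfer_result`.
#' @param reference,comparison Arm names among `"auto"`, `"fauto"`,
#'   `"baseline"`; percent differences are relative to `reference`.
#' @param ... Passed to [cohort_table()].
#' @export
compare_arms <- function(result, reference = "baseline", comparison = "auto",
                         ...) {
  stopifnot(inherits(result, "vs_transfer_result"))
  keep <- !vapply(result$metrics[[reference]], is.null, logical(1)) &
    !vapply(result$metrics[[comparison]], is.null, logical(1))
  cohort_table(paired_cohort(result$metrics[[reference]][keep],
                             result$metrics[[comparison]][keep],
                             labels = c(reference, comparison)), ...)
}
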