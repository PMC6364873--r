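# The prioritized (lexicographic epsilon-constraint) planner. Each priority
# is one LP over nonnegative beam weights; percentile-dose objectives and
# constraints are linearized with CVaR-style auxiliary variables, so every
# phase stays a linear program. After phase k its achieved value is frozen
# (relaxed by the wish-list delta, or fixed at the goal for "sufficient"
# objectives) as a constraint for all later phases.

# --- LP model accumulator ---------------------------------------------------

new_lp_model <- function(nvar) {
  env <- new.env(parent = emptyenv())
  env$nvar <- nvar
  env$nrow <- 0L
  env$i <- list(); env$j <- list(); env$x <- list()
  env$rhs <- list(); env$labels <- list(); env$screen <- list()
  env
}

lp_add_vars <- function(env, k) {
  idx <- env$nvar + seq_len(k)
  env$nvar <- env$nvar + as.integer(k)
  idx
}

# rows: `i` are 1..r block-relative row ids aligned with rhs/label length r.
# `screen = TRUE` marks pure max-dose rows (a'w [- t] <= b) eligible for
# row generation: they may start inactive and are added back only while
# violated, which is exact at the returned tolerance.
lp_add_rows <- function(env, i, j, x, rhs, label, screen = FALSE) {
  env$i[[length(env$i) + 1L]] <- env$nrow + as.integer(i)
  env$j[[length(env$j) + 1L]] <- as.integer(j)
  env$x[[length(env$x) + 1L]] <- as.double(x)
  env$rhs[[length(env$rhs) + 1L]] <- as.double(rhs)
  env$labels[[length(env$labels) + 1L]] <- rep_len(label, length(rhs))
  env$screen[[length(env$screen) + 1L]] <- rep_len(isTRUE(screen), length(rhs))
  env$nrow <- env$nrow + length(rhs)
  invisible(env)
}

lp_assemble <- function(env) {
  list(A = sparseMatrix(i = unlist(env$i), j = unlist(env$j), x = unlist(env$x),
                        dims = c(env$nrow, env$nvar)),
       b = unlist(env$rhs),
       labels = unlist(env$labels),
       screen = unlist(env$screen))
}

# Row-generation wrapper around solve_lp: screened rows start inactive
# (keeping the `keep_init` largest by row magnitude per contiguous block),
# and violated ones are re-activated until none remain. Exact at tolerance
# `viol_tol` relative to the right-hand side.
solve_lp_gen <- function(c_vec, lp, tol = 1e-8, keep_init = 120L,
                         max_rounds = 12L, viol_tol = 1e-8) {
  m <- nrow(lp$A)
  active <- !lp$screen
  if (any(lp$screen)) {
    rmax <- Matrix::rowSums(abs(lp$A))
    blocks <- split(which(lp$screen), cumsum(c(TRUE, diff(which(lp$screen)) != 1L)))
    for (bk in blocks) {
      k <- min(keep_init, length(bk))
      active[bk[order(rmax[bk], decreasing = TRUE)[seq_len(k)]]] <- TRUE
    }
  } else {
    return(c(solve_lp(c_vec, lp$A, lp$b, tol = tol), list(rows_used = m)))
  }
  res <- NULL
  for (round in seq_len(max_rounds)) {
    idx <- which(active)
    res <- solve_lp(c_vec, lp$A[idx, , drop = FALSE], lp$b[idx], tol = tol)
    viol <- drop(lp$A %*% res$x) - lp$b
    viol[idx] <- -Inf
    bad <- which(viol > viol_tol * (1 + abs(lp$b)))
    if (length(bad) == 0L) break
    if (length(bad) > 500L) bad <- bad[order(viol[bad], decreasing = TRUE)[1:500]]
    active[bad] <- TRUE
  }
  res$violated_row <- if (!is.na(res$violated_row)) which(active)[res$violated_row] else NA_integer_
  res$rows_used <- sum(active)
  res
}

# sparse triplets of a dose submatrix (structure voxel rows, Gy/MU)
dose_triplets <- function(S) {
  Tm <- methods::as(S, "TsparseMatrix")
  list(i = Tm@i + 1L, j = Tm@j + 1L, x = Tm@x, nrow = nrow(S))
}

# --- structure handling -----------------------------------------------------

#' Collect named structure masks from a phantom and optional shell sets
#'
#' @param phantom A `vs_phantom`.
#' @param ... Any number of `vs_shell_set` objects; their masks are added
#'   under names `shell_<distance>`.
#' @return Named list of logical masks on the phantom grid.
#' @export
gather_structures <- function(phantom, ...) {
  out <- phantom$masks
  for (s in list(...)) {
    stopifnot(inherits(s, "vs_shell_set"))
    for (nm in names(s$masks)) out[[paste0("shell_", nm)]] <- s$masks[[nm]]
  }
  out
}

# rows of S carrying at least one nonzero dose entry; dropping all-zero
# rows is exact for max-dose (<=) constraints and epigraphs
nonzero_rows <- function(S) {
  S[Matrix::rowSums(abs(S)) > 0, , drop = FALSE]
}

# Gy/MU dose rows of one structure; errors on missing/empty structures
structure_rows <- function(infl, structures, name) {
  mask <- structures[[name]]
  if (is.null(mask)) abort(sprintf("wish-list references unknown structure '%s'", name))
  rows <- which(mask[infl$voxel_index])
  if (length(rows) == 0L)
    abort(sprintf("structure '%s' has no voxels inside the body grid", name))
  infl$A[rows, , drop = FALSE] / 100
}

# --- metric machinery -------------------------------------------------------

# Add hard-constraint rows for one wish-list constraint.
add_constraint_rows <- function(env, infl, structures, structure, metric,
                                alpha, bound_gy, sense, nb) {
  S <- structure_rows(infl, structures, structure)
  tp <- dose_triplets(S)
  lab <- sprintf("%s %s %s %.4g Gy", metric, structure,
                 if (sense == "le") "<=" else ">=", bound_gy)
  if (metric == "Dmax" && sense == "le") {
    tp <- dose_triplets(nonzero_rows(S))
    if (tp$nrow > 0L)
      lp_add_rows(env, tp$i, tp$j, tp$x, rep(bound_gy, tp$nrow), lab,
                  screen = TRUE)
  } else if (metric == "Dmean") {
    cm <- Matrix::colMeans(S)
    sgn <- if (sense == "le") 1 else -1
    lp_add_rows(env, rep(1L, sum(cm != 0)), which(cm != 0),
                sgn * cm[cm != 0], sgn * bound_gy, lab)
  } else if (metric == "tail_mean_high" && sense == "le") {
    au <- add_tail_high_aux(env, tp, alpha)
    lp_add_rows(env, rep(1L, 1L + tp$nrow), c(au$zeta, au$t),
                c(1, rep(1 / au$k, tp$nrow)), bound_gy, lab)
  } else if (metric == "tail_mean_low" && sense == "ge") {
    au <- add_tail_low_aux(env, tp, alpha)
    lp_add_rows(env, rep(1L, 1L + tp$nrow), c(au$zeta, au$s),
                c(-1, rep(1 / au$k, tp$nrow)), -bound_gy, lab)
  } else {
    abort(sprintf("unsupported constraint: %s with sense '%s'", metric, sense))
  }
  invisible(env)
}

# CVaR auxiliaries for the cold tail: zeta - s_i - d_i <= 0
add_tail_low_aux <- function(env, tp, alpha) {
  k <- ceiling(alpha * tp$nrow)
  zeta <- lp_add_vars(env, 1L)
  s <- lp_add_vars(env, tp$nrow)
  lp_add_rows(env,
              i = c(tp$i, seq_len(tp$nrow), seq_len(tp$nrow)),
              j = c(tp$j, rep(zeta, tp$nrow), s),
              x = c(-tp$x, rep(1, tp$nrow), rep(-1, tp$nrow)),
              rhs = rep(0, tp$nrow), label = "cvar-low aux")
  list(zeta = zeta, s = s, k = k)
}

# CVaR auxiliaries for the hot tail: d_i - zeta - t_i <= 0
add_tail_high_aux <- function(env, tp, alpha = 0.02) {
  k <- ceiling(alpha * tp$nrow)
  zeta <- lp_add_vars(env, 1L)
  t <- lp_add_vars(env, tp$nrow)
  lp_add_rows(env,
              i = c(tp$i, seq_len(tp$nrow), seq_len(tp$nrow)),
              j = c(tp$j, rep(zeta, tp$nrow), t),
              x = c(tp$x, rep(-1, tp$nrow), rep(-1, tp$nrow)),
              rhs = rep(0, tp$nrow), label = "cvar-high aux")
  list(zeta = zeta, t = t, k = k)
}

# Prepare one objective: auxiliary variables/rows, the cost vector direction
# (always minimized internally), and a freeze function adding the
# epsilon-constraint after the phase.
prepare_objective <- function(env, infl, structures, obj, nb) {
  metric <- obj$metric
  if (metric == "total_mu") {
    cost <- function(nvar) {
      cv <- rep(0, nvar); cv[seq_len(nb)] <- 1; cv
    }
    return(list(cost = cost, sign = 1,
                freeze = function(env, bound)
                  lp_add_rows(env, rep(1L, nb), seq_len(nb), rep(1, nb), bound,
                              sprintf("MU <= %.6g", bound))))
  }
  S <- structure_rows(infl, structures, obj$structure)
  tp <- dose_triplets(S)
  if (metric == "Dmax" && obj$direction == "min") {
    tp <- dose_triplets(nonzero_rows(S))
    t <- lp_add_vars(env, 1L)
    if (tp$nrow > 0L)
      lp_add_rows(env, c(tp$i, seq_len(tp$nrow)), c(tp$j, rep(t, tp$nrow)),
                  c(tp$x, rep(-1, tp$nrow)), rep(0, tp$nrow), "dmax epigraph",
                  screen = TRUE)
    cost <- function(nvar) { cv <- rep(0, nvar); cv[t] <- 1; cv }
    return(list(cost = cost, sign = 1,
                freeze = function(env, bound)
                  lp_add_rows(env, 1L, t, 1, bound,
                              sprintf("Dmax %s <= %.6g Gy", obj$structure, bound))))
  }
  if (metric == "tail_mean_low" && obj$direction == "max") {
    au <- add_tail_low_aux(env, tp, obj$alpha)
    cost <- function(nvar) {
      cv <- rep(0, nvar); cv[au$zeta] <- -1; cv[au$s] <- 1 / au$k; cv
    }
    return(list(cost = cost, sign = -1,
                freeze = function(env, bound)
                  lp_add_rows(env, rep(1L, 1L + length(au$s)), c(au$zeta, au$s),
                              c(-1, rep(1 / au$k, length(au$s))), -bound,
                              sprintf("tail_mean_low %s >= %.6g Gy",
                                      obj$structure, bound))))
  }
  if (metric == "tail_mean_high" && obj$direction == "min") {
    au <- add_tail_high_aux(env, tp, obj$alpha)
    cost <- function(nvar) {
      cv <- rep(0, nvar); cv[au$zeta] <- 1; cv[au$t] <- 1 / au$k; cv
    }
    return(list(cost = cost, sign = 1,
                freeze = function(env, bound)
                  lp_add_rows(env, rep(1L, 1L + length(au$t)), c(au$zeta, au$t),
                              c(1, rep(1 / au$k, length(au$t))), bound,
                              sprintf("tail_mean_high %s <= %.6g Gy",
                                      obj$structure, bound))))
  }
  if (metric == "Dmean") {
    cm <- Matrix::colMeans(S)
    sgn <- if (obj$direction == "min") 1 else -1
    cost <- function(nvar) {
      cv <- rep(0, nvar); cv[seq_len(nb)] <- sgn * cm; cv
    }
    return(list(cost = cost, sign = sgn,
                freeze = function(env, bound)
                  lp_add_rows(env, rep(1L, sum(cm != 0)), which(cm != 0),
                              sgn * cm[cm != 0], sgn * bound,
                              sprintf("Dmean %s bound %.6g Gy", obj$structure, bound))))
  }
  abort(sprintf("unsupported objective: %s (%s)", metric, obj$direction))
}

# --- lexicographic solve ----------------------------------------------------

#' Solve a wish-list by prioritized epsilon-constraint optimization
#'
#' For priorities k = 1..K in order, minimizes (or maximizes) objective k
#' subject to all hard constraints plus the frozen bounds of earlier phases:
#' a minimized objective j < k is bounded by `delta * achieved_j`, a
#' maximized one by `achieved_j / delta`, and a sufficient objective whose
#' goal was met is fixed at its goal. Every phase is one LP over
#' nonnegative beam weights and CVaR auxiliaries. The returned plan is the
#' final phase's solution (the lowest priority, total-MU economy by default,
#' makes it unique in practice).
#'
#' @param infl A `vs_influence`.
#' @param wl A [wishlist()].
#' @param structures Named list of masks, see [gather_structures()].
#' @param lp_tol Interior-point convergence tolerance.
#' @return List with elements `plan` (a `vs_plan`) and `report` (a
#'   `vs_solve_report` tibble of per-phase achieved values, frozen bounds
#'   and solver statuses).
#' @export
solve_lexicographic <- function(infl, wl, structures, lp_tol = 1e-8) {
  stopifnot(inherits(infl, "vs_influence"), inherits(wl, "vs_wishlist"))
  nb <- ncol(infl$A)
  env <- new_lp_model(nb)
  for (r in seq_len(nrow(wl$constraints))) {
    cn <- wl$constraints[r, ]
    add_constraint_rows(env, infl, structures, cn$structure, cn$metric,
                        cn$alpha, cn$bound_gy, cn$sense, nb)
  }
  objs <- wl$objectives[order(wl$objectives$priority), ]
  prepared <- lapply(seq_len(nrow(objs)), function(r)
    prepare_objective(env, infl, structures, objs[r, ], nb))

  rows <- list(priority = integer(), structure = character(),
               metric = character(), direction = character(),
               achieved = double(), bound = double(), status = character(),
               iterations = integer())
  x_final <- NULL
  overall <- "optimal"
  for (r in seq_len(nrow(objs))) {
    po <- prepared[[r]]
    lp <- lp_assemble(env)
    cv <- po$cost(env$nvar)
    res <- solve_lp(cv, lp$A, lp$b, tol = lp_tol)
    status <- res$status
    if (status %in% c("maxit", "stalled") && res$pinf < 1e-6)
      status <- "optimal"
    if (status != "optimal" && !is.null(x_final)) {
      # the previous phase's solution is a feasible witness for this phase's
      # constraint set by construction; a failure here is numerical, so fall
      # back to the witness (suboptimal in this phase's objective only)
      viol <- max(drop(lp$A %*% x_final) - lp$b)
      if (viol <= 1e-6 * (1 + max(abs(lp$b)))) {
        res$x <- x_final
        res$obj <- sum(cv * x_final)
        status <- "fallback"
        warn(sprintf("phase %d (%s %s): solver %s; kept previous phase's feasible plan",
                     objs$priority[r], objs$metric[r], objs$structure[r],
                     res$status))
      }
    }
    achieved <- po$sign * res$obj
    ob <- objs[r, ]
    if (status == "infeasible") {
      viol <- if (!is.na(res$violated_row)) lp$labels[res$violated_row] else "unknown"
      warn(sprintf("phase %d (%s %s) infeasible; violating constraint: %s",
                   ob$priority, ob$metric, ob$structure, viol))
      overall <- "infeasible"
      rows <- record_phase(rows, ob, NA_real_, NA_real_, status, res$iterations)
      break
    }
    if (status %in% c("unbounded", "maxit", "stalled")) {
      abort(sprintf("solver failure in phase %d (%s %s): status %s",
                    ob$priority, ob$metric, ob$structure, status))
    }
    goal_tol <- 1e-6 * (1 + abs(ob$goal_gy %||% 0))
    sufficient_met <- isTRUE(ob$sufficient) && !is.na(ob$goal_gy) &&
      ((ob$direction == "max" && achieved >= ob$goal_gy - goal_tol) ||
         (ob$direction == "min" && achieved <= ob$goal_gy + goal_tol))
    # tiny absolute slack keeps later phases' feasible sets full-dimensional
    eps <- 1e-6 * (1 + abs(achieved))
    bound <- if (sufficient_met) {
      if (ob$direction == "max") ob$goal_gy - eps else ob$goal_gy + eps
    } else if (ob$direction == "min") {
      wl$delta * achieved + eps
    } else {
      achieved / wl$delta - eps
    }
    po$freeze(env, bound)
    rows <- record_phase(rows, ob,
                         if (sufficient_met) ob$goal_gy else achieved,
                         bound,
                         if (sufficient_met) "goal_reached" else status,
                         res$iterations)
    x_final <- res$x
  }
  report <- structure(as_tibble(rows), class = c("vs_solve_report", class(tibble())))
  weights <- if (is.null(x_final)) rep(0, nb) else x_final[seq_len(nb)]
  plan <- new_plan(weights, infl, wl, overall, report)
  list(plan = plan, report = report)
}

record_phase <- function(rows, ob, achieved, bound, status, iters) {
  rows$priority <- c(rows$priority, ob$priority)
  rows$structure <- c(rows$structure, ob$structure)
  rows$metric <- c(rows$metric, ob$metric)
  rows$direction <- c(rows$direction, ob$direction)
  rows$achieved <- c(rows$achieved, achieved)
  rows$bound <- c(rows$bound, bound)
  rows$status <- c(rows$status, status)
  rows$iterations <- c(rows$iterations, iters)
  rows
}

# --- plans ------------------------------------------------------------------

new_plan <- function(weights, infl, wl, status, report, weight_zero_rel = 1e-6) {
  if (max(weights) > 0) weights[weights < weight_zero_rel * max(weights)] <- 0
  active <- which(weights > 0)
  plan <- structure(
    list(weights = setNames(weights, infl$beams$beam_id),
         beams = infl$beams,
         beam_count = length(active),
         node_count = length(unique(infl$beams$node[active])),
         total_mu = sum(weights),
         status = status,
         report = report,
         wishlist_hash = rlang::hash(wl)),
    class = "vs_plan"
  )
  plan$delivery_minutes <- estimate_delivery(plan)
  plan
}

#' @export
print.vs_plan <- function(x, ...) {
  cat(sprintf("<vs_plan> %s: %d beams on %d nodes, %.0f MU, est. %.1f min\n",
              x$status, x$beam_count, x$node_count, x$total_mu,
              x$delivery_minutes))
  invisible(x)
}

#' Delivery-time surrogate model
#'
#' `minutes = setup + nodes * sec_per_node / 60 + beams * sec_per_beam / 60 +
#' MU / mu_per_min`, monotone in every count. The default coefficients are
#' the package's own plausible robot timings, not published values.
#'
#' @param setup_min Fixed setup time (minutes).
#' @param sec_per_node Robot travel time per visited node (seconds).
#' @param sec_per_beam Per-beam overhead (seconds).
#' @param mu_per_min Delivery rate (MU per minute).
#' @export
delivery_model <- function(setup_min = 5, sec_per_node = 10, sec_per_beam = 5,
                           mu_per_min = 800) {
  structure(list(setup_min = setup_min, sec_per_node = sec_per_node,
                 sec_per_beam = sec_per_beam, mu_per_min = mu_per_min),
            class = "vs_delivery_model")
}

#' Estimate delivery time of a plan in minutes
#' @param plan A `vs_plan`.
#' @param model A [delivery_model()].
#' @export
estimate_delivery <- function(plan, model = delivery_model()) {
  model$setup_min + plan$node_count * model$sec_per_node / 60 +
    plan$beam_count * model$sec_per_beam / 60 +
    plan$total_mu / model$mu_per_min
}

#' Remove low-weight beams and re-solve
#'
#' Iteratively drops beams with weight below `weight_floor * max(weight)`
#' (and, if still above `max_beams`, all but the heaviest `max_beams`),
#' re-solves the wish-list on the restricted candidate set, and stops at a
#' fixed point. If a restricted solve fails, the last feasible plan is
#' returned with `sparsify_converged = FALSE`.
#'
#' @param plan A solved `vs_plan`.
#' @param infl The `vs_influence` it was solved on.
#' @param wl,structures As in [solve_lexicographic()].
#' @param max_beams Target maximum number of active beams.
#' @param weight_floor Relative weight threshold.
#' @export
sparsify <- function(plan, infl, wl, structures, max_beams = Inf,
                     weight_floor = 0.01) {
  cur <- plan
  cur_infl <- infl
  keep_global <- seq_len(ncol(infl$A))
  for (it in seq_len(20L)) {
    w <- cur$weights
    active <- which(w > 0)
    low <- which(w > 0 & w < weight_floor * max(w))
    if (length(low) == 0L && length(active) <= max_beams) {
      cur$sparsify_converged <- TRUE
      return(cur)
    }
    keep <- setdiff(active, low)
    if (length(keep) > max_beams)
      keep <- keep[order(w[keep], decreasing = TRUE)[seq_len(max_beams)]]
    keep_global <- keep_global[keep]
    cur_infl <- subset_influence(infl, keep_global)
    sol <- tryCatch(solve_lexicographic(cur_infl, wl, structures),
                    error = function(e) NULL)
    if (is.null(sol) || sol$plan$status != "optimal") {
      warn("sparsify: restricted solve failed; returning last feasible plan")
      cur$sparsify_converged <- FALSE
      return(cur)
    }
    # express on the full beam list
    w_full <- setNames(rep(0, ncol(infl$A)), infl$beams$beam_id)
    w_full[keep_global] <- sol$plan$weights
    cur <- new_plan(unname(w_full), infl, wl, sol$plan$status, sol$report)
  }
  cur$sparsify_converged <- FALSE
  cur
}

subset_influence <- function(infl, cols) {
  out <- infl
  out$A <- infl$A[, cols, drop = FALSE]
  out$beams <- infl$beams[cols, ]
  out
}

#' Extract per-shell maximum doses from a plan
#'
#' The individualized shell constraints of the two-step workflow: for each
#' shell, the maximum voxel dose delivered by the plan, reported in cGy
#' (rounded to the nearest integer cGy by default). Values are expected to
#' be nonincreasing with distance; a violation is reported as a warning.
#'
#' @param plan A solved `vs_plan`.
#' @param infl The `vs_influence` used to solve it.
#' @param shells A `vs_shell_set` (typically at 1, 3, 5 cm).
#' @param round_cgy Round to integer cGy (default TRUE).
#' @return A `vs_shell_constraints` tibble with `distance_cm`, `dmax_cgy`.
#' @export
extract_shell_dmax <- function(plan, infl, shells, round_cgy = TRUE) {
  dose_cgy <- drop(as.matrix(infl$A %*% plan$weights))
  vals <- vapply(seq_along(shells$masks), function(i) {
    rows <- which(shells$masks[[i]][infl$voxel_index])
    if (length(rows) == 0L) return(NA_real_)
    max(dose_cgy[rows])
  }, double(1))
  if (any(is.na(vals)))
    warn(sprintf("empty shell(s) at %s cm excluded from constraints",
                 paste(shells$distances_cm[is.na(vals)], collapse = ", ")))
  if (round_cgy) vals <- round(vals)
  out <- tibble(distance_cm = shells$distances_cm, dmax_cgy = vals)
  out <- out[!is.na(out$dmax_cgy), ]
  if (is.unsorted(rev(out$dmax_cgy), strictly = FALSE))
    warn("shell Dmax values are not nonincreasing with distance")
  structure(out, class = c("vs_shell_constraints", class(tibble())))
}
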