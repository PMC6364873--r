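#' Prescription for single-fraction radiosurgery
#'
#' Default: 12 Gy prescribed at the 80% isodose line (so the in-target
#' maximum is 12 / 0.8 = 15 Gy), with a coverage goal of 98% of the target
#' receiving the full prescription.
#'
#' @param dose_gy Prescribed dose (Gy).
#' @param isodose_fraction Prescription isodose as a fraction of the target
#'   maximum, in (0, 1].
#' @param coverage_fraction Required covered fraction of the target, in
#'   (0, 1).
#' @export
prescription <- function(dose_gy = 12, isodose_fraction = 0.8,
                         coverage_fraction = 0.98) {
  if (isodose_fraction <= 0 || isodose_fraction > 1)
    abort("isodose_fraction must lie in (0, 1]")
  if (coverage_fraction <= 0 || coverage_fraction >= 1)
    abort("coverage_fraction must lie in (0, 1)")
  if (dose_gy <= 0) abort("dose_gy must be positive")
  structure(list(dose_gy = dose_gy, isodose_fraction = isodose_fraction,
                 coverage_fraction = coverage_fraction,
                 ptv_max_gy = dose_gy / isodose_fraction),
            class = "vs_prescription")
}

#' Mean dose of the hottest / coldest tail of a structure
#'
#' `tail_mean_high(d, alpha)` is the mean of the hottest `ceiling(alpha * n)`
#' voxel doses; `tail_mean_low` the mean of the coldest. These are the convex
#' (CVaR-style) surrogates the optimizer uses for near-maximum dose and
#' coverage; exact D2% and V12Gy are always recomputed by sorting during
#' evaluation.
#'
#' @param doses Voxel doses over a nonempty structure (Gy).
#' @param alpha Tail fraction in (0, 1]; `alpha = 1` gives the mean dose.
#' @return Tail mean in Gy.
#' @export
tail_mean_high <- function(doses, alpha) {
  check_tail_args(doses, alpha)
  k <- ceiling(alpha * length(doses))
  mean(sort(doses, decreasing = TRUE)[seq_len(k)])
}

#' @rdname tail_mean_high
#' @export
tail_mean_low <- function(doses, alpha) {
  check_tail_args(doses, alpha)
  k <- ceiling(alpha * length(doses))
  mean(sort(doses)[seq_len(k)])
}

check_tail_args <- function(doses, alpha) {
  if (length(doses) == 0L) abort("empty structure")
  if (alpha <= 0 || alpha > 1) abort("alpha must lie in (0, 1]")
}

wishlist_metrics <- function() c("Dmax", "Dmean", "tail_mean_high", "tail_mean_low")

#' Construct a wish-list
#'
#' A wish-list is the declarative input of the prioritized optimizer: a set
#' of hard constraints that every phase must respect, and an ordered list of
#' objectives optimized one priority at a time, earlier objectives being
#' frozen (with relaxation factor `delta`) into constraints for later
#' phases. An objective with a goal and `sufficient = TRUE` stops being
#' minimized/maximized once the goal is met and becomes a constraint at the
#' goal.
#'
#' @param constraints Tibble with columns `structure`, `metric` (one of
#'   `Dmax`, `Dmean`, `tail_mean_high`, `tail_mean_low`), `alpha` (tail
#'   fraction, NA for Dmax/Dmean), `bound_gy`, `sense` (`"le"` or `"ge"`).
#' @param objectives Tibble with columns `priority` (unique, contiguous from
#'   1), `structure`, `metric` (wish-list metrics plus `"total_mu"`),
#'   `alpha`, `direction` (`"min"`/`"max"`), `goal_gy`, `sufficient`.
#' @param delta Epsilon-constraint relaxation factor (>= 1) applied when an
#'   achieved objective is frozen for later phases.
#' @export
wishlist <- function(constraints, objectives, delta = 1.03) {
  constraints <- as_tibble(constraints)
  objectives <- as_tibble(objectives)
  if (delta < 1) abort("delta must be >= 1")
  if (!all(constraints$metric %in% wishlist_metrics()))
    abort("unknown constraint metric")
  if (!all(objectives$metric %in% c(wishlist_metrics(), "total_mu")))
    abort("unknown objective metric")
  pr <- sort(objectives$priority)
  if (!identical(as.integer(pr), seq_along(pr)))
    abort("objective priorities must be unique and contiguous from 1")
  structure(list(constraints = constraints, objectives = objectives,
                 delta = delta),
            class = "vs_wishlist")
}

#' Default wish-list for vestibular schwannoma planning
#'
#' Hard constraints: target Dmax at the prescription's implied maximum
#' (12 / 0.8 = 15 Gy by default) and organ-at-risk Dmax bounds (the defaults
#' are the package's own clinically plausible choices, not published
#' values). Objectives, in priority order: target coverage via the
#' coldest-2%-mean surrogate, sufficient at the prescription dose; then
#' minimization of maximum dose on the shells at 1, 3 and 5 cm (closest
#' first); finally total MU.
#'
#' @param rx A [prescription()].
#' @param oar_dmax_gy Named vector of hard organ-at-risk Dmax bounds (Gy).
#' @param shell_distances_cm Shell distances carrying Dmax objectives.
#' @param delta Relaxation factor, see [wishlist()].
#' @export
default_vs_wishlist <- function(rx = prescription(),
                                oar_dmax_gy = c(brainstem = 12, cochlea = 12,
                                                trigeminal_nerve = 15,
                                                facial_nerve = 15),
                                shell_distances_cm = c(1, 3, 5),
                                delta = 1.03) {
  constraints <- tibble(
    structure = c("PTV", names(oar_dmax_gy)),
    metric = "Dmax",
    alpha = NA_real_,
    bound_gy = c(rx$ptv_max_gy, unname(oar_dmax_gy)),
    sense = "le"
  )
  ns <- length(shell_distances_cm)
  objectives <- tibble(
    priority = seq_len(ns + 2L),
    structure = c("PTV", paste0("shell_", format_distance(shell_distances_cm)), "MU"),
    metric = c("tail_mean_low", rep("Dmax", ns), "total_mu"),
    alpha = c(1 - rx$coverage_fraction, rep(NA_real_, ns), NA_real_),
    direction = c("max", rep("min", ns + 1L)),
    goal_gy = c(rx$dose_gy, rep(NA_real_, ns + 1L)),
    sufficient = c(TRUE, rep(FALSE, ns + 1L))
  )
  wishlist(constraints, objectives, delta)
}

#' Serialize / parse a wish-list as YAML
#' @param wl A [wishlist()].
#' @param path File path.
#' @export
write_wishlist <- function(wl, path) {
  yaml::write_yaml(list(
    format = "shellplan-wishlist-1",
    delta = wl$delta,
    constraints = lapply(seq_len(nrow(wl$constraints)), function(i)
      as.list(wl$constraints[i, ])),
    objectives = lapply(seq_len(nrow(wl$objectives)), function(i)
      as.list(wl$objectives[i, ]))
  ), path)
  invisible(path)
}

#' @rdname write_wishlist
#' @export
read_wishlist <- function(path) {
  sc <- yaml::read_yaml(path)
  fix_na <- function(df) {
    df$alpha <- as.double(df$alpha)
    df
  }
  cons <- dplyr::bind_rows(lapply(sc$constraints, function(r)
    tibble(structure = r$structure, metric = r$metric,
           alpha = if (is.null(r$alpha)) NA_real_ else as.double(r$alpha),
           bound_gy = r$bound_gy, sense = r$sense)))
  objs <- dplyr::bind_rows(lapply(sc$objectives, function(r)
    tibble(priority = as.integer(r$priority), structure = r$structure,
           metric = r$metric,
           alpha = if (is.null(r$alpha)) NA_real_ else as.double(r$alpha),
           direction = r$direction,
           goal_gy = if (is.null(r$goal_gy)) NA_real_ else as.double(r$goal_gy),
           sufficient = isTRUE(r$sufficient))))
  wishlist(fix_na(cons), fix_na(objs), sc$delta)
}

#' @export
print.vs_wishlist <- function(x, ...) {
  cat("<vs_wishlist> delta =", x$delta, "\n hard constraints:\n")
  print(x$constraints, n = Inf)
  cat(" objectives (by priority):\n")
  print(x$objectives, n = Inf)
  invisible(x)
}
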