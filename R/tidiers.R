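# broom-style tidiers for the package's fitted objects.

#' Tidy a plan into a per-beam tibble
#'
#' @param x A `vs_plan`.
#' @param active_only Keep only beams with positive weight.
#' @param ... Unused.
#' @return Tibble with beam identity, geometry and weight (MU).
#' @export
tidy.vs_plan <- function(x, active_only = FALSE, ...) {
  out <- dplyr::mutate(x$beams, weight_mu = unname(x$weights),
                       active = .data$weight_mu > 0)
  if (active_only) out <- dplyr::filter(out, .data$active)
  out
}

#' One-row summary of a plan
#' @param x A `vs_plan`.
#' @param ... Unused.
#' @export
glance.vs_plan <- function(x, ...) {
  tibble(status = x$status, beams = x$beam_count, nodes = x$node_count,
         total_mu = x$total_mu, delivery_minutes = x$delivery_minutes)
}

#' Per-phase tibble of a lexicographic solve report
#' @param x A `vs_solve_report`.
#' @param ... Unused.
#' @export
tidy.vs_solve_report <- function(x, ...) as_tibble(x)

#' Tidy a cohort comparison into its per-metric table
#' @param x A `vs_cohort_comparison`.
#' @param ... Unused.
#' @export
tidy.vs_cohort_comparison <- function(x, ...) x$table

#' One-row summary of a transfer experiment
#'
#' @param x A `vs_transfer_result`.
#' @param ... Unused.
#' @return Tibble: patient counts, acceptability per arm, fixed
#'   constraints.
#' @export
glance.vs_transfer_result <- function(x, ...) {
  ok <- is.na(x$patients$error)
  tibble(
    n_patients = nrow(x$patients),
    n_failed = sum(!ok),
    auto_acceptable = sum(x$patients$auto_acceptable[ok]),
    fauto_acceptable = sum(x$patients$fauto_acceptable[ok]),
    fauto_min_coverage_pct = min(x$patients$fauto_coverage_pct[ok], na.rm = TRUE),
    fixed_shell_cgy = paste(x$fixed_constraints$dmax_cgy, collapse = "/")
  )
}
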