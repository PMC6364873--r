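# ggplot2 visualisations: cumulative DVH curves and the per-patient
# percent-difference panel of a paired cohort comparison.

#' Plot a cumulative DVH
#'
#' @param object A `vs_dvh`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.vs_dvh <- function(object, ...) {
  df <- tibble(dose_gy = c(0, object$doses[order(object$doses)]),
               volume_pct = c(100, 100 * rev(seq_along(object$doses)) /
                                length(object$doses)))
  ggplot2::ggplot(df, ggplot2::aes(.data$dose_gy, .data$volume_pct)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::labs(x = "Dose (Gy)", y = "Volume (%)",
                  title = object$structure %||% "DVH") +
    ggplot2::theme_minimal()
}

#' Plot several structure DVHs of one dose distribution
#'
#' @param dose Full-grid dose array (Gy).
#' @param phantom A `vs_phantom`.
#' @param structures Structure names to include.
#' @export
plot_dvh <- function(dose, phantom,
                     structures = c("PTV", "brainstem", "cochlea")) {
  vox_cc <- phantom$spacing_mm^3 / 1000
  df <- dplyr::bind_rows(lapply(structures, function(nm) {
    m <- phantom$masks[[nm]]
    if (is.null(m) || !any(m)) return(NULL)
    d <- sort(dose[m])
    tibble(structure = nm, dose_gy = c(0, d),
           volume_pct = c(100, 100 * rev(seq_along(d)) / length(d)))
  }))
  ggplot2::ggplot(df, ggplot2::aes(.data$dose_gy, .data$volume_pct,
                                   colour = .data$structure)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::labs(x = "Dose (Gy)", y = "Volume (%)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Percent-difference panel of a paired comparison
#'
#' One column per metric, one point per patient, with the population mean
#' marked; positive values favour the comparison condition.
#'
#' @param object A `vs_cohort_comparison`.
#' @param metrics Optional subset of metric names (e.g. `"D2%"`).
#' @param ... Unused.
#' @export
autoplot.vs_cohort_comparison <- function(object, metrics = NULL, ...) {
  pd <- object$percent_diff
  if (!is.null(metrics)) pd <- dplyr::filter(pd, .data$metric %in% metrics)
  pd <- dplyr::mutate(pd, label = paste(.data$metric, .data$structure))
  mu <- dplyr::summarise(dplyr::group_by(pd, .data$label),
                         m = mean(.data$percent_diff, na.rm = TRUE),
                         .groups = "drop")
  ggplot2::ggplot(pd, ggplot2::aes(.data$label, .data$percent_diff)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.5, position = ggplot2::position_jitter(width = 0.1)) +
    ggplot2::geom_point(data = mu, ggplot2::aes(.data$label, .data$m),
                        colour = "red", size = 3, shape = 18) +
    ggplot2::labs(x = NULL,
                  y = sprintf("(%s - %s) / %s  (%%)", object$labels[1],
                              object$labels[2], object$labels[1])) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
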