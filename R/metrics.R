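# Plan evaluation: DVHs, near-maximum doses, dose-bath volumes, coverage,
# conformity indices, coverage rescaling, and the per-plan metrics report.
# Conventions (documented, exact, no interpolation): V_D counts voxels with
# dose >= D (closed threshold); D at volume-fraction f is the
# ceiling(f * n)-th hottest voxel's dose (order statistic).

#' Dose-volume histogram of a structure
#'
#' Exact empirical representation: the sorted voxel doses, no binning.
#'
#' @param dose Full-grid dose array (Gy).
#' @param mask Nonempty logical structure mask on the same grid.
#' @param voxel_cc Volume of one voxel in cc.
#' @param structure Optional structure name (for printing/plots).
#' @return A `vs_dvh`.
#' @export
dvh <- function(dose, mask, voxel_cc, structure = NULL) {
  if (!any(mask)) abort("dvh: empty structure mask")
  stopifnot(identical(dim(dose), dim(mask)))
  structure(list(doses = sort(dose[mask], decreasing = TRUE),
                 voxel_cc = voxel_cc, structure = structure),
            class = "vs_dvh")
}

#' Dose received by the hottest fraction of a structure
#'
#' `d_at_volume(x, 0.02)` is D2%: the `ceiling(0.02 * n)`-th hottest voxel's
#' dose. `fraction = 1` gives the minimum dose.
#'
#' @param x A `vs_dvh`.
#' @param fraction Volume fraction in (0, 1].
#' @return Dose in Gy.
#' @export
d_at_volume <- function(x, fraction = 0.02) {
  stopifnot(inherits(x, "vs_dvh"))
  if (fraction <= 0 || fraction > 1) abort("fraction must lie in (0, 1]")
  x$doses[ceiling(fraction * length(x$doses))]
}

#' Volume receiving at least a dose
#'
#' Closed threshold: voxels with dose `>= D` count.
#'
#' @param x A `vs_dvh`.
#' @param dose_gy Threshold dose D (Gy), >= 0.
#' @return Named vector: `cc` (absolute) and `pct` (percent of structure).
#' @export
v_at_dose <- function(x, dose_gy) {
  stopifnot(inherits(x, "vs_dvh"), dose_gy >= 0)
  n <- sum(x$doses >= dose_gy)
  c(cc = n * x$voxel_cc, pct = 100 * n / length(x$doses))
}

#' Target coverage: percent of the PTV at or above the prescription dose
#'
#' @param dose Full-grid dose array (Gy).
#' @param ptv_mask Nonempty logical PTV mask.
#' @param rx A [prescription()].
#' @export
coverage <- function(dose, ptv_mask, rx = prescription()) {
  if (!any(ptv_mask)) abort("coverage: empty PTV mask")
  100 * mean(dose[ptv_mask] >= rx$dose_gy)
}

#' Conformity indices of the prescription isodose volume
#'
#' The prescription isodose volume (PIV) is taken within the body mask.
#' Two common variants are reported: the plain volume ratio `PIV / PTV` and
#' the inverse-overlap (Paddick-reciprocal) index
#' `(PIV * PTV) / overlap^2`; both equal 1 for perfect conformity. With no
#' overlap the inverse-overlap variant is undefined and reported as NA.
#'
#' @inheritParams coverage
#' @param body_mask Logical body mask.
#' @param headline Which variant is the headline value (`"ratio"` or
#'   `"inverse_overlap"`).
#' @return List with `ratio`, `inverse_overlap` and `headline`.
#' @export
conformity_index <- function(dose, ptv_mask, body_mask, rx = prescription(),
                             headline = c("ratio", "inverse_overlap")) {
  headline <- match.arg(headline)
  piv <- dose >= rx$dose_gy & body_mask
  npiv <- sum(piv)
  nptv <- sum(ptv_mask)
  if (npiv == 0L) abort("prescription isodose volume is empty")
  nov <- sum(piv & ptv_mask)
  inv <- if (nov == 0L) NA_real_ else (npiv * nptv) / nov^2
  out <- list(ratio = npiv / nptv, inverse_overlap = inv, headline = headline)
  out$value <- out[[headline]]
  out
}

#' Rescale a dose distribution to a target coverage
#'
#' The exact scale factor is `rx$dose_gy / d_k`, with `d_k` the
#' `ceiling(target * n)`-th hottest PTV voxel dose, so the rescaled coverage
#' meets the target exactly by the order-statistic definition. If
#' `hard_check` is supplied and rejects an upscale (`factor > 1`), the
#' unscaled dose is returned flagged `achieved = FALSE`.
#'
#' @inheritParams coverage
#' @param target Target covered fraction (default 0.98).
#' @param hard_check Optional `function(factor)` returning TRUE when the
#'   scaled plan still satisfies its hard constraints.
#' @return List with `dose`, `factor`, `achieved`.
#' @export
rescale_to_coverage <- function(dose, ptv_mask, rx = prescription(),
                                target = rx$coverage_fraction,
                                hard_check = NULL) {
  dptv <- dose[ptv_mask]
  if (length(dptv) == 0L || max(dptv) <= 0) abort("PTV dose is zero; cannot rescale")
  k <- ceiling(target * length(dptv))
  dk <- sort(dptv, decreasing = TRUE)[k]
  if (dk <= 0) abort("coverage target unreachable: k-th hottest PTV dose is zero")
  s <- rx$dose_gy / dk
  # guard against the product landing one ulp below the threshold, which
  # would silently drop every voxel tied at the k-th order statistic
  while (s * dk < rx$dose_gy) s <- s * (1 + .Machine$double.eps)
  if (s > 1 && !is.null(hard_check) && !isTRUE(hard_check(s))) {
    return(list(dose = dose, factor = 1, achieved = FALSE))
  }
  list(dose = s * dose, factor = s, achieved = TRUE)
}

#' Full per-plan metrics report
#'
#' Computes the standard evaluation record for one dose distribution:
#' target coverage and conformity, OAR D2%/Dmean, patient (body) dose-bath
#' volumes V_D for D in 1..10 Gy, shell D2% at the evaluation distances,
#' and the plan's MU / node / beam / delivery-time summary. Missing or
#' empty structures yield explicit NA rows, never silent zeros.
#'
#' @param dose Full-grid dose array (Gy).
#' @param phantom A `vs_phantom`.
#' @param shells A `vs_shell_set` (evaluation distances, e.g. 1,2,3,5,7 cm).
#' @param plan Optional `vs_plan` for MU/node/beam/time rows.
#' @param rx A [prescription()].
#' @param vd_gy Dose-bath thresholds (Gy).
#' @return A `vs_plan_metrics` tibble: `metric`, `structure`, `value`,
#'   `unit`.
#' @export
plan_report <- function(dose, phantom, shells, plan = NULL,
                        rx = prescription(), vd_gy = c(1, 2, 3, 4, 6, 8, 10)) {
  vox_cc <- phantom$spacing_mm^3 / 1000
  masks <- phantom$masks
  add <- function(acc, metric, structure, value, unit)
    dplyr::bind_rows(acc, tibble(metric = metric, structure = structure,
                                 value = value, unit = unit))
  out <- tibble(metric = character(), structure = character(),
                value = double(), unit = character())
  out <- add(out, sprintf("V%gGy", rx$dose_gy), "PTV",
             coverage(dose, masks$PTV, rx), "%")
  if (any(dose >= rx$dose_gy & masks$body)) {
    ci <- conformity_index(dose, masks$PTV, masks$body, rx)
  } else {
    ci <- list(ratio = NA_real_, inverse_overlap = NA_real_)
  }
  out <- add(out, "CI", "PTV", ci$ratio, "")
  out <- add(out, "CI_inverse_overlap", "PTV", ci$inverse_overlap, "")
  oars <- c("brainstem", "trigeminal_nerve", "facial_nerve", "cochlea")
  for (nm in oars) {
    if (is.null(masks[[nm]]) || !any(masks[[nm]])) {
      out <- add(out, "D2%", nm, NA_real_, "Gy")
      if (nm == "brainstem") out <- add(out, "Dmean", nm, NA_real_, "Gy")
      next
    }
    h <- dvh(dose, masks[[nm]], vox_cc, nm)
    out <- add(out, "D2%", nm, d_at_volume(h, 0.02), "Gy")
    if (nm == "brainstem") out <- add(out, "Dmean", nm, mean(h$doses), "Gy")
  }
  hb <- dvh(dose, masks$body, vox_cc, "body")
  for (D in vd_gy)
    out <- add(out, sprintf("V%gGy", D), "patient",
               unname(v_at_dose(hb, D)["cc"]), "cc")
  for (i in seq_along(shells$masks)) {
    nm <- paste0("shell_", names(shells$masks)[i])
    val <- if (shells$empty[i]) NA_real_ else
      d_at_volume(dvh(dose, shells$masks[[i]], vox_cc, nm), 0.02)
    out <- add(out, "D2%", nm, val, "Gy")
  }
  out <- add(out, "MU", "plan", if (is.null(plan)) NA_real_ else plan$total_mu, "MU")
  out <- add(out, "Nodes", "plan", if (is.null(plan)) NA_real_ else plan$node_count, "")
  out <- add(out, "Beams", "plan", if (is.null(plan)) NA_real_ else plan$beam_count, "")
  out <- add(out, "TreatmentTime", "plan",
             if (is.null(plan)) NA_real_ else plan$delivery_minutes, "min")
  structure(out, class = c("vs_plan_metrics", class(tibble())))
}
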