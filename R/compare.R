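# Paired cohort comparison: per-patient percent differences, exact Wilcoxon
# signed-rank tests, and mean +/- SD aggregation of metric tables.

#' Percent difference relative to a reference value
#'
#' `(m - a) / m * 100`: positive when the comparison value `a` is smaller
#' than the reference `m` (an improvement for dose-bath metrics).
#' Vectorized; a zero reference is undefined and yields NA with a warning.
#'
#' @param m Reference value(s).
#' @param a Comparison value(s).
#' @export
percent_diff <- function(m, a) {
  out <- (m - a) / m * 100
  if (any(m == 0, na.rm = TRUE)) {
    warn("percent_diff: zero reference value(s); reported as NA")
    out[m == 0] <- NA_real_
  }
  out
}

#' Paired Wilcoxon signed-rank test with exact enumeration
#'
#' Zero differences are dropped (with `p = 1` and a warning when nothing
#' remains); tied absolute differences receive mid-ranks. In `exact` mode
#' the null distribution of the positive-rank sum W+ is computed by full
#' enumeration over all 2^n sign assignments of the observed ranks (via a
#' generating-function convolution, exact also under ties); `approx` uses
#' the normal approximation with tie-corrected variance and continuity
#' correction. `auto` selects exact for n <= 20 after zero removal.
#'
#' @param x,y Paired samples (equal length); or differences in `x` with
#'   `y = NULL`.
#' @param alternative `"two.sided"`, `"less"` or `"greater"` (of `x - y`).
#' @param mode `"auto"`, `"exact"` or `"approx"`.
#' @return List of class `vs_wilcoxon`: `statistic` (W+), `p.value`, `n`
#'   (after zero removal), `mode`, `alternative`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, alternative = c("two.sided", "less", "greater"),
                                 mode = c("auto", "exact", "approx")) {
  alternative <- match.arg(alternative)
  mode <- match.arg(mode)
  d <- if (is.null(y)) x else {
    if (length(x) != length(y)) abort("x and y must have equal length")
    x - y
  }
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warn("all paired differences are zero; p = 1")
    return(new_wilcoxon(0, 1, 0L, mode, alternative))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (mode == "auto") mode <- if (n <= 20L) "exact" else "approx"
  if (mode == "exact") {
    # distribution of 2*W+ over doubled mid-ranks (integers)
    r2 <- as.integer(round(2 * r))
    counts <- c(1, rep(0, sum(r2))) # counts[w + 1] over achievable 2*W+ sums
    for (ri in r2) {
      shifted <- c(rep(0, ri), counts[seq_len(length(counts) - ri)])
      counts <- counts + shifted
    }
    total <- 2^n
    w2 <- as.integer(round(2 * W))
    p_le <- sum(counts[seq_len(w2 + 1L)]) / total
    p_ge <- sum(counts[seq.int(w2 + 1L, length(counts))]) / total
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_le, p_ge)),
                less = p_le,
                greater = p_ge)
  } else {
    e <- sum(r) / 2
    v <- sum(r^2) / 4
    z <- W - e
    cc <- 0.5 # continuity correction
    p <- switch(alternative,
                two.sided = 2 * pnorm(-(abs(z) - cc) / sqrt(v)),
                less = pnorm((z + cc) / sqrt(v)),
                greater = pnorm(-(z - cc) / sqrt(v)))
    p <- min(1, p)
  }
  new_wilcoxon(W, p, n, mode, alternative)
}

new_wilcoxon <- function(W, p, n, mode, alternative) {
  structure(list(statistic = W, p.value = p, n = n, mode = mode,
                 alternative = alternative),
            class = "vs_wilcoxon")
}

#' @export
print.vs_wilcoxon <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank (%s, %s): W+ = %g, n = %d, p = %.4g\n",
              x$mode, x$alternative, x$statistic, x$n, x$p.value))
  invisible(x)
}

#' Mean and sample standard deviation with reporting-style rounding
#'
#' @param values Numeric vector.
#' @param digits Rounding digits (e.g. 0 for integer-cGy tables); `NULL`
#'   for no rounding.
#' @return One-row tibble: `n`, `mean`, `sd` (sample, n-1 denominator; NA
#'   for n < 2).
#' @export
aggregate_mean_sd <- function(values, digits = NULL) {
  n <- length(values)
  m <- mean(values)
  s <- if (n >= 2L) sd(values) else NA_real_
  if (!is.null(digits)) {
    m <- round(m, digits)
    s <- round(s, digits)
  }
  tibble(n = n, mean = m, sd = s)
}

#' Pair two conditions of per-patient metric reports
#'
#' @param reference,comparison Lists of `vs_plan_metrics` (same patients,
#'   same order). Percent differences are computed relative to `reference`.
#' @param labels Length-2 condition labels.
#' @return A `vs_paired_cohort`.
#' @export
paired_cohort <- function(reference, comparison,
                          labels = c("reference", "comparison")) {
  if (length(reference) != length(comparison))
    abort("conditions must contain the same patients")
  if (length(reference) < 2L) abort("need at least 2 patients for paired testing")
  structure(list(reference = reference, comparison = comparison,
                 labels = labels, n = length(reference)),
            class = "vs_paired_cohort")
}

metric_key <- function(m) paste(m$metric, m$structure, sep = " | ")

#' Paired comparison table of a cohort
#'
#' For every metric in the registry (the union of metric rows of the
#' reference condition): per-condition mean +/- SD, a two-sided exact
#' Wilcoxon signed-rank p value, and a significance flag at `alpha`.
#' Patients missing a metric are excluded pairwise with the retained count
#' reported. The result also carries the per-patient percent-difference
#' matrix (relative to the reference condition) with population means.
#'
#' @param cohort A [paired_cohort()].
#' @param alpha Significance level.
#' @param mode Wilcoxon mode, see [wilcoxon_signed_rank()].
#' @return A `vs_cohort_comparison`: list with `table` (one row per metric)
#'   and `percent_diff` (long tibble patient x metric).
#' @export
cohort_table <- function(cohort, alpha = 0.05, mode = "exact") {
  stopifnot(inherits(cohort, "vs_paired_cohort"))
  keys <- metric_key(cohort$reference[[1L]])
  meta <- cohort$reference[[1L]][, c("metric", "structure", "unit")]
  get_vals <- function(cond, key)
    vapply(cond, function(m) {
      v <- m$value[metric_key(m) == key]
      if (length(v) == 1L) v else NA_real_
    }, double(1))
  rows <- lapply(seq_along(keys), function(i) {
    va <- get_vals(cohort$reference, keys[i])
    vb <- get_vals(cohort$comparison, keys[i])
    ok <- !is.na(va) & !is.na(vb)
    n <- sum(ok)
    p <- if (n >= 2L && any(va[ok] != vb[ok]))
      suppressWarnings(wilcoxon_signed_rank(va[ok], vb[ok], mode = mode)$p.value)
    else if (n >= 2L) 1 else NA_real_
    tibble(metric = meta$metric[i], structure = meta$structure[i],
           unit = meta$unit[i], n_pairs = n,
           mean_ref = mean(va[ok]), sd_ref = if (n >= 2) sd(va[ok]) else NA_real_,
           mean_cmp = mean(vb[ok]), sd_cmp = if (n >= 2) sd(vb[ok]) else NA_real_,
           p_value = p, significant = !is.na(p) & p < alpha)
  })
  tab <- dplyr::bind_rows(rows)
  pd <- dplyr::bind_rows(lapply(seq_len(cohort$n), function(pt) {
    mr <- cohort$reference[[pt]]
    mc <- cohort$comparison[[pt]]
    vals <- suppressWarnings(percent_diff(mr$value, mc$value))
    tibble(patient = pt, metric = mr$metric, structure = mr$structure,
           percent_diff = vals)
  }))
  pd_mean <- dplyr::summarise(
    dplyr::group_by(pd, .data$metric, .data$structure),
    mean_percent_diff = mean(.data$percent_diff, na.rm = TRUE), .groups = "drop")
  structure(list(table = tab, percent_diff = pd, percent_diff_mean = pd_mean,
                 labels = cohort$labels, alpha = alpha),
            class = "vs_cohort_comparison")
}

#' @export
print.vs_cohort_comparison <- function(x, ...) {
  cat(sprintf("<vs_cohort_comparison> %s vs %s (alpha = %g)\n",
              x$labels[1], x$labels[2], x$alpha))
  print(x$table, n = Inf)
  invisible(x)
}
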