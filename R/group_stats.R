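# Treated-vs-control nonparametric comparisons.
#
# Residue monitoring data are heavily zero-inflated (mostly non-detects), so
# the group comparison is rank-based: a Kruskal-Wallis test per timepoint,
# with midranks and the standard tie correction, against the chi-square
# reference distribution. The wrapper handles the fully tied degenerate case
# (e.g. all samples non-detect), where the tie-corrected statistic is 0/0.

#' Midranks of a numeric vector
#'
#' Average ("mid") ranks, with tied values sharing the mean of the ranks
#' they occupy. Ranks always sum to n(n+1)/2.
#'
#' @param values non-empty numeric vector.
#' @return numeric vector of ranks.
#' @export
rank_with_ties <- function(values) {
  if (!length(values)) {
    abort_config("cannot rank an empty vector")
  }
  rank(values, ties.method = "average")
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square p-value on k-1 degrees
#' of freedom (via [stats::kruskal.test()]). When every pooled value is
#' identical there is no rank variation and the test is defined as H = 0,
#' p = 1 (the tie-correction denominator would otherwise be zero).
#'
#' @param groups list of >= 2 non-empty numeric vectors.
#' @return list: `statistic` (H), `df`, `p_value`, `method_note`.
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    abort_config("kruskal_wallis needs at least two groups")
  }
  if (any(vapply(groups, length, 0L) == 0)) {
    abort_config("every group must be non-empty")
  }
  pooled <- unlist(groups, use.names = FALSE)
  df <- length(groups) - 1L
  if (length(unique(pooled)) == 1L) {
    return(list(statistic = 0, df = df, p_value = 1,
                method_note = "all pooled values tied; H defined as 0"))
  }
  kt <- kruskal.test(groups)
  ties <- any(duplicated(pooled))
  list(
    statistic = unname(kt$statistic),
    df = unname(kt$parameter),
    p_value = kt$p.value,
    method_note = if (ties) "tie correction applied" else "no ties"
  )
}

#' Per-timepoint treated-vs-control comparison
#'
#' For each timepoint, tests whether resolved residue concentrations differ
#' between hives at treated and control fields, using the Kruskal-Wallis
#' test on one value per hive. Non-detects enter as zeros under the default
#' policy. Timepoints where one arm has no samples are skipped with a
#' warning. No multiplicity adjustment is applied by default (the timepoints
#' are reported as separate tests); `adjust = "holm"` adds an adjusted
#' p-value column.
#'
#' @param study a `residue_study`.
#' @param substance substance to test.
#' @param policy censoring policy for resolving concentrations.
#' @param matrix matrix to test, default `"pollen"`.
#' @param timepoints timepoints to test (default: all present).
#' @param adjust `"none"` (default) or `"holm"`.
#' @return tibble: `substance, timepoint, n_treated, n_control, statistic,
#'   df, p_value` (+ `adjusted_p` if requested).
#' @export
per_timepoint_comparison <- function(study, substance, policy = "reported_value",
                                     matrix = "pollen", timepoints = NULL,
                                     adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  samples <- dplyr::filter(study$samples, .data$matrix == !!matrix)
  m <- dplyr::filter(study$measurements,
                     .data$substance == !!substance,
                     .data$status != "not_analyzed",
                     .data$sample_id %in% samples$sample_id)
  if (!nrow(m)) {
    abort_validation(paste0("no analyzed measurements for substance: ", substance))
  }
  dat <- dplyr::inner_join(m, samples, by = "sample_id")
  dat$conc <- resolve_concentration(dat, policy)
  # one value per hive x timepoint (mean, in case of replicate collections)
  dat <- dplyr::summarise(
    dplyr::group_by(dat, .data$hive_id, .data$treatment_arm, .data$timepoint),
    conc = mean(.data$conc), .groups = "drop"
  )
  tps <- timepoints %||% sort(unique(dat$timepoint))
  rows <- lapply(tps, function(tp) {
    d <- dat[dat$timepoint == tp, , drop = FALSE]
    treated <- d$conc[d$treatment_arm == "treated"]
    control <- d$conc[d$treatment_arm == "control"]
    if (!length(treated) || !length(control)) {
      warn(sprintf("timepoint %s lacks a %s arm: skipped", tp,
                   if (length(treated)) "control" else "treated"))
      return(NULL)
    }
    kw <- kruskal_wallis(list(treated = treated, control = control))
    tibble::tibble(
      substance = substance, timepoint = tp,
      n_treated = length(treated), n_control = length(control),
      statistic = kw$statistic, df = kw$df, p_value = kw$p_value
    )
  })
  out <- dplyr::bind_rows(rows)
  if (adjust == "holm" && nrow(out)) {
    out$adjusted_p <- stats::p.adjust(out$p_value, method = "holm")
  }
  out
}

#' Correlation between pollen composition and residue level
#'
#' Tests whether the crop-pollen fraction of a sample relates to its residue
#' concentration. Defaults to Spearman's rank correlation (computed on
#' midranks), in keeping with the nonparametric treatment of the residue
#' data; Pearson is available by flag. Pairs with a missing component are
#' dropped; at least 3 complete pairs are required.
#'
#' @param fraction crop-pollen fractions in `[0, 1]`.
#' @param concentration residue concentrations, ug/kg.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return list: `estimate`, `p_value`, `n`, `method`, `note`.
#' @export
composition_correlation <- function(fraction, concentration,
                                    method = c("spearman", "pearson")) {
  method <- match.arg(method)
  keep <- !is.na(fraction) & !is.na(concentration)
  x <- fraction[keep]
  y <- concentration[keep]
  if (length(x) < 3) {
    abort_config("correlation needs at least 3 complete pairs")
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    return(list(estimate = NA_real_, p_value = NA_real_, n = length(x),
                method = method, note = "zero variance: coefficient undefined"))
  }
  ct <- suppressWarnings(cor.test(x, y, method = method, exact = FALSE))
  list(estimate = unname(ct$estimate), p_value = ct$p.value, n = length(x),
       method = method, note = "ok")
}
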