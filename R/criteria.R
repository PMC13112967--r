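#' Configure a DHETG decision rule
#'
#' The core rule requires an adjusted p-value strictly below `alpha` and a
#' strictly positive `diff_mean` exceeding `log2(fold)` (fold = 3 gives the
#' log2 threshold 1.585...; the comparison uses full precision, not the
#' printed rounding). Two optional constraints tighten the rule: a minimum
#' difference in expressing-cell fraction (`min_beta_points`, percentage
#' points) and a cap on the contrast set's mean expression
#' (`max_contrast_ge`, log2 units — "contrast cells should not express the
#' gene"). All comparisons are strict, so boundary genes are excluded.
#'
#' @param alpha Significance level in (0, 1), default 0.05.
#' @param correction `"bonferroni"` or `"bh"` — must match how the stats
#'   table's `p_adj` was computed.
#' @param fold Linear fold-change threshold > 1, default 3.
#' @param min_beta_points Optional beta threshold in (0, 100].
#' @param max_contrast_ge Optional `ge_c` cap >= 0 in log2 units.
#' @return An object of class `criteria_config`.
#' @export
criteria_config <- function(alpha = 0.05,
                            correction = c("bonferroni", "bh"),
                            fold = 3,
                            min_beta_points = NULL,
                            max_contrast_ge = NULL) {
  correction <- match.arg(correction)
  if (!(alpha > 0 && alpha < 1)) {
    .stop_class("alpha must lie in (0, 1)", "dhetg_schema_error")
  }
  if (!(fold > 1)) .stop_class("fold must exceed 1", "dhetg_schema_error")
  if (!is.null(min_beta_points) &&
      !(min_beta_points > 0 && min_beta_points <= 100)) {
    .stop_class("min_beta_points must lie in (0, 100]", "dhetg_schema_error")
  }
  if (!is.null(max_contrast_ge) && max_contrast_ge < 0) {
    .stop_class("max_contrast_ge must be >= 0", "dhetg_schema_error")
  }
  structure(list(alpha = alpha, correction = correction, fold = fold,
                 log2_fold = log2(fold),
                 min_beta_points = min_beta_points,
                 max_contrast_ge = max_contrast_ge),
            class = "criteria_config")
}

#' Classify genes as DHETGs for one contrast
#'
#' Applies a [criteria_config()] to a GeneStats table: selected genes satisfy
#' `p_adj < alpha` AND `diff_mean > log2(fold)` AND, when configured,
#' `beta > min_beta_points` AND `ge_c < max_contrast_ge`. A pure function of
#' its inputs.
#'
#' @param stats data.frame from [contrast_stats()].
#' @param cfg A [criteria_config()].
#' @return Character vector of selected gene symbols (sorted).
#' @export
classify_dhetg <- function(stats, cfg) {
  stopifnot(inherits(cfg, "criteria_config"))
  req <- c("gene", "diff_mean", "p_adj")
  if (!is.null(cfg$min_beta_points)) req <- c(req, "beta")
  if (!is.null(cfg$max_contrast_ge)) req <- c(req, "ge_c")
  missing_cols <- setdiff(req, names(stats))
  if (length(missing_cols) > 0) {
    .stop_class("stats table missing column(s): %s", "dhetg_schema_error",
                paste(missing_cols, collapse = ", "))
  }
  keep <- stats$p_adj < cfg$alpha & stats$diff_mean > cfg$log2_fold
  if (!is.null(cfg$min_beta_points)) {
    keep <- keep & stats$beta > cfg$min_beta_points
  }
  if (!is.null(cfg$max_contrast_ge)) {
    keep <- keep & stats$ge_c < cfg$max_contrast_ge
  }
  sort(stats$gene[keep])
}

#' Fold-threshold sensitivity of a DHETG classification
#'
#' Re-classifies the same stats table at several fold thresholds. Selections
#' are nested: a laxer fold can only enlarge the set, so counts decrease
#' monotonically with increasing stringency.
#'
#' @param stats data.frame from [contrast_stats()].
#' @param cfg Base [criteria_config()]; its `fold` is overridden.
#' @param folds Numeric vector of fold thresholds, all > 1.
#' @return Named list mapping each fold (as character) to a gene set.
#' @export
fold_sensitivity <- function(stats, cfg, folds = c(2, 3, 5)) {
  if (any(folds <= 1)) .stop_class("all folds must exceed 1", "dhetg_schema_error")
  out <- lapply(folds, function(f) {
    cfg_f <- cfg
    cfg_f$fold <- f
    cfg_f$log2_fold <- log2(f)
    classify_dhetg(stats, cfg_f)
  })
  names(out) <- as.character(folds)
  out
}
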