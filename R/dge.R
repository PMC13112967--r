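#' Log-transform CPM values
#'
#' `log2(1 + x)`: the pseudocount of 1 makes zero CPM map to an expression
#' value of exactly 0.
#'
#' @param x Non-negative CPM value(s).
#' @return `log2(1 + x)`.
#' @export
log_cpm <- function(x) {
  if (any(!is.finite(x)) || any(x < 0)) {
    .stop_class("log_cpm needs finite non-negative CPM values",
                "dhetg_domain_error")
  }
  log2(1 + x)
}

#' Average expression (GE) of a gene over a cell set
#'
#' Arithmetic mean of `log2(1 + CPM)` over the given cells, the GE quantity
#' that `Diff_Mean` is built from.
#'
#' @param ds An `ExpressionDataset`.
#' @param gene Gene symbol.
#' @param cells Non-empty cell-id vector.
#' @return Mean expression in log2 units.
#' @export
mean_expression <- function(ds, gene, cells) {
  if (length(cells) == 0) .stop_class("empty cell list", "dhetg_schema_error")
  if (!gene %in% gene_names(ds)) {
    .stop_class("unknown gene: %s", "dhetg_schema_error", gene)
  }
  mean(log_cpm(.cpm_values(ds, gene, cells)[, 1]))
}

#' Fraction of cells expressing a gene
#'
#' Share of cells with CPM strictly above `expr_threshold`. The default
#' threshold of 0 counts any expression, the convention behind the beta
#' (expressing-cell fraction difference) criterion.
#'
#' @inheritParams mean_expression
#' @param expr_threshold CPM detection threshold (default 0).
#' @return Fraction in `[0, 1]`.
#' @export
expressing_fraction <- function(ds, gene, cells, expr_threshold = 0) {
  if (length(cells) == 0) .stop_class("empty cell list", "dhetg_schema_error")
  if (!gene %in% gene_names(ds)) {
    .stop_class("unknown gene: %s", "dhetg_schema_error", gene)
  }
  mean(.cpm_values(ds, gene, cells)[, 1] > expr_threshold)
}

# Shared two-sided rank-sum p given pooled midranks.
# w: observed rank sum of the target group; combs: precomputed k-subsets of
# 1..N for the exact path (NULL -> normal approximation).
.rank_sum_p_core <- function(r, nt, nc, combs = NULL) {
  N <- nt + nc
  w <- sum(r[seq_len(nt)])
  mu <- nt * (N + 1) / 2
  if (all(r == r[1])) return(1)              # fully tied: no evidence
  if (!is.null(combs)) {
    k <- nrow(combs)
    # rank sum of whichever group has size k (distribution is the same pool)
    wk <- if (nt <= nc) w else N * (N + 1) / 2 - w
    muk <- k * (N + 1) / 2
    Wk <- colSums(matrix(r[combs], nrow = k))
    mean(abs(Wk - muk) >= abs(wk - muk) - 1e-12)
  } else {
    tie <- tabulate(match(r, unique(r)))
    sigma2 <- nt * nc / 12 * ((N + 1) - sum(tie^3 - tie) / (N * (N - 1)))
    if (sigma2 <= 0) return(1)
    z <- (abs(w - mu) - 0.5) / sqrt(sigma2)  # continuity correction
    min(1, 2 * pnorm(-max(z, 0)))
  }
}

.exact_combs <- function(nt, nc, exact_cutoff, max_arrangements) {
  k <- min(nt, nc)
  N <- nt + nc
  if (k <= exact_cutoff && choose(N, k) <= max_arrangements) {
    utils::combn(N, k)
  } else {
    NULL
  }
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Mann-Whitney/Wilcoxon rank-sum test using midranks for ties. For small
#' groups (`min(n) <= exact_cutoff` and at most `max_arrangements` subsets)
#' the p-value is computed by exact enumeration of the permutation null:
#' `P(|W - E W| >= |w_obs - E W|)` over all equally likely assignments of the
#' pooled midranks. Otherwise a normal approximation with tie correction and
#' continuity correction is used. Fully tied input yields p = 1. The p-value
#' depends on the data only through ranks, so it is invariant under strictly
#' monotone transforms (log2(1+CPM) and CPM give identical p).
#'
#' @param values_t,values_c Non-empty numeric vectors (target/contrast).
#' @param exact_cutoff Largest `min(n)` for which exact enumeration is
#'   attempted (default 8).
#' @param max_arrangements Cap on the number of enumerated subsets
#'   (default 1e6).
#' @return p-value in `[0, 1]`.
#' @export
rank_sum_p <- function(values_t, values_c, exact_cutoff = 8,
                       max_arrangements = 1e6) {
  nt <- length(values_t)
  nc <- length(values_c)
  if (nt == 0 || nc == 0) {
    .stop_class("both value lists must be non-empty", "dhetg_schema_error")
  }
  r <- rank(c(values_t, values_c))
  .rank_sum_p_core(r, nt, nc,
                   combs = .exact_combs(nt, nc, exact_cutoff, max_arrangements))
}

#' Adjust p-values for multiple testing
#'
#' Bonferroni (`min(1, p * m)`) or Benjamini-Hochberg step-up adjustment, with
#' an explicit multiplicity `m` that may exceed the number of p-values — e.g.
#' when target-gene p-values are extracted from a genome-wide corrected
#' output, `m` is the full gene count. For BH the supplied p-values must then
#' be the `length(p)` smallest of the conceptual m-list (true when extracting
#' a subset of a larger family is interpreted conservatively: absent p-values
#' are treated as large).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param method `"bonferroni"` or `"bh"`.
#' @param m Multiplicity, at least `length(p)` (default `length(p)`).
#' @return Adjusted p-values, same order as input.
#' @export
adjust_p <- function(p, method = c("bonferroni", "bh"), m = length(p)) {
  method <- match.arg(method)
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    .stop_class("p-values must lie in [0, 1]", "dhetg_domain_error")
  }
  if (m < length(p)) {
    .stop_class("multiplicity m (%d) smaller than number of p-values (%d)",
                "dhetg_schema_error", m, length(p))
  }
  if (method == "bonferroni") {
    pmin(1, p * m)
  } else {
    n <- length(p)
    if (n == 0) return(numeric(0))
    o <- order(p, decreasing = TRUE)
    ro <- order(o)
    pmin(1, cummin(m / (n:1) * p[o]))[ro]
  }
}

#' Per-gene differential expression statistics for one contrast
#'
#' Computes, for every requested gene, the quantities a DHETG decision is
#' based on: mean log2(1+CPM) in the target and contrast sets (`ge_t`,
#' `ge_c`), their difference (`diff_mean`, the log2 fold-change), the
#' two-sided Wilcoxon rank-sum p-value (`p_raw`), its multiplicity-adjusted
#' value (`p_adj`), and the expressing-cell fractions and their difference in
#' percentage points (`beta_t`, `beta_c`, `beta`).
#'
#' @param ds An `ExpressionDataset`.
#' @param contrast A [contrast_spec()].
#' @param genes Gene symbols to test (default: all dataset genes).
#' @param correction `"bonferroni"` or `"bh"`.
#' @param m Multiplicity for the correction; defaults to the total number of
#'   genes in the dataset (genome-wide correction), not just `length(genes)`.
#' @param expr_threshold CPM threshold for "expressing" (default 0).
#' @param exact_cutoff,max_arrangements Passed to [rank_sum_p()].
#' @return data.frame with one row per gene, sorted by gene symbol, columns
#'   `gene`, `ge_t`, `ge_c`, `diff_mean`, `p_raw`, `p_adj`, `beta_t`,
#'   `beta_c`, `beta`.
#' @export
contrast_stats <- function(ds, contrast, genes = gene_names(ds),
                           correction = c("bonferroni", "bh"), m = NULL,
                           expr_threshold = 0, exact_cutoff = 8,
                           max_arrangements = 1e6) {
  stopifnot(inherits(ds, "ExpressionDataset"), inherits(contrast, "contrast_spec"))
  correction <- match.arg(correction)
  if (length(genes) == 0) .stop_class("empty gene list", "dhetg_schema_error")
  bad <- setdiff(genes, gene_names(ds))
  if (length(bad) > 0) {
    .stop_class("unknown gene(s): %s", "dhetg_schema_error",
                paste(head(bad, 5), collapse = ", "))
  }
  if (is.null(m)) m <- ncol(ds$cpm)
  genes <- sort(genes)

  xt <- .cpm_values(ds, genes, contrast$target_cells)
  xc <- .cpm_values(ds, genes, contrast$contrast_cells)
  nt <- nrow(xt)
  nc <- nrow(xc)

  ge_t <- colMeans(log2(1 + xt))
  ge_c <- colMeans(log2(1 + xc))
  beta_t <- colMeans(xt > expr_threshold)
  beta_c <- colMeans(xc > expr_threshold)

  combs <- .exact_combs(nt, nc, exact_cutoff, max_arrangements)
  pooled <- rbind(xt, xc)
  p_raw <- vapply(seq_along(genes), function(j) {
    .rank_sum_p_core(rank(pooled[, j]), nt, nc, combs)
  }, numeric(1))

  data.frame(
    gene = genes,
    ge_t = unname(ge_t),
    ge_c = unname(ge_c),
    diff_mean = unname(ge_t - ge_c),
    p_raw = p_raw,
    p_adj = adjust_p(p_raw, correction, m),
    beta_t = unname(beta_t),
    beta_c = unname(beta_c),
    beta = unname(beta_t - beta_c) * 100,
    stringsAsFactors = FALSE
  )
}

#' Write a GeneStats table to CSV
#'
#' @param stats data.frame from [contrast_stats()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gene_stats <- function(stats, path) {
  data.table::fwrite(stats, path)
  invisible(path)
}
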