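#' Per-IDG-class share of DHETG hits
#'
#' Counts hits per target class and normalises each count to the class's
#' total size in the catalogue, yielding the share (in percent) of a class's
#' genes that came out as DHETGs. Shares are computed at full precision; the
#' `share_pct_rendered` column rounds to 3 decimals for display.
#'
#' @param hits Character vector of DHETG symbols; must all be present in the
#'   catalogue.
#' @param catalog data.frame with columns `symbol`, `idg_class`.
#' @param class_totals Optional named vector class -> total gene count;
#'   defaults to the class sizes of `catalog`. Must cover all nine classes
#'   present in the catalogue.
#' @return data.frame with one row per class: `idg_class`, `n_hits`,
#'   `class_total`, `share_pct`, `share_pct_rendered`.
#' @export
class_share <- function(hits, catalog, class_totals = NULL) {
  catalog <- as.data.frame(catalog, stringsAsFactors = FALSE)
  hits <- unique(as.character(hits))
  unknown <- setdiff(hits, catalog$symbol)
  if (length(unknown) > 0) {
    .stop_class("hit gene(s) absent from catalogue: %s", "dhetg_integrity_error",
                paste(unknown, collapse = ", "))
  }
  classes <- IDG_CLASSES[IDG_CLASSES %in% catalog$idg_class]
  if (is.null(class_totals)) {
    class_totals <- table(factor(catalog$idg_class, levels = classes))
    class_totals <- setNames(as.integer(class_totals), classes)
  } else {
    missing_cls <- setdiff(classes, names(class_totals))
    if (length(missing_cls) > 0) {
      .stop_class("class_totals missing class(es): %s", "dhetg_schema_error",
                  paste(missing_cls, collapse = ", "))
    }
  }
  hit_class <- catalog$idg_class[match(hits, catalog$symbol)]
  n_hits <- vapply(classes, function(cl) sum(hit_class == cl), integer(1))
  totals <- as.numeric(class_totals[classes])
  if (any(n_hits > totals)) {
    .stop_class("more hits than catalogue genes in a class", "dhetg_integrity_error")
  }
  share <- ifelse(totals > 0, 100 * n_hits / totals, 0)
  data.frame(idg_class = classes,
             n_hits = n_hits,
             class_total = as.integer(totals),
             share_pct = share,
             share_pct_rendered = round(share, 3),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Cross-cell-type multiplicity of DHETG hits
#'
#' Measures how often the same gene is a DHETG in more than one target cell
#' type. A gene's multiplicity is the number of cell types whose hit set
#' contains it. Two shared-gene percentages are emitted because the natural
#' denominators differ: `shared_pct_of_hits` divides the number of distinct
#' shared genes by the total count of (cell type, gene) hit occurrences, and
#' `shared_pct_of_genes` divides it by the number of distinct genes in the
#' union.
#'
#' @param per_celltype_hits Named list: cell type -> character vector of
#'   DHETG symbols.
#' @return A list of class `multiplicity_report` with elements `total_hits`,
#'   `n_distinct_genes`, `counts_by_multiplicity` (named integer vector,
#'   k -> gene count), `shared_gene_count`, `shared_pct_of_hits`,
#'   `shared_pct_of_genes`.
#' @export
multiplicity_report <- function(per_celltype_hits) {
  if (length(per_celltype_hits) == 0 || is.null(names(per_celltype_hits))) {
    .stop_class("per_celltype_hits must be a non-empty named list",
                "dhetg_schema_error")
  }
  sets <- lapply(per_celltype_hits, function(s) unique(as.character(s)))
  total_hits <- sum(lengths(sets))
  genes <- unlist(sets, use.names = FALSE)
  mult <- table(genes)
  counts <- table(factor(as.integer(mult), levels = seq_len(length(sets))))
  counts <- setNames(as.integer(counts), names(counts))
  counts <- counts[counts > 0]
  shared <- sum(mult >= 2)
  structure(list(
    total_hits = total_hits,
    n_distinct_genes = length(mult),
    counts_by_multiplicity = counts,
    shared_gene_count = shared,
    shared_pct_of_hits = if (total_hits > 0) 100 * shared / total_hits else 0,
    shared_pct_of_genes = if (length(mult) > 0) 100 * shared / length(mult) else 0
  ), class = "multiplicity_report")
}

#' @exportS3Method base::print
print.multiplicity_report <- function(x, ...) {
  cat(sprintf("multiplicity_report: %d hits over %d distinct genes\n",
              x$total_hits, x$n_distinct_genes))
  for (k in names(x$counts_by_multiplicity)) {
    cat(sprintf("  in %s cell type(s): %d gene(s)\n", k,
                x$counts_by_multiplicity[[k]]))
  }
  cat(sprintf("  shared (>=2): %d genes = %.1f%% of hits, %.1f%% of genes\n",
              x$shared_gene_count, x$shared_pct_of_hits, x$shared_pct_of_genes))
  invisible(x)
}
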