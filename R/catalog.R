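#' Map a human target list to another species via an orthology table
#'
#' Applies the orthologue-mapping rules used when translating a human
#' druggable-genome list to mouse symbols: human genes with no orthologue are
#' dropped; genes with several orthologues contribute one catalogue entry per
#' orthologue; a mouse symbol reached from several human genes is kept once,
#' with the first-encountered IDG class (conflicting classes are logged via a
#' warning).
#'
#' @param human_genes data.frame with columns `symbol` and `idg_class`
#'   (unique symbols, classes among [idg_classes()]).
#' @param orthology data.frame with columns `human_symbol`, `mouse_symbol`;
#'   one row per orthologue pair. Humans absent from the table count as
#'   lacking an orthologue.
#' @return List with `catalog` (data.frame `symbol`, `idg_class`,
#'   `source_symbol`) and `report` (named list of stage counts:
#'   `n_input`, `n_no_orthologue`, `n_expanded`, `n_duplicates_removed`,
#'   `n_after_orthology`).
#' @export
map_orthologues <- function(human_genes, orthology) {
  human_genes <- as.data.frame(human_genes, stringsAsFactors = FALSE)
  if (nrow(human_genes) == 0) {
    .stop_class("empty input gene list", "dhetg_schema_error")
  }
  if (!all(c("symbol", "idg_class") %in% names(human_genes))) {
    .stop_class("human_genes needs columns symbol, idg_class", "dhetg_schema_error")
  }
  if (anyDuplicated(human_genes$symbol)) {
    .stop_class("duplicate input symbols", "dhetg_integrity_error")
  }
  bad <- setdiff(unique(human_genes$idg_class), IDG_CLASSES)
  if (length(bad) > 0) {
    .stop_class("unknown idg_class value(s): %s", "dhetg_schema_error",
                paste(bad, collapse = ", "))
  }
  orthology <- as.data.frame(orthology, stringsAsFactors = FALSE)
  if (!all(c("human_symbol", "mouse_symbol") %in% names(orthology))) {
    .stop_class("orthology table needs columns human_symbol, mouse_symbol",
                "dhetg_schema_error")
  }
  ok <- nzchar(orthology$human_symbol) & nzchar(orthology$mouse_symbol) &
    !is.na(orthology$human_symbol) & !is.na(orthology$mouse_symbol)
  if (any(!ok)) {
    .stop_class("malformed orthology row(s) at line(s): %s",
                "dhetg_schema_error", paste(which(!ok), collapse = ", "))
  }

  # expand each human gene to its orthologues, preserving input row order
  idx <- split(seq_len(nrow(orthology)), orthology$human_symbol)
  rows <- lapply(seq_len(nrow(human_genes)), function(i) {
    h <- human_genes$symbol[i]
    mi <- idx[[h]]
    if (is.null(mi)) return(NULL)
    data.frame(symbol = orthology$mouse_symbol[mi],
               idg_class = human_genes$idg_class[i],
               source_symbol = h, stringsAsFactors = FALSE)
  })
  mapped_per_input <- vapply(rows, function(r) if (is.null(r)) 0L else nrow(r),
                             integer(1))
  expanded <- do.call(rbind, rows[mapped_per_input > 0])
  if (is.null(expanded)) {
    expanded <- data.frame(symbol = character(), idg_class = character(),
                           source_symbol = character())
  }

  dup <- duplicated(expanded$symbol)
  conflicts <- unique(expanded$symbol[dup][
    expanded$idg_class[dup] !=
      expanded$idg_class[match(expanded$symbol[dup], expanded$symbol)]])
  if (length(conflicts) > 0) {
    warning(sprintf(
      "IDG class conflict for collapsed orthologue(s) %s; keeping first-encountered class",
      paste(conflicts, collapse = ", ")), call. = FALSE)
  }
  catalog <- expanded[!dup, , drop = FALSE]
  rownames(catalog) <- NULL

  report <- list(
    n_input = nrow(human_genes),
    n_no_orthologue = sum(mapped_per_input == 0),
    n_expanded = sum(pmax(mapped_per_input - 1L, 0L)),
    n_duplicates_removed = sum(dup),
    n_after_orthology = nrow(catalog)
  )
  list(catalog = catalog, report = report)
}

#' Align a catalogue with the dataset's gene symbols via an alias table
#'
#' Symbols already present in the dataset pass through; absent symbols with a
#' resolving alias are renamed; symbols with neither a match nor a usable
#' alias are dropped and listed. Resolution is single-hop and case-sensitive:
#' dataset symbols are authoritative. An alias pointing at a symbol itself
#' absent from the dataset counts as unresolved.
#'
#' @param genes Catalogue data.frame (`symbol`, `idg_class`, optionally
#'   `source_symbol`).
#' @param dataset_genes Character vector of dataset gene symbols.
#' @param aliases data.frame with columns `catalog_symbol`, `dataset_symbol`;
#'   may be empty.
#' @return List with `catalog` (aligned, unique symbols all present in
#'   `dataset_genes`), `dropped` (character vector), and `report` (counts:
#'   `n_input`, `n_matched`, `n_alias_resolved`, `n_dropped`, `n_final`).
#' @export
resolve_aliases <- function(genes, dataset_genes, aliases = NULL) {
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  if (is.null(genes$source_symbol)) genes$source_symbol <- genes$symbol
  if (is.null(aliases)) {
    aliases <- data.frame(catalog_symbol = character(),
                          dataset_symbol = character())
  }
  aliases <- as.data.frame(aliases, stringsAsFactors = FALSE)
  if (nrow(aliases) > 0 &&
      !all(c("catalog_symbol", "dataset_symbol") %in% names(aliases))) {
    .stop_class("alias table needs columns catalog_symbol, dataset_symbol",
                "dhetg_schema_error")
  }

  n_input <- nrow(genes)
  present <- genes$symbol %in% dataset_genes
  ali <- aliases$dataset_symbol[match(genes$symbol, aliases$catalog_symbol)]
  resolvable <- !present & !is.na(ali) & ali %in% dataset_genes
  genes$symbol[resolvable] <- ali[resolvable]

  keep <- present | resolvable
  dropped <- genes$symbol[!keep]
  out <- genes[keep, , drop = FALSE]
  dup <- duplicated(out$symbol)        # alias renames can collide
  out <- out[!dup, , drop = FALSE]
  rownames(out) <- NULL

  report <- list(
    n_input = n_input,
    n_matched = sum(present),
    n_alias_resolved = sum(resolvable),
    n_dropped = length(dropped),
    n_final = nrow(out)
  )
  list(catalog = out, dropped = dropped, report = report)
}

#' Build a dataset-aligned target catalogue
#'
#' Convenience wrapper running [map_orthologues()] (when an orthology table is
#' given) followed by [resolve_aliases()], and merging the stage reports.
#'
#' @param target_list data.frame (`symbol`, `idg_class`) of source targets.
#' @param dataset_genes Dataset gene symbols.
#' @param orthology Optional orthology table (`human_symbol`, `mouse_symbol`);
#'   omit for a same-species catalogue.
#' @param aliases Optional alias table (`catalog_symbol`, `dataset_symbol`).
#' @return List with `catalog`, `dropped`, `report`.
#' @export
build_target_catalog <- function(target_list, dataset_genes,
                                 orthology = NULL, aliases = NULL) {
  if (!is.null(orthology)) {
    st1 <- map_orthologues(target_list, orthology)
    genes <- st1$catalog
    rep1 <- st1$report
  } else {
    genes <- as.data.frame(target_list, stringsAsFactors = FALSE)
    genes$source_symbol <- genes$symbol
    rep1 <- list(n_input = nrow(genes), n_no_orthologue = 0L,
                 n_expanded = 0L, n_duplicates_removed = 0L,
                 n_after_orthology = nrow(genes))
  }
  st2 <- resolve_aliases(genes, dataset_genes, aliases)
  list(catalog = st2$catalog, dropped = st2$dropped,
       report = c(rep1, st2$report[c("n_matched", "n_alias_resolved",
                                     "n_dropped", "n_final")]))
}
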