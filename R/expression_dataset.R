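#' Construct an expression dataset
#'
#' Bundles a non-negative cells-by-genes CPM matrix with per-cell metadata.
#' CPM values are taken as given (already depth-normalised); no
#' re-normalisation is performed. Cell order follows the metadata; the matrix
#' is reordered to match.
#'
#' @param cpm Numeric matrix (base or [Matrix::Matrix]) of CPM values,
#'   cells in rows, genes in columns. Row names are cell ids, column names
#'   gene symbols.
#' @param meta data.frame with columns `sample_name`, `region_label`,
#'   `subclass_label`, `class_label`; one row per cell.
#' @return An object of class `ExpressionDataset`: a list with elements
#'   `cpm` (cells x genes) and `meta`.
#' @export
expression_dataset <- function(cpm, meta) {
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  req <- c("sample_name", "region_label", "subclass_label", "class_label")
  missing_cols <- setdiff(req, names(meta))
  if (length(missing_cols) > 0) {
    .stop_class("metadata is missing required column(s): %s",
                "dhetg_schema_error", paste(missing_cols, collapse = ", "))
  }
  meta <- meta[, req]
  meta[] <- lapply(meta, as.character)
  if (anyDuplicated(meta$sample_name)) {
    .stop_class("duplicate cell id(s) in metadata: %s", "dhetg_integrity_error",
                paste(unique(meta$sample_name[duplicated(meta$sample_name)]),
                      collapse = ", "))
  }
  if (any(!nzchar(meta$region_label) | !nzchar(meta$subclass_label) |
            !nzchar(meta$class_label) |
            is.na(meta$region_label) | is.na(meta$subclass_label) |
            is.na(meta$class_label))) {
    .stop_class("every cell needs non-empty region_label, subclass_label and class_label",
                "dhetg_schema_error")
  }
  if (is.null(rownames(cpm)) || is.null(colnames(cpm))) {
    .stop_class("cpm matrix needs cell ids as row names and gene symbols as column names",
                "dhetg_schema_error")
  }
  if (anyDuplicated(colnames(cpm))) {
    .stop_class("duplicate gene symbol(s) in matrix: %s", "dhetg_integrity_error",
                paste(unique(colnames(cpm)[duplicated(colnames(cpm))]),
                      collapse = ", "))
  }
  if (anyDuplicated(rownames(cpm))) {
    .stop_class("duplicate cell id(s) in matrix", "dhetg_integrity_error")
  }
  unknown <- setdiff(rownames(cpm), meta$sample_name)
  if (length(unknown) > 0) {
    .stop_class("matrix cell(s) absent from metadata: %s",
                "dhetg_integrity_error",
                paste(head(unknown, 5), collapse = ", "))
  }
  absent <- setdiff(meta$sample_name, rownames(cpm))
  if (length(absent) > 0) {
    .stop_class("metadata cell(s) absent from matrix: %s",
                "dhetg_integrity_error", paste(head(absent, 5), collapse = ", "))
  }
  cpm <- cpm[meta$sample_name, , drop = FALSE]
  vals <- if (inherits(cpm, "sparseMatrix")) cpm@x else as.vector(cpm)
  if (any(!is.finite(vals))) {
    .stop_class("cpm matrix contains non-finite values", "dhetg_domain_error")
  }
  if (any(vals < 0)) {
    .stop_class("cpm matrix contains negative values", "dhetg_domain_error")
  }
  structure(list(cpm = cpm, meta = meta), class = "ExpressionDataset")
}

#' @exportS3Method base::print
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset: %d cells x %d genes\n",
              nrow(x$cpm), ncol(x$cpm)))
  cat(sprintf("  regions:    %s\n",
              paste(unique(x$meta$region_label), collapse = ", ")))
  cat(sprintf("  classes:    %s\n",
              paste(unique(x$meta$class_label), collapse = ", ")))
  cat(sprintf("  subclasses: %d\n", length(unique(x$meta$subclass_label))))
  invisible(x)
}

#' @rdname expression_dataset
#' @param ds An `ExpressionDataset`.
#' @export
gene_names <- function(ds) colnames(ds$cpm)

#' @rdname expression_dataset
#' @export
cell_ids <- function(ds) rownames(ds$cpm)

# cells x genes CPM sub-matrix as dense base matrix
.cpm_values <- function(ds, genes, cells) {
  as.matrix(ds$cpm[cells, genes, drop = FALSE])
}

#' Load an expression dataset from disk
#'
#' Reads a CPM matrix plus cell metadata. Two on-disk encodings are supported:
#' `"dense-delimited"` (CSV/TSV, first column the cell id, header row of gene
#' symbols; separator auto-detected) and `"matrix-market"` (coordinate `.mtx`
#' with companion one-symbol-per-line gene and cell index files). Matrices
#' stored genes-by-cells are transposed on load; internally the orientation is
#' always cells x genes.
#'
#' @param matrix_path Path to the matrix file.
#' @param meta_path Path to the metadata CSV/TSV (columns `sample_name`,
#'   `region_label`, `subclass_label`, `class_label`).
#' @param format `"dense-delimited"` or `"matrix-market"`.
#' @param genes_path,cells_path Index files, required for `"matrix-market"`.
#' @return An [expression_dataset()].
#' @export
load_expression <- function(matrix_path, meta_path,
                            format = c("dense-delimited", "matrix-market"),
                            genes_path = NULL, cells_path = NULL) {
  format <- match.arg(format)
  for (p in c(matrix_path, meta_path, genes_path, cells_path)) {
    if (!file.exists(p)) .stop_class("file not found: %s", "dhetg_schema_error", p)
  }
  meta <- data.table::fread(meta_path, data.table = FALSE,
                            colClasses = "character")
  if (format == "dense-delimited") {
    dt <- data.table::fread(matrix_path, data.table = FALSE)
    ids <- as.character(dt[[1]])
    m <- as.matrix(dt[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
    # on-disk genes x cells: gene ids in column 1, cell ids in header
    if (!any(ids %in% meta$sample_name) &&
        any(colnames(m) %in% meta$sample_name)) {
      m <- t(m)
    }
  } else {
    if (is.null(genes_path) || is.null(cells_path)) {
      .stop_class("matrix-market format needs genes_path and cells_path",
                  "dhetg_schema_error")
    }
    m <- as(Matrix::readMM(matrix_path), "CsparseMatrix")
    genes <- readLines(genes_path)
    cells <- readLines(cells_path)
    if (nrow(m) == length(cells) && ncol(m) == length(genes)) {
      dimnames(m) <- list(cells, genes)
    } else if (nrow(m) == length(genes) && ncol(m) == length(cells)) {
      dimnames(m) <- list(genes, cells)
      m <- Matrix::t(m)
    } else {
      .stop_class("matrix dimensions %d x %d match neither index file (%d genes, %d cells)",
                  "dhetg_integrity_error", nrow(m), ncol(m),
                  length(genes), length(cells))
    }
  }
  expression_dataset(m, meta)
}

#' Write an expression dataset to disk
#'
#' Inverse of [load_expression()]; used for round-tripping and by the
#' `simulate` CLI subcommand.
#'
#' @inheritParams load_expression
#' @param ds An `ExpressionDataset`.
#' @return Invisibly, the paths written.
#' @export
write_expression <- function(ds, matrix_path, meta_path,
                             format = c("dense-delimited", "matrix-market"),
                             genes_path = NULL, cells_path = NULL) {
  format <- match.arg(format)
  data.table::fwrite(ds$meta, meta_path, sep = "\t")
  if (format == "dense-delimited") {
    df <- data.frame(sample_name = rownames(ds$cpm),
                     as.matrix(ds$cpm), check.names = FALSE)
    data.table::fwrite(df, matrix_path)
  } else {
    if (is.null(genes_path) || is.null(cells_path)) {
      .stop_class("matrix-market format needs genes_path and cells_path",
                  "dhetg_schema_error")
    }
    Matrix::writeMM(as(Matrix::Matrix(ds$cpm, sparse = TRUE), "generalMatrix"),
                    matrix_path)
    writeLines(colnames(ds$cpm), genes_path)
    writeLines(rownames(ds$cpm), cells_path)
  }
  invisible(c(matrix_path, meta_path, genes_path, cells_path))
}
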