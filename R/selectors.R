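#' Describe a cell selection by metadata labels
#'
#' A selector matches cells whose annotations satisfy every given criterion
#' (region AND subclass AND class), minus any excluded subclasses. This
#' mirrors filtering the metadata first by `region_label`, then by
#' `subclass_label` (or `class_label` for whole-class selections).
#'
#' @param regions,subclasses,classes Character vectors of admissible labels;
#'   `NULL` means "no constraint on this field". At least one must be given.
#' @param exclude_subclasses Subclass labels removed from the match (e.g. a
#'   combined subclass dropped from both sides of a contrast).
#' @return An object of class `cell_selector`.
#' @export
cell_selector <- function(regions = NULL, subclasses = NULL, classes = NULL,
                          exclude_subclasses = NULL) {
  if (is.null(regions) && is.null(subclasses) && is.null(classes)) {
    .stop_class("at least one of regions/subclasses/classes must be given",
                "dhetg_schema_error")
  }
  if (!is.null(exclude_subclasses) && !is.null(subclasses) &&
      length(intersect(exclude_subclasses, subclasses)) > 0) {
    .stop_class("exclude_subclasses overlaps subclasses: %s",
                "dhetg_schema_error",
                paste(intersect(exclude_subclasses, subclasses), collapse = ", "))
  }
  structure(list(regions = regions, subclasses = subclasses,
                 classes = classes, exclude_subclasses = exclude_subclasses),
            class = "cell_selector")
}

#' Select cells matching a selector
#'
#' Returns the ids of all cells matching every criterion of `sel`, in dataset
#' (metadata) order. A selector matching zero cells returns an empty vector;
#' contrast construction errors on empty sets downstream.
#'
#' @param ds An `ExpressionDataset`.
#' @param sel A [cell_selector()].
#' @return Character vector of cell ids.
#' @export
select_cells <- function(ds, sel) {
  stopifnot(inherits(ds, "ExpressionDataset"), inherits(sel, "cell_selector"))
  meta <- ds$meta
  keep <- rep(TRUE, nrow(meta))
  if (!is.null(sel$regions))    keep <- keep & meta$region_label %in% sel$regions
  if (!is.null(sel$subclasses)) keep <- keep & meta$subclass_label %in% sel$subclasses
  if (!is.null(sel$classes))    keep <- keep & meta$class_label %in% sel$classes
  if (!is.null(sel$exclude_subclasses)) {
    keep <- keep & !(meta$subclass_label %in% sel$exclude_subclasses)
  }
  meta$sample_name[keep]
}

#' Pool cells over several selectors
#'
#' Union of per-selector matches, deduplicated, in dataset order — e.g. a
#' motor-cortex group pooling primary and secondary motor areas, or a sensory
#' group pooling visual/auditory/somatosensory areas.
#'
#' @param ds An `ExpressionDataset`.
#' @param selectors List of [cell_selector()] objects (at least one).
#' @return Character vector of cell ids.
#' @export
pool_cells <- function(ds, selectors) {
  if (inherits(selectors, "cell_selector")) selectors <- list(selectors)
  if (length(selectors) == 0) {
    .stop_class("pool_cells needs at least one selector", "dhetg_schema_error")
  }
  hit <- unique(unlist(lapply(selectors, function(s) select_cells(ds, s)),
                       use.names = FALSE))
  ds$meta$sample_name[ds$meta$sample_name %in% hit]
}

#' Define a target/contrast cell-set pair
#'
#' @param label Contrast label, unique within a plan.
#' @param target_cells,contrast_cells Disjoint, non-empty cell-id vectors
#'   (Set T and Set C).
#' @param ds Optional `ExpressionDataset`; when given, ids are checked
#'   against it.
#' @return An object of class `contrast_spec`.
#' @export
contrast_spec <- function(label, target_cells, contrast_cells, ds = NULL) {
  if (length(target_cells) == 0 || length(contrast_cells) == 0) {
    .stop_class("contrast '%s': target and contrast sets must be non-empty",
                "dhetg_schema_error", label)
  }
  if (length(intersect(target_cells, contrast_cells)) > 0) {
    .stop_class("contrast '%s': target and contrast sets overlap",
                "dhetg_schema_error", label)
  }
  if (!is.null(ds)) {
    bad <- setdiff(c(target_cells, contrast_cells), cell_ids(ds))
    if (length(bad) > 0) {
      .stop_class("contrast '%s': unknown cell id(s): %s",
                  "dhetg_integrity_error", label,
                  paste(head(bad, 5), collapse = ", "))
    }
  }
  structure(list(label = label,
                 target_cells = as.character(target_cells),
                 contrast_cells = as.character(contrast_cells)),
            class = "contrast_spec")
}
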