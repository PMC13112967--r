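# Contrast plans and set combination.
#
# A "cell type" is a label resolving to one or more subclass_label values via
# type_map (default: the label itself). Plans bundle one target cell set with
# an ordered list of contrast_spec objects sharing that target set.

.resolve_type <- function(type_label, type_map) {
  if (!is.null(type_map) && type_label %in% names(type_map)) {
    type_map[[type_label]]
  } else {
    type_label
  }
}

.type_cells <- function(ds, regions, type_label, type_map,
                        exclude_subclasses = NULL) {
  subs <- setdiff(.resolve_type(type_label, type_map), exclude_subclasses)
  if (length(subs) == 0) {
    .stop_class("cell type '%s' fully excluded", "dhetg_schema_error", type_label)
  }
  select_cells(ds, cell_selector(regions = regions, subclasses = subs,
                                 exclude_subclasses = exclude_subclasses))
}

.new_plan <- function(target_label, contrasts, mode) {
  labels <- vapply(contrasts, `[[`, character(1), "label")
  if (anyDuplicated(labels)) {
    .stop_class("duplicate contrast labels in plan", "dhetg_schema_error")
  }
  structure(list(target_label = target_label, contrasts = contrasts,
                 mode = mode), class = "comparison_plan")
}

#' @exportS3Method base::print
print.comparison_plan <- function(x, ...) {
  cat(sprintf("comparison_plan (%s): target '%s', %d contrast(s)\n",
              x$mode, x$target_label, length(x$contrasts)))
  for (ct in x$contrasts) {
    cat(sprintf("  %-24s n_target=%d n_contrast=%d\n", ct$label,
                length(ct$target_cells), length(ct$contrast_cells)))
  }
  invisible(x)
}

#' Conservative one-vs-one intra-regional plan
#'
#' One pairwise contrast between the target cell type and each other cell
#' type of the same region. Downstream, the intersection of all pairwise
#' DHETG sets is the conservative result. Exclusion rules (e.g. a combined
#' subclass dropped from both target and contrast sides of specific pairs)
#' are supported via `exclusions`.
#'
#' @param ds An `ExpressionDataset`.
#' @param region Character vector of `region_label` values defining the region.
#' @param target_type Target cell-type label.
#' @param contrast_types Labels of the contrast cell types (must not contain
#'   `target_type`).
#' @param type_map Optional named list mapping a type label to its
#'   `subclass_label` values (default: label == subclass).
#' @param exclusions Optional named list: for a contrast label, subclasses to
#'   drop from both target and contrast cells of that pair.
#' @return A `comparison_plan`.
#' @export
plan_intra_conservative <- function(ds, region, target_type, contrast_types,
                                    type_map = NULL, exclusions = NULL) {
  if (target_type %in% contrast_types) {
    .stop_class("target type '%s' also listed as contrast type",
                "dhetg_schema_error", target_type)
  }
  target_subs <- .resolve_type(target_type, type_map)
  contrasts <- lapply(contrast_types, function(ct_label) {
    excl <- exclusions[[ct_label]]
    tcells <- .type_cells(ds, region, target_type, type_map, excl)
    ccells <- .type_cells(ds, region, ct_label, type_map, excl)
    overlap_subs <- intersect(target_subs, .resolve_type(ct_label, type_map))
    if (length(overlap_subs) > 0) {
      ccells <- setdiff(ccells, tcells)
    }
    if (length(tcells) == 0) {
      .stop_class("empty target set for '%s' (region %s)", "dhetg_schema_error",
                  target_type, paste(region, collapse = "/"))
    }
    if (length(ccells) == 0) {
      .stop_class("empty contrast set for '%s' (region %s)", "dhetg_schema_error",
                  ct_label, paste(region, collapse = "/"))
    }
    contrast_spec(sprintf("%s_vs_%s", target_type, ct_label), tcells, ccells,
                  ds = ds)
  })
  # with per-pair exclusions the target set may differ between pairs; without
  # them it is identical throughout
  .new_plan(target_type, contrasts, "intra_conservative")
}

#' Non-conservative one-vs-all intra-regional plan
#'
#' Exactly two contrasts: the target cell type against all pooled GABAergic
#' cells and against all pooled glutamatergic cells, with the target's own
#' cells removed from its class pool. The intersection of the two DHETG sets
#' is the non-conservative result.
#'
#' @inheritParams plan_intra_conservative
#' @param classes The two top class labels to pool (default
#'   `c("GABAergic", "glutamatergic")`).
#' @return A `comparison_plan`.
#' @export
plan_intra_onevsall <- function(ds, region, target_type, type_map = NULL,
                                classes = c("GABAergic", "glutamatergic")) {
  tcells <- .type_cells(ds, region, target_type, type_map)
  if (length(tcells) == 0) {
    .stop_class("empty target set for '%s'", "dhetg_schema_error", target_type)
  }
  contrasts <- lapply(classes, function(cl) {
    pool <- select_cells(ds, cell_selector(regions = region, classes = cl))
    pool <- setdiff(pool, tcells)
    if (length(pool) == 0) {
      .stop_class("empty %s pool after removing target '%s'",
                  "dhetg_schema_error", cl, target_type)
    }
    contrast_spec(sprintf("%s_vs_all_%s", target_type, cl), tcells, pool,
                  ds = ds)
  })
  .new_plan(target_type, contrasts, "intra_onevsall")
}

#' Inter-regional plan against pooled region groups
#'
#' One contrast per regional group: the target cell type in its home region
#' against its counterpart (same subclasses) pooled over the group's regions.
#' Groups can be restricted to a target class (e.g. a hippocampus group that
#' only applies to GABAergic targets); requesting such a group for a target
#' of another class is a configuration error.
#'
#' @param ds An `ExpressionDataset`.
#' @param target_type Target cell-type label.
#' @param home_region Character vector of `region_label` values of the home
#'   region.
#' @param region_groups Named list: group label -> character vector of
#'   `region_label` values pooled into that group's contrast set.
#' @param type_map Optional type label -> subclasses map.
#' @param group_class_restriction Optional named character vector: group
#'   label -> the only `class_label` allowed to use that group.
#' @return A `comparison_plan`.
#' @export
plan_inter_regional <- function(ds, target_type, home_region, region_groups,
                                type_map = NULL,
                                group_class_restriction = NULL) {
  tcells <- .type_cells(ds, home_region, target_type, type_map)
  if (length(tcells) == 0) {
    .stop_class("target type '%s' absent from home region", "dhetg_schema_error",
                target_type)
  }
  target_class <- unique(ds$meta$class_label[match(tcells, ds$meta$sample_name)])
  subs <- .resolve_type(target_type, type_map)
  contrasts <- lapply(names(region_groups), function(grp) {
    if (!is.null(group_class_restriction) &&
        grp %in% names(group_class_restriction) &&
        !all(target_class %in% group_class_restriction[[grp]])) {
      .stop_class("group '%s' is restricted to class '%s' targets",
                  "dhetg_schema_error", grp, group_class_restriction[[grp]])
    }
    pool <- pool_cells(ds, lapply(region_groups[[grp]], function(reg) {
      cell_selector(regions = reg, subclasses = subs)
    }))
    pool <- setdiff(pool, tcells)
    if (length(pool) == 0) {
      .stop_class("target type '%s' absent from group '%s'",
                  "dhetg_schema_error", target_type, grp)
    }
    contrast_spec(sprintf("%s_vs_%s", target_type, grp), tcells, pool, ds = ds)
  })
  .new_plan(target_type, contrasts, "inter_regional")
}

#' Combine per-contrast DHETG sets
#'
#' Computes, from a named collection of per-contrast gene sets: the full
#' intersection; the exclusive Venn cells (each gene assigned to the unique
#' cell of contrasts containing it) and their cumulative counterparts (genes
#' in *at least* the named contrasts); and the majority-rule sets for every
#' quorum k in 1..n. The Venn decomposition is materialised only up to
#' `venn_cap` contrasts (2^n cells); beyond that a warning is raised and only
#' intersection/majority are returned.
#'
#' @param sets Named list of character vectors (label -> gene set).
#' @param venn_cap Largest n for which Venn cells are materialised (default 6).
#' @return An object of class `intersection_result` with elements
#'   `per_contrast_sets`, `full_intersection`, `venn_exclusive`,
#'   `venn_cumulative` (both NULL above `venn_cap`), `majority_sets`.
#' @export
combine_sets <- function(sets, venn_cap = 6) {
  if (length(sets) == 0 || is.null(names(sets)) || any(!nzchar(names(sets)))) {
    .stop_class("combine_sets needs a non-empty named list of gene sets",
                "dhetg_schema_error")
  }
  sets <- lapply(sets, function(s) sort(unique(as.character(s))))
  labels <- names(sets)
  n <- length(sets)
  full <- Reduce(intersect, sets)
  all_genes <- sort(unique(unlist(sets, use.names = FALSE)))

  # gene -> number of sets containing it
  member <- vapply(sets, function(s) all_genes %in% s,
                   logical(length(all_genes)))
  member <- matrix(member, nrow = length(all_genes),
                   dimnames = list(all_genes, labels))
  mult <- rowSums(member)

  majority_sets <- lapply(seq_len(n), function(k) all_genes[mult >= k])
  names(majority_sets) <- as.character(seq_len(n))

  venn_exclusive <- NULL
  venn_cumulative <- NULL
  if (n <= venn_cap) {
    subset_names <- character(0)
    venn_exclusive <- list()
    venn_cumulative <- list()
    for (k in seq_len(n)) {
      for (cmb in as.data.frame(utils::combn(labels, k),
                                stringsAsFactors = FALSE)) {
        nm <- paste(cmb, collapse = "&")
        inside <- rowSums(member[, cmb, drop = FALSE]) == k
        venn_cumulative[[nm]] <- all_genes[inside]
        venn_exclusive[[nm]] <- all_genes[inside & mult == k]
        subset_names <- c(subset_names, nm)
      }
    }
  } else {
    warning(sprintf(
      "%d contrasts exceed the Venn cap of %d; Venn cells omitted", n, venn_cap),
      call. = FALSE)
  }

  structure(list(per_contrast_sets = sets,
                 full_intersection = full,
                 venn_exclusive = venn_exclusive,
                 venn_cumulative = venn_cumulative,
                 majority_sets = majority_sets),
            class = "intersection_result")
}

#' @exportS3Method base::print
print.intersection_result <- function(x, ...) {
  cat(sprintf("intersection_result over %d contrast(s)\n",
              length(x$per_contrast_sets)))
  for (nm in names(x$per_contrast_sets)) {
    cat(sprintf("  %-28s %d gene(s)\n", nm, length(x$per_contrast_sets[[nm]])))
  }
  cat(sprintf("  full intersection: %d gene(s)\n", length(x$full_intersection)))
  invisible(x)
}

#' Intersect an intra-regional DHETG set with inter-regional Venn cells
#'
#' For each exclusive Venn cell of an inter-regional [combine_sets()] result,
#' its intersection with the intra-regional gene set. The cell named after
#' all contrasts is the full inter-regional intersection, so the combined
#' full intersection is included. When Venn cells were omitted (above the
#' cap), only the full intersection is intersected.
#'
#' @param intra Character vector: the intra-regional DHETG set.
#' @param inter An `intersection_result` from the inter-regional plan.
#' @return Named list of gene sets (one per Venn cell, or
#'   `full_intersection` only).
#' @export
combine_intra_inter <- function(intra, inter) {
  stopifnot(inherits(inter, "intersection_result"))
  intra <- sort(unique(as.character(intra)))
  cells <- inter$venn_exclusive
  if (is.null(cells)) {
    cells <- list(full_intersection = inter$full_intersection)
  }
  lapply(cells, function(s) intersect(intra, s))
}
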