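# Config-driven screening pipeline: load -> catalogue -> per-plan contrast
# stats -> per-regime classification -> combination -> reports + manifest.

.read_tsv_opt <- function(path) {
  if (is.null(path)) return(NULL)
  if (!file.exists(path)) {
    .stop_class("file not found: %s", "dhetg_schema_error", path)
  }
  data.table::fread(path, data.table = FALSE, colClasses = "character")
}

.validate_run_config <- function(config) {
  for (key in c("dataset", "plans", "criteria", "output_dir")) {
    if (is.null(config[[key]])) {
      .stop_class("run config missing key '%s'", "dhetg_schema_error", key)
    }
  }
  if (is.null(names(config$criteria)) || any(!nzchar(names(config$criteria)))) {
    .stop_class("criteria regimes must be named", "dhetg_schema_error")
  }
  if (anyDuplicated(names(config$criteria))) {
    .stop_class("criteria regime names must be unique", "dhetg_schema_error")
  }
  invisible(config)
}

.criteria_from_config <- function(x) {
  criteria_config(alpha = x$alpha %||% 0.05,
                  correction = x$correction %||% "bonferroni",
                  fold = x$fold %||% 3,
                  min_beta_points = x$min_beta_points,
                  max_contrast_ge = x$max_contrast_ge)
}

.plan_from_config <- function(ds, p, type_map) {
  mode <- p$mode %||% "intra_conservative"
  switch(mode,
    intra_conservative = plan_intra_conservative(
      ds, region = unlist(p$region), target_type = p$target_type,
      contrast_types = unlist(p$contrast_types), type_map = type_map,
      exclusions = p$exclusions),
    intra_onevsall = plan_intra_onevsall(
      ds, region = unlist(p$region), target_type = p$target_type,
      type_map = type_map,
      classes = unlist(p$classes %||% c("GABAergic", "glutamatergic"))),
    inter_regional = plan_inter_regional(
      ds, target_type = p$target_type, home_region = unlist(p$home_region),
      region_groups = lapply(p$region_groups, unlist), type_map = type_map,
      group_class_restriction = p$group_class_restriction),
    custom = {
      contrasts <- lapply(p$contrasts, function(ct) {
        contrast_spec(ct$label, unlist(ct$target_cells),
                      unlist(ct$contrast_cells), ds = ds)
      })
      .new_plan(p$target_type %||% "custom", contrasts, "custom")
    },
    .stop_class("unknown plan mode '%s'", "dhetg_schema_error", mode)
  )
}

#' Run the full screening pipeline from a config
#'
#' Executes load, catalogue build, per-plan differential expression, per-
#' regime DHETG classification and set combination, and writes per-contrast
#' GeneStats CSVs, intersection JSONs, a count summary CSV and a run
#' manifest into the output directory. Idempotent given fixed inputs
#' (manifest timestamps aside).
#'
#' @param config Path to a JSON run config, or an equivalent named list.
#'   Keys: `dataset` (`matrix`, `meta`, `format`, optional `genes`/`cells`),
#'   optional `catalog` (`targets`, optional `orthology`, `aliases`),
#'   optional `type_map`, `plans` (list of plan descriptions with `name` and
#'   `mode`), `criteria` (named regimes), `output_dir`, optional
#'   `multiplicity` (`"dataset"` or `"catalog"`), optional `seed`.
#' @param output_dir Overrides the config's output directory.
#' @return Invisibly, a list with the per-plan/per-regime results and the
#'   manifest.
#' @export
run_screen <- function(config, output_dir = NULL) {
  t0 <- Sys.time()
  if (is.character(config)) {
    if (!file.exists(config)) {
      .stop_class("config file not found: %s", "dhetg_schema_error", config)
    }
    config <- jsonlite::read_json(config, simplifyVector = FALSE)
  }
  .validate_run_config(config)
  out_dir <- output_dir %||% config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  timings <- list()
  stage <- function(name, expr) {
    ts <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      # prepend the stage name but keep the condition class for exit codes
      stop(structure(
        class = unique(c(class(e), "error", "condition")),
        list(message = sprintf("stage '%s' failed: %s", name,
                               conditionMessage(e)), call = NULL)))
    })
    timings[[name]] <<- as.numeric(difftime(Sys.time(), ts, units = "secs"))
    res
  }

  dcfg <- config$dataset
  ds <- stage("load", load_expression(
    dcfg$matrix, dcfg$meta, format = dcfg$format %||% "dense-delimited",
    genes_path = dcfg$genes, cells_path = dcfg$cells))

  cat_res <- stage("catalog", {
    if (!is.null(config$catalog)) {
      build_target_catalog(
        .read_tsv_opt(config$catalog$targets), gene_names(ds),
        orthology = .read_tsv_opt(config$catalog$orthology),
        aliases = .read_tsv_opt(config$catalog$aliases))
    } else {
      list(catalog = data.frame(symbol = gene_names(ds),
                                idg_class = NA_character_),
           dropped = character(), report = NULL)
    }
  })
  target_genes <- intersect(cat_res$catalog$symbol, gene_names(ds))
  m_mult <- if (identical(config$multiplicity, "catalog")) {
    length(target_genes)
  } else {
    length(gene_names(ds))
  }

  type_map <- lapply(config$type_map, unlist)
  regimes <- lapply(config$criteria, .criteria_from_config)
  results <- list()
  for (p in config$plans) {
    pname <- p$name %||% p$target_type
    plan <- stage(paste0("plan:", pname), .plan_from_config(ds, p, type_map))
    stats_by_contrast <- list()
    for (ct in plan$contrasts) {
      needs_bh <- any(vapply(regimes, function(r) r$correction == "bh",
                             logical(1)))
      st <- stage(paste0("dge:", ct$label), {
        s <- contrast_stats(ds, ct, genes = target_genes,
                            correction = "bonferroni", m = m_mult)
        if (needs_bh) s$p_adj_bh <- adjust_p(s$p_raw, "bh", m_mult)
        s
      })
      stats_by_contrast[[ct$label]] <- st
      write_gene_stats(st, file.path(out_dir,
        sprintf("stats_%s_%s.csv", pname, gsub("[^A-Za-z0-9_.-]+", "_", ct$label))))
    }
    per_regime <- lapply(regimes, function(cfg_r) {
      sets <- lapply(stats_by_contrast, function(s) {
        if (cfg_r$correction == "bh") s$p_adj <- s$p_adj_bh
        classify_dhetg(s, cfg_r)
      })
      combine_sets(sets)
    })
    results[[pname]] <- list(plan = plan, stats = stats_by_contrast,
                             regimes = per_regime)
    for (rn in names(per_regime)) {
      r <- per_regime[[rn]]
      jsonlite::write_json(
        list(target = plan$target_label, mode = plan$mode, regime = rn,
             per_contrast = r$per_contrast_sets,
             full_intersection = r$full_intersection,
             venn_exclusive = r$venn_exclusive,
             venn_cumulative_counts = lapply(r$venn_cumulative, length),
             majority = r$majority_sets),
        file.path(out_dir, sprintf("intersections_%s_%s.json", pname, rn)),
        auto_unbox = TRUE, pretty = TRUE, null = "list")
    }
  }

  summary_rows <- do.call(rbind, unlist(lapply(names(results), function(pn) {
    lapply(names(results[[pn]]$regimes), function(rn) {
      r <- results[[pn]]$regimes[[rn]]
      data.frame(plan = pn, regime = rn,
                 contrast = c(names(r$per_contrast_sets), "FULL_INTERSECTION"),
                 n_dhetg = c(lengths(r$per_contrast_sets),
                             length(r$full_intersection)),
                 stringsAsFactors = FALSE)
    })
  }), recursive = FALSE))
  data.table::fwrite(summary_rows, file.path(out_dir, "summary_counts.csv"))

  manifest <- list(
    package = "dhetgscreen",
    version = as.character(packageVersion("dhetgscreen")),
    seed = config$seed %||% NA,
    config = config,
    catalog_report = cat_res$report,
    n_target_genes = length(target_genes),
    multiplicity_m = m_mult,
    stage_seconds = timings,
    wall_clock_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    finished_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "list",
                       force = TRUE)
  invisible(list(results = results, summary = summary_rows,
                 catalog = cat_res, manifest = manifest))
}
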