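# Synthetic zero-inflated scRNA-seq generator with planted marker genes.
#
# Generative model, per cell and gene: the cell expresses the gene with
# probability pi (zero-inflation); expressed cells draw CPM = 2^X with
# X ~ Normal(mu, sd) (log-normal on the log2 scale), non-expressed cells get
# CPM 0. Rank-sum tests are invariant under monotone transforms, so the
# expressed-level shape does not affect test validity; log-normal keeps the
# planted log2 effects directly interpretable.

#' Default subclass table for simulations
#'
#' Six neuronal subclasses nested in the two top classes, mirroring the
#' glutamatergic layer types and GABAergic interneuron types of a cortical
#' region.
#'
#' @return data.frame with columns `label`, `class_label`.
#' @export
default_subclasses <- function() {
  data.frame(
    label = c("L2-3 IT", "L5 IT", "L6 IT", "Pvalb", "Sst", "Vip"),
    class_label = c(rep("glutamatergic", 3), rep("GABAergic", 3)),
    stringsAsFactors = FALSE
  )
}

#' Describe a planted marker gene
#'
#' @param gene Gene symbol (appended to the simulated gene index).
#' @param pattern One of `"fully_selective"` (level and expressing-probability
#'   shift in the target group only), `"relative_selective"` (full shift in
#'   the target group, half the level shift in other subclasses of the same
#'   class), `"ladder"` (explicit per-group expressed-level means, emulating a
#'   gene whose expression steps down over cell groups by more than the fold
#'   threshold at each step), or `"beta_only"` (expressing-probability shift
#'   without a level shift).
#' @param target_subclass Subclass label of the target group.
#' @param target_region Optional region label restricting the target group.
#' @param log2_effect Non-negative shift added to the expressed-level log2
#'   mean in target cells.
#' @param beta_shift Percentage points added to the expressing probability in
#'   target cells (probabilities are clipped to `[0, 1]` with a warning).
#' @param ladder_levels Named numeric vector for `"ladder"`: names are
#'   subclass labels or `"region:subclass"` keys, values expressed-level log2
#'   means for cells of that group.
#' @return An object of class `planted_effect`.
#' @export
planted_effect <- function(gene,
                           pattern = c("fully_selective", "relative_selective",
                                       "ladder", "beta_only"),
                           target_subclass = NULL, target_region = NULL,
                           log2_effect = 0, beta_shift = 0,
                           ladder_levels = NULL) {
  pattern <- match.arg(pattern)
  if (log2_effect < 0) {
    .stop_class("log2_effect must be >= 0", "dhetg_schema_error")
  }
  if (pattern == "ladder" &&
      (is.null(ladder_levels) || is.null(names(ladder_levels)))) {
    .stop_class("ladder pattern needs named ladder_levels", "dhetg_schema_error")
  }
  if (pattern != "ladder" && is.null(target_subclass)) {
    .stop_class("pattern '%s' needs a target_subclass", "dhetg_schema_error",
                pattern)
  }
  structure(list(gene = gene, pattern = pattern,
                 target_subclass = target_subclass,
                 target_region = target_region,
                 log2_effect = log2_effect, beta_shift = beta_shift,
                 ladder_levels = ladder_levels),
            class = "planted_effect")
}

#' Configure the synthetic-data generator
#'
#' Defaults state a plausible Smart-seq-like world: a handful of cortical
#' regions, six subclasses nested in the two neuronal top classes, moderate
#' zero-inflation (30% of cells expressing a typical gene) and expressed
#' levels around log2 CPM 3 with spread 1.5.
#'
#' @param regions Region labels (default four: two "target" cortical areas
#'   plus pooled motor/sensory stand-ins).
#' @param subclasses data.frame `label`, `class_label`
#'   (default [default_subclasses()]).
#' @param cells_per_type_per_region Cells per (region, subclass) group.
#' @param n_genes Number of background genes (planted genes are appended).
#' @param idg_class_probs Named proportions over [idg_classes()] used to
#'   assign a class to every simulated gene.
#' @param baseline_log2_mean,baseline_sd Expressed-level log2 mean and sd.
#' @param expressing_prob_baseline Baseline expressing probability.
#' @param planted List of [planted_effect()] objects.
#' @param seed Master seed; per-gene streams are derived from it so adding
#'   genes does not perturb existing ones.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(regions = c("ACA", "mPFC", "Mo", "Se"),
                       subclasses = default_subclasses(),
                       cells_per_type_per_region = 100,
                       n_genes = 500,
                       idg_class_probs = NULL,
                       baseline_log2_mean = 3,
                       baseline_sd = 1.5,
                       expressing_prob_baseline = 0.3,
                       planted = list(),
                       seed = 1L) {
  if (cells_per_type_per_region < 1 || n_genes < 1) {
    .stop_class("counts must be positive", "dhetg_schema_error")
  }
  if (expressing_prob_baseline < 0 || expressing_prob_baseline > 1) {
    .stop_class("expressing_prob_baseline must lie in [0, 1]", "dhetg_schema_error")
  }
  if (is.null(idg_class_probs)) {
    # enzyme-heavy mix loosely shaped like a druggable-genome catalogue
    idg_class_probs <- setNames(
      c(0.11, 0.06, 0.06, 0.09, 0.38, 0.01, 0.20, 0.04, 0.05), IDG_CLASSES)
  }
  if (!setequal(names(idg_class_probs), IDG_CLASSES)) {
    .stop_class("idg_class_probs must be named by the nine IDG classes",
                "dhetg_schema_error")
  }
  if (inherits(planted, "planted_effect")) planted <- list(planted)
  pg <- vapply(planted, `[[`, character(1), "gene")
  if (anyDuplicated(pg)) {
    .stop_class("duplicate planted gene symbols", "dhetg_schema_error")
  }
  structure(list(regions = regions, subclasses = subclasses,
                 cells_per_type_per_region = cells_per_type_per_region,
                 n_genes = n_genes,
                 idg_class_probs = idg_class_probs[IDG_CLASSES],
                 baseline_log2_mean = baseline_log2_mean,
                 baseline_sd = baseline_sd,
                 expressing_prob_baseline = expressing_prob_baseline,
                 planted = planted, seed = as.integer(seed)),
            class = "sim_config")
}

# deterministic per-cell metadata implied by a sim_config
.sim_metadata <- function(cfg) {
  grid <- expand.grid(sub_i = seq_len(nrow(cfg$subclasses)),
                      region = cfg$regions, stringsAsFactors = FALSE)
  n_per <- cfg$cells_per_type_per_region
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    sub <- cfg$subclasses$label[grid$sub_i[i]]
    cls <- cfg$subclasses$class_label[grid$sub_i[i]]
    reg <- grid$region[i]
    data.frame(
      sample_name = sprintf("%s.%s.c%03d", reg, gsub("[^A-Za-z0-9]+", "_", sub),
                            seq_len(n_per)),
      region_label = reg, subclass_label = sub, class_label = cls,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

.sim_gene_names <- function(cfg) {
  c(sprintf("g%05d", seq_len(cfg$n_genes)),
    vapply(cfg$planted, `[[`, character(1), "gene"))
}

# per-cell (pi, mu) for one gene; eff NULL for background genes
.gene_params <- function(cfg, meta, eff = NULL) {
  pi <- rep(cfg$expressing_prob_baseline, nrow(meta))
  mu <- rep(cfg$baseline_log2_mean, nrow(meta))
  if (!is.null(eff)) {
    if (eff$pattern == "ladder") {
      keys1 <- paste(meta$region_label, meta$subclass_label, sep = ":")
      for (k in names(eff$ladder_levels)) {
        in_group <- if (grepl(":", k, fixed = TRUE)) keys1 == k
                    else meta$subclass_label == k
        if (!any(in_group)) {
          .stop_class("planted gene '%s': ladder group '%s' matches no cells",
                      "dhetg_schema_error", eff$gene, k)
        }
        mu[in_group] <- eff$ladder_levels[[k]]
      }
    } else {
      in_target <- meta$subclass_label == eff$target_subclass
      if (!is.null(eff$target_region)) {
        in_target <- in_target & meta$region_label == eff$target_region
      }
      if (!any(in_target)) {
        .stop_class("planted gene '%s': target group matches no cells",
                    "dhetg_schema_error", eff$gene)
      }
      if (eff$pattern != "beta_only") {
        mu[in_target] <- mu[in_target] + eff$log2_effect
      }
      if (eff$pattern == "relative_selective") {
        cls <- cfg$subclasses$class_label[
          match(eff$target_subclass, cfg$subclasses$label)]
        sib <- meta$class_label == cls & !in_target
        mu[sib] <- mu[sib] + eff$log2_effect / 2
      }
      pi[in_target] <- pi[in_target] + eff$beta_shift / 100
    }
  }
  if (any(pi > 1 | pi < 0)) {
    warning(sprintf("expressing probability clipped to [0, 1] for gene '%s'",
                    if (is.null(eff)) "?" else eff$gene), call. = FALSE)
    pi <- pmin(1, pmax(0, pi))
  }
  list(pi = pi, mu = mu)
}

# derived 32-bit seed for gene stream j (j = 0 reserved for catalogue draws)
.gene_seed <- function(master, j) {
  as.integer((as.numeric(master) * 48271 + 7919 * j) %% 2147483647)
}

#' Simulate an expression dataset with planted markers
#'
#' Draws a zero-inflated log-normal CPM matrix over the configured
#' region-by-subclass cell groups, applies all planted effects, and returns
#' the dataset together with a ground-truth answer key. Byte-identical for
#' identical configs (including seed); each gene has its own derived random
#' stream, so adding genes leaves existing genes' values unchanged.
#'
#' @param cfg A [sim_config()].
#' @return List with `dataset` (an [expression_dataset()]) and `truth`
#'   (list: `planted` effects echoed per gene, `catalog` data.frame
#'   `symbol`/`idg_class` over all simulated genes, `config` echo).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  meta <- .sim_metadata(cfg)
  genes <- .sim_gene_names(cfg)
  if (anyDuplicated(genes)) {
    .stop_class("planted gene symbol collides with background gene names",
                "dhetg_schema_error")
  }
  planted_by_gene <- setNames(cfg$planted,
                              vapply(cfg$planted, `[[`, character(1), "gene"))
  n_cells <- nrow(meta)

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)

  cpm <- matrix(0, nrow = n_cells, ncol = length(genes),
                dimnames = list(meta$sample_name, genes))
  for (j in seq_along(genes)) {
    eff <- planted_by_gene[[genes[j]]]
    par <- .gene_params(cfg, meta, eff)
    set.seed(.gene_seed(cfg$seed, j))
    expressed <- runif(n_cells) < par$pi
    level <- 2^rnorm(n_cells, mean = par$mu, sd = cfg$baseline_sd)
    cpm[, j] <- ifelse(expressed, level, 0)
  }

  set.seed(.gene_seed(cfg$seed, 0L))
  idg <- sample(names(cfg$idg_class_probs), length(genes), replace = TRUE,
                prob = cfg$idg_class_probs)

  list(
    dataset = expression_dataset(cpm, meta),
    truth = list(
      planted = cfg$planted,
      catalog = data.frame(symbol = genes, idg_class = idg,
                           stringsAsFactors = FALSE),
      config = cfg
    )
  )
}

# E[log2(1 + 2^X)] for X ~ Normal(mu, sd); memoised over unique mu
.mean_log1p_lognormal <- function(mu, sd) {
  uniq <- unique(mu)
  vals <- vapply(uniq, function(m) {
    stats::integrate(function(x) log2(1 + 2^x) * stats::dnorm(x, m, sd),
                     lower = m - 10 * sd, upper = m + 10 * sd)$value
  }, numeric(1))
  vals[match(mu, uniq)]
}

#' Expected qualification of planted genes under a criteria regime
#'
#' Computes, from the generative parameters (not from any sampled data),
#' each planted gene's population-level `diff_mean`, `beta` and contrast-set
#' GE for every contrast of a plan, and whether it is expected to pass the
#' effect-size criteria of `criteria` (the p-value criterion is attainable
#' for any non-zero population effect at sufficient cell numbers and is not
#' assessed here). Used as the oracle for parameter-recovery tests. The
#' population GE of a cell group is `pi * E[log2(1 + 2^X)]`, with the
#' expectation evaluated by numerical integration.
#'
#' @param cfg The [sim_config()] that generated (or will generate) the data.
#' @param criteria A [criteria_config()].
#' @param plan A `comparison_plan` whose cell ids follow `cfg`'s naming.
#' @return data.frame with one row per (planted gene, contrast): `gene`,
#'   `contrast`, `pop_diff_mean`, `pop_beta`, `pop_ge_c`, `expected_pass`.
#' @export
expected_qualification <- function(cfg, criteria, plan) {
  stopifnot(inherits(cfg, "sim_config"), inherits(criteria, "criteria_config"),
            inherits(plan, "comparison_plan"))
  meta <- .sim_metadata(cfg)
  rows <- list()
  for (eff in cfg$planted) {
    par <- .gene_params(cfg, meta, eff)
    ge_cell <- par$pi * .mean_log1p_lognormal(par$mu, cfg$baseline_sd)
    for (ct in plan$contrasts) {
      it <- match(ct$target_cells, meta$sample_name)
      ic <- match(ct$contrast_cells, meta$sample_name)
      if (any(is.na(it)) || any(is.na(ic))) {
        .stop_class("plan cell ids do not match the sim_config's naming",
                    "dhetg_integrity_error")
      }
      diff <- mean(ge_cell[it]) - mean(ge_cell[ic])
      beta <- (mean(par$pi[it]) - mean(par$pi[ic])) * 100
      ge_c <- mean(ge_cell[ic])
      pass <- diff > criteria$log2_fold
      if (!is.null(criteria$min_beta_points)) {
        pass <- pass && beta > criteria$min_beta_points
      }
      if (!is.null(criteria$max_contrast_ge)) {
        pass <- pass && ge_c < criteria$max_contrast_ge
      }
      rows[[length(rows) + 1]] <- data.frame(
        gene = eff$gene, contrast = ct$label, pop_diff_mean = diff,
        pop_beta = beta, pop_ge_c = ge_c, expected_pass = pass,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(gene = character(), contrast = character(),
                      pop_diff_mean = numeric(), pop_beta = numeric(),
                      pop_ge_c = numeric(), expected_pass = logical()))
  }
  do.call(rbind, rows)
}
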