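# Shared fixtures and independent oracles.

# Toy dataset: 2 regions x (2 glutamatergic + 2 GABAergic subclasses),
# n_per cells each, deterministic values.
toy_dataset <- function(n_per = 3, n_genes = 4, seed = 42) {
  set.seed(seed)
  meta <- expand.grid(
    region_label = c("ACA", "VISp"),
    subclass_label = c("L2-3 IT", "L5 IT", "Pvalb", "Sst"),
    idx = seq_len(n_per),
    stringsAsFactors = FALSE
  )
  meta$class_label <- ifelse(meta$subclass_label %in% c("Pvalb", "Sst"),
                             "GABAergic", "glutamatergic")
  meta$sample_name <- sprintf("c%03d", seq_len(nrow(meta)))
  meta <- meta[, c("sample_name", "region_label", "subclass_label", "class_label")]
  cpm <- matrix(round(rexp(nrow(meta) * n_genes, rate = 0.05), 3),
                nrow = nrow(meta),
                dimnames = list(meta$sample_name,
                                sprintf("gene%02d", seq_len(n_genes))))
  cpm[cpm < 5] <- 0   # some zeros for beta
  expression_dataset(cpm, meta)
}

# Independent exact two-sided rank-sum oracle: enumerate every assignment of
# nt pooled observations to the target group via bitmasks (no combn), and
# measure P(|W - EW| >= |w_obs - EW|). Only for nt + nc <= 20.
oracle_rank_sum_exact <- function(values_t, values_c) {
  nt <- length(values_t)
  N <- nt + length(values_c)
  stopifnot(N <= 20)
  r <- rank(c(values_t, values_c))
  w_obs <- sum(r[seq_len(nt)])
  mu <- nt * (N + 1) / 2
  ws <- c()
  for (mask in 0:(2^N - 1)) {
    bits <- as.integer(intToBits(mask))[seq_len(N)]
    if (sum(bits) == nt) ws <- c(ws, sum(r[bits == 1]))
  }
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-12)
}

# Monte-Carlo permutation oracle for larger groups.
oracle_rank_sum_mc <- function(values_t, values_c, n_perm = 2e5, seed = 7) {
  set.seed(seed)
  nt <- length(values_t)
  N <- nt + length(values_c)
  r <- rank(c(values_t, values_c))
  mu <- nt * (N + 1) / 2
  w_obs <- sum(r[seq_len(nt)])
  ws <- replicate(n_perm, sum(r[sample.int(N, nt)]))
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-12)
}

# build a minimal GeneStats-shaped data.frame
make_stats <- function(gene, diff_mean, p_adj, ge_c = 0, beta = 100,
                       p_raw = p_adj) {
  data.frame(gene = gene, ge_t = ge_c + diff_mean, ge_c = ge_c,
             diff_mean = diff_mean, p_raw = p_raw, p_adj = p_adj,
             beta_t = beta / 100, beta_c = 0, beta = beta,
             stringsAsFactors = FALSE)
}
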