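test_that("conservative plan builds one pairwise contrast per contrast type", {
  ds <- toy_dataset(n_per = 4)
  plan <- plan_intra_conservative(ds, region = "ACA", target_type = "Pvalb",
                                  contrast_types = c("Sst", "L2-3 IT", "L5 IT"))
  expect_length(plan$contrasts, 3)
  tsets <- lapply(plan$contrasts, `[[`, "target_cells")
  expect_true(all(vapply(tsets, identical, logical(1), tsets[[1]])))
  for (ct in plan$contrasts) {
    expect_length(intersect(ct$target_cells, ct$contrast_cells), 0)
  }
  expect_error(
    plan_intra_conservative(ds, "ACA", "Pvalb", c("Pvalb", "Sst")),
    class = "dhetg_schema_error")
  expect_error(
    plan_intra_conservative(ds, "ACA", "Pvalb", "CA3sp"),
    regexp = "CA3sp")
})

test_that("per-pair exclusion drops a combined subclass from both sides", {
  # SUB/CA1-style rule: the combined subclass belongs to both type maps and
  # is omitted from both sides of that specific pair
  meta <- data.frame(
    sample_name = sprintf("h%02d", 1:12),
    region_label = "HIP",
    subclass_label = rep(c("CA1sp", "SUB-Sp Ndst4", "CA1sp/SUB-sp Kcnip1",
                           "DG"), each = 3),
    class_label = "glutamatergic", stringsAsFactors = FALSE)
  cpm <- matrix(1, 12, 2, dimnames = list(meta$sample_name, c("gA", "gB")))
  ds <- expression_dataset(cpm, meta)
  tm <- list(CA1 = c("CA1sp", "CA1sp/SUB-sp Kcnip1"),
             SUB = c("SUB-Sp Ndst4", "CA1sp/SUB-sp Kcnip1"),
             DG = "DG")
  plan <- plan_intra_conservative(
    ds, "HIP", "SUB", c("CA1", "DG"), type_map = tm,
    exclusions = list(CA1 = "CA1sp/SUB-sp Kcnip1"))
  vs_ca1 <- plan$contrasts[[1]]
  combined <- meta$sample_name[meta$subclass_label == "CA1sp/SUB-sp Kcnip1"]
  expect_length(intersect(vs_ca1$target_cells, combined), 0)
  expect_length(intersect(vs_ca1$contrast_cells, combined), 0)
  # the unexcluded pair keeps the combined subclass in the target set
  vs_dg <- plan$contrasts[[2]]
  expect_setequal(intersect(vs_dg$target_cells, combined), combined)
})

test_that("one-vs-all plan pools both classes and removes the target type", {
  ds <- toy_dataset(n_per = 4)
  plan <- plan_intra_onevsall(ds, region = "ACA", target_type = "Pvalb")
  expect_length(plan$contrasts, 2)
  tcells <- plan$contrasts[[1]]$target_cells
  gaba_pool <- plan$contrasts[[grep("GABAergic",
    vapply(plan$contrasts, `[[`, character(1), "label"))]]$contrast_cells
  glut_pool <- plan$contrasts[[grep("glutamatergic",
    vapply(plan$contrasts, `[[`, character(1), "label"))]]$contrast_cells
  # target absent from its own class pool; other pool untouched
  expect_length(intersect(tcells, gaba_pool), 0)
  aca_gaba <- select_cells(ds, cell_selector(regions = "ACA",
                                             classes = "GABAergic"))
  aca_glut <- select_cells(ds, cell_selector(regions = "ACA",
                                             classes = "glutamatergic"))
  expect_setequal(gaba_pool, setdiff(aca_gaba, tcells))
  expect_setequal(glut_pool, aca_glut)

  # glutamatergic target: GABAergic pool unchanged, glutamatergic pool shrunk
  plan_g <- plan_intra_onevsall(ds, "ACA", "L5 IT")
  pools <- lapply(plan_g$contrasts, `[[`, "contrast_cells")
  expect_setequal(pools[[1]], aca_gaba)
  expect_setequal(pools[[2]], setdiff(aca_glut, plan_g$contrasts[[1]]$target_cells))
})

test_that("inter-regional plan pools region groups and enforces restrictions", {
  ds <- toy_dataset(n_per = 4)
  groups <- list(Se = "VISp")
  plan <- plan_inter_regional(ds, "Pvalb", home_region = "ACA",
                              region_groups = groups)
  expect_length(plan$contrasts, 1)
  ct <- plan$contrasts[[1]]
  expect_true(all(ds$meta$region_label[match(ct$contrast_cells,
                                             ds$meta$sample_name)] == "VISp"))
  expect_true(all(ds$meta$subclass_label[match(ct$contrast_cells,
                                               ds$meta$sample_name)] == "Pvalb"))

  # group restricted to GABAergic targets errors for a glutamatergic one
  expect_error(
    plan_inter_regional(ds, "L5 IT", "ACA", groups,
                        group_class_restriction = c(Se = "GABAergic")),
    class = "dhetg_schema_error")
  # target type absent from a group names the group
  expect_error(
    plan_inter_regional(ds, "Pvalb", "ACA", list(HIP = "HIP")),
    regexp = "HIP")
})

test_that("combine_sets reproduces the hand-enumerated example", {
  res <- combine_sets(list(A = c("g1", "g2"), B = "g1", C = c("g1", "g3")))
  expect_identical(res$full_intersection, "g1")
  expect_identical(res$majority_sets[["2"]], "g1")
  expect_identical(res$venn_exclusive[["A"]], "g2")
  expect_identical(res$venn_exclusive[["A&B&C"]], "g1")
  expect_identical(res$venn_cumulative[["A&C"]], "g1")

  one <- combine_sets(list(only = c("x", "y")))
  expect_identical(one$full_intersection, c("x", "y"))
  expect_identical(one$majority_sets[["1"]], c("x", "y"))

  with_empty <- combine_sets(list(A = c("g1"), B = character(0)))
  expect_length(with_empty$full_intersection, 0)
})

test_that("venn cells partition the union; majority sets are nested", {
  set.seed(31)
  for (rep in 1:5) {
    n <- sample(2:5, 1)
    sets <- lapply(seq_len(n), function(i) {
      sample(sprintf("g%02d", 1:15), sample(0:10, 1))
    })
    names(sets) <- LETTERS[seq_len(n)]
    res <- combine_sets(sets)
    all_genes <- sort(unique(unlist(sets)))
    excl <- res$venn_exclusive
    expect_setequal(unlist(excl, use.names = FALSE), all_genes)
    expect_equal(sum(lengths(excl)), length(all_genes))  # pairwise disjoint
    # full intersection within every per-contrast set; majority nesting
    for (s in res$per_contrast_sets) {
      expect_true(all(res$full_intersection %in% s))
    }
    for (k in seq_len(n - 1)) {
      expect_true(all(res$majority_sets[[as.character(k + 1)]] %in%
                        res$majority_sets[[as.character(k)]]))
    }
    expect_identical(res$majority_sets[[as.character(n)]],
                     res$full_intersection)
    # invariant under permutation of input sets
    perm <- sample(n)
    res_p <- combine_sets(sets[perm])
    expect_identical(res_p$full_intersection, res$full_intersection)
    expect_identical(res_p$majority_sets, res$majority_sets)
  }
})

test_that("combine_sets caps the Venn decomposition with a warning", {
  sets <- setNames(replicate(7, c("g1", "g2"), simplify = FALSE), letters[1:7])
  expect_warning(res <- combine_sets(sets, venn_cap = 6), "Venn cap")
  expect_null(res$venn_exclusive)
  expect_identical(res$full_intersection, c("g1", "g2"))
  expect_length(res$majority_sets, 7)
})

test_that("combine_intra_inter intersects intra hits with inter Venn cells", {
  inter <- combine_sets(list(Mo = c("g2", "g3", "g5"), Se = c("g2", "g3"),
                             PFC = c("g2", "g4")))
  out <- combine_intra_inter(c("g1", "g2", "g5"), inter)
  expect_identical(out[["Mo&Se&PFC"]], "g2")   # full-intersection cell
  expect_identical(out[["Mo"]], "g5")
  expect_length(out[["Se"]], 0)

  disjoint <- combine_intra_inter("zz", inter)
  expect_true(all(lengths(disjoint) == 0))
  empty <- combine_intra_inter(character(0), inter)
  expect_true(all(lengths(empty) == 0))
})
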