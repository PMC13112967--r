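test_that("construction enforces schema, integrity and domain invariants", {
  ds <- toy_dataset()
  expect_s3_class(ds, "ExpressionDataset")
  expect_identical(cell_ids(ds), ds$meta$sample_name)

  meta <- ds$meta
  cpm <- as.matrix(ds$cpm)

  expect_error(expression_dataset(cpm, meta[, -4]),
               class = "dhetg_schema_error")

  meta_dup <- meta
  meta_dup$sample_name[2] <- meta_dup$sample_name[1]
  expect_error(expression_dataset(cpm, meta_dup),
               class = "dhetg_integrity_error")

  cpm_dupgene <- cpm
  colnames(cpm_dupgene)[2] <- colnames(cpm_dupgene)[1]
  expect_error(expression_dataset(cpm_dupgene, meta),
               class = "dhetg_integrity_error")

  cpm_neg <- cpm
  cpm_neg[1, 1] <- -1
  expect_error(expression_dataset(cpm_neg, meta),
               class = "dhetg_domain_error")

  meta_empty <- meta
  meta_empty$class_label[3] <- ""
  expect_error(expression_dataset(cpm, meta_empty),
               class = "dhetg_schema_error")
})

test_that("matrix rows are reordered to metadata order", {
  ds <- toy_dataset()
  perm <- sample(nrow(ds$cpm))
  ds2 <- expression_dataset(as.matrix(ds$cpm)[perm, ], ds$meta)
  expect_identical(as.matrix(ds2$cpm), as.matrix(ds$cpm))
})

test_that("dense and sparse round-trips reproduce the dataset", {
  ds <- toy_dataset()
  tmp <- withr::local_tempdir()

  write_expression(ds, file.path(tmp, "m.csv"), file.path(tmp, "meta.tsv"))
  dense <- load_expression(file.path(tmp, "m.csv"), file.path(tmp, "meta.tsv"))
  expect_equal(as.matrix(dense$cpm), as.matrix(ds$cpm))
  expect_identical(dense$meta, ds$meta)

  write_expression(ds, file.path(tmp, "m.mtx"), file.path(tmp, "meta.tsv"),
                   format = "matrix-market",
                   genes_path = file.path(tmp, "genes.txt"),
                   cells_path = file.path(tmp, "cells.txt"))
  sparse <- load_expression(file.path(tmp, "m.mtx"), file.path(tmp, "meta.tsv"),
                            format = "matrix-market",
                            genes_path = file.path(tmp, "genes.txt"),
                            cells_path = file.path(tmp, "cells.txt"))
  # dense and sparse loads of the same data are value-identical
  expect_equal(as.matrix(sparse$cpm), as.matrix(dense$cpm))
  expect_identical(gene_names(sparse), gene_names(dense))
})

test_that("genes-by-cells matrices are transposed on load", {
  ds <- toy_dataset()
  tmp <- withr::local_tempdir()
  df <- data.frame(gene = gene_names(ds), t(as.matrix(ds$cpm)),
                   check.names = FALSE)
  data.table::fwrite(df, file.path(tmp, "t.csv"))
  data.table::fwrite(ds$meta, file.path(tmp, "meta.tsv"), sep = "\t")
  got <- load_expression(file.path(tmp, "t.csv"), file.path(tmp, "meta.tsv"))
  expect_equal(as.matrix(got$cpm), as.matrix(ds$cpm))

  # transposed Matrix Market with index files also lands cells x genes
  write_expression(ds, file.path(tmp, "m.mtx"), file.path(tmp, "meta.tsv"),
                   format = "matrix-market",
                   genes_path = file.path(tmp, "genes.txt"),
                   cells_path = file.path(tmp, "cells.txt"))
  Matrix::writeMM(Matrix::t(Matrix::Matrix(as.matrix(ds$cpm), sparse = TRUE)),
                  file.path(tmp, "mt.mtx"))
  got2 <- load_expression(file.path(tmp, "mt.mtx"), file.path(tmp, "meta.tsv"),
                          format = "matrix-market",
                          genes_path = file.path(tmp, "genes.txt"),
                          cells_path = file.path(tmp, "cells.txt"))
  expect_equal(as.matrix(got2$cpm), as.matrix(ds$cpm))
})

test_that("loader rejects matrix cells missing from metadata", {
  ds <- toy_dataset()
  tmp <- withr::local_tempdir()
  write_expression(ds, file.path(tmp, "m.csv"), file.path(tmp, "meta.tsv"))
  short_meta <- ds$meta[-1, ]
  data.table::fwrite(short_meta, file.path(tmp, "meta2.tsv"), sep = "\t")
  expect_error(load_expression(file.path(tmp, "m.csv"),
                               file.path(tmp, "meta2.tsv")),
               class = "dhetg_integrity_error")
})

test_that("select_cells filters on all given criteria in dataset order", {
  ds <- toy_dataset()
  gaba <- select_cells(ds, cell_selector(classes = "GABAergic"))
  expect_setequal(gaba, ds$meta$sample_name[ds$meta$class_label == "GABAergic"])
  expect_identical(gaba, ds$meta$sample_name[ds$meta$sample_name %in% gaba])

  pv_aca <- select_cells(ds, cell_selector(regions = "ACA",
                                           subclasses = "Pvalb"))
  expect_true(all(ds$meta$region_label[match(pv_aca, ds$meta$sample_name)] == "ACA"))
  expect_true(all(ds$meta$subclass_label[match(pv_aca, ds$meta$sample_name)] == "Pvalb"))

  # exclusion removes a subclass from an otherwise matching selection
  excl <- select_cells(ds, cell_selector(regions = "ACA",
                                         classes = "GABAergic",
                                         exclude_subclasses = "Sst"))
  expect_true(all(ds$meta$subclass_label[match(excl, ds$meta$sample_name)] == "Pvalb"))

  expect_identical(select_cells(ds, cell_selector(regions = "HIP")),
                   character(0))
  expect_error(cell_selector(), class = "dhetg_schema_error")
  expect_error(cell_selector(subclasses = "Sst", exclude_subclasses = "Sst"),
               class = "dhetg_schema_error")
})

test_that("select_cells is idempotent and stable under selector permutation", {
  ds <- toy_dataset()
  a <- select_cells(ds, cell_selector(regions = c("ACA", "VISp"),
                                      subclasses = c("Pvalb", "Sst")))
  b <- select_cells(ds, cell_selector(regions = c("VISp", "ACA"),
                                      subclasses = c("Sst", "Pvalb")))
  expect_identical(a, b)
})

test_that("pool_cells unions selectors without duplicates, preserving order", {
  ds <- toy_dataset()
  s1 <- cell_selector(regions = "ACA")
  s2 <- cell_selector(regions = "VISp")
  both <- pool_cells(ds, list(s1, s2))
  expect_identical(both, ds$meta$sample_name)

  overlap <- pool_cells(ds, list(s1, cell_selector(regions = "ACA",
                                                   classes = "GABAergic")))
  expect_identical(overlap, select_cells(ds, s1))
  expect_identical(pool_cells(ds, list(s1)), select_cells(ds, s1))

  # union distributes over selector lists
  u12 <- pool_cells(ds, list(s1, s2))
  expect_setequal(u12, union(pool_cells(ds, list(s1)), pool_cells(ds, list(s2))))
  expect_error(pool_cells(ds, list()), class = "dhetg_schema_error")
})

test_that("contrast_spec rejects empty, overlapping and unknown cell sets", {
  ds <- toy_dataset()
  expect_error(contrast_spec("x", character(0), "c001"),
               class = "dhetg_schema_error")
  expect_error(contrast_spec("x", c("c001", "c002"), c("c002", "c003")),
               class = "dhetg_schema_error")
  expect_error(contrast_spec("x", "c001", "nope", ds = ds),
               class = "dhetg_integrity_error")
  ok <- contrast_spec("x", "c001", "c002", ds = ds)
  expect_s3_class(ok, "contrast_spec")
})
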