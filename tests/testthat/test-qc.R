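test_that("normalization matches the closed form and preserves zeros", {
  # count 4 in a cell of total 2500 -> ln(17); count 10000 of 10000 -> ln(10001)
  counts <- matrix(0, 3, 2, dimnames = list(c("g1", "g2", "MT-ND1"), c("a", "b")))
  counts["g1", "a"] <- 4
  counts["g2", "a"] <- 2496
  counts["g1", "b"] <- 10000
  sce <- normalize_log(make_sce(counts))
  lc <- as.matrix(assay(sce, "logcounts"))
  expect_equal(lc["g1", "a"], log(17))
  expect_equal(lc["g1", "b"], log(10001))
  expect_equal(lc["MT-ND1", "a"], 0)
  expect_identical(lc == 0, as.matrix(counts) == 0)

  expect_error(normalize_log(make_sce(matrix(c(1, 0, 0, 0), 2))), "zero total")
})

test_that("cell filters apply the inclusive gene bounds and strict mito bound", {
  n_genes <- 5000
  genes <- c(sprintf("G%04d", seq_len(n_genes - 1)), "MT-ND1")
  counts <- Matrix::Matrix(0, n_genes, 4, sparse = TRUE,
                           dimnames = list(genes, c("lo", "ok", "hi", "mito")))
  counts[seq_len(150), "lo"] <- 1          # 150 genes: below min
  counts[seq_len(250), "ok"] <- 2          # 250 genes, mito 1/500 = 0.2%
  counts[n_genes, "ok"] <- 0
  counts[seq_len(4500), "hi"] <- 1         # 4500 genes: above max
  counts[seq_len(250), "mito"] <- 2
  counts[n_genes, "mito"] <- 100           # mito fraction 100/600 = 16.7%
  sce <- SingleCellExperiment::SingleCellExperiment(list(counts = counts))
  res <- filter_cells_genes(sce, min_cells_per_gene = 1)
  expect_equal(res$qc$drop_reason, c("min_genes", NA, "max_genes", "mito_fraction"))
  expect_equal(colnames(res$sce), "ok")
  expect_error(filter_cells_genes(sce, min_genes = 4000, max_genes = 200), "below")
})

test_that("boundary cells at exactly 200 or 4000 detected genes are retained", {
  n_genes <- 4200
  counts <- Matrix::Matrix(0, n_genes, 2, sparse = TRUE)
  rownames(counts) <- sprintf("G%04d", seq_len(n_genes))
  counts[seq_len(200), 1] <- 1
  counts[seq_len(4000), 2] <- 1
  sce <- SingleCellExperiment::SingleCellExperiment(list(counts = counts))
  expect_warning(res <- filter_cells_genes(sce, min_cells_per_gene = 1),
                 "mitochondrial")
  expect_true(all(res$qc$keep))
})

test_that("genes detected in fewer than the minimum number of retained cells are dropped", {
  counts <- matrix(1, 4, 5)
  rownames(counts) <- c("common", "rare2", "rare3", "absent")
  counts["rare2", ] <- c(1, 1, 0, 0, 0)   # 2 cells: dropped
  counts["rare3", ] <- c(1, 1, 1, 0, 0)   # 3 cells: kept
  counts["absent", ] <- 0
  sce <- make_sce(counts)
  suppressWarnings(res <- filter_cells_genes(sce, min_genes = 1, max_genes = 10))
  expect_setequal(rownames(res$sce), c("common", "rare3"))
  expect_true("rare2" %in% res$genes_dropped)
})

test_that("hormone coexpression and cross-lineage rules flag the right cells", {
  lc <- matrix(0, 3, 4,
               dimnames = list(c("INS", "GCG", "KRT19"),
                               c("coexpr", "pure_beta", "cross", "alpha")))
  lc["INS", "coexpr"] <- 7.0; lc["GCG", "coexpr"] <- 5.5
  lc["INS", "pure_beta"] <- 7.0
  lc["INS", "cross"] <- 7.0; lc["KRT19", "cross"] <- 3.5
  lc["GCG", "alpha"] <- 7.0
  sce <- make_log_sce(lc)
  res <- remove_hormone_doublets(sce)
  expect_setequal(colnames(res$sce), c("pure_beta", "alpha"))
  expect_equal(res$dropped$rule[res$dropped$barcode == "coexpr"],
               "ins_gcg_coexpression")
  expect_equal(res$dropped$rule[res$dropped$barcode == "cross"],
               "cross_lineage")
  expect_match(res$dropped$detail[res$dropped$barcode == "cross"], "KRT19")

  no_ins <- make_log_sce(matrix(1, 2, 1, dimnames = list(c("GCG", "KRT19"), "c1")))
  expect_error(remove_hormone_doublets(no_ins), "INS and GCG")
})

test_that("ambient pool assignment and round-then-clip subtraction are exact", {
  # pool: two barcodes (totals 100 each) with 3 pooled counts of gene A out
  # of 200 -> proportion 0.015; a 160-UMI cell expects 2.4 ambient counts
  counts <- matrix(0, 2, 4,
                   dimnames = list(c("A", "B"),
                                   c("e1", "e2", "cell1", "cell2")))
  counts["A", ] <- c(2, 1, 3, 1)
  counts["B", ] <- c(98, 99, 157, 159)
  sce <- make_sce(counts)
  res <- ambient_correct(sce, umi_cutoff = 100, prominence = 0.01)
  expect_setequal(res$pool_barcodes, c("e1", "e2"))
  expect_true("A" %in% res$ambient_genes)
  corrected <- as.matrix(assay(res$sce, "counts"))
  expect_equal(corrected["A", "cell1"], 1)  # 3 - round(2.4) = 1
  expect_equal(corrected["A", "cell2"], 0)  # 1 - round(2.4) clipped at 0
  expect_identical(corrected[, c("e1", "e2")],
                   as.matrix(counts)[, c("e1", "e2")])

  # corrected counts never exceed raw counts
  expect_true(all(corrected <= as.matrix(counts)))

  # no barcodes below the cutoff: warn and return unchanged
  big <- make_sce(matrix(200, 2, 2))
  expect_warning(unchanged <- ambient_correct(big), "no barcodes")
  expect_identical(as.matrix(assay(unchanged$sce, "counts")),
                   as.matrix(assay(big, "counts")))
})

test_that("ambient correction removes contaminating hormone counts but spares true expression", {
  cfg <- small_sim_config(seed = 71, ambient_fraction = 0.05, doublet_rate = 0,
                          n_empty_droplets = 300)
  sce <- simulate_dataset(cfg)
  res <- ambient_correct(sce)
  non_endo <- colData(sce)$cell_type %in% c("acinar", "ductal", "stellate")
  raw <- assay(sce, "counts")
  cor <- assay(res$sce, "counts")
  expect_true(all(as.matrix(cor) <= as.matrix(raw)))

  hormones <- c("INS", "GCG")
  before <- mean(as.matrix(raw[hormones, non_endo]))
  after <- mean(as.matrix(cor[hormones, non_endo]))
  expect_lt(after, 0.5 * before)

  alpha <- colData(sce)$cell_type == "alpha"
  beta <- colData(sce)$cell_type == "beta"
  gcg_rel <- abs(mean(cor["GCG", alpha]) - mean(raw["GCG", alpha])) /
    mean(raw["GCG", alpha])
  ins_rel <- abs(mean(cor["INS", beta]) - mean(raw["INS", beta])) /
    mean(raw["INS", beta])
  expect_lt(gcg_rel, 0.10)
  expect_lt(ins_rel, 0.10)
})

test_that("planted hormone doublets are removed at default thresholds", {
  cfg <- sim_config(seed = 81, doublet_rate = 0.05)
  sce <- simulate_dataset(cfg)
  cells <- sce[, colData(sce)$cell_type != "empty"]
  norm <- normalize_log(cells)
  res <- remove_hormone_doublets(norm)
  cd <- colData(cells)
  ab <- cd$is_doublet &
    ((cd$cell_type == "alpha" & cd$partner_type == "beta") |
       (cd$cell_type == "beta" & cd$partner_type == "alpha"))
  expect_gt(sum(ab), 10)
  removed <- mean(rownames(cd)[ab] %in% res$dropped$barcode)
  expect_gte(removed, 0.8)
  # true singlets are essentially never flagged
  singlets <- rownames(cd)[!cd$is_doublet]
  expect_lt(mean(singlets %in% res$dropped$barcode), 0.01)
})
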