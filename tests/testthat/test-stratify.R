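# Small fixture: one cell per combinatorial group, built so that the
# binarization produces exactly None / A-only / B-only / Both.
four_group_sce <- function(panel_values = c(1, 2, 3, 4),
                           panel_counts = c(0, 1, 2, 3)) {
  lc <- rbind(
    ARX = c(0.0, 0.7, 0.0, 0.7),
    MAFB = c(0.0, 0.4, 0.7, 0.7),
    PANEL = panel_values
  )
  counts <- rbind(ARX = (lc["ARX", ] > 0) * 1, MAFB = (lc["MAFB", ] > 0) * 1,
                  PANEL = panel_counts)
  sce <- make_sce(counts, logcounts = lc,
                  cell_type = rep("alpha", 4),
                  donor = c("D1", "D1", "D2", "D2"))
  sce
}

test_that("threshold binarization assigns the four combinatorial groups", {
  sce <- four_group_sce()
  res <- binarize_and_classify(sce, "ARX", "MAFB", cell_type = "alpha")
  expect_equal(as.character(res$cells$group),
               c("None", "A-only", "B-only", "Both"))
  expect_equal(unname(res$fractions), rep(0.25, 4))
  expect_equal(res$n, 4)
  # per-donor fractions sum to one
  expect_true(all(abs(rowSums(res$by_donor) - 1) < 1e-9))

  # a value exactly at the threshold is called low
  lc_eq <- rbind(ARX = 0.5, MAFB = 0.7)
  sce_eq <- make_log_sce(lc_eq, cell_type = "alpha")
  res_eq <- binarize_and_classify(sce_eq, "ARX", "MAFB", cell_type = "alpha")
  expect_equal(as.character(res_eq$cells$group), "B-only")

  expect_error(binarize_and_classify(sce, "ARX", "ARX"), "differ")
  expect_error(binarize_and_classify(sce, "ARX", "NOPE"), "absent")
  expect_error(binarize_and_classify(sce, "ARX", "MAFB", cell_type = "beta"),
               "no cells")
})

test_that("nonzero detection mode and threshold monotonicity behave as expected", {
  cfg <- small_sim_config(seed = 101, ambient_fraction = 0, doublet_rate = 0,
                          n_empty_droplets = 0)
  sce <- normalize_log(simulate_dataset(cfg))
  both_frac <- vapply(c(0, 0.5, 1, 2, 4), function(thr) {
    binarize_and_classify(sce, "ARX", "MAFB", cell_type = "alpha",
                          threshold = thr)$fractions[["Both"]]
  }, numeric(1))
  expect_true(all(diff(both_frac) <= 0))

  nz <- binarize_and_classify(sce, "ARX", "MAFB", cell_type = "alpha",
                              detection = "nonzero")
  thr0 <- binarize_and_classify(sce, "ARX", "MAFB", cell_type = "alpha",
                                threshold = 0)
  expect_equal(nz$fractions, thr0$fractions)

  # partition property: group counts sum to the number of target cells
  expect_equal(sum(nz$counts), nz$n)
})

test_that("dot-plot statistics use detectable fractions and sample-SD z-scores", {
  sce <- four_group_sce(panel_values = c(1, 2, 3, 4), panel_counts = c(0, 1, 2, 3))
  groups <- binarize_and_classify(sce, "ARX", "MAFB", cell_type = "alpha")
  stats <- dotplot_stats(sce, groups, "PANEL")
  expect_equal(stats$mean_expr, c(1, 2, 3, 4))
  expect_equal(stats$z, c(-1.1619, -0.3873, 0.3873, 1.1619), tolerance = 1e-4)
  expect_equal(stats$pct_detected, c(0, 1, 1, 1))

  # equal group means: zero variance convention, z = 0 with flag
  flat <- four_group_sce(panel_values = c(2, 2, 2, 2))
  groups_f <- binarize_and_classify(flat, "ARX", "MAFB", cell_type = "alpha")
  stats_f <- dotplot_stats(flat, groups_f, "PANEL")
  expect_equal(stats_f$z, rep(0, 4))
  expect_true(all(stats_f$zero_variance))

  # gene undetected everywhere
  zero <- four_group_sce(panel_values = c(0, 0, 0, 0), panel_counts = c(0, 0, 0, 0))
  groups_z <- binarize_and_classify(zero, "ARX", "MAFB", cell_type = "alpha")
  stats_z <- dotplot_stats(zero, groups_z, "PANEL")
  expect_equal(stats_z$pct_detected, rep(0, 4))
  expect_equal(stats_z$z, rep(0, 4))

  # missing panel genes are skipped with a message
  expect_message(dotplot_stats(sce, groups, c("PANEL", "NOPE")), "NOPE")
})

test_that("group comparisons adjust across the joint family and order deterministically", {
  set.seed(55)
  lc <- rbind(
    ARX = rep(c(0, 2, 0, 2), each = 25),
    MAFB = rep(c(0, 0, 2, 2), each = 25),
    G1 = c(rnorm(75, 1), rnorm(25, 3)),  # elevated in Both
    G2 = rnorm(100, 1)                   # null
  )
  sce <- make_log_sce(pmax(lc, 0), cell_type = rep("alpha", 100))
  groups <- binarize_and_classify(sce, "ARX", "MAFB", cell_type = "alpha")
  res <- compare_groups(sce, groups, c("G1", "G2"))
  expect_equal(nrow(res), 6)
  expect_equal(unique(res$group1), "Both")
  expect_true(all(res$p_adj >= res$p))
  expect_true(all(res$p_adj[res$gene == "G1"] < 0.05))
  expect_identical(res$gene, rep(c("G1", "G2"), each = 3))

  res2 <- compare_groups(sce, groups, c("G1", "G2"))
  expect_identical(res, res2)

  # all-pairs mode covers every combination
  ap <- compare_groups(sce, groups, "G1", scheme = "all_pairs")
  expect_equal(nrow(ap), 6)
})

test_that("detected-gene diagnostics split cells by TF level", {
  # every cell detects 1500 genes; fraction above 1000 is 1 in both strata
  n_genes <- 1600
  counts <- Matrix::Matrix(0, n_genes, 4, sparse = TRUE)
  rownames(counts) <- c("ARX", sprintf("G%04d", seq_len(n_genes - 1)))
  counts[2:1501, ] <- 1
  counts["ARX", 1:2] <- 5
  lc <- counts
  lc["ARX", 1:2] <- 2 # high stratum
  sce <- SingleCellExperiment::SingleCellExperiment(
    list(counts = counts, logcounts = lc))
  res <- detected_genes_by_level(sce, "ARX")
  expect_setequal(res$stratum, c("low", "high"))
  expect_equal(res$frac_gt_1000, c(1, 1))
  expect_equal(res$median_detected[res$stratum == "high"], 1501)

  # an empty stratum is absent from the output
  all_high <- sce
  SummarizedExperiment::assay(all_high, "logcounts")["ARX", ] <- 2
  res_high <- detected_genes_by_level(all_high, "ARX")
  expect_equal(res_high$stratum, "high")

  expect_error(detected_genes_by_level(sce, "NOPE"), "absent")
})

test_that("library size independent of TF state gives comparable detected-gene medians", {
  cfg <- small_sim_config(seed = 111, ambient_fraction = 0, doublet_rate = 0,
                          n_empty_droplets = 0,
                          n_cells_per_type = c(alpha = 600))
  sce <- normalize_log(simulate_dataset(cfg))
  res <- detected_genes_by_level(sce, "MAFB", cell_type = "alpha")
  med <- res$median_detected
  expect_lt(abs(diff(med)) / max(med), 0.10)
})

test_that("intensity classification recovers planted hi/lo fractions per donor", {
  tab <- data.frame(donor = "D1", marker_a = 10, marker_b = 2)
  res <- classify_intensity(tab, c(marker_a = 5, marker_b = 5))
  expect_equal(as.character(res$cells$label), "hi/lo")

  below <- data.frame(marker_a = c(1, 2), marker_b = c(0, 1))
  res_b <- classify_intensity(below, c(marker_a = 5, marker_b = 5))
  expect_equal(unname(res_b$fractions), c(1, 0, 0, 0))

  planted <- c(0.41, 0.19, 0.09, 0.30)
  sim <- simulate_intensity(2369, planted, seed = 13)
  rec <- classify_intensity(sim, c(marker_a = 5, marker_b = 5))
  sd3 <- 3 * sqrt(planted * (1 - planted) / 2369)
  expect_true(all(abs(rec$fractions - planted) <= sd3))
  expect_true(all(abs(rowSums(rec$by_donor) - 1) < 1e-9))

  # missing intensities are excluded and counted
  holes <- data.frame(marker_a = c(10, NA), marker_b = c(2, 3))
  expect_message(res_h <- classify_intensity(holes, c(marker_a = 5, marker_b = 5)),
                 "excluded")
  expect_equal(res_h$n_excluded, 1)
  expect_equal(nrow(res_h$cells), 1)

  # per-donor threshold table
  thr <- data.frame(donor = c("D1", "D2"), marker_a = c(5, 20), marker_b = c(5, 20))
  two <- data.frame(donor = c("D1", "D2"), marker_a = c(10, 10), marker_b = c(2, 2))
  res_t <- classify_intensity(two, thr)
  expect_equal(as.character(res_t$cells$label), c("hi/lo", "lo/lo"))
})
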