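test_that("the generator is deterministic given a seed", {
  cfg <- small_sim_config(seed = 5)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(as.matrix(counts(a)), as.matrix(counts(b)))
  expect_identical(as.data.frame(colData(a)), as.data.frame(colData(b)))
  d <- simulate_dataset(small_sim_config(seed = 6))
  expect_false(identical(as.matrix(counts(a)), as.matrix(counts(d))))
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(nb_dispersion = 0), "dispersion")
  expect_error(sim_config(tf_on_fractions = list(alpha = c(0.5, 0.5, 0.1, 0.1),
                                                 beta = c(0.22, 0.04, 0.52, 0.22))),
               "sum to 1")
  expect_error(sim_config(ambient_fraction = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(n_genes = 10), "at least")
})

test_that("planted TF-state fractions are recovered within 3 binomial SDs", {
  target <- c(0.10, 0.04, 0.48, 0.38)
  cfg <- sim_config(seed = 21, n_cells_per_type = c(alpha = 2000L),
                    ambient_fraction = 0, doublet_rate = 0,
                    n_empty_droplets = 0)
  sce <- normalize_log(simulate_dataset(cfg))
  res <- binarize_and_classify(sce, "ARX", "MAFB", cell_type = "alpha")
  sd3 <- 3 * sqrt(target * (1 - target) / 2000)
  expect_true(all(abs(res$fractions - target) <= sd3))
  # classification agrees with planted truth for almost every cell
  truth <- colData(sce)$tf_group
  expect_gt(mean(as.character(res$cells$group) == truth), 0.9)
})

test_that("increasing ambient contamination raises hormone counts in non-endocrine cells", {
  hormone_in_acinar <- function(af) {
    cfg <- small_sim_config(seed = 31, ambient_fraction = af,
                            doublet_rate = 0, n_empty_droplets = 0)
    sce <- simulate_dataset(cfg)
    acinar <- colData(sce)$cell_type == "acinar"
    mean(as.matrix(counts(sce)[c("INS", "GCG"), acinar]))
  }
  levels <- c(0, 0.02, 0.05, 0.10)
  means <- vapply(levels, hormone_in_acinar, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("planted doublets carry at least as many UMIs as either parent profile", {
  cfg <- small_sim_config(seed = 41, doublet_rate = 0.1)
  sce <- simulate_dataset(cfg)
  cd <- colData(sce)
  dbl <- which(cd$is_doublet)
  expect_gt(length(dbl), 5)
  totals <- Matrix::colSums(counts(sce))
  # the doublet barcode holds the sum of both parents' counts, so its
  # total dominates the sampled partner's singlet total (restrict to
  # partners that are not themselves doublet barcodes)
  partner <- cd$partner_index[dbl]
  ok <- !cd$is_doublet[partner]
  expect_gt(sum(ok), 0)
  expect_true(all(totals[dbl][ok] >= totals[partner][ok]))
})

test_that("hormone doublet thresholds are rarely exceeded without planted doublets", {
  cfg <- sim_config(seed = 51, n_cells_per_type = c(alpha = 1200L, beta = 800L),
                    doublet_rate = 0, ambient_fraction = 0,
                    n_empty_droplets = 0)
  sce <- normalize_log(simulate_dataset(cfg))
  lc <- assay(sce, "logcounts")
  both_high <- as.numeric(lc["INS", ]) > 6.5 & as.numeric(lc["GCG", ]) > 5.0
  expect_lt(mean(both_high), 0.005)
})

test_that("simulated bulk aggregation produces exact TPM sums", {
  counts <- cbind(c(1, 3), c(3, 1))
  sce <- make_sce(counts, cell_type = c("alpha", "alpha"))
  expect_equal(unname(simulate_bulk(sce, "alpha")), c(5e5, 5e5))

  one <- make_sce(cbind(c(0, 10)), cell_type = "beta")
  expect_equal(unname(simulate_bulk(one, "beta")), c(0, 1e6))

  expect_error(simulate_bulk(one, "ductal"), "unknown cell type")

  # bulk of the same cells is perfectly proportional to their pseudobulk
  cfg <- small_sim_config(seed = 61, doublet_rate = 0)
  sim <- simulate_dataset(cfg)
  sim <- sim[, colData(sim)$cell_type != "empty"]
  tpm <- simulate_bulk(sim, "alpha")
  pb <- pseudobulk(sim, "alpha")
  expect_equal(stats::cor(tpm, pb), 1.0, tolerance = 1e-12)
})

test_that("ephys simulation is seeded and honours the null effect map", {
  groups <- rep(c("None", "A-only", "B-only", "Both"), each = 30)
  a <- simulate_ephys(groups, seed = 3)
  b <- simulate_ephys(groups, seed = 3)
  expect_identical(a, b)
  expect_error(simulate_ephys(groups, noise_sd = -1), "non-negative")

  # zero effect map: feature means differ only by sampling noise
  null_tab <- simulate_ephys(groups, effect_map = list(), seed = 4)
  m <- tapply(null_tab$exocytosis_early_fF_pF, null_tab$tf_group, mean)
  expect_lt(diff(range(m)), 4 / sqrt(30))

  # default effects shift only the Both group, never cell size
  eff <- simulate_ephys(groups, seed = 5)
  size_m <- tapply(eff$cell_size_pF, eff$tf_group, mean)
  expect_lt(diff(range(size_m)), 4 / sqrt(30))
  exo_m <- tapply(eff$exocytosis_early_fF_pF, eff$tf_group, mean)
  expect_gt(exo_m[["Both"]], max(exo_m[c("None", "A-only", "B-only")]))
})

test_that("intensity simulation plants the requested fractions", {
  tab <- simulate_intensity(3000, c(0.41, 0.19, 0.09, 0.30), seed = 9)
  planted <- prop.table(table(tab$true_label))
  target <- c("lo/lo" = 0.41, "hi/lo" = 0.19, "lo/hi" = 0.09, "hi/hi" = 0.30)
  sd3 <- 3 * sqrt(target * (1 - target) / 3000)
  expect_true(all(abs(planted[names(target)] - target) <= sd3))
  expect_error(simulate_intensity(10, c(0.5, 0.5, 0.5, 0.5)), "sum to 1")
})
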