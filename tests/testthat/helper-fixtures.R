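# Shared fixtures: hand-built SingleCellExperiments for arithmetic checks
# and a scaled-down simulator configuration for the heavier tests.

library(Matrix)
library(SingleCellExperiment)

# SCE from a dense genes x cells count matrix (and optional logcounts).
make_sce <- function(counts, logcounts = NULL, cell_type = NULL,
                     donor = NULL) {
  counts <- Matrix::Matrix(as.matrix(counts), sparse = TRUE)
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("c%02d", seq_len(ncol(counts)))
  }
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("g%02d", seq_len(nrow(counts)))
  }
  assays <- list(counts = counts)
  if (!is.null(logcounts)) {
    logcounts <- Matrix::Matrix(as.matrix(logcounts), sparse = TRUE)
    dimnames(logcounts) <- dimnames(counts)
    assays$logcounts <- logcounts
  }
  cd <- S4Vectors::DataFrame(row.names = colnames(counts))
  if (!is.null(cell_type)) cd$cell_type <- cell_type
  if (!is.null(donor)) cd$donor <- donor
  SingleCellExperiment::SingleCellExperiment(assays = assays, colData = cd)
}

# SCE carrying only a logcounts assay (for rules operating on the
# normalized scale); counts mirror the logcounts' nonzero pattern.
make_log_sce <- function(logcounts, ...) {
  lc <- as.matrix(logcounts)
  make_sce(counts = (lc > 0) * 1, logcounts = lc, ...)
}

# Small, fast simulator configuration used across tests.
small_sim_config <- function(seed = 1L, ...) {
  args <- list(...)
  defaults <- list(
    seed = seed,
    n_cells_per_type = c(alpha = 250, beta = 150, delta = 30,
                         acinar = 30, ductal = 30, stellate = 30),
    n_genes = 300L,
    n_empty_droplets = 150L,
    n_donors = 3L
  )
  defaults[names(args)] <- args
  do.call(sim_config, defaults)
}

# Adjusted Rand index between two labelings.
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (max_index - expected)
}

# Direct step-up Benjamini-Hochberg, written independently of p.adjust.
bh_step_up <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in rev(seq_len(m))) {
    prev <- min(prev, m / i * p[o[i]])
    adj[o[i]] <- prev
  }
  adj
}

# Exact two-sided Mann-Whitney p by full enumeration of rank assignments.
mwu_enumerated_p <- function(x, y) {
  n <- length(x)
  m <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(n + m, n)
  us <- apply(combos, 2, function(idx) sum(r[idx])) - n * (n + 1) / 2
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  min(1, p)
}
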