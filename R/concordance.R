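#' Pseudobulk profile of one cell type
#'
#' Per-gene mean raw UMI count across the cells of a type — the
#' single-cell stand-in used for bulk comparisons.
#'
#' @param sce `SingleCellExperiment` with `counts` and
#'   `colData$cell_type`.
#' @param cell_type Type to aggregate.
#' @return Named numeric vector of mean UMI per gene.
#' @export
pseudobulk <- function(sce, cell_type) {
  cd <- SummarizedExperiment::colData(sce)
  keep <- cd$cell_type == cell_type
  if (!any(keep)) stop("unknown or empty cell type '", cell_type, "'")
  Matrix::rowMeans(
    SummarizedExperiment::assay(sce, "counts")[, keep, drop = FALSE]
  )
}

#' Detection-filtered bulk versus pseudobulk correlation
#'
#' Restricts to genes passing both modality detection filters — bulk
#' log2(TPM) above `bulk_min_log2tpm` (default 1) and single-cell mean
#' UMI above `sc_min_umi` (default 1) — and returns the Pearson
#' correlation of the log2-transformed values.
#'
#' @param bulk_tpm Named vector of bulk TPM values.
#' @param pseudo Named vector of pseudobulk mean UMI (see
#'   [pseudobulk()]).
#' @param bulk_min_log2tpm,sc_min_umi Detection cutoffs (exclusive).
#' @return List with `r`, `n_genes`, `genes` (surviving symbols).
#' @export
expression_concordance <- function(bulk_tpm, pseudo,
                                   bulk_min_log2tpm = 1, sc_min_umi = 1) {
  shared <- intersect(names(bulk_tpm), names(pseudo))
  b <- bulk_tpm[shared]
  s <- pseudo[shared]
  pass <- b > 0 & log2(pmax(b, .Machine$double.xmin)) > bulk_min_log2tpm &
    s > sc_min_umi
  genes <- shared[pass]
  if (length(genes) < 3L) stop("fewer than 3 genes pass both detection filters")
  r <- stats::cor(log2(b[genes]), log2(s[genes]))
  list(r = r, n_genes = length(genes), genes = genes)
}

# Bulk alpha-vs-beta differential expression by the z-score rule:
# log2 fold change of mean TPM (with pseudocount); p from a per-gene
# Welch z across replicate log2(TPM + 1) values when both sides have
# replicates, otherwise from standardizing the log-ratio across genes
# (the single-donor approximation); BH adjustment; significant when
# |log2FC| >= fc_cutoff and adjusted p < alpha.
bulk_de_zscore <- function(bulk_a, bulk_b, pseudocount = 1,
                           fc_cutoff = 1, alpha = 0.05) {
  bulk_a <- as.matrix(bulk_a)
  bulk_b <- as.matrix(bulk_b)
  shared <- intersect(rownames(bulk_a), rownames(bulk_b))
  a <- bulk_a[shared, , drop = FALSE]
  b <- bulk_b[shared, , drop = FALSE]
  log2fc <- log2((rowMeans(a) + pseudocount) / (rowMeans(b) + pseudocount))
  if (ncol(a) >= 2L && ncol(b) >= 2L) {
    la <- log2(a + 1)
    lb <- log2(b + 1)
    se <- sqrt(apply(la, 1, stats::var) / ncol(la) +
                 apply(lb, 1, stats::var) / ncol(lb))
    z <- (rowMeans(la) - rowMeans(lb)) / pmax(se, .Machine$double.eps)
  } else {
    s <- stats::sd(log2fc)
    z <- if (is.na(s) || s == 0) rep(0, length(log2fc)) else
      (log2fc - mean(log2fc)) / s
  }
  p <- 2 * stats::pnorm(-abs(z))
  p_adj <- bh_adjust(p)
  data.frame(
    gene = shared, log2fc = as.numeric(log2fc), z = as.numeric(z),
    p = p, p_adj = p_adj,
    significant = abs(log2fc) >= fc_cutoff & p_adj < alpha,
    stringsAsFactors = FALSE
  )
}

# Single-cell alpha-vs-beta differential expression: log2 ratio of mean
# UMI (with pseudocount), Mann-Whitney p on normalized expression, BH.
sc_de_mwu <- function(sce, alpha_type = "alpha", beta_type = "beta",
                      genes = NULL, pseudocount = 1,
                      fc_cutoff = 1, alpha = 0.05) {
  cd <- SummarizedExperiment::colData(sce)
  ia <- cd$cell_type == alpha_type
  ib <- cd$cell_type == beta_type
  if (!any(ia) || !any(ib)) stop("both cell types must be present")
  counts <- SummarizedExperiment::assay(sce, "counts")
  lc <- SummarizedExperiment::assay(sce, "logcounts")
  if (is.null(genes)) genes <- rownames(counts)
  genes <- intersect(genes, rownames(counts))
  ma <- Matrix::rowMeans(counts[genes, ia, drop = FALSE])
  mb <- Matrix::rowMeans(counts[genes, ib, drop = FALSE])
  log2fc <- log2((ma + pseudocount) / (mb + pseudocount))
  p <- vapply(genes, function(g) {
    mwu_test(as.numeric(lc[g, ia]), as.numeric(lc[g, ib]))$p.value
  }, numeric(1))
  p_adj <- bh_adjust(p)
  data.frame(
    gene = genes, mean_alpha = as.numeric(ma), mean_beta = as.numeric(mb),
    log2fc = as.numeric(log2fc), p = as.numeric(p), p_adj = p_adj,
    significant = abs(log2fc) >= fc_cutoff & p_adj < alpha,
    stringsAsFactors = FALSE
  )
}

#' Paired bulk / single-cell differential-expression concordance
#'
#' Runs alpha-versus-beta differential expression in both modalities —
#' bulk TPM by the z-score rule, single-cell by log2 mean-UMI ratio with
#' Mann-Whitney p — and compares the two log2 fold-change vectors on
#' genes significant in both: Pearson correlation and the number of
#' jointly significant genes changing in opposite directions.
#'
#' @param bulk_alpha,bulk_beta Gene x sample TPM matrices (or named
#'   vectors for single samples).
#' @param sce `SingleCellExperiment` with `counts`, `logcounts` and
#'   `colData$cell_type` covering both types.
#' @param alpha_type,beta_type Cell-type labels in `colData`.
#' @param genes Optional gene restriction; default is the intersection of
#'   bulk and single-cell gene sets.
#' @param pseudocount Added to means before the log-ratio (default 1; set
#'   0 for noise-free fixtures with strictly positive means).
#' @param fc_cutoff,alpha Significance rule: |log2FC| >= cutoff and BH
#'   adjusted p below alpha.
#' @return List with `bulk` and `sc` DE tables, `fc_correlation`,
#'   `n_joint` (jointly significant genes) and `discordant` (opposite
#'   sign among them). With no jointly significant genes the correlation
#'   is `NA` and `empty` is TRUE.
#' @export
de_and_fc_concordance <- function(bulk_alpha, bulk_beta, sce,
                                  alpha_type = "alpha", beta_type = "beta",
                                  genes = NULL, pseudocount = 1,
                                  fc_cutoff = 1, alpha = 0.05) {
  if (is.null(dim(bulk_alpha))) bulk_alpha <- cbind(sample1 = bulk_alpha)
  if (is.null(dim(bulk_beta))) bulk_beta <- cbind(sample1 = bulk_beta)
  bulk <- bulk_de_zscore(bulk_alpha, bulk_beta, pseudocount = pseudocount,
                         fc_cutoff = fc_cutoff, alpha = alpha)
  if (is.null(genes)) {
    genes <- intersect(bulk$gene,
                       rownames(SummarizedExperiment::assay(sce, "counts")))
  }
  sc <- sc_de_mwu(sce, alpha_type, beta_type, genes = genes,
                  pseudocount = pseudocount, fc_cutoff = fc_cutoff,
                  alpha = alpha)
  joint <- intersect(bulk$gene[bulk$significant], sc$gene[sc$significant])
  fb <- bulk$log2fc[match(joint, bulk$gene)]
  fs <- sc$log2fc[match(joint, sc$gene)]
  empty <- length(joint) == 0L
  if (empty) {
    warning("no genes significant in both modalities")
  }
  r <- if (length(joint) >= 2L) stats::cor(fb, fs) else NA_real_
  list(
    bulk = bulk, sc = sc,
    fc_correlation = r,
    n_joint = length(joint),
    joint_genes = joint,
    discordant = if (empty) 0L else sum(sign(fb) != sign(fs)),
    empty = empty
  )
}
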