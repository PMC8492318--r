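#' Ambient-RNA correction from empty droplets
#'
#' Barcodes whose total UMI count is at or below `umi_cutoff` (default
#' 100) define the ambient pool. Genes accounting for at least
#' `prominence` of the pooled ambient counts form the ambient gene list;
#' for each such gene the expected ambient count in every cell (ambient
#' pool proportion times the cell's total UMI) is rounded half-up,
#' subtracted from the raw count and clipped at zero. The subtraction is
#' applied only where the raw count is consistent with a purely ambient
#' origin — at most `expected + 3 * sqrt(expected)`, a Poisson upper
#' band; a count clearly above that band marks a cell genuinely
#' expressing the gene (for example glucagon in an alpha cell, which also
#' dominates the ambient pool) and is left untouched. Non-ambient genes
#' and the ambient-pool barcodes themselves are never altered.
#'
#' @param sce `SingleCellExperiment` with a raw `counts` assay over all
#'   barcodes (called cells and empty droplets).
#' @param umi_cutoff Total-UMI threshold defining the ambient pool
#'   (inclusive).
#' @param prominence Minimum share of pooled ambient counts for a gene to
#'   be treated as ambient. The default, `max(0.001, 3 / n_genes)`, is
#'   0.1% for transcriptome-scale matrices but never falls below three
#'   times the uniform share, so that on small gene panels only genuinely
#'   over-represented genes are called ambient.
#' @return A list with `sce` (corrected counts), `ambient_genes`,
#'   `ambient_proportion` (pool gene proportions), and `pool_barcodes`.
#' @export
ambient_correct <- function(sce, umi_cutoff = 100, prominence = NULL) {
  if (is.null(prominence)) prominence <- min(0.05, max(0.001, 3 / nrow(sce)))
  counts <- SummarizedExperiment::assay(sce, "counts")
  totals <- Matrix::colSums(counts)
  pool <- totals <= umi_cutoff
  if (!any(pool)) {
    warning("no barcodes at or below the ambient UMI cutoff; returning input unchanged")
    return(list(sce = sce, ambient_genes = character(0),
                ambient_proportion = NULL, pool_barcodes = character(0)))
  }
  pooled <- Matrix::rowSums(counts[, pool, drop = FALSE])
  prop <- pooled / sum(pooled)
  ambient_genes <- names(prop)[prop >= prominence & pooled > 0]

  cells <- which(!pool)
  if (length(ambient_genes) && length(cells)) {
    block <- as.matrix(counts[ambient_genes, cells, drop = FALSE])
    expected <- outer(prop[ambient_genes], totals[cells])
    ambient_like <- block <= expected + 3 * sqrt(expected)
    corrected <- pmax(0, block - floor(expected + 0.5)) # round half-up, clip
    corrected[!ambient_like] <- block[!ambient_like]
    counts[ambient_genes, cells] <- corrected
    counts <- Matrix::drop0(counts)
    SummarizedExperiment::assay(sce, "counts") <- counts
  }
  list(sce = sce, ambient_genes = ambient_genes, ambient_proportion = prop,
       pool_barcodes = colnames(counts)[pool])
}

#' Cell and gene quality-control filters
#'
#' Retains cells with a detected-gene count inside `[min_genes,
#' max_genes]` (inclusive) and a mitochondrial fraction strictly below
#' `max_mito_fraction`; afterwards retains genes detected in at least
#' `min_cells_per_gene` of the retained cells. Mitochondrial genes are
#' recognized by symbol pattern; if none match, the fraction is treated as
#' zero with a warning.
#'
#' @param sce `SingleCellExperiment` with a `counts` assay (called cells
#'   only; remove empty droplets first, e.g. via [ambient_correct()]'s
#'   pool).
#' @param min_genes,max_genes Inclusive bounds on detected genes per cell.
#' @param max_mito_fraction Exclusive upper bound on the mitochondrial
#'   UMI fraction.
#' @param min_cells_per_gene Minimum retained cells a gene must be
#'   detected in.
#' @param mito_pattern Regular expression identifying mitochondrial gene
#'   symbols.
#' @return A list with `sce` (filtered), `qc` (per input barcode:
#'   `detected_genes`, `total_umi`, `mito_fraction`, `keep`,
#'   `drop_reason`), and `genes_dropped`.
#' @export
filter_cells_genes <- function(sce, min_genes = 200L, max_genes = 4000L,
                               max_mito_fraction = 0.10,
                               min_cells_per_gene = 3L,
                               mito_pattern = "^MT-") {
  if (min_genes >= max_genes) stop("min_genes must be below max_genes")
  counts <- SummarizedExperiment::assay(sce, "counts")
  if (ncol(counts) == 0L || nrow(counts) == 0L) stop("empty count matrix")
  if (is.null(colnames(counts))) {
    colnames(sce) <- sprintf("cell%05d", seq_len(ncol(counts)))
    counts <- SummarizedExperiment::assay(sce, "counts")
  }
  detected <- Matrix::colSums(counts > 0)
  total <- Matrix::colSums(counts)
  mito <- grepl(mito_pattern, rownames(counts))
  if (!any(mito)) {
    warning("no mitochondrial genes matched '", mito_pattern,
            "'; treating mitochondrial fraction as 0")
    mito_frac <- rep(0, ncol(counts))
  } else {
    mito_frac <- Matrix::colSums(counts[mito, , drop = FALSE]) / pmax(total, 1)
  }

  reason <- rep(NA_character_, ncol(counts))
  reason[detected < min_genes] <- "min_genes"
  reason[detected > max_genes] <- "max_genes"
  reason[is.na(reason) & mito_frac >= max_mito_fraction] <- "mito_fraction"
  keep <- is.na(reason)

  qc <- data.frame(
    barcode = colnames(counts),
    detected_genes = as.integer(detected),
    total_umi = as.numeric(total),
    mito_fraction = as.numeric(mito_frac),
    keep = keep,
    drop_reason = reason,
    stringsAsFactors = FALSE
  )

  out <- sce[, keep]
  kept_counts <- SummarizedExperiment::assay(out, "counts")
  gene_cells <- Matrix::rowSums(kept_counts > 0)
  gene_keep <- gene_cells >= min_cells_per_gene
  genes_dropped <- rownames(out)[!gene_keep]
  out <- out[gene_keep, ]
  list(sce = out, qc = qc, genes_dropped = genes_dropped)
}

#' Library-size log normalization
#'
#' Adds a `logcounts` assay with entries `ln(count / cell_total *
#' size_factor + 1)` — natural-log UMI per `size_factor` (default 10,000)
#' — preserving sparsity (zero counts stay exactly zero).
#'
#' @param sce `SingleCellExperiment` with a `counts` assay; every cell
#'   total must be positive.
#' @param size_factor Target library size (default 1e4).
#' @return The input with a `logcounts` assay added.
#' @export
normalize_log <- function(sce, size_factor = 1e4) {
  counts <- SummarizedExperiment::assay(sce, "counts")
  totals <- Matrix::colSums(counts)
  if (any(totals == 0)) stop("cells with zero total counts cannot be normalized")
  scaled <- counts %*% Matrix::Diagonal(x = size_factor / totals)
  scaled <- methods::as(scaled, "CsparseMatrix")
  scaled@x <- log1p(scaled@x)
  dimnames(scaled) <- dimnames(counts)
  SummarizedExperiment::assay(sce, "logcounts") <- scaled
  sce
}

#' Hormone-coexpression doublet removal
#'
#' Two rules on the normalized log scale flag probable doublets: (1) cells
#' coexpressing INS above `ins_threshold` (default 6.5) and GCG above
#' `gcg_threshold` (default 5.0); (2) cells with INS or GCG above their
#' respective thresholds that also express a marker of a different,
#' non-paired lineage above `positive_level`. Each dropped barcode records
#' the rule (and triggering marker) that fired.
#'
#' @param sce `SingleCellExperiment` with a `logcounts` assay containing
#'   INS and GCG.
#' @param ins_threshold,gcg_threshold Normalized-log thresholds for the
#'   coexpression rule.
#' @param marker_table Marker table for the cross-lineage rule; INS, GCG
#'   and the hormone's own lineage markers are excluded as evidence.
#' @param positive_level Normalized-log level above which another lineage
#'   marker counts as expressed (default 3, roughly ten counts in a
#'   5,000-UMI cell — high enough that ambient sampling noise on rare
#'   lineage markers does not flag true singlets).
#' @return List with `sce` (kept cells) and `dropped` (barcode, rule,
#'   detail).
#' @export
remove_hormone_doublets <- function(sce, ins_threshold = 6.5,
                                    gcg_threshold = 5.0,
                                    marker_table = default_marker_table(),
                                    positive_level = 3.0) {
  lc <- SummarizedExperiment::assay(sce, "logcounts")
  if (!all(c("INS", "GCG") %in% rownames(lc))) {
    stop("INS and GCG must be present in the gene set")
  }
  marker_table <- check_marker_table(marker_table)
  ins <- as.numeric(lc["INS", ])
  gcg <- as.numeric(lc["GCG", ])

  rule <- rep(NA_character_, ncol(lc))
  detail <- rep(NA_character_, ncol(lc))

  co <- ins > ins_threshold & gcg > gcg_threshold
  rule[co] <- "ins_gcg_coexpression"
  detail[co] <- sprintf("INS=%.2f, GCG=%.2f", ins[co], gcg[co])

  cross_markers <- function(own_type) {
    mk <- marker_table[marker_table$cell_type != own_type, , drop = FALSE]
    mk <- mk[!mk$gene %in% c("INS", "GCG"), , drop = FALSE]
    mk[mk$gene %in% rownames(lc), , drop = FALSE]
  }
  flag_cross <- function(hormone_high, own_type, label) {
    mk <- cross_markers(own_type)
    if (!nrow(mk)) return()
    expr <- as.matrix(lc[mk$gene, , drop = FALSE]) > positive_level
    hit <- hormone_high & is.na(rule) & colSums(expr) > 0
    if (any(hit)) {
      first <- apply(expr[, hit, drop = FALSE], 2, function(z) mk$gene[which(z)[1]])
      rule[hit] <<- "cross_lineage"
      detail[hit] <<- paste0(label, "+", first)
    }
  }
  flag_cross(ins > ins_threshold, "beta", "INS")
  flag_cross(gcg > gcg_threshold, "alpha", "GCG")

  dropped <- data.frame(
    barcode = colnames(lc)[!is.na(rule)],
    rule = rule[!is.na(rule)],
    detail = detail[!is.na(rule)],
    stringsAsFactors = FALSE
  )
  list(sce = sce[, is.na(rule)], dropped = dropped)
}
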