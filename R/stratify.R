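#' Binarize a TF pair and classify cells into four combinatorial groups
#'
#' For cells of the target type, each transcription factor is called
#' "detected" when its normalized log expression (natural log of UMI per
#' 10,000 + 1) exceeds the threshold (default 0.5); values exactly at the
#' threshold are called low. The joint detection status yields the four
#' groups None / A-only / B-only / Both, with pooled and per-donor
#' fractions.
#'
#' @param sce `SingleCellExperiment` with `logcounts`; `colData` must
#'   carry `cell_type` (unless `cell_type = NULL`) and, for per-donor
#'   fractions, `donor`.
#' @param gene_a,gene_b TF gene symbols (e.g. ARX/MAFB for alpha cells,
#'   MAFA/MAFB for beta cells).
#' @param cell_type Target type; `NULL` uses every cell.
#' @param threshold Detection threshold on the normalized log scale.
#' @param detection `"threshold"` (default) calls a TF detected when its
#'   normalized value exceeds `threshold`; `"nonzero"` calls it detected
#'   on any positive count.
#' @return An object of class `tf_group_result`: list with `cells`
#'   (barcode, donor, detection indicators, group), `fractions` (pooled,
#'   ordered None, A-only, B-only, Both), `by_donor` (donor x group
#'   fraction matrix), `counts`, `n`, `pair`, `threshold`.
#' @examples
#' # see vignette("tf-stratification") for an end-to-end example
#' @export
binarize_and_classify <- function(sce, gene_a, gene_b, cell_type = NULL,
                                  threshold = 0.5,
                                  detection = c("threshold", "nonzero")) {
  detection <- match.arg(detection)
  if (gene_a == gene_b) stop("gene_a and gene_b must differ")
  lc <- SummarizedExperiment::assay(sce, "logcounts")
  for (g in c(gene_a, gene_b)) {
    if (!g %in% rownames(lc)) stop("TF gene '", g, "' absent from matrix")
  }
  cd <- SummarizedExperiment::colData(sce)
  keep <- if (is.null(cell_type)) rep(TRUE, ncol(lc)) else cd$cell_type == cell_type
  if (!any(keep)) stop("no cells of type '", cell_type, "'")

  a <- as.numeric(lc[gene_a, keep])
  b <- as.numeric(lc[gene_b, keep])
  cut <- if (detection == "threshold") threshold else 0
  a_det <- a > cut
  b_det <- b > cut
  group <- factor(
    ifelse(a_det & b_det, "Both",
           ifelse(a_det, "A-only", ifelse(b_det, "B-only", "None"))),
    levels = tf_group_levels
  )
  donor <- if ("donor" %in% names(cd)) as.character(cd$donor[keep]) else
    rep("all", sum(keep))

  counts <- table(group)
  fractions <- as.numeric(counts) / sum(counts)
  names(fractions) <- names(counts)
  by_donor <- prop.table(table(donor, group), margin = 1)

  out <- list(
    cells = data.frame(
      barcode = colnames(lc)[keep],
      donor = donor,
      a_detected = a_det,
      b_detected = b_det,
      group = group,
      stringsAsFactors = FALSE
    ),
    fractions = fractions,
    by_donor = by_donor,
    counts = counts,
    n = sum(keep),
    pair = c(gene_a = gene_a, gene_b = gene_b),
    cell_type = if (is.null(cell_type)) NA_character_ else cell_type,
    threshold = cut
  )
  class(out) <- "tf_group_result"
  out
}

#' @exportS3Method base::print
print.tf_group_result <- function(x, ...) {
  cat(sprintf("TF group classification: %s / %s (threshold %.2f)\n",
              x$pair[["gene_a"]], x$pair[["gene_b"]], x$threshold))
  cat(sprintf("  %d cells%s\n", x$n,
              if (is.na(x$cell_type)) "" else paste0(" of type ", x$cell_type)))
  print(round(x$fractions, 4))
  invisible(x)
}

# Map a cell barcode set onto the group labels of a tf_group_result.
groups_for_barcodes <- function(groups, barcodes) {
  idx <- match(barcodes, groups$cells$barcode)
  groups$cells$group[idx]
}

#' Dot-plot summary statistics per gene and TF group
#'
#' For each panel gene and group: the fraction of cells with a detectable
#' transcript (raw count > 0), the group mean normalized expression, and
#' the z-score of that mean across the four groups (sample SD over group
#' means). Genes with zero variance across groups report z = 0 with a
#' flag; empty groups are excluded from the z-score.
#'
#' @param sce `SingleCellExperiment` with `counts` and `logcounts`.
#' @param groups A `tf_group_result` from [binarize_and_classify()].
#' @param gene_panel Character vector of gene symbols, or a data.frame
#'   with columns `category` and `gene`.
#' @return data.frame with one row per gene x group: `gene`, optional
#'   `category`, `group`, `pct_detected`, `mean_expr`, `z`,
#'   `zero_variance`.
#' @export
dotplot_stats <- function(sce, groups, gene_panel) {
  panel <- as_gene_panel(gene_panel)
  counts <- SummarizedExperiment::assay(sce, "counts")
  lc <- SummarizedExperiment::assay(sce, "logcounts")
  missing <- setdiff(panel$gene, rownames(lc))
  if (length(missing)) {
    message("panel genes absent, skipped: ", paste(missing, collapse = ", "))
    panel <- panel[!panel$gene %in% missing, , drop = FALSE]
  }
  cells <- groups$cells
  idx <- match(cells$barcode, colnames(lc))

  rows <- list()
  for (i in seq_len(nrow(panel))) {
    g <- panel$gene[i]
    cnt <- as.numeric(counts[g, idx])
    expr <- as.numeric(lc[g, idx])
    means <- tapply(expr, cells$group, mean)
    pct <- tapply(cnt > 0, cells$group, mean)
    present <- !is.na(means)
    s <- stats::sd(means[present])
    zero_var <- is.na(s) || s == 0
    z <- rep(NA_real_, length(means))
    z[present] <- if (zero_var) 0 else (means[present] - mean(means[present])) / s
    rows[[i]] <- data.frame(
      gene = g,
      category = if ("category" %in% names(panel)) panel$category[i] else NA_character_,
      group = factor(names(means), levels = tf_group_levels),
      pct_detected = as.numeric(pct),
      mean_expr = as.numeric(means),
      z = z,
      zero_variance = zero_var,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

as_gene_panel <- function(gene_panel) {
  if (is.data.frame(gene_panel)) {
    if (!"gene" %in% names(gene_panel)) stop("gene_panel needs a 'gene' column")
    gene_panel
  } else {
    data.frame(gene = as.character(gene_panel), stringsAsFactors = FALSE)
  }
}

#' Mann-Whitney group comparisons over a gene panel
#'
#' Two-sided Mann-Whitney U tests of each panel gene between the "Both"
#' group and each other group (or all pairs), on normalized log
#' expression, with Benjamini-Hochberg adjustment across the full gene x
#' comparison family by default.
#'
#' @param sce `SingleCellExperiment` with `logcounts`.
#' @param groups A `tf_group_result`.
#' @param gene_panel Character vector or data.frame with a `gene` column.
#' @param scheme `"both_vs_each"` (default) or `"all_pairs"`.
#' @param family `"joint"` adjusts across all genes and comparisons
#'   together (default); `"per_comparison"` adjusts within each
#'   comparison.
#' @param min_cells Groups with fewer cells are skipped (default 1).
#' @return data.frame of class `group_test_result`: `gene`, `group1`,
#'   `group2`, `median1`, `median2`, `statistic`, `p`, `p_adj`, `stars`.
#' @export
compare_groups <- function(sce, groups, gene_panel,
                           scheme = c("both_vs_each", "all_pairs"),
                           family = c("joint", "per_comparison"),
                           min_cells = 1L) {
  scheme <- match.arg(scheme)
  family <- match.arg(family)
  panel <- as_gene_panel(gene_panel)
  lc <- SummarizedExperiment::assay(sce, "logcounts")
  missing <- setdiff(panel$gene, rownames(lc))
  if (length(missing)) {
    message("panel genes absent, skipped: ", paste(missing, collapse = ", "))
    panel <- panel[!panel$gene %in% missing, , drop = FALSE]
  }
  cells <- groups$cells
  idx <- match(cells$barcode, colnames(lc))
  present <- names(which(table(cells$group) >= max(1L, min_cells)))
  present <- tf_group_levels[tf_group_levels %in% present]
  if (length(present) < 2L) stop("need at least two non-empty groups")

  pairs <- if (scheme == "both_vs_each") {
    if (!"Both" %in% present) stop("'Both' group is empty")
    lapply(setdiff(present, "Both"), function(g) c("Both", g))
  } else {
    utils::combn(present, 2, simplify = FALSE)
  }

  rows <- list()
  k <- 0L
  for (g in panel$gene) {
    expr <- as.numeric(lc[g, idx])
    for (pr in pairs) {
      x <- expr[cells$group == pr[1]]
      y <- expr[cells$group == pr[2]]
      tt <- mwu_test(x, y)
      k <- k + 1L
      rows[[k]] <- data.frame(
        gene = g, group1 = pr[1], group2 = pr[2],
        median1 = stats::median(x), median2 = stats::median(y),
        statistic = tt$statistic, p = tt$p.value,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  comparison <- paste(out$group1, "vs", out$group2)
  out$p_adj <- if (family == "joint") {
    bh_adjust(out$p)
  } else {
    stats::ave(out$p, comparison, FUN = bh_adjust)
  }
  out$stars <- sig_stars(out$p_adj)
  rownames(out) <- NULL
  class(out) <- c("group_test_result", class(out))
  out
}

#' Detected genes per cell in TF-low versus TF-high cells
#'
#' Splits cells by detection of one TF (low: normalized value at or below
#' the threshold; high: above) and summarizes the per-cell number of
#' detected genes in each stratum — the diagnostic used to argue that TF
#' bimodality is not a dropout artifact.
#'
#' @param sce `SingleCellExperiment` with `counts` and `logcounts`.
#' @param tf_gene TF symbol.
#' @param threshold Normalized-log detection threshold (default 0.5).
#' @param cell_type Optional type restriction (needs `colData$cell_type`).
#' @return data.frame with one row per non-empty stratum: `stratum`, `n`,
#'   `median_detected`, `q1`, `q3`, `frac_gt_1000`.
#' @export
detected_genes_by_level <- function(sce, tf_gene, threshold = 0.5,
                                    cell_type = NULL) {
  lc <- SummarizedExperiment::assay(sce, "logcounts")
  if (!tf_gene %in% rownames(lc)) stop("TF gene '", tf_gene, "' absent")
  counts <- SummarizedExperiment::assay(sce, "counts")
  keep <- rep(TRUE, ncol(lc))
  if (!is.null(cell_type)) {
    keep <- SummarizedExperiment::colData(sce)$cell_type == cell_type
  }
  detected <- Matrix::colSums(counts[, keep, drop = FALSE] > 0)
  high <- as.numeric(lc[tf_gene, keep]) > threshold
  strata <- list(low = detected[!high], high = detected[high])
  rows <- lapply(names(strata), function(s) {
    d <- strata[[s]]
    if (!length(d)) return(NULL)
    q <- stats::quantile(d, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(stratum = s, n = length(d), median_detected = q[2],
               q1 = q[1], q3 = q[3], frac_gt_1000 = mean(d > 1000),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Four-way hi/lo classification of two-channel marker intensities
#'
#' Tissue-image analogue of the transcript classification: per-cell
#' continuous intensities for two markers are thresholded into lo/lo,
#' hi/lo, lo/hi and hi/hi, with composite and per-donor fractions. A
#' value strictly above its threshold is "hi". Cells with missing
#' intensities are excluded and counted.
#'
#' @param intensity_table data.frame with columns `marker_a`, `marker_b`
#'   and optionally `donor`.
#' @param thresholds Either a named vector `c(marker_a = , marker_b = )`
#'   applied to all cells, or a data.frame with columns `donor`,
#'   `marker_a`, `marker_b` for per-donor thresholds (thresholds are held
#'   fixed within a donor's tissue).
#' @return List with `cells` (input rows plus `label`), `fractions`
#'   (composite, ordered lo/lo, hi/lo, lo/hi, hi/hi), `by_donor`,
#'   `n_excluded`.
#' @export
classify_intensity <- function(intensity_table, thresholds) {
  stopifnot(all(c("marker_a", "marker_b") %in% names(intensity_table)))
  tab <- intensity_table
  ok <- !is.na(tab$marker_a) & !is.na(tab$marker_b)
  n_excluded <- sum(!ok)
  if (n_excluded > 0) {
    message(n_excluded, " cell(s) with missing intensities excluded")
  }
  tab <- tab[ok, , drop = FALSE]
  donor <- if ("donor" %in% names(tab)) as.character(tab$donor) else
    rep("all", nrow(tab))

  if (is.data.frame(thresholds)) {
    stopifnot(all(c("donor", "marker_a", "marker_b") %in% names(thresholds)))
    m <- match(donor, thresholds$donor)
    if (anyNA(m)) stop("missing thresholds for donor(s): ",
                       paste(unique(donor[is.na(m)]), collapse = ", "))
    thr_a <- thresholds$marker_a[m]
    thr_b <- thresholds$marker_b[m]
  } else {
    thr_a <- thresholds[["marker_a"]]
    thr_b <- thresholds[["marker_b"]]
  }
  a_hi <- tab$marker_a > thr_a
  b_hi <- tab$marker_b > thr_b
  levels4 <- c("lo/lo", "hi/lo", "lo/hi", "hi/hi")
  label <- factor(
    ifelse(a_hi & b_hi, "hi/hi",
           ifelse(a_hi, "hi/lo", ifelse(b_hi, "lo/hi", "lo/lo"))),
    levels = levels4
  )
  counts <- table(label)
  fractions <- as.numeric(counts) / max(1, sum(counts))
  names(fractions) <- levels4
  tab$label <- label
  list(
    cells = tab,
    fractions = fractions,
    by_donor = prop.table(table(donor, label), margin = 1),
    n_excluded = n_excluded
  )
}
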