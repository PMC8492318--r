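#' PCA and Louvain clustering
#'
#' Standard graph-based clustering: top highly variable genes by
#' log-expression variance, per-gene centering/scaling to unit variance
#' with linear regression-out of the mitochondrial fraction, PCA,
#' k-nearest-neighbour graph on the leading components, and Louvain
#' community detection at the given resolution. The Louvain pass is
#' seeded, so identical inputs give identical assignments.
#'
#' @param sce `SingleCellExperiment` with a `logcounts` assay. If a
#'   `mito_fraction` column is present in `colData` it is regressed out of
#'   each gene before scaling; otherwise it is computed from `counts` with
#'   `mito_pattern`.
#' @param n_hvg Number of highly variable genes (default 2000, capped at
#'   the gene count).
#' @param n_pcs Number of principal components (default 20).
#' @param resolution Louvain resolution (default 0.6).
#' @param knn_k Neighbours per cell in the graph (default 20).
#' @param seed Seed for the Louvain pass.
#' @param mito_pattern Regex for mitochondrial symbols, used only when
#'   `colData` lacks `mito_fraction`.
#' @return The input with `colData$cluster` (factor) and a `"PCA"` entry
#'   in `reducedDims`.
#' @export
embed_and_cluster <- function(sce, n_hvg = 2000L, n_pcs = 20L,
                              resolution = 0.6, knn_k = 20L, seed = 1L,
                              mito_pattern = "^MT-") {
  if (resolution <= 0) stop("resolution must be positive")
  lc <- SummarizedExperiment::assay(sce, "logcounts")
  n_cells <- ncol(lc)
  if (n_cells < 2L * n_pcs) stop("need at least 2 * n_pcs cells")

  means <- Matrix::rowMeans(lc)
  vars <- Matrix::rowMeans(lc^2) - means^2
  vars <- vars * n_cells / max(1, n_cells - 1)
  n_hvg <- min(n_hvg, sum(vars > 0))
  hvg <- names(sort(vars, decreasing = TRUE))[seq_len(n_hvg)]

  X <- t(as.matrix(lc[hvg, , drop = FALSE])) # cells x genes

  cd <- SummarizedExperiment::colData(sce)
  if ("mito_fraction" %in% names(cd)) {
    mito_frac <- cd$mito_fraction
  } else {
    counts <- SummarizedExperiment::assay(sce, "counts")
    mito <- grepl(mito_pattern, rownames(counts))
    mito_frac <- if (any(mito)) {
      as.numeric(Matrix::colSums(counts[mito, , drop = FALSE]) /
                   pmax(Matrix::colSums(counts), 1))
    } else {
      rep(0, n_cells)
    }
  }
  if (stats::var(mito_frac) > 0) {
    design <- cbind(1, mito_frac)
    X <- stats::lm.fit(design, X)$residuals
  } else {
    X <- scale(X, center = TRUE, scale = FALSE)
  }

  sds <- apply(X, 2, stats::sd)
  degenerate <- sds == 0
  if (any(degenerate)) {
    message(sum(degenerate), " zero-variance gene(s) dropped from scaling")
    X <- X[, !degenerate, drop = FALSE]
    sds <- sds[!degenerate]
  }
  X <- sweep(X, 2, sds, "/")

  n_pcs <- min(n_pcs, ncol(X), n_cells - 1L)
  pca <- stats::prcomp(X, rank. = n_pcs, center = FALSE, scale. = FALSE)
  scores <- pca$x

  adj <- knn_edges(scores, k = min(knn_k, n_cells - 1L))
  g <- igraph::graph_from_edgelist(adj, directed = FALSE)
  g <- igraph::simplify(g)
  cl <- withr::with_seed(as.integer(seed), {
    igraph::cluster_louvain(g, resolution = resolution)
  })
  clusters <- factor(igraph::membership(cl))

  SummarizedExperiment::colData(sce)$cluster <- clusters
  SingleCellExperiment::reducedDim(sce, "PCA") <- scores
  sce
}

# k-nearest-neighbour edge list (Euclidean) computed blockwise.
knn_edges <- function(scores, k, block = 512L) {
  n <- nrow(scores)
  sq <- rowSums(scores^2)
  edges <- vector("list", ceiling(n / block))
  bi <- 0L
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    d2 <- outer(sq[idx], sq, "+") - 2 * scores[idx, , drop = FALSE] %*% t(scores)
    d2[cbind(seq_along(idx), idx)] <- Inf
    nn <- apply(d2, 1, function(r) order(r)[seq_len(k)]) # k x block
    bi <- bi + 1L
    edges[[bi]] <- cbind(rep(idx, each = k), as.integer(nn))
  }
  do.call(rbind, edges)
}

#' Annotate clusters with cell types by marker expression
#'
#' Each cluster is labelled with the cell type whose markers have the
#' highest mean z-scored expression across clusters: for every marker the
#' per-cluster mean log-expression is z-scored across clusters, and a
#' cluster's score for a type is the mean over that type's markers. Ties
#' are broken toward the type with more markers detected in the cluster,
#' then lexicographically, with a warning. Markers absent from the matrix
#' are skipped with a message.
#'
#' @param sce `SingleCellExperiment` with `logcounts` and
#'   `colData$cluster`.
#' @param marker_table data.frame with `cell_type` and `gene` columns.
#' @return The input with `colData$cell_type` filled per cell.
#' @export
annotate_clusters <- function(sce, marker_table = default_marker_table()) {
  marker_table <- check_marker_table(marker_table)
  cd <- SummarizedExperiment::colData(sce)
  if (is.null(cd$cluster)) stop("run embed_and_cluster() first")
  lc <- SummarizedExperiment::assay(sce, "logcounts")

  missing <- setdiff(unique(marker_table$gene), rownames(lc))
  if (length(missing)) {
    message("markers absent from matrix, skipped: ",
            paste(missing, collapse = ", "))
    marker_table <- marker_table[!marker_table$gene %in% missing, , drop = FALSE]
  }
  if (!nrow(marker_table)) stop("no marker genes present in the matrix")

  clusters <- levels(droplevels(factor(cd$cluster)))
  genes <- unique(marker_table$gene)
  cluster_means <- vapply(clusters, function(cl) {
    Matrix::rowMeans(lc[genes, cd$cluster == cl, drop = FALSE])
  }, numeric(length(genes)))
  cluster_means <- matrix(cluster_means, nrow = length(genes),
                          dimnames = list(genes, clusters))

  z <- t(apply(cluster_means, 1, function(m) {
    s <- stats::sd(m)
    if (is.na(s) || s == 0) rep(0, length(m)) else (m - mean(m)) / s
  }))
  types <- sort(unique(marker_table$cell_type))
  scores <- vapply(types, function(ty) {
    g <- marker_table$gene[marker_table$cell_type == ty]
    colMeans(z[g, , drop = FALSE])
  }, numeric(length(clusters)))
  scores <- matrix(scores, nrow = length(clusters),
                   dimnames = list(clusters, types))

  label_of <- vapply(clusters, function(cl) {
    s <- scores[cl, ]
    best <- which(s == max(s))
    if (length(best) > 1L) {
      n_detected <- vapply(types[best], function(ty) {
        g <- marker_table$gene[marker_table$cell_type == ty]
        sum(cluster_means[g, cl] > 0)
      }, numeric(1))
      best <- best[n_detected == max(n_detected)]
      if (length(best) > 1L) best <- best[order(types[best])]
      warning("tie in cluster ", cl, " annotation; resolved to '",
              types[best[1]], "'")
    }
    types[best[1]]
  }, character(1))

  SummarizedExperiment::colData(sce)$cell_type <-
    unname(label_of[as.character(cd$cluster)])
  sce
}

#' Relabel rare cells by a positivity threshold
#'
#' Replaces manual lasso selection of rare endocrine populations: cells of
#' a parent type whose normalized expression of a gene exceeds the
#' threshold are relabelled (e.g. PPY-positive cells in the delta cluster
#' become gamma, GHRL-positive become epsilon).
#'
#' @param sce `SingleCellExperiment` with `logcounts` and
#'   `colData$cell_type`.
#' @param parent_type Type to search within.
#' @param gene Positivity gene.
#' @param new_type Replacement label.
#' @param threshold Normalized-log positivity threshold (default 0.5,
#'   matching the TF binarization scale).
#' @return The input with updated `colData$cell_type`.
#' @export
select_rare_cells <- function(sce, parent_type, gene, new_type,
                              threshold = 0.5) {
  lc <- SummarizedExperiment::assay(sce, "logcounts")
  if (!gene %in% rownames(lc)) stop("gene '", gene, "' missing from matrix")
  cd <- SummarizedExperiment::colData(sce)
  if (is.null(cd$cell_type)) stop("run annotate_clusters() first")
  hit <- cd$cell_type == parent_type & as.numeric(lc[gene, ]) > threshold
  SummarizedExperiment::colData(sce)$cell_type[hit] <- new_type
  sce
}
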