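#' Write a 10x-style Matrix Market triplet
#'
#' Writes `matrix.mtx` (genes x barcodes, integer counts),
#' `features.tsv` (gene id, symbol, class) and `barcodes.tsv` to a
#' directory, plus the cell metadata as `cells.tsv` when ground-truth or
#' annotation columns are present.
#'
#' @param sce `SingleCellExperiment` with a `counts` assay.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_tenx <- function(sce, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  counts <- SummarizedExperiment::assay(sce, "counts")
  Matrix::writeMM(counts, file.path(dir, "matrix.mtx"))
  rd <- SummarizedExperiment::rowData(sce)
  feat <- data.frame(
    gene_id = if ("gene_id" %in% names(rd)) rd$gene_id else rownames(counts),
    gene_symbol = if ("gene_symbol" %in% names(rd)) rd$gene_symbol else rownames(counts),
    gene_class = if ("gene_class" %in% names(rd)) rd$gene_class else "Gene Expression",
    stringsAsFactors = FALSE
  )
  utils::write.table(feat, file.path(dir, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  cd <- as.data.frame(SummarizedExperiment::colData(sce))
  if (ncol(cd) > 0) {
    utils::write.table(cd, file.path(dir, "cells.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read a 10x-style Matrix Market triplet
#'
#' Reads `matrix.mtx`, `features.tsv` and `barcodes.tsv` (as written by
#' [write_tenx()] or Cell Ranger's uncompressed triplet) into a
#' `SingleCellExperiment`; `cells.tsv`, when present, populates
#' `colData`.
#'
#' @param dir Directory containing the triplet.
#' @return A `SingleCellExperiment` with a sparse `counts` assay.
#' @export
read_tenx <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                        "CsparseMatrix")
  feat <- utils::read.table(file.path(dir, "features.tsv"), sep = "\t",
                            header = FALSE, stringsAsFactors = FALSE)
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  symbols <- if (ncol(feat) >= 2) feat[[2]] else feat[[1]]
  dimnames(counts) <- list(symbols, barcodes)
  rd <- S4Vectors::DataFrame(
    gene_id = feat[[1]],
    gene_symbol = symbols,
    row.names = symbols
  )
  if (ncol(feat) >= 3) rd$gene_class <- feat[[3]]
  cd_path <- file.path(dir, "cells.tsv")
  cd <- if (file.exists(cd_path)) {
    tab <- utils::read.table(cd_path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
    S4Vectors::DataFrame(tab, row.names = barcodes)
  } else {
    S4Vectors::DataFrame(barcode = barcodes, row.names = barcodes)
  }
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts), rowData = rd, colData = cd
  )
}

#' Read or write a marker table (TSV with cell_type, gene columns)
#' @param path TSV path.
#' @return data.frame with `cell_type` and `gene`.
#' @export
read_marker_table <- function(path) {
  check_marker_table(utils::read.table(path, sep = "\t", header = TRUE,
                                       stringsAsFactors = FALSE))
}

#' @rdname read_marker_table
#' @param marker_table data.frame to write.
#' @export
write_marker_table <- function(marker_table, path) {
  utils::write.table(check_marker_table(marker_table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene panel (TSV with category, gene columns)
#' @param path TSV path.
#' @return data.frame with `category` and `gene`.
#' @export
read_gene_panel <- function(path) {
  panel <- utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  if (!"gene" %in% names(panel)) stop("panel needs a 'gene' column")
  panel
}
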