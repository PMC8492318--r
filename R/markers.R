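#' Default islet cell-type marker table
#'
#' A reconstruction of the canonical marker set used to annotate islet
#' cell clusters: hormone genes for the endocrine lineages (GCG, INS, SST,
#' PPY, GHRL) plus well-established exocrine, ductal, endothelial,
#' stellate and immune markers. Users with their own marker list can pass
#' any data frame with the same two columns to every function that accepts
#' a `marker_table`.
#'
#' @return A data.frame with columns `cell_type` and `gene`.
#' @examples
#' head(default_marker_table())
#' @export
default_marker_table <- function() {
  data.frame(
    cell_type = c(
      "alpha", "alpha", "alpha",
      "beta", "beta", "beta",
      "delta", "delta",
      "gamma",
      "epsilon",
      "acinar", "acinar",
      "ductal", "ductal",
      "endothelial", "endothelial",
      "stellate", "stellate",
      "immune", "immune"
    ),
    gene = c(
      "GCG", "TM4SF4", "IRX2",
      "INS", "IAPP", "HADH",
      "SST", "HHEX",
      "PPY",
      "GHRL",
      "PRSS1", "CPA1",
      "KRT19", "SPP1",
      "PECAM1", "VWF",
      "COL1A1", "PDGFRB",
      "PTPRC", "CD68"
    ),
    stringsAsFactors = FALSE
  )
}

# Validate a user-supplied marker table.
check_marker_table <- function(marker_table) {
  if (!is.data.frame(marker_table) ||
      !all(c("cell_type", "gene") %in% names(marker_table))) {
    stop("'marker_table' must be a data.frame with columns 'cell_type' and 'gene'")
  }
  marker_table
}
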