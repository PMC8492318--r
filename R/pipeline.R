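#' Pipeline configuration
#'
#' Bundles every stage's parameters — each threshold from the processing
#' recipe surfaced under its own name with the recipe value as default —
#' plus the input source (a simulation configuration or a 10x triplet
#' directory) and stage toggles. Validated eagerly, so an inconsistent
#' configuration fails before any stage runs.
#'
#' @param sim A [sim_config()] to simulate input data, or `NULL` when
#'   reading from `counts_dir`.
#' @param counts_dir Directory with a 10x triplet (used when `sim` is
#'   `NULL`).
#' @param seed Top-level seed; the simulation and Louvain seeds derive
#'   from it.
#' @param ambient_umi_cutoff,ambient_prominence Ambient-pool definition
#'   and gene prominence cutoff.
#' @param min_genes,max_genes,max_mito_fraction,min_cells_per_gene Cell
#'   and gene QC bounds.
#' @param size_factor Normalization size factor.
#' @param ins_doublet_threshold,gcg_doublet_threshold,positive_level
#'   Hormone-doublet rule thresholds.
#' @param n_hvg,n_pcs,resolution,knn_k Clustering parameters.
#' @param marker_table Cell-type markers for doublet screening and
#'   cluster annotation.
#' @param tf_pairs Named list: cell type -> `c(gene_a, gene_b)`.
#' @param tf_threshold Binarization threshold on the normalized log
#'   scale.
#' @param gene_panel Genes for dot-plot and group statistics; default is
#'   the simulator's functional program panel.
#' @param bulk_alpha,bulk_beta Optional named TPM vectors (or gene x
#'   sample matrices) enabling the concordance stage.
#' @param ephys_table Optional Patch-Seq style data.frame enabling the
#'   electrophysiology stage.
#' @param run_ambient,run_cluster Stage toggles.
#' @param ambient_first When `FALSE` (default) the QC filters and the
#'   hormone-doublet rule are evaluated on uncorrected counts and the
#'   ambient correction is applied to the retained cells afterwards, so
#'   that subtracting the hormone-dominated ambient expectation cannot
#'   erase a doublet's coexpression evidence. `TRUE` corrects the full
#'   barcode matrix before any filtering.
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            counts_dir = NULL,
                            seed = 1L,
                            ambient_umi_cutoff = 100,
                            ambient_prominence = NULL,
                            min_genes = 200L,
                            max_genes = 4000L,
                            max_mito_fraction = 0.10,
                            min_cells_per_gene = 3L,
                            size_factor = 1e4,
                            ins_doublet_threshold = 6.5,
                            gcg_doublet_threshold = 5.0,
                            positive_level = 3.0,
                            n_hvg = 2000L,
                            n_pcs = 20L,
                            resolution = 0.6,
                            knn_k = 20L,
                            marker_table = default_marker_table(),
                            tf_pairs = list(alpha = c("ARX", "MAFB"),
                                            beta = c("MAFA", "MAFB")),
                            tf_threshold = 0.5,
                            gene_panel = default_program_genes(),
                            bulk_alpha = NULL,
                            bulk_beta = NULL,
                            ephys_table = NULL,
                            run_ambient = TRUE,
                            run_cluster = TRUE,
                            ambient_first = FALSE) {
  cfg <- as.list(environment())
  validate_pipeline_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

validate_pipeline_config <- function(cfg) {
  if (cfg$min_genes >= cfg$max_genes) stop("min_genes must be below max_genes")
  for (nm in c("max_mito_fraction", "ambient_umi_cutoff", "size_factor",
               "ins_doublet_threshold", "gcg_doublet_threshold",
               "tf_threshold", "resolution")) {
    if (cfg[[nm]] < 0) stop("'", nm, "' must be non-negative")
  }
  if (cfg$resolution <= 0) stop("resolution must be positive")
  if (is.null(cfg$sim) && is.null(cfg$counts_dir)) {
    stop("either 'sim' or 'counts_dir' must be provided")
  }
  check_marker_table(cfg$marker_table)
  invisible(cfg)
}

#' Run the full stratification pipeline
#'
#' Executes simulate (or read) -> ambient correction -> cell/gene QC ->
#' log normalization -> hormone-doublet removal -> clustering ->
#' annotation -> rare-cell relabelling -> TF binarization and group
#' statistics per configured pair, writing tables, a drop ledger that
#' accounts for every input barcode exactly once, and a machine-readable
#' summary (group fractions, counts per filter, every threshold used).
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory; created if needed. `NULL` skips all
#'   file output.
#' @return Invisibly, a list: `sce` (processed object), `summary`,
#'   `ledger`, `qc`, per-pair `tf_groups`, `dotplot`, `group_tests`, and
#'   optional `concordance` / `ephys` results.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  validate_pipeline_config(config)
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  sce <- if (!is.null(config$sim)) {
    simulate_dataset(config$sim)
  } else {
    read_tenx(config$counts_dir)
  }
  n_input <- ncol(sce)
  ledger <- list()

  # ambient estimation on the full barcode matrix, then drop the pool;
  # the corrected counts are swapped in either immediately
  # (ambient_first) or after the hormone-doublet rule has seen the
  # uncorrected values
  ambient_genes <- character(0)
  corrected <- NULL
  if (config$run_ambient) {
    amb <- ambient_correct(sce, umi_cutoff = config$ambient_umi_cutoff,
                           prominence = config$ambient_prominence)
    ambient_genes <- amb$ambient_genes
    if (length(amb$pool_barcodes)) {
      ledger$empty <- data.frame(barcode = amb$pool_barcodes,
                                 stage = "ambient", reason = "ambient_pool",
                                 stringsAsFactors = FALSE)
    }
    keep_bc <- !colnames(sce) %in% amb$pool_barcodes
    if (config$ambient_first) {
      sce <- amb$sce[, keep_bc]
    } else {
      corrected <- SummarizedExperiment::assay(amb$sce, "counts")[, keep_bc,
                                                                  drop = FALSE]
      sce <- sce[, keep_bc]
    }
  }

  fc <- filter_cells_genes(sce,
                           min_genes = config$min_genes,
                           max_genes = config$max_genes,
                           max_mito_fraction = config$max_mito_fraction,
                           min_cells_per_gene = config$min_cells_per_gene)
  sce <- fc$sce
  qc_drops <- fc$qc[!fc$qc$keep, , drop = FALSE]
  if (nrow(qc_drops)) {
    ledger$qc <- data.frame(barcode = qc_drops$barcode, stage = "qc",
                            reason = qc_drops$drop_reason,
                            stringsAsFactors = FALSE)
  }
  SummarizedExperiment::colData(sce)$mito_fraction <-
    fc$qc$mito_fraction[match(colnames(sce), fc$qc$barcode)]

  sce <- normalize_log(sce, size_factor = config$size_factor)

  dbl <- remove_hormone_doublets(sce,
                                 ins_threshold = config$ins_doublet_threshold,
                                 gcg_threshold = config$gcg_doublet_threshold,
                                 marker_table = config$marker_table,
                                 positive_level = config$positive_level)
  sce <- dbl$sce
  if (nrow(dbl$dropped)) {
    ledger$doublet <- data.frame(barcode = dbl$dropped$barcode,
                                 stage = "doublet", reason = dbl$dropped$rule,
                                 stringsAsFactors = FALSE)
  }

  # swap in ambient-corrected counts for the retained cells
  if (!is.null(corrected)) {
    SummarizedExperiment::assay(sce, "counts") <-
      corrected[rownames(sce), colnames(sce), drop = FALSE]
    sce <- normalize_log(sce, size_factor = config$size_factor)
  }

  if (config$run_cluster) {
    sce <- embed_and_cluster(sce, n_hvg = config$n_hvg, n_pcs = config$n_pcs,
                             resolution = config$resolution,
                             knn_k = config$knn_k, seed = config$seed)
    sce <- annotate_clusters(sce, marker_table = config$marker_table)
    if ("PPY" %in% rownames(sce)) {
      sce <- select_rare_cells(sce, "delta", "PPY", "gamma",
                               threshold = config$tf_threshold)
    }
    if ("GHRL" %in% rownames(sce)) {
      sce <- select_rare_cells(sce, "delta", "GHRL", "epsilon",
                               threshold = config$tf_threshold)
    }
  }

  tf_groups <- list()
  dotplots <- list()
  group_tests <- list()
  cd <- SummarizedExperiment::colData(sce)
  for (ty in names(config$tf_pairs)) {
    if (!ty %in% cd$cell_type) next
    pair <- config$tf_pairs[[ty]]
    if (!all(pair %in% rownames(sce))) next
    res <- binarize_and_classify(sce, pair[1], pair[2], cell_type = ty,
                                 threshold = config$tf_threshold)
    tf_groups[[ty]] <- res
    panel <- intersect(as_gene_panel(config$gene_panel)$gene, rownames(sce))
    if (length(panel)) {
      dotplots[[ty]] <- dotplot_stats(sce, res, panel)
      if (sum(res$counts >= 3) >= 2 && res$counts[["Both"]] >= 3) {
        group_tests[[ty]] <- compare_groups(sce, res, panel, min_cells = 3L)
      }
    }
  }

  concordance <- NULL
  if (!is.null(config$bulk_alpha) && !is.null(config$bulk_beta)) {
    concordance <- de_and_fc_concordance(config$bulk_alpha, config$bulk_beta, sce)
  }
  ephys <- NULL
  if (!is.null(config$ephys_table)) {
    ephys <- compare_ephys_groups(config$ephys_table)
  }

  ledger <- if (length(ledger)) do.call(rbind, unname(ledger)) else
    data.frame(barcode = character(0), stage = character(0),
               reason = character(0), stringsAsFactors = FALSE)
  summary <- list(
    n_input_barcodes = n_input,
    n_empty = sum(ledger$stage == "ambient"),
    n_qc_dropped = sum(ledger$stage == "qc"),
    n_doublet_dropped = sum(ledger$stage == "doublet"),
    n_retained = ncol(sce),
    n_ambient_genes = length(ambient_genes),
    cells_per_type = if ("cell_type" %in%
                         names(SummarizedExperiment::colData(sce))) {
      as.list(table(SummarizedExperiment::colData(sce)$cell_type))
    } else NULL,
    tf_fractions = lapply(tf_groups, function(r) as.list(r$fractions)),
    thresholds = config[c("ambient_umi_cutoff", "ambient_prominence",
                          "min_genes", "max_genes", "max_mito_fraction",
                          "min_cells_per_gene", "size_factor",
                          "ins_doublet_threshold", "gcg_doublet_threshold",
                          "positive_level", "n_hvg", "n_pcs", "resolution",
                          "knn_k", "tf_threshold", "seed")]
  )
  stopifnot(summary$n_input_barcodes ==
              summary$n_retained + nrow(ledger))

  if (!is.null(out_dir)) {
    utils::write.table(fc$qc, file.path(out_dir, "qc_table.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(ledger, file.path(out_dir, "drop_ledger.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cell_table <- as.data.frame(SummarizedExperiment::colData(sce))
    utils::write.table(cell_table, file.path(out_dir, "cell_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (ty in names(group_tests)) {
      utils::write.table(group_tests[[ty]],
                         file.path(out_dir, paste0("group_tests_", ty, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    for (ty in names(dotplots)) {
      utils::write.table(dotplots[[ty]],
                         file.path(out_dir, paste0("dotplot_", ty, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
  }

  invisible(list(sce = sce, summary = summary, ledger = ledger, qc = fc$qc,
                 tf_groups = tf_groups, dotplot = dotplots,
                 group_tests = group_tests, concordance = concordance,
                 ephys = ephys, ambient_genes = ambient_genes))
}
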