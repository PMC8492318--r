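#' Configuration for the islet single-cell simulator
#'
#' Builds and validates the configuration driving [simulate_dataset()].
#' Defaults emulate a dispersed human-islet 10x run: ten cell types with
#' alpha/beta dominance, hormone genes carrying a large share of each
#' endocrine cell's library, bimodal on/off transcription-factor states
#' for ARX/MAFB (alpha) and MAFA/MAFB (beta), a functional gene program
#' coupled to the dual-positive state, multiplicative donor effects,
#' ambient contamination drawn from the pooled cell profile, two-cell
#' doublet barcodes, and empty droplets carrying only ambient counts.
#'
#' @param seed Integer seed; identical configurations produce identical
#'   datasets.
#' @param n_cells_per_type Named integer vector of cells per type.
#' @param n_genes Total number of genes (named genes plus background).
#' @param marker_table Cell-type marker table (see
#'   [default_marker_table()]).
#' @param tf_pairs Named list mapping a cell type to its TF pair
#'   `c(gene_a, gene_b)`.
#' @param tf_on_fractions Named list mapping each paired type to a
#'   4-vector of group probabilities in the order None, A-only, B-only,
#'   Both; each must sum to 1.
#' @param program_effect Fold change (> 0) applied to functional-program
#'   genes in dual-positive ("Both") cells; 1 disables the coupling.
#' @param nb_dispersion Negative-binomial dispersion (1/size); must be
#'   positive.
#' @param library_size_lognormal `c(meanlog, sdlog)` of per-cell library
#'   sizes.
#' @param mito_fraction_beta_params `c(a, b)` of the Beta distribution of
#'   per-cell mitochondrial fractions.
#' @param ambient_fraction Proportion of each cell's expected counts drawn
#'   from the pooled ambient profile.
#' @param doublet_rate Proportion of cell barcodes that are two-cell
#'   mixtures.
#' @param n_donors Number of donors; donor effects are gene-level
#'   lognormal factors with `donor_sigma`.
#' @param donor_sigma Log-sd of the donor batch factors.
#' @param n_empty_droplets Number of cell-free barcodes.
#' @param empty_umi_cap Maximum total UMI of an empty droplet.
#' @param tf_on_mean,tf_off_mean Expected TF counts (at the reference
#'   library size) in the on and off states. The off state is a small
#'   epsilon rather than exactly zero so that dropout and true absence
#'   remain distinguishable.
#' @param profile_seed Seed for the background gene-abundance profile.
#'   The relative transcriptome is a fixed property of the simulated
#'   tissue, so it is drawn from its own seed: datasets generated with
#'   different run seeds share gene profiles (as biological replicates
#'   of one tissue would) while cells, donors and counts are resampled.
#' @return A validated object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_cells_per_type = c(
                         alpha = 1080L, beta = 480L, delta = 50L,
                         gamma = 12L, epsilon = 4L, acinar = 66L,
                         ductal = 94L, endothelial = 44L,
                         stellate = 154L, immune = 16L
                       ),
                       n_genes = 600L,
                       marker_table = default_marker_table(),
                       tf_pairs = list(
                         alpha = c("ARX", "MAFB"),
                         beta = c("MAFA", "MAFB")
                       ),
                       tf_on_fractions = list(
                         alpha = c(0.10, 0.04, 0.48, 0.38),
                         beta = c(0.22, 0.04, 0.52, 0.22)
                       ),
                       program_effect = 2,
                       nb_dispersion = 0.1,
                       library_size_lognormal = c(meanlog = log(5000), sdlog = 0.35),
                       mito_fraction_beta_params = c(2.5, 47.5),
                       ambient_fraction = 0.02,
                       doublet_rate = 0.03,
                       n_donors = 5L,
                       donor_sigma = 0.1,
                       n_empty_droplets = 500L,
                       empty_umi_cap = 80,
                       tf_on_mean = 10,
                       tf_off_mean = 0.01,
                       profile_seed = 7151L) {
  cfg <- list(
    seed = as.integer(seed),
    n_cells_per_type = n_cells_per_type,
    n_genes = as.integer(n_genes),
    marker_table = check_marker_table(marker_table),
    tf_pairs = tf_pairs,
    tf_on_fractions = tf_on_fractions,
    program_effect = program_effect,
    nb_dispersion = nb_dispersion,
    library_size_lognormal = library_size_lognormal,
    mito_fraction_beta_params = mito_fraction_beta_params,
    ambient_fraction = ambient_fraction,
    doublet_rate = doublet_rate,
    n_donors = as.integer(n_donors),
    donor_sigma = donor_sigma,
    n_empty_droplets = as.integer(n_empty_droplets),
    empty_umi_cap = empty_umi_cap,
    tf_on_mean = tf_on_mean,
    tf_off_mean = tf_off_mean,
    profile_seed = as.integer(profile_seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

tf_group_levels <- c("None", "A-only", "B-only", "Both")

validate_sim_config <- function(cfg) {
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be positive")
  if (any(cfg$n_cells_per_type < 0)) stop("cell counts must be non-negative")
  if (is.null(names(cfg$n_cells_per_type))) stop("n_cells_per_type must be named")
  for (frac in c(cfg$ambient_fraction, cfg$doublet_rate)) {
    if (frac < 0 || frac > 1) stop("fractions must lie in [0, 1]")
  }
  for (ty in names(cfg$tf_on_fractions)) {
    f <- cfg$tf_on_fractions[[ty]]
    if (length(f) != 4L || any(f < 0) || any(f > 1)) {
      stop("tf_on_fractions must be 4-vectors of probabilities")
    }
    if (abs(sum(f) - 1) > 1e-9) {
      stop("tf_on_fractions for '", ty, "' must sum to 1")
    }
    if (!ty %in% names(cfg$tf_pairs)) {
      stop("tf_on_fractions given for '", ty, "' but no TF pair defined")
    }
  }
  named <- length(sim_gene_universe(cfg)$named)
  if (cfg$n_genes < named) {
    stop("n_genes must be at least ", named,
         " (markers, hormones, TFs, program and mitochondrial genes)")
  }
  invisible(cfg)
}

# Functional gene program coupled to dual-positive TF states: genes drawn
# from the ion-flux / glucose-metabolism / trafficking / exocytosis blocks
# the four-way groups are contrasted on.
default_program_genes <- function() {
  c("ABCC8", "KCNJ6", "KCNK16", "KCTD12", "ACLY", "PKM", "G6PC2",
    "GPX3", "GSTA4", "VAMP2", "SYT7", "PCLO", "TSPAN7", "RGS9")
}

mito_gene_set <- c("MT-ND1", "MT-CO1", "MT-CO2", "MT-ATP6", "MT-CYB")
mito_gene_props <- c(0.30, 0.25, 0.20, 0.15, 0.10)
hormone_genes <- c(
  alpha = "GCG", beta = "INS", delta = "SST",
  gamma = "PPY", epsilon = "GHRL"
)

sim_gene_universe <- function(cfg) {
  tf_genes <- unique(unlist(cfg$tf_pairs))
  named <- unique(c(
    unname(hormone_genes), tf_genes, cfg$marker_table$gene,
    default_program_genes(), mito_gene_set
  ))
  n_bg <- cfg$n_genes - length(named)
  bg <- if (n_bg > 0) sprintf("BG%04d", seq_len(n_bg)) else character(0)
  genes <- c(named, bg)
  class_of <- rep("background", length(genes))
  names(class_of) <- genes
  class_of[intersect(genes, unname(hormone_genes))] <- "hormone"
  class_of[intersect(genes, cfg$marker_table$gene)] <- "marker"
  class_of[intersect(genes, unname(hormone_genes))] <- "hormone"
  class_of[intersect(genes, default_program_genes())] <- "program"
  class_of[intersect(genes, tf_genes)] <- "tf"
  class_of[intersect(genes, mito_gene_set)] <- "mito"
  list(genes = genes, named = named, background = bg, class_of = class_of,
       tf_genes = tf_genes)
}

# Relative (unnormalized) expression weights per type, excluding
# mitochondrial and TF genes which are handled per cell.
sim_base_weights <- function(cfg, universe) {
  genes <- universe$genes
  types <- names(cfg$n_cells_per_type)
  W <- matrix(0, length(genes), length(types),
              dimnames = list(genes, types))
  bg_w <- stats::rlnorm(length(universe$background), meanlog = 0, sdlog = 1)
  W[universe$background, ] <- bg_w
  hormone_w <- c(alpha = 400, beta = 450, delta = 300, gamma = 300, epsilon = 250)
  for (ty in intersect(names(hormone_genes), types)) {
    W[hormone_genes[[ty]], ty] <- hormone_w[[ty]]
  }
  mk <- cfg$marker_table
  for (i in seq_len(nrow(mk))) {
    if (mk$cell_type[i] %in% types && mk$gene[i] %in% genes &&
        !(mk$gene[i] %in% hormone_genes)) {
      W[mk$gene[i], mk$cell_type[i]] <- 40
    }
  }
  prog <- intersect(default_program_genes(), genes)
  for (ty in types) {
    W[prog, ty] <- if (ty %in% names(cfg$tf_pairs)) 4 else 1
  }
  W[mito_gene_set, ] <- 0
  W[universe$tf_genes, ] <- 0
  W
}

#' Simulate an islet-like droplet scRNA-seq dataset with ground truth
#'
#' Draws UMI counts for a multi-donor mixture of islet cell types from a
#' negative-binomial model with type-specific gene means, bimodal TF
#' on/off states coupled to a functional gene program in dual-positive
#' cells, gene-level donor factors, ambient contamination shared across
#' all barcodes, planted two-cell doublets, and empty droplets. Ground
#' truth (cell type, TF group, doublet flag, donor, ambient profile) is
#' carried in the returned object's column data and metadata.
#'
#' @param config A [sim_config()] object.
#' @return A [SingleCellExperiment::SingleCellExperiment] with a sparse
#'   `counts` assay (genes x barcodes, cells followed by empty droplets),
#'   ground-truth columns in `colData`, gene classes in `rowData`, and the
#'   configuration, ambient profile and program gene list in `metadata`.
#' @examples
#' cfg <- sim_config(n_cells_per_type = c(alpha = 50, beta = 30),
#'                   n_genes = 120, n_empty_droplets = 40)
#' sce <- simulate_dataset(cfg)
#' table(sce$cell_type)
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  withr::with_seed(config$seed, simulate_dataset_impl(config))
}

simulate_dataset_impl <- function(cfg) {
  universe <- sim_gene_universe(cfg)
  genes <- universe$genes
  n_genes <- length(genes)
  types <- names(cfg$n_cells_per_type)
  n_cells <- sum(cfg$n_cells_per_type)
  if (n_cells == 0L) stop("no cells requested")

  W <- withr::with_seed(cfg$profile_seed, sim_base_weights(cfg, universe))
  donor_f <- matrix(
    stats::rlnorm(n_genes * cfg$n_donors, meanlog = 0, sdlog = cfg$donor_sigma),
    n_genes, cfg$n_donors, dimnames = list(genes, NULL)
  )
  donor_f[mito_gene_set, ] <- 1

  cell_type <- rep(types, times = cfg$n_cells_per_type)
  donor <- sample.int(cfg$n_donors, n_cells, replace = TRUE)
  tf_group <- rep(NA_character_, n_cells)
  for (ty in names(cfg$tf_pairs)) {
    idx <- which(cell_type == ty)
    if (length(idx) && !is.null(cfg$tf_on_fractions[[ty]])) {
      tf_group[idx] <- sample(tf_group_levels, length(idx), replace = TRUE,
                              prob = cfg$tf_on_fractions[[ty]])
    }
  }

  lib <- stats::rlnorm(n_cells, cfg$library_size_lognormal[[1]],
                       cfg$library_size_lognormal[[2]])
  mito_f <- stats::rbeta(n_cells, cfg$mito_fraction_beta_params[[1]],
                         cfg$mito_fraction_beta_params[[2]])

  # Expected proportions per (type, tf_group) combo; donor factors applied
  # per cell below. TF shares are relative to the reference library size.
  lib_ref <- exp(cfg$library_size_lognormal[[1]])
  s_on <- cfg$tf_on_mean / lib_ref
  s_off <- cfg$tf_off_mean / lib_ref
  prog <- intersect(default_program_genes(), genes)

  combo_key <- paste(cell_type, ifelse(is.na(tf_group), ".", tf_group), sep = "|")
  combos <- unique(combo_key)
  P <- matrix(0, n_genes, length(combos), dimnames = list(genes, combos))
  for (cb in combos) {
    parts <- strsplit(cb, "|", fixed = TRUE)[[1]]
    ty <- parts[1]; grp <- parts[2]
    w <- W[, ty]
    if (grp == "Both") w[prog] <- w[prog] * cfg$program_effect
    q <- w / sum(w)
    if (ty %in% names(cfg$tf_pairs) && grp != ".") {
      pair <- cfg$tf_pairs[[ty]]
      sa <- if (grp %in% c("A-only", "Both")) s_on else s_off
      sb <- if (grp %in% c("B-only", "Both")) s_on else s_off
      q <- q * (1 - sa - sb)
      q[pair[1]] <- sa
      q[pair[2]] <- sb
    }
    P[, cb] <- q
  }

  p_cells <- P[, match(combo_key, combos), drop = FALSE] *
    donor_f[, donor, drop = FALSE]
  p_cells <- sweep(p_cells, 2, colSums(p_cells), "/")
  # fold in mitochondrial fraction
  p_cells <- sweep(p_cells, 2, 1 - mito_f, "*")
  p_cells[mito_gene_set, ] <- outer(mito_gene_props, mito_f)

  mu <- sweep(p_cells, 2, lib, "*")
  ambient_profile <- rowSums(mu) / sum(mu)
  if (cfg$ambient_fraction > 0) {
    mu <- (1 - cfg$ambient_fraction) * mu +
      cfg$ambient_fraction * outer(ambient_profile, lib)
  }

  counts <- matrix(
    stats::rnbinom(length(mu), mu = as.numeric(mu), size = 1 / cfg$nb_dispersion),
    n_genes, n_cells
  )

  # two-cell doublets: add a sampled partner's counts onto the barcode
  is_doublet <- rep(FALSE, n_cells)
  partner_type <- rep(NA_character_, n_cells)
  partner_index <- rep(NA_integer_, n_cells)
  n_dbl <- round(cfg$doublet_rate * n_cells)
  if (n_dbl > 0 && n_cells >= 2) {
    dbl <- sample.int(n_cells, n_dbl)
    partner <- vapply(dbl, function(i) {
      j <- sample.int(n_cells, 1L)
      while (j == i) j <- sample.int(n_cells, 1L)
      j
    }, integer(1))
    counts[, dbl] <- counts[, dbl] + counts[, partner]
    is_doublet[dbl] <- TRUE
    partner_type[dbl] <- cell_type[partner]
    partner_index[dbl] <- partner
  }

  # empty droplets: pure ambient, small totals
  n_empty <- cfg$n_empty_droplets
  if (n_empty > 0) {
    empty_tot <- pmax(1, round(stats::runif(n_empty, 5, cfg$empty_umi_cap)))
    empty_counts <- vapply(
      empty_tot,
      function(t) stats::rmultinom(1, t, ambient_profile)[, 1],
      integer(n_genes)
    )
  } else {
    empty_counts <- matrix(0L, n_genes, 0)
  }

  barcodes <- c(sprintf("CELL%05d", seq_len(n_cells)),
                if (n_empty > 0) sprintf("EMPTY%04d", seq_len(n_empty)))
  mat <- cbind(counts, empty_counts)
  dimnames(mat) <- list(genes, barcodes)
  mat <- methods::as(Matrix::Matrix(mat, sparse = TRUE), "CsparseMatrix")

  cd <- S4Vectors::DataFrame(
    barcode = barcodes,
    cell_type = c(cell_type, rep("empty", n_empty)),
    donor = c(paste0("D", donor), rep(NA_character_, n_empty)),
    tf_group = c(tf_group, rep(NA_character_, n_empty)),
    is_doublet = c(is_doublet, rep(FALSE, n_empty)),
    partner_type = c(partner_type, rep(NA_character_, n_empty)),
    partner_index = c(partner_index, rep(NA_integer_, n_empty)),
    true_library = c(lib, if (n_empty > 0) empty_tot else numeric(0)),
    true_mito_fraction = c(mito_f, rep(NA_real_, n_empty)),
    row.names = barcodes
  )
  rd <- S4Vectors::DataFrame(
    gene_id = genes,
    gene_symbol = genes,
    gene_class = unname(universe$class_of[genes]),
    row.names = genes
  )
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = mat),
    colData = cd,
    rowData = rd,
    metadata = list(
      sim_config = cfg,
      ambient_profile = ambient_profile,
      program_genes = prog,
      tf_pairs = cfg$tf_pairs
    )
  )
}

#' Matched bulk profile from simulated cells
#'
#' Aggregates raw counts over the non-doublet cells of one type and
#' rescales to transcripts per million, emulating a FACS-sorted bulk
#' library of the same population.
#'
#' @param sce A simulated dataset from [simulate_dataset()], or any
#'   `SingleCellExperiment` with a `counts` assay and a `cell_type`
#'   column.
#' @param cell_type The type to aggregate.
#' @param exclude_doublets Drop barcodes flagged `is_doublet` (default
#'   TRUE; ignored when the column is absent).
#' @return Named numeric vector of TPM values (sums to 1e6).
#' @export
simulate_bulk <- function(sce, cell_type, exclude_doublets = TRUE) {
  cd <- SummarizedExperiment::colData(sce)
  if (!cell_type %in% cd$cell_type) {
    stop("unknown cell type '", cell_type, "'")
  }
  keep <- cd$cell_type == cell_type
  if (exclude_doublets && "is_doublet" %in% names(cd)) {
    keep <- keep & !cd$is_doublet
  }
  if (!any(keep)) stop("no cells of type '", cell_type, "' after doublet exclusion")
  s <- Matrix::rowSums(SummarizedExperiment::assay(sce, "counts")[, keep, drop = FALSE])
  1e6 * s / sum(s)
}

default_ephys_baselines <- function() {
  c(
    cell_size_pF = 5.5,
    exocytosis_early_fF_pF = 20,
    exocytosis_late_fF_pF = 30,
    ca_current_early_pA_pF = 8,
    ca_current_late_pA_pF = 4,
    ca_conductance_late_nS_pF = 0.5,
    na_current_pA_pF = 30
  )
}

#' Default TF-group effects on electrophysiology features
#'
#' Dual-positive ("Both") cells are shifted upward on early exocytosis and
#' the calcium current/conductance features, while cell size is left
#' unshifted in every group (the null feature). Shifts are expressed in
#' units of the simulation noise SD.
#' @return Named list mapping feature to a named vector of per-group
#'   shifts.
#' @export
default_ephys_effects <- function() {
  list(
    exocytosis_early_fF_pF = c(Both = 1.5),
    ca_current_early_pA_pF = c(Both = 1.5),
    ca_current_late_pA_pF = c(Both = 1.5),
    ca_conductance_late_nS_pF = c(Both = 1.5)
  )
}

#' Simulate a Patch-Seq style electrophysiology table
#'
#' Gaussian features with TF-group-specific mean shifts for a set of cells
#' with known group labels. Features include cell size, early/late
#' exocytosis, early/late Ca2+ current, late Ca2+ conductance and Na+
#' current; by default only the "Both" group is shifted and cell size is
#' identical across groups.
#'
#' @param groups Character vector of TF group labels (one per cell), or a
#'   data.frame with columns `tf_group` and optionally `donor`.
#' @param effect_map Named list: feature -> named vector of per-group mean
#'   shifts in units of `noise_sd`. See [default_ephys_effects()].
#' @param noise_sd Non-negative Gaussian noise SD applied to every
#'   feature.
#' @param seed Integer seed.
#' @param baselines Named vector of feature baselines.
#' @return data.frame with `tf_group`, optional `donor`, and one column
#'   per feature.
#' @export
simulate_ephys <- function(groups, effect_map = default_ephys_effects(),
                           noise_sd = 1, seed = 1L,
                           baselines = default_ephys_baselines()) {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  donor <- NULL
  if (is.data.frame(groups)) {
    donor <- groups$donor
    groups <- groups$tf_group
  }
  groups <- as.character(groups)
  n <- length(groups)
  withr::with_seed(as.integer(seed), {
    out <- data.frame(tf_group = groups, stringsAsFactors = FALSE)
    if (!is.null(donor)) out$donor <- donor
    for (feat in names(baselines)) {
      shift <- rep(0, n)
      fx <- effect_map[[feat]]
      if (!is.null(fx)) {
        for (g in names(fx)) shift[groups == g] <- fx[[g]] * noise_sd
      }
      out[[feat]] <- baselines[[feat]] + shift + stats::rnorm(n, 0, noise_sd)
    }
    out
  })
}

#' Simulate a two-channel marker-intensity table
#'
#' Bimodal (low/high) per-cell immunofluorescence intensities for two
#' markers, with planted four-way population fractions, for exercising
#' [classify_intensity()].
#'
#' @param n_cells Number of cells.
#' @param fractions 4-vector of planted fractions in the order lo/lo,
#'   hi/lo, lo/hi, hi/hi (must sum to 1).
#' @param n_donors Number of donors; cells assigned uniformly.
#' @param lo_mean,hi_mean,sd Gaussian parameters of the low and high
#'   intensity modes (shared by both channels).
#' @param seed Integer seed.
#' @return data.frame with `donor`, `marker_a`, `marker_b`, and the
#'   planted `true_label`.
#' @export
simulate_intensity <- function(n_cells, fractions, n_donors = 3L,
                               lo_mean = 2, hi_mean = 10, sd = 1.5,
                               seed = 1L) {
  # allow rounded percentage sets (e.g. 41/19/9/30) that sum to 99-101%
  if (abs(sum(fractions) - 1) > 0.02) stop("fractions must sum to 1")
  fractions <- fractions / sum(fractions)
  labels <- c("lo/lo", "hi/lo", "lo/hi", "hi/hi")
  withr::with_seed(as.integer(seed), {
    lab <- sample(labels, n_cells, replace = TRUE, prob = fractions)
    a_hi <- lab %in% c("hi/lo", "hi/hi")
    b_hi <- lab %in% c("lo/hi", "hi/hi")
    data.frame(
      donor = paste0("D", sample.int(n_donors, n_cells, replace = TRUE)),
      marker_a = stats::rnorm(n_cells, ifelse(a_hi, hi_mean, lo_mean), sd),
      marker_b = stats::rnorm(n_cells, ifelse(b_hi, hi_mean, lo_mean), sd),
      true_label = lab,
      stringsAsFactors = FALSE
    )
  })
}
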