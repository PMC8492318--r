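# isletTF

Stratification of pancreatic islet α and β cells into combinatorial
transcription-factor (TF) subpopulations from droplet single-cell
RNA-seq.

## The scientific problem

Islet-enriched transcription factors control the identity and secretory
competence of the endocrine pancreas: ARX and MAFB in glucagon-secreting
α cells, MAFA and MAFB in insulin-secreting β cells. In droplet
scRNA-seq these factors show *bimodal* detection — within one islet
preparation there is always a clear subpopulation of α or β cells in
which a given factor is not detected at all. Scoring each cell for a
*pair* of factors therefore splits a lineage into four combinatorial
groups, and the dual-positive group is enriched for glucose-sensing,
ion-flux and exocytosis gene programs — a signature of functionally
mature cells that extends to electrophysiology in Patch-Seq data.

`isletTF` is for computational biologists who want to run, audit or
extend this analysis. It implements the complete chain:

1. **Ambient-RNA correction** — empty droplets (≤ 100 total UMI) define
   an ambient pool; prominent ambient genes have their expected ambient
   count (pool proportion × cell total, round-half-up, clipped at 0)
   subtracted wherever the observed count is consistent with a purely
   ambient origin.
2. **QC filters** — cells with 200–4000 detected genes and < 10%
   mitochondrial UMIs; genes detected in ≥ 3 retained cells.
3. **Normalization** — per cell, `ln(count / total × 10⁴ + 1)`.
4. **Hormone-doublet removal** — cells coexpressing INS > 6.5 and
   GCG > 5.0 (normalized log units), or expressing INS/GCG together with
   another lineage's marker, are dropped with the triggering rule
   recorded.
5. **Clustering and annotation** — HVG selection, mito-regressed
   scaling, PCA, kNN graph, seeded Louvain at resolution 0.6; clusters
   labelled by z-scored marker means; γ/ε cells recovered from the δ
   cluster by a PPY/GHRL positivity rule.
6. **TF stratification** (the core) — a factor is *detected* when its
   normalized value exceeds 0.5; the joint status of the pair assigns
   None / A-only / B-only / Both, with pooled and per-donor fractions,
   dot-plot summaries (% detected, mean expression, z-score across
   groups), and Mann-Whitney group tests with Benjamini-Hochberg
   adjustment. A hi/lo intensity classifier provides the
   immunofluorescence analogue.
7. **Concordance** — bulk (TPM) versus pseudobulk (mean UMI) expression
   correlation under detection filters (log₂TPM > 1, UMI > 1), and
   paired α-vs-β differential-expression fold-change concordance.
8. **Electrophysiology** — Mann-Whitney/BH comparison of Patch-Seq
   features (exocytosis, Ca²⁺ currents, conductance, cell size) across
   TF groups.

A negative-binomial simulator (`simulate_dataset()`) generates
islet-like data with complete ground truth — cell types, TF states,
doublets, ambient profile, donors — so every stage is testable offline.

## Worked example

```r
library(isletTF)

cfg  <- sim_config(seed = 1)                 # 2,000 cells + 500 empty droplets
pipe <- pipeline_config(sim = cfg, seed = 1)
res  <- run_pipeline(pipe, out_dir = "run1")

res$tf_groups$alpha
#> TF group classification: ARX / MAFB (threshold 0.50)
#>   797 cells of type alpha
#>   None A-only B-only   Both
#> 0.0991 0.0477 0.4918 0.3614

res$tf_groups$beta
#> TF group classification: MAFA / MAFB (threshold 0.50)
#>   433 cells of type beta
#>   None A-only B-only   Both
#> 0.2055 0.0416 0.4942 0.2587
```

The α cells split into 9.9% dual-negative, 4.8% ARX-only, 49.2%
MAFB-only and 36.1% dual-positive — recovering the fractions the
simulator planted (10/4/48/38) within binomial error; the β split
recovers 22/4/52/22 the same way. The run directory contains the QC
table, a drop ledger accounting for every input barcode
(2,500 = 1,818 retained + 500 empty + 150 QC + 32 doublets in this run),
per-group test tables and a `summary.json` of all thresholds used.

Group tests on a functional gene panel show the dual-positive
enrichment:

```r
panel <- read_gene_panel(system.file("extdata", "beta_function_panel.tsv",
                                     package = "isletTF"))
gt <- compare_groups(res$sce, res$tf_groups$beta, panel)
head(gt[order(gt$p_adj), c("gene", "group2", "median1", "median2", "p_adj", "stars")])
#>     gene group2 median1 median2    p_adj stars
#> 27   PKM B-only    4.04    3.38 6.52e-24    **
#> 42  SYT7 B-only    3.95    3.33 6.52e-24    **
#> 24  ACLY B-only    3.89    3.22 1.38e-23    **
```

`median1` is the Both group: the program genes run roughly 2-fold higher
in dual-positive cells, exactly as planted (`program_effect = 2`).

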