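# lymphtraj

Donor-aware single-cell RNA-seq analysis of peripheral lymphoid cells
across clinical sepsis trajectories.

Sepsis survivors follow distinct courses: some recover rapidly (RAP),
others enter chronic critical illness (CCI, ≥14 ICU days with persistent
organ dysfunction), a trajectory associated with lymphocyte exhaustion
and poor outcomes. Comparing these groups with droplet scRNA-seq raises
a statistical trap: thousands of cells per patient are not independent
observations. Cells are nested within donors, and a test that ignores
this pseudoreplication will declare condition differences at many times
its nominal error rate. `lymphtraj` packages an end-to-end pipeline
built around that problem, for analysts working with cohort-structured
droplet data:

- **Droplet QC** — Monte-Carlo multinomial cell calling against an
  ambient RNA profile (cells kept at BH FDR < 0.01), artificial-doublet
  kNN scoring, and a strict `< 5%` spliced mitochondrial filter.
- **Embedding** — log-normalization (library-size or scran-style pooled
  factors), 50-component PCA, diversity-penalized linear batch
  integration, and Louvain clustering on a shared-nearest-neighbor
  graph (k = 100, resolution 0.1).
- **Consensus annotation** — six reference-based annotators
  (rank-correlation scoring with fine-tuning, plus kNN label transfer)
  vote; a cell is labeled only when the modal harmonized label exceeds
  a strict 0.80 vote fraction (5 of 6 passes, 4 of 5 does not).
- **Composition** — cohort × subtype cross-tabs with
  percent-of-cohort, per-subject fractions, ANOVA/Tukey and
  Kruskal–Wallis comparisons, division index.
- **Mixed-model DE** — the core: gene-wise REML fits of
  `y = β₀ + β₁·I(CCI) + b_donor + ε`, `b ~ N(0, τ²)`, with donor-block
  closed forms, Satterthwaite degrees of freedom, BH correction, and
  lineage-specific thresholds (B 0.5, CD8 T 0.1, NK/CD4 T 0.01).
- **Exhaustion scoring** — signed, expression-bin-matched module
  scores for curated NK and CD8 TEM exhaustion panels (TIGIT, TOX,
  LAG3, PDCD1, … up; TCF7, CD226, KLRK1 down), tested with the same
  donor-aware model.
- **Enrichment** — one-sided Fisher/hypergeometric over-representation
  of DE genes against GMT collections, universe = tested genes.
- **Synthetic cohorts** — a hierarchical negative-binomial generator
  (donors in cohorts, donor random intercepts, marker programs,
  composition shifts, mito content, empties, doublets, planted
  condition and exhaustion effects) with full ground truth, so every
  stage is benchmarked against known truth.

## Worked example

Simulate a RAP-vs-CCI cohort, run QC, and test CD8 TEM genes with the
donor-aware model:

```r
library(lymphtraj)

cfg <- sim_config(seed = 42, cohorts = c("RAP", "CCI"),
                  donors_per_cohort = c(RAP = 4, CCI = 5),
                  cells_per_donor = 200, n_genes = 1000, n_empty = 1500)
sim <- simulate_cohort(cfg)

qc <- run_qc(sim$counts, n_mc = 2000, seed = 42)
qc$summary
#> barcodes           called doublets_removed     mito_removed             kept
#>     3390             1890               92              295             1503

norm <- lognormalize(qc$filtered)
meta <- sim$truth$cells[match(qc$filtered$barcodes, sim$truth$cells$barcode), ]
meta <- data.frame(barcode = meta$barcode, donor = meta$donor,
                   cohort = meta$cohort, consensus = meta$true_type)

de <- de_celltype(norm, meta, "CD8 TEM")   # RAP reference, CCI comparison
head(de[order(de$p_adj), c("gene", "beta1", "se", "p", "p_adj", "direction")], 5)
#>      gene beta1    se        p    p_adj direction
#> 13  PDCD1 0.775 0.144 2.67e-07 0.000266        up
#> 237 G0213 0.866 0.182 4.14e-06 0.002064        up
#> 5    CD96 0.996 0.179 1.03e-04 0.023082        up
#> 8   KLRG1 0.981 0.159 1.16e-04 0.023082        up
#> 254 G0230 1.109 0.161 7.94e-05 0.023082        up
```

`beta1` is the CCI-vs-RAP log-fold effect; the generator planted
effects of 1 on a set of CD8 TEM genes and a +1 exhaustion shift on the
panel genes, and the top hits recover both (PDCD1, CD96, KLRG1 are
exhaustion-panel genes; G0213/G0230 carry planted condition effects)
with estimates near their true values.

```r
ms <- module_score(norm, cd8tem_exhaustion_panel(), seed = 42)
exhaustion_test(ms, meta, contrast = c("RAP", "CCI"), cell_types = "CD8 TEM")
#>   cell_type   contrast estimate    se   df        p    tau2 sigma2 n_cells n_donors
#> 1   CD8 TEM CCI vs RAP     1.95 0.171 7.86 3.67e-06 0.00283  0.934     164        9
```

The signed exhaustion score rises by ≈ 2 in CCI CD8 TEM cells (a +1
shift on up-genes plus a −1 shift on the down-gene contributes twice to
the signed score), tested on ~8 Satterthwaite degrees of freedom — the
donor count, not the cell count, carries the inference.

The full pipeline (simulate → qc → cluster → annotate → compose → de →
score) runs from one config: `run_pipeline(default_run_config(seed = 1,
outdir = "run1"))`, or from a shell via
`Rscript inst/scripts/lymphtraj.R --config run.yaml`.

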