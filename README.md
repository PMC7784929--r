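# sctme — single-cell tumor microenvironment analysis toolkit

`sctme` is an R package for dissecting tumor microenvironments from droplet
single-cell RNA-seq, built around the analysis style used for
nasopharyngeal-carcinoma atlases: distinguish malignant from non-malignant
epithelial cells by copy-number profiles inferred from expression, decompose
intratumoral heterogeneity into cross-tumor NMF signatures, derive
rule-based marker signatures for immune subclusters, score those signatures
in bulk cohorts and test their survival association, and test
ligand-receptor co-expression between cell clusters by label permutation.
It ships a synthetic-data generator that plants every kind of structure the
pipeline is supposed to find, so each stage is validated against known
ground truth.

## The methods in brief

* **QC / normalization** — keep cells with 201–9,000 expressed genes and
  ≤ 20% mitochondrial UMIs; log-normalize (`ln(1 + 10^4 x/total)`); regress
  total and mitochondrial counts out of each gene and standardize.
* **Clustering / annotation** — PCA on the 6,000 most variable genes
  (robust binned-dispersion ranking), SNN graph (K = 30), Louvain
  modularity; clusters annotated by curated marker-set mean expression.
* **Doublets** — simulated-doublet nearest-neighbor scoring at an expected
  rate of 0.06, plus iterative removal of subclusters that co-express two
  major-type marker sets.
* **Inferred CNV** — `log2(TPM+1)`, per-cell centering, 101-gene moving
  average within chromosomes, normal-reference subtraction, clipping to
  ±1 with a (−0.3, 0.3) dead zone; per tumor, two-way Ward clustering
  against normal epithelium calls each cell malignant or non-malignant,
  and tumors with < 50 malignant cells are not retained.
* **Malignant signatures** — per-tumor NMF (k = 4, Frobenius multiplicative
  updates, NNDSVD init) on centered non-negative expression; metagenes
  clustered across tumors by 1 − Pearson distance; each group consolidated
  by averaging its members' top-100 loadings and keeping the top 30 genes.
* **Immune markers** — a gene marks a subcluster iff its mean is > 2.5-fold
  the other subclusters of the type, detected in > 25% of its cells, and
  strictly the type-wide maximum.
* **Bulk survival** — ssGSEA (rank-weight exponent 0.25) on genes expressed
  in ≥ 50% of samples, median split, Kaplan-Meier/log-rank and
  covariate-adjusted Cox (age, sex, smoking, stage).
* **Interactions** — for cluster pairs where ligand and receptor are each
  detected in > 10% of cells, T = (mean ligand in sender + mean receptor in
  receiver)/2, with p = share of 1,000 joint label permutations exceeding T.

## Worked example

Simulate a two-tumor dataset with a normal control, call malignant cells
from inferred CNV profiles, and test a planted prognostic signature in a
simulated bulk cohort:

```r
library(sctme)

cfg <- sim_config(n_samples = 2, cells_per_sample = 300, n_genes = 1000,
                  seed = 1)
ds  <- simulate_sc_dataset(cfg)
ds$cm
#> CountMatrix: 1000 genes x 954 cells, 3 samples, 461646 stored entries

qs  <- qc_filter(ds$cm)
nm  <- normalize_and_scale(qs$cm)
cl  <- cluster_cells(nm, select_hvg(nm, 500), K = 30, seed = 0)
annotate_major_types(nm, cl, ds$truth$type_markers)$cluster_type
#>            1            2            3            4            5            6
#>          "T" "epithelial"          "B" "fibroblast"    "myeloid" "epithelial"

meta <- qs$cm$cell_meta
epi  <- subset_cells(qs$cm, which(meta$major_type == "epithelial"))
ref  <- epi$cell_meta$cell_id[epi$cell_meta$sample_id == "N01"]
prof <- infer_cnv_profile(epi, ds$positions, ref)
calls <- classify_malignant(prof, setNames(epi$cell_meta$sample_id,
                                           epi$cell_meta$cell_id), "N01")
calls$tumor_summary
#>     sample_id n_cells n_malignant retained resolved
#> T01       T01     108          64     TRUE     TRUE
#> T02       T02     117          78     TRUE     TRUE

sigs <- signature_set(list(malig = sprintf("g%04d", 300:340)))
bk   <- simulate_bulk_cohort(cfg, sigs, effects = c(malig = 0.7))
signature_survival(bk$expr, sigs, bk$surv)
#>   signature       hr    ci_lo    ci_hi        cox_p    logrank_p n_high n_low
#> 1     malig 2.647713 1.697526 4.129764 1.761551e-05 7.843743e-06     60    60
```

The tumor summary shows both tumors retained (each with ≥ 50 malignant
cells); the generator planted a whole-chromosome gain and loss in 60% of
tumor epithelium, and the calls match that truth with balanced accuracy
above 0.95 (see the test suite). In the bulk cohort, the signature was
planted with a log-hazard ratio of 0.7 per activity SD; the high/low median
split recovers a significantly elevated hazard (HR 2.6, Cox p ≈ 2e-5).

`run_pipeline(list(seed = 1), "out/")` runs every stage in order on a
simulated dataset and writes TSV/GMT outputs plus a provenance manifest.

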