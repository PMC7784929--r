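# Shared fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Default desk-scale dataset: 2 tumors + normal, no doublets.
base_dataset <- function() cached_fixture("base", function() {
  simulate_sc_dataset(sim_config(n_samples = 2, cells_per_sample = 300,
                                 n_genes = 1000, doublet_rate = 0, seed = 1))
})

base_normalized <- function() cached_fixture("base_nm", function() {
  normalize_and_scale(base_dataset()$cm)
})

# Clustering + annotation on the base dataset.
base_annotation <- function() cached_fixture("base_ann", function() {
  ds <- base_dataset()
  nm <- base_normalized()
  cl <- cluster_cells(nm, select_hvg(nm, 500), K = 30, seed = 0)
  ann <- annotate_major_types(nm, cl, ds$truth$type_markers)
  list(clusters = cl, ann = ann)
})

# Area under the ROC curve via the rank statistic.
auroc <- function(score, positive) {
  r <- rank(score)
  np <- sum(positive)
  (mean(r[positive]) - (np + 1) / 2) / sum(!positive)
}

# A tiny CountMatrix from a dense matrix.
toy_cm <- function(m, sample_id = "s1") {
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("c%02d", seq_len(ncol(m)))
  count_matrix(m, data.frame(cell_id = colnames(m), sample_id = sample_id,
                             stringsAsFactors = FALSE))
}
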