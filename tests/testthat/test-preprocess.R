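test_that("QC boundaries follow the strict-inequality removal rules", {
  # 300 genes incl. 10 mito; three crafted cells around each boundary
  G <- 300
  genes <- c(sprintf("MT-%d", 1:10), sprintf("g%03d", 1:(G - 10)))
  make_cell <- function(n_expressed, mito_frac) {
    v <- integer(G)
    # non-mito expressed genes, one count each; mito UMIs appended on MT-1
    n_non <- n_expressed - 1
    v[10 + seq_len(n_non)] <- 1L
    total_non <- n_non
    v[1] <- round(mito_frac / (1 - mito_frac) * total_non)
    v
  }
  m <- cbind(make_cell(200, 0.05),   # too few genes
             make_cell(201, 0.20),   # exactly at both boundaries: retained
             make_cell(250, 0.21))   # mito just above 20%
  rownames(m) <- genes; colnames(m) <- c("low", "edge", "mito")
  cm <- toy_cm(m)
  met <- qc_metrics(cm)
  expect_equal(met$n_genes, c(200, 201, 250))   # includes the expressed mito gene
  expect_equal(met$mito_pct[2], 20, tolerance = 1e-6)
  res <- qc_filter(cm)
  expect_equal(colnames(res$cm$counts), "edge")
  expect_equal(res$report$removed_low_genes, 1)
  expect_equal(res$report$removed_high_mito, 1)

  # idempotence
  res2 <- qc_filter(res$cm)
  expect_identical(as.matrix(res2$cm$counts), as.matrix(res$cm$counts))

  # retained cells of a simulated dataset satisfy the machine-checkable bounds
  qs <- qc_filter(base_dataset()$cm)
  mq <- qc_metrics(qs$cm)
  expect_true(all(mq$n_genes >= 201 & mq$n_genes <= 9000))
  expect_true(all(mq$mito_pct <= 20))
})

test_that("log normalization and covariate-regressed scaling behave as specified", {
  m <- matrix(rpois(200 * 60, 3), 200,
              dimnames = list(sprintf("g%03d", 1:200), sprintf("c%02d", 1:60)))
  m[1, ] <- 0                          # all-zero gene
  cm <- toy_cm(m)
  nm <- normalize_and_scale(cm)
  # direct formula check: ln(1 + 1e4 * count / total)
  tot <- colSums(m)
  expect_equal(nm$lognorm[5, 7], unname(log1p(1e4 * m[5, 7] / tot[7])))
  # a cell with total 10,000 and count 10 maps to ln(11)
  m2 <- matrix(0L, 2, 101, dimnames = list(c("gA", "gB"), NULL))
  m2[1, ] <- c(10L, rep(1L, 100)); m2[2, ] <- c(9990L, rep(99L, 100))
  colnames(m2) <- sprintf("c%03d", 1:101)
  nm2 <- normalize_and_scale(toy_cm(m2))
  expect_equal(nm2$lognorm["gA", 1], log(11))
  # residual rows: mean ~ 0, zero-variance gene all zero
  expect_true(all(abs(rowMeans(nm$scaled)) < 1e-8))
  expect_equal(unname(nm$scaled[1, ]), rep(0, 60))
})

test_that("variable-gene selection finds a planted high-variance block with a deterministic tie rule", {
  set.seed(5)
  G <- 1000; n <- 100
  # Poisson background with a spread of means; the planted block is strongly
  # overdispersed at comparable means, interleaved across the mean bins
  lam <- rep(seq(1, 10, length.out = 50), 20)
  m <- matrix(rpois(G * n, rep(lam, n)), G,
              dimnames = list(sprintf("g%04d", 1:G), sprintf("c%03d", 1:n)))
  block_idx <- head(which(lam >= 3)[seq(1, 700, by = 14)], 50)
  block <- sprintf("g%04d", block_idx)
  m[block, ] <- matrix(rnbinom(50 * n, mu = rep(2 * lam[block_idx], n),
                               size = 0.5), 50)
  nm <- normalize_and_scale(toy_cm(m))
  hv <- select_hvg(nm, 50)
  expect_length(block, 50)
  expect_setequal(hv, block)
  # n equal to the gene count returns every gene
  expect_setequal(select_hvg(nm, G), rownames(m))
  expect_error(select_hvg(nm, G + 1), "exceeds")
  # exact ties at the cutoff resolve lexicographically
  m3 <- matrix(1L, 4, 50, dimnames = list(c("gB", "gA", "gD", "gC"), NULL))
  colnames(m3) <- sprintf("c%02d", 1:50)
  nm3 <- normalize_and_scale(toy_cm(m3))
  expect_equal(select_hvg(nm3, 2), c("gA", "gB"))
})

test_that("SNN clustering separates planted blobs and is deterministic", {
  # five clean cell-type blobs: no malignant structure, no subclusters
  blob <- simulate_sc_dataset(sim_config(
    n_samples = 1, cells_per_sample = 500, n_genes = 600,
    subclusters_per_type = c(), malignant_frac = 0, n_programs = 0,
    doublet_rate = 0, seed = 8))
  nmb <- normalize_and_scale(blob$cm)
  clb <- cluster_cells(nmb, select_hvg(nmb, 300), K = 30, seed = 0)
  truth <- blob$cm$cell_meta$major_type[match(names(clb$cluster),
                                              blob$cm$cell_meta$cell_id)]
  # adjusted Rand index against the planted types
  ari <- function(a, b) {
    tab <- table(a, b)
    sij <- sum(choose(tab, 2)); si <- sum(choose(rowSums(tab), 2))
    sj <- sum(choose(colSums(tab), 2)); sn <- choose(sum(tab), 2)
    (sij - si * sj / sn) / ((si + sj) / 2 - si * sj / sn)
  }
  expect_gte(ari(clb$cluster, truth), 0.95)
  # determinism on the richer base dataset
  ds <- base_dataset()
  nm <- base_normalized()
  cl <- base_annotation()$clusters
  cl2 <- cluster_cells(nm, select_hvg(nm, 500), K = 30, seed = 0)
  expect_identical(cl$cluster, cl2$cluster)
  # a homogeneous blob at low resolution stays one cluster
  one <- subset_cells(ds$cm, which(ds$cm$cell_meta$major_type == "T"))
  nm1 <- normalize_and_scale(one)
  cl1 <- cluster_cells(nm1, rownames(nm1$scaled), K = 30, resolution = 0.05,
                       seed = 0)
  expect_equal(length(unique(cl1$cluster)), 1L)
  expect_error(cluster_cells(nm1, K = ncol(nm1$scaled)), "fewer cells")
})

test_that("curated-set annotation recovers planted types and ties are unassigned", {
  ds <- base_dataset()
  ann <- base_annotation()$ann
  cl <- base_annotation()$clusters$cluster
  truth <- ds$cm$cell_meta$major_type[match(names(cl), ds$cm$cell_meta$cell_id)]
  # every cluster's call matches its dominant planted type
  for (k in unique(cl)) {
    dom <- names(sort(-table(truth[cl == k])))[1]
    expect_equal(unname(ann$cluster_type[as.character(k)]), dom)
  }
  expect_gte(mean(ann$cell_type == truth), 0.95)

  # exact score tie -> unassigned under the default margin
  m <- matrix(5L, 4, 30, dimnames = list(c("a1", "a2", "b1", "b2"), NULL))
  colnames(m) <- sprintf("c%02d", 1:30)
  nm <- normalize_and_scale(toy_cm(m))
  sets <- signature_set(list(A = c("a1", "a2"), B = c("b1", "b2")))
  out <- annotate_major_types(nm, rep(1L, 30), sets)
  expect_equal(unname(out$cluster_type), "unassigned")
  suppressWarnings(
    expect_error(annotate_major_types(nm, rep(1L, 30),
                                      signature_set(list(A = "zz"))),
                 "missing"))
})

test_that("doublet scores are deterministic, equal on identical cells, and rank planted doublets highly", {
  # identical cells: every score equal
  m <- matrix(2L, 150, 120, dimnames = list(sprintf("g%03d", 1:150),
                                            sprintf("c%03d", 1:120)))
  cm <- toy_cm(m)
  db0 <- score_doublets(cm, seed = 0)
  expect_equal(length(unique(db0$score)), 1L)

  ds <- simulate_sc_dataset(sim_config(n_samples = 2, cells_per_sample = 300,
                                       n_genes = 1000, doublet_rate = 0.1,
                                       seed = 1))
  db <- score_doublets(ds$cm, seed = 0)
  db2 <- score_doublets(ds$cm, seed = 0)
  expect_identical(db$score, db2$score)
  truth <- ds$cm$cell_meta$is_doublet
  expect_gte(auroc(db$score, truth), 0.9)
  # heterotypic doublets are the detectable fraction and rank near-perfectly
  het <- truth & ds$cm$cell_meta$major_type == "doublet_mix"
  keep <- het | !truth
  expect_gte(auroc(db$score[keep], het[keep]), 0.95)
})

test_that("iterative cluster-based removal excises a planted heterotypic doublet subcluster", {
  ds <- base_dataset()
  cm <- add_planted_doublets(ds$cm, "T", "B", 60,
                             subcluster_a = "T_s1", subcluster_b = "B_s1",
                             seed = 2)
  nm <- normalize_and_scale(cm)
  cl <- cluster_cells(nm, select_hvg(nm, 500), K = 30, seed = 0)
  ann <- annotate_major_types(nm, cl, ds$truth$type_markers)
  db <- score_doublets(cm, seed = 0)
  rem <- iterative_cluster_doublet_removal(cm, ann$cell_type,
                                           ds$truth$type_markers,
                                           doublet = db, seed = 0)
  planted <- cm$cell_meta$cell_id[cm$cell_meta$is_doublet]
  expect_gte(mean(planted %in% rem$removed), 0.8)
  # false removals stay rare
  expect_lt(sum(!(rem$removed %in% planted)) / (ncol(cm$counts) - length(planted)),
            0.05)
  expect_equal(rem$removed_fraction,
               length(rem$removed) / ncol(cm$counts))

  # with no doublets planted, nothing is removed
  ann0 <- base_annotation()$ann
  rem0 <- iterative_cluster_doublet_removal(ds$cm, ann0$cell_type,
                                            ds$truth$type_markers, seed = 0)
  expect_length(rem0$removed, 0)
})
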