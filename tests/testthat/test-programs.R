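test_that("NMF factorizes a rank-1 matrix exactly and is deterministic", {
  set.seed(1)
  w <- runif(60); h <- runif(25)
  A <- outer(w, h)
  dimnames(A) <- list(sprintf("g%02d", 1:60), sprintf("c%02d", 1:25))
  fit <- suppressWarnings(nmf_per_tumor(A, k = 1, min_cell_frac = 0,
                                        center = FALSE, max_iter = 2000,
                                        tol = 1e-10))
  recon <- fit$W %*% fit$H * sqrt(sum((A %*% t(fit$H))^2)) # scale-free check below
  expect_lt(tail(fit$objective, 1), 1e-6)
  # recovered loading is proportional to w (cosine 1)
  cosw <- sum(fit$metagenes[[1]]$loading * w) /
    sqrt(sum(w^2) * sum(fit$metagenes[[1]]$loading^2))
  expect_gt(cosw, 1 - 1e-8)

  fit2 <- suppressWarnings(nmf_per_tumor(A, k = 1, min_cell_frac = 0,
                                         center = FALSE, max_iter = 2000,
                                         tol = 1e-10))
  expect_equal(fit$W, fit2$W, tolerance = 1e-12)
  expect_error(nmf_per_tumor(-A, k = 1), "non-negative")
})

test_that("NMF objective is non-increasing and metagene count is tumors x k", {
  ds <- base_dataset()
  meta <- ds$cm$cell_meta
  nm <- base_normalized()
  mg <- list()
  for (tu in c("T01", "T02")) {
    mal <- meta$cell_id[meta$is_malignant & meta$sample_id == tu]
    fit <- suppressWarnings(
      nmf_per_tumor(as.matrix(nm$lognorm[, mal]), k = 4, tumor_id = tu,
                    seed = 0))
    expect_true(all(diff(fit$objective) <= 1e-8))
    expect_length(fit$metagenes, 4)
    expect_true(all(fit$W >= 0))
    mg <- c(mg, fit$metagenes)
  }
  expect_length(mg, 2 * 4)
  assign("base_metagenes", mg, envir = .fixture_cache)
})

test_that("planted orthogonal programs are matched by metagenes at high cosine", {
  ds <- cached_fixture("ortho", function() {
    simulate_sc_dataset(sim_config(
      n_samples = 1, cells_per_sample = 400, n_genes = 1000,
      doublet_rate = 0, n_programs = 4, program_alpha = 0.05,
      program_fold = 6, seed = 4))
  })
  meta <- ds$cm$cell_meta
  mal <- meta$cell_id[meta$is_malignant]
  nm <- normalize_and_scale(ds$cm)
  fit <- suppressWarnings(
    nmf_per_tumor(as.matrix(nm$lognorm[, mal]), k = 4, seed = 0))
  for (p in names(ds$truth$program_sets)) {
    pg <- ds$truth$program_sets[[p]]
    best <- max(vapply(fit$metagenes, function(m) {
      ind <- as.numeric(names(m$loading) %in% pg)
      sum(m$loading * ind) / sqrt(sum(m$loading^2) * sum(ind))
    }, 0))
    expect_gte(best, 0.9)
  }
})

test_that("metagene distances equal one minus Pearson correlation with scale invariance", {
  mk <- function(v, id, j = 1) structure(
    list(tumor_id = id, factor_index = j,
         loading = v, ranked_genes = names(sort(-v))), class = "Metagene")
  g <- sprintf("g%d", 1:5)
  a <- setNames(c(1, 2, 3, 4, 5), g)
  b <- setNames(c(5, 3, 1, 2, 4), g)
  c3 <- setNames(c(2, 2, 7, 1, 3), g)
  D <- metagene_correlation(list(mk(a, "t1"), mk(b, "t2"), mk(c3, "t3")))
  # brute-force oracle
  expect_equal(D[1, 2], 1 - cor(a, b))
  expect_equal(D[1, 3], 1 - cor(a, c3))
  expect_equal(D[2, 3], 1 - cor(b, c3))
  expect_equal(diag(D), rep(0, 3), ignore_attr = TRUE)
  # identical and scaled loadings are at distance 0
  D2 <- metagene_correlation(list(mk(a, "t1"), mk(a, "t2"), mk(2 * a, "t3")))
  expect_equal(max(abs(D2)), 0)
  # different gene universes are mapped onto the union with zero fill
  d <- setNames(c(1, 5), c("g1", "g9"))
  D3 <- metagene_correlation(list(mk(a, "t1"), mk(d, "t4")))
  au <- setNames(numeric(6), c(g, "g9")); au[g] <- a
  du <- setNames(numeric(6), c(g, "g9")); du[c("g1", "g9")] <- d
  expect_equal(D3[1, 2], 1 - cor(au, du))
  # constant loading vector: warning, distance 1
  e <- setNames(rep(2, 5), g)
  expect_warning(D4 <- metagene_correlation(list(mk(a, "t1"), mk(e, "t5"))),
                 "constant")
  expect_equal(D4[1, 2], 1)
})

test_that("metagene clustering partitions program families and is order invariant", {
  mg <- get("base_metagenes", envir = .fixture_cache)
  D <- metagene_correlation(mg)
  n <- length(mg)
  expect_equal(cluster_metagenes(D, n), setNames(1:n, colnames(D)),
               ignore_attr = TRUE)
  expect_error(cluster_metagenes(D, n + 1), "out of range")
  part <- cluster_metagenes(D, 3)
  perm <- c(5, 2, 7, 1, 8, 3, 6, 4)
  part_perm <- cluster_metagenes(metagene_correlation(mg[perm]), 3)
  # same partition up to label renaming
  expect_equal(length(unique(part)), length(unique(part_perm)))
  a <- part[colnames(D)]
  b <- part_perm[colnames(D)]
  expect_true(all(outer(a, a, "==") == outer(b, b, "==")))
})

test_that("signature consolidation follows the loading-averaging rule", {
  mk <- function(v, id, j) structure(
    list(tumor_id = id, factor_index = j, loading = v,
         ranked_genes = names(sort(-v))), class = "Metagene")
  m1 <- mk(setNames(c(0.4, 0.8), c("g1", "g2")), "t1", 1)
  m2 <- mk(setNames(c(0.6, 0.2), c("g1", "g3")), "t2", 1)
  sig <- consolidate_signature(list(m1, m2), "s")
  expect_equal(sig$loading,
               c(g1 = 0.5, g2 = 0.4, g3 = 0.1))
  expect_equal(sig$markers, c("g1", "g2", "g3"))

  # single member: identity on its positive top loadings
  sig1 <- consolidate_signature(list(m1), "s1")
  expect_equal(sig1$loading, c(g2 = 0.8, g1 = 0.4))
  expect_equal(sig1$markers, c("g2", "g1"))

  # candidate pool smaller than 30 truncates the marker list
  expect_length(sig$markers, 3)

  # consolidated loading never exceeds the member maximum
  mg <- get("base_metagenes", envir = .fixture_cache)
  sigs <- consolidate_signature(mg[1:3], "s3")
  member_max <- Reduce(pmax, lapply(mg[1:3], function(m) {
    v <- setNames(numeric(length(sigs$loading)), names(sigs$loading))
    common <- intersect(names(m$loading), names(v))
    v[common] <- m$loading[common]
    v
  }))
  expect_true(all(sigs$loading <= member_max + 1e-12))
})

test_that("cell signature scoring separates program-expressing cells and is null-calibrated", {
  ds <- cached_fixture("ortho", function() stop("built earlier"))
  meta <- ds$cm$cell_meta
  nm <- normalize_and_scale(ds$cm)
  sigs <- ds$truth$program_sets
  sc <- score_cells(nm, sigs, seed = 0)
  act <- ds$truth$program_activity
  mal <- meta$is_malignant
  for (p in colnames(act)) {
    expressing <- meta$cell_id[mal & act[, p] > 0.5]
    silent <- meta$cell_id[mal & act[, p] < 0.1]
    s <- sc$score[, p]
    lab <- c(rep(TRUE, length(expressing)), rep(FALSE, length(silent)))
    expect_gte(auroc(s[c(expressing, silent)], lab), 0.9)
  }
  # a random gene set on cells without planted structure scores ~ 0
  normals <- meta$cell_id[meta$major_type == "T"]
  nm_t <- normalize_and_scale(subset_cells(ds$cm, match(normals,
                                                        colnames(ds$cm$counts))))
  set.seed(2)
  rnd <- signature_set(list(rand = sample(rownames(nm_t$lognorm), 40)))
  sc0 <- score_cells(nm_t, rnd, seed = 1)
  expect_lt(abs(mean(sc0$score[, 1])), 0.05)
  # single gene, control disabled: score equals the scaled expression row
  one <- signature_set(list(g = rownames(nm$scaled)[500]))
  sc1 <- score_cells(nm, one, method = "mean")
  expect_equal(unname(sc1$score[, 1]), unname(nm$scaled[500, ]))
})
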