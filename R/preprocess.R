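# Cell QC, normalization/scaling, variable-gene selection, SNN clustering,
# curated-set annotation, and doublet handling.

#' QC thresholds
#'
#' Cells are retained when 201 <= expressed genes <= 9000 and the
#' mitochondrial UMI fraction is <= 20%. The bounds follow the strict
#' inequalities of the filtering rule (cells with < 201 or > 9000 expressed
#' genes, or > 20% mitochondrial UMIs, are removed), so the boundary values
#' themselves are retained.
#'
#' @param min_genes,max_genes inclusive bounds on expressed-gene count.
#' @param max_mito_pct inclusive upper bound on mitochondrial UMI percentage.
#' @param mito_prefix gene-id prefix identifying mitochondrial genes.
#' @param mito_genes optional explicit mitochondrial gene list (overrides the
#'   prefix).
#' @return list of class \code{QcThresholds}.
#' @export
qc_thresholds <- function(min_genes = 201, max_genes = 9000,
                          max_mito_pct = 20, mito_prefix = "MT-",
                          mito_genes = NULL) {
  if (min_genes >= max_genes) stop("min_genes must be < max_genes", call. = FALSE)
  if (max_mito_pct < 0 || max_mito_pct > 100)
    stop("max_mito_pct must be in [0, 100]", call. = FALSE)
  structure(list(min_genes = min_genes, max_genes = max_genes,
                 max_mito_pct = max_mito_pct, mito_prefix = mito_prefix,
                 mito_genes = mito_genes), class = "QcThresholds")
}

qc_mito_idx <- function(cm, t) {
  if (!is.null(t$mito_genes)) which(rownames(cm$counts) %in% t$mito_genes)
  else grep(paste0("^", t$mito_prefix), rownames(cm$counts))
}

#' Per-cell QC metrics
#'
#' @param cm CountMatrix.
#' @param t QcThresholds (used for mitochondrial gene identification).
#' @return data.frame with cell_id, n_genes (expressed genes), total_umi,
#'   mito_umi, mito_pct.
#' @export
qc_metrics <- function(cm, t = qc_thresholds()) {
  mito <- qc_mito_idx(cm, t)
  total <- Matrix::colSums(cm$counts)
  data.frame(cell_id = colnames(cm$counts),
             n_genes = Matrix::colSums(cm$counts > 0),
             total_umi = total,
             mito_umi = if (length(mito)) Matrix::colSums(cm$counts[mito, , drop = FALSE]) else 0,
             mito_pct = if (length(mito))
               100 * Matrix::colSums(cm$counts[mito, , drop = FALSE]) / pmax(total, 1)
             else 0,
             stringsAsFactors = FALSE)
}

#' Filter cells on QC thresholds
#'
#' @param cm CountMatrix.
#' @param t QcThresholds.
#' @return list(cm = filtered CountMatrix, report = removal counts per reason
#'   and the metrics table).
#' @export
qc_filter <- function(cm, t = qc_thresholds()) {
  m <- qc_metrics(cm, t)
  low <- m$n_genes < t$min_genes
  high <- m$n_genes > t$max_genes
  mito <- m$mito_pct > t$max_mito_pct
  keep <- !(low | high | mito)
  if (!any(keep))
    stop(paste0("no cells pass QC (", sum(low), " low-gene, ", sum(high),
                " high-gene, ", sum(mito), " high-mito)"), call. = FALSE)
  report <- list(n_input = ncol(cm$counts),
                 removed_low_genes = sum(low),
                 removed_high_genes = sum(high),
                 removed_high_mito = sum(mito & !low & !high),
                 n_retained = sum(keep),
                 metrics = m)
  list(cm = subset_cells(cm, keep), report = report)
}

#' Log-normalize and scale a count matrix
#'
#' Log normalization is \code{ln(1 + 1e4 * count / cell_total)}. Scaling then
#' regresses, per gene, the log-normalized values on per-cell total and
#' mitochondrial UMI counts and standardizes the residuals to unit variance
#' (zero-variance genes get all-zero residual rows).
#'
#' @param cm CountMatrix (QC already applied).
#' @param mito_prefix prefix identifying mitochondrial genes.
#' @param scale_max residual values clipped to +/- this bound (Inf disables).
#' @return list of class \code{NormalizedMatrix}: \code{lognorm} (sparse genes
#'   x cells), \code{scaled} (dense genes x cells residual matrix),
#'   \code{counts} (the source counts), \code{covariates} (per-cell totals
#'   regressed out).
#' @export
normalize_and_scale <- function(cm, mito_prefix = "MT-", scale_max = 10) {
  counts <- cm$counts
  total <- Matrix::colSums(counts)
  if (any(total == 0)) stop("cells with zero total counts", call. = FALSE)
  mito <- grep(paste0("^", mito_prefix), rownames(counts))
  mito_total <- if (length(mito))
    Matrix::colSums(counts[mito, , drop = FALSE]) else rep(0, ncol(counts))
  lognorm <- counts
  lognorm@x <- log1p(1e4 * lognorm@x / rep.int(total, diff(lognorm@p)))

  X <- cbind(1, total, mito_total)
  qrX <- qr(X)
  Y <- t(as.matrix(lognorm))                  # cells x genes
  resid <- Y - qr.fitted(qrX, Y)              # per-gene regression residuals
  s <- apply(resid, 2, sd)
  zero <- s < 1e-12
  resid[, !zero] <- sweep(resid[, !zero, drop = FALSE], 2, s[!zero], "/")
  resid[, zero] <- 0
  resid <- pmin(pmax(resid, -scale_max), scale_max)
  structure(list(lognorm = lognorm, scaled = t(resid), counts = counts,
                 cell_meta = cm$cell_meta,
                 covariates = data.frame(total = total, mito = mito_total)),
            class = "NormalizedMatrix")
}

#' @export
print.NormalizedMatrix <- function(x, ...) {
  cat(sprintf("NormalizedMatrix: %d genes x %d cells (log-normalized + scaled residuals)\n",
              nrow(x$lognorm), ncol(x$lognorm)))
  invisible(x)
}

#' Select highly variable genes
#'
#' Genes are ranked by the variance of log-normalized expression standardized
#' within mean-expression bins (robust z-score of the variance against its
#' bin median and MAD, so highly variable genes cannot mask each other);
#' ties break lexicographically on gene id.
#'
#' @param nm NormalizedMatrix.
#' @param n number of genes to return (default 6000, capped at the gene count
#'   by the caller; an error is raised if n exceeds it).
#' @param n_bins number of mean-expression bins.
#' @return character vector of n gene ids, ranked most variable first.
#' @export
select_hvg <- function(nm, n = 6000, n_bins = 20) {
  G <- nrow(nm$lognorm)
  if (n > G) stop("n exceeds the number of genes", call. = FALSE)
  mu <- Matrix::rowMeans(nm$lognorm)
  v <- row_vars_sparse(nm$lognorm)
  bin <- cut(rank(mu, ties.method = "first"), breaks = n_bins, labels = FALSE)
  z <- numeric(G)
  for (b in unique(bin)) {
    sel <- bin == b
    sb <- stats::mad(v[sel])
    if (is.na(sb) || sb < 1e-12) sb <- sd(v[sel])
    z[sel] <- if (is.na(sb) || sb < 1e-12) 0
              else (v[sel] - median(v[sel])) / sb
  }
  ids <- rownames(nm$lognorm)
  ids[order(-z, ids)][seq_len(n)]
}

row_vars_sparse <- function(m) {
  mu <- Matrix::rowMeans(m)
  Matrix::rowSums(m^2) / ncol(m) - mu^2
}

#' Cluster cells on an SNN graph
#'
#' PCA on the scaled residuals of the variable genes, a shared-nearest-
#' neighbor graph (Jaccard weights over K-nearest-neighbor sets, pruned below
#' 1/15), and Louvain modularity optimization.
#'
#' @param nm NormalizedMatrix.
#' @param hvg variable gene ids (rows of the scaled matrix to use).
#' @param n_pcs principal components kept.
#' @param K neighborhood size of the SNN graph.
#' @param resolution Louvain resolution.
#' @param seed RNG seed for the community detection.
#' @return list of class \code{ClusterAssignment}: \code{cluster} (integer
#'   per cell, named), \code{pca} (cells x n_pcs scores), parameters.
#' @export
cluster_cells <- function(nm, hvg = NULL, n_pcs = 20, K = 30,
                          resolution = 1.0, seed = 0) {
  n <- ncol(nm$scaled)
  if (n <= K) stop("fewer cells than the K parameter", call. = FALSE)
  if (is.null(hvg)) hvg <- rownames(nm$scaled)
  X <- t(nm$scaled[hvg, , drop = FALSE])
  n_pcs <- min(n_pcs, ncol(X), nrow(X) - 1L)
  pc <- prcomp(X, center = FALSE, scale. = FALSE, rank. = n_pcs)
  scores <- pc$x
  knn <- knn_indices(scores, K)
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), each = K),
                            j = as.vector(t(knn)), x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(A)
  jac <- shared
  jac@x <- jac@x / (2 * K - jac@x)
  jac@x[jac@x < 1 / 15] <- 0
  jac <- Matrix::drop0(jac)
  Matrix::diag(jac) <- 0
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "max", weighted = TRUE)
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  cl <- igraph::membership(comm)
  structure(list(cluster = setNames(as.integer(cl), rownames(X)),
                 pca = scores,
                 params = list(n_hvg = length(hvg), n_pcs = n_pcs, K = K,
                               resolution = resolution, seed = seed)),
            class = "ClusterAssignment")
}

# K nearest neighbors (excluding self) by Euclidean distance; ties broken by
# index for determinism.
knn_indices <- function(scores, K) {
  d <- as.matrix(dist(scores))
  n <- nrow(d)
  t(vapply(seq_len(n), function(i) {
    o <- order(d[i, ], seq_len(n))
    o[o != i][seq_len(K)]
  }, integer(K)))
}

#' Default curated marker sets for major cell types
#' @return SignatureSet with epithelial, myeloid, T, B and fibroblast (CAF)
#'   marker genes.
#' @export
curated_type_sets <- function() {
  signature_set(list(
    epithelial = c("EPCAM", "KRT19", "KRT18", "KRT5", "KRT15"),
    myeloid = c("LYZ", "CD68", "MS4A6A", "CD1E", "IL3RA", "LAMP3"),
    T = c("CD2", "CD3D", "CD3E", "CD3G"),
    B = c("CD79A", "CD79B", "CD19", "MS4A1"),
    fibroblast = c("COL1A1", "COL3A1", "DCN")))
}

# Mean scaled expression of each curated set in each cell (sets x cells).
curated_set_scores <- function(nm, sets) {
  present <- lapply(sets, function(g) intersect(g, rownames(nm$scaled)))
  n_miss <- sum(lengths(sets) - lengths(present))
  if (n_miss > 0)
    warning(sprintf("%d curated gene(s) absent from the matrix", n_miss),
            call. = FALSE)
  if (all(lengths(present) == 0))
    stop("all curated genes missing from the matrix", call. = FALSE)
  t(vapply(present, function(g) {
    if (!length(g)) return(rep(NA_real_, ncol(nm$scaled)))
    colMeans(nm$scaled[g, , drop = FALSE])
  }, numeric(ncol(nm$scaled))))
}

#' Annotate clusters with major cell types from curated sets
#'
#' Each cluster receives the type whose curated set has the highest mean
#' scaled expression over the cluster's cells; when the top two scores are
#' within \code{margin}, the cluster is "unassigned".
#'
#' @param nm NormalizedMatrix.
#' @param clusters ClusterAssignment (or integer vector per cell).
#' @param sets curated SignatureSet (default \code{\link{curated_type_sets}}).
#' @param margin minimal lead of the best score over the runner-up.
#' @return list: \code{cluster_type} (named per cluster), \code{cell_type}
#'   (per cell), \code{scores} (clusters x types mean score matrix).
#' @export
annotate_major_types <- function(nm, clusters, sets = curated_type_sets(),
                                 margin = 0) {
  cl <- if (inherits(clusters, "ClusterAssignment")) clusters$cluster else clusters
  sc <- curated_set_scores(nm, sets)            # types x cells
  ids <- sort(unique(cl))
  cmean <- vapply(ids, function(k) rowMeans(sc[, cl == k, drop = FALSE]),
                  numeric(nrow(sc)))
  cmean <- matrix(cmean, nrow = nrow(sc),
                  dimnames = list(rownames(sc), as.character(ids)))
  cluster_type <- apply(cmean, 2, function(v) {
    v[is.na(v)] <- -Inf
    o <- order(-v)
    if (length(v) > 1 && v[o[1]] - v[o[2]] <= margin) "unassigned"
    else names(v)[o[1]]
  })
  list(cluster_type = cluster_type,
       cell_type = unname(cluster_type[as.character(cl)]),
       scores = t(cmean))
}

#' Score cells for doublet likelihood with simulated doublets
#'
#' Synthetic doublets are built by summing random pairs of observed cells;
#' observed and synthetic profiles are embedded in a common PCA space and
#' each observed cell is scored by the fraction of synthetic doublets among
#' its k nearest neighbors, converted to a doublet probability under the
#' expected doublet rate. The calling threshold sits at the antimode of the
#' score distribution (overridable).
#'
#' @param cm CountMatrix (at least 100 cells).
#' @param expected_rate expected doublet rate (default 0.06).
#' @param n_synth synthetic doublets simulated (default: two per cell).
#' @param k neighborhood size (default \code{round(0.5 * sqrt(n_total))}).
#' @param n_pcs,n_var_genes embedding parameters.
#' @param threshold manual score threshold overriding the antimode.
#' @param seed RNG seed.
#' @return list of class \code{DoubletScores}: \code{score} (per cell, named),
#'   \code{call} (logical), \code{threshold}.
#' @export
score_doublets <- function(cm, expected_rate = 0.06, n_synth = NULL, k = NULL,
                           n_pcs = 30, n_var_genes = 1000, threshold = NULL,
                           seed = 0) {
  n <- ncol(cm$counts)
  if (n < 100) stop("doublet scoring needs at least 100 cells", call. = FALSE)
  set.seed(seed)
  if (is.null(n_synth)) n_synth <- 2L * n
  p1 <- sample.int(n, n_synth, replace = TRUE)
  p2 <- (p1 + sample.int(n - 1, n_synth, replace = TRUE) - 1) %% n + 1
  synth <- cm$counts[, p1, drop = FALSE] + cm$counts[, p2, drop = FALSE]
  all_counts <- cbind(cm$counts, synth)
  total <- Matrix::colSums(all_counts)
  ln <- all_counts
  ln@x <- log1p(1e4 * ln@x / rep.int(total, diff(ln@p)))
  v <- row_vars_sparse(ln[, seq_len(n), drop = FALSE])
  ids <- rownames(ln)
  top <- ids[order(-v, ids)][seq_len(min(n_var_genes, length(ids)))]
  X <- t(as.matrix(ln[top, , drop = FALSE]))
  X <- sweep(X, 2, colMeans(X))
  n_pcs <- min(n_pcs, ncol(X), nrow(X) - 1L)
  pc <- prcomp(X, center = FALSE, rank. = n_pcs)
  if (is.null(k)) k <- max(5L, round(0.5 * sqrt(n + n_synth)))
  knn <- knn_indices(pc$x, k)[seq_len(n), , drop = FALSE]
  q <- rowMeans(knn > n)                 # fraction of synthetic neighbors
  rho <- n_synth / (n + n_synth)
  lr <- (q * (1 - rho)) / pmax((1 - q) * rho, 1e-12)
  score <- expected_rate * lr / (expected_rate * lr + 1 - expected_rate)
  names(score) <- colnames(cm$counts)
  thr <- if (!is.null(threshold)) threshold else score_antimode(score, expected_rate)
  structure(list(score = score, call = score > thr, threshold = thr,
                 expected_rate = expected_rate), class = "DoubletScores")
}

# Antimode of the score density between its outer modes; falls back to the
# (1 - expected_rate) quantile for unimodal or degenerate score sets.
score_antimode <- function(score, expected_rate) {
  if (length(unique(score)) < 3) return(max(score))
  d <- density(score, n = 256)
  y <- d$y
  locmin <- which(diff(sign(diff(y))) == 2) + 1
  locmax <- which(diff(sign(diff(y))) == -2) + 1
  if (length(locmin) && length(locmax) >= 2) {
    lo <- min(locmax); hi <- max(locmax)
    cand <- locmin[locmin > lo & locmin < hi]
    if (length(cand)) return(d$x[cand[which.min(y[cand])]])
  }
  unname(quantile(score, 1 - expected_rate))
}

#' Iterative cluster-based doublet removal
#'
#' Alternates subclustering within each major cell type with removal of
#' subclusters that look like heterotypic doublets: subclusters whose mean
#' scaled expression exceeds \code{co_express_cut} for curated sets of two or
#' more major types, or whose median doublet score exceeds the scoring
#' threshold. Stops when an iteration removes nothing.
#'
#' @param cm CountMatrix.
#' @param cell_types per-cell major-type labels (from
#'   \code{\link{annotate_major_types}}).
#' @param sets curated SignatureSet.
#' @param doublet optional \code{DoubletScores} for the same cells.
#' @param co_express_cut scaled-expression cut above which a curated set
#'   counts as expressed by a subcluster.
#' @param max_iter maximum alternations.
#' @param min_cells smallest major-type population that gets subclustered.
#' @param seed RNG seed for subclustering.
#' @return list: \code{cm} (cleaned CountMatrix), \code{removed} (cell ids),
#'   \code{log} (per-iteration removal counts).
#' @export
iterative_cluster_doublet_removal <- function(cm, cell_types,
                                              sets = curated_type_sets(),
                                              doublet = NULL,
                                              co_express_cut = 0.25,
                                              max_iter = 5, min_cells = 60,
                                              seed = 0) {
  stopifnot(length(cell_types) == ncol(cm$counts))
  names(cell_types) <- colnames(cm$counts)
  removed <- character(0)
  log <- integer(0)
  for (iter in seq_len(max_iter)) {
    nm <- normalize_and_scale(cm)
    sc <- curated_set_scores(nm, sets)
    drop_cells <- character(0)
    for (t in setdiff(unique(cell_types[colnames(cm$counts)]), "unassigned")) {
      sel <- which(cell_types[colnames(cm$counts)] == t)
      if (length(sel) < min_cells) next
      sub_nm <- normalize_and_scale(subset_cells(cm, sel))
      hvg <- select_hvg(sub_nm, min(1000, nrow(sub_nm$lognorm)))
      K <- min(10L, length(sel) - 1L)
      cl <- cluster_cells(sub_nm, hvg, n_pcs = 10, K = K, resolution = 2,
                          seed = seed)$cluster
      for (k in unique(cl)) {
        cells_k <- names(cl)[cl == k]
        msc <- rowMeans(sc[, cells_k, drop = FALSE], na.rm = TRUE)
        co <- sum(msc > co_express_cut, na.rm = TRUE) >= 2
        dbl <- !is.null(doublet) &&
          median(doublet$score[cells_k], na.rm = TRUE) > doublet$threshold
        if (co || dbl) drop_cells <- c(drop_cells, cells_k)
      }
    }
    log <- c(log, length(drop_cells))
    if (!length(drop_cells)) break
    removed <- c(removed, drop_cells)
    keep <- !(colnames(cm$counts) %in% drop_cells)
    cm <- subset_cells(cm, keep)
  }
  list(cm = cm, removed = removed, log = log,
       removed_fraction = length(removed) / (ncol(cm$counts) + length(removed)))
}
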