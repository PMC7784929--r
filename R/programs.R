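# Per-tumor NMF metagenes, cross-tumor clustering, signature consolidation,
# and per-cell signature scoring.

#' Non-negative matrix factorization of one tumor's malignant cells
#'
#' Frobenius-objective multiplicative updates from an NNDSVD initialization.
#' The input is a non-negative genes x cells matrix (typically log-normalized
#' expression of the tumor's malignant cells restricted to genes expressed in
#' at least \code{min_cell_frac} of them). Metagene loadings are the columns
#' of W, L2-normalized, with ranked gene lists (descending loading, gene-id
#' tie-break).
#'
#' @param expr non-negative genes x cells matrix with dimnames.
#' @param k number of factors (default 4).
#' @param tumor_id label stored on the metagenes.
#' @param min_cell_frac expression filter: keep genes with a nonzero value in
#'   at least this fraction of cells (default 0.02).
#' @param center when TRUE (default), each gene is centered across the
#'   tumor's cells and negative values are set to zero before factorizing,
#'   so factors describe relative expression programs rather than the shared
#'   baseline; set FALSE to factorize the raw log-normalized values.
#' @param max_iter,tol update iterations and relative-change stopping
#'   tolerance.
#' @param seed RNG seed (the factorization itself is deterministic given the
#'   init; the seed covers tie perturbation in degenerate inits).
#' @return list of class \code{MetageneSet}: \code{metagenes} (list of k
#'   Metagene: tumor_id, factor_index, loading, ranked genes), \code{W},
#'   \code{H}, \code{objective} (per recorded iteration), \code{converged}.
#'   A metagene's \code{loading} is its factor-specific loading: the
#'   L2-normalized W column minus, per gene, the median loading over the
#'   other factors (clipped at zero), which removes the noise floor common to
#'   all factors; the raw normalized column is kept as \code{loading_raw}.
#' @export
nmf_per_tumor <- function(expr, k = 4, tumor_id = "tumor", min_cell_frac = 0.02,
                          center = TRUE, max_iter = 500, tol = 1e-6, seed = 0) {
  expr <- as.matrix(expr)
  if (any(expr < 0)) stop("NMF input must be non-negative", call. = FALSE)
  keep <- rowMeans(expr > 0) >= min_cell_frac
  A <- expr[keep, , drop = FALSE]
  if (center) A <- pmax(A - rowMeans(A), 0)
  if (nrow(A) < k) stop("fewer filtered genes than factors", call. = FALSE)
  set.seed(seed)
  init <- nndsvd_init(A, k)
  W <- init$W; H <- init$H
  eps <- 1e-12
  obj <- numeric(0)
  prev <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, A)) / (crossprod(W) %*% H + eps)
    W <- W * (A %*% t(H)) / (W %*% tcrossprod(H) + eps)
    if (it %% 10 == 0 || it == max_iter) {
      e <- sqrt(sum((A - W %*% H)^2))
      obj <- c(obj, e)
      if (e <= 1e-9 * max(sqrt(sum(A^2)), 1e-12) ||
          (is.finite(prev) && abs(prev - e) <= tol * max(prev, 1e-12))) {
        converged <- TRUE
        break
      }
      prev <- e
    }
  }
  if (!converged)
    warning(sprintf("NMF did not converge in %d iterations (error %.4g)",
                    max_iter, tail(obj, 1)), call. = FALSE)
  norms <- sqrt(colSums(W^2))
  norms[norms == 0] <- 1
  Wn <- sweep(W, 2, norms, "/")
  # factor-specific loadings: subtract, per gene, the median loading over the
  # other factors (clip at 0), removing the noise floor shared by all factors
  Wspec <- Wn
  if (k >= 2) {
    for (j in seq_len(k)) {
      others <- Wn[, -j, drop = FALSE]
      Wspec[, j] <- pmax(Wn[, j] - apply(others, 1, median), 0)
    }
    sn <- sqrt(colSums(Wspec^2))
    sn[sn == 0] <- 1
    Wspec <- sweep(Wspec, 2, sn, "/")
  }
  metagenes <- lapply(seq_len(k), function(j) {
    loading <- setNames(Wspec[, j], rownames(A))
    o <- order(-loading, names(loading))
    structure(list(tumor_id = tumor_id, factor_index = j,
                   loading = loading,
                   loading_raw = setNames(Wn[, j], rownames(A)),
                   ranked_genes = names(loading)[o]),
              class = "Metagene")
  })
  structure(list(metagenes = metagenes, W = Wn, H = H, objective = obj,
                 converged = converged, genes = rownames(A)),
            class = "MetageneSet")
}

# NNDSVD initialization (Boutsidis & Gallopoulos): split each SVD factor pair
# into its positive and negative parts and keep the dominant one.
nndsvd_init <- function(A, k) {
  s <- svd(A, nu = k, nv = k)
  W <- matrix(0, nrow(A), k)
  H <- matrix(0, k, ncol(A))
  W[, 1] <- sqrt(s$d[1]) * abs(s$u[, 1])
  H[1, ] <- sqrt(s$d[1]) * abs(s$v[, 1])
  if (k >= 2) {
    for (j in 2:k) {
      u <- s$u[, j]; v <- s$v[, j]
      up <- pmax(u, 0); un <- pmax(-u, 0)
      vp <- pmax(v, 0); vn <- pmax(-v, 0)
      n_up <- sqrt(sum(up^2)); n_vp <- sqrt(sum(vp^2))
      n_un <- sqrt(sum(un^2)); n_vn <- sqrt(sum(vn^2))
      if (n_up * n_vp >= n_un * n_vn) {
        scale <- sqrt(s$d[j] * n_up * n_vp)
        if (n_up > 0) W[, j] <- scale * up / n_up
        if (n_vp > 0) H[j, ] <- scale * vp / n_vp
      } else {
        scale <- sqrt(s$d[j] * n_un * n_vn)
        if (n_un > 0) W[, j] <- scale * un / n_un
        if (n_vn > 0) H[j, ] <- scale * vn / n_vn
      }
    }
  }
  mean_a <- mean(A)
  W[W < 1e-12] <- mean_a / 100
  H[H < 1e-12] <- mean_a / 100
  list(W = W, H = H)
}

#' Pairwise metagene distances (1 - Pearson correlation)
#'
#' Loadings are mapped to the union gene universe with zeros for absent
#' genes; the distance between two metagenes is one minus the Pearson
#' correlation of their mapped loadings.
#'
#' @param metagenes list of Metagene (possibly from several tumors).
#' @return symmetric distance matrix with zero diagonal; metagene labels are
#'   "tumor_id.factor_index".
#' @export
metagene_correlation <- function(metagenes) {
  if (length(metagenes) < 2) stop("need at least 2 metagenes", call. = FALSE)
  universe <- sort(unique(unlist(lapply(metagenes, function(m) names(m$loading)))))
  L <- vapply(metagenes, function(m) {
    v <- setNames(numeric(length(universe)), universe)
    v[names(m$loading)] <- m$loading
    v
  }, numeric(length(universe)))
  colnames(L) <- vapply(metagenes, function(m)
    paste(m$tumor_id, m$factor_index, sep = "."), "")
  sds <- apply(L, 2, sd)
  if (any(sds < 1e-15))
    warning("constant metagene loading vector(s); distance set to 1", call. = FALSE)
  r <- suppressWarnings(cor(L))
  r[is.na(r)] <- 0
  D <- 1 - r
  diag(D) <- 0
  D
}

#' Cluster metagenes into signature groups
#'
#' Average-linkage hierarchical clustering on the 1 - r distance matrix, cut
#' into \code{n_signatures} groups.
#'
#' @param D distance matrix from \code{\link{metagene_correlation}}.
#' @param n_signatures number of groups (the original analysis chose its
#'   count manually; there is no universal default).
#' @param linkage linkage method.
#' @return named integer vector: group per metagene label.
#' @export
cluster_metagenes <- function(D, n_signatures, linkage = "average") {
  if (n_signatures < 1 || n_signatures > nrow(D))
    stop("n_signatures out of range", call. = FALSE)
  hc <- hclust(as.dist(D), method = linkage)
  cutree(hc, k = n_signatures)
}

#' Suggest a signature count by mean silhouette width
#'
#' @param D metagene distance matrix.
#' @param k_range candidate counts.
#' @return the candidate with the highest mean silhouette width.
#' @export
suggest_n_signatures <- function(D, k_range = 2:8) {
  k_range <- k_range[k_range < nrow(D) & k_range >= 2]
  sil <- vapply(k_range, function(k) {
    cl <- cluster_metagenes(D, k)
    mean_silhouette(D, cl)
  }, 0)
  k_range[which.max(sil)]
}

mean_silhouette <- function(D, cl) {
  n <- nrow(D)
  s <- vapply(seq_len(n), function(i) {
    own <- cl == cl[i]
    a <- if (sum(own) > 1) mean(D[i, own & seq_len(n) != i]) else 0
    bs <- vapply(setdiff(unique(cl), cl[i]),
                 function(k) mean(D[i, cl == k]), 0)
    if (!length(bs)) return(0)
    b <- min(bs)
    (b - a) / max(a, b)
  }, 0)
  mean(s)
}

#' Consolidate member metagenes into a malignant signature
#'
#' The candidate pool is the union of each member's top \code{top_n_pool}
#' genes; a gene's consolidated loading is the sum of its loadings over the
#' members whose top list contains it, divided by the member count m. The
#' marker list is the top \code{top_n_markers} genes by consolidated loading
#' (gene-id tie-break).
#'
#' @param members list of Metagene.
#' @param signature_id label.
#' @param top_n_pool per-member pool size (default 100).
#' @param top_n_markers marker list size (default 30).
#' @return list of class \code{MalignantSignature}: \code{signature_id},
#'   \code{members} (labels), \code{loading} (consolidated, descending),
#'   \code{markers}.
#' @export
consolidate_signature <- function(members, signature_id = "signature",
                                  top_n_pool = 100, top_n_markers = 30) {
  stopifnot(length(members) >= 1)
  m <- length(members)
  tops <- lapply(members, function(mg) {
    pos <- mg$loading[mg$loading > 0]
    o <- order(-pos, names(pos))
    head(pos[o], top_n_pool)
  })
  pool <- sort(unique(unlist(lapply(tops, names))))
  cons <- setNames(numeric(length(pool)), pool)
  for (tp in tops) cons[names(tp)] <- cons[names(tp)] + tp
  cons <- cons / m
  o <- order(-cons, names(cons))
  cons <- cons[o]
  structure(list(signature_id = signature_id,
                 members = vapply(members, function(mg)
                   paste(mg$tumor_id, mg$factor_index, sep = "."), ""),
                 loading = cons,
                 markers = head(names(cons), top_n_markers)),
            class = "MalignantSignature")
}

#' Derive consolidated malignant signatures across tumors
#'
#' Runs \code{\link{metagene_correlation}}, \code{\link{cluster_metagenes}}
#' and \code{\link{consolidate_signature}} over all metagenes.
#'
#' @param metagenes flat list of Metagene from every retained tumor.
#' @param n_signatures group count.
#' @param top_n_pool,top_n_markers consolidation parameters.
#' @return list: \code{signatures} (list of MalignantSignature),
#'   \code{partition}, \code{distance}, and \code{signature_set} (markers as
#'   a SignatureSet).
#' @export
derive_malignant_signatures <- function(metagenes, n_signatures,
                                        top_n_pool = 100, top_n_markers = 30) {
  D <- metagene_correlation(metagenes)
  part <- cluster_metagenes(D, n_signatures)
  sigs <- lapply(sort(unique(part)), function(g) {
    consolidate_signature(metagenes[part == g],
                          signature_id = sprintf("malignant_sig%d", g),
                          top_n_pool = top_n_pool,
                          top_n_markers = top_n_markers)
  })
  set <- signature_set(setNames(lapply(sigs, `[[`, "markers"),
                                vapply(sigs, `[[`, "", "signature_id")))
  list(signatures = sigs, partition = part, distance = D, signature_set = set)
}

#' Score cells for signature activity
#'
#' Default method: mean scaled expression of the signature genes minus the
#' mean over an expression-matched random control set (\code{n_ctrl} control
#' genes per signature gene, drawn from the same mean-expression bin, fixed
#' seed). \code{method = "mean"} skips the control subtraction.
#'
#' @param nm NormalizedMatrix.
#' @param sigs SignatureSet.
#' @param method "control" (default) or "mean".
#' @param n_ctrl controls per signature gene.
#' @param n_bins expression bins for control matching.
#' @param seed RNG seed for control sampling.
#' @return list of class \code{CellSignatureScore}: \code{score} (cells x
#'   signatures matrix), \code{method}.
#' @export
score_cells <- function(nm, sigs, method = c("control", "mean"),
                        n_ctrl = 100, n_bins = 25, seed = 0) {
  method <- match.arg(method)
  genes <- rownames(nm$scaled)
  set.seed(seed)
  mu <- Matrix::rowMeans(nm$lognorm)
  bin <- cut(rank(mu, ties.method = "first"), breaks = n_bins, labels = FALSE)
  names(bin) <- genes
  out <- matrix(NA_real_, ncol(nm$scaled), length(sigs),
                dimnames = list(colnames(nm$scaled), names(sigs)))
  for (j in seq_along(sigs)) {
    present <- intersect(sigs[[j]], genes)
    if (!length(present)) {
      warning(sprintf("signature '%s' has no genes in the matrix; skipped",
                      names(sigs)[j]), call. = FALSE)
      next
    }
    s <- colMeans(nm$scaled[present, , drop = FALSE])
    if (method == "control") {
      ctrl <- unique(unlist(lapply(present, function(g) {
        pool <- genes[bin == bin[g]]
        sample(pool, min(n_ctrl, length(pool)))
      })))
      s <- s - colMeans(nm$scaled[ctrl, , drop = FALSE])
    }
    out[, j] <- s
  }
  structure(list(score = out, method = method), class = "CellSignatureScore")
}
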