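# Ligand-receptor interaction enrichment between cluster pairs by label
# permutation.

#' Permutation test for ligand-receptor co-expression between clusters
#'
#' For every ordered cluster pair (a, b) and every pair whose ligand is
#' expressed (count >= 1) in more than \code{min_expr_frac} of a's cells and
#' whose receptor is expressed in more than \code{min_expr_frac} of b's
#' cells, the statistic T = (mean ligand log-normalized expression in a +
#' mean receptor expression in b) / 2 is compared with its null distribution
#' under \code{n_perm} joint permutations of the cluster labels of all
#' included cells. p = #(T_perm > T_obs) / n_perm (strict inequality; a
#' conservative >= variant is available).
#'
#' @param nm NormalizedMatrix.
#' @param clusters per-cell cluster labels (named by cell id or aligned).
#' @param lr LigandReceptorTable.
#' @param n_perm permutations (default 1000).
#' @param min_expr_frac expression-fraction filter (default 0.10, strict).
#' @param min_cells clusters smaller than this are excluded (default 10).
#' @param conservative use >= instead of > when counting permuted statistics
#'   (avoids p = 0 under exact ties).
#' @param seed RNG seed.
#' @return data.frame of InteractionRecords sorted by (p_value, pair_id):
#'   pair_id, ligand_gene, receptor_gene, cluster_a, cluster_b, f_l, f_r,
#'   statistic, p_value, n_perm.
#' @export
test_interactions <- function(nm, clusters, lr, n_perm = 1000,
                              min_expr_frac = 0.10, min_cells = 10,
                              conservative = FALSE, seed = 0) {
  cells <- colnames(nm$lognorm)
  if (!is.null(names(clusters))) clusters <- clusters[cells]
  stopifnot(length(clusters) == length(cells))
  clusters <- as.character(clusters)
  sizes <- table(clusters)
  keep_cl <- names(sizes)[sizes >= min_cells]
  if (length(keep_cl) < 2) stop("need at least 2 clusters of sufficient size",
                                call. = FALSE)
  inc <- clusters %in% keep_cl
  labs <- clusters[inc]
  genes_needed <- unique(c(lr$ligand_gene, lr$receptor_gene))
  absent <- setdiff(genes_needed, rownames(nm$lognorm))
  if (length(absent)) {
    warning(sprintf("pair gene(s) absent from matrix: %s; pairs skipped",
                    paste(absent, collapse = ", ")), call. = FALSE)
    lr <- lr[!(lr$ligand_gene %in% absent | lr$receptor_gene %in% absent), ,
             drop = FALSE]
  }
  if (!nrow(lr)) return(empty_interactions())
  X <- as.matrix(nm$lognorm[unique(c(lr$ligand_gene, lr$receptor_gene)),
                            inc, drop = FALSE])
  det <- X > 0

  grp_mean <- function(lab) {
    gs <- rowsum(t(X), lab)                  # clusters x genes (sums)
    gs / as.vector(table(lab)[rownames(gs)])
  }
  obs_mean <- grp_mean(labs)                 # clusters x genes
  obs_frac <- rowsum(t(det) + 0, labs) / as.vector(table(labs)[keep_cl])

  # enumerate records passing the expression filter
  recs <- list()
  for (i in seq_len(nrow(lr))) {
    lg <- lr$ligand_gene[i]; rg <- lr$receptor_gene[i]
    for (a in keep_cl) for (b in keep_cl) {
      if (a == b) next
      f_l <- obs_frac[a, lg]; f_r <- obs_frac[b, rg]
      if (f_l > min_expr_frac && f_r > min_expr_frac) {
        recs[[length(recs) + 1]] <- data.frame(
          pair_id = lr$pair_id[i], ligand_gene = lg, receptor_gene = rg,
          cluster_a = a, cluster_b = b, f_l = f_l, f_r = f_r,
          statistic = (obs_mean[a, lg] + obs_mean[b, rg]) / 2,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(recs)) return(empty_interactions())
  recs <- do.call(rbind, recs)
  exceed <- numeric(nrow(recs))
  set.seed(seed)
  for (p in seq_len(n_perm)) {
    perm <- grp_mean(sample(labs))
    tp <- (perm[cbind(recs$cluster_a, recs$ligand_gene)] +
             perm[cbind(recs$cluster_b, recs$receptor_gene)]) / 2
    exceed <- exceed + if (conservative) (tp >= recs$statistic)
                       else (tp > recs$statistic)
  }
  recs$p_value <- exceed / n_perm
  recs$n_perm <- n_perm
  recs <- recs[order(recs$p_value, recs$pair_id, recs$cluster_a, recs$cluster_b), ]
  rownames(recs) <- NULL
  recs
}

empty_interactions <- function() {
  data.frame(pair_id = character(0), ligand_gene = character(0),
             receptor_gene = character(0), cluster_a = character(0),
             cluster_b = character(0), f_l = numeric(0), f_r = numeric(0),
             statistic = numeric(0), p_value = numeric(0),
             n_perm = integer(0), stringsAsFactors = FALSE)
}
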