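# Copy-number inference from smoothed expression and malignant-cell
# classification against a normal reference.
#
# Order of operations: log2(TPM+1) -> per-cell centering -> chromosome-wise
# moving average (window 101, shrinking at chromosome edges) -> subtraction
# of the normal-reference profile -> clip to [-1, 1] and zero the (-0.3, 0.3)
# dead zone.

#' Transform counts to log2(TPM + 1)
#'
#' TPM here is the per-cell UMI proportion of a gene times 1e6.
#'
#' @param cm CountMatrix (or a genes x cells matrix).
#' @return dense genes x cells matrix of log2(1 + 1e6 * count / cell_total).
#' @export
to_log_tpm <- function(cm) {
  m <- if (inherits(cm, "CountMatrix")) cm$counts else cm
  total <- Matrix::colSums(m)
  if (any(total == 0)) stop("cells with zero total counts", call. = FALSE)
  out <- as.matrix(m)
  out <- log2(1 + sweep(out, 2, total, "/") * 1e6)
  out
}

#' Smooth expression along the genome
#'
#' Genes are ordered by the position table; per cell, values are mean-centered
#' and replaced by a centered moving average of width \code{w} computed within
#' each chromosome (the window shrinks to the available genes at chromosome
#' edges; it never crosses a boundary).
#'
#' @param logtpm genes x cells matrix (gene ids as rownames).
#' @param positions GenePositionTable; genes missing from it are excluded with
#'   a message.
#' @param w window width (odd; default 101).
#' @return genes x cells matrix over the position-ordered genes, with
#'   attribute \code{chrom} (per-gene chromosome).
#' @export
smooth_cnv <- function(logtpm, positions, w = 101) {
  ord_genes <- positions$gene_id[positions$gene_id %in% rownames(logtpm)]
  n_missing <- nrow(logtpm) - length(ord_genes)
  if (n_missing > 0)
    message(sprintf("%d gene(s) without positions excluded from CNV analysis",
                    n_missing))
  if (!length(ord_genes)) stop("no genes with positions", call. = FALSE)
  x <- logtpm[ord_genes, , drop = FALSE]
  x <- sweep(x, 2, colMeans(x))              # per-cell centering
  chrom <- positions$chrom[match(ord_genes, positions$gene_id)]
  h <- (w - 1) %/% 2
  out <- x
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    n <- length(idx)
    if (n == 0) { warning(sprintf("chromosome %s has no genes", ch)); next }
    cs <- apply(x[idx, , drop = FALSE], 2, cumsum)
    cs <- rbind(0, matrix(cs, nrow = n))
    lo <- pmax(seq_len(n) - h, 1L)
    hi <- pmin(seq_len(n) + h, n)
    out[idx, ] <- (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) /
      (hi - lo + 1)
  }
  attr(out, "chrom") <- chrom
  out
}

#' Subtract the normal-reference profile
#'
#' @param smoothed genes x cells smoothed matrix.
#' @param reference_cells cell ids (or column indices) of the normal
#'   reference.
#' @return matrix with the per-gene reference mean subtracted from every cell.
#' @export
reference_normalize <- function(smoothed, reference_cells) {
  if (is.character(reference_cells))
    reference_cells <- match(reference_cells, colnames(smoothed))
  reference_cells <- reference_cells[!is.na(reference_cells)]
  if (!length(reference_cells)) stop("empty reference set", call. = FALSE)
  ref_mean <- rowMeans(smoothed[, reference_cells, drop = FALSE])
  out <- sweep(smoothed, 1, ref_mean)
  attr(out, "chrom") <- attr(smoothed, "chrom")
  out
}

#' Clip scores and zero the dead zone
#'
#' Values above 1 become 1, below -1 become -1; values with absolute value
#' strictly below \code{dead_zone} become 0 (the +/-0.3 boundary itself is
#' kept).
#'
#' @param S genes x cells score matrix.
#' @param clip clipping bound.
#' @param dead_zone half-width of the zeroed band.
#' @param reference_cells optional reference cell ids stored on the profile.
#' @return list of class \code{CnvProfile}: \code{score} (cells x genes),
#'   \code{genes}, \code{chrom}, parameters.
#' @export
clip_and_threshold <- function(S, clip = 1.0, dead_zone = 0.3,
                               reference_cells = NULL) {
  chrom <- attr(S, "chrom")
  S <- pmin(pmax(S, -clip), clip)
  S[abs(S) < dead_zone] <- 0
  structure(list(score = t(S), genes = rownames(S), chrom = chrom,
                 w = attr(S, "w"), clip = clip, dead_zone = dead_zone,
                 reference_cells = reference_cells),
            class = "CnvProfile")
}

#' @export
print.CnvProfile <- function(x, ...) {
  cat(sprintf("CnvProfile: %d cells x %d ordered genes (clip %.1f, dead zone %.1f)\n",
              nrow(x$score), ncol(x$score), x$clip, x$dead_zone))
  invisible(x)
}

#' Infer a CNV profile from counts
#'
#' Convenience wrapper running \code{\link{to_log_tpm}},
#' \code{\link{smooth_cnv}}, \code{\link{reference_normalize}} and
#' \code{\link{clip_and_threshold}}.
#'
#' @param cm CountMatrix restricted to the cells of interest (epithelial).
#' @param positions GenePositionTable.
#' @param reference_cells cell ids of the normal reference.
#' @param w,clip,dead_zone procedure parameters.
#' @return CnvProfile.
#' @export
infer_cnv_profile <- function(cm, positions, reference_cells, w = 101,
                              clip = 1.0, dead_zone = 0.3) {
  lt <- to_log_tpm(cm)
  sm <- smooth_cnv(lt, positions, w)
  nn <- reference_normalize(sm, reference_cells)
  clip_and_threshold(nn, clip, dead_zone, reference_cells = reference_cells)
}

#' Classify malignant vs non-malignant epithelial cells
#'
#' Per tumor sample, the tumor's epithelial cells are pooled with the normal
#' sample's epithelial cells and their CNV profiles are cut into two
#' hierarchical clusters (Ward linkage on Euclidean distances by default).
#' The cluster with the larger fraction of normal-sample cells is called
#' non-malignant; the other is called malignant only when it is genuinely
#' depleted of normal cells (normal fraction below \code{depletion} times the
#' pooled normal share) -- when both clusters carry normal cells at near the
#' pooled rate the tumor has no separable aberrant population and every cell
#' is called non-malignant. Ties are called non-malignant. Tumors with fewer
#' than \code{min_malignant} malignant cells are flagged as not retained.
#'
#' @param profile CnvProfile over all epithelial cells.
#' @param sample_of named vector: sample id per cell id.
#' @param normal_sample id of the normal sample.
#' @param min_malignant retention threshold (default 50).
#' @param depletion normal-cell depletion factor below which a cluster
#'   qualifies as malignant (default 0.5).
#' @param linkage,metric hierarchical clustering choices.
#' @return list of class \code{MalignancyCall}: \code{call} (named per-cell
#'   label, tumor cells only), \code{tumor_summary} (per-tumor data.frame with
#'   n_malignant, retained, resolved).
#' @export
classify_malignant <- function(profile, sample_of, normal_sample,
                               min_malignant = 50, depletion = 0.5,
                               linkage = "ward.D2", metric = "euclidean") {
  cells <- rownames(profile$score)
  sample_of <- sample_of[cells]
  normal_cells <- cells[sample_of == normal_sample]
  if (!length(normal_cells)) stop("normal sample has no cells", call. = FALSE)
  tumors <- setdiff(unique(sample_of), normal_sample)
  call <- character(0)
  summ <- list()
  for (tu in tumors) {
    tcells <- cells[sample_of == tu]
    if (length(tcells) < 2) {
      warning(sprintf("tumor %s has < 2 epithelial cells; skipped", tu))
      summ[[tu]] <- data.frame(sample_id = tu, n_cells = length(tcells),
                               n_malignant = NA_integer_, retained = FALSE,
                               resolved = FALSE)
      next
    }
    pool <- c(tcells, normal_cells)
    hc <- hclust(dist(profile$score[pool, , drop = FALSE], method = metric),
                 method = linkage)
    grp <- cutree(hc, k = 2)
    norm_frac <- vapply(1:2, function(k)
      mean(pool[grp == k] %in% normal_cells), 0)
    if (all(norm_frac == 0)) {
      warning(sprintf("tumor %s: no cluster contains normal cells; unresolved", tu))
      summ[[tu]] <- data.frame(sample_id = tu, n_cells = length(tcells),
                               n_malignant = NA_integer_, retained = FALSE,
                               resolved = FALSE)
      next
    }
    pooled_share <- length(normal_cells) / length(pool)
    if (norm_frac[1] == norm_frac[2] ||
        min(norm_frac) >= depletion * pooled_share) {
      # no cluster is depleted of normal cells: no separable aberrant group
      lab <- setNames(rep("non_malignant", length(tcells)), tcells)
    } else {
      mal_cluster <- which.min(norm_frac)
      lab <- ifelse(grp[seq_along(tcells)] == mal_cluster,
                    "malignant", "non_malignant")
      names(lab) <- tcells
    }
    n_mal <- sum(lab == "malignant")
    call <- c(call, lab)
    summ[[tu]] <- data.frame(sample_id = tu, n_cells = length(tcells),
                             n_malignant = n_mal,
                             retained = n_mal >= min_malignant,
                             resolved = TRUE)
  }
  structure(list(call = call, tumor_summary = do.call(rbind, summ),
                 min_malignant = min_malignant),
            class = "MalignancyCall")
}

#' @export
print.MalignancyCall <- function(x, ...) {
  cat(sprintf("MalignancyCall: %d cells called, %d/%d tumors retained (>= %d malignant cells)\n",
              length(x$call), sum(x$tumor_summary$retained),
              nrow(x$tumor_summary), x$min_malignant))
  invisible(x)
}
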