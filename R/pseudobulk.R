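# Pseudobulk aggregation and comparison with bulk profiles.

#' Sum single-cell counts to pseudobulk per sample
#'
#' @param cm CountMatrix.
#' @return genes x samples matrix of summed UMIs.
#' @export
pseudobulk <- function(cm) {
  s <- factor(cm$cell_meta$sample_id)
  out <- vapply(levels(s), function(k)
    Matrix::rowSums(cm$counts[, s == k, drop = FALSE]),
    numeric(nrow(cm$counts)))
  matrix(out, nrow(cm$counts),
         dimnames = list(rownames(cm$counts), levels(s)))
}

#' Correlate pseudobulk with matched bulk profiles
#'
#' Per shared sample, the Pearson correlation between log1p(summed UMIs per
#' gene) and log1p(bulk abundance) over the shared genes.
#'
#' @param cm CountMatrix.
#' @param bulk genes x samples bulk matrix.
#' @param sample_map named vector mapping single-cell sample ids to bulk
#'   column names (default: identity on shared names).
#' @param min_genes minimum shared genes (default 50).
#' @return data.frame of class \code{BulkComparison}: sample, r, n_genes.
#' @export
pseudobulk_correlate <- function(cm, bulk, sample_map = NULL, min_genes = 50) {
  pb <- pseudobulk(cm)
  if (is.null(sample_map)) {
    shared <- intersect(colnames(pb), colnames(bulk))
    sample_map <- setNames(shared, shared)
  }
  if (!length(sample_map)) stop("no shared samples", call. = FALSE)
  genes <- intersect(rownames(pb), rownames(bulk))
  if (length(genes) < min_genes)
    stop(sprintf("only %d shared genes (need >= %d)", length(genes), min_genes),
         call. = FALSE)
  rows <- lapply(names(sample_map), function(s) {
    data.frame(sample = s,
               r = cor(log1p(pb[genes, s]), log1p(bulk[genes, sample_map[[s]]])),
               n_genes = length(genes), stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("BulkComparison", "data.frame"))
}
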