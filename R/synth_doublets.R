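# Planting a typed doublet population onto a simulated dataset.

#' Append planted heterotypic doublets of a chosen type pair
#'
#' Builds n doublets by summing the counts of a random cell of
#' \code{type_a} and a random cell of \code{type_b} (within the same sample)
#' and downsampling to the sample's median library size, then appends them to
#' the CountMatrix with truth columns set. Used to emulate a discrete
#' heterotypic-doublet subcluster.
#'
#' @param cm CountMatrix whose cell_meta has major_type and is_doublet.
#' @param type_a,type_b parent major types.
#' @param n number of doublets.
#' @param subcluster_a,subcluster_b optional parent subcluster restriction;
#'   a coherent doublet subcluster needs homogeneous parents.
#' @param seed RNG seed.
#' @return CountMatrix with n extra cells (is_doublet TRUE, major_type
#'   "doublet_mix").
#' @export
add_planted_doublets <- function(cm, type_a, type_b, n, subcluster_a = NULL,
                                 subcluster_b = NULL, seed = 0) {
  set.seed(seed)
  meta <- cm$cell_meta
  pool_a <- meta$major_type == type_a & !meta$is_doublet
  pool_b <- meta$major_type == type_b & !meta$is_doublet
  if (!is.null(subcluster_a)) pool_a <- pool_a & meta$subcluster %in% subcluster_a
  if (!is.null(subcluster_b)) pool_b <- pool_b & meta$subcluster %in% subcluster_b
  ok_samples <- intersect(unique(meta$sample_id[pool_a]),
                          unique(meta$sample_id[pool_b]))
  if (!length(ok_samples)) stop("no sample contains both types", call. = FALSE)
  s <- sample(ok_samples, n, replace = TRUE)
  new_cols <- vector("list", n)
  new_meta <- vector("list", n)
  totals <- Matrix::colSums(cm$counts)
  for (i in seq_len(n)) {
    in_s <- meta$sample_id == s[i]
    a <- sample(meta$cell_id[in_s & pool_a], 1)
    b <- sample(meta$cell_id[in_s & pool_b], 1)
    v <- cm$counts[, a] + cm$counts[, b]
    target <- round(median(totals[meta$cell_id[in_s]]))
    v <- downsample_counts(v, target)
    new_cols[[i]] <- v
    new_meta[[i]] <- data.frame(cell_id = sprintf("%s_pd%04d", s[i], i),
                                sample_id = s[i], major_type = "doublet_mix",
                                subcluster = NA_character_,
                                is_malignant = FALSE, is_doublet = TRUE,
                                parent1 = a, parent2 = b,
                                stringsAsFactors = FALSE)
  }
  add <- do.call(cbind, new_cols)
  nm <- do.call(rbind, new_meta)
  # de-duplicate planted ids against multiple draws in the same sample
  nm$cell_id <- make.unique(nm$cell_id)
  colnames(add) <- nm$cell_id
  rownames(add) <- rownames(cm$counts)
  keep_cols <- intersect(names(meta), names(nm))
  count_matrix(cbind(as.matrix(cm$counts), add),
               rbind(meta[, keep_cols, drop = FALSE], nm[, keep_cols, drop = FALSE]))
}
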