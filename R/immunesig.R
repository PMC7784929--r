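# Rule-based marker signatures for immune subclusters.
#
# A gene is a marker of subcluster s (within one major cell type) iff
#   (1) its linear-scale mean expression in s is > fc_min-fold the mean over
#       the other subclusters of the same type,
#   (2) it is detectably expressed (count >= 1) in > pct_min % of s's cells,
#   (3) its mean in s is strictly the highest among all subclusters of the
#       type (ties disqualify every tied subcluster).
# All three inequalities are strict.

#' Derive immune subcluster marker signatures
#'
#' @param nm NormalizedMatrix over the immune cells.
#' @param subclusters per-cell subcluster labels (named by cell id or aligned
#'   with the matrix columns).
#' @param major_type_of named vector mapping subcluster id to its major cell
#'   type; markers are derived within each major type separately.
#' @param fc_min fold-change threshold (strict; default 2.5). Fold change is
#'   computed on linear-scale means: \code{expm1} of the log-normalized
#'   values, with pseudocount 1e-9 added to both means.
#' @param pct_min detection threshold in percent (strict; default 25).
#' @param min_cells subclusters smaller than this are skipped with a warning.
#' @param fc_space "linear" (default) or "log": scale on which the means for
#'   the fold change are taken.
#' @return list: \code{signatures} (SignatureSet; subclusters with no passing
#'   gene are absent), \code{records} (data.frame of MarkerRecord fields:
#'   gene_id, subcluster_id, fold_change, pct_in, is_max_mean),
#'   \code{signatureless} (subcluster ids with zero markers).
#' @export
derive_markers <- function(nm, subclusters, major_type_of, fc_min = 2.5,
                           pct_min = 25, min_cells = 3,
                           fc_space = c("linear", "log")) {
  fc_space <- match.arg(fc_space)
  cells <- colnames(nm$lognorm)
  if (!is.null(names(subclusters))) subclusters <- subclusters[cells]
  stopifnot(length(subclusters) == length(cells))
  eps <- 1e-9
  lin <- as.matrix(nm$lognorm)
  if (fc_space == "linear") lin <- expm1(lin)
  detected <- nm$counts > 0
  records <- list()
  sig <- list()
  signatureless <- character(0)
  for (mt in unique(major_type_of)) {
    subs <- names(major_type_of)[major_type_of == mt]
    subs <- intersect(subs, unique(subclusters))
    if (length(subs) < 2) {
      warning(sprintf("major type %s has < 2 subclusters; skipped", mt),
              call. = FALSE)
      next
    }
    sizes <- vapply(subs, function(s) sum(subclusters == s, na.rm = TRUE), 0L)
    small <- sizes < min_cells
    if (any(small)) {
      warning(sprintf("subcluster(s) %s have < %d cells; skipped",
                      paste(subs[small], collapse = ", "), min_cells),
              call. = FALSE)
      subs <- subs[!small]
      if (length(subs) < 2) next
    }
    means <- vapply(subs, function(s)
      rowMeans(lin[, which(subclusters == s), drop = FALSE]),
      numeric(nrow(lin)))
    # strict max-mean winner per gene (0 when tied at the top)
    top <- apply(means, 1, function(v) {
      o <- order(-v)
      if (length(v) > 1 && v[o[1]] == v[o[2]]) 0L else o[1]
    })
    for (si in seq_along(subs)) {
      s <- subs[si]
      in_cells <- which(subclusters == s)
      out_cells <- which(subclusters %in% setdiff(subs, s))
      in_mean <- means[, si]
      out_mean <- rowMeans(lin[, out_cells, drop = FALSE])
      fc <- (in_mean + eps) / (out_mean + eps)
      pct <- 100 * Matrix::rowSums(detected[, in_cells, drop = FALSE]) /
        length(in_cells)
      is_max <- top == si
      pass <- fc > fc_min & pct > pct_min & is_max
      if (any(pass)) {
        g <- rownames(lin)[pass]
        o <- order(-fc[pass], g)
        sig[[s]] <- g[o]
        records[[s]] <- data.frame(gene_id = g[o], subcluster_id = s,
                                   major_type = mt,
                                   fold_change = fc[pass][o],
                                   pct_in = pct[pass][o],
                                   is_max_mean = TRUE,
                                   stringsAsFactors = FALSE)
      } else {
        signatureless <- c(signatureless, s)
      }
    }
  }
  list(signatures = if (length(sig)) signature_set(sig) else NULL,
       records = if (length(records)) do.call(rbind, c(records, list(make.row.names = FALSE))),
       signatureless = signatureless)
}
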