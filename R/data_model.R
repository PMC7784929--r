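#' @importFrom methods as is new
#' @importFrom stats cor cor.test cutree dist hclust kmeans lm median p.adjust
#'   prcomp quantile rbinom density rgamma rlnorm rnbinom rnorm runif sd setNames
#'   var wilcox.test rexp rmultinom pnorm
#' @importFrom utils head read.delim write.table tail
NULL

# ---- CountMatrix -----------------------------------------------------------

#' Construct a CountMatrix
#'
#' The universal single-cell carrier of the pipeline: a genes x cells matrix of
#' non-negative integer UMI counts plus a per-cell metadata table.
#'
#' @param counts genes x cells matrix (dense or \code{Matrix} sparse) of
#'   non-negative integer UMI counts. Row names are gene ids, column names are
#'   cell barcodes; they can instead be supplied via \code{gene_ids} /
#'   \code{cell_ids}.
#' @param cell_meta data.frame with one row per cell, containing at least
#'   \code{sample_id}. Optional columns carry cluster labels and, for synthetic
#'   data, ground truth.
#' @param gene_ids,cell_ids optional identifier vectors overriding dimnames.
#' @return object of class \code{CountMatrix} with elements \code{counts}
#'   (a \code{dgCMatrix}) and \code{cell_meta}.
#' @export
count_matrix <- function(counts, cell_meta = NULL, gene_ids = NULL, cell_ids = NULL) {
  if (!is.null(gene_ids)) rownames(counts) <- gene_ids
  if (!is.null(cell_ids)) colnames(counts) <- cell_ids
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene and cell identifiers", call. = FALSE)
  if (!inherits(counts, "sparseMatrix"))
    counts <- Matrix::Matrix(counts, sparse = TRUE, doDiag = FALSE)
  counts <- as(as(counts, "CsparseMatrix"), "generalMatrix")
  x <- counts@x
  if (any(x < 0)) stop("counts contain negative entries", call. = FALSE)
  if (any(x != round(x))) stop("counts contain non-integer entries", call. = FALSE)
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids", call. = FALSE)
  if (anyDuplicated(colnames(counts))) stop("duplicate cell barcodes", call. = FALSE)
  if (is.null(cell_meta)) {
    cell_meta <- data.frame(cell_id = colnames(counts),
                            sample_id = "sample1",
                            stringsAsFactors = FALSE)
  }
  if (!"cell_id" %in% names(cell_meta)) {
    if (nrow(cell_meta) != ncol(counts))
      stop("cell_meta rows do not match number of cells", call. = FALSE)
    cell_meta$cell_id <- colnames(counts)
  }
  if (!setequal(cell_meta$cell_id, colnames(counts)) ||
      nrow(cell_meta) != ncol(counts))
    stop("cell_meta does not align one-to-one with cell barcodes", call. = FALSE)
  cell_meta <- cell_meta[match(colnames(counts), cell_meta$cell_id), , drop = FALSE]
  rownames(cell_meta) <- NULL
  if (!"sample_id" %in% names(cell_meta))
    stop("cell_meta must contain sample_id", call. = FALSE)
  structure(list(counts = counts, cell_meta = cell_meta), class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d genes x %d cells, %d samples, %d stored entries\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$cell_meta$sample_id)),
              length(x$counts@x)))
  invisible(x)
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' Subset a CountMatrix by cells (and optionally genes)
#'
#' @param cm CountMatrix.
#' @param cells logical/integer/character index over cells.
#' @param genes optional index over genes.
#' @return CountMatrix restricted to the selection.
#' @export
subset_cells <- function(cm, cells, genes = NULL) {
  if (is.character(cells)) cells <- match(cells, colnames(cm$counts))
  counts <- cm$counts[, cells, drop = FALSE]
  if (!is.null(genes)) counts <- counts[genes, , drop = FALSE]
  meta <- cm$cell_meta[match(colnames(counts), cm$cell_meta$cell_id), , drop = FALSE]
  count_matrix(counts, meta)
}

#' Read a MatrixMarket count matrix with gene/barcode sidecars
#'
#' Follows the 10x convention: a coordinate MTX file plus one-id-per-line TSVs
#' for genes (first column used) and barcodes, optionally joined with a cell
#' metadata TSV keyed on barcode.
#'
#' @param path_matrix path to the \code{.mtx} file.
#' @param path_genes,path_barcodes TSVs with one row per matrix row/column.
#' @param path_meta optional TSV with a \code{cell_id} column to join.
#' @return CountMatrix.
#' @export
read_count_matrix <- function(path_matrix, path_genes, path_barcodes,
                              path_meta = NULL) {
  m <- Matrix::readMM(path_matrix)
  genes <- read.delim(path_genes, header = FALSE, stringsAsFactors = FALSE)[[1]]
  barcodes <- read.delim(path_barcodes, header = FALSE, stringsAsFactors = FALSE)[[1]]
  if (length(genes) != nrow(m))
    stop(sprintf("gene file has %d entries but matrix has %d rows",
                 length(genes), nrow(m)), call. = FALSE)
  if (length(barcodes) != ncol(m))
    stop(sprintf("barcode file has %d entries but matrix has %d columns",
                 length(barcodes), ncol(m)), call. = FALSE)
  meta <- NULL
  if (!is.null(path_meta)) {
    meta <- read.delim(path_meta, stringsAsFactors = FALSE)
    if (!"cell_id" %in% names(meta))
      stop("metadata file lacks a cell_id column", call. = FALSE)
    meta <- meta[match(barcodes, meta$cell_id), , drop = FALSE]
    meta$cell_id <- barcodes
  }
  count_matrix(m, meta, gene_ids = genes, cell_ids = barcodes)
}

#' Write a CountMatrix as MTX + sidecar TSVs
#'
#' @param cm CountMatrix.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_count_matrix <- function(cm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("matrix.mtx", "genes.tsv", "barcodes.tsv", "cell_meta.tsv"))
  Matrix::writeMM(cm$counts, paths[1])
  writeLines(rownames(cm$counts), paths[2])
  writeLines(colnames(cm$counts), paths[3])
  write.table(cm$cell_meta, paths[4], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

# ---- GenePositionTable -----------------------------------------------------

#' Default chromosome ordering (human autosomes + X, Y)
#' @export
default_chromosomes <- function() paste0("chr", c(1:22, "X", "Y"))

#' Build a gene position table
#'
#' Coordinates are 1-based inclusive. Rows are sorted by (chromosome rank,
#' start, gene_id); the declared chromosome ordering is kept as an attribute
#' and drives the genomic ordering used by the copy-number moving average.
#'
#' @param df data.frame with columns gene_id, chrom, start, end.
#' @param chromosomes ordered chromosome list; rows on chromosomes outside the
#'   list are dropped with a warning.
#' @return data.frame of class \code{GenePositionTable}.
#' @export
gene_position_table <- function(df, chromosomes = default_chromosomes()) {
  need <- c("gene_id", "chrom", "start", "end")
  if (!all(need %in% names(df)))
    stop("position table needs columns gene_id, chrom, start, end", call. = FALSE)
  if (any(df$start > df$end))
    stop("start > end for some genes", call. = FALSE)
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id in position table", call. = FALSE)
  unknown <- !(df$chrom %in% chromosomes)
  if (any(unknown)) {
    warning(sprintf("%d gene(s) on chromosomes outside the declared ordering excluded",
                    sum(unknown)), call. = FALSE)
    df <- df[!unknown, , drop = FALSE]
  }
  rank <- match(df$chrom, chromosomes)
  df <- df[order(rank, df$start, df$gene_id), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("GenePositionTable", "data.frame"),
            chromosomes = chromosomes)
}

#' Read a gene position TSV
#'
#' @param path TSV with columns gene_id, chrom, start, end (header optional if
#'   named exactly so; otherwise the first four columns are used in order).
#' @param chromosomes ordered chromosome list.
#' @return GenePositionTable.
#' @export
read_gene_positions <- function(path, chromosomes = default_chromosomes()) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "chrom", "start", "end") %in% names(df))) {
    df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    names(df)[1:4] <- c("gene_id", "chrom", "start", "end")
  }
  gene_position_table(df[, c("gene_id", "chrom", "start", "end")], chromosomes)
}

# ---- SignatureSet (GMT) ----------------------------------------------------

#' Construct a signature set
#'
#' @param sets named list of character gene vectors (order-preserving).
#' @param weights optional named list of numeric loading vectors aligned with
#'   \code{sets}.
#' @return named list of class \code{SignatureSet}.
#' @export
signature_set <- function(sets, weights = NULL) {
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("signatures must be named", call. = FALSE)
  for (nm in names(sets)) {
    g <- sets[[nm]]
    if (length(g) == 0) stop(sprintf("signature '%s' is empty", nm), call. = FALSE)
    if (anyDuplicated(g)) stop(sprintf("duplicate genes in signature '%s'", nm), call. = FALSE)
  }
  structure(sets, class = c("SignatureSet", "list"), weights = weights)
}

#' @export
print.SignatureSet <- function(x, ...) {
  cat(sprintf("SignatureSet: %d signature(s)\n", length(x)))
  for (nm in names(x))
    cat(sprintf("  %s: %d genes (%s%s)\n", nm, length(x[[nm]]),
                paste(head(x[[nm]], 3), collapse = ", "),
                if (length(x[[nm]]) > 3) ", ..." else ""))
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file: per line, name, description, then tab-separated genes.
#' @return SignatureSet.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(fields, length, 1L) < 3L
  if (any(bad))
    stop(sprintf("GMT line %d has fewer than 3 fields", which(bad)[1]), call. = FALSE)
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[`, "", 1L)
  signature_set(sets)
}

#' Write a SignatureSet to GMT
#'
#' @param sigs SignatureSet.
#' @param path output path.
#' @param descriptions optional per-signature description strings.
#' @return invisibly, \code{path}.
#' @export
write_gmt <- function(sigs, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sigs))
  lines <- vapply(seq_along(sigs), function(i) {
    paste(c(names(sigs)[i], descriptions[i], sigs[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

# ---- SurvivalTable ---------------------------------------------------------

#' Validate a survival/covariate table
#'
#' @param df data.frame with sample_id, time, event and covariate columns
#'   (age, sex, smoking, stage, optional ebv_dna_group).
#' @return the validated data.frame, classed \code{SurvivalTable}.
#' @export
survival_table <- function(df) {
  need <- c("sample_id", "time", "event")
  if (!all(need %in% names(df)))
    stop("survival table needs sample_id, time, event", call. = FALSE)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids", call. = FALSE)
  if (any(df$time < 0)) stop("negative survival times", call. = FALSE)
  if (!all(df$event %in% c(0, 1))) stop("event must be 0/1", call. = FALSE)
  structure(df, class = c("SurvivalTable", "data.frame"))
}

#' Read a survival table TSV
#' @param path TSV path.
#' @return SurvivalTable.
#' @export
read_survival_table <- function(path) survival_table(read.delim(path, stringsAsFactors = FALSE))

# ---- LigandReceptorTable ---------------------------------------------------

#' Validate a ligand-receptor pair table
#'
#' @param df data.frame with ligand_gene, receptor_gene and pair_id columns
#'   (pair_id generated as "ligand_receptor" when absent).
#' @return data.frame classed \code{LigandReceptorTable}.
#' @export
lr_table <- function(df) {
  if (!all(c("ligand_gene", "receptor_gene") %in% names(df)))
    stop("pair table needs ligand_gene and receptor_gene", call. = FALSE)
  if (!"pair_id" %in% names(df))
    df$pair_id <- paste(df$ligand_gene, df$receptor_gene, sep = "_")
  if (anyDuplicated(df$pair_id)) stop("duplicate pair ids", call. = FALSE)
  if (any(!nzchar(df$ligand_gene)) || any(!nzchar(df$receptor_gene)))
    stop("empty gene identifiers in pair table", call. = FALSE)
  structure(df, class = c("LigandReceptorTable", "data.frame"))
}

#' Read a ligand-receptor pair TSV
#' @param path TSV path.
#' @return LigandReceptorTable.
#' @export
read_lr_table <- function(path) lr_table(read.delim(path, stringsAsFactors = FALSE))
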