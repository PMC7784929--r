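# Pipeline orchestration: validated config, dependency-ordered stages,
# TSV/GMT outputs and a provenance manifest.

pipeline_defaults <- function() {
  list(
    seed = 1L,
    stages = c("qc", "cluster", "doublets", "cnv", "programs", "immunesig",
               "interactions"),
    sim = list(),
    qc = list(min_genes = 201, max_genes = 9000, max_mito_pct = 20,
              mito_prefix = "MT-"),
    cluster = list(n_hvg = 1000, n_pcs = 20, K = 30, resolution = 1.0),
    doublets = list(expected_rate = 0.06),
    cnv = list(w = 101, clip = 1.0, dead_zone = 0.3, min_malignant = 50),
    programs = list(k = 4, n_signatures = 3, top_n_pool = 100,
                    top_n_markers = 30),
    interactions = list(n_perm = 1000, min_expr_frac = 0.10)
  )
}

#' Validate a pipeline configuration
#'
#' Accepts a YAML path or a nested list; unknown keys (at either level) are
#' rejected, defaults fill the gaps, and cross-field constraints
#' (min_genes < max_genes, positive window, ...) are checked before any stage
#' runs.
#'
#' @param config YAML file path or named list.
#' @return validated config list of class \code{PipelineConfig}.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  def <- pipeline_defaults()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (sec in setdiff(names(def), c("seed", "stages", "sim"))) {
    if (!is.null(config[[sec]])) {
      bad <- setdiff(names(config[[sec]]), names(def[[sec]]))
      if (length(bad))
        stop(sprintf("unknown key(s) in section '%s': %s", sec,
                     paste(bad, collapse = ", ")), call. = FALSE)
      def[[sec]][names(config[[sec]])] <- config[[sec]]
    }
  }
  for (k in c("seed", "stages", "sim"))
    if (!is.null(config[[k]])) def[[k]] <- config[[k]]
  if (def$qc$min_genes >= def$qc$max_genes)
    stop("qc: min_genes must be < max_genes", call. = FALSE)
  if (def$cnv$w < 1 || def$cnv$w %% 2 == 0)
    stop("cnv: window must be a positive odd integer", call. = FALSE)
  if (def$programs$k < 1) stop("programs: k must be >= 1", call. = FALSE)
  structure(def, class = "PipelineConfig")
}

#' Run the full pipeline on synthetic data
#'
#' Stages run in dependency order: simulation, QC, normalization + clustering
#' + annotation, doublet scoring and iterative removal, CNV inference and
#' malignant classification, per-tumor NMF with signature consolidation,
#' subcluster marker derivation, and ligand-receptor permutation testing.
#' Outputs are written as TSV/GMT under \code{outdir} together with
#' \code{manifest.json} recording the seed, parameters, a parameter hash and
#' per-stage dimensions. Identical configs yield identical manifests.
#'
#' @param config \code{\link{pipeline_config}} input.
#' @param outdir output directory.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config = list(), outdir = tempfile("sctme_run_")) {
  cfg <- pipeline_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "sctme",
                   version = as.character(utils::packageVersion("sctme")),
                   seed = cfg$seed,
                   config = unclass(cfg),
                   stages = list())
  note <- function(stage, ...) manifest$stages[[stage]] <<- list(...)

  sim <- do.call(sim_config, c(cfg$sim, list(seed = cfg$seed)))
  ds <- simulate_sc_dataset(sim)
  write.table(ds$positions, file.path(outdir, "gene_positions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  note("simulate", n_genes = nrow(ds$cm$counts), n_cells = ncol(ds$cm$counts))

  qc <- qc_filter(ds$cm, do.call(qc_thresholds, cfg$qc))
  cm <- qc$cm
  note("qc", retained = qc$report$n_retained,
       removed = qc$report$n_input - qc$report$n_retained)

  nm <- normalize_and_scale(cm)
  hvg <- select_hvg(nm, min(cfg$cluster$n_hvg, nrow(nm$lognorm)))
  cl <- cluster_cells(nm, hvg, n_pcs = cfg$cluster$n_pcs,
                      K = min(cfg$cluster$K, ncol(nm$scaled) - 1L),
                      resolution = cfg$cluster$resolution, seed = cfg$seed)
  ann <- annotate_major_types(nm, cl, ds$truth$type_markers)
  note("cluster", n_clusters = length(unique(cl$cluster)),
       types = as.list(table(ann$cell_type)))

  dbl <- score_doublets(cm, expected_rate = cfg$doublets$expected_rate,
                        seed = cfg$seed)
  rem <- iterative_cluster_doublet_removal(cm, ann$cell_type,
                                           ds$truth$type_markers,
                                           doublet = dbl, seed = cfg$seed)
  cm <- rem$cm
  cell_type <- ann$cell_type[match(colnames(cm$counts), names(cl$cluster))]
  note("doublets", removed = length(rem$removed),
       remaining = ncol(cm$counts))

  epi <- which(cell_type == "epithelial")
  calls <- NULL
  if (length(epi) >= 3) {
    epi_cm <- subset_cells(cm, epi)
    ref <- epi_cm$cell_meta$cell_id[epi_cm$cell_meta$sample_id ==
                                      ds$truth$normal_sample]
    prof <- infer_cnv_profile(epi_cm, ds$positions, ref, w = cfg$cnv$w,
                              clip = cfg$cnv$clip,
                              dead_zone = cfg$cnv$dead_zone)
    calls <- classify_malignant(prof,
                                setNames(epi_cm$cell_meta$sample_id,
                                         epi_cm$cell_meta$cell_id),
                                ds$truth$normal_sample,
                                min_malignant = cfg$cnv$min_malignant)
    write.table(data.frame(cell_id = names(calls$call), call = calls$call),
                file.path(outdir, "malignant_calls.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(calls$tumor_summary, file.path(outdir, "tumor_summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    note("cnv", n_called = length(calls$call),
         n_malignant = sum(calls$call == "malignant"),
         retained_tumors = sum(calls$tumor_summary$retained))
  }

  if (!is.null(calls) && any(calls$tumor_summary$retained)) {
    nm_all <- normalize_and_scale(cm)
    mg <- list()
    for (tu in calls$tumor_summary$sample_id[calls$tumor_summary$retained]) {
      mal <- names(calls$call)[calls$call == "malignant" &
                                 grepl(paste0("^", tu, "_"), names(calls$call))]
      expr <- as.matrix(nm_all$lognorm[, mal, drop = FALSE])
      fit <- nmf_per_tumor(expr, k = cfg$programs$k, tumor_id = tu,
                           seed = cfg$seed)
      mg <- c(mg, fit$metagenes)
    }
    if (length(mg) >= 2) {
      sigs <- derive_malignant_signatures(mg, cfg$programs$n_signatures,
                                          cfg$programs$top_n_pool,
                                          cfg$programs$top_n_markers)
      write_gmt(sigs$signature_set, file.path(outdir, "malignant_signatures.gmt"))
      note("programs", n_metagenes = length(mg),
           n_signatures = length(sigs$signatures))
    }
  }

  sub_lab <- cm$cell_meta$subcluster
  if (!all(is.na(sub_lab))) {
    names(sub_lab) <- cm$cell_meta$cell_id
    types_of <- vapply(strsplit(unique(stats::na.omit(sub_lab)), "_s"),
                       `[`, "", 1)
    names(types_of) <- unique(stats::na.omit(sub_lab))
    nm_all <- normalize_and_scale(cm)
    mk <- derive_markers(nm_all, sub_lab, types_of)
    if (!is.null(mk$signatures))
      write_gmt(mk$signatures, file.path(outdir, "subcluster_signatures.gmt"))
    if (!is.null(mk$records))
      write.table(mk$records, file.path(outdir, "marker_records.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    note("immunesig",
         n_signatures = if (is.null(mk$signatures)) 0 else length(mk$signatures),
         signatureless = length(mk$signatureless))
  }

  if (nrow(ds$truth$lr_plan) > 0) {
    nm_all <- normalize_and_scale(cm)
    lr <- lr_table(ds$truth$lr_plan[, c("ligand_gene", "receptor_gene")])
    labs <- setNames(cell_type, colnames(cm$counts))
    labs[is.na(labs)] <- "unassigned"
    recs <- test_interactions(nm_all, labs, lr,
                              n_perm = cfg$interactions$n_perm,
                              min_expr_frac = cfg$interactions$min_expr_frac,
                              seed = cfg$seed)
    write.table(recs, file.path(outdir, "interactions.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    note("interactions", n_records = nrow(recs))
  }

  manifest$param_hash <- config_hash(manifest$config)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

# Stable hash of the configuration (md5 of its canonical JSON).
config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}
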