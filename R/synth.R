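# Synthetic single-cell / bulk data with planted ground truth.
#
# The generator draws UMI counts gene-wise from a negative binomial with
# gene-specific mean and shared dispersion. Structure is planted
# multiplicatively on expected counts:
#   - major-type marker blocks (renormalized within type, so cell totals are
#     type-independent),
#   - immune subcluster marker blocks,
#   - whole-chromosome dosage factors in malignant cells (NOT renormalized:
#     a 2x gain really doubles expected UMIs on that chromosome),
#   - convex mixtures of shared co-expression programs in malignant cells,
#   - ligand/receptor elevation in chosen source/target types.
# Doublets are sums of two random same-sample cells downsampled to the
# sample's median library size.

#' Configuration for the synthetic single-cell dataset
#'
#' Defaults describe the desk-scale study conditions used throughout the test
#' suite: 4 tumor samples plus one normal nasopharynx-like control, 300 cells
#' per sample over 5 major cell types, a miniature 6-chromosome genome, one
#' whole-chromosome gain (2x) and one loss (0.5x) in malignant epithelial
#' cells, 3 shared malignant co-expression programs and a 6% doublet rate.
#'
#' @param n_samples number of tumor samples.
#' @param cells_per_sample singlet cells simulated per sample.
#' @param n_genes total genes (including mitochondrial block).
#' @param n_chromosomes chromosomes of the miniature genome.
#' @param type_props named mixture proportions over major cell types (must sum
#'   to 1).
#' @param marker_genes_per_type,marker_fold size and fold elevation of each
#'   major-type marker block.
#' @param subclusters_per_type named integer vector: subclusters per type.
#' @param subcluster_marker_genes,subcluster_marker_fold size and fold of each
#'   subcluster marker block.
#' @param malignant_frac fraction of tumor-sample epithelial cells that are
#'   malignant (the normal sample has none).
#' @param cnv_plan data.frame(chrom, kind, dosage): whole-chromosome dosage
#'   factors applied to malignant expected counts.
#' @param n_programs,program_genes,program_fold planted co-expression programs
#'   shared across tumors: count, genes per program, peak fold elevation.
#' @param program_alpha Dirichlet concentration of per-cell program mixtures.
#' @param doublet_rate fraction of doublets added per sample.
#' @param lib_meanlog,lib_sdlog lognormal library-size parameters.
#' @param nb_size shared negative-binomial size (inverse dispersion).
#' @param mito_frac_genes fraction of genes in the mitochondrial block
#'   (ids prefixed \code{MT-}).
#' @param mito_expr_frac expected fraction of a cell's UMIs that are
#'   mitochondrial.
#' @param lr_plan data.frame(source_type, target_type, fold): planted
#'   ligand-receptor co-expression; genes are assigned by the generator.
#' @param n_bulk,censor_rate,bulk_noise_sdlog bulk-cohort plan: samples,
#'   censoring fraction, lognormal measurement noise.
#' @param seed integer seed making the whole dataset reproducible.
#' @return validated list of class \code{SimConfig}.
#' @export
sim_config <- function(n_samples = 4,
                       cells_per_sample = 300,
                       n_genes = 1500,
                       n_chromosomes = 6,
                       type_props = c(epithelial = 0.40, T = 0.25, B = 0.15,
                                      myeloid = 0.15, fibroblast = 0.05),
                       marker_genes_per_type = 40,
                       marker_fold = 8,
                       subclusters_per_type = c(T = 3, B = 2, myeloid = 2),
                       subcluster_marker_genes = 15,
                       subcluster_marker_fold = 4,
                       malignant_frac = 0.6,
                       cnv_plan = data.frame(chrom = c("chr2", "chr4"),
                                             kind = c("gain", "loss"),
                                             dosage = c(2.0, 0.5)),
                       n_programs = 3,
                       program_genes = 50,
                       program_fold = 3,
                       program_alpha = 0.5,
                       doublet_rate = 0.06,
                       lib_meanlog = log(2000),
                       lib_sdlog = 0.3,
                       nb_size = 2,
                       mito_frac_genes = 0.02,
                       mito_expr_frac = 0.08,
                       lr_plan = data.frame(source_type = "myeloid",
                                            target_type = "T",
                                            fold = 6),
                       n_bulk = 120,
                       censor_rate = 0.3,
                       bulk_noise_sdlog = 0.3,
                       seed = 1L) {
  cfg <- as.list(environment())
  if (abs(sum(type_props) - 1) > 1e-8)
    stop("type_props must sum to 1", call. = FALSE)
  if (any(cnv_plan$dosage <= 0)) stop("dosage factors must be > 0", call. = FALSE)
  if (n_samples < 1 || cells_per_sample < 1 || n_genes < 1)
    stop("counts must be positive", call. = FALSE)
  if (doublet_rate < 0 || doublet_rate >= 1)
    stop("doublet_rate must be in [0, 1)", call. = FALSE)
  n_special <- marker_genes_per_type * length(type_props) +
    subcluster_marker_genes * sum(subclusters_per_type) +
    n_programs * program_genes + 2 * nrow(lr_plan) +
    ceiling(mito_frac_genes * n_genes)
  if (n_special > n_genes)
    stop("planted blocks exceed n_genes", call. = FALSE)
  structure(cfg, class = "SimConfig")
}

# Assign disjoint gene blocks for every planted structure. Mito genes come
# first; everything else is drawn from the remaining pool in order.
assign_gene_blocks <- function(cfg) {
  n_mito <- ceiling(cfg$mito_frac_genes * cfg$n_genes)
  gene_ids <- c(sprintf("MT-%d", seq_len(n_mito)),
                sprintf("g%04d", seq_len(cfg$n_genes - n_mito)))
  pool <- setdiff(seq_len(cfg$n_genes), seq_len(n_mito))
  take <- function(k) {
    idx <- pool[seq_len(k)]
    pool <<- pool[-seq_len(k)]
    idx
  }
  types <- names(cfg$type_props)
  type_markers <- lapply(types, function(t) take(cfg$marker_genes_per_type))
  names(type_markers) <- types
  sub_markers <- list()
  for (t in names(cfg$subclusters_per_type)) {
    for (j in seq_len(cfg$subclusters_per_type[[t]])) {
      sub_markers[[paste0(t, "_s", j)]] <- take(cfg$subcluster_marker_genes)
    }
  }
  programs <- lapply(seq_len(cfg$n_programs), function(p) take(cfg$program_genes))
  names(programs) <- sprintf("program%d", seq_len(cfg$n_programs))
  lr_genes <- NULL
  if (nrow(cfg$lr_plan) > 0) {
    lr_genes <- data.frame(ligand = vapply(seq_len(nrow(cfg$lr_plan)),
                                           function(i) take(1L), 1L),
                           receptor = vapply(seq_len(nrow(cfg$lr_plan)),
                                             function(i) take(1L), 1L))
  }
  list(gene_ids = gene_ids, n_mito = n_mito, type_markers = type_markers,
       sub_markers = sub_markers, programs = programs, lr_genes = lr_genes)
}

#' Simulate a multi-sample single-cell UMI dataset with known truth
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return list with elements \code{cm} (\code{CountMatrix}; cell_meta carries
#'   the truth columns major_type, subcluster, is_malignant, is_doublet),
#'   \code{truth} (gene-level truth, program activities, planted signature
#'   sets, ligand-receptor plan with assigned genes, normal sample id) and
#'   \code{positions} (\code{GenePositionTable} over the non-mitochondrial
#'   genes of the miniature genome).
#' @export
simulate_sc_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed)
  blocks <- assign_gene_blocks(cfg)
  G <- cfg$n_genes
  gene_ids <- blocks$gene_ids
  mito_idx <- seq_len(blocks$n_mito)
  types <- names(cfg$type_props)

  # baseline gene weights; planted-structure genes get a moderately expressed
  # baseline (markers and co-expression programs are, by nature, expressed
  # genes); mitochondrial block rescaled to its target share
  w_base <- rgamma(G, shape = 0.3, rate = 1) + 1e-4
  special <- unique(c(unlist(blocks$type_markers), unlist(blocks$sub_markers),
                      unlist(blocks$programs), unlist(blocks$lr_genes)))
  if (length(special))
    w_base[special] <- rgamma(length(special), shape = 4, rate = 4) + 0.1
  w_base[mito_idx] <- w_base[mito_idx] *
    (cfg$mito_expr_frac / (1 - cfg$mito_expr_frac)) *
    sum(w_base[-mito_idx]) / sum(w_base[mito_idx])

  # per-type relative expression profiles (normalized so totals match)
  type_profile <- sapply(types, function(t) {
    w <- w_base
    w[blocks$type_markers[[t]]] <- w[blocks$type_markers[[t]]] * cfg$marker_fold
    w / sum(w)
  })

  samples <- c(sprintf("T%02d", seq_len(cfg$n_samples)), "N01")
  cells <- list(); metas <- list()
  cnv_mult <- rep(1, G)  # per-gene dosage applied to malignant cells
  pos <- synthetic_gene_positions(cfg, blocks)
  for (i in seq_len(nrow(cfg$cnv_plan))) {
    on_chr <- which(gene_ids %in% pos$gene_id[pos$chrom == cfg$cnv_plan$chrom[i]])
    cnv_mult[on_chr] <- cfg$cnv_plan$dosage[i]
  }

  prog_act_all <- list()
  for (s in samples) {
    n <- cfg$cells_per_sample
    type <- sample(types, n, replace = TRUE, prob = cfg$type_props)
    sub <- rep(NA_character_, n)
    for (t in names(cfg$subclusters_per_type)) {
      k <- cfg$subclusters_per_type[[t]]
      sel <- which(type == t)
      sub[sel] <- paste0(t, "_s", sample.int(k, length(sel), replace = TRUE))
    }
    malignant <- type == "epithelial" & s != "N01" &
      runif(n) < cfg$malignant_frac
    lib <- rlnorm(n, cfg$lib_meanlog, cfg$lib_sdlog)

    mu <- type_profile[, type, drop = FALSE]  # genes x cells
    # subcluster marker elevation, renormalized within cell
    for (sc in names(blocks$sub_markers)) {
      sel <- which(sub == sc)
      if (!length(sel)) next
      mu[blocks$sub_markers[[sc]], sel] <- mu[blocks$sub_markers[[sc]], sel] *
        cfg$subcluster_marker_fold
    }
    # ligand/receptor elevation in source/target types
    if (!is.null(blocks$lr_genes)) {
      for (i in seq_len(nrow(cfg$lr_plan))) {
        mu[blocks$lr_genes$ligand[i], type == cfg$lr_plan$source_type[i]] <-
          mu[blocks$lr_genes$ligand[i], type == cfg$lr_plan$source_type[i]] *
          cfg$lr_plan$fold[i]
        mu[blocks$lr_genes$receptor[i], type == cfg$lr_plan$target_type[i]] <-
          mu[blocks$lr_genes$receptor[i], type == cfg$lr_plan$target_type[i]] *
          cfg$lr_plan$fold[i]
      }
    }
    mu <- sweep(mu, 2, colSums(mu), "/")
    mu <- sweep(mu, 2, lib, "*")
    # malignant-only structure, applied after normalization so a dosage of 2
    # really doubles expected UMIs on the affected chromosome
    prog_act <- matrix(0, n, cfg$n_programs,
                       dimnames = list(NULL, names(blocks$programs)))
    if (any(malignant)) {
      mu[, malignant] <- mu[, malignant, drop = FALSE] * cnv_mult
      if (cfg$n_programs > 0) {
        a <- matrix(rgamma(sum(malignant) * cfg$n_programs,
                           shape = cfg$program_alpha), ncol = cfg$n_programs)
        a <- a / rowSums(a)
        prog_act[malignant, ] <- a
        for (p in seq_len(cfg$n_programs)) {
          gsel <- blocks$programs[[p]]
          mu[gsel, malignant] <- mu[gsel, malignant, drop = FALSE] *
            rep(1 + (cfg$program_fold - 1) * a[, p], each = length(gsel))
        }
      }
    }
    counts <- matrix(rnbinom(G * n, mu = as.vector(mu), size = cfg$nb_size),
                     nrow = G)

    # doublets: sum two distinct singlets, downsample to median library size
    n_d <- round(cfg$doublet_rate * n)
    parent1 <- parent2 <- rep(NA_character_, n)
    cell_ids <- sprintf("%s_c%04d", s, seq_len(n))
    if (n_d > 0) {
      p1 <- sample.int(n, n_d, replace = TRUE)
      p2 <- (p1 + sample.int(n - 1, n_d, replace = TRUE) - 1) %% n + 1
      dsum <- counts[, p1, drop = FALSE] + counts[, p2, drop = FALSE]
      target <- round(median(colSums(counts)))
      dcounts <- apply(dsum, 2, downsample_counts, target = target)
      counts <- cbind(counts, dcounts)
      cell_ids <- c(cell_ids, sprintf("%s_d%04d", s, seq_len(n_d)))
      type <- c(type, ifelse(type[p1] == type[p2], type[p1], "doublet_mix"))
      sub <- c(sub, rep(NA_character_, n_d))
      malignant <- c(malignant, rep(FALSE, n_d))
      parent1 <- c(parent1, sprintf("%s_c%04d", s, p1))
      parent2 <- c(parent2, sprintf("%s_c%04d", s, p2))
      prog_act <- rbind(prog_act, matrix(0, n_d, cfg$n_programs))
    }
    is_doub <- c(rep(FALSE, n), rep(TRUE, max(0, n_d)))
    colnames(counts) <- cell_ids
    cells[[s]] <- counts
    metas[[s]] <- data.frame(cell_id = cell_ids, sample_id = s,
                             major_type = type, subcluster = sub,
                             is_malignant = malignant, is_doublet = is_doub,
                             parent1 = parent1[seq_along(cell_ids)],
                             parent2 = parent2[seq_along(cell_ids)],
                             stringsAsFactors = FALSE)
    prog_act_all[[s]] <- prog_act
  }

  counts <- do.call(cbind, cells)
  rownames(counts) <- gene_ids
  meta <- do.call(rbind, metas)
  rownames(meta) <- NULL
  cm <- count_matrix(counts, meta)

  gene_truth <- data.frame(gene_id = gene_ids,
                           marker_of = NA_character_,
                           subcluster_marker_of = NA_character_,
                           program = NA_character_,
                           stringsAsFactors = FALSE)
  for (t in types) gene_truth$marker_of[blocks$type_markers[[t]]] <- t
  for (sc in names(blocks$sub_markers))
    gene_truth$subcluster_marker_of[blocks$sub_markers[[sc]]] <- sc
  for (p in names(blocks$programs)) gene_truth$program[blocks$programs[[p]]] <- p

  lr_plan <- cfg$lr_plan
  if (!is.null(blocks$lr_genes)) {
    lr_plan$ligand_gene <- gene_ids[blocks$lr_genes$ligand]
    lr_plan$receptor_gene <- gene_ids[blocks$lr_genes$receptor]
  }

  truth <- list(
    cell = meta,
    gene = gene_truth,
    program_activity = do.call(rbind, prog_act_all),
    type_markers = signature_set(lapply(blocks$type_markers,
                                        function(i) gene_ids[i])),
    subcluster_markers = if (length(blocks$sub_markers))
      signature_set(lapply(blocks$sub_markers, function(i) gene_ids[i])),
    program_sets = if (cfg$n_programs > 0)
      signature_set(lapply(blocks$programs, function(i) gene_ids[i])),
    lr_plan = lr_plan,
    cnv_plan = cfg$cnv_plan,
    normal_sample = "N01"
  )
  list(cm = cm, truth = truth, positions = pos)
}

# Downsample a count vector to a target library size by sampling molecules
# without replacement (hypergeometric thinning), as droplet capture does.
downsample_counts <- function(v, target) {
  tot <- sum(v)
  if (tot <= target) return(v)
  picked <- sample.int(tot, target)
  cs <- cumsum(v)
  tabulate(findInterval(picked - 1L, c(0L, cs), rightmost.closed = FALSE),
           nbins = length(v) + 1L)[-(length(v) + 1L)]
}

# Evenly space the non-mitochondrial genes across a miniature genome.
synthetic_gene_positions <- function(cfg, blocks) {
  gene_ids <- blocks$gene_ids[-seq_len(blocks$n_mito)]
  n <- length(gene_ids)
  chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
  per <- ceiling(n / cfg$n_chromosomes)
  idx <- seq_len(n) - 1L
  df <- data.frame(gene_id = gene_ids,
                   chrom = chroms[idx %/% per + 1L],
                   start = (idx %% per) * 1000L + 1L,
                   end = (idx %% per) * 1000L + 501L,
                   stringsAsFactors = FALSE)
  gene_position_table(df, chromosomes = chroms)
}

#' Simulate a bulk expression cohort with survival tied to signature activity
#'
#' Each bulk sample is an expected pseudobulk over the generator's cell-type
#' profiles (mixture weights jittered per sample) in which the genes of each
#' supplied signature are scaled by \code{exp(0.5 * a_sk)}, where
#' \code{a_sk ~ N(0,1)} is the sample's latent activity of signature k.
#' Survival times follow an exponential proportional-hazards model with linear
#' predictor \code{sum_k effect_k * a_sk} plus small covariate effects;
#' censoring is independent exponential calibrated to the configured rate.
#'
#' @param cfg a \code{\link{sim_config}} (fields n_bulk, censor_rate,
#'   bulk_noise_sdlog, seed are used).
#' @param signatures \code{SignatureSet} whose activities drive expression and
#'   hazard.
#' @param effects named log-hazard-ratio per signature (per 1 SD of activity);
#'   defaults to 0 for all.
#' @param seed overrides \code{cfg$seed} when given.
#' @return list with \code{expr} (genes x samples, linear-scale), \code{surv}
#'   (\code{SurvivalTable} with age/sex/smoking/stage covariates) and
#'   \code{truth} (activity matrix and per-sample hazard multiplier).
#' @export
simulate_bulk_cohort <- function(cfg, signatures, effects = NULL, seed = NULL) {
  stopifnot(inherits(cfg, "SimConfig"), length(signatures) >= 1)
  set.seed(if (is.null(seed)) cfg$seed + 10000L else seed)
  blocks <- assign_gene_blocks(cfg)   # deterministic layout, no RNG
  gene_ids <- blocks$gene_ids
  sig_names <- names(signatures)
  if (is.null(effects)) effects <- setNames(rep(0, length(signatures)), sig_names)
  effects <- effects[sig_names]
  effects[is.na(effects)] <- 0

  n <- cfg$n_bulk
  types <- names(cfg$type_props)
  w_base <- rgamma(cfg$n_genes, shape = 0.3, rate = 1) + 1e-4
  type_profile <- sapply(types, function(t) {
    w <- w_base
    w[blocks$type_markers[[t]]] <- w[blocks$type_markers[[t]]] * cfg$marker_fold
    w / sum(w)
  })

  activity <- matrix(rnorm(n * length(signatures)), n,
                     dimnames = list(NULL, sig_names))
  mix <- matrix(rgamma(n * length(types), shape = 5), n)
  mix <- mix / rowSums(mix)
  expr <- type_profile %*% t(mix) * 1e6      # genes x samples, CPM-ish scale
  for (k in seq_along(signatures)) {
    gsel <- match(signatures[[k]], gene_ids)
    gsel <- gsel[!is.na(gsel)]
    if (!length(gsel)) next
    expr[gsel, ] <- expr[gsel, ] * rep(exp(0.5 * activity[, k]),
                                       each = length(gsel))
  }
  expr <- expr * matrix(rlnorm(length(expr), 0, cfg$bulk_noise_sdlog),
                        nrow(expr))
  rownames(expr) <- gene_ids
  colnames(expr) <- sprintf("B%03d", seq_len(n))

  age <- rnorm(n, 50, 10)
  sex <- sample(c("male", "female"), n, replace = TRUE)
  smoking <- sample(c("yes", "no"), n, replace = TRUE)
  stage <- sample(c("I-II", "III-IV"), n, replace = TRUE)
  lp <- as.vector(activity %*% effects) +
    0.01 * (age - 50) + 0.2 * (stage == "III-IV")
  h0 <- 0.1
  ev_time <- rexp(n, rate = h0 * exp(lp))
  if (cfg$censor_rate > 0) {
    c_time <- rexp(n, rate = h0 * cfg$censor_rate / (1 - cfg$censor_rate))
  } else {
    c_time <- rep(Inf, n)
  }
  surv <- survival_table(data.frame(
    sample_id = colnames(expr),
    time = pmin(ev_time, c_time),
    event = as.integer(ev_time <= c_time),
    age = age, sex = sex, smoking = smoking, stage = stage,
    stringsAsFactors = FALSE))
  list(expr = expr, surv = surv,
       truth = list(activity = activity, log_hazard = lp,
                    hazard_multiplier = exp(lp), effects = effects))
}
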