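# ssGSEA scoring of bulk samples, median split, survival estimation and
# association tests.

#' Filter a bulk matrix to genes expressed in a minimum fraction of samples
#'
#' @param expr genes x samples matrix.
#' @param min_frac minimum fraction of samples with a positive value
#'   (default 0.5).
#' @return filtered matrix.
#' @export
filter_expressed <- function(expr, min_frac = 0.5) {
  expr[rowMeans(expr > 0) >= min_frac, , drop = FALSE]
}

#' Single-sample gene set enrichment scores
#'
#' Per sample, genes are ranked by expression (descending; gene-id tie-break)
#' and the enrichment score is the sum over the ranked list of the difference
#' between the weighted in-set cumulative step and the uniform out-of-set
#' cumulative step. Weights are the descending rank values (N, N-1, ..., 1)
#' raised to \code{alpha} and normalized over the set, which makes the score
#' invariant under strictly increasing per-sample transforms. A signature
#' covering every gene scores 0 by convention.
#'
#' @param expr genes x samples matrix (already filtered; see
#'   \code{\link{filter_expressed}}).
#' @param sigs SignatureSet; genes absent from the matrix are dropped with a
#'   warning, empty signatures are skipped.
#' @param alpha weighting exponent (default 0.25).
#' @param normalize min-max rescale scores across samples per signature.
#' @return list of class \code{SsgseaResult}: \code{score} (samples x
#'   signatures), \code{alpha}, \code{normalized}.
#' @export
ssgsea_score <- function(expr, sigs, alpha = 0.25, normalize = FALSE) {
  genes <- rownames(expr)
  N <- length(genes)
  ES <- matrix(NA_real_, ncol(expr), length(sigs),
               dimnames = list(colnames(expr), names(sigs)))
  present <- lapply(sigs, function(g) {
    hit <- intersect(g, genes)
    if (length(hit) < length(g))
      warning(sprintf("%d signature gene(s) absent from the matrix dropped",
                      length(g) - length(hit)), call. = FALSE)
    hit
  })
  keep <- lengths(present) > 0
  if (any(!keep))
    warning("signature(s) with no present genes skipped", call. = FALSE)
  w_all <- (N:1)^alpha
  for (s in seq_len(ncol(expr))) {
    o <- order(-expr[, s], genes)
    ranked <- genes[o]
    for (j in which(keep)) {
      hit <- ranked %in% present[[j]]
      n_in <- sum(hit)
      if (n_in == N) { ES[s, j] <- 0; next }
      w <- w_all * hit
      p_in <- cumsum(w) / sum(w)
      p_out <- cumsum(!hit) / (N - n_in)
      ES[s, j] <- sum(p_in - p_out)
    }
  }
  if (normalize) {
    for (j in which(keep)) {
      rng <- range(ES[, j])
      if (diff(rng) > 0) ES[, j] <- (ES[, j] - rng[1]) / diff(rng)
    }
  }
  structure(list(score = ES, alpha = alpha, normalized = normalize),
            class = "SsgseaResult")
}

#' Split samples at the median score
#'
#' Scores strictly above the median are "high"; scores at or below it are
#' "low" (deterministic tie rule, conservative for high-expression claims).
#'
#' @param scores named numeric vector.
#' @return factor with levels low, high, named like \code{scores}.
#' @export
median_split <- function(scores) {
  if (length(scores) < 2) stop("need at least 2 samples", call. = FALSE)
  med <- median(scores)
  if (all(scores == med)) stop("all scores identical; no split possible", call. = FALSE)
  factor(ifelse(scores > med, "high", "low"), levels = c("low", "high"))
}

#' Kaplan-Meier curves and log-rank test per group
#'
#' @param surv SurvivalTable.
#' @param labels per-sample group factor aligned on sample_id names (or
#'   positionally).
#' @return list of class \code{KmFit}: \code{fit} (a
#'   \code{survival::survfit}), \code{curves} (data.frame time/surv/at
#'   risk/group), \code{logrank_p}.
#' @export
km_fit <- function(surv, labels) {
  labels <- align_labels(surv, labels)
  if (any(table(labels) == 0)) stop("empty group", call. = FALSE)
  df <- data.frame(time = surv$time, event = surv$event, group = labels)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  p <- NA_real_
  if (length(unique(labels)) >= 2) {
    sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
    p <- 1 - stats::pchisq(sd$chisq, length(sd$n) - 1)
  }
  if (is.null(fit$strata)) fit$strata <- setNames(length(fit$time),
                                                  paste0("group=", labels[1]))
  strata <- rep(names(fit$strata), fit$strata)
  curves <- data.frame(group = sub("^group=", "", strata),
                       time = fit$time, n_risk = fit$n.risk,
                       n_event = fit$n.event, surv = fit$surv)
  structure(list(fit = fit, curves = curves, logrank_p = p), class = "KmFit")
}

align_labels <- function(surv, labels) {
  if (!is.null(names(labels))) {
    miss <- setdiff(surv$sample_id, names(labels))
    if (length(miss)) stop("labels missing for some samples", call. = FALSE)
    labels <- labels[surv$sample_id]
  }
  stopifnot(length(labels) == nrow(surv))
  labels
}

#' Cox proportional-hazards association of a group with survival
#'
#' Partial-likelihood fit (Efron tie handling) of the high/low group plus the
#' standard covariates present in the table (age, sex, smoking, stage, and
#' ebv_dna_group when available); Wald confidence interval and p-value for
#' the group term, coded high = 1.
#'
#' @param surv SurvivalTable.
#' @param labels group factor (levels low, high).
#' @param covariates covariate column names to adjust for; defaults to those
#'   of the standard set present in \code{surv}.
#' @return list of class \code{CoxFit}: \code{hr}, \code{ci} (2-vector),
#'   \code{p}, \code{coef} (all coefficients), \code{flag} (NULL or a
#'   diagnostic string), \code{model}.
#' @export
cox_fit <- function(surv, labels,
                    covariates = intersect(c("age", "sex", "smoking", "stage",
                                             "ebv_dna_group"), names(surv))) {
  labels <- align_labels(surv, labels)
  if (sum(surv$event) < 1) stop("no events", call. = FALSE)
  df <- data.frame(time = surv$time, event = surv$event, group = labels)
  for (cv in covariates) df[[cv]] <- surv[[cv]]
  fm <- stats::as.formula(paste("survival::Surv(time, event) ~ group",
                                if (length(covariates))
                                  paste("+", paste(covariates, collapse = " + "))
                                else ""))
  flag <- NULL
  fit <- withCallingHandlers(
    survival::coxph(fm, data = df, ties = "efron"),
    warning = function(w) {
      flag <<- conditionMessage(w)
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)
  i <- grep("^grouphigh", rownames(sm$coefficients))[1]
  structure(list(hr = unname(sm$coefficients[i, "exp(coef)"]),
                 ci = unname(sm$conf.int[i, c("lower .95", "upper .95")]),
                 p = unname(sm$coefficients[i, "Pr(>|z|)"]),
                 coef = stats::coef(fit),
                 flag = flag, model = fit),
            class = "CoxFit")
}

#' @export
print.CoxFit <- function(x, ...) {
  cat(sprintf("Cox fit: HR (high vs low) = %.3f [%.3f, %.3f], p = %.3g%s\n",
              x$hr, x$ci[1], x$ci[2], x$p,
              if (!is.null(x$flag)) " (flagged)" else ""))
  invisible(x)
}

#' Associate scores with a clinical variable
#'
#' Two-sided tests: Wilcoxon rank-sum for a 2-level grouping (exact when both
#' groups have <= 20 samples and there are no ties, normal approximation with
#' tie correction otherwise), Spearman or Pearson correlation for a numeric
#' variable.
#'
#' @param scores named numeric vector per sample.
#' @param variable grouping factor (wilcoxon) or numeric vector, named by
#'   sample id or aligned positionally.
#' @param kind "wilcoxon", "spearman" or "pearson".
#' @return list: \code{statistic}, \code{p}, \code{kind}, and \code{estimate}
#'   (correlation) where applicable.
#' @export
associate <- function(scores, variable, kind = c("wilcoxon", "spearman", "pearson")) {
  kind <- match.arg(kind)
  if (!is.null(names(variable)) && !is.null(names(scores)))
    variable <- variable[names(scores)]
  stopifnot(length(variable) == length(scores))
  if (kind == "wilcoxon") {
    f <- factor(variable)
    if (nlevels(f) != 2) stop("wilcoxon needs a 2-level grouping", call. = FALSE)
    n1 <- sum(f == levels(f)[1]); n2 <- sum(f == levels(f)[2])
    if (min(n1, n2) < 3) stop("need at least 3 samples per group", call. = FALSE)
    exact <- max(n1, n2) <= 20 && !anyDuplicated(scores)
    wt <- wilcox.test(scores ~ f, exact = exact, correct = !exact)
    list(statistic = unname(wt$statistic), p = wt$p.value, kind = kind)
  } else {
    if (length(scores) < 3) stop("need at least 3 samples", call. = FALSE)
    ct <- suppressWarnings(cor.test(scores, as.numeric(variable), method = kind))
    list(statistic = unname(ct$statistic), estimate = unname(ct$estimate),
         p = ct$p.value, kind = kind)
  }
}

#' Score signatures in a bulk cohort and test survival association
#'
#' ssGSEA scoring (after the expressed-gene filter), median split per
#' signature, Kaplan-Meier/log-rank and covariate-adjusted Cox.
#'
#' @param expr genes x samples bulk matrix.
#' @param sigs SignatureSet.
#' @param surv SurvivalTable covering the samples.
#' @param alpha ssGSEA exponent.
#' @param min_expr_frac expressed-gene filter fraction.
#' @return data.frame per signature: hr, ci_lo, ci_hi, cox_p, logrank_p,
#'   n_high, n_low; with the \code{SsgseaResult} attached as attribute
#'   \code{scores}.
#' @export
signature_survival <- function(expr, sigs, surv, alpha = 0.25,
                               min_expr_frac = 0.5) {
  expr <- filter_expressed(expr[, surv$sample_id, drop = FALSE], min_expr_frac)
  ss <- ssgsea_score(expr, sigs, alpha = alpha)
  rows <- lapply(colnames(ss$score), function(sg) {
    sc <- setNames(ss$score[, sg], rownames(ss$score))
    if (all(is.na(sc))) return(NULL)
    grp <- median_split(sc)
    km <- km_fit(surv, grp)
    cx <- cox_fit(surv, grp)
    data.frame(signature = sg, hr = cx$hr, ci_lo = cx$ci[1], ci_hi = cx$ci[2],
               cox_p = cx$p, logrank_p = km$logrank_p,
               n_high = sum(grp == "high"), n_low = sum(grp == "low"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "scores") <- ss
  out
}
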