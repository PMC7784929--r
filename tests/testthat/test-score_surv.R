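test_that("ssGSEA scores match a direct running-sum evaluation and its conventions", {
  expr <- matrix(c(5, 4, 3, 2, 1,
                   1, 3, 5, 2, 4), 5,
                 dimnames = list(sprintf("g%d", 1:5), c("s1", "s2")))
  sigs <- signature_set(list(two = c("g1", "g3"), all = sprintf("g%d", 1:5)))
  res <- ssgsea_score(expr, sigs, alpha = 0.25)

  # brute-force oracle for the 2-gene set on each sample
  oracle <- function(x, set, alpha) {
    genes <- names(x)
    o <- order(-x, genes)
    ranked <- genes[o]
    N <- length(genes)
    hit <- ranked %in% set
    w <- (N:1)^alpha * hit
    sum(cumsum(w) / sum(w) - cumsum(!hit) / (N - sum(hit)))
  }
  expect_equal(res$score["s1", "two"],
               oracle(setNames(expr[, 1], rownames(expr)), c("g1", "g3"), 0.25))
  expect_equal(res$score["s2", "two"],
               oracle(setNames(expr[, 2], rownames(expr)), c("g1", "g3"), 0.25))
  # the all-gene signature scores 0 by convention
  expect_equal(unname(res$score[, "all"]), c(0, 0))
  # rank invariance: strictly increasing transform leaves ES unchanged
  expr2 <- expr; expr2[, 1] <- exp(expr2[, 1] / 2) + 5
  res2 <- ssgsea_score(expr2, sigs, alpha = 0.25)
  expect_equal(res2$score["s1", "two"], res$score["s1", "two"])
  # absent genes are dropped with a warning; empty signatures skipped
  expect_warning(ssgsea_score(expr, signature_set(list(x = c("g1", "zz")))),
                 "absent")
})

test_that("expressed-gene filter keeps genes expressed in at least half the samples", {
  expr <- matrix(c(1, 0, 0, 2,
                   3, 4, 0, 0,
                   0, 0, 0, 1), 3, byrow = TRUE,
                 dimnames = list(c("a", "b", "c"), sprintf("s%d", 1:4)))
  kept <- filter_expressed(expr, 0.5)
  expect_equal(rownames(kept), c("a", "b"))
})

test_that("median split sends scores above the median to high, ties to low", {
  s <- setNames(c(1, 2, 3, 4), sprintf("p%d", 1:4))
  sp <- median_split(s)
  expect_equal(as.character(sp), c("low", "low", "high", "high"))
  # odd n: the median holder goes low
  s5 <- setNames(c(10, 20, 30, 40, 50), sprintf("p%d", 1:5))
  expect_equal(sum(median_split(s5) == "high"), 2)
  expect_error(median_split(setNames(c(5, 5, 5), c("a", "b", "c"))),
               "identical")
})

test_that("Kaplan-Meier estimator matches the product-limit closed form", {
  surv <- survival_table(data.frame(
    sample_id = sprintf("p%d", 1:4),
    time = c(2, 3, 4, 5), event = c(1, 0, 0, 0)))
  km <- km_fit(surv, factor(rep("all", 4), levels = c("all")))
  expect_equal(km$curves$surv[km$curves$time == 2], 0.75)
  # no events: survival stays 1
  surv0 <- survival_table(data.frame(
    sample_id = sprintf("p%d", 1:4),
    time = c(2, 3, 4, 5), event = rep(0, 4)))
  km0 <- km_fit(surv0, factor(rep("all", 4)))
  expect_true(all(km0$curves$surv == 1))
  # duplicating every subject leaves the curve unchanged
  survd <- survival_table(data.frame(
    sample_id = sprintf("p%d", 1:8),
    time = rep(c(2, 3, 4, 5), 2), event = rep(c(1, 0, 0, 0), 2)))
  kmd <- km_fit(survd, factor(rep("all", 8)))
  expect_equal(kmd$curves$surv[kmd$curves$time == 2], 0.75)
})

test_that("Cox fit matches a grid search of the explicit partial likelihood", {
  # 6 subjects, distinct event times, binary group
  surv <- survival_table(data.frame(
    sample_id = sprintf("p%d", 1:6),
    time = c(1, 2.5, 3, 4.2, 5, 7),
    event = c(1, 1, 0, 1, 1, 1)))
  grp <- factor(c("high", "low", "high", "low", "high", "low"),
                levels = c("low", "high"))
  fit <- cox_fit(surv, grp, covariates = character(0))

  x <- as.integer(grp == "high")
  pl <- function(beta) {
    ll <- 0
    for (i in which(surv$event == 1)) {
      risk <- which(surv$time >= surv$time[i])
      ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
    }
    ll
  }
  grid <- seq(-3, 3, by = 1e-4)
  beta_hat <- grid[which.max(vapply(grid, pl, 0))]
  expect_equal(log(fit$hr), beta_hat, tolerance = 1e-3)
})

test_that("Cox null calibration covers HR = 1 and planted effects are recovered", {
  cfg <- sim_config(n_bulk = 120, censor_rate = 0.2, seed = 40)
  sigs <- signature_set(list(s = sprintf("g%04d", 200:240)))
  covered <- 0
  set.seed(41)
  n_null <- 60
  for (i in 1:n_null) {
    bk <- simulate_bulk_cohort(cfg, sigs, effects = c(s = 0), seed = 4000 + i)
    grp <- factor(sample(c("low", "high"), 120, replace = TRUE),
                  levels = c("low", "high"))
    fit <- cox_fit(bk$surv, grp, covariates = character(0))
    if (fit$ci[1] <= 1 && 1 <= fit$ci[2]) covered <- covered + 1
  }
  expect_gte(covered / n_null, 0.9)

  # planted log-HR 0.7, n = 400: mean recovery within +-0.15
  cfg2 <- sim_config(n_bulk = 400, censor_rate = 0.1, seed = 42)
  est <- vapply(1:25, function(i) {
    bk <- simulate_bulk_cohort(cfg2, sigs, effects = c(s = 0.7),
                               seed = 5000 + i)
    unname(coef(survival::coxph(
      survival::Surv(time, event) ~ bk$truth$activity[, "s"],
      data = bk$surv)))
  }, 0)
  expect_lt(abs(mean(est) - 0.7), 0.15)
})

test_that("association tests match exhaustive and closed-form oracles", {
  # Wilcoxon U for a 3 vs 3 comparison vs exhaustive enumeration
  x <- c(1.2, 3.4, 2.2); y <- c(4.4, 5.1, 3.9)
  scores <- setNames(c(x, y), sprintf("p%d", 1:6))
  grp <- factor(rep(c("a", "b"), each = 3))
  res <- associate(scores, grp, kind = "wilcoxon")
  u_direct <- sum(outer(x, y, ">"))          # U statistic by enumeration
  expect_equal(res$statistic, u_direct)
  # exact p: proportion of label assignments with U at least as extreme
  combos <- combn(6, 3)
  all_u <- apply(combos, 2, function(idx)
    sum(outer(scores[idx], scores[-idx], ">")))
  p_exact <- mean(abs(all_u - 4.5) >= abs(u_direct - 4.5))
  expect_equal(res$p, p_exact, tolerance = 1e-9)

  # perfectly monotone pair: Spearman rho = 1
  a <- setNames(1:8, sprintf("p%d", 1:8))
  b <- setNames((1:8)^3 + 2, sprintf("p%d", 1:8))
  expect_equal(associate(a, b, kind = "spearman")$estimate, 1)

  # null calibration: p-values uniform under permuted labels
  set.seed(6)
  ps <- vapply(1:400, function(i) {
    s <- setNames(rnorm(24), sprintf("p%d", 1:24))
    g <- factor(sample(rep(c("a", "b"), each = 12)))
    associate(s, g, kind = "wilcoxon")$p
  }, 0)
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("signature survival pipeline flags a protective planted signature", {
  cfg <- sim_config(n_bulk = 200, censor_rate = 0.2, seed = 43)
  sigs <- signature_set(list(protective = sprintf("g%04d", 300:340),
                             neutral = sprintf("g%04d", 400:440)))
  hr_prot <- vapply(1:10, function(i) {
    bk <- simulate_bulk_cohort(cfg, sigs,
                               effects = c(protective = -0.8, neutral = 0),
                               seed = 6000 + i)
    res <- suppressWarnings(signature_survival(bk$expr, sigs, bk$surv))
    res$hr[res$signature == "protective"]
  }, 0)
  expect_gte(mean(hr_prot < 1), 0.9)
})
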