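test_that("one-vs-rest DEG screen recovers planted markers and nulls cleanly", {
  co <- make_cohort(n_samples = 60, n_genes = 200, k = 3, effect = 3,
                    hazards = rep(0.002, 3), n_marker = 8, seed = 1)
  degs <- deg_one_vs_rest(co$expression, co$labels)
  # every C1 marker (shifted ~3 log2 units, > 4-fold) is recovered
  expect_true(all(co$markers$C1 %in% degs$C1$genes))
  # identical "groups": split duplicated data, nothing passes
  X <- co$expression[1:50, 1:10]
  dup <- cbind(X, X)
  colnames(dup) <- sprintf("S%02d", 1:20)
  same <- deg_one_vs_rest(dup, rep(1:2, each = 10), p_thresh = 0.05,
                          lfc_thresh = 0)
  # paired halves have identical means; log2FC exactly 0
  expect_equal(nrow(same$C1$table[same$C1$table$passed, ]), 0)
  # undersized subtype is skipped with a warning
  expect_warning(sk <- deg_one_vs_rest(co$expression[1:20, ],
                                       c(rep(1, 2), rep(2, 29), rep(3, 29))),
                 "skipped")
  expect_false("C1" %in% names(sk))
})

test_that("DEG type-I error under label permutation sits at the nominal level", {
  set.seed(2)
  expr <- matrix(2^rnorm(150 * 45, 3), 150, 45,
                 dimnames = list(sprintf("g%03d", 1:150), sprintf("S%02d", 1:45)))
  rates <- vapply(1:40, function(i) {
    labs <- sample(rep(1:3, 15))
    res <- deg_one_vs_rest(expr, labs, p_thresh = 0.05, lfc_thresh = 0)
    mean(unlist(lapply(res, function(r) r$table$p < 0.05)))
  }, 0)
  se <- sd(rates) / sqrt(length(rates))
  expect_lt(abs(mean(rates) - 0.05), 2 * se + 0.005)
})

test_that("ANOVA screen is calibrated, detects shifts, and reduces to t^2", {
  set.seed(3)
  m <- matrix(rnorm(400 * 30), 400, 30)
  null_p <- anova_screen(m, rep(1:3, each = 10))$p
  expect_gt(ks.test(null_p, "punif")$p.value, 0.01)
  m[1, 1:10] <- m[1, 1:10] + 5
  expect_true(anova_screen(m, rep(1:3, each = 10))$passed[1])
  # algebraic identity at k = 2: F equals the pooled-variance t squared
  x <- matrix(rnorm(30), 1)
  g <- rep(1:2, each = 15)
  f <- anova_screen(x, g)$f
  t2 <- t.test(x[1, g == 1], x[1, g == 2], var.equal = TRUE)$statistic^2
  expect_equal(unname(f), unname(t2), tolerance = 1e-10)
  # degenerate zero-variance feature flagged, p = 0
  z <- rbind(c(rep(0, 10), rep(1, 10), rep(2, 10)))
  res <- anova_screen(z, rep(1:3, each = 10))
  expect_true(res$degenerate[1])
  expect_equal(res$p[1], 0)
})

test_that("Fisher pair screen matches the hypergeometric oracle and classifies direction", {
  mut <- rbind(g1 = c(rep(1, 10), rep(0, 30)),
               g2 = c(rep(1, 10), rep(0, 30)),
               g3 = c(rep(0, 10), rep(1, 10), rep(0, 20)),
               dead = rep(0, 40))
  colnames(mut) <- paste0("s", 1:40)
  res <- fisher_pair_patterns(mut)
  expect_equal(attr(res, "skipped"), "dead")
  co_row <- res[res$gene_a == "g1" & res$gene_b == "g2", ]
  expect_equal(co_row$direction, "co_occurrence")
  expect_lt(co_row$p, 0.001)
  expect_equal(co_row$p, fisher_oracle(10, 0, 0, 30), tolerance = 1e-9)
  ex_row <- res[res$gene_a == "g1" & res$gene_b == "g3", ]
  expect_equal(ex_row$direction, "exclusivity")
  # (5,0,0,5): maximal co-occurrence, exact two-sided enumeration
  m2 <- rbind(a = c(rep(1, 5), rep(0, 5)), b = c(rep(1, 5), rep(0, 5)))
  colnames(m2) <- paste0("s", 1:10)
  r2 <- fisher_pair_patterns(m2)
  expect_equal(r2$p, fisher_oracle(5, 0, 0, 5), tolerance = 1e-12)
  # independence: p roughly uniform
  set.seed(4)
  big <- matrix(rbinom(20 * 60, 1, 0.4), 20, 60,
                dimnames = list(paste0("g", 1:20), paste0("s", 1:60)))
  ps <- fisher_pair_patterns(big)$p
  expect_gt(mean(ps), 0.3)   # Fisher p is conservative-discrete; far from 0
})

test_that("correlation screen handles sign modes and recovers planted cis pairs", {
  set.seed(5)
  x <- rnorm(20)
  X <- rbind(f = x)
  colnames(X) <- paste0("s", 1:20)
  Yp <- rbind(f = x); Yn <- rbind(f = -x)
  colnames(Yp) <- colnames(Yn) <- colnames(X)
  expect_true(correlation_screen(X, Yp)$flagged)
  expect_false(correlation_screen(X, Yn, sign = "positive")$flagged)
  expect_true(correlation_screen(X, Yn, sign = "absolute")$flagged)
  co <- make_cohort(n_samples = 150, n_genes = 100, k = 2, effect = 1,
                    hazards = c(0.002, 0.003), n_marker = 5, seed = 5)
  om <- make_paired_omics(co, cis_genes = 40, r_target = 0.8, seed = 5)
  scr <- correlation_screen(om$cnv, co$expression)
  cis <- scr[scr$feature_x %in% om$cis_genes, ]
  expect_gte(mean(cis$flagged), 0.95)
  # p values agree with cor.test
  one <- scr[1, ]
  ct <- cor.test(om$cnv[one$feature_x, ], co$expression[one$feature_x, ])
  expect_equal(one$p, ct$p.value, tolerance = 1e-9)
})

test_that("Kaplan-Meier matches the empirical survival curve without censoring", {
  set.seed(6)
  surv <- data.frame(time = rexp(80, 0.01), event = 1)
  res <- survival_compare(surv, rep(1:2, 40))
  sm <- summary(res$fit)
  # oracle: empirical survival function of each group
  for (g in 1:2) {
    t_g <- surv$time[rep(1:2, 40) == g]
    idx <- sm$strata == paste0("group=", g)
    emp <- vapply(sm$time[idx], function(t) mean(t_g > t), 0)
    expect_equal(sm$surv[idx], emp, tolerance = 1e-12)
  }
  # survival at t = 0 is 1
  expect_true(all(sm$surv <= 1))
  # identical groups: chi-square ~ 0, p ~ 1
  dup <- data.frame(time = rep(surv$time, 2), event = 1)
  same <- survival_compare(dup, rep(1:2, each = 80))
  expect_lt(same$chisq, 1e-9)
  expect_gt(same$p, 0.99)
})

test_that("log-rank separates planted hazard groups and flags zero-event groups", {
  set.seed(7)
  surv <- data.frame(time = c(rexp(100, 0.01), rexp(100, 0.03)), event = 1)
  res <- survival_compare(surv, rep(1:2, each = 100))
  expect_lt(res$p, 0.001)
  expect_warning(
    survival_compare(data.frame(time = rexp(20, 0.01),
                                event = rep(c(1, 0), each = 10)),
                     rep(1:2, each = 10)),
    "zero events")
})

test_that("the internal log-rank statistic matches survdiff", {
  for (s in 1:5) {
    set.seed(s)
    time <- rexp(40, 0.01)
    event <- rbinom(40, 1, 0.8)
    group <- rbinom(40, 1, 0.5)
    if (length(unique(group)) < 2 || sum(event) == 0) next
    ours <- pathsubtype:::logrank_chisq(time, event, group)
    ref <- survival::survdiff(survival::Surv(time, event) ~ group)$chisq
    expect_equal(ours, ref, tolerance = 1e-8)
  }
})

test_that("univariate Cox recovers planted effects and rejects constants", {
  set.seed(8)
  x <- rnorm(200)
  time <- rexp(200, rate = 0.01 * exp(0.7 * x))
  surv <- data.frame(time = time, event = 1)
  fit <- cox_univariate(surv, x)
  expect_true(fit$ci[1] < exp(0.7) && exp(0.7) < fit$ci[2])
  # independent covariate: HR near 1, CI covers 1
  fit0 <- cox_univariate(surv, rnorm(200))
  expect_true(fit0$ci[1] < 1 && 1 < fit0$ci[2])
  expect_error(cox_univariate(surv, rep(1, 200)), "lack of variation")
  # binary covariate: Cox score test agrees with the log-rank chi-square
  g <- rbinom(200, 1, 0.5)
  fitg <- cox_univariate(surv, g)
  score <- fitg$fit$score
  lr <- pathsubtype:::logrank_chisq(surv$time, surv$event, g)
  expect_equal(score, lr, tolerance = 1e-6)
})

test_that("maxstat finds a planted step cutpoint and degenerates gracefully", {
  set.seed(9)
  n <- 120
  score <- runif(n)
  rate <- ifelse(score > median(score), 0.03, 0.005)
  surv <- data.frame(time = rexp(n, rate), event = 1)
  res <- maxstat_cutpoint(surv, score, n_perm = 50, seed = 9)
  ranks <- rank(score)
  cut_rank <- sum(score <= res$cutpoint)
  expect_lte(abs(cut_rank - n / 2), 1)
  expect_lt(res$p_perm, 0.05)
  # two distinct values: the single candidate is returned
  s2 <- rep(c(0, 1), each = 10)
  sv2 <- data.frame(time = rexp(20, 0.01), event = 1)
  r2 <- maxstat_cutpoint(sv2, s2, n_perm = 20, seed = 1)
  expect_equal(nrow(r2$trace), 1)
  expect_equal(r2$cutpoint, 0.5)
  # no threshold can satisfy an absurd group-size bound
  expect_error(maxstat_cutpoint(sv2, s2, min_group_frac = 0.9), "group-size")
})

test_that("the naive maxstat p is anti-conservative relative to the permutation p", {
  set.seed(10)
  naive_hits <- 0; perm_hits <- 0
  n_sim <- 20
  for (i in 1:n_sim) {
    surv <- data.frame(time = rexp(50, 0.01), event = 1)
    res <- maxstat_cutpoint(surv, rnorm(50), n_perm = 49, seed = i)
    naive_hits <- naive_hits + (res$p_naive < 0.05)
    perm_hits <- perm_hits + (res$p_perm < 0.05)
  }
  expect_gt(naive_hits, n_sim * 0.05)   # selection inflates the naive test
  expect_lte(perm_hits, n_sim * 0.3)
})
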