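test_that("the context enumerator spans exactly the strand-collapsed classes", {
  ctx <- sbs96_contexts()
  expect_equal(nrow(ctx), 96)
  expect_equal(anyDuplicated(ctx$label), 0)
  expect_equal(length(unique(ctx$substitution)), 6)
  expect_true(all(table(ctx$substitution) == 16))
  expect_true(all(ctx$ref %in% c("C", "T")))
  expect_equal(substr(ctx$context, 2, 2), ctx$ref)
})

test_that("MAF-lite reading validates columns, contexts and variant types", {
  rows <- data.frame(
    sample = c("s1", "s1", "s2", "s2"),
    chrom = "chr1", pos = 1:4,
    ref = c("C", "G", "CC", "T"), alt = c("T", "A", "TT", "G"),
    type = c("SNP", "SNP", "DNP", "SNP"),
    ref_context = c("ACG", "CGT", "ACC", "ATG"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cat1 <- read_maf(path)
  expect_equal(nrow(cat1$records), 4)
  expect_equal(sum(cat1$records$snv), 3)       # DNP retained but flagged
  # malformed context (middle base != ref) is rejected row-wise
  rows$ref_context[1] <- "AAG"
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_message(cat2 <- read_maf(path), "rejected 1")
  expect_equal(nrow(cat2$records), 3)
  expect_equal(nrow(cat2$rejected), 1)
  # missing required column rejects the file
  write.table(rows[, -7], path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_maf(path), "ref_context")
})

test_that("context matrix strand-collapses by reverse complement and conserves counts", {
  rec <- data.frame(
    sample = c("s1", "s1", "s1"),
    chrom = "chr1", pos = 1:3,
    ref = c("C", "G", "G"), alt = c("T", "A", "A"),
    type = "SNP",
    ref_context = c("ACG", "CGT", "NGT"))
  cat1 <- pathsubtype:::new_mutation_catalog(rec)
  M <- build_context_matrix(cat1)
  # C>T at A_G counts directly; G>A at C_T reverse-complements to A[C>T]G
  expect_equal(unname(M$counts["A[C>T]G", "s1"]), 2L)
  expect_equal(M$skipped, 1)                   # ambiguous N flank
  expect_equal(sum(M$counts), 2)
  # conservation on a generated catalog
  W <- random_signature_profiles(2, seed = 9)
  model <- make_signature_model(W, matrix(c(3, 1, 1, 3), 2), seed = 9)
  cat2 <- make_mutation_catalog(model, 77, seed = 9)
  expect_equal(unname(colSums(build_context_matrix(cat2)$counts)), c(77L, 77L))
})

test_that("DBS records are summarized separately and TMB counts add up", {
  rec <- data.frame(
    sample = c("s1", "s1", "s1", "s2", "s3", "s3", "s3"),
    chrom = "chr1", pos = 1:7,
    ref = c("C", "C", "CC", "T", "C", "C", "C"),
    alt = c("T", "A", "TT", "G", "T", "T", "G"),
    type = c("SNP", "SNP", "DNP", "SNP", "SNP", "SNP", "SNP"),
    ref_context = c("ACG", "ACG", "ACC", "ATG", "ACG", "ACG", "ACG"))
  cat1 <- pathsubtype:::new_mutation_catalog(rec)
  dbs <- summarize_dbs(cat1)
  expect_equal(dbs$count[dbs$sample == "s1" & dbs$dbs == "CC>TT"], 1)
  burden <- tmb(cat1)
  expect_equal(burden$total, c(3L, 1L, 3L))
  expect_equal(burden$snv, c(2L, 1L, 3L))
  expect_true(all(burden$snv <= burden$total))
  # additivity under catalog concatenation
  both <- pathsubtype:::new_mutation_catalog(rbind(rec, rec))
  expect_equal(tmb(both)$total, 2L * burden$total)
})

test_that("KL-NMF recovers planted factors with a monotone objective", {
  W0 <- matrix(0, 96, 2)
  W0[1:40, 1] <- 1 / 40
  W0[50:96, 2] <- 1 / 47
  H0 <- matrix(c(400, 50, 60, 380, 250, 250, 500, 10), 2, 4)
  V <- W0 %*% H0
  rownames(V) <- sbs96_contexts()$label
  colnames(V) <- paste0("s", 1:4)
  sig <- extract_signatures(V, k_range = 2, restarts = 5, max_iter = 1000,
                            seed = 1)
  fit <- sig$fits[["2"]]
  cs <- cosine_similarity(fit$W, W0)
  expect_true(all(apply(cs, 2, max) >= 0.99))
  d <- diff(fit$objective)
  expect_true(all(d <= 1e-8 * pmax(abs(fit$objective[-length(fit$objective)]), 1)))
  # restart determinism under a fixed seed
  sig2 <- extract_signatures(V, k_range = 2, restarts = 5, max_iter = 1000,
                             seed = 1)
  expect_identical(sig$fits[["2"]]$W, sig2$fits[["2"]]$W)
})

test_that("rank-1 KL-NMF equals the closed-form marginal fixed point", {
  set.seed(2)
  V <- matrix(rpois(96 * 5, 20), 96, 5,
              dimnames = list(sbs96_contexts()$label, paste0("s", 1:5)))
  sig <- extract_signatures(V, k_range = 1, restarts = 3, max_iter = 2000,
                            seed = 2)
  W <- sig$fits[["1"]]$W
  marg <- rowSums(V) / sum(V)
  expect_gt(cosine_similarity(W, matrix(marg))[1, 1], 0.9999)
  expect_equal(unname(colSums(sig$fits[["1"]]$H)), unname(colSums(V)),
               tolerance = 1e-3)
})

test_that("reference matching reports argmax cosine and validates row order", {
  labels <- sbs96_contexts()$label
  ref <- random_signature_profiles(3, seed = 4)
  colnames(ref) <- c("REF1", "REF2", "REF3")
  exact <- match_reference(ref[, c(2, 1), drop = FALSE], ref)
  expect_equal(exact$best_match, c("REF2", "REF1"))
  expect_equal(exact$cosine, c(1, 1), tolerance = 1e-12)
  # orthogonal point masses have similarity 0
  A <- matrix(0, 96, 1, dimnames = list(labels, "X"))
  A[1, 1] <- 1
  B <- matrix(0, 96, 1, dimnames = list(labels, "Y"))
  B[2, 1] <- 1
  expect_equal(cosine_similarity(A, B)[1, 1], 0)
  # Dirichlet jitter at concentration 200 stays close
  set.seed(4)
  for (j in 1:3) {
    g <- rgamma(96, shape = 200 * ref[, j] + 1e-9)
    noisy <- matrix(g / sum(g), dimnames = list(labels, "N"))
    expect_gte(match_reference(noisy, ref)$cosine, 0.95)
  }
  bad <- ref[c(2, 1, 3:96), ]
  expect_error(match_reference(ref, bad), "canonical 96 contexts")
})

test_that("bipartite matching maximizes the one-to-one assignment", {
  ref <- random_signature_profiles(3, seed = 5)
  colnames(ref) <- paste0("R", 1:3)
  res <- match_reference(ref[, c(3, 1, 2)], ref, bipartite = TRUE)
  expect_setequal(res$bipartite_match, paste0("R", 1:3))
  expect_equal(res$bipartite_match, c("R3", "R1", "R2"))
})

test_that("refitting recovers planted mixtures and bounds spurious exposure", {
  W <- random_signature_profiles(3, seed = 6)
  set.seed(6)
  H0 <- matrix(rgamma(3 * 20, 2), 3, 20)
  model <- make_signature_model(W, H0, seed = 6)
  cat1 <- make_mutation_catalog(model, 1000, seed = 6)
  refit <- refit_exposures(build_context_matrix(cat1), W, n_boot = 10, seed = 6)
  truth <- sweep(H0, 2, colSums(H0), "/")
  expect_lt(sqrt(mean((refit$fractions - truth)^2)), 0.05)
  expect_equal(dim(refit$boot)[1], 10)
  expect_true(all(refit$boot >= 0))
  # single-signature truth: competitors get <= 2% of the total
  solo <- make_signature_model(W, matrix(c(1, 0, 0), 3, 5), seed = 7)
  cat2 <- make_mutation_catalog(solo, 1000, seed = 7)
  r2 <- refit_exposures(build_context_matrix(cat2), W, n_boot = 2, seed = 7)
  expect_true(all(colSums(r2$fractions[-1, , drop = FALSE]) <= 0.02))
})

test_that("signature-expression screen flags engineered genes, not anti-correlated ones", {
  set.seed(8)
  H <- matrix(runif(2 * 30), 2, 30,
              dimnames = list(c("SBSA", "SBSB"), sprintf("S%02d", 1:30)))
  H <- sweep(H, 2, colSums(H), "/")
  expr <- rbind(
    pos = 5 * H["SBSA", ] + rnorm(30, sd = 1e-3),
    neg = -5 * H["SBSA", ] + rnorm(30, sd = 1e-3),
    flat = rep(1, 30))
  colnames(expr) <- colnames(H)
  scr <- signature_expression_screen(H, expr)
  expect_true(scr$flagged[scr$gene == "pos" & scr$signature == "SBSA"])
  expect_false(scr$flagged[scr$gene == "neg" & scr$signature == "SBSA"])
  expect_equal(attr(scr, "skipped"), "flat")
})

test_that("the null rate of the joint exposure screen matches its analytic level", {
  set.seed(9)
  n <- 150
  H <- matrix(runif(n), 1, n, dimnames = list("SBSA", sprintf("S%03d", 1:n)))
  expr <- matrix(rnorm(2000 * n), 2000, n,
                 dimnames = list(sprintf("g%04d", 1:2000), colnames(H)))
  scr <- signature_expression_screen(H, expr)
  # joint flag = {r > max(0.2, critical r at p = .05)} under the null
  r_p <- sqrt(qt(0.975, n - 2)^2 / (qt(0.975, n - 2)^2 + n - 2))
  r_star <- max(0.2, r_p)
  t_star <- r_star * sqrt((n - 2) / (1 - r_star^2))
  expected <- pt(t_star, n - 2, lower.tail = FALSE)
  rate <- mean(scr$flagged)
  se <- sqrt(expected * (1 - expected) / 2000)
  expect_lt(abs(rate - expected), 3 * se + 1e-12)
})
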