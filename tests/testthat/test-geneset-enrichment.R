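test_that("GMT round trip parses, collapses duplicates and rejects bad input", {
  path <- write_toy_gmt(list(S1 = c("A", "B", "C"), S2 = c("A", "A", "B")))
  coll <- read_gmt(path)
  expect_setequal(coll$sets$S1, c("A", "B", "C"))
  expect_setequal(coll$sets$S2, c("A", "B"))    # duplicate collapsed
  bad <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("S1\tdesc\tA", "S2\tonly-two-fields"), bad)
  expect_error(read_gmt(bad), "line 2")
  dup <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("S1\tdesc\tA", "S1\tdesc\tB"), dup)
  expect_error(read_gmt(dup), "duplicated set name")
  out <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(coll, out)
  expect_identical(read_gmt(out)$sets, coll$sets)
})

test_that("jaccard matches hand enumeration", {
  expect_equal(jaccard(c("A", "B"), c("A", "B")), 1)
  expect_equal(jaccard(c("A", "B"), c("C", "D")), 0)
  expect_equal(jaccard(c("A", "B", "C"), c("B", "C", "D")), 0.5)
  expect_error(jaccard(character(0), "A"), "non-empty")
})

test_that("greedy de-duplication matches the brute-force replay and is idempotent", {
  # identical pair: one retained, log carries J = 1
  twin <- new_geneset_collection(list(A = letters[1:5], B = letters[1:5]))
  res <- dedup_collection(twin, 0.6)
  expect_length(res$collection$sets, 1)
  expect_equal(res$log$jaccard, 1)
  # all below threshold: idempotent passthrough
  free <- new_geneset_collection(list(A = letters[1:5], B = letters[10:14]))
  expect_identical(dedup_collection(free, 0.6)$collection$sets, free$sets)

  # 5-set toys with engineered overlaps, checked against the oracle
  toys <- list(
    list(A = letters[1:10], B = letters[2:10], C = letters[1:4],
         D = letters[15:20], E = c(letters[1:8], "x", "y")),
    list(P = letters[1:6], Q = letters[4:9], R = letters[1:9],
         S = letters[20:26], T = letters[5:9]))
  for (sets in toys) {
    coll <- new_geneset_collection(sets)
    got <- dedup_collection(coll, 0.6)
    expect_setequal(names(got$collection$sets), dedup_oracle(sets, 0.6))
    # retained pairwise similarity strictly below threshold
    nm <- names(got$collection$sets)
    for (i in seq_along(nm)) for (j in seq_len(i - 1)) {
      expect_lt(jaccard(got$collection$sets[[i]], got$collection$sets[[j]]), 0.6)
    }
    again <- dedup_collection(got$collection, 0.6)
    expect_identical(again$collection$sets, got$collection$sets)
    expect_equal(nrow(again$log), 0)
  }

  # idempotence on random collections
  for (s in 1:5) {
    set.seed(s)
    sets <- lapply(1:8, function(i) sample(letters, sample(4:12, 1)))
    names(sets) <- paste0("R", 1:8)
    once <- dedup_collection(new_geneset_collection(sets), 0.5)
    twice <- dedup_collection(once$collection, 0.5)
    expect_identical(twice$collection$sets, once$collection$sets)
  }
})

test_that("enrichment walk matches the direct oracle and peaks for top genes", {
  set.seed(2)
  genes <- sprintf("g%02d", 1:10)
  expr <- matrix(rexp(10 * 4), 10, 4, dimnames = list(genes, paste0("S", 1:4)))
  # make g01 the clear top gene of sample 1 only
  expr["g01", ] <- c(50, 0.01, 0.01, 0.01)
  coll <- new_geneset_collection(list(TOP = "g01", TRIO = genes[2:4]))
  E <- score_enrichment(expr, coll, min_size = 1)
  for (j in 1:4) {
    expect_equal(E$scores["TRIO", j],
                 walk_score_oracle(expr[, j], genes, genes[2:4]),
                 tolerance = 1e-12)
  }
  expect_equal(which.max(E$scores["TOP", ]), c(S1 = 1L))
})

test_that("scores are invariant to gene order and monotone transforms", {
  set.seed(3)
  genes <- sprintf("g%02d", 1:30)
  expr <- matrix(rexp(30 * 5), 30, 5, dimnames = list(genes, paste0("S", 1:5)))
  coll <- new_geneset_collection(list(A = genes[1:8], B = genes[10:20]))
  E <- score_enrichment(expr, coll)
  perm <- sample(30)
  expect_equal(score_enrichment(expr[perm, ], coll)$scores, E$scores)
  expect_equal(score_enrichment(2 * expr, coll)$scores, E$scores)
  # random strictly monotone maps preserve ranks hence scores
  for (s in 1:5) {
    set.seed(s)
    f <- function(x) exp(x / max(x)) + 0.1 * x
    expect_equal(score_enrichment(apply(expr, 2, f), coll)$scores, E$scores)
  }
})

test_that("size bounds are applied after universe intersection and logged", {
  genes <- sprintf("g%02d", 1:20)
  expr <- matrix(rexp(20 * 3), 20, 3, dimnames = list(genes, paste0("S", 1:3)))
  coll <- new_geneset_collection(list(
    small = genes[1:2], ok = genes[1:6],
    half_out = c(genes[1:3], "absent1", "absent2")))
  E <- score_enrichment(expr, coll, min_size = 5)
  expect_setequal(rownames(E$scores), "ok")
  expect_setequal(E$dropped$set, c("small", "half_out"))
  expect_error(score_enrichment(expr,
    new_geneset_collection(list(X = c("nope", "nada")))), "overlap")
})

test_that("differential enrichment flags planted shifts and is label-symmetric", {
  set.seed(4)
  scores <- matrix(rnorm(20 * 40), 20, 40,
                   dimnames = list(paste0("sig", 1:20), paste0("S", 1:40)))
  scores[7, 1:20] <- scores[7, 1:20] + 5
  gA <- paste0("S", 1:20); gB <- paste0("S", 21:40)
  tab <- differential_enrichment(scores, gA, gB, p_thresh = 0.01, fc_thresh = 0)
  expect_equal(tab$signature[1], "sig7")
  swapped <- differential_enrichment(scores, gB, gA, p_thresh = 0.01, fc_thresh = 0)
  i <- match(tab$signature, swapped$signature)
  expect_equal(swapped$t[i], -tab$t, tolerance = 1e-12)
  expect_equal(swapped$p[i], tab$p, tolerance = 1e-12)
  # identical groups (same values duplicated): nothing flagged, p = 1
  dup <- cbind(scores[, 1:5], scores[, 1:5])
  colnames(dup) <- paste0("S", 1:10)
  same <- differential_enrichment(dup, paste0("S", 1:5), paste0("S", 6:10))
  expect_false(any(same$passed))
  expect_equal(same$t, rep(0, 20), tolerance = 1e-12)
  # zero variance in both groups: p reported NaN and flagged NA, not dropped
  flat <- matrix(1, 2, 10, dimnames = list(c("f1", "f2"), paste0("S", 1:10)))
  fres <- differential_enrichment(flat, paste0("S", 1:5), paste0("S", 6:10))
  expect_true(all(is.nan(fres$p)))
  expect_true(all(is.na(fres$passed)))
  expect_equal(nrow(fres), 2)
})
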