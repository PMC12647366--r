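# Shared fixture builders. Everything is generated in code at test time.

# Write a GMT file from a named list of gene vectors; returns the path.
write_toy_gmt <- function(sets, source = "toy") {
  path <- withr::local_tempfile(fileext = ".gmt", .local_envir = parent.frame())
  writeLines(vapply(names(sets), function(nm)
    paste(c(nm, source, sets[[nm]]), collapse = "\t"), ""), path)
  path
}

# Latent-factor expression: `sizes[i]` genes loading on factor i plus
# `n_noise` independent genes; high within-module correlation, none across.
make_module_expr <- function(sizes, n_noise = 30, n_samples = 100,
                             loading = 0.9, seed = 1) {
  set.seed(seed)
  factors <- matrix(rnorm(length(sizes) * n_samples), length(sizes))
  blocks <- lapply(seq_along(sizes), function(i) {
    t(sapply(seq_len(sizes[i]), function(j)
      loading * factors[i, ] + sqrt(1 - loading^2) * rnorm(n_samples)))
  })
  X <- do.call(rbind, c(blocks, list(matrix(rnorm(n_noise * n_samples),
                                            n_noise, n_samples))))
  rownames(X) <- sprintf("g%03d", seq_len(nrow(X)))
  colnames(X) <- sprintf("S%03d", seq_len(n_samples))
  list(expr = X,
       truth = c(rep(seq_along(sizes), times = sizes), rep(0L, n_noise)))
}

# Small separable cohort plus a hub matrix covering every subtype.
make_classifier_fixture <- function(n = 160, k = 5, effect = 3, seed = 7,
                                    genes_per_subtype = 2) {
  cohort <- make_cohort(n_samples = n, n_genes = 100, k = k, effect = effect,
                        seed = seed, n_marker = 10,
                        hazards = seq(0.0015, 0.0035, length.out = k))
  hub_genes <- as.vector(sapply(cohort$markers, `[`,
                                seq_len(genes_per_subtype)))
  list(cohort = cohort, hub = cohort$expression[hub_genes, ])
}

# Independent greedy de-dup oracle: replays the full pairwise-matrix greedy
# in visitation order (size desc, name), with the same preference rule, but
# written as a direct replay over an explicit conflict matrix.
dedup_oracle <- function(sets, threshold) {
  nm <- names(sets)
  J <- outer(nm, nm, Vectorize(function(a, b)
    length(intersect(sets[[a]], sets[[b]])) /
      length(union(sets[[a]], sets[[b]]))))
  dimnames(J) <- list(nm, nm)
  visit <- nm[order(-lengths(sets), nm)]
  pref <- function(a, b) {
    ua <- sum(!(sets[[a]] %in% sets[[b]]))
    ub <- sum(!(sets[[b]] %in% sets[[a]]))
    if (ua != ub) ua > ub else a < b
  }
  kept <- character(0)
  for (cand in visit) {
    clash <- kept[J[cand, kept] >= threshold]
    if (length(clash) == 0) kept <- c(kept, cand)
    else if (all(vapply(clash, function(r) pref(cand, r), TRUE)))
      kept <- c(setdiff(kept, clash), cand)
  }
  sort(kept)
}

# Direct ssGSEA-style walk for one sample, written independently of the
# package implementation (explicit position loop).
walk_score_oracle <- function(values, genes, set, tau = 1) {
  r <- rank(values, ties.method = "average")
  ord <- order(-r, genes)
  g <- genes[ord]; w <- r[ord]^tau
  inset <- g %in% set
  n <- length(genes); m <- sum(inset)
  p_in <- 0; p_out <- 0; total <- 0
  win_sum <- sum(w[inset])
  for (i in seq_len(n)) {
    if (inset[i]) p_in <- p_in + w[i] / win_sum else p_out <- p_out + 1 / (n - m)
    total <- total + (p_in - p_out)
  }
  unname(total / n)
}

# Two-sided Fisher p by exhaustive hypergeometric enumeration.
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n_ <- c + d; k <- a + c
  xs <- max(0, k - n_):min(k, m)
  probs <- dhyper(xs, m, n_, k)
  obs <- dhyper(a, m, n_, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Hand TOM formula for a small adjacency matrix.
tom_oracle <- function(A) {
  p <- nrow(A)
  k <- rowSums(A) - 1
  TOM <- diag(p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i == j) next
    l <- sum(A[i, -c(i, j)] * A[-c(i, j), j])
    TOM[i, j] <- (l + A[i, j]) / (min(k[i], k[j]) + 1 - A[i, j])
  }
  TOM
}

# Exhaustive PAM oracle: the medoid set minimizing total distance.
pam_oracle <- function(D, k) {
  n <- nrow(D)
  best <- NULL
  for (med in utils::combn(n, k, simplify = FALSE)) {
    cost <- sum(apply(D[, med, drop = FALSE], 1, min))
    if (is.null(best) || cost < best$cost) best <- list(medoids = med, cost = cost)
  }
  best$labels <- apply(D[, best$medoids, drop = FALSE], 1, which.min)
  best
}
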