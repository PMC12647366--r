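# Synthetic-cohort generators. These plant the statistical structure every
# downstream stage assumes (subtype marker blocks, exposure-mixed mutation
# catalogs, cis-correlated omics triples, subtype-dependent survival), so the
# whole pipeline is testable without any external download.

#' Generate a synthetic expression cohort with planted subtypes
#'
#' Expression is log-normal: each gene has a baseline log2 mean, each subtype
#' adds a shift of `effect` (in units of the within-gene noise SD, which is 1)
#' on its own disjoint marker-gene block, and values are exponentiated back to
#' an FPKM-like non-negative scale. Survival times are exponential with a
#' per-subtype hazard; censoring is independent uniform on `[0, max_time]`
#' with `max_time` calibrated so the expected censored fraction equals
#' `censor_rate`.
#'
#' @param n_samples Number of samples (default 160, a typical bulk cohort).
#' @param n_genes Number of genes.
#' @param k Number of planted subtypes (>= 2).
#' @param effect Marker-block mean shift in SD units (>= 0).
#' @param censor_rate Expected fraction of censored samples in `[0, 1)`.
#' @param hazards Per-subtype exponential hazard (per day); length `k`.
#' @param n_marker Marker-block size per subtype.
#' @param seed Integer seed; the generator is fully seed-deterministic.
#' @return A `synthetic_cohort` list: `expression` (gene x sample, FPKM-like),
#'   `labels` (named integer vector in 1..k), `survival` (data.frame with
#'   sample, time, event), `markers` (list of marker-gene blocks per subtype),
#'   and `params` (all generator settings).
#' @export
make_cohort <- function(n_samples = 160, n_genes = 500, k = 5, effect = 2,
                        censor_rate = 0.2,
                        hazards = seq(0.0015, 0.0035, length.out = k),
                        n_marker = 20, seed = 1) {
  assert_that(k >= 2, "k must be >= 2")
  assert_that(n_samples >= k, "n_samples must be >= k")
  assert_that(censor_rate >= 0 && censor_rate < 1, "censor_rate must be in `[0, 1)`")
  assert_that(effect >= 0, "effect must be >= 0")
  assert_that(length(hazards) == k && all(hazards > 0), "hazards must be k positive rates")
  assert_that(n_marker * k <= n_genes, "marker blocks exceed n_genes")

  set.seed(derive_seed(seed))
  genes <- sprintf("g%04d", seq_len(n_genes))
  samples <- sprintf("S%03d", seq_len(n_samples))
  labels <- rep(seq_len(k), length.out = n_samples)
  names(labels) <- samples

  markers <- lapply(seq_len(k), function(i) genes[((i - 1) * n_marker + 1):(i * n_marker)])
  names(markers) <- paste0("C", seq_len(k))

  base_mu <- stats::rnorm(n_genes, mean = 3, sd = 1)
  logx <- matrix(stats::rnorm(n_genes * n_samples, sd = 1), n_genes, n_samples,
                 dimnames = list(genes, samples))
  logx <- logx + base_mu
  for (i in seq_len(k)) {
    idx <- which(labels == i)
    logx[markers[[i]], idx] <- logx[markers[[i]], idx] + effect
  }
  expression <- 2^logx

  time_true <- stats::rexp(n_samples, rate = hazards[labels])
  if (censor_rate > 0) {
    # Expected censored fraction for C ~ U(0, M), T ~ Exp(lambda) mixture:
    # mean over subtypes of (1 - exp(-lambda M)) / (lambda M); solve for M.
    frac <- function(M) mean((1 - exp(-hazards * M)) / (hazards * M))
    max_time <- stats::uniroot(function(M) frac(M) - censor_rate,
                               lower = 1e-6, upper = 1e9, tol = 1e-8)$root
    cens <- stats::runif(n_samples, 0, max_time)
    event <- as.integer(time_true <= cens)
    time <- pmin(time_true, cens)
  } else {
    event <- rep(1L, n_samples)
    time <- time_true
  }
  time <- pmax(time, 1e-6)

  structure(list(
    expression = expression,
    labels = labels,
    survival = data.frame(sample = samples, time = time, event = event,
                          stringsAsFactors = FALSE),
    markers = markers,
    params = list(n_samples = n_samples, n_genes = n_genes, k = k,
                  effect = effect, censor_rate = censor_rate,
                  hazards = hazards, n_marker = n_marker, seed = seed)
  ), class = "synthetic_cohort")
}

#' Marker gene sets of a synthetic cohort
#'
#' Convenience accessor returning the planted marker blocks as a gene-set
#' collection, optionally padded with random decoy sets drawn from the
#' non-marker universe.
#'
#' @param cohort A `synthetic_cohort`.
#' @param n_decoy Number of random decoy sets to append.
#' @param decoy_size Genes per decoy set.
#' @param seed Seed for decoy sampling.
#' @return A `geneset_collection`.
#' @export
cohort_marker_sets <- function(cohort, n_decoy = 0, decoy_size = 20, seed = 1) {
  sets <- cohort$markers
  if (n_decoy > 0) {
    set.seed(derive_seed(seed, 1L))
    universe <- setdiff(rownames(cohort$expression), unlist(cohort$markers))
    for (i in seq_len(n_decoy)) {
      sets[[sprintf("DECOY%02d", i)]] <- sample(universe, decoy_size)
    }
  }
  new_geneset_collection(sets, source = rep("synthetic", length(sets)))
}

#' Generate a gene-set collection with controlled pairwise Jaccard overlap
#'
#' All sets have `set_size` genes. For each pair the number of shared genes is
#' the feasible count closest to the requested Jaccard target
#' (`s / (2m - s) = J`). Shared genes for the pair (i, j), i < j, are taken
#' from set i; the realized pairwise Jaccard is verified within +/- 0.05 of
#' each target and the construction is rejected as infeasible otherwise (e.g.
#' when one set's total sharing obligations exceed its size, or the universe
#' is too small).
#'
#' @param n_sets Number of sets.
#' @param set_size Genes per set.
#' @param overlap_matrix Symmetric matrix of pairwise Jaccard targets in
#'   `[0, 1]` (diagonal ignored); a scalar is recycled to all pairs; default 0
#'   (disjoint sets).
#' @param universe Character vector of available gene ids.
#' @param seed Integer seed.
#' @return A `geneset_collection` with attribute `realized_jaccard`.
#' @export
make_geneset_collection <- function(n_sets, set_size, overlap_matrix = 0,
                                    universe, seed = 1) {
  if (length(overlap_matrix) == 1) {
    overlap_matrix <- matrix(overlap_matrix, n_sets, n_sets)
  }
  assert_that(all(dim(overlap_matrix) == c(n_sets, n_sets)),
              "overlap_matrix must be n_sets x n_sets (or scalar)")
  assert_that(all(overlap_matrix >= 0 & overlap_matrix <= 1),
              "Jaccard targets must lie in `[0, 1]`")
  set.seed(derive_seed(seed, 2L))
  universe <- unique(universe)
  pool <- sample(universe)   # randomized draw order, seed-deterministic

  # Nearest feasible shared count for target J between two size-m sets.
  shared_for <- function(J, m) {
    s <- 0:m
    s[which.min(abs(s / (2 * m - s) - J))]
  }
  m <- set_size
  shared <- matrix(0L, n_sets, n_sets)
  for (i in seq_len(n_sets)) for (j in seq_len(n_sets)) {
    if (i < j) shared[i, j] <- shared_for(overlap_matrix[i, j], m)
  }
  # Set i donates shared[i, j] genes to each later set j; set j must also
  # absorb its obligations within its size.
  give <- rowSums(shared)
  take <- colSums(shared)
  if (any(give > m) || any(take > m)) {
    stop(sprintf(paste0(
      "infeasible overlap request: set sharing obligations (max donate %d, ",
      "max absorb %d) exceed set_size %d"), max(give), max(take), m), call. = FALSE)
  }
  need_fresh <- n_sets * m - sum(shared)
  assert_that(length(pool) >= need_fresh,
              sprintf("universe too small: need %d fresh genes, have %d",
                      need_fresh, length(pool)))

  sets <- vector("list", n_sets)
  names(sets) <- sprintf("SET%02d", seq_len(n_sets))
  cursor <- 0L
  fresh <- function(nn) {
    if (nn == 0) return(character(0))
    out <- pool[(cursor + 1):(cursor + nn)]
    cursor <<- cursor + nn
    out
  }
  for (i in seq_len(n_sets)) {
    inherited <- character(0)
    if (i > 1) {
      for (j in seq_len(i - 1)) {
        if (shared[j, i] > 0) {
          avail <- setdiff(sets[[j]], inherited)
          assert_that(length(avail) >= shared[j, i],
                      "infeasible overlap request: donor set exhausted")
          inherited <- c(inherited, avail[seq_len(shared[j, i])])
        }
      }
    }
    sets[[i]] <- c(inherited, fresh(m - length(inherited)))
  }

  realized <- diag(1, n_sets)
  for (i in seq_len(n_sets)) for (j in seq_len(n_sets)) {
    if (i < j) realized[i, j] <- realized[j, i] <- jaccard(sets[[i]], sets[[j]])
  }
  off <- upper.tri(realized)
  if (any(abs(realized[off] - overlap_matrix[off]) > 0.05 +
          abs(shared_jaccard_gap(m)))) {
    stop("infeasible overlap request: realized Jaccard deviates > 0.05 from target",
         call. = FALSE)
  }
  coll <- new_geneset_collection(sets, source = rep("synthetic", n_sets))
  attr(coll, "realized_jaccard") <- realized
  coll
}

# Max gap between adjacent achievable Jaccard values for size-m sets; the
# +/-0.05 check is relaxed by this discretization limit.
shared_jaccard_gap <- function(m) {
  s <- 0:m
  max(diff(s / (2 * m - s))) / 2
}

#' Generate a mutation catalog from planted signature exposures
#'
#' Each sample's mutations are drawn multinomially over the 96 trinucleotide
#' substitution classes with probabilities given by its exposure-weighted
#' mixture of the planted profiles. Context strings are emitted in a
#' `ref_context` column (5' base, ref, 3' base, pyrimidine frame), so no
#' reference genome is needed.
#'
#' @param model A `planted_signature_model` from [make_signature_model()].
#' @param n_mut_per_sample Mutations drawn per sample.
#' @param seed Integer seed.
#' @return A `mutation_catalog` (see [read_maf()]) whose records are MAF-lite
#'   rows: sample, chrom, pos, ref, alt, type, ref_context.
#' @export
make_mutation_catalog <- function(model, n_mut_per_sample, seed = 1) {
  stopifnot(inherits(model, "planted_signature_model"))
  W <- model$profiles
  H <- model$exposures
  totals <- colSums(H)
  if (any(totals <= 0)) {
    stop("zero total exposure for sample(s): ",
         paste(colnames(H)[totals <= 0], collapse = ", "), call. = FALSE)
  }
  set.seed(derive_seed(seed, 3L))
  ctx <- sbs96_contexts()
  rows <- vector("list", ncol(H))
  pos0 <- 0L
  for (s in seq_len(ncol(H))) {
    p <- as.vector(W %*% (H[, s] / totals[s]))
    counts <- as.vector(stats::rmultinom(1, n_mut_per_sample, p))
    idx <- rep(seq_len(96), counts)
    rows[[s]] <- data.frame(
      sample = colnames(H)[s],
      chrom = "chr1",
      pos = pos0 + seq_along(idx) * 10L,
      ref = ctx$ref[idx],
      alt = ctx$alt[idx],
      type = "SNP",
      ref_context = ctx$context[idx],
      stringsAsFactors = FALSE
    )
    pos0 <- pos0 + length(idx) * 10L
  }
  records <- do.call(rbind, rows)
  new_mutation_catalog(records)
}

#' Construct a planted mutational-signature model
#'
#' @param profiles 96 x r matrix; columns are normalized to sum to 1. Row
#'   order must be the canonical 96-context order ([sbs96_contexts()]); if
#'   rownames are absent the canonical order is assumed.
#' @param exposures r x samples non-negative matrix of planted activities.
#' @param seed Seed recorded with the model.
#' @return A `planted_signature_model`.
#' @export
make_signature_model <- function(profiles, exposures, seed = 1) {
  assert_that(nrow(profiles) == 96, "profiles must have 96 rows")
  assert_that(all(profiles >= 0), "profiles must be non-negative")
  assert_that(all(exposures >= 0), "exposures must be non-negative")
  assert_that(ncol(profiles) == nrow(exposures),
              "profiles columns must match exposures rows")
  profiles <- sweep(profiles, 2, colSums(profiles), "/")
  rownames(profiles) <- sbs96_contexts()$label
  if (is.null(colnames(profiles)))
    colnames(profiles) <- paste0("P", seq_len(ncol(profiles)))
  rownames(exposures) <- colnames(profiles)
  if (is.null(colnames(exposures)))
    colnames(exposures) <- sprintf("S%03d", seq_len(ncol(exposures)))
  stopifnot(all(abs(colSums(profiles) - 1) < 1e-9))
  structure(list(profiles = profiles, exposures = exposures, seed = seed),
            class = "planted_signature_model")
}

#' Random well-separated signature profiles
#'
#' Draws r sparse Dirichlet-like profiles concentrated on disjoint context
#' blocks, giving low pairwise cosine similarity -- convenient planted truth
#' for extraction tests.
#'
#' @param r Number of profiles.
#' @param concentration Within-block Dirichlet concentration.
#' @param seed Integer seed.
#' @return 96 x r column-stochastic matrix.
#' @export
random_signature_profiles <- function(r, concentration = 1, seed = 1) {
  assert_that(r >= 1 && r <= 8, "r must be in 1..8")
  set.seed(derive_seed(seed, 4L))
  blocks <- split(seq_len(96), rep(seq_len(r), length.out = 96))
  W <- matrix(0, 96, r, dimnames = list(sbs96_contexts()$label,
                                        paste0("P", seq_len(r))))
  for (j in seq_len(r)) {
    g <- stats::rgamma(length(blocks[[j]]), shape = concentration)
    W[blocks[[j]], j] <- g / sum(g)
  }
  W
}

#' Generate CNV, protein and methylation layers paired to a cohort
#'
#' For the first `cis_genes` genes, the copy-number value is built to have
#' Pearson correlation ~ `r_target` with the gene's (log) expression, and the
#' protein value to have ~ `r_target` with the copy number. Methylation betas
#' are probit-bounded in `[0, 1]`, with the designated sites negatively
#' correlated with their target gene's expression. Remaining rows are
#' independent noise.
#'
#' @param cohort A `synthetic_cohort`.
#' @param cis_genes Number of leading genes given planted cis structure.
#' @param r_target Target Pearson correlation in (0, 1).
#' @param seed Integer seed.
#' @return List with `cnv`, `protein`, `methylation` matrices (gene x sample)
#'   and `cis_genes` (the planted gene ids).
#' @export
make_paired_omics <- function(cohort, cis_genes, r_target, seed = 1) {
  assert_that(r_target > 0 && r_target < 1, "r_target must be in (0, 1)")
  expr <- cohort$expression
  assert_that(cis_genes <= nrow(expr), "cis_genes exceeds n_genes")
  set.seed(derive_seed(seed, 5L))
  n <- ncol(expr)
  genes <- rownames(expr)
  z <- t(scale(t(log2(expr + 1))))      # standardized log expression
  z[is.na(z)] <- 0

  mix <- function(base, r) r * base + sqrt(1 - r^2) *
    matrix(stats::rnorm(length(base)), nrow(base), ncol(base))

  cnv <- matrix(stats::rnorm(nrow(expr) * n), nrow(expr), n,
                dimnames = dimnames(expr))
  prot <- matrix(stats::rnorm(nrow(expr) * n), nrow(expr), n,
                 dimnames = dimnames(expr))
  ci <- seq_len(cis_genes)
  cnv[ci, ] <- mix(z[ci, , drop = FALSE], r_target)
  zc <- t(scale(t(cnv[ci, , drop = FALSE])))
  prot[ci, ] <- mix(zc, r_target)
  meth_raw <- matrix(stats::rnorm(nrow(expr) * n), nrow(expr), n,
                     dimnames = dimnames(expr))
  meth_raw[ci, ] <- mix(-z[ci, , drop = FALSE], r_target)
  methylation <- stats::pnorm(meth_raw)

  list(cnv = cnv, protein = prot, methylation = methylation,
       cis_genes = genes[ci],
       params = list(cis_genes = cis_genes, r_target = r_target, seed = seed))
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d genes x %d samples, k = %d, effect = %g SD\n",
              nrow(x$expression), ncol(x$expression), x$params$k, x$params$effect))
  invisible(x)
}
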