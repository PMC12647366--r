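# Mutational-signature analysis: 96-trinucleotide-context catalogs from
# MAF-lite input, de novo extraction by Kullback-Leibler NMF with cophenetic
# rank selection, cosine matching against a reference catalogue, and
# non-negative least-squares refitting with bootstrap stability.

BASES <- c("A", "C", "G", "T")
SBS_SUBSTITUTIONS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' The canonical 96 trinucleotide substitution classes
#'
#' Strand-collapsed single-base substitutions: the six pyrimidine-reference
#' changes crossed with the 16 combinations of 5'/3' flanking bases, in the
#' conventional fixed order (substitution major, then 5' base, then 3' base:
#' `A[C>A]A`, `A[C>A]C`, ...).
#'
#' @return Data.frame with 96 rows: label, substitution, ref, alt, flank5,
#'   flank3 and context (the 3-base ref_context string).
#' @export
sbs96_contexts <- function() {
  grid <- expand.grid(flank3 = BASES, flank5 = BASES,
                      substitution = SBS_SUBSTITUTIONS,
                      stringsAsFactors = FALSE)[, c("substitution", "flank5", "flank3")]
  grid <- grid[order(match(grid$substitution, SBS_SUBSTITUTIONS),
                     grid$flank5, grid$flank3), ]
  ref <- substr(grid$substitution, 1, 1)
  alt <- substr(grid$substitution, 3, 3)
  data.frame(
    label = paste0(grid$flank5, "[", grid$substitution, "]", grid$flank3),
    substitution = grid$substitution, ref = ref, alt = alt,
    flank5 = grid$flank5, flank3 = grid$flank3,
    context = paste0(grid$flank5, ref, grid$flank3),
    stringsAsFactors = FALSE, row.names = NULL)
}

revcomp_base <- function(b) c(A = "T", C = "G", G = "C", T = "A", N = "N")[b]

new_mutation_catalog <- function(records, rejected = NULL) {
  required <- c("sample", "chrom", "pos", "ref", "alt", "type", "ref_context")
  assert_that(all(required %in% colnames(records)),
              paste("catalog records missing columns:",
                    paste(setdiff(required, colnames(records)), collapse = ", ")))
  structure(list(records = records, rejected = rejected %||%
                   records[0, , drop = FALSE]),
            class = "mutation_catalog")
}

#' @export
print.mutation_catalog <- function(x, ...) {
  cat(sprintf("mutation_catalog: %d records, %d samples (%d rejected rows)\n",
              nrow(x$records), length(unique(x$records$sample)),
              nrow(x$rejected)))
  invisible(x)
}

is_snv <- function(records) {
  nchar(records$ref) == 1 & nchar(records$alt) == 1 &
    records$ref != records$alt &
    records$ref %in% BASES & records$alt %in% BASES
}

#' Read a MAF-lite mutation table
#'
#' Tab-separated with header columns sample, chrom, pos, ref, alt, type,
#' ref_context (5' base + ref + 3' base). SNV rows whose context is
#' malformed (wrong length or middle base not equal to ref) are rejected
#' row-wise and reported; non-SNV rows (DNPs, indels) are retained and
#' flagged in the `snv` column.
#'
#' @param path Path to a MAF-lite TSV.
#' @return A `mutation_catalog` with `records` (including a logical `snv`
#'   column) and `rejected` (the malformed rows).
#' @export
read_maf <- function(path) {
  assert_that(file.exists(path), paste0("file not found: ", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("sample", "chrom", "pos", "ref", "alt", "type", "ref_context")
  missing <- setdiff(required, colnames(df))
  if (length(missing) > 0) {
    stop("MAF-lite file missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df$sample <- as.character(df$sample)
  snv <- is_snv(df)
  bad <- snv & (nchar(df$ref_context) != 3 |
                  substr(df$ref_context, 2, 2) != df$ref)
  rejected <- df[bad, , drop = FALSE]
  if (nrow(rejected) > 0) {
    message(sprintf("read_maf: rejected %d SNV row(s) with malformed ref_context",
                    nrow(rejected)))
  }
  df <- df[!bad, , drop = FALSE]
  df$snv <- is_snv(df)
  new_mutation_catalog(df, rejected = rejected)
}

#' Write a mutation catalog as MAF-lite TSV
#'
#' @param cat A `mutation_catalog`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_maf <- function(cat, path) {
  cols <- c("sample", "chrom", "pos", "ref", "alt", "type", "ref_context")
  write_table_tsv(cat$records[, cols], path)
}

#' Build the 96-context count matrix from a mutation catalog
#'
#' Purine-reference SNVs are reverse-complemented (substitution and both
#' flanks) into the pyrimidine frame before counting, so column sums equal
#' per-sample strand-collapsed SNV counts. Rows with an ambiguous base (N)
#' in the context are skipped and counted.
#'
#' @param cat A `mutation_catalog`.
#' @return A `context_matrix`: list with `counts` (96 x samples integer
#'   matrix in canonical row order) and `skipped` (ambiguous-base rows).
#' @export
build_context_matrix <- function(cat) {
  rec <- cat$records
  assert_that(nrow(rec) > 0, "catalog is empty")
  rec <- rec[is_snv(rec), , drop = FALSE]
  f5 <- substr(rec$ref_context, 1, 1)
  f3 <- substr(rec$ref_context, 3, 3)
  ref <- rec$ref; alt <- rec$alt
  pur <- ref %in% c("A", "G")
  # reverse complement: flanks swap and complement, bases complement
  nf5 <- ifelse(pur, revcomp_base(f3), f5)
  nf3 <- ifelse(pur, revcomp_base(f5), f3)
  nref <- ifelse(pur, revcomp_base(ref), ref)
  nalt <- ifelse(pur, revcomp_base(alt), alt)
  ambiguous <- nf5 == "N" | nf3 == "N" | nref == "N" | nalt == "N" |
    is.na(nf5) | is.na(nf3)
  skipped <- sum(ambiguous)
  keep <- !ambiguous
  labels <- paste0(nf5[keep], "[", nref[keep], ">", nalt[keep], "]", nf3[keep])
  ctx <- sbs96_contexts()
  samples <- sort(unique(cat$records$sample))
  counts <- matrix(0L, 96, length(samples),
                   dimnames = list(ctx$label, samples))
  tab <- table(factor(labels, levels = ctx$label),
               factor(rec$sample[keep], levels = samples))
  counts[, ] <- as.integer(tab)
  structure(list(counts = counts, skipped = skipped),
            class = "context_matrix")
}

#' @export
print.context_matrix <- function(x, ...) {
  cat(sprintf("context_matrix: 96 x %d samples, %d mutations (%d skipped)\n",
              ncol(x$counts), sum(x$counts), x$skipped))
  invisible(x)
}

#' Summarize doublet base substitutions
#'
#' DBS rows (two-base ref and alt) are tallied by ref>alt pair per sample;
#' they are deliberately excluded from the 96-context matrix.
#'
#' @param cat A `mutation_catalog`.
#' @return Data.frame with sample, dbs (e.g. "CC>TT") and count.
#' @export
summarize_dbs <- function(cat) {
  rec <- cat$records
  dbs <- rec[nchar(rec$ref) == 2 & nchar(rec$alt) == 2, , drop = FALSE]
  if (nrow(dbs) == 0) {
    return(data.frame(sample = character(0), dbs = character(0),
                      count = integer(0), stringsAsFactors = FALSE))
  }
  tab <- as.data.frame(table(sample = dbs$sample,
                             dbs = paste0(dbs$ref, ">", dbs$alt)),
                       stringsAsFactors = FALSE)
  names(tab)[3] <- "count"
  tab[tab$count > 0, ]
}

#' Tumour mutational burden per sample
#'
#' @param cat A `mutation_catalog`.
#' @return Data.frame with sample, total (all somatic records) and snv
#'   (single-base substitutions only). Raw counts, not per-megabase.
#' @export
tmb <- function(cat) {
  rec <- cat$records
  samples <- sort(unique(rec$sample))
  total <- as.integer(table(factor(rec$sample, levels = samples)))
  snv <- as.integer(table(factor(rec$sample[is_snv(rec)], levels = samples)))
  data.frame(sample = samples, total = total, snv = snv,
             stringsAsFactors = FALSE)
}

# ---- KL-divergence NMF (multiplicative updates) ----

kl_divergence <- function(V, WH) {
  eps <- 1e-12
  sum(V * log((V + eps) / (WH + eps)) - V + WH)
}

nmf_kl <- function(V, r, max_iter = 500, tol = 1e-6) {
  n <- nrow(V); m <- ncol(V)
  eps <- 1e-12
  W <- matrix(stats::runif(n * r, 0.1, 1), n, r)
  H <- matrix(stats::runif(r * m, 0.1, 1), r, m)
  obj <- numeric(0)
  prev <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    WH <- W %*% H + eps
    H <- H * (t(W) %*% (V / WH)) / pmax(colSums(W), eps)
    WH <- W %*% H + eps
    W <- W * ((V / WH) %*% t(H)) / rep(pmax(rowSums(H), eps), each = n)
    cur <- kl_divergence(V, W %*% H)
    obj <- c(obj, cur)
    if (is.finite(prev) && abs(prev - cur) <= tol * max(1, abs(prev))) {
      converged <- TRUE
      break
    }
    prev <- cur
  }
  scale <- colSums(W)
  W <- sweep(W, 2, pmax(scale, eps), "/")
  H <- sweep(H, 1, scale, "*")
  list(W = W, H = H, objective = obj, converged = converged)
}

#' De novo mutational-signature extraction by KL-NMF
#'
#' Multiplicative-update NMF under generalized Kullback-Leibler divergence,
#' restarted from random initializations; the best restart by final
#' objective is retained per rank. Rank is chosen at the cophenetic-
#' coefficient drop point: the largest k before the first decrease exceeding
#' `coph_delta` (classic consensus-of-restarts construction: samples are
#' co-assigned when they share a dominant signature).
#'
#' @param M A `context_matrix` or bare 96 x sample count matrix with every
#'   column sum > 0.
#' @param k_range Candidate ranks (k = 1 allowed; cophenetic is NA there).
#' @param restarts Random restarts per rank (default 30).
#' @param max_iter,tol Multiplicative-update stopping rule.
#' @param coph_delta Cophenetic drop tolerance for rank choice (default 0.02).
#' @param seed Integer seed.
#' @return A `signature_set`: per-k fits (`W` 96 x k column-stochastic, `H`
#'   k x samples, objective trace, convergence flag, cophenetic), `chosen_k`
#'   and a per-k diagnostics data.frame.
#' @export
extract_signatures <- function(M, k_range = 2:5, restarts = 30,
                               max_iter = 500, tol = 1e-6, coph_delta = 0.02,
                               seed = 1) {
  V <- if (inherits(M, "context_matrix")) M$counts else M
  assert_that(nrow(V) == 96, "context matrix must have 96 rows")
  assert_that(all(colSums(V) > 0), "every sample column sum must be > 0")
  assert_that(all(k_range >= 1 & k_range <= min(96, ncol(V)) - 1),
              "k_range out of bounds")
  storage.mode(V) <- "double"
  set.seed(derive_seed(seed, 21L))
  fits <- list()
  for (k in k_range) {
    best <- NULL
    conn_sum <- matrix(0, ncol(V), ncol(V))
    for (rs in seq_len(restarts)) {
      fit <- nmf_kl(V, k, max_iter = max_iter, tol = tol)
      if (is.null(best) || utils::tail(fit$objective, 1) <
            utils::tail(best$objective, 1)) best <- fit
      dom <- apply(fit$H, 2, which.max)
      conn_sum <- conn_sum + outer(dom, dom, "==")
    }
    consensus <- conn_sum / restarts
    coph <- NA_real_
    if (k >= 2 && ncol(V) >= 3) {
      dmat <- stats::as.dist(1 - consensus)
      hc <- stats::hclust(dmat, method = "average")
      coph <- suppressWarnings(stats::cor(dmat, stats::cophenetic(hc)))
      if (is.na(coph)) coph <- 1   # zero-variance distances: perfect consensus
    }
    dimnames(best$W) <- list(sbs96_contexts()$label, paste0("SBS", LETTERS[seq_len(k)]))
    dimnames(best$H) <- list(colnames(best$W), colnames(V))
    fits[[as.character(k)]] <- list(
      k = k, W = best$W, H = best$H, objective = best$objective,
      converged = best$converged, cophenetic = coph)
  }
  coph <- vapply(fits, `[[`, 0, "cophenetic")
  ks <- vapply(fits, `[[`, 0, "k")
  chosen <- ks[length(ks)]
  drops <- which(diff(coph) < -coph_delta)
  if (length(drops) > 0) chosen <- ks[drops[1]]
  diagnostics <- data.frame(k = ks, cophenetic = coph,
                            objective = vapply(fits, function(f)
                              utils::tail(f$objective, 1), 0),
                            converged = vapply(fits, `[[`, TRUE, "converged"),
                            row.names = NULL)
  structure(list(fits = fits, chosen_k = unname(chosen),
                 diagnostics = diagnostics,
                 settings = list(restarts = restarts, max_iter = max_iter,
                                 tol = tol, coph_delta = coph_delta,
                                 seed = seed)),
            class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat("signature_set; chosen rank k =", x$chosen_k, "\n")
  print(x$diagnostics, row.names = FALSE)
  invisible(x)
}

#' Cosine similarity between profile columns
#'
#' @param A,B Matrices with matching row order.
#' @return Matrix of cosine similarities, columns of A x columns of B.
#' @export
cosine_similarity <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  num <- t(A) %*% B
  den <- outer(sqrt(colSums(A^2)), sqrt(colSums(B^2)))
  num / pmax(den, .Machine$double.eps)
}

#' Match extracted signatures against a reference catalogue
#'
#' Per extracted signature the argmax-cosine reference is reported
#' (independent matches, as is common practice); an optional one-to-one
#' assignment maximizing total cosine is also available.
#'
#' @param W 96 x r extracted profiles (or a `signature_set`, using the
#'   chosen rank) with canonical rownames.
#' @param ref 96 x m reference catalogue; rownames must equal the canonical
#'   96-context labels in order.
#' @param bipartite If TRUE also compute the optimal one-to-one assignment.
#' @return Data.frame: signature, best_match, cosine (and, when requested,
#'   bipartite_match, bipartite_cosine).
#' @export
match_reference <- function(W, ref, bipartite = FALSE) {
  if (inherits(W, "signature_set")) W <- W$fits[[as.character(W$chosen_k)]]$W
  labels <- sbs96_contexts()$label
  if (!identical(rownames(ref), labels)) {
    stop(paste("reference catalogue rows must be the canonical 96 contexts",
               "in order (see sbs96_contexts()$label); reorder the rows to",
               "that layout"), call. = FALSE)
  }
  assert_that(identical(rownames(W), labels),
              "extracted profiles must use the canonical 96-context row order")
  cs <- cosine_similarity(W, ref)
  best <- apply(cs, 1, which.max)
  out <- data.frame(signature = colnames(W),
                    best_match = colnames(ref)[best],
                    cosine = cs[cbind(seq_len(nrow(cs)), best)],
                    stringsAsFactors = FALSE)
  if (bipartite) {
    r <- ncol(W)
    assert_that(r <= 8, "bipartite matching supported up to 8 signatures")
    perms <- permutations_of(seq_len(ncol(ref)), r)
    scores <- vapply(perms, function(p) sum(cs[cbind(seq_len(r), p)]), 0)
    bestp <- perms[[which.max(scores)]]
    out$bipartite_match <- colnames(ref)[bestp]
    out$bipartite_cosine <- cs[cbind(seq_len(r), bestp)]
  }
  out
}

# All injective r-length arrangements of items (small r only).
permutations_of <- function(items, r) {
  if (r == 0) return(list(integer(0)))
  out <- list()
  rec <- function(prefix, remaining) {
    if (length(prefix) == r) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    for (x in remaining) rec(c(prefix, x), setdiff(remaining, x))
  }
  rec(integer(0), items)
  out
}

#' Refit sample exposures to reference signatures with bootstrap stability
#'
#' Point estimates by non-negative least squares per sample
#' ([pracma::lsqnonneg()]); each bootstrap replicate resamples every
#' sample's mutations multinomially at its observed total and refits,
#' yielding per-signature stability summaries.
#'
#' @param M A `context_matrix` or 96 x sample count matrix.
#' @param ref_signatures 96 x r column-stochastic reference profiles.
#' @param n_boot Bootstrap replicates (default 100).
#' @param seed Integer seed.
#' @return A `refitting_result`: `exposures` (r x samples, count scale),
#'   `fractions` (per-sample fractions of total), `boot` (n_boot x r x
#'   samples array of fractions), `stability` (per signature x sample SD and
#'   presence frequency across replicates) and `zero_samples`.
#' @export
refit_exposures <- function(M, ref_signatures, n_boot = 100, seed = 1) {
  V <- if (inherits(M, "context_matrix")) M$counts else M
  storage.mode(V) <- "double"
  R <- as.matrix(ref_signatures)
  assert_that(nrow(R) == 96 && nrow(V) == 96, "96-row matrices required")
  assert_that(all(abs(colSums(R) - 1) < 1e-6),
              "reference profiles must be column-stochastic")
  r <- ncol(R); n <- ncol(V)
  fit_one <- function(v) {
    if (sum(v) == 0) return(rep(0, r))
    pracma::lsqnonneg(R, v)$x
  }
  expo <- apply(V, 2, fit_one)
  if (is.null(dim(expo))) expo <- matrix(expo, nrow = r)
  dimnames(expo) <- list(colnames(R), colnames(V))
  totals <- colSums(expo)
  fractions <- sweep(expo, 2, pmax(totals, .Machine$double.eps), "/")
  fractions[, totals == 0] <- 0
  zero_samples <- colnames(V)[colSums(V) == 0]

  set.seed(derive_seed(seed, 31L))
  boot <- array(NA_real_, c(n_boot, r, n),
                dimnames = list(NULL, colnames(R), colnames(V)))
  for (b in seq_len(n_boot)) {
    for (s in seq_len(n)) {
      tot <- sum(V[, s])
      if (tot == 0) { boot[b, , s] <- 0; next }
      v <- as.vector(stats::rmultinom(1, tot, V[, s] / tot))
      e <- fit_one(v)
      et <- sum(e)
      boot[b, , s] <- if (et > 0) e / et else 0
    }
  }
  stability <- data.frame(
    signature = rep(colnames(R), times = n),
    sample = rep(colnames(V), each = r),
    sd = as.vector(apply(boot, c(2, 3), stats::sd)),
    presence = as.vector(apply(boot > 1e-6, c(2, 3), mean)),
    stringsAsFactors = FALSE)
  structure(list(exposures = expo, fractions = fractions, boot = boot,
                 stability = stability, zero_samples = zero_samples,
                 n_boot = n_boot),
            class = "refitting_result")
}

#' Genes positively correlated with signature exposures
#'
#' Pearson correlation of each gene's expression with each signature's
#' per-sample exposure fraction; rows passing r > r_thresh and
#' `p < p_thresh` are flagged (positive screen). Constant genes are skipped
#' and logged.
#'
#' @param H_frac r x sample matrix of exposure fractions (or a
#'   `refitting_result`).
#' @param expr Gene x sample expression matrix; >= 10 shared samples.
#' @param r_thresh,p_thresh Flag thresholds (defaults 0.2 and 0.05).
#' @return Data.frame gene x signature rows: r, p, flagged; attribute
#'   `skipped` lists constant genes.
#' @export
signature_expression_screen <- function(H_frac, expr, r_thresh = 0.2,
                                        p_thresh = 0.05) {
  H <- if (inherits(H_frac, "refitting_result")) H_frac$fractions else H_frac
  shared <- intersect(colnames(H), colnames(expr))
  assert_that(length(shared) >= 10, "need >= 10 shared samples")
  H <- H[, shared, drop = FALSE]
  X <- expr[, shared, drop = FALSE]
  sds <- apply(X, 1, stats::sd)
  skipped <- rownames(X)[sds == 0]
  X <- X[sds > 0, , drop = FALSE]
  n <- length(shared)
  rmat <- stats::cor(t(X), t(H))
  pmat <- cor_pvalue(rmat, n)
  out <- data.frame(
    gene = rep(rownames(rmat), times = ncol(rmat)),
    signature = rep(colnames(rmat), each = nrow(rmat)),
    r = as.vector(rmat), p = as.vector(pmat),
    stringsAsFactors = FALSE)
  out$flagged <- out$r > r_thresh & out$p < p_thresh
  out <- out[order(match(out$signature, colnames(rmat)), -out$r), ]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Read / write a COSMIC-layout signature TSV
#'
#' First column holds the 96 context labels (`A[C>A]A`, ...), remaining
#' columns one signature each; rows are validated and reordered into the
#' canonical order.
#'
#' @param path Path to the TSV.
#' @return 96 x m numeric matrix in canonical row order.
#' @export
read_signature_tsv <- function(path) {
  m <- read_matrix_tsv(path)
  labels <- sbs96_contexts()$label
  assert_that(setequal(rownames(m), labels),
              "signature TSV rows must be the 96 canonical context labels")
  m[labels, , drop = FALSE]
}

#' @rdname read_signature_tsv
#' @param W 96 x m matrix with canonical rownames.
#' @export
write_signature_tsv <- function(W, path) {
  write_matrix_tsv(W, path, id_col = "context")
}
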