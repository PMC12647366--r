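# Consensus subtyping: resampled PAM clustering of the pathway-activity
# matrix, k selection from within-cluster consensus and CDF delta-area, and
# silhouette-based label refinement.

#' PAM clustering of a dissimilarity matrix
#'
#' Thin wrapper over [cluster::pam()] (BUILD + SWAP), keeping the interface
#' the rest of the pipeline uses: a symmetric zero-diagonal dissimilarity
#' matrix in, labels and medoid indices out. Deterministic for fixed input.
#'
#' @param D Symmetric dissimilarity matrix with zero diagonal.
#' @param k Number of clusters, 1 <= k < n.
#' @return List with `labels` (integer vector, named by sample), `medoids`
#'   (indices into the samples) and `cost` (sum of distances to medoids).
#' @export
pam_cluster <- function(D, k) {
  D <- as.matrix(D)
  n <- nrow(D)
  assert_that(k >= 1 && k < n, "k must satisfy 1 <= k < n")
  assert_that(isTRUE(all.equal(D, t(D), tolerance = 1e-8)) &&
                all(abs(diag(D)) < 1e-12),
              "D must be symmetric with zero diagonal")
  fit <- cluster::pam(stats::as.dist(D), k = k, diss = TRUE)
  medoids <- as.integer(fit$id.med)
  labels <- fit$clustering
  if (!is.null(rownames(D))) names(labels) <- rownames(D)
  cost <- sum(D[cbind(seq_len(n), medoids[labels])])
  list(labels = labels, medoids = medoids, cost = cost)
}

#' Consensus clustering by resampled PAM
#'
#' For each candidate k, samples are repeatedly subsampled (without
#' replacement), PAM is run on the Minkowski distance between the
#' subsample's score columns, and the consensus matrix entry (i, j) is the
#' fraction of co-clustered runs among runs where both samples were drawn.
#' Pairs never co-sampled get consensus 0 and are counted in
#' `never_cosampled`. Final per-k labels come from PAM on `1 - consensus`.
#' Samples are canonicalized by name internally so the result is equivariant
#' under input column permutation.
#'
#' @param E An `enrichment_matrix` or bare feature x sample matrix.
#' @param k_range Candidate cluster numbers (within 2..n-1).
#' @param subsample Fraction of samples drawn per repetition (default 0.8).
#' @param reps Repetitions per k (default 10; statistically thin -- the test
#'   suite uses considerably more).
#' @param minkowski_p Minkowski distance exponent (default 2, Euclidean).
#' @param seed Integer seed driving all resampling.
#' @return A `consensus_result`: per-k consensus matrices, labels, mean
#'   within-cluster consensus, CDF area and delta-area, empty-cluster flags,
#'   `never_cosampled` counts, and the call settings.
#' @export
consensus_cluster <- function(E, k_range = 2:6, subsample = 0.8, reps = 10,
                              minkowski_p = 2, seed = 1) {
  scores <- if (inherits(E, "enrichment_matrix")) E$scores else E
  n <- ncol(scores)
  assert_that(reps >= 2, "reps must be >= 2")
  assert_that(all(k_range >= 2 & k_range <= n - 1),
              "k_range must lie within [2, n-1]")
  ids <- colnames(scores) %||% sprintf("S%03d", seq_len(n))
  colnames(scores) <- ids
  canon <- order(ids)
  back <- order(canon)
  X <- t(scores[, canon, drop = FALSE])
  D <- as.matrix(stats::dist(X, method = "minkowski", p = minkowski_p))

  m <- max(2L, floor(subsample * n))
  set.seed(derive_seed(seed, 11L))
  subs <- lapply(seq_len(reps), function(i) sort(sample.int(n, m)))
  S <- matrix(0, n, n)
  for (idx in subs) S[idx, idx] <- S[idx, idx] + 1
  never <- sum(S[upper.tri(S)] == 0)
  if (never > 0) {
    warning(sprintf("%d sample pairs were never co-sampled; their consensus is 0",
                    never))
  }

  per_k <- list()
  for (k in k_range) {
    I <- matrix(0, n, n)
    empty_runs <- 0L
    for (idx in subs) {
      fit <- cluster::pam(stats::as.dist(D[idx, idx]), k = k, diss = TRUE)
      cl <- fit$clustering
      if (length(unique(cl)) < k) empty_runs <- empty_runs + 1L
      for (cc in unique(cl)) {
        ii <- idx[cl == cc]
        I[ii, ii] <- I[ii, ii] + 1
      }
    }
    M <- matrix(0, n, n)
    pos <- S > 0
    M[pos] <- I[pos] / S[pos]
    diag(M) <- 1
    M <- M[back, back, drop = FALSE]
    dimnames(M) <- list(ids, ids)
    labels <- pam_cluster(1 - M, k)$labels
    vals <- M[upper.tri(M)]
    cdf <- stats::ecdf(vals)
    xs <- sort(unique(c(0, vals, 1)))
    area <- sum(diff(xs) * cdf(xs[-length(xs)]))
    wc <- vapply(seq_len(k), function(cc) {
      ii <- which(labels == cc)
      if (length(ii) < 2) return(1)
      sub <- M[ii, ii]
      mean(sub[upper.tri(sub)])
    }, 0)
    per_k[[as.character(k)]] <- list(
      k = k, consensus = M, labels = labels,
      mean_within_consensus = mean(wc), cluster_consensus = wc,
      cdf_area = area, empty_cluster_flag = empty_runs > reps / 2)
  }
  areas <- vapply(per_k, `[[`, 0, "cdf_area")
  delta <- c(areas[1], diff(areas) / areas[-length(areas)])
  for (i in seq_along(per_k)) per_k[[i]]$delta_area <- unname(delta[i])

  structure(list(per_k = per_k, k_range = k_range,
                 never_cosampled = never,
                 settings = list(subsample = subsample, reps = reps,
                                 minkowski_p = minkowski_p, seed = seed)),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  tr <- consensus_trace(x)
  cat("consensus_result over k =", paste(x$k_range, collapse = ", "), "\n")
  print(tr, row.names = FALSE)
  invisible(x)
}

#' Per-k decision trace of a consensus run
#'
#' @param res A `consensus_result`.
#' @return Data.frame with k, mean within-cluster consensus, CDF area,
#'   delta-area and the empty-cluster flag.
#' @export
consensus_trace <- function(res) {
  do.call(rbind, lapply(res$per_k, function(p) data.frame(
    k = p$k, mean_within_consensus = p$mean_within_consensus,
    min_cluster_consensus = min(p$cluster_consensus),
    cdf_area = p$cdf_area, delta_area = p$delta_area,
    empty_cluster_flag = p$empty_cluster_flag)))
}

#' Choose the number of clusters from a consensus run
#'
#' Picks the largest k for which every cluster's mean consensus reaches the
#' floor (a stable solution leaves no loosely co-clustered group behind)
#' and whose CDF delta-area gain over k-1 exceeds `delta_epsilon` (the CDF
#' has not yet flattened). If no k meets the floor, returns the argmax of
#' the minimum cluster consensus with a warning.
#'
#' @param res A `consensus_result` with >= 2 candidate k.
#' @param mean_consensus_floor Per-cluster stability floor (default 0.85).
#' @param delta_epsilon Minimum relative CDF-area gain; below ~5% the CDF
#'   is flattening and further splits only fragment stable clusters
#'   (default 0.05).
#' @return List with `k` (chosen), `trace` (per-k statistics) and
#'   `floor_met` (logical).
#' @export
select_k <- function(res, mean_consensus_floor = 0.85, delta_epsilon = 0.05) {
  assert_that(length(res$per_k) >= 2, "need >= 2 candidate k")
  tr <- consensus_trace(res)
  ok <- tr$min_cluster_consensus >= mean_consensus_floor &
    tr$delta_area > delta_epsilon
  if (any(ok)) {
    k <- max(tr$k[ok])
    floor_met <- TRUE
  } else {
    warning("no k meets the cluster-consensus floor; returning argmax consensus")
    k <- tr$k[which.max(tr$min_cluster_consensus)]
    floor_met <- FALSE
  }
  list(k = k, trace = tr, floor_met = floor_met)
}

#' Silhouette widths of a labeled dissimilarity matrix
#'
#' @param D Symmetric dissimilarity matrix.
#' @param labels Integer cluster labels.
#' @return Data.frame with cluster, neighbor and width per sample.
#' @export
silhouette_widths <- function(D, labels) {
  sil <- cluster::silhouette(as.integer(labels), dmatrix = as.matrix(D))
  data.frame(sample = rownames(as.matrix(D)) %||% seq_along(labels),
             cluster = sil[, "cluster"], neighbor = sil[, "neighbor"],
             width = sil[, "sil_width"], stringsAsFactors = FALSE)
}

#' Silhouette-based refinement of cluster labels
#'
#' Iteratively offers each negative-width sample a move to its neighbouring
#' cluster (the one minimizing b(i)); a move is kept only if it raises that
#' sample's width, does not empty its cluster, and does not lower the
#' overall mean width -- so the mean silhouette is non-decreasing across
#' iterations by construction. Every accepted or rejected move is logged.
#'
#' @param D Symmetric dissimilarity matrix.
#' @param labels Initial integer labels (>= 2 non-empty clusters).
#' @param max_iter Maximum refinement sweeps (default 10).
#' @return List with `labels` (refined), `report` (final per-sample widths,
#'   per-cluster and overall means), `moves` (log data.frame) and
#'   `mean_width_trace` (one value per completed sweep, non-decreasing).
#' @export
silhouette_refine <- function(D, labels, max_iter = 10) {
  D <- as.matrix(D)
  labels <- as.integer(labels)
  assert_that(length(unique(labels)) >= 2, "need >= 2 clusters")
  moves <- list()
  mean_trace <- numeric(0)
  cur <- silhouette_widths(D, labels)
  mean_trace <- mean(cur$width)
  for (iter in seq_len(max_iter)) {
    neg <- order(cur$width)[cur$width[order(cur$width)] < 0]
    if (length(neg) == 0) break
    changed <- FALSE
    for (i in neg) {
      if (cur$width[i] >= 0) next       # may have been fixed by earlier move
      from <- labels[i]; to <- cur$neighbor[i]
      if (sum(labels == from) <= 1) {
        moves[[length(moves) + 1]] <- data.frame(
          iter = iter, sample = i, from = from, to = to,
          accepted = FALSE, reason = "would_empty_cluster")
        next
      }
      cand <- labels; cand[i] <- to
      cand_sil <- silhouette_widths(D, cand)
      if (cand_sil$width[i] > cur$width[i] &&
          mean(cand_sil$width) >= mean(cur$width)) {
        labels <- cand
        cur <- cand_sil
        changed <- TRUE
        moves[[length(moves) + 1]] <- data.frame(
          iter = iter, sample = i, from = from, to = to,
          accepted = TRUE, reason = "width_improved")
      } else {
        moves[[length(moves) + 1]] <- data.frame(
          iter = iter, sample = i, from = from, to = to,
          accepted = FALSE, reason = "no_improvement")
      }
    }
    mean_trace <- c(mean_trace, mean(cur$width))
    if (!changed) break
  }
  per_cluster <- tapply(cur$width, cur$cluster, mean)
  list(labels = labels,
       report = list(widths = cur, per_cluster_mean = per_cluster,
                     overall_mean = mean(cur$width)),
       moves = if (length(moves)) do.call(rbind, moves) else
         data.frame(iter = integer(0), sample = integer(0), from = integer(0),
                    to = integer(0), accepted = logical(0),
                    reason = character(0)),
       mean_width_trace = mean_trace)
}
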