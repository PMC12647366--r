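# Single-sample pathway-activity scoring and differential signature screens.
#
# The score is a rank-based weighted Kolmogorov-Smirnov random walk computed
# independently per sample (ssGSEA-style, weight exponent 1, normalized by
# the universe size). Because it depends only on within-sample ranks it is
# invariant under any strictly monotone per-sample transform of expression.

#' Per-sample pathway-activity scores for a gene-set collection
#'
#' For each sample, genes are ordered by decreasing expression rank (average
#' ranks on ties; residual ties broken by gene name so results do not depend
#' on input row order). Walking down that list, the in-set cumulative
#' fraction is weighted by rank^tau and the out-of-set fraction is uniform;
#' the score is the mean difference of the two cumulative fractions over the
#' whole list.
#'
#' @param expr Gene x sample non-negative expression matrix with rownames.
#' @param coll A `geneset_collection`.
#' @param min_size,max_size Set-size bounds applied after intersecting each
#'   set with the expression universe; sets outside the bounds are dropped
#'   and logged (defaults 5 and 5000).
#' @param tau Rank weight exponent (default 1).
#' @return An `enrichment_matrix`: list with `scores` (signature x sample),
#'   `universe_size`, `dropped` (data.frame of dropped sets and reasons) and
#'   `settings`.
#' @export
score_enrichment <- function(expr, coll, min_size = 5, max_size = 5000, tau = 1) {
  assert_that(ncol(expr) >= 2, "need at least 2 samples")
  assert_that(!is.null(rownames(expr)), "expr must have gene rownames")
  universe <- rownames(expr)
  inter <- lapply(coll$sets, intersect, universe)
  sizes <- lengths(inter)
  if (all(sizes == 0)) stop("no gene set overlaps the expression universe", call. = FALSE)
  keep <- sizes >= min_size & sizes <= max_size
  dropped <- data.frame(
    set = names(coll$sets)[!keep],
    size_in_universe = sizes[!keep],
    reason = ifelse(sizes[!keep] < min_size, "below_min_size", "above_max_size"),
    stringsAsFactors = FALSE)
  assert_that(any(keep), "no gene set within the size bounds")
  sets <- inter[keep]

  n <- length(universe)
  n_samp <- ncol(expr)
  scores <- matrix(NA_real_, length(sets), n_samp,
                   dimnames = list(names(sets), colnames(expr)))
  set_idx <- lapply(sets, function(g) match(g, universe))
  for (j in seq_len(n_samp)) {
    r <- rank(expr[, j], ties.method = "average")
    ord <- order(-r, universe)           # decreasing rank, ties by gene name
    w <- r[ord]^tau
    pos_of <- integer(n); pos_of[ord] <- seq_len(n)
    for (s in seq_along(sets)) {
      m <- length(set_idx[[s]])
      inset <- logical(n)
      inset[pos_of[set_idx[[s]]]] <- TRUE
      win <- w * inset
      p_in <- cumsum(win) / sum(win)
      p_out <- cumsum(!inset) / (n - m)
      scores[s, j] <- sum(p_in - p_out) / n
    }
  }
  structure(list(scores = scores, universe_size = n, dropped = dropped,
                 settings = list(min_size = min_size, max_size = max_size,
                                 tau = tau, method = "rank_walk")),
            class = "enrichment_matrix")
}

#' @export
print.enrichment_matrix <- function(x, ...) {
  cat(sprintf("enrichment_matrix: %d signatures x %d samples (universe %d)\n",
              nrow(x$scores), ncol(x$scores), x$universe_size))
  invisible(x)
}

#' Differential enrichment of signatures between two groups
#'
#' Two-sample Welch t test per signature, with a fold-change measure
#' appropriate for signed scores: when both group means are positive the
#' ratio of means is thresholded (`max(ratio, 1/ratio) >= fc_thresh`),
#' otherwise the absolute difference of means is compared with `fc_thresh`
#' and the mode is recorded per row in `fc_mode`.
#'
#' @param E An `enrichment_matrix` (or bare signature x sample matrix).
#' @param groupA,groupB Disjoint character vectors of sample ids (>= 2 each).
#' @param p_thresh,fc_thresh Significance / fold-change thresholds
#'   (defaults 0.01 and 2).
#' @return Data.frame sorted by p: signature, t, p, p_adj (BH), mean_A,
#'   mean_B, difference, ratio, fc_mode, passed. Signatures with zero
#'   variance in both groups get `p = NaN` and `passed = NA`.
#' @export
differential_enrichment <- function(E, groupA, groupB, p_thresh = 0.01,
                                    fc_thresh = 2) {
  scores <- if (inherits(E, "enrichment_matrix")) E$scores else E
  assert_that(length(intersect(groupA, groupB)) == 0, "groups must be disjoint")
  assert_that(length(groupA) >= 2 && length(groupB) >= 2,
              "each group needs >= 2 samples")
  assert_that(all(c(groupA, groupB) %in% colnames(scores)),
              "group samples missing from the score matrix")
  res <- lapply(rownames(scores), function(sig) {
    a <- scores[sig, groupA]; b <- scores[sig, groupB]
    ma <- mean(a); mb <- mean(b)
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      t_stat <- NaN; p <- NaN
    } else {
      tt <- stats::t.test(a, b)
      t_stat <- unname(tt$statistic); p <- tt$p.value
    }
    ratio <- if (ma > 0 && mb > 0) ma / mb else NA_real_
    fc_mode <- if (!is.na(ratio)) "ratio" else "difference"
    pass_fc <- if (!is.na(ratio)) max(ratio, 1 / ratio) >= fc_thresh
               else abs(ma - mb) >= fc_thresh
    data.frame(signature = sig, t = t_stat, p = p,
               mean_A = ma, mean_B = mb, difference = ma - mb,
               ratio = ratio, fc_mode = fc_mode,
               passed = if (is.nan(p)) NA else (p < p_thresh && pass_fc),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p), c("signature", "t", "p", "p_adj", "mean_A", "mean_B",
                      "difference", "ratio", "fc_mode", "passed")]
}
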