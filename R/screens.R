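# Downstream statistical screens: one-vs-rest differential expression,
# multi-group ANOVA feature screens, Fisher mutation-pattern tests, and
# generic correlation screens (cis-regulation, methylation, SBS-expression).

#' One-vs-rest differential expression per subtype
#'
#' Welch two-sample t on log2(x + 1) for each subtype against the rest.
#' The gene list applies the raw p and |log2FC| thresholds (screen parity
#' with common practice); BH-adjusted p values are always reported so FDR
#' control is available. log2FC is computed on the log2(mean + 1) scale.
#'
#' @param expr Gene x sample matrix.
#' @param labels Subtype labels per sample (each subtype needs >= 3 samples;
#'   smaller ones are skipped with a warning).
#' @param p_thresh,lfc_thresh List thresholds (defaults 0.05 and 2).
#' @return Named list per subtype: `table` (gene, t, p, p_adj, log2fc,
#'   passed) and `genes` (the passing list).
#' @export
deg_one_vs_rest <- function(expr, labels, p_thresh = 0.05, lfc_thresh = 2) {
  assert_that(length(labels) == ncol(expr), "labels must match samples")
  lx <- log2(expr + 1)
  out <- list()
  for (s in sort(unique(labels))) {
    idx <- which(labels == s)
    if (length(idx) < 3) {
      warning(sprintf("subtype %s has < 3 samples; skipped", s))
      next
    }
    A <- lx[, idx, drop = FALSE]
    B <- lx[, -idx, drop = FALSE]
    nA <- ncol(A); nB <- ncol(B)
    mA <- rowMeans(A); mB <- rowMeans(B)
    vA <- apply(A, 1, stats::var); vB <- apply(B, 1, stats::var)
    se2 <- vA / nA + vB / nB
    t_stat <- (mA - mB) / sqrt(se2)
    df <- se2^2 / ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1))
    p <- 2 * stats::pt(-abs(t_stat), df)
    log2fc <- log2(rowMeans(expr[, idx, drop = FALSE]) + 1) -
      log2(rowMeans(expr[, -idx, drop = FALSE]) + 1)
    tab <- data.frame(gene = rownames(expr), t = t_stat, p = p,
                      p_adj = stats::p.adjust(p, "BH"), log2fc = log2fc,
                      stringsAsFactors = FALSE, row.names = NULL)
    tab$passed <- !is.na(tab$p) & tab$p < p_thresh & abs(tab$log2fc) > lfc_thresh
    tab <- tab[order(tab$p), ]
    out[[paste0("C", s)]] <- list(table = tab, genes = tab$gene[tab$passed])
  }
  out
}

#' One-way ANOVA screen over matrix features
#'
#' Classic equal-variance one-way ANOVA F test per feature (row); for k = 2
#' groups F equals the pooled-variance t squared. Features with zero
#' within-group variance everywhere but distinct group means get p = 0 and
#' a `degenerate` flag.
#'
#' @param m Feature x sample matrix.
#' @param labels Group labels (>= 3 groups).
#' @param p_thresh Pass threshold (default 0.05).
#' @return Data.frame: feature, f, p, p_adj, passed, degenerate.
#' @export
anova_screen <- function(m, labels, p_thresh = 0.05) {
  groups <- sort(unique(labels))
  assert_that(length(groups) >= 2, "need >= 2 groups")
  assert_that(length(labels) == ncol(m), "labels must match samples")
  g <- factor(labels)
  n <- ncol(m); k <- nlevels(g)
  idx <- split(seq_len(n), g)
  ns <- lengths(idx)
  gm <- rowMeans(m)
  ssb <- 0; ssw <- 0
  for (ii in idx) {
    mu <- rowMeans(m[, ii, drop = FALSE])
    ssb <- ssb + length(ii) * (mu - gm)^2
    ssw <- ssw + rowSums((m[, ii, drop = FALSE] - mu)^2)
  }
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  p <- stats::pf(f, k - 1, n - k, lower.tail = FALSE)
  degenerate <- ssw == 0 & ssb > 0
  p[degenerate] <- 0
  f[degenerate] <- Inf
  data.frame(feature = rownames(m) %||% seq_len(nrow(m)), f = f, p = p,
             p_adj = stats::p.adjust(p, "BH"),
             passed = !is.na(p) & p < p_thresh, degenerate = degenerate,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Pairwise Fisher tests of mutation co-occurrence / mutual exclusivity
#'
#' For every gene pair the 2x2 table of per-sample mutation status is tested
#' two-sided with Fisher's exact test; direction is co-occurrence when the
#' sample odds ratio exceeds 1, exclusivity otherwise. Genes mutated in no
#' or all samples are skipped and logged.
#'
#' @param mut Binary gene x sample mutation matrix (>= 2 genes).
#' @param p_thresh Significance flag threshold (default 0.05).
#' @return Data.frame per pair: gene_a, gene_b, the four counts (both,
#'   a_only, b_only, neither), odds ratio direction, p, p_adj, significant;
#'   attribute `skipped` lists the degenerate genes.
#' @export
fisher_pair_patterns <- function(mut, p_thresh = 0.05) {
  assert_that(nrow(mut) >= 2, "need >= 2 genes")
  mut <- mut > 0
  n <- ncol(mut)
  rates <- rowSums(mut)
  skipped <- rownames(mut)[rates == 0 | rates == n]
  keep <- rownames(mut)[rates > 0 & rates < n]
  rows <- list()
  for (i in seq_along(keep)) {
    for (j in seq_len(i - 1L)) {
      a <- keep[j]; b <- keep[i]
      both <- sum(mut[a, ] & mut[b, ])
      a_only <- sum(mut[a, ] & !mut[b, ])
      b_only <- sum(!mut[a, ] & mut[b, ])
      neither <- n - both - a_only - b_only
      tab <- matrix(c(both, a_only, b_only, neither), 2)
      p <- stats::fisher.test(tab)$p.value
      or <- (both * neither) / max(a_only * b_only, .Machine$double.eps)
      rows[[length(rows) + 1]] <- data.frame(
        gene_a = a, gene_b = b, both = both, a_only = a_only,
        b_only = b_only, neither = neither,
        direction = if (or > 1) "co_occurrence" else "exclusivity",
        p = p, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_a = character(0), gene_b = character(0), both = integer(0),
               a_only = integer(0), b_only = integer(0), neither = integer(0),
               direction = character(0), p = numeric(0))
  out$p_adj <- stats::p.adjust(out$p, "BH")
  out$significant <- out$p < p_thresh
  out <- out[order(out$p), ]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Generic Pearson correlation screen between two omics layers
#'
#' Serves the cis-regulation (CNV-mRNA, positive r), CNV-mRNA-protein
#' triple (intersection of pairwise screens), methylation-expression
#' (absolute r) and SBS-expression variants. `pairing = "matched"`
#' correlates identically named features; `"all"` crosses every X feature
#' with every Y feature.
#'
#' @param X,Y Feature x sample matrices sharing >= 10 samples.
#' @param pairing "matched" (default) or "all".
#' @param r_thresh,p_thresh Flag thresholds (defaults 0.5 and 0.05).
#' @param sign "positive" flags r > r_thresh; "absolute" flags
#'   |r| > r_thresh.
#' @return Data.frame: feature_x, feature_y, r, p, flagged; attribute
#'   `skipped` lists constant features.
#' @export
correlation_screen <- function(X, Y, pairing = c("matched", "all"),
                               r_thresh = 0.5, p_thresh = 0.05,
                               sign = c("positive", "absolute")) {
  pairing <- match.arg(pairing)
  sign <- match.arg(sign)
  shared <- intersect(colnames(X), colnames(Y))
  assert_that(length(shared) >= 10, "need >= 10 shared samples")
  X <- X[, shared, drop = FALSE]
  Y <- Y[, shared, drop = FALSE]
  const_x <- rownames(X)[apply(X, 1, stats::sd) == 0]
  const_y <- rownames(Y)[apply(Y, 1, stats::sd) == 0]
  X <- X[!rownames(X) %in% const_x, , drop = FALSE]
  Y <- Y[!rownames(Y) %in% const_y, , drop = FALSE]
  n <- length(shared)
  if (pairing == "matched") {
    feats <- intersect(rownames(X), rownames(Y))
    assert_that(length(feats) > 0, "no matched features")
    r <- vapply(feats, function(f) stats::cor(X[f, ], Y[f, ]), 0)
    out <- data.frame(feature_x = feats, feature_y = feats, r = r,
                      p = cor_pvalue(r, n), stringsAsFactors = FALSE,
                      row.names = NULL)
  } else {
    rmat <- stats::cor(t(X), t(Y))
    out <- data.frame(
      feature_x = rep(rownames(rmat), times = ncol(rmat)),
      feature_y = rep(colnames(rmat), each = nrow(rmat)),
      r = as.vector(rmat), p = as.vector(cor_pvalue(rmat, n)),
      stringsAsFactors = FALSE)
  }
  out$flagged <- out$p < p_thresh &
    (if (sign == "positive") out$r > r_thresh else abs(out$r) > r_thresh)
  out <- out[order(-abs(out$r)), ]
  rownames(out) <- NULL
  attr(out, "skipped") <- c(const_x, const_y)
  out
}
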