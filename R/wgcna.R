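# Co-expression network analysis: soft-threshold selection by scale-free
# fit, unsigned adjacency and topological overlap, average-linkage module
# detection with a static tree cut, module eigengenes, gene-significance /
# module-membership statistics, and per-subtype hub-gene selection.

#' Pick a soft-threshold power by scale-free topology fit
#'
#' For each candidate power the unsigned adjacency `|cor|^power` is formed,
#' connectivities are binned, and the scale-free fit R^2 comes from the
#' log10 frequency ~ log10 connectivity regression. The smallest power
#' reaching `rsq_cut` with a negative slope is chosen; if none qualifies,
#' the argmax R^2 (negative slope preferred) is returned.
#'
#' @param expr Gene x sample matrix (>= 20 samples recommended; warns below).
#' @param powers Candidate powers (default 1:20).
#' @param rsq_cut Scale-free fit target (default 0.8).
#' @param n_bins Connectivity histogram bins (default 10).
#' @return List with `power` (chosen beta), `fit_table` (power, rsq, slope,
#'   mean_connectivity) and `dropped` (constant genes removed).
#' @export
pick_soft_threshold <- function(expr, powers = 1:20, rsq_cut = 0.8,
                                n_bins = 10) {
  if (ncol(expr) < 20) warning("fewer than 20 samples; scale-free fit is unstable")
  sds <- apply(expr, 1, stats::sd)
  dropped <- rownames(expr)[sds == 0]
  expr <- expr[sds > 0, , drop = FALSE]
  C <- abs(stats::cor(t(expr)))
  diag(C) <- 0
  rows <- lapply(powers, function(p) {
    k <- rowSums(C^p)
    brk <- seq(min(k), max(k), length.out = n_bins + 1)
    bin <- cut(k, breaks = brk, include.lowest = TRUE)
    freq <- tapply(k, bin, length)
    kmean <- tapply(k, bin, mean)
    ok <- !is.na(freq) & freq > 0 & kmean > 0
    if (sum(ok) < 3) {
      return(data.frame(power = p, rsq = NA_real_, slope = NA_real_,
                        mean_connectivity = mean(k)))
    }
    fit <- stats::lm(log10(freq[ok]) ~ log10(kmean[ok]))
    data.frame(power = p, rsq = summary(fit)$r.squared,
               slope = unname(stats::coef(fit)[2]),
               mean_connectivity = mean(k))
  })
  tab <- do.call(rbind, rows)
  qual <- which(!is.na(tab$rsq) & tab$rsq >= rsq_cut & tab$slope < 0)
  power <- if (length(qual) > 0) {
    tab$power[qual[1]]
  } else {
    neg <- which(!is.na(tab$rsq) & tab$slope < 0)
    pool <- if (length(neg) > 0) neg else which(!is.na(tab$rsq))
    tab$power[pool[which.max(tab$rsq[pool])]]
  }
  list(power = power, fit_table = tab, dropped = dropped)
}

#' Build the unsigned co-expression network and its topological overlap
#'
#' Adjacency `a_ij = |cor(x_i, x_j)|^beta`; topological overlap
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` where
#' `l_ij = sum_u a_iu a_uj` over u distinct from i, j and `k` is the
#' connectivity excluding the diagonal. Constant genes (NaN correlations)
#' are dropped.
#'
#' @param expr Gene x sample matrix.
#' @param beta Soft-threshold power (>= 1).
#' @return A `coexpression_network`: `adjacency`, `tom` (both gene x gene,
#'   entries in `[0, 1]`, diagonal 1), `beta`, `dropped`.
#' @export
build_tom <- function(expr, beta) {
  assert_that(beta >= 1, "beta must be >= 1")
  sds <- apply(expr, 1, stats::sd)
  dropped <- rownames(expr)[sds == 0]
  expr <- expr[sds > 0, , drop = FALSE]
  A <- abs(stats::cor(t(expr)))^beta
  diag(A) <- 1
  k <- rowSums(A) - 1
  AA <- A %*% A
  L <- AA - 2 * A          # l_ij for i != j (diagonal of A is 1)
  num <- L + A
  den <- outer(k, k, pmin) + 1 - A
  TOM <- num / den
  diag(TOM) <- 1
  TOM <- pmin(pmax((TOM + t(TOM)) / 2, 0), 1)
  assert_that(all(TOM >= 0 & TOM <= 1), "TOM out of [0,1]")
  structure(list(adjacency = A, tom = TOM, beta = beta, dropped = dropped),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf("coexpression_network: %d genes, beta = %g\n",
              nrow(x$tom), x$beta))
  invisible(x)
}

WGCNA_COLOURS <- c("turquoise", "blue", "brown", "yellow", "green", "red",
                   "black", "pink", "magenta", "purple", "greenyellow",
                   "tan", "salmon", "cyan", "midnightblue", "lightcyan")

#' Detect co-expression modules by static tree cut
#'
#' Average-linkage hierarchical clustering on `1 - TOM`, cut at a fixed
#' height (default 0.99 of the maximum merge height); clusters smaller than
#' `min_module_size` become "grey" (unassigned). Modules are labelled with
#' the conventional colour names ordered by size (ties by the
#' lexicographically smallest member), so labels do not depend on gene
#' input order.
#'
#' @param net A `coexpression_network`.
#' @param min_module_size Minimum genes per module (default 30).
#' @param cut_height Static cut height; default `0.99 * max merge height`.
#' @return Named character vector gene -> module colour ("grey" =
#'   unassigned); all-grey results warn.
#' @export
detect_modules <- function(net, min_module_size = 30, cut_height = NULL) {
  TOM <- net$tom
  genes <- rownames(TOM)
  hc <- stats::hclust(stats::as.dist(1 - TOM), method = "average")
  ch <- cut_height %||% (0.99 * max(hc$height))
  cl <- stats::cutree(hc, h = ch)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_module_size]
  modules <- rep("grey", length(genes))
  names(modules) <- genes
  if (length(keep) == 0) {
    warning("no module reaches min_module_size; all genes grey")
    return(modules)
  }
  anchors <- vapply(keep, function(cc) min(genes[cl == cc]), "")
  keep <- keep[order(-sizes[keep], anchors)]
  for (i in seq_along(keep)) {
    modules[cl == as.integer(keep[i])] <- WGCNA_COLOURS[
      ((i - 1) %% length(WGCNA_COLOURS)) + 1]
  }
  modules
}

#' Module eigengenes, gene significance and module membership
#'
#' The eigengene of a module is the first principal component of its
#' standardized expression, sign-anchored so the mean gene loading is
#' positive. MM is the correlation of each gene with its own module's
#' eigengene; GS is the correlation of each gene with the one-hot indicator
#' of each subtype.
#'
#' @param expr Gene x sample matrix.
#' @param modules Named gene -> module colour vector from
#'   [detect_modules()].
#' @param subtype_labels Integer/character subtype labels per sample.
#' @return A `hub_gene_report`: `gs` (gene x subtype correlations), `mm`
#'   (named vector, NA for grey genes), `modules`, `eigengenes`
#'   (sample x module).
#' @export
module_stats <- function(expr, modules, subtype_labels) {
  mods <- setdiff(unique(modules), "grey")
  assert_that(length(mods) > 0, "no non-grey modules")
  samples <- colnames(expr)
  assert_that(length(subtype_labels) == length(samples),
              "labels must match samples")
  eig <- sapply(mods, function(m) {
    genes <- names(modules)[modules == m]
    X <- t(expr[genes, , drop = FALSE])
    X <- scale(X)
    X[is.na(X)] <- 0
    if (ncol(X) == 1) return(as.vector(X))
    sv <- svd(X, nu = 1, nv = 1)
    e <- sv$u[, 1] * sv$d[1]
    if (mean(sv$v[, 1]) < 0) e <- -e
    e
  })
  rownames(eig) <- samples
  mm <- rep(NA_real_, nrow(expr))
  names(mm) <- rownames(expr)
  for (m in mods) {
    genes <- names(modules)[modules == m]
    mm[genes] <- as.vector(stats::cor(t(expr[genes, , drop = FALSE]), eig[, m]))
  }
  subtypes <- sort(unique(subtype_labels))
  onehot <- sapply(subtypes, function(s) as.numeric(subtype_labels == s))
  colnames(onehot) <- paste0("C", subtypes)
  gs <- stats::cor(t(expr), onehot)
  structure(list(gs = gs, mm = mm, modules = modules, eigengenes = eig),
            class = "hub_gene_report")
}

#' @export
print.hub_gene_report <- function(x, ...) {
  cat(sprintf("hub_gene_report: %d genes, %d modules, %d subtypes\n",
              length(x$mm), ncol(x$eigengenes), ncol(x$gs)))
  invisible(x)
}

#' Select per-subtype hub genes from GS/MM statistics
#'
#' Genes in a non-grey module with `|GS| > gs_thresh` and `|MM| > mm_thresh`
#' for the subtype, ranked by |GS| descending, ties by |MM| then gene name;
#' the top `top_n` per subtype are returned (all qualifying genes, with a
#' warning, when fewer qualify).
#'
#' @param report A `hub_gene_report`.
#' @param gs_thresh,mm_thresh Selection thresholds (defaults 0.3 and 0.8).
#' @param top_n Hub genes per subtype (default 10).
#' @return Named list (per subtype) of data.frames: gene, module, gs, mm.
#' @export
select_hub_genes <- function(report, gs_thresh = 0.3, mm_thresh = 0.8,
                             top_n = 10) {
  out <- list()
  for (s in colnames(report$gs)) {
    gs <- report$gs[, s]
    mm <- report$mm
    qual <- names(gs)[!is.na(mm) & abs(gs) > gs_thresh & abs(mm) > mm_thresh &
                        report$modules[names(gs)] != "grey"]
    if (length(qual) == 0) {
      warning(sprintf("no hub gene qualifies for subtype %s", s))
      out[[s]] <- data.frame(gene = character(0), module = character(0),
                             gs = numeric(0), mm = numeric(0))
      next
    }
    ord <- order(-abs(gs[qual]), -abs(mm[qual]), qual)
    qual <- qual[ord]
    if (length(qual) < top_n) {
      warning(sprintf("subtype %s: only %d of %d requested hub genes qualify",
                      s, length(qual), top_n))
    }
    sel <- utils::head(qual, top_n)
    out[[s]] <- data.frame(gene = sel, module = unname(report$modules[sel]),
                           gs = unname(gs[sel]), mm = unname(mm[sel]),
                           stringsAsFactors = FALSE)
  }
  out
}
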