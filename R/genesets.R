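# Gene-set collections: GMT I/O, Jaccard similarity, and greedy redundancy
# filtering of near-duplicate signatures.

new_geneset_collection <- function(sets, source = NULL) {
  assert_that(!is.null(names(sets)) && !anyDuplicated(names(sets)),
              "set names must be present and unique")
  sets <- lapply(sets, function(g) unique(as.character(g)))
  assert_that(all(lengths(sets) > 0), "sets must be non-empty")
  source <- source %||% rep("unknown", length(sets))
  names(source) <- names(sets)
  structure(list(sets = sets, source = source), class = "geneset_collection")
}

#' @export
print.geneset_collection <- function(x, ...) {
  cat(sprintf("geneset_collection: %d sets, sizes %d..%d\n",
              length(x$sets), min(lengths(x$sets)), max(lengths(x$sets))))
  invisible(x)
}

#' @export
length.geneset_collection <- function(x) length(x$sets)

#' Read a GMT gene-set file
#'
#' Tab-separated GMT dialect: set name, description/source, then gene ids.
#' Duplicate gene ids within a set are collapsed; duplicated set names and
#' lines with fewer than three fields are rejected with the line number.
#'
#' @param path Path to a GMT file.
#' @return A `geneset_collection` (fields `sets`, `source`).
#' @export
read_gmt <- function(path) {
  assert_that(file.exists(path), paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad) > 0) {
    stop(sprintf("GMT line %d has fewer than 3 fields", bad[1]), call. = FALSE)
  }
  nm <- vapply(parts, `[[`, "", 1)
  if (anyDuplicated(nm)) {
    stop(sprintf("duplicated set name: %s", nm[duplicated(nm)][1]), call. = FALSE)
  }
  src <- vapply(parts, `[[`, "", 2)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- nm
  new_geneset_collection(sets, source = src)
}

#' Write a gene-set collection as GMT
#'
#' @param coll A `geneset_collection`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(coll, path) {
  lines <- vapply(names(coll$sets), function(nm) {
    paste(c(nm, coll$source[[nm]], coll$sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Jaccard similarity of two gene sets
#'
#' @param a,b Non-empty character vectors of gene ids.
#' @return |a intersect b| / |a union b| in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  assert_that(length(a) > 0 && length(b) > 0, "sets must be non-empty")
  length(intersect(a, b)) / length(union(a, b))
}

#' Greedy Jaccard de-duplication of a gene-set collection
#'
#' Sets are visited in descending size, ties broken lexicographically by
#' name. A candidate conflicting (Jaccard >= `threshold`) with already
#' retained sets is resolved by representative preference: greater unique
#' content (genes not shared with the opponent), ties by canonical-source
#' rank (`source_rank`, lower = preferred), then name order. The retained
#' collection has all pairwise Jaccard < `threshold`; every removal is
#' logged with its winning representative and the similarity.
#'
#' @param coll A `geneset_collection`.
#' @param threshold Jaccard threshold in (0, 1]; default 0.60.
#' @param source_rank Optional named numeric vector of source preference
#'   ranks (lower wins ties); unlisted sources rank last.
#' @return List with `collection` (retained) and `log` (data.frame of
#'   removed, kept, jaccard).
#' @export
dedup_collection <- function(coll, threshold = 0.60, source_rank = NULL) {
  assert_that(threshold > 0 && threshold <= 1, "threshold must be in (0, 1]")
  nm <- names(coll$sets)
  sizes <- lengths(coll$sets)
  order_idx <- order(-sizes, nm)
  visit <- nm[order_idx]
  rank_of <- function(set_name) {
    src <- coll$source[[set_name]]
    if (!is.null(source_rank) && src %in% names(source_rank)) source_rank[[src]]
    else Inf
  }
  # TRUE when a should be the representative over b.
  prefers <- function(a, b) {
    ua <- length(setdiff(coll$sets[[a]], coll$sets[[b]]))
    ub <- length(setdiff(coll$sets[[b]], coll$sets[[a]]))
    if (ua != ub) return(ua > ub)
    ra <- rank_of(a); rb <- rank_of(b)
    if (ra != rb) return(ra < rb)
    a < b
  }
  retained <- character(0)
  log <- list()
  for (cand in visit) {
    conflicts <- retained[vapply(retained, function(r)
      jaccard(coll$sets[[cand]], coll$sets[[r]]) >= threshold, TRUE)]
    if (length(conflicts) == 0) {
      retained <- c(retained, cand)
    } else if (all(vapply(conflicts, function(r) prefers(cand, r), TRUE))) {
      for (r in conflicts) {
        log[[length(log) + 1]] <- data.frame(
          removed = r, kept = cand,
          jaccard = jaccard(coll$sets[[cand]], coll$sets[[r]]),
          stringsAsFactors = FALSE)
      }
      retained <- c(setdiff(retained, conflicts), cand)
    } else {
      # candidate loses to the most-preferred conflicting retained set
      best <- conflicts[1]
      for (r in conflicts[-1]) if (prefers(r, best)) best <- r
      log[[length(log) + 1]] <- data.frame(
        removed = cand, kept = best,
        jaccard = jaccard(coll$sets[[cand]], coll$sets[[best]]),
        stringsAsFactors = FALSE)
    }
  }
  retained <- nm[nm %in% retained]    # restore input order
  out <- new_geneset_collection(coll$sets[retained],
                                source = coll$source[retained])
  log_df <- if (length(log)) do.call(rbind, log) else
    data.frame(removed = character(0), kept = character(0),
               jaccard = numeric(0), stringsAsFactors = FALSE)
  list(collection = out, log = log_df)
}
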