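# Drug-sensitivity stratification by subtype and signature status, and
# two-class immunophenotyping of cell-type score matrices.

#' Stratify drug sensitivity by subtype
#'
#' Rows with AUC above the threshold are retained (GDSC convention used
#' here: higher AUC = sensitive; flip with `higher_is_sensitive = FALSE`,
#' which retains AUC below the threshold). A drug is sensitive for a
#' subtype when at least one cell line of that subtype is sensitive
#' (`min_fraction` raises the bar to a fraction of the subtype's lines).
#' Universal drugs are sensitive in every subtype; subtype-specific drugs
#' in exactly one.
#'
#' @param table Data.frame with columns cell_line, subtype, drug, auc (and
#'   optionally ic50, targets).
#' @param auc_threshold Retention threshold (default 0.7).
#' @param higher_is_sensitive Direction convention (default TRUE; logged).
#' @param min_fraction Minimum fraction of a subtype's lines that must be
#'   sensitive (default 0 = presence-based).
#' @return List with `retained` (filtered rows), `per_subtype` (drug sets),
#'   `universal`, `specific` (per subtype), `shared` (sensitive in > 1 but
#'   not all subtypes) and `counts`.
#' @export
stratify_drugs <- function(table, auc_threshold = 0.7,
                           higher_is_sensitive = TRUE, min_fraction = 0) {
  need <- c("cell_line", "subtype", "drug", "auc")
  assert_that(all(need %in% colnames(table)),
              paste("drug table needs columns:", paste(need, collapse = ", ")))
  assert_that(!anyDuplicated(table[, c("cell_line", "drug")]),
              "(cell_line, drug) pairs must be unique")
  assert_that(all(table$auc >= 0 & table$auc <= 1), "AUC must lie in [0, 1]")
  message(sprintf(
    "stratify_drugs: AUC %s %.2f treated as SENSITIVE (set higher_is_sensitive to flip)",
    if (higher_is_sensitive) ">" else "<", auc_threshold))
  retained <- if (higher_is_sensitive) table[table$auc > auc_threshold, ]
              else table[table$auc < auc_threshold, ]
  subtypes <- sort(unique(table$subtype))
  lines_per <- lapply(subtypes, function(s)
    unique(table$cell_line[table$subtype == s]))
  names(lines_per) <- subtypes
  empty <- subtypes[lengths(lines_per) == 0]
  if (length(empty) > 0) warning("subtype(s) with no lines excluded: ",
                                 paste(empty, collapse = ", "))
  per_subtype <- lapply(subtypes, function(s) {
    rows <- retained[retained$subtype == s, ]
    if (min_fraction <= 0) return(sort(unique(rows$drug)))
    tot <- length(lines_per[[s]])
    cnt <- table(rows$drug)
    sort(names(cnt)[cnt / tot >= min_fraction])
  })
  names(per_subtype) <- subtypes
  active <- setdiff(subtypes, empty)
  universal <- Reduce(intersect, per_subtype[active])
  specific <- lapply(active, function(s)
    setdiff(per_subtype[[s]], unique(unlist(per_subtype[setdiff(active, s)]))))
  names(specific) <- active
  all_sensitive <- sort(unique(unlist(per_subtype)))
  shared <- setdiff(all_sensitive, c(universal, unlist(specific)))
  list(retained = retained, per_subtype = per_subtype,
       universal = sort(universal), specific = specific, shared = shared,
       counts = data.frame(subtype = subtypes,
                           n_sensitive = lengths(per_subtype)))
}

#' Join signature exposures with a signature-drug marker table
#'
#' Samples whose exposure fraction for a signature exceeds the activity
#' floor inherit the marker table's drugs for that signature; sensitive
#' markers become recommendations, resistant ones contraindications.
#'
#' @param exposures r x sample matrix of per-sample signature fractions.
#' @param sbs_drug_table Data.frame with columns signature, drug, direction
#'   ("sensitive" or "resistant").
#' @param activity_floor Minimum exposure fraction (default 0.05).
#' @return Data.frame: sample, signature, exposure, drug, direction,
#'   recommendation ("recommended"/"contraindicated"); empty with a warning
#'   when no signature names intersect.
#' @export
sbs_drug_match <- function(exposures, sbs_drug_table, activity_floor = 0.05) {
  need <- c("signature", "drug", "direction")
  assert_that(all(need %in% colnames(sbs_drug_table)),
              paste("marker table needs columns:", paste(need, collapse = ", ")))
  shared <- intersect(rownames(exposures), sbs_drug_table$signature)
  empty <- data.frame(sample = character(0), signature = character(0),
                      exposure = numeric(0), drug = character(0),
                      direction = character(0), recommendation = character(0),
                      stringsAsFactors = FALSE)
  if (length(shared) == 0) {
    warning("no signature names shared between exposures and marker table")
    return(empty)
  }
  rows <- list()
  for (sig in shared) {
    markers <- sbs_drug_table[sbs_drug_table$signature == sig, ]
    active <- colnames(exposures)[exposures[sig, ] > activity_floor]
    for (s in active) {
      rows[[length(rows) + 1]] <- data.frame(
        sample = s, signature = sig, exposure = exposures[sig, s],
        drug = markers$drug, direction = markers$direction,
        recommendation = ifelse(markers$direction == "sensitive",
                                "recommended", "contraindicated"),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$sample, out$signature, out$drug), ]
}

#' Two-class immunophenotyping from cell-type scores
#'
#' Rows (cell types) are z-scored and samples are consensus-clustered with
#' k fixed at 2; the class with the higher mean aggregate z-score is
#' labelled "immune-inflamed" ("hot"), the other "immune-desert" ("cold").
#'
#' @param cell_scores Cell-type x sample matrix (>= 2 cell types, >= 10
#'   samples; constant matrices are rejected).
#' @param reps,subsample Consensus settings (defaults 50 and 0.8).
#' @param seed Integer seed.
#' @return List with `labels` (factor immune-inflamed/immune-desert per
#'   sample), `consensus` (the k = 2 consensus result) and `class_means`
#'   (per-class mean z-score per cell type).
#' @export
immunophenotype <- function(cell_scores, reps = 50, subsample = 0.8, seed = 1) {
  assert_that(nrow(cell_scores) >= 2, "need >= 2 cell types")
  assert_that(ncol(cell_scores) >= 10, "need >= 10 samples")
  sds <- apply(cell_scores, 1, stats::sd)
  assert_that(any(sds > 0), "cell-score matrix is constant")
  Z <- cell_scores[sds > 0, , drop = FALSE]
  Z <- t(scale(t(Z)))
  res <- consensus_cluster(Z, k_range = 2, reps = reps,
                           subsample = subsample, seed = seed)
  cl <- res$per_k[["2"]]$labels
  agg <- colMeans(Z)
  means <- tapply(agg, cl, mean)
  hot <- as.integer(names(means)[which.max(means)])
  labels <- factor(ifelse(cl == hot, "immune-inflamed", "immune-desert"),
                   levels = c("immune-inflamed", "immune-desert"))
  names(labels) <- colnames(cell_scores)
  class_means <- vapply(sort(unique(cl)), function(cc)
    rowMeans(Z[, cl == cc, drop = FALSE]), numeric(nrow(Z)))
  colnames(class_means) <- ifelse(sort(unique(cl)) == hot,
                                  "immune-inflamed", "immune-desert")
  list(labels = labels, consensus = res, class_means = class_means)
}
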