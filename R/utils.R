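#' @keywords internal
"_PACKAGE"

# Shared helpers: small argument checks and TSV I/O used across the pipeline.

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

#' Read a tab-separated matrix (features x samples)
#'
#' First column holds feature identifiers, remaining columns are samples.
#'
#' @param path Path to a TSV file.
#' @return Numeric matrix with feature rownames and sample colnames.
#' @export
read_matrix_tsv <- function(path) {
  assert_that(file.exists(path), paste0("file not found: ", path))
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write a matrix as TSV (features x samples)
#'
#' @param m Matrix with rownames.
#' @param path Output path.
#' @param id_col Name for the identifier column.
#' @return Invisibly, `path`.
#' @export
write_matrix_tsv <- function(m, path, id_col = "feature") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_table_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Pearson correlation p-value from the t distribution; matches cor.test.
cor_pvalue <- function(r, n) {
  t <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(-abs(t), df = n - 2)
}

# Adjusted Rand index between two labelings (Hubert & Arabie).
#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions of the same samples.
#'
#' @param a,b Label vectors of equal length.
#' @return Scalar ARI in `[-1, 1]`; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  assert_that(length(a) == length(b), "label vectors must have equal length")
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# Map an arbitrary user seed plus a stream offset into the 32-bit range.
derive_seed <- function(seed, offset = 0L) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(offset)) %% 2147483647) + 1L
}
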