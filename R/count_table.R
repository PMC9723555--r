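#' Construct and validate a taxa-by-sample count table
#'
#' A count table is the substrate of every analysis in this package: a
#' numeric matrix with taxa in rows and samples in columns, unique row and
#' column names, and non-negative entries. Raw tables hold read counts;
#' normalization may turn entries into non-integer reals, so integer-ness is
#' only asserted by operations that require it (singleton removal,
#' rarefaction).
#'
#' @param counts numeric matrix, taxa x samples.
#' @param taxon_ids optional character vector of row names (defaults to
#'   `rownames(counts)`).
#' @param sample_ids optional character vector of column names (defaults to
#'   `colnames(counts)`).
#' @return the validated matrix, with dimnames set.
#' @examples
#' m <- matrix(c(5, 1, 0, 3), 2, 2,
#'             dimnames = list(c("t1", "t2"), c("s1", "s2")))
#' count_table(m)
#' @export
count_table <- function(counts, taxon_ids = rownames(counts),
                        sample_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) stop("count table entries must be numeric")
  rownames(counts) <- taxon_ids
  colnames(counts) <- sample_ids
  validate_count_table(counts)
  counts
}

#' Validate a count table
#'
#' Checks the invariants every count table must satisfy: unique non-missing
#' taxon and sample identifiers, at least one sample, and all entries finite
#' and non-negative.
#'
#' @param x numeric matrix, taxa x samples.
#' @return `x`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_count_table <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) stop("count table must be a numeric matrix")
  if (ncol(x) < 1L) stop("count table must have at least one sample")
  tid <- rownames(x); sid <- colnames(x)
  if (is.null(tid) || anyNA(tid) || any(tid == "")) {
    stop("count table must have non-empty taxon ids as row names")
  }
  if (is.null(sid) || anyNA(sid) || any(sid == "")) {
    stop("count table must have non-empty sample ids as column names")
  }
  if (anyDuplicated(tid)) stop("duplicate taxon ids: ",
                               paste(unique(tid[duplicated(tid)]), collapse = ", "))
  if (anyDuplicated(sid)) stop("duplicate sample ids: ",
                               paste(unique(sid[duplicated(sid)]), collapse = ", "))
  if (anyNA(x) || any(!is.finite(x))) stop("count table entries must be finite")
  if (any(x < 0)) stop("count table entries must be non-negative")
  invisible(x)
}

# stop() unless every entry is (numerically) a whole number
assert_integer_counts <- function(x, what) {
  if (any(abs(x - round(x)) > 1e-9)) {
    stop(what, " requires integer counts; table contains non-integer entries")
  }
  invisible(x)
}

#' Per-sample sequencing depths
#'
#' @param table count table (taxa x samples matrix).
#' @return named numeric vector of column sums.
#' @export
sample_sums <- function(table) {
  validate_count_table(table)
  colSums(table)
}

#' Convert counts to per-sample relative abundances
#'
#' Divides each sample (column) by its total so that every column sums to 1.
#' Zero counts stay zero. All abundance thresholds in this package are
#' evaluated on these proportions.
#'
#' @param table count table with strictly positive column sums.
#' @return matrix of the same shape whose columns each sum to 1.
#' @examples
#' m <- count_table(matrix(c(600, 300, 100), 3, 1,
#'                  dimnames = list(c("a", "b", "c"), "s1")))
#' relative_abundances(m)
#' @export
relative_abundances <- function(table) {
  validate_count_table(table)
  cs <- colSums(table)
  zero <- cs == 0
  if (any(zero)) {
    stop("sample(s) with zero total count: ",
         paste(colnames(table)[zero], collapse = ", "))
  }
  sweep(table, 2L, cs, "/")
}

# resolve a sample id or index against a table, with a clear error
resolve_sample <- function(table, sample) {
  if (is.character(sample)) {
    j <- match(sample, colnames(table))
    if (is.na(j)) stop("unknown sample: ", sample)
  } else {
    j <- as.integer(sample)
    if (j < 1L || j > ncol(table)) stop("sample index out of range: ", sample)
  }
  j
}
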