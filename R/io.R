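#' Read a taxa-by-sample count table from TSV
#'
#' The expected dialect is a plain tab-separated file with one header row of
#' ids; the first header cell (conventionally `#TaxonID`) labels the row-id
#' column. Parsing is strict: ragged rows, duplicate ids, non-numeric or
#' negative cells are all rejected.
#'
#' @param path path to a TSV file.
#' @param orientation `"taxa"` if taxa are in rows (default), `"samples"` if
#'   samples are in rows (the table is transposed after reading so that the
#'   returned matrix is always taxa x samples).
#' @return a validated count table (see [count_table()]).
#' @export
read_count_table <- function(path, orientation = c("taxa", "samples")) {
  orientation <- match.arg(orientation)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("count table file needs a header and at least one row: ", path)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1L]]
  ncol_expect <- length(header)
  if (ncol_expect < 2L) stop("count table header must contain at least one id")
  body <- cells[-1L]
  bad <- which(vapply(body, length, 1L) != ncol_expect)
  if (length(bad)) stop("ragged row(s) in ", path, " at line(s): ",
                        paste(bad + 1L, collapse = ", "))
  row_ids <- vapply(body, `[[`, "", 1L)
  col_ids <- header[-1L]
  vals <- suppressWarnings(
    vapply(body, function(r) as.numeric(r[-1L]), numeric(ncol_expect - 1L))
  )
  # vapply over rows gives columns-in-rows; transpose back
  m <- if (is.matrix(vals)) t(vals) else matrix(vals, nrow = length(body))
  if (anyNA(m)) stop("non-numeric cell(s) in count table: ", path)
  dimnames(m) <- list(row_ids, col_ids)
  if (orientation == "samples") m <- t(m)
  count_table(m)
}

#' Write a count table to TSV
#'
#' Emits the same dialect [read_count_table()] reads, preserving row and
#' column order, so that write-then-read is the identity.
#'
#' @param table count table.
#' @param path output path.
#' @param id_header label for the first header cell.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path, id_header = "#TaxonID") {
  validate_count_table(table)
  header <- paste(c(id_header, colnames(table)), collapse = "\t")
  rows <- vapply(seq_len(nrow(table)), function(i) {
    paste(c(rownames(table)[i], format(table[i, ], trim = TRUE, scientific = FALSE,
                                       digits = 15)), collapse = "\t")
  }, "")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read DNA sequences from FASTA
#'
#' Headers are truncated at the first whitespace; sequences are uppercased
#' and restricted to the alphabet `{A, C, G, T, N}`. Duplicate ids, empty
#' records, and out-of-alphabet characters are errors.
#'
#' @param path path to a FASTA file.
#' @return named character vector of uppercase DNA sequences (a "sequence
#'   set"), names being the taxon ids.
#' @export
read_fasta <- function(path) {
  # readDNAStringSet silently drops invalid letters with a warning; promote
  # that to an error so malformed records cannot slip through
  dss <- withCallingHandlers(
    Biostrings::readDNAStringSet(path),
    warning = function(w) stop("invalid FASTA record in ", path, ": ",
                               conditionMessage(w))
  )
  ids <- sub("\\s.*$", "", names(dss))
  seqs <- toupper(as.character(dss))
  names(seqs) <- ids
  validate_sequence_set(seqs)
  seqs
}

#' Validate a sequence set
#'
#' @param seqs named character vector of DNA sequences.
#' @return `seqs`, invisibly, if valid.
#' @export
validate_sequence_set <- function(seqs) {
  if (length(seqs) == 0L) stop("empty sequence set")
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids))) stop("sequences must be named by taxon id")
  if (anyDuplicated(ids)) stop("duplicate sequence id(s): ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(!nzchar(seqs))) stop("empty sequence(s): ",
                               paste(ids[!nzchar(seqs)], collapse = ", "))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) stop("sequence(s) with characters outside {A,C,G,T,N}: ",
                     paste(ids[bad], collapse = ", "))
  invisible(seqs)
}

#' Write a sequence set to FASTA
#'
#' @param seqs named character vector of DNA sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  validate_sequence_set(seqs)
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  invisible(path)
}

#' Read a rooted phylogenetic tree from Newick
#'
#' Wraps [ape::read.tree()] with the validation UniFrac computations need:
#' unique leaf labels and non-negative branch lengths. Missing branch
#' lengths are treated as zero, so they contribute nothing to UniFrac sums.
#'
#' @param path path to a Newick file (or use `text` for a literal string).
#' @param text optional Newick string, read instead of `path`.
#' @return an [ape::phylo] tree.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  tr <- tryCatch(
    if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (!inherits(tr, "phylo")) stop("could not parse Newick input (unbalanced or malformed)")
  validate_tree(tr)
}

#' Validate a phylogenetic tree for UniFrac use
#'
#' @param tree an [ape::phylo] object.
#' @return the tree (with missing branch lengths replaced by 0), invisibly
#'   returned visibly for chaining.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate leaf label(s): ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  }
  if (is.null(tree$edge.length)) {
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  tree$edge.length[is.na(tree$edge.length)] <- 0
  if (any(tree$edge.length < 0)) stop("negative branch length(s) in tree")
  tree
}

#' Write a tree to Newick
#'
#' @param tree an [ape::phylo] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read sample metadata from TSV
#'
#' The file must contain a `sample_id` column; the conventional analysis
#' columns (`run_id`, `subject_id`, `replicate_group`, `category`,
#' `timepoint`) are added as empty strings when absent. Sample ids must be
#' unique.
#'
#' @param path path to a TSV file with a header row.
#' @return data.frame keyed by `sample_id`.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  if (!"sample_id" %in% names(df)) stop("metadata must contain a sample_id column")
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in metadata")
  for (col in c("run_id", "subject_id", "replicate_group", "category", "timepoint")) {
    if (!col %in% names(df)) df[[col]] <- ""
  }
  df
}

#' Write sample metadata to TSV
#'
#' @param meta data.frame with a `sample_id` column.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
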