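# Alignment scoring used throughout: match +1, mismatch -1, affine gaps
# (open 5, extend 2, the classic blastn costs), free end gaps on the
# reference (the query is aligned end-to-end against the best-fitting region
# of the reference). The affine gap cost keeps near-identical sequences on
# the ungapped path, so k scattered substitutions score exactly (L-k)/L
# identity; a cheap linear gap would occasionally "rescue" mismatches via
# one-base shifts and blur the 97% decision boundary. N never matches.
match_submat <- function() {
  m <- matrix(-1, 5, 5, dimnames = list(c("A", "C", "G", "T", "N"),
                                        c("A", "C", "G", "T", "N")))
  diag(m)[1:4] <- 1
  m
}

# Align a set of queries against one reference; returns identity/coverage per
# query. identity = matches / alignment columns (gap columns count as
# mismatches); coverage = query bases aligned to reference bases / query
# length. Query bases overhanging the reference ends lower both.
align_to_reference <- function(queries, reference) {
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(queries),
    subject = Biostrings::DNAString(reference),
    type = "global-local", substitutionMatrix = match_submat(),
    gapOpening = 5, gapExtension = 2
  )
  pv <- as.character(Biostrings::alignedPattern(aln))
  sv <- as.character(Biostrings::alignedSubject(aln))
  qlen <- nchar(queries)
  res <- mapply(function(p, s, ql) {
    pc <- strsplit(p, "", fixed = TRUE)[[1L]]
    sc <- strsplit(s, "", fixed = TRUE)[[1L]]
    cols <- length(pc)
    matches <- sum(pc == sc & pc %in% c("A", "C", "G", "T"))
    aligned <- sum(pc != "-" & sc != "-")
    c(identity = matches / cols, coverage = aligned / ql)
  }, pv, sv, qlen)
  data.frame(identity = res["identity", ], coverage = res["coverage", ],
             row.names = NULL)
}

#' Pairwise identity and coverage between a query and a reference sequence
#'
#' Performs a semi-global alignment with free end gaps on the reference: the
#' query is aligned end-to-end against the best-scoring region of the
#' reference (scoring: match +1, mismatch -1, affine gaps with open cost 5
#' and extension cost 2 per base). Identity is the
#' fraction of matching alignment columns, with gap columns counted as
#' mismatches; coverage is the fraction of query bases aligned to actual
#' reference bases (query overhang beyond the reference, and query bases
#' opposite reference gaps, reduce it). `N` bases count as mismatches.
#'
#' @param query,reference non-empty DNA strings over `{A,C,G,T,N}`.
#' @return named numeric vector with elements `identity` and `coverage`,
#'   both in `[0, 1]`.
#' @examples
#' pairwise_identity("ACGTACGT", "ACGTACGT")
#' @export
pairwise_identity <- function(query, reference) {
  if (!nzchar(query) || !nzchar(reference)) stop("empty sequence")
  r <- align_to_reference(query, reference)
  c(identity = r$identity[1L], coverage = r$coverage[1L])
}

new_match_table <- function(taxon_id, status, best_reference, identity,
                            coverage, hamming) {
  structure(
    data.frame(taxon_id = taxon_id, status = status,
               best_reference = best_reference, identity = identity,
               coverage = coverage, hamming = hamming,
               stringsAsFactors = FALSE, row.names = NULL),
    class = c("match_table", "data.frame")
  )
}

#' Classify observed taxa against a reference community by sequence identity
#'
#' Each observed taxon is assigned its best reference member (highest
#' identity, ties broken by higher coverage, then lexicographic member id)
#' and called `matched` iff identity >= `min_identity` and coverage >=
#' `min_coverage`; otherwise `spurious`. The defaults (97% identity over 90%
#' of the query) are the conventional positive-hit criteria for matching
#' OTUs/ASVs to known reference sequences.
#'
#' @param observed named character vector of observed representative
#'   sequences.
#' @param ref a [reference_community()] (or a named character vector of
#'   reference sequences).
#' @param min_identity minimum identity for a positive hit (default 0.97).
#' @param min_coverage minimum query coverage for a positive hit (default
#'   0.90).
#' @return a `match_table` data.frame with one row per observed taxon:
#'   `taxon_id`, `status` (matched/spurious), `best_reference`, `identity`,
#'   `coverage`, `hamming` (NA here).
#' @export
classify_by_identity <- function(observed, ref, min_identity = 0.97,
                                 min_coverage = 0.90) {
  validate_sequence_set(observed)
  members <- reference_members(ref)
  member_ids <- sort(names(members))
  best_id <- rep(NA_character_, length(observed))
  best_ident <- rep(-1, length(observed))
  best_cov <- rep(-1, length(observed))
  for (mid in member_ids) {
    r <- align_to_reference(observed, members[[mid]])
    better <- r$identity > best_ident |
      (r$identity == best_ident & r$coverage > best_cov)
    # member_ids are scanned in lexicographic order, so ties keep the first id
    best_id[better] <- mid
    best_ident[better] <- r$identity[better]
    best_cov[better] <- r$coverage[better]
  }
  matched <- best_ident >= min_identity & best_cov >= min_coverage
  new_match_table(names(observed), ifelse(matched, "matched", "spurious"),
                  ifelse(matched, best_id, best_id), best_ident, best_cov,
                  NA_integer_)
}

#' Classify observed taxa against a reference community by Hamming distance
#'
#' The ASV-style rule: an observed sequence is `matched` iff its minimum
#' Hamming distance to any equal-length reference sequence is at most
#' `max_distance` (default 1); sequences at distance greater than 1 from
#' every reference are spurious. Sequences with no equal-length reference
#' have infinite distance and are spurious.
#'
#' @param observed named character vector of observed sequences.
#' @param ref a [reference_community()] or named character vector.
#' @param max_distance maximum Hamming distance for a match (default 1).
#' @return a `match_table` data.frame (identity/coverage are NA; `hamming`
#'   holds the minimum distance, NA when no equal-length reference exists).
#' @export
classify_by_hamming <- function(observed, ref, max_distance = 1L) {
  validate_sequence_set(observed)
  members <- reference_members(ref)
  if (length(members) == 0L) stop("empty reference set")
  mem_split <- lapply(members, function(s) strsplit(s, "", fixed = TRUE)[[1L]])
  mem_len <- vapply(members, nchar, 1L)
  res <- lapply(observed, function(q) {
    qc <- strsplit(q, "", fixed = TRUE)[[1L]]
    same <- which(mem_len == length(qc))
    if (!length(same)) return(list(d = NA_integer_, ref = NA_character_))
    d <- vapply(same, function(i) sum(qc != mem_split[[i]]), 1L)
    k <- which.min(d)
    list(d = d[k], ref = names(members)[same[k]])
  })
  dmin <- vapply(res, `[[`, 1L, "d")
  bref <- vapply(res, `[[`, "", "ref")
  matched <- !is.na(dmin) & dmin <= max_distance
  new_match_table(names(observed), ifelse(matched, "matched", "spurious"),
                  ifelse(matched, bref, bref), NA_real_, NA_real_, dmin)
}

#' Classify taxa using synthetic ground-truth labels
#'
#' For generator output, the true/spurious dichotomy is known by
#' construction: taxa labeled `true` are matched (to themselves, since true
#' taxa carry their reference member's id), all other labels (contaminant,
#' satellite, singleton_artifact) are spurious. This lets downstream
#' benchmarking be tested independently of sequence alignment.
#'
#' @param taxon_ids character vector of taxa to classify.
#' @param truth ground-truth data.frame from the generator (columns
#'   `taxon_id`, `label`).
#' @return a `match_table` data.frame.
#' @export
classify_by_label <- function(taxon_ids, truth) {
  i <- match(taxon_ids, truth$taxon_id)
  if (anyNA(i)) stop("taxa missing from ground truth: ",
                     paste(taxon_ids[is.na(i)], collapse = ", "))
  lab <- truth$label[i]
  matched <- lab == "true"
  new_match_table(taxon_ids, ifelse(matched, "matched", "spurious"),
                  ifelse(matched, taxon_ids, NA_character_),
                  NA_real_, NA_real_, NA_integer_)
}

#' Collapse redundant sequences by greedy centroid clustering
#'
#' Sequences are processed in decreasing length order (ties broken
#' lexicographically by id). Each sequence joins the first existing centroid
#' (in founding order) to which its identity is at least
#' `identity_threshold` with coverage at least `min_coverage`; otherwise it
#' founds a new cluster. This mirrors de-novo centroid clustering at 97%
#' identity as used to remove redundancy among spurious OTUs pooled across
#' sequencing runs.
#'
#' @param seqs named character vector of sequences.
#' @param identity_threshold clustering identity threshold (default 0.97).
#' @param min_coverage minimum coverage against the centroid (default 0.90).
#' @return data.frame with columns `taxon_id`, `cluster_id` (the centroid's
#'   taxon id) and `is_centroid`.
#' @export
collapse_redundant <- function(seqs, identity_threshold = 0.97,
                               min_coverage = 0.90) {
  validate_sequence_set(seqs)
  ord <- order(-nchar(seqs), names(seqs))
  seqs <- seqs[ord]
  centroid_ids <- character(0)
  centroid_seqs <- character(0)
  assignment <- character(length(seqs))
  for (i in seq_along(seqs)) {
    hit <- NA_character_
    exact <- match(seqs[[i]], centroid_seqs)
    if (!is.na(exact)) {
      hit <- centroid_ids[exact]
    } else if (length(centroid_ids)) {
      for (k in seq_along(centroid_ids)) {
        r <- align_to_reference(seqs[[i]], centroid_seqs[[k]])
        if (r$identity[1L] >= identity_threshold &&
            r$coverage[1L] >= min_coverage) {
          hit <- centroid_ids[k]
          break
        }
      }
    }
    if (is.na(hit)) {
      centroid_ids <- c(centroid_ids, names(seqs)[i])
      centroid_seqs <- c(centroid_seqs, seqs[[i]])
      hit <- names(seqs)[i]
    }
    assignment[i] <- hit
  }
  data.frame(taxon_id = names(seqs), cluster_id = assignment,
             is_centroid = names(seqs) == assignment,
             stringsAsFactors = FALSE, row.names = NULL)
}
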