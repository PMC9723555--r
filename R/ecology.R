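#' Pooled two-proportion z-test for category exclusivity
#'
#' Tests whether a taxon's prevalence in its top category differs from the
#' runner-up category, using the pooled two-proportion z statistic
#' z = (p1 - p2) / sqrt(phat (1 - phat) (1/n1 + 1/n2)) with
#' phat = (x1 + x2) / (n1 + n2) and a two-sided normal p-value. No
#' continuity correction is applied (the intended regime is large sample
#' counts per category). Categories with zero total are excluded.
#'
#' @param positives named integer vector: positive samples per category.
#' @param totals named integer vector: total samples per category (same
#'   names).
#' @return list with `z`, `p`, `top_category`, `runner_up_category`,
#'   `top_prevalence` and `runner_up_prevalence` (percents).
#' @examples
#' exclusivity_test(c(human = 40, soil = 0), c(human = 100, soil = 100))
#' @export
exclusivity_test <- function(positives, totals) {
  if (is.null(names(positives)) || is.null(names(totals)) ||
      !setequal(names(positives), names(totals))) {
    stop("positives and totals must be named by the same categories")
  }
  totals <- totals[names(positives)]
  usable <- totals >= 1
  if (sum(usable) < 2L) stop("fewer than 2 usable categories")
  x <- positives[usable]; n <- totals[usable]
  if (any(x > n) || any(x < 0)) stop("positives must lie in [0, totals]")
  prev <- x / n
  ord <- order(-prev, names(x))
  i1 <- ord[1L]; i2 <- ord[2L]
  phat <- (x[i1] + x[i2]) / (n[i1] + n[i2])
  se <- sqrt(phat * (1 - phat) * (1 / n[i1] + 1 / n[i2]))
  z <- if (se == 0) 0 else unname((prev[i1] - prev[i2]) / se)
  p <- 2 * stats::pnorm(-abs(z))
  list(z = z, p = p,
       top_category = names(x)[i1], runner_up_category = names(x)[i2],
       top_prevalence = unname(100 * prev[i1]),
       runner_up_prevalence = unname(100 * prev[i2]))
}

#' Prevalence and exclusivity of spurious taxa across sample categories
#'
#' For each taxon, prevalence in a category is the percentage of that
#' category's samples in which the taxon occurs above `abundance_threshold`
#' relative abundance. Following the occurrence-map convention, samples
#' with no hit to any of the taxa (all-zero columns) are excluded from the
#' denominators by default, since absence there cannot be distinguished
#' from a primer/region mismatch. For taxa occurring in at least two
#' categories the top category is tested against the runner-up with
#' [exclusivity_test()]; p-values are Benjamini-Hochberg adjusted across
#' all tested taxa, and a taxon is called exclusive when the adjusted p is
#' below `alpha` and its top prevalence exceeds the runner-up.
#'
#' @param occurrence taxa x samples matrix of per-sample relative
#'   abundances (fractions in `[0, 1]`); typically the occurrence map of
#'   spurious taxa only, so columns need not sum to 1.
#' @param meta metadata data.frame with columns `sample_id` and `category`
#'   covering all samples.
#' @param abundance_threshold positivity threshold (default 0.0025).
#' @param drop_no_hit drop samples with no taxon above zero (default TRUE).
#' @param alpha significance level on adjusted p-values (default 0.05).
#' @return list with `prevalence` (long data.frame: `taxon_id`, `category`,
#'   `n_samples`, `n_positive`, `prevalence`) and `exclusivity` (per-taxon
#'   data.frame: `taxon_id`, `top_category`, `top_prevalence`,
#'   `runner_up_category`, `runner_up_prevalence`, `z`, `p`, `p_adj`,
#'   `exclusive`).
#' @export
prevalence_by_category <- function(occurrence, meta,
                                   abundance_threshold = 0.0025,
                                   drop_no_hit = TRUE, alpha = 0.05) {
  if (!is.matrix(occurrence) || !is.numeric(occurrence)) {
    stop("occurrence must be a numeric matrix")
  }
  i <- match(colnames(occurrence), meta$sample_id)
  if (anyNA(i)) stop("samples missing from metadata: ",
                     paste(colnames(occurrence)[is.na(i)], collapse = ", "))
  category <- meta$category[i]
  if (anyNA(category) || any(!nzchar(category))) {
    stop("unknown (empty) category label for some samples")
  }
  if (drop_no_hit) {
    hit <- colSums(occurrence > 0) > 0
    occurrence <- occurrence[, hit, drop = FALSE]
    category <- category[hit]
  }
  if (ncol(occurrence) == 0L) stop("no samples left after dropping no-hit samples")
  cats <- sort(unique(category))
  totals <- vapply(cats, function(cc) sum(category == cc), 1L)
  pos <- vapply(cats, function(cc) {
    rowSums(occurrence[, category == cc, drop = FALSE] > abundance_threshold)
  }, numeric(nrow(occurrence)))
  if (is.null(dim(pos))) pos <- matrix(pos, nrow = nrow(occurrence),
                                       dimnames = list(rownames(occurrence), cats))
  prevalence <- do.call(rbind, lapply(seq_along(cats), function(k) {
    data.frame(taxon_id = rownames(occurrence), category = cats[k],
               n_samples = totals[k], n_positive = pos[, k],
               prevalence = 100 * pos[, k] / totals[k],
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  tests <- lapply(seq_len(nrow(occurrence)), function(r) {
    if (length(cats) < 2L) return(NULL)
    tt <- exclusivity_test(stats::setNames(pos[r, ], cats),
                           stats::setNames(totals, cats))
    data.frame(taxon_id = rownames(occurrence)[r],
               top_category = tt$top_category,
               top_prevalence = tt$top_prevalence,
               runner_up_category = tt$runner_up_category,
               runner_up_prevalence = tt$runner_up_prevalence,
               z = tt$z, p = tt$p, stringsAsFactors = FALSE)
  })
  exclusivity <- do.call(rbind, tests)
  if (!is.null(exclusivity)) {
    exclusivity$p_adj <- stats::p.adjust(exclusivity$p, method = "BH")
    exclusivity$exclusive <- exclusivity$p_adj < alpha &
      exclusivity$top_prevalence > exclusivity$runner_up_prevalence
  }
  list(prevalence = prevalence, exclusivity = exclusivity)
}

#' Run redundancy of spurious taxon clusters
#'
#' Counts, for each cluster of spurious sequences, the number of distinct
#' sequencing runs contributing at least one member. Most contamination is
#' sporadic: the bulk of spurious clusters typically occur in a single run,
#' implicating run-specific cross-contamination rather than generalist
#' artifacts.
#'
#' @param assignments data.frame with columns `cluster_id` and `run_id`
#'   (one row per spurious taxon).
#' @return data.frame with columns `cluster_id` and `n_runs`, one row per
#'   cluster.
#' @export
run_redundancy <- function(assignments) {
  if (is.null(assignments) || nrow(assignments) == 0L) stop("empty input")
  if (!all(c("cluster_id", "run_id") %in% names(assignments))) {
    stop("assignments must have cluster_id and run_id columns")
  }
  counts <- vapply(split(assignments$run_id, assignments$cluster_id),
                   function(r) length(unique(r)), 1L)
  data.frame(cluster_id = names(counts), n_runs = unname(counts),
             stringsAsFactors = FALSE)
}

#' Cluster per-run spurious sequences and count run redundancy
#'
#' Pools the spurious sequences of several runs, collapses them at 97%
#' identity via [collapse_redundant()], and reports how many runs each
#' resulting cluster appears in.
#'
#' @param seqs_by_run named list of sequence sets (one per run; taxon ids
#'   must be unique across runs).
#' @param identity_threshold clustering threshold (default 0.97).
#' @return data.frame as from [run_redundancy()].
#' @export
run_redundancy_from_sequences <- function(seqs_by_run,
                                          identity_threshold = 0.97) {
  if (length(seqs_by_run) == 0L) stop("empty input")
  if (is.null(names(seqs_by_run))) {
    names(seqs_by_run) <- paste0("run", seq_along(seqs_by_run))
  }
  pooled <- unlist(unname(seqs_by_run))
  runs <- rep(names(seqs_by_run), vapply(seqs_by_run, length, 1L))
  names(runs) <- names(pooled)
  clusters <- collapse_redundant(pooled, identity_threshold)
  clusters$run_id <- runs[clusters$taxon_id]
  run_redundancy(clusters)
}
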