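# match-table lookup with a hard error when taxa are unaccounted for
match_status <- function(taxon_ids, matches) {
  i <- match(taxon_ids, matches$taxon_id)
  if (anyNA(i)) stop("taxa missing from match table: ",
                     paste(taxon_ids[is.na(i)], collapse = ", "))
  matches[i, , drop = FALSE]
}

#' Relative abundance of the first spurious taxon in a sample
#'
#' Scanning a sample's taxa in decreasing relative abundance, the first
#' spurious taxon appears at the maximum per-sample abundance over the
#' spurious set. This statistic, recorded per reference-community sample,
#' is what motivates a consensus filtering cutoff: in benchmark data almost
#' all values fall below 0.25% relative abundance.
#'
#' @param table count table (unfiltered).
#' @param matches `match_table` covering the table's taxa.
#' @param sample sample id or index.
#' @return the abundance in percent, or `NA` if no spurious taxon has
#'   nonzero count in the sample.
#' @export
first_spurious_abundance <- function(table, matches, sample) {
  validate_count_table(table)
  j <- resolve_sample(table, sample)
  p <- relative_abundances(table)[, j]
  st <- match_status(rownames(table), matches)
  sp <- st$status == "spurious" & p > 0
  if (!any(sp)) return(NA_real_)
  100 * max(p[sp])
}

#' Benchmark a count table against a reference community under a filter
#'
#' Applies the filter, then scores every sample: how many retained taxa are
#' spurious, what fraction of reference members is still detected (positive
#' hits), and how much relative abundance the retained spurious taxa carry.
#' Denominators count only taxa with nonzero count in the given sample; a
#' taxon absent from a sample cannot be detected there. Positive hits count
#' distinct reference members, so multiple observed taxa matching one
#' member ("satellites") cannot push the fraction above 100%; the
#' `n_matched_taxa` column exposes that multiplicity.
#'
#' Relative abundances (for `first_spurious_abundance` and
#' `cumulative_spurious_abundance`) are computed on the unfiltered input
#' table, since filtering preserves raw counts without re-normalization.
#'
#' @param table count table (unfiltered, integer counts).
#' @param matches `match_table` covering all taxa of `table`.
#' @param reference a [reference_community()] or character vector of member
#'   ids (used for the positive-hit denominator).
#' @param spec a [filter_spec()].
#' @return data.frame with one row per sample: `sample_id`, `n_taxa_total`,
#'   `n_spurious`, `spurious_fraction` (%), `n_positive_hits`,
#'   `positive_hit_fraction` (%), `n_matched_taxa`,
#'   `first_spurious_abundance` (%), `cumulative_spurious_abundance` (%).
#' @export
benchmark_sample <- function(table, matches, reference,
                             spec = filter_spec()) {
  validate_count_table(table)
  member_ids <- if (is.character(reference)) reference else reference_ids(reference)
  if (length(member_ids) == 0L) stop("empty reference set")
  st_all <- match_status(rownames(table), matches)
  filtered <- apply_filter(table, spec)
  p_unf <- relative_abundances(table)
  st_f <- match_status(rownames(filtered), matches)
  out <- lapply(seq_len(ncol(table)), function(j) {
    present <- filtered[, j] > 0
    st <- st_f[present, , drop = FALSE]
    n_total <- sum(present)
    n_sp <- sum(st$status == "spurious")
    hits <- unique(st$best_reference[st$status == "matched"])
    hits <- hits[hits %in% member_ids]
    sp_unfiltered <- st_all$status == "spurious" & table[, j] > 0
    retained_sp <- rownames(filtered)[present][st$status == "spurious"]
    data.frame(
      sample_id = colnames(table)[j],
      n_taxa_total = n_total,
      n_spurious = n_sp,
      spurious_fraction = if (n_total > 0) 100 * n_sp / n_total else NA_real_,
      n_positive_hits = length(hits),
      positive_hit_fraction = 100 * length(hits) / length(member_ids),
      n_matched_taxa = sum(st$status == "matched"),
      first_spurious_abundance =
        if (any(sp_unfiltered)) 100 * max(p_unf[sp_unfiltered, j]) else NA_real_,
      cumulative_spurious_abundance = 100 * sum(p_unf[retained_sp, j]),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Summarize a benchmark result as mean and SD over replicate samples
#'
#' @param result data.frame from [benchmark_sample()].
#' @return one-row data.frame of means and standard deviations (n-1) of the
#'   per-sample metrics.
#' @export
benchmark_summary <- function(result) {
  num <- c("n_taxa_total", "spurious_fraction", "positive_hit_fraction",
           "first_spurious_abundance", "cumulative_spurious_abundance")
  means <- vapply(num, function(v) mean(result[[v]], na.rm = TRUE), 1)
  sds <- vapply(num, function(v) {
    x <- result[[v]][!is.na(result[[v]])]
    if (length(x) > 1L) stats::sd(x) else 0
  }, 1)
  out <- as.data.frame(as.list(c(means, stats::setNames(sds, paste0(num, "_sd")))))
  out$n_samples <- nrow(result)
  out
}

#' Sweep relative-abundance filtering thresholds over benchmark datasets
#'
#' Runs [benchmark_sample()] in relative-abundance mode at each threshold on
#' every dataset and reports, per threshold, the mean and standard deviation
#' across datasets of the spurious-taxon fraction and the positive-hit
#' fraction (each dataset first averaged over its replicate samples). The
#' default grid, 0 to 0.5% in 0.05% steps, spans the range in which the
#' trade-off between removing spurious taxa and losing true members plays
#' out.
#'
#' @param datasets list of datasets, each a list with elements `table`,
#'   `matches` and `reference`.
#' @param thresholds strictly increasing vector of cutoffs (fractions).
#' @return data.frame of class `sweep_curve`: `threshold`,
#'   `mean_spurious_fraction`, `sd_spurious_fraction`,
#'   `mean_positive_hit_fraction`, `sd_positive_hit_fraction` (percents).
#' @export
threshold_sweep <- function(datasets, thresholds = seq(0, 0.005, by = 0.0005)) {
  if (length(datasets) == 0L) stop("at least one dataset is required")
  if (length(thresholds) == 0L) stop("empty threshold list")
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop("thresholds must be strictly increasing")
  }
  rows <- lapply(thresholds, function(th) {
    per_ds <- vapply(datasets, function(d) {
      res <- benchmark_sample(d$table, d$matches, d$reference,
                              filter_spec("relative_abundance", cutoff = th))
      c(mean(res$spurious_fraction, na.rm = TRUE),
        mean(res$positive_hit_fraction, na.rm = TRUE))
    }, numeric(2L))
    sdv <- function(x) if (length(x) > 1L) stats::sd(x) else 0
    data.frame(threshold = th,
               mean_spurious_fraction = mean(per_ds[1L, ]),
               sd_spurious_fraction = sdv(per_ds[1L, ]),
               mean_positive_hit_fraction = mean(per_ds[2L, ]),
               sd_positive_hit_fraction = sdv(per_ds[2L, ]))
  })
  structure(do.call(rbind, rows), class = c("sweep_curve", "data.frame"))
}
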