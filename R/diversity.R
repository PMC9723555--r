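#' Observed richness of a sample
#'
#' The count of taxa with nonzero count in a sample. Without filtering this
#' number inflates with sequencing depth, because ever more rare (and often
#' spurious) taxa cross the detection limit.
#'
#' @param table count table.
#' @param sample sample id or index.
#' @return integer richness.
#' @export
richness <- function(table, sample) {
  validate_count_table(table)
  j <- resolve_sample(table, sample)
  sum(table[, j] > 0)
}

#' Effective microbial richness (EMR) of a sample
#'
#' The number of taxa whose relative abundance in the sample strictly
#' exceeds `emr_cutoff` (default 0.25%). Because it is defined on
#' proportions, EMR is invariant to multiplying the sample by any positive
#' constant, hence unaffected by sequencing depth or scaling normalization
#' — unlike plain richness. Equivalently, EMR is the count of taxa that
#' survive rescaling the sample to 1000 reads and dropping taxa occurring
#' below 2.5 rescaled counts (exact ties at the cutoff are dropped).
#'
#' @param table count table.
#' @param sample sample id or index.
#' @param emr_cutoff relative-abundance cutoff (default 0.0025).
#' @return integer effective richness.
#' @examples
#' m <- count_table(matrix(c(600, 300, 97, 2, 1), 5, 1,
#'        dimnames = list(paste0("t", 1:5), "s1")))
#' effective_richness(m, "s1")  # 3
#' @export
effective_richness <- function(table, sample, emr_cutoff = 0.0025) {
  validate_count_table(table)
  j <- resolve_sample(table, sample)
  p <- relative_abundances(table[, j, drop = FALSE])[, 1L]
  sum(p > emr_cutoff)
}

#' Shannon effective count of a sample
#'
#' The exponential of the Shannon entropy (natural log) of the sample's
#' taxon proportions: an evenness-aware effective number of species, equal
#' to k for k equally abundant taxa and 1 for a single taxon.
#'
#' @param table count table.
#' @param sample sample id or index.
#' @return positive real effective count.
#' @export
shannon_effective <- function(table, sample) {
  validate_count_table(table)
  j <- resolve_sample(table, sample)
  x <- table[, j]
  if (sum(x) == 0) stop("sample has zero total count: ", colnames(table)[j])
  exp(vegan::diversity(x, index = "shannon"))
}

#' Alpha-diversity profile of all samples
#'
#' @param table count table with positive sample sums.
#' @param emr_cutoff EMR cutoff (default 0.0025).
#' @return data.frame with one row per sample: `sample_id`, `richness`,
#'   `effective_richness`, `shannon_effective`.
#' @export
diversity_profile <- function(table, emr_cutoff = 0.0025) {
  validate_count_table(table)
  data.frame(
    sample_id = colnames(table),
    richness = vapply(seq_len(ncol(table)), function(j) richness(table, j), 1L),
    effective_richness = vapply(seq_len(ncol(table)), function(j)
      effective_richness(table, j, emr_cutoff), 1L),
    shannon_effective = vapply(seq_len(ncol(table)), function(j)
      shannon_effective(table, j), 1),
    stringsAsFactors = FALSE
  )
}

#' Interquartile range of richness per group
#'
#' IQR = Q3 - Q1 with linear-interpolation quantiles (type 7), used as a
#' proxy for richness variation of a subject across time points. Stringent
#' abundance filtering typically shrinks these IQRs markedly.
#'
#' @param values numeric vector of richness values.
#' @param grouping factor/vector of group labels (e.g. subject ids), same
#'   length as `values`.
#' @return data.frame with columns `group`, `n`, `iqr`.
#' @export
richness_iqr <- function(values, grouping) {
  if (length(values) != length(grouping)) stop("values and grouping lengths differ")
  groups <- split(values, grouping)
  small <- vapply(groups, length, 1L) < 2L
  if (any(small)) stop("group(s) with fewer than 2 values: ",
                       paste(names(groups)[small], collapse = ", "))
  data.frame(
    group = names(groups),
    n = vapply(groups, length, 1L),
    iqr = vapply(groups, function(v)
      unname(diff(stats::quantile(v, c(0.25, 0.75), type = 7))), 1),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Coefficients of variation of richness within and across sequencing runs
#'
#' Within-run CV: for each (run, replicate group) with at least 2
#' replicates, 100 * sd / mean of the replicate richness values. Across-run
#' CV: for each replicate group sequenced in at least 2 runs, the CV over
#' the per-run replicate means — i.e. the run-to-run variation of the same
#' sample. SD is the n-1 sample standard deviation.
#'
#' @param values numeric vector of richness values.
#' @param run vector of run ids, same length.
#' @param group vector of replicate-group ids, same length.
#' @return list with data.frames `within_run` (`run`, `group`, `n`, `cv`)
#'   and `across_run` (`group`, `n_runs`, `cv`).
#' @export
richness_cv <- function(values, run, group) {
  if (length(values) != length(run) || length(values) != length(group)) {
    stop("values, run and group must have the same length")
  }
  cv <- function(x) {
    m <- mean(x)
    if (m == 0) stop("cannot compute CV: group mean is 0")
    100 * stats::sd(x) / m
  }
  key <- interaction(run, group, drop = TRUE)
  cells <- split(seq_along(values), key)
  within <- do.call(rbind, lapply(cells, function(idx) {
    if (length(idx) < 2L) return(NULL)
    data.frame(run = run[idx[1L]], group = group[idx[1L]],
               n = length(idx), cv = cv(values[idx]),
               stringsAsFactors = FALSE)
  }))
  rownames(within) <- NULL
  per_group <- split(seq_along(values), group)
  across <- do.call(rbind, lapply(names(per_group), function(g) {
    idx <- per_group[[g]]
    run_means <- vapply(split(values[idx], run[idx]), mean, 1)
    if (length(run_means) < 2L) return(NULL)
    data.frame(group = g, n_runs = length(run_means), cv = cv(run_means),
               stringsAsFactors = FALSE)
  }))
  if (is.null(across)) {
    stop("across-run CV requires at least 2 runs per replicate group")
  }
  rownames(across) <- NULL
  list(within_run = within, across_run = across)
}
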