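#' Specify a taxon-filtering strategy
#'
#' Two strategies are supported, mirroring common practice in amplicon
#' analysis: removal of singletons (taxa represented by a single read across
#' all samples) and removal of taxa that never exceed a relative-abundance
#' cutoff in any sample. The consensus cutoff is 0.25% (0.0025), the level
#' below which spurious taxa concentrate in reference-community benchmarks.
#'
#' @param mode one of `"none"`, `"singleton"`, `"relative_abundance"`.
#' @param cutoff relative-abundance cutoff in `[0, 1]`; used only in
#'   `relative_abundance` mode. Default 0.0025 (0.25%).
#' @return an object of class `filter_spec`.
#' @export
filter_spec <- function(mode = c("relative_abundance", "singleton", "none"),
                        cutoff = 0.0025) {
  mode <- match.arg(mode)
  if (!is.numeric(cutoff) || length(cutoff) != 1L || is.na(cutoff) ||
      cutoff < 0 || cutoff > 1) {
    stop("cutoff must be a single number in [0, 1]")
  }
  structure(list(mode = mode, cutoff = cutoff), class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  cat("<filter_spec> mode =", x$mode)
  if (x$mode == "relative_abundance") cat(", cutoff =", x$cutoff)
  cat("\n")
  invisible(x)
}

#' Remove singleton taxa
#'
#' Removes exactly those taxa whose total count summed across all samples
#' equals 1. Singletons are a raw-count concept, so non-integer tables are
#' rejected. The sample set is unchanged.
#'
#' @param table count table with integer counts.
#' @return the table restricted to taxa with total count != 1.
#' @export
filter_singletons <- function(table) {
  validate_count_table(table)
  assert_integer_counts(table, "filter_singletons")
  keep <- rowSums(table) != 1
  table[keep, , drop = FALSE]
}

#' Filter taxa by a relative-abundance cutoff
#'
#' Retains exactly those taxa whose relative abundance exceeds `cutoff`
#' (strictly) in at least one sample. Proportions are computed on the
#' unfiltered table and retained taxa keep their original counts; no
#' re-normalization takes place. Exact ties at the cutoff are removed,
#' which keeps the rule consistent with effective microbial richness
#' (taxa occurring *above* the cutoff) and with its reads-based phrasing
#' (removal of taxa occurring below 2.5 counts per 1000 reads).
#'
#' @param table count table with positive sample sums.
#' @param spec a [filter_spec()], or a single numeric cutoff in `[0, 1]`.
#' @return the table restricted to retained taxa.
#' @export
filter_relative_abundance <- function(table, spec = filter_spec()) {
  if (is.numeric(spec)) spec <- filter_spec("relative_abundance", cutoff = spec)
  p <- relative_abundances(table)
  keep <- apply(p, 1L, max) > spec$cutoff
  table[keep, , drop = FALSE]
}

#' Apply a filter specification to a count table
#'
#' Dispatches on the mode of a [filter_spec()]; `mode = "none"` is the
#' identity.
#'
#' @param table count table.
#' @param spec a [filter_spec()].
#' @return the filtered table.
#' @export
apply_filter <- function(table, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  switch(spec$mode,
    none = { validate_count_table(table); table },
    singleton = filter_singletons(table),
    relative_abundance = filter_relative_abundance(table, spec)
  )
}

#' Normalize samples to the minimum sum count
#'
#' Deterministic scaling normalization: each sample is multiplied by
#' (minimum column sum) / (its column sum), so that afterwards all column
#' sums equal the minimum. Relative abundances are preserved exactly.
#'
#' @param table count table with positive sample sums.
#' @return the scaled table (entries generally non-integer).
#' @export
normalize_min_sum <- function(table) {
  validate_count_table(table)
  cs <- colSums(table)
  if (any(cs == 0)) {
    stop("sample(s) with zero total count: ",
         paste(colnames(table)[cs == 0], collapse = ", "))
  }
  sweep(table, 2L, min(cs) / cs, "*")
}

#' Rarefy samples to a fixed depth
#'
#' Subsamples each sample without replacement to exactly `depth` reads
#' (random rarefaction, via [vegan::rrarefy()]). Requires integer counts and
#' `depth` no larger than any sample sum. The RNG state is saved and
#' restored, so rarefaction is reproducible given `seed` and leaves the
#' caller's random stream untouched.
#'
#' @param table count table with integer counts.
#' @param depth target depth (positive integer).
#' @param seed integer seed.
#' @return count table with all column sums equal to `depth`.
#' @export
rarefy <- function(table, depth, seed) {
  validate_count_table(table)
  assert_integer_counts(table, "rarefy")
  if (!is.numeric(depth) || length(depth) != 1L || depth < 1 ||
      abs(depth - round(depth)) > 1e-9) {
    stop("depth must be a positive integer")
  }
  cs <- colSums(table)
  low <- cs < depth
  if (any(low)) {
    stop("depth ", depth, " exceeds the sum of sample(s): ",
         paste(colnames(table)[low], collapse = ", "))
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  # rrarefy emits an advisory about count magnitudes; depths are validated
  # above, so silence it
  out <- t(suppressWarnings(vegan::rrarefy(t(round(table)), sample = depth)))
  dimnames(out) <- dimnames(table)
  count_table(out)
}
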