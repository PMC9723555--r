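# shared config validation / output plumbing for the experiment drivers
check_filters <- function(filters) {
  if (is.null(filters) || length(filters) == 0L) {
    stop("config error: at least one filter_spec is required")
  }
  if (!all(vapply(filters, inherits, TRUE, "filter_spec"))) {
    stop("config error: filters must be a list of filter_spec objects")
  }
  if (is.null(names(filters)) || any(!nzchar(names(filters)))) {
    names(filters) <- vapply(filters, function(f)
      if (f$mode == "relative_abundance") sprintf("relabund_%g", f$cutoff)
      else f$mode, "")
  }
  filters
}

write_outputs <- function(out_dir, tables, config) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(tables)) {
    utils::write.table(tables[[nm]], file.path(out_dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  # provenance: everything needed to re-run bit-identically
  prov <- config
  prov$filters <- lapply(config$filters, unclass)
  prov$design <- if (!is.null(config$design)) unclass(config$design)
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(out_dir)
}

#' Run a filtering-threshold benchmarking experiment
#'
#' Simulates replicate reference-community datasets (or uses supplied
#' ones), classifies observed taxa as matched or spurious, benchmarks every
#' filter in `config$filters`, and sweeps relative-abundance thresholds.
#' This is the experiment that motivates a consensus cutoff: with
#' contaminants individually below the cutoff, relative-abundance filtering
#' removes them entirely while singleton removal does not.
#'
#' @param config list with elements: `design` (a [synthetic_design()]) or
#'   `datasets` (list of `list(table, matches, reference)`); `filters`
#'   (named list of [filter_spec()]); optional `n_datasets` (default 3),
#'   `match_method` (`"label"` or `"identity"`, default `"label"`),
#'   `thresholds` (default 0 to 0.5% step 0.05%), `out_dir`.
#' @return list with `benchmarks` (per filter x dataset x sample
#'   data.frame), `summary` (per filter x dataset means +/- SD),
#'   `sweep` (a `sweep_curve`), `first_spurious` (per dataset x sample).
#' @export
run_threshold_experiment <- function(config) {
  filters <- check_filters(config$filters)
  datasets <- config$datasets
  if (is.null(datasets)) {
    if (is.null(config$design)) stop("config error: need design or datasets")
    n_datasets <- if (is.null(config$n_datasets)) 3L else config$n_datasets
    method <- if (is.null(config$match_method)) "label" else config$match_method
    datasets <- lapply(seq_len(n_datasets), function(i) {
      design <- config$design
      design$seed <- derive_seed(design$seed, 5000 + i)
      study <- simulate_counts(design)
      matches <- if (method == "identity") {
        classify_by_identity(study$sequences, study$reference)
      } else {
        classify_by_label(rownames(study$counts), study$truth)
      }
      list(table = study$counts, matches = matches,
           reference = study$reference, name = paste0("dataset", i))
    })
  }
  bench <- list(); summ <- list()
  for (fn in names(filters)) {
    for (d in datasets) {
      res <- benchmark_sample(d$table, d$matches, d$reference, filters[[fn]])
      res$filter <- fn
      res$dataset <- if (is.null(d$name)) "dataset1" else d$name
      bench[[paste(fn, res$dataset[1L])]] <- res
      s <- benchmark_summary(res)
      s$filter <- fn
      s$dataset <- res$dataset[1L]
      summ[[paste(fn, res$dataset[1L])]] <- s
    }
  }
  thresholds <- if (is.null(config$thresholds)) seq(0, 0.005, by = 0.0005)
                else config$thresholds
  sweep_res <- threshold_sweep(datasets, thresholds)
  first_sp <- do.call(rbind, lapply(datasets, function(d) {
    data.frame(
      dataset = if (is.null(d$name)) "dataset1" else d$name,
      sample_id = colnames(d$table),
      first_spurious_abundance = vapply(colnames(d$table), function(s)
        first_spurious_abundance(d$table, d$matches, s), 1),
      stringsAsFactors = FALSE, row.names = NULL)
  }))
  out <- list(benchmarks = do.call(rbind, unname(bench)),
              summary = do.call(rbind, unname(summ)),
              sweep = sweep_res, first_spurious = first_sp)
  write_outputs(config$out_dir,
                list(benchmarks = out$benchmarks, summary = out$summary,
                     sweep = as.data.frame(out$sweep),
                     first_spurious = out$first_spurious),
                config)
  out
}

#' Run a multi-run reproducibility experiment
#'
#' Simulates (or takes) a multi-run study in which the same replicate
#' groups are sequenced in every run with run-specific contaminant pools,
#' computes per-sample richness under each filter, and summarizes
#' reproducibility as within-run and across-run coefficients of variation
#' plus per-group IQRs. Across-run CVs require at least 2 runs; with a
#' single run only within-run CVs are reported.
#'
#' @param config list with elements: `design` (a [synthetic_design()]) or
#'   `study` (a `synthetic_study`); `filters` (named list of
#'   [filter_spec()]); optional `out_dir`.
#' @return list with `richness` (per filter x sample), `cv_within`,
#'   `cv_across` (NULL for single-run designs), `iqr` (per filter x group).
#' @export
run_reproducibility_experiment <- function(config) {
  filters <- check_filters(config$filters)
  study <- config$study
  if (is.null(study)) {
    if (is.null(config$design)) stop("config error: need design or study")
    study <- simulate_study(config$design)
  }
  meta <- study$metadata
  rich <- list(); cvw <- list(); cva <- list(); iqr <- list()
  multi_run <- length(unique(meta$run_id)) >= 2L
  for (fn in names(filters)) {
    filtered <- apply_filter(study$counts, filters[[fn]])
    rv <- vapply(meta$sample_id, function(s) richness(filtered, s), 1L)
    rich[[fn]] <- data.frame(filter = fn, sample_id = meta$sample_id,
                             richness = rv, stringsAsFactors = FALSE,
                             row.names = NULL)
    if (multi_run) {
      cv <- richness_cv(rv, meta$run_id, meta$replicate_group)
      cv$within_run$filter <- fn
      cv$across_run$filter <- fn
      cvw[[fn]] <- cv$within_run
      cva[[fn]] <- cv$across_run
    } else {
      cells <- split(rv, interaction(meta$run_id, meta$replicate_group,
                                     drop = TRUE))
      cvw[[fn]] <- do.call(rbind, lapply(names(cells), function(key) {
        v <- cells[[key]]
        if (length(v) < 2L || mean(v) == 0) return(NULL)
        data.frame(run = meta$run_id[1L], group = sub("^[^.]*\\.", "", key),
                   n = length(v), cv = 100 * stats::sd(v) / mean(v),
                   filter = fn, stringsAsFactors = FALSE)
      }))
    }
    groups_ok <- table(meta$replicate_group)
    if (all(groups_ok >= 2L)) {
      ir <- richness_iqr(rv, meta$replicate_group)
      ir$filter <- fn
      iqr[[fn]] <- ir
    }
  }
  out <- list(richness = do.call(rbind, unname(rich)),
              cv_within = do.call(rbind, unname(cvw)),
              cv_across = if (multi_run) do.call(rbind, unname(cva)) else NULL,
              iqr = do.call(rbind, unname(iqr)))
  tabs <- list(richness = out$richness, cv_within = out$cv_within)
  if (!is.null(out$cv_across)) tabs$cv_across <- out$cv_across
  if (!is.null(out$iqr)) tabs$iqr <- out$iqr
  write_outputs(config$out_dir, tabs, config)
  out
}

#' Run a beta-diversity filtering experiment
#'
#' Computes UniFrac distance matrices under every combination of filter and
#' distance specification, plus per-group median within-group distances
#' (the over-time / across-run variation summary). Unweighted UniFrac is
#' presence/absence-based and thus maximally sensitive to low-abundance
#' spurious taxa; generalized UniFrac down-weights them.
#'
#' @param config list with elements: `design` or `study` (as in
#'   [run_reproducibility_experiment()]); `filters` (named list of
#'   [filter_spec()]); `distances` (named list of [distance_spec()],
#'   default unweighted + generalized at alpha 0.5); optional `out_dir`.
#' @return list with `matrices` (nested list filter -> distance -> matrix)
#'   and `medians` (data.frame: filter, metric, group, median distance).
#' @export
run_betadiv_experiment <- function(config) {
  filters <- check_filters(config$filters)
  distances <- config$distances
  if (is.null(distances)) {
    distances <- list(unweighted = distance_spec("unweighted_unifrac"),
                      generalized = distance_spec("generalized_unifrac", 0.5))
  }
  study <- config$study
  if (is.null(study)) {
    if (is.null(config$design)) stop("config error: need design or study")
    study <- simulate_study(config$design)
  }
  if (is.null(study$tree)) stop("config error: study has no tree")
  meta <- study$metadata
  matrices <- list(); medians <- list()
  for (fn in names(filters)) {
    filtered <- apply_filter(study$counts, filters[[fn]])
    matrices[[fn]] <- list()
    for (dn in names(distances)) {
      D <- distance_matrix(study$tree, filtered, distances[[dn]])
      matrices[[fn]][[dn]] <- D
      med <- median_within_group(D, meta$replicate_group)
      if (!is.null(med)) {
        med$filter <- fn
        med$metric <- dn
        medians[[paste(fn, dn)]] <- med
      }
    }
  }
  out <- list(matrices = matrices, medians = do.call(rbind, unname(medians)))
  write_outputs(config$out_dir, list(medians = out$medians), config)
  out
}
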