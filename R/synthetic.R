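# Deterministic seed derivation: one master seed, disjoint offset ranges per
# component, so adding runs/samples never perturbs streams drawn earlier.
derive_seed <- function(seed, offset) {
  ((seed %% 2147483647) * 48271 + offset) %% 2147483647
}

# evaluate expr under set.seed(seed) without disturbing the caller's RNG
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

random_sequence <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# substitution-only mutation at k distinct positions
mutate_sequence <- function(seq, k) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  pos <- sample.int(length(chars), k)
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

hamming_identity <- function(a, b) {
  ac <- strsplit(a, "", fixed = TRUE)[[1L]]
  bc <- strsplit(b, "", fixed = TRUE)[[1L]]
  sum(ac == bc) / length(ac)
}

#' Describe a synthetic amplicon study design
#'
#' The generator emulates the statistical structure of contaminated 16S
#' amplicon sequencing of defined communities: a true community with an
#' even, log-distributed (10-fold dilution series) or exponentially
#' decreasing rank-abundance profile; run-specific contaminant pools whose
#' members carry about 1% cumulative relative abundance per sample and
#' individually stay at low abundance; low-abundance "satellite"
#' sequence-error variants of true taxa (1-3 substitutions); occasional
#' count-1 singleton artifacts; and per-sample sequencing depth varying
#' around 25,000 reads. Defaults put every contaminant strictly below the
#' 0.25% consensus cutoff; `contaminant_max_abundance = 0.0044` reproduces
#' the rare outlier regime in which a contaminant crosses it.
#'
#' @param n_true_taxa number of true community members (default 8, the size
#'   of common commercial DNA standards).
#' @param profile `"even"`, `"log"` (successive 10-fold dilutions) or
#'   `"exponential"` (geometric with ratio `r`).
#' @param r geometric ratio in `(0, 1]` for the exponential profile.
#' @param n_runs number of sequencing runs.
#' @param replicate_groups number of replicate groups (subjects/samples
#'   re-sequenced in every run).
#' @param replicates_per_group technical replicates per group per run.
#' @param depth_mean,depth_sd sequencing depth distribution (normal,
#'   truncated at 1000 reads, rounded).
#' @param contaminant_pool_size contaminants available to each run.
#' @param contaminant_sample_prob probability that a pool member enters a
#'   given sample.
#' @param contaminant_min_abundance,contaminant_max_abundance log-uniform
#'   range for individual contaminant relative abundances.
#' @param cumulative_spurious_target mean cumulative relative abundance of
#'   contaminants per sample (default 0.01); individual contaminants are
#'   rescaled toward it but never above `contaminant_max_abundance`.
#' @param pool_overlap_prob probability that a run's pool slot reuses a
#'   contaminant already seen in another run (low values make most
#'   contaminants run-exclusive).
#' @param satellite_rate expected satellites per true taxon (Poisson).
#' @param satellite_substitutions integer vector of substitution counts a
#'   satellite may carry (default 1:3).
#' @param satellite_min_abundance,satellite_max_abundance log-uniform range
#'   for satellite relative abundances (default keeps them below 0.1%).
#' @param satellite_sample_prob probability a satellite enters a sample.
#' @param singleton_rate expected singleton artifacts per sample (Poisson);
#'   each is a new taxon with count exactly 1.
#' @param subject_sd lognormal SD used to perturb the reference profile per
#'   replicate group when `replicate_groups > 1` (inter-individual
#'   variation); single-group designs use the reference profile as is.
#' @param seq_length representative sequence length in nt.
#' @param category sample category label written to metadata.
#' @param seed master seed; all randomness derives from it.
#' @return object of class `synthetic_design`.
#' @export
synthetic_design <- function(n_true_taxa = 8,
                             profile = c("even", "log", "exponential"),
                             r = 0.5,
                             n_runs = 1,
                             replicate_groups = 1,
                             replicates_per_group = 3,
                             depth_mean = 25000, depth_sd = 7000,
                             contaminant_pool_size = 25,
                             contaminant_sample_prob = 0.8,
                             contaminant_min_abundance = 1e-4,
                             contaminant_max_abundance = 1.5e-3,
                             cumulative_spurious_target = 0.01,
                             pool_overlap_prob = 0.1,
                             satellite_rate = 0.5,
                             satellite_substitutions = 1:3,
                             satellite_min_abundance = 5e-5,
                             satellite_max_abundance = 1e-3,
                             satellite_sample_prob = 0.5,
                             singleton_rate = 1,
                             subject_sd = 0.75,
                             seq_length = 250,
                             category = "human",
                             seed = 1) {
  profile <- match.arg(profile)
  if (n_true_taxa < 1) stop("n_true_taxa must be >= 1")
  if (r <= 0 || r > 1) stop("geometric ratio r must lie in (0, 1]")
  stopifnot(n_runs >= 1, replicate_groups >= 1, replicates_per_group >= 1,
            depth_mean >= 1000, depth_sd >= 0, contaminant_pool_size >= 0,
            seq_length >= 20)
  for (f in c("contaminant_sample_prob", "contaminant_min_abundance",
              "contaminant_max_abundance", "cumulative_spurious_target",
              "pool_overlap_prob", "satellite_min_abundance",
              "satellite_max_abundance", "satellite_sample_prob")) {
    v <- get(f)
    if (!is.numeric(v) || v < 0 || v > 1) stop(f, " must lie in [0, 1]")
  }
  if (contaminant_min_abundance > contaminant_max_abundance) {
    stop("contaminant_min_abundance exceeds contaminant_max_abundance")
  }
  if (satellite_rate < 0 || singleton_rate < 0 || subject_sd < 0) {
    stop("rates and subject_sd must be non-negative")
  }
  structure(as.list(environment()), class = "synthetic_design")
}

#' @export
print.synthetic_design <- function(x, ...) {
  cat("<synthetic_design>", x$n_true_taxa, "true taxa (", x$profile,
      "profile ),", x$n_runs, "run(s) x", x$replicate_groups, "group(s) x",
      x$replicates_per_group, "replicate(s), seed", x$seed, "\n")
  invisible(x)
}

profile_proportions <- function(design) {
  n <- design$n_true_taxa
  p <- switch(design$profile,
    even = rep(1, n),
    log = 10^-(seq_len(n) - 1),
    exponential = design$r^(seq_len(n) - 1)
  )
  p / sum(p)
}

#' Generate a synthetic reference community
#'
#' Builds the expected profile from the design (`even`: 1/n each; `log`:
#' successive 10-fold dilutions, renormalized; `exponential`: proportions
#' proportional to r^k) and draws mutually divergent reference sequences
#' (pairwise identity below 90%, enforced by rejection sampling).
#'
#' @param design a [synthetic_design()].
#' @return a [reference_community()] with members `m01`, `m02`, ...
#' @export
make_reference <- function(design) {
  stopifnot(inherits(design, "synthetic_design"))
  p <- profile_proportions(design)
  ids <- sprintf("m%02d", seq_len(design$n_true_taxa))
  seqs <- with_seed(derive_seed(design$seed, 1), {
    out <- character(0)
    while (length(out) < design$n_true_taxa) {
      cand <- random_sequence(design$seq_length)
      if (all(vapply(out, function(s) hamming_identity(cand, s), 1) < 0.90)) {
        out <- c(out, cand)
      }
    }
    out
  })
  names(seqs) <- ids
  reference_community(seqs, stats::setNames(p, ids),
                      distribution_label = switch(design$profile,
                        even = "even", log = "log", exponential = "custom"))
}

# contaminant library bookkeeping: each run pool either reuses an existing
# library entry (prob pool_overlap_prob) or founds a new contaminant
build_run_pools <- function(design) {
  library_seqs <- character(0)
  first_run <- character(0)
  pools <- vector("list", design$n_runs)
  for (r in seq_len(design$n_runs)) {
    res <- with_seed(derive_seed(design$seed, 200 + r), {
      pool <- character(0)
      new_seqs <- character(0)
      new_first <- character(0)
      for (slot in seq_len(design$contaminant_pool_size)) {
        known <- c(names(library_seqs), names(new_seqs))
        avail <- setdiff(known, pool)
        reuse <- length(avail) > 0 && stats::runif(1) < design$pool_overlap_prob
        if (reuse) {
          pool <- c(pool, if (length(avail) == 1L) avail else sample(avail, 1L))
        } else {
          id <- sprintf("contam%04d", length(known) + 1L)
          new_seqs[[id]] <- random_sequence(design$seq_length)
          new_first[[id]] <- paste0("run", r)
          pool <- c(pool, id)
        }
      }
      list(pool = pool, new_seqs = new_seqs, new_first = new_first)
    })
    library_seqs <- c(library_seqs, res$new_seqs)
    first_run <- c(first_run, res$new_first)
    pools[[r]] <- res$pool
  }
  list(pools = pools, seqs = library_seqs, first_run = first_run)
}

build_satellites <- function(design, reference) {
  with_seed(derive_seed(design$seed, 400), {
    ids <- character(0); seqs <- character(0); parents <- character(0)
    for (m in names(reference$members)) {
      k <- stats::rpois(1, design$satellite_rate)
      if (k > 0) for (i in seq_len(k)) {
        id <- sprintf("sat_%s_%d", m, i)
        nsub <- sample(design$satellite_substitutions, 1L)
        ids <- c(ids, id)
        seqs[[id]] <- mutate_sequence(reference$members[[m]], nsub)
        parents[[id]] <- m
      }
    }
    list(ids = ids, seqs = seqs, parents = parents)
  })
}

# log-uniform draw
rlogunif <- function(n, lo, hi) {
  if (lo <= 0 || hi < lo) stop("invalid log-uniform range")
  exp(stats::runif(n, log(lo), log(hi)))
}

# one sample's counts; returns list(counts over `taxa`, singleton additions)
simulate_one_sample <- function(design, group_profile, pool, satellites,
                                sample_seed, singleton_prefix) {
  with_seed(sample_seed, {
    depth <- max(1000, round(stats::rnorm(1, design$depth_mean, design$depth_sd)))
    # contaminants present in this sample
    inc <- pool[stats::runif(length(pool)) < design$contaminant_sample_prob]
    ca <- numeric(0)
    if (length(inc) && design$cumulative_spurious_target > 0) {
      a <- rlogunif(length(inc), design$contaminant_min_abundance,
                    design$contaminant_max_abundance)
      s <- max(0, stats::rnorm(1, design$cumulative_spurious_target,
                               0.15 * design$cumulative_spurious_target))
      ca <- pmin(a * s / sum(a), design$contaminant_max_abundance)
      names(ca) <- inc
    }
    sa <- numeric(0)
    if (length(satellites$ids)) {
      inc_s <- satellites$ids[stats::runif(length(satellites$ids)) <
                                design$satellite_sample_prob]
      if (length(inc_s)) {
        sa <- rlogunif(length(inc_s), design$satellite_min_abundance,
                       design$satellite_max_abundance)
        names(sa) <- inc_s
      }
    }
    spurious_mass <- sum(ca) + sum(sa)
    pvec <- c(group_profile * (1 - spurious_mass), ca, sa)
    counts <- stats::rmultinom(1, depth, pvec)[, 1L]
    names(counts) <- names(pvec)
    n_single <- stats::rpois(1, design$singleton_rate)
    singles <- if (n_single > 0) {
      ids <- sprintf("%s_sg%d", singleton_prefix, seq_len(n_single))
      stats::setNames(vapply(ids, function(i)
        random_sequence(design$seq_length), ""), ids)
    } else NULL
    list(counts = counts, singles = singles)
  })
}

#' Simulate a complete multi-run amplicon study with ground truth
#'
#' Generates a reference community, run-specific contaminant pools, study
#' satellites, per-sample count vectors (multinomial at a truncated-normal
#' depth), singleton artifacts, sample metadata, representative sequences
#' for every taxon, a random bifurcating tree over all taxa (exponential
#' branch lengths) for UniFrac testing, and a ground-truth table labeling
#' every taxon as `true`, `contaminant`, `satellite` or
#' `singleton_artifact`. The same replicate groups are re-simulated in
#' every run, so run-to-run differences arise from depth noise and the
#' run's contaminant pool — the situation in which abundance filtering
#' should restore reproducibility. All output is a deterministic function
#' of `design$seed`.
#'
#' @param design a [synthetic_design()].
#' @return list of class `synthetic_study` with elements `counts` (merged
#'   taxa x samples count table), `metadata` (data.frame: `sample_id`,
#'   `run_id`, `subject_id`, `replicate_group`, `category`, `timepoint`),
#'   `truth` (data.frame: `taxon_id`, `label`, `source_run`,
#'   `parent_taxon`), `reference`, `sequences` (named vector covering all
#'   taxa), `tree` ([ape::phylo]) and `design`.
#' @export
simulate_study <- function(design) {
  stopifnot(inherits(design, "synthetic_design"))
  reference <- make_reference(design)
  true_ids <- names(reference$members)
  contam <- build_run_pools(design)
  satellites <- build_satellites(design, reference)

  group_profiles <- lapply(seq_len(design$replicate_groups), function(g) {
    base <- reference$expected_profile
    if (design$replicate_groups > 1 && design$subject_sd > 0) {
      pert <- with_seed(derive_seed(design$seed, 100 + g),
                        base * stats::rlnorm(length(base), 0, design$subject_sd))
      pert / sum(pert)
    } else base
  })

  cols <- list(); meta <- list(); single_seqs <- character(0)
  single_run <- character(0)
  for (r in seq_len(design$n_runs)) {
    for (g in seq_len(design$replicate_groups)) {
      for (k in seq_len(design$replicates_per_group)) {
        sid <- sprintf("grp%02d_run%02d_rep%02d", g, r, k)
        res <- simulate_one_sample(
          design, group_profiles[[g]], contam$pools[[r]], satellites,
          derive_seed(design$seed, 1e6 + r * 1e4 + g * 1e2 + k), sid)
        counts <- res$counts
        if (!is.null(res$singles)) {
          counts <- c(counts, stats::setNames(rep(1, length(res$singles)),
                                              names(res$singles)))
          single_seqs <- c(single_seqs, res$singles)
          single_run <- c(single_run,
                          stats::setNames(rep(paste0("run", r),
                                              length(res$singles)),
                                          names(res$singles)))
        }
        cols[[sid]] <- counts
        meta[[sid]] <- data.frame(
          sample_id = sid, run_id = paste0("run", r),
          subject_id = sprintf("grp%02d", g),
          replicate_group = sprintf("grp%02d", g),
          category = design$category, timepoint = as.character(r),
          stringsAsFactors = FALSE)
      }
    }
  }
  all_taxa <- unique(c(true_ids, names(contam$seqs), satellites$ids,
                       names(single_seqs)))
  m <- matrix(0, nrow = length(all_taxa), ncol = length(cols),
              dimnames = list(all_taxa, names(cols)))
  for (sid in names(cols)) m[names(cols[[sid]]), sid] <- cols[[sid]]
  # artifact taxa that were never realized with a nonzero count do not exist
  # as observed taxa; drop them (true members always stay)
  keep <- rowSums(m) > 0 | all_taxa %in% true_ids
  m <- m[keep, , drop = FALSE]
  all_taxa <- rownames(m)

  label <- ifelse(all_taxa %in% true_ids, "true",
           ifelse(all_taxa %in% names(contam$seqs), "contaminant",
           ifelse(all_taxa %in% satellites$ids, "satellite",
                  "singleton_artifact")))
  source_run <- rep(NA_character_, length(all_taxa))
  source_run[label == "contaminant"] <-
    contam$first_run[all_taxa[label == "contaminant"]]
  source_run[label == "singleton_artifact"] <-
    single_run[all_taxa[label == "singleton_artifact"]]
  parent <- rep(NA_character_, length(all_taxa))
  parent[label == "satellite"] <- satellites$parents[all_taxa[label == "satellite"]]
  truth <- data.frame(taxon_id = all_taxa, label = label,
                      source_run = source_run, parent_taxon = parent,
                      stringsAsFactors = FALSE, row.names = NULL)

  sequences <- c(reference$members, contam$seqs, satellites$seqs, single_seqs)
  sequences <- sequences[all_taxa]

  tree <- with_seed(derive_seed(design$seed, 300), {
    if (length(all_taxa) >= 2) {
      tr <- ape::rtree(length(all_taxa), br = stats::rexp)
      tr$tip.label <- sample(all_taxa)
      tr
    } else NULL
  })

  structure(list(counts = count_table(m),
                 metadata = do.call(rbind, unname(meta)),
                 truth = truth, reference = reference,
                 sequences = sequences, tree = tree, design = design),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("<synthetic_study>", nrow(x$counts), "taxa x", ncol(x$counts),
      "samples;", sum(x$truth$label == "true"), "true,",
      sum(x$truth$label != "true"), "spurious taxa\n")
  invisible(x)
}

#' Simulate a single-run set of reference-community replicates
#'
#' Convenience wrapper around [simulate_study()] for the mock-community
#' benchmarking case: one run, one replicate group.
#'
#' @param design a [synthetic_design()]; `n_runs` and `replicate_groups`
#'   are forced to 1.
#' @param n_samples number of replicate samples.
#' @return a `synthetic_study` list (see [simulate_study()]).
#' @export
simulate_counts <- function(design, n_samples = design$replicates_per_group) {
  stopifnot(inherits(design, "synthetic_design"))
  design$n_runs <- 1
  design$replicate_groups <- 1
  design$replicates_per_group <- n_samples
  simulate_study(design)
}

#' Simulate one community sequenced at increasing depths
#'
#' Emulates re-sequencing the same library at increasing cluster densities
#' by drawing reads incrementally: the sample at depth d[k+1] contains all
#' reads of the sample at depth d[k] plus new multinomial draws. Richness
#' therefore grows monotonically with depth by construction, as it does
#' when one physical library is sequenced deeper.
#'
#' @param proportions named vector of true taxon proportions (summing to 1).
#' @param depths increasing vector of sequencing depths.
#' @param seed integer seed.
#' @return count table with one column per depth (named `d<depth>`).
#' @export
simulate_depth_series <- function(proportions, depths, seed) {
  if (abs(sum(proportions) - 1) > 1e-9) stop("proportions must sum to 1")
  if (is.unsorted(depths, strictly = TRUE)) stop("depths must be increasing")
  with_seed(seed, {
    m <- matrix(0, nrow = length(proportions), ncol = length(depths),
                dimnames = list(names(proportions), paste0("d", depths)))
    acc <- numeric(length(proportions))
    prev <- 0
    for (k in seq_along(depths)) {
      acc <- acc + stats::rmultinom(1, depths[k] - prev, proportions)[, 1L]
      prev <- depths[k]
      m[, k] <- acc
    }
    count_table(m)
  })
}
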