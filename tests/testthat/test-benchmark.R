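# a small hand-built benchmark scenario: 8-member reference, mixed matches
hand_benchmark <- function() {
  taxa <- c(sprintf("m%02d", 1:8), "sp1", "sp2")
  counts <- matrix(c(4000, 2000, 1000, 800, 700, 600, 500, 0, 30, 8), 10, 1,
                   dimnames = list(taxa, "s1"))
  matches <- classify_by_label(
    taxa, data.frame(taxon_id = taxa,
                     label = c(rep("true", 8), "contaminant", "contaminant")))
  list(table = count_table(counts), matches = matches,
       reference = sprintf("m%02d", 1:8))
}

test_that("first spurious abundance is the max over the spurious set", {
  h <- hand_benchmark()
  # spurious proportions: 30/9638 and 8/9638 -> max = 30/9638
  expect_equal(first_spurious_abundance(h$table, h$matches, "s1"),
               100 * 30 / 9638)
  expect_error(first_spurious_abundance(h$table, h$matches, "nope"), "unknown")

  # no spurious taxa: NA
  clean <- h$table[1:7, , drop = FALSE]
  expect_true(is.na(first_spurious_abundance(clean, h$matches, "s1")))

  # max over the spurious set, positions irrelevant:
  # abundances 50, 30, 19, 0.8, 0.2 % with taxa 4 and 5 spurious -> 0.8%
  m <- count_table(matrix(c(500, 300, 190, 8, 2), 5, 1,
                          dimnames = list(paste0("t", 1:5), "s")))
  mt <- classify_by_label(paste0("t", 1:5),
    data.frame(taxon_id = paste0("t", 1:5),
               label = c("true", "true", "true", "contaminant", "contaminant")))
  expect_equal(first_spurious_abundance(m, mt, "s"), 0.8)
})

test_that("benchmark_sample scores spurious and positive-hit fractions", {
  h <- hand_benchmark()
  # no filter: 9 taxa nonzero (m08 has 0 count), 2 spurious, 7/8 members hit
  b <- benchmark_sample(h$table, h$matches, h$reference, filter_spec("none"))
  expect_equal(b$n_taxa_total, 9)
  expect_equal(b$spurious_fraction, 100 * 2 / 9)
  expect_equal(b$positive_hit_fraction, 100 * 7 / 8)  # 87.5
  expect_equal(b$cumulative_spurious_abundance, 100 * 38 / 9638)

  # all matched, all members detected: 0% spurious, 100% hits
  clean <- h$table[1:8, , drop = FALSE]
  clean["m08", 1] <- 100
  b2 <- benchmark_sample(clean, h$matches, h$reference, filter_spec("none"))
  expect_equal(b2$spurious_fraction, 0)
  expect_equal(b2$positive_hit_fraction, 100)

  # 20 retained taxa of which 9 spurious -> 45%
  taxa <- sprintf("x%02d", 1:20)
  m <- count_table(matrix(10, 20, 1, dimnames = list(taxa, "s")))
  mt <- classify_by_label(taxa, data.frame(
    taxon_id = taxa, label = c(rep("true", 11), rep("contaminant", 9))))
  b3 <- benchmark_sample(m, mt, taxa[1:11], filter_spec("none"))
  expect_equal(b3$spurious_fraction, 45)

  expect_error(benchmark_sample(h$table[1:9, , drop = FALSE],
                                h$matches[1:3, ], h$reference,
                                filter_spec("none")),
               "missing from match table")
})

test_that("positive hits count distinct members, not matched taxa", {
  # two observed taxa matched to the same member cannot exceed 100%
  taxa <- c("a", "b")
  m <- count_table(matrix(c(60, 40), 2, 1, dimnames = list(taxa, "s")))
  mt <- structure(data.frame(taxon_id = taxa, status = "matched",
                             best_reference = c("m01", "m01"),
                             identity = 1, coverage = 1, hamming = NA_integer_),
                  class = c("match_table", "data.frame"))
  b <- benchmark_sample(m, mt, c("m01", "m02"), filter_spec("none"))
  expect_equal(b$n_positive_hits, 1)
  expect_equal(b$positive_hit_fraction, 50)
  expect_equal(b$n_matched_taxa, 2)
})

test_that("threshold sweep has the expected grid, SD and monotonicity", {
  expect_length(seq(0, 0.005, by = 0.0005), 11L)  # default grid size

  h <- hand_benchmark()
  sw1 <- threshold_sweep(list(h))
  expect_equal(nrow(sw1), 11L)
  expect_true(all(sw1$sd_spurious_fraction == 0))  # single dataset: SD 0
  expect_true(all(diff(sw1$mean_spurious_fraction) <= 0))
  expect_true(all(diff(sw1$mean_positive_hit_fraction) <= 0))

  # spurious taxa all below 0.2%: none left at thresholds >= 0.2%
  d <- synthetic_design(seed = 31)
  st <- simulate_counts(d, n_samples = 3)
  ds <- list(table = st$counts,
             matches = classify_by_label(rownames(st$counts), st$truth),
             reference = st$reference)
  sw2 <- threshold_sweep(list(ds, h))
  expect_true(all(sw2$sd_spurious_fraction >= 0))
  high <- sw2$threshold >= 0.002
  per_ds <- threshold_sweep(list(ds))
  expect_true(all(per_ds$mean_spurious_fraction[high] == 0))

  expect_error(threshold_sweep(list(h), numeric(0)), "empty")
  expect_error(threshold_sweep(list(h), c(0.002, 0.001)), "increasing")
  expect_error(threshold_sweep(list(), ), "dataset")
})

test_that("benchmark with mode none equals relative-abundance at cutoff 0", {
  d <- synthetic_design(seed = 32)
  st <- simulate_counts(d, n_samples = 2)
  mt <- classify_by_label(rownames(st$counts), st$truth)
  b_none <- benchmark_sample(st$counts, mt, st$reference, filter_spec("none"))
  b_zero <- benchmark_sample(st$counts, mt, st$reference,
                             filter_spec("relative_abundance", 0))
  expect_equal(b_none, b_zero)
})

test_that("label-matched benchmark equals generator ground truth exactly", {
  d <- synthetic_design(seed = 33, singleton_rate = 2)
  st <- simulate_counts(d, n_samples = 4)
  mt <- classify_by_label(rownames(st$counts), st$truth)
  b <- benchmark_sample(st$counts, mt, st$reference, filter_spec("none"))
  for (j in seq_len(ncol(st$counts))) {
    present <- rownames(st$counts)[st$counts[, j] > 0]
    truth_sp <- sum(st$truth$label[match(present, st$truth$taxon_id)] != "true")
    expect_equal(b$spurious_fraction[j], 100 * truth_sp / length(present))
  }
})

test_that("benchmark summary reports means and n-1 SDs over replicates", {
  d <- synthetic_design(seed = 34)
  st <- simulate_counts(d, n_samples = 3)
  mt <- classify_by_label(rownames(st$counts), st$truth)
  b <- benchmark_sample(st$counts, mt, st$reference, filter_spec("singleton"))
  s <- benchmark_summary(b)
  expect_equal(s$spurious_fraction, mean(b$spurious_fraction))
  expect_equal(s$spurious_fraction_sd, sd(b$spurious_fraction))
  expect_equal(s$n_samples, 3L)
})
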