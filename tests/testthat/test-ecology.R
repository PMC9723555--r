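test_that("exclusivity z-test matches the pooled two-proportion formula", {
  # 40/100 vs 0/100: z = 0.4 / sqrt(0.2*0.8*(2/100)) ~ 7.071
  r <- exclusivity_test(c(human = 40, soil = 0), c(human = 100, soil = 100))
  expect_equal(r$z, 0.4 / sqrt(0.2 * 0.8 * (1 / 100 + 1 / 100)))
  expect_equal(r$z, 7.0710678, tolerance = 1e-6)
  expect_lt(r$p, 1e-10)
  expect_identical(r$top_category, "human")

  # identical proportions: z = 0, p = 1
  r2 <- exclusivity_test(c(a = 5, b = 5), c(a = 10, b = 10))
  expect_equal(r2$z, 0)
  expect_equal(r2$p, 1)

  # all-zero prevalences are not exclusive and do not blow up
  r3 <- exclusivity_test(c(a = 0, b = 0), c(a = 30, b = 30))
  expect_equal(r3$z, 0)
  expect_equal(r3$p, 1)

  # swapping the two categories flips z's sign via the top/runner-up roles;
  # p is unchanged (two-sided)
  r4 <- exclusivity_test(c(soil = 0, human = 40), c(soil = 100, human = 100))
  expect_equal(abs(r4$z), abs(r$z))
  expect_equal(r4$p, r$p)
  expect_identical(r4$top_category, "human")

  # fewer than 2 usable categories errors
  expect_error(exclusivity_test(c(a = 3, b = 0), c(a = 10, b = 0)), "fewer than 2")
})

test_that("z-test agrees with the chi-squared two-proportion test", {
  for (case in list(c(12, 40, 3, 35), c(20, 50, 18, 55), c(1, 30, 0, 25))) {
    r <- exclusivity_test(c(x = case[1], y = case[3]),
                          c(x = case[2], y = case[4]))
    pt <- suppressWarnings(
      prop.test(c(case[1], case[3]), c(case[2], case[4]), correct = FALSE))
    expect_equal(r$z^2, unname(pt$statistic), tolerance = 1e-10)
    expect_equal(r$p, pt$p.value, tolerance = 1e-10)
  }
})

test_that("prevalence by category counts positives above the threshold", {
  # 6 samples in 2 categories; occurrence map of 2 spurious taxa
  occ <- matrix(0, 2, 6, dimnames = list(c("spA", "spB"), paste0("s", 1:6)))
  occ["spA", c("s1", "s2")] <- 0.01       # above threshold in 2 of 4 human
  occ["spB", "s5"] <- 0.001               # nonzero but below threshold
  occ["spB", "s6"] <- 0.01
  meta <- data.frame(sample_id = paste0("s", 1:6),
                     category = rep(c("human", "soil"), c(4, 2)))
  res <- prevalence_by_category(occ, meta, drop_no_hit = FALSE)
  pv <- res$prevalence
  get <- function(t, cc) pv$prevalence[pv$taxon_id == t & pv$category == cc]
  expect_equal(get("spA", "human"), 50)
  expect_equal(get("spA", "soil"), 0)
  expect_equal(get("spB", "soil"), 50)
  expect_identical(res$exclusivity$top_category[
    res$exclusivity$taxon_id == "spA"], "human")

  # taxon above threshold in all samples of its top category
  occ2 <- occ
  occ2["spA", 1:4] <- 0.02
  res2 <- prevalence_by_category(occ2, meta, drop_no_hit = FALSE)
  expect_equal(res2$prevalence$prevalence[
    res2$prevalence$taxon_id == "spA" &
      res2$prevalence$category == "human"], 100)

  # prevalence is invariant to sample order
  perm <- sample(colnames(occ))
  res3 <- prevalence_by_category(occ[, perm], meta, drop_no_hit = FALSE)
  pv3 <- res3$prevalence[order(res3$prevalence$taxon_id, res3$prevalence$category), ]
  pv0 <- pv[order(pv$taxon_id, pv$category), ]
  expect_equal(pv3$prevalence, pv0$prevalence)
})

test_that("no-hit samples are dropped from denominators by default", {
  occ <- matrix(0, 1, 4, dimnames = list("spA", paste0("s", 1:4)))
  occ["spA", c("s1", "s2")] <- 0.01
  meta <- data.frame(sample_id = paste0("s", 1:4),
                     category = rep("human", 4))
  kept <- prevalence_by_category(occ, meta, drop_no_hit = TRUE)
  expect_equal(kept$prevalence$n_samples, 2)
  expect_equal(kept$prevalence$prevalence, 100)
  all4 <- prevalence_by_category(occ, meta, drop_no_hit = FALSE)
  expect_equal(all4$prevalence$prevalence, 50)
  expect_error(prevalence_by_category(occ, meta[1:2, ]), "missing from metadata")
})

test_that("BH adjustment is applied across clusters", {
  set.seed(91)
  n_taxa <- 20
  occ <- matrix(0, n_taxa, 60,
                dimnames = list(paste0("t", 1:n_taxa), paste0("s", 1:60)))
  cat <- rep(c("human", "soil"), each = 30)
  # taxon 1 strongly human-exclusive; the rest weakly random
  occ[1, cat == "human"] <- 0.01
  for (r in 2:n_taxa) occ[r, sample(60, 8)] <- 0.01
  meta <- data.frame(sample_id = colnames(occ), category = cat)
  res <- prevalence_by_category(occ, meta, drop_no_hit = FALSE)
  ex <- res$exclusivity
  expect_equal(ex$p_adj, p.adjust(ex$p, method = "BH"))
  expect_true(ex$exclusive[ex$taxon_id == "t1"])
})

test_that("run redundancy counts distinct runs per cluster", {
  asg <- data.frame(cluster_id = c("c1", "c1", "c2", "c3", "c3", "c3"),
                    run_id = c("r1", "r1", "r2", "r1", "r2", "r3"))
  rr <- run_redundancy(asg)
  expect_equal(rr$n_runs[rr$cluster_id == "c1"], 1L)
  expect_equal(rr$n_runs[rr$cluster_id == "c2"], 1L)
  expect_equal(rr$n_runs[rr$cluster_id == "c3"], 3L)
  expect_equal(nrow(rr), length(unique(asg$cluster_id)))  # partition
  expect_error(run_redundancy(asg[0, ]), "empty")
})

test_that("identical contaminants across runs collapse into one cluster", {
  set.seed(92)
  shared <- rand_dna(150)
  runs <- list(
    run1 = c(a1 = shared, a2 = rand_dna(150)),
    run2 = c(b1 = shared, b2 = rand_dna(150)),
    run3 = c(c1 = shared),
    run4 = c(d1 = rand_dna(150)),
    run5 = c(e1 = rand_dna(150))
  )
  rr <- run_redundancy_from_sequences(runs)
  # the shared contaminant occurs in 3 of 5 runs; all others in one
  expect_equal(sort(rr$n_runs, decreasing = TRUE)[1], 3L)
  expect_equal(sum(rr$n_runs == 1L), nrow(rr) - 1L)
})

test_that("category-exclusive synthetic contaminants are detected", {
  # a contaminant present above threshold in most samples of one category
  # and never elsewhere should be flagged exclusive at n=50 per category
  set.seed(93)
  hits <- 0L
  n_rep <- 50L
  for (i in seq_len(n_rep)) {
    occ <- matrix(0, 3, 100,
                  dimnames = list(paste0("t", 1:3), paste0("s", 1:100)))
    cat <- rep(c("human", "soil"), each = 50)
    pos <- sample(which(cat == "human"), 30)
    occ[1, pos] <- 0.01
    occ[2, sample(100, 20)] <- 0.01   # background taxa in both categories
    occ[3, sample(100, 20)] <- 0.01
    meta <- data.frame(sample_id = colnames(occ), category = cat)
    res <- prevalence_by_category(occ, meta, drop_no_hit = FALSE)
    if (res$exclusivity$exclusive[res$exclusivity$taxon_id == "t1"] &&
        res$exclusivity$top_category[res$exclusivity$taxon_id == "t1"] == "human") {
      hits <- hits + 1L
    }
  }
  expect_gte(hits / n_rep, 0.95)
})
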