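two_leaf <- function() read_newick(text = "(A:1,B:1);")

table_from_presence <- function(tips, pres_a, pres_b) {
  m <- matrix(0, length(tips), 2, dimnames = list(tips, c("sA", "sB")))
  m[pres_a, "sA"] <- 10
  m[pres_b, "sB"] <- 10
  count_table(m)
}

test_that("unweighted UniFrac matches hand-computed small cases", {
  tr <- two_leaf()
  expect_equal(unweighted_unifrac(tr, table_from_presence(c("A", "B"), "A", "A"),
                                  "sA", "sB"), 0)
  expect_equal(unweighted_unifrac(tr, table_from_presence(c("A", "B"), "A", "B"),
                                  "sA", "sB"), 1)
  expect_equal(unweighted_unifrac(tr, table_from_presence(c("A", "B"),
                                                          c("A", "B"), "A"),
                                  "sA", "sB"), 0.5)

  # errors: taxon not in tree; both samples empty
  bad <- count_table(matrix(c(1, 1), 2, 2,
                            dimnames = list(c("A", "Z"), c("sA", "sB"))))
  expect_error(unweighted_unifrac(tr, bad, "sA", "sB"), "absent from tree")
  empty <- count_table(matrix(c(1, 0, 0, 0, 0, 0), 2, 3,
                              dimnames = list(c("A", "B"), c("s0", "sA", "sB"))))
  expect_error(unweighted_unifrac(tr, empty, "sA", "sB"), "empty")
})

test_that("generalized UniFrac matches hand-computed cases at every alpha", {
  tr <- two_leaf()
  tab <- table_from_presence(c("A", "B"), "A", "B")
  for (a in c(0, 0.25, 0.5, 1)) {
    expect_equal(generalized_unifrac(tr, tab, "sA", "sB", alpha = a), 1)
  }
  same <- count_table(matrix(c(6, 4, 3, 2), 2, 2,
                             dimnames = list(c("A", "B"), c("sA", "sB"))))
  expect_equal(generalized_unifrac(tr, same, "sA", "sB"), 0)
  expect_error(generalized_unifrac(tr, same, "sA", "sB", alpha = 2), "alpha")
})

test_that("unweighted UniFrac equals branch-enumeration oracle exhaustively", {
  # every rooted binary shape with 2..6 leaves, random branch lengths,
  # every pair of nonempty presence sets
  shapes <- tree_shapes()
  for (i in seq_along(shapes)) {
    tr <- shape_tree(shapes[i], seed = 500 + i)
    tips <- sort(tr$tip.label)
    n <- length(tips)
    subsets <- lapply(seq_len(2^n - 1), function(mask)
      tips[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0])
    # implementation side, all pairs at once via the shared-prep matrix path
    m <- vapply(subsets, function(ss) as.numeric(tips %in% ss) * 10,
                numeric(n))
    dimnames(m) <- list(tips, paste0("p", seq_along(subsets)))
    D <- distance_matrix(tr, count_table(m), distance_spec("unweighted_unifrac"))
    branch_tips <- oracle_branch_tips(tr)
    O <- matrix(0, length(subsets), length(subsets))
    for (a in seq_along(subsets)) {
      for (b in seq_along(subsets)) {
        O[a, b] <- oracle_unweighted(tr, subsets[[a]], subsets[[b]], branch_tips)
      }
    }
    expect_equal(unname(D), O, tolerance = 1e-12)
    # spot-check the scalar entry point against the same oracle
    expect_equal(unweighted_unifrac(tr, count_table(m), "p1", "p3"),
                 oracle_unweighted(tr, subsets[[1]], subsets[[3]]))
  }
})

test_that("generalized UniFrac at alpha=1 equals weighted-normalized oracle", {
  shapes <- tree_shapes()
  six_leaf <- shapes[nchar(shapes) == max(nchar(shapes)) |
                       grepl("F", shapes, fixed = TRUE)]
  set.seed(77)
  for (rep in 1:100) {
    tr <- shape_tree(sample(six_leaf, 1), seed = 600 + rep)
    tips <- tr$tip.label
    m <- matrix(rpois(2 * length(tips), 20) + 1, length(tips), 2,
                dimnames = list(tips, c("sA", "sB")))
    tab <- count_table(m)
    pa <- m[, 1] / sum(m[, 1]); pb <- m[, 2] / sum(m[, 2])
    expect_equal(generalized_unifrac(tr, tab, "sA", "sB", alpha = 1),
                 oracle_weighted_normalized(tr, pa, pb), tolerance = 1e-10)
  }
})

test_that("UniFrac distances are symmetric, bounded and zero on self", {
  d <- synthetic_design(n_true_taxa = 15, profile = "exponential", r = 0.7,
                        seed = 78)
  st <- simulate_counts(d, n_samples = 4)
  for (spec in list(distance_spec("unweighted_unifrac"),
                    distance_spec("generalized_unifrac", 0.5))) {
    D <- distance_matrix(st$tree, st$counts, spec)
    expect_true(isSymmetric(D))
    expect_equal(unname(diag(D)), rep(0, ncol(D)))
    expect_true(all(D >= 0 & D <= 1 + 1e-12))
  }
  # duplicated sample has distance 0 to its copy
  dup <- cbind(st$counts, st$counts[, 1, drop = FALSE])
  colnames(dup)[ncol(dup)] <- "copy"
  D2 <- distance_matrix(st$tree, count_table(dup), distance_spec())
  expect_equal(D2[colnames(st$counts)[1], "copy"], 0)
})

test_that("unweighted UniFrac depends only on presence/absence", {
  tr <- shape_tree(tree_shapes()[12], seed = 79)
  tips <- tr$tip.label
  m <- matrix(c(5, 0, 2, 0, 9, 1, 0, 3, 3, 0, 4, 0), length(tips), 2,
              dimnames = list(tips, c("sA", "sB")))
  base <- unweighted_unifrac(tr, count_table(m), "sA", "sB")
  m2 <- m * 13
  m2[m2 > 0] <- m2[m2 > 0] + 7   # perturb abundances, preserve support
  expect_equal(unweighted_unifrac(tr, count_table(m2), "sA", "sB"), base)
})

test_that("distance matrix agrees with independent pairwise calls", {
  d <- synthetic_design(n_true_taxa = 10, seed = 80)
  st <- simulate_counts(d, n_samples = 3)
  D <- distance_matrix(st$tree, st$counts, distance_spec("generalized_unifrac"))
  for (a in 1:2) for (b in (a + 1):3) {
    expect_equal(D[a, b], generalized_unifrac(st$tree, st$counts, a, b))
  }
})

test_that("unweighted UniFrac agrees with phyloseq on a random instance", {
  skip_if_not_installed("phyloseq")
  tr <- shape_tree(tree_shapes()[10], seed = 81)
  set.seed(82)
  m <- matrix(rbinom(3 * length(tr$tip.label), 5, 0.6),
              length(tr$tip.label), 3,
              dimnames = list(tr$tip.label, c("s1", "s2", "s3")))
  m[, 1] <- m[, 1] + 1  # avoid empty samples
  m[1, 2] <- m[1, 2] + 1
  m[2, 3] <- m[2, 3] + 1
  ours <- distance_matrix(tr, count_table(m), distance_spec("unweighted_unifrac"))
  ps <- phyloseq::phyloseq(phyloseq::otu_table(m, taxa_are_rows = TRUE),
                           phyloseq::phy_tree(tr))
  theirs <- as.matrix(phyloseq::UniFrac(ps, weighted = FALSE))
  expect_equal(ours, theirs[rownames(ours), colnames(ours)], tolerance = 1e-8)
})

test_that("median within-group distances summarize a distance matrix", {
  D <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  res <- median_within_group(D, c("g", "g", "g"))
  expect_equal(res$median_distance, 2)
  expect_equal(res$n_pairs, 3)
  res2 <- median_within_group(D, c("g", "g", "h"))
  expect_equal(res2$median_distance, 1)
  res3 <- median_within_group(D, c("g", "g", "g"), pairs = "consecutive",
                              order_by = c(1, 2, 3))
  expect_equal(res3$median_distance, 2)  # pairs (a,b)=1 and (b,c)=3
})
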