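# small in-code fixtures shared across test files

tiny_table <- function() {
  count_table(matrix(c(5, 1, 0, 3), 2, 2,
                     dimnames = list(c("t1", "t2"), c("s1", "s2"))))
}

# random integer count table with a fixed seed
rand_table <- function(seed, n_taxa = 12, n_samples = 4, lambda = 40) {
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed({
    m <- matrix(rpois(n_taxa * n_samples, lambda), n_taxa, n_samples,
                dimnames = list(sprintf("t%02d", seq_len(n_taxa)),
                                sprintf("s%02d", seq_len(n_samples))))
    count_table(m)
  })
}

rand_dna <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# substitute exactly k distinct positions with a different base
substitute_bases <- function(seq, k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  pos <- sample.int(length(chars), k)
  for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  paste(chars, collapse = "")
}

# every rooted binary tree shape with 2..6 leaves, as newick templates with
# branch-length placeholders filled by the caller
tree_shapes <- function() {
  c(
    "(A:%f,B:%f);",
    "((A:%f,B:%f):%f,C:%f);",
    "((A:%f,B:%f):%f,(C:%f,D:%f):%f);",
    "(((A:%f,B:%f):%f,C:%f):%f,D:%f);",
    "((((A:%f,B:%f):%f,C:%f):%f,D:%f):%f,E:%f);",
    "(((A:%f,B:%f):%f,(C:%f,D:%f):%f):%f,E:%f);",
    "(((A:%f,B:%f):%f,C:%f):%f,(D:%f,E:%f):%f);",
    "(((((A:%f,B:%f):%f,C:%f):%f,D:%f):%f,E:%f):%f,F:%f);",
    "((((A:%f,B:%f):%f,(C:%f,D:%f):%f):%f,E:%f):%f,F:%f);",
    "((((A:%f,B:%f):%f,C:%f):%f,(D:%f,E:%f):%f):%f,F:%f);",
    "((((A:%f,B:%f):%f,C:%f):%f,D:%f):%f,(E:%f,F:%f):%f);",
    "(((A:%f,B:%f):%f,(C:%f,D:%f):%f):%f,(E:%f,F:%f):%f);",
    "((A:%f,B:%f):%f,((C:%f,D:%f):%f,(E:%f,F:%f):%f):%f);"
  )
}

# build a tree from a shape template with random positive branch lengths
shape_tree <- function(template, seed) {
  set.seed(seed)
  n <- lengths(regmatches(template, gregexpr("%f", template, fixed = TRUE)))
  lens <- round(runif(n, 0.1, 2), 3)
  read_newick(text = do.call(sprintf, c(list(template), as.list(lens))))
}

# independent oracle: descendant tip sets by naive recursive edge walking
# (no phangorn, no shared code with the implementation)
oracle_branch_tips <- function(tree) {
  ntip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  walk <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    unlist(lapply(kids[[as.character(node)]], walk))
  }
  lapply(tree$edge[, 2L], walk)
}

# oracle unweighted unifrac: direct branch enumeration from the definition
oracle_unweighted <- function(tree, pres_a, pres_b,
                              tips = oracle_branch_tips(tree)) {
  num <- 0; den <- 0
  for (e in seq_along(tips)) {
    inA <- any(tips[[e]] %in% pres_a)
    inB <- any(tips[[e]] %in% pres_b)
    L <- tree$edge.length[e]
    if (inA || inB) den <- den + L
    if (xor(inA, inB)) num <- num + L
  }
  num / den
}

# oracle weighted-normalized unifrac: sum L|pA-pB| / sum L(pA+pB)
oracle_weighted_normalized <- function(tree, prop_a, prop_b) {
  tips <- oracle_branch_tips(tree)
  num <- 0; den <- 0
  for (e in seq_along(tips)) {
    pa <- sum(prop_a[tips[[e]]])
    pb <- sum(prop_b[tips[[e]]])
    L <- tree$edge.length[e]
    num <- num + L * abs(pa - pb)
    den <- den + L * (pa + pb)
  }
  num / den
}
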