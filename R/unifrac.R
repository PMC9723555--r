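# logical incidence matrix: edges x tips, TRUE when the tip descends from
# the edge's child node
branch_tip_matrix <- function(tree) {
  ntip <- length(tree$tip.label)
  children <- tree$edge[, 2L]
  desc <- phangorn::Descendants(tree, children, type = "tips")
  M <- matrix(FALSE, nrow = nrow(tree$edge), ncol = ntip,
              dimnames = list(NULL, tree$tip.label))
  for (e in seq_along(children)) M[e, desc[[e]]] <- TRUE
  M
}

# validate the (tree, table) pair and return proportion columns aligned to
# tree tips (tips absent from the table get proportion 0)
unifrac_prep <- function(tree, table) {
  tree <- validate_tree(tree)
  validate_count_table(table)
  used <- rownames(table)[rowSums(table) > 0]
  missing <- setdiff(used, tree$tip.label)
  if (length(missing)) stop("taxa absent from tree: ",
                            paste(missing, collapse = ", "))
  M <- branch_tip_matrix(tree)
  P <- matrix(0, nrow = length(tree$tip.label), ncol = ncol(table),
              dimnames = list(tree$tip.label, colnames(table)))
  shared <- intersect(rownames(table), tree$tip.label)
  cs <- colSums(table)
  nonzero <- cs > 0
  P[shared, nonzero] <- sweep(table[shared, nonzero, drop = FALSE], 2L,
                              cs[nonzero], "/")
  list(tree = tree, M = M, P = P, L = tree$edge.length)
}

unifrac_pair_unweighted <- function(L, presA, presB) {
  if (!any(presA) && !any(presB)) stop("both samples are empty")
  uniq <- xor(presA, presB)
  union <- presA | presB
  sum(L[uniq]) / sum(L[union])
}

unifrac_pair_generalized <- function(L, pA, pB, alpha) {
  tot <- pA + pB
  use <- tot > 0
  if (!any(use)) stop("both samples are empty")
  w <- L[use] * tot[use]^alpha
  sum(w * abs(pA[use] - pB[use]) / tot[use]) / sum(w)
}

#' Unweighted UniFrac distance between two samples
#'
#' The fraction of total branch length (over branches leading to taxa
#' present in at least one of the two samples) that leads to taxa present
#' in exactly one sample. Depends only on presence/absence, which makes it
#' highly sensitive to low-abundance (and hence spurious) taxa.
#'
#' @param tree rooted [ape::phylo] tree whose leaves cover all taxa with
#'   nonzero counts.
#' @param table count table.
#' @param sample_a,sample_b sample ids or indices.
#' @return distance in `[0, 1]`.
#' @export
unweighted_unifrac <- function(tree, table, sample_a, sample_b) {
  prep <- unifrac_prep(tree, table)
  ja <- resolve_sample(table, sample_a)
  jb <- resolve_sample(table, sample_b)
  presA <- as.vector(prep$M %*% (prep$P[, ja] > 0)) > 0
  presB <- as.vector(prep$M %*% (prep$P[, jb] > 0)) > 0
  unifrac_pair_unweighted(prep$L, presA, presB)
}

#' Generalized UniFrac distance between two samples
#'
#' For each branch b with length L_b, let p_b be the fraction of a sample's
#' reads descending from b. The generalized UniFrac distance is
#' sum_b L_b (pA_b + pB_b)^alpha |pA_b - pB_b| / (pA_b + pB_b), divided by
#' sum_b L_b (pA_b + pB_b)^alpha, over branches with pA_b + pB_b > 0.
#' `alpha` interpolates between emphasizing rare lineages (alpha = 0) and
#' abundant ones (alpha = 1, the weighted-normalized case); alpha = 0.5 is
#' the usual compromise.
#'
#' @inheritParams unweighted_unifrac
#' @param alpha abundance weighting exponent in `[0, 1]` (default 0.5).
#' @return distance in `[0, 1]`.
#' @export
generalized_unifrac <- function(tree, table, sample_a, sample_b, alpha = 0.5) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1) {
    stop("alpha must be a single number in [0, 1]")
  }
  prep <- unifrac_prep(tree, table)
  ja <- resolve_sample(table, sample_a)
  jb <- resolve_sample(table, sample_b)
  pA <- as.vector(prep$M %*% prep$P[, ja])
  pB <- as.vector(prep$M %*% prep$P[, jb])
  unifrac_pair_generalized(prep$L, pA, pB, alpha)
}

#' Specify a beta-diversity distance
#'
#' @param metric `"unweighted_unifrac"` or `"generalized_unifrac"`.
#' @param alpha abundance weighting for generalized UniFrac (default 0.5).
#' @return object of class `distance_spec`.
#' @export
distance_spec <- function(metric = c("unweighted_unifrac", "generalized_unifrac"),
                          alpha = 0.5) {
  metric <- match.arg(metric)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1) {
    stop("alpha must be a single number in [0, 1]")
  }
  structure(list(metric = metric, alpha = alpha), class = "distance_spec")
}

#' All-pairs UniFrac distance matrix
#'
#' Computes the full symmetric distance matrix for all samples of a table,
#' sharing the branch bookkeeping across pairs.
#'
#' @param tree rooted [ape::phylo] tree.
#' @param table count table with at least 2 samples.
#' @param spec a [distance_spec()].
#' @return symmetric numeric matrix with zero diagonal, dimnames the sample
#'   ids.
#' @export
distance_matrix <- function(tree, table, spec = distance_spec()) {
  stopifnot(inherits(spec, "distance_spec"))
  if (ncol(table) < 2L) stop("distance matrix requires at least 2 samples")
  prep <- unifrac_prep(tree, table)
  n <- ncol(table)
  BP <- prep$M %*% prep$P                       # branch proportions per sample
  Bpres <- prep$M %*% (prep$P > 0) > 0          # branch presence per sample
  D <- matrix(0, n, n, dimnames = list(colnames(table), colnames(table)))
  for (a in seq_len(n - 1L)) {
    for (b in seq(a + 1L, n)) {
      d <- if (spec$metric == "unweighted_unifrac") {
        unifrac_pair_unweighted(prep$L, Bpres[, a], Bpres[, b])
      } else {
        unifrac_pair_generalized(prep$L, BP[, a], BP[, b], spec$alpha)
      }
      D[a, b] <- D[b, a] <- d
    }
  }
  D
}

#' Median within-group distance per group
#'
#' Summarizes a distance matrix as the median of all within-group pairwise
#' distances for each group (e.g. over-time variation of each subject's
#' microbiota profile). With `pairs = "consecutive"` only distances between
#' consecutive samples (in `order_by` order) are used.
#'
#' @param dmat symmetric distance matrix with sample ids as dimnames.
#' @param grouping named vector or vector aligned with `colnames(dmat)`
#'   giving each sample's group (e.g. subject id).
#' @param pairs `"all"` (default) or `"consecutive"`.
#' @param order_by optional vector (e.g. timepoints) used to order samples
#'   within a group for `pairs = "consecutive"`.
#' @return data.frame with columns `group`, `n_pairs`, `median_distance`.
#' @export
median_within_group <- function(dmat, grouping, pairs = c("all", "consecutive"),
                                order_by = NULL) {
  pairs <- match.arg(pairs)
  ids <- colnames(dmat)
  if (length(grouping) != length(ids)) stop("grouping length must match samples")
  out <- lapply(unique(grouping), function(g) {
    idx <- which(grouping == g)
    if (length(idx) < 2L) return(NULL)
    if (pairs == "consecutive") {
      if (!is.null(order_by)) idx <- idx[order(order_by[idx])]
      d <- vapply(seq_len(length(idx) - 1L), function(k)
        dmat[idx[k], idx[k + 1L]], 1)
    } else {
      d <- dmat[idx, idx][lower.tri(matrix(0, length(idx), length(idx)))]
    }
    data.frame(group = g, n_pairs = length(d), median_distance = stats::median(d),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
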