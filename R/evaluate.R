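#' Triplet agreement between two trees
#'
#' Samples leaf triplets shared by both trees and scores the fraction on
#' which the trees agree about which pair is closest (deepest MRCA by
#' topological depth). A triplet left unresolved by a multifurcation is
#' scored 1/3 (the random-guess equivalent), so a random binary tree scores
#' about 1/3 against any reference.
#'
#' @param tree1,tree2 `lineage_tree`s sharing leaf labels (times not
#'   required).
#' @param n_triplets triplets to sample (default 2000; all triplets are
#'   enumerated when fewer exist).
#' @param seed optional seed.
#' @return scalar agreement in \[0, 1\].
#' @export
triplet_agreement <- function(tree1, tree2, n_triplets = 2000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  depth_time <- function(tr) {
    d <- integer(tr$n_node)
    for (v in seq_len(tr$n_node)[-1]) d[v] <- d[tr$parent[v]] + 1L
    lineage_tree(tr$parent, d, tr$label)
  }
  M1 <- tree_mrca_times(depth_time(tree1))
  M2 <- tree_mrca_times(depth_time(tree2))
  shared <- intersect(rownames(M1), rownames(M2))
  if (length(shared) < 3) stop("need at least 3 shared leaves")
  M1 <- M1[shared, shared]; M2 <- M2[shared, shared]
  n <- length(shared)
  total <- choose(n, 3)
  trips <- if (total <= n_triplets) {
    t(utils::combn(n, 3))
  } else {
    cbind(sample.int(n, n_triplets, replace = TRUE),
          sample.int(n, n_triplets, replace = TRUE),
          sample.int(n, n_triplets, replace = TRUE))
  }
  ok <- trips[, 1] != trips[, 2] & trips[, 1] != trips[, 3] &
    trips[, 2] != trips[, 3]
  trips <- trips[ok, , drop = FALSE]
  score_one <- function(i, j, k, M) {
    d <- c(M[i, j], M[i, k], M[j, k])
    mx <- max(d)
    w <- which(d == mx)
    if (length(w) > 1) 0L else w  # 0 = unresolved
  }
  s <- vapply(seq_len(nrow(trips)), function(t3) {
    i <- trips[t3, 1]; j <- trips[t3, 2]; k <- trips[t3, 3]
    a <- score_one(i, j, k, M1)
    b <- score_one(i, j, k, M2)
    if (a == 0L || b == 0L) return(1 / 3)
    as.numeric(a == b)
  }, numeric(1))
  mean(s)
}

#' Match recovered restricted clades against planted commitments
#'
#' A planted commitment (fate + true descendant leaf set) counts as
#' recovered when some reported clade of the same fate overlaps its sampled
#' leaf set with Jaccard similarity at least `jaccard_min`. Precision is
#' computed over reported clades of the planted fates only.
#'
#' @param clades output of [find_restricted_clades()].
#' @param truth data.frame with `fate` and a list-column `leaves` (sampled
#'   leaf labels of each planted clade).
#' @param jaccard_min match threshold (default 0.75).
#' @return list with `precision`, `recall`, `matched` (per-truth logical).
#' @export
clade_recovery <- function(clades, truth, jaccard_min = 0.75) {
  members <- attr(clades, "members")
  fates <- unique(truth$fate)
  rel <- which(clades$fate %in% fates)
  matched_truth <- logical(nrow(truth))
  matched_clade <- logical(length(rel))
  for (i in seq_len(nrow(truth))) {
    tset <- truth$leaves[[i]]
    for (jj in seq_along(rel)) {
      j <- rel[jj]
      if (clades$fate[j] != truth$fate[i]) next
      if (jaccard_chr(tset, members[[j]]) >= jaccard_min) {
        matched_truth[i] <- TRUE
        matched_clade[jj] <- TRUE
      }
    }
  }
  list(precision = if (length(rel) == 0) NA_real_ else mean(matched_clade),
       recall = mean(matched_truth),
       matched = matched_truth)
}

#' Random binary tree over given leaf labels (for baselines)
#' @param labels leaf labels.
#' @param seed optional seed.
#' @return a `lineage_tree` (topology with unit-depth times).
#' @export
random_binary_tree <- function(labels, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  phy <- ape::rtree(length(labels), tip.label = sample(labels))
  as_lineage_tree(phy)
}
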