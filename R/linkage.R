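#' Ancestral linkage of cells to a target category
#'
#' For each source cell, the raw score is the day of the deepest (most
#' recent) common ancestor shared with any cell of the target set (excluding
#' the cell itself when it is a target). The background expectation is the
#' mean raw score under permutations that reposition the target label set
#' uniformly over all leaves, preserving its size; linkage = raw -
#' background, in days. Positive linkage means more recent shared ancestry
#' with the target than expected by chance.
#'
#' @param tree dated `lineage_tree`.
#' @param targets character vector of target cell IDs (leaf labels).
#' @param sources cell IDs to score (default all leaves).
#' @param n_perm background permutations (default 100).
#' @param seed optional seed.
#' @return data.frame `cell_id`, `raw` (days), `background`, `linkage`.
#' @export
ancestral_linkage <- function(tree, targets, sources = NULL, n_perm = 100,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  leaves <- tree_leaves(tree)
  ids <- tree$label[leaves]
  if (is.null(sources)) sources <- ids
  t_idx <- leaves[ids %in% targets]
  if (length(t_idx) == 0) stop("target set is empty")
  raw <- mrca_depth_to_set(tree, t_idx)
  bg <- matrix(NA_real_, length(leaves), n_perm)
  for (k in seq_len(n_perm)) {
    perm <- sample(leaves, length(t_idx))
    bg[, k] <- mrca_depth_to_set(tree, perm)
  }
  bgm <- rowMeans(bg)
  names(raw) <- names(bgm) <- ids
  s <- intersect(sources, ids)
  data.frame(cell_id = s, raw = raw[s], background = bgm[s],
             linkage = raw[s] - bgm[s], row.names = NULL)
}

# internal: for every leaf, the day of its deepest ancestor whose subtree
# contains a member of `set` other than the leaf itself; NA if none (set is
# the leaf alone)
mrca_depth_to_set <- function(tree, set_idx) {
  n <- tree$n_node
  cnt <- integer(n)
  cnt[set_idx] <- 1L
  for (v in n:2) cnt[tree$parent[v]] <- cnt[tree$parent[v]] + cnt[v]
  leaves <- tree_leaves(tree)
  vapply(leaves, function(l) {
    need <- if (cnt[l] > 0) 2L else 1L  # exclude self
    p <- tree$parent[l]
    while (!is.na(p)) {
      if (cnt[p] >= need) return(tree$time[p])
      # once above self, the self-exclusion is already accounted: cnt at any
      # ancestor includes the leaf when it is a target, so `need` stays
      p <- tree$parent[p]
    }
    NA_real_
  }, numeric(1))
}

#' Pairwise ancestral linkage between categories
#'
#' Iterates [ancestral_linkage()] with every category as the target,
#' averages per source category, symmetrizes by averaging reciprocal
#' source-target values, and reports permutation p-values under the same
#' target-repositioning scheme.
#'
#' @param tree dated `lineage_tree`.
#' @param labels named leaf category labels.
#' @param n_perm permutations (default 100).
#' @param seed optional seed.
#' @return list with `linkage` (symmetric category matrix, days), `raw`
#'   (directional source x target matrix before symmetrization), `p`
#'   (symmetrized permutation p-values).
#' @export
pairwise_linkage <- function(tree, labels, n_perm = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  leaves <- tree_leaves(tree)
  ids <- tree$label[leaves]
  lab <- as.character(labels[ids])
  cats <- sort(unique(lab))
  M <- matrix(NA_real_, length(cats), length(cats),
              dimnames = list(cats, cats))
  P <- M
  for (tg in cats) {
    t_idx <- leaves[lab == tg]
    raw <- mrca_depth_to_set(tree, t_idx)
    bg <- matrix(NA_real_, length(leaves), n_perm)
    for (k in seq_len(n_perm)) {
      perm <- sample(leaves, length(t_idx))
      bg[, k] <- mrca_depth_to_set(tree, perm)
    }
    link <- raw - rowMeans(bg)
    for (sc in cats) {
      sel <- lab == sc
      M[sc, tg] <- mean(link[sel], na.rm = TRUE)
      obs <- mean(raw[sel], na.rm = TRUE)
      nullm <- colMeans(bg[sel, , drop = FALSE], na.rm = TRUE)
      P[sc, tg] <- (1 + sum(nullm >= obs)) / (n_perm + 1)
    }
  }
  list(linkage = (M + t(M)) / 2, raw = M, p = (P + t(P)) / 2)
}

#' Linkage variability across replicate trees
#'
#' @param trees list of dated `lineage_tree`s (replicate embryos).
#' @param labels_list list of matching leaf label vectors.
#' @param ... passed to [pairwise_linkage()].
#' @return list with `mean` and `variance` matrices across replicates, and
#'   `per_tree` (list of linkage matrices).
#' @export
pairwise_linkage_replicates <- function(trees, labels_list, ...) {
  res <- mapply(function(tr, lb) pairwise_linkage(tr, lb, ...)$linkage,
                trees, labels_list, SIMPLIFY = FALSE)
  cats <- sort(unique(unlist(lapply(res, colnames))))
  arr <- array(NA_real_, c(length(cats), length(cats), length(res)),
               dimnames = list(cats, cats, NULL))
  for (i in seq_along(res)) {
    cc <- colnames(res[[i]])
    arr[cc, cc, i] <- res[[i]]
  }
  list(mean = apply(arr, 1:2, mean, na.rm = TRUE),
       variance = apply(arr, 1:2, stats::var, na.rm = TRUE),
       per_tree = res)
}

#' Impute ancestral scores as descendant means
#'
#' Node score = mean score over descendant leaves; with
#' [expand_time_bins()] this yields time-binned trajectories.
#'
#' @param tree dated `lineage_tree`.
#' @param score named numeric vector over leaf cell IDs (finite).
#' @param bin_width optional; when given, a binned trajectory is returned
#'   too.
#' @return list with `node_scores` (vector over nodes) and `binned`
#'   (data.frame or NULL).
#' @export
impute_ancestral_scores <- function(tree, score, bin_width = NULL) {
  leaves <- tree_leaves(tree)
  ids <- tree$label[leaves]
  if (any(!is.finite(score[ids])))
    stop("every leaf needs a finite score")
  n <- tree$n_node
  s <- numeric(n); cnt <- numeric(n)
  s[leaves] <- score[ids]; cnt[leaves] <- 1
  for (v in n:2) {
    p <- tree$parent[v]
    s[p] <- s[p] + s[v]; cnt[p] <- cnt[p] + cnt[v]
  }
  node_scores <- s / cnt
  binned <- if (!is.null(bin_width))
    expand_time_bins(tree, node_scores, bin_width = bin_width,
                     weights = cnt) else NULL
  list(node_scores = node_scores, binned = binned)
}

#' Smoothed rate of change of a binned series
#'
#' Applies a centered rolling mean (window = 2 bins) and a centered
#' two-point slope: derivative at bin i is
#' `(s[i+1] - s[i-1]) / (t[i+1] - t[i-1])` on the smoothed series.
#' Endpoints are reported as missing.
#'
#' @param times bin times (strictly increasing).
#' @param values series values.
#' @param window rolling-mean window in bins (default 2).
#' @return data.frame `time`, `smoothed`, `rate` (NA at endpoints).
#' @export
rate_of_change <- function(times, values, window = 2) {
  n <- length(values)
  if (n < 3) stop("need at least 3 bins for a derivative")
  sm <- stats::filter(values, rep(1 / window, window), sides = 2)
  sm <- as.numeric(sm)
  sm[is.na(sm)] <- values[is.na(sm)]
  rate <- rep(NA_real_, n)
  for (i in 2:(n - 1))
    rate[i] <- (sm[i + 1] - sm[i - 1]) / (times[i + 1] - times[i - 1])
  data.frame(time = times, smoothed = sm, rate = rate)
}

#' Heritability of a per-clade score across neighboring clades
#'
#' Pairs each candidate node with its nearest neighboring candidate node by
#' tree path distance (days; ties by node ID) and reports the squared
#' Pearson correlation between the paired mean scores.
#'
#' @param tree dated `lineage_tree`.
#' @param nodes integer node indices of the candidate clades (>= 3).
#' @param values per-candidate mean score (parallel to `nodes`).
#' @return list with `pairs` (data.frame node, neighbor, value,
#'   neighbor_value) and `r_squared`.
#' @export
clade_heritability <- function(tree, nodes, values) {
  if (length(nodes) < 3) stop("need at least 3 clades")
  depth <- tree_depths(tree)
  # pairwise path distance via MRCA depths over candidate nodes
  anc <- lapply(nodes, function(v) c(v, tree_ancestors(tree, v)))
  D <- matrix(Inf, length(nodes), length(nodes))
  for (i in seq_along(nodes)) for (j in seq_along(nodes)) {
    if (i == j) next
    m <- intersect(anc[[i]], anc[[j]])[1]  # deepest common ancestor
    D[i, j] <- depth[nodes[i]] + depth[nodes[j]] - 2 * depth[m]
  }
  nn <- vapply(seq_along(nodes), function(i) {
    o <- order(D[i, ], nodes)  # ties by node ID
    o[o != i][1]
  }, integer(1))
  pairs <- data.frame(node = nodes, neighbor = nodes[nn],
                      value = values, neighbor_value = values[nn])
  r2 <- stats::cor(pairs$value, pairs$neighbor_value)^2
  list(pairs = pairs, r_squared = r2)
}

#' Transcriptional divergence among close lineage relatives
#'
#' For each cell, the mean Euclidean embedding distance to all leaves within
#' a lineage-distance cap: either a number of edges on the (collapsed) tree
#' path between leaves (`mode = "edges"`, default cap 3) or a day window on
#' MRCA depth (`mode = "days"`). Cells with no neighbors get `NA`.
#'
#' @param tree dated `lineage_tree`.
#' @param embedding numeric matrix, rows = leaf cell IDs.
#' @param max_lineage_distance cap (edges or days).
#' @param mode `"edges"` or `"days"`.
#' @param labels optional named category labels for per-category medians.
#' @return list with `per_cell` (data.frame cell_id, divergence,
#'   n_neighbors) and `per_category` (named medians or NULL).
#' @export
transcriptional_divergence <- function(tree, embedding,
                                       max_lineage_distance = 3,
                                       mode = c("edges", "days"),
                                       labels = NULL) {
  mode <- match.arg(mode)
  leaves <- tree_leaves(tree)
  ids <- tree$label[leaves]
  if (!all(ids %in% rownames(embedding)))
    stop("embedding must cover all leaves")
  E <- embedding[ids, , drop = FALSE]
  if (any(!is.finite(E))) stop("embedding must be finite")
  nl <- length(leaves)
  if (mode == "edges") {
    g <- igraph::graph_from_edgelist(
      cbind(tree$parent[!is.na(tree$parent)],
            which(!is.na(tree$parent))), directed = FALSE)
    LD <- igraph::distances(g, v = leaves, to = leaves)
    near <- LD <= max_lineage_distance
  } else {
    Mt <- tree_mrca_times(tree)
    leaf_day <- tree$time[leaves]
    near <- outer(leaf_day, rep(1, nl)) - Mt <= max_lineage_distance
  }
  diag(near) <- FALSE
  ED <- as.matrix(stats::dist(E))
  div <- vapply(seq_len(nl), function(i) {
    nb <- which(near[i, ])
    if (length(nb) == 0) NA_real_ else mean(ED[i, nb])
  }, numeric(1))
  per_cell <- data.frame(cell_id = ids, divergence = div,
                         n_neighbors = rowSums(near))
  per_cat <- NULL
  if (!is.null(labels)) {
    lab <- as.character(labels[ids])
    per_cat <- tapply(div, lab, stats::median, na.rm = TRUE)
  }
  list(per_cell = per_cell, per_category = per_cat)
}

#' Proliferation score: close relatives within a time window
#'
#' For each leaf, the number of other leaves whose most recent common
#' ancestor with it falls within the preceding `window` days (default 24 h)
#' of the leaf's sampling day.
#'
#' @param tree dated `lineage_tree`.
#' @param window days (default 1).
#' @param labels optional named category labels for per-category means.
#' @return list with `per_cell` (data.frame cell_id, score) and
#'   `per_category` (named means or NULL).
#' @export
proliferation_score <- function(tree, window = 1, labels = NULL) {
  leaves <- tree_leaves(tree)
  nlv <- tree_n_leaves(tree)
  score <- vapply(leaves, function(l) {
    cutoff <- tree$time[l] - window
    top <- l
    p <- tree$parent[l]
    while (!is.na(p) && tree$time[p] >= cutoff) {
      top <- p
      p <- tree$parent[p]
    }
    nlv[top] - 1
  }, numeric(1))
  ids <- tree$label[leaves]
  per_cat <- NULL
  if (!is.null(labels))
    per_cat <- tapply(score, as.character(labels[ids]), mean)
  list(per_cell = data.frame(cell_id = ids, score = score),
       per_category = per_cat)
}

#' Within-clade transcriptional similarity versus a subtype-matched null
#'
#' Observed statistic: mean pairwise cosine similarity across all cell pairs
#' in the clade. Null: sets of equal size sampled from all cells of the
#' clade's most common subtype (with replacement, flagged, when the pool is
#' smaller than the clade). One-sided upper p-values with add-one
#' correction; Benjamini-Hochberg across clades.
#'
#' @param clades restricted clades ([find_restricted_clades()] output).
#' @param embedding numeric matrix, rows = cell IDs.
#' @param subtypes named subtype labels over cells.
#' @param n_perm permutations per clade (default 1000).
#' @param fdr FDR level for the significance flag (default 0.05).
#' @param seed optional seed.
#' @return data.frame per clade: `clade`, `n_cells`, `subtype`, `observed`,
#'   `null_mean`, `null_sd`, `z`, `p`, `fdr_significant`, `resampled`.
#' @export
within_clade_similarity <- function(clades, embedding, subtypes,
                                    n_perm = 1000, fdr = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  members <- attr(clades, "members")
  En <- embedding / sqrt(rowSums(embedding^2))
  mean_cos <- function(cells) {
    S <- tcrossprod(En[cells, , drop = FALSE])
    mean(S[upper.tri(S)])
  }
  rows <- list()
  for (i in seq_along(members)) {
    m <- intersect(members[[i]], rownames(embedding))
    if (length(m) < 3) next
    st <- names(sort(table(as.character(subtypes[m])), decreasing = TRUE))[1]
    pool <- names(subtypes)[as.character(subtypes) == st]
    pool <- intersect(pool, rownames(embedding))
    repl <- length(pool) < length(m)
    obs <- mean_cos(m)
    null <- vapply(seq_len(n_perm), function(k)
      mean_cos(sample(pool, length(m), replace = repl)), numeric(1))
    z <- (obs - mean(null)) / stats::sd(null)
    p <- (1 + sum(null >= obs)) / (n_perm + 1)
    rows[[length(rows) + 1]] <- data.frame(
      clade = i, n_cells = length(m), subtype = st, observed = obs,
      null_mean = mean(null), null_sd = stats::sd(null), z = z, p = p,
      resampled = repl)
  }
  out <- do.call(rbind, rows)
  if (!is.null(out)) {
    out$p_adj <- stats::p.adjust(out$p, "BH")
    out$fdr_significant <- out$p_adj <= fdr
  }
  out
}
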