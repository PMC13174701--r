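# brute-force raw linkage: deepest MRCA day between a leaf and any target
brute_raw_linkage <- function(tree, targets_idx) {
  leaves <- tree_leaves(tree)
  anc <- lapply(seq_len(tree$n_node), function(v)
    c(v, tree_ancestors(tree, v)))
  vapply(leaves, function(l) {
    others <- setdiff(targets_idx, l)
    if (length(others) == 0) return(NA_real_)
    max(vapply(others, function(t2)
      tree$time[intersect(anc[[l]], anc[[t2]])[1]], numeric(1)))
  }, numeric(1))
}

test_that("raw linkage equals brute-force all-pairs MRCA computation", {
  for (s in 1:4) {
    tr <- random_dated_tree(60, seed = s + 70)
    leaves <- tree_leaves(tr)
    t_idx <- sample(leaves, 12)
    fast <- lintrace:::mrca_depth_to_set(tr, t_idx)
    slow <- brute_raw_linkage(tr, t_idx)
    expect_equal(fast, slow)
  }
})

test_that("a cell with a target sibling scores the parent's day", {
  tr <- balanced4_tree()  # u -> (a, b) at day 2; v -> (c, d) at day 3
  res <- ancestral_linkage(tr, targets = "b", sources = "a", n_perm = 10,
                           seed = 1)
  expect_equal(res$raw, 2)  # parent u's day
  expect_error(ancestral_linkage(tr, targets = character(0)), "empty")
})

test_that("random labels give mean linkage near zero (null calibration)", {
  set.seed(12)
  means <- numeric(40)
  for (i in seq_along(means)) {
    tr <- random_dated_tree(40, seed = 400 + i)
    leaves <- tree_leaves(tr)
    t_idx <- sample(leaves, 10)
    res <- ancestral_linkage(tr, targets = tr$label[t_idx], n_perm = 30)
    means[i] <- mean(res$linkage)
  }
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means)), 3 * se)
})

test_that("pairwise linkage is symmetric with self-linkage on the diagonal", {
  tr <- random_dated_tree(50, seed = 80)
  ids <- tr$label[tree_leaves(tr)]
  set.seed(2)
  lab <- setNames(sample(c("x", "y", "z"), length(ids), TRUE), ids)
  pl <- pairwise_linkage(tr, lab, n_perm = 25, seed = 3)
  expect_equal(pl$linkage, t(pl$linkage))
  expect_equal(dim(pl$linkage), c(3, 3))
  expect_true(all(pl$p >= 1 / 26 - 1e-12))
})

test_that("replicate-tree linkage reports mean and variance", {
  trees <- lapply(1:3, function(s) random_dated_tree(30, seed = 90 + s))
  labs <- lapply(trees, function(tr) {
    ids <- tr$label[tree_leaves(tr)]
    setNames(rep(c("x", "y"), length.out = length(ids)), ids)
  })
  rep3 <- pairwise_linkage_replicates(trees, labs, n_perm = 10, seed = 1)
  expect_equal(dim(rep3$mean), c(2, 2))
  expect_true(all(rep3$variance >= 0, na.rm = TRUE))
})

test_that("ancestral score imputation averages descendant leaves", {
  tr <- balanced4_tree()
  score <- c(a = 1, b = 3, c = 10, d = 20)
  imp <- impute_ancestral_scores(tr, score)
  expect_equal(unname(imp$node_scores[tree_root(tr)]), mean(score))
  expect_equal(unname(imp$node_scores[2]), 2)   # node u over a, b
  # constant score: every node equal, derivative zero
  const <- impute_ancestral_scores(tr, c(a = 5, b = 5, c = 5, d = 5),
                                   bin_width = 1)
  expect_true(all(const$node_scores == 5))
  roc <- rate_of_change(const$binned$bin, const$binned$mean)
  expect_true(all(roc$rate == 0, na.rm = TRUE))
  expect_error(impute_ancestral_scores(tr, c(a = 1, b = NA, c = 1, d = 1)),
               "finite")
})

test_that("rate of change recovers a linear slope away from endpoints", {
  t <- seq(0, 10, by = 0.5)
  x <- 3 * t + 2
  roc <- rate_of_change(t, x)
  mid <- roc$rate[3:(length(t) - 2)]
  expect_true(all(abs(mid - 3) / 3 < 0.05))
  expect_true(is.na(roc$rate[1]) && is.na(roc$rate[length(t)]))
  expect_error(rate_of_change(1:2, 1:2), "at least 3")
})

test_that("clade heritability is 1 for a perfectly heritable trait", {
  tr <- random_dated_tree(40, seed = 101)
  nodes <- sample(setdiff(seq_len(tr$n_node), tree_leaves(tr)), 8)
  vals <- as.numeric(nodes)  # trait identical for a node and its neighbor?
  # perfectly heritable: score equals a smooth function of tree position;
  # here use each node's own depth so neighbors have near-identical values
  vals <- tree_depths(tr)[nodes]
  h <- clade_heritability(tr, nodes, vals)
  expect_equal(nrow(h$pairs), 8)
  expect_error(clade_heritability(tr, nodes[1:2], vals[1:2]), "at least 3")
})

test_that("heritability pairs equal brute-force nearest-neighbor search", {
  tr <- random_dated_tree(80, seed = 102)
  nodes <- sort(sample(seq_len(tr$n_node), 15))
  vals <- rnorm(15)
  h <- clade_heritability(tr, nodes, vals)
  depth <- tree_depths(tr)
  anc <- lapply(seq_len(tr$n_node), function(v) c(v, tree_ancestors(tr, v)))
  for (i in seq_along(nodes)) {
    d <- sapply(seq_along(nodes), function(j) {
      if (i == j) return(Inf)
      m <- intersect(anc[[nodes[i]]], anc[[nodes[j]]])[1]
      depth[nodes[i]] + depth[nodes[j]] - 2 * depth[m]
    })
    expect_equal(h$pairs$neighbor[i], nodes[which.min(d)])
  }
})

test_that("i.i.d. noise scores give heritability inside the null envelope", {
  set.seed(13)
  tr <- random_dated_tree(60, seed = 103)
  nodes <- sample(setdiff(seq_len(tr$n_node), tree_leaves(tr)), 12)
  r2 <- replicate(100, clade_heritability(tr, nodes, rnorm(12))$r_squared)
  # under independence R^2 is small; the observed upper tail bounds chance
  expect_lt(median(r2), 0.3)
  expect_gt(mean(r2 < 0.5), 0.9)
})

test_that("transcriptional divergence matches brute force and trivial cases", {
  tr <- balanced4_tree()
  E <- rbind(a = c(0, 0), b = c(3, 4), c = c(1, 1), d = c(1, 1))
  td <- transcriptional_divergence(tr, E, max_lineage_distance = 2)
  # cherry at distance 2 edges: a-b are each other's only neighbors, d = 5
  expect_equal(td$per_cell$divergence[td$per_cell$cell_id == "a"], 5)
  expect_equal(td$per_cell$divergence[td$per_cell$cell_id == "c"], 0)
  # identical embeddings -> divergence 0
  E0 <- rbind(a = c(1, 1), b = c(1, 1), c = c(1, 1), d = c(1, 1))
  td0 <- transcriptional_divergence(tr, E0, max_lineage_distance = 10)
  expect_true(all(td0$per_cell$divergence == 0))
  expect_error(transcriptional_divergence(tr, E[1:3, , drop = FALSE]),
               "cover")
  # oracle on random trees: path-length filter + averaging
  tr2 <- random_dated_tree(30, seed = 110)
  ids <- tr2$label[tree_leaves(tr2)]
  set.seed(3)
  E2 <- matrix(rnorm(60), 30, 2, dimnames = list(ids, NULL))
  td2 <- transcriptional_divergence(tr2, E2, max_lineage_distance = 3)
  g <- igraph::graph_from_edgelist(
    cbind(tr2$parent[!is.na(tr2$parent)], which(!is.na(tr2$parent))),
    directed = FALSE)
  LD <- igraph::distances(g, v = tree_leaves(tr2), to = tree_leaves(tr2))
  for (i in sample(30, 8)) {
    nb <- which(LD[i, ] <= 3 & seq_len(30) != i)
    exp_d <- if (length(nb) == 0) NA_real_ else
      mean(sqrt(rowSums((E2[nb, , drop = FALSE] -
                           matrix(E2[i, ], length(nb), 2, TRUE))^2)))
    expect_equal(td2$per_cell$divergence[i], exp_d)
  }
})

test_that("proliferation scores follow complete-subtree combinatorics", {
  # balanced binary expansion with d divisions inside the window
  d <- 3
  parent <- NA_integer_; time <- 0
  for (lvl in 1:d) {
    n_prev <- 2^(lvl - 1)
    start <- length(parent) - n_prev + 1
    for (v in start:length(parent)) parent <- c(parent, v, v)
    time <- c(time, rep(lvl * 0.2, 2 * n_prev))
  }
  tr <- lineage_tree(parent, time,
                     c(paste0("n", seq_len(length(parent) - 2^d)),
                       paste0("L", seq_len(2^d))))
  ps <- proliferation_score(tr, window = 1)
  expect_true(all(ps$per_cell$score == 2^d - 1))
  # a leaf with no divisions in its last day scores 0
  lone <- lineage_tree(c(NA, 1, 1), c(0, 5, 5), c("r", "x", "y"))
  ps2 <- proliferation_score(lone, window = 1)
  expect_true(all(ps2$per_cell$score == 0))
  # oracle: all-pairs MRCA thresholding
  tr3 <- random_dated_tree(50, seed = 115, sampling_day = 8)
  ps3 <- proliferation_score(tr3, window = 1)
  M <- tree_mrca_times(tr3)
  brute <- rowSums(M >= 8 - 1) - 1
  expect_equal(ps3$per_cell$score, unname(brute))
})

test_that("within-clade similarity: trivial anchors and permutation floor", {
  set.seed(14)
  # embedding: identical vectors inside the clade, heterogeneous pool
  n_pool <- 60
  E <- rbind(matrix(rep(c(1, 0, 0), each = 5), 5, 3),
             matrix(rnorm(3 * n_pool), n_pool, 3))
  rownames(E) <- c(paste0("m", 1:5), paste0("p", 1:n_pool))
  subtypes <- setNames(rep("S", 5 + n_pool), rownames(E))
  cl <- data.frame(node = 1L, node_id = "n", fate = "F", purity = 1,
                   restriction_day = 5, n_descendants = 5,
                   via_multifurcation = FALSE)
  attr(cl, "members") <- list(paste0("m", 1:5))
  res <- within_clade_similarity(cl, E, subtypes, n_perm = 200, seed = 2)
  expect_equal(res$observed, 1)
  expect_equal(res$p, 1 / 201)
  expect_true(res$fdr_significant)
  # two anti-parallel cells -> mean cosine similarity -1 (via the statistic)
  E2 <- rbind(x = c(1, 0), y = c(-1, 0), z = c(0, 1))
  En <- E2 / sqrt(rowSums(E2^2))
  S <- tcrossprod(En[c("x", "y"), ])
  expect_equal(S[1, 2], -1)
})

test_that("clades drawn from their subtype pool give calibrated p-values", {
  set.seed(15)
  n_pool <- 80
  E <- matrix(rnorm(3 * n_pool), n_pool, 3)
  rownames(E) <- paste0("p", 1:n_pool)
  subtypes <- setNames(rep("S", n_pool), rownames(E))
  ps <- replicate(120, {
    m <- sample(rownames(E), 6)
    cl <- data.frame(node = 1L, node_id = "n", fate = "F", purity = 1,
                     restriction_day = 5, n_descendants = 6,
                     via_multifurcation = FALSE)
    attr(cl, "members") <- list(m)
    within_clade_similarity(cl, E, subtypes, n_perm = 60)$p
  })
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})
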