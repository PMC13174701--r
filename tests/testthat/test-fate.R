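lab4 <- c(a = "ecto", b = "ecto", c = "meso", d = "endo")

test_that("node fate distributions aggregate descendants correctly", {
  tr <- balanced4_tree()
  fd <- node_fate_distributions(tr, lab4)
  root <- tree_root(tr)
  expect_equal(unname(fd$counts[root, ]), c(2L, 1L, 1L))  # ecto, endo, meso
  leaves <- tree_leaves(tr)
  for (l in leaves)
    expect_equal(max(fd$props[l, ]), 1)  # leaf is a point mass
  expect_error(node_fate_distributions(tr, lab4[-1]), "unlabeled")
})

test_that("fate distributions equal brute-force descendant enumeration", {
  set.seed(20)
  for (s in 1:4) {
    tr <- random_dated_tree(30, seed = s)
    ids <- tr$label[tree_leaves(tr)]
    lab <- setNames(sample(c("x", "y", "z"), 30, TRUE), ids)
    fd <- node_fate_distributions(tr, lab)
    for (v in sample(tr$n_node, 8)) {
      below <- tr$label[tree_leaf_sets(tr, v)]
      expect_equal(unname(fd$counts[v, ]),
                   as.vector(table(factor(lab[below], colnames(fd$counts)))))
    }
  }
})

test_that("fate bias has the stated anchors and invariances", {
  q <- c(0.25, 0.25, 0.25, 0.25)
  expect_equal(fate_bias(c(1, 0, 0, 0), q), 1)
  expect_equal(fate_bias(q, q), 0)
  # p uniform over 2 of 4 equi-frequent root categories -> 1 - ln2/ln4 = 0.5
  expect_equal(fate_bias(c(0.5, 0.5, 0, 0), q), 0.5)
  # invariant to category order; empty category changes nothing
  expect_equal(fate_bias(c(0, 0.5, 0.5, 0), q[c(2, 1, 4, 3)]), 0.5)
  expect_equal(fate_bias(c(0.5, 0.5, 0, 0, 0), c(q, 0)), 0.5)
  expect_error(fate_bias(c(1, 0), c(1, 0)), "degenerate")
})

test_that("time-bin expansion follows the half-open convention", {
  # node with parent day 6.0, own day 7.0: contributes to [6.0, 6.5) and
  # [6.5, 7.0), not [7.0, 7.5)
  tr <- lineage_tree(c(NA, 1, 2, 2), c(5.0, 6.0, 7.0, 7.0),
                     c("r", "p", "a", "b"))
  vals <- c(0, 10, 1, 2)  # leaves a, b span [6.0, 7.0)
  eb <- expand_time_bins(tr, vals, bin_width = 0.5,
                         weights = rep(1, 4))
  expect_equal(eb$mean[eb$bin == 6.0], 1.5)  # mean of a and b
  expect_equal(eb$mean[eb$bin == 6.5], 1.5)
  expect_true(is.na(eb$mean[eb$bin == 7.0]))  # own day excluded (half-open)
  expect_equal(eb$mean[eb$bin == 5.5], 10)   # p spans [5.0, 6.0)
})

test_that("per-bin weighted means equal a brute-force node-bin loop", {
  for (s in 1:3) {
    tr <- random_dated_tree(40, seed = s + 50)
    vals <- stats::rnorm(tr$n_node)
    w <- tree_n_leaves(tr)
    bw <- 0.5
    eb <- expand_time_bins(tr, vals, bin_width = bw)
    root <- tree_root(tr)
    for (bi in seq_len(nrow(eb))) {
      b <- eb$bin[bi]
      num <- 0; den <- 0
      for (v in seq_len(tr$n_node)) {
        start <- if (v == root) tr$time[root] else tr$time[tr$parent[v]]
        end <- tr$time[v]
        inside <- (start <= b && b < end) || (b == end && start == end)
        if (inside) { num <- num + vals[v] * w[v]; den <- den + w[v] }
      }
      if (den > 0) expect_equal(eb$mean[bi], num / den)
    }
  }
})

test_that("permutation test is calibrated at the trivial extremes", {
  cfg <- sim_config(sampling_day = 7.4)
  tr <- sim_tree_sized(cfg, 50, 250, start_seed = 2)$tree
  ids <- tr$label[tree_leaves(tr)]
  # all labels identical: bias undefined via degenerate root -> error
  same <- setNames(rep("only", length(ids)), ids)
  expect_error(bias_permutation_test(tr, same, n_perm = 10),
               "degenerate")
  expect_error(bias_permutation_test(tr, NULL, n_perm = 1), "at least 2")
  # two planted pure subtrees give bias ~1 late and p at the floor
  kids <- tree_children(tr)[[tree_root(tr)]]
  stem <- if (length(kids) == 1) kids else tree_root(tr)
  halves <- tree_children(tr)[[stem]]
  if (length(halves) >= 2) {
    lab <- setNames(rep("a", length(ids)), ids)
    lab[tr$label[tree_leaf_sets(tr, halves[1])]] <- "b"
    res <- bias_permutation_test(tr, lab, n_perm = 50, seed = 1)
    late <- which(res$bin >= max(res$bin) - 1 & !is.na(res$p))
    expect_true(any(res$p[late] <= 1 / 51 + 1e-9))
  }
})

test_that("permutation p-values respect the add-one floor and reproducibility", {
  cfg <- sim_config(sampling_day = 7)
  tr <- sim_tree_sized(cfg, 30, 150, start_seed = 1)$tree
  ids <- tr$label[tree_leaves(tr)]
  set.seed(3)
  lab <- setNames(sample(c("a", "b"), length(ids), TRUE), ids)
  r1 <- bias_permutation_test(tr, lab, n_perm = 20, seed = 7)
  r2 <- bias_permutation_test(tr, lab, n_perm = 20, seed = 7)
  expect_identical(r1, r2)
  expect_true(all(r1$p >= 1 / 21 - 1e-12, na.rm = TRUE))
})

test_that("restricted clades: highest qualifying node wins, nesting excluded", {
  tr <- caterpillar_tree()  # r -> A, n2 -> B, n3 -> (C, D)
  lab <- c(A = "meso", B = "ecto", C = "ecto", D = "ecto")
  cl <- find_restricted_clades(tr, lab)
  ecto <- cl[cl$fate == "ecto", ]
  expect_equal(nrow(ecto), 1)           # only the highest node (n2)
  expect_equal(ecto$node_id, "n2")
  expect_equal(ecto$n_descendants, 3)
  expect_equal(ecto$restriction_day, 4)
  expect_equal(ecto$purity, 1)
})

test_that("multifurcation rule selects the parent for jointly pure children", {
  # trifurcation: two children pure for F, third a different fate
  tr <- lineage_tree(c(NA, 1, 1, 1, 2, 2, 3, 3, 4, 4),
                     c(0, 2, 2, 2, 5, 5, 5, 5, 5, 5),
                     c("r", "x", "y", "z", "a", "b", "c", "d", "e", "f"))
  lab <- c(a = "F", b = "F", c = "F", d = "F", e = "G", f = "G")
  cl <- find_restricted_clades(tr, lab)
  Frow <- cl[cl$fate == "F", ]
  expect_equal(nrow(Frow), 1)
  expect_equal(Frow$node_id, "r")
  expect_true(Frow$via_multifurcation)
  expect_equal(Frow$n_descendants, 4)
  expect_equal(Frow$restriction_day, 0)  # parent node's day
  members <- attr(cl, "members")[[which(cl$fate == "F")]]
  expect_setequal(members, c("a", "b", "c", "d"))
})

test_that("planted pure commitments are recovered at their true nodes", {
  cfg <- sim_config(seed = 41, sampling_day = 8)
  tr <- sim_tree_sized(cfg, 80, 400, start_seed = 4)$tree
  fm <- simulate_fate_map(tr, data.frame(day = c(4.6, 5.1),
                                         fate = c("nc", "pm")),
                          leakage = 0, seed = 9)
  cl <- find_restricted_clades(tr, fm$labels)
  members <- attr(cl, "members")
  for (i in seq_len(nrow(fm$truth))) {
    planted <- tr$label[tree_leaf_sets(tr, fm$truth$node[i])]
    j <- which(cl$fate == fm$truth$fate[i])
    expect_equal(length(j), 1)
    expect_setequal(members[[j]], planted)
  }
})

test_that("sibling outputs quote the parent's non-focal descendants", {
  # balanced cherry of two planted fates: each clade's sibling is the other
  tr <- balanced4_tree()
  lab <- c(a = "F", b = "F", c = "G", d = "G")
  cl <- find_restricted_clades(tr, lab)
  so <- sibling_outputs(tr, cl, lab)
  for (i in seq_len(nrow(cl))) {
    other <- setdiff(c("F", "G"), cl$fate[i])
    expect_equal(unname(so$composition[i, other]), 2L)
    expect_equal(unname(so$composition[i, cl$fate[i]]), 0L)
  }
  # sibling 20x larger with cap 10 -> excluded
  big <- lineage_tree(c(NA, 1, 1, rep(3, 40), 2, 2),
                      c(0, 1, 1, rep(5, 40), 5, 5),
                      c("r", "p", "q", paste0("s", 1:40), "a", "b"))
  lab2 <- setNames(c(rep("G", 40), "F", "F"),
                   c(paste0("s", 1:40), "a", "b"))
  cl2 <- find_restricted_clades(big, lab2)
  so2 <- sibling_outputs(big, cl2, lab2, size_ratio_cap = 10)
  Fi <- which(cl2$fate == "F")
  expect_true(so2$per_clade$excluded[Fi])
})

test_that("PMI matches closed forms for nesting and self co-occurrence", {
  set.seed(6)
  n <- 10000
  a <- runif(n) < 0.5
  b <- runif(n) < 0.5
  pres <- cbind(A = a, B = b)
  pmi <- pmi_cooccurrence(pres)
  se <- 3 * sqrt((1 / 0.25 - 1) / n)  # delta-method scale for log ratio
  expect_lt(abs(pmi["A", "B"]), 3 * se)
  # j present in every clade containing i -> PMI = log(1 / P(j))
  j <- a | (runif(n) < 0.3)
  pres2 <- cbind(I = a, J = j)
  pmi2 <- pmi_cooccurrence(pres2)
  expect_equal(pmi2["I", "J"], log(1 / mean(j)))
  expect_equal(pmi2["I", "I"], log(1 / mean(a)))
  # never co-occurring -> -Inf; absent category -> NA flagged
  pres3 <- cbind(X = c(TRUE, FALSE), Y = c(FALSE, TRUE), Z = c(FALSE, FALSE))
  pmi3 <- pmi_cooccurrence(pres3)
  expect_equal(pmi3["X", "Y"], -Inf)
  expect_true(all(is.na(pmi3["Z", ])))
  expect_equal(attr(pmi3, "undefined_categories"), "Z")
})

test_that("bipotency curves match independent planting", {
  set.seed(7)
  n_clades <- 4000
  days <- runif(n_clades, 4, 6)
  cl <- data.frame(node = seq_len(n_clades), node_id = as.character(seq_len(n_clades)),
                   fate = "nc", purity = 1, restriction_day = days,
                   n_descendants = 2, via_multifurcation = FALSE)
  # members: each clade gets its own leaves; plant A and B independently 0.3
  members <- lapply(seq_len(n_clades), function(i) {
    out <- c()
    if (runif(1) < 0.3) out <- c(out, paste0("a", i))
    if (runif(1) < 0.3) out <- c(out, paste0("b", i))
    if (length(out) == 0) out <- paste0("n", i)
    out
  })
  attr(cl, "members") <- members
  labs <- unlist(lapply(members, function(m) m))
  lab <- setNames(ifelse(grepl("^a", labs), "A",
                         ifelse(grepl("^b", labs), "B", "none")), labs)
  tr <- balanced4_tree()  # unused by curves (no trajectories requested)
  bc <- bipotency_curves(tr, cl, lab, "A", "B", bin_width = 10)
  expect_equal(nrow(bc$curves), 1)
  ci <- qnorm(0.995) * sqrt(0.09 * 0.91 / n_clades)
  expect_lt(abs(bc$curves$p_both - 0.09), ci + 0.01)
  expect_equal(bc$curves$expected, bc$curves$p_a * bc$curves$p_b)
  # clade containing only A counts toward P(A), not P(A and B)
  one <- cl[1, ]; attr(one, "members") <- list("solo")
  bco <- bipotency_curves(tr, one, c(solo = "A"), "A", "B")
  expect_equal(bco$curves$p_a, 1)
  expect_equal(bco$curves$p_both, 0)
})

test_that("well-separated fate-distribution clusters yield two motifs", {
  # build a tree whose early nodes split into two clean composition groups
  cfg <- sim_config(seed = 55, sampling_day = 8)
  tr <- sim_tree_sized(cfg, 300, 900, start_seed = 6)$tree
  kids <- tree_children(tr)
  root <- tree_root(tr)
  stem <- kids[[root]][1]
  halves <- kids[[stem]]
  while (length(halves) == 1) halves <- kids[[halves]]
  ids <- tr$label[tree_leaves(tr)]
  lab <- setNames(rep("typeA", length(ids)), ids)
  lab[tr$label[tree_leaf_sets(tr, halves[1])]] <- "typeB"
  fm <- fate_bias_motifs(tr, lab, max_day = 8.5, min_descendants = 10,
                         k = 10, seed = 1)
  # the two pure composition groups are coherent and mutually distinct
  # (mixed-composition ancestors above the split are left unconstrained)
  sub1 <- c(halves[1], lintrace:::which_descendants(tr, halves[1]))
  sub2 <- c(halves[2], lintrace:::which_descendants(tr, halves[2]))
  m1 <- fm$nodes$motif[fm$nodes$node %in% sub1]
  m2 <- fm$nodes$motif[fm$nodes$node %in% sub2]
  expect_equal(length(unique(m1)), 1)
  expect_equal(length(unique(m2)), 1)
  expect_false(unique(m1) == unique(m2))
  expect_equal(max(fm$trajectories), 1)  # normalized to the global max
  expect_error(fate_bias_motifs(tr, lab, max_day = 2.1, k = 20),
               "qualifying")
})

test_that("nodes below the descendant floor are excluded from motifs", {
  cfg <- sim_config(seed = 56, sampling_day = 8)
  tr <- sim_tree_sized(cfg, 200, 900, start_seed = 6)$tree
  ids <- tr$label[tree_leaves(tr)]
  set.seed(1)
  lab <- setNames(sample(c("u", "v"), length(ids), TRUE), ids)
  fm <- fate_bias_motifs(tr, lab, max_day = 8.5, min_descendants = 50,
                         k = 5, seed = 1)
  expect_true(all(fm$nodes$n_desc >= 50))
})
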