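#' Descendant fate distributions at every node
#'
#' Tallies, for every node, the number of descendant leaves in each fate
#' category by a single postorder aggregation; a leaf's distribution is a
#' point mass on its own label.
#'
#' @param tree rooted `lineage_tree`.
#' @param labels named character vector (or factor) of leaf fate labels,
#'   names = leaf cell IDs. Every leaf must be labeled.
#' @param categories optional category order; defaults to sorted unique
#'   labels.
#' @return list with `counts` (nodes x categories integer matrix), `props`
#'   (row-normalized), `n_desc` (per-node descendant leaf count).
#' @export
node_fate_distributions <- function(tree, labels, categories = NULL) {
  leaves <- tree_leaves(tree)
  ids <- tree$label[leaves]
  miss <- setdiff(ids, names(labels))
  if (length(miss) > 0)
    stop("unlabeled leaves: ", paste(utils::head(miss, 5), collapse = ", "),
         if (length(miss) > 5) sprintf(" (+%d more)", length(miss) - 5) else "")
  lab <- as.character(labels[ids])
  if (is.null(categories)) categories <- sort(unique(lab))
  n <- tree$n_node
  C <- matrix(0L, n, length(categories),
              dimnames = list(tree$label, categories))
  C[cbind(leaves, match(lab, categories))] <- 1L
  for (v in n:2) {
    p <- tree$parent[v]
    C[p, ] <- C[p, ] + C[v, ]
  }
  n_desc <- rowSums(C)
  list(counts = C, props = C / pmax(n_desc, 1), n_desc = n_desc)
}

#' Entropy-based fate bias score
#'
#' `1 - H(p) / H(q)` where `H` is the plug-in Shannon entropy (`0 log 0 = 0`)
#' and `q` is the root distribution of the same tree. 0 means the node's
#' distribution matches the root composition; 1 means complete restriction
#' to one fate. Entropies are computed on the union support, and the score
#' is clipped to \[0, 1\] (a node can be more even than the root on categories
#' the root lacks). A degenerate single-category root is an error.
#'
#' @param p numeric vector of proportions (a node's fate distribution).
#' @param q_root root fate distribution on the same (or a super-) support.
#' @return scalar in \[0, 1\].
#' @export
fate_bias <- function(p, q_root) {
  Hq <- plugin_entropy(q_root)
  if (Hq <= 0) stop("degenerate root distribution: fate bias undefined")
  min(1, max(0, 1 - plugin_entropy(p) / Hq))
}

plugin_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Assign node values to half-open time bins along incoming branches
#'
#' A node contributes its value to every bin whose representative time (the
#' bin's left edge) lies in `[parent_day, node_day)`; the root contributes
#' from `origin_day`. Weighted per-bin summaries use `weights` (typically
#' descendant counts).
#'
#' @param tree dated `lineage_tree`.
#' @param values numeric vector over nodes.
#' @param bin_width bin width in days (default 0.5).
#' @param weights per-node weights (default descendant leaf counts).
#' @param origin_day day the root's own interval starts (default the root's
#'   time).
#' @return data.frame with `bin` (left edge), `mean` (weighted mean of
#'   contributing node values), `n_nodes`, `weight`.
#' @export
expand_time_bins <- function(tree, values, bin_width = 0.5, weights = NULL,
                             origin_day = NULL) {
  if (is.null(weights)) weights <- tree_n_leaves(tree)
  inc <- bin_incidence(tree, bin_width, origin_day)
  members <- lapply(inc$members, function(m) m[!is.na(values[m])])
  out <- data.frame(bin = inc$bins)
  out$mean <- vapply(members, function(m)
    if (length(m) == 0) NA_real_ else
      sum(values[m] * weights[m]) / sum(weights[m]), numeric(1))
  out$n_nodes <- lengths(members)
  out$weight <- vapply(members, function(m) sum(weights[m]), numeric(1))
  out
}

# internal: bins (left edges) and the node sets contributing to each
bin_incidence <- function(tree, bin_width = 0.5, origin_day = NULL) {
  root <- tree_root(tree)
  if (is.null(origin_day)) origin_day <- tree$time[root]
  start <- ifelse(is.na(tree$parent), origin_day, tree$time[tree$parent])
  end <- tree$time
  lo <- floor(min(start) / bin_width) * bin_width
  hi <- max(end)
  bins <- seq(lo, hi, by = bin_width)
  members <- lapply(bins, function(b)
    which(start <= b & (b < end | (b == end & end == start))))
  list(bins = bins, members = members)
}

#' Permutation test for binned weighted mean fate bias
#'
#' The observed statistic is the descendant-weighted mean fate bias per time
#' bin. The null preserves each node's descendant count and the overall root
#' distribution: each permutation redraws every node's fate counts as a
#' multinomial sample of its `n_desc` labels from the root distribution, and
#' the binned statistic is recomputed. P-values use the add-one correction
#' and are one-sided upper.
#'
#' @param tree dated `lineage_tree`.
#' @param labels named leaf fate labels.
#' @param n_perm number of permutations (default 100, minimum 2).
#' @param bin_width bin width in days.
#' @param seed optional seed.
#' @return data.frame per bin: `bin`, `observed`, `null_mean`, `null_lo`,
#'   `null_hi` (null range), `p`; attribute `null` holds the full null
#'   matrix (bins x permutations).
#' @export
bias_permutation_test <- function(tree, labels, n_perm = 100,
                                  bin_width = 0.5, seed = NULL) {
  if (n_perm < 2) stop("need at least 2 permutations")
  if (!is.null(seed)) set.seed(seed)
  fd <- node_fate_distributions(tree, labels)
  root <- tree_root(tree)
  q <- fd$props[root, ]
  w <- fd$n_desc
  inc <- bin_incidence(tree, bin_width)
  bias <- apply(fd$props, 1, fate_bias, q_root = q)
  binned <- function(b) vapply(inc$members, function(m)
    if (length(m) == 0) NA_real_ else
      sum(b[m] * w[m]) / sum(w[m]), numeric(1))
  obs <- binned(bias)
  nullmat <- matrix(NA_real_, length(inc$bins), n_perm)
  n <- tree$n_node
  for (k in seq_len(n_perm)) {
    cnt <- t(vapply(w, function(m) stats::rmultinom(1, m, q)[, 1],
                    numeric(length(q))))
    props <- cnt / pmax(rowSums(cnt), 1)
    b <- apply(props, 1, fate_bias, q_root = q)
    nullmat[, k] <- binned(b)
  }
  p <- vapply(seq_along(obs), function(i) {
    nv <- nullmat[i, !is.na(nullmat[i, ])]
    if (is.na(obs[i]) || length(nv) == 0) return(NA_real_)
    (1 + sum(nv >= obs[i])) / (length(nv) + 1)
  }, numeric(1))
  out <- data.frame(bin = inc$bins, observed = obs,
                    null_mean = rowMeans(nullmat, na.rm = TRUE),
                    null_lo = apply(nullmat, 1, function(x)
                      suppressWarnings(min(x, na.rm = TRUE))),
                    null_hi = apply(nullmat, 1, function(x)
                      suppressWarnings(max(x, na.rm = TRUE))),
                    p = p)
  attr(out, "null") <- nullmat
  out
}

#' Identify fate-restricted clades
#'
#' Two-pass procedure per fate: pass 1 marks every node whose descendants
#' are at least `purity` one fate; pass 2 walks root-down and keeps only the
#' highest qualifying node, excluding its descendants from further selection
#' for that fate. At a node with more than two children where two or more
#' child branches independently qualify for the same fate, the parent is
#' selected once for those children (`via_multifurcation = TRUE`), the most
#' parsimonious single restriction event at an unresolved split; its
#' restriction day is the parent node's day.
#'
#' @param tree dated `lineage_tree`.
#' @param labels named leaf fate labels.
#' @param purity minimum descendant purity (default 0.9).
#' @param min_descendants smallest clade reported (default 2; single leaves
#'   are trivially pure).
#' @return data.frame with `node`, `node_id`, `fate`, `purity`,
#'   `restriction_day`, `n_descendants`, `via_multifurcation`; attribute
#'   `members` is a list of leaf-label vectors per clade.
#' @export
find_restricted_clades <- function(tree, labels, purity = 0.9,
                                   min_descendants = 2) {
  fd <- node_fate_distributions(tree, labels)
  cats <- colnames(fd$counts)
  kids <- tree_children(tree)
  qual <- fd$props >= purity & fd$counts > 0
  res <- list()
  members <- list()
  for (f in cats) {
    blocked <- rep(FALSE, tree$n_node)
    for (v in seq_len(tree$n_node)) {   # preorder
      if (blocked[v]) { next }
      if (!is.na(tree$parent[v]) && blocked[tree$parent[v]]) {
        blocked[v] <- TRUE; next
      }
      if (qual[v, f] && fd$n_desc[v] >= min_descendants) {
        res[[length(res) + 1]] <- data.frame(
          node = v, node_id = tree$label[v], fate = f,
          purity = fd$props[v, f], restriction_day = tree$time[v],
          n_descendants = fd$n_desc[v], via_multifurcation = FALSE)
        members[[length(members) + 1]] <-
          tree$label[tree_leaf_sets(tree, v)]
        blocked[v] <- TRUE
      } else if (length(kids[[v]]) > 2) {
        qc <- kids[[v]][qual[kids[[v]], f] &
                          fd$n_desc[kids[[v]]] >= 1]
        if (length(qc) >= 2 && sum(fd$n_desc[qc]) >= min_descendants) {
          cnt <- sum(fd$counts[qc, f]); tot <- sum(fd$n_desc[qc])
          res[[length(res) + 1]] <- data.frame(
            node = v, node_id = tree$label[v], fate = f,
            purity = cnt / tot, restriction_day = tree$time[v],
            n_descendants = tot, via_multifurcation = TRUE)
          members[[length(members) + 1]] <- tree$label[sort(unlist(
            lapply(qc, function(c) tree_leaf_sets(tree, c))))]
          for (c0 in qc) blocked[c0] <- TRUE
        }
      }
    }
  }
  out <- if (length(res) > 0) do.call(rbind, res) else
    data.frame(node = integer(0), node_id = character(0), fate = character(0),
               purity = numeric(0), restriction_day = numeric(0),
               n_descendants = numeric(0), via_multifurcation = logical(0))
  rownames(out) <- NULL
  attr(out, "members") <- members
  out
}

#' Sibling composition of fate-restricted clades
#'
#' For each restricted clade, siblings are the descendants of the parent
#' node excluding the focal clade (for multifurcation-selected clades, the
#' same node's non-focal descendants). Sibling groups more than
#' `size_ratio_cap` times larger than the focal clade are excluded to keep
#' comparable lineage depth. Composition is tallied per category and a
#' global fold enrichment (sibling frequency over background frequency
#' across all leaves) is reported; categories absent globally give `NA`.
#'
#' @param tree dated `lineage_tree`.
#' @param clades output of [find_restricted_clades()].
#' @param labels named leaf category labels (may differ from the fate labels
#'   that defined the clades).
#' @param size_ratio_cap maximum sibling/focal size ratio (default 10).
#' @return list with `per_clade` (data.frame clade index, sibling size,
#'   excluded flag), `composition` (clade x category sibling counts) and
#'   `enrichment` (named vector of fold enrichments over the global
#'   frequencies).
#' @export
sibling_outputs <- function(tree, clades, labels, size_ratio_cap = 10) {
  members <- attr(clades, "members")
  leaves <- tree_leaves(tree)
  ids <- tree$label[leaves]
  lab <- as.character(labels[ids])
  cats <- sort(unique(lab))
  glob <- table(factor(lab, cats)) / length(lab)
  comp <- matrix(0L, nrow(clades), length(cats),
                 dimnames = list(NULL, cats))
  sizes <- integer(nrow(clades)); excl <- logical(nrow(clades))
  for (i in seq_len(nrow(clades))) {
    v <- clades$node[i]
    anchor <- if (clades$via_multifurcation[i]) v else tree$parent[v]
    if (is.na(anchor)) { excl[i] <- TRUE; next }  # root clade: no sibling
    sib <- setdiff(tree$label[tree_leaf_sets(tree, anchor)], members[[i]])
    sizes[i] <- length(sib)
    if (length(sib) == 0 ||
        length(sib) > size_ratio_cap * clades$n_descendants[i]) {
      excl[i] <- TRUE; next
    }
    comp[i, ] <- table(factor(labels[sib], cats))
  }
  tot <- colSums(comp[!excl, , drop = FALSE])
  freq <- tot / max(sum(tot), 1)
  enr <- ifelse(glob > 0, freq / as.numeric(glob), NA_real_)
  names(enr) <- cats
  list(per_clade = data.frame(clade = seq_len(nrow(clades)),
                              sibling_size = sizes, excluded = excl),
       composition = comp, enrichment = enr)
}

#' Clade co-occurrence by pointwise mutual information
#'
#' Treats each clade as a unit and scores every category pair by
#' `PMI(i, j) = log P(i, j) / (P(i) P(j))` over the clade-by-category
#' presence matrix. Pairs never co-occurring give `-Inf`; categories present
#' in no clade give `NA` rows/columns (flagged).
#'
#' @param presence logical or 0/1 matrix, clades x categories.
#' @return numeric PMI matrix with attribute `undefined_categories`.
#' @export
pmi_cooccurrence <- function(presence) {
  if (nrow(presence) < 1) stop("need at least one clade")
  P <- crossprod(matrix(as.numeric(presence > 0), nrow(presence))) /
    nrow(presence)
  colnames(P) <- rownames(P) <- colnames(presence)
  marg <- diag(P)
  pmi <- log(P / outer(marg, marg))
  bad <- names(marg)[marg == 0]
  pmi[marg == 0, ] <- NA_real_
  pmi[, marg == 0] <- NA_real_
  attr(pmi, "undefined_categories") <- bad
  pmi
}

#' Clade presence matrix for categories
#'
#' @param clades output of [find_restricted_clades()].
#' @param labels named leaf category labels.
#' @param categories optional category set.
#' @return logical matrix clades x categories: category present among the
#'   clade's descendants.
#' @export
clade_presence <- function(clades, labels, categories = NULL) {
  members <- attr(clades, "members")
  if (is.null(categories)) categories <- sort(unique(as.character(labels)))
  out <- t(vapply(members, function(m)
    categories %in% unique(as.character(labels[m])),
    logical(length(categories))))
  colnames(out) <- categories
  out
}

#' Bipotency curves for two output categories
#'
#' Bins restricted clades by restriction day and reports, per bin, the
#' fraction of clades containing each output category, the fraction
#' containing both (bipotent), and the product of the marginals (the
#' expectation under independence). Optionally returns recentered fate-bias
#' trajectories for the bipotent clades: within each bipotent clade, the
#' fate bias of the two outputs (progenitor category excluded) is expanded
#' over time bins and recentered to time-since-restriction.
#'
#' @param tree dated `lineage_tree`.
#' @param clades restricted clades (e.g. all clades of one progenitor fate).
#' @param labels named leaf output-category labels.
#' @param cat_a,cat_b the two output categories.
#' @param bin_width restriction-day bin width (default 0.5).
#' @param trajectories if TRUE, compute recentered bias trajectories.
#' @param progenitor optional label of undifferentiated cells, excluded from
#'   trajectory distributions.
#' @return list with `curves` (data.frame bin, n_clades, p_a, p_b, p_both,
#'   expected) and `trajectories` (data.frame clade, time_since_restriction,
#'   bias; NULL unless requested). Empty bins are absent (missing, not
#'   zero).
#' @export
bipotency_curves <- function(tree, clades, labels, cat_a, cat_b,
                             bin_width = 0.5, trajectories = FALSE,
                             progenitor = NULL) {
  members <- attr(clades, "members")
  has <- function(m, cat) any(labels[m] == cat, na.rm = TRUE)
  has_a <- vapply(members, has, logical(1), cat = cat_a)
  has_b <- vapply(members, has, logical(1), cat = cat_b)
  bin <- floor(clades$restriction_day / bin_width) * bin_width
  ub <- sort(unique(bin))
  curves <- data.frame(
    bin = ub,
    n_clades = vapply(ub, function(b) sum(bin == b), numeric(1)),
    p_a = vapply(ub, function(b) mean(has_a[bin == b]), numeric(1)),
    p_b = vapply(ub, function(b) mean(has_b[bin == b]), numeric(1)),
    p_both = vapply(ub, function(b) mean((has_a & has_b)[bin == b]),
                    numeric(1)))
  curves$expected <- curves$p_a * curves$p_b
  traj <- NULL
  if (trajectories) {
    rows <- list()
    for (i in which(has_a & has_b)) {
      sub <- extract_subtree(tree, clades$node[i])
      lv <- sub$label[tree_leaves(sub)]
      lab2 <- as.character(labels[lv])
      lab3 <- ifelse(!is.na(lab2) & lab2 %in% c(cat_a, cat_b), lab2,
                     "__other__")
      names(lab3) <- lv
      fd <- node_fate_distributions(sub, lab3,
                                    categories = c(cat_a, cat_b, "__other__"))
      # bias over the two outputs only (progenitor/other excluded); nodes
      # with no output descendants get NA
      out_counts <- fd$counts[, c(cat_a, cat_b), drop = FALSE]
      out_n <- rowSums(out_counts)
      bias <- vapply(seq_len(nrow(out_counts)), function(j) {
        if (out_n[j] == 0) return(NA_real_)
        p <- out_counts[j, ] / out_n[j]
        min(1, max(0, 1 - plugin_entropy(p) / log(2)))
      }, numeric(1))
      eb <- expand_time_bins(sub, bias, bin_width = bin_width,
                             weights = pmax(out_n, 1e-9))
      eb <- eb[!is.na(eb$mean), , drop = FALSE]
      if (nrow(eb) > 0)
        rows[[length(rows) + 1]] <- data.frame(
          clade = i,
          time_since_restriction = eb$bin - clades$restriction_day[i],
          bias = eb$mean)
    }
    traj <- if (length(rows) > 0) do.call(rbind, rows) else NULL
  }
  list(curves = curves, trajectories = traj)
}

#' Fate-bias motifs among early ancestral nodes
#'
#' Nodes with inferred day at most `max_day` and at least `min_descendants`
#' descendant cells are embedded by their fate-proportion vectors; a k-NN
#' graph (Euclidean) is clustered with the Leiden algorithm
#' (modularity objective) at the given resolution. Per motif and time bin,
#' the descendant-weighted fate bias is summed and the whole matrix is
#' normalized to its maximum.
#'
#' @param tree dated `lineage_tree`.
#' @param labels named leaf fate labels.
#' @param max_day latest node day considered.
#' @param min_descendants minimum descendant cells per node (default 50).
#' @param k neighbors in the k-NN graph (default 20).
#' @param resolution Leiden resolution (default 0.5).
#' @param bin_width time-bin width for the motif trajectories.
#' @param seed optional seed (community detection is stochastic).
#' @return list with `nodes` (data.frame node, day, n_desc, motif) and
#'   `trajectories` (motif x bin matrix of weighted bias, max-normalized).
#' @export
fate_bias_motifs <- function(tree, labels, max_day, min_descendants = 50,
                             k = 20, resolution = 0.5, bin_width = 0.5,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fd <- node_fate_distributions(tree, labels)
  sel <- which(tree$time <= max_day & fd$n_desc >= min_descendants)
  if (length(sel) < k + 1)
    stop(sprintf("only %d qualifying nodes; need at least k + 1 = %d",
                 length(sel), k + 1))
  X <- fd$props[sel, , drop = FALSE]
  D <- as.matrix(stats::dist(X))
  edges <- list()
  for (i in seq_along(sel)) {
    nn <- order(D[i, ])[2:(k + 1)]
    edges[[i]] <- cbind(i, nn)
  }
  em <- unique(t(apply(do.call(rbind, edges), 1, sort)))
  g <- igraph::graph_from_edgelist(em, directed = FALSE)
  cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                               resolution = resolution, n_iterations = 5)
  motif <- igraph::membership(cl)
  root <- tree_root(tree)
  q <- fd$props[root, ]
  bias <- apply(fd$props, 1, fate_bias, q_root = q)
  inc <- bin_incidence(tree, bin_width)
  motifs <- sort(unique(motif))
  traj <- matrix(0, length(motifs), length(inc$bins),
                 dimnames = list(paste0("motif_", motifs), inc$bins))
  for (mi in seq_along(motifs)) {
    nodes_m <- sel[motif == motifs[mi]]
    for (bi in seq_along(inc$bins)) {
      m <- intersect(inc$members[[bi]], nodes_m)
      if (length(m) > 0)
        traj[mi, bi] <- sum(bias[m] * fd$n_desc[m])
    }
  }
  if (max(traj) > 0) traj <- traj / max(traj)
  list(nodes = data.frame(node = sel, day = tree$time[sel],
                          n_desc = fd$n_desc[sel],
                          motif = as.integer(motif)),
       trajectories = traj)
}
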