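#' Rate model for branch-length estimation
#'
#' Per-character relative editing-rate multipliers (default the
#' (0.3, 0.4, 1.2) cycle across sites), a per-edge pseudocount of edits, and
#' a free global scale (fixed by time calibration).
#'
#' @param n_characters number of characters.
#' @param relative_rates positive multipliers recycled across characters.
#' @param pseudocount edits added to every edge (default 1).
#' @return list of class `rate_model`.
#' @export
rate_model <- function(n_characters, relative_rates = c(0.3, 0.4, 1.2),
                       pseudocount = 1) {
  if (any(relative_rates <= 0)) stop("relative rates must be > 0")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  structure(list(rates = rep(relative_rates, length.out = n_characters),
                 pseudocount = pseudocount),
            class = "rate_model")
}

#' Sankoff ancestral state reconstruction for irreversible characters
#'
#' Minimum-cost ancestral labeling under the recorder model: an
#' unedited-to-mark transition costs 1, any change away from an installed
#' mark is forbidden (infinite cost), and missing leaf states impose no cost
#' for any parent state. The root is forced unedited and ties are resolved
#' toward the unedited state, pushing edits tipward.
#'
#' @param tree rooted `lineage_tree`.
#' @param matrix integer character matrix whose rows cover the tree's leaf
#'   labels (0 = unedited, 1..M marks, NA missing).
#' @return integer matrix nodes x characters of reconstructed states (leaf
#'   rows repeat the observations; missing leaf states are imputed).
#' @export
sankoff_ancestral <- function(tree, matrix) {
  if (!inherits(tree, "lineage_tree")) stop("need a rooted lineage_tree")
  leaves <- tree_leaves(tree)
  if (!all(tree$label[leaves] %in% rownames(matrix)))
    stop("matrix does not cover all tree leaves")
  M <- matrix[tree$label[leaves], , drop = FALSE]
  nchar <- ncol(M)
  nstate <- max(1L, max(M, na.rm = TRUE)) + 1L  # states 0..max mark
  n <- tree$n_node
  kids <- tree_children(tree)
  BIG <- 1e9
  # cost[[v]] is nstate x nchar
  cost <- vector("list", n)
  leafrow <- integer(n); leafrow[leaves] <- seq_along(leaves)
  for (v in n:1) {
    if (length(kids[[v]]) == 0) {
      C <- matrix(BIG, nstate, nchar)
      s <- M[leafrow[v], ]
      miss <- is.na(s)
      C[, miss] <- 0
      C[cbind(s[!miss] + 1L, which(!miss))] <- 0
      cost[[v]] <- C
    } else {
      C <- matrix(0, nstate, nchar)
      for (ch in kids[[v]]) {
        Cc <- cost[[ch]]
        # from unedited: stay (cost Cc[1,]) or one edit into any mark
        mark_min <- if (nstate > 1)
          apply(Cc[-1, , drop = FALSE], 2, min) else rep(BIG, nchar)
        contrib <- rbind(pmin(Cc[1, ], 1 + mark_min),
                         Cc[-1, , drop = FALSE])  # from mark m: must stay m
        C <- C + contrib
      }
      cost[[v]] <- pmin(C, BIG)
    }
  }
  states <- matrix(0L, n, nchar, dimnames = list(tree$label, colnames(M)))
  # root forced unedited
  for (v in seq_len(n)) {
    if (length(kids[[v]]) == 0) next
    sv <- states[v, ]
    for (ch in kids[[v]]) {
      Cc <- cost[[ch]]
      sc <- sv  # marks are inherited unchanged
      ue <- which(sv == 0L)
      if (length(ue) > 0) {
        stay <- Cc[1, ue]
        if (nstate > 1) {
          marks <- Cc[-1, ue, drop = FALSE]
          best_mark <- apply(marks, 2, which.min)
          best_cost <- marks[cbind(best_mark, seq_along(ue))] + 1
          # tie resolved toward unedited
          pick <- ifelse(stay <= best_cost, 0L, as.integer(best_mark))
        } else pick <- rep(0L, length(ue))
        sc[ue] <- pick
      }
      states[ch, ] <- sc
    }
  }
  states
}

#' Minimum parsimony cost implied by a Sankoff reconstruction
#' @param tree rooted `lineage_tree`.
#' @param states node x character state matrix (see [sankoff_ancestral()]).
#' @return total number of edits across all edges.
#' @export
parsimony_cost <- function(tree, states) {
  ch <- which(!is.na(tree$parent))
  sum(vapply(ch, function(v)
    sum(states[tree$parent[v], ] == 0L & states[v, ] > 0L), numeric(1)))
}

#' Per-edge inferred mutation counts
#' @inheritParams parsimony_cost
#' @return integer vector indexed by child node (0 for the root).
#' @export
edge_mutations <- function(tree, states) {
  out <- integer(tree$n_node)
  ch <- which(!is.na(tree$parent))
  for (v in ch)
    out[v] <- sum(states[tree$parent[v], ] == 0L & states[v, ] > 0L)
  out
}

#' Collapse mutationless internal edges
#'
#' Removes internal edges with zero inferred state changes, promoting the
#' child's children to the parent; leaf edges are never collapsed. The
#' result is a multifurcating tree. Idempotent.
#'
#' @param tree rooted `lineage_tree`.
#' @param states node x character ancestral states from
#'   [sankoff_ancestral()].
#' @return list with `tree` (collapsed `lineage_tree`), `states` (rows for
#'   kept nodes), `mutations` (per-edge counts indexed by child), and
#'   `node_map` (old node index of every kept node).
#' @export
collapse_mutationless <- function(tree, states) {
  muts <- edge_mutations(tree, states)
  leaves <- tree_leaves(tree)
  is_leaf <- seq_len(tree$n_node) %in% leaves
  drop <- !is_leaf & !is.na(tree$parent) & muts == 0
  # re-point parents through dropped nodes (preorder: parents resolved first)
  newpar <- tree$parent
  for (v in seq_len(tree$n_node)) {
    p <- newpar[v]
    while (!is.na(p) && drop[p]) p <- newpar[p]
    newpar[v] <- p
  }
  keep <- which(!drop)
  newid <- integer(tree$n_node); newid[keep] <- seq_along(keep)
  parent <- ifelse(is.na(newpar[keep]), NA_integer_, newid[newpar[keep]])
  out <- lineage_tree(as.integer(parent), tree$time[keep], tree$label[keep])
  st <- states[keep, , drop = FALSE]
  m2 <- edge_mutations(out, st)
  list(tree = out, states = st, mutations = m2, node_map = keep)
}

#' Maximum-likelihood branch lengths under the exponential editing model
#'
#' Models edits as independent exponential processes across characters: a
#' character at risk on an edge (unedited at the parent and observed in at
#' least one leaf below) is edited with probability `1 - exp(-r_c * t)` and
#' survives unedited otherwise. Edge lengths maximize
#' `sum(log(1 - exp(-r_c t)))` over edited characters minus `sum(r_c t)`
#' over surviving characters, with `pseudocount` extra edits (at the mean
#' at-risk rate) per edge. Because edges are conditionally independent given
#' the ancestral states, the joint optimum is found by safeguarded per-edge
#' Newton iterations; the objective is concave in each length.
#'
#' @param tree rooted (possibly multifurcating) `lineage_tree`.
#' @param states ancestral states (nodes x characters).
#' @param model a [rate_model()].
#' @param leaf_observed optional logical matrix (leaves x characters) marking
#'   states observed in the leaf data; defaults to non-missing entries of
#'   `states` leaf rows. Characters missing below an edge are excluded from
#'   both likelihood terms.
#' @param tol convergence tolerance on edge lengths (default 1e-8).
#' @param max_iter maximum Newton sweeps (default 200).
#' @return numeric vector of edge lengths indexed by child node (0 at the
#'   root), with attributes `flagged` (children of edges with no at-risk
#'   characters) and `iterations`.
#' @export
ml_branch_lengths <- function(tree, states, model,
                              leaf_observed = NULL, tol = 1e-8,
                              max_iter = 200) {
  n <- tree$n_node
  leaves <- tree_leaves(tree)
  r <- model$rates
  if (length(r) != ncol(states))
    stop("rate model does not match the number of characters")
  if (is.null(leaf_observed)) {
    leaf_observed <- !is.na(states[leaves, , drop = FALSE])
  }
  # obs_below[v, c]: character observed in >= 1 leaf of v's subtree
  obs_below <- matrix(FALSE, n, ncol(states))
  obs_below[leaves, ] <- leaf_observed[match(tree$label[leaves],
                                             rownames(leaf_observed)), ,
                                       drop = FALSE]
  for (v in n:2) {
    p <- tree$parent[v]
    obs_below[p, ] <- obs_below[p, ] | obs_below[v, ]
  }
  ch <- which(!is.na(tree$parent))
  len <- numeric(n)
  flagged <- integer(0)
  iters <- 0L
  edge_info <- lapply(ch, function(v) {
    p <- tree$parent[v]
    at_risk <- states[p, ] == 0L & obs_below[v, ]
    edited <- at_risk & states[v, ] > 0L
    list(v = v, r_ed = r[edited], R_surv = sum(r[at_risk & !edited]),
         rbar = if (any(at_risk)) mean(r[at_risk]) else mean(r),
         n_at_risk = sum(at_risk))
  })
  solve_edge <- function(e) {
    pc <- model$pseudocount
    if (e$n_at_risk == 0) {
      flagged <<- c(flagged, e$v)
      return(if (pc > 0) pc / e$rbar else 0)
    }
    r_ed <- e$r_ed
    if (pc > 0) r_ed <- c(r_ed, rep(e$rbar, 1) )  # weight handled below
    w_ed <- c(rep(1, length(e$r_ed)), if (pc > 0) pc else NULL)
    if (length(r_ed) == 0) return(0)
    if (e$R_surv == 0) {
      flagged <<- c(flagged, e$v)
      return((length(e$r_ed) + pc) / e$rbar)
    }
    f <- function(t) sum(w_ed * r_ed * exp(-r_ed * t) /
                           (1 - exp(-r_ed * t))) - e$R_surv
    # bracket: f decreasing, f(0+) = +Inf
    hi <- 1
    while (f(hi) > 0 && hi < 1e6) hi <- hi * 2
    lo <- hi / 1e8
    while (f(lo) < 0 && lo > 1e-12) lo <- lo / 10
    t <- 0.5 * (lo + hi)
    for (it in 1:100) {
      ft <- f(t)
      if (ft > 0) lo <- t else hi <- t
      ex <- exp(-r_ed * t)
      fp <- -sum(w_ed * r_ed^2 * ex / (1 - ex)^2)
      t_new <- t - ft / fp
      if (!is.finite(t_new) || t_new <= lo || t_new >= hi)
        t_new <- 0.5 * (lo + hi)
      if (abs(t_new - t) < tol * max(1, t)) { t <- t_new; break }
      t <- t_new
    }
    t
  }
  prev <- rep(Inf, length(edge_info))
  for (sweep in seq_len(max_iter)) {
    iters <- sweep
    cur <- vapply(edge_info, solve_edge, numeric(1))
    if (max(abs(cur - prev)) < tol) { prev <- cur; break }
    prev <- cur
  }
  len[ch] <- prev
  structure(len, flagged = unique(flagged), iterations = iters)
}

#' Joint maximum-likelihood node times under the ultrametric constraint
#'
#' The joint alternative to free per-edge lengths: node times are optimized
#' directly with the root fixed at depth 0 and every leaf fixed at depth 1,
#' maximizing the same exponential-editing likelihood. The objective is
#' concave in each node time given the others, so coordinate ascent with 1-D
#' optimization converges to the joint optimum; constraining leaves to a
#' common depth pools information across paths and substantially stabilizes
#' node-day estimates on large trees.
#'
#' @inheritParams ml_branch_lengths
#' @param tol convergence tolerance on node times (default 1e-6).
#' @param max_sweeps maximum coordinate sweeps (default 50).
#' @return numeric vector of relative node depths in \[0, 1\] (leaves at 1),
#'   with attribute `sweeps`.
#' @export
ml_node_times <- function(tree, states, model, leaf_observed = NULL,
                          tol = 1e-6, max_sweeps = 50) {
  n <- tree$n_node
  leaves <- tree_leaves(tree)
  r <- model$rates
  if (is.null(leaf_observed))
    leaf_observed <- !is.na(states[leaves, , drop = FALSE])
  obs_below <- matrix(FALSE, n, ncol(states))
  obs_below[leaves, ] <- leaf_observed[match(tree$label[leaves],
                                             rownames(leaf_observed)), ,
                                       drop = FALSE]
  for (v in n:2) {
    p <- tree$parent[v]
    obs_below[p, ] <- obs_below[p, ] | obs_below[v, ]
  }
  ch <- which(!is.na(tree$parent))
  r_ed <- vector("list", n); R_surv <- numeric(n); rbar <- numeric(n)
  for (v in ch) {
    p <- tree$parent[v]
    at_risk <- states[p, ] == 0L & obs_below[v, ]
    edited <- at_risk & states[v, ] > 0L
    r_ed[[v]] <- r[edited]
    R_surv[v] <- sum(r[at_risk & !edited])
    rbar[v] <- if (any(at_risk)) mean(r[at_risk]) else mean(r)
  }
  pc <- model$pseudocount
  edge_ll <- function(v, dt) {
    dt <- max(dt, 1e-9)
    sum(log1p(-exp(-r_ed[[v]] * dt))) +
      (if (pc > 0) pc * log1p(-exp(-rbar[v] * dt)) else 0) -
      R_surv[v] * dt
  }
  # init: depth fraction along each root-leaf path (monotone, leaves at 1)
  d_root <- integer(n)
  for (v in ch) d_root[v] <- d_root[tree$parent[v]] + 1L
  m_down <- integer(n)
  for (v in n:1) {
    p <- tree$parent[v]
    if (!is.na(p)) m_down[p] <- max(m_down[p], m_down[v] + 1L)
  }
  t_cur <- d_root / pmax(d_root + m_down, 1)
  t_cur[leaves] <- 1
  root <- tree_root(tree)
  t_cur[root] <- 0
  kids <- tree_children(tree)
  internal <- setdiff(which(d_root > 0), leaves)  # non-root internal nodes
  sweeps <- 0L
  # scale of time units: leaf depth 1 spans the true duration; editing rates
  # are relative, so depths are later calibrated to days
  for (s in seq_len(max_sweeps)) {
    sweeps <- s
    delta <- 0
    for (v in internal) {
      p <- tree$parent[v]
      lo <- t_cur[p]
      hi <- min(t_cur[kids[[v]]])
      if (hi - lo < 1e-9) next
      f <- function(t) edge_ll(v, t - lo) +
        sum(vapply(kids[[v]], function(c0) edge_ll(c0, t_cur[c0] - t),
                   numeric(1)))
      opt <- stats::optimize(f, c(lo + 1e-9, hi - 1e-9), maximum = TRUE,
                             tol = 1e-8)
      delta <- max(delta, abs(opt$maximum - t_cur[v]))
      t_cur[v] <- opt$maximum
    }
    if (delta < tol) break
  }
  structure(t_cur, sweeps = sweeps)
}

#' Log-likelihood of edge lengths under the editing model
#' @inheritParams ml_branch_lengths
#' @param lengths edge lengths indexed by child node.
#' @return scalar log-likelihood (pseudocount terms included).
#' @export
editing_loglik <- function(tree, states, model, lengths,
                           leaf_observed = NULL) {
  n <- tree$n_node
  leaves <- tree_leaves(tree)
  r <- model$rates
  if (is.null(leaf_observed))
    leaf_observed <- !is.na(states[leaves, , drop = FALSE])
  obs_below <- matrix(FALSE, n, ncol(states))
  obs_below[leaves, ] <- leaf_observed[match(tree$label[leaves],
                                             rownames(leaf_observed)), ,
                                       drop = FALSE]
  for (v in n:2) {
    p <- tree$parent[v]
    obs_below[p, ] <- obs_below[p, ] | obs_below[v, ]
  }
  ll <- 0
  for (v in which(!is.na(tree$parent))) {
    p <- tree$parent[v]
    t <- lengths[v]
    at_risk <- states[p, ] == 0L & obs_below[v, ]
    edited <- at_risk & states[v, ] > 0L
    rbar <- if (any(at_risk)) mean(r[at_risk]) else mean(r)
    if (t <= 0) { if (sum(edited) + model$pseudocount > 0) ll <- ll - Inf; next }
    ll <- ll + sum(log1p(-exp(-r[edited] * t))) +
      model$pseudocount * log1p(-exp(-rbar * t)) -
      sum(r[at_risk & !edited]) * t
  }
  ll
}

#' Calibrate branch lengths to embryonic days
#'
#' Multiplies all edge lengths by a single scalar so the maximum
#' root-to-leaf depth equals `sampling_day - origin_day`, then assigns each
#' node `origin_day + depth`. Leaves shallower than the maximum (estimation
#' noise) are reported, not stretched.
#'
#' @param tree rooted `lineage_tree` (topology source).
#' @param lengths edge lengths indexed by child node.
#' @param sampling_day embryonic day of sampling.
#' @param origin_day embryonic day of the root (default 0).
#' @return a dated `lineage_tree` with attributes `scale` and
#'   `shallow_leaves` (labels of leaves not reaching the sampling day).
#' @export
calibrate_times <- function(tree, lengths, sampling_day, origin_day = 0) {
  n <- tree$n_node
  depth <- numeric(n)
  for (v in seq_len(n)[-1]) depth[v] <- depth[tree$parent[v]] + lengths[v]
  leaves <- tree_leaves(tree)
  mx <- max(depth[leaves])
  if (mx <= 0) stop("zero total depth: cannot calibrate")
  scale <- (sampling_day - origin_day) / mx
  time <- origin_day + depth * scale
  out <- lineage_tree(tree$parent, time, tree$label)
  shallow <- leaves[depth[leaves] < mx - 1e-9]
  attr(out, "scale") <- scale
  attr(out, "shallow_leaves") <- tree$label[shallow]
  out
}

#' Convenience wrapper: ancestral states, collapse, lengths, calibration
#'
#' @param tree rooted `lineage_tree` (topology; times ignored).
#' @param matrix leaf character matrix.
#' @param sampling_day,origin_day calibration anchors.
#' @param model optional [rate_model()].
#' @param method `"ultrametric"` (joint node-time optimum, default) or
#'   `"free"` (independent per-edge lengths, rescaled by maximum depth).
#' @return list with `tree` (dated, collapsed), `states`, `mutations`
#'   (per-edge, indexed by child), `node_map`, `lengths`.
#' @export
date_tree <- function(tree, matrix, sampling_day, origin_day = 0,
                      model = NULL, method = c("ultrametric", "free")) {
  method <- match.arg(method)
  if (is.null(model)) model <- rate_model(ncol(matrix))
  states <- sankoff_ancestral(tree, matrix)
  col <- collapse_mutationless(tree, states)
  leaves <- tree_leaves(col$tree)
  leaf_obs <- !is.na(matrix[col$tree$label[leaves], , drop = FALSE])
  if (method == "ultrametric") {
    depth <- ml_node_times(col$tree, col$states, model,
                           leaf_observed = leaf_obs)
    lens <- numeric(col$tree$n_node)
    chx <- which(!is.na(col$tree$parent))
    lens[chx] <- depth[chx] - depth[col$tree$parent[chx]]
  } else {
    lens <- ml_branch_lengths(col$tree, col$states, model,
                              leaf_observed = leaf_obs)
  }
  dated <- calibrate_times(col$tree, lens, sampling_day, origin_day)
  list(tree = dated, states = col$states, mutations = col$mutations,
       node_map = col$node_map, lengths = lens)
}

#' Number of extant cells over time
#'
#' Counts, for each grid day, the branches whose lifetime contains that day:
#' a branch is extant from its parent node's time (inclusive) to its child
#' node's time (exclusive); leaf branches are additionally counted as extant
#' at the sampling day itself.
#'
#' @param tree dated `lineage_tree`.
#' @param grid numeric vector of days.
#' @return integer vector of counts parallel to `grid`.
#' @export
extant_cells <- function(tree, grid) {
  e <- tree_edges(tree)
  vapply(grid, function(t)
    sum(e$parent_time <= t &
          (t < e$child_time | (e$child_is_leaf & t == e$child_time))),
    numeric(1))
}

#' Fraction of branches marked by an edit
#'
#' Observed branches are the edges of the collapsed tree; every node with
#' `k > 2` children implies `k - 2` hidden (unmarked) branches. The overall
#' marked fraction is observed / (observed + hidden). Per time bin, an
#' observed branch is placed at its parent-child midpoint and the hidden
#' branches of a multifurcation at evenly spaced midpoints between the node's
#' day and the median of its children's days.
#'
#' @param tree dated, collapsed (multifurcating) `lineage_tree`; internal
#'   non-root nodes must have >= 2 children.
#' @param bin_width bin width in days (default 0.5).
#' @return list with `overall` (scalar fraction), `per_bin` (data.frame bin
#'   start, n_observed, n_hidden, fraction), `n_observed`, `n_hidden`.
#' @export
marked_fraction <- function(tree, bin_width = 0.5) {
  kids <- tree_children(tree)
  root <- tree_root(tree)
  ks <- lengths(kids)
  if (any(ks == 1 & seq_along(ks) != root))
    stop("unary non-root nodes are not allowed")
  e <- tree_edges(tree)
  obs_times <- (e$parent_time + e$child_time) / 2
  hid_times <- numeric(0)
  for (v in which(ks > 2)) {
    k <- ks[v]
    med <- stats::median(tree$time[kids[[v]]])
    pts <- seq(tree$time[v], med, length.out = k)
    hid_times <- c(hid_times, pts[2:(k - 1)])
  }
  n_obs <- nrow(e); n_hid <- length(hid_times)
  brk <- function(t) floor(t / bin_width) * bin_width
  bins <- sort(unique(c(brk(obs_times), brk(hid_times))))
  per_bin <- data.frame(
    bin = bins,
    n_observed = vapply(bins, function(b) sum(brk(obs_times) == b), numeric(1)),
    n_hidden = vapply(bins, function(b) sum(brk(hid_times) == b), numeric(1)))
  per_bin$fraction <- per_bin$n_observed /
    (per_bin$n_observed + per_bin$n_hidden)
  list(overall = n_obs / (n_obs + n_hid), per_bin = per_bin,
       n_observed = n_obs, n_hidden = n_hid)
}
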