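#' Rooted lineage tree
#'
#' Light-weight rooted (possibly multifurcating) tree used throughout the
#' package. Nodes are stored in topological order (every parent index is
#' smaller than its children's indices), which makes a preorder traversal
#' `1:n` and a postorder traversal `n:1`. Node times are absolute days
#' (embryonic day for calibrated trees); they may be `NA` for undated
#' topologies.
#'
#' @param parent integer vector; `parent[i]` is the index of node `i`'s
#'   parent, `NA` for the root (exactly one root is required).
#' @param time numeric vector of node times in days (`NA` allowed).
#' @param label character vector of node labels; leaf labels are cell IDs.
#' @return An object of class `lineage_tree`: a list with elements `parent`,
#'   `time`, `label` and `n_node`.
#' @export
lineage_tree <- function(parent, time = rep(NA_real_, length(parent)),
                         label = NULL) {
  n <- length(parent)
  parent <- as.integer(parent)
  if (sum(is.na(parent)) != 1L)
    stop("a lineage_tree must have exactly one root (one NA parent)")
  if (any(parent[!is.na(parent)] >= seq_len(n)[!is.na(parent)]))
    stop("nodes must be topologically ordered (parent index < child index)")
  if (is.null(label)) label <- paste0("node_", seq_len(n))
  time <- as.numeric(time)
  pt <- time[ifelse(is.na(parent), 1L, parent)]
  ok <- !is.na(parent) & !is.na(time) & !is.na(pt)
  if (any(time[ok] < pt[ok] - 1e-9))
    stop("child times must be >= parent times")
  structure(list(parent = parent, time = time, label = as.character(label),
                 n_node = n), class = "lineage_tree")
}

#' @export
print.lineage_tree <- function(x, ...) {
  cat(sprintf("<lineage_tree> %d nodes, %d leaves", x$n_node,
              length(tree_leaves(x))))
  if (!all(is.na(x$time)))
    cat(sprintf(", days %.2f-%.2f", min(x$time, na.rm = TRUE),
                max(x$time, na.rm = TRUE)))
  cat("\n")
  invisible(x)
}

#' Children lists, leaves and roots
#'
#' @param tree a `lineage_tree`.
#' @return `tree_children()`: a list mapping each node to an integer vector of
#'   children; `tree_leaves()`: integer indices of leaves; `tree_root()`: the
#'   root index.
#' @export
tree_children <- function(tree) {
  kids <- vector("list", tree$n_node)
  p <- tree$parent
  idx <- which(!is.na(p))
  for (i in idx) kids[[p[i]]] <- c(kids[[p[i]]], i)
  kids
}

#' @rdname tree_children
#' @export
tree_leaves <- function(tree) {
  setdiff(seq_len(tree$n_node), unique(tree$parent[!is.na(tree$parent)]))
}

#' @rdname tree_children
#' @export
tree_root <- function(tree) which(is.na(tree$parent))

#' Per-node number of descendant leaves
#' @param tree a `lineage_tree`.
#' @return integer vector over nodes; leaves count themselves (1).
#' @export
tree_n_leaves <- function(tree) {
  n <- tree$n_node
  is_leaf <- rep(TRUE, n)
  is_leaf[tree$parent[!is.na(tree$parent)]] <- FALSE
  cnt <- as.integer(is_leaf)
  for (i in n:2) cnt[tree$parent[i]] <- cnt[tree$parent[i]] + cnt[i]
  cnt
}

#' Leaf indices below each node (list), or below one node
#' @param tree a `lineage_tree`.
#' @param node optional single node index; if given, returns its leaf set only.
#' @export
tree_leaf_sets <- function(tree, node = NULL) {
  n <- tree$n_node
  leaves <- tree_leaves(tree)
  sets <- vector("list", n)
  for (l in leaves) sets[[l]] <- l
  for (i in n:2) {
    p <- tree$parent[i]
    sets[[p]] <- c(sets[[p]], sets[[i]])
  }
  if (!is.null(node)) return(sort(sets[[node]]))
  sets
}

#' Edge table of a lineage tree
#'
#' @param tree a `lineage_tree`.
#' @return data.frame with columns `parent`, `child`, `parent_time`,
#'   `child_time`, `length` (days) and `child_is_leaf`.
#' @export
tree_edges <- function(tree) {
  ch <- which(!is.na(tree$parent))
  p <- tree$parent[ch]
  is_leaf <- rep(TRUE, tree$n_node)
  is_leaf[p] <- FALSE
  data.frame(parent = p, child = ch,
             parent_time = tree$time[p], child_time = tree$time[ch],
             length = tree$time[ch] - tree$time[p],
             child_is_leaf = is_leaf[ch])
}

#' Depth of each node from the root, in days
#' @param tree a dated `lineage_tree`.
#' @export
tree_depths <- function(tree) tree$time - tree$time[tree_root(tree)]

#' Pairwise MRCA times between leaves
#'
#' Time (day) of the most recent common ancestor for every pair of leaves,
#' computed in a single postorder sweep. The diagonal holds each leaf's own
#' time.
#'
#' @param tree a dated `lineage_tree`.
#' @return symmetric numeric matrix with leaf labels as dimnames.
#' @export
tree_mrca_times <- function(tree) {
  leaves <- tree_leaves(tree)
  nl <- length(leaves)
  pos <- integer(tree$n_node); pos[leaves] <- seq_len(nl)
  M <- matrix(NA_real_, nl, nl, dimnames = list(tree$label[leaves],
                                                tree$label[leaves]))
  diag(M) <- tree$time[leaves]
  sets <- vector("list", tree$n_node)
  for (l in leaves) sets[[l]] <- pos[l]
  kids <- tree_children(tree)
  for (v in tree$n_node:1) {
    k <- kids[[v]]
    if (length(k) == 0) next
    acc <- sets[[k[1]]]
    for (j in seq_along(k)[-1]) {
      b <- sets[[k[j]]]
      M[acc, b] <- tree$time[v]
      M[b, acc] <- tree$time[v]
      acc <- c(acc, b)
    }
    sets[[v]] <- acc
  }
  M
}

#' Convert between lineage_tree and ape phylo
#'
#' Leaves keep their labels; internal nodes get stable `node_i` labels. Edge
#' lengths are taken from node-time differences when times are available.
#'
#' @param tree a `lineage_tree`.
#' @return an [ape::phylo] object.
#' @export
as_phylo <- function(tree) {
  n <- tree$n_node
  leaves <- tree_leaves(tree)
  internal <- setdiff(seq_len(n), leaves)
  ntip <- length(leaves)
  map <- integer(n)
  map[leaves] <- seq_len(ntip)
  map[internal] <- ntip + seq_along(internal)  # internal in index (preorder) order
  ch <- which(!is.na(tree$parent))
  edge <- cbind(map[tree$parent[ch]], map[ch])
  phy <- list(edge = edge, tip.label = tree$label[leaves],
              Nnode = length(internal),
              node.label = tree$label[internal])
  if (!any(is.na(tree$time)))
    phy$edge.length <- tree$time[ch] - tree$time[tree$parent[ch]]
  class(phy) <- "phylo"
  attr(phy, "order") <- "cladewise"
  phy
}

#' @rdname as_phylo
#' @param phy an [ape::phylo] object (rooted).
#' @param root_time day assigned to the root; node times are root_time plus
#'   cumulative edge length (edge count when the tree has no lengths).
#' @export
as_lineage_tree <- function(phy, root_time = 0) {
  if (!ape::is.rooted(phy)) stop("phylo object must be rooted")
  phy <- stats::reorder(phy, "cladewise")
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  root <- ntip + 1L
  # order: root first, then edges in cladewise order give parents before children
  ord <- c(root, phy$edge[, 2])
  newid <- integer(nn); newid[ord] <- seq_len(nn)
  parent <- rep(NA_integer_, nn)
  parent[newid[phy$edge[, 2]]] <- newid[phy$edge[, 1]]
  len <- if (!is.null(phy$edge.length)) phy$edge.length else rep(1, nrow(phy$edge))
  time <- rep(NA_real_, nn)
  time[newid[root]] <- root_time
  for (i in seq_len(nrow(phy$edge))) {
    e <- phy$edge[i, ]
    time[newid[e[2]]] <- time[newid[e[1]]] + len[i]
  }
  lab <- character(nn)
  lab[newid[seq_len(ntip)]] <- phy$tip.label
  ilab <- if (!is.null(phy$node.label) && length(phy$node.label) == phy$Nnode)
    phy$node.label else paste0("node_", ntip + seq_len(phy$Nnode))
  lab[newid[ntip + seq_len(phy$Nnode)]] <- ilab
  lineage_tree(parent, time, lab)
}

#' Serialize a lineage tree as newick plus node metadata
#'
#' Newick branch lengths are in days (when the tree is dated); a companion TSV
#' carries one row per node with its stable ID, time and leaf flag.
#'
#' @param tree a `lineage_tree`.
#' @param newick_file,meta_file output paths.
#' @export
write_lineage_tree <- function(tree, newick_file, meta_file = NULL) {
  phy <- as_phylo(tree)
  ape::write.tree(phy, file = newick_file)
  if (!is.null(meta_file)) {
    leaves <- tree_leaves(tree)
    meta <- data.frame(node_id = tree$label, time = tree$time,
                       is_leaf = seq_len(tree$n_node) %in% leaves,
                       n_descendants = tree_n_leaves(tree))
    utils::write.table(meta, meta_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(newick_file)
}

#' @rdname write_lineage_tree
#' @param root_time day of the root used when reading back.
#' @export
read_lineage_tree <- function(newick_file, root_time = 0) {
  as_lineage_tree(ape::read.tree(newick_file), root_time = root_time)
}

#' Ancestor walk utilities
#'
#' `tree_ancestors()` returns the root-ward path (excluding the node itself).
#' @param tree a `lineage_tree`.
#' @param node node index.
#' @export
tree_ancestors <- function(tree, node) {
  out <- integer(0)
  p <- tree$parent[node]
  while (!is.na(p)) {
    out <- c(out, p)
    p <- tree$parent[p]
  }
  out
}

# internal: canonical newick of a topology (sorted children), for isomorphism
# checks in tests
canonical_topology <- function(tree) {
  kids <- tree_children(tree)
  rec <- function(v) {
    if (length(kids[[v]]) == 0) return(tree$label[v])
    parts <- sort(vapply(kids[[v]], rec, character(1)))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  rec(tree_root(tree))
}
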