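#' State codes used in character matrices
#'
#' Characters are (cassette, site) positions; states are integers: 0 =
#' unedited (`UE`), 1..8 = lineage marks (`M1`..`M8`), `NA` = missing (`ND`,
#' silenced or undetected).
#' @name state-codes
NULL

state_to_code <- function(s) ifelse(is.na(s), "ND",
                                    ifelse(s == 0L, "UE", paste0("M", s)))
code_to_state <- function(code) {
  out <- rep(NA_integer_, length(code))
  out[code == "UE"] <- 0L
  m <- grepl("^M\\d+$", code)
  out[m] <- as.integer(sub("^M", "", code[m]))
  out
}

#' Build a character matrix from a filtered allele table
#'
#' One character per (intBC, site) in the whitelist. The state of each
#' (cell, character) is taken from the dominant allele (largest UMI count,
#' ties by read count then mark ID); intBCs undetected in a cell give
#' missing states for all of that cassette's characters. Cells detecting
#' `min_detect` or fewer of the whitelisted intBCs are dropped (strict
#' `>` rule: with 35 cassettes, 26/35 = 74.3% is dropped, 27/35 = 77.1%
#' kept).
#'
#' @param table filtered, classified allele table (donor singlets only).
#' @param whitelist character vector of expected intBC IDs.
#' @param sites_per_cassette number of edit sites per cassette (default 3).
#' @param min_detect minimum detected intBC fraction (default 0.75,
#'   exclusive).
#' @return integer matrix cells x characters (dimnames set), with attributes
#'   `dropped` (cell IDs failing the detection filter) and `cassette`
#'   (cassette of each column).
#' @export
build_character_matrix <- function(table, whitelist, sites_per_cassette = 3,
                                   min_detect = 0.75) {
  if (length(whitelist) == 0) stop("empty intBC whitelist")
  table <- table[table$intBC %in% whitelist, , drop = FALSE]
  dom <- dominant_alleles(table)
  cells <- sort(unique(dom$cell_id))
  char_ids <- as.vector(t(outer(whitelist,
                                paste0("s", seq_len(sites_per_cassette)),
                                paste, sep = ".")))
  M <- matrix(NA_integer_, length(cells), length(char_ids),
              dimnames = list(cells, char_ids))
  idx <- cbind(match(dom$cell_id, cells),
               match(paste0(dom$intBC, ".s", dom$site), char_ids))
  ok <- !is.na(idx[, 2])
  M[idx[ok, , drop = FALSE]] <- code_to_state(dom$lineage_mark[ok])
  # detection: fraction of whitelisted intBCs with at least one allele
  det <- vapply(cells, function(cl)
    length(unique(dom$intBC[dom$cell_id == cl])) / length(whitelist),
    numeric(1))
  keep <- det > min_detect
  out <- M[keep, , drop = FALSE]
  attr(out, "dropped") <- cells[!keep]
  attr(out, "cassette") <- sub("\\.s\\d+$", "", char_ids)
  out
}

# internal: enumerate mutations (character, mark state) and their carrier
# rows within a subset of a character matrix
enumerate_mutations <- function(M, rows) {
  res <- list()
  for (j in seq_len(ncol(M))) {
    v <- M[rows, j]
    tab <- table(v[!is.na(v) & v > 0])
    for (s in names(tab))
      res[[length(res) + 1]] <- list(char = j, state = as.integer(s),
                                     carriers = rows[!is.na(v) & v == as.integer(s)],
                                     prevalence = as.integer(tab[[s]]))
  }
  res
}

#' Greedy recursive partition into high-confidence clades
#'
#' Recursively extracts clades supported by shared mutations: candidate
#' mutations are ranked by prevalence; the most prevalent seeds a group of
#' mutations whose carrier sets have Jaccard similarity above `jaccard_min`
#' with the seed's; the provisional clade (union of carriers) is refined to
#' the mutations present in more than `refine_prev` of its cells (missing
#' states count as compatible), and cells matching every refined mutation
#' (state equal or missing) are assigned. Splits are only made when supported
#' by at least `min_edits` shared mutations and containing at least
#' `min_frac` of the input cells; recursion is limited to `max_depth`.
#' Top-level cells matching no clade are flagged as likely doublets, not
#' silently dropped.
#'
#' @param matrix character matrix from [build_character_matrix()].
#' @param jaccard_min carrier-set Jaccard threshold for grouping mutations
#'   with the seed (default 0.9, exclusive).
#' @param refine_prev within-clade prevalence required of refined mutations
#'   (default 0.9, exclusive; missing compatible).
#' @param min_edits minimum shared mutations per split (default 3).
#' @param min_frac minimum clade size as a fraction of all input cells
#'   (default 0.01).
#' @param max_depth maximum recursion depth (default 3).
#' @return a `clade_partition`: list with `clades` (recursive list, each
#'   clade a list with `members` (cell IDs), `mutations`, `depth`,
#'   `children`) and `unassigned` (likely-doublet cell IDs).
#' @export
greedy_partition <- function(matrix, jaccard_min = 0.9, refine_prev = 0.9,
                             min_edits = 3, min_frac = 0.01, max_depth = 3) {
  if (nrow(matrix) == 0) stop("empty character matrix")
  n_total <- nrow(matrix)
  min_cells <- max(1, ceiling(min_frac * n_total))

  split_level <- function(rows, depth) {
    clades <- list()
    remaining <- rows
    repeat {
      if (length(remaining) < max(min_cells, 2)) break
      muts <- enumerate_mutations(matrix, remaining)
      if (length(muts) == 0) break
      prev <- vapply(muts, `[[`, integer(1), "prevalence")
      ord <- order(prev, decreasing = TRUE)
      found <- NULL
      for (si in ord) {
        if (prev[si] < min_cells) break
        seed <- muts[[si]]
        jac <- vapply(muts, function(m) {
          i <- length(intersect(m$carriers, seed$carriers))
          i / (length(m$carriers) + length(seed$carriers) - i)
        }, numeric(1))
        group <- muts[jac > jaccard_min]
        provisional <- sort(unique(unlist(lapply(group, `[[`, "carriers"))))
        # refine: mutations present in > refine_prev of provisional cells,
        # missing treated as compatible
        refined <- Filter(function(m) {
          v <- matrix[provisional, m$char]
          obs <- !is.na(v)
          sum(obs) == 0 || sum(v[obs] == m$state) / sum(obs) > refine_prev
        }, muts)
        if (length(refined) < min_edits) next
        # cells matching every refined mutation (equal state or missing)
        match_ok <- rep(TRUE, length(remaining))
        for (m in refined) {
          v <- matrix[remaining, m$char]
          match_ok <- match_ok & (is.na(v) | v == m$state)
        }
        members <- remaining[match_ok]
        if (length(members) < min_cells) next
        if (length(members) == length(remaining) &&
            length(clades) == 0 && setequal(remaining, rows)) next
        found <- list(members = members, refined = refined)
        break
      }
      if (is.null(found)) break
      clades[[length(clades) + 1]] <- list(
        members = rownames(matrix)[found$members],
        mutations = data.frame(
          character = colnames(matrix)[vapply(found$refined, `[[`,
                                              integer(1), "char")],
          state = vapply(found$refined, `[[`, integer(1), "state")),
        depth = depth,
        children = list())
      remaining <- setdiff(remaining, found$members)
    }
    if (depth < max_depth) {
      for (k in seq_along(clades)) {
        rows_k <- match(clades[[k]]$members, rownames(matrix))
        sub <- split_level(rows_k, depth + 1)
        clades[[k]]$children <- sub$clades
      }
    }
    list(clades = clades, remaining = remaining)
  }

  top <- split_level(seq_len(n_total), 1L)
  structure(list(clades = top$clades,
                 unassigned = rownames(matrix)[top$remaining]),
            class = "clade_partition")
}

#' Neighbor-joining subtree on a custom edit distance
#'
#' Characters are used only if detected (non-missing) in more than
#' `min_char_detect` of the clade's cells and no single lineage mark reaches
#' `max_mark_freq` of cells. The pairwise distance between two cells is the
#' fraction of characters, among those observed in both, with differing
#' states (any mark-vs-different-mark or mark-vs-unedited mismatch costs 1).
#' Pairs with no co-observed characters get the matrix maximum + 1 and are
#' flagged. Classic O(n^3) neighbor joining ([ape::nj()]) is run on this
#' matrix.
#'
#' @param matrix character matrix restricted to one clade.
#' @param min_char_detect,max_mark_freq character filters (defaults 0.5
#'   exclusive, 0.95).
#' @return an unrooted [ape::phylo] (for >= 4 cells; 3 cells give the unique
#'   star, fewer a trivial topology), with attribute `no_overlap_pairs`.
#' @export
nj_subtree <- function(matrix, min_char_detect = 0.5, max_mark_freq = 0.95) {
  n <- nrow(matrix)
  if (n < 3) {
    phy <- list(edge = cbind(rep(n + 1L, n), seq_len(n)),
                tip.label = rownames(matrix), Nnode = 1L)
    class(phy) <- "phylo"
    return(phy)
  }
  detect <- colMeans(!is.na(matrix))
  mark_max <- apply(matrix, 2, function(v) {
    v <- v[!is.na(v) & v > 0]
    if (length(v) == 0) return(0)
    max(table(v)) / n
  })
  use <- detect > min_char_detect & mark_max <= max_mark_freq
  M <- matrix[, use, drop = FALSE]
  D <- edit_distance_matrix(M)
  no_overlap <- attr(D, "no_overlap_pairs")
  if (n == 3) {
    phy <- list(edge = cbind(rep(4L, 3), 1:3), tip.label = rownames(matrix),
                Nnode = 1L, edge.length = rep(1, 3))
    class(phy) <- "phylo"
  } else {
    phy <- ape::nj(D)
    phy$edge.length[phy$edge.length < 0] <- 0
  }
  attr(phy, "no_overlap_pairs") <- no_overlap
  phy
}

#' Pairwise edit distance on a character matrix
#'
#' Fraction of co-observed characters with differing states; pairs with no
#' co-observed characters are set to the observed maximum + 1 and reported in
#' the `no_overlap_pairs` attribute. Symmetric with a zero diagonal.
#'
#' @param M integer character matrix.
#' @return numeric distance matrix.
#' @export
edit_distance_matrix <- function(M) {
  n <- nrow(M)
  diffs <- matrix(0, n, n)
  co <- matrix(0, n, n)
  for (j in seq_len(ncol(M))) {
    v <- M[, j]
    obs <- which(!is.na(v))
    if (length(obs) < 2) next
    vo <- v[obs]
    d <- outer(vo, vo, "!=")
    diffs[obs, obs] <- diffs[obs, obs] + d
    co[obs, obs] <- co[obs, obs] + 1
  }
  D <- diffs / co
  diag(D) <- 0
  bad <- which(co == 0 & upper.tri(co), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    mx <- max(D[is.finite(D)], 0)
    D[co == 0] <- mx + 1
    diag(D) <- 0
  }
  dimnames(D) <- list(rownames(M), rownames(M))
  attr(D, "no_overlap_pairs") <- bad
  D
}

#' Root an unrooted subtree by a character-based proxy outgroup
#'
#' The proxy set is the cells carrying the globally most frequent non-missing
#' edited state (character, mark) in the clade. Every edge is scored by the
#' Jaccard overlap between the proxy set and the leaf set on either side; the
#' tree is rooted on the edge with maximal overlap. Ties are broken by the
#' smaller matching side, then by the lexicographically smallest leaf label.
#' If no edited state is present the tree is rooted at the first leaf edge
#' and flagged degenerate.
#'
#' @param tree unrooted [ape::phylo] covering the matrix cells.
#' @param matrix character matrix for the clade.
#' @return rooted [ape::phylo] with attribute `degenerate`.
#' @export
root_subtree <- function(tree, matrix) {
  tips <- tree$tip.label
  M <- matrix[tips, , drop = FALSE]
  best <- NULL
  for (j in seq_len(ncol(M))) {
    v <- M[, j]
    tab <- table(v[!is.na(v) & v > 0])
    if (length(tab) == 0) next
    for (s in names(tab))
      if (is.null(best) || tab[[s]] > best$count)
        best <- list(char = j, state = as.integer(s), count = tab[[s]])
  }
  if (is.null(best)) {
    out <- ape::root(tree, outgroup = sort(tips)[1], resolve.root = TRUE)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  proxy <- tips[!is.na(M[, best$char]) & M[, best$char] == best$state]
  if (length(proxy) == length(tips)) {
    out <- ape::root(tree, outgroup = sort(tips)[1], resolve.root = TRUE)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  ntip <- length(tips)
  # leaf set under each edge's child in the stored orientation
  lt <- as_lineage_tree_topology(tree)
  sets <- tree_leaf_sets(lt$tree)
  score_edge <- function(child_node) {
    side <- lt$tree$label[sets[[child_node]]]
    other <- setdiff(tips, side)
    j1 <- jaccard_chr(proxy, side); j2 <- jaccard_chr(proxy, other)
    if (j1 >= j2) list(score = j1, side = side) else list(score = j2, side = other)
  }
  cand <- which(!is.na(lt$tree$parent))
  scored <- lapply(cand, score_edge)
  sc <- vapply(scored, `[[`, numeric(1), "score")
  sz <- vapply(scored, function(x) length(x$side), numeric(1))
  first_leaf <- vapply(scored, function(x) sort(x$side)[1], character(1))
  o <- order(-sc, sz, first_leaf)
  pick <- scored[[o[1]]]
  og <- pick$side
  if (length(og) == length(tips)) og <- setdiff(tips, og)  # safety
  out <- tryCatch(ape::root(tree, outgroup = og, resolve.root = TRUE),
                  error = function(e)
                    ape::root(tree, outgroup = og[1], resolve.root = TRUE))
  attr(out, "degenerate") <- FALSE
  out
}

jaccard_chr <- function(a, b) {
  i <- length(intersect(a, b))
  if (i == 0 && length(a) + length(b) == 0) return(0)
  i / (length(a) + length(b) - i)
}

# internal: arbitrary rooted lineage_tree view of a (possibly unrooted) phylo,
# keeping its stored orientation
as_lineage_tree_topology <- function(phy) {
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  root <- setdiff(phy$edge[, 1], phy$edge[, 2])[1]
  ord <- c(root, phy$edge[, 2])
  newid <- integer(nn); newid[ord] <- seq_len(nn)
  parent <- rep(NA_integer_, nn)
  parent[newid[phy$edge[, 2]]] <- newid[phy$edge[, 1]]
  lab <- character(nn)
  lab[newid[seq_len(ntip)]] <- phy$tip.label
  lab[newid[(ntip + 1):nn]] <- paste0("int_", (ntip + 1):nn)
  list(tree = lineage_tree(parent, rep(NA_real_, nn), lab), newid = newid)
}

#' Assemble rooted subtrees into an embryo tree and split into clones
#'
#' Attaches one rooted subtree per top-level clade under a single root, in
#' partition order, and returns both the embryo-level tree and the clone
#' trees (one per direct descendant of the root). Leaf sets of the clone
#' trees partition the embryo leaf set; a duplicated leaf across subtrees is
#' an error.
#'
#' @param partition a `clade_partition` (used for ordering / bookkeeping).
#' @param subtrees list of rooted trees (`lineage_tree` or [ape::phylo]), one
#'   per top-level clade.
#' @return list with `embryo` (a `lineage_tree`, undated) and `clones` (list
#'   of `lineage_tree`).
#' @export
assemble_and_split <- function(partition, subtrees) {
  subtrees <- lapply(subtrees, function(s)
    if (inherits(s, "phylo")) as_lineage_tree_topology(s)$tree else s)
  all_leaves <- unlist(lapply(subtrees, function(s) s$label[tree_leaves(s)]))
  if (anyDuplicated(all_leaves))
    stop("duplicate leaf across subtrees: ",
         paste(unique(all_leaves[duplicated(all_leaves)]), collapse = ", "))
  parent <- NA_integer_; time <- NA_real_; label <- "root"
  for (s in subtrees) {
    off <- length(parent)
    p <- s$parent + off
    p[is.na(s$parent)] <- 1L
    parent <- c(parent, p)
    time <- c(time, s$time)
    label <- c(label, s$label)
  }
  embryo <- lineage_tree(parent, time, label)
  kids <- tree_children(embryo)[[1]]
  clones <- lapply(kids, function(k) extract_subtree(embryo, k))
  list(embryo = embryo, clones = clones)
}

#' Extract the subtree rooted at a node
#' @param tree a `lineage_tree`.
#' @param node node index to use as the new root.
#' @return a `lineage_tree`.
#' @export
extract_subtree <- function(tree, node) {
  keep <- c(node, which_descendants(tree, node))
  keep <- sort(keep)
  newid <- integer(tree$n_node); newid[keep] <- seq_along(keep)
  parent <- tree$parent[keep]
  parent <- ifelse(keep == node, NA_integer_, newid[parent])
  lineage_tree(as.integer(parent), tree$time[keep], tree$label[keep])
}

#' End-to-end tree reconstruction from a character matrix
#'
#' Runs [greedy_partition()], builds a neighbor-joining subtree
#' ([nj_subtree()] + [root_subtree()]) for every partition leaf clade (and
#' for residual cells within split clades), assembles the clade hierarchy,
#' and returns the embryo tree plus clone trees via [assemble_and_split()].
#'
#' @param matrix character matrix from [build_character_matrix()].
#' @param nj_scope `"top"` (default): exact neighbor joining across each
#'   top-level clade's full cell set, the accurate choice at desk scale;
#'   `"leaf"`: neighbor joining only within the deepest greedy clades with
#'   hierarchical assembly of the nested splits, the scalable choice for
#'   very large embryos.
#' @param ... passed to [greedy_partition()].
#' @return list with `embryo`, `clones`, `partition`, and `dropped`
#'   (top-level unassigned cells, reported as likely doublets).
#' @export
reconstruct_tree <- function(matrix, nj_scope = c("top", "leaf"), ...) {
  nj_scope <- match.arg(nj_scope)
  part <- greedy_partition(matrix, ...)
  build_clade <- function(clade) {
    kids <- if (nj_scope == "top") list() else clade$children
    covered <- unlist(lapply(kids, `[[`, "members"))
    residual <- setdiff(clade$members, covered)
    sub_kids <- lapply(kids, build_clade)
    parts <- sub_kids
    if (length(residual) >= 3) {
      phy <- nj_subtree(matrix[residual, , drop = FALSE])
      phy <- root_subtree(phy, matrix)
      parts <- c(parts, list(as_lineage_tree_topology(phy)$tree))
    } else if (length(residual) > 0) {
      for (cell in residual)
        parts <- c(parts, list(lineage_tree(NA_integer_, NA_real_, cell)))
    }
    if (length(parts) == 1) return(parts[[1]])
    # join parts under a fresh node
    parent <- NA_integer_; time <- NA_real_
    label <- "clade"
    for (s in parts) {
      off <- length(parent)
      p <- s$parent + off
      p[is.na(s$parent)] <- 1L
      parent <- c(parent, p)
      time <- c(time, s$time)
      label <- c(label, s$label)
    }
    lineage_tree(parent, time, label)
  }
  if (length(part$clades) == 0) {
    cells <- setdiff(rownames(matrix), part$unassigned)
    phy <- nj_subtree(matrix[cells, , drop = FALSE])
    phy <- root_subtree(phy, matrix)
    subtrees <- list(as_lineage_tree_topology(phy)$tree)
    fake_part <- structure(list(clades = list(list(members = cells)),
                                unassigned = part$unassigned),
                           class = "clade_partition")
    asm <- assemble_and_split(fake_part, subtrees)
  } else {
    subtrees <- lapply(part$clades, build_clade)
    asm <- assemble_and_split(part, subtrees)
  }
  # relabel internal nodes stably
  tree <- asm$embryo
  leaves <- tree_leaves(tree)
  internal <- setdiff(seq_len(tree$n_node), leaves)
  tree$label[internal] <- sprintf("node_%05d", internal)
  asm$embryo <- tree
  asm$clones <- lapply(tree_children(tree)[[tree_root(tree)]],
                       function(k) extract_subtree(tree, k))
  list(embryo = asm$embryo, clones = asm$clones, partition = part,
       dropped = part$unassigned)
}
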