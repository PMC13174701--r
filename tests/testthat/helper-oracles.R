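# exhaustive minimum-cost labeling for small trees (independent oracle):
# enumerates all internal-state assignments (root forced unedited) under the
# irreversible cost model and returns the minimum total cost
brute_sankoff_cost <- function(tree, M, n_state) {
  BIG <- 1e9
  Tc <- matrix(BIG, n_state, n_state)
  Tc[1, ] <- 1; Tc[1, 1] <- 0
  diag(Tc) <- 0
  leaves <- tree_leaves(tree)
  internal <- setdiff(seq_len(tree$n_node), c(tree_root(tree), leaves))
  combos <- as.matrix(do.call(expand.grid,
                              rep(list(0:(n_state - 1)), length(internal))))
  if (nrow(combos) == 0) combos <- matrix(0L, 1, 0)
  best <- Inf
  lrow <- match(tree$label[leaves], rownames(M))
  for (ci in seq_len(ncol(M))) {
    st <- matrix(0L, nrow(combos), tree$n_node)
    if (length(internal) > 0) st[, internal] <- combos
    for (li in seq_along(leaves)) {
      s <- M[lrow[li], ci]
      st[, leaves[li]] <- if (is.na(s)) -1L else s
    }
    cost <- numeric(nrow(combos))
    for (v in seq_len(tree$n_node)[-1]) {
      p <- tree$parent[v]
      sv <- st[, v]; sp <- st[, p]
      skip <- sv < 0  # missing leaf: no cost for any parent state
      idx <- cbind(sp + 1L, pmax(sv, 0L) + 1L)
      add <- Tc[idx]; add[skip] <- 0
      cost <- cost + add
    }
    mc <- min(cost)
    if (ci == 1) total <- mc else total <- total + mc
  }
  total
}
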