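# Shared fixtures: small hand-built trees and sized simulations.

# manual caterpillar: root(1,d2.0) -> A(leaf,d8), n2(d4) -> B(leaf,d8), n3(d6) -> C,D (leaves d8)
caterpillar_tree <- function() {
  lineage_tree(parent = c(NA, 1, 1, 3, 3, 5, 5),
               time = c(2, 8, 4, 8, 6, 8, 8),
               label = c("r", "A", "n2", "B", "n3", "C", "D"))
}

# balanced 4-leaf tree with known times
balanced4_tree <- function() {
  lineage_tree(parent = c(NA, 1, 1, 2, 2, 3, 3),
               time = c(0, 2, 3, 5, 5, 5, 5),
               label = c("r", "u", "v", "a", "b", "c", "d"))
}

# simulate a division tree with leaf count in [lo, hi], scanning seeds
sim_tree_sized <- function(cfg, lo, hi, start_seed = 1, max_tries = 200) {
  for (s in start_seed:(start_seed + max_tries)) {
    tr <- simulate_division_tree(cfg, seed = s)
    n <- length(tree_leaves(tr))
    if (n >= lo && n <= hi) return(list(tree = tr, seed = s))
  }
  stop("no seed produced a tree in the requested size range")
}

# random dated tree via ape::rtree, leaves pushed to a common sampling day
random_dated_tree <- function(n, seed, sampling_day = 8) {
  set.seed(seed)
  phy <- ape::rtree(n)
  tr <- as_lineage_tree(phy, root_time = 0)
  # rescale so deepest leaf = sampling_day, then set all leaves to that day
  d <- tree_depths(tr)
  tr$time <- tr$time * (sampling_day / max(d))
  leaves <- tree_leaves(tr)
  tr$time[leaves] <- sampling_day
  # enforce monotonicity (parents of leaves may exceed after rescale: no)
  tr
}

# minimal clean allele table for one cell: one allele per (intBC, site)
clean_allele_rows <- function(cell, states, umi = 20, rpu = 8) {
  # states: named integer vector, names like BC01.s1
  cass <- sub("\\.s\\d+$", "", names(states))
  site <- as.integer(sub("^.*\\.s", "", names(states)))
  obs <- !is.na(states)
  data.frame(cell_id = cell, intBC = cass[obs], site = site[obs],
             lineage_mark = ifelse(states[obs] == 0, "UE",
                                   paste0("M", states[obs])),
             umi_count = umi, read_count = umi * rpu)
}
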