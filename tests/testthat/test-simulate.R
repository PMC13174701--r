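test_that("config validation rejects bad parameters", {
  expect_error(sim_config(mark_probs = c(0.5, 0.5, 0.5)), "mark_probs")
  expect_error(sim_config(sampling_fraction = 1.5), "probabilities")
  expect_error(sim_config(division_rates = c(0.5, Inf)), "finite")
  expect_error(sim_config(n_cassettes = 0), "counts")
})

test_that("zero division rate yields the founder alone", {
  cfg <- sim_config(division_rates = c(0, 0), division_breaks = 4.5)
  tr <- simulate_division_tree(cfg, seed = 1)
  expect_equal(length(tree_leaves(tr)), 1L)
  expect_equal(max(tr$time), cfg$sampling_day)
})

test_that("constant-rate pure birth matches e^{rT} expected leaf count", {
  # E[N(T)] = e^{rT} for a pure-birth process started from one lineage
  r <- 0.8; T <- 4
  cfg <- sim_config(origin_day = 0, sampling_day = T,
                    division_breaks = numeric(0), division_rates = r)
  n <- vapply(1:400, function(s)
    length(tree_leaves(simulate_division_tree(cfg, seed = s))), numeric(1))
  expected <- exp(r * T)
  se <- sd(n) / sqrt(length(n))
  expect_lt(abs(mean(n) - expected), 3 * se)
})

test_that("identical seed gives byte-identical trees", {
  cfg <- sim_config(sampling_day = 7)
  t1 <- simulate_division_tree(cfg, seed = 42)
  t2 <- simulate_division_tree(cfg, seed = 42)
  expect_identical(t1, t2)
  expect_identical(ape::write.tree(as_phylo(t1)),
                   ape::write.tree(as_phylo(t2)))
})

test_that("node times increase from root to leaves and leaves end at sampling", {
  cfg <- sim_config(sampling_day = 7.5)
  tr <- simulate_division_tree(cfg, seed = 5)
  e <- tree_edges(tr)
  expect_true(all(e$length >= 0))
  expect_true(all(tr$time[tree_leaves(tr)] == 7.5))
})

test_that("zero site rate leaves everything unedited", {
  cfg <- sim_config(site_rate_scale = 0, silencing_rate = 0, sampling_day = 6)
  tr <- simulate_division_tree(cfg, seed = 2)
  ed <- simulate_editing(tr, cfg, seed = 3)
  expect_true(all(ed$leaf_matrix == 0L))
})

test_that("editing on a single branch matches 1 - exp(-rt) within binomial CI", {
  # one founder, no divisions: a single branch of length t
  t <- 3; r_scale <- 0.4
  cfg <- sim_config(origin_day = 0, sampling_day = t,
                    division_breaks = numeric(0), division_rates = 0,
                    n_cassettes = 3334, sites_per_cassette = 3,
                    relative_rates = 1, site_rate_scale = r_scale,
                    silencing_rate = 0)
  tr <- simulate_division_tree(cfg, seed = 1)
  ed <- simulate_editing(tr, cfg, seed = 9)
  n <- ncol(ed$leaf_matrix)  # ~10,000 replicate characters
  p_hat <- mean(ed$leaf_matrix > 0)
  p <- 1 - exp(-r_scale * t)
  ci <- qnorm(0.995) * sqrt(p * (1 - p) / n)
  expect_lt(abs(p_hat - p), ci)
})

test_that("editing is irreversible along every path", {
  cfg <- sim_config(sampling_day = 7.5, site_rate_scale = 0.1)
  tr <- simulate_division_tree(cfg, seed = 4)
  ed <- simulate_editing(tr, cfg, seed = 5)
  for (v in seq_len(tr$n_node)[-1]) {
    p <- tr$parent[v]
    sp <- ed$states[p, ]; sv <- ed$states[v, ]
    both <- !is.na(sp) & !is.na(sv)
    marked <- both & sp > 0
    expect_true(all(sv[marked] == sp[marked]))
  }
})

test_that("mark frequencies follow mark_probs (chi-square GOF)", {
  probs <- c(0.4, 0.3, 0.2, 0.1)
  cfg <- sim_config(origin_day = 0, sampling_day = 4,
                    division_breaks = numeric(0), division_rates = 0,
                    n_cassettes = 40000, sites_per_cassette = 1,
                    marks_per_site = 4, mark_probs = probs,
                    relative_rates = 1, site_rate_scale = 1,
                    silencing_rate = 0)
  tr <- simulate_division_tree(cfg, seed = 1)
  ed <- simulate_editing(tr, cfg, seed = 6)
  marks <- ed$leaf_matrix[ed$leaf_matrix > 0]
  gof <- chisq.test(tabulate(marks, 4), p = probs)
  expect_gt(gof$p.value, 0.01)
})

test_that("a silencing event blanks the cassette in every descendant leaf", {
  cfg <- sim_config(sampling_day = 7, silencing_rate = 0.15)
  tr <- sim_tree_sized(cfg, 30, 200, start_seed = 1)$tree
  ed <- simulate_editing(tr, cfg, seed = 7)
  ev <- ed$silencing_events
  expect_gt(nrow(ev), 0)  # near-certain at this rate and tree size
  spc <- cfg$sites_per_cassette
  for (i in seq_len(nrow(ev))) {
    cols <- (ev$cassette[i] - 1) * spc + seq_len(spc)
    below <- c(ev$node[i], lintrace:::which_descendants(tr, ev$node[i]))
    leaves_below <- intersect(below, tree_leaves(tr))
    expect_true(all(is.na(ed$states[leaves_below, cols])))
  }
})

test_that("fate map labels exactly the committed subtrees", {
  cfg <- sim_config(sampling_day = 8)
  tr <- sim_tree_sized(cfg, 60, 400, start_seed = 1)$tree
  fm <- simulate_fate_map(tr, data.frame(day = c(4.8, 5.2),
                                         fate = c("neural", "mesoderm")),
                          leakage = 0, seed = 3)
  expect_equal(nrow(fm$truth), 2)
  for (i in 1:2) {
    committed <- tr$label[tree_leaf_sets(tr, fm$truth$node[i])]
    expect_true(all(fm$labels[committed] == fm$truth$fate[i]))
  }
  uncommitted <- setdiff(names(fm$labels),
                         unlist(lapply(fm$truth$node, function(v)
                           tr$label[tree_leaf_sets(tr, v)])))
  expect_true(all(fm$labels[uncommitted] == "progenitor"))
})

test_that("single commitment at the stem with zero leakage labels all leaves", {
  cfg <- sim_config(sampling_day = 7)
  tr <- sim_tree_sized(cfg, 20, 300, start_seed = 1)$tree
  # the stem branch spans the earliest days: one commitment there covers all
  day0 <- tr$time[tree_root(tr)] + 0.01
  fm <- simulate_fate_map(tr, data.frame(day = day0, fate = "ecto"),
                          leakage = 0, seed = 1)
  expect_true(all(fm$labels == "ecto"))
})

test_that("leakage flips committed labels at the requested rate", {
  cfg <- sim_config(origin_day = 0, sampling_day = 7,
                    division_breaks = numeric(0), division_rates = 1.4)
  tr <- sim_tree_sized(cfg, 3000, 30000, start_seed = 1)$tree
  day0 <- tr$time[tree_root(tr)] + 0.01
  fm <- simulate_fate_map(
    tr, data.frame(day = day0, fate = "a"),
    fate_hierarchy = data.frame(fate = c("root", "a", "b"),
                                parent = c(NA, "root", "root")),
    leakage = 0.05, seed = 2)
  n <- length(fm$labels)
  off <- mean(fm$labels != "a")
  ci <- qnorm(0.995) * sqrt(0.05 * 0.95 / n)
  expect_lt(abs(off - 0.05), ci)
})

test_that("noise-free allele tables recover true states as dominant alleles", {
  cfg <- sim_config(sampling_day = 7, sampling_fraction = 1,
                    doublet_fraction = 0, ambient_rate = 0,
                    host_fraction = 0, silencing_rate = 0)
  tr <- sim_tree_sized(cfg, 20, 200, start_seed = 1)$tree
  ed <- simulate_editing(tr, cfg, seed = 8)
  rd <- simulate_allele_table(ed$leaf_matrix, cfg, seed = 9)
  dom <- lintrace:::dominant_alleles(rd$allele_table)
  # barcodes map 1:1 to cells here
  truth <- rd$truth
  for (i in sample(nrow(dom), 50)) {
    cell <- truth$members[truth$cell_id == dom$cell_id[i]]
    char <- paste0(dom$intBC[i], ".s", dom$site[i])
    expect_equal(dom$lineage_mark[i],
                 lintrace:::state_to_code(ed$leaf_matrix[cell, char]))
  }
})

test_that("doublet fraction matches the configured rate (binomial CI)", {
  cfg <- sim_config(origin_day = 0, sampling_day = 7.2,
                    division_breaks = numeric(0), division_rates = 1.3,
                    n_cassettes = 4, host_fraction = 0, ambient_rate = 0,
                    doublet_fraction = 0.06, sampling_fraction = 1)
  tr <- sim_tree_sized(cfg, 8000, 30000, start_seed = 1)$tree
  ed <- simulate_editing(tr, cfg, seed = 11)
  rd <- simulate_allele_table(ed$leaf_matrix, cfg, seed = 12)
  n <- nrow(rd$truth)
  # merging consumes two cells per doublet barcode: observed barcode-level
  # fraction of merged units
  frac <- mean(rd$truth$label == "donor_donor_doublet")
  d <- cfg$doublet_fraction
  expected <- d / (1 - d)  # n_doub = d * n_units; barcodes = n_units - n_doub
  ci <- qnorm(0.995) * sqrt(expected * (1 - expected) / n)
  expect_lt(abs(frac - expected), ci + 0.002)
})

test_that("ambient alleles always sit below the reads-per-UMI filter floor", {
  cfg <- sim_config(sampling_day = 7, ambient_rate = 3, host_fraction = 0,
                    doublet_fraction = 0)
  tr <- sim_tree_sized(cfg, 30, 300, start_seed = 1)$tree
  ed <- simulate_editing(tr, cfg, seed = 13)
  rd <- simulate_allele_table(ed$leaf_matrix, cfg, seed = 14)
  tab <- rd$allele_table
  rpu <- tab$read_count / tab$umi_count
  # true alleles have rpu >= 4 by construction; everything below is ambient
  expect_true(any(rpu < 4))
  filtered <- filter_alleles(tab)
  expect_true(all(filtered$read_count / filtered$umi_count >= 4))
})

test_that("full generator wrapper is reproducible from the config seed", {
  cfg <- sim_config(seed = 77, sampling_day = 7)
  a <- simulate_recorder_experiment(cfg)
  b <- simulate_recorder_experiment(cfg)
  expect_identical(a$tree, b$tree)
  expect_identical(a$editing$leaf_matrix, b$editing$leaf_matrix)
  expect_identical(a$reads$allele_table, b$reads$allele_table)
})
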