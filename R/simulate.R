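#' Simulation configuration for a recorder-bearing embryo
#'
#' Defines the generative model used by the synthetic data module: a
#' pure-birth division tree with a piecewise-constant division-rate schedule,
#' irreversible per-site exponential editing across `n_cassettes x
#' sites_per_cassette` characters, heritable per-cassette silencing, capture
#' subsampling of leaves, and allele-table noise (ambient alleles, doublets,
#' host cells).
#'
#' Defaults emulate the study conditions of an intermediate-kinetics recorder
#' line in a chimeric mouse embryo: 35 cassettes of 3 edit sites with 8
#' possible marks each (105 characters), founders seeded at ~E2 and sampled at
#' E9.5, slow early divisions (0.5/day before E4.5) followed by fast growth
#' (1.4/day), per-site editing rates cycling (0.3, 0.4, 1.2) x `site_rate_scale`
#' chosen so that roughly three quarters of divisions are marked by at least
#' one edit, ~50% capture, and realistic single-cell noise levels.
#'
#' @param seed integer seed used by [simulate_recorder_experiment()].
#' @param origin_day embryonic day of the founder cell (root).
#' @param sampling_day embryonic day at which leaves are sampled;
#'   `duration = sampling_day - origin_day`.
#' @param division_breaks,division_rates piecewise-constant division schedule:
#'   rate `division_rates[i]` applies on embryonic days up to
#'   `division_breaks[i]`; the last rate extends to `sampling_day`.
#' @param n_cassettes,sites_per_cassette,marks_per_site recorder geometry.
#' @param site_rate_scale overall edits/day scale; per-character rates are
#'   `site_rate_scale * rep(relative_rates, length.out = n_characters)`.
#' @param relative_rates per-site relative editing-rate cycle.
#' @param mark_probs probability of each mark given an edit (length
#'   `marks_per_site`, sums to 1).
#' @param silencing_rate heritable silencing events per cassette per day.
#' @param sampling_fraction probability that a leaf is captured.
#' @param doublet_fraction probability that a captured barcode is a merged
#'   pair of cells.
#' @param ambient_rate expected number of spurious ambient alleles per cell.
#' @param host_fraction probability that a captured cell is host-derived
#'   (carries no cassettes).
#' @param umi_mu,umi_size,rpu_mu,rpu_size negative-binomial parameters for
#'   true-allele UMI counts (shifted to a minimum of 5) and reads-per-UMI
#'   (shifted to a minimum of 4). Ambient alleles always have reads-per-UMI
#'   <= 3.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       origin_day = 2.0,
                       sampling_day = 9.5,
                       division_breaks = 4.5,
                       division_rates = c(0.5, 1.4),
                       n_cassettes = 35L,
                       sites_per_cassette = 3L,
                       marks_per_site = 8L,
                       site_rate_scale = 0.06,
                       relative_rates = c(0.3, 0.4, 1.2),
                       mark_probs = rep(1 / marks_per_site, marks_per_site),
                       silencing_rate = 0.002,
                       sampling_fraction = 0.5,
                       doublet_fraction = 0.05,
                       ambient_rate = 0.5,
                       host_fraction = 0.25,
                       umi_mu = 15, umi_size = 2, rpu_mu = 6, rpu_size = 2) {
  cfg <- list(seed = as.integer(seed), origin_day = origin_day,
              sampling_day = sampling_day,
              division_breaks = division_breaks,
              division_rates = division_rates,
              n_cassettes = as.integer(n_cassettes),
              sites_per_cassette = as.integer(sites_per_cassette),
              marks_per_site = as.integer(marks_per_site),
              site_rate_scale = site_rate_scale,
              relative_rates = relative_rates,
              mark_probs = mark_probs,
              silencing_rate = silencing_rate,
              sampling_fraction = sampling_fraction,
              doublet_fraction = doublet_fraction,
              ambient_rate = ambient_rate,
              host_fraction = host_fraction,
              umi_mu = umi_mu, umi_size = umi_size,
              rpu_mu = rpu_mu, rpu_size = rpu_size)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$sampling_day > cfg$origin_day)
  if (any(!is.finite(cfg$division_rates)) || any(cfg$division_rates < 0))
    stop("division rates must be finite and >= 0")
  if (length(cfg$division_rates) != length(cfg$division_breaks) + 1L)
    stop("need one more division rate than breaks")
  probs <- c(cfg$sampling_fraction, cfg$doublet_fraction, cfg$host_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (abs(sum(cfg$mark_probs) - 1) > 1e-8 || any(cfg$mark_probs < 0))
    stop("mark_probs must be a probability vector summing to 1")
  if (cfg$site_rate_scale < 0 || cfg$silencing_rate < 0 ||
      cfg$ambient_rate < 0 || any(cfg$relative_rates <= 0))
    stop("rates must be >= 0 (relative rates > 0)")
  if (cfg$n_cassettes < 1 || cfg$sites_per_cassette < 1 ||
      cfg$marks_per_site < 1)
    stop("counts must be >= 1")
  invisible(cfg)
}

#' Per-character editing rates implied by a configuration
#' @param config a `sim_config`.
#' @return numeric vector of edits/day, one per character
#'   (cassette x site, cassette-major order).
#' @export
character_rates <- function(config) {
  nchar <- config$n_cassettes * config$sites_per_cassette
  config$site_rate_scale * rep(config$relative_rates, length.out = nchar)
}

#' Character IDs (cassette x site) for a configuration
#' @param config a `sim_config`.
#' @export
character_ids <- function(config) {
  as.vector(t(outer(sprintf("BC%02d", seq_len(config$n_cassettes)),
                    sprintf("s%d", seq_len(config$sites_per_cassette)),
                    paste, sep = ".")))
}

# draw the waiting time to the next division starting at absolute day t0
# under the piecewise-constant schedule; Inf if no division before `end`.
piecewise_next_event <- function(t0, breaks, rates, end) {
  e <- stats::rexp(1)
  t <- t0
  seg_ends <- c(breaks, end)
  for (i in seq_along(rates)) {
    if (seg_ends[i] <= t) next
    r <- rates[i]
    cap <- r * (seg_ends[i] - t)
    if (r > 0 && e < cap) return(t + e / r)
    e <- e - cap
    t <- seg_ends[i]
    if (t >= end) break
  }
  Inf
}

#' Simulate a pure-birth division tree
#'
#' Each extant branch divides at the schedule rate evaluated at the current
#' embryonic day; leaves are truncated at `sampling_day`. The founder is the
#' root node at `origin_day`; if it divides, the root has a single child
#' carrying the stem branch, so root-to-first-division editing is modelled.
#'
#' @param config a [sim_config()].
#' @param seed optional integer; when given, `set.seed(seed)` is called.
#' @return a `lineage_tree` with exact node times; internal node times are
#'   division times, leaf times equal `sampling_day`.
#' @export
simulate_division_tree <- function(config, seed = NULL) {
  validate_sim_config(config)
  if (!is.null(seed)) set.seed(seed)
  t0 <- config$origin_day; tend <- config$sampling_day
  cap <- 1024L
  parent <- rep(NA_integer_, cap); time <- rep(NA_real_, cap)
  parent[1] <- NA_integer_; time[1] <- t0
  n <- 1L
  grow <- function() {
    parent <<- c(parent, rep(NA_integer_, cap)); time <<- c(time, rep(NA_real_, cap))
    cap <<- 2L * cap
  }
  add_node <- function(p, t) {
    if (n + 1L > cap) grow()
    n <<- n + 1L
    parent[n] <<- p; time[n] <<- t
    n
  }
  # queue holds nodes each of which still owes one child branch (two entries
  # per pending division)
  first <- piecewise_next_event(t0, config$division_breaks,
                                config$division_rates, tend)
  if (!is.finite(first)) {
    add_node(1L, tend)  # founder never divides: single captured leaf
  } else {
    v2 <- add_node(1L, first)
    queue <- integer(2048L); queue[1:2] <- v2
    qhead <- 1L; qtail <- 2L
    push <- function(x) {
      if (qtail + 2L > length(queue)) queue <<- c(queue, integer(length(queue)))
      queue[qtail + 1L] <<- x; queue[qtail + 2L] <<- x
      qtail <<- qtail + 2L
    }
    while (qhead <= qtail) {
      v <- queue[qhead]; qhead <- qhead + 1L
      nxt <- piecewise_next_event(time[v], config$division_breaks,
                                  config$division_rates, tend)
      if (!is.finite(nxt)) {
        add_node(v, tend)
      } else {
        push(add_node(v, nxt))
      }
    }
  }
  parent <- parent[seq_len(n)]; time <- time[seq_len(n)]
  is_leaf <- !(seq_len(n) %in% parent[!is.na(parent)])
  lab <- character(n)
  lab[is_leaf] <- sprintf("cell_%05d", seq_len(sum(is_leaf)))
  lab[!is_leaf] <- sprintf("node_%05d", which(!is_leaf))
  lineage_tree(parent, time, lab)
}

#' Simulate irreversible editing and cassette silencing on a lineage
#'
#' For every character the first edit time along a root-to-leaf path is
#' exponential with the character's rate; once installed, a mark (drawn from
#' `mark_probs`) is inherited by all descendants. Silencing events arrive per
#' cassette per branch as a Poisson process; a silenced cassette is `NA`
#' (missing) at every descendant node for all of its characters.
#'
#' @param lineage a dated `lineage_tree` from [simulate_division_tree()].
#' @param config a [sim_config()].
#' @param seed optional integer seed.
#' @return list with `states` (full node x character integer matrix; 0 =
#'   unedited, 1..M = marks, NA = silenced), `leaf_matrix` (rows = captured
#'   cell IDs; here all leaves), `rates`, and `silencing_events`
#'   (data.frame node/cassette).
#' @export
simulate_editing <- function(lineage, config, seed = NULL) {
  if (any(is.na(lineage$time))) stop("lineage tree must have node times")
  validate_sim_config(config)
  if (!is.null(seed)) set.seed(seed)
  rates <- character_rates(config)
  nchar <- length(rates)
  spc <- config$sites_per_cassette
  cass_of <- rep(seq_len(config$n_cassettes), each = spc)
  n <- lineage$n_node
  S <- matrix(0L, n, nchar,
              dimnames = list(lineage$label, character_ids(config)))
  sil_node <- integer(0); sil_cass <- integer(0)
  for (i in seq_len(n)[-1]) {
    p <- lineage$parent[i]
    dt <- lineage$time[i] - lineage$time[p]
    s <- S[p, ]
    # silencing per cassette (skip cassettes already missing)
    active_cass <- unique(cass_of[!is.na(s)])
    if (config$silencing_rate > 0 && length(active_cass) > 0) {
      hit <- active_cass[stats::runif(length(active_cass)) <
                           1 - exp(-config$silencing_rate * dt)]
      if (length(hit) > 0) {
        s[cass_of %in% hit] <- NA_integer_
        sil_node <- c(sil_node, rep(i, length(hit)))
        sil_cass <- c(sil_cass, hit)
      }
    }
    unedited <- which(!is.na(s) & s == 0L)
    if (length(unedited) > 0 && dt > 0) {
      hit <- unedited[stats::runif(length(unedited)) <
                        1 - exp(-rates[unedited] * dt)]
      if (length(hit) > 0)
        s[hit] <- sample.int(config$marks_per_site, length(hit),
                             replace = TRUE, prob = config$mark_probs)
    }
    S[i, ] <- s
  }
  leaves <- tree_leaves(lineage)
  list(states = S,
       leaf_matrix = S[leaves, , drop = FALSE],
       rates = rates,
       silencing_events = data.frame(node = sil_node, cassette = sil_cass))
}

#' Plant nested fate commitments on a simulated lineage
#'
#' At each requested commitment, one branch extant at (spanning) the requested
#' day is chosen — preferring, when `size` is given, the clade whose leaf
#' count is closest to the target — and all of its descendant leaves receive
#' the fate label. Each committed leaf is independently flipped to a random
#' sibling fate (same parent in the fate hierarchy) with probability
#' `leakage`. Uncommitted leaves carry the hierarchy root label.
#'
#' @param lineage dated `lineage_tree`.
#' @param commitments data.frame with columns `day`, `fate` and optionally
#'   `size` (target clade leaf count) or `node` (exact node index to commit,
#'   which must be extant at the requested day).
#' @param fate_hierarchy data.frame with columns `fate`, `parent` (`NA` for
#'   the root label); defaults to a flat hierarchy rooted at `"progenitor"`.
#' @param leakage per-leaf label flip probability.
#' @param seed optional integer seed.
#' @return list with `labels` (named character vector over leaf cell IDs) and
#'   `truth` (data.frame node/fate/day of the planted commitments).
#' @export
simulate_fate_map <- function(lineage, commitments, fate_hierarchy = NULL,
                              leakage = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(c("day", "fate") %in% names(commitments)))
  if (is.null(fate_hierarchy))
    fate_hierarchy <- data.frame(
      fate = c("progenitor", unique(as.character(commitments$fate))),
      parent = c(NA, rep("progenitor", length(unique(commitments$fate)))))
  root_fate <- fate_hierarchy$fate[is.na(fate_hierarchy$parent)][1]
  if (any(commitments$day <= lineage$time[tree_root(lineage)]) ||
      any(commitments$day >= max(lineage$time)))
    stop("commitment days must lie strictly within the tree's time span")
  leaves <- tree_leaves(lineage)
  leaf_sets <- tree_leaf_sets(lineage)
  nlv <- tree_n_leaves(lineage)
  edges <- tree_edges(lineage)
  labels <- stats::setNames(rep(root_fate, length(leaves)),
                            lineage$label[leaves])
  committed_nodes <- integer(0)
  truth <- data.frame(node = integer(0), fate = character(0),
                      day = numeric(0))
  ord <- order(commitments$day)
  for (k in ord) {
    day <- commitments$day[k]; fate <- as.character(commitments$fate[k])
    cand <- edges$child[edges$parent_time <= day & day < edges$child_time]
    # avoid nesting inside an already committed clade
    if (length(committed_nodes) > 0) {
      blocked <- unlist(lapply(committed_nodes, function(v)
        c(v, which_descendants(lineage, v))))
      cand <- setdiff(cand, blocked)
    }
    if (length(cand) == 0)
      stop(sprintf("no free extant branch at day %.2f for fate '%s'", day, fate))
    if (!is.null(commitments$node) && !is.na(commitments$node[k])) {
      v <- as.integer(commitments$node[k])
      if (!(v %in% cand))
        stop(sprintf("requested node %d is not a free extant branch at day %.2f",
                     v, day))
    } else if (!is.null(commitments$size) && !is.na(commitments$size[k])) {
      v <- cand[which.min(abs(nlv[cand] - commitments$size[k]))]
    } else v <- sample(cand, 1)
    committed_nodes <- c(committed_nodes, v)
    labels[lineage$label[leaf_sets[[v]]]] <- fate
    truth <- rbind(truth, data.frame(node = v, fate = fate, day = day))
  }
  if (leakage > 0) {
    committed <- names(labels)[labels != root_fate]
    flip <- committed[stats::runif(length(committed)) < leakage]
    for (cell in flip) {
      f <- labels[cell]
      par <- fate_hierarchy$parent[match(f, fate_hierarchy$fate)]
      sibs <- setdiff(fate_hierarchy$fate[!is.na(fate_hierarchy$parent) &
                                            fate_hierarchy$parent == par], f)
      if (length(sibs) > 0) labels[cell] <- sample(sibs, 1)
    }
  }
  list(labels = labels, truth = truth)
}

# internal: all descendant node indices of v (excluding v)
which_descendants <- function(tree, v) {
  out <- integer(0); stack <- v
  kids <- tree_children(tree)
  while (length(stack) > 0) {
    x <- stack[1]; stack <- stack[-1]
    out <- c(out, kids[[x]])
    stack <- c(stack, kids[[x]])
  }
  out
}

rnb_shift <- function(n, mu, size, min) min + stats::rnbinom(n, mu = mu, size = size)

#' Simulate a noisy allele table from a character matrix
#'
#' Applies capture subsampling, generates UMI and read support for true
#' alleles (shifted negative binomials placing truth above the default filter
#' floors), injects ambient alleles with reads-per-UMI <= 3, forms
#' donor-donor doublets by merging two cells' alleles under one barcode, and
#' adds host-derived cells carrying no cassette alleles but a high
#' host-signal score. Also emits per-barcode QC records (total/mito/LTC UMIs,
#' host signal) for the QC module.
#'
#' @param leaf_matrix integer character matrix (cells x characters) from
#'   [simulate_editing()].
#' @param config a [sim_config()].
#' @param seed optional integer seed.
#' @return list with `allele_table` (data.frame: cell_id, intBC, site,
#'   lineage_mark, umi_count, read_count), `qc` (per-barcode QC records),
#'   `truth` (per-barcode class label and constituent cells), and `captured`
#'   (captured leaf cell IDs, pre-noise).
#' @export
simulate_allele_table <- function(leaf_matrix, config, seed = NULL) {
  validate_sim_config(config)
  if (!is.null(seed)) set.seed(seed)
  cells <- rownames(leaf_matrix)
  captured <- cells[stats::runif(length(cells)) < config$sampling_fraction]
  n_cap <- length(captured)
  spc <- config$sites_per_cassette
  char_ids <- colnames(leaf_matrix)
  cass_of <- sub("\\.s\\d+$", "", char_ids)
  site_of <- as.integer(sub("^.*\\.s", "", char_ids))

  # host cells: host_fraction of all captured barcodes
  n_host <- if (config$host_fraction > 0)
    round(config$host_fraction / (1 - config$host_fraction) * n_cap) else 0L
  host_ids <- if (n_host > 0) sprintf("host_%05d", seq_len(n_host)) else character(0)

  units <- c(captured, host_ids)
  is_host <- c(rep(FALSE, n_cap), rep(TRUE, n_host))
  if (length(units) == 0) {
    empty_tab <- data.frame(cell_id = character(0), intBC = character(0),
                            site = integer(0), lineage_mark = character(0),
                            umi_count = integer(0), read_count = integer(0))
    return(list(allele_table = empty_tab,
                qc = data.frame(cell_id = character(0),
                                total_umis = numeric(0),
                                mito_umis = numeric(0),
                                ltc_umis = numeric(0),
                                host_signal = numeric(0),
                                capture_id = character(0)),
                truth = data.frame(cell_id = character(0),
                                   label = character(0),
                                   members = character(0)),
                captured = captured))
  }
  ord <- sample(length(units))
  units <- units[ord]; is_host <- is_host[ord]
  n_doub <- min(round(config$doublet_fraction * length(units)),
                floor(length(units) / 2))
  # first 2*n_doub units pair up into n_doub barcodes
  barcode_members <- c(
    if (n_doub > 0) lapply(seq_len(n_doub), function(i)
      units[c(2 * i - 1, 2 * i)]) else list(),
    as.list(units[seq_len(length(units) - 2 * n_doub) + 2 * n_doub]))
  bc_ids <- sprintf("bc_%05d", seq_along(barcode_members))

  one_cell_rows <- function(cell) {
    s <- leaf_matrix[cell, ]
    obs <- which(!is.na(s))
    if (length(obs) == 0) return(NULL)
    k <- length(obs)
    # support is drawn per cassette (sites share one transcript) with mild
    # per-site jitter, so true alleles respect the within-cassette relative
    # filters by construction
    cu <- unique(cass_of[obs])
    base_umi <- stats::setNames(rnb_shift(length(cu), config$umi_mu,
                                          config$umi_size, 5L), cu)
    base_rpu <- stats::setNames(rnb_shift(length(cu), config$rpu_mu,
                                          config$rpu_size, 4L), cu)
    umi <- pmax(5L, round(base_umi[cass_of[obs]] *
                            stats::runif(k, 0.7, 1)))
    rpu <- pmax(4L, round(base_rpu[cass_of[obs]] *
                            stats::runif(k, 0.85, 1)))
    data.frame(intBC = cass_of[obs], site = site_of[obs],
               lineage_mark = ifelse(s[obs] == 0L, "UE",
                                     paste0("M", s[obs])),
               umi_count = as.integer(umi), rpu = as.integer(rpu))
  }

  tabs <- vector("list", length(barcode_members))
  truth_label <- character(length(barcode_members))
  for (i in seq_along(barcode_members)) {
    mem <- barcode_members[[i]]
    hosts <- is_host[match(mem, units)]
    truth_label[i] <- if (length(mem) == 1) {
      if (hosts[1]) "host" else "donor"
    } else if (all(hosts)) "host_host_doublet" else if (any(hosts))
      "donor_host_doublet" else "donor_donor_doublet"
    rows <- do.call(rbind, lapply(mem[!hosts], one_cell_rows))
    # ambient alleles, one block per constituent cell
    n_amb <- stats::rpois(1, config$ambient_rate * length(mem))
    if (n_amb > 0) {
      ac <- sample(length(char_ids), n_amb, replace = TRUE)
      amb <- data.frame(intBC = cass_of[ac], site = site_of[ac],
                        lineage_mark = paste0("M", sample.int(
                          config$marks_per_site, n_amb, replace = TRUE,
                          prob = config$mark_probs)),
                        umi_count = 1L + stats::rpois(n_amb, 1),
                        rpu = sample(1:3, n_amb, replace = TRUE))
      rows <- rbind(rows, amb)
    }
    if (!is.null(rows) && nrow(rows) > 0) {
      rows$cell_id <- bc_ids[i]
      tabs[[i]] <- rows
    }
  }
  tab <- as.data.frame(data.table::rbindlist(tabs[!vapply(tabs, is.null, logical(1))]))
  if (nrow(tab) == 0) {
    tab <- data.frame(cell_id = character(0), intBC = character(0),
                      site = integer(0), lineage_mark = character(0),
                      umi_count = integer(0), read_count = integer(0))
  } else {
    # duplicate (cell,intBC,site,mark) rows from doublet merging: sum counts
    dt <- data.table::as.data.table(tab)
    dt <- dt[, list(umi_count = sum(umi_count),
                    read_count = sum(umi_count * rpu)),
             by = c("cell_id", "intBC", "site", "lineage_mark")]
    tab <- as.data.frame(dt)[, c("cell_id", "intBC", "site", "lineage_mark",
                                 "umi_count", "read_count")]
  }

  # per-barcode QC records; totals roughly log-normal, doublets sum
  n_bc <- length(barcode_members)
  size_f <- lengths(barcode_members)
  total <- round(stats::rlnorm(n_bc, log(2e4), 0.3)) * size_f
  mito <- stats::rbinom(n_bc, total, 0.01)
  ltc_agg <- tapply(tab$umi_count, tab$cell_id, sum)
  ltc <- as.numeric(ltc_agg[bc_ids])
  ltc[is.na(ltc)] <- 0
  host_members <- vapply(seq_len(n_bc), function(i)
    sum(is_host[match(barcode_members[[i]], units)]), numeric(1))
  host_sig <- stats::rnorm(n_bc, 0, 1) + 4 * host_members / size_f
  qc <- data.frame(cell_id = bc_ids, total_umis = total, mito_umis = mito,
                   ltc_umis = as.numeric(ltc), host_signal = host_sig,
                   capture_id = "capture_1")
  truth <- data.frame(cell_id = bc_ids, label = truth_label,
                      members = vapply(barcode_members, paste,
                                       character(1), collapse = ";"))
  list(allele_table = tab, qc = qc, truth = truth, captured = captured)
}

#' Run the full synthetic-embryo generator
#'
#' Convenience wrapper seeding the RNG once from `config$seed` and chaining
#' [simulate_division_tree()], [simulate_editing()], an optional
#' [simulate_fate_map()], and [simulate_allele_table()].
#'
#' @param config a [sim_config()].
#' @param commitments optional commitment table for [simulate_fate_map()].
#' @param leakage fate-label leakage probability.
#' @return list with `tree`, `editing`, `fates` (or NULL), `reads`
#'   (allele table + QC + truth), and `config`.
#' @export
simulate_recorder_experiment <- function(config = sim_config(),
                                         commitments = NULL, leakage = 0) {
  set.seed(config$seed)
  tree <- simulate_division_tree(config)
  editing <- simulate_editing(tree, config)
  fates <- if (!is.null(commitments))
    simulate_fate_map(tree, commitments, leakage = leakage) else NULL
  reads <- simulate_allele_table(editing$leaf_matrix, config)
  list(tree = tree, editing = editing, fates = fates, reads = reads,
       config = config)
}
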