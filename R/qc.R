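#' Adaptive two-component Gaussian-mixture threshold
#'
#' Fits a two-component one-dimensional Gaussian mixture to a vector of
#' scores and returns the cutoff separating the lower-mean from the
#' higher-mean component: the smallest value between the two component means
#' at which the posterior responsibility flips to the higher-mean component.
#' Used wherever the QC workflow removes "the lower peak" of a per-capture
#' distribution.
#'
#' When the distribution does not actually support two components — the
#' Bayesian information criterion prefers a single Gaussian, or the fitted
#' component means differ by less than half a pooled standard deviation, or
#' the fit fails outright (e.g. all values identical) — the `degenerate`
#' flag is set and `cutoff` is `NA`: callers must not filter.
#'
#' @param values numeric vector of at least 20 finite values.
#' @param min_separation minimum |mean difference| in pooled-SD units for a
#'   non-degenerate split.
#' @return list with `cutoff`, `degenerate`, `means`, `sds`, `weights`.
#' @export
gmm_threshold <- function(values, min_separation = 0.5) {
  if (length(values) < 20) stop("gmm_threshold needs at least 20 values")
  if (any(!is.finite(values))) stop("gmm_threshold: non-finite values")
  deg <- list(cutoff = NA_real_, degenerate = TRUE,
              means = rep(mean(values), 2), sds = rep(stats::sd(values), 2),
              weights = c(0.5, 0.5))
  if (stats::sd(values) == 0) return(deg)
  mclustBIC <- mclust::mclustBIC  # Mclust resolves this in the caller frame
  fit <- tryCatch(
    mclust::Mclust(values, G = 2, modelNames = c("V", "E"), verbose = FALSE),
    error = function(e) NULL)
  if (is.null(fit)) return(deg)
  mu <- fit$parameters$mean
  sig2 <- fit$parameters$variance$sigmasq
  if (length(sig2) == 1) sig2 <- rep(sig2, 2)
  w <- fit$parameters$pro
  o <- order(mu)
  mu <- mu[o]; sig2 <- sig2[o]; w <- w[o]
  pooled <- sqrt(sum(w * sig2))
  fit1 <- tryCatch(
    mclust::Mclust(values, G = 1, modelNames = "V", verbose = FALSE),
    error = function(e) NULL)
  one_wins <- !is.null(fit1) && is.finite(fit1$bic) && is.finite(fit$bic) &&
    fit1$bic >= fit$bic  # mclust BIC: larger is better
  if (one_wins || !is.finite(pooled) || pooled == 0 ||
      (mu[2] - mu[1]) < min_separation * pooled)
    return(list(cutoff = NA_real_, degenerate = TRUE, means = mu,
                sds = sqrt(sig2), weights = w))
  grid <- seq(mu[1], mu[2], length.out = 512)
  post_hi <- w[2] * stats::dnorm(grid, mu[2], sqrt(sig2[2]))
  post_lo <- w[1] * stats::dnorm(grid, mu[1], sqrt(sig2[1]))
  flip <- which(post_hi >= post_lo)
  cutoff <- if (length(flip) == 0) mean(mu) else grid[flip[1]]
  list(cutoff = cutoff, degenerate = FALSE, means = mu, sds = sqrt(sig2),
       weights = w)
}

#' Remove low-quality cells from per-cell QC records
#'
#' Per capture: (i) adaptive threshold ([gmm_threshold()], on log1p counts)
#' applied to mitochondrial counts among cells with detectable mitochondrial
#' signal, removing the lower peak; (ii) adaptive threshold on total UMI
#' counts among cells passing the mitochondrial filter and with mitochondrial
#' fraction below `mito_cap`; (iii) a hard floor of `min_umis` total UMIs,
#' applied last across all captures. Cells at or above `mito_cap`
#' mitochondrial fraction are removed as low-quality.
#'
#' @param records data.frame with columns `cell_id`, `total_umis`,
#'   `mito_umis`, `capture_id`.
#' @param min_umis hard minimum total-UMI cutoff (default 5000; a lower value
#'   such as 100 can be passed for shallowly sequenced captures).
#' @param mito_cap maximum mitochondrial fraction (default 0.02).
#' @return character vector of retained cell IDs.
#' @export
filter_cells <- function(records, min_umis = 5000, mito_cap = 0.02) {
  if (nrow(records) == 0) return(character(0))
  stopifnot(all(records$mito_umis <= records$total_umis))
  keep <- character(0)
  for (cap in unique(records$capture_id)) {
    r <- records[records$capture_id == cap, , drop = FALSE]
    pass <- rep(TRUE, nrow(r))
    with_mito <- r$mito_umis > 0
    if (sum(with_mito) >= 20) {
      th <- gmm_threshold(log1p(r$mito_umis[with_mito]))
      if (!th$degenerate)
        pass[with_mito][log1p(r$mito_umis[with_mito]) < th$cutoff] <- FALSE
    }
    frac <- r$mito_umis / pmax(r$total_umis, 1)
    pass[frac >= mito_cap] <- FALSE
    pop <- which(pass)
    if (length(pop) >= 20) {
      th <- gmm_threshold(log1p(r$total_umis[pop]))
      if (!th$degenerate)
        pass[pop][log1p(r$total_umis[pop]) < th$cutoff] <- FALSE
    }
    keep <- c(keep, r$cell_id[pass])
  }
  records$cell_id[records$cell_id %in% keep &
                    records$total_umis >= min_umis]
}

#' Filter ambient and artifactual alleles from an allele table
#'
#' Keeps alleles with at least `min_umis` UMIs and `min_rpu` reads per UMI.
#' Within each (cell, intBC) pair, alleles whose reads-per-UMI falls below
#' `rel_frac` of the pair maximum are dropped unless they reach `rescue_rpu`
#' reads per UMI, and every allele's UMI count must reach `rel_frac` of the
#' pair's maximum UMI count. The filter is idempotent.
#'
#' @param table allele table (cell_id, intBC, site, lineage_mark, umi_count,
#'   read_count).
#' @param min_umis,min_rpu absolute support floors (defaults 5 UMIs, 4
#'   reads/UMI).
#' @param rel_frac within-pair relative threshold (default 0.25).
#' @param rescue_rpu reads-per-UMI value that rescues a low-relative allele
#'   (default 10).
#' @return the filtered allele table.
#' @export
filter_alleles <- function(table, min_umis = 5, min_rpu = 4,
                           rel_frac = 0.25, rescue_rpu = 10) {
  if (nrow(table) == 0) return(table)
  bad <- table$umi_count == 0 & table$read_count > 0
  if (any(bad)) {
    warning(sprintf("dropping %d malformed alleles (0 UMIs, >0 reads)",
                    sum(bad)))
    table <- table[!bad, , drop = FALSE]
  }
  dt <- data.table::as.data.table(table)
  dt[, rpu := read_count / umi_count]
  dt <- dt[umi_count >= min_umis & rpu >= min_rpu]
  if (nrow(dt) > 0) {
    dt[, `:=`(max_rpu = max(rpu), max_umi = max(umi_count)),
       by = c("cell_id", "intBC")]
    dt <- dt[(rpu >= rel_frac * max_rpu | rpu >= rescue_rpu) &
               umi_count >= rel_frac * max_umi]
    dt[, c("max_rpu", "max_umi") := NULL]
  }
  dt[, rpu := NULL]
  as.data.frame(dt)
}

# internal: dominant allele per (cell,intBC,site); ties broken by read_count
# then lexicographic mark ID (deterministic)
dominant_alleles <- function(table) {
  dt <- data.table::as.data.table(table)
  data.table::setorder(dt, cell_id, intBC, site, -umi_count, -read_count,
                       lineage_mark)
  as.data.frame(dt[, utils::head(.SD, 1), by = c("cell_id", "intBC", "site")])
}

#' Classify barcodes as donor, host or doublets
#'
#' Implements the donor/host/doublet calling cascade: (i) donor calls by
#' adaptive thresholding ([gmm_threshold()]) on the log ratio of
#' median-normalized LTC UMIs to median-normalized transcriptome UMIs per
#' capture; (ii) donor cells whose host-signal score exceeds an adaptive
#' threshold become donor-host doublets; (iii) per (cell, intBC) a dominant
#' allele (largest UMI fraction) is selected and the allele-conflict fraction
#' — reads on non-dominant alleles over total reads, restricted to
#' integrations with low background conflict — flags donor-donor doublets
#' when strictly above `conflict_cap`; (iv) host cells whose normalized
#' transcriptome counts exceed the point where the local donor-doublet
#' frequency (rolling window) crosses 50% become host-host doublets.
#'
#' @param table filtered allele table (see [filter_alleles()]).
#' @param qc per-cell QC records with `cell_id`, `total_umis`, `ltc_umis`,
#'   `host_signal`, `capture_id`.
#' @param retained optional character vector of cell IDs that passed
#'   [filter_cells()]; others are labelled `low_quality`.
#' @param conflict_cap conflict fraction above which (strictly) a donor cell
#'   is a donor-donor doublet (default 0.03).
#' @param background_conflict_max integrations whose median per-cell conflict
#'   is below this are "low background" and enter the per-cell conflict
#'   recomputation (default 0.01).
#' @param window rolling-window width (cells) for the host-host doublet
#'   frequency estimate (default 501).
#' @return data.frame `cell_id`, `label` with one row per cell in `qc`;
#'   labels in donor/host/donor_host_doublet/donor_donor_doublet/
#'   host_host_doublet/low_quality.
#' @export
classify_cells <- function(table, qc, retained = NULL, conflict_cap = 0.03,
                           background_conflict_max = 0.01, window = 501) {
  if (is.null(retained)) retained <- qc$cell_id
  lab <- stats::setNames(rep("low_quality", nrow(qc)), qc$cell_id)
  r <- qc[qc$cell_id %in% retained, , drop = FALSE]
  for (cap in unique(r$capture_id)) {
    rc <- r[r$capture_id == cap, , drop = FALSE]
    med_ltc <- stats::median(rc$ltc_umis)
    med_txn <- stats::median(rc$total_umis)
    if (med_ltc <= 0) med_ltc <- 1
    ratio <- (rc$ltc_umis / med_ltc) / (rc$total_umis / med_txn)
    th <- gmm_threshold(log1p(ratio))
    if (th$degenerate)
      stop("classify_cells: no separable donor seed population in capture ",
           cap, " (LTC/transcriptome ratio mixture is degenerate)")
    donor <- log1p(ratio) >= th$cutoff
    lab[rc$cell_id] <- ifelse(donor, "donor", "host")

    # donor-host doublets from host signal among donors
    if (sum(donor) >= 20) {
      th_h <- gmm_threshold(rc$host_signal[donor])
      if (!th_h$degenerate)
        lab[rc$cell_id[donor & rc$host_signal >= th_h$cutoff]] <-
          "donor_host_doublet"
    }

    # donor-donor doublets from allele conflict
    donors_now <- rc$cell_id[lab[rc$cell_id] == "donor"]
    conf <- allele_conflict(table[table$cell_id %in% donors_now, ,
                                  drop = FALSE],
                            background_conflict_max = background_conflict_max)
    dd <- conf$cell_id[conf$conflict > conflict_cap]
    lab[dd] <- "donor_donor_doublet"

    # host-host doublets from local doublet frequency along normalized counts
    norm_txn <- rc$total_umis / med_txn
    is_donorish <- lab[rc$cell_id] %in%
      c("donor", "donor_donor_doublet", "donor_host_doublet")
    if (sum(is_donorish) >= window) {
      o <- order(norm_txn[is_donorish])
      flag <- as.numeric(lab[rc$cell_id[is_donorish]][o] != "donor")
      roll <- stats::filter(flag, rep(1 / window, window), sides = 2)
      cross <- which(!is.na(roll) & roll > 0.5)
      if (length(cross) > 0) {
        cutoff_norm <- sort(norm_txn[is_donorish])[cross[1]]
        hh <- rc$cell_id[lab[rc$cell_id] == "host" & norm_txn > cutoff_norm]
        lab[hh] <- "host_host_doublet"
      }
    }
  }
  data.frame(cell_id = names(lab), label = unname(lab))
}

#' Per-cell allele conflict fractions
#'
#' For each (cell, intBC) the dominant allele is the one with the largest UMI
#' fraction (ties by read count, then mark ID); the conflict fraction is the
#' share of reads on non-dominant alleles. Integrations whose median per-cell
#' conflict exceeds `background_conflict_max` are excluded as high-background
#' before per-cell conflict is recomputed.
#'
#' @inheritParams classify_cells
#' @return data.frame `cell_id`, `conflict`.
#' @export
allele_conflict <- function(table, background_conflict_max = 0.01) {
  if (nrow(table) == 0)
    return(data.frame(cell_id = character(0), conflict = numeric(0)))
  dt <- data.table::as.data.table(table)
  data.table::setorder(dt, cell_id, intBC, site, -umi_count, -read_count,
                       lineage_mark)
  dt[, dominant := seq_len(.N) == 1L, by = c("cell_id", "intBC", "site")]
  # background conflict per integration, across cells
  per_cell_bc <- dt[, list(conflict = sum(read_count[!dominant]) /
                             sum(read_count)), by = c("cell_id", "intBC")]
  bg <- per_cell_bc[, list(bg = stats::median(conflict)), by = "intBC"]
  low_bg <- bg$intBC[bg$bg < background_conflict_max]
  use <- dt[intBC %in% low_bg]
  if (nrow(use) == 0) use <- dt
  out <- use[, list(conflict = sum(read_count[!dominant]) / sum(read_count)),
             by = "cell_id"]
  res <- merge(data.frame(cell_id = unique(dt$cell_id)), as.data.frame(out),
               by = "cell_id", all.x = TRUE)
  res$conflict[is.na(res$conflict)] <- 0
  res
}
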