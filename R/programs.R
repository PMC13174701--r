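#' Library-size normalization and log transform
#'
#' Scales each cell's counts to a common total and applies `log1p`; the
#' expected preprocessing for [local_autocorrelation()] and
#' [score_programs()].
#'
#' @param counts cells x genes numeric matrix of raw counts.
#' @param target total counts per cell after scaling (default 20000).
#' @return normalized matrix of the same shape.
#' @export
normalize_expression <- function(counts, target = 2e4) {
  tot <- rowSums(counts)
  log1p(counts / pmax(tot, 1) * target)
}

#' Lineage-tree neighbor kernel
#'
#' For each leaf, the `k` nearest leaves by tree distance (path length in
#' days on the dated tree) with weights `exp(-d^2 / sigma^2)`, row-
#' normalized to sum to 1. With fewer than `k + 1` leaves all others are
#' used (flagged).
#'
#' @param tree dated `lineage_tree`.
#' @param k neighbors (default 5).
#' @param sigma kernel bandwidth in days (default 2).
#' @return list of class `tree_kernel` with `neighbors` (n x k index
#'   matrix into the leaf ordering), `weights` (n x k, rows sum to 1),
#'   `cell_ids`, and `flagged` (TRUE when k >= n).
#' @export
tree_kernel <- function(tree, k = 5, sigma = 2.0) {
  leaves <- tree_leaves(tree)
  nl <- length(leaves)
  flagged <- FALSE
  if (k >= nl) { k <- nl - 1; flagged <- TRUE }
  if (k < 1) stop("need at least 2 leaves")
  Mt <- tree_mrca_times(tree)
  d_leaf <- tree$time[leaves]
  D <- outer(d_leaf, d_leaf, "+") - 2 * Mt
  diag(D) <- Inf
  nb <- matrix(0L, nl, k)
  W <- matrix(0, nl, k)
  for (i in seq_len(nl)) {
    nb[i, ] <- order(D[i, ])[seq_len(k)]
    d <- D[i, nb[i, ]]
    w <- exp(-d^2 / sigma^2)
    if (sum(w) == 0) w <- rep(1, k)
    W[i, ] <- w / sum(w)
  }
  structure(list(neighbors = nb, weights = W,
                 cell_ids = tree$label[leaves], flagged = flagged),
            class = "tree_kernel")
}

# internal: dense row-stochastic kernel matrix
kernel_matrix <- function(kernel) {
  nl <- length(kernel$cell_ids)
  W <- matrix(0, nl, nl, dimnames = list(kernel$cell_ids, kernel$cell_ids))
  for (i in seq_len(nl)) W[i, kernel$neighbors[i, ]] <- kernel$weights[i, ]
  W
}

#' Gene-level local autocorrelation on a lineage kernel
#'
#' For gene g with standardized expression z, the statistic is
#' `C_g = mean_i sum_j w_ij z_i z_j` — a correlation-like local covariance
#' in \[-1, 1\], high when a gene's expression covaries among lineage
#' neighbors. Significance is assessed by permuting cells (jointly for all
#' genes per permutation): `Z = (C - mean(null)) / sd(null)`. Zero-variance
#' genes get C = 0 and are flagged.
#'
#' @param expr cells x genes normalized expression matrix (rows named by
#'   cell ID, matching the kernel).
#' @param kernel a [tree_kernel()].
#' @param n_perm permutations (default 200).
#' @param c_min retention threshold on C (default 0.1, exclusive).
#' @param seed optional seed.
#' @return data.frame per gene: `gene`, `C`, `Z`, `retained`,
#'   `zero_variance`.
#' @export
local_autocorrelation <- function(expr, kernel, n_perm = 200, c_min = 0.1,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  E <- expr[kernel$cell_ids, , drop = FALSE]
  n <- nrow(E)
  sds <- apply(E, 2, stats::sd)
  zerov <- sds == 0
  Zs <- scale(E)
  Zs[, zerov] <- 0
  W <- kernel_matrix(kernel)
  Cstat <- colSums(Zs * (W %*% Zs)) / n
  nullC <- matrix(NA_real_, n_perm, ncol(E))
  for (k in seq_len(n_perm)) {
    pi <- sample.int(n)
    Zp <- Zs[pi, , drop = FALSE]
    nullC[k, ] <- colSums(Zp * (W %*% Zp)) / n
  }
  nsd <- apply(nullC, 2, stats::sd)
  Zscore <- (Cstat - colMeans(nullC)) / nsd
  Zscore[zerov] <- 0
  Cstat[zerov] <- 0
  data.frame(gene = colnames(E), C = Cstat, Z = Zscore,
             retained = Cstat > c_min & !zerov,
             zero_variance = zerov, row.names = NULL)
}

#' Pairwise local-correlation Z-scores between genes
#'
#' The pairwise statistic is the symmetrized local covariance
#' `(z_g' W z_h + z_h' W z_g) / (2n)` between standardized genes on the
#' lineage kernel; its null (cells permuted jointly, shared across all
#' pairs) yields a permutation Z-score matrix used for program grouping.
#'
#' @inheritParams local_autocorrelation
#' @param genes character vector of genes to include (typically the
#'   retained set from [local_autocorrelation()]).
#' @return symmetric Z matrix (genes x genes) with attribute `C` (the
#'   statistic matrix).
#' @export
pairwise_local_correlation <- function(expr, kernel, genes, n_perm = 200,
                                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  E <- expr[kernel$cell_ids, genes, drop = FALSE]
  n <- nrow(E)
  Zs <- scale(E)
  Zs[, apply(E, 2, stats::sd) == 0] <- 0
  W <- kernel_matrix(kernel)
  stat <- function(Zm) {
    S <- crossprod(Zm, W %*% Zm) / n
    (S + t(S)) / 2
  }
  obs <- stat(Zs)
  g <- ncol(E)
  m1 <- matrix(0, g, g); m2 <- matrix(0, g, g)
  for (k in seq_len(n_perm)) {
    S <- stat(Zs[sample.int(n), , drop = FALSE])
    m1 <- m1 + S
    m2 <- m2 + S^2
  }
  mu <- m1 / n_perm
  sdv <- sqrt(pmax(m2 / n_perm - mu^2, 1e-12))
  Z <- (obs - mu) / sdv
  dimnames(Z) <- list(genes, genes)
  attr(Z, "C") <- obs
  Z
}

#' Group genes into programs from a pairwise Z matrix
#'
#' Coarse clusters are cut from an average-linkage hierarchical clustering
#' of the Z matrix (distance `max(Z) - Z`, cut so that coarse clusters hang
#' together at roughly the `z_min` level); within each coarse cluster gene
#' groups are merged agglomeratively (always the pair with the highest
#' merged mean pairwise Z) while the merged group's mean pairwise Z stays at
#' or above `z_min`. Groups with fewer than `min_genes` genes are
#' discarded. The greedy-maximum merge order makes the result independent of
#' gene input order on block-structured inputs.
#'
#' @param Z symmetric pairwise Z matrix (genes x genes).
#' @param z_min minimum mean pairwise Z of a program (default 80).
#' @param min_genes minimum program size (default 4).
#' @return data.frame `gene`, `program` (program IDs `P1`, `P2`, ... in
#'   decreasing program-Z order); attribute `programs` is a data.frame of
#'   per-program size and mean pairwise Z.
#' @export
group_programs <- function(Z, z_min = 80, min_genes = 4) {
  genes <- colnames(Z)
  if (length(genes) == 0)
    return(structure(data.frame(gene = character(0), program = character(0)),
                     programs = data.frame()))
  if (length(genes) < 2) coarse <- stats::setNames(1L, genes)
  else {
    d <- stats::as.dist(max(Z) - Z)
    hc <- stats::hclust(d, method = "average")
    coarse <- stats::cutree(hc, h = max(Z) - z_min)
  }
  groups <- list()
  for (cl in unique(coarse)) {
    gg <- genes[coarse == cl]
    # agglomerative merging within the coarse cluster
    parts <- as.list(gg)
    repeat {
      if (length(parts) < 2) break
      best <- NULL
      for (i in seq_along(parts)) for (j in seq_along(parts)) {
        if (j <= i) next
        mg <- c(parts[[i]], parts[[j]])
        zz <- Z[mg, mg]
        mz <- mean(zz[upper.tri(zz)])
        if (mz >= z_min && (is.null(best) || mz > best$mz))
          best <- list(i = i, j = j, mz = mz)
      }
      if (is.null(best)) break
      merged <- sort(c(parts[[best$i]], parts[[best$j]]))
      parts <- c(parts[-c(best$i, best$j)], list(merged))
    }
    groups <- c(groups, parts)
  }
  keep <- groups[lengths(groups) >= min_genes]
  if (length(keep) == 0)
    return(structure(data.frame(gene = character(0), program = character(0)),
                     programs = data.frame()))
  meanz <- vapply(keep, function(g) {
    zz <- Z[g, g]; mean(zz[upper.tri(zz)])
  }, numeric(1))
  o <- order(meanz, decreasing = TRUE)
  keep <- keep[o]; meanz <- meanz[o]
  out <- do.call(rbind, lapply(seq_along(keep), function(i)
    data.frame(gene = keep[[i]], program = paste0("P", i))))
  structure(out,
            programs = data.frame(program = paste0("P", seq_along(keep)),
                                  n_genes = lengths(keep),
                                  mean_z = meanz))
}

#' Score program activity per cell with bin-matched controls
#'
#' Genes are split into `n_bins` bins by mean expression; each program's
#' per-cell score is the mean expression of program genes minus the mean
#' expression of `controls_per_gene` random genes drawn from each program
#' gene's bin (the program's own genes are excluded from control pools,
#' except when a bin holds nothing else). Seed-reproducible; invariant to
#' gene order within a program.
#'
#' @param expr cells x genes normalized expression.
#' @param programs data.frame `gene`, `program` (see [group_programs()]).
#' @param n_bins expression bins (default 25).
#' @param controls_per_gene control genes per program gene (default 100).
#' @param seed optional seed.
#' @return cells x programs numeric matrix of scores.
#' @export
score_programs <- function(expr, programs, n_bins = 25,
                           controls_per_gene = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  missing_genes <- setdiff(programs$gene, colnames(expr))
  if (length(missing_genes) > 0)
    stop("program genes absent from matrix: ",
         paste(missing_genes, collapse = ", "))
  mu <- colMeans(expr)
  qs <- stats::quantile(mu, probs = seq(0, 1, length.out = n_bins + 1))
  bin <- cut(mu, breaks = unique(qs), include.lowest = TRUE, labels = FALSE)
  names(bin) <- colnames(expr)
  prog_ids <- unique(programs$program)
  out <- matrix(0, nrow(expr), length(prog_ids),
                dimnames = list(rownames(expr), prog_ids))
  for (pid in prog_ids) {
    gg <- sort(programs$gene[programs$program == pid])
    ctrl <- unlist(lapply(gg, function(g) {
      pool <- setdiff(names(bin)[bin == bin[g]], gg)
      if (length(pool) == 0) pool <- names(bin)[bin == bin[g]]
      sample(pool, min(controls_per_gene, length(pool)),
             replace = length(pool) < controls_per_gene)
    }))
    out[, pid] <- rowMeans(expr[, gg, drop = FALSE]) -
      rowMeans(expr[, ctrl, drop = FALSE])
  }
  out
}
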