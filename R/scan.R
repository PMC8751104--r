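#' Correlate off-diagonals of a similarity and a genetic correlation matrix
#'
#' Pearson correlation over the M(M-1)/2 upper-triangle pairs, with the
#' two-sided p-value from the t distribution on M(M-1)/2 - 2 degrees of
#' freedom (as `stats::cor.test`). A zero-variance off-diagonal vector (e.g.
#' the all-zero similarity matrix of a constant covariate) is degenerate:
#' r is undefined and p = 1 by convention.
#'
#' @param S Similarity matrix ([similarity_kernel()]).
#' @param P Genetic correlation matrix (same environments, same order).
#' @return List with `r`, `p`, `n_pairs`, `degenerate`.
#' @export
correlate_offdiag <- function(S, P) {
  stopifnot(is.matrix(S), is.matrix(P), all(dim(S) == dim(P)))
  if (nrow(S) < 4L) stop("need at least 4 environments")
  ut <- upper.tri(S)
  x <- S[ut]; y <- P[ut]
  if (sd(x) < 1e-14 || sd(y) < 1e-14)
    return(list(r = NA_real_, p = 1, n_pairs = sum(ut), degenerate = TRUE))
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n_pairs = sum(ut),
       degenerate = FALSE)
}

#' Bonferroni significance threshold for the covariate scan
#'
#' `alpha / (n_covariates * n_traits)`; e.g. 0.05/(6,510 x 6) = 1.28e-6 for
#' the standard 30-stage, 14-factor, six-trait analysis.
#'
#' @param n_covariates Number of environmental covariates scanned.
#' @param n_traits Number of traits.
#' @param alpha Family-wise error level.
#' @return The per-test p-value threshold.
#' @export
bonferroni_threshold <- function(n_covariates, n_traits, alpha = 0.05) {
  stopifnot(n_covariates >= 1, n_traits >= 1, alpha >= 0, alpha < 1)
  alpha / (n_covariates * n_traits)
}

#' Number of environment pairs fitted by the pairwise bivariate models
#'
#' @param M Number of environments.
#' @return M(M-1)/2.
#' @export
#' @examples
#' n_env_pairs(52) # 1326
n_env_pairs <- function(M) {
  stopifnot(M >= 2)
  as.integer(M * (M - 1) / 2)
}

# within-cluster dispersion of the gap statistic:
# W = 0.5 * sum_r sum(dist within cluster r) / n_r, with unsquared Euclidean
# distances as in the conventional clusGap default (d.power = 1)
.gap_W <- function(dmat, labels) {
  s <- 0
  for (ix in split(seq_along(labels), labels))
    s <- s + sum(dmat[ix, ix]) / (2 * length(ix))
  s / 2
}

#' Cluster environmental covariates with a gap-statistic cluster count
#'
#' Covariates are represented by their standardised environment-value vectors
#' (mean 0, SD 1 across environments; constant covariates become zero
#' vectors). Complete-linkage hierarchical clustering on Euclidean distances
#' gives the hierarchy; the number of clusters is chosen by the gap statistic
#' with `B_ref` uniform reference datasets drawn over the feature bounding box
#' and the firstSEmax rule. The hierarchy is computed once per dataset and cut
#' at every candidate k.
#'
#' @param cov_table Environments-by-covariates matrix
#'   ([build_covariate_table()]).
#' @param max_k Largest cluster count considered (default
#'   `min(50, n_covariates - 1)`).
#' @param B_ref Number of uniform reference datasets (default 50).
#' @return Integer cluster labels (1..k) named by covariate id, with
#'   attributes `"k"`, `"gap"` (data.frame `k`, `logW`, `E_logW`, `gap`,
#'   `SE_sim`) and `"hclust"`.
#' @export
cluster_covariates <- function(cov_table, max_k = NULL, B_ref = 50L) {
  Xf <- t(cov_table) # covariates as observations, environments as features
  mu <- rowMeans(Xf)
  s <- apply(Xf, 1L, sd)
  s[s < 1e-14] <- Inf # constant covariates -> zero vectors
  Xf <- (Xf - mu) / s
  n <- nrow(Xf)
  if (n < 2L) stop("need at least 2 covariates to cluster")
  if (is.null(max_k)) max_k <- min(50L, n - 1L)
  if (max_k < 1L) stop("'max_k' must be >= 1")
  max_k <- min(max_k, n - 1L)

  cuts_all_k <- function(M) {
    d <- dist(M)
    hc <- hclust(d, method = "complete")
    dmat <- as.matrix(d)
    W <- vapply(seq_len(max_k), function(k)
      .gap_W(dmat, if (k == 1L) rep(1L, nrow(M)) else cutree(hc, k)),
      numeric(1))
    list(hc = hc, logW = log(W))
  }
  obs <- cuts_all_k(Xf)

  lo <- apply(Xf, 2L, min); hi <- apply(Xf, 2L, max)
  logW_ref <- matrix(NA_real_, B_ref, max_k)
  for (b in seq_len(B_ref)) {
    Xr <- vapply(seq_along(lo), function(j) runif(n, lo[j], hi[j]),
                 numeric(n))
    logW_ref[b, ] <- cuts_all_k(Xr)$logW
  }
  E_logW <- colMeans(logW_ref)
  SE_sim <- apply(logW_ref, 2L, sd) * sqrt(1 + 1 / B_ref)
  gap <- E_logW - obs$logW
  k_hat <- cluster::maxSE(gap, SE_sim, method = "firstSEmax")
  labels <- if (k_hat == 1L) rep(1L, n) else cutree(obs$hc, k_hat)
  names(labels) <- rownames(Xf)
  structure(labels, k = k_hat,
            gap = data.frame(k = seq_len(max_k), logW = obs$logW,
                             E_logW = E_logW, gap = gap, SE_sim = SE_sim),
            hclust = obs$hc)
}

#' Scan all covariates against a genetic correlation matrix
#'
#' Computes, for every covariate column, the Pearson correlation between the
#' off-diagonals of its linear-kernel similarity matrix and of the genetic
#' correlation matrix, with p-values and Bonferroni significance calls.
#'
#' @param cov_table Environments-by-covariates matrix.
#' @param P Genetic correlation matrix over the same environments (row order
#'   is matched by name).
#' @param n_covariates_total,n_traits Totals defining the Bonferroni
#'   correction (defaults: covariates in `cov_table`, one trait).
#' @param alpha Family-wise level (default 0.05).
#' @return Data.frame with one row per covariate: `covariate`, `factor`,
#'   `start`, `end`, `r`, `r2`, `p`, `neg_log10_p`, `significant`,
#'   `degenerate`; the threshold is in `attr(, "threshold")`.
#' @export
scan_covariates <- function(cov_table, P, n_covariates_total = ncol(cov_table),
                            n_traits = 1L, alpha = 0.05) {
  envs <- rownames(P)
  stopifnot(all(envs %in% rownames(cov_table)))
  ct <- cov_table[envs, , drop = FALSE]
  thr <- bonferroni_threshold(n_covariates_total, n_traits, alpha)
  res <- lapply(colnames(ct), function(id)
    correlate_offdiag(similarity_kernel(ct, id), P))
  r <- vapply(res, `[[`, numeric(1), "r")
  p <- vapply(res, `[[`, numeric(1), "p")
  info <- attr(cov_table, "info")
  if (is.null(info))
    info <- data.frame(covariate = colnames(ct), factor = NA, start = NA,
                       end = NA)
  out <- data.frame(
    covariate = colnames(ct),
    factor = info$factor[match(colnames(ct), info$covariate)],
    start = info$start[match(colnames(ct), info$covariate)],
    end = info$end[match(colnames(ct), info$covariate)],
    r = r, r2 = r^2, p = p, neg_log10_p = -log10(p),
    significant = !is.na(p) & p < thr,
    degenerate = vapply(res, `[[`, logical(1), "degenerate"),
    stringsAsFactors = FALSE
  )
  attr(out, "threshold") <- thr
  out
}

#' Select one covariate per cluster among the significant ones
#'
#' Within each cluster, among the significant covariates, the one with the
#' highest r-squared is selected; exact ties break deterministically towards
#' the earlier window (smaller start stage, then end stage, then factor
#' order). Clusters without significant members select nothing.
#'
#' @param scan_result Data.frame from [scan_covariates()].
#' @param clusters Labels from [cluster_covariates()] over the same
#'   covariates.
#' @return `scan_result` with columns `cluster_id` and `selected` added.
#' @export
prune_significant <- function(scan_result, clusters) {
  stopifnot(all(scan_result$covariate %in% names(clusters)))
  scan_result$cluster_id <-
    as.integer(clusters[scan_result$covariate])
  scan_result$selected <- FALSE
  fac_rank <- match(scan_result$factor, unique(scan_result$factor))
  for (cl in unique(scan_result$cluster_id)) {
    ix <- which(scan_result$cluster_id == cl & scan_result$significant)
    if (!length(ix)) next
    ord <- order(-scan_result$r2[ix], scan_result$start[ix],
                 scan_result$end[ix], fac_rank[ix])
    scan_result$selected[ix[ord[1L]]] <- TRUE
  }
  scan_result
}
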