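#' Reaction-norm slopes of varieties on an environmental covariate
#'
#' The additive genetic effects predicted at each environment are scaled by
#' that environment's genetic standard deviation, the covariate is
#' standardised to mean 0 and SD 1 across environments, and each variety's
#' scaled effects are regressed on the standardised covariate by ordinary
#' least squares (with intercept). The slope is the variety's sensitivity to
#' the covariate.
#'
#' @param fits Named list of `"gblup_fit"` objects, one per environment.
#' @param cov_table Environments-by-covariates matrix.
#' @param covariate_id Covariate column to use.
#' @return Data.frame with `variety_id`, `slope`, `intercept`, `n_env_used`.
#' @export
estimate_slopes <- function(fits, cov_table, covariate_id) {
  envs <- intersect(names(fits), rownames(cov_table))
  if (length(envs) < 2L) stop("need fits and covariate values for >= 2 environments")
  x <- cov_table[envs, covariate_id]
  if (sd(x) < 1e-14) stop("covariate constant across environments")
  xs <- (x - mean(x)) / sd(x)
  W <- vapply(envs, function(e)
    fits[[e]]$u_hat / sqrt(max(fits[[e]]$sigma_u2, 1e-10)),
    numeric(length(fits[[envs[1L]]]$u_hat)))
  xc <- xs - mean(xs)
  slope <- as.numeric(W %*% xc) / sum(xc^2)
  data.frame(variety_id = rownames(W), slope = slope,
             intercept = rowMeans(W) - slope * mean(xs),
             n_env_used = length(envs), stringsAsFactors = FALSE)
}

#' Mixed-model genome-wide association on slopes
#'
#' P3D/EMMAX scheme: the polygenic model slope ~ N(mu, G sg2 + I se2) is
#' fitted once by REML without markers; each SNP is then tested as a fixed
#' effect by generalised least squares with those variance components held
#' fixed, using the eigendecomposition of G to diagonalise the covariance.
#' Only SNPs with minor allele frequency strictly above `maf_min` (computed on
#' the analysed varieties) are tested; markers collinear with the intercept
#' get p = 1 and are flagged. No principal components are included.
#'
#' @param slopes Data.frame from [estimate_slopes()] (or named numeric
#'   vector).
#' @param geno Imputed `"ecgc_geno"` object.
#' @param G Genomic relationship matrix.
#' @param maf_min MAF cutoff (strict).
#' @return Data.frame per SNP: `snp`, `chrom`, `bp`, `maf`, `beta`, `se`,
#'   `p`, `neg_log10_p`, `flagged`; variance components in
#'   `attr(, "varcomp")`.
#' @export
mm_gwas <- function(slopes, geno, G, maf_min = 0.05) {
  if (is.data.frame(slopes))
    slopes <- setNames(slopes$slope, slopes$variety_id)
  v <- intersect(names(slopes)[!is.na(slopes)],
                 intersect(rownames(geno$doses), rownames(G)))
  n <- length(v)
  if (n < 50L) stop("need slopes and genotypes for >= 50 varieties")
  s <- slopes[v]
  gsub <- geno
  gsub$doses <- gsub$doses[v, , drop = FALSE]
  gsub <- filter_maf(gsub, maf_min)
  M <- gsub$doses
  Gs <- G[v, v]

  fit <- reml_spectral(s, matrix(1, n, 1), Gs, tol = 1e-8)
  eg <- eigen(Gs, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  w <- 1 / (max(fit$sigma_u2, 0) * d + max(fit$sigma_e2, 1e-12))
  U <- eg$vectors
  ts <- as.numeric(crossprod(U, s))
  t1 <- as.numeric(crossprod(U, rep(1, n)))
  TM <- crossprod(U, M) # n x p transformed markers

  a11 <- sum(w * t1^2)
  b1 <- sum(w * t1 * ts)
  a12 <- as.numeric(crossprod(TM, w * t1))
  a22 <- as.numeric(crossprod(TM^2, w))
  b2 <- as.numeric(crossprod(TM, w * ts))
  det <- a11 * a22 - a12^2
  flagged <- det <= 1e-10 * a11 * pmax(a22, 1e-300)
  det[flagged] <- NA
  beta <- (a11 * b2 - a12 * b1) / det
  se_b <- sqrt(a11 / det)
  tstat <- beta / se_b
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p[flagged] <- 1
  beta[flagged] <- NA
  out <- data.frame(
    snp = colnames(M),
    chrom = gsub$map$chrom, bp = gsub$map$bp,
    maf = snp_maf(gsub),
    beta = beta, se = se_b, p = p, neg_log10_p = -log10(p),
    flagged = flagged, stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "varcomp") <- c(sigma_g2 = fit$sigma_u2, sigma_e2 = fit$sigma_e2)
  out
}

#' Storey q-values and FDR p-value threshold
#'
#' The null proportion pi0 is estimated on the lambda grid 0.05, 0.10, ...,
#' 0.90 by a cubic smoothing spline extrapolated to the largest lambda and
#' clipped to (0, 1]. Q-values are the step-up minima of
#' pi0 * m * p_(i) / i; the threshold is the largest p-value whose q-value is
#' at or below `fdr_level` (`NA` when there is no discovery).
#'
#' @param p Vector of p-values.
#' @param fdr_level Target FDR (default 0.05).
#' @return List with `threshold` (p-value scale; `NA` if none), `qvalues`
#'   (same order as `p`) and `pi0`.
#' @export
fdr_threshold <- function(p, fdr_level = 0.05) {
  stopifnot(length(p) >= 1, all(p >= 0 & p <= 1, na.rm = TRUE))
  ok <- !is.na(p)
  pv <- p[ok]
  m <- length(pv)
  lam <- seq(0.05, 0.90, by = 0.05)
  pi0_l <- vapply(lam, function(l) mean(pv > l) / (1 - l), numeric(1))
  pi0 <- if (m < 100L) {
    min(1, max(pi0_l[length(lam)], .Machine$double.eps))
  } else {
    fit <- smooth.spline(lam, pi0_l, df = 3)
    min(1, max(predict(fit, x = max(lam))$y, .Machine$double.eps))
  }
  ord <- order(pv)
  q_ord <- pi0 * m * pv[ord] / seq_len(m)
  q_ord <- rev(cummin(rev(q_ord)))
  q <- numeric(m)
  q[ord] <- pmin(q_ord, 1)
  disc <- pv[q <= fdr_level]
  out_q <- rep(NA_real_, length(p))
  out_q[ok] <- q
  list(threshold = if (length(disc)) max(disc) else NA_real_,
       qvalues = out_q, pi0 = pi0)
}

#' Group significant SNPs into chromosomal regions
#'
#' Single-linkage chaining: consecutive significant SNPs on the same
#' chromosome merge into one region when strictly less than `region_gap_bp`
#' apart; a gap of exactly `region_gap_bp` separates regions.
#'
#' @param gwas_result Data.frame from [mm_gwas()].
#' @param p_threshold P-value cutoff defining significance.
#' @param region_gap_bp Gap defining region boundaries (default 1e5).
#' @return Data.frame with `region_id`, `chrom`, `start_bp`, `end_bp`,
#'   `n_snps`, `best_neg_log10_p`, `snps` (comma-separated member ids).
#' @export
group_regions <- function(gwas_result, p_threshold, region_gap_bp = 100000) {
  sig <- gwas_result[!is.na(gwas_result$p) & !is.na(p_threshold) &
                       gwas_result$p <= p_threshold, , drop = FALSE]
  if (!nrow(sig))
    return(data.frame(region_id = integer(0), chrom = character(0),
                      start_bp = numeric(0), end_bp = numeric(0),
                      n_snps = integer(0), best_neg_log10_p = numeric(0),
                      snps = character(0), stringsAsFactors = FALSE))
  sig <- sig[order(sig$chrom, sig$bp), , drop = FALSE]
  new_region <- c(TRUE, sig$chrom[-1L] != sig$chrom[-nrow(sig)] |
                    diff(sig$bp) >= region_gap_bp)
  rid <- cumsum(new_region)
  out <- do.call(rbind, lapply(split(sig, rid), function(d)
    data.frame(chrom = d$chrom[1L], start_bp = min(d$bp),
               end_bp = max(d$bp), n_snps = nrow(d),
               best_neg_log10_p = max(d$neg_log10_p),
               snps = paste(d$snp, collapse = ","),
               stringsAsFactors = FALSE)))
  out <- data.frame(region_id = seq_len(nrow(out)), out,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Validate regions by variety subsampling
#'
#' Repeats the GWAS on random subsets of the varieties (default 80%, 10
#' replicates) and counts, for each region, the replicates in which any member
#' SNP reaches the full-data significance threshold. Regions with counts of at
#' least `subsample_min_count` (default 5, i.e. counts > 4) are flagged
#' reliable.
#'
#' @param slopes,geno,G As in [mm_gwas()].
#' @param regions Regions from [group_regions()] on the full data.
#' @param p_threshold The full-data FDR threshold.
#' @param config An `"ecgc_config"` (fraction, replicates, minimum count,
#'   seed, MAF cutoff).
#' @param seed_stage Substream name (default `"subsample"`).
#' @return `regions` with `subsample_count` and `reliable` columns.
#' @export
subsample_validate <- function(slopes, geno, G, regions, p_threshold,
                               config = run_config(),
                               seed_stage = "subsample") {
  if (!nrow(regions) || is.na(p_threshold)) {
    regions$subsample_count <- integer(nrow(regions))
    regions$reliable <- logical(nrow(regions))
    return(regions)
  }
  if (is.data.frame(slopes))
    slopes <- setNames(slopes$slope, slopes$variety_id)
  v_all <- names(slopes)[!is.na(slopes)]
  n_sub <- floor(config$subsample_fraction * length(v_all))
  members <- strsplit(regions$snps, ",", fixed = TRUE)
  # under P3D the per-SNP test is unchanged by dropping other markers, so
  # only the region members need re-testing in each replicate
  keep <- colnames(geno$doses) %in% unlist(members)
  geno_m <- geno
  geno_m$doses <- geno_m$doses[, keep, drop = FALSE]
  geno_m$map <- geno_m$map[keep, , drop = FALSE]
  counts <- integer(nrow(regions))
  for (rep_i in seq_len(config$subsample_reps)) {
    v_sub <- with_stage_seed(config$rng_seed,
                             paste0(seed_stage, "_", rep_i),
                             sample(v_all, n_sub))
    gw <- mm_gwas(slopes[v_sub], geno_m, G, maf_min = config$maf_min)
    sig_snp <- gw$snp[!is.na(gw$p) & gw$p <= p_threshold]
    hit <- vapply(members, function(sn) any(sn %in% sig_snp), logical(1))
    counts <- counts + hit
  }
  regions$subsample_count <- counts
  regions$reliable <- counts >= config$subsample_min_count
  regions
}

#' Selection-history trend of slopes along an environmental covariate
#'
#' For each environment, the record-count-weighted mean slope of the varieties
#' evaluated there is computed; the Pearson correlation of these means with
#' the covariate values across environments indicates directional selection
#' for sensitivity to the covariate.
#'
#' @param slopes Data.frame from [estimate_slopes()] (or named vector).
#' @param x Named covariate values, one per environment.
#' @param trials Trial table giving the per-environment record counts per
#'   variety.
#' @return List with `r`, `p`, `n_env`, `mean_slopes` (named by environment),
#'   `degenerate`.
#' @export
selection_trend <- function(slopes, x, trials) {
  if (is.data.frame(slopes))
    slopes <- setNames(slopes$slope, slopes$variety_id)
  envs <- intersect(names(x), unique(trials$environment_id))
  if (length(envs) < 4L) stop("need slopes and covariates for >= 4 environments")
  ms <- vapply(envs, function(e) {
    d <- trials[trials$environment_id == e, "variety_id"]
    cnt <- table(d)
    vv <- intersect(names(cnt), names(slopes)[!is.na(slopes)])
    if (!length(vv)) return(NA_real_)
    sum(slopes[vv] * as.numeric(cnt[vv])) / sum(as.numeric(cnt[vv]))
  }, numeric(1))
  keep <- !is.na(ms)
  if (sum(keep) < 4L || sd(ms[keep]) < 1e-14 || sd(x[envs][keep]) < 1e-14)
    return(list(r = NA_real_, p = 1, n_env = sum(keep),
                mean_slopes = ms, degenerate = TRUE))
  ct <- cor.test(ms[keep], x[envs][keep])
  list(r = unname(ct$estimate), p = ct$p.value, n_env = sum(keep),
       mean_slopes = ms, degenerate = FALSE)
}
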