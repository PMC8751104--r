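#' Mean-impute missing genotype doses
#'
#' Missing doses are replaced by the per-SNP mean dose (a continuous value).
#' SNPs with no observed genotype are dropped with a warning.
#'
#' @param geno An `"ecgc_geno"` object (see [read_genotypes()]).
#' @return The imputed `"ecgc_geno"` object.
#' @export
mean_impute <- function(geno) {
  stopifnot(inherits(geno, "ecgc_geno"))
  X <- geno$doses
  all_na <- colSums(!is.na(X)) == 0L
  if (any(all_na)) {
    warning(sum(all_na), " all-missing SNP(s) dropped")
    ecgc_log("dropped %d all-missing SNP(s)", sum(all_na))
    X <- X[, !all_na, drop = FALSE]
    geno$map <- geno$map[!all_na, , drop = FALSE]
  }
  nas <- which(is.na(X))
  if (length(nas)) {
    mu <- colMeans(X, na.rm = TRUE)
    X[nas] <- mu[(nas - 1L) %/% nrow(X) + 1L]
  }
  geno$doses <- X
  geno
}

#' Per-SNP minor allele frequency
#'
#' @param geno An imputed `"ecgc_geno"` object.
#' @return Numeric vector of MAFs, one per SNP.
#' @export
snp_maf <- function(geno) {
  p <- colMeans(geno$doses) / 2
  pmin(p, 1 - p)
}

#' Filter SNPs by minor allele frequency
#'
#' Retains SNPs whose MAF is strictly greater than `maf_min`; a SNP with MAF
#' exactly at the cutoff is excluded.
#'
#' @param geno An imputed `"ecgc_geno"` object.
#' @param maf_min MAF cutoff (default 0.05).
#' @return The filtered `"ecgc_geno"` object.
#' @export
filter_maf <- function(geno, maf_min = 0.05) {
  stopifnot(inherits(geno, "ecgc_geno"))
  if (anyNA(geno$doses)) stop("impute genotypes before MAF filtering")
  keep <- snp_maf(geno) > maf_min
  if (!any(keep)) stop("no SNP passes the MAF filter")
  geno$doses <- geno$doses[, keep, drop = FALSE]
  geno$map <- geno$map[keep, , drop = FALSE]
  rownames(geno$map) <- NULL
  geno
}

#' VanRaden genomic relationship matrix
#'
#' G = W W' / (2 * sum_i p_i (1 - p_i)) with W the column-centered dose matrix
#' (doses minus twice the sample allele frequency). Monomorphic SNPs contribute
#' nothing and are dropped beforehand.
#'
#' @param geno An imputed `"ecgc_geno"` object.
#' @return A symmetric varieties-by-varieties matrix with variety ids as
#'   dimnames.
#' @export
vanraden_grm <- function(geno) {
  stopifnot(inherits(geno, "ecgc_geno"))
  X <- geno$doses
  if (anyNA(X)) stop("impute genotypes before computing the GRM")
  p <- colMeans(X) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("all SNPs are monomorphic; GRM undefined")
  X <- X[, poly, drop = FALSE]
  p <- p[poly]
  W <- sweep(X, 2L, 2 * p)
  denom <- 2 * sum(p * (1 - p))
  G <- tcrossprod(W) / denom
  G <- (G + t(G)) / 2
  dimnames(G) <- list(rownames(X), rownames(X))
  G
}
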