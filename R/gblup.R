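# Exact one-ratio REML on the model y = Xb + u + e, u ~ N(0, K su2),
# e ~ N(0, I se2), via eigendecomposition of K projected onto the orthogonal
# complement of the fixed-effect space. Profiling out se2 leaves a smooth
# one-dimensional likelihood in the ratio gamma = su2/se2, maximised by
# golden-section/Brent search; no iterative REML scheme is needed.
reml_spectral <- function(y, X, K, tol = 1e-8) {
  n <- length(y)
  qx <- qr(X)
  r <- qx$rank
  if (r < ncol(X)) X <- X[, qx$pivot[seq_len(r)], drop = FALSE]
  Qf <- qr.Q(qr(X), complete = TRUE)
  Q2 <- Qf[, seq.int(r + 1L, n), drop = FALSE]
  A <- crossprod(Q2, K %*% Q2)
  eg <- eigen((A + t(A)) / 2, symmetric = TRUE)
  xi <- pmax(eg$values, 0)
  eta <- as.numeric(crossprod(eg$vectors, crossprod(Q2, y)))
  df <- n - r
  nll <- function(lg) {
    g <- exp(lg)
    d <- g * xi + 1
    se2 <- sum(eta^2 / d) / df
    0.5 * (df * log(se2) + sum(log(d)))
  }
  opt <- optimize(nll, c(-18, 18), tol = max(tol, 1e-10))
  gamma <- exp(opt$minimum)
  d <- gamma * xi + 1
  se2 <- sum(eta^2 / d) / df
  su2 <- gamma * se2
  list(sigma_u2 = su2, sigma_e2 = se2, gamma = gamma, X = X, df = df,
       loglik = -opt$objective - 0.5 * df)
}

#' Fit a single-trait GBLUP model at one environment
#'
#' Model: y = Xb + Zu + e with u ~ N(0, G su2) over all genotyped varieties
#' and e ~ N(0, I se2). Variance components are estimated by exact restricted
#' maximum likelihood via a spectral decomposition (one variance ratio,
#' profiled residual variance), fixed effects by generalised least squares,
#' and additive effects (BLUPs) are predicted for every variety in the
#' relationship matrix, including varieties without records at this
#' environment.
#'
#' @param y Numeric response vector (one record per element).
#' @param X Fixed-effect design matrix (rows match `y`); aliased columns are
#'   dropped. Use `NULL` for an intercept only.
#' @param variety Character vector (length of `y`) of variety ids, all present
#'   in `rownames(G)`.
#' @param G Genomic relationship matrix ([vanraden_grm()]).
#' @param tol REML tolerance.
#' @return A list of class `"gblup_fit"`: `sigma_u2`, `sigma_e2`, `h2`,
#'   `beta` (fixed effects), `u_hat` (named BLUPs for all varieties in `G`),
#'   `y_adj` (y minus fixed effects), `loglik`, `n_records`.
#' @export
fit_gblup <- function(y, X = NULL, variety, G, tol = 1e-8) {
  n <- length(y)
  stopifnot(length(variety) == n)
  if (length(unique(variety)) < 2L) stop("need records on >= 2 varieties")
  if (!all(variety %in% rownames(G)))
    stop("varieties absent from the relationship matrix")
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  K <- G[variety, variety, drop = FALSE]
  fit <- reml_spectral(y, X, K, tol)
  X <- fit$X
  su2 <- max(fit$sigma_u2, 1e-10)
  se2 <- max(fit$sigma_e2, 1e-10)
  V <- su2 * K + diag(se2, n)
  Vc <- chol(V)
  Vinv <- chol2inv(Vc)
  VX <- Vinv %*% X
  beta <- solve(crossprod(X, VX), crossprod(VX, y))
  resid <- as.numeric(y - X %*% beta)
  u_hat <- as.numeric(su2 * G[, variety, drop = FALSE] %*% (Vinv %*% resid))
  names(u_hat) <- rownames(G)
  structure(list(
    sigma_u2 = fit$sigma_u2, sigma_e2 = fit$sigma_e2,
    h2 = fit$sigma_u2 / (fit$sigma_u2 + fit$sigma_e2),
    beta = setNames(as.numeric(beta), colnames(X)),
    u_hat = u_hat, y_adj = resid, loglik = fit$loglik, n_records = n
  ), class = "gblup_fit")
}

#' @export
print.gblup_fit <- function(x, ...) {
  cat(sprintf(
    "GBLUP fit: n = %d, sigma_u2 = %.4g, sigma_e2 = %.4g, h2 = %.3f\n",
    x$n_records, x$sigma_u2, x$sigma_e2, x$h2))
  invisible(x)
}
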