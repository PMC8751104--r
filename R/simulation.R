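#' Sample a correlation matrix from the LKJ distribution
#'
#' Onion-method construction: the leading 2 x 2 correlation is
#' `2 Beta(b, b) - 1` with `b = eta + (M - 2)/2`, and each subsequent row is a
#' point drawn inside the elliptope via a Beta-distributed squared radius and
#' a uniform direction. For M = 2 the off-diagonal has variance
#' `1 / (2 eta + 1)`.
#'
#' @param M Matrix dimension (>= 2).
#' @param eta Shape parameter; larger values concentrate mass near the
#'   identity.
#' @return An M x M correlation matrix.
#' @export
sample_lkj <- function(M, eta = 4) {
  stopifnot(M >= 2, eta > 0)
  R <- diag(M)
  b <- eta + (M - 2) / 2
  r <- 2 * rbeta(1, b, b) - 1
  R[1, 2] <- R[2, 1] <- r
  if (M > 2) for (k in 2:(M - 1)) {
    b <- b - 0.5
    y <- rbeta(1, k / 2, b)
    u <- rnorm(k)
    u <- u / sqrt(sum(u^2))
    w <- sqrt(y) * u
    L <- t(chol(R[1:k, 1:k]))
    z <- as.numeric(L %*% w)
    R[k + 1, 1:k] <- z
    R[1:k, k + 1] <- z
  }
  R
}

#' Simulate a genetic correlation matrix with planted covariate signal
#'
#' Environment covariate values `x_j` are standard normal; the signal
#' component of each off-diagonal is `x_j x_k`. Noise correlations are an LKJ
#' draw whose off-diagonals are rescaled so that
#' `var(noise) = var(x_j x_k) (1 - r2) / r2`, making `r2` the proportion of
#' off-diagonal variance explained by the covariate. The diagonal is set to
#' the mean of `x_j^2` and the matrix standardised by its diagonal. Under
#' strong noise (small `r2`) the standardised entries legitimately exceed
#' \[-1, 1\] in magnitude; the scan statistic is a scale-free correlation of
#' off-diagonals and is unaffected. A draw with non-finite entries (possible
#' only in degenerate corner cases) is repaired with [near_pd()] and logged.
#'
#' @param r2 Signal variance proportion in (0, 1).
#' @param M Number of environments (>= 3).
#' @param eta LKJ shape (default 4).
#' @return List with `P` (M x M symmetric matrix, unit diagonal), `x`
#'   (covariate vector), and the construction's `var_signal` and
#'   `var_noise`.
#' @export
simulate_corr_matrix <- function(r2, M, eta = 4) {
  stopifnot(r2 > 0, r2 < 1, M >= 3)
  x <- rnorm(M)
  ut <- upper.tri(diag(M))
  xx <- tcrossprod(x)
  v_sig <- var(xx[ut])
  C <- sample_lkj(M, eta)
  noise <- C[ut]
  scale <- sqrt(v_sig * (1 - r2) / r2 / var(noise))
  S <- matrix(0, M, M)
  S[ut] <- xx[ut] + scale * noise
  S <- S + t(S)
  diag(S) <- mean(x^2)
  P <- S / mean(x^2)
  if (any(!is.finite(P))) { # degenerate draw; repair and continue
    ecgc_log("simulated matrix degenerate; repaired with near_pd")
    P[!is.finite(P)] <- 0
    P <- near_pd(P, corr = TRUE)
  }
  list(P = P, x = x, var_signal = v_sig,
       var_noise = var(scale * noise))
}

#' ROC curve points from pooled scores
#'
#' @param score Numeric scores (higher = more positive).
#' @param label Logical or 0/1 vector of true labels.
#' @return Data.frame `threshold`, `fpr`, `tpr`, sorted from the strictest
#'   threshold, starting at (0, 0) and ending at (1, 1).
#' @export
roc_points <- function(score, label) {
  label <- as.logical(label)
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]; l <- label[ord]
  n1 <- sum(l); n0 <- sum(!l)
  stopifnot(n1 > 0, n0 > 0)
  keep <- which(c(diff(s) != 0, TRUE)) # end of each tie group
  tp <- cumsum(l)[keep]; fp <- cumsum(!l)[keep]
  data.frame(threshold = c(Inf, s[keep]),
             fpr = c(0, fp / n0), tpr = c(0, tp / n1))
}

#' Area under the ROC curve
#'
#' Computed by the rank (Mann-Whitney) formula, which equals the trapezoidal
#' area under [roc_points()] with tied scores handled by average ranks.
#'
#' @inheritParams roc_points
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(score, label) {
  label <- as.logical(label)
  n1 <- sum(label); n0 <- sum(!label)
  stopifnot(n1 > 0, n0 > 0)
  r <- rank(score)
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Simulation study configuration
#'
#' Defaults encode the method's standard power-study design: r-squared grid
#' \{0.01, 0.018, 0.025, 0.035, 0.053, 0.075, 0.1, 0.15\}, environment-count
#' grid \{5, 10, 15, 20, 30, 40, 50, 60\}, LKJ eta = 4, 99 true-negative
#' covariates per replicate, with a desk-scale default of 200 replicates per
#' grid cell (2000 at publication scale).
#'
#' @param r2_grid,M_grid Grids of signal proportions and environment counts.
#' @param eta LKJ shape.
#' @param reps Replicates per grid cell.
#' @param n_negatives True-negative covariates per replicate.
#' @param rng_seed Master seed.
#' @return A list of class `"ecgc_sim_config"`.
#' @export
sim_config <- function(r2_grid = c(0.01, 0.018, 0.025, 0.035, 0.053, 0.075,
                                   0.1, 0.15),
                       M_grid = c(5, 10, 15, 20, 30, 40, 50, 60),
                       eta = 4, reps = 200L, n_negatives = 99L,
                       rng_seed = 1L) {
  stopifnot(all(r2_grid > 0 & r2_grid < 1), all(M_grid >= 3), eta > 0,
            reps >= 1, n_negatives >= 1)
  structure(list(r2_grid = r2_grid, M_grid = M_grid, eta = eta,
                 reps = as.integer(reps),
                 n_negatives = as.integer(n_negatives),
                 rng_seed = as.integer(rng_seed)),
            class = "ecgc_sim_config")
}

#' Power study of the covariate scan on simulated correlation matrices
#'
#' For every (r2, M) cell and replicate, one planted covariate (true positive)
#' and `n_negatives` independent standard-normal covariates (true negatives)
#' are scanned against a simulated genetic correlation matrix with
#' [correlate_offdiag()]; -log10 p-values pooled over replicates give the ROC
#' curve and AUC of the cell.
#'
#' @param config A `"ecgc_sim_config"` (see [sim_config()]).
#' @return List with `auc` (data.frame `r2`, `M`, `auc`, `n_pos`, `n_neg`)
#'   and `curves` (named list of [roc_points()] data.frames).
#' @export
run_power_study <- function(config = sim_config()) {
  auc_rows <- list()
  curves <- list()
  for (M in config$M_grid) for (r2 in config$r2_grid) {
    cell <- sprintf("r2=%g_M=%g", r2, M)
    res <- with_stage_seed(config$rng_seed, paste0("power_", cell), {
      score <- numeric(0); label <- logical(0)
      for (rep_i in seq_len(config$reps)) {
        sim <- simulate_corr_matrix(r2, M, config$eta)
        covs <- cbind(sim$x, matrix(rnorm(M * config$n_negatives), M))
        colnames(covs) <- c("pos", paste0("neg", seq_len(config$n_negatives)))
        rownames(covs) <- paste0("E", seq_len(M))
        dimnames(sim$P) <- list(rownames(covs), rownames(covs))
        p <- vapply(colnames(covs), function(id)
          correlate_offdiag(similarity_kernel(covs, id), sim$P)$p,
          numeric(1))
        score <- c(score, -log10(p))
        label <- c(label, c(TRUE, rep(FALSE, config$n_negatives)))
      }
      list(score = score, label = label)
    })
    auc_rows[[cell]] <- data.frame(
      r2 = r2, M = M, auc = roc_auc(res$score, res$label),
      n_pos = sum(res$label), n_neg = sum(!res$label))
    curves[[cell]] <- roc_points(res$score, res$label)
  }
  list(auc = do.call(rbind, c(auc_rows, list(make.row.names = FALSE))),
       curves = curves)
}
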