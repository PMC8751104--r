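#' Match adjusted records between two environments
#'
#' Records are keyed by (variety, year); a variety evaluated at both
#' environments in the same year occupies one row with both entries. When a
#' variety has several records at one environment in one year, one record is
#' drawn uniformly at random (deterministic under [with_stage_seed()]).
#' Unmatched records keep a missing partner.
#'
#' @param adj Data.frame with columns `variety_id`, `environment_id`, `year`,
#'   `y_adj` (adjusted phenotypes from [fit_gblup()]).
#' @param env_j,env_k The two environment ids.
#' @return Data.frame with columns `variety_id`, `year`, `y1`, `y2`.
#' @export
match_records <- function(adj, env_j, env_k) {
  pick <- function(env) {
    d <- adj[adj$environment_id == env, c("variety_id", "year", "y_adj")]
    if (!nrow(d)) return(d)
    key <- paste(d$variety_id, d$year)
    keep <- unlist(lapply(split(seq_len(nrow(d)), key), function(ix) {
      if (length(ix) == 1L) ix else ix[sample.int(length(ix), 1L)]
    }), use.names = FALSE)
    d[sort(keep), , drop = FALSE]
  }
  d1 <- pick(env_j); d2 <- pick(env_k)
  out <- merge(d1, d2, by = c("variety_id", "year"), all = TRUE,
               suffixes = c("_1", "_2"))
  data.frame(variety_id = out$variety_id, year = out$year,
             y1 = out$y_adj_1, y2 = out$y_adj_2, stringsAsFactors = FALSE)
}

#' Bivariate REML genetic covariance between two environments
#'
#' Fits the two-trait model `[y1; y2] = Xb + [u1; u2] + [e1; e2]` with
#' `[u1; u2] ~ N(0, Su (x) G)` and residuals independent between records
#' except for the two records of a matched (variety, year) row, which share
#' the residual covariance. The residual covariance is fixed at zero when no
#' row is observed in both environments. Estimation is by average-information
#' REML warm-started from the two single-trait spectral fits; the genetic and
#' residual covariance matrices are kept positive semi-definite by constraint
#' at every step.
#'
#' @param paired Matched table from [match_records()].
#' @param G Genomic relationship matrix.
#' @param tol Convergence tolerance on the relative parameter change.
#' @param max_iter Maximum AI-REML iterations.
#' @return A list of class `"bivar_fit"`: `Su` and `Se` (2 x 2 covariance
#'   matrices), `rg` (genetic correlation), `converged`, `n_obs`, `n_shared`
#'   (rows observed in both environments), `loglik`, `iterations`.
#' @export
fit_bivariate <- function(paired, G, tol = 1e-8, max_iter = 200L) {
  p1 <- which(!is.na(paired$y1)); p2 <- which(!is.na(paired$y2))
  if (length(p1) < 3L || length(p2) < 3L)
    stop("need >= 3 records in each environment")
  y <- c(paired$y1[p1], paired$y2[p2])
  env <- rep(1:2, c(length(p1), length(p2)))
  variety <- c(paired$variety_id[p1], paired$variety_id[p2])
  if (!all(variety %in% rownames(G)))
    stop("varieties absent from the relationship matrix")
  n1 <- length(p1); n2 <- length(p2)
  n <- length(y)
  shared <- intersect(p1, p2)
  est_se12 <- length(shared) >= 1L

  # records ordered env-1 block then env-2 block
  Gs <- G[variety, variety, drop = FALSE]
  b1 <- seq_len(n1); b2 <- n1 + seq_len(n2)
  G11 <- Gs[b1, b1, drop = FALSE]
  G22 <- Gs[b2, b2, drop = FALSE]
  G12 <- Gs[b1, b2, drop = FALSE]
  # partner index of the other-environment record of the same matched row
  partner <- rep(NA_integer_, n)
  if (est_se12) {
    m2 <- match(p1, p2)
    has <- !is.na(m2)
    partner[b1[has]] <- n1 + m2[has]
    partner[n1 + m2[has]] <- b1[has]
  }
  conn <- which(!is.na(partner))
  X <- cbind(int1 = rep(1:0, c(n1, n2)), int2 = rep(0:1, c(n1, n2)))

  vy <- var(y)
  floor_v <- 1e-8 * vy
  par_names <- c("su11", "su22", "su12", "se1", "se2",
                 if (est_se12) "se12")
  constrain <- function(th) {
    th[c("su11", "su22", "se1", "se2")] <-
      pmax(th[c("su11", "su22", "se1", "se2")], floor_v)
    b <- 0.999 * sqrt(th[["su11"]] * th[["su22"]])
    th[["su12"]] <- max(min(th[["su12"]], b), -b)
    if (est_se12) {
      b <- 0.999 * sqrt(th[["se1"]] * th[["se2"]])
      th[["se12"]] <- max(min(th[["se12"]], b), -b)
    }
    th
  }
  conn0 <- as.integer(conn - 1L)
  pconn0 <- as.integer(partner[conn] - 1L)
  relik <- function(th) {
    r <- .bivar_relik_cpp(unname(th), G11, G22, G12, y, X,
                          conn0, pconn0, est_se12)
    if (!isTRUE(r$ok)) return(NULL)
    list(ll = r$ll, P = r$P, Py = as.numeric(r$Py))
  }
  derivs <- function(cur, th) {
    d <- .bivar_derivs_cpp(cur$P, cur$Py, G11, G22, G12,
                           conn0, pconn0, est_se12)
    list(score = setNames(as.numeric(d$score), par_names), AI = d$AI)
  }

  # warm start: single-trait spectral REML per side, mild positive covariance
  th <- c(su11 = NA_real_, su22 = NA_real_, su12 = 0,
          se1 = NA_real_, se2 = NA_real_)
  for (s in 1:2) {
    bs <- if (s == 1L) b1 else b2
    f <- reml_spectral(y[bs], matrix(1, length(bs), 1),
                       Gs[bs, bs, drop = FALSE], tol = 1e-6)
    th[[paste0("su", s, s)]] <- max(f$sigma_u2, floor_v)
    th[[paste0("se", s)]] <- max(f$sigma_e2, floor_v)
  }
  th[["su12"]] <- 0.4 * sqrt(th[["su11"]] * th[["su22"]])
  if (est_se12) th <- c(th, se12 = 0)
  th <- constrain(th)

  cur <- relik(th)
  if (is.null(cur)) stop("initial bivariate system not positive definite")
  converged <- FALSE
  iter <- 0L
  stagn <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    dv <- derivs(cur, th)
    AI <- dv$AI + diag(1e-8 * max(diag(dv$AI)) + 1e-12, nrow(dv$AI))
    delta <- tryCatch(solve(AI, dv$score), error = function(e) NULL)
    cap <- 2 * (abs(th) + 0.1 * vy) # trust region per parameter
    if (is.null(delta) || any(!is.finite(delta)))
      delta <- dv$score
    shrink <- max(abs(delta) / cap)
    if (shrink > 1) delta <- delta / shrink
    try_step <- function(delta) {
      step <- 1
      for (h in 1:25) {
        th_try <- constrain(th + step * delta)
        nxt <- relik(th_try)
        if (!is.null(nxt) && nxt$ll >= cur$ll - 1e-10)
          return(list(th = th_try, cur = nxt))
        step <- step / 2
      }
      NULL
    }
    res <- try_step(delta)
    if (is.null(res)) { # gradient fallback
      g <- dv$score
      g <- g / max(max(abs(g) / cap), 1e-12)
      res <- try_step(g)
    }
    if (is.null(res)) {
      # stationary, or pinned at the correlation bound (e.g. duplicated
      # traits drive the genetic correlation to its limit)
      at_bound <- abs(th[["su12"]]) >=
        0.999 * sqrt(th[["su11"]] * th[["su22"]]) - 1e-12
      converged <- max(abs(dv$score)) < 1e-4 * n || at_bound
      break
    }
    rel <- max(abs(res$th - th) / (abs(th) + 1e-3 * vy))
    dll <- res$cur$ll - cur$ll
    th <- res$th; cur <- res$cur
    if (rel < max(tol, 1e-9)) { converged <- TRUE; break }
    # stationary: repeated steps that neither move the parameters nor
    # improve the likelihood appreciably (flat or boundary optimum)
    stagn <- if (dll < 1e-7 * (1 + abs(cur$ll)) && rel < 1e-3)
      stagn + 1L else 0L
    if (stagn >= 3L) { converged <- TRUE; break }
  }
  Su <- matrix(c(th["su11"], th["su12"], th["su12"], th["su22"]), 2, 2)
  se12 <- if (est_se12) th[["se12"]] else 0
  Se <- matrix(c(th["se1"], se12, se12, th["se2"]), 2, 2)
  structure(list(
    Su = Su, Se = Se,
    rg = Su[1, 2] / sqrt(Su[1, 1] * Su[2, 2]),
    converged = converged, n_obs = n, n_shared = length(shared),
    loglik = cur$ll, iterations = iter
  ), class = "bivar_fit")
}

#' @export
print.bivar_fit <- function(x, ...) {
  cat(sprintf("Bivariate REML fit: n = %d (%d shared rows), rg = %.3f%s\n",
              x$n_obs, x$n_shared, x$rg,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Nearest positive (semi-)definite matrix
#'
#' Higham alternating-projections repair (via [Matrix::nearPD()]); with
#' `corr = TRUE` the unit diagonal is enforced.
#'
#' @param m Square symmetric matrix.
#' @param corr Constrain to a correlation matrix?
#' @param eig_tol Relative eigenvalue tolerance defining positive definiteness.
#' @return The repaired matrix.
#' @export
near_pd <- function(m, corr = FALSE, eig_tol = 1e-8) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (max(abs(m - t(m))) > 1e-8 * max(1, max(abs(m))))
    stop("input must be symmetric")
  res <- Matrix::nearPD((m + t(m)) / 2, corr = corr, keepDiag = FALSE,
                        eig.tol = 1e-6, posd.tol = eig_tol, maxit = 100)
  out <- as.matrix(res$mat)
  dimnames(out) <- dimnames(m)
  out
}

#' Assemble the genetic correlation matrix from pairwise fits
#'
#' Off-diagonals are the pairwise genetic covariances; the genetic variance of
#' environment j is the mean of its M - 1 per-pair estimates. The covariance
#' matrix is repaired to positive definiteness ([near_pd()]) and standardised
#' to a correlation matrix with exact unit diagonal. Non-converged pairs are
#' excluded (their covariance entry falls back to zero); more than 20% flagged
#' pairs is an error.
#'
#' @param fits Named list of `"bivar_fit"` objects, names `"<envj>||<envk>"`.
#' @param envs Character vector of environment ids (defines order).
#' @return An M x M genetic correlation matrix with attributes `"n_flagged"`
#'   and `"cov"` (the pre-standardisation covariance matrix).
#' @export
assemble_correlation <- function(fits, envs) {
  M <- length(envs)
  C <- matrix(0, M, M, dimnames = list(envs, envs))
  diag_sum <- setNames(numeric(M), envs)
  diag_n <- setNames(numeric(M), envs)
  flagged <- 0L
  for (nm in names(fits)) {
    pr <- strsplit(nm, "||", fixed = TRUE)[[1L]]
    f <- fits[[nm]]
    if (!isTRUE(f$converged)) {
      flagged <- flagged + 1L
      ecgc_log("pair %s excluded (REML not converged)", nm)
      next
    }
    C[pr[1L], pr[2L]] <- C[pr[2L], pr[1L]] <- f$Su[1, 2]
    diag_sum[pr] <- diag_sum[pr] + diag(f$Su)
    diag_n[pr] <- diag_n[pr] + 1
  }
  if (flagged > 0.2 * length(fits))
    stop("correlation matrix unreliable: >20% of pairwise fits flagged")
  if (any(diag_n == 0)) stop("environment(s) with no usable pairwise fit")
  diag(C) <- diag_sum / diag_n
  Cpd <- near_pd(C, corr = FALSE)
  P <- stats::cov2cor(Cpd)
  P <- (P + t(P)) / 2
  diag(P) <- 1
  P[P > 1] <- 1; P[P < -1] <- -1
  attr(P, "n_flagged") <- flagged
  attr(P, "cov") <- Cpd
  P
}
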