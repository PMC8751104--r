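test_that("GBLUP is scale-equivariant", {
  g <- h_geno(60, 300, seed = 10)
  G <- vanraden_grm(g)
  set.seed(1)
  ids <- rep(rownames(G), 2)
  y <- as.numeric(h_chol(G) %*% rnorm(60))[match(ids, rownames(G))] +
    rnorm(120)
  f1 <- fit_gblup(y, NULL, ids, G)
  f3 <- fit_gblup(3 * y, NULL, ids, G)
  expect_equal(f3$sigma_u2, 9 * f1$sigma_u2, tolerance = 1e-4)
  expect_equal(f3$sigma_e2, 9 * f1$sigma_e2, tolerance = 1e-4)
  expect_equal(f3$u_hat, 3 * f1$u_hat, tolerance = 1e-4)
  expect_equal(f3$h2, f1$h2, tolerance = 1e-6)
})

test_that("with G = I and balanced replicates REML matches one-way ANOVA", {
  # y_ij = mu + u_i + e_ij, 2 records each: REML variance components have
  # the closed form su2 = (MSB - MSW)/2, se2 = MSW
  set.seed(21)
  n <- 40
  G <- diag(n); dimnames(G) <- list(sprintf("v%02d", 1:n),
                                    sprintf("v%02d", 1:n))
  u <- rnorm(n, 0, sqrt(2))
  ids <- rep(rownames(G), each = 2)
  y <- u[match(ids, rownames(G))] + rnorm(2 * n)
  fit <- fit_gblup(y, NULL, ids, G, tol = 1e-12)
  gm <- tapply(y, ids, mean)[unique(ids)]
  msb <- 2 * sum((gm - mean(y))^2) / (n - 1)
  msw <- sum((y - rep(gm, each = 2))^2) / n
  expect_equal(fit$sigma_e2, msw, tolerance = 1e-6)
  expect_equal(fit$sigma_u2, max((msb - msw) / 2, 0), tolerance = 1e-6)
})

test_that("REML estimates are invariant to record order", {
  g <- h_geno(40, 200, seed = 12)
  G <- vanraden_grm(g)
  set.seed(5)
  ids <- sample(rownames(G), 80, replace = TRUE)
  y <- as.numeric(h_chol(G) %*% rnorm(40))[match(ids, rownames(G))] +
    rnorm(80)
  f1 <- fit_gblup(y, NULL, ids, G)
  perm <- sample(80)
  f2 <- fit_gblup(y[perm], NULL, ids[perm], G)
  expect_equal(f1$sigma_u2, f2$sigma_u2, tolerance = 1e-6)
  expect_equal(f1$u_hat, f2$u_hat, tolerance = 1e-5)
})

test_that("record matching pairs by (variety, year) and is seeded", {
  adj <- data.frame(
    variety_id = c("a", "b", "b", "c", "a", "b"),
    environment_id = c("E1", "E1", "E1", "E1", "E2", "E2"),
    year = c(2000, 2000, 2000, 2001, 2000, 2000),
    y_adj = 1:6)
  m1 <- with_stage_seed(1, "match", match_records(adj, "E1", "E2"))
  expect_setequal(paste(m1$variety_id, m1$year),
                  c("a 2000", "b 2000", "c 2001"))
  expect_equal(m1$y1[m1$variety_id == "a"], 1)
  expect_equal(m1$y2[m1$variety_id == "a"], 5)
  expect_true(is.na(m1$y2[m1$variety_id == "c"])) # only in E1
  expect_true(m1$y1[m1$variety_id == "b"] %in% c(2, 3)) # random duplicate
  m2 <- with_stage_seed(1, "match", match_records(adj, "E1", "E2"))
  expect_identical(m1, m2)
})

test_that("bivariate REML: identical traits give correlation near 1", {
  g <- h_geno(100, 400, seed = 13)
  G <- vanraden_grm(g)
  set.seed(2)
  u <- as.numeric(h_chol(G) %*% rnorm(100))
  y <- u + rnorm(100)
  paired <- data.frame(variety_id = rownames(G), year = 2000, y1 = y, y2 = y)
  fit <- fit_bivariate(paired, G)
  expect_gte(fit$rg, 0.99)
})

test_that("bivariate REML is unbiased under zero genetic correlation", {
  g <- h_geno(120, 400, seed = 14)
  G <- vanraden_grm(g)
  L <- h_chol(G)
  set.seed(3)
  rgs <- replicate(12, {
    u <- L %*% matrix(rnorm(240), 120, 2)
    paired <- data.frame(variety_id = rownames(G), year = 2000,
                         y1 = as.numeric(u[, 1] + rnorm(120)),
                         y2 = as.numeric(u[, 2] + rnorm(120)))
    fit_bivariate(paired, G)$rg
  })
  expect_lt(abs(mean(rgs)), 0.2)
})

test_that("residual covariance is fixed at zero for disconnected designs", {
  g <- h_geno(80, 300, seed = 15)
  G <- vanraden_grm(g)
  set.seed(4)
  u <- h_chol(G) %*% matrix(rnorm(160), 80, 2)
  paired <- data.frame(
    variety_id = rownames(G), year = 2000,
    y1 = ifelse(seq_len(80) <= 40, as.numeric(u[, 1]) + rnorm(80), NA),
    y2 = ifelse(seq_len(80) > 40, as.numeric(u[, 2]) + rnorm(80), NA))
  fit <- fit_bivariate(paired, G)
  expect_identical(fit$n_shared, 0L)
  expect_identical(fit$Se[1, 2], 0)
})

test_that("near_pd repairs and preserves", {
  A <- diag(3)
  expect_equal(near_pd(A), A, tolerance = 1e-10)
  set.seed(6)
  B <- crossprod(matrix(rnorm(16), 4)) + diag(4)
  expect_equal(near_pd(B), B, tolerance = 1e-8)
  # indefinite input: output PSD and matching the spectral projection oracle
  eg <- eigen(crossprod(matrix(rnorm(9), 3)))
  Q <- eg$vectors
  M <- Q %*% diag(c(1.2, 0.9, -0.05)) %*% t(Q)
  Mp <- near_pd(M)
  expect_gte(min(eigen(Mp, symmetric = TRUE)$values), -1e-10)
  clip <- Q %*% diag(pmax(c(1.2, 0.9, -0.05), 0)) %*% t(Q)
  expect_lte(norm(Mp - M, "F"), norm(clip - M, "F") + 1e-6)
  expect_error(near_pd(matrix(1:4, 2)), "symmetric")
})

test_that("assembly reproduces a consistent covariance matrix exactly", {
  envs <- paste0("E", 1:4)
  set.seed(7)
  C <- crossprod(matrix(rnorm(16), 4)) + diag(4)
  dimnames(C) <- list(envs, envs)
  fits <- list()
  for (a in 1:3) for (b in (a + 1):4)
    fits[[paste0(envs[a], "||", envs[b])]] <- structure(
      list(Su = C[c(a, b), c(a, b)], Se = diag(2),
           rg = C[a, b] / sqrt(C[a, a] * C[b, b]),
           converged = TRUE, n_obs = 10L, n_shared = 5L),
      class = "bivar_fit")
  P <- assemble_correlation(fits, envs)
  expect_equal(unclass(P), cov2cor(C), tolerance = 1e-7,
               ignore_attr = TRUE)
  expect_equal(diag(P), setNames(rep(1, 4), envs))
  expect_equal(attr(P, "cov"), C, tolerance = 1e-7)
})

test_that("assembly repairs indefinite estimates and flags failures", {
  envs <- paste0("E", 1:3)
  # strongly inconsistent off-diagonals force an indefinite raw matrix
  Su_of <- function(v1, v2, c12) matrix(c(v1, c12, c12, v2), 2)
  fits <- list(
    "E1||E2" = structure(list(Su = Su_of(1, 1, 0.95), converged = TRUE),
                         class = "bivar_fit"),
    "E1||E3" = structure(list(Su = Su_of(1, 1, 0.95), converged = TRUE),
                         class = "bivar_fit"),
    "E2||E3" = structure(list(Su = Su_of(1, 1, -0.95), converged = TRUE),
                         class = "bivar_fit"))
  P <- assemble_correlation(fits, envs)
  expect_gte(min(eigen(unclass(P), symmetric = TRUE)$values), -1e-8)
  expect_equal(diag(P), setNames(rep(1, 3), envs))
  expect_true(all(abs(P) <= 1))
  # one of three non-converged exceeds the 20% tolerance
  fits$`E1||E2`$converged <- FALSE
  expect_error(assemble_correlation(fits, envs), "unreliable")
})
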