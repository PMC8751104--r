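h_fit <- function(u_hat, sigma_u2 = 1) {
  structure(list(u_hat = u_hat, sigma_u2 = sigma_u2, sigma_e2 = 1,
                 h2 = 0.5), class = "gblup_fit")
}

test_that("slopes recover a noiseless linear response exactly", {
  x <- c(E1 = 1, E2 = 2, E3 = 4, E4 = 7)
  xs <- (x - mean(x)) / sd(x)
  v <- sprintf("V%02d", 1:5)
  # scaled effect w_vj = 0.7 * xs_j + per-variety offset
  fits <- lapply(seq_along(x), function(j)
    h_fit(setNames(0.7 * xs[j] + seq_len(5), v)))
  names(fits) <- names(x)
  ct <- matrix(x, 4, 1, dimnames = list(names(x), "f_s1_e1"))
  sl <- estimate_slopes(fits, ct, "f_s1_e1")
  expect_equal(sl$slope, rep(0.7, 5), tolerance = 1e-12)
  expect_identical(sl$n_env_used, rep(4L, 5))
  # constant effects across environments -> slope 0
  fits0 <- lapply(seq_along(x), function(j) h_fit(setNames(seq_len(5), v)))
  names(fits0) <- names(x)
  expect_equal(estimate_slopes(fits0, ct, "f_s1_e1")$slope, rep(0, 5))
})

test_that("slopes are invariant to rescaling the covariate", {
  set.seed(41)
  v <- sprintf("V%02d", 1:8)
  x <- c(E1 = 3, E2 = 9, E3 = 1, E4 = 5, E5 = 12)
  fits <- lapply(seq_along(x), function(j)
    h_fit(setNames(rnorm(8), v), sigma_u2 = runif(1, 0.5, 2)))
  names(fits) <- names(x)
  ct1 <- matrix(x, 5, 1, dimnames = list(names(x), "c"))
  ct2 <- ct1 * 37
  expect_equal(estimate_slopes(fits, ct1, "c")$slope,
               estimate_slopes(fits, ct2, "c")$slope, tolerance = 1e-12)
})

test_that("GWAS tests only SNPs above the MAF cutoff", {
  set.seed(42)
  g <- h_geno(120, 300, seed = 42)
  # force one SNP to MAF exactly 0.05 and one monomorphic
  g$doses[, 1] <- c(rep(1, 12), rep(0, 108))
  g$doses[, 2] <- 0
  G <- vanraden_grm(g)
  slopes <- setNames(rnorm(120), rownames(G))
  gw <- mm_gwas(slopes, g, G, maf_min = 0.05)
  expect_false(any(c(colnames(g$doses)[1:2]) %in% gw$snp))
  expect_true(all(gw$maf > 0.05))
  expect_true(all(gw$p > 0 & gw$p <= 1))
})

test_that("GWAS p-values are calibrated under the null", {
  # slopes independent of genotypes, no structure
  set.seed(43)
  nrej <- replicate(10, {
    g <- h_geno(150, 400, seed = sample.int(1e6, 1))
    G <- vanraden_grm(g)
    s <- setNames(rnorm(150), rownames(G))
    gw <- mm_gwas(s, g, G)
    ks.test(gw$p, "punif")$p.value
  })
  expect_gte(sum(nrej > 0.01), 8)
})

test_that("GWAS finds a planted QTL", {
  set.seed(44)
  hits <- replicate(10, {
    g <- h_geno(300, 1000, seed = sample.int(1e6, 1))
    G <- vanraden_grm(g)
    maf <- snp_maf(g)
    qtl <- sample(which(maf > 0.3), 1)
    z <- scale(g$doses[, qtl])[, 1]
    s <- setNames(sqrt(0.2) * z + sqrt(0.8) * rnorm(300), rownames(G))
    gw <- mm_gwas(s, g, G)
    top <- gw$snp[order(gw$p)[1:10]]
    colnames(g$doses)[qtl] %in% top
  })
  expect_gte(sum(hits), 8)
})

test_that("GWAS p-values do not depend on variety order", {
  g <- h_geno(100, 200, seed = 45)
  G <- vanraden_grm(g)
  set.seed(9)
  s <- setNames(rnorm(100), rownames(G))
  gw1 <- mm_gwas(s, g, G)
  perm <- sample(100)
  g2 <- g; g2$doses <- g$doses[perm, ]
  gw2 <- mm_gwas(s[perm], g2, G[perm, perm])
  expect_equal(gw1$p, gw2$p, tolerance = 1e-8)
})

test_that("q-value threshold matches a brute-force implementation", {
  expect_true(is.na(fdr_threshold(rep(1, 50))$threshold))
  expect_equal(fdr_threshold(1e-9)$threshold, 1e-9)
  set.seed(46)
  p <- c(rep(1e-9, 100), runif(900))
  res <- fdr_threshold(p, 0.05)
  # brute force: Storey pi0 by identical recipe, step-up q-values
  lam <- seq(0.05, 0.90, 0.05)
  pi0_l <- sapply(lam, function(l) mean(p > l) / (1 - l))
  pi0 <- min(1, max(predict(smooth.spline(lam, pi0_l, df = 3),
                            x = 0.9)$y, .Machine$double.eps))
  ord <- order(p)
  q <- pi0 * length(p) * p[ord] / seq_along(p)
  q <- rev(cummin(rev(q)))
  thr <- max(p[ord][q <= 0.05])
  expect_equal(res$threshold, thr)
  expect_equal(res$pi0, pi0)
  qv <- numeric(length(p)); qv[ord] <- pmin(q, 1)
  expect_equal(res$qvalues, qv)
})

test_that("region grouping is strict at the gap and per chromosome", {
  gw <- data.frame(
    snp = paste0("s", 1:5),
    chrom = c("c1", "c1", "c1", "c2", "c2"),
    bp = c(100000, 150000, 250000, 100000, 210000),
    maf = 0.3, beta = 0, se = 1,
    p = c(1e-8, 1e-8, 1e-8, 1e-8, 0.5),
    neg_log10_p = 8, flagged = FALSE)
  reg <- group_regions(gw, 1e-6, 100000)
  # 100k & 150k chain; 250k is exactly 100k from 150k -> separate; c2 alone
  expect_identical(nrow(reg), 3L)
  expect_identical(reg$n_snps, c(2L, 1L, 1L))
  expect_identical(reg$chrom, c("c1", "c1", "c2"))
  # order invariance and idempotence
  reg2 <- group_regions(gw[sample(5), ], 1e-6, 100000)
  expect_identical(reg, reg2)
  expect_identical(nrow(group_regions(gw, NA, 1e5)), 0L)
})

test_that("subsampling counts are deterministic and flag reliability", {
  set.seed(47)
  g <- h_geno(150, 500, seed = 47)
  G <- vanraden_grm(g)
  maf <- snp_maf(g)
  qtl <- which(maf > 0.3)[1]
  z <- scale(g$doses[, qtl])[, 1]
  slopes <- setNames(sqrt(0.5) * z + sqrt(0.5) * rnorm(150), rownames(G))
  gw <- mm_gwas(slopes, g, G)
  # generous threshold: the strong QTL stays significant in every subsample
  thr <- 1e-4
  expect_lt(gw$p[gw$snp == colnames(g$doses)[qtl]], 1e-8)
  reg <- group_regions(gw, thr, 1e5)
  cfg <- run_config(rng_seed = 11, subsample_reps = 5,
                    subsample_min_count = 3)
  r1 <- subsample_validate(slopes, g, G, reg, thr, cfg)
  r2 <- subsample_validate(slopes, g, G, reg, thr, cfg)
  expect_identical(r1$subsample_count, r2$subsample_count)
  expect_identical(r1$reliable, r1$subsample_count >= 3L)
  qreg <- grepl(colnames(g$doses)[qtl], r1$snps)
  expect_gte(r1$subsample_count[qreg], 3L)
})

test_that("selection trend correlates weighted mean slopes with covariates", {
  envs <- paste0("E", 1:5)
  trials <- data.frame(
    variety_id = c("a", "a", "b", "a", "b", "a", "b", "a", "b", "b"),
    environment_id = envs[c(1, 1, 1, 2, 2, 3, 3, 4, 4, 5)])
  slopes <- c(a = 2, b = -1)
  x <- setNames(c(0.3, -1, 2, 0.5, -0.2), envs)
  res <- selection_trend(slopes, x, trials)
  ms <- sapply(envs, function(e) {
    d <- trials[trials$environment_id == e, ]
    cnt <- table(d$variety_id)
    sum(slopes[names(cnt)] * as.numeric(cnt)) / sum(cnt)
  })
  ct <- cor.test(ms, x)
  expect_equal(res$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(res$p, ct$p.value, tolerance = 1e-12)
  # mean slopes equal to the covariate -> r = 1
  per_env <- data.frame(variety_id = paste0("v", 1:5),
                        environment_id = envs)
  res1 <- selection_trend(setNames(as.numeric(x), paste0("v", 1:5)),
                          x, per_env)
  expect_equal(res1$r, 1, tolerance = 1e-12)
  # a single variety everywhere -> constant mean slopes, degenerate
  one <- data.frame(variety_id = "a", environment_id = envs)
  res2 <- selection_trend(setNames(2, "a"), x, one)
  expect_true(res2$degenerate)
  expect_identical(res2$p, 1)
})
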