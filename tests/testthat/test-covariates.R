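test_that("stage partition tiles the growth period in near-equal blocks", {
  # exact division: 10-day pre, 20-day post -> every stage is one day
  p <- assign_stages(as.Date("2000-06-01"), as.Date("2000-06-10"),
                     as.Date("2000-06-30"), 10, 20)
  expect_equal(nrow(p), 30L)
  expect_equal(as.numeric(table(p$stage)), rep(1, 30))
  # 23-day pre period: floor-boundary oracle
  p2 <- assign_stages(0L, 22L, 60L, 10, 20)
  pre_len <- as.numeric(table(p2$stage[p2$stage <= 10]))
  expect_equal(pre_len, diff(c(0, floor(seq_len(10) * 23 / 10))))
  expect_equal(sum(pre_len), 23)
  expect_lte(diff(range(pre_len)), 1)
  expect_error(assign_stages(0L, 0L, 30L, 10, 20), "sowing < flowering")
  expect_error(assign_stages(0L, 3L, 30L, 10, 20), "too few days")
})

test_that("stage partition covers every day exactly once (random cases)", {
  set.seed(11)
  for (i in 1:20) {
    n_pre <- sample(2:12, 1); n_post <- sample(2:25, 1)
    pre <- n_pre + sample(0:40, 1); post <- n_post + sample(0:60, 1)
    sow <- as.Date("2001-05-01") + sample(0:30, 1)
    p <- assign_stages(sow, sow + pre - 1, sow + pre - 1 + post,
                       n_pre, n_post)
    expect_identical(p$date, seq(sow, sow + pre + post - 1, by = 1))
    expect_true(all(diff(p$stage) %in% c(0L, 1L)))
    expect_equal(max(p$stage), n_pre + n_post)
    expect_equal(max(p$stage[p$date <= sow + pre - 1]), n_pre)
  }
})

test_that("stage means average the daily values", {
  sow <- as.Date("2000-06-01")
  p <- assign_stages(sow, sow + 4, sow + 9, 2, 2)
  w <- data.frame(environment_id = "E1", date = seq(sow, sow + 9, by = 1),
                  factor = "tmean", value = 1:10)
  # 5-day pre period in 2 floor-boundary blocks: days 1-2 and 3-5
  expect_equal(stage_means(w, p, "tmean", "E1"),
               c(mean(1:2), mean(3:5), mean(6:7), mean(8:10)))
  wc <- w; wc$value <- 5
  expect_equal(stage_means(wc, p, "tmean", "E1"), rep(5, 4))
  expect_error(stage_means(w[-3, ], p, "tmean", "E1"), "missing on")
  # brute force over random partitions
  set.seed(3)
  for (i in 1:5) {
    p2 <- assign_stages(sow, sow + sample(5:15, 1), sow + sample(30:40, 1),
                        3, 4)
    w2 <- data.frame(environment_id = "E1", date = p2$date,
                     factor = "f", value = rnorm(nrow(p2)))
    expect_equal(stage_means(w2, p2, "f", "E1"),
                 as.numeric(tapply(w2$value, p2$stage, mean)))
  }
})

test_that("covariate table has S(S+1)/2 covariates per factor", {
  expect_identical(n_window_covariates(30), 465L)
  expect_identical(n_window_covariates(2), 3L)
  sow <- as.Date("2000-06-01")
  trials <- data.frame(variety_id = "v1", environment_id = "E1",
                       year = 2000, sowing_date = sow,
                       flowering_date = sow + 3,
                       maturity_date = sow + 7, yield = 1)
  w <- data.frame(environment_id = "E1", date = seq(sow, sow + 7, by = 1),
                  factor = "tmean", value = c(2, 2, 2, 2, 4, 4, 4, 4))
  cfg <- run_config(n_pre_stages = 1, n_post_stages = 1)
  ct <- build_covariate_table(trials, w, cfg)
  # stage means [2, 4] -> covariates {2, 4, 3}
  expect_equal(sort(unname(ct[1, ])), c(2, 3, 4))
  expect_identical(colnames(ct),
                   c("tmean_s1_e1", "tmean_s2_e2", "tmean_s1_e2"))
})

test_that("environment covariates average records with equal weight", {
  sow <- as.Date("2000-06-01")
  trials <- data.frame(
    variety_id = c("v1", "v2"), environment_id = "E1", year = 2000,
    sowing_date = c(sow, sow + 1), flowering_date = c(sow + 3, sow + 4),
    maturity_date = c(sow + 7, sow + 8), yield = 1)
  w <- data.frame(environment_id = "E1",
                  date = seq(sow, sow + 8, by = 1), factor = "f",
                  value = rnorm(9))
  cfg <- run_config(n_pre_stages = 2, n_post_stages = 2)
  ct <- build_covariate_table(trials, w, cfg)
  per_record <- sapply(1:2, function(i) {
    p <- assign_stages(trials$sowing_date[i], trials$flowering_date[i],
                       trials$maturity_date[i], 2, 2)
    stage_means(w, p, "f", "E1")
  })
  expect_equal(unname(ct[1, 1:4]), rowMeans(per_record))
  # a single-record environment reproduces that record's stage means
  ct1 <- build_covariate_table(trials[1, ], w, cfg)
  expect_equal(unname(ct1[1, 1:4]), per_record[, 1])
})

test_that("photoperiod follows solar geometry", {
  expect_equal(photoperiod(0, as.Date("2000-07-15")), 12, tolerance = 0.2)
  for (lat in c(-50, -20, 10, 45, 60))
    expect_equal(photoperiod(lat, as.Date("2000-03-20")), 12,
                 tolerance = 0.3)
  expect_gt(photoperiod(35, as.Date("2000-06-21")),
            photoperiod(35, as.Date("2000-12-21")))
  expect_error(photoperiod(70, as.Date("2000-06-21")), "polar")
})

test_that("similarity kernel is the centered outer product", {
  ct <- matrix(c(1, 2, 3), 3, 1,
               dimnames = list(c("E1", "E2", "E3"), "f_s1_e1"))
  S <- similarity_kernel(ct, "f_s1_e1")
  expect_equal(S["E1", "E3"], -1)
  expect_equal(S["E1", "E2"], 0)
  expect_false(attr(S, "degenerate"))
  Sc <- similarity_kernel(matrix(5, 4, 1,
                                 dimnames = list(paste0("E", 1:4), "c")), "c")
  expect_true(all(Sc == 0))
  expect_true(attr(Sc, "degenerate"))
  set.seed(8)
  x <- rnorm(7)
  ctr <- matrix(x, 7, 1, dimnames = list(paste0("E", 1:7), "r"))
  Sr <- similarity_kernel(ctr, "r")
  expect_lt(max(abs(Sr - tcrossprod(x - mean(x)))), 1e-12)
  # invariance to adding a constant
  ctr2 <- ctr + 100
  expect_equal(unclass(similarity_kernel(ctr2, "r")), unclass(Sr),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("outlier mask is per environment, 3 SD, strict", {
  base <- data.frame(variety_id = "v", year = 2000,
                     sowing_date = as.Date("2000-06-01"),
                     flowering_date = as.Date("2000-08-01"),
                     maturity_date = as.Date("2000-10-01"))
  tr_eq <- cbind(base[rep(1, 10), ], environment_id = "E1", yield = 7)
  expect_identical(mask_outliers(tr_eq, "yield")$yield, rep(7, 10))
  set.seed(2)
  tr_n <- cbind(base[rep(1, 1001), ], environment_id = "E1",
                yield = c(rnorm(1000), 10))
  out <- mask_outliers(tr_n, "yield")
  expect_true(is.na(out$yield[1001]))
  # with 19 values c(x, -x, 0 x 17): 3 SD equals x exactly -> kept (strict)
  tr_b <- cbind(base[rep(1, 19), ], environment_id = "E1",
                yield = c(6, -6, rep(0, 17)))
  expect_false(anyNA(mask_outliers(tr_b, "yield")$yield))
  # with 21 values the same extreme exceeds 3 SD -> masked
  tr_m <- cbind(base[rep(1, 21), ], environment_id = "E1",
                yield = c(6, -6, rep(0, 19)))
  expect_identical(which(is.na(mask_outliers(tr_m, "yield")$yield)),
                   c(1L, 2L))
})
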