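#' Synthetic dataset configuration
#'
#' Defines the conditions the generator emulates: a panel of inbred-like
#' varieties genotyped at biallelic SNPs in Hardy-Weinberg-like frequencies,
#' multi-year trials at M environments with sparse, unbalanced variety
#' coverage, daily weather per environment, and phenotypes generated under
#' the reaction-norm decomposition `u_j = sigma_uj (beta x_j + u~_j)` with
#' `beta ~ N(0, G sigma_beta2)` partly driven by planted QTLs, and residual
#' genetic effects correlated across environments with an exchangeable
#' structure.
#'
#' @param n_varieties,n_snps,n_chrom Panel dimensions.
#' @param n_founders,block_snps Varieties are inbred-line mosaics of two
#'   founder genomes inherited in blocks of `block_snps` consecutive SNPs,
#'   giving the family relatedness and local linkage disequilibrium typical
#'   of a breeding panel (and making genomic prediction of unobserved
#'   varieties informative).
#' @param n_env Number of environments M.
#' @param n_years Trial years per environment.
#' @param n_obs_per_env_year Varieties evaluated per environment-year (drawn
#'   at random; creates the sparse unbalanced coverage typical of historical
#'   trials).
#' @param n_qtl Number of planted QTLs for the sensitivity beta.
#' @param qtl_var_prop Proportion of `sigma_beta2` explained by the QTLs (the
#'   rest is polygenic).
#' @param sigma_beta2 Variance of the sensitivity slopes.
#' @param h2 Narrow-sense heritability within each environment.
#' @param rho_resid Exchangeable correlation of the residual genetic effects
#'   across environments.
#' @param factors Meteorological factor names to simulate (noise factors are
#'   independent of the phenotypes).
#' @param causal_factor,causal_window The planted covariate: factor name and
#'   stage window (start, end) under the generator's staging.
#' @param n_pre_stages,n_post_stages Staging used to place the planted
#'   window.
#' @param x_sd Spread of the planted covariate values across environments (on
#'   the scale of the model's standardised covariate).
#' @param signal_amp Weather-scale amplitude of the planted signal.
#' @param trait_name,mu Trait column name and overall mean.
#' @param year_sd SD of the year effects.
#' @param rng_seed Master seed.
#' @return A list of class `"ecgc_synth_config"`.
#' @export
synth_config <- function(n_varieties = 300L, n_snps = 2000L, n_chrom = 5L,
                         n_founders = 24L, block_snps = 25L,
                         n_env = 20L, n_years = 3L,
                         n_obs_per_env_year = 80L,
                         n_qtl = 3L, qtl_var_prop = 0.5, sigma_beta2 = 1,
                         h2 = 0.5, rho_resid = 0.3,
                         factors = "tmean",
                         causal_factor = "tmean", causal_window = c(1L, 2L),
                         n_pre_stages = 2L, n_post_stages = 4L,
                         x_sd = 0.7, signal_amp = 3,
                         trait_name = "yield", mu = 30, year_sd = 1.5,
                         rng_seed = 1L) {
  stopifnot(n_varieties >= 1, n_snps >= 1, n_chrom >= 1, n_env >= 2,
            n_years >= 1, n_obs_per_env_year >= 1, n_qtl >= 0,
            h2 > 0, h2 < 1, sigma_beta2 >= 0,
            causal_factor %in% factors,
            length(causal_window) == 2L,
            causal_window[2L] <= n_pre_stages + n_post_stages)
  structure(as.list(environment()), class = "ecgc_synth_config")
}

# seasonal weather parameters per factor: list(base, seasonal amplitude,
# daily noise SD); unknown factors get a generic profile
.factor_profile <- function(f) {
  profiles <- list(
    tmean = c(20, 6, 1.2), tmax = c(26, 6, 1.5), tmin = c(15, 6, 1.2),
    precipitation = c(6, 3, 4), vapour_pressure = c(18, 6, 1.5),
    sunshine = c(6, 2, 2), radiation = c(180, 60, 30)
  )
  if (f %in% names(profiles)) profiles[[f]] else c(10, 3, 1.5)
}

#' Generate a complete synthetic multi-environment dataset
#'
#' Produces genotypes, trials, weather, and a truth record under the
#' configuration of [synth_config()]. SNP doses are Binomial(2, p) with
#' p ~ Uniform(0.1, 0.9); the planted covariate values x_j are centred
#' normals clipped so that `x_j^2 sigma_beta2 <= 0.9`; residual genetic
#' variances are `1 - x_j^2 sigma_beta2` floored at 0.05; phenotypes follow
#' y = mu + year + sigma_uj (beta x_j + u~_j) + e with the residual variance
#' set by `h2`. The causal factor's daily weather carries an additive offset
#' `signal_amp * x_j` on the days of the planted stage window, so the
#' environment covariate of that window is an affine image of x_j.
#'
#' @param cfg A `"ecgc_synth_config"`.
#' @return List with `geno` (`"ecgc_geno"`), `trials`, `weather`, `G`, and
#'   `truth` (list: `beta`, `x`, `u` (true additive effects, varieties x
#'   environments), `qtl`, `causal_covariate`, `sigma_beta2`).
#' @export
generate_dataset <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "ecgc_synth_config"))
  seed <- cfg$rng_seed
  nv <- cfg$n_varieties; ns <- cfg$n_snps; M <- cfg$n_env
  vids <- sprintf("V%04d", seq_len(nv))
  envs <- sprintf("E%02d", seq_len(M))

  # genotypes: inbred founders, varieties as two-founder block mosaics
  geno <- with_stage_seed(seed, "geno", {
    p <- runif(ns, 0.1, 0.9)
    founders <- 2L * matrix(rbinom(cfg$n_founders * ns, 1L,
                                   rep(p, each = cfg$n_founders)),
                            nrow = cfg$n_founders)
    chrom <- sprintf("chr%d", rep(seq_len(cfg$n_chrom), length.out = ns))
    chrom <- sort(chrom)
    block <- unlist(lapply(split(seq_len(ns), chrom), function(ix)
      (seq_along(ix) - 1L) %/% cfg$block_snps), use.names = FALSE)
    block_id <- cumsum(c(TRUE, diff(block) != 0 |
                           chrom[-1L] != chrom[-ns]))
    nb <- max(block_id)
    doses <- matrix(0, nv, ns, dimnames = list(vids, NULL))
    for (v in seq_len(nv)) {
      par2 <- sample.int(cfg$n_founders, 2L)
      pick <- par2[sample.int(2L, nb, replace = TRUE)]
      doses[v, ] <- founders[cbind(pick[block_id], seq_len(ns))]
    }
    colnames(doses) <- sprintf("S%05d", seq_len(ns))
    bp <- unlist(lapply(split(seq_len(ns), chrom), function(ix)
      sort(sample.int(5e7, length(ix)))), use.names = FALSE)
    map <- data.frame(snp = colnames(doses), chrom = chrom, bp = bp,
                      stringsAsFactors = FALSE)
    structure(list(doses = doses, map = map), class = "ecgc_geno")
  })
  G <- vanraden_grm(mean_impute(geno))

  # planted covariate values, one per environment; the per-environment
  # genetic variance is fixed at 1, so x_j^2 sigma_beta2 must stay below it
  if (cfg$x_sd^2 * cfg$sigma_beta2 > 0.9)
    stop("covariate effect too large for unit genetic variance")
  x <- with_stage_seed(seed, "x", rnorm(M, 0, cfg$x_sd))
  if (cfg$sigma_beta2 > 0) {
    lim <- sqrt(0.9 / cfg$sigma_beta2) # tail draws clipped to the bound
    x <- pmin(pmax(x, -lim), lim)
  }
  names(x) <- envs

  # sensitivity slopes: planted QTLs + polygenic background
  truth_qtl <- data.frame(snp = character(0), effect = numeric(0))
  beta <- setNames(numeric(nv), vids)
  if (cfg$sigma_beta2 > 0) {
    bres <- with_stage_seed(seed, "beta", {
      maf <- snp_maf(geno)
      cand <- which(maf > 0.2)
      qsnp <- sample(cand, min(cfg$n_qtl, length(cand)))
      Zq <- scale(geno$doses[, qsnp, drop = FALSE])
      gam <- rnorm(length(qsnp))
      bq <- as.numeric(Zq %*% gam)
      if (sd(bq) > 0)
        bq <- bq * sqrt(cfg$qtl_var_prop * cfg$sigma_beta2) / sd(bq)
      Lg <- t(chol(G + diag(1e-6, nv)))
      bp_ <- as.numeric(Lg %*% rnorm(nv))
      bp_ <- bp_ * sqrt((1 - cfg$qtl_var_prop) * cfg$sigma_beta2) /
        max(sd(bp_), 1e-12)
      b <- bq + bp_
      b <- b - mean(b)
      b <- b * sqrt(cfg$sigma_beta2) / max(sd(b), 1e-12)
      list(beta = setNames(b, vids),
           qtl = data.frame(snp = colnames(geno$doses)[qsnp],
                            effect = gam, stringsAsFactors = FALSE))
    })
    beta <- bres$beta
    truth_qtl <- bres$qtl
  }

  # residual genetic effects, exchangeable across environments
  s2_res <- pmax(1 - x^2 * cfg$sigma_beta2, 0.05)
  Rho <- matrix(cfg$rho_resid, M, M); diag(Rho) <- 1
  Sig_res <- sqrt(s2_res) %o% sqrt(s2_res) * Rho
  u_tilde <- with_stage_seed(seed, "resid", {
    Lg <- t(chol(G + diag(1e-6, nv)))
    Lg %*% matrix(rnorm(nv * M), nv, M) %*% chol(Sig_res)
  })
  dimnames(u_tilde) <- list(vids, envs)
  # sigma_uj = 1 throughout: u_j = beta x_j + u~_j
  U <- outer(beta, x) + u_tilde

  # phenology: fixed day-of-year scheme per environment across years
  phen <- with_stage_seed(seed, "phenology", data.frame(
    environment_id = envs,
    sow_doy = sample(150:165, M, replace = TRUE),
    pre_len = sample(40:50, M, replace = TRUE),
    post_len = sample(70:80, M, replace = TRUE),
    stringsAsFactors = FALSE
  ))
  years <- 2001:(2000 + cfg$n_years)

  # trials
  sigma_e <- sqrt((1 - cfg$h2) / cfg$h2) # sigma_u2 = 1
  trials <- with_stage_seed(seed, "trials", {
    year_eff <- setNames(rnorm(length(years), 0, cfg$year_sd),
                         as.character(years))
    rows <- list()
    for (j in seq_len(M)) for (yr in years) {
      vs <- sample(vids, min(cfg$n_obs_per_env_year, nv))
      sow <- as.Date(sprintf("%d-01-01", yr)) + phen$sow_doy[j] - 1L
      flo <- sow + phen$pre_len[j]
      mat <- flo + phen$post_len[j]
      y <- cfg$mu + year_eff[as.character(yr)] + U[vs, envs[j]] +
        rnorm(length(vs), 0, sigma_e)
      rows[[length(rows) + 1L]] <- data.frame(
        variety_id = vs, environment_id = envs[j], year = yr,
        sowing_date = sow, flowering_date = flo, maturity_date = mat,
        y = as.numeric(y), stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    names(out)[names(out) == "y"] <- cfg$trait_name
    out
  })
  attr(trials, "traits") <- cfg$trait_name

  # daily weather with the planted signal on the causal window's days
  weather <- with_stage_seed(seed, "weather", {
    rows <- list()
    for (j in seq_len(M)) {
      env_off <- rnorm(length(cfg$factors), 0, 0.3)
      names(env_off) <- cfg$factors
      for (yr in years) {
        sow <- as.Date(sprintf("%d-01-01", yr)) + phen$sow_doy[j] - 1L
        flo <- sow + phen$pre_len[j]
        mat <- flo + phen$post_len[j]
        dates <- seq(sow - 5L, mat + 5L, by = 1L)
        part <- assign_stages(sow, flo, mat, cfg$n_pre_stages,
                              cfg$n_post_stages)
        sig_days <- part$date[part$stage >= cfg$causal_window[1L] &
                                part$stage <= cfg$causal_window[2L]]
        doy <- as.integer(format(dates, "%j"))
        for (f in cfg$factors) {
          pr <- .factor_profile(f)
          v <- pr[1L] + pr[2L] * sin(2 * pi * (doy - 110) / 365) +
            env_off[f] + rnorm(length(dates), 0, pr[3L])
          if (f == cfg$causal_factor)
            v <- v + cfg$signal_amp * x[j] * (dates %in% sig_days)
          rows[[length(rows) + 1L]] <- data.frame(
            environment_id = envs[j], date = dates, factor = f, value = v,
            stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  })

  truth_qtl <- merge(truth_qtl, geno$map, by = "snp", sort = FALSE)
  list(
    geno = geno, trials = trials, weather = weather, G = G,
    truth = list(
      beta = beta, x = x, u = U, qtl = truth_qtl,
      causal_covariate = sprintf("%s_s%d_e%d", cfg$causal_factor,
                                 cfg$causal_window[1L],
                                 cfg$causal_window[2L]),
      sigma_beta2 = cfg$sigma_beta2, config = cfg
    )
  )
}

#' Write a synthetic dataset to CSV/JSON files
#'
#' Writes `geno.csv`, `map.csv`, `trials.csv`, `weather.csv` in the formats
#' read by [read_genotypes()], [read_trials()] and [read_weather()], plus
#' `truth.json`.
#'
#' @param ds Output of [generate_dataset()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, `dir`.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(data.frame(variety_id = rownames(ds$geno$doses), ds$geno$doses,
                       check.names = FALSE),
            file.path(dir, "geno.csv"), row.names = FALSE)
  write.csv(ds$geno$map, file.path(dir, "map.csv"), row.names = FALSE)
  write.csv(ds$trials, file.path(dir, "trials.csv"), row.names = FALSE)
  write.csv(ds$weather, file.path(dir, "weather.csv"), row.names = FALSE)
  truth <- ds$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
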