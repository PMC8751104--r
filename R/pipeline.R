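#' Run the full environmental-covariate search pipeline
#'
#' Chains all analysis steps on in-memory inputs: genotype QC and genomic
#' relationship matrix; per-environment single-trait GBLUP (adjusted
#' phenotypes and additive effects); stage-window environmental covariates;
#' pairwise bivariate REML genetic correlations; the Bonferroni-corrected
#' covariate scan with gap-statistic cluster pruning; and, for every selected
#' covariate, reaction-norm slopes, mixed-model GWAS with FDR thresholding,
#' 100-kb region grouping, subsampling validation and the selection-history
#' trend.
#'
#' @param geno `"ecgc_geno"` genotypes (raw; imputation and MAF filtering are
#'   applied here).
#' @param trials Trial table ([read_trials()] format).
#' @param weather Daily weather table.
#' @param config An `"ecgc_config"`.
#' @param traits Trait columns to analyse (default: all in `trials`).
#' @param min_records,min_varieties Per-environment data requirements below
#'   which an environment is skipped for a trait.
#' @param B_ref,max_k Gap-statistic settings (see [cluster_covariates()]).
#' @param run_gwas Run the slope-GWAS stage (Step 5)?
#' @param run_subsample Run subsampling validation within Step 5?
#' @return A list: `G`, `cov_table`, `clusters`, `scan_threshold`, and
#'   per-trait results under `traits` (each with `fits`, `P`, `pair_fits`
#'   summary, `scan`, `gwas`).
#' @export
run_ecgc <- function(geno, trials, weather, config = run_config(),
                     traits = NULL, min_records = 10L, min_varieties = 5L,
                     B_ref = 50L, max_k = NULL,
                     run_gwas = TRUE, run_subsample = TRUE) {
  if (is.null(traits)) traits <- attr(trials, "traits")
  stopifnot(length(traits) >= 1)
  ecgc_log("pipeline start: %d trial records, %d traits",
           nrow(trials), length(traits))

  geno <- mean_impute(geno)
  geno <- filter_maf(geno, config$maf_min)
  G <- vanraden_grm(geno)
  ecgc_log("GRM built from %d SNPs x %d varieties",
           ncol(geno$doses), nrow(G))

  cov_table <- build_covariate_table(trials, weather, config)
  ecgc_log("covariate table: %d environments x %d covariates",
           nrow(cov_table), ncol(cov_table))
  clusters <- with_stage_seed(config$rng_seed, "gap",
                              cluster_covariates(cov_table, max_k = max_k,
                                                 B_ref = B_ref))
  ecgc_log("covariates clustered into %d group(s)", attr(clusters, "k"))

  res_traits <- list()
  for (trait in traits) {
    tr <- mask_outliers(trials, trait)
    tr <- tr[!is.na(tr[[trait]]) & tr$variety_id %in% rownames(G), ,
             drop = FALSE]
    envs_all <- intersect(rownames(cov_table), unique(tr$environment_id))

    # Step 0: per-environment GBLUP
    fits <- list()
    adj <- list()
    for (e in envs_all) {
      d <- tr[tr$environment_id == e, , drop = FALSE]
      if (nrow(d) < min_records ||
          length(unique(d$variety_id)) < min_varieties) {
        ecgc_log("%s: environment %s skipped (too few records)", trait, e)
        next
      }
      X <- if (length(unique(d$year)) > 1L)
        model.matrix(~ factor(year), data = d)
      else matrix(1, nrow(d), 1)
      fits[[e]] <- fit_gblup(d[[trait]], X, d$variety_id, G,
                             tol = config$reml_tol)
      adj[[e]] <- data.frame(variety_id = d$variety_id, environment_id = e,
                             year = d$year, y_adj = fits[[e]]$y_adj,
                             stringsAsFactors = FALSE)
    }
    envs <- names(fits)
    if (length(envs) < 4L) {
      ecgc_log("%s: only %d usable environment(s); trait skipped",
               trait, length(envs))
      next
    }
    adj <- do.call(rbind, adj)
    ecgc_log("%s: GBLUP fitted at %d environments (mean h2 = %.2f)",
             trait, length(envs),
             mean(vapply(fits, `[[`, numeric(1), "h2")))

    # Step 3: pairwise bivariate REML
    pair_fits <- with_stage_seed(config$rng_seed, paste0("match_", trait), {
      out <- list()
      for (a in seq_len(length(envs) - 1L)) for (b in (a + 1L):length(envs)) {
        nm <- paste0(envs[a], "||", envs[b])
        out[[nm]] <- tryCatch({
          paired <- match_records(adj, envs[a], envs[b])
          fit_bivariate(paired, G, tol = config$reml_tol,
                        max_iter = config$reml_max_iter)
        }, error = function(e) {
          ecgc_log("%s: pair %s failed: %s", trait, nm, conditionMessage(e))
          structure(list(Su = diag(2), Se = diag(2), rg = NA,
                         converged = FALSE, n_obs = 0L, n_shared = 0L),
                    class = "bivar_fit")
        })
      }
      out
    })
    P <- assemble_correlation(pair_fits, envs)
    ecgc_log("%s: genetic correlation matrix assembled (%d pairs, %d flagged)",
             trait, length(pair_fits), attr(P, "n_flagged"))

    # Step 4: covariate scan
    scan <- scan_covariates(cov_table, P,
                            n_covariates_total = ncol(cov_table),
                            n_traits = length(traits),
                            alpha = config$scan_alpha)
    scan <- prune_significant(scan, clusters)
    ecgc_log("%s: %d significant covariate(s), %d selected after pruning",
             trait, sum(scan$significant), sum(scan$selected))

    # Step 5: slopes, GWAS, regions, subsampling, selection trend
    gwas_res <- list()
    if (run_gwas && any(scan$selected)) {
      for (cov_id in scan$covariate[scan$selected]) {
        slopes <- estimate_slopes(fits, cov_table, cov_id)
        gw <- mm_gwas(slopes, geno, G, maf_min = config$maf_min)
        fd <- fdr_threshold(gw$p, config$fdr_level)
        regions <- group_regions(gw, fd$threshold, config$region_gap_bp)
        if (run_subsample)
          regions <- subsample_validate(
            slopes, geno, G, regions, fd$threshold, config,
            seed_stage = paste0("subsample_", trait, "_", cov_id))
        trend <- selection_trend(slopes, cov_table[, cov_id], tr)
        gwas_res[[cov_id]] <- list(slopes = slopes, gwas = gw,
                                   fdr = fd, regions = regions,
                                   trend = trend)
        ecgc_log("%s / %s: %d region(s)%s", trait, cov_id, nrow(regions),
                 if (run_subsample && nrow(regions))
                   sprintf(", %d reliable", sum(regions$reliable)) else "")
      }
    }
    res_traits[[trait]] <- list(fits = fits, P = P,
                                pair_converged = vapply(
                                  pair_fits, `[[`, logical(1), "converged"),
                                scan = scan, gwas = gwas_res)
  }
  list(G = G, cov_table = cov_table, clusters = clusters,
       scan_threshold = bonferroni_threshold(ncol(cov_table),
                                             length(traits),
                                             config$scan_alpha),
       traits = res_traits)
}
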