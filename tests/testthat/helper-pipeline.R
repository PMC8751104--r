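# End-to-end pipeline runs on synthetic data are expensive; several test
# files (and several acceptance checks) share them through this memoised
# helper. Results are keyed by (seed, sigma_beta2).
.pipeline_cache <- new.env(parent = emptyenv())

h_pipeline_run <- function(seed, sigma_beta2 = 1) {
  key <- sprintf("s%d_b%g", seed, sigma_beta2)
  if (!is.null(.pipeline_cache[[key]])) return(.pipeline_cache[[key]])
  ds <- generate_dataset(synth_config(rng_seed = seed,
                                      sigma_beta2 = sigma_beta2))
  cfg <- run_config(n_pre_stages = 2, n_post_stages = 4, rng_seed = seed)
  res <- run_ecgc(ds$geno, ds$trials, ds$weather, cfg,
                  run_gwas = sigma_beta2 > 0)
  tr <- res$traits[[1]]
  causal <- ds$truth$causal_covariate
  causal_cluster <- unname(res$clusters[causal])
  detected <- any(tr$scan$selected &
                    tr$scan$cluster_id == causal_cluster)
  slope_cor <- NA_real_
  if (length(tr$gwas)) {
    sl <- tr$gwas[[1]]$slopes
    slope_cor <- cor(sl$slope[match(names(ds$truth$beta), sl$variety_id)],
                     ds$truth$beta)
  }
  out <- list(
    truth = ds$truth,
    scan = tr$scan, clusters = res$clusters,
    scan_threshold = res$scan_threshold,
    P = tr$P, pair_converged = tr$pair_converged,
    gwas = tr$gwas,
    causal_p = tr$scan$p[tr$scan$covariate == causal],
    causal_significant =
      tr$scan$significant[tr$scan$covariate == causal],
    detected = detected, slope_cor = slope_cor
  )
  .pipeline_cache[[key]] <- out
  out
}
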