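#' Pipeline log message
#'
#' Lightweight timestamped logging used by every pipeline stage. Silenced with
#' `options(ecgc.verbose = FALSE)`.
#'
#' @param ... Passed to [sprintf()].
#' @return Invisibly, the message string.
#' @export
ecgc_log <- function(...) {
  msg <- sprintf(...)
  if (!is.null(.ecgc_env$collect))
    .ecgc_env$collect <- c(.ecgc_env$collect, msg)
  if (isTRUE(getOption("ecgc.verbose", TRUE)))
    message(sprintf("[ecgc %s] %s", format(Sys.time(), "%H:%M:%S"), msg))
  invisible(msg)
}

#' Run configuration
#'
#' Holds every tunable constant of the pipeline. Defaults encode the standard
#' analysis settings: 10 pre-flowering and 20 post-flowering growth stages,
#' minor allele frequency strictly above 0.05, a 0.05 family-wise scan level,
#' FDR 0.05 for the slope GWAS, 100-kb region grouping, and 10 subsampling
#' replicates of 80% of varieties with a reliability cutoff of at least 5 hits
#' (counts > 4).
#'
#' @param n_pre_stages Stages between sowing and flowering (default 10).
#' @param n_post_stages Stages between flowering and maturity (default 20).
#' @param maf_min Minor-allele-frequency cutoff; SNPs with MAF strictly greater
#'   are kept (default 0.05).
#' @param scan_alpha Family-wise error level for the Bonferroni-corrected
#'   covariate scan (default 0.05).
#' @param fdr_level FDR level for the slope GWAS (default 0.05).
#' @param region_gap_bp Significant SNPs closer than this merge into one region
#'   (default 1e5).
#' @param subsample_fraction Fraction of varieties kept per subsampling
#'   replicate (default 0.8).
#' @param subsample_reps Number of subsampling replicates (default 10).
#' @param subsample_min_count Minimum number of replicates in which a region
#'   must reach significance to be called reliable (default 5).
#' @param rng_seed Master seed; every stochastic stage derives a named
#'   substream from it (see [stage_seed()]).
#' @param reml_tol REML convergence tolerance (default 1e-8).
#' @param reml_max_iter Maximum REML iterations (default 200).
#' @return A list of class `"ecgc_config"`.
#' @export
run_config <- function(n_pre_stages = 10L, n_post_stages = 20L,
                       maf_min = 0.05, scan_alpha = 0.05, fdr_level = 0.05,
                       region_gap_bp = 100000L, subsample_fraction = 0.8,
                       subsample_reps = 10L, subsample_min_count = 5L,
                       rng_seed = 1L, reml_tol = 1e-8, reml_max_iter = 200L) {
  cfg <- list(
    n_pre_stages = as.integer(n_pre_stages),
    n_post_stages = as.integer(n_post_stages),
    maf_min = maf_min, scan_alpha = scan_alpha, fdr_level = fdr_level,
    region_gap_bp = as.numeric(region_gap_bp),
    subsample_fraction = subsample_fraction,
    subsample_reps = as.integer(subsample_reps),
    subsample_min_count = as.integer(subsample_min_count),
    rng_seed = as.integer(rng_seed),
    reml_tol = reml_tol, reml_max_iter = as.integer(reml_max_iter)
  )
  for (f in c("maf_min", "scan_alpha", "fdr_level", "subsample_fraction"))
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0 || cfg[[f]] > 1)
      stop(sprintf("'%s' must be in (0, 1]", f))
  if (cfg$n_pre_stages < 1L || cfg$n_post_stages < 1L)
    stop("stage counts must be >= 1")
  if (cfg$region_gap_bp <= 0) stop("'region_gap_bp' must be > 0")
  if (cfg$subsample_reps < 1L) stop("'subsample_reps' must be >= 1")
  structure(cfg, class = "ecgc_config")
}

#' Read a run configuration from a YAML file
#'
#' The file holds a flat mapping mirroring the arguments of [run_config()];
#' unknown keys are kept (e.g. input paths used by the command-line interface).
#'
#' @param path Path to a YAML file.
#' @return A list of class `"ecgc_config"` with any extra keys attached.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(run_config))
  cfg <- do.call(run_config, raw[intersect(names(raw), known)])
  extra <- raw[setdiff(names(raw), known)]
  for (k in names(extra)) cfg[[k]] <- extra[[k]]
  cfg
}

#' Read a genotype table
#'
#' Genotypes are coded as allele doses in \{0, 1, 2\} (missing allowed). CSV
#' input is a varieties-by-SNPs table whose first column holds variety ids and
#' whose header row holds SNP ids, with a side table giving the marker map.
#' VCF input (requires the `vcfR` package) is converted to ALT-allele doses;
#' non-biallelic records are skipped with a warning.
#'
#' @param path Path to the genotype CSV or VCF.
#' @param format `"csv"` or `"vcf"`.
#' @param map_path For CSV input, path to a CSV with columns `snp`, `chrom`,
#'   `bp`. Ignored for VCF (map taken from the records).
#' @return An object of class `"ecgc_geno"`: list with `doses`
#'   (varieties x SNPs numeric matrix) and `map` (data.frame `snp`, `chrom`,
#'   `bp`, sorted by position within chromosome).
#' @export
read_genotypes <- function(path, format = c("csv", "vcf"), map_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("genotype file not found: ", path)
  if (format == "csv") {
    tab <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(tab[[1L]])
    if (anyDuplicated(ids)) stop("duplicated variety id in genotype table")
    doses <- as.matrix(tab[, -1L, drop = FALSE])
    storage.mode(doses) <- "double"
    rownames(doses) <- ids
    bad <- doses[!is.na(doses)]
    if (any(bad < 0 | bad > 2)) stop("invalid dose: values must lie in [0, 2]")
    if (is.null(map_path)) stop("'map_path' is required for CSV genotypes")
    map <- read.csv(map_path, stringsAsFactors = FALSE)
    need <- c("snp", "chrom", "bp")
    if (!all(need %in% names(map))) stop("map must have columns snp, chrom, bp")
    map <- map[match(colnames(doses), map$snp), need]
    if (anyNA(map$snp)) stop("map is missing entries for some SNPs")
  } else {
    if (!requireNamespace("vcfR", quietly = TRUE))
      stop("VCF import requires the 'vcfR' package")
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    multi <- grepl(",", fix[, "ALT"]) | is.na(fix[, "ALT"]) |
      nchar(fix[, "REF"]) != 1L | nchar(fix[, "ALT"]) != 1L
    if (any(multi)) {
      warning(sum(multi), " non-biallelic VCF record(s) skipped")
      v <- v[!multi, ]
      fix <- fix[!multi, , drop = FALSE]
    }
    gt <- vcfR::extract.gt(v, element = "GT")
    dose <- apply(gt, 2, function(g) {
      a <- strsplit(gsub("\\|", "/", g), "/", fixed = FALSE)
      vapply(a, function(x) {
        if (length(x) < 2L || anyNA(x) || any(x == "."))
          return(NA_real_)
        sum(x != "0")
      }, numeric(1))
    })
    doses <- t(dose) # varieties x snps
    snp_id <- fix[, "ID"]
    snp_id[is.na(snp_id) | snp_id == "."] <-
      paste0(fix[, "CHROM"], "_", fix[, "POS"])[is.na(snp_id) | snp_id == "."]
    colnames(doses) <- snp_id
    if (anyDuplicated(rownames(doses))) stop("duplicated variety id in VCF")
    map <- data.frame(snp = snp_id, chrom = fix[, "CHROM"],
                      bp = as.numeric(fix[, "POS"]), stringsAsFactors = FALSE)
  }
  ord <- order(map$chrom, map$bp)
  map <- map[ord, , drop = FALSE]
  rownames(map) <- NULL
  doses <- doses[, map$snp, drop = FALSE]
  structure(list(doses = doses, map = map), class = "ecgc_geno")
}

#' @export
print.ecgc_geno <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d varieties x %d SNPs on %d chromosome(s)\n",
              nrow(x$doses), ncol(x$doses), length(unique(x$map$chrom))))
  invisible(x)
}

#' Read phenotype trial records
#'
#' Required columns: `variety_id`, `environment_id`, `year`, `sowing_date`,
#' `flowering_date`, `maturity_date` (ISO-8601 dates; maturity may be missing),
#' plus one column per trait. Records whose dates violate
#' sowing < flowering < maturity are excluded with a log entry.
#'
#' @param path Path to the trial CSV.
#' @return A data.frame with parsed `Date` columns; trait column names are in
#'   `attr(, "traits")`.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("trial file not found: ", path)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("variety_id", "environment_id", "year",
            "sowing_date", "flowering_date", "maturity_date")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("trial table missing column(s): ",
                         paste(miss, collapse = ", "))
  for (d in grep("_date$", need, value = TRUE))
    tab[[d]] <- as.Date(tab[[d]])
  tab$variety_id <- as.character(tab$variety_id)
  tab$environment_id <- as.character(tab$environment_id)
  bad <- (!is.na(tab$flowering_date) & tab$flowering_date <= tab$sowing_date) |
    (!is.na(tab$maturity_date) & !is.na(tab$flowering_date) &
       tab$maturity_date <= tab$flowering_date)
  if (any(bad)) {
    ecgc_log("excluded %d trial record(s) with inconsistent phenology dates",
             sum(bad))
    tab <- tab[!bad, , drop = FALSE]
  }
  rownames(tab) <- NULL
  attr(tab, "traits") <- setdiff(names(tab), need)
  tab
}

#' Read daily weather records
#'
#' Long format with columns `environment_id`, `date` (ISO-8601), `factor`,
#' `value`: one value per (environment, date, meteorological factor).
#'
#' @param path Path to the weather CSV.
#' @return A data.frame with a parsed `Date` column.
#' @export
read_weather <- function(path) {
  if (!file.exists(path)) stop("weather file not found: ", path)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("environment_id", "date", "factor", "value")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("weather table missing column(s): ",
                         paste(miss, collapse = ", "))
  tab$date <- as.Date(tab$date)
  tab$environment_id <- as.character(tab$environment_id)
  if (anyDuplicated(tab[, c("environment_id", "date", "factor")]))
    stop("duplicated (environment, date, factor) in weather table")
  tab
}

#' Write / read a square matrix as CSV
#'
#' Used for genomic relationship, similarity and genetic correlation matrices:
#' a square CSV with ids as both header and first column.
#'
#' @param m Square numeric matrix with dimnames.
#' @param path Output path.
#' @return `write_matrix_csv`: invisibly, `path`. `read_matrix_csv`: the
#'   matrix.
#' @export
write_matrix_csv <- function(m, path) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m), !is.null(rownames(m)))
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  m
}
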