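#' Number of stage-window covariates per meteorological factor
#'
#' With S growth stages there are S single-stage windows plus S(S-1)/2
#' multi-stage spans, i.e. S(S+1)/2 covariates per factor. For the standard
#' 30-stage partition this gives 465, and 465 x 14 factors = 6,510 covariates.
#'
#' @param n_stages Total number of growth stages S.
#' @return Integer covariate count.
#' @export
#' @examples
#' n_window_covariates(30) # 465
n_window_covariates <- function(n_stages) {
  stopifnot(n_stages >= 1)
  as.integer(n_stages * (n_stages + 1) / 2)
}

#' Partition a growth period into equal-sized stages
#'
#' The pre-flowering period (sowing through flowering) is tiled by `n_pre`
#' contiguous blocks and the post-flowering period (the day after flowering
#' through maturity) by `n_post` blocks. Block boundaries are
#' floor-interpolated on cumulative day counts, so block lengths differ by at
#' most one day and remainder days fall in later blocks. The flowering day
#' belongs to the last pre-flowering stage and the maturity day to the last
#' stage.
#'
#' @param sowing,flowering,maturity `Date`s (or integers) with
#'   sowing < flowering < maturity.
#' @param n_pre,n_post Stage counts for the two periods.
#' @return A data.frame with columns `date` and `stage` (1 .. n_pre + n_post)
#'   covering every day from sowing to maturity exactly once.
#' @export
assign_stages <- function(sowing, flowering, maturity, n_pre, n_post) {
  if (is.na(sowing) || is.na(flowering) || is.na(maturity))
    stop("phenology dates must not be missing")
  if (!(sowing < flowering && flowering < maturity))
    stop("dates must satisfy sowing < flowering < maturity")
  L1 <- as.integer(flowering - sowing) + 1L # sowing..flowering inclusive
  L2 <- as.integer(maturity - flowering)   # flowering+1..maturity
  if (L1 < n_pre || L2 < n_post)
    stop(sprintf("too few days: %d pre / %d post for %d + %d stages",
                 L1, L2, n_pre, n_post))
  block <- function(L, n) {
    b <- floor(seq_len(n) * L / n) # upper boundaries, 0-based exclusive
    rep(seq_len(n), times = diff(c(0L, b)))
  }
  data.frame(
    date = seq(sowing, maturity, by = 1L),
    stage = c(block(L1, n_pre), block(L2, n_post) + n_pre)
  )
}

#' Stage means of a daily meteorological factor
#'
#' Averages the daily values of one factor at one environment over the days of
#' each growth stage.
#'
#' @param weather Daily weather table (see [read_weather()]).
#' @param partition Stage partition from [assign_stages()].
#' @param factor_name Meteorological factor to average.
#' @param environment_id Environment whose weather series to use.
#' @return Numeric vector of length max(partition$stage).
#' @export
stage_means <- function(weather, partition, factor_name, environment_id) {
  w <- weather[weather$environment_id == environment_id &
                 weather$factor == factor_name, , drop = FALSE]
  v <- w$value[match(partition$date, w$date)]
  if (anyNA(v)) {
    gap <- partition$date[which(is.na(v))[1L]]
    stop(sprintf("weather for environment %s, factor %s missing on %s",
                 environment_id, factor_name, format(gap)))
  }
  as.numeric(tapply(v, partition$stage, mean))
}

# span covariates from a vector of stage means: windows (a, b), a <= b,
# ordered single stages first then spans by (a, b); value = unweighted mean of
# the stage means a..b
window_means <- function(sm) {
  S <- length(sm)
  cs <- c(0, cumsum(sm))
  out <- numeric(n_window_covariates(S))
  a_idx <- integer(length(out)); b_idx <- integer(length(out))
  out[1:S] <- sm; a_idx[1:S] <- 1:S; b_idx[1:S] <- 1:S
  k <- S
  if (S > 1L) for (a in 1:(S - 1L)) for (b in (a + 1L):S) {
    k <- k + 1L
    out[k] <- (cs[b + 1L] - cs[a]) / (b - a + 1L)
    a_idx[k] <- a; b_idx[k] <- b
  }
  list(value = out, start = a_idx, end = b_idx)
}

#' Build the environment-by-covariate table
#'
#' For every trial record with complete phenology, the growth period is staged
#' ([assign_stages()]) and daily values of each meteorological factor are
#' averaged within stages. Stage means are then averaged over all records of
#' the environment (equal weight per record), and every stage window (a, b)
#' receives the unweighted mean of stage means a..b. With S stages this yields
#' S(S+1)/2 covariates per factor per environment.
#'
#' @param trials Trial table ([read_trials()]).
#' @param weather Daily weather table ([read_weather()]).
#' @param config An `"ecgc_config"` (stage counts are taken from it).
#' @param factors Factors to use; default all factors present in `weather`.
#' @return A numeric matrix (environments x covariates) with covariate ids
#'   `"<factor>_s<a>_e<b>"` as column names and a data.frame
#'   `attr(, "info")` with columns `covariate`, `factor`, `start`, `end`.
#' @export
build_covariate_table <- function(trials, weather, config = run_config(),
                                  factors = NULL) {
  if (is.null(factors)) factors <- sort(unique(weather$factor))
  n_pre <- config$n_pre_stages; n_post <- config$n_post_stages
  S <- n_pre + n_post
  ok <- !is.na(trials$sowing_date) & !is.na(trials$flowering_date) &
    !is.na(trials$maturity_date)
  if (!all(ok))
    ecgc_log("covariates: %d record(s) without full phenology skipped",
             sum(!ok))
  tr <- trials[ok, , drop = FALSE]
  envs <- sort(unique(trials$environment_id))
  # stage means are identical for records sharing (environment, dates);
  # compute once per distinct phenology and weight by record count
  key <- paste(tr$environment_id, tr$sowing_date, tr$flowering_date,
               tr$maturity_date)
  uk <- !duplicated(key)
  ucount <- table(key)
  stage_env <- matrix(NA_real_, nrow = 0, ncol = S)
  rows <- list()
  for (i in which(uk)) {
    part <- assign_stages(tr$sowing_date[i], tr$flowering_date[i],
                          tr$maturity_date[i], n_pre, n_post)
    sm <- vapply(factors, function(f)
      stage_means(weather, part, f, tr$environment_id[i]), numeric(S))
    rows[[key[i]]] <- list(env = tr$environment_id[i], sm = sm,
                           w = as.numeric(ucount[[key[i]]]))
  }
  info <- do.call(rbind, lapply(factors, function(f) {
    wm <- window_means(numeric(S) + 1)
    data.frame(covariate = sprintf("%s_s%d_e%d", f, wm$start, wm$end),
               factor = f, start = wm$start, end = wm$end,
               stringsAsFactors = FALSE)
  }))
  out <- matrix(NA_real_, nrow = length(envs), ncol = nrow(info),
                dimnames = list(envs, info$covariate))
  dropped <- character(0)
  for (e in envs) {
    re <- Filter(function(r) r$env == e, rows)
    if (!length(re)) { dropped <- c(dropped, e); next }
    w <- vapply(re, `[[`, numeric(1), "w")
    sm_env <- Reduce(`+`, Map(function(r) r$sm * r$w, re)) / sum(w)
    vals <- unlist(lapply(seq_along(factors), function(fi)
      window_means(sm_env[, fi])$value), use.names = FALSE)
    out[e, ] <- vals
  }
  if (length(dropped)) {
    warning("environment(s) without valid records excluded: ",
            paste(dropped, collapse = ", "))
    out <- out[setdiff(envs, dropped), , drop = FALSE]
  }
  attr(out, "info") <- info
  out
}

#' Astronomical photoperiod
#'
#' Sunrise-to-sunset daylength in hours from the standard solar-declination
#' formula with a zero-elevation sun. Valid for latitudes below the polar
#' circles.
#'
#' @param latitude_deg Latitude in degrees (|latitude| < 66.5).
#' @param date A `Date` (vectorised).
#' @return Daylength in hours.
#' @export
#' @examples
#' photoperiod(35, as.Date("2000-06-21")) # ~14.4 h
photoperiod <- function(latitude_deg, date) {
  if (any(abs(latitude_deg) >= 66.5))
    stop("photoperiod undefined at polar latitudes")
  doy <- as.integer(format(as.Date(date), "%j"))
  decl <- -23.44 * cos(2 * pi * (doy + 10) / 365.24) * pi / 180
  phi <- latitude_deg * pi / 180
  cosw <- pmin(1, pmax(-1, -tan(phi) * tan(decl)))
  24 * acos(cosw) / pi
}

#' Linear-kernel similarity matrix of one covariate
#'
#' s_jk = (x_j - xbar)(x_k - xbar): the outer product of the mean-centered
#' covariate values over environments. A covariate constant across
#' environments yields the all-zero matrix, flagged degenerate.
#'
#' @param cov_table Covariate table from [build_covariate_table()] (or any
#'   environments-by-covariates matrix).
#' @param covariate_id Column to use.
#' @return An M x M symmetric rank-<=1 matrix with environment ids as
#'   dimnames and a logical attribute `"degenerate"`.
#' @export
similarity_kernel <- function(cov_table, covariate_id) {
  x <- cov_table[, covariate_id]
  if (length(x) < 3L) stop("need covariate values for >= 3 environments")
  xc <- x - mean(x)
  S <- tcrossprod(xc)
  dimnames(S) <- list(rownames(cov_table), rownames(cov_table))
  attr(S, "degenerate") <- isTRUE(all(abs(xc) < 1e-12))
  S
}

#' Mask phenotypic outliers
#'
#' Per environment and trait, values strictly outside mean +/- 3 SD are set
#' missing; values exactly on the boundary are kept. Environments with fewer
#' than three non-missing values are skipped with a log entry.
#'
#' @param trials Trial table ([read_trials()]).
#' @param trait Trait column name.
#' @return The trial table with outliers masked.
#' @export
mask_outliers <- function(trials, trait) {
  stopifnot(trait %in% names(trials))
  n_masked <- 0L
  for (e in unique(trials$environment_id)) {
    idx <- which(trials$environment_id == e & !is.na(trials[[trait]]))
    if (length(idx) < 3L) {
      ecgc_log("outlier mask: environment %s has < 3 values for %s; skipped",
               e, trait)
      next
    }
    v <- trials[[trait]][idx]
    m <- mean(v); s <- sd(v)
    out <- abs(v - m) > 3 * s
    if (any(out)) {
      trials[[trait]][idx[out]] <- NA_real_
      n_masked <- n_masked + sum(out)
    }
  }
  if (n_masked) ecgc_log("outlier mask: %d %s value(s) set missing",
                         n_masked, trait)
  trials
}
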