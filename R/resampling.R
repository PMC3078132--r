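## Moving-block bootstrap for autocorrelated orientation series, and the
## two-level trajectory/block resampling scheme used to summarize repeated
## independent simulations.

new_bootstrap_summary <- function(resample_means, n_resamples, block_length,
                                  confidence_level, seed, series_mean,
                                  series_sd, between_sd = NA_real_,
                                  warning = NULL) {
  alpha <- (1 - confidence_level) / 2
  ci <- unname(stats::quantile(resample_means, c(alpha, 1 - alpha),
                               type = 7, names = FALSE))
  structure(list(
    mean = mean(resample_means),
    sd = stats::sd(resample_means),
    ci_low = ci[1],
    ci_high = ci[2],
    n_resamples = n_resamples,
    block_length = block_length,
    confidence_level = confidence_level,
    seed = seed,
    series_mean = series_mean,
    series_sd = series_sd,
    between_trajectory_sd = between_sd,
    warning = warning
  ), class = "BootstrapSummary")
}

#' @export
print.BootstrapSummary <- function(x, ...) {
  cat(sprintf("<BootstrapSummary> mean %.4g +/- %.4g (resample SD), %g%% CI [%.4g, %.4g], %d resamples, block %d\n",
              x$mean, x$sd, 100 * x$confidence_level, x$ci_low, x$ci_high,
              x$n_resamples, x$block_length))
  invisible(x)
}

## index matrix of one blocked resample per row: ceil(L/b) block starts drawn
## with replacement, blocks concatenated and truncated to length L.
block_resample_means <- function(series, n_resamples, block_length) {
  L <- length(series)
  b <- as.integer(block_length)
  nblocks <- ceiling(L / b)
  starts <- matrix(sample.int(L - b + 1L, n_resamples * nblocks, replace = TRUE),
                   nrow = n_resamples)
  offsets <- 0:(b - 1L)
  ## rows: resamples; columns: concatenated block positions, truncated to L
  full <- matrix(0L, nrow = n_resamples, ncol = nblocks * b)
  for (j in seq_len(nblocks))
    full[, (j - 1L) * b + seq_len(b)] <- starts[, j] + rep(offsets, each = n_resamples)
  full <- full[, seq_len(L), drop = FALSE]
  rowMeans(matrix(series[full], nrow = n_resamples))
}

#' Moving-block bootstrap summary of a scalar time series
#'
#' Resampled series are built by drawing `ceiling(L / block_length)`
#' contiguous blocks with replacement and truncating to the original length;
#' the summary describes the distribution of resample means (percentile
#' confidence interval). Blocks preserve short-range autocorrelation, so the
#' resample SD is an honest standard error for correlated series when the
#' block length exceeds the series' correlation time.
#'
#' @param series numeric vector (one scalar per frame), length at least
#'   `2 * block_length`.
#' @param n_resamples number of resampled datasets (>= 100; default 1000).
#' @param block_length block size in frames (e.g. frames spanning 1 ns).
#' @param confidence_level CI level in (0, 1) (default 0.95).
#' @param seed integer seed; a fixed seed gives a bit-identical summary.
#' @return object of class `BootstrapSummary` with elements `mean`, `sd`
#'   (SD of resample means, the headline uncertainty), `ci_low`, `ci_high`,
#'   `series_mean`, `series_sd` (plain time-series SD), `n_resamples`,
#'   `block_length`, `confidence_level`, `seed`.
#' @export
block_bootstrap <- function(series, n_resamples = 1000L, block_length,
                            confidence_level = 0.95, seed = 1L) {
  series <- as.numeric(series)
  if (anyNA(series)) pd_stop("series contains NA", "contract_violation")
  if (!is_scalar_number(block_length) || block_length < 1)
    pd_stop("block_length must be a positive frame count", "configuration_error")
  if (length(series) < 2L * block_length)
    pd_stop(sprintf("series length %d is shorter than two blocks of %d frames",
                    length(series), as.integer(block_length)),
            "insufficient_data_error")
  if (n_resamples < 100L)
    pd_stop("n_resamples must be at least 100", "configuration_error")
  if (confidence_level <= 0 || confidence_level >= 1)
    pd_stop("confidence_level must be in (0, 1)", "configuration_error")
  means <- with_seed(seed,
                     block_resample_means(series, as.integer(n_resamples),
                                          block_length))
  new_bootstrap_summary(means, as.integer(n_resamples),
                        as.integer(block_length), confidence_level,
                        as.integer(seed), mean(series), stats::sd(series))
}

#' Two-level bootstrap over repeated trajectories
#'
#' Resamples whole trajectories with replacement, then blocks within each
#' drawn trajectory; each resampled dataset's statistic is the mean of its
#' per-trajectory blocked-resample means. This propagates both
#' between-trajectory spread and within-trajectory autocorrelated noise, the
#' appropriate scheme when several independent simulations of the same
#' system are summarized together.
#'
#' @param series_set list of numeric series (one per trajectory), each at
#'   least `2 * block_length` long. A single series falls back to
#'   [block_bootstrap()] and records a warning in the result.
#' @inheritParams block_bootstrap
#' @return a `BootstrapSummary`; `between_trajectory_sd` is the plain SD of
#'   the per-trajectory means.
#' @export
multi_trajectory_summary <- function(series_set, n_resamples = 1000L,
                                     block_length, confidence_level = 0.95,
                                     seed = 1L) {
  if (!is.list(series_set) || length(series_set) == 0L)
    pd_stop("series_set must be a non-empty list of series", "contract_violation")
  if (length(series_set) == 1L) {
    out <- block_bootstrap(series_set[[1]], n_resamples, block_length,
                           confidence_level, seed)
    out$warning <- "single trajectory: fell back to within-trajectory block bootstrap"
    return(out)
  }
  series_set <- lapply(series_set, as.numeric)
  lens <- lengths(series_set)
  if (any(lens < 2L * block_length))
    pd_stop("every series must be at least two blocks long",
            "insufficient_data_error")
  if (n_resamples < 100L)
    pd_stop("n_resamples must be at least 100", "configuration_error")
  nt <- length(series_set)
  b <- as.integer(block_length)
  means <- with_seed(seed, {
    ## per-trajectory pools of blocked-resample means, drawn once and reused
    pool_size <- max(200L, ceiling(4 * n_resamples / nt))
    pools <- lapply(series_set, block_resample_means,
                    n_resamples = pool_size, block_length = b)
    vapply(seq_len(n_resamples), function(r) {
      picked <- sample.int(nt, nt, replace = TRUE)
      mean(vapply(picked, function(tj) pools[[tj]][sample.int(pool_size, 1L)],
                  numeric(1)))
    }, numeric(1))
  })
  traj_means <- vapply(series_set, mean, numeric(1))
  pooled <- unlist(series_set)
  new_bootstrap_summary(means, as.integer(n_resamples), b, confidence_level,
                        as.integer(seed),
                        series_mean = mean(traj_means),
                        series_sd = stats::sd(pooled),
                        between_sd = stats::sd(traj_means))
}

#' Serialize a BootstrapSummary to JSON
#' @param x a `BootstrapSummary`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bootstrap_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
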