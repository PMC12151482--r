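#' Ensemble summary statistics
#'
#' Mean, noise (`CV^2`) and skewness of a sample of concentrations, using the
#' population-variance convention (divisor `n`): `cv2` is the second central
#' moment over the squared mean, skewness the third central moment over the
#' second to the power 3/2. Degenerate (constant) samples have `cv2 = 0` and
#' `skewness = 0` by convention. Standard errors are nonparametric bootstrap
#' (resampling individual values; see [population_stats()] for colony-level
#' resampling).
#'
#' @param x Numeric vector of concentrations (n >= 1).
#' @param n_boot Number of bootstrap resamples for standard errors; 0 skips
#'   them (SEs are `NA`).
#' @return A one-row tibble: `n`, `mean`, `cv2`, `skewness`, `se_mean`,
#'   `se_cv2`, `se_skewness`.
#' @examples
#' summary_stats(c(1, 2, 3), n_boot = 0)
#' @export
summary_stats <- function(x, n_boot = 200) {
  if (length(x) == 0) stop("empty sample")
  if (any(!is.finite(x))) stop("non-finite values in sample")
  est <- moment_estimates(x)
  se <- c(NA_real_, NA_real_, NA_real_)
  if (n_boot > 0 && length(x) > 1) {
    boots <- vapply(seq_len(n_boot), function(i) {
      moment_estimates(x[sample.int(length(x), replace = TRUE)])
    }, numeric(3))
    se <- apply(boots, 1, stats::sd)
  }
  tibble::tibble(
    n = length(x),
    mean = est[1], cv2 = est[2], skewness = est[3],
    se_mean = se[1], se_cv2 = se[2], se_skewness = se[3]
  )
}

# mean, cv2 (divisor n), skewness; degenerate samples -> cv2 = skew = 0.
moment_estimates <- function(x) {
  m <- mean(x)
  v <- mean((x - m)^2)
  if (v == 0) return(c(m, 0, 0))
  if (m == 0) stop("cv2 undefined: zero mean with nonzero variance")
  c(m, v / m^2, mean((x - m)^3) / v^1.5)
}

#' Time-averaged statistics of a single long trajectory
#'
#' Ergodicity cross-check: instead of an ensemble of replicates at a fixed
#' time, estimates the stationary statistics by averaging one long trajectory
#' over time. Uses the equispaced sampling-grid rows of the trajectory after
#' discarding a burn-in, so equal weights amount to a time average.
#'
#' @param trajectory A trajectory tibble from [simulate_lineage_feedback()]
#'   or [simulate_lineage_partitioning()].
#' @param burn_in Time to discard from the start (default: the first quarter
#'   of the trajectory).
#' @param n_boot Bootstrap resamples for standard errors (note these ignore
#'   autocorrelation along the trajectory and are optimistic).
#' @return A one-row tibble as from [summary_stats()].
#' @examples
#' p <- burst_params(10, 10, 1)
#' tr <- simulate_lineage_feedback(p, t_end = 200, x0 = 100, seed = 1,
#'                                 sample_times = seq(0, 200, by = 0.2))
#' time_average_stats(tr)
#' @export
time_average_stats <- function(trajectory, burn_in = NULL, n_boot = 0) {
  stopifnot(all(c("time", "x", "event") %in% names(trajectory)))
  grid <- trajectory[trajectory$event == "sample", ]
  if (is.null(burn_in)) burn_in <- max(grid$time) / 4
  keep <- grid$x[grid$time >= burn_in]
  if (length(keep) < 10) stop("too few grid samples after burn-in")
  summary_stats(keep, n_boot = n_boot)
}

#' Kolmogorov--Smirnov distance between samples and a stationary law
#'
#' Sup-norm distance between the empirical cdf of `samples` and a reference
#' cdf: either a [stationary_law()] (whose cdf is evaluated exactly) or any
#' vectorized cdf function.
#'
#' @param samples Numeric vector, n >= 10.
#' @param law A [stationary_law()] or a function `q -> F(q)`.
#' @return The KS distance in `[0, 1]`.
#' @examples
#' p <- burst_params(10, 10, 1)
#' law <- stationary_law(p, "single_cell")
#' set.seed(1)
#' ks_distance(rstationary(5000, law), law) # small
#' @export
ks_distance <- function(samples, law) {
  if (length(samples) < 10) stop("need at least 10 samples")
  cdf <- if (inherits(law, "stationary_law")) {
    function(q) pstationary(q, law)
  } else if (is.function(law)) {
    law
  } else {
    stop("`law` must be a stationary_law or a cdf function")
  }
  n <- length(samples)
  fx <- cdf(sort(samples))
  if (any(!is.finite(fx))) stop("reference cdf returned non-finite values")
  max(pmax(seq_len(n) / n - fx, fx - (seq_len(n) - 1) / n))
}

#' Compare single-cell and population summary statistics
#'
#' Ratios (population over single-cell) of mean, noise and skewness, with
#' standard errors propagated by the delta method and a flag for whether the
#' departure from 1 exceeds two standard errors.
#'
#' @param sc_stats,pop_stats One-row tibbles as returned by [summary_stats()]
#'   or [population_stats()].
#' @return A tibble with columns `metric`, `single_cell`, `population`,
#'   `ratio`, `se_ratio`, `significant`.
#' @export
compare_perspectives <- function(sc_stats, pop_stats) {
  stopifnot(nrow(sc_stats) == 1, nrow(pop_stats) == 1)
  metric <- c("mean", "cv2", "skewness")
  se_cols <- paste0("se_", metric)
  sc <- unlist(sc_stats[metric])
  pop <- unlist(pop_stats[metric])
  sc_se <- unlist(sc_stats[se_cols])
  pop_se <- unlist(pop_stats[se_cols])
  ratio <- pop / sc
  se_ratio <- abs(ratio) * sqrt((sc_se / sc)^2 + (pop_se / pop)^2)
  tibble::tibble(
    metric = metric,
    single_cell = unname(sc),
    population = unname(pop),
    ratio = unname(ratio),
    se_ratio = unname(se_ratio),
    significant = unname(abs(ratio - 1) > 2 * se_ratio)
  )
}
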