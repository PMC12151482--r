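#' Build a validated experiment configuration
#'
#' Bundles the name of a canned perspective-comparison experiment with its
#' parameters, replicate counts, seed, and output directory. A config plus a
#' seed reproduces outputs exactly.
#'
#' Experiments (all compare single-cell and population perspectives):
#' * `feedback_sweep`: dilution-feedback model over a grid of feedback
#'   strengths `k`, burst frequency re-tuned by [burst_frequency_for_mean()]
#'   to hold the single-cell mean fixed; analytic and simulated moments.
#' * `cycle_noise_sweep`: partitioning model, protein noise versus cell-cycle
#'   noise `cv2_tau`; the single-cell curve is flat at the
#'   [predicted_partition_cv2()] value, the population curve rises.
#' * `mean_scaling`: partitioning model, noise versus mean on log axes.
#' * `burst_vs_partition`: bursty partitioning model, noise versus mean burst
#'   size at fixed partitioning noise.
#' * `divergence`: a parameter point where only the population law exists;
#'   single-cell mean grows without bound while the population mean plateaus.
#' * `equivalence_checks`: deterministic timer (noise equal in both
#'   perspectives) and constant-division-rate model with growth-coupled burst
#'   frequency (identical distributions in both perspectives).
#' * `degradation_sweep`: adds constant degradation `d`; as `d` dominates
#'   dilution both perspectives converge to the unregulated gamma law.
#' * `growth_coupled`: burst frequency proportional to the growth rate;
#'   reports the population/single-cell mean and noise ratios.
#' * `adder`: size-homeostatic adder cycle; population noise rises with
#'   added-size noise while the single-cell curve stays nearly flat.
#'
#' @param experiment Experiment name (see Details).
#' @param seed Integer seed.
#' @param scale Multiplier on replicate counts (default 1 = full scale:
#'   5000 lineages, 2000 colonies, 6 generations; use e.g. 0.1 for a fast
#'   run).
#' @param out_dir Optional output directory for TSV tables.
#' @param ... Experiment-specific overrides (e.g. `k_grid`, `cv2_tau_grid`,
#'   `beta_grid`, `d_grid`, `target_mean`, `epsilon`).
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(experiment, seed = 1, scale = 1,
                              out_dir = NULL, ...) {
  experiments <- c("feedback_sweep", "cycle_noise_sweep", "mean_scaling",
                   "burst_vs_partition", "divergence", "equivalence_checks",
                   "degradation_sweep", "growth_coupled", "adder")
  if (!is.character(experiment) || length(experiment) != 1 ||
      !experiment %in% experiments) {
    stop("unknown experiment; must be one of: ",
         paste(experiments, collapse = ", "))
  }
  stopifnot(is.numeric(seed), length(seed) == 1,
            is.numeric(scale), scale > 0)
  extra <- list(...)
  if (length(extra) && is.null(names(extra))) {
    stop("experiment overrides must be named")
  }
  structure(
    c(list(experiment = experiment, seed = as.integer(seed), scale = scale,
           out_dir = out_dir), extra),
    class = "experiment_config"
  )
}

n_scaled <- function(n, scale) max(50L, as.integer(round(n * scale)))

#' Run a canned perspective-comparison experiment
#'
#' Executes the experiment described by an [experiment_config()] (or by a
#' name plus overrides) and returns its result tables; if the config has an
#' `out_dir`, tables are also written as TSV along with the full
#' configuration for provenance.
#'
#' @param config An `experiment_config`, or an experiment name.
#' @param ... Passed to [experiment_config()] when `config` is a name.
#' @return A list with elements `experiment`, `tables` (named list of
#'   tibbles), and `config`.
#' @examples
#' \donttest{
#' res <- run_experiment("cycle_noise_sweep", seed = 1, scale = 0.05)
#' res$tables$stats
#' }
#' @export
run_experiment <- function(config, ...) {
  if (is.character(config)) config <- experiment_config(config, ...)
  stopifnot(inherits(config, "experiment_config"))
  set.seed(config$seed)
  runner <- switch(config$experiment,
    feedback_sweep = exp_feedback_sweep,
    cycle_noise_sweep = exp_cycle_noise_sweep,
    mean_scaling = exp_mean_scaling,
    burst_vs_partition = exp_burst_vs_partition,
    divergence = exp_divergence,
    equivalence_checks = exp_equivalence_checks,
    degradation_sweep = exp_degradation_sweep,
    growth_coupled = exp_growth_coupled,
    adder = exp_adder
  )
  tables <- runner(config)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(tables)) {
      write_tsv_table(tables[[nm]],
                      file.path(config$out_dir,
                                paste0(config$experiment, "_", nm, ".tsv")))
    }
    cfg_flat <- vapply(config, function(v) paste(format(v), collapse = ","),
                       character(1))
    writeLines(paste0(names(cfg_flat), " = ", cfg_flat),
               file.path(config$out_dir,
                         paste0(config$experiment, "_config.txt")))
  }
  list(experiment = config$experiment, tables = tables, config = config)
}

# ---- individual experiments -------------------------------------------------

exp_feedback_sweep <- function(cfg) {
  k_grid <- cfg$k_grid %||% c(0, 0.002, 0.005, 0.01, 0.02, 0.05)
  target <- cfg$target_mean %||% 100
  beta <- cfg$beta %||% 10
  gamma <- cfg$gamma %||% 1
  n_lin <- n_scaled(5000, cfg$scale)
  n_col <- n_scaled(400, cfg$scale)
  t_col <- cfg$t_colony %||% 8
  stats <- purrr::map_dfr(k_grid, function(k) {
    lam <- burst_frequency_for_mean(target, k, beta, gamma)
    p <- burst_params(lam, beta, gamma, k = k)
    ana <- dplyr::bind_rows(
      stationary_moments(p, "single_cell"),
      stationary_moments(p, "population")
    )
    ana$source <- "analytic"
    sc <- simulate_feedback_ensemble(p, n_lin, t_end = 30 / gamma)
    sc_stats <- summary_stats(sc$x, n_boot = 100)
    snaps <- simulate_colonies(n_col, p, stop = list(time = t_col / gamma),
                               x0 = function(n) {
                                 rstationary(n, stationary_law(p,
                                                               "single_cell"))
                               })
    pop_stats <- population_stats(snaps, n_boot = 100)
    sim <- tibble::tibble(
      perspective = c("single_cell", "population"),
      mean = c(sc_stats$mean, pop_stats$mean),
      cv2 = c(sc_stats$cv2, pop_stats$cv2),
      skewness = c(sc_stats$skewness, pop_stats$skewness),
      source = "simulation"
    )
    out <- dplyr::bind_rows(ana, sim)
    out$k <- k
    out$lambda <- lam
    out
  })
  list(stats = stats)
}

partition_base_params <- function(cfg, beta = NULL) {
  gamma <- cfg$gamma %||% log(2)
  target <- cfg$target_mean %||% 20
  beta <- beta %||% (cfg$beta %||% 10)
  lam <- gamma * target / beta
  burst_params(lam, beta, gamma, k = 0)
}

exp_cycle_noise_sweep <- function(cfg) {
  cv2_grid <- cfg$cv2_tau_grid %||% c(0, 0.25, 0.5, 1)
  eps <- cfg$epsilon %||% 1
  p <- partition_base_params(cfg)
  target <- cfg$target_mean %||% 20
  n_lin <- n_scaled(5000, cfg$scale)
  n_col <- n_scaled(2000, cfg$scale)
  gens <- cfg$generations %||% 6
  pm <- partition_model(eps)
  stats <- purrr::map_dfr(cv2_grid, function(cv2) {
    cyc <- cycle_model("timer", cv2_tau = cv2)
    sc <- simulate_partition_ensemble(p, pm, cyc, n = n_lin,
                                      n_generations = gens)
    sc_stats <- summary_stats(sc$x, n_boot = 100)
    snaps <- simulate_colonies(n_col, p, pm, cyc,
                               stop = list(generations = gens),
                               synthesis = "deterministic")
    pop_stats <- population_stats(snaps, n_boot = 100)
    tibble::tibble(
      cv2_tau = cv2,
      perspective = c("single_cell", "population", "analytic_sc"),
      mean = c(sc_stats$mean, pop_stats$mean, target),
      cv2 = c(sc_stats$cv2, pop_stats$cv2,
              predicted_partition_cv2(target, eps, 0)),
      se_cv2 = c(sc_stats$se_cv2, pop_stats$se_cv2, NA)
    )
  })
  list(stats = stats)
}

exp_mean_scaling <- function(cfg) {
  means <- cfg$mean_grid %||% c(5, 10, 20, 50, 100)
  eps <- cfg$epsilon %||% 1
  gamma <- cfg$gamma %||% log(2)
  cv2_tau <- cfg$cv2_tau %||% 1
  n_lin <- n_scaled(3000, cfg$scale)
  n_col <- n_scaled(1000, cfg$scale)
  gens <- cfg$generations %||% 6
  pm <- partition_model(eps)
  cyc <- cycle_model("timer", cv2_tau = cv2_tau)
  stats <- purrr::map_dfr(means, function(mm) {
    p <- burst_params(gamma * mm / 10, 10, gamma, k = 0)
    sc <- simulate_partition_ensemble(p, pm, cyc, n = n_lin,
                                      n_generations = gens)
    snaps <- simulate_colonies(n_col, p, pm, cyc,
                               stop = list(generations = gens),
                               synthesis = "deterministic")
    tibble::tibble(
      target_mean = mm,
      perspective = c("single_cell", "population", "analytic_sc"),
      cv2 = c(summary_stats(sc$x, n_boot = 0)$cv2,
              population_stats(snaps, n_boot = 0)$cv2,
              predicted_partition_cv2(mm, eps, 0))
    )
  })
  list(stats = stats)
}

exp_burst_vs_partition <- function(cfg) {
  beta_grid <- cfg$beta_grid %||% c(0.2, 1, 5)
  eps <- cfg$epsilon %||% 1
  target <- cfg$target_mean %||% 20
  n_lin <- n_scaled(5000, cfg$scale)
  n_col <- n_scaled(500, cfg$scale)
  gens <- cfg$generations %||% 6
  pm <- partition_model(eps)
  cyc <- cycle_model("timer", cv2_tau = 1)
  stats <- purrr::map_dfr(beta_grid, function(b) {
    p <- partition_base_params(cfg, beta = b)
    sc <- simulate_partition_ensemble(p, pm, cyc, n = n_lin,
                                      n_generations = gens, bursty = TRUE)
    sc_stats <- summary_stats(sc$x, n_boot = 100)
    snaps <- simulate_colonies(n_col, p, pm, cyc,
                               stop = list(generations = gens),
                               synthesis = "bursty")
    pop_stats <- population_stats(snaps, n_boot = 100)
    tibble::tibble(
      beta = b,
      perspective = c("single_cell", "population", "analytic_sc"),
      cv2 = c(sc_stats$cv2, pop_stats$cv2,
              predicted_partition_cv2(target, eps, b)),
      se_cv2 = c(sc_stats$se_cv2, pop_stats$se_cv2, NA)
    )
  })
  list(stats = stats)
}

exp_divergence <- function(cfg) {
  # only the population law exists: lambda/gamma = 1.2, k*beta = 2
  p <- burst_params(cfg$lambda %||% 1.2, cfg$beta %||% 10, cfg$gamma %||% 1,
                    k = cfg$k %||% 0.2)
  checkpoints <- cfg$checkpoints %||% c(4, 8, 12, 16)
  n_lin <- n_scaled(2000, cfg$scale)
  n_col <- n_scaled(300, cfg$scale)
  sc <- purrr::map_dfr(checkpoints, function(tt) {
    xs <- simulate_feedback_ensemble(p, n_lin, t_end = tt, x0 = 0,
                                     cap = 1e12)
    tibble::tibble(time = tt, perspective = "single_cell",
                   mean = mean(xs$x))
  })
  pop <- purrr::map_dfr(checkpoints, function(tt) {
    snaps <- simulate_colonies(n_col, p, stop = list(time = tt), x0 = 0)
    tibble::tibble(time = tt, perspective = "population",
                   mean = population_stats(snaps, n_boot = 0)$mean)
  })
  list(means = dplyr::bind_rows(sc, pop),
       analytic = dplyr::bind_cols(
         tibble::tibble(existence = existence_status(p)),
         stationary_moments(p, "population")
       ))
}

exp_equivalence_checks <- function(cfg) {
  gens <- cfg$generations %||% 6
  # S10-type check: deterministic timer, partitioning noise only
  p <- partition_base_params(cfg)
  pm <- partition_model(cfg$epsilon %||% 1)
  cyc0 <- cycle_model("timer", cv2_tau = 0)
  n_lin <- n_scaled(5000, cfg$scale)
  n_col <- n_scaled(1500, cfg$scale)
  sc <- simulate_partition_ensemble(p, pm, cyc0, n = n_lin,
                                    n_generations = gens)
  snaps <- simulate_colonies(n_col, p, pm, cyc0,
                             stop = list(generations = gens),
                             synthesis = "deterministic")
  timer0 <- compare_perspectives(summary_stats(sc$x),
                                 population_stats(snaps))
  # constant division rate, growth-coupled burst frequency: identical laws
  p2 <- burst_params(cfg$lambda2 %||% 8, cfg$beta %||% 10,
                     cfg$gamma %||% log(2), k = cfg$k2 %||% 0.02,
                     burst_mode = "growth_coupled",
                     dilution_mode = "constant")
  sc2 <- simulate_feedback_ensemble(p2, n_scaled(4000, cfg$scale),
                                    t_end = 30 / p2$gamma, x0 = 0)
  snaps2 <- simulate_colonies(n_scaled(400, cfg$scale), p2,
                              stop = list(generations = gens), x0 = 0)
  pooled2 <- pool_cells(snaps2)
  const_dilution <- compare_perspectives(summary_stats(sc2$x),
                                         population_stats(snaps2))
  ks <- stats::ks.test(sc2$x, pooled2$x)$statistic
  list(timer_deterministic = timer0,
       constant_dilution = const_dilution,
       constant_dilution_ks = tibble::tibble(ks_distance = unname(ks)))
}

exp_degradation_sweep <- function(cfg) {
  gamma <- cfg$gamma %||% 1
  d_grid <- cfg$d_grid %||% c(0, 2, 10, 50) * gamma
  beta <- cfg$beta %||% 10
  k <- cfg$k %||% 0.01
  lam <- cfg$lambda %||% 5
  n_lin <- n_scaled(3000, cfg$scale)
  stats <- purrr::map_dfr(d_grid, function(dd) {
    p <- burst_params(lam, beta, gamma, k = k, d = dd)
    xs <- simulate_feedback_ensemble(p, n_lin, t_end = 30 / (gamma + dd),
                                     x0 = lam * beta / (gamma + dd))
    # unregulated gamma reference with total decay rate gamma + d
    ref <- function(q) stats::pgamma(q, shape = lam / (gamma + dd),
                                     scale = beta)
    tibble::tibble(
      d = dd,
      mean = mean(xs$x),
      cv2 = summary_stats(xs$x, n_boot = 0)$cv2,
      ks_to_gamma = ks_distance(xs$x, ref)
    )
  })
  list(stats = stats)
}

exp_growth_coupled <- function(cfg) {
  p <- burst_params(cfg$lambda %||% 5, cfg$beta %||% 10, cfg$gamma %||% 1,
                    k = cfg$k %||% 0.01, burst_mode = "growth_coupled")
  n_lin <- n_scaled(4000, cfg$scale)
  n_col <- n_scaled(400, cfg$scale)
  sc <- simulate_feedback_ensemble(p, n_lin, t_end = 40 / p$gamma, x0 = 0)
  snaps <- simulate_colonies(n_col, p, stop = list(time = 8 / p$gamma),
                             x0 = mean(sc$x))
  cmp <- compare_perspectives(summary_stats(sc$x), population_stats(snaps))
  list(comparison = cmp)
}

exp_adder <- function(cfg) {
  cv2_added_grid <- cfg$cv2_added_grid %||% c(0, 0.25, 0.5, 1)
  eps <- cfg$epsilon %||% 1
  p <- partition_base_params(cfg)
  pm <- partition_model(eps)
  n_lin <- n_scaled(3000, cfg$scale)
  n_col <- n_scaled(800, cfg$scale)
  gens <- cfg$generations %||% 6
  stats <- purrr::map_dfr(cv2_added_grid, function(cv2a) {
    cyc <- cycle_model("adder", cv2_added = cv2a, mean_added = 1)
    sc <- simulate_partition_ensemble(p, pm, cyc, n = n_lin,
                                      n_generations = gens)
    snaps <- simulate_colonies(n_col, p, pm, cyc,
                               stop = list(generations = gens),
                               synthesis = "deterministic")
    sc_stats <- summary_stats(sc$x, n_boot = 100)
    pop_stats <- population_stats(snaps, n_boot = 100)
    tibble::tibble(
      cv2_added = cv2a,
      perspective = c("single_cell", "population"),
      mean = c(sc_stats$mean, pop_stats$mean),
      cv2 = c(sc_stats$cv2, pop_stats$cv2),
      se_cv2 = c(sc_stats$se_cv2, pop_stats$se_cv2)
    )
  })
  list(stats = stats)
}
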