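#' Exact event-driven lineage trajectory of the feedback model
#'
#' Simulates one single-cell trajectory of the burst-dilution feedback model:
#' bursts arrive as a Poisson process (rate `lambda`, or `lambda/(1+kx)` in
#' growth-coupled mode, generated by exact thinning against the bound
#' `lambda`), sizes are exponential with mean `beta`, and in between bursts
#' the concentration follows the dilution flow [flow_map()]. Division has no
#' effect on concentration in the single-cell perspective of this model, so
#' no division events are generated. The trajectory is reported on a sampling
#' grid with every burst time included (no interpolation across events).
#'
#' @param params A [burst_params()] object.
#' @param t_end End time, > 0.
#' @param x0 Initial concentration (default 0).
#' @param seed Optional integer seed.
#' @param sample_times Sampling grid; defaults to 201 equispaced times in
#'   `[0, t_end]`.
#' @param cap Divergence guard: if the concentration exceeds `cap` the
#'   trajectory is flagged diverging (attribute `"diverging"`), not an error.
#' @return A tibble with columns `time`, `x`, `event` (`"sample"` or
#'   `"burst"`; burst rows give the post-jump value), carrying attributes
#'   `diverging` and `params`.
#' @examples
#' p <- burst_params(lambda = 100 / 21, beta = 10, gamma = 1, k = 0.01)
#' tr <- simulate_lineage_feedback(p, t_end = 20, x0 = 100, seed = 1)
#' @export
simulate_lineage_feedback <- function(params, t_end, x0 = 0, seed = NULL,
                                      sample_times = NULL, cap = 1e9) {
  stopifnot(inherits(params, "burst_params"), t_end > 0, x0 >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(sample_times)) sample_times <- seq(0, t_end, length.out = 201)
  sample_times <- sort(unique(pmin(pmax(sample_times, 0), t_end)))

  ev_t <- 0
  ev_x <- x0
  t <- 0
  x <- x0
  diverging <- FALSE
  if (params$lambda > 0) {
    repeat {
      dt <- stats::rexp(1, params$lambda)
      if (t + dt > t_end) break
      x <- flow_map(x, dt, params)
      t <- t + dt
      accept <- params$burst_mode == "constant" ||
        stats::runif(1) < 1 / (1 + params$k * x)
      if (accept) {
        x <- x + stats::rexp(1, 1 / params$beta)
        ev_t <- c(ev_t, t)
        ev_x <- c(ev_x, x)
        if (x > cap) diverging <- TRUE
      }
    }
  }

  out <- grid_from_events(ev_t, ev_x, sample_times, params)
  attr(out, "diverging") <- diverging
  attr(out, "params") <- params
  out
}

# Fill a sampling grid from post-event states by flowing forward from the
# most recent event; event times are rows of their own.
grid_from_events <- function(ev_t, ev_x, sample_times, params) {
  idx <- findInterval(sample_times, ev_t)
  grid_x <- flow_map(ev_x[idx], sample_times - ev_t[idx], params)
  out <- tibble::tibble(
    time = c(sample_times, ev_t[-1]),
    x = c(grid_x, ev_x[-1]),
    event = c(rep("sample", length(sample_times)),
              rep("burst", length(ev_t) - 1))
  )
  dplyr::arrange(out, .data$time, .data$event)
}

#' Endpoint ensemble of the feedback model
#'
#' Simulates `n` independent single-cell replicates of the feedback model and
#' returns their concentrations at `t_end`. The default integrator is the
#' exact event-driven scheme (vectorized across replicates); a fixed-step
#' tau-leaping integrator (Poisson number of bursts per step) is available as
#' a cross-check.
#'
#' @param params A [burst_params()] object.
#' @param n Number of replicates.
#' @param t_end End time; acts as burn-in when `x0` starts away from
#'   stationarity.
#' @param x0 Initial concentration(s): a scalar, a vector of length `n`, or a
#'   function `n -> vector`. Defaults to the stationary single-cell mean when
#'   it exists, else 0.
#' @param seed Optional integer seed.
#' @param cap Divergence guard (replicates exceeding it are flagged).
#' @param method `"exact"` (default) or `"tau_leap"`.
#' @param dt Tau-leaping step; default `0.01 / gamma`.
#' @return A tibble with columns `replicate`, `x`, `diverging`.
#' @examples
#' p <- burst_params(lambda = 10, beta = 10, gamma = 1)
#' xs <- simulate_feedback_ensemble(p, n = 500, t_end = 30, seed = 1)
#' mean(xs$x) # near 100
#' @export
simulate_feedback_ensemble <- function(params, n, t_end, x0 = NULL,
                                       seed = NULL, cap = 1e9,
                                       method = c("exact", "tau_leap"),
                                       dt = NULL) {
  stopifnot(inherits(params, "burst_params"), n >= 1, t_end > 0)
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  x <- init_ensemble_x0(x0, n, params)
  diverging <- rep(FALSE, n)

  if (method == "tau_leap") {
    dt <- dt %||% (0.01 / params$gamma)
    n_steps <- ceiling(t_end / dt)
    dt <- t_end / n_steps
    for (s in seq_len(n_steps)) {
      rate <- burst_rate(x, params)
      x <- flow_map(x, dt, params)
      nb <- stats::rpois(n, rate * dt)
      hit <- nb > 0
      if (any(hit)) {
        x[hit] <- x[hit] +
          stats::rgamma(sum(hit), shape = nb[hit], scale = params$beta)
      }
      diverging <- diverging | x > cap
    }
    return(tibble::tibble(replicate = seq_len(n), x = x,
                          diverging = diverging))
  }

  tcur <- numeric(n)
  active <- rep(TRUE, n)
  if (params$lambda == 0) {
    x <- flow_map(x, t_end, params)
    active[] <- FALSE
  }
  while (any(active)) {
    idx <- which(active)
    dtb <- stats::rexp(length(idx), params$lambda)
    tnew <- tcur[idx] + dtb
    fin <- tnew >= t_end
    if (any(fin)) {
      i <- idx[fin]
      x[i] <- flow_map(x[i], t_end - tcur[i], params)
      active[i] <- FALSE
    }
    if (any(!fin)) {
      i <- idx[!fin]
      x[i] <- flow_map(x[i], dtb[!fin], params)
      accept <- if (params$burst_mode == "constant") {
        rep(TRUE, length(i))
      } else {
        stats::runif(length(i)) < 1 / (1 + params$k * x[i])
      }
      ib <- i[accept]
      if (length(ib)) {
        x[ib] <- x[ib] + stats::rexp(length(ib), 1 / params$beta)
      }
      tcur[i] <- tnew[!fin]
      diverging[i] <- diverging[i] | x[i] > cap
    }
  }
  tibble::tibble(replicate = seq_len(n), x = x, diverging = diverging)
}

init_ensemble_x0 <- function(x0, n, params) {
  if (is.null(x0)) {
    x0 <- if (params$k == 0 || existence_status(params) == "both") {
      if (params$lambda > 0) {
        stationary_moments(params, "single_cell")$mean
      } else 0
    } else 0
  }
  if (is.function(x0)) x0 <- x0(n)
  rep_len(x0, n)
}

#' Lineage trajectory of the molecule-partitioning model
#'
#' Simulates a single-cell lineage in which the concentration evolves inside
#' each cell cycle either deterministically (`dx/dt = lambda*beta - gamma*x`)
#' or through bursts plus constant-rate dilution (`bursty = TRUE`), and jumps
#' at division according to the partitioning kernel, following one of the two
#' daughters uniformly at random. Cell-cycle lengths are i.i.d. from the
#' calibrated gamma law (timer) or set by an adder size threshold. The run
#' spans `n_generations` population doublings, i.e. a horizon of
#' `n_generations * ln(2) / gamma`; the progenitor starts at a uniformly
#' random phase of its first cycle so that sampled statistics are
#' cycle-phase-stationary.
#'
#' @param params A [burst_params()] (its `k` is ignored here: the
#'   partitioning model has constant dilution).
#' @param partition A [partition_model()].
#' @param cycle A [cycle_model()] of kind `"timer"` or `"adder"`.
#' @param n_generations Number of population doublings to simulate, >= 1.
#' @param x0 Initial concentration; defaults to the fixed point
#'   `lambda*beta/(gamma+d)`.
#' @param seed Optional integer seed.
#' @param bursty Use bursty synthesis instead of deterministic.
#' @param sample_times Optional sampling grid (defaults to 201 points).
#' @return A tibble with columns `time`, `x`, `event` (`"sample"`,
#'   `"burst"`, `"division"`; jump rows give post-jump values).
#' @examples
#' p <- burst_params(lambda = 20 * log(2) / 10, beta = 10, gamma = log(2))
#' tr <- simulate_lineage_partitioning(p, partition_model(1),
#'   cycle_model("timer", cv2_tau = 1), n_generations = 6, seed = 1)
#' @export
simulate_lineage_partitioning <- function(params, partition, cycle,
                                          n_generations, x0 = NULL,
                                          seed = NULL, bursty = FALSE,
                                          sample_times = NULL) {
  stopifnot(inherits(params, "burst_params"),
            inherits(partition, "partition_model"),
            inherits(cycle, "cycle_model"),
            cycle$kind %in% c("timer", "adder"),
            n_generations >= 1)
  if (!is.null(seed)) set.seed(seed)
  g <- params$gamma
  d <- params$d
  t_end <- n_generations * log(2) / g
  m <- params$lambda * params$beta / (g + d)
  x <- x0 %||% m
  if (is.null(sample_times)) sample_times <- seq(0, t_end, length.out = 201)

  st <- init_cycle_state(1, cycle, params)
  tdiv <- st$tdiv
  vol <- st$vol
  t <- 0
  ev_t <- 0
  ev_x <- x
  ev_e <- "start"

  evolve <- function(x, dur) {
    if (!bursty) {
      return(list(x = m + (x - m) * exp(-(g + d) * dur), bt = NULL,
                  bx = NULL))
    }
    bt <- bx <- numeric(0)
    rem <- dur
    tt <- 0
    while (rem > 0 && params$lambda > 0) {
      dtb <- stats::rexp(1, params$lambda)
      if (dtb >= rem) {
        x <- x * exp(-(g + d) * rem)
        rem <- 0
      } else {
        x <- x * exp(-(g + d) * dtb) + stats::rexp(1, 1 / params$beta)
        tt <- tt + dtb
        rem <- rem - dtb
        bt <- c(bt, tt)
        bx <- c(bx, x)
      }
    }
    if (params$lambda == 0) x <- x * exp(-(g + d) * dur)
    list(x = x, bt = bt, bx = bx)
  }

  while (tdiv <= t_end) {
    ev <- evolve(x, tdiv - t)
    if (length(ev$bt)) {
      ev_t <- c(ev_t, t + ev$bt)
      ev_x <- c(ev_x, ev$bx)
      ev_e <- c(ev_e, rep("burst", length(ev$bt)))
    }
    x <- ev$x
    t <- tdiv
    pair <- partition_pair(x, partition)
    x <- pair[cbind(1, 1 + (stats::runif(1) < 0.5))]
    ev_t <- c(ev_t, t)
    ev_x <- c(ev_x, x)
    ev_e <- c(ev_e, "division")
    nxt <- next_division(x_vol = vol, cycle, params)
    vol <- nxt$vol
    tdiv <- t + nxt$tau
  }
  ev <- evolve(x, t_end - t)
  if (length(ev$bt)) {
    ev_t <- c(ev_t, t + ev$bt)
    ev_x <- c(ev_x, ev$bx)
    ev_e <- c(ev_e, rep("burst", length(ev$bt)))
  }

  # piecewise-exponential fill between events (constant-dilution flow)
  cparams <- burst_params(params$lambda, params$beta, g, k = 0, d = d)
  sample_times <- sort(unique(pmin(pmax(sample_times, 0), t_end)))
  idx <- findInterval(sample_times, ev_t)
  gx <- m + (ev_x[idx] - m) * exp(-(g + d) * (sample_times - ev_t[idx]))
  if (bursty) {
    # bursty synthesis: between events the flow is pure decay toward 0
    gx <- ev_x[idx] * exp(-(g + d) * (sample_times - ev_t[idx]))
  }
  out <- tibble::tibble(
    time = c(sample_times, ev_t[-1]),
    x = c(gx, ev_x[-1]),
    event = c(rep("sample", length(sample_times)), ev_e[-1])
  )
  out <- dplyr::arrange(out, .data$time, .data$event)
  attr(out, "params") <- cparams
  out
}

# Initial cycle state for n lineages/cells: first division time at a uniform
# random phase of the first cycle; adder tracks volume.
init_cycle_state <- function(n, cycle, params, phase = "stationary") {
  g <- params$gamma
  if (cycle$kind == "timer") {
    tau <- draw_cycle_times(n, cycle, g)
    vol <- rep(NA_real_, n)
  } else if (cycle$kind == "adder") {
    rate <- cycle$growth_rate %||% g
    vol <- rep(1, n)
    delta <- draw_added_sizes(n, cycle)
    tau <- log1p(delta / vol) / rate
  } else {
    stop("init_cycle_state is for timer/adder cycles")
  }
  if (phase == "stationary") tau <- tau * (1 - stats::runif(n))
  if (cycle$kind == "adder") {
    rate <- cycle$growth_rate %||% g
    # volume at (phase-shifted) division, halved for the next cycle
    vol <- vol * exp(rate * tau) / 2
    # vol now is the NEXT newborn volume; division handler uses it
  }
  list(tdiv = tau, vol = vol)
}

draw_added_sizes <- function(n, cycle) {
  if (cycle$cv2_added == 0) {
    rep(cycle$mean_added, n)
  } else {
    shape <- 1 / cycle$cv2_added
    stats::rgamma(n, shape = shape, scale = cycle$mean_added / shape)
  }
}

# Next cell-cycle duration after a division; for the adder, x_vol is the
# newborn volume (mother's division volume already halved by the caller via
# init bookkeeping).
next_division <- function(x_vol, cycle, params) {
  g <- params$gamma
  if (cycle$kind == "timer") {
    list(tau = draw_cycle_times(length(x_vol), cycle, g), vol = x_vol)
  } else {
    rate <- cycle$growth_rate %||% g
    delta <- draw_added_sizes(length(x_vol), cycle)
    tau <- log1p(delta / x_vol) / rate
    list(tau = tau, vol = (x_vol + delta) / 2)
  }
}

#' Endpoint ensemble of the partitioning model
#'
#' Vectorized simulation of `n` independent lineages of the partitioning
#' model (see [simulate_lineage_partitioning()]) returning concentrations at
#' the horizon `n_generations * ln(2) / gamma`. Each lineage starts at a
#' uniformly random phase of its first cell cycle.
#'
#' @inheritParams simulate_lineage_partitioning
#' @param n Number of lineages.
#' @return A tibble with columns `replicate`, `x`.
#' @examples
#' p <- burst_params(lambda = 20 * log(2) / 10, beta = 10, gamma = log(2))
#' xs <- simulate_partition_ensemble(p, partition_model(1),
#'   cycle_model("timer", cv2_tau = 1), n = 500, n_generations = 6, seed = 1)
#' @export
simulate_partition_ensemble <- function(params, partition, cycle, n,
                                        n_generations, bursty = FALSE,
                                        x0 = NULL, seed = NULL) {
  stopifnot(inherits(params, "burst_params"),
            inherits(partition, "partition_model"),
            inherits(cycle, "cycle_model"),
            cycle$kind %in% c("timer", "adder"),
            n >= 1, n_generations >= 1)
  if (!is.null(seed)) set.seed(seed)
  g <- params$gamma
  d <- params$d
  lam <- params$lambda
  beta <- params$beta
  t_end <- rep(n_generations * log(2) / g, n)
  if (cycle$kind == "adder") {
    # a deterministic adder self-synchronizes its division phase whatever the
    # initial phase; jitter the sampling time within one generation so the
    # ensemble measures the phase-stationary (time-averaged) statistics
    t_end <- t_end - stats::runif(n) * log(2) / g
  }
  m <- lam * beta / (g + d)
  x <- rep_len(x0 %||% m, n)

  st <- init_cycle_state(n, cycle, params)
  tdiv <- st$tdiv
  vol <- st$vol
  tcur <- numeric(n)

  evolve_det <- function(x, dur) m + (x - m) * exp(-(g + d) * dur)
  evolve_bursty <- function(x, dur) {
    rem <- dur
    if (lam == 0) return(x * exp(-(g + d) * dur))
    act <- rem > 0
    while (any(act)) {
      i <- which(act)
      dtb <- stats::rexp(length(i), lam)
      over <- dtb >= rem[i]
      io <- i[over]
      if (length(io)) {
        x[io] <- x[io] * exp(-(g + d) * rem[io])
        rem[io] <- 0
      }
      ib <- i[!over]
      if (length(ib)) {
        x[ib] <- x[ib] * exp(-(g + d) * dtb[!over]) +
          stats::rexp(length(ib), 1 / beta)
        rem[ib] <- rem[ib] - dtb[!over]
      }
      act[i] <- rem[i] > 0
    }
    x
  }
  evolve <- if (bursty) evolve_bursty else evolve_det

  repeat {
    div <- tdiv <= t_end
    if (!any(div)) break
    i <- which(div)
    x[i] <- evolve(x[i], tdiv[i] - tcur[i])
    pair <- partition_pair(x[i], partition)
    side <- 1 + (stats::runif(length(i)) < 0.5)
    x[i] <- pair[cbind(seq_along(i), side)]
    tcur[i] <- tdiv[i]
    nxt <- next_division(vol[i], cycle, params)
    vol[i] <- nxt$vol
    tdiv[i] <- tcur[i] + nxt$tau
  }
  x <- evolve(x, t_end - tcur)
  tibble::tibble(replicate = seq_len(n), x = x)
}
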