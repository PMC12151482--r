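#' Agent-based colony simulation
#'
#' Expands a colony from one progenitor, tracking every cell. Within each
#' cell, concentration evolves by the model's expression dynamics (bursts and
#' dilution, or deterministic synthesis); divisions are generated either by
#' the state-dependent hazard `gamma/(1+kx)` (exact thinning against the
#' bound `gamma`), by i.i.d. timer durations, or by an adder size rule; at
#' each division the mother is replaced by two daughters with concentrations
#' `x+` and `2x - x+` from the partition kernel (perfect kernel: both inherit
#' `x`). All cells are advanced deterministically to the exact stop time for
#' the snapshot.
#'
#' Stop criteria (`stop` is a one-element named list):
#' * `time`: snapshot at a fixed time.
#' * `generations`: snapshot after `n` population doublings, i.e. at
#'   `n * ln(2) / gamma` (for a deterministic timer this gives exactly `2^n`
#'   cells).
#' * `max_cells`: run until the colony reaches that many live cells.
#'
#' A guard `max_cells` (default 2^16) is always active; exceeding it
#' truncates the run and flags the snapshot (`truncated = TRUE`), never
#' silently.
#'
#' @param params A [burst_params()] object.
#' @param partition A [partition_model()] (default: perfect partitioning).
#' @param cycle A [cycle_model()]; `"hazard_feedback"` (default) ties division
#'   to the growth rate, `"timer"`/`"adder"` use the partitioning-model cycle
#'   machinery.
#' @param stop One-element named list: `list(time=)`, `list(generations=)`,
#'   or `list(max_cells=)`.
#' @param x0 Progenitor concentration: a number, or a function `n -> vector`
#'   (e.g. [rstationary()] for a warm start); defaults to the stationary
#'   single-cell mean (hazard cycles, when it exists) or the fixed point
#'   `lambda*beta/(gamma+d)`.
#' @param seed Optional integer seed.
#' @param synthesis `"auto"` (bursty for hazard cycles, deterministic for
#'   timer/adder), `"deterministic"`, or `"bursty"`.
#' @param max_cells Hard cap on the number of cells ever created.
#' @param colony_id Identifier stored with the snapshot.
#' @return A `colony_snapshot`: list with `cells` (tibble: `cell`, `parent`,
#'   `birth_time`, `division_time`, `x`, `volume`, `alive`), `time`,
#'   `n_cells` (live cells), `truncated`, `colony_id`.
#' @examples
#' p <- burst_params(lambda = 20 * log(2) / 10, beta = 10, gamma = log(2))
#' snap <- simulate_colony(p, partition_model(1),
#'   cycle_model("timer", cv2_tau = 0), stop = list(generations = 4),
#'   seed = 1)
#' snap$n_cells # 16
#' @export
simulate_colony <- function(params,
                            partition = partition_model(0),
                            cycle = cycle_model("hazard_feedback"),
                            stop = list(generations = 6),
                            x0 = NULL, seed = NULL,
                            synthesis = c("auto", "deterministic", "bursty"),
                            max_cells = 65536L, colony_id = 1L) {
  stopifnot(inherits(params, "burst_params"),
            inherits(partition, "partition_model"),
            inherits(cycle, "cycle_model"))
  synthesis <- match.arg(synthesis)
  if (length(stop) != 1 || is.null(names(stop)) ||
      !names(stop) %in% c("time", "generations", "max_cells")) {
    stop("`stop` must be exactly one of list(time=), list(generations=), ",
         "list(max_cells=)")
  }
  if (!is.null(seed)) set.seed(seed)
  if (cycle$kind == "hazard_feedback" && synthesis == "deterministic") {
    stop("hazard_feedback division requires bursty synthesis")
  }
  bursty <- switch(synthesis,
    auto = cycle$kind == "hazard_feedback",
    deterministic = FALSE,
    bursty = TRUE
  )
  g <- params$gamma
  d <- params$d
  t_stop <- switch(names(stop),
    time = stop$time,
    generations = stop$generations * log(2) / g,
    max_cells = Inf
  )
  stop_cells <- if (names(stop) == "max_cells") stop$max_cells else Inf
  if (is.finite(stop_cells)) max_cells <- max(max_cells, 2 * stop_cells)
  if (cycle$kind == "adder" && names(stop) == "generations") {
    # deterministic adders self-synchronize division phase; jitter the
    # snapshot within one generation for phase-stationary pooled statistics
    t_stop <- t_stop - stats::runif(1) * log(2) / g
  }

  m_fix <- params$lambda * params$beta / (g + d)
  if (is.function(x0)) x0 <- x0(1)
  if (is.null(x0)) {
    x0 <- if (cycle$kind == "hazard_feedback" &&
              existence_status(params) == "both" && params$lambda > 0) {
      stationary_moments(params, "single_cell")$mean
    } else {
      m_fix
    }
  }

  # growing cell table
  cap0 <- 256L
  id <- integer(cap0); parent <- integer(cap0)
  birth <- numeric(cap0); divt <- rep(NA_real_, cap0)
  xb <- numeric(cap0); xf <- rep(NA_real_, cap0)
  vol <- rep(NA_real_, cap0); tdiv_pending <- rep(NA_real_, cap0)
  alive <- logical(cap0)
  n_cells <- 0L
  truncated <- FALSE

  add_cell <- function(par, t_birth, x_birth, v_birth, t_division) {
    if (n_cells + 1L > length(id)) {
      grow <- function(v, fill) c(v, rep(fill, length(v)))
      id <<- grow(id, NA_integer_); parent <<- grow(parent, NA_integer_)
      birth <<- grow(birth, NA_real_); divt <<- grow(divt, NA_real_)
      xb <<- grow(xb, NA_real_); xf <<- grow(xf, NA_real_)
      vol <<- grow(vol, NA_real_); tdiv_pending <<- grow(tdiv_pending, NA_real_)
      alive <<- grow(alive, FALSE)
    }
    n_cells <<- n_cells + 1L
    i <- n_cells
    id[i] <<- i; parent[i] <<- par
    birth[i] <<- t_birth; xb[i] <<- x_birth; vol[i] <<- v_birth
    tdiv_pending[i] <<- t_division
    alive[i] <<- TRUE
    i
  }

  # bursty evolution of one cell over a duration (constant-dilution decay
  # toward 0 plus bursts; for hazard cycles dilution is the feedback flow)
  evolve_cell <- function(x, dur) {
    if (!bursty) return(m_fix + (x - m_fix) * exp(-(g + d) * dur))
    if (params$lambda == 0) return(flow_map(x, dur, params))
    rem <- dur
    while (rem > 0) {
      dtb <- stats::rexp(1, params$lambda)
      if (dtb >= rem) {
        x <- flow_map(x, rem, params)
        rem <- 0
      } else {
        x <- flow_map(x, dtb, params)
        rem <- rem - dtb
        acc <- params$burst_mode == "constant" ||
          stats::runif(1) < 1 / (1 + params$k * x)
        if (acc) x <- x + stats::rexp(1, 1 / params$beta)
      }
    }
    x
  }

  # progenitor; vol[j] is the cell's newborn volume (adder mode only)
  if (cycle$kind == "hazard_feedback") {
    add_cell(NA_integer_, 0, x0, NA_real_, NA_real_)
  } else {
    st <- init_cycle_state(1, cycle, params)
    add_cell(NA_integer_, 0, x0,
             if (cycle$kind == "adder") 1 else NA_real_, st$tdiv)
  }

  # process cells in chronological order of birth
  pending <- 1L
  live_count <- function() sum(alive[seq_len(n_cells)])
  while (length(pending) > 0) {
    j <- pending[which.min(birth[pending])]
    pending <- setdiff(pending, j)

    if (cycle$kind == "hazard_feedback") {
      res <- run_hazard_cell(xb[j], birth[j], t_stop, params)
      x_end <- res$x; t_div <- res$t_div
    } else {
      t_div <- tdiv_pending[j]
      if (t_div <= t_stop) {
        x_end <- evolve_cell(xb[j], t_div - birth[j])
      } else {
        t_div <- NA_real_
        x_end <- NA_real_
      }
    }

    if (!is.na(t_div) && t_div <= t_stop) {
      if (n_cells + 2L > max_cells) {
        truncated <- TRUE
        pending <- c(pending, j)
        break
      }
      divt[j] <- t_div
      alive[j] <- FALSE
      xf[j] <- x_end
      pair <- partition_pair(x_end, partition)
      if (cycle$kind == "hazard_feedback") {
        i1 <- add_cell(j, t_div, pair[1], NA_real_, NA_real_)
        i2 <- add_cell(j, t_div, pair[2], NA_real_, NA_real_)
      } else {
        v_child <- if (cycle$kind == "adder") {
          rate <- cycle$growth_rate %||% g
          # mother volume grew exponentially from birth; halved at division
          vol[j] * exp(rate * (t_div - birth[j])) / 2
        } else NA_real_
        n1 <- next_division(v_child, cycle, params)
        n2 <- next_division(v_child, cycle, params)
        i1 <- add_cell(j, t_div, pair[1], v_child, t_div + n1$tau)
        i2 <- add_cell(j, t_div, pair[2], v_child, t_div + n2$tau)
      }
      pending <- c(pending, i1, i2)
      if (live_count() >= stop_cells) {
        # snapshot the moment the target size is reached
        t_stop <- t_div
        break
      }
    } else {
      # alive at the snapshot: advance to t_stop
      if (cycle$kind == "hazard_feedback") {
        xf[j] <- x_end
      } else {
        xf[j] <- evolve_cell(xb[j], t_stop - birth[j])
      }
    }
  }
  # any cells left pending (truncation / max_cells stop): advance to t_stop
  for (j in pending) {
    if (is.finite(t_stop) && birth[j] <= t_stop) {
      xf[j] <- if (cycle$kind == "hazard_feedback") {
        run_hazard_cell(xb[j], birth[j], t_stop, params,
                        divisions = FALSE)$x
      } else {
        evolve_cell(xb[j], t_stop - birth[j])
      }
    }
  }

  keep <- seq_len(n_cells)
  cells <- tibble::tibble(
    cell = id[keep], parent = parent[keep],
    birth_time = birth[keep], division_time = divt[keep],
    x = xf[keep], volume = vol[keep], alive = alive[keep]
  )
  structure(
    list(cells = cells, time = t_stop, n_cells = sum(cells$alive),
         truncated = truncated, colony_id = colony_id,
         params = params, partition = partition, cycle = cycle),
    class = "colony_snapshot"
  )
}

# One cell under the state-dependent division hazard: competing bursts
# (bound lambda) and division proposals (bound gamma), both thinned exactly.
# Returns the division time (or NA if alive at t_stop) and the concentration
# at division/t_stop.
run_hazard_cell <- function(x, t_birth, t_stop, params, divisions = TRUE) {
  lam <- params$lambda
  g <- params$gamma
  total <- lam + if (divisions) g else 0
  t <- t_birth
  repeat {
    if (total == 0) {
      return(list(x = flow_map(x, t_stop - t, params), t_div = NA_real_))
    }
    dt <- stats::rexp(1, total)
    if (t + dt >= t_stop) {
      return(list(x = flow_map(x, t_stop - t, params), t_div = NA_real_))
    }
    x <- flow_map(x, dt, params)
    t <- t + dt
    if (stats::runif(1) < lam / total) {
      acc <- params$burst_mode == "constant" ||
        stats::runif(1) < 1 / (1 + params$k * x)
      if (acc) x <- x + stats::rexp(1, 1 / params$beta)
    } else {
      # division proposal at bound gamma; exact thinning by hazard/gamma
      if (stats::runif(1) < division_hazard(x, params) / g) {
        return(list(x = x, t_div = t))
      }
    }
  }
}

#' @export
print.colony_snapshot <- function(x, ...) {
  cat(sprintf("<colony_snapshot> t = %.4g, %d live cells%s\n",
              x$time, x$n_cells,
              if (x$truncated) " [TRUNCATED at max_cells]" else ""))
  invisible(x)
}

#' Simulate many independent colonies
#'
#' Runs [simulate_colony()] `n_colonies` times with independently derived
#' child random streams, so results for one colony do not depend on how many
#' others are simulated.
#'
#' @inheritParams simulate_colony
#' @param n_colonies Number of colonies.
#' @param seed Seed for the master stream from which per-colony seeds are
#'   derived.
#' @return A list of `colony_snapshot` objects (class `"colony_set"`).
#' @export
simulate_colonies <- function(n_colonies, params,
                              partition = partition_model(0),
                              cycle = cycle_model("hazard_feedback"),
                              stop = list(generations = 6),
                              x0 = NULL, seed = NULL,
                              synthesis = c("auto", "deterministic",
                                            "bursty"),
                              max_cells = 65536L) {
  synthesis <- match.arg(synthesis)
  if (!is.null(seed)) set.seed(seed)
  child_seeds <- sample.int(.Machine$integer.max, n_colonies)
  out <- lapply(seq_len(n_colonies), function(i) {
    simulate_colony(params, partition, cycle, stop = stop, x0 = x0,
                    seed = child_seeds[i], synthesis = synthesis,
                    max_cells = max_cells, colony_id = i)
  })
  class(out) <- "colony_set"
  out
}

#' Pool all live cells of one or more colony snapshots
#'
#' @param snapshots A `colony_snapshot`, a list of them (`colony_set`), or a
#'   tibble with columns `colony` and `x`.
#' @return A tibble with columns `colony` and `x`, one row per live cell.
#' @export
pool_cells <- function(snapshots) {
  if (inherits(snapshots, "colony_snapshot")) snapshots <- list(snapshots)
  if (is.data.frame(snapshots)) {
    stopifnot(all(c("colony", "x") %in% names(snapshots)))
    return(tibble::as_tibble(snapshots[, c("colony", "x")]))
  }
  purrr::map_dfr(snapshots, function(s) {
    live <- s$cells[s$cells$alive, ]
    tibble::tibble(colony = s$colony_id, x = live$x)
  })
}

#' Population summary statistics across colonies
#'
#' Pools all live cells across colonies with equal per-cell weight and
#' returns mean, noise and skewness with bootstrap standard errors obtained
#' by resampling whole colonies (respecting within-colony dependence).
#'
#' @param snapshots See [pool_cells()].
#' @param n_boot Bootstrap resamples (colony-level).
#' @return A one-row tibble: `n`, `n_colonies`, `mean`, `cv2`, `skewness`,
#'   `se_mean`, `se_cv2`, `se_skewness`.
#' @export
population_stats <- function(snapshots, n_boot = 200) {
  cells <- pool_cells(snapshots)
  if (nrow(cells) == 0) stop("no live cells to pool")
  est <- moment_estimates(cells$x)
  ids <- unique(cells$colony)
  se <- c(NA_real_, NA_real_, NA_real_)
  if (n_boot > 0 && length(ids) > 1) {
    split_x <- split(cells$x, cells$colony)
    boots <- vapply(seq_len(n_boot), function(i) {
      take <- sample(length(split_x), replace = TRUE)
      moment_estimates(unlist(split_x[take], use.names = FALSE))
    }, numeric(3))
    se <- apply(boots, 1, stats::sd)
  }
  tibble::tibble(
    n = nrow(cells), n_colonies = length(ids),
    mean = est[1], cv2 = est[2], skewness = est[3],
    se_mean = se[1], se_cv2 = se[2], se_skewness = se[3]
  )
}

#' Fitted exponential growth rate of the population
#'
#' Estimates the population growth rate from colony cell counts over time:
#' within each colony the live-cell count at time `t` is one plus the number
#' of divisions up to `t`; counts are averaged across colonies on a time grid
#' and a line is fitted to the log counts over the later part of the run
#' (default: last half).
#'
#' @param snapshots See [pool_cells()]; snapshots must carry lineage times.
#' @param window Fraction of `[0, T]` used for the fit.
#' @param n_grid Number of grid points.
#' @return A one-row tibble: `mu` (fitted rate), `se_mu`, `doubling_time`.
#' @export
estimate_growth_rate <- function(snapshots, window = c(0.5, 1),
                                 n_grid = 25) {
  if (inherits(snapshots, "colony_snapshot")) snapshots <- list(snapshots)
  t_end <- snapshots[[1]]$time
  grid <- seq(window[1] * t_end, window[2] * t_end, length.out = n_grid)
  counts <- rowMeans(vapply(snapshots, function(s) {
    dt <- s$cells$division_time
    dt <- dt[!is.na(dt)]
    vapply(grid, function(tt) 1 + sum(dt <= tt), numeric(1))
  }, numeric(length(grid))))
  fit <- stats::lm(log(counts) ~ grid)
  mu <- unname(stats::coef(fit)[2])
  se <- summary(fit)$coefficients[2, 2]
  tibble::tibble(mu = mu, se_mu = se, doubling_time = log(2) / mu)
}

#' Export a colony's lineage tree as a newick string
#'
#' Branch lengths are cell lifetimes (division time, or the snapshot time for
#' live cells, minus birth time); leaf labels are `c<cell id>`. The string
#' parses back (e.g. with [ape::read.tree()]) to the same topology, with one
#' leaf per cell alive at the snapshot.
#'
#' @param snapshot A `colony_snapshot` with its lineage table.
#' @return A single newick string.
#' @export
export_lineage_newick <- function(snapshot) {
  stopifnot(inherits(snapshot, "colony_snapshot"))
  cells <- snapshot$cells
  if (nrow(cells) == 0) stop("snapshot carries no lineage tree")
  t_end <- snapshot$time
  kids <- split(cells$cell, factor(cells$parent, levels = cells$cell))
  fmt <- function(i) {
    len <- (if (is.na(cells$division_time[i])) t_end else
      cells$division_time[i]) - cells$birth_time[i]
    ch <- kids[[as.character(i)]]
    if (is.null(ch) || length(ch) == 0) {
      sprintf("c%d:%.10g", cells$cell[i], len)
    } else {
      sprintf("(%s,%s):%.10g", fmt(ch[1]), fmt(ch[2]), len)
    }
  }
  root <- cells$cell[is.na(cells$parent)]
  body <- fmt(root)
  # a lone progenitor still needs surrounding parentheses to parse
  if (!startsWith(body, "(")) body <- paste0("(", body, ")")
  paste0(body, ";")
}
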