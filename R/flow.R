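#' Deterministic dilution flow between bursts
#'
#' Advances the concentration along the dilution flow
#' `dx/dt = -gamma * x / (1 + k x) - d * x` for a duration `t`, i.e. the
#' deterministic part of the piecewise-deterministic process in between burst
#' events. In `dilution_mode = "constant"` the flow is plain exponential decay
#' at rate `gamma + d` regardless of `k`.
#'
#' For `d = 0` the solution satisfies the implicit relation
#' `log(x) + k x = log(x0) + k x0 - gamma t`, solved here with a
#' bracketed Newton iteration in `log(x)` (numerically equivalent to the
#' principal Lambert-W branch but overflow-safe for large `k x0`). With both
#' `d > 0` and `k > 0` the flow is integrated numerically ([deSolve::ode()]).
#'
#' @param x0 Initial concentration(s), >= 0. Recycled against `t`.
#' @param t Duration(s), >= 0. Recycled against `x0`.
#' @param params A [burst_params()] object.
#' @return Concentration(s) after time `t`; strictly decreasing in `t` for
#'   `x0 > 0`, exactly 0 for `x0 = 0`.
#' @examples
#' p <- burst_params(lambda = 10, beta = 10, gamma = 1, k = 0)
#' flow_map(100, log(2), p) # pure exponential decay: 50
#' @export
flow_map <- function(x0, t, params) {
  stopifnot(inherits(params, "burst_params"))
  if (any(x0 < 0, na.rm = TRUE)) stop("`x0` must be non-negative")
  if (any(t < 0, na.rm = TRUE)) stop("`t` must be non-negative")
  n <- max(length(x0), length(t))
  x0 <- rep_len(x0, n)
  t <- rep_len(t, n)
  g <- params$gamma
  k <- params$k
  d <- params$d
  if (k == 0 || params$dilution_mode == "constant") {
    return(x0 * exp(-(g + d) * t))
  }
  if (d == 0) {
    out <- numeric(n)
    pos <- x0 > 0 & t > 0
    out[x0 > 0 & t == 0] <- x0[x0 > 0 & t == 0]
    if (any(pos)) {
      out[pos] <- flow_newton(x0[pos], t[pos], g, k)
    }
    return(out)
  }
  # k > 0 and d > 0: no closed form attempted; integrate numerically
  vapply(seq_len(n), function(i) {
    if (x0[i] == 0 || t[i] == 0) return(x0[i])
    sol <- deSolve::ode(
      y = c(x = x0[i]), times = c(0, t[i]),
      func = function(tt, y, parms) {
        list(-g * y / (1 + k * y) - d * y)
      },
      parms = NULL, rtol = 1e-12, atol = 1e-14
    )
    max(unname(sol[nrow(sol), "x"]), 0)
  }, numeric(1))
}

# Solve log(x) + k*x = log(x0) + k*x0 - gamma*t for x, vectorized.
# Root is bracketed by u_lo = log(x0) - gamma*t (pure exponential decay is
# faster than feedback dilution) and u_hi = log(x0); f(u) = u + k e^u - c is
# increasing and convex, so Newton from u_hi converges monotonically.
flow_newton <- function(x0, t, gamma, k) {
  c0 <- log(x0) + k * x0 - gamma * t
  u <- log(x0)
  for (i in 1:100) {
    eu <- exp(u)
    f <- u + k * eu - c0
    step <- f / (1 + k * eu)
    u <- u - step
    if (all(abs(step) < 1e-14 * pmax(1, abs(u)))) break
  }
  exp(u)
}

#' State-dependent cell-division hazard
#'
#' The division propensity equals the cellular growth rate
#' `gamma / (1 + k x)`: a cell with concentration `x` divides in `[t, t+dt)`
#' with probability `gamma/(1+kx) dt`. Monotone non-increasing in `x`,
#' bounded above by `gamma` (which enables exact thinning in the colony
#' simulator). In `dilution_mode = "constant"` the hazard is `gamma`
#' independently of `x`.
#'
#' @param x Concentration(s), >= 0.
#' @param params A [burst_params()] object.
#' @return Division rate(s).
#' @examples
#' p <- burst_params(lambda = 1, beta = 10, gamma = 1, k = 0.01)
#' division_hazard(100, p) # 0.5
#' @export
division_hazard <- function(x, params) {
  stopifnot(inherits(params, "burst_params"))
  if (any(x < 0, na.rm = TRUE)) stop("`x` must be non-negative")
  if (params$dilution_mode == "constant") {
    return(rep_len(params$gamma, length(x)))
  }
  params$gamma / (1 + params$k * x)
}

# Burst propensity: constant lambda, or lambda/(1+kx) when growth-coupled.
burst_rate <- function(x, params) {
  if (params$burst_mode == "constant") {
    return(rep_len(params$lambda, length(x)))
  }
  params$lambda / (1 + params$k * x)
}

#' Calibrate the mean cell-cycle time to the population growth rate
#'
#' For gamma-distributed i.i.d. cell-cycle times with squared CV `cv2_tau`,
#' returns the mean duration such that the Euler--Lotka relation
#' `2 E[exp(-gamma * tau_d)] = 1` holds, i.e. the binary-splitting population
#' grows exponentially at rate `gamma` and doubles every `ln(2)/gamma`.
#' With shape `a = 1/cv2_tau` the closed form is
#' `mean_tau = a (2^(1/a) - 1) / gamma`; `cv2_tau = 0` (deterministic timer)
#' gives `ln(2)/gamma`.
#'
#' @param cv2_tau Squared CV of the cell-cycle time, >= 0.
#' @param gamma Target population growth rate, > 0.
#' @return The calibrated mean cell-cycle duration.
#' @examples
#' calibrate_cycle_mean(0, log(2)) # 1
#' calibrate_cycle_mean(1, log(2)) # 1/log(2)
#' @export
calibrate_cycle_mean <- function(cv2_tau, gamma) {
  stopifnot(is.numeric(cv2_tau), cv2_tau >= 0)
  if (!is.numeric(gamma) || length(gamma) != 1 || gamma <= 0) {
    stop("`gamma` must be a single positive rate")
  }
  ifelse(cv2_tau == 0,
         log(2) / gamma,
         (2^cv2_tau - 1) / (cv2_tau * gamma))
}

# Draw n cell-cycle durations for a timer cycle model. The default mean is
# ln(2)/gamma for every cv2_tau (the deterministic-timer value): under a
# fixed mean the stationary single-cell partitioning noise eps/(2 ln2 xbar)
# is exactly invariant to the cycle-time distribution.
draw_cycle_times <- function(n, cycle, gamma) {
  mean_tau <- cycle$mean_tau %||% (log(2) / gamma)
  if (cycle$cv2_tau == 0) {
    rep(mean_tau, n)
  } else {
    shape <- 1 / cycle$cv2_tau
    stats::rgamma(n, shape = shape, scale = mean_tau / shape)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
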