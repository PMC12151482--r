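#' Parameters of the burst-dilution feedback model
#'
#' Bundles the parameters of the bursty gene-expression model in proliferating
#' cells. Protein concentration `x` jumps up at burst events (sizes
#' exponentially distributed with mean `beta`) and is diluted in between by
#' cellular growth. With feedback (`k > 0`) the growth rate -- and hence both
#' the dilution flow and the cell-division propensity -- is `gamma / (1 + k x)`:
#' high concentration slows growth, creating effective positive feedback on
#' concentration.
#'
#' @param lambda Burst frequency (events per unit time, >= 0). In
#'   `burst_mode = "growth_coupled"` this is the maximum rate; the actual rate
#'   is `lambda / (1 + k x)`, scaling with the growth rate.
#' @param beta Mean burst size (concentration units, > 0).
#' @param gamma Maximum dilution rate (per unit time, > 0).
#' @param k Feedback strength (per concentration unit, >= 0). `k = 0` recovers
#'   the unregulated model with constant dilution.
#' @param d Constant degradation rate (per unit time, >= 0, default 0), an
#'   additive `-d x` term in the dilution flow for short-lived proteins.
#' @param burst_mode `"constant"` (default) for a concentration-independent
#'   burst frequency, or `"growth_coupled"` for a burst rate proportional to
#'   the growth rate.
#' @param dilution_mode `"feedback"` (default): dilution flow and division
#'   hazard both equal the growth rate `gamma / (1 + k x)`. `"constant"`:
#'   dilution and division stay at rate `gamma` regardless of `x` (used to
#'   study concentration-dependent burst frequencies in isolation).
#'
#' @return An object of class `"burst_params"`.
#' @examples
#' p <- burst_params(lambda = 100 / 21, beta = 10, gamma = 1, k = 0.01)
#' p
#' @export
burst_params <- function(lambda, beta, gamma, k = 0, d = 0,
                         burst_mode = c("constant", "growth_coupled"),
                         dilution_mode = c("feedback", "constant")) {
  burst_mode <- match.arg(burst_mode)
  dilution_mode <- match.arg(dilution_mode)
  stopifnot(
    is.numeric(lambda), length(lambda) == 1, is.finite(lambda), lambda >= 0,
    is.numeric(beta), length(beta) == 1, is.finite(beta), beta > 0,
    is.numeric(gamma), length(gamma) == 1, is.finite(gamma), gamma > 0,
    is.numeric(k), length(k) == 1, is.finite(k), k >= 0,
    is.numeric(d), length(d) == 1, is.finite(d), d >= 0
  )
  structure(
    list(lambda = lambda, beta = beta, gamma = gamma, k = k, d = d,
         burst_mode = burst_mode, dilution_mode = dilution_mode),
    class = "burst_params"
  )
}

#' @export
print.burst_params <- function(x, ...) {
  cat("<burst_params>\n")
  cat(sprintf("  burst frequency lambda: %g (%s)\n", x$lambda, x$burst_mode))
  cat(sprintf("  mean burst size beta:   %g\n", x$beta))
  cat(sprintf("  max dilution rate gamma: %g (%s dilution)\n",
              x$gamma, x$dilution_mode))
  cat(sprintf("  feedback strength k:    %g\n", x$k))
  if (x$d > 0) cat(sprintf("  degradation rate d:     %g\n", x$d))
  invisible(x)
}

#' Random molecule partitioning at cell division
#'
#' Describes how a mother's concentration `x` is split between two daughters.
#' One daughter inherits `x+` with conditional mean `x` and conditional
#' variance `epsilon * x`, bounded inside `(0, 2x)`; the other receives
#' `2x - x+`. `epsilon = 0` forces perfect partitioning (`x+ = x` with
#' probability one).
#'
#' @param epsilon Partitioning-noise magnitude (concentration units, >= 0).
#' @param kernel Distribution family for `x+`: `"beta_matched"` (default), a
#'   symmetric beta on `(0, 2x)` matching the mean/variance contract exactly
#'   whenever `x > epsilon`; `"binomial_discretized"`, a binomial draw over
#'   `n = round(x / epsilon)` effective molecules rescaled to concentration
#'   units (matching binomial segregation statistics); or `"perfect"`.
#' @return An object of class `"partition_model"`.
#' @seealso [draw_partition()]
#' @examples
#' partition_model(epsilon = 1)
#' @export
partition_model <- function(epsilon = 0,
                            kernel = c("beta_matched", "binomial_discretized",
                                       "perfect")) {
  kernel <- match.arg(kernel)
  stopifnot(is.numeric(epsilon), length(epsilon) == 1, is.finite(epsilon),
            epsilon >= 0)
  if (epsilon == 0) kernel <- "perfect"
  if (kernel == "perfect") epsilon <- 0
  structure(list(epsilon = epsilon, kernel = kernel),
            class = "partition_model")
}

#' @export
print.partition_model <- function(x, ...) {
  cat(sprintf("<partition_model> epsilon = %g, kernel = %s\n",
              x$epsilon, x$kernel))
  invisible(x)
}

#' Cell-division timing mechanism
#'
#' Three mechanisms for when a cell divides:
#' * `"hazard_feedback"`: division is a point process with state-dependent
#'   rate `gamma / (1 + k x)` (the growth rate); no timing parameters needed.
#' * `"timer"`: i.i.d. cell-cycle durations, gamma-distributed with squared
#'   coefficient of variation `cv2_tau`; the mean defaults to `ln(2)/gamma`
#'   for every `cv2_tau` (under a fixed mean the stationary single-cell
#'   partitioning noise is exactly invariant to the cycle-time distribution),
#'   unless `mean_tau` is supplied -- e.g. from [calibrate_cycle_mean()] to
#'   pin the population growth rate at `gamma` instead.
#' * `"adder"`: cell volume grows exponentially at `growth_rate` and division
#'   fires once the added volume since birth reaches a gamma-distributed
#'   threshold (mean `mean_added`, squared CV `cv2_added`), uncorrelated with
#'   newborn size; volume halves at division.
#'
#' @param kind One of `"hazard_feedback"`, `"timer"`, `"adder"`.
#' @param cv2_tau Squared CV of the cell-cycle time (timer mode, >= 0;
#'   0 gives a deterministic timer).
#' @param mean_tau Mean cell-cycle time (timer mode). Leave `NULL` to
#'   calibrate from `cv2_tau` and the model's `gamma` at simulation time.
#' @param mean_added,cv2_added,growth_rate Adder-mode parameters: mean added
#'   volume (> 0), squared CV of the added volume (>= 0), and exponential
#'   volume growth rate (> 0; defaults to the model's `gamma` when `NULL`).
#' @return An object of class `"cycle_model"`.
#' @examples
#' cycle_model("timer", cv2_tau = 1)
#' cycle_model("adder", cv2_added = 0.25)
#' @export
cycle_model <- function(kind = c("hazard_feedback", "timer", "adder"),
                        cv2_tau = 0, mean_tau = NULL,
                        mean_added = 1, cv2_added = 0, growth_rate = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(cv2_tau), length(cv2_tau) == 1, cv2_tau >= 0)
  if (!is.null(mean_tau)) {
    stopifnot(is.numeric(mean_tau), length(mean_tau) == 1, mean_tau > 0)
  }
  if (kind == "adder") {
    stopifnot(mean_added > 0, cv2_added >= 0)
    if (!is.null(growth_rate)) stopifnot(growth_rate > 0)
  }
  structure(
    list(kind = kind, cv2_tau = cv2_tau, mean_tau = mean_tau,
         mean_added = mean_added, cv2_added = cv2_added,
         growth_rate = growth_rate),
    class = "cycle_model"
  )
}

#' @export
print.cycle_model <- function(x, ...) {
  cat(sprintf("<cycle_model> kind = %s", x$kind))
  if (x$kind == "timer") {
    cat(sprintf(", cv2_tau = %g, mean_tau = %s", x$cv2_tau,
                if (is.null(x$mean_tau)) "(calibrated)" else
                  format(x$mean_tau)))
  }
  if (x$kind == "adder") {
    cat(sprintf(", mean_added = %g, cv2_added = %g",
                x$mean_added, x$cv2_added))
  }
  cat("\n")
  invisible(x)
}
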