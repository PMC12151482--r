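#' Stationary statistics of the unregulated (no-feedback) model
#'
#' With `k = 0` the stationary concentration law in both perspectives is the
#' gamma distribution with shape `lambda/gamma` and scale `beta`, so
#' `mean = lambda beta / gamma`, `CV^2 = beta / mean`, and
#' `skewness = 2 sqrt(beta / mean)`; the ratio skewness/CV equals 2 exactly.
#'
#' @param lambda Burst frequency, >= 0.
#' @param beta Mean burst size, > 0.
#' @param gamma Dilution rate, > 0.
#' @return A tibble with columns `perspective` (`"both"`), `mean`, `cv2`,
#'   `skewness`.
#' @examples
#' unregulated_stats(10, 10, 1)
#' @export
unregulated_stats <- function(lambda, beta, gamma) {
  stopifnot(lambda >= 0, beta > 0, gamma > 0)
  m <- lambda * beta / gamma
  tibble::tibble(
    perspective = "both",
    mean = m,
    cv2 = if (m > 0) beta / m else 0,
    skewness = if (m > 0) 2 * sqrt(beta / m) else 0
  )
}

# Raw moment of order n of a stationary law, from its exact gamma-mixture
# representation: E[x^n] = (w1 * rising(a, n) + w2 * rising(a + 1, n)) / s^n.
law_raw_moment <- function(law, n) {
  rising <- function(a, n) exp(lgamma(a + n) - lgamma(a))
  (law$weights[1] * rising(law$shape, n) +
     law$weights[2] * rising(law$shape + 1, n)) / law$tilt^n
}

# Raw moment by adaptive quadrature of the density itself (the normative
# numerical oracle; independent of the mixture closed form).
law_raw_moment_quadrature <- function(law, n) {
  s <- law$tilt
  stats::integrate(function(u) (u / s)^n * dstationary(u / s, law) / s,
                   0, Inf, rel.tol = 1e-12, abs.tol = 1e-12,
                   subdivisions = 500L)$value
}

#' Exact stationary moments in either perspective
#'
#' Mean, noise (squared coefficient of variation) and skewness of the
#' stationary concentration law. The default evaluates exact closed forms
#' derived from the gamma-mixture representation of the law;
#' `method = "quadrature"` integrates the density directly and serves as an
#' independent numerical check (the two agree to near machine precision).
#'
#' @param params A [burst_params()] object.
#' @param perspective `"single_cell"` or `"population"`.
#' @param method `"closed_form"` (default) or `"quadrature"`.
#' @return A tibble with columns `perspective`, `mean`, `cv2`, `skewness`.
#' @examples
#' p <- burst_params(lambda = 100 / 21, beta = 10, gamma = 1, k = 0.01)
#' stationary_moments(p, "single_cell") # mean 100, cv2 0.2
#' stationary_moments(p, "population")  # mean ~84, cv2 ~0.221
#' @export
stationary_moments <- function(params,
                               perspective = c("single_cell", "population"),
                               method = c("closed_form", "quadrature")) {
  perspective <- match.arg(perspective)
  method <- match.arg(method)
  law <- stationary_law(params, perspective)
  raw <- switch(method,
    closed_form = vapply(1:3, law_raw_moment, numeric(1), law = law),
    quadrature = vapply(1:3, law_raw_moment_quadrature, numeric(1), law = law)
  )
  m1 <- raw[1]
  v <- raw[2] - m1^2
  m3c <- raw[3] - 3 * m1 * v - m1^3
  tibble::tibble(
    perspective = perspective,
    mean = m1,
    cv2 = v / m1^2,
    skewness = m3c / v^1.5
  )
}

#' Burst frequency achieving a target single-cell mean
#'
#' Inverts the single-cell stationary mean: returns the burst frequency
#' `lambda = gamma * m / (beta * (1 + k beta + k m))` such that the
#' single-cell stationary mean equals `target_mean = m`. Used to hold the
#' single-cell mean fixed while sweeping the feedback strength. The result
#' always satisfies the single-cell existence condition.
#'
#' @param target_mean Desired single-cell stationary mean, >= 0.
#' @param k Feedback strength, >= 0.
#' @param beta Mean burst size, > 0.
#' @param gamma Dilution rate, > 0.
#' @return The burst frequency `lambda`.
#' @examples
#' burst_frequency_for_mean(100, k = 1 / 100, beta = 10, gamma = 1) # 100/21
#' burst_frequency_for_mean(100, k = 0, beta = 10, gamma = 1)       # 10
#' @export
burst_frequency_for_mean <- function(target_mean, k, beta, gamma) {
  stopifnot(target_mean >= 0, k >= 0, beta > 0, gamma > 0)
  gamma * target_mean / (beta * (1 + k * beta + k * target_mean))
}

#' Weak-feedback approximations of the stationary statistics
#'
#' First-order-in-`k` approximations at fixed single-cell mean `m`:
#' single-cell `CV^2 ~ (beta/m)(1 + k (beta + m))` and
#' `skewness ~ 2 sqrt(beta/m) (1 + (k/2)(beta + m))`; the population
#' statistics relate to their single-cell counterparts as
#' `mean x (1 - k beta)`, `CV^2 x (1 + k beta)`, `skewness x (1 + k beta / 2)`.
#' Valid for small `k`; accuracy degrades as `O(k^2)`.
#'
#' @param params A [burst_params()] object supplying `k`, `beta`, `gamma`.
#' @param fixed_mean The single-cell mean held fixed (via
#'   [burst_frequency_for_mean()]).
#' @return A tibble with one row per perspective: `perspective`, `mean`,
#'   `cv2`, `skewness`.
#' @examples
#' p <- burst_params(lambda = 1, beta = 10, gamma = 1, k = 0.001)
#' weak_feedback_approx(p, fixed_mean = 100)
#' @export
weak_feedback_approx <- function(params, fixed_mean) {
  stopifnot(inherits(params, "burst_params"), fixed_mean > 0)
  k <- params$k
  beta <- params$beta
  m <- fixed_mean
  cv2_sc <- (beta / m) * (1 + k * (beta + m))
  skew_sc <- 2 * sqrt(beta / m) * (1 + (k / 2) * (beta + m))
  tibble::tibble(
    perspective = c("single_cell", "population"),
    mean = c(m, m * (1 - k * beta)),
    cv2 = c(cv2_sc, cv2_sc * (1 + k * beta)),
    skewness = c(skew_sc, skew_sc * (1 + k * beta / 2))
  )
}

#' Strong-feedback limit of the single-cell statistics
#'
#' As the feedback strength grows without bound while the single-cell mean is
#' held fixed at `m` (burst frequency adjusted via
#' [burst_frequency_for_mean()]), the single-cell noise and skewness converge
#' to finite limits: `CV^2 -> 1 + 2 beta / m` and, with
#' `b = beta / (m + beta)`, `skewness -> 2 (1 - b^3) / (1 - b^2)^(3/2)`.
#' The corresponding population statistics are unbounded: they diverge as
#' `k -> Inf` because the population mean is dragged to zero by
#' fast-proliferating low-concentration cells.
#'
#' @param mean_sc Fixed single-cell stationary mean, > 0.
#' @param beta Mean burst size, > 0.
#' @return A tibble with `perspective = "single_cell"`, the limiting `cv2`
#'   and `skewness`, and a logical `population_diverges` column.
#' @examples
#' strong_feedback_limit(100, 10) # cv2 limit 1.2
#' @export
strong_feedback_limit <- function(mean_sc, beta) {
  stopifnot(mean_sc > 0, beta > 0)
  b <- beta / (mean_sc + beta)
  tibble::tibble(
    perspective = "single_cell",
    cv2 = 1 + 2 * beta / mean_sc,
    skewness = 2 * (1 - b^3) / (1 - b^2)^1.5,
    population_diverges = TRUE
  )
}

#' Predicted single-cell noise from partitioning and bursting
#'
#' Closed-form steady-state squared coefficient of variation of the
#' single-cell concentration in the partitioning model with constant dilution
#' `gamma` and cycle mean calibrated so the population doubles every
#' `ln(2)/gamma`:
#' \deqn{CV^2_x = \frac{1}{\bar x}\left(\frac{\varepsilon}{2\ln 2} + \beta\right),}
#' the sum of a partitioning-noise contribution (invariant to the cell-cycle
#' time distribution) and a transcriptional-bursting contribution. `beta = 0`
#' recovers the deterministic-synthesis case.
#'
#' @param mean Steady-state mean concentration, > 0.
#' @param epsilon Partitioning-noise magnitude, >= 0.
#' @param beta Mean burst size contribution, >= 0 (0 for deterministic
#'   synthesis).
#' @return The predicted `CV^2`.
#' @examples
#' predicted_partition_cv2(20, 1, 0) # 1/(40 log(2))
#' predicted_partition_cv2(20, 1, 5)
#' @export
predicted_partition_cv2 <- function(mean, epsilon, beta = 0) {
  stopifnot(mean > 0, epsilon >= 0, beta >= 0)
  (epsilon / (2 * log(2)) + beta) / mean
}

#' Tidy a stationary law
#'
#' `tidy()` returns the law's defining quantities (shape exponent, tilt rate,
#' mixture weights, normalization prefactor) as a term/estimate tibble;
#' `glance()` returns a one-row summary with the exact stationary moments.
#'
#' @param x A [stationary_law()] object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.stationary_law <- function(x, ...) {
  tibble::tibble(
    term = c("shape", "tilt_rate", "weight_shape", "weight_shape_plus_1",
             "norm_const"),
    estimate = c(x$shape, x$tilt, x$weights[1], x$weights[2], x$norm_const)
  )
}

#' @rdname tidy.stationary_law
#' @export
glance.stationary_law <- function(x, ...) {
  mom <- stationary_moments(x$params, x$perspective)
  tibble::tibble(
    perspective = x$perspective,
    mean = mom$mean, cv2 = mom$cv2, skewness = mom$skewness,
    shape = x$shape, tilt = x$tilt
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
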