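#' Existence of the stationary concentration distribution
#'
#' Classifies a parameter set by which perspectives admit a stationary
#' protein-concentration distribution. The single-cell (lineage) law requires
#' a positive tilt rate `eta = 1/beta - lambda k / gamma`, i.e.
#' `lambda k beta / gamma < 1`: the mean synthesis rate `lambda beta` must stay
#' below the maximum rate of concentration decrease `gamma / k`. The
#' population law requires `rho = 1/beta - k xi > 0` with
#' `xi = (lambda/gamma) / (k beta + 1)`, i.e. `(lambda/gamma - 1) k beta < 1`
#' -- a strictly weaker condition, because slow-growing high-concentration
#' cells are demographically suppressed in the population. The single-cell
#' region is therefore nested inside the population region, and no parameter
#' set is ever single-cell-only.
#'
#' @param params A [burst_params()] object.
#' @return One of `"both"`, `"population_only"`, `"neither"`.
#' @examples
#' existence_status(burst_params(0.9, 10, 1, k = 5))   # "both"-or-more
#' existence_status(burst_params(2, 10, 1, k = 0.2))   # "neither"
#' @export
existence_status <- function(params) {
  stopifnot(inherits(params, "burst_params"))
  sc <- params$lambda * params$k * params$beta / params$gamma < 1
  pop <- (params$lambda / params$gamma - 1) * params$k * params$beta < 1
  if (sc) "both" else if (pop) "population_only" else "neither"
}

#' Exact stationary concentration law
#'
#' Constructs the exact stationary protein-concentration distribution of the
#' burst-dilution feedback model in either perspective. Both laws share the
#' functional form
#' \deqn{p(x) = (1 + k x)\, \beta s^2 / \Gamma(a)\; e^{-s x} (s x)^{a - 1},}
#' with shape `a = lambda/gamma` and tilt `s = eta = 1/beta - lambda k/gamma`
#' in the single-cell perspective, and shape `a = xi = (lambda/gamma)/(k beta + 1)`
#' with tilt `s = rho = 1/beta - k xi` in the population perspective. Because
#' `s + k a = 1/beta` in both cases, the law is exactly the two-component
#' gamma mixture `w1 Gamma(a, s) + w2 Gamma(a + 1, s)` with weights
#' `w1 = beta s`, `w2 = beta k a`, which the density, distribution, quantile
#' and sampling helpers exploit. At `k = 0` both perspectives collapse to a
#' gamma law with shape `lambda/gamma` and scale `beta`.
#'
#' @param params A [burst_params()] object.
#' @param perspective `"single_cell"` or `"population"`.
#' @return An object of class `"stationary_law"` with fields `perspective`,
#'   `shape`, `tilt`, `weights` (mixture weights), `norm_const` (the density
#'   prefactor `beta * tilt^2 / Gamma(shape)`), and `params`.
#' @examples
#' p <- burst_params(lambda = 100 / 21, beta = 10, gamma = 1, k = 0.01)
#' law <- stationary_law(p, "single_cell")
#' integrate(dstationary, 0, Inf, law = law)$value # 1
#' @export
stationary_law <- function(params,
                           perspective = c("single_cell", "population")) {
  perspective <- match.arg(perspective)
  stopifnot(inherits(params, "burst_params"))
  if (params$lambda <= 0) {
    stop("no stationary distribution: burst frequency `lambda` must be ",
         "positive (the law degenerates to a point mass at 0)")
  }
  z <- params$lambda / params$gamma
  if (perspective == "single_cell") {
    shape <- z
    tilt <- 1 / params$beta - params$lambda * params$k / params$gamma
    if (tilt <= 0) {
      stop("no stationary single-cell distribution: the tilt rate ",
           "eta = 1/beta - lambda*k/gamma = ", signif(tilt, 4),
           " is not positive (requires lambda*k*beta/gamma < 1)")
    }
  } else {
    shape <- z / (params$k * params$beta + 1)
    tilt <- 1 / params$beta - params$k * shape
    if (tilt <= 0) {
      stop("no stationary population distribution: the tilt rate ",
           "rho = 1/beta - k*xi = ", signif(tilt, 4),
           " is not positive (requires (lambda/gamma - 1)*k*beta < 1)")
    }
  }
  w1 <- params$beta * tilt
  structure(
    list(perspective = perspective, shape = shape, tilt = tilt,
         weights = c(w1, 1 - w1),
         norm_const = params$beta * tilt^2 / gamma(shape),
         params = params),
    class = "stationary_law"
  )
}

#' @export
print.stationary_law <- function(x, ...) {
  cat(sprintf("<stationary_law> %s perspective\n", x$perspective))
  cat(sprintf("  shape = %g, tilt rate = %g\n", x$shape, x$tilt))
  cat(sprintf("  gamma-mixture weights: %.4g (shape), %.4g (shape + 1)\n",
              x$weights[1], x$weights[2]))
  invisible(x)
}

#' Density, distribution, quantile and random generation for a stationary law
#'
#' `dstationary()` evaluates the exact stationary density directly from its
#' closed form (on the log scale for stability); `pstationary()`,
#' `qstationary()` and `rstationary()` use the equivalent two-component gamma
#' mixture representation.
#'
#' @param x,q Concentration(s), >= 0.
#' @param p Probabilities.
#' @param n Number of draws.
#' @param law A [stationary_law()] object.
#' @param log Return the log density?
#' @return Numeric vector.
#' @export
dstationary <- function(x, law, log = FALSE) {
  stopifnot(inherits(law, "stationary_law"))
  a <- law$shape
  s <- law$tilt
  k <- law$params$k
  beta <- law$params$beta
  out <- rep(-Inf, length(x))
  pos <- !is.na(x) & x > 0
  out[pos] <- log1p(k * x[pos]) + log(beta) + 2 * log(s) - lgamma(a) -
    s * x[pos] + (a - 1) * (log(s) + log(x[pos]))
  zero <- !is.na(x) & x == 0
  if (any(zero)) {
    out[zero] <- if (a > 1) -Inf else if (a == 1) log(beta) + 2 * log(s) else Inf
  }
  out[is.na(x)] <- NA_real_
  if (log) out else exp(out)
}

#' @rdname dstationary
#' @export
pstationary <- function(q, law) {
  stopifnot(inherits(law, "stationary_law"))
  law$weights[1] * stats::pgamma(q, shape = law$shape, rate = law$tilt) +
    law$weights[2] * stats::pgamma(q, shape = law$shape + 1, rate = law$tilt)
}

#' @rdname dstationary
#' @export
qstationary <- function(p, law) {
  stopifnot(inherits(law, "stationary_law"))
  vapply(p, function(pp) {
    if (is.na(pp)) return(NA_real_)
    if (pp <= 0) return(0)
    if (pp >= 1) return(Inf)
    hi <- stats::qgamma(pp, shape = law$shape + 1, rate = law$tilt) + 1
    while (pstationary(hi, law) < pp) hi <- hi * 2
    stats::uniroot(function(x) pstationary(x, law) - pp, c(0, hi),
                   tol = 1e-12)$root
  }, numeric(1))
}

#' @rdname dstationary
#' @export
rstationary <- function(n, law) {
  stopifnot(inherits(law, "stationary_law"))
  comp <- stats::runif(n) < law$weights[2]
  stats::rgamma(n, shape = law$shape + comp, rate = law$tilt)
}
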