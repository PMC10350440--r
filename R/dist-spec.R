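#' Supported distribution families
#'
#' Continuous families (`lognormal`, `normal`, `gamma`, `weibull`) are judged
#' by the Anderson-Darling statistic; discrete families (`poisson`,
#' `negative_binomial`) by the chi-square statistic.
#'
#' @format Character vectors.
#' @name dist-families
NULL

#' @rdname dist-families
#' @export
DIST_FAMILIES <- c("lognormal", "normal", "gamma", "weibull",
                   "poisson", "negative_binomial")

#' @rdname dist-families
#' @export
DISCRETE_FAMILIES <- c("poisson", "negative_binomial")

.param_names <- list(
  lognormal = c("meanlog", "sdlog"),
  normal = c("mean", "sd"),
  gamma = c("shape", "rate"),
  weibull = c("shape", "scale"),
  poisson = "lambda",
  negative_binomial = c("size", "mu")
)

#' Distribution specification
#'
#' A `dist_spec` describes one stochastic model input: a parametric family,
#' an optional location shift, and an optional exact-zero atom (`zero_mass`)
#' used to represent non-detects.  A draw equals 0 with probability
#' `zero_mass`, and `location + Y` otherwise, where `Y` follows the stated
#' family.
#'
#' @param family One of [DIST_FAMILIES].
#' @param params Named numeric vector of family parameters
#'   (`lognormal`: meanlog, sdlog; `normal`: mean, sd; `gamma`: shape, rate;
#'   `weibull`: shape, scale; `poisson`: lambda;
#'   `negative_binomial`: size, mu).
#' @param location Non-negative shift added to the continuous part.
#' @param zero_mass Probability in `[0, 1)` of an exact zero.
#' @return An object of class `dist_spec`.
#' @export
#' @examples
#' sp <- dist_spec("lognormal", c(meanlog = 0, sdlog = 1))
#' dist_mean(sp)  # exp(1/2)
dist_spec <- function(family, params, location = 0, zero_mass = 0) {
  family <- match.arg(family, DIST_FAMILIES)
  wanted <- .param_names[[family]]
  if (is.null(names(params)) && length(params) == length(wanted))
    names(params) <- wanted
  if (!all(wanted %in% names(params)))
    stop("family '", family, "' needs parameters: ",
         paste(wanted, collapse = ", "), call. = FALSE)
  params <- params[wanted]
  if (anyNA(params) || any(!is.finite(params)))
    stop("non-finite distribution parameters", call. = FALSE)
  ok <- switch(family,
    lognormal = params[["sdlog"]] >= 0,
    normal = params[["sd"]] >= 0,
    gamma = all(params > 0),
    weibull = all(params > 0),
    poisson = params[["lambda"]] > 0,
    negative_binomial = all(params > 0))
  if (!ok) stop("invalid parameters for family '", family, "'", call. = FALSE)
  if (location < 0) stop("location must be >= 0", call. = FALSE)
  if (zero_mass < 0 || zero_mass >= 1)
    stop("zero_mass must lie in [0, 1)", call. = FALSE)
  structure(list(family = family, params = params,
                 location = location, zero_mass = zero_mass),
            class = "dist_spec")
}

#' @export
print.dist_spec <- function(x, ...) {
  cat("<dist_spec> ", x$family, "(",
      paste(sprintf("%s=%.6g", names(x$params), x$params), collapse = ", "),
      ")", sep = "")
  if (x$location != 0) cat(" + location", format(x$location))
  if (x$zero_mass > 0) cat(" | zero_mass", format(x$zero_mass))
  cat("\n")
  invisible(x)
}

#' @rdname dist_spec
#' @param spec A `dist_spec`.
#' @export
dist_is_discrete <- function(spec) spec$family %in% DISCRETE_FAMILIES

.cont_moments <- function(spec) {
  p <- spec$params
  switch(spec$family,
    lognormal = {
      m <- exp(p[["meanlog"]] + p[["sdlog"]]^2 / 2)
      v <- (exp(p[["sdlog"]]^2) - 1) * m^2
      c(m, v)
    },
    normal = c(p[["mean"]], p[["sd"]]^2),
    gamma = c(p[["shape"]] / p[["rate"]], p[["shape"]] / p[["rate"]]^2),
    weibull = {
      m <- p[["scale"]] * gamma(1 + 1 / p[["shape"]])
      v <- p[["scale"]]^2 * gamma(1 + 2 / p[["shape"]]) - m^2
      c(m, v)
    },
    poisson = c(p[["lambda"]], p[["lambda"]]),
    negative_binomial = c(p[["mu"]], p[["mu"]] + p[["mu"]]^2 / p[["size"]]))
}

#' Analytic moments of a `dist_spec`
#'
#' Moments account for the location shift and the zero atom.
#'
#' @param spec A `dist_spec`.
#' @return `dist_mean`/`dist_sd` return a single number.
#' @export
dist_mean <- function(spec) {
  mv <- .cont_moments(spec)
  (1 - spec$zero_mass) * (spec$location + mv[1])
}

#' @rdname dist_mean
#' @export
dist_sd <- function(spec) {
  mv <- .cont_moments(spec)
  m1 <- spec$location + mv[1]
  ex2 <- (1 - spec$zero_mass) * (mv[2] + m1^2)
  sqrt(max(ex2 - dist_mean(spec)^2, 0))
}

.cont_fun <- function(spec, what) {
  p <- spec$params
  switch(spec$family,
    lognormal = switch(what,
      d = function(x) stats::dlnorm(x, p[["meanlog"]], p[["sdlog"]]),
      p = function(x) stats::plnorm(x, p[["meanlog"]], p[["sdlog"]]),
      q = function(u) stats::qlnorm(u, p[["meanlog"]], p[["sdlog"]]),
      r = function(n) stats::rlnorm(n, p[["meanlog"]], p[["sdlog"]])),
    normal = switch(what,
      d = function(x) stats::dnorm(x, p[["mean"]], p[["sd"]]),
      p = function(x) stats::pnorm(x, p[["mean"]], p[["sd"]]),
      q = function(u) stats::qnorm(u, p[["mean"]], p[["sd"]]),
      r = function(n) stats::rnorm(n, p[["mean"]], p[["sd"]])),
    gamma = switch(what,
      d = function(x) stats::dgamma(x, p[["shape"]], p[["rate"]]),
      p = function(x) stats::pgamma(x, p[["shape"]], p[["rate"]]),
      q = function(u) stats::qgamma(u, p[["shape"]], p[["rate"]]),
      r = function(n) stats::rgamma(n, p[["shape"]], p[["rate"]])),
    weibull = switch(what,
      d = function(x) stats::dweibull(x, p[["shape"]], p[["scale"]]),
      p = function(x) stats::pweibull(x, p[["shape"]], p[["scale"]]),
      q = function(u) stats::qweibull(u, p[["shape"]], p[["scale"]]),
      r = function(n) stats::rweibull(n, p[["shape"]], p[["scale"]])),
    poisson = switch(what,
      d = function(x) stats::dpois(x, p[["lambda"]]),
      p = function(x) stats::ppois(x, p[["lambda"]]),
      q = function(u) stats::qpois(u, p[["lambda"]]),
      r = function(n) stats::rpois(n, p[["lambda"]])),
    negative_binomial = switch(what,
      d = function(x) stats::dnbinom(x, size = p[["size"]], mu = p[["mu"]]),
      p = function(x) stats::pnbinom(x, size = p[["size"]], mu = p[["mu"]]),
      q = function(u) stats::qnbinom(u, size = p[["size"]], mu = p[["mu"]]),
      r = function(n) stats::rnbinom(n, size = p[["size"]], mu = p[["mu"]])))
}

#' Distribution functions of a `dist_spec`
#'
#' `dist_cdf` is the CDF of the full mixture (zero atom included),
#' `dist_quantile` its generalised inverse, `dist_pmf` the probability mass
#' of a discrete family (continuous part only), and `dist_sample` draws
#' `n` values using R's RNG stream.
#'
#' @param spec A `dist_spec`.
#' @param x,q Numeric vector of evaluation points / probabilities.
#' @param n Number of draws.
#' @export
dist_cdf <- function(spec, x) {
  f <- .cont_fun(spec, "p")
  cont <- f(x - spec$location)
  # the zero atom sits at 0; the continuous part may extend below it
  spec$zero_mass * (x >= 0) + (1 - spec$zero_mass) * cont
}

#' @rdname dist_cdf
#' @export
dist_quantile <- function(spec, q) {
  stopifnot(all(q >= 0 & q <= 1))
  f <- .cont_fun(spec, "q")
  out <- ifelse(q <= spec$zero_mass, 0,
                spec$location +
                  f(pmax((q - spec$zero_mass) / (1 - spec$zero_mass), 0)))
  out
}

#' @rdname dist_cdf
#' @export
dist_pmf <- function(spec, x) {
  if (!dist_is_discrete(spec))
    stop("dist_pmf is defined for discrete families only", call. = FALSE)
  f <- .cont_fun(spec, "d")
  f(x - spec$location)
}

#' @rdname dist_cdf
#' @export
dist_sample <- function(spec, n) {
  stopifnot(n >= 0)
  r <- .cont_fun(spec, "r")
  out <- spec$location + r(n)
  if (spec$zero_mass > 0) {
    zero <- stats::runif(n) < spec$zero_mass
    out[zero] <- 0
  }
  out
}

#' Lognormal specification from arithmetic moments
#'
#' Inverts the lognormal moment equations: given a target arithmetic mean
#' \eqn{m > 0} and SD \eqn{s \ge 0}, returns the `dist_spec` with
#' \eqn{\sigma^2 = \log(1 + (s/m)^2)} and
#' \eqn{\mu = \log(m) - \sigma^2 / 2}, whose analytic mean and SD equal the
#' inputs exactly.  This is the convention used to report fitted output
#' distributions (location 0, arithmetic mean and SD).
#'
#' @param mean Target arithmetic mean, > 0.
#' @param sd Target arithmetic SD, >= 0 (0 gives the degenerate limit
#'   `sdlog = 0`).
#' @param location Optional shift, kept out of the moment matching.
#' @param zero_mass Optional exact-zero atom; when > 0 the *positive part*
#'   is matched to `mean`/`sd`.
#' @return A lognormal `dist_spec`.
#' @export
#' @examples
#' sp <- lognormal_from_moments(1.14, 1.12)
#' c(dist_mean(sp), dist_sd(sp))
lognormal_from_moments <- function(mean, sd, location = 0, zero_mass = 0) {
  if (!is.finite(mean) || mean <= 0)
    stop("mean must be a positive number", call. = FALSE)
  if (!is.finite(sd) || sd < 0)
    stop("sd must be non-negative", call. = FALSE)
  s2 <- log(1 + (sd / mean)^2)
  mu <- log(mean) - s2 / 2
  dist_spec("lognormal", c(meanlog = mu, sdlog = sqrt(s2)),
            location = location, zero_mass = zero_mass)
}
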