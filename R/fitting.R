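#' Maximum-likelihood fit of one family to the positive part of a sample
#'
#' Zeros are removed before fitting (they are modelled as a separate point
#' mass, see [select_best_fit]).  Discrete families are fitted to the
#' rounded values.  Closed forms are used where they exist (lognormal,
#' normal, Poisson); gamma, Weibull and negative-binomial use profile
#' likelihood with a one-dimensional numeric search.
#'
#' @param samples Numeric vector; positive values are used.
#' @param family One of [DIST_FAMILIES].
#' @return A `dist_spec` for the positive part (zero_mass = 0).
#' @keywords internal
fit_family_mle <- function(samples, family) {
  family <- match.arg(family, DIST_FAMILIES)
  x <- samples[samples > 0]
  if (length(x) < 2)
    stop("need at least two positive samples to fit '", family, "'",
         call. = FALSE)
  if (family %in% DISCRETE_FAMILIES) x <- round(x)
  m <- mean(x)
  switch(family,
    lognormal = {
      lx <- log(x)
      mu <- mean(lx)
      sig <- sqrt(mean((lx - mu)^2))
      dist_spec("lognormal", c(meanlog = mu, sdlog = max(sig, 1e-12)))
    },
    normal = dist_spec("normal",
                       c(mean = m, sd = max(sqrt(mean((x - m)^2)), 1e-12))),
    gamma = {
      # profile out the rate: rate = shape / mean
      nll <- function(ls) {
        a <- exp(ls)
        -sum(stats::dgamma(x, shape = a, rate = a / m, log = TRUE))
      }
      opt <- stats::optimize(nll, c(-7, 12))
      a <- exp(opt$minimum)
      dist_spec("gamma", c(shape = a, rate = a / m))
    },
    weibull = {
      nll <- function(lk) {
        k <- exp(lk)
        sc <- mean(x^k)^(1 / k)  # profile MLE of scale
        -sum(stats::dweibull(x, shape = k, scale = sc, log = TRUE))
      }
      opt <- stats::optimize(nll, c(-5, 6))
      k <- exp(opt$minimum)
      dist_spec("weibull", c(shape = k, scale = mean(x^k)^(1 / k)))
    },
    poisson = dist_spec("poisson", c(lambda = m)),
    negative_binomial = {
      v <- stats::var(x)
      size0 <- if (v > m) m^2 / (v - m) else 100
      nll <- function(lsz) {
        -sum(stats::dnbinom(x, size = exp(lsz), mu = m, log = TRUE))
      }
      opt <- stats::optimize(nll, log(size0) + c(-6, 6))
      dist_spec("negative_binomial", c(size = exp(opt$minimum), mu = m))
    })
}

#' Anderson-Darling statistic
#'
#' \deqn{A^2 = -n - \frac{1}{n}\sum_{i=1}^{n}(2i-1)\,[\log F(x_{(i)}) +
#'   \log(1 - F(x_{(n+1-i)}))]}
#' evaluated against the CDF of a fully specified continuous `dist_spec`.
#' Samples are sorted internally.  A CDF value of exactly 0 or 1 at a
#' sample means the fit is degenerate and is an error.
#'
#' @param samples Numeric vector, n >= 1.
#' @param spec A continuous `dist_spec` with `zero_mass = 0`.
#' @return The non-negative statistic (lower = better fit).
#' @export
#' @examples
#' sp <- dist_spec("normal", c(mean = 0, sd = 1))
#' anderson_darling_statistic(0, sp)  # -1 - 2*log(0.5) = 0.3863
anderson_darling_statistic <- function(samples, spec) {
  if (dist_is_discrete(spec) || spec$zero_mass > 0)
    stop("Anderson-Darling requires a continuous spec without a zero atom",
         call. = FALSE)
  n <- length(samples)
  if (n < 1) stop("need at least one sample", call. = FALSE)
  x <- sort(samples)
  u <- dist_cdf(spec, x)
  if (any(u <= 0 | u >= 1))
    stop("degenerate fit: CDF value of 0 or 1 at a sample", call. = FALSE)
  i <- seq_len(n)
  a2 <- -n - mean((2 * i - 1) * (log(u) + log(1 - rev(u))))
  a2
}

.sturges_bins <- function(n) max(2L, ceiling(log2(n)) + 1L)

#' Chi-square goodness-of-fit statistic
#'
#' \eqn{\sum (O_b - E_b)^2 / E_b} over bins.  For discrete families the
#' bins are integer values between the observed extremes with open tails
#' (tail mass from the CDF); bins are merged inwards from both tails until
#' every expected count is at least `min_expected` (or only two bins
#' remain).  For continuous specs, equal-probability bins are used with the
#' bin count given by Sturges' rule.
#'
#' @param samples Numeric vector, length >= 5 x number of bins is
#'   recommended.
#' @param spec A `dist_spec`.
#' @param bins Optional bin count override for the continuous case.
#' @param min_expected Minimum expected count per bin before tail merging
#'   stops (default 5).
#' @return The non-negative statistic.
#' @export
chi_square_statistic <- function(samples, spec, bins = NULL,
                                 min_expected = 5) {
  n <- length(samples)
  if (n < 5) stop("need at least five samples", call. = FALSE)
  if (dist_is_discrete(spec)) {
    x <- round(samples)
    lo <- min(x); hi <- max(x)
    vals <- lo:hi
    obs <- tabulate(x - lo + 1L, nbins = length(vals))
    expd <- n * dist_pmf(spec, vals)
    # open tails: fold the mass outside [lo, hi] into the edge bins
    expd[1] <- expd[1] + n * dist_cdf(spec, lo - 1L)
    expd[length(expd)] <- expd[length(expd)] +
      n * (1 - dist_cdf(spec, hi))
    # merge inwards from both tails until expectations are large enough
    while (length(expd) > 2 &&
           (expd[1] < min_expected || expd[length(expd)] < min_expected)) {
      if (expd[1] <= expd[length(expd)]) {
        expd[2] <- expd[2] + expd[1]; obs[2] <- obs[2] + obs[1]
        expd <- expd[-1]; obs <- obs[-1]
      } else {
        k <- length(expd)
        expd[k - 1] <- expd[k - 1] + expd[k]; obs[k - 1] <- obs[k - 1] + obs[k]
        expd <- expd[-k]; obs <- obs[-k]
      }
    }
    if (any(expd <= 0))
      stop("empty bin expectation even after merging", call. = FALSE)
    return(sum((obs - expd)^2 / expd))
  }
  k <- if (is.null(bins)) .sturges_bins(n) else as.integer(bins)
  if (k < 2) stop("need at least two bins", call. = FALSE)
  breaks <- dist_quantile(spec, seq(0, 1, length.out = k + 1))
  breaks[1] <- -Inf; breaks[k + 1] <- Inf
  breaks <- unique(breaks)
  if (length(breaks) < 3)
    stop("degenerate spec: could not form bins", call. = FALSE)
  obs <- as.vector(table(cut(samples, breaks)))
  p <- diff(dist_cdf(spec, breaks))
  p[1] <- dist_cdf(spec, breaks[2])       # left tail closed at -Inf
  p[length(p)] <- 1 - dist_cdf(spec, breaks[length(breaks) - 1])
  expd <- n * p
  if (any(expd <= 0))
    stop("empty bin expectation even after merging", call. = FALSE)
  sum((obs - expd)^2 / expd)
}

#' Select the best-fitting family for a sample
#'
#' Fits each candidate family by maximum likelihood to the positive part of
#' the sample (the observed zero fraction becomes the spec's `zero_mass`),
#' scores continuous candidates with the Anderson-Darling statistic and
#' discrete candidates with the chi-square statistic, and returns the
#' candidate with the smallest statistic.  Ties are broken by candidate
#' order.  Only the relative ranking of statistics is used; no p-values are
#' computed.
#'
#' @param samples Numeric vector, n >= 5.
#' @param candidates Character vector of families from [DIST_FAMILIES].
#' @return A `fit_result` list: `spec` (with `zero_mass` set), `family`,
#'   `statistic`, `test` (`"anderson_darling"` or `"chi_square"`).
#' @export
#' @examples
#' set.seed(1)
#' x <- rlnorm(200)
#' select_best_fit(x, c("normal", "lognormal"))$family
select_best_fit <- function(samples, candidates) {
  if (length(candidates) == 0)
    stop("need at least one candidate family", call. = FALSE)
  if (length(samples) < 5)
    stop("need at least five samples", call. = FALSE)
  zero_frac <- mean(samples == 0)
  pos <- samples[samples > 0]
  results <- list()
  for (fam in candidates) {
    res <- tryCatch({
      spec <- fit_family_mle(samples, fam)
      if (fam %in% DISCRETE_FAMILIES) {
        stat <- chi_square_statistic(pos, spec)
        test <- "chi_square"
      } else {
        stat <- anderson_darling_statistic(pos, spec)
        test <- "anderson_darling"
      }
      spec$zero_mass <- zero_frac
      list(spec = spec, family = fam, statistic = stat, test = test)
    }, error = function(e) NULL)
    if (!is.null(res)) results[[length(results) + 1]] <- res
  }
  if (length(results) == 0)
    stop("all candidate fits are degenerate", call. = FALSE)
  stats <- vapply(results, `[[`, numeric(1), "statistic")
  best <- results[[which.min(stats)]]  # which.min keeps first on ties
  structure(best, class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> family:", x$family,
      sprintf(" %s statistic: %.5g\n", x$test, x$statistic))
  print(x$spec)
  invisible(x)
}

#' Write a table of fit results to CSV
#'
#' One row per variable: family, JSON-encoded parameter vector, location,
#' zero mass, test name and statistic.
#'
#' @param fits Named list of `fit_result` objects.
#' @param path Output CSV path.
#' @return The data frame, invisibly.
#' @export
write_fits_csv <- function(fits, path) {
  df <- do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    data.frame(variable = nm, family = f$family,
               params = as.character(jsonlite::toJSON(as.list(f$spec$params),
                                                      auto_unbox = TRUE,
                                                      digits = NA)),
               location = f$spec$location, zero_mass = f$spec$zero_mass,
               test = f$test, statistic = f$statistic,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
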