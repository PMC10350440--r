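test_that("lognormal_from_moments inverts the moment equations", {
  # closed-form inversion, checked against moments of 1e6 draws during
  # development: mu = -0.2068, sigma = 0.8219
  sp <- lognormal_from_moments(1.14, 1.12)
  expect_equal(unname(sp$params[["meanlog"]]), -0.2068, tolerance = 1e-3)
  expect_equal(unname(sp$params[["sdlog"]]), 0.8219, tolerance = 1e-3)
  # analytic moments reproduce the requested values exactly
  set.seed(3)
  for (i in 1:25) {
    m <- runif(1, 1e-4, 50); s <- runif(1, 0, 3 * m)
    sp <- lognormal_from_moments(m, s)
    expect_equal(dist_mean(sp), m, tolerance = 1e-12)
    expect_equal(dist_sd(sp), s, tolerance = 1e-12)
  }
  # degenerate limit and round trip
  sp <- lognormal_from_moments(2, 1e-9)
  expect_equal(unname(sp$params[["meanlog"]]), log(2), tolerance = 1e-9)
  sp1 <- lognormal_from_moments(1.14, 1.12)
  sp2 <- lognormal_from_moments(dist_mean(sp1), dist_sd(sp1))
  expect_equal(sp2$params, sp1$params, tolerance = 1e-12)
  expect_error(lognormal_from_moments(0, 1), "positive")
})

test_that("dist_spec validates and its functions are consistent", {
  expect_error(dist_spec("lognormal", c(meanlog = 0, sdlog = -1)),
               "invalid parameters")
  expect_error(dist_spec("cauchy", c(0, 1)))
  expect_error(dist_spec("normal", c(mean = 0, sd = 1), zero_mass = 1),
               "zero_mass")
  sp <- dist_spec("lognormal", c(meanlog = 0, sdlog = 1), zero_mass = 0.3)
  # quantile is the inverse of the CDF above the zero atom
  for (q in c(0.31, 0.5, 0.9, 0.99)) {
    x <- dist_quantile(sp, q)
    expect_equal(dist_cdf(sp, x), q, tolerance = 1e-9)
  }
  expect_identical(dist_quantile(sp, 0.2), 0)  # inside the atom
  set.seed(1)
  x <- dist_sample(sp, 2e4)
  expect_equal(mean(x == 0), 0.3, tolerance = 0.03)
  expect_equal(mean(x), dist_mean(sp), tolerance = 0.05)
})

test_that("anderson_darling_statistic matches hand evaluation", {
  sp <- dist_spec("normal", c(mean = 0, sd = 1))
  # single sample at the median: -1 - (log .5 + log .5) = 2 log 2 - 1
  expect_equal(anderson_darling_statistic(0, sp), 2 * log(2) - 1,
               tolerance = 1e-12)
  # invariance under a strictly increasing transform (exp), i.e. rank/CDF
  set.seed(7)
  z <- rnorm(50)
  a_norm <- anderson_darling_statistic(z, sp)
  a_lnorm <- anderson_darling_statistic(exp(z),
    dist_spec("lognormal", c(meanlog = 0, sdlog = 1)))
  expect_equal(a_norm, a_lnorm, tolerance = 1e-10)
  # 100 equi-probable quantiles: near-perfect fit, and equal to the
  # direct-formula oracle
  u <- (seq_len(100) - 0.5) / 100
  x <- qnorm(u)
  a <- anderson_darling_statistic(x, sp)
  expect_lt(a, 0.05)
  expect_equal(a, brute_ad_from_u(pnorm(sort(x))), tolerance = 1e-10)
  expect_gte(a, 0)
  # degenerate fit: CDF hits 0/1
  tight <- dist_spec("normal", c(mean = 0, sd = 1e-300))
  expect_error(anderson_darling_statistic(c(-1, 1), tight), "degenerate")
})

test_that("chi_square_statistic matches direct arithmetic", {
  sp <- dist_spec("normal", c(mean = 0, sd = 1))
  # two equal-probability bins, observed {60, 40}: (10^2/50)*2 = 4
  x <- c(qnorm(seq(0.005, 0.495, length.out = 60)),
         qnorm(seq(0.505, 0.995, length.out = 40)))
  expect_equal(chi_square_statistic(x, sp, bins = 2), 4.0,
               tolerance = 1e-12)
  # observed equal to expected in every bin -> 0
  x <- qnorm((seq_len(64) - 0.5) / 64)
  expect_equal(chi_square_statistic(x, sp, bins = 4), 0, tolerance = 1e-12)
  expect_error(chi_square_statistic(1:3, sp), "five")
})

test_that("discrete chi_square matches an independent tabulation oracle", {
  set.seed(11)
  x <- rpois(97, 55)
  sp <- dist_spec("poisson", c(lambda = mean(x)))
  got <- chi_square_statistic(x, sp)
  # oracle: tabulate integer counts, fold open tails, merge the smaller
  # outer bin inwards until all expectations >= 5
  vals <- min(x):max(x)
  obs <- as.numeric(table(factor(x, levels = vals)))
  expd <- 97 * dpois(vals, mean(x))
  expd[1] <- expd[1] + 97 * ppois(min(x) - 1, mean(x))
  k <- length(vals)
  expd[k] <- expd[k] + 97 * (1 - ppois(max(x), mean(x)))
  while (length(expd) > 2 && (expd[1] < 5 || expd[length(expd)] < 5)) {
    if (expd[1] <= expd[length(expd)]) {
      expd[2] <- expd[2] + expd[1]; obs[2] <- obs[2] + obs[1]
      expd <- expd[-1]; obs <- obs[-1]
    } else {
      j <- length(expd)
      expd[j - 1] <- expd[j - 1] + expd[j]
      obs[j - 1] <- obs[j - 1] + obs[j]
      expd <- expd[-j]; obs <- obs[-j]
    }
  }
  expect_equal(got, sum((obs - expd)^2 / expd), tolerance = 1e-12)
})

test_that("select_best_fit ranks by statistic with stated tie-break", {
  set.seed(5)
  x <- rlnorm(500)
  best <- select_best_fit(x, c("normal", "lognormal"))
  expect_identical(best$family, "lognormal")
  expect_identical(best$test, "anderson_darling")
  # single candidate
  one <- select_best_fit(x, "gamma")
  expect_identical(one$family, "gamma")
  # exact tie -> first in input order (duplicate candidates tie exactly)
  tie <- select_best_fit(x, c("gamma", "gamma", "lognormal"))
  expect_identical(tie$family, "lognormal")  # still beats the tied pair
  expect_identical(select_best_fit(x, c("gamma", "weibull"))$family,
                   select_best_fit(x, c("gamma", "weibull", "gamma"))$family)
  # zero handling: observed zero fraction becomes the spec's zero atom
  xz <- c(x, rep(0, 125))
  bz <- select_best_fit(xz, c("lognormal", "normal"))
  expect_identical(bz$spec$zero_mass, mean(xz == 0))
})

test_that("select_best_fit prefers negative binomial on overdispersed counts", {
  set.seed(9)
  x <- rnbinom(500, size = 4, mu = 55)
  best <- select_best_fit(x, c("poisson", "negative_binomial"))
  expect_identical(best$family, "negative_binomial")
  expect_identical(best$test, "chi_square")
})

test_that("fitting 1e4 seeded lognormal draws recovers mu, sigma within 0.02", {
  set.seed(13)
  x <- rlnorm(1e4, meanlog = 0.5, sdlog = 0.8)
  fit <- fit_family_mle(x, "lognormal")
  expect_lt(abs(fit$params[["meanlog"]] - 0.5), 0.02)
  expect_lt(abs(fit$params[["sdlog"]] - 0.8), 0.02)
})

test_that("write_fits_csv round-trips the fit description", {
  set.seed(2)
  fits <- list(conc = select_best_fit(rlnorm(100), c("lognormal", "gamma")))
  path <- tempfile(fileext = ".csv")
  df <- write_fits_csv(fits, path)
  back <- read.csv(path)
  expect_identical(back$variable, "conc")
  expect_identical(back$family, fits$conc$family)
  p <- jsonlite::fromJSON(back$params)
  expect_equal(p$meanlog, unname(fits$conc$spec$params[["meanlog"]]),
               tolerance = 1e-12)
})
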