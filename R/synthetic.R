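#' Moments of an upper-truncated lognormal
#'
#' Closed-form mean and SD of `X | X <= upper` for
#' `X ~ Lognormal(meanlog, sdlog)`:
#' `E[X^k | X <= q] = exp(k mu + k^2 s^2 / 2) *
#'   Phi((log q - mu - k s^2)/s) / Phi((log q - mu)/s)`.
#'
#' @param meanlog,sdlog Log-scale parameters.
#' @param upper Truncation point, > 0 (`Inf` for no truncation).
#' @return `c(mean, sd)`.
#' @keywords internal
tlnorm_moments <- function(meanlog, sdlog, upper) {
  if (!is.finite(upper)) {
    m <- exp(meanlog + sdlog^2 / 2)
    return(c(m, m * sqrt(exp(sdlog^2) - 1)))
  }
  z <- (log(upper) - meanlog) / sdlog
  # log-scale ratio of normal CDFs: stable far into the tails
  lp0 <- stats::pnorm(z, log.p = TRUE)
  if (!is.finite(lp0)) return(c(upper, 0))  # essentially all mass truncated
  m1 <- exp(meanlog + sdlog^2 / 2 +
              stats::pnorm(z - sdlog, log.p = TRUE) - lp0)
  m2 <- exp(2 * meanlog + 2 * sdlog^2 +
              stats::pnorm(z - 2 * sdlog, log.p = TRUE) - lp0)
  c(m1, sqrt(max(m2 - m1^2, 0)))
}

#' Fit a truncated lognormal to target moments
#'
#' Finds `(meanlog, sdlog)` so that the lognormal truncated above at
#' `upper` has the requested mean and SD (least squares on relative moment
#' errors, started from the untruncated closed-form inversion).  Some
#' targets are infeasible on a bounded support — e.g. an SD close to the
#' theoretical maximum `sqrt(mean * (upper - mean))`.  The mean is
#' prioritised (its error is weighted 100x in the objective): if the mean
#' cannot be matched within `tol` a warning is raised; an SD shortfall is
#' reported silently through `sd_err` and left to the caller.
#'
#' @param mean,sd Target arithmetic moments of the truncated variable.
#' @param upper Upper support bound (> mean), or `Inf`.
#' @param tol Relative mean error above which a warning is raised.
#' @return List: `meanlog`, `sdlog`, `upper`, achieved `mean`, `sd`,
#'   `mean_err`, `sd_err`.
#' @keywords internal
match_truncated_lognormal <- function(mean, sd, upper, tol = 0.005) {
  if (mean <= 0) stop("mean must be > 0", call. = FALSE)
  if (sd < 0) stop("sd must be >= 0", call. = FALSE)
  if (is.finite(upper) && upper <= mean)
    stop("upper bound must exceed the target mean", call. = FALSE)
  if (sd == 0)
    return(list(meanlog = log(mean), sdlog = 0, upper = upper,
                mean = mean, sd = 0, mean_err = 0, sd_err = 0))
  s2 <- log(1 + (sd / mean)^2)
  start <- c(log(mean) - s2 / 2, log(sqrt(s2)))
  if (!is.finite(upper))
    return(list(meanlog = start[1], sdlog = exp(start[2]), upper = Inf,
                mean = mean, sd = sd, mean_err = 0, sd_err = 0))
  # two-stage: for a candidate sdlog, solve meanlog so the truncated mean
  # is exact (monotone in meanlog -> uniroot), then search sdlog for the
  # closest SD.  The mean is thereby pinned; the SD is best-effort.
  meanlog_for <- function(sdlog) {
    g <- function(ml) tlnorm_moments(ml, sdlog, upper)[1] - mean
    lo <- log(mean) - sdlog^2 / 2 - 5 * sdlog - 1
    # the truncated mean approaches `upper` only once ml - log(upper)
    # dominates sdlog^2, hence the quadratic head-room
    hi <- log(upper) + 3 * sdlog^2 + 10 * sdlog + 10
    stats::uniroot(g, c(lo, hi), tol = 1e-12)$root
  }
  sd_gap <- function(ls) {
    s <- exp(ls)
    tryCatch((tlnorm_moments(meanlog_for(s), s, upper)[2] / sd - 1)^2,
             error = function(e) 1e6)
  }
  opt <- stats::optimize(sd_gap, start[2] + c(-6, 3), tol = 1e-10)
  sdlog <- exp(opt$minimum)
  meanlog <- meanlog_for(sdlog)
  got <- tlnorm_moments(meanlog, sdlog, upper)
  mean_err <- abs(got[1] / mean - 1)
  sd_err <- abs(got[2] / sd - 1)
  if (mean_err > tol)
    warning(sprintf(paste0("truncated-lognormal mean match off by %.2g ",
                           "(targets mean=%.4g sd=%.4g on [0, %.4g] are ",
                           "infeasible)"), mean_err, mean, sd, upper),
            call. = FALSE)
  list(meanlog = meanlog, sdlog = sdlog, upper = upper,
       mean = got[1], sd = got[2], mean_err = mean_err, sd_err = sd_err)
}

#' Sample an upper-truncated lognormal by inverse CDF
#' @keywords internal
rtlnorm <- function(n, meanlog, sdlog, upper) {
  if (sdlog == 0) return(rep(exp(meanlog), n))
  pmax_u <- if (is.finite(upper))
    stats::plnorm(upper, meanlog, sdlog) else 1
  stats::qlnorm(stats::runif(n) * pmax_u, meanlog, sdlog)
}

#' Generator profile for the packaged survey
#'
#' Bundles the packaged concentration-summary and exposure tables into a
#' `generator_spec`: per-cell targets (mean, SD, max, n, assumed zero
#' fraction) and questionnaire targets (per-category DI/EF, resident
#' count, body-weight mean).  The assumed zero fraction defaults to 10%
#' for cells whose printed minimum is 0 (per-cell non-detect counts are
#' not published), 0 otherwise, and 1 for all-zero cells.
#'
#' @param residents Number of questionnaire records (default 97, the
#'   number of valid questionnaires in the survey).
#' @param cv Coefficient of variation assumed for DI and EF (default 0.3).
#' @param zero_fraction Assumed zero share for cells with minimum 0.
#' @return A `generator_spec` list: `concentrations` (with `zero_frac`
#'   column), `exposure`, `residents`, `cv`.
#' @export
ningxia_profile <- function(residents = 97, cv = 0.3, zero_fraction = 0.1) {
  tabs <- ningxia_tables()
  conc <- as.data.frame(tabs$concentrations)
  conc$zero_frac <- ifelse(conc$mean == 0, 1,
                           ifelse(conc$min == 0, zero_fraction, 0))
  structure(list(concentrations = conc, exposure = tabs$exposure,
                 residents = residents, cv = cv),
            class = "generator_spec")
}

#' Generate sample-level concentration measurements
#'
#' Emulates laboratory measurements for one (category, metal) cell: a
#' zero-inflated lognormal whose positive part is moment-matched *under
#' truncation at the cell's observed maximum*, so the overall sample mean
#' and SD approach the cell's targets while no value exceeds the recorded
#' maximum or falls below 0.
#'
#' @param profile A `generator_spec` (see [ningxia_profile]).
#' @param category,metal Cell to generate.
#' @param n Number of samples; default the cell's survey `n`.
#' @param seed Optional RNG seed for reproducibility.
#' @return Numeric vector of length `n` in `[0, max]`.
#' @export
#' @examples
#' x <- generate_concentration_samples(ningxia_profile(), "cereal", "Cr",
#'                                     seed = 1)
#' length(x)  # 59, the survey sample count
generate_concentration_samples <- function(profile, category, metal,
                                           n = NULL, seed = NULL) {
  stopifnot(inherits(profile, "generator_spec"))
  conc <- profile$concentrations
  row <- conc[conc$category == category & conc$metal == metal, , drop = FALSE]
  if (nrow(row) != 1)
    stop("no generator targets for (", category, ", ", metal, ")",
         call. = FALSE)
  if (is.null(n)) n <- row$n
  if (!is.null(seed)) set.seed(seed)
  if (row$mean == 0) return(numeric(n))
  zm <- row$zero_frac
  if (row$sd == 0) {
    if (zm > 0)
      stop("infeasible targets: sd 0 with a nonzero zero fraction and ",
           "nonzero mean", call. = FALSE)
    return(rep(row$mean, n))
  }
  pos <- .positive_part_moments(row$mean, row$sd, zm)
  if (is.null(pos))
    stop("infeasible targets: zero fraction ", zm,
         " implies non-positive variance for the positive part",
         call. = FALSE)
  fit <- match_truncated_lognormal(pos$mean, pos$sd, row$max)
  if (fit$sd_err > 0.05)
    warning("(", category, ", ", metal, "): target SD ", signif(pos$sd, 4),
            " is not attainable on [0, ", row$max, "]; generating with SD ",
            signif(fit$sd, 4), call. = FALSE)
  zero <- stats::runif(n) < zm
  out <- numeric(n)
  out[!zero] <- rtlnorm(sum(!zero), fit$meanlog, fit$sdlog, fit$upper)
  out
}

#' Generate questionnaire records
#'
#' Emulates the dietary survey: per resident, a body weight and a daily
#' intake (DI, g/day) and exposure frequency (EF, day/year) for every food
#' category.  DI is lognormal with the profile's target mean and CV; EF is
#' lognormal moment-matched under truncation at 365 (an EF target of 365 —
#' daily consumption — stays constant).  Body weight is drawn from a
#' discrete family: Poisson for `sex = "male"`, negative binomial for
#' `sex = "female"`, and pooled Poisson by default, with the profile's
#' target mean.
#'
#' @param profile A `generator_spec`.
#' @param n Number of residents (default the profile's 97).
#' @param seed Optional RNG seed.
#' @param sex `"pooled"` (default), `"male"` or `"female"`.
#' @param bw_size Negative-binomial size for the female fit.
#' @return Data frame: `resident`, `bw_kg`, then `di.<category>` and
#'   `ef.<category>` columns.
#' @export
generate_questionnaire <- function(profile, n = NULL, seed = NULL,
                                   sex = c("pooled", "male", "female"),
                                   bw_size = 45) {
  stopifnot(inherits(profile, "generator_spec"))
  sex <- match.arg(sex)
  if (is.null(n)) n <- profile$residents
  if (!is.null(seed)) set.seed(seed)
  exposure <- as.data.frame(profile$exposure)
  bw_mean <- exposure$bw[1]
  bw <- if (sex == "female")
    stats::rnbinom(n, size = bw_size, mu = bw_mean)
  else
    stats::rpois(n, bw_mean)
  out <- data.frame(resident = seq_len(n), bw_kg = bw)
  for (i in seq_len(nrow(exposure))) {
    frow <- exposure[i, ]
    cv <- profile$cv
    di <- if (cv > 0 && frow$di > 0) {
      sp <- lognormal_from_moments(frow$di, cv * frow$di)
      dist_sample(sp, n)
    } else rep(frow$di, n)
    ef <- if (frow$ef >= 365 || cv == 0 || frow$ef == 0) {
      rep(frow$ef, n)
    } else {
      fit <- match_truncated_lognormal(frow$ef, cv * frow$ef, 365)
      rtlnorm(n, fit$meanlog, fit$sdlog, fit$upper)
    }
    out[[paste0("di.", frow$category)]] <- di
    out[[paste0("ef.", frow$category)]] <- ef
  }
  out
}

#' Write synthetic datasets to disk
#'
#' Generates `samples.csv` (category, metal, sample_id, concentration) and
#' `questionnaire.csv` for a profile, reproducibly from a seed.
#'
#' @param profile A `generator_spec`.
#' @param out_dir Output directory (created if needed).
#' @param seed RNG seed.
#' @return Invisibly, the two file paths.
#' @export
write_synthetic_data <- function(profile, out_dir, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  conc <- profile$concentrations
  rows <- lapply(seq_len(nrow(conc)), function(i) {
    x <- generate_concentration_samples(profile, conc$category[i],
                                        conc$metal[i])
    data.frame(category = conc$category[i], metal = conc$metal[i],
               sample_id = seq_along(x), concentration = x,
               stringsAsFactors = FALSE)
  })
  samples <- do.call(rbind, rows)
  qn <- generate_questionnaire(profile)
  sp <- file.path(out_dir, "samples.csv")
  qp <- file.path(out_dir, "questionnaire.csv")
  utils::write.csv(samples, sp, row.names = FALSE)
  utils::write.csv(qn, qp, row.names = FALSE)
  invisible(c(samples = sp, questionnaire = qp))
}
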