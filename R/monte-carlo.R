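#' Simulation configuration
#'
#' @param iterations Number of Monte Carlo iterations (default 10000, the
#'   point at which the exposure distributions are stable).
#' @param seed Integer RNG seed; `NULL` leaves the RNG state alone.
#' @param coupling `"shared_person"` (default): each iteration is one
#'   simulated resident — a single body-weight draw is reused across all
#'   food categories.  `"independent"`: every stochastic symbol is drawn
#'   independently, including one body weight per category.
#' @param hi_threshold Hazard-index exceedance threshold (default 1).
#' @param r_threshold Carcinogenic-risk exceedance threshold
#'   (default 1e-4, the US EPA maximum acceptable level).
#' @param quantiles Quantile levels to report (default 10/50/90th).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(iterations = 10000, seed = NULL,
                              coupling = c("shared_person", "independent"),
                              hi_threshold = 1, r_threshold = 1e-4,
                              quantiles = c(0.1, 0.5, 0.9)) {
  coupling <- match.arg(coupling)
  if (iterations < 1) stop("iterations must be >= 1", call. = FALSE)
  if (hi_threshold <= 0 || r_threshold <= 0)
    stop("thresholds must be > 0", call. = FALSE)
  if (any(quantiles < 0 | quantiles > 1))
    stop("quantiles must lie in [0, 1]", call. = FALSE)
  structure(list(iterations = as.integer(iterations), seed = seed,
                 coupling = coupling, hi_threshold = hi_threshold,
                 r_threshold = r_threshold, quantiles = quantiles),
            class = "simulation_config")
}

#' Build input distribution specs from summary tables
#'
#' Translates a concentration-summary table and an exposure-factor table
#' into the named `dist_spec` set consumed by [sample_inputs] /
#' [run_simulation]:
#' * concentrations: zero-inflated lognormal, positive part moment-matched
#'   so the overall mean/SD equal the table's (cells whose minimum is 0 get
#'   `zero_mass`, default 10%; all-zero cells become a point mass at 0);
#' * daily intake: lognormal with the table mean and CV `cv_intake`;
#' * exposure frequency: lognormal with CV `cv_intake`, except EF = 365
#'   which is kept degenerate (daily consumption has no room to vary up);
#' * body weight: one pooled spec, Poisson by default with the table mean.
#'
#' Cells with SD 0 become point masses (degenerate normals).
#'
#' @param stats A [concentration_stats] table.
#' @param factors An [exposure_factors] table.
#' @param cv_intake Coefficient of variation for DI and EF (default 0.3).
#' @param zero_mass Zero fraction assumed for cells with a 0 minimum.
#' @param bw_family `"poisson"` (default), `"negative_binomial"`, or
#'   `"fixed"` (degenerate at the table mean, for point-mass checks).
#' @param bw_size Negative-binomial size when `bw_family` demands it.
#' @return Named list of `dist_spec`: `conc.<category>.<metal>`,
#'   `di.<category>`, `ef.<category>`, `bw`.
#' @export
input_specs_from_tables <- function(stats, factors, cv_intake = 0.3,
                                    zero_mass = 0.1,
                                    bw_family = c("poisson",
                                                  "negative_binomial",
                                                  "fixed"),
                                    bw_size = 45) {
  stats <- concentration_stats(as.data.frame(stats))
  factors <- exposure_factors(as.data.frame(factors))
  bw_family <- match.arg(bw_family)
  specs <- list()
  point_mass <- function(v) dist_spec("normal", c(mean = v, sd = 0))
  for (i in seq_len(nrow(stats))) {
    row <- stats[i, ]
    nm <- paste("conc", row$category, row$metal, sep = ".")
    specs[[nm]] <- if (row$mean == 0) {
      point_mass(0)
    } else if (row$sd == 0) {
      point_mass(row$mean)
    } else {
      zm <- if (row$min == 0) zero_mass else 0
      pos <- .positive_part_moments(row$mean, row$sd, zm)
      if (is.null(pos)) {
        pos <- list(mean = row$mean, sd = row$sd); zm <- 0
      }
      lognormal_from_moments(pos$mean, pos$sd, zero_mass = zm)
    }
  }
  for (i in seq_len(nrow(factors))) {
    frow <- factors[i, ]
    specs[[paste0("di.", frow$category)]] <-
      if (cv_intake > 0 && frow$di > 0)
        lognormal_from_moments(frow$di, cv_intake * frow$di)
      else point_mass(frow$di)
    specs[[paste0("ef.", frow$category)]] <-
      if (frow$ef >= 365 || cv_intake == 0 || frow$ef == 0)
        point_mass(frow$ef)
      else lognormal_from_moments(frow$ef, cv_intake * frow$ef)
  }
  bw <- factors$bw[1]
  specs$bw <- switch(bw_family,
    poisson = dist_spec("poisson", c(lambda = bw)),
    negative_binomial = dist_spec("negative_binomial",
                                  c(size = bw_size, mu = bw)),
    fixed = point_mass(bw))
  specs
}

# overall (mean, sd) with zero fraction zm -> moments of the positive part;
# NULL if the implied positive-part variance is not positive
.positive_part_moments <- function(mean, sd, zm) {
  if (zm == 0) return(list(mean = mean, sd = sd))
  mp <- mean / (1 - zm)
  vp <- (mean^2 + sd^2) / (1 - zm) - mp^2
  if (vp <= 0) return(NULL)
  list(mean = mp, sd = sqrt(vp))
}

#' Draw the Monte Carlo input matrices
#'
#' Draws `iterations` values for every required stochastic symbol.  The
#' required set is one concentration spec per (category, metal), one DI and
#' one EF spec per category, and one body-weight spec (`bw`).  Under
#' `shared_person` coupling the single body-weight column is reused for
#' every category; under `independent` coupling a separate body-weight
#' column is drawn per category.  Given the same `(seed, iterations)` the
#' draws are reproducible bit-for-bit (variables are sampled in a fixed
#' documented order: concentrations by category then metal, then DI, EF,
#' then body weight).
#'
#' @param specs Named list of `dist_spec` as from
#'   [input_specs_from_tables].
#' @param config A [simulation_config].
#' @param categories Category set (default [FOOD_CATEGORIES]).
#' @return List with matrices `conc` (iterations x category.metal),
#'   `di`, `ef`, `bw` (iterations x category).
#' @export
sample_inputs <- function(specs, config = simulation_config(),
                          categories = FOOD_CATEGORIES) {
  it <- config$iterations
  need_conc <- as.vector(outer(categories, METALS,
                               function(c, m) paste("conc", c, m, sep = ".")))
  need <- c(need_conc, paste0("di.", categories), paste0("ef.", categories),
            "bw")
  miss <- setdiff(need, names(specs))
  if (length(miss))
    stop("missing distribution spec(s) for: ",
         paste(utils::head(miss, 8), collapse = ", "),
         if (length(miss) > 8) ", ..." else "", call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)
  draw <- function(nms) {
    m <- vapply(nms, function(nm) dist_sample(specs[[nm]], it), numeric(it))
    if (it == 1) m <- matrix(m, nrow = 1, dimnames = list(NULL, nms))
    m
  }
  conc <- draw(need_conc)
  di <- draw(paste0("di.", categories))
  ef <- draw(paste0("ef.", categories))
  colnames(di) <- colnames(ef) <- categories
  if (config$coupling == "shared_person") {
    bw1 <- dist_sample(specs$bw, it)
    bw <- matrix(bw1, nrow = it, ncol = length(categories))
  } else {
    bw <- vapply(categories, function(.) dist_sample(specs$bw, it),
                 numeric(it))
    if (it == 1) bw <- matrix(bw, nrow = 1)
  }
  colnames(bw) <- categories
  bw[bw <= 0] <- 1e-8  # discrete BW families can emit 0; keep doses finite
  list(conc = conc, di = di, ef = ef, bw = bw)
}

#' Empirical percentiles
#'
#' Order statistics with linear interpolation between closest ranks
#' (type-7 convention: `quantile(x, q, type = 7)`).
#'
#' @param values Non-empty numeric vector.
#' @param q Quantile levels in `[0, 1]`.
#' @return Numeric vector of the same length as `q`.
#' @export
#' @examples
#' empirical_percentiles(1:100, 0.5)  # 50.5
empirical_percentiles <- function(values, q = c(0.1, 0.5, 0.9)) {
  if (length(values) == 0)
    stop("empirical_percentiles needs a non-empty vector", call. = FALSE)
  if (any(q < 0 | q > 1)) stop("q must lie in [0, 1]", call. = FALSE)
  stats::quantile(values, probs = q, type = 7, names = FALSE)
}

#' Exceedance probability
#'
#' Fraction of values strictly greater than a threshold.
#'
#' @param values Numeric vector.
#' @param threshold Threshold.
#' @return Proportion in `[0, 1]`.
#' @export
exceedance_probability <- function(values, threshold) {
  if (length(values) == 0)
    stop("exceedance_probability needs a non-empty vector", call. = FALSE)
  mean(values > threshold)
}

#' Moment-matched lognormal description of simulated output
#'
#' Location-0 lognormal whose arithmetic mean and SD equal the sample mean
#' and SD.  Descriptive only: reported percentiles stay empirical.
#'
#' @param values Non-negative values, not all zero.
#' @return A lognormal `dist_spec`.
#' @export
fit_output_distribution <- function(values) {
  if (any(values < 0)) stop("values must be >= 0", call. = FALSE)
  if (all(values == 0))
    stop("cannot fit an output distribution to all-zero values",
         call. = FALSE)
  lognormal_from_moments(mean(values), stats::sd(values))
}

#' Run the probabilistic risk simulation
#'
#' Propagates the input distributions through the deterministic risk
#' equations: per iteration and category, dose(metal) =
#' C x (DI/1000) x EF x ED / (BW x LT x 365), HQ = dose / RfD with the
#' medium-matched RfD, HI = sum of the eight HQs, R = SF x dose(As); plus
#' the totals over categories.  ED and LT are taken from the exposure
#' table and held fixed (no distribution is available for them).
#'
#' @param specs Named `dist_spec` list ([input_specs_from_tables]).
#' @param factors An [exposure_factors] table (supplies ED/LT and the
#'   category set).
#' @param tox A [toxicity_reference] table.
#' @param config A [simulation_config].
#' @param keep_draws Keep the per-iteration output draws in the result
#'   (attribute `"draws"`); needed for sensitivity analysis.
#' @return A data frame of class `simulation_summary`: one row per
#'   quantity (`HI.<category>`, `R.<category>`, `HI.total`, `R.total`) with
#'   the empirical percentiles, the exceedance probability against the
#'   matching threshold, and the moment-fitted lognormal mean/SD
#'   (NA for all-zero quantities).  Attributes: `draws` (if kept),
#'   `inputs` (the sampled input matrices), `config`.
#' @export
run_simulation <- function(specs, factors, tox,
                           config = simulation_config(),
                           keep_draws = TRUE) {
  factors <- exposure_factors(as.data.frame(factors))
  tox <- toxicity_reference(as.data.frame(tox))
  categories <- factors$category
  inp <- sample_inputs(specs, config, categories)
  it <- config$iterations
  hi <- matrix(0, it, length(categories),
               dimnames = list(NULL, categories))
  rr <- hi
  for (ci in seq_along(categories)) {
    cat_i <- categories[ci]
    frow <- factors[ci, ]
    medium <- category_medium(cat_i)
    scale <- (inp$di[, cat_i] / 1000) * inp$ef[, cat_i] * frow$ed /
      (inp$bw[, cat_i] * frow$lt * 365)
    for (met in METALS) {
      trow <- tox[tox$metal == met & tox$medium == medium, , drop = FALSE]
      if (nrow(trow) != 1)
        stop("no RfD for: ", met, "/", medium, call. = FALSE)
      expo <- inp$conc[, paste("conc", cat_i, met, sep = ".")] * scale
      hi[, ci] <- hi[, ci] + expo / trow$rfd
      if (met == "As" && !is.na(trow$sf))
        rr[, ci] <- trow$sf * expo
    }
  }
  draws <- cbind(hi, rowSums(hi), rr, rowSums(rr))
  colnames(draws) <- c(paste0("HI.", categories), "HI.total",
                       paste0("R.", categories), "R.total")
  thr <- c(rep(config$hi_threshold, length(categories) + 1),
           rep(config$r_threshold, length(categories) + 1))
  qs <- config$quantiles
  summ <- data.frame(quantity = colnames(draws),
                     mean = colMeans(draws),
                     sd = apply(draws, 2, stats::sd),
                     stringsAsFactors = FALSE, row.names = NULL)
  pm <- t(apply(draws, 2, empirical_percentiles, q = qs))
  colnames(pm) <- paste0("p", format(100 * qs, trim = TRUE))
  summ <- cbind(summ, pm)
  summ$threshold <- thr
  summ$exceedance <- vapply(seq_along(thr), function(i)
    exceedance_probability(draws[, i], thr[i]), numeric(1))
  ln <- t(vapply(seq_len(ncol(draws)), function(i) {
    v <- draws[, i]
    if (all(v == 0)) return(c(NA_real_, NA_real_))
    sp <- fit_output_distribution(v)
    c(dist_mean(sp), dist_sd(sp))
  }, numeric(2)))
  summ$ln_mean <- ln[, 1]
  summ$ln_sd <- ln[, 2]
  attr(summ, "config") <- config
  attr(summ, "inputs") <- inp
  if (keep_draws) attr(summ, "draws") <- draws
  class(summ) <- c("simulation_summary", "data.frame")
  summ
}

#' @export
print.simulation_summary <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("Monte Carlo summary (%d iterations, %s coupling)\n",
              cfg$iterations, cfg$coupling))
  shown <- as.data.frame(x)
  num <- vapply(shown, is.numeric, logical(1))
  shown[num] <- lapply(shown[num], signif, 4)
  print(shown, row.names = FALSE)
  invisible(x)
}
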