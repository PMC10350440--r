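#' Metals and food categories covered by the model
#'
#' `METALS` are the eight elements quantified in the survey.  `FOOD_CATEGORIES`
#' are the canonical snake-case identifiers of the exposure media; drinking
#' water is the only `water` medium, everything else is `food`.
#'
#' @format Character vectors.
#' @name domain-constants
NULL

#' @rdname domain-constants
#' @export
METALS <- c("Al", "As", "Cr", "Cd", "Cu", "Ni", "Pb", "Zn")

#' @rdname domain-constants
#' @export
FOOD_CATEGORIES <- c("drinking_water", "meat", "cereal", "beans", "potatoes",
                     "solanaceous_fruit", "vegetables", "fruit")

#' @rdname domain-constants
#' @export
CATEGORY_DISPLAY <- c(drinking_water = "Drinking water", meat = "Meat",
                      cereal = "Cereal", beans = "Beans",
                      potatoes = "Potatoes",
                      solanaceous_fruit = "Solanaceous fruit",
                      vegetables = "Vegetables", fruit = "Fruit")

#' @rdname domain-constants
#' @param category Character vector of category identifiers.
#' @export
category_medium <- function(category) {
  ifelse(category == "drinking_water", "water", "food")
}

.check_metal <- function(metal) {
  bad <- setdiff(unique(metal), METALS)
  if (length(bad))
    stop("unknown metal code(s): ", paste(bad, collapse = ", "),
         "; expected one of ", paste(METALS, collapse = ", "), call. = FALSE)
  invisible(metal)
}

.check_category <- function(category) {
  bad <- setdiff(unique(category), FOOD_CATEGORIES)
  if (length(bad))
    stop("unknown food category(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  invisible(category)
}

#' Validated input tables
#'
#' Light S3 wrappers around data frames holding the three model inputs:
#' per-cell concentration summaries (`concentration_stats`), per-category
#' exposure factors (`exposure_factors`), and per-metal-per-medium toxicity
#' reference values (`toxicity_reference`).  The constructors validate the
#' schema and value ranges and return the data frame with an added class.
#'
#' @param df A data frame with the documented columns.
#' @return The validated, classed data frame.
#' @name input-tables
NULL

#' @rdname input-tables
#' @details `concentration_stats` columns: `category`, `metal`, `mean`,
#'   `sd`, `min`, `max`, `n`, `safe_limit`.  Units are mg/kg for food and
#'   mg/L for drinking water.
#' @export
concentration_stats <- function(df) {
  need <- c("category", "metal", "mean", "sd", "min", "max", "n", "safe_limit")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("concentration table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  .check_category(df$category)
  .check_metal(df$metal)
  for (col in c("mean", "sd", "min", "max", "safe_limit")) {
    bad <- which(!is.finite(df[[col]]) | df[[col]] < 0)
    if (length(bad))
      stop("concentration table: negative or non-finite '", col,
           "' in row ", bad[1], " (", df$category[bad[1]], ", ",
           df$metal[bad[1]], ")", call. = FALSE)
  }
  bad <- which(df$min > df$mean | df$mean > df$max)
  if (length(bad))
    stop("concentration table: min <= mean <= max violated in row ", bad[1],
         " (", df$category[bad[1]], ", ", df$metal[bad[1]], ")",
         call. = FALSE)
  if (any(df$n < 1)) stop("concentration table: n must be >= 1", call. = FALSE)
  class(df) <- c("concentration_stats", "data.frame")
  df
}

#' @rdname input-tables
#' @details `exposure_factors` columns: `category`, `di` (daily intake,
#'   g/day; drinking-water mL/day is treated as g/day at density 1 g/mL),
#'   `ef` (exposure frequency, day/year), `ed` (exposure duration, years),
#'   `bw` (body weight, kg), `lt` (averaging lifetime, years).
#' @export
exposure_factors <- function(df) {
  need <- c("category", "di", "ef", "ed", "bw", "lt")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("exposure table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  .check_category(df$category)
  ok <- df$di >= 0 & df$ef >= 0 & df$ef <= 365 & df$ed > 0 & df$bw > 0 &
    df$lt > 0 & df$ed <= df$lt
  bad <- which(!ok | !stats::complete.cases(df[need[-1]]))
  if (length(bad))
    stop("exposure table: invalid factor(s) in row ", bad[1], " (",
         df$category[bad[1]], "): need di >= 0, 0 <= ef <= 365, ",
         "0 < ed <= lt, bw > 0", call. = FALSE)
  class(df) <- c("exposure_factors", "data.frame")
  df
}

#' @rdname input-tables
#' @details `toxicity_reference` columns: `metal`, `medium` (`water` or
#'   `food`), `rfd` (oral reference dose, mg/(kg d)), `sf` (cancer slope
#'   factor, (kg d)/mg; `NA` for non-carcinogens).
#' @export
toxicity_reference <- function(df) {
  need <- c("metal", "medium", "rfd")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("toxicity table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  .check_metal(df$metal)
  bad <- setdiff(unique(df$medium), c("water", "food"))
  if (length(bad))
    stop("toxicity table: unknown medium '", bad[1], "'", call. = FALSE)
  bad <- which(!is.finite(df$rfd) | df$rfd <= 0)
  if (length(bad))
    stop("toxicity table: RfD must be > 0; offending row ", bad[1], " (",
         df$metal[bad[1]], ", ", df$medium[bad[1]], ")", call. = FALSE)
  if (is.null(df$sf)) df$sf <- NA_real_
  if (any(!is.na(df$sf) & df$sf <= 0))
    stop("toxicity table: slope factor must be > 0 where present",
         call. = FALSE)
  class(df) <- c("toxicity_reference", "data.frame")
  df
}

.as_factor_row <- function(factors) {
  if (is.data.frame(factors)) {
    if (nrow(factors) != 1)
      stop("'factors' must describe a single category (one row)",
           call. = FALSE)
    factors <- as.list(factors)
  }
  need <- c("di", "ef", "ed", "bw", "lt")
  miss <- setdiff(need, names(factors))
  if (length(miss))
    stop("exposure factors are missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  factors[need]
}

#' Average daily exposure dose
#'
#' Chronic daily dose of a metal from one dietary category,
#' \deqn{EXPO = \frac{C \times DI \times EF \times ED}{BW \times LT}}
#' with C in mg/kg (mg/L for water), DI in g/day (divided by 1000 to kg/day;
#' drinking-water mL/day is taken as g/day at density 1 g/mL), EF in
#' day/year, ED and LT in years (LT converted to days via 365), and BW in
#' kg.  The result is in mg/(kg day).  When EF = 365 and ED = LT the
#' expression reduces to `conc * (di/1000) / bw`.
#'
#' @param conc Concentration(s), mg/kg or mg/L; vectorised.
#' @param factors Exposure factors: a named list or one-row data frame with
#'   `di`, `ef`, `ed`, `bw`, `lt`.
#' @return Dose(s) in mg/(kg day).
#' @export
#' @examples
#' cereal <- list(di = 313.92, ef = 365, ed = 70, bw = 54.93, lt = 70)
#' compute_expo(0.2564, cereal)  # 1.4653e-3
compute_expo <- function(conc, factors) {
  f <- .as_factor_row(factors)
  if (any(!is.finite(conc) | conc < 0))
    stop("concentration must be finite and >= 0", call. = FALSE)
  if (f$bw <= 0 || f$lt <= 0)
    stop("body weight and lifetime must be > 0", call. = FALSE)
  if (f$di < 0 || f$ef < 0 || f$ef > 365 || f$ed <= 0)
    stop("invalid exposure factors (need di >= 0, 0 <= ef <= 365, ed > 0)",
         call. = FALSE)
  conc * (f$di / 1000) * f$ef * f$ed / (f$bw * f$lt * 365)
}

#' Hazard quotient
#'
#' HQ = dose / RfD.  HQ >= 1 flags a serious noncarcinogenic risk from the
#' single contaminant; HQ < 1 is considered not serious.
#'
#' @param expo Dose(s), mg/(kg day), >= 0.
#' @param rfd Oral reference dose, mg/(kg day), > 0.
#' @return Dimensionless quotient(s).
#' @export
hazard_quotient <- function(expo, rfd) {
  if (!is.finite(rfd) || rfd <= 0)
    stop("RfD must be a positive number", call. = FALSE)
  if (any(!is.finite(expo) | expo < 0))
    stop("exposure dose must be finite and >= 0", call. = FALSE)
  expo / rfd
}

#' Hazard index
#'
#' Sum of the hazard quotients of all contaminants in one medium.  HI <= 1
#' means no notable adverse noncarcinogenic effect is expected.
#'
#' @param hqs Numeric vector of HQs, all >= 0, non-empty.
#' @return The sum.
#' @export
hazard_index <- function(hqs) {
  if (length(hqs) == 0)
    stop("hazard_index needs at least one HQ", call. = FALSE)
  if (any(!is.finite(hqs) | hqs < 0))
    stop("HQs must be finite and >= 0", call. = FALSE)
  sum(hqs)
}

#' Incremental lifetime carcinogenic risk
#'
#' R = SF x dose, the linear low-dose extrapolation of lifetime cancer
#' probability.  Acceptability anchors: 1e-6 negligible (US EPA), 1e-5
#' (WHO), 1e-4 maximum acceptable (US EPA).  In this model only As carries
#' a slope factor (1.5 (kg d)/mg).
#'
#' @param expo Dose(s), mg/(kg day), >= 0.
#' @param sf Cancer slope factor, (kg d)/mg, > 0.  `NA` (no slope factor
#'   known for the metal) is an error.
#' @return Dimensionless lifetime probability increment(s).
#' @export
carcinogenic_risk <- function(expo, sf = 1.5) {
  if (is.na(sf))
    stop("no cancer slope factor available for this metal", call. = FALSE)
  if (!is.finite(sf) || sf <= 0)
    stop("slope factor must be > 0", call. = FALSE)
  if (any(!is.finite(expo) | expo < 0))
    stop("exposure dose must be finite and >= 0", call. = FALSE)
  sf * expo
}

#' Assemble the deterministic risk table
#'
#' Computes, for every food category: the HQ of each metal (dose from the
#' category-mean concentration, RfD matched to the category's medium), the
#' category HI, and the As carcinogenic risk, plus grand totals TTHQ
#' (sum of HIs) and TR (sum of Rs).
#'
#' @param stats A [concentration_stats] table covering every
#'   (category, metal) pair.
#' @param factors An [exposure_factors] table with one row per category.
#' @param tox A [toxicity_reference] table with an RfD for every metal in
#'   both media.
#' @return A data frame of class `risk_table`: one row per category,
#'   columns `HQ_Al` ... `HQ_Zn`, `HI`, `R_As`; attributes `tthq` and `tr`
#'   hold the grand totals.
#' @export
#' @examples
#' tabs <- ningxia_tables()
#' rt <- build_risk_table(tabs$concentrations, tabs$exposure, tabs$toxicity)
#' attr(rt, "tthq")
build_risk_table <- function(stats, factors, tox) {
  stats <- concentration_stats(as.data.frame(stats))
  factors <- exposure_factors(as.data.frame(factors))
  tox <- toxicity_reference(as.data.frame(tox))
  cats <- unique(stats$category)
  missing_rfd <- character(0)
  out <- data.frame(category = cats, stringsAsFactors = FALSE)
  hq_cols <- paste0("HQ_", METALS)
  for (col in hq_cols) out[[col]] <- NA_real_
  out$HI <- NA_real_
  out$R_As <- NA_real_
  for (i in seq_along(cats)) {
    cat_i <- cats[i]
    medium <- category_medium(cat_i)
    frow <- factors[factors$category == cat_i, , drop = FALSE]
    if (nrow(frow) != 1)
      stop("exposure factors missing for category '", cat_i, "'",
           call. = FALSE)
    hqs <- numeric(length(METALS))
    for (j in seq_along(METALS)) {
      met <- METALS[j]
      crow <- stats[stats$category == cat_i & stats$metal == met, ,
                    drop = FALSE]
      if (nrow(crow) != 1)
        stop("concentration missing for (", cat_i, ", ", met, ")",
             call. = FALSE)
      trow <- tox[tox$metal == met & tox$medium == medium, , drop = FALSE]
      if (nrow(trow) != 1) {
        missing_rfd <- c(missing_rfd, paste0(met, "/", medium))
        next
      }
      expo <- compute_expo(crow$mean, frow)
      hqs[j] <- hazard_quotient(expo, trow$rfd)
      if (met == "As")
        out$R_As[i] <- carcinogenic_risk(expo, trow$sf)
    }
    out[i, hq_cols] <- hqs
    out$HI[i] <- hazard_index(hqs)
  }
  if (length(missing_rfd))
    stop("no RfD for: ", paste(unique(missing_rfd), collapse = ", "),
         call. = FALSE)
  attr(out, "tthq") <- sum(out$HI)
  attr(out, "tr") <- sum(out$R_As)
  class(out) <- c("risk_table", "data.frame")
  out
}

#' @export
print.risk_table <- function(x, ...) {
  shown <- as.data.frame(x)
  hq_cols <- c(paste0("HQ_", METALS), "HI")
  shown[hq_cols] <- lapply(shown[hq_cols], function(v) sprintf("%.4f", v))
  shown$R_As <- ifelse(x$R_As == 0, "0", sprintf("%.3g", x$R_As))
  print(shown, row.names = FALSE)
  cat(sprintf("TTHQ = %.4f   TR = %.3g\n",
              attr(x, "tthq"), attr(x, "tr")))
  invisible(x)
}

#' Over-limit ratio
#'
#' Percentage of samples whose concentration strictly exceeds a regulatory
#' safe limit, rounded to one decimal (the convention of published
#' over-limit rows).
#'
#' @param samples Non-empty numeric vector of sample concentrations.
#' @param limit Safe limit, > 0.
#' @return Percentage in `[0, 100]`, one decimal.
#' @export
#' @examples
#' over_limit_ratio(c(0.25, 0.15, 0.10, 0.19), 0.2)  # 25
over_limit_ratio <- function(samples, limit) {
  if (length(samples) == 0)
    stop("over_limit_ratio needs at least one sample", call. = FALSE)
  if (!is.finite(limit) || limit <= 0)
    stop("limit must be > 0", call. = FALSE)
  round(100 * mean(samples > limit), 1)
}
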