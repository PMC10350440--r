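#' Load and validate the three input tables from CSV
#'
#' CSV schemas:
#' * concentrations: `category, metal, mean, sd, min, max, n, safe_limit`
#' * exposure: `category, di_g_per_day, ef_day_per_year, ed_years, bw_kg,
#'   lt_years`
#' * toxicity: `metal, medium, rfd, sf` (empty `sf` = no slope factor)
#'
#' Categories use canonical snake-case identifiers (see
#' [FOOD_CATEGORIES]).  Errors name the offending file, row and column.
#'
#' @param concentrations,exposure,toxicity Paths to the three CSVs.
#' @return List of validated tables: `concentrations`
#'   ([concentration_stats]), `exposure` ([exposure_factors], with short
#'   column names `di`, `ef`, `ed`, `bw`, `lt`), `toxicity`
#'   ([toxicity_reference]).
#' @export
load_tables <- function(concentrations, exposure, toxicity) {
  for (p in c(concentrations, exposure, toxicity))
    if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
  conc <- utils::read.csv(concentrations, stringsAsFactors = FALSE)
  expo <- utils::read.csv(exposure, stringsAsFactors = FALSE)
  tox <- utils::read.csv(toxicity, stringsAsFactors = FALSE)
  long <- c(di = "di_g_per_day", ef = "ef_day_per_year", ed = "ed_years",
            bw = "bw_kg", lt = "lt_years")
  miss <- setdiff(long, names(expo))
  if (length(miss))
    stop("exposure CSV '", exposure, "' is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  for (nm in names(long)) expo[[nm]] <- expo[[long[nm]]]
  expo <- expo[c("category", names(long))]
  if (!is.null(tox$sf)) tox$sf <- suppressWarnings(as.numeric(tox$sf))
  list(concentrations = concentration_stats(conc),
       exposure = exposure_factors(expo),
       toxicity = toxicity_reference(tox))
}

#' Packaged survey fixtures
#'
#' The published summary tables for the northern-Ningxia dietary survey:
#' per-cell concentration statistics with regulatory safe limits (eight
#' metals x eight categories), exposure factors per category, and
#' toxicity reference values.  `ningxia_output_fits` additionally returns
#' the published lognormal descriptions of the per-category simulated HI
#' and R outputs (location 0, arithmetic mean/SD), usable as direct
#' sampling inputs for reproduction runs.
#'
#' @return `ningxia_tables`: the [load_tables] list.
#'   `ningxia_output_fits`: a data frame with `category`, `quantity`
#'   (`"HI"`/`"R"`), `family`, `location`, `mean`, `sd`.
#' @export
#' @examples
#' names(ningxia_tables())
ningxia_tables <- function() {
  dir <- system.file("extdata", "ningxia", package = "metalrisk",
                     mustWork = TRUE)
  load_tables(file.path(dir, "concentrations.csv"),
              file.path(dir, "exposure.csv"),
              file.path(dir, "toxicity.csv"))
}

#' @rdname ningxia_tables
#' @export
ningxia_output_fits <- function() {
  dir <- system.file("extdata", "ningxia", package = "metalrisk",
                     mustWork = TRUE)
  utils::read.csv(file.path(dir, "output_fits.csv"),
                  stringsAsFactors = FALSE)
}

#' Write / read a deterministic risk table as CSV
#'
#' One row per category plus a `total` row carrying TTHQ and TR.
#'
#' @param rt A `risk_table` from [build_risk_table].
#' @param path CSV path.
#' @return `write_risk_table` returns `path` invisibly; `read_risk_table`
#'   returns the reconstructed `risk_table`.
#' @export
write_risk_table <- function(rt, path) {
  stopifnot(inherits(rt, "risk_table"))
  df <- as.data.frame(rt)
  total <- df[1, ]
  total$category <- "total"
  total[paste0("HQ_", METALS)] <- NA_real_
  total$HI <- attr(rt, "tthq")
  total$R_As <- attr(rt, "tr")
  utils::write.csv(rbind(df, total), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_risk_table
#' @export
read_risk_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tot <- df[df$category == "total", , drop = FALSE]
  df <- df[df$category != "total", , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "tthq") <- if (nrow(tot)) tot$HI else sum(df$HI)
  attr(df, "tr") <- if (nrow(tot)) tot$R_As else sum(df$R_As)
  class(df) <- c("risk_table", "data.frame")
  df
}

.r_bucket <- function(r) {
  if (is.na(r)) return("no slope factor")
  if (r == 0) return("zero (not detected)")
  if (r <= 1e-6) return("negligible (<= 1e-6, US EPA)")
  if (r <= 1e-5) return("below WHO level (<= 1e-5)")
  if (r <= 1e-4) return("below maximum acceptable (<= 1e-4)")
  "EXCEEDS maximum acceptable (> 1e-4)"
}

#' Render a plain-text risk report
#'
#' Mirrors the deterministic table (HQ/HI per category, flags for HQ >= 1
#' and HI > 1), the carcinogenic risks with their acceptability bucket
#' (1e-6 / 1e-5 / 1e-4 anchors), and — when present — the probabilistic
#' summary and the sensitivity ranking.  At least one artifact must be
#' given; absent sections are omitted.
#'
#' @param risk_table Optional `risk_table`.
#' @param summary Optional `simulation_summary`.
#' @param sensitivity Optional `sensitivity_report`.
#' @return Character vector of report lines.
#' @export
render_report <- function(risk_table = NULL, summary = NULL,
                          sensitivity = NULL) {
  if (is.null(risk_table) && is.null(summary) && is.null(sensitivity))
    stop("nothing to report", call. = FALSE)
  lines <- character(0)
  add <- function(...) lines <<- c(lines, sprintf(...))
  if (!is.null(risk_table)) {
    add("== Deterministic risk table ==")
    for (i in seq_len(nrow(risk_table))) {
      row <- risk_table[i, ]
      hqs <- as.numeric(row[paste0("HQ_", METALS)])
      flags <- METALS[hqs >= 1]
      add("%-18s HI = %.4f%s%s", row$category, row$HI,
          if (row$HI > 1) "  [HI > 1]" else "",
          if (length(flags)) paste0("  [HQ >= 1: ",
                                    paste(flags, collapse = ","), "]")
          else "")
      add("%-18s R(As) = %s  -> %s", "", format(signif(row$R_As, 3)),
          .r_bucket(row$R_As))
    }
    add("TTHQ = %.4f%s", attr(risk_table, "tthq"),
        if (attr(risk_table, "tthq") > 1) "  [> 1]" else "")
    add("TR   = %s  -> %s", format(signif(attr(risk_table, "tr"), 3)),
        .r_bucket(attr(risk_table, "tr")))
  }
  if (!is.null(summary)) {
    cfg <- attr(summary, "config")
    add("== Probabilistic summary (%d iterations, %s coupling) ==",
        cfg$iterations, cfg$coupling)
    for (i in seq_len(nrow(summary))) {
      row <- summary[i, ]
      add("%-12s exceedance(> %.3g) = %.2f%%", row$quantity, row$threshold,
          100 * row$exceedance)
    }
  }
  if (!is.null(sensitivity)) {
    add("== Sensitivity (contribution to variance) ==")
    for (i in seq_len(nrow(sensitivity)))
      add("%-28s %+6.1f%%", sensitivity$variable[i],
          sensitivity$contribution_pct[i])
  }
  lines
}
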