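#' Spearman rank correlation
#'
#' Pearson correlation of midranks (average ranks for ties).  Errors on
#' constant vectors — a constant input carries no rank information; the
#' caller decides what that means (see [contribution_to_variance]).
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation in `[-1, 1]`.
#' @export
rank_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("x and y must have equal length >= 3", call. = FALSE)
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop("rank correlation undefined for a constant vector", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

#' Contribution-to-variance sensitivity report
#'
#' Apportions the output's variance among the stochastic inputs as the
#' signed normalised squared rank correlation,
#' \deqn{contribution_i = sign(\rho_i) \times 100 \times
#'   \rho_i^2 / \sum_j \rho_j^2}
#' (the rank-correlation method popularised by spreadsheet risk tools).
#' A positive value means the input is positively associated with the
#' output.  Constant inputs get contribution 0 with a warning.  Absolute
#' contributions sum to exactly 100.
#'
#' @param inputs Matrix or data frame of input draws, one named column per
#'   input, rows aligned with `output` by iteration.
#' @param output Numeric vector of output draws.
#' @return A data frame of class `sensitivity_report` with columns
#'   `variable`, `rho`, `contribution_pct`, ordered by decreasing
#'   `abs(contribution_pct)`.
#' @export
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(2000), ncol = 2, dimnames = list(NULL, c("a", "b")))
#' contribution_to_variance(x, x[, 1] - x[, 2])
contribution_to_variance <- function(inputs, output) {
  inputs <- as.matrix(inputs)
  if (ncol(inputs) < 1) stop("need at least one input", call. = FALSE)
  if (nrow(inputs) != length(output))
    stop("inputs and output must be aligned by iteration", call. = FALSE)
  if (is.null(colnames(inputs)))
    colnames(inputs) <- paste0("x", seq_len(ncol(inputs)))
  rho <- vapply(seq_len(ncol(inputs)), function(j) {
    xj <- inputs[, j]
    if (length(unique(xj)) < 2) {
      warning("input '", colnames(inputs)[j],
              "' is constant; contribution set to 0", call. = FALSE)
      return(0)
    }
    rank_correlation(xj, output)
  }, numeric(1))
  tot <- sum(rho^2)
  if (tot == 0)
    stop("all rank correlations are zero: no attributable variance",
         call. = FALSE)
  contrib <- sign(rho) * 100 * rho^2 / tot
  out <- data.frame(variable = colnames(inputs), rho = rho,
                    contribution_pct = contrib, stringsAsFactors = FALSE)
  out <- out[order(-abs(out$contribution_pct)), ]
  rownames(out) <- NULL
  class(out) <- c("sensitivity_report", "data.frame")
  out
}

#' @export
print.sensitivity_report <- function(x, ...) {
  shown <- as.data.frame(x)
  shown$rho <- sprintf("%+.3f", shown$rho)
  shown$contribution_pct <- sprintf("%+.1f%%", shown$contribution_pct)
  print(shown, row.names = FALSE)
  invisible(x)
}

#' Sensitivity analysis of a finished simulation
#'
#' Convenience wrapper: runs [contribution_to_variance] of one output
#' quantity of a [run_simulation] result against all sampled inputs
#' (concentrations, DI, EF, and the body weight).
#'
#' @param summary A `simulation_summary` with kept draws.
#' @param quantity Output column name, e.g. `"HI.total"` or `"R.total"`.
#' @param include Which input groups enter the report.  The default is all
#'   of them; `"concentration"` alone mirrors published
#'   contribution-to-variance charts that list only metal-by-food
#'   concentration variables.
#' @return A `sensitivity_report`.
#' @export
simulation_sensitivity <- function(summary, quantity = "HI.total",
                                   include = c("concentration", "intake",
                                               "frequency", "bw")) {
  include <- match.arg(include, several.ok = TRUE)
  draws <- attr(summary, "draws")
  inp <- attr(summary, "inputs")
  if (is.null(draws) || is.null(inp))
    stop("simulation was run without keep_draws = TRUE", call. = FALSE)
  if (!quantity %in% colnames(draws))
    stop("unknown output quantity '", quantity, "'", call. = FALSE)
  di <- inp$di; colnames(di) <- paste0("di.", colnames(di))
  ef <- inp$ef; colnames(ef) <- paste0("ef.", colnames(ef))
  parts <- list(concentration = inp$conc, intake = di, frequency = ef,
                bw = cbind(bw = inp$bw[, 1]))
  inputs <- do.call(cbind, parts[include])
  keep <- apply(inputs, 2, function(v) length(unique(v)) > 1)
  contribution_to_variance(inputs[, keep, drop = FALSE], draws[, quantity])
}
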