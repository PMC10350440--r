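# Independent oracles used across test files.  These are deliberately
# naive re-implementations kept separate from the package code paths.

# type-7 quantile: h = (n-1) q + 1, linear interpolation between order stats
brute_quantile <- function(x, q) {
  s <- sort(x)
  n <- length(s)
  vapply(q, function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    hi <- ceiling(h)
    s[lo] + (h - lo) * (s[hi] - s[lo])
  }, numeric(1))
}

# Spearman as Pearson on midranks, spelled out
brute_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  num <- sum((rx - mx) * (ry - my))
  num / sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# Anderson-Darling by direct formula evaluation on given CDF values
brute_ad_from_u <- function(u) {
  n <- length(u)
  u <- sort(u)
  i <- seq_len(n)
  -n - sum((2 * i - 1) * (log(u) + log(1 - u[n + 1 - i]))) / n
}

# fixture tables, loaded once per test session
nx <- ningxia_tables()
nx_risk <- build_risk_table(nx$concentrations, nx$exposure, nx$toxicity)

factor_row <- function(category) {
  as.list(nx$exposure[nx$exposure$category == category, ])
}

conc_mean <- function(category, metal) {
  cs <- nx$concentrations
  cs$mean[cs$category == category & cs$metal == metal]
}
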