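---
title: "Dietary toxic-metal risk assessment: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dietary toxic-metal risk assessment: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model implemented by **metalrisk**, the
assumptions baked into its defaults, and the design choices made where the
underlying methodology left room.  It states no empirical result that the
package's test suite and `scripts/acceptance.R` do not themselves compute.

## 1. The deterministic risk chain

Oral exposure to a metal through one dietary category is the standard US
EPA average daily dose,

$$\mathrm{EXPO} = \frac{C \cdot DI \cdot EF \cdot ED}{BW \cdot LT},$$

which `compute_expo()` evaluates with the unit conventions that reproduce
published risk tables from survey summaries:

| symbol | meaning | unit | handling |
|---|---|---|---|
| $C$ | concentration in the food | mg/kg (mg/L water) | mean of the category's samples |
| $DI$ | daily intake | g/day | divided by 1000; water mL/day taken as g/day at 1 g/mL |
| $EF$ | exposure frequency | day/year | 0–365, from the questionnaire |
| $ED$ | exposure duration | year | fixed at 70 |
| $BW$ | body weight | kg | survey mean 54.93 |
| $LT$ | averaging lifetime | year | fixed at 70, converted to days via ×365 (no leap days) |

With $EF = 365$ and $ED = LT$ the ratio $EF\cdot ED/(LT\cdot 365)$ is
exactly 1 and the dose collapses to $C\,(DI/1000)/BW$ — a property the
test suite asserts to machine precision, and the reason drinking-water
risks reproduce published values exactly.

Noncarcinogenic risk is judged by the hazard quotient
$HQ = \mathrm{EXPO}/RfD$ per metal (`hazard_quotient()`), the per-category
hazard index $HI = \sum HQ$ (`hazard_index()`), and the grand total TTHQ
across categories.  The oral reference doses are medium-specific (the Al
RfD is 1.0 mg/(kg·d) in water but 0.0005 in food).  Carcinogenic risk is
linear low-dose, $R = SF \cdot \mathrm{EXPO}$ with $SF = 1.5$ (kg·d)/mg
for arsenic only, read against the 1e-6 / 1e-5 / 1e-4 acceptability
anchors.  A single exposure routine serves both paths; the carcinogenic
and noncarcinogenic dose formulas are identical.

**Known inconsistencies in the reference table.**  Re-deriving the
published deterministic table from its own inputs reproduces almost every
cell to four decimals, with three documented exceptions the package
resolves in favour of internal consistency:

* the printed meat-As HQ (0.4080) disagrees with the same row's printed HI
  and R, both of which imply 0.468 — we compute 0.4681 and match the row's
  HI exactly;
* the printed cereal-Cu HQ (0.0806) implies an RfD of 0.02 rather than the
  stated 0.037 — we follow the stated RfD (HQ 0.0436), which lowers cereal
  HI by ~3% and TTHQ by ~0.6%, inside the documented 1.5% band;
* the printed fruit-As HQ (0.4180) recomputes to 0.41786; the printed
  value is consistent with a dose pre-rounded to 1.254e-4 before division.

Rounding for reports follows the published presentation: HQ/HI to four
decimals, R to three significant figures; all comparisons in tests use
unrounded values.

## 2. Distribution fitting

`select_best_fit()` fits each candidate family by maximum likelihood to
the *positive part* of a sample and carries the observed zero fraction as
an exact-zero atom (`zero_mass`) in the returned spec.  Zeros here are
non-detects: minima of 0 in the concentration summaries and 10th
percentiles of 0.00 in published output tables cannot come from any purely
lognormal model, so the zero mass is a first-class model component rather
than a data-cleaning step.  Censored-likelihood treatment below a
detection limit is out of scope.

Continuous candidates (lognormal, normal, gamma, Weibull) are scored by
the Anderson–Darling statistic

$$A^2 = -n - \frac{1}{n}\sum_{i=1}^n (2i-1)\bigl[\ln F(x_{(i)}) +
\ln(1 - F(x_{(n+1-i)}))\bigr],$$

discrete candidates (Poisson, negative binomial — used for body weight)
by the chi-square statistic over integer bins with open tails, merged
inwards until every expected count reaches 5.  Continuous chi-square
binning, when requested, uses equal-probability bins with the count from
Sturges' rule.  Selection uses the raw statistics only — no p-values —
because only the relative ranking matters and no critical values are
published for the original analysis; ties break by candidate order.
Discrete families are fitted to body-weight data after rounding to
integers (the original analysis fitted discrete families to continuous
weights without saying how; rounding is our documented choice).

`lognormal_from_moments()` is the bridge between arithmetic summaries and
log-scale parameters: $\sigma^2 = \ln(1 + (s/m)^2)$,
$\mu = \ln m - \sigma^2/2$, exact by construction, and the convention in
which all fitted output distributions are reported (location 0,
arithmetic mean and SD).

## 3. Monte Carlo propagation

`run_simulation()` draws every stochastic symbol per iteration and pushes
it through the deterministic equations; nothing is re-derived
analytically, so the point-mass limit (all SDs zero) reproduces the
deterministic table *exactly*, a property used as a test oracle.

Choices that the original methodology left open:

* **Coupling** (default `shared_person`): one iteration is one simulated
  resident — a single BW draw is reused across all categories, because the
  dose equation describes one person's intake.  `independent` draws every
  variable independently and exists to reproduce published
  output-distribution parameterisations, where per-category results were
  fitted separately.
* **ED and LT are not sampled** (fixed 70 years): they come from
  literature with no reported spread.
* **Output percentiles are empirical** (type-7 linear interpolation), not
  read off the fitted lognormal: the published percentile columns are not
  consistent with the lognormals implied by their own mean/SD columns, so
  the fitted spec is treated as descriptive only.
* **Exceedance is strict** (`values > threshold`), matching the published
  "probability of exceeding" language; 10,000 iterations (the default) is
  where exceedance estimates stabilise to within a percentage point of
  much longer runs, which the suite checks against a 100,000-iteration
  run.
* Discrete body-weight families can emit 0 kg draws with vanishing
  probability; these are clamped to a small positive value to keep doses
  finite.

No variance reduction (Latin hypercube, antithetic variates) and no 2-D
separation of variability from uncertainty are implemented.

## 4. Sensitivity analysis

`contribution_to_variance()` implements the rank-correlation method used
by spreadsheet risk tools: for each input, the Spearman correlation
$\rho_i$ with the output, reported as the signed normalised square
$\mathrm{sign}(\rho_i)\,100\,\rho_i^2/\sum_j\rho_j^2$.  Absolute
contributions sum to exactly 100% and the measure is invariant to
monotone transforms of any input.  Constant inputs contribute 0 with a
warning; if *all* correlations vanish there is no attributable variance
and the function errors.

The default report covers concentrations, daily intakes, exposure
frequencies and body weight.  For comparisons against published
contribution charts, `simulation_sensitivity(include = "concentration")`
restricts the report to metal-by-food concentration variables, because
those charts list only such variables; with all inputs included, body
weight's negative contribution outranks the leading concentration for
total HI, which would make an ordering comparison against the published
charts meaningless.

## 5. The synthetic-data generator

The generator emulates what the analysis pipeline needs to see — not the
full field campaign.  Per concentration cell it draws a zero-inflated
lognormal whose **positive part is moment-matched under truncation at the
cell's observed maximum**:

1. the zero fraction (default 10% where the cell's minimum is 0; per-cell
   non-detect counts are not published) converts the overall mean/SD
   targets into positive-part targets;
2. for a candidate $\sigma$, $\mu$ is solved by root-finding so the
   truncated mean is exact; $\sigma$ is then searched for the closest SD
   (closed-form truncated-lognormal moments throughout);
3. sampling is by inverse CDF restricted to $[0, \mathrm{max}]$, so the
   support discipline holds by construction.

Naive matching followed by clipping would bias the cereal-Cr mean ~11%
low — the truncation-aware match is what makes the generator close the
loop with the deterministic stage.  Some cells are infeasible: a target
SD can exceed what any distribution on $[0,\mathrm{max}]$ with the target
mean allows (potatoes-As sits essentially at that bound).  The generator
then pins the mean, attains the closest SD, and warns.

Questionnaire records get per-category DI (lognormal) and EF (lognormal
truncated at 365 day/year; an EF target of 365 stays constant) with a
default CV of 0.3 — a stated, configurable assumption, typical of
food-frequency intake data, standing in for unpublished dispersions — and
body weight from a Poisson (pooled default; Poisson for males, negative
binomial for females when stratified, mirroring the published fits).  EF
targets close to the 365 cap cannot attain CV 0.3 under truncation; the
mean is preserved and the SD saturates.

What a green generator test does **not** establish: real concentration
data have spatial structure, inter-metal correlation within a sample, and
seasonal effects; the generator has none of these, by design.

## 6. Numerical conventions

* Validation errors name the offending table, row and cell; unknown
  metals/categories are rejected at the boundary.
* All randomness flows through R's RNG; every simulation and generator
  call is reproducible from a single seed, and draws are made in a fixed
  documented order.
* The Anderson–Darling statistic errors on CDF values of exactly 0 or 1
  at a sample (degenerate fit) rather than returning infinity.
* CSV outputs from the CLI carry a provenance header line (subcommand,
  seed, fixture source).

## 7. Limitations

Toxicokinetics and bioavailability after food processing are not
modelled; exposure is oral-only (no dermal or inhalation routes) and not
age- or sex-stratified in the risk equations.  The published total-R
exceedance figure is not reproducible from the published output-table
parameters under independence (the original computation evidently
resampled empirical zero-inflated inputs that were not reported), so the
package asserts only bounds and threshold-monotonicity for that quantity.
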