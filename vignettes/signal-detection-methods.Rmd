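---
title: "Disproportionality signal detection and time-to-onset methods"
author: "faersignal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection and time-to-onset methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

## The problem

Spontaneous-report databases such as FAERS collect voluntary adverse-event
reports without any denominator of exposed patients, so incidence cannot be
estimated. What can be screened is *disproportionality*: whether an event is
reported with a given drug more often than the database background would
predict. `faersignal` implements the standard screening pipeline for
quarterly delimited-ASCII report packets — deduplication, 2x2 contingency
construction, four disproportionality statistics with joint positivity
criteria, cohort descriptives, and a Weibull time-to-onset analysis — plus a
synthetic FAERS-like generator so every stage is testable offline.

## Deduplication

A case (CASEID) may be reported repeatedly as follow-up versions, each with
its own PRIMARYID. Following the FDA-recommended procedure, for each CASEID
the version with the latest FDA receipt date (FDA_DT) is kept; ties break to
the highest PRIMARYID. From 2019Q1 onward, quarterly packets also carry
deleted-case catalogs; all cases named there are removed after version
selection. Whether deletion runs before or after version selection does not
change the final set (the two operations commute on the final case set, a
property the test suite asserts), so the order is an implementation detail.

FDA_DT is compared as an 8-digit string, which for complete dates equals
chronological order. Partial dates (`YYYY`, `YYYYMM`) sort before complete
dates sharing their prefix and trigger a warning rather than an imputation;
real receipt dates are essentially always complete, and the package's policy
throughout is to exclude-and-flag rather than impute.

## The 2x2 table and its statistics

For a target drug and event term, distinct case-level (case, drug, event)
pairs are cross-tabulated:

|            | target event | other events |
|------------|--------------|--------------|
| target drug | a | b |
| other drugs | c | d |

The counting unit is the deduplicated case: a case contributes at most one
count to a cell for a given (drug, event) pair, which matches case-level
characteristics tables (one cohort had 441 case reports carrying 908 event
terms). Event-level counting is available via `counting = "event"` for
sensitivity analyses.

Four statistics are computed per table (N = a+b+c+d, E = (a+b)(a+c)/N):

* **ROR** = ad/bc, with the log-scale Wald 95% interval
  `exp(ln ROR ± 1.96·sqrt(1/a+1/b+1/c+1/d))`.
* **PRR** = [a/(a+b)]/[c/(c+d)], interval
  `exp(ln PRR ± 1.96·sqrt(1/a − 1/(a+b) + 1/c − 1/(c+d)))`, used jointly
  with the Yates-corrected chi-square
  `N(|ad−bc| − N/2)² / [(a+b)(c+d)(a+c)(b+d)]` (floored at 0 when the
  continuity correction overshoots) per the MHRA convention.
* **BCPNN information component**: `IC = log2((a+0.5)/(E+0.5))`, a shrunk
  observed-to-expected ratio, with the closed-form lower credibility bound
  `IC025 = IC − 3.3·a^(−1/2) − 2·a^(−3/2)` (valid for a ≥ 1; at a = 0 the
  bound is reported as −Inf). The original expectation/variance formulation
  is available via `variant = "bate"`.
* **MGPS/EBGM**: the observed count is modelled as Poisson(λE) with a
  two-component gamma mixture prior on λ. The posterior is again a gamma
  mixture, so `EBGM = 2^(E[log2 λ | a])` has a closed form through digamma
  functions and `EBGM05` is found by monotone root-finding on the posterior
  mixture CDF. The default prior is the canonical starting point
  (α1 = 0.2, β1 = 0.1, α2 = 2, β2 = 4, w = 1/3), kept fixed for
  reproducibility; `fit_mgps_prior()` maximizes the marginal
  negative-binomial mixture likelihood when database-wide tuning is wanted,
  returning the default with a flag if optimization fails or the input is
  under-determined.

**Zero cells.** Rather than dropping a pair, any zero cell triggers the
Haldane–Anscombe +0.5 correction of all four cells, with an explicit
`corrected` flag; corrected estimates converge to uncorrected ones as counts
grow, which the tests check on a scaling sequence.

### Joint criteria

A pair is a signal under the conservative joint rule when **all** of:
a ≥ 3, PRR ≥ 2 with chi-square ≥ 4, ROR 95% lower bound > 1, IC025 > 0, and
EBGM05 > 2 (strict, as conventionally printed). The case-count gate a ≥ 3 is
applied to every method. A disjunctive mode (`criteria = "any"`) is also
implemented, since screening practice sometimes labels a pair positive when
any single method crosses its threshold; the conjunctive rule is the
default. Under "all", the false-positive rate on background pairs is far
below any single method's nominal rate — the planted-signal test asserts it
stays at or below 5%.

## Cohort descriptives

`describe_cohort()` reproduces the standard characteristics table blocks
with percentages rounded half away from zero at 2 decimals (matching how
such tables are printed). Time-to-onset bins are reported against two
denominators — all reports, and valid-only records — because both appear in
practice and they answer different questions (data completeness vs onset
distribution).

## Time to onset and the Weibull model

TTO is the day difference between the earliest primary-suspect therapy
start date and the event date. Partial or missing dates exclude the record
as `missing`; negative differences as `negative_outlier`; exclusion reasons
are retained. Quartiles use the `(n+1)p` order-statistic convention
(R `type = 6`): on small samples it lands on observed values, and it matches
the convention of the major commercial statistics systems these tables are
usually produced with.

The two-parameter Weibull is fit by maximum likelihood on
(log shape, log scale) with BFGS; 95% CIs come from the observed information
matrix on the log-parameter scale, back-transformed. The shape parameter β
classifies the hazard: β < 1 (CI entirely below 1) is *early failure*
(decreasing hazard — the typical picture for immune-related adverse events
concentrated in the first treatment cycle), CI entirely above 1 is
*wear-out*, a CI containing 1 with the estimate within 0.15 of 1 is
*random*, and a CI containing 1 with a distant point estimate is reported
*indeterminate*. The 0.15 band is a pragmatic choice — wide uninformative
CIs should not be labelled "constant hazard" just because they cover 1.

**Zero-day onsets.** Events on the therapy start day produce day-0 values,
outside the Weibull support. The default shifts exact zeros to 0.5 day for
the likelihood only (binning and order statistics see the raw zeros); an
interval-censored likelihood treating each recorded day d as [d, d+1) is
available via `zero_handling = "interval"`. The two agree closely on
realistic data.

A known tension in published TTO analyses, preserved here deliberately: a
Weibull with scale ≈ 24 days and shape 0.7 implies a theoretical median of
≈ 14 days, while observed onset medians of ≈ 4 days with Q1 = 0 indicate
zero-inflation the plain Weibull cannot express. The generator therefore
cannot simultaneously match an observed bin distribution that puts > 90% of
events in the first month and the published Weibull parameters; profile
checks target the categorical marginals and the generating parameters, not
both.

## The synthetic generator

`generate_packets()` emulates the data features the pipeline must survive:
follow-up versions sharing a CASEID (always with strictly later FDA_DT and
higher PRIMARYID, so the intended winner is unambiguous), quarterly
deleted-case catalogs, primary-suspect role codes, blanked therapy dates,
multi-outcome reports, and planted drug–event relative reporting rates
(target-drug cases draw their PTs with probability scaled by λ relative to
the uniform background, renormalized). Onset times are Weibull draws rounded
to whole days — matching the day resolution of real dates — with the
pre-rounding values kept in the truth ledger so distributional checks avoid
discretization artifacts. Everything derives from one seed; equal configs
give byte-identical packets.

Outcome codes need care: a report is serious exactly when it carries at
least one outcome code, and published outcome frequencies are marginal over
the whole cohort while summing above 100%. The generator solves the small
fixed-point problem of finding per-outcome Bernoulli probabilities that,
after conditioning serious reports on "at least one outcome", reproduce the
requested marginals.

Generic defaults (`generator_config()`) describe a plausible mid-sized
screen: 1000 cases, 20 background drugs, 50 PTs, ~2 event terms per case,
5% duplicated cases, 2% deletions, 10% missing therapy dates, exponential-
like onsets (shape 1, scale 30 days). `toripalimab_profile()` instead fixes
every marginal to the published toripalimab cohort (441 reports, 89.57%
pharmacist-reported, 99.77% serious, onset Weibull scale 23.88/shape 0.70,
10.66% missing dates).

What the generator does **not** emulate — so what passing tests do not show
about real data: real drug vocabularies and polypharmacy, indication
channeling and other reporting biases, duplicate cases under *different*
CASEIDs (probabilistic duplicate detection is out of scope), masking by
competing signals, and MedDRA's full multiaxial hierarchy (the shipped
mapping assigns each PT a single primary SOC; real MedDRA is licensed).

## Numerical choices

* Marginal products in the chi-square are computed in double precision
  (32-bit integer overflow is a real risk at database scale).
* The EBGM posterior mixture weight uses log-sum-exp; EBGM05 root-finding
  brackets the 5th percentile between extreme component quantiles with
  `tol = 1e-10`.
* Prior fitting optimizes on log/logit-transformed parameters with
  L-BFGS-B bounds wide enough to be vacuous in practice.
* The Weibull start point is shape 1, scale = mean; the likelihood is
  smooth and unimodal in these coordinates for positive data, and the
  MLE is verified in tests against a 50x50 grid and an independent fitter.
* Test problem sizes: the exhaustive formula sweep covers every table with
  N ≤ 60 (~600k tables, vectorized) plus 1000 random larger tables;
  EBGM quadrature checks run on 200 random tables; parameter recovery uses
  100 replicates of n = 394; the end-to-end planted-signal run uses 5000
  cases. These sizes make the full suite complete in a few minutes on one
  CPU while leaving the statistical assertions well-powered.

## Limitations

Disproportionality is hypothesis-generating only: with no exposure
denominator, neither incidence nor causality can be inferred, and
reporting biases (stimulated reporting, channeling, geography) pass straight
through the statistics. The pipeline deliberately implements no stratified
or regression-based adjustments (out of scope here), no fuzzy duplicate
detection, and no competing-risks analysis of onset times.
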