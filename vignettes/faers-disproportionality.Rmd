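---
title: "Disproportionality signal detection and time-to-onset analysis for spontaneous adverse-event reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection and time-to-onset analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

## The problem

Spontaneous-reporting systems such as the FDA Adverse Event Reporting
System (FAERS) collect unsolicited reports of suspected adverse drug
reactions (ADRs). They have no denominator — nobody knows how many patients
took a drug without an event — so risk cannot be estimated directly.
*Disproportionality analysis* works around this by asking whether a
drug–event pair is reported *more often than expected* given the rest of
the database. `faersignal` implements the complete desk workflow for one
target drug (the shipped defaults are configured for tildrakizumab, an
IL-23 p19 inhibitor used in moderate-to-severe plaque psoriasis): record
cleaning, 2×2 contingency construction at the MedDRA preferred-term (PT)
and system-organ-class (SOC) levels, four signal-detection algorithms,
time-to-onset (TTO) modelling, and descriptive reporting — plus a
synthetic FAERS-like generator so that every stage can be validated
against known ground truth without downloading the real database.

## Record cleaning

FAERS quarterly extracts are `$`-delimited ASCII tables covering seven
areas (DEMO, DRUG, REAC, THER, INDI, OUTC, RPSR). Cleaning follows the
standard sequence, in a fixed order:

1. **Deduplication.** Cases are resubmitted across quarters under the same
   `CASEID` with new `PRIMARYID`s and `FDA_DT`s. We keep one row per
   `CASEID`: the latest `FDA_DT`, ties broken by the largest `PRIMARYID`.
   The common alternative — largest `PRIMARYID` outright — is available as
   `deduplicate(mode = "max_primaryid")`; the two agree whenever versions
   are submitted in order, which is how real resubmissions behave.
   Deduplication is applied across the whole loaded quarter range, not per
   quarter, because resubmissions cross quarter boundaries.
2. **Target-drug matching.** `DRUGNAME` entries are matched
   case-insensitively, whitespace-normalized, and *exactly* against a
   synonym list (12 brand/generic/blinded-label variants ship as the
   default). Substring matching is deliberately off by default — free-text
   drug names produce combination-name collisions — but available behind a
   flag.
3. **Primary-suspect filter.** Only reports documenting the target drug
   with role code `PS` form the target case set. Reports mentioning the
   target in a non-suspect role (SS/C/I) remain in the background, since
   the background is meant to be "all other ADR reporting"; a
   `drop_target_mentions` flag removes them entirely for sensitivity
   analysis.
4. **PT and indication exclusions.** Administration/logistics terms
   ("Product dose omission issue", "Needle issue", ...) are not adverse
   reactions and are removed from reaction lists; "Product used for
   unknown indication" is removed from indications. A case whose only
   reactions were excluded is dropped and logged.

Every stage logs its count into a `cleaning_report`, whose counts are
non-increasing by construction.

## The 2×2 table and the four algorithms

For one (drug, term) pair:

|                | term reported | term not reported |
|----------------|---------------|-------------------|
| target drug    | a             | b                 |
| all other drugs| c             | d                 |

with n = a+b+c+d. The counting unit is the **unique report**: a report
listing the same PT twice counts once, and at SOC level a report counts
toward a SOC if at least one of its PTs maps there. Report-level counting
is the common FAERS practice and matches how case counts are tabulated in
published descriptive tables.

The four estimators:

* **ROR** (reporting odds ratio) = ad/bc, with
  95% CI = exp(ln ROR ± 1.96·√(1/a+1/b+1/c+1/d)).
* **PRR** (proportional reporting ratio) = [a/(a+b)]/[c/(c+d)], with the
  Pearson χ² = n(ad−bc)²/[(a+b)(c+d)(a+c)(b+d)], no Yates correction by
  default (the convention in the FAERS disproportionality literature; a
  flag enables it).
* **IC** (BCPNN information component) = log2(RRR), where
  RRR = a·n/[(a+b)(a+c)] is the observed-over-expected reporting ratio.
  The lower bound IC025 uses the Norén closed-form approximation
  IC − 3.3(a+0.5)^(−1/2) − 2.0(a+0.5)^(−3/2). A "fixed-width" mode
  (IC − constant) is provided purely as a compatibility option for
  published outputs whose IC−IC025 gap is constant across rows; it is not
  a standard interval and is documented as such.
* **EBGM** (gamma-Poisson shrinkage). The default reporting surface uses
  the simplified form: point estimate = RRR with
  EB05 = exp(ln RRR − 1.645·√(1/a+1/b+1/c+1/d)). This reproduces the
  identity IC = log2(EBGM) that published signal tables display row by
  row. The full DuMouchel empirical-Bayes fit is available as
  `mgps_full()`: a two-component gamma mixture prior on the reporting
  ratio λ, five hyperparameters fitted by maximizing the marginal
  negative-binomial-mixture likelihood of the observed a given
  E = (a+b)(a+c)/n, with EBGM = 2^{E[log2 λ | a]} and EB05 the 5th
  posterior percentile. It can back the whole signal table via
  `signal_table(..., ebgm_mode = "dumouchel")`.

Useful algebraic facts (all property-tested): IC ≡ log2(RRR) exactly;
whenever ad > bc, ROR > PRR > RRR; doubling every cell leaves the three
ratios unchanged and doubles χ².

**Zero cells** are an error by default — with the standard N ≥ 3 reporting
threshold a zero a-cell never reaches the table, and zero b/c/d cells
signal a degenerate background — with the Haldane–Anscombe +0.5 correction
behind a flag.

**Signal classification.** The conventional thresholds: ROR requires
N ≥ 3 and CI lower bound > 1; PRR requires PRR ≥ 2, χ² ≥ 4, N ≥ 3; BCPNN
requires IC025 > 0; MGPS requires EB05 > 2. A term is *positive* when the
ROR criterion holds and *significant* when **any** two or more criteria
hold. Whether "significant" should additionally demand the ROR criterion
among the two is genuinely ambiguous in the field's usage; we chose
"any two" because the four criteria are treated symmetrically in the
counting, and expose `signal_criteria(require_ror = TRUE)` for the
stricter reading. All thresholds are configurable.

## Time to onset

TTO = event date − earliest fully specified therapy start date of the
primary-suspect target drug, in days; one TTO per report (group analyses
reuse the report's TTO for each of its PTs/SOCs, mirroring how TTO
distributions are plotted per term from report-level intervals). Reports
with partial (`YYYYMM`, `YYYY`) or missing dates on either side are
excluded with a reason, as are input errors where the event precedes the
start; exclusions are data, never silent drops, and inclusion + exclusion
counts always equal the input count.

The TTO distribution is modelled as Weibull(β, η) by maximum likelihood on
the log-parameters, with 95% CIs from the observed information
(delta method on the log scale, exponentiated). Day counts of zero —
events on the day therapy started — are shifted by +0.5 day and the shift
is logged. β < 1 marks the *early-failure* profile: the hazard of a first
ADR report is highest soon after starting therapy and decreases with time;
η is the time by which 63.2% (1 − e^{−1}) of events have occurred,
whatever β. Goodness of fit uses the one-sample Kolmogorov–Smirnov test
against the *fitted* Weibull with the asymptotic p-value (no Lilliefors
adjustment for estimated parameters — the common practice in TTO
analyses, and a known anti-conservative simplification). Median TTO
differences across SOCs/PTs use the Kruskal–Wallis rank test with tie
correction, unadjusted for multiplicity.

Binning: months are 30-day windows, quarters aggregate three months, and
the twelfth month extends to the 365-day year cutoff so the bins partition
[0, 365]; values beyond 365 days form the over-one-year tail. Published
quarterly TTO series rarely state their bin edges; these defaults are the
natural calendar-free choice and are configurable. Growth rates are
(N_t − N_{t−1})/N_{t−1} in percent at one decimal, undefined (NA) after an
empty bin.

## The synthetic generator

`generate_dataset()` emits a full FAERS-dialect quarterly file set with a
ground-truth ledger, so the cleaning rules, contingency counts, signal
classification and TTO pipeline can each be checked against known
answers. What it emulates:

* multi-drug reports (truncated-geometric drug count, mean ≈ 2.7 with the
  default p = 0.6) with exactly one primary-suspect drug per report, the
  target appearing under a random synonym variant;
* background drug–PT co-occurrence from a 58-term demonstration
  vocabulary across 12 SOCs, with configurable injected relative risks
  for target reports (PT probability = baseline × RR, capped);
* duplicate case versions (same `CASEID`, strictly increasing
  `PRIMARYID` and `FDA_DT`) at a configurable rate, so the deduplication
  rule has a unique correct answer;
* heavy categorical missingness with Unknown as a first-class category;
  the default demographic targets reflect the composition typical of a
  recently approved dermatology biologic: 16% missing sex, 58% missing
  age, 79% missing weight, consumer-dominated reporting (~52%), ~68% US
  reports, and year-on-year growth in report volume;
* therapy/event dates whose difference follows Weibull(β = 0.89,
  η = 269.56 days) — the early-failure onset profile — with a configurable
  fraction of partial dates (default 5%) and of event-before-start input
  errors (default 1%) to exercise the exclusion logic;
* one exclusion-list PT and the uninformative indication term injected at
  a configurable rate (default 2%).

What it does **not** emulate: reporting-delay dynamics, drug–drug
interactions, real MedDRA coding beyond the flat PT→SOC lookup,
correlated PT co-reporting within a report (PTs are independent
Bernoulli draws given the drug), or the masking effect that a dominant
reporter drug exerts on the background. Passing tests on synthetic data
therefore demonstrate that the *pipeline arithmetic and decision rules*
are correct under known truth — not that the criteria have any particular
operating characteristics on real FAERS data, where duplicates are
messier, drug names dirtier, and backgrounds confounded.

Free parameters the published study conditions do not pin down — the
drugs-per-report and PTs-per-report distributions, the background drug
list, baseline PT probabilities — were chosen once at field-plausible
values (roughly 1–3 PTs and 1–5 drugs per report) and left alone.

## Numerical choices

* Weibull MLE: BFGS on (log β, log η) from a log-moment start
  (β₀ = 1.2826/sd(log x)); CIs from the inverted observed-information
  matrix on the log scale. Cross-checked in the tests against
  `MASS::fitdistr` (dual route) with our optimum's log-likelihood required
  to be at least as good.
* MGPS: Nelder–Mead on the five transformed hyperparameters from
  DuMouchel's classic start (0.2, 0.1, 2, 4, 1/3); the fit aborts if the
  optimum fails to improve on its initialization. EB05 is found by
  root-finding on the posterior mixture CDF. Hyperparameter recovery is
  verified on 10⁴ simulated tables with a known two-gamma prior (mixture
  mean recovered within 10%; observed error ≈ 0.4%).
* Dates are kept as text until needed; partial dates are never coerced to
  a day. Dedup ties compare `PRIMARYID` numerically.
* Percentages are reported at one decimal with the full total (unknowns
  included) as denominator, matching descriptive-table convention.
* Rounded values (2 decimals for estimators, 1 for percents) appear only
  in exported files; full precision is retained in memory.

## Problem sizes used by the test suite

The suite validates recovery at the published study's scale: 200
replicates of n = 335 for Weibull shape recovery (mean MLE shape within
±0.02 of the true 0.89; CI coverage within [0.90, 0.99]), 10⁵-report
generator runs for demographic marginal fidelity (3 standard errors), and
50 seeded end-to-end runs at 3,000 reports for signal recovery (an
injected RR = 10 PT classified significant in ≥95% of runs, null-PT
ROR-flag rate ≤10% — an empirical specificity screen, not a calibrated
test level).

## Known limitations

* The simplified EBGM surface equals RRR, i.e. no shrinkage at the point
  estimate; genuine shrinkage requires `ebgm_mode = "dumouchel"`.
* The BCPNN IC025 is a closed-form approximation, not the full posterior
  credible bound.
* No masking-effect or innocent-bystander correction, and no
  multiple-testing adjustment: the classification criteria are exactly
  the conventional thresholds, which behave as a screen.
* Drug-name handling is a synonym list, not RxNorm normalization; the
  PT→SOC map is a flat demonstration table, not a licensed MedDRA
  dictionary.
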