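# faersignal

Pharmacovigilance signal detection for FAERS-style spontaneous
adverse-event reports. The package implements the complete desk workflow
for one target drug — the shipped defaults are configured for
tildrakizumab, an IL-23 p19 inhibitor used in plaque psoriasis — from raw
`$`-delimited quarterly tables to classified safety signals and a
time-to-onset model, together with a synthetic FAERS-like generator with
ground truth so the whole pipeline is testable without the real database.

## What it computes

Spontaneous-report databases have no exposure denominator, so drug–event
association is assessed by disproportionality on a 2×2 table per
(drug, term) pair — `a` target-drug reports with the term, `b` without,
`c`/`d` likewise for all other reports (n = a+b+c+d):

* **ROR** = ad/bc with 95% CI exp(ln ROR ± 1.96·√(1/a+1/b+1/c+1/d))
* **PRR** = [a/(a+b)]/[c/(c+d)] with Pearson
  χ² = n(ad−bc)²/[(a+b)(c+d)(a+c)(b+d)]
* **IC** = log2(RRR) where RRR = a·n/[(a+b)(a+c)], with the Norén
  closed-form IC025
* **EBGM** with EB05 — simplified closed form by default, full DuMouchel
  empirical-Bayes gamma-Poisson shrinker (`mgps_full()`) as an option

A term is **positive** when the ROR criterion is met (N ≥ 3 and CI lower
bound > 1) and **significant** when ≥ 2 of the four algorithm criteria are
met (PRR ≥ 2 & χ² ≥ 4 & N ≥ 3; IC025 > 0; EB05 > 2).

Time to onset (therapy start → event, in days) is summarized
(median/IQR), binned into 30-day months and quarters with growth rates,
and fitted with a Weibull law by maximum likelihood: shape β < 1 means an
early-failure profile (hazard decreasing with time on therapy) and scale
η is the time by which 63.2% of events have occurred. Goodness of fit by
Kolmogorov–Smirnov; group comparisons by Kruskal–Wallis.

Cleaning follows the standard FAERS sequence: cross-quarter case
deduplication (latest `FDA_DT`, ties to largest `PRIMARYID`), synonym
matching of the target drug (12 shipped name variants), primary-suspect
filtering, and removal of administration/logistics PTs and the
uninformative indication term.

## Worked example

```r
library(faersignal)

cfg <- faers_config(
  n_reports = 20000, target_fraction = 0.06, seed = 42,
  injected_signals = data.frame(
    pt = c("Vulvovaginal candidiasis", "Herpes zoster"),
    rr = c(25, 6)))
ds <- generate_dataset(cfg, out_dir = "demo_faers")

cl <- clean_cases(ds$tables)
print(cl$report)
#> Cleaning report (target-drug pipeline)
#>   raw DEMO rows                              22072
#>   unique cases after dedup                   20000
#>   cases mentioning target (any role)         1533
#>   cases with target as primary suspect       1261
#>   target cases after PT exclusion            1261
#>   excluded PT rows removed: 393

tabs <- build_all(cl$target, cl$background, level = "PT")
sig  <- signal_table(tabs[tabs$a > 0 & tabs$c > 0])
sig[order(-sig$ror)][1:3]
#>                       term  N   ror ror_low ror_high   prr   chi2   ic ic025
#> 1 Vulvovaginal candidiasis 74 28.43   19.33    41.83 26.82 659.63 3.35  2.97
#> 2            Herpes zoster 54  5.40    3.94     7.40  5.21 137.47 2.04  1.59
#> 3                 Migraine 26  1.64    1.09     2.46  1.62   5.69 0.64 -0.01
#>    ebgm ebgm05 classification
#> 1 10.21   7.38    significant
#> 2  4.12   3.16    significant
#> 3  1.56   1.11       positive

tt <- compute_tto(cl$target)
f  <- fit_weibull(tt$tto$tto_days)
print(f)
#> Weibull TTO fit (n = 390, 2 zero-day values shifted by +0.5)
#>   shape beta = 0.871 (95% CI 0.807-0.941)  [early onset type]
#>   scale eta  = 258.47 days (95% CI 229.22-291.46)
#>   ~63.2% of events occur within 258.5 days
weibull_ks_test(tt$tto$tto_days, f)$p_value
#> [1] 0.94
```

The two injected terms come out `significant` (all four criteria for the
RR = 25 term), a baseline term drifts into `positive` — the expected
false-positive behaviour of the ROR screen — and the fitted Weibull
recovers the generator's early-onset truth (β = 0.89, η = 269.56 days)
within its confidence intervals; the KS p-value ≫ 0.05 says the day
counts are compatible with the fitted Weibull.

The full orchestrated run (`run_pipeline(input, out_dir)`) additionally
writes SOC-level signals, algorithm-overlap counts, demographics,
sex-stratified signals with a z-test on the log-ROR difference, and a JSON
run log with stage counts.

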