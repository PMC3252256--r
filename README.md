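# abxflow

Hospital antibiotic-use surveillance in WHO ATC/DDD units: ward stock
accounting versus pharmacy sales, and the statistics that say how far the
latter can be trusted.

Hospitals usually measure antibiotic consumption by what the pharmacy sells
to each ward. Wards, however, buy for a shelf, not for a patient: sales lag
and overshoot true use as ward stock fluctuates, and the distortion grows
as the registration interval shrinks. abxflow is for pharmacoepidemiologists
and stewardship teams who want to quantify that distortion. It implements:

- **DDD units** — conversion of pack counts (vials, bags, tablets) and
  milligram amounts to defined daily doses via an editable ATC/DDD
  reference table, plus the DDDs/100-bed-days utilisation rate.
- **Two accounting routes** — weekly consumption per ward × agent from
  (a) shelf counts corrected for deliveries, loans, discharge take-aways,
  discards and returns (the balance
  `C_w = S_{w-1} − S_w + inflows − outflows`), with holiday count gaps
  averaged by block; and (b) pharmacy sales net of returns.
- **Agreement statistics** — dual registrations per ward × agent ×
  k-week interval (k = 1..4); intraclass correlation from two-way ANOVA
  variance components, `ICC = σ_s² / (σ_s² + σ_e²)` with exact F-based
  confidence intervals and the 0.7 sufficiency threshold; Bland-Altman
  mean difference and limits of agreement `d̄ ± 1.96·s_d`, converted to
  interval-level DDD use ranges.
- **A ward/pharmacy simulator** — daily Poisson demand, reorder-point
  ordering (small frequent parenteral orders, lumpy oral bulk), incidental
  stock flows at ≈1% of use, and missing count blocks — so the entire
  pipeline is testable without hospital data.

Everything takes a data frame and returns a tibble; results have
`tidy()`/`glance()` methods and `autoplot()`.

## Worked example

```r
library(abxflow)

bundle <- run_pipeline(default_study_config(seed = 42))

dplyr::filter(bundle$consumption, class == "All BSAs")
#>   ward_id    class    pharmacy_ddd ward_ddd diff_pct
#> 1 all_wards  All BSAs        3972.    3944.      0.7
#> 2 endo_haem  All BSAs         700.     695.      0.7
#> 3 gastro_inf All BSAs         812.     848.     -4.5
#> 4 pulmonary  All BSAs        1206.    1191.      1.2
#> 5 urology_1  All BSAs         624.     591       5.4
#> 6 urology_2  All BSAs         630      620.      1.7
```

Over the full 26 weeks the two methods agree to 0.7% overall, while single
wards deviate by up to ±5% — the shelf buffers the short run, not the long
run. Reliability by stratum and interval length:

```r
dplyr::filter(bundle$reliability, stratum != "all")
#>   k stratum      n   icc ci_low ci_high sufficient
#> 1 1 oral       130 0.127 -0.045   0.293 FALSE
#> 2 1 parenteral 910 0.775  0.748   0.800 TRUE
#> 3 2 oral        65 0.278  0.039   0.488 FALSE
#> 4 2 parenteral 455 0.915  0.898   0.928 TRUE
#> 5 3 oral        40 0.420  0.129   0.645 FALSE
#> 6 3 parenteral 280 0.959  0.948   0.967 TRUE
#> 7 4 oral        30 0.526  0.210   0.742 FALSE
#> 8 4 parenteral 210 0.972  0.964   0.979 TRUE
```

Parenteral agents (ordered often, in small amounts) clear the 0.7
reliability threshold already at one week; oral ciprofloxacin (bought in
5-50 DDD bulk against a ~10 DDD weekly use) stays below it even at four
weeks — the interval-length and route gradients that motivate caution with
short-interval pharmacy data. The Bland-Altman side of the same comparison:

```r
pairs4 <- build_paired_registrations(
  bundle$pharmacy_series, bundle$ward_series,
  k = 4, omit_weeks = c(12, 26)
)
glance(bland_altman(pairs4))
#>   mean_difference sd_difference loa_low loa_high n_pairs mean_of_means
#> 1         0.00255          6.51   -12.7     12.8     240          15.2
autoplot(bland_altman(pairs4))
```

A near-zero mean difference (no systematic bias) with ±12.8 DDD limits per
registration. `agreement_report()` anchors those limits at the mean
interval use to give the percent bands that shrink from ≈7% (1-week) to
≈2% (4-week) for all agents combined, but only reach ≈14% for oral agents.

Input CSVs (shelf counts, flow records, sales ledger) run through the same
pipeline with `run_pipeline_files()`; `inst/cli/abxflow.R` wraps simulate /
account / compare / report / demo subcommands for shell use.

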