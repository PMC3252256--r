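---
title: "Measuring hospital antibiotic use: ward stock accounting, pharmacy sales, and how well they agree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring hospital antibiotic use: ward stock accounting, pharmacy sales, and how well they agree}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abxflow)
library(dplyr)
```

## The measurement problem

Most European hospitals monitor antibiotic consumption through pharmacy
sales: the DDDs (WHO defined daily doses) sold by the hospital pharmacy to
each ward. But wards hold their own drug stock, so sales measure stock
*replenishment*, not patient consumption. Between an order and the doses it
eventually supplies sits a shelf whose level fluctuates with ordering
habits, loans between wards, discards of expired drugs, and packs sent home
with discharged patients. Over a long window the two signals must almost
agree — the shelf cannot drift forever — but over a short registration
interval (a week, a month) pharmacy data can misstate true use badly,
especially for cheap, storable oral formulations bought in bulk.

abxflow implements both measurement routes and the statistics that quantify
how well the proxy tracks the reference, plus a simulator that generates
ward/pharmacy data with exactly this structure so the whole pipeline can be
validated end to end.

## The two accounting routes

**Ward stock accounting** (the reference method). A pharmacist counts the
shelf (vials, infusion bags, tablets) at every week boundary; packs convert
to DDDs via a reference table (`ddd_reference()`); consumption in week $w$
is the stock balance

$$C_w = S_{w-1} - S_w + \text{deliveries}_w + \text{loans in}_w
      - \text{loans out}_w - \text{discharge take-aways}_w
      - \text{discards}_w - \text{returns}_w,$$

implemented by `ward_consumption()`. When counts are missing for a run of
weeks (holidays), the balance is applied across the whole gap — the gap
total is the only quantity computable without the missing counts — and
split evenly over the gap's weeks, which are flagged imputed. This
conserves the series total exactly; the tests assert it.

**Pharmacy sales** (the proxy). `pharmacy_consumption()` sums the DDDs of
every order per ward × agent × week and subtracts returns. Cells with no
records are zero — a ward that ordered nothing consumed, by this method,
nothing. A return-heavy week may go negative; no floor is applied, because
the negative value is real information about stock flowing backwards. The
same gap-averaging (`impute_missing_blocks()`) is applied to the pharmacy
series as to the ward series, so neither method is smoothed relative to the
other.

Both series aggregate over **registration intervals** of $k$ weeks
(`aggregate_intervals()`): retained weeks, sorted, are partitioned into
consecutive non-overlapping blocks of $k$ and summed. A 26-week study
divides evenly for $k \in \{1, 2\}$; for $k \in \{3, 4\}$ two weeks must be
omitted first, and the default drops weeks 12 and 26 — the weeks whose
counts were incompletely acquired in the scenario the package emulates, so
the omission also discards the least reliable data. Week indexing is
1-based throughout and intervals are closed week ranges. An indivisible
combination is a configuration error naming the remainder, never a silent
truncation.

`build_paired_registrations()` joins the two aggregated series into dual
registrations — one (pharmacy, ward) pair per ward × agent × interval.
Pairs where both methods record zero are **retained**: in a realistic
five-ward, eight-agent study roughly half of all registrations are
double zeros (carbapenems are simply not used on urology wards), and
dropping them would overstate between-cell variance and misrepresent the
workload a surveillance system actually faces.

## Agreement statistics

**Reliability (ICC).** Each dual registration is a subject measured by two
fixed methods, a two-way mixed-effects layout. `anova_mean_squares()`
computes the subject, method and error mean squares from explicit sums of
squares, and `icc_from_anova()` forms the consistency, single-measures
intraclass correlation

$$\mathrm{ICC} = \frac{MS_s - MS_e}{MS_s + (k-1)\,MS_e}
             = \frac{\sigma_s^2}{\sigma_s^2 + \sigma_e^2},$$

with $\sigma_s^2 = (MS_s - MS_e)/k$ the between-subject and $\sigma_e^2 =
MS_e$ the within-subject variance component ($k = 2$ raters). The
consistency variant is deliberate: a systematic level shift between
pharmacy and ward figures is the business of the Bland-Altman analysis, so
the ICC is left to measure relative ordering. An absolute-agreement variant
(ICC(A,1), McGraw & Wong) sits behind `icc(type = "agreement")`. The 95%
confidence interval comes from the exact F ratio $MS_s/MS_e$ with
$(n-1, (n-1)(k-1))$ degrees of freedom, transformed through the same
formula — fully specified, standard for single-measure ICCs. The
conventional sufficiency threshold is 0.7, applied inclusively
(`reliability_verdict()`). Degenerate inputs (no variance at all, e.g. an
all-zero stratum) yield an explicitly undefined ICC with a reason, never a
`NaN` that propagates silently.

**Bias and limits of agreement.** `bland_altman()` summarises the
differences $d_i = \text{pharmacy}_i - \text{ward}_i$ (this orientation
everywhere) by their mean, their $n-1$ standard deviation, and limits
$\bar d \pm 1.96\, s_d$ — the conventional normal-range multiplier, not a
$t$ quantile. `loa_to_use_range()` then anchors the limits at the mean
interval-level use, $((P + W)/2)/\text{intervals}$, to express agreement as
a DDD range with percent deviations. The report tables add the
per-registration limits to the mean use directly (`n_cells_per_interval =
1`): a design choice worth spelling out, since one could also argue for
scaling the limits by the number of registrations summed per interval.
Scaling by the 40 ward × agent cells would treat the per-cell bias bound as
if it struck every cell simultaneously in the same direction, and produces
bands several times wider than the interval totals themselves — not a
usable summary. The unscaled form answers the practical question "how far
from the mean use could a single registration-interval figure plausibly
sit", and is the convention the package's report tables follow.

## The simulator

`simulate_wards()` realises the mechanism that separates the two signals.
Per ward × agent, each day:

1. **Demand**: a Poisson draw of pack units (rate = mean weekly DDDs /
   pack size / 7). Unmet demand is backordered and served as soon as stock
   arrives, mirroring same-day resupply from a neighbouring ward or the
   pharmacy. An optional `patient_courses` model draws Poisson patient
   arrivals, each consuming a 4-8 day course, for burstier weekly totals.
2. **Ordering**: when shelf stock falls below the route's reorder point, an
   order of a sampled size is placed and delivered the same day (one sales
   record, one delivery flow). Defaults: parenteral agents reorder at 8
   DDDs with uniform 5-10 DDD orders; oral ciprofloxacin reorders at 15
   DDDs with 5-50 DDD orders weighted so the median order is 20 DDDs —
   small frequent parenteral orders versus lumpy oral bulk, the contrast
   that drives the oral stratum's poor short-interval reliability.
3. **Incidental flows**: one-pack loans, discards, discharge take-aways and
   returns at configured rates, defaulting to about 1% of use in total for
   the three non-consumption removals.
4. **Counting**: stock is recorded at each week boundary, except boundaries
   inside a configured missing-count block (defaults: weeks 10-12 and
   25-26, the holiday gaps). In a daily-tick simulation the real protocol's
   within-day ordering (count after morning doses, before orders) reduces
   to the placement of the boundary, which is what the package implements.

An eight-week burn-in runs before the study window so stock starts in its
reorder-policy steady state; without it, the arbitrary initial shelf level
drains through the window and biases pharmacy totals low — a start-up
artifact a real ward stocked for years would not show. Random streams are
split per ward × agent via a per-cell seed hash, so extending a
configuration with a new agent leaves every other series bit-identical.

The default scenario (`default_study_config()`) is calibrated to a
26-week, five-ward surveillance profile of a mid-size tertiary-care
hospital: a cephalosporin-heavy pulmonary ward, a mixed
gastro/infectious-diseases ward, an endocrinology/haematology ward, and two
ciprofloxacin-dominated urology wards with zero carbapenem use. Expected
totals: ≈3 970 DDDs over 26 weeks, half of it ciprofloxacin, 77% of that
oral. Within-class splits (3rd-generation cephalosporins 50/30/20 across
cefotaxime/ceftazidime/ceftriaxone; carbapenems 60/40 across
meropenem/imipenem) and the reorder parameters are free choices, set once
to reproduce the order-count magnitudes (tens of orders per agent over 26
weeks) and not tuned thereafter.

What the simulator does **not** emulate: seasonal or outbreak-driven demand
trends, correlated demand across agents (therapy switching), per-patient
attribution, data-entry errors, and any intra-day structure beyond the
morning-dose/ordering sequence. Passing tests therefore demonstrate that
the accounting and statistics are correct *given* records of this form,
and that the qualitative reliability gradients (interval length, route)
emerge from stock dynamics alone — not that real hospital data meet the
model's assumptions.

## Correctness properties the tests pin down

* **End-to-end conservation**: with complete flow records,
  `ward_consumption()` reproduces the simulator's true weekly consumption
  to ≤ 1e-9 for every ward × agent × week, across 1 000 fuzzed small
  scenarios and both demand models.
* **Ledger identity**: pharmacy sales equal true consumption + net stock
  change + non-consumption outflows − loans in, exactly.
* **Mass conservation** under gap imputation and interval aggregation, and
  the $k$-invariance of the summed pair differences.
* **ANOVA oracle**: the closed-form mean squares match an independent
  `lm()`/`anova()` fit on random layouts.
* **Statistical structure**: ICC = 1 on identical and constant-offset
  pairs; affine invariance; monotone decline with added noise; variance
  component recovery ($\sigma_s^2 = 9$, $\sigma_e^2 = 1$) within the F
  interval.
* **Study-scale gradients**: over 20 simulator replicates, mean ICC at
  4-week intervals exceeds the 1-week value, and parenteral reliability
  exceeds oral at 1 week; the agreement band narrows monotonically from 1-
  to 4-week intervals.

Problem sizes were chosen to keep the default suite comfortably under a few
minutes: fuzz scenarios use 1-3 wards × 2-4 agents × 4-8 weeks, and the
replicate-based checks use 20 runs of the full five-ward scenario.

## Numerical and reporting conventions

Percentages in report tables are rounded half-away-from-zero to one
decimal (`round_half_out()`) at serialization only; every internal value
keeps full precision, and a test asserts that no report-layer rounding
feeds back into computation. Percent differences with a zero pharmacy
denominator are reported as missing, matching the convention of printing a
dash for never-ordered agents. The 2-week mean-use figure quoted in
summaries of such studies is often the doubled 1-week figure (2 × 152.8 =
305.6); the package reports the directly computed value (≈305.66), the
discrepancy being one rounding step.

## Known limitations

* The ICC confidence interval for the consistency form is exact only under
  normality of the components; with many double-zero registrations the
  distribution is far from normal and the interval should be read as
  approximate. Any analysis of this design shares the caveat.
* Bed-day denominators enter only as scalars (`ddd_per_100_bed_days()`);
  there is no census ingestion.
* No regression-based (proportional-bias) Bland-Altman extension: the
  plots produced by `autoplot()` are the right tool for spotting
  a trend of differences with magnitude, but the package does not model it.
* The DDD reference ships as editable configuration because DDD
  assignments change between ATC index years; users comparing against
  other studies must pin the same index year.
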