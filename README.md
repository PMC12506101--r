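# bmirrda

Body mass index (BMI) is recorded opportunistically and inconsistently across
electronic health record (EHR) systems: primary care holds directly coded BMI
values, heights, weights and BMI category codes; hospital episodes only carry
obesity diagnoses; maternity and child-measurement programmes hold structured
heights and weights for specific subpopulations. `bmirrda` turns these four
linked sources into a single **research-ready data asset (RRDA)**: one
harmonised BMI entry per person per day, with a harmonised category, the
originating source and its trust rank, and a pregnancy flag — plus the
completeness metrics needed to judge how usable the resulting asset is.

It is written for epidemiologists and data scientists working inside trusted
research environments (TREs) who need a reproducible, auditable alternative to
ad hoc per-project BMI extraction.

## The method

The pipeline runs in five stages:

1. **Extraction.** Coded events are matched against user-supplied Read
   Version 2 / ICD-10 code lists and standardised to SI units (with a
   magnitude heuristic for unit-less heights). Implausible values are removed
   — BMI strictly below 12 or above 100 kg/m², heights and weights outside
   configurable bounds — exact duplicates are collapsed, and everything is
   collated into one longitudinal component table. Multiple same-day entries
   from different sources are deliberately retained.
2. **Cohort.** Persons with unreliable linkage, missing week of birth,
   invalid sex, or death within 31 days of study start are excluded (with a
   telescoping exclusion flow). Residency gaps are imputed to the study
   bounds, and per-branch contribution windows are derived: children and
   young people (CYP, ages 2–18 inclusive, 24–228 months) are censored the
   day before their 19th birthday; adults (19–100) at death, out-migration or
   study end.
3. **Derivation.** Child weights are paired with the nearest height within
   180 days; adult weights carry the most recent height forward. BMI is
   weight/height² (kg/m²). Adults are categorised at the conventional
   18.5/25/30 cut-points; children via the LMS (Box–Cox) growth-reference
   transform, `z = ((x/M)^L − 1)/(L·S)`, against configurable percentile
   thresholds (defaults: 2nd/85th/95th).
4. **Cleaning.** Categories are encoded 1–4 (underweight → obese). Same-day
   entries are checked pairwise: value pairs must agree within 5% (relative
   to the smaller) *and* share a category; category-only entries must match
   every other entry's category; both members of any violating pair are
   removed. Adults are additionally screened over time: a change exceeding
   10 kg/m² per year (pro-rated for longer gaps, pregnancy windows exempt)
   is removed.
5. **Selection.** Each surviving person-day is resolved to the entry from the
   most trusted source (rank 1 = directly coded primary-care BMI … rank 6 =
   hospital obesity diagnosis), and entries within ±294 days of a recorded
   birth are pregnancy-flagged.

Every input record is accounted for as *kept*, *removed with a reason*, or
*out of branch*, and the whole run is deterministic.

Because the underlying national data live in a TRE and cannot be shipped, the
package includes a **synthetic linked-EHR generator** (`generate_scenario()`)
producing all six input tables with ground-truth labels, and an independent
naive **reference implementation** (`reference_rrda()`) used for
record-for-record differential testing of the pipeline.

## Worked example

```r
library(bmirrda)

scen <- generate_scenario(scenario_config(n_persons = 100, seed = 42))
run  <- build_rrda(scen$inputs, scen$reference, cfg = scen$config)
run
#> <bmi_rrda_run>
#>   RRDA entries : 655
#>   persons      : 79 with entries / 92 eligible
#>   removed      : 235 records; 82 cleaning decisions
```

655 harmonised person-days survive for 79 of the 92 eligible persons; 235 raw
records were removed with logged reasons (unmatched codes, implausible
values, unpaired weights, same-day and over-time conflicts, rank losers), and
82 of those removals were cleaning decisions.

```r
run$rrda[1:4, c("person_id", "bmi_date", "bmi_value", "category",
                "source", "rank", "branch")]
#>   person_id bmi_date   bmi_value category source  rank branch
#> 1 P0001     2001-10-12      21.9 normal   WLGP       1 adult
#> 2 P0001     2005-11-09      23.4 normal   WLGP       2 adult
#> 3 P0002     2005-09-04      19.4 normal   WLGP       1 adult
#> 4 P0003     2000-12-25      23.0 normal   WLGP       2 adult
```

Rank 1 rows came from directly coded BMI values; rank 2 rows were derived
from a height–weight pair in the same source. How much coverage survives if
only recent records are preserved, relative to the population present at the
study end:

```r
preservation_coverage(run$rrda, run$windows, cfg = scen$config)
#>   branch window_label window_start denominator covered proportion
#> 1    CYP           1y   2022-01-01           7       4      0.571
#> 2    CYP           5y   2018-01-01           7       6      0.857
#> 3    CYP          23y   2000-01-01           7       6      0.857
#> 4  adult           1y   2022-01-01          42      19      0.452
#> 5  adult           5y   2018-01-01          42      38      0.905
#> 6  adult          23y   2000-01-01          42      41      0.976
```

Keeping only the last year of records would cover 45% of the adult
population; preserving the full study period raises that to 98% — the
synthetic population is recorded far more densely than a real one, so these
proportions illustrate the metric, not national completeness.

`annual_coverage()`, `repeat_measurement_stats()` and
`source_overlap_counts()` report yearly coverage and category mix,
repeat-measurement histograms, and upset-plot style source combinations.

A command-line front end over the same functions ships in
`inst/scripts/bmirrda` (`simulate`, `run`, `metrics` subcommands); `cmd_run()`
writes the asset together with its audit log, cleaning decisions, exclusion
flow, metric reports and a run manifest.

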