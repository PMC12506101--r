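---
title: "Harmonising BMI from linked EHR sources: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonising BMI from linked EHR sources}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmirrda)
```

# The problem

BMI appears in routine health data in four shapes: directly coded BMI values,
separate height and weight measurements, coded BMI categories, and obesity
diagnoses. No single source covers the population — primary care dominates
for adults, school measurement programmes for children, maternity bookings
for pregnant women, hospital episodes contribute only an obese label — and
the same person may be measured in several sources on the same day, in
different units, with occasional implausible or contradictory entries.

`bmirrda` resolves this into one entry per person per day with a harmonised
category. This vignette documents the models and rules, the parameters that
matter, the numerical conventions, and the limits of what the synthetic
evidence shows.

# Cohort model

**Week of birth.** Birth dates arrive at week granularity (an anonymisation
convention). All ages are computed from the Monday of the recorded week, so
every derived age is a deterministic function of the stored value. Month
arithmetic uses calendar anniversaries with end-of-month rollback.

**Branches.** A record belongs to the child/young-person branch (CYP) when
the person is 24–228 completed months old at the record date, and to the
adult branch when 19–100 completed years old. Both intervals are closed; at
exactly 19 years (228 completed months) they touch, and the child test takes
precedence so no record maps to both. Records under 2 years are excluded:
BMI category allocation is not routine at that age. This is one genuine
ambiguity in the cohort definitions — 2–18 inclusive in months runs to the
19th birthday, while adults start at 19 — and we resolved it in favour of
the explicit month interval, while *person-time* for the CYP branch still
ends the day before the 19th birthday.

**Exclusions and censoring.** Persons are excluded, in a fixed order, for:
unaccepted linkage-status codes (defaults 1, 4, 39 accepted), missing week
of birth, invalid sex code, death before study start, and death within 31
days of study start. The last rule merges two readings of the cohort
definition ("alive for more than 31 days" versus exclusion "after 31 days of
the study start"); we implement the cohort-definition reading: excluded iff
death date < study start + 31 days. Contribution windows then run from
max(study start, first residency episode, branch entry age) to the earliest
of death, last residency end, ageing out of the branch, or study end; missing
residency dates are imputed to the study bounds. When the residency end was
imputed and ties with the study end, the exit reason reads `study_end`.

# Measurement model

**Units.** Heights are standardised to metres (`cm`, `mm` converted; `lb`,
`stone`, `g` for weights). When the unit string is absent, a magnitude
heuristic treats heights above 3 as centimetres — no human standing height
is ambiguous around 3 m — and logs the decision. Unknown units and
non-positive values reject the record to the audit log rather than guessing.

**Plausibility.** BMI values strictly below 12 or strictly above 100 kg/m²
are removed; the boundary values themselves are kept (a literal reading of
"below 12 and over 100"). Heights outside 0.5–2.5 m and weights outside
5–350 kg are removed. The height/weight constants are package defaults, not
published facts — the rule exists in the methodology but its constants are
not printed — so they are configuration, not contract. A single weight range
is used for both branches because plausibility filtering runs before branch
assignment is possible.

**Pairing.** For children, each weight is paired with the height whose date
is nearest within a 180-day window (ties to the earlier height date):
children grow too fast for stale heights. For adults, the most recent height
on or before the weight date is carried forward; a weight earlier than every
height falls back to the earliest later height. A config switch
(`adult_height_mode = "single"`) instead uses one study-wide most recent
height — both readings of "the most recent height … paired with all the
weights" are supported, with carry-forward as the default because adult
height is near-constant and carry-forward is the convention the method's
discussion describes. The entry's date is the *weight* date: weight varies
much faster than height.

**Categories.** Adults: half-open intervals [18.5, 25), [25, 30), [30, ∞)
close the one-decimal gaps of the conventional printed ranges (24.9–25,
29.9–30); BMI exactly 30 is obese. Children: the LMS transform
`z = ((x/M)^L − 1)/(L·S)` (or `log(x/M)/S` at `L = 0`) against a
user-supplied sex- and age-indexed growth reference, linearly interpolated
between grid ages; the category thresholds are the normal quantiles of
configurable percentiles, default 2nd/85th/95th (z ≈ −2.054, 1.036, 1.645).
Jurisdictions differ here (85th/95th vs 91st/98th), so the percentiles are
parameters rather than constants, and the package ships only a synthetic
reference — real analyses must supply their governed reference table.

# Cleaning rules

Categories are encoded underweight = 1, normal = 2, overweight = 3,
obese = 4, and entries within a person-day are ordered by ascending BMI and
category before checking.

**Same-day.** Two value-bearing entries are consistent iff their relative
difference — denominator the smaller value, a symmetric-conservative choice —
is below 5% *and* their categories agree. A category-only entry is consistent
only with entries sharing its category; any disagreement (one category apart
or more) marks both members of the pair inconsistent. All marked entries are
removed; singletons pass. Mixed days compose the two rules: values against
values by the value rule, category-only entries against everyone by
category. A two-category conflict cannot be more trustworthy than a
one-category conflict, so any categorical disagreement removes the pair.

**Over-time (adults only).** Scanning each person's value-bearing entries
chronologically, an entry is removed when its change from the last kept
value exceeds `overtime_max_annual_delta × max(gap_days, 365)/365` — i.e. at
most 10 kg/m² of change within any one year, pro-rated upwards for longer
gaps. Flooring the rate window at one year means short-interval measurement
noise (a few tenths of a unit within weeks) is never penalised, while a
jump of more than the annual allowance inside a week is still caught.
Entries within the pregnancy window are exempt and do not move the
comparison baseline, so a post-partum return to baseline is not flagged.
Children change rapidly by design and are only cleaned same-day. The exact
over-time rule used on the national asset is not printed in the main
methodology; this rate rule is therefore the package's own declared,
swappable stand-in (`overtime_max_annual_delta`).

**Daily selection.** The minimum-rank entry wins (rank 1 = coded
primary-care BMI value, 2 = primary-care height/weight, 3 = maternity
height/weight, 4 = child-programme height/weight, 5 = primary-care category
code, 6 = hospital obesity diagnosis). Ties break by ascending BMI value
(valueless entries last), then source name — fixed so runs are
bit-reproducible.

**Pregnancy flag.** An entry within ±294 days (42 weeks) of any recorded
baby's birth date for that person is flagged; the record is kept, flagged,
so users can decide how to treat pregnancy-related weight.

# The synthetic generator and what it shows

`generate_scenario()` emulates the six input tables: demographics with
week-of-birth anonymisation, deaths, in/out-migration and injected exclusion
triggers; residency episodes with missing dates; primary-care events coded in
the illustrative (non-authoritative) Read-style code list; hospital obesity
episodes for persons whose true BMI is ≥ 30; maternity bookings ~210 days
before each birth with pregnancy weight gain; and child-programme
measurements. Children follow the synthetic growth reference at a
person-specific z-score (sd 1.0); adults follow a start BMI ~ N(26, 3.5²)
with annual drift ~ N(0, 0.3²) and sub-percent measurement noise. Default
recording rates (0.25 coded BMI, 0.10 height/weight pairs per adult-year,
0.40 child measurements per child-year, 0.08 admissions and pregnancies per
year at risk) were chosen once as structurally plausible magnitudes for the
respective programmes; the generator aims at structural realism (shapes,
linkage, error modes), not at reproducing any national population's margins.

Two properties make the generator a usable oracle:

* natural events get distinct dates per person, and deliberate same-day
  duplicates are written to be exactly consistent, so the only same-day
  removals a correct pipeline can make are the injected conflict pairs
  (30% apart — far from the 5% boundary); this is what makes
  precision = recall = 1.0 a meaningful, deterministic expectation;
* every record carries a truth label (`clean`, `extreme_outlier`,
  `unit_error`, `same_day_conflict`, `over_time_conflict`, `under_2`), and
  the expected asset is computed by `reference_rrda()`, a naive loop-based
  re-implementation kept on a separate code path from the staged pipeline.

Injected unit errors use the two patterns a standardiser must handle:
centimetre heights mislabelled as metres (quarantined by the plausibility
bounds) and pound weights mislabelled as kilograms (structurally
undetectable at a single record; they survive to the asset or fall to the
over-time rule, identically in both implementations).

**What passing tests do not show.** Real EHR data have correlated
measurement error, free-text units, miscoded identities, seasonal and
policy-driven recording patterns, and genuinely ambiguous same-day
disagreements near the 5% boundary. Differential equality shows the two
implementations agree on the declared rules; it cannot show the rules are
clinically optimal, and the synthetic coverage/preservation percentages are
far higher than national EHR completeness because synthetic persons are
recorded densely.

# Numerical choices and degenerate inputs

* Dates are ISO-8601 calendar dates; all printed intervals are closed unless
  stated half-open above.
* The LMS reference is interpolated linearly and is exact at grid knots;
  ages outside the grid are errors, and the pipeline validates up front that
  the reference spans the configured child age range.
* Relative difference uses the smaller value as denominator; comparisons use
  strict inequalities exactly as documented (`< 5%` consistent, `> allowance`
  removed).
* Exact-duplicate collapse keeps the first occurrence in file order and
  records the multiplicity in the audit log.
* Empty inputs produce an empty asset, empty audit and a zero-count
  exclusion flow rather than errors; weights with no pairable height and
  heights used by no weight are accounted (`unpaired_weight`,
  `unpaired_height`) rather than silently dropped.
* All randomness lives in the generator and is governed by a single seed;
  the pipeline itself is deterministic, and outputs are staged and moved so
  failed runs leave no partial files.

# Problem sizes used in verification

The differential suite compares the staged pipeline with the naive reference
implementation on 100 scenarios of 200 persons over 10 years (~65,000
harmonised entries in total); invariants (person-day uniqueness, record
accounting, exclusion-flow telescoping, preservation monotonicity,
categorisation monotonicity, LMS median-zero, same-day oracle equality) are
checked over ≥ 1000 generated cases each; parameter recovery injects
same-day conflicts at 5% of person-days across 20 seeds. These sizes give
the deterministic rules no room to hide while keeping a full verification
run within a few minutes on one CPU.

# Known limitations

* Code lists are user-supplied data; the shipped list is illustrative only.
* Height loss with ageing is not modelled; carry-forward over long intervals
  inflates derived BMI slightly for older adults.
* The over-time rule is a declared stand-in for an unpublished rule and
  should be revisited against the governed implementation when accessible.
* No imputation and no averaging of same-day values: conflicting entries are
  removed, not reconciled (algorithms in the growthcleanr family are a
  complementary alternative).
* Ethnicity, deprivation and rural–urban strata are out of scope; grouping
  columns can be joined by the user downstream.
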