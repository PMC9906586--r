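---
title: "Measuring self-injury mortality and its societal cost"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring self-injury mortality and its societal cost}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(simcost)
```

## The measure

Self-injury mortality (SIM) broadens suicide surveillance to the drug
intoxication deaths that medicolegal practice mostly certifies as
accidents or as undetermined intent, on the argument that such deaths
overwhelmingly arise from repetitive self-harming substance use. The
composite is:

* **all suicides** — ICD-10 underlying causes U03, X60–X84 and the
  intentional-self-harm sequelae code Y87.0 — at any age, regardless of
  the certified manner field;
* **80%** of unintentional drug intoxication deaths (X40–X45, manner
  "accident") among persons aged 15 and over;
* **90%** of drug intoxication deaths of undetermined intent (Y10–Y15)
  in the same age range.

`classify_cause()` implements the code sets, `sim_weights()` holds the
fractions and the age cutoff (all overridable, so the suicide-only
measure is the special case `accident_drug_weight = 0,
undetermined_drug_weight = 0`), and `compute_weighted_counts()` applies
them to aggregated death strata. Two conventions matter:

* **Fractions apply to expected counts.** The 80%/90% fractions multiply
  real-valued stratum counts rather than sampling individual deaths, so
  the measure is deterministic; fractional counts are preserved until
  display.
* **Weight-then-average.** Counts are weighted within each calendar year
  and then annual-averaged over the two-year period. Because the weights
  are linear the opposite order gives identical results, and the suite
  tests that commutativity explicitly.
* **Age cutoff by band lower bound.** The five-year bands align with the
  cutoff, so "15–19" is the first band included in the drug components.
  Unknown-age strata stay in the suicide component (no age restriction)
  but contribute zero to the age-restricted components, and are dropped
  with a warning from cost aggregation, which needs a representative age.

## The cost model

Costs are estimated per death and aggregated linearly, in three
components, all expressed in base-year (default 2019) dollars.

**Medical spending** is assigned by place of death — on scene/at home,
dead on arrival, emergency department, hospital after admission, nursing
home, hospice — with unit costs varying by injury mechanism and age
group. Emergency transportation is added to every death *except* those
on scene/at home, and coroner/medical examiner cost is added for
autopsied deaths (in aggregate mode, an expected autopsy fraction). The
unit-cost tables are mandatory inputs: the published study drew them
from a national injury-costing system whose values are not printed in
the published report, so this package ships only clearly labelled synthetic tables
(`generate_parameter_bundle()`) with a documented schema for supplying
real ones.

**Work loss** follows the human-capital approach. For a decedent of sex
$s$ and age $a$, with one-year survival probabilities $p_s(\cdot)$ and
combined annual earnings $E_s(\cdot)$ (wages + fringe benefits +
household work, looked up by the age band containing each single year of
age),

$$W_s(a) \;=\; \sum_{k \ge 0} \Big(\prod_{j=0}^{k} p_s(a+j)\Big)\,
E_s(a+k)\,(1+r)^{-k},$$

with $r$ the annual discount rate (default 3%) and the first year
undiscounted. Year $k$ is weighted by the probability of living
*through* age $a+k$; at $r=0$ these weights sum to the curtate remaining
life expectancy, which is exactly the `e` column a consistent life table
must carry. This convention (rather than weighting year $k$ by survival
to its start) is what makes the degenerate cases exact: certain survival
for exactly $n$ remaining years at $r=0$ with constant earnings $E$
gives $nE$, and zero survival immediately after the death age gives
zero. The discounting convention is isolated in one function, so a
mid-year alternative is a one-line change.

**Quality-of-life loss** monetizes the quality-adjusted life years lost
from a value per statistical life (VSL, default \$10.7 million, the
figure used in US federal regulatory analysis). Subtracting the
population-average lifetime work loss $\bar W$ (evaluated at birth,
sex-averaged with configurable weights, default 0.5/0.5) from the VSL
gives the average lifetime quality-of-life loss; dividing by life
expectancy at birth $e_0$ gives a per-year value

$$v \;=\; (\mathrm{VSL} - \bar W)/e_0,$$

which is then carried over the decedent's expected remaining years with
the same survival-weighted discounted stream as work loss, scaled by a
quality-of-life fraction (default 0.80, reflecting the reduced baseline
quality of life reported for people with substance-use and mood
disorders). Two consequences are tested as identities: with the fraction
at 1, no discounting and an average-newborn decedent, work loss plus
quality-of-life loss reconstruct the VSL exactly; and the loss is linear
in the fraction.

The per-year value is *not* further tailored by age or sex beyond the
survival stream: the published description mentions that such tailoring
is possible but does not print a formula, so this package applies the
uniform per-year value and flags the choice here.

All components pass through a price index (`inflate_to_base_year()`)
when the unit tables are denominated in another year; the default index
is flat. `total` is always the exact full-precision sum of the three
components; rounding to 0.1 million dollars or whole dollars happens
only at presentation.

### Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `vsl` | 10,700,000 | dollars | value per statistical life |
| `qol_fraction` | 0.80 | — | share of the average person's QoL loss attributed to a SIM death |
| `discount_rate` | 0.03 | per year | present-value discounting beyond the first year |
| `base_year` | 2019 | year | dollar denomination of all outputs |
| `suicide_weight` | 1.0 | — | fraction of suicides counted |
| `accident_drug_weight` | 0.80 | — | fraction of X40–X45 accident deaths counted |
| `undetermined_drug_weight` | 0.90 | — | fraction of Y10–Y15 deaths counted |
| `min_age_drug_component` | 15 | years | band lower-bound cutoff for the drug components |
| `autopsy_fraction` | bundle-specific | — | expected autopsy share in aggregate mode |
| `sex_weights` | 0.5/0.5 | — | sex mix for the population-average work loss |

## Reporting conventions

Every printed integer in the reference tables uses half-away-from-zero
rounding: percent changes (`percent_change()`), component-to-medical
ratios (`component_ratio()`), and per-capita dollars. National rows are
computed from national totals, never by summing display-rounded state
rows.

**Quintiles.** Per-capita percent changes are ranked descending over the
51 jurisdictions and labelled in blocks of 11/10/10/10/10. Tied values
share the better quintile and later blocks shrink so the cumulative
boundaries are preserved. On the reference data this rule widens the top
SIM quintile to 12 states — two states tie at +153% across the 11/12
boundary — which coincides with the published description of the top
quintile as the states "exceeding 152%". Because the published
map-quintile construction is not otherwise specified, the package emits
both the rule-based labels and the raw thresholds
(`attr(x, "quintile_thresholds")`) rather than hard-coding either.

**Regions.** The eight-region Bureau of Economic Analysis grouping ships
as an editable fixture (`bea_regions()`), with the District of Columbia
a state-level peer in the Mideast.

## The reference fixtures and their quirks

The five published tables are embedded verbatim as machine-readable
fixtures (`load_reference_table("T1")` … `"T5"`), including the national
rows; costs are in millions of 2019 dollars as printed. Replaying them
through the reporting layer reproduces the published ratios, rises,
rankings and percent changes. Three transcription-level quirks are worth
knowing; the test suite encodes all three rather than papering over
them:

* One printed row (Alabama, suicide 2018/2019) has components that sum
  0.5 million away from its printed total; every other row in the
  suicide tables is within 0.2.
* Five of the 104 per-capita percent-change cells differ by one point
  when recomputed from the display-rounded per-capita values printed
  beside them; the source evidently computed them from unrounded
  values. The other 99 cells reproduce exactly.
* The composite-measure ratio pair for 2018/2019 (and the work-loss
  ratio for 1999/2000) land on half-integers when recomputed from
  display-rounded components (e.g. 1,476.51), so they are checked to
  within one integer unit rather than exactly.

Populations are not printed; where needed they are back-solved from each
row's count and crude rate (`count / rate × 100,000`), which reproduces
printed per-capita values to within 0.1%.

The absolute dollar totals themselves (for example the \$1.12 trillion
national SIM cost) are **not** independently recomputable from public
inputs, because the underlying medical and earnings unit-cost tables are
unpublished. They are therefore validated only through fixture
arithmetic — ratios, shares, rises and per-capita changes — and the
engine is validated against oracles and synthetic ground truth instead.

## What the synthetic generator does and does not emulate

`scenario_config()` defines a scenario whose defaults are the study
conditions: all 51 jurisdictions, periods 1999/2000 and 2018/2019,
first-period crude rates calibrated to the published national values
(suicide 10.4 per 100,000), a 1.4× rise in suicide rates and a 2.5× rise
in both drug-poisoning classes between periods, and period populations
implied by the published count/rate pairs. Counts are Poisson per
(state, year, cause code, age band, sex) stratum — the natural law for
rare-event death registration — with an optional negative-binomial
switch for robustness experiments; a fixed seed fixes every draw.

The stylized parts, deliberately not matched to any real state: the age
pyramid (a single national shape), the age and sex rate curves (smooth
multipliers, male-skewed, zero below age 10, small in 10–14), the code
mix within each cause class, and the place-of-death/mechanism profile
(`default_profile_mix()`, most deaths on scene or at home). Passing
tests on generated data therefore demonstrates that the *pipeline*
recovers known ground truth — classification, weighting, averaging,
costing and aggregation are correct and unbiased — not that any real
state's epidemiology is reproduced.

`expected_truth()` computes the scenario's analytic expectations with no
sampling: expected weighted counts are `rate × population / 100,000 ×
weight` summed over strata, and expected costs apply the same per-death
cost surface to those expectations. The recovery test draws 200 Poisson
replicates of a three-jurisdiction scenario and requires every pipeline
mean (weighted count and each cost component) to fall within three
Monte-Carlo standard errors of the analytic value; three jurisdictions
keep the suite fast while leaving the per-replicate statistics identical
in distribution to any larger subset, since everything is linear in
population.

The generated life table uses a Gompertz-like hazard with an infant
bump, closes at age 100, and carries the curtate life expectancy implied
by its own survival column, so the bundle satisfies the engine's
internal-consistency identity by construction. Earnings follow a
hump-shaped age profile peaking in the 40s.

## Numerical choices and degenerate inputs

* Aggregated strata are costed at the **band midpoint** age (0 for
  infants, 2 for ages 1–4, 87 for 85+); earnings are band-constant, so
  within-band age choice only affects results through survival.
* Medical cost cells may use `"all"` wildcards for mechanism and age
  group; a more specific cell always shadows a wildcard, and a missing
  cell is a named error, never a silent zero.
* A life table must cover consecutive single years per sex; an age
  outside the table is an error. Zero life expectancy is allowed only
  where the table closes.
* `qol_per_year()` refuses configurations where the average lifetime
  work loss reaches the VSL, which would imply a negative
  quality-of-life value.
* Suppressed cells in mortality exports default to drop-with-warning;
  state-level counts at this aggregation exceed typical suppression
  thresholds, so the default mirrors practice while `"keep"` retains
  them as `NA` for sensitivity work.
* Ranking ties break alphabetically; quintile ties share the better
  quintile (both documented above).

## Known limitations

* Underlying cause only: multiple-cause (contributing-cause) records are
  out of scope.
* No uncertainty intervals on cost estimates — consistent with the
  published analysis, which computed none; the Monte-Carlo machinery
  here quantifies sampling error of the *synthetic* pipeline, not of the
  real-world estimates.
* The quality-of-life per-year value is uniform across age and sex
  (see above); the autopsy flag is only available in expectation for
  aggregate data.
* The synthetic cost tables are placeholders with realistic orders of
  magnitude, suitable for testing and method development, not for
  substantive cost estimates.
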