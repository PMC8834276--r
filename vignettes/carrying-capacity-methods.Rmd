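---
title: "Methods: visitor carrying capacity and Delphi aggregation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: visitor carrying capacity and Delphi aggregation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(etcc)
```

## The model

The package implements the three-stage Cifuentes visitor-capacity cascade.
For a recreation zone of area $A$ (m²) with a per-visitor space standard
$a$ (m²/visitor) and a rotation factor $R_f$ (availability hours divided by
average visit hours),

$$\mathrm{PCC} = \frac{A}{a} \, R_f$$

visitors per day fit physically. Site-specific limiting variables — here
climatic day counts such as frost or fog days — each become a correction
percentage $C_f = (m/M_t)\times 100$ and discount the PCC multiplicatively,

$$\mathrm{RCC} = \mathrm{PCC}\prod_i \frac{100 - C_{f_i}}{100},$$

and the management deficit $FM = \frac{I_{mc}-E_{mc}}{I_{mc}}\times 100$
(ideal versus existing ranger staffing, with the ideal set by a
one-guardian-per-1000-ha standard) discounts once more,

$$\mathrm{ECC} = \mathrm{RCC}\,\frac{100 - FM}{100}.$$

Annual figures are daily figures times the operating season length, which
is site configuration (alpine sites close most of the year), not something
the engine infers.

Two variants are worth flagging. First, the subtractive RCC form
$\mathrm{RCC} = \mathrm{PCC} - \sum_i C_{f_i}$ circulates in the older
literature; it is available behind `mode = "subtractive"` in
`real_carrying_capacity()` but is not the default, because subtracting
percentages from a visitor count mixes units. Second, the ECC and FM
formulas are sometimes typeset with misplaced parentheses
($\mathrm{RCC}\times(100 - FM/100)$); the forms above are the dimensionally
consistent ones and are what the package computes.

## Assumptions

- Zones are scalar areas; no spatial structure, no congestion dynamics
  within a zone, $V = 1$ visitor per $a$ m².
- Correction factors are independent, so they compose multiplicatively;
  order is irrelevant (a tested invariant).
- Limiting variables and the management deficit apply uniformly over the
  operating season; there is no month-by-month resolution.
- One management record per site applies to all of its zones.

## Parameters that matter

| parameter | unit | default | why |
|---|---|---|---|
| `space_per_visitor_m2` | m²/visitor | 2500 (extensive), 1500 (intensive) | the IUCN-style free-movement standards for the two recreation classes |
| `availability_hours`, `average_visit_hours` | h | 8 and 8 | full-day destinations: one visit turnover per day ($R_f = 1$) |
| `Mt` for day-count variables | days | 365 | a day-count limiting variable is bounded by the year |
| `Mt` for hour-count variables | hours | none | no natural base (daylight hours per year vary by convention); must be configured, or a percentage supplied directly |
| `hectares_per_guardian` | ha | 1000 | the Department of Environment staffing standard |
| `operating_days` | days | per site | season length is local knowledge, not computed |

## Rounding

Visitor counts are integers at reporting boundaries only; everything
internal is full precision (`*_exact` columns). The defaults in
`rounding_policy()` — floor for daily PCC and RCC, ceiling for daily ECC,
half-up integer percentages — are the conventions that reproduce the
packaged worked dataset's published table, reverse-engineered from it
(e.g. 1143.2 → 1143 but 1.48 → 2). They are policy, not mathematics, and
all three are configurable. Half-up rounding is implemented explicitly
(`round_half_up()`) because base R rounds half to even.

One consequence needs care: a policy that floors RCC but ceilings ECC can
round ECC above RCC when the two pre-rounding values are less than one
visitor apart. The stage functions are left pure; `compute_site()` clamps
the rounded chain so a reported result always satisfies
PCC ≥ RCC ≥ ECC. The property tests assert the ordering on pre-rounding
values in the close regime and on rounded values otherwise.

## Injected RCC

For the packaged worked dataset the published daily RCC values (1, 2, 4, 6,
1, 2, 1, 3) cannot be recovered from the published correction percentages
by either RCC formula — multiplicatively, Lar ET1 gives 944 visitors/day
against a published 1. Whatever transformation the original analysts
applied is unstated. The package therefore treats observed RCC as optional
injected data: `compute_site(options = list(rcc_daily_override = ...))`
replaces the computed daily RCC for named zones, which is exactly what is
needed to drive the ECC stage to the published values. Computed RCC remains
the default everywhere else, and the injection is recorded in the result
(`rcc_injected`). One published ECC row (a pre-rounding 2.4 printed as 2)
contradicts the ceiling convention the other five rows follow; it is
documented and excluded from the reproduction set rather than special-cased.

## Delphi aggregation

Items are five-point Likert scores (1 = not at all influential … 5 =
extremely influential) grouped into dimensions. Per item the package
reports n, mean, sample SD and sample variance (the $n-1$ denominator; the
source tables this emulates do not state theirs, and their printed SD/V
columns are mutually inconsistent, so they are not reproduction targets).
Ranking within a dimension is competition ranking on descending means:
ties share the smallest rank and the next rank skips. The dimension mean
weights items equally — not by respondent count — which is what reproduces
the published 3.38 / 3.14 dimension scores.

Item retirement between rounds is an explicit per-round plan (a list of
ids), because the emulated survey removed items "according to the experts'
opinions" with no numeric rule. Attrition is likewise explicit and nested.
When the last round's plan removes an item, the final prioritized table
excludes it and ranks are recomputed; the narrated timing of the final
removal is ambiguous in the source, and the plan format can express either
reading (remove in round r's plan vs. round r+1 with no round r+1 matrix).

## The synthetic generators

`generate_site_dataset()` emulates a protected-area system: total areas
3,000–80,000 ha; four recreation-zone classes covering at most ~3% of the
site (extensive classes an order of magnitude larger than intensive);
climatic limiting-day counts drawn Poisson with intensities near the three
packaged synoptic stations' long-term means, truncated at 365 so the
`m ≤ Mt` invariant holds by construction; seasons drawn from
{109, 155, 365} days; guardian staffing 0.3–1.2 per 1000 ha with the
existing capacity a 20–60% fraction of the ideal. `generate_panel()`
emulates the expert survey: 38 experts, three rounds, nested dropout
0/3/2 (so respondent counts run 38 → 35 → 33), 40 items with 2/1/1
retired after each round, responses drawn by discretizing a latent
Gaussian (item mean in [1,5], dispersion 1) at fixed cut-points
1.5/2.5/3.5/4.5 with clamping at the scale ends. The latent-plus-cut-points
design gives "effect size" a single knob and a closed-form discretized
expectation (`likert_expectation()`), which the recovery tests use as an
oracle.

Sub-seeding: artifact $i$ under master seed $s$ uses the stream seeded with
$(1009\,s + i) \bmod (2^{31}-1)$, so generating more sites or rounds never
perturbs earlier ones, and regeneration under a fixed seed is
byte-identical.

What the generators do **not** emulate: spatial zone geometry, correlated
limiting variables, within-year seasonality, expert covariances or
systematic response styles (acquiescence, central tendency), and
informative (non-random) dropout. A green synthetic test therefore
establishes that the pipeline's arithmetic and bookkeeping are correct
under the stated statistical model — not that the model captures any
particular real survey.

## Numerical choices and degenerate inputs

- Half-up rounding uses an absolute epsilon of 1e-9 before the floor to
  absorb binary representation error; all rounded quantities are far from
  that scale.
- Empty correction-factor lists and FM = 0 are identities (tested).
- Zero-area zones yield zero at every stage; a closed season
  (`operating_days = 0`) is allowed in `annualize()` but not in a site
  profile (1–366).
- Ties in ranking are broken for presentation by input order; the rank
  values themselves depend only on the means.
- Subtractive RCC and both RCC modes floor at zero rather than going
  negative.

## Known limitations

- No uncertainty propagation or sensitivity analysis on the correction
  factors; the cascade is deterministic given its inputs.
- The hour-based limiting variable has no default denominator and must be
  configured; the package refuses to guess.
- The validation report checks referential and accounting consistency, not
  plausibility (e.g. it will not flag a 2-hour season).
- Delphi consensus statistics beyond mean/SD/variance/rank (e.g. Kendall's
  W) are out of scope.
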