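---
title: "Paired-mode reporting ratios: model, generator, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paired-mode reporting ratios: model, generator, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reportratio)
```

## The measurement problem

Abortion — and to a lesser degree miscarriage — is underreported in fertility
surveys. Survey programmes therefore collect pregnancy outcomes twice from
the same woman: once in an interviewer-administered face-to-face (FTF)
pregnancy history that records each pregnancy's outcome and end date, and
once in a private audio computer-assisted self-interview (ACASI) that asks a
single count question per outcome over a stated reference period (lifetime in
the 2002 round; the five calendar years preceding the interview year from
2006 onward). Comparing the two answers from the same respondent separates
mode effects (privacy) from other response processes (recall, question
burden).

`reportratio` implements the within-subject comparison as a pipeline:
reporting ratios, percentile-bootstrap inference, recall-window variants,
demographic stratification, a lifetime-confusion sensitivity analysis, and a
synthetic-cohort generator with per-event ground truth so that every stage is
testable without the restricted microdata.

## The statistic

For outcome category $c$ (birth; loss = miscarriage/stillbirth/ectopic;
abortion) and a recall window $W$ matched between modes, the reporting ratio
is

$$
R_c = \frac{\#\{i : A_{ic} \ge 1\}}{\#\{i : F_{ic}(W) \ge 1\}},
$$

where $A_{ic}$ is woman $i$'s self-administered count and $F_{ic}(W)$ the
number of her history events of category $c$ ending inside $W$. The numerator
and denominator count *women reporting at least one event*, not events: the
self-administered module yields counts, but the comparison is who disclosed
at all. An event-count ratio is available (`statistic = "events"`) as a
clearly labelled secondary statistic. $R_c = 1$ is parity; $R_c > 1$ means
more women disclose in the self-administered mode.

Windows are whole calendar months; dates are century-month codes (months
since January 1900, the convention of the public-use files). All membership
is closed-interval. The `standard` window is January of (interview year − 5)
through December of (interview year − 1), exactly as the five-year items
phrase it. The 2002 round compares lifetime reports in both modes.

The `expanded` ratio keeps the five-year numerator but widens the history
denominator to start six years before the interview year, probing date
misdating: events misdated into the self-administered window are matched by
history events just outside it, pulling the expanded ratio below the standard
one. Because "up to six years prior" fixes no exact endpoints, the window's
close defaults to the interview month, with `expanded_end = "dec_prior_year"`
as a configurable alternative; the default is the wider (more conservative)
reading. With the default, the extra months of the interview year can admit
history events that the self-administered window excludes by construction, so
expanded ratios — particularly for births — may drop below 1 in simulation.
Either way the denominator can only grow, so the expanded ratio is never
above the standard one.

## Inference

Standard errors for a ratio of paired indicator sums have no convenient
closed form, so inference is by bootstrap. The respondent is the resampling
unit — resampling rows of the respondent table keeps each woman's two mode
responses paired — and each of $B$ (default 5000) replicates recomputes the
ratio. Confidence intervals are percentile intervals; quantiles use linear
interpolation between order statistics (`stats::quantile` type 7), stated
explicitly so results are bit-reproducible. Replicates with an empty
denominator are excluded from the percentiles, capped at 1% of $B$: rare
sparse-category accidents should not crash an analysis, frequent ones mean
the category is too sparse to analyse and raise an error instead.

Two difference tests are provided. Across disjoint cohorts (survey rounds),
replicate $b$ of one bootstrap is differenced with replicate $b$ of the other
(any pairing is valid under independence; the fixed pairing is reproducible)
and significance is zero-exclusion of the central 95% interval of
differences. Within one cohort, subgroup contrasts resample the *full*
cohort each replicate and recompute both stratum ratios on the replicate,
preserving the dependence induced by shared sampling. Across outcomes —
whose numerators share respondents in a way no simple resampling scheme
respects — the conservative non-overlap test on the two confidence intervals
(`ci_nonoverlap()`) is used. No multiple-testing correction is applied.

The delta-method approximation to the ratio's standard error appears only in
the test suite, as an independent check on the bootstrap, never in the
analysis path.

## The synthetic-cohort generator

`generator_config()` + `generate_cohort()` emulate the response processes
hypothesised to drive mode differences, with a per-event truth ledger so
that detection machinery can be validated against known ground truth.

Per woman: demographics are drawn independently per axis; the interview month
is uniform over the round's field period; per category, the number of true
events over the simulated `span_years` (default 15) is Poisson with mean
`event_rate`, event months uniform over the span. Then two reporting
channels:

* **FTF channel** — each event is disclosed with probability
  `p_ftf[category]` (optionally scaled per subgroup and/or suppressed
  wholesale for a `p_never_discloser` fraction of women, a woman-level
  random effect the observed data cannot distinguish from event-level
  suppression); disclosed events get a recorded month equal to truth plus a
  symmetric two-sided geometric error with SD `misdate_sd_months`, clamped
  at the interview month. The two-sided geometric was chosen because month
  errors are discrete, a single parameter tunes the spread, and its tails
  are heavier than a discretised normal; no error law is implied by the
  instruments themselves.
* **ACASI channel** — each event is kept with probability
  `p_acasi[category]`; the five-year count is kept-in-window events plus
  out-of-window events telescoped in with probability `telescope_in_prob`;
  with probability `confusion_prob` the woman instead answers with her
  lifetime kept counts. The self-administered module has no dates, so its
  misdating analogue is exactly this telescoping/confusion pair. For the
  2002 round the items are lifetime counts and neither mechanism applies.

Defaults are one fixed choice of realistic study conditions: cohort size
11297 and the demographic mix of the 2011–2015 unweighted female sample;
per-category disclosure higher in the private mode than the interview
(`p_ftf` = 0.97/0.70/0.45 vs `p_acasi` = 0.98/0.88/0.60 for
birth/loss/abortion), ordered by outcome sensitivity; 15-year histories with
five-year event means of roughly 0.60 births, 0.25 losses and 0.16
recognised abortions' worth of events per woman over the span; a 5-month
misdating SD; 2% telescoping; 4% lifetime confusion. These produce reporting
ratios in the neighbourhood observed in recent survey rounds (births near
1.1, losses and abortions near 1.4–1.5) without being fitted to any
particular published table.

Two generator features exist purely to create scenarios with closed-form
answers: `events_fixed` (an exact event count per woman per category) and
`event_placement` (`"inwindow"` / `"prewindow"` force all true events inside
or before the standard window). With one in-window event per woman and no
telescoping, confusion or misdating, the population reporting ratio is
exactly $p_\mathrm{acasi}/p_\mathrm{ftf}$, which the test suite uses for
calibration, bootstrap-coverage and type-I-error checks.

What the generator does *not* emulate: ongoing pregnancies (the data model
carries the flag but no current pregnancies are simulated), correlation of
event rates with demographics beyond explicit multipliers, abortions
misreported as miscarriages (a cross-category misclassification probability
is deliberately left at zero because the observed data cannot identify it),
non-response correlated with history length, or survey weights. Passing
tests therefore show the *machinery* is correct under the modelled
processes, not that the model captures every feature of real survey data.

## Sensitivity analysis

`discordant_reporters()` finds women reporting an outcome in the five-year
self-administered module but none in the same window of their history;
`lifetime_match_proportion()` computes, among them, the share whose
self-administered count *exactly equals* their lifetime history count of
that category. Exact equality is deliberate — the question is whether the
woman answered the five-year item with her lifetime number, and "the same
number" is the operative phrase; a ≥ rule would also sweep in unrelated
underreporting of the history. Published results cover births and
abortions; the loss category is computed too but has no external
counterpart.

## Missing data and validation rules

The survey documentation does not state how refused or not-ascertained
self-administered modules were handled. Here a respondent with a missing
module (or invalid demographics, or an impossible pregnancy record) is
excluded at cohort construction and counted in a per-reason exclusion log —
she has only one usable mode, so she cannot contribute to a within-subject
ratio under any rule. Stillbirths are pooled into the loss category on both
sides to match the self-administered item's wording; `drop_stillbirth`
removes them from the history side as a sensitivity option since the exact
published recode is unstated. Multiple births are one pregnancy. Current
pregnancies never enter any count. An education axis exists in some survey
rounds but has no stable recode across them and no published stratified
results, so it is not among the five recoded axes.

## Numerical and design notes

* Ratios are carried at full double precision; rounding to two decimals
  happens only in `render_table()`/`format_ratio_ci()`.
* Denominator zero is an error naming category and stratum, except inside
  `stratified_ratios()`, where the failing level is returned as `NA` with a
  note so the other levels survive.
* `generate_cohort()` seeds one RNG stream from `config$seed`; the three
  stages called standalone seed at fixed offsets (+0, +1, +2) so each is
  independently reproducible. Bootstrap functions take their own `seed` and
  restore the caller's RNG state.
* The simulation sizes used by the test suite (up to 50 000 women for
  closed-form recovery, 200 cohorts of 5 000 for bootstrap coverage, 100
  cohorts of 3 000 for the type-I check) were chosen so Monte-Carlo bounds
  (3σ, or ±4 points on coverage) are decisive at desk scale.

## Worked example

```{r example, eval = FALSE}
sim <- generate_cohort(generator_config(n = 5000, seed = 2026))
co <- sim$cohort

ratio_table(co)
bootstrap_ratio(co, "abortion", B = 1000, seed = 1)
stratified_ratios(co, "loss", "poverty")
lifetime_match_proportion(co, "birth")
```

Real microdata flow through the identical pipeline via `read_cohort()` with
a column schema (`nsfg_schema()` maps the public-use variable names), and
`run_pipeline()` orchestrates cohort loading or simulation, the analyses,
and publication-shaped table rendering from one YAML/JSON configuration.

## Known limitations

* The reporting ratio is an aggregate; it supports bivariate subgroup
  comparisons but cannot enter multivariate models.
* Women who disclose in neither mode are invisible to the statistic.
* The across-outcome non-overlap test is conservative by construction.
* Bootstrap quantile conventions differ across software in the last decimal;
  the interpolation rule used here is documented above precisely so such
  differences are attributable.
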