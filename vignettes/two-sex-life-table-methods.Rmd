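---
title: "Methods: the age-stage two-sex life table in twosexlt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the age-stage two-sex life table in twosexlt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twosexlt)
```

## The data and its assumptions

The unit of observation is one individual followed from oviposition to
death under a **daily census**: ages and stage durations are whole days,
and age 0 is the day of oviposition. An individual with egg duration
*d* occupies the egg stage at ages 0..*d*−1, the larval stage starting
at age *d*, and so on; the duration recorded for the stage an individual
died in is the number of days it was alive there. Three conventions are
built into the data model and validation:

- **No censoring.** Rearing is assumed to continue until every
  individual has died; records that would require censoring (e.g. an
  unsexed adult) are rejected. Escaped or lost individuals, if any, must
  be removed before analysis.
- **One larval stage.** Instars are not distinguished: only the total
  larval duration enters the table, which is the granularity at which
  such studies report durations.
- **Eggs are credited to the female.** Fecundity is recorded per female
  per adult day; the male contribution through pairing is not modelled.

## Schedules

With *N* the initial egg number, the age-stage survival rate is
`s_xj = (alive at age x in stage j) / N`, with female and male adults as
separate stages. The combination formulas

- `l_x = Σ_j s_xj`
- `m_x = Σ_j s_xj f_xj / Σ_j s_xj`  (0 where nobody is alive)

are the standard ones of the age-stage framework. They make two exact
identities hold on *every* cohort, which the tests exploit heavily:

- `Σ_x l_x m_x = (total eggs laid) / N = F̄ · N_f / N`, where `F̄` is
  mean lifetime fecundity over all adult females and `N_f` their count;
- `GRR = Σ_x m_x ≥ R0`, since `l_x ≤ 1`.

Sums run over the cohort's finite support `0..max_age`; no tail
extrapolation is performed, and schedules are not smoothed or
interpolated.

Summary-statistic conventions (they matter for matching published
tables): stage-duration means are taken over individuals *completing*
the stage; APOP is the 1-based adult day of a female's first egg and
TPOP = pre-adult duration + APOP, both computed **per individual** over
females that laid at least one egg; the oviposition period is the
*count of days with ≥ 1 egg* (not last-minus-first), which is what
reproduces integer values like 1.00 for single-day layers; lifetime
fecundity averages over **all** adult females, zero-layers included.
Statistics over empty subsets are reported as absent (`NA`), never as
zero.

## Population parameters and numerics

`r` solves `Σ_x e^(−r(x+1)) l_x m_x = 1`. The `x+1` exponent is the
convention of the two-sex life table literature with age indexed from
zero; `intrinsic_rate(..., convention = "x")` gives the `e^(−rx)` form
for comparison with sources that use it. The residual is strictly
decreasing in `r`, so the root is unique whenever any reproduction
occurred. The solver is a bracketed bisection: initial bracket
[−1, 1]/day, widened geometrically to at most ±5/day (an error beyond
that — no biologically meaningful rate survives it), stopping when the
residual falls below `tol` (default 1e-10, well below any demographic
signal). Bisection was preferred over derivative-based iterations
because it cannot overshoot and needs no starting guess; a fine-grid
scan of the residual serves as an independent oracle in the tests.

Degenerate inputs are defined, not patched: a cohort with no
reproduction has `R0 = GRR = 0` and an *undefined* `r`, `λ`, `T`
(`intrinsic_rate()` errors; `population_params()` returns `NA`).
Note that `T = ln(R0)/r` recomputed from *printed, rounded* `R0` and
`r` only approximates a printed `T`; that is rounding, not an
inconsistency.

## Bootstrap inference

The resampling unit is the **whole individual** — the only unit that
keeps the schedules well defined — drawn `N` per resample with
replacement, and the full pipeline is recomputed per resample. `B`
defaults to 10,000, a good SE at desk-scale runtime; raise it towards
1e6 where publication-grade table SEs are wanted. A resample can leave
a statistic undefined (no female ⇒ no `r`); such resamples are excluded
from that statistic's mean/SE and reported via `valid_count`, rather
than imputing a value. One root seed drives an analysis;
per-group/per-statistic streams are derived from it, so a fixed seed
reproduces every resample bit-identically.

Two groups are compared by pairing their resamples by index, taking the
percentile `100(1−α)%` interval of the `B` differences (type-7
quantiles; percentile rather than BCa, the simplest faithful reading of
a "CI of difference" rule), and flagging significance when it excludes
zero. The pairwise pattern is condensed by an insert-and-absorb compact
letter display, ordered so "a" sits on the largest mean; decoding the
letters recovers the significance relation exactly (a tested property).
Letters are computed per statistic across groups, as in published
tables' per-row superscripts.

## The synthetic cohort generator

`simulate_cohort()` emulates the observation scheme above, one
individual at a time: stage durations `1 + round(Gamma(mean, sd))`
(sd 0 gives synchronous development — e.g. all eggs hatching the same
day); stage completion as Bernoulli trials, with the death day uniform
over the failed stage's drawn duration (the within-stage death timing
is unobservable in published summaries and affects only the shape of
`l_x` inside that stage); sex as Bernoulli(`p_female`); lifetime
fecundity as negative binomial (mean, size); laying starting
`1 + Poisson(apop_mean − 1)` adult days after emergence on
`1 + Poisson(ovi_days_mean − 1)` consecutive days, the eggs spread
multinomially with each laying day getting at least one egg when
possible.

The six shipped presets (21–36 °C, editable YAML) are calibrated once
from printed rearing summaries: duration means, stage-completion
fractions from the n(N) transition counts, sex ratios from adult
counts, APOP, laying-day counts and mean fecundities. Individual-level
spread is identifiable from a bootstrap SE of a plain mean (SE·√n ≈
sample SD), and the duration SDs and fecundity dispersions were set
that way — truncated to near-Poisson where the implied variance fell
below the mean, as a negative binomial cannot be underdispersed. The
distribution families themselves are modelling choices (the simplest
matching the printed first moments and the integer daily census), so
simulated cohorts reproduce means, survival fractions and integer
censuses, **not** the true joint distribution of real life histories:
passing recovery tests shows the pipeline is correct and the generator
self-consistent, not that any particular field population behaves this
way. No temperature-response model is fitted across presets.

`theoretical_schedules()` provides the generator's ground truth as a
large Monte-Carlo cohort (default 200,000 individuals) pushed through
the same pipeline.

## Validation problem sizes

The shipped tests exercise: exact hand-computed schedules on 1–3 record
cohorts; day-by-day brute-force tallies and grid-scan root checks on
random 50–80 egg cohorts; the framework identities on 100 random
cohorts of 60 eggs; parameter recovery on twenty 2,000-egg cohorts
against a 200,000-individual oracle; the growth/no-growth sign pattern
across the six presets at their study sizes over 20 replicates; and
bootstrap determinism at B = 10,000. These sizes give stable checks at
interactive runtimes.

## Known limitations

- Sub-daily resolution, censoring and larval instars are out of scope
  by design.
- `r`, `λ` and `T` are undefined (not zero) for cohorts without
  reproduction, so bootstrap SEs for those statistics near the
  no-growth boundary are conditional on reproduction occurring in the
  resample — mirrored in `valid_count`.
- The generator's dispersion parameters are calibrated from published
  SEs of means; where a table mixes conventions, the preset reflects
  the stated mean and the implied-variance truncation above.
- Population projection (stable stage distribution, reproductive
  values) is not implemented; the five parameters are the product.
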