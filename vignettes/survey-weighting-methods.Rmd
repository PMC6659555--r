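---
title: "Design, weighting and replication methods in svysmoke"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Design, weighting and replication methods in svysmoke}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svysmoke)
```

## The measurement problem

National face-to-face surveys of adult smokers are often fielded as
stratified multistage quota designs: a country is divided into
geographic strata (major regions crossed with urbanization level),
enumeration-area-sized clusters are sampled within strata proportionally
to adult population, interviewers walk a randomised route approaching
every k-th dwelling, a household screener counts the adult smokers by
sex, one smoker per sex is selected by the next-birthday rule, and a
cluster is worked until a fixed number of interviews is completed. An
eligible smoker is an adult (18+) who smokes at least monthly and has
smoked more than 100 cigarettes over their lifetime.

Such designs yield unequal and only approximately known inclusion
probabilities, so analysis rests on a chain of constructed weights and
on replication-based variance estimation. `svysmoke` implements that
chain end to end and, because the protocol's operating characteristics
cannot be derived in closed form, pairs it with a synthetic-population
simulator so every step can be validated against a known truth.

## The sampling protocol as implemented

**Cluster allocation.** `allocate_clusters()` apportions the country's
cluster budget (default 100) to strata by largest-remainder
(Hamilton) allocation on adult population, with a floor (default 2
clusters) per stratum. Strata whose proportional share falls below the
floor are fixed at the floor and the remainder is re-apportioned among
the rest; remainder ties break toward the larger population and then
frame order. Clusters are then drawn by simple random sampling within
each stratum.

**The random walk.** In the field the route is seeded by GPS and walked
door to door; without geography this is modelled as a uniformly random
permutation of the cluster's dwellings with every `walk_step`-th
(default 5th) dwelling from a random start approached — a systematic
sample that preserves the design's key property, approximately equal
household inclusion probability within a stratum, which is exactly the
approximation the weighting step assumes.

**Contact, screening, selection.** A household is contacted if any of
up to `max_contact_attempts` (default 4) tries succeeds, with the
household's contact propensity taken as its most reachable member's. A
contacted household is screened (an optional screener-refusal
propensity, default 0, models households whose eligibility is never
determined); the screener reports the exact counts of male and female
adult smokers. One smoker per sex is selected uniformly at random among
the same-sex candidates — the next-birthday rule is an equal-probability
device because birthdays are uniform over the year, so simulating
calendar birthdays would add nothing testable. A selected smoker
completes the interview with their cooperation propensity; refusals are
never substituted within the household. The cluster stops at
`quota_per_cluster` (default 10) completed interviews; a selected
person reached after the quota is met is neither interviewed nor
counted as a refusal. If the route is exhausted first, the shortfall is
recorded on the sample and summarised in a single warning.

**Disposition accounting.** Every outcome is tallied into the nine raw
disposition counts (attempted, contacted, eligibility determined, no
eligibles, with eligibles, households with selection, individuals
selected, refusals, completed), whose internal consistency rules are
enforced on construction. `compute_rates()` derives the seven standard
quantities (eligibility rate, estimated eligible households, household
contact/cooperation/response rates, individual cooperation/response
rates) at full precision. Reporting rounds half away from zero — rates
to 3 decimals, the estimated-eligible count to an integer — and every
chained quantity (the estimated-eligible count, and the household
response rate built on it) uses the unrounded inputs. This is the only
convention consistent with the packaged six-country reference table:
rounding the Germany eligibility rate first would give
0.358 × 10325 = 3696 estimated eligibles where the table prints 3694 =
(1104/3086) × 10325. A rate with a zero denominator is returned as an
explicit undefined marker (`NA` plus a listing in the `"undefined"`
attribute), never as a silent `NaN`.

## The four-step weights

1. **Initial weight** — the number of same-sex adult smokers in the
   respondent's household, i.e. the reciprocal of the within-household
   selection probability `1/k`.
2. **Design weight** — household inclusion is treated as equal within a
   stratum, so inclusion of a person within the stratum is proportional
   to their within-household selection probability. The unknown
   within-stratum constant cancels into a per-stratum scale factor,
   fixed so each stratum's weight total equals its adult population. A
   stratum with population but no respondents is merged into the
   largest-population sampled stratum of the same region (falling back
   to the country) before scaling.
3. **Calibration** — a post-stratification adjustment to external
   benchmark smoker counts over stratum, sex and age group. The default
   is raking (iterative proportional fitting) over the three margins
   separately, which is robust to sparse joint cells at a sample size
   of ~1000 per country; full joint-cell post-stratification is
   available (`mode = "cell"`) when joint benchmark cells are supplied,
   with cells under `min_cell_count` (default 5) respondents collapsed
   into the nearest age group within the same stratum × sex to avoid
   extreme weights. Raking iterates to a maximum relative margin error
   below `tolerance` (default 1e-8, a numerical-identity criterion
   rather than a statistical one) within `max_iterations` (default
   200); non-convergence — possible only with structurally infeasible
   targets — is an error reporting the final margin errors. The
   benchmark interface takes population-scale smoker *counts*; margins
   supplied as prevalences must be multiplied by the corresponding
   population totals first.
4. **Rescaling** — weights are multiplied by `n / sum(w)` so each
   country's weights average exactly 1, the convention that makes
   weights comparable across countries and under which the Hájek
   (weighted-mean) estimator is the appropriate form for means and
   proportions, the population scale having been discarded.

No weight trimming is applied by default, matching the four-step
construction; nonresponse adjustment is implicit in calibration rather
than a separate response-propensity step. Only interviewed smokers are
weighted — non-smoking household members enter the procedure solely
through the screener counts.

## Rao–Wu rescaled bootstrap

For stratified multistage designs, variances are estimated by the
rescaled cluster bootstrap: independently per replicate and stratum,
`n_h − 1` of the stratum's `n_h` sampled clusters are drawn *with*
replacement, and respondent `i` in cluster `c` receives

```
w_i(b) = w_i × (n_h / (n_h − 1)) × m_c(b)
```

where `m_c(b)` is the number of times `c` was drawn. The multiplicities
have mean `(n_h − 1)/n_h`, so replicate weights are unbiased for the
base weight; a respondent's weight is exactly zero whenever their
cluster is never drawn, which happens with probability
`(1 − 1/n_h)^(n_h − 1)`. Strata left with a single cluster are collapsed
with the nearest sampled stratum in frame order (a proxy for geographic
adjacency) before replication, since the factor is undefined at
`n_h = 1`.

By default every replicate column is **re-calibrated** to the benchmark
margins, so the variance-reducing effect of calibration propagates into
the standard errors; the raking core operates on the whole
respondent × B matrix at once, so this costs little. Recalibrated
columns are rescaled back to the base column's total, keeping all
replicates on the mean-1 analysis scale (Hájek estimators are invariant
to this; totals users should work from design-scale weights). Setting
`recalibrate = FALSE` replicates the base weights unadjusted — the
difference between the two variance estimates is itself a diagnostic
for how much calibration contributes. The bootstrap variance is
`(1/B) Σ (θ_b − θ̂)²` around the full-sample estimate; percentile
intervals use type-7 quantiles of the replicates. The CLI-scale default
is `B = 1000`; the validation study uses `B = 500`.

## What the synthetic populations emulate — and what they do not

`generate_population()` reproduces the structural features the protocol
and the weights interact with: strata with fixed adult populations,
enumeration-area clusters (default ~400 adults, roughly 210 households
— large enough that an every-5th-dwelling route can supply a
10-interview quota at ~30% smoker prevalence, and consistent with
fieldwork scales of ~100 attempted addresses per cluster), households
with 1–4 adults from a configurable size distribution, and smoker
status assigned independently per adult from sex × age (optionally
stratum-specific) prevalences. Binary smoker attributes with known
per-sex prevalences serve as estimands; contact and cooperation
propensities can be constant, per-sex (to inject differential
nonresponse), or Beta-distributed.

Deliberately *not* emulated: real geography (no coordinates, no actual
regional boundaries — excluded territories are simply omitted strata),
within-household correlation of smoking (smoker status is independent
across household members given sex and age, the simplest testable
default; clustering of smoking within households would raise the
initial-weight variance but not the estimators' validity), interviewer
effects, seasonal fieldwork suspensions, and multi-household addresses
(collapsed to single households). Passing
validation on these populations therefore demonstrates that the
*algorithms* are correct under the design's stated assumptions, not
that any real survey achieved unbiasedness — real-world frame error,
informative nonresponse within calibration cells, and benchmark error
are outside what the simulator can falsify.

## The validation study

The design-based checks run on one synthetic country of 40,000 adults
in 8 strata (4 regions × 2 urbanization levels), 40 sampled clusters,
quota 10 — about 400 interviews per run, a deliberately scaled-down
analogue of a 100-cluster/1000-interview national survey. Under full
response, over 500 independent fieldwork draws, the mean of the
calibrated Hájek prevalence estimator stays within 3 Monte-Carlo
standard errors of the true population value for each configured
attribute; under female cooperation halved, calibrated estimates are an
order of magnitude less biased than design-weight-only estimates. For
one realised sample, the Rao–Wu variance (B = 500, recalibrated) is
compared with the Monte-Carlo variance of the estimator across the 500
draws — the median ratio over 20 samples falls within [0.75, 1.33] —
and 95% percentile intervals cover the truth in 90–99% of the runs.

## Numerical and degenerate-input conventions

* Half-up rounding (`round_half_up()`) is used wherever the reference
  table's printed precision matters; base R's banker's rounding would
  not reproduce it.
* Raking leaves margin levels with zero current weighted total
  untouched within a replicate column (they are structural zeros of
  that resample); the main calibration path instead refuses margin
  levels with positive targets and no respondents.
* Allocation, selection and resampling draw from R's global RNG;
  population, fieldwork and bootstrap stages take independent seeds so
  each source of variation can be held fixed separately.
* An empty household smoker list selects nobody; a cluster allocation
  infeasible under the floor, a non-positive prevalence or weight, and
  a zero total weight are errors, not warnings.

## Known limitations

The simulator's systematic-walk model preserves equal within-stratum
inclusion only approximately once quota stopping truncates routes —
precisely the approximation the weighting adopts, so simulation results
quantify, rather than hide, its consequences. The bootstrap ignores
without-replacement corrections at both stages (standard for this
estimator) and will mildly overstate variance when the sampled fraction
of clusters is large. Longitudinal (attrition) weights and pooled
multi-country weights are out of scope.
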