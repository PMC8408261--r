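---
title: "Order memory as a Bayesian prior on event-time reports: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Order memory as a Bayesian prior on event-time reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ordtime)
```

## The experimental setting this package models

A trial lasts 16.5 s, divided into 11 slots of 1.5 s. The item occupying
a slot appears at the slot onset (for 1 s, followed by 0.5 s of blank).
The first and last slots always hold anchor items that delineate the
episode; the 1–3 items of interest occupy slots drawn uniformly without
replacement from the 9 intermediate slots (2–10). After presentation,
participants report each intermediate item's time on a continuous
slider, so a report is a real number in \[0, 16.5\] s.

Two empirical regularities drive the modeling. First, single-item
reports are broadly distributed around the true time, except near the
beginning, middle and end of the trial. Second, with two or three items
the *relative order* of reports is far more often correct than the
single-item report noise would predict if items were encoded
independently — and the remembered order visibly biases the absolute
reports themselves.

## The Bayesian observer

For $n$ intermediate items at true slots $t_1 < \dots < t_n$, the
internal evidence available at report time is

* noisy internal times $\hat t_i$, one independent draw per item from
  the single-item report likelihood $P_1(\hat t \mid t_i)$, and
* a discrete internal order $\hat\sigma$, stored *separately*:
  $\hat\sigma$ equals the true order $\sigma$ with probability
  $1 - P_\sigma$ and is otherwise uniform over the $n! - 1$ wrong
  permutations. $\hat\sigma$ need not be consistent with the
  $\hat t_i$.

The observer inverts this generative model over ordered tuples of
distinct intermediate slots (the schedule prior is uniform over them):

$$
P_{\mathrm{post}}(t_1,\dots,t_n \mid \hat t, \hat\sigma) \propto
 \prod_i P_1(\hat t_i \mid t_i)\,
 \Big[(1-P_\sigma)\,\delta_{\hat\sigma,\sigma(t)} +
      \tfrac{P_\sigma}{n!-1}(1-\delta_{\hat\sigma,\sigma(t)})\Big],
$$

and reports the posterior mean of each $t_i$. As $P_\sigma \to 0$ the
order memory acts as a hard prior: posterior mass survives only on
tuples consistent with $\hat\sigma$, so the mean reports are weakly
ordered by the internal order and ordering mistakes in the *reports*
occur only when the internal order itself is wrong.

### Parameters that matter

| parameter | meaning | default | why |
|---|---|---|---|
| `n_slots`, `slot_duration` | grid geometry | 11, 1.5 s | the experimental protocol |
| `p_sigma` | order-mistake probability | 0.08 ($n=2$), 0.1 ($n=3$) | the values used for the two- and three-item simulations |
| `pseudocount` | additive count per likelihood bin | 0.5 | keeps rarely observed bins from annihilating the posterior; 0 recovers the raw empirical matrix |
| `n_samples` | Monte-Carlo reps per configuration | 10,000 | standard error of a rate estimate below 0.005 |

### Numerical choices

* **Integrals are sums.** Presentation times take 9 discrete values
  (slot onsets), and the schedule prior is uniform over tuples of them,
  so the posterior and its means are computed by exact enumeration over
  all ordered tuples of distinct intermediate slots (72 for $n=2$, 504
  for $n=3$). Nothing is approximated inside a single decoding step; all
  Monte-Carlo error comes from sampling the internal representations.
* **Internal times enter through their bin.** The posterior looks up
  $P_1(\hat t \mid t)$ through the report bin
  $\lfloor \hat t / 1.5\rfloor + 1$ (clipped to 1–11). Raw internal
  times are produced by bootstrap-resampling the stored raw reports per
  slot, not by sampling the binned matrix, so the resampler keeps the
  full within-bin structure while the posterior stays a finite table.
  Whether one should instead evaluate a smoothed continuous likelihood
  at the raw $\hat t$ is the main fidelity uncertainty, mostly affecting
  the earliest and latest slots where the distributions are narrow.
* **One shared likelihood for all ranks.** The single-item likelihood is
  estimated from single-item sessions only and re-used for every item
  rank. A per-rank override would be straightforward but there is no
  single-item data per rank to estimate it from.
* **Ties get half credit.** Resampled internal times are draws from a
  finite sample set, so exact ties occur with positive probability.
  Everywhere an ordering is scored — empirical accuracy, naive flip
  probabilities, permutation tables — a tie is shared equally over the
  tie-consistent orderings (1/2 each for a two-item tie). On real
  continuous slider data ties are measure-zero, so the convention is
  inert there.
* **Degenerate posteriors error out.** If every tuple has zero
  likelihood (possible with `pseudocount = 0` and an unobserved bin),
  the decoder raises an explicit error rather than silently
  renormalizing.

## The synthetic generator

There is no public generative model for the report noise, so the
package defines the minimal family that reproduces the qualitative
shape of the observed single-item distributions, and uses it as the
fixed study condition for every test:

* **Regular reporters** draw each item's internal time from a Gaussian
  centered on the true onset, truncated to the trial window, with SD
  2.5 s at ordinary slots and 0.5 s at the anchor slots (first, middle,
  last) — wide everywhere except beginning, middle and end. The trial's
  internal order is corrupted with probability `order_error` (wrong
  permutations equiprobable), and the sorted times are dealt out
  according to that order, so the reported order *is* the internal
  order. This makes the generator's corruption rate exactly
  identifiable from the ordering accuracy (`fit_p_sigma()`), which the
  parameter-recovery test exploits.
* **Quantizers** (fraction 0.10) retain only ordinal information: the
  rank-$i$ item of $n$ is always reported at the onset of the mean
  $i$-th order statistic of the slot draw — slot indices
  $10i/(n+1)$, e.g. 5 s and 10 s for two items. This emulates the
  rank-only component visible in multi-item report histograms.
* **Random responders** (fraction 0.25) report uniformly over the
  trial. The fraction sits between the exclusion rates implied by the
  two- and three-item participant counts before and after selection.

What the generator does **not** emulate: bimodal report shapes, the
extra reliability of consecutive sequences at the trial edges,
training-trial feedback effects, and any content effect of the delay
task (two-item-with-delay sessions differ only by a 16 s delay flag).
Tests passing on this generator therefore validate the machinery and
the model's internal logic, not the fit of the noise family to any
particular human dataset.

## Participant selection

A random responder orders two items correctly with probability 1/2 and
three items with probability 1/6, so over 15 trials the expected number
of correct orderings is 7.5 and 2.5. Sessions are excluded when their
correct-ordering count is compatible with that chance mode: fewer than
10 of 15 for two-item sessions, 6 or fewer of 15 for three-item
sessions, no exclusion for single-item sessions. For session lengths
other than 15 the thresholds scale proportionally (10/15 and 7/15) —
a deliberate generalization, since the protocol itself fixes 15 trials.

## Design choices made where the design was open

* **Naive predictions weight slot configurations uniformly.** The naive
  independent-encoding accuracy aggregates flip probabilities over the
  36 slot pairs (or 84 triples) with equal weight rather than weighting
  by empirical trial frequency; schedules are uniform by design, so the
  two weightings coincide in expectation and the uniform one is
  deterministic given the likelihood.
* **Exhaustive before Monte-Carlo.** Naive predictions enumerate all
  stored-sample pairs/triples when there are at most $10^6$
  combinations and fall back to seeded Monte-Carlo above that.
* **One-way ANOVA for slot dependence.** "Reported position depends on
  presented position" is tested as a one-way fixed-effects F test of
  reported position (reports in slot units) on the presented slot as a
  categorical factor. Published F statistics for this contrast have an
  ambiguous degrees-of-freedom notation, so no attempt is made to match
  them numerically.
* **No multiple-testing correction** in the per-slot Welch tests or
  across flip-matrix cells, mirroring the original analyses.
* **Seed fan-out.** The pipeline takes one base seed and derives stage
  seeds as `seed + stage counter`, so stages are individually
  reproducible and the whole run is byte-identical across repeats.
  Times are serialized with 6 decimals.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic
data: likelihoods from 150–200 simulated single-item participants
(~2,000–3,000 reports), $10^4$ two-item and $4\times10^3$ three-item
Bayesian trials, a $10^4$-trial parameter-recovery run, and a reduced
end-to-end pipeline (30–40 participants per experiment, $10^3$
Bayesian trials). These sizes put Monte-Carlo standard errors well
below the effect sizes being asserted while keeping a full run on one
CPU in a few minutes.

## Known limitations

* The decoder is exact only because the slot grid is small and
  discrete; a continuous-time treatment (or many more slots) would need
  a different posterior representation.
* The order-error model treats all wrong permutations as equiprobable.
  A transposition-distance-weighted model is a natural extension point
  but is deliberately out of scope.
* Quantizer participants are deterministic in the generator; real
  rank-only reporters presumably jitter around their rank anchors.
* `fit_p_sigma()` identifies the corruption rate only under the
  generator's report-follows-internal-order convention; on data where
  time noise itself flips reports it estimates the total flip rate, an
  upper bound on $P_\sigma$.
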