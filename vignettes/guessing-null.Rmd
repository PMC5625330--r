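---
title: "The Monte Carlo guessing null for source errors in paired action recall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Monte Carlo guessing null for source errors in paired action recall}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(guessnull)
```

## The problem

In a paired generation/recall design, two people take turns inventing
actions for a set of cue symbols (say, acting out the letter *X* with their
bodies). The next day, each participant is asked to re-perform either the
actions they performed themselves (*recall own*) or the ones they watched
their partner perform (*recall partner*). Every action produced at test is
coded against the pair's encoding record as

* a **correct recall** — it belongs to the task's target source,
* a **source error** — it belongs to the pair but to the *other* source, or
* an **intrusion** — it was never generated by either member.

Source errors are the quantity of interest (they measure source-memory
failure, e.g. claiming an observed action as self-performed), but they are
contaminated by guessing: a participant who simply invents plausible
actions at test will sometimes hit the partner's repertoire by accident,
because some solutions to a cue are much more popular than others. The
package's core computation is a per-participant Monte Carlo estimate of
how many source errors guessing alone would produce.

## The guessing null

**Frequency norms.** For each cue, the probability of a coded action is its
relative frequency among *all* generation-phase performances in the
experiment (duplicated performances count every occurrence — the norms
describe the population action space, not the deduplicated encoding sets).
`build_frequency_norms()` computes these.

**Simulated test phase.** For one participant and one cue, take the number
of actions $k$ that the participant actually reported for that cue and draw
$k$ distinct actions from the cue's norms by weighted sampling *without
replacement* (successive draws, renormalizing the remaining mass — exactly
the semantics of `sample(..., prob = )`). Each drawn action either matches
the participant's own encoding set, matches the partner's set, or matches
neither ("novel"). Summing over cues and defining source errors as
partner-matches under recall-own (self-matches under recall-partner), one
replicate yields counts $(SE, N)$ of simulated source errors and novels.
Over $R$ replicates (default 500),

$$\text{ratio} = \frac{1}{R'}\sum_{i=1}^{R'} \frac{SE_i}{SE_i + N_i},$$

where the sum runs over the $R'$ replicates with $SE_i + N_i > 0$.
Replicates with a $0/0$ denominator are excluded rather than scored as
zero — the ratio estimates the conditional probability that a guessed
*error* is a source error, and a replicate with no errors carries no
information about that conditional; the number of excluded replicates is
reported in every result.

**Scaling to the observed data.** Observed intrusions must be guesses
(they match nothing that was encoded, so they cannot be retrieval), which
makes them the natural yardstick:

$$\widehat{SE}_{\text{guess}} = \text{intrusions}_{\text{obs}} \times
  \frac{\text{ratio}}{1 - \text{ratio}}.$$

`simulate_guessing_ratio()` and `predict_source_errors()` implement the two
steps; `guessing_predictions()` maps them over every participant × task ×
load-condition cell. The difference *observed − predicted* is then the
guessing-corrected source-error effect analysed downstream.

Two guards apply. If *every* replicate is degenerate the cell is flagged
and predicts zero (with a warning). If the ratio reaches 1 — possible only
when the norms' support is entirely covered by the pair, so novel outcomes
cannot occur — the odds are undefined; the cell is flagged and predicts
`NA`. A reported per-cue count exceeding the cue's support is truncated to
the support size with a warning.

An exact enumeration oracle, `enumerate_guess_distribution()`, computes
the distribution of the sampler on supports of at most 12 actions by a
dynamic program over subsets (equivalent to summing all ordered draw
sequences). The test suite uses it to verify the sampler's inclusion
probabilities and the ratio estimator's convergence; it is deliberately
independent of the sampling code path.

## Inference on observed versus predicted errors

* `paired_t_onetailed()` — the step-down test, one-tailed in the direction
  observed > predicted, with the effect size $d_{av}$ = mean difference
  over the average of the two condition SDs. $d_{av}$ is the default
  because it scales the paired change by condition variability rather than
  difference variability; $d_z$ is available via `d_method = "d_z"`. With
  zero-variance differences the result is flagged: $t = 0$, $p = 0.5$ when
  the mean difference is also zero, $t = \pm\infty$ otherwise.
* `mixed_anova()` — classical two-way mixed decomposition (one
  between-subjects factor, one within-subjects factor), fitted via
  `aov()` with an `Error(subject)` stratum: the between effect is tested
  against subjects-within-groups, the within effect and interaction
  against the subject × within error. Partial $\eta^2$ accompanies each
  effect. Zero-SS effects report $F = 0$ even when the error term is also
  zero. Unbalanced within-cells are rejected with a pointer to listwise
  handling; unequal group sizes are supported.
* `within_subject_ci()` — Cousineau–Morey intervals: subject-center, add
  back the grand mean, inflate by $\sqrt{C/(C-1)}$, and take t-based 95%
  half-widths. For two conditions this equals the paired-difference CI
  half-width divided by $\sqrt 2$.
* `smc_effect()` / `fixed_effect_summary()` — the per-experiment effect
  for forest summaries is the standardized mean change
  $d = \bar{x}_{\text{diff}} / s_{\text{diff}}$ with change-score variance
  $1/n + d^2/2n$; pooling is fixed-effect inverse-variance. No
  random-effects model or heterogeneity statistics are offered: with three
  small experiments a between-study variance estimate would be noise.
* `dienes_bf()` — the replication Bayes factor: the alternative's effect
  prior is a normal folded at zero (one-tailed) whose scale is a prior
  study's effect; the data enter as a normal likelihood summarized by mean
  and SE. Computed in closed form (marginal normal × normal-CDF truncation
  factor) and by adaptive quadrature of the peak-centered, log-scaled
  integrand; both values are stored and must agree, which the tests check
  across a parameter grid to 1e-6 relative error. All terms are kept in
  log space because the likelihood can underflow long before the Bayes
  factor itself becomes extreme.

No multiplicity correction is applied to the step-down tests, mirroring
the analysis the pipeline reproduces; ANOVA follow-ups in that tradition
use Bonferroni adjustment, which callers can apply to the emitted p-values.

## The synthetic experiment generator

`simulate_experiment()` emulates the paired design end to end so that the
whole pipeline is testable without any external data, and so that the
generator's parameters serve as ground truth for recovery tests.

* **Action space** — 15 cue symbols by default, each with a support of
  20–40 distinct coded actions and a Zipf (rank-power) popularity vector
  with exponent 1; a Dirichlet option gives unstructured random simplices.
  Exponent 0 recovers the uniform limit.
* **Generation phase** — members alternate turns (focal first), three
  exemplars per cue each by default (four matches the heavier two-session
  variants). A draw duplicates the partner's earlier action with
  probability `p_partner_duplicate`, repeats an own action with
  `p_self_repeat`, and otherwise draws a fresh action from the popularity
  restricted to codes unused by the pair. The defaults (0.5% / 1.3%)
  reflect the low duplication rates of the confederate-run variant; naive
  pairs in the published data run an order of magnitude higher (5–14%),
  and those rates are a constructor argument away.
* **Test phase** — each duplicate-filtered encoded item is retrieved
  independently (own 0.65, observed 0.45 by default), and a retrieved
  item's source is confused with probability 0.2. These three defaults
  were chosen once by moment-matching the published mean counts of the
  confederate experiment (≈ 23.8 correct / 8.3 source errors in recall
  own, ≈ 15.9 / 7.7 in recall partner, out of 45); a single symmetric
  confusion parameter cannot reproduce all four cells exactly and no
  further fitting was attempted. Guessing adds Poisson(0.6) ad-hoc
  actions per cue, drawn from the *realized* generation-phase frequency
  distribution of the dataset — the method's own assumption about how
  ad-hoc solutions arise. This matters: drawing guesses from the latent
  popularity instead would make the null miscalibrated by construction,
  because sampling without replacement at generation flattens realized
  frequencies relative to latent popularity. With probability 0.05 a
  guess falls outside the inventory entirely and is emitted as a
  `NOVEL:` action, exercising the true-novel path of the intrusion count.
* **Load and monitoring** — an optional cue → load schedule attenuates
  the retrievability of actions *observed* under load by a multiplicative
  penalty (performance is never under load; the design is unbalanced by
  construction). In extended-recall mode every retrieved item is produced
  and then accepted or rejected; a would-be source error is caught with
  probability `monitoring_strictness` (0.7 by default), emulating the
  report/withhold procedure.

What the generator does *not* emulate: output interference or retrieval
dynamics (items are retrieved independently), participant heterogeneity in
retrieval or guessing rates beyond binomial/Poisson noise, any perceptual
or verbal structure of the actions, and confederate behaviour. Passing
calibration tests on this generator therefore shows that the estimator is
correct *under the null model's own assumptions* — it cannot show that
real recall data satisfy those assumptions.

## Numerical and design choices

* Repeated reports of the same action at test count once (first report):
  re-performing an already-reported item carries no new source
  information. Self-repeats at generation keep the first occurrence.
* Actions performed by *both* pair members are removed from both encoding
  sets before coding; a test-phase report of such an action is excluded
  from all tallies rather than scored as an intrusion, since the action
  has no unique source and scoring it as an intrusion would contaminate
  the intrusion-based scaling.
* Norms include duplicated generation events; duplicate filtering applies
  to retrieval analyses only.
* Observed `NOVEL:` actions count toward the intrusion total even though
  the simulation's action space cannot produce them; the method assumes
  guesses follow the generation-phase distribution, and the package keeps
  that assumption rather than second-guessing it.
* All orders (`trial_index`, `output_order`) are 1-based. All randomness
  flows from explicit integer seeds through private RNG streams
  (`withr::with_seed`), and every prediction records its seed; fixed
  seed + inputs reproduce every output byte for byte. For that reason the
  run manifest records versions, settings and an input hash but no
  timestamps.
* Withheld items in extended recall are labelled and retained for
  diagnostics but never tallied; downstream analyses use reported items
  only.

## Problem sizes in the test suite

The suite checks calibration with 200 synthetic participants under pure
guessing (confusion 0, all guesses inside the inventory) at 500 Monte
Carlo replicates per participant; sensitivity on a three-point confusion
grid (0.05/0.15/0.30) with 120 participants each; the type-I error of the
full pipeline over 500 replicate mini-experiments (3 cues, support 20,
9 pairs); the ratio estimator against exact enumeration at 50,000
replicates on a 6-action support; and the ANOVA engine against a
hand-computed sums-of-squares oracle on 50 random balanced designs. These
sizes were chosen to make sampling bands tight relative to the effects
being checked while keeping the default test run comfortably fast.

## Known limitations

* The guessing null conditions on the observed intrusion count; for
  participants with zero intrusions the prediction is zero regardless of
  the ratio, which makes per-participant predictions coarse at low error
  counts (the analyses aggregate across participants for this reason).
* `mixed_anova()` covers one between- and one within-subject factor — the
  designs the pipeline itself produces. Doubly-repeated-measures designs
  should be aggregated or fitted with a dedicated mixed-model package.
* Fixed-effect pooling treats the per-experiment SMC variances as known;
  with three studies of 17–19 participants that is an approximation, made
  deliberately to match the forest summaries the pipeline reproduces.
* The guessing null is calibrated in the regime the design actually
  occupies (supports of 20–40 actions per cue, a handful of reports per
  cue). When the support is artificially cramped — a few times the number
  of reported items — sequential without-replacement depletion makes the
  partner-hit fraction depend on the number of error draws, and the null
  becomes slightly anti-conservative. Keep synthetic supports at the
  design's scale when using the generator for power or calibration work.
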