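# guessnull

Monte Carlo guessing baselines for source errors in paired action recall.

## The problem

In paired generation/recall experiments, two people take turns inventing
actions for cue symbols; the next day each recalls either their own or
their partner's actions. Every recalled action is coded as a **correct
recall**, a **source error** (right pair, wrong person — e.g. claiming an
observed action as self-performed, the *observation inflation* error), or
an **intrusion** (never generated by either member). Source errors are the
measure of interest for source-monitoring research, but raw counts
conflate genuine memory failures with lucky guesses: popular solutions to
a cue get re-invented at test and sometimes coincide with the partner's
repertoire.

`guessnull` implements the analysis pipeline around a per-participant
Monte Carlo null for this guessing contamination:

1. **Frequency norms.** Per cue, actions get probabilities proportional to
   their generation-phase frequencies across the whole experiment.
2. **Simulated guessing.** For each participant, the number of actions they
   reported per cue is drawn from the cue's norms by weighted sampling
   without replacement and classified against the pair's encoding sets.
   Over R = 500 replicates, with SE and N the simulated source-error and
   novel counts,

   ratio = mean over non-degenerate replicates of SE / (SE + N).

3. **Scaling.** Observed intrusions must be guesses, so

   predicted source errors = intrusions_observed × ratio / (1 − ratio).

Downstream, observed − predicted differences are analysed with one-tailed
paired t tests (effect size d_av), mixed ANOVA, Cousineau–Morey
within-subject CIs, fixed-effect standardized-mean-change meta-analysis
(forest data included), and Dienes-style half-normal-prior replication
Bayes factors. A generative simulator of the full paired design provides
ground-truth datasets for calibration and recovery testing.

## Worked example

```r
library(guessnull)

sim <- simulate_experiment(n_pairs = 20, seed = 2026)   # synthetic dataset
an  <- run_analysis(sim$generation, sim$recall, n_reps = 500, seed = 2026)
an
#> <recall_analysis> 40 participants, 20 pairs, seed 2026, 500 reps
#>
#> Mean reported counts (per task x condition):
#>             task condition     category  n  mean   sd
#> 1     recall_own      none      correct 20 23.25 4.51
#> 2     recall_own      none    intrusion 20  6.00 2.05
#> 3     recall_own      none source_error 20  4.85 2.03
#> 4 recall_partner      none      correct 20 17.75 2.92
#> 5 recall_partner      none    intrusion 20  6.65 2.62
#> 6 recall_partner      none source_error 20  6.70 2.81
#>
#> Observed vs predicted source errors (one-tailed paired t):
#>             task condition  n mean_diff statistic df  p.value d_av d_method
#> 1     recall_own      none 20      3.00      7.02 19 5.56e-07  2.2     d_av
#> 2 recall_partner      none 20      4.68      7.26 19 3.44e-07  2.6     d_av
```

The counts table is the Table-1-style summary (per task and load
condition). The paired tests compare each participant's observed
source-error count with the count predicted from guessing alone: here the
generator's source-confusion parameter is 0.2, so observed counts exceed
the guessing prediction by ~3–4.7 errors and both one-tailed tests reject
decisively. With `p_source_confusion = 0` the same pipeline produces mean
differences within sampling noise of zero — the calibration property the
test suite checks.

Cross-experiment pooling and replication Bayes factors:

```r
priors <- tibble::tibble(label = c("recall_own", "recall_partner"),
                         data_mean = c(0.15, 0.22), data_se = c(0.20, 0.25),
                         prior_sd  = c(1.28, 2.04))
run_meta(an$effects, priors = priors)
#> recall_own: Fixed-effect summary: 1.569 [0.914, 2.223] over 1 studies
#> recall_partner: Fixed-effect summary: 1.623 [0.956, 2.290] over 1 studies
#>
#> Replication Bayes factors:
#>            label  bf10 bf10_numeric data_mean data_se prior_sd
#> 1     recall_own 0.313        0.313      0.15    0.20     1.28
#> 2 recall_partner 0.288        0.288      0.22    0.25     2.04
```

A `bf10` of 0.31 means the data favour a null effect about 3:1 over an
effect the size of the prior study's. `autoplot()` on a meta result draws
the forest plot; `plot_source_errors()` draws observed-vs-predicted bars
with within-subject CIs; `write_analysis_bundle()` emits the CSV/JSON
report bundle. See the methods vignette (`vignettes/guessing-null.Rmd`)
for the model, its assumptions and the numerical choices.

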