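# ordtime

Bayesian modeling of how memorized serial order biases memory for the
absolute times of events.

## The problem

In slot-based time-report experiments, a trial of 16.5 s is divided into
11 slots of 1.5 s; the first and last slot hold anchor items, and one to
three intermediate items appear at the onsets of randomly chosen distinct
intermediate slots. Participants later report each intermediate item's
presentation time on a continuous slider. Single-item reports are noisy,
yet the *relative order* of two or three items is reported far more
accurately than independent noisy time estimates could explain — and the
remembered order visibly drags the absolute time reports apart: the
earlier of two items presented in the *same* slot (on different trials)
is reported earlier than the later one.

`ordtime` implements a Bayesian observer that explains this interaction.
The internal evidence for a trial consists of noisy internal times
\(\hat t_1,\dots,\hat t_n\) — one independent draw per item from the
empirical single-item report likelihood \(P_1(\hat t \mid t)\) — plus a
*separately stored*, discrete internal order \(\hat\sigma\) which equals
the true order \(\sigma\) with probability \(1-P_\sigma\) and is otherwise
one of the \(n!-1\) wrong permutations, each with probability
\(P_\sigma/(n!-1)\). The posterior over ordered tuples of distinct
intermediate slots \((t_1,\dots,t_n)\) under a uniform schedule prior is

\[
P_{\mathrm{post}}(t_1,\dots,t_n \mid \hat t, \hat\sigma) \propto
  \prod_{i=1}^{n} P_1(\hat t_i \mid t_i)\;
  P(\hat\sigma \mid t_1,\dots,t_n),
\]

and the model's reported time for item *i* is the posterior mean of
\(t_i\). Because the order term acts as a prior, a reliable order memory
(\(P_\sigma\) small) pulls the time reports into agreement with
\(\hat\sigma\), reproducing both the high ordering accuracy and the
rank-dependent report shifts. Default simulation settings are
\(P_\sigma = 0.08\) for two intermediate items and \(0.1\) for three.

The package provides, per module:

- **Synthetic data** — `make_schedule()`, `simulate_session()`: schedule
  and session generators with truncated-Gaussian report noise, anchor
  slots, a rank-only "quantizer" subpopulation and a random-responder
  contaminant.
- **Likelihood estimation** — `estimate_likelihood()`,
  `sample_internal_time()`: binned row-stochastic estimate of
  \(P_1(\hat t\mid t)\) plus a bootstrap resampler of raw reports.
- **Bayesian decoder** — `order_likelihood()`, `posterior()`,
  `posterior_mean_reports()`, `simulate_reports()`,
  `simulate_experiment_records()`.
- **Order analysis** — `naive_flip_probability()`,
  `naive_permutation_table()`, `empirical_order_stats()`,
  `compare_accuracies()` (Fisher exact),
  `expected_correct_under_random()`, `fit_p_sigma()`.
- **Report analysis** — `summarize_reports()`,
  `rank_difference_tests()` (Welch), `slot_dependence_test()` (one-way
  F), `report_slope()`.
- **QC** — `select_participants()`, `qc_histogram()`,
  `apply_selection()`.
- **Pipeline** — `run_pipeline()`, `validate_records()`,
  `read_run_config()`; a shell wrapper lives in
  `inst/scripts/run_pipeline.R`.

## Worked example

```r
library(ordtime)

# 1. single-item sessions -> empirical report likelihood
rec1 <- simulate_session("exp1", n_participants = 150,
                         noise = noise_profile(quantizer_fraction = 0,
                                               random_responder_fraction = 0),
                         seed = 204)
lik <- estimate_likelihood(rec1)

# 2. Bayesian observer on two-item trials
brec <- simulate_experiment_records("exp2", lik, n_trials = 5000,
                                    p_sigma = 0.08, seed = 205)
st <- empirical_order_stats(brec)
st
#> <order_stats> 5000 trials of 2 items; correct-order accuracy 0.954

# 3. the naive independent-encoding prediction is much worse ...
fm <- naive_flip_matrix(lik)
round(1 - mean(fm$flip_prob), 3)
#> [1] 0.864

# ... and falls with slot separation, unlike the Bayesian observer
round(tapply(fm$flip_prob, fm$slot_j - fm$slot_i, mean), 3)
#>     1     2     3     4     5     6     7     8
#> 0.339 0.195 0.093 0.033 0.020 0.007 0.003 0.001

# 4. order bias on absolute reports: at a shared slot the rank-1 item is
#    reported earlier than the rank-2 item
s <- summarize_reports(brec)
round(s$mean_report[s$item_rank == 1 & s$presented_slot == 6] -
      s$mean_report[s$item_rank == 2 & s$presented_slot == 6], 2)
#> [1] -1.08
```

Accuracy 0.954 means the observer reports the correct two-item order on
95.4% of trials even though independent encoding of the same noisy times
would manage only ~86%; the −1.08 s difference at slot 6 is the
order-induced shift of absolute time reports.

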