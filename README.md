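# adhereda

Day-ahead adherence prediction for tablet-based cognitive training, with
per-participant convolutional classifiers and domain-adversarial transfer
between participants.

## The problem

Cognitive training trials for older adults prescribe a weekly schedule —
typically 5 play days per week with 45–60 minute target sessions over an
8–12 week structured phase — and their benefit depends on participants
actually following it. A participant's day is **adherent** when they play
for at least 10 minutes. Given the last *N* days of four daily behavioral
predictors (minutes played, sessions, maximum task level, tasks
completed), the package predicts whether the participant will meet the
criterion on day *N + 1*, so that a support system can send reminders
before a lapse rather than after.

A separate model is trained for every participant, because playing
patterns are strongly individual — but a 30-day training period yields
only 30 − N labeled windows. The package implements three training arms
around this scarcity:

* **no source, no DA** — a 1D-CNN (two convolution + max-pooling blocks,
  a dense layer, 2-unit softmax) trained on the target's windows alone;
* **with source, no DA** — the training windows of the target's *source
  participants* are pooled in directly;
* **with source, with DA** — a domain-adversarial network (DANN): a
  domain head attached to the shared feature extractor through a
  **gradient reversal layer** (forward identity, backward −λ·gradient) is
  trained to tell source windows from target windows while the reversed
  gradient drives the extractor toward features on which it cannot,
  aligning the domains so the source labels transfer.

Source participants are the target's neighbors in playing-pattern space:
each participant's daily play-time series is encoded as a **Gramian
angular field** (GAF) — after rescaling into the arccos domain,
θᵢ = arccos(xᵢ) and G(i, j) = cos(θᵢ + θⱼ) — and K-means (K = 4) on
features of these fields groups participants with similar patterns. The
window size N itself comes from the data: the Fourier amplitude of the
daily play series peaks at the weekly cycle under a 5-of-7 schedule,
giving N = 7.

The original trial datasets are not publicly deposited, so the package
includes a first-class synthetic cohort generator (archetypal playing
patterns with controllable between-participant disparity) that every
stage is tested against.

## Worked example

Because per-participant margins are small, arm comparisons are drawn
across replicate cohorts; five replicates of a 20-participant cohort with
strong per-participant disparity (`shift = 2`) take under 20 seconds on
one core:

```r
library(adhereda)
library(dplyr)

runs <- purrr::map(1:5, function(s) {
  cohort <- generate_cohort(cohort_spec(
    20, archetype_mix = c(consistent = 0.5, consistent_with_lapses = 0.5),
    shift = 2, seed = s
  ))
  cfg <- cnn_config(epochs = 120, seed = s)
  res <- run_within_study(
    cohort, k = 4, seed = s, cfg = cfg,
    dann = dann_config(base = cfg, lambda = 1, lambda_schedule = "annealed")
  )
  mutate(tidy(res), replicate = s)
})
all <- bind_rows(runs)

all |> group_by(arm) |> summarise(accuracy = mean(accuracy), f1 = mean(f1))
#> # A tibble: 3 × 3
#>   arm                 accuracy    f1
#>   <chr>                  <dbl> <dbl>
#> 1 no_source_no_da        0.613 0.593
#> 2 with_source_no_da      0.707 0.681
#> 3 with_source_with_da    0.718 0.689

wide <- all |> select(replicate, participant_id, arm, f1) |>
  tidyr::pivot_wider(names_from = arm, values_from = f1)
sign_test(wide$with_source_with_da, wide$with_source_no_da)
#> Exact sign test: 44 positive / 23 negative of 67 non-tied pairs, p = 0.01393
```

Reading the numbers: training only on a target's own 23 windows reaches
61% mean test accuracy; pooling same-cluster source windows lifts it to
71%; adversarial adaptation adds another point and improves the
per-participant F1 for significantly more participants than it hurts
(exact sign test, p ≈ 0.014). `autoplot(res)` plots an arm × metric
panel, `compare_arms(res)` runs the sign test and repeated-measures ANOVA
on one experiment, and `run_cross_study()` repeats the protocol with
sources restricted to the other of two studies.

The window-size selector reproduces the study-wide value directly:

```r
select_window_size(rep(c(45, 45, 45, 45, 45, 0, 0), length.out = 30))
#> [1] 7
```

## Package tour

| Stage | Functions |
| --- | --- |
| Synthetic cohorts | `archetype_spec()`, `archetype_preset()`, `generate_participant()`, `cohort_spec()`, `generate_cohort()` |
| Preprocessing | `label_adherence()`, `split_train_test()`, `select_window_size()`, `normalize_features()`, `make_windows()`, `prepare_participant()` |
| GAF imaging | `rescale_to_unit()`, `to_polar()`, `gaf_matrix()`, `gaf()`, `render_gaf_image()`, `write_gaf_png()`, `cohort_gafs()` |
| Clustering | `extract_features()`, `cluster_participants()`, `cluster_cohort()`, `source_pool()` |
| Models | `cnn_config()`, `dann_config()`, `build_cnn()`, `convolve1d()`, `grl_backward()`, `train_baseline()`, `train_pooled()`, `train_dann()`, `predict_adherence()` |
| Experiments | `run_arm()`, `run_within_study()`, `run_cross_study()`, `compute_metrics()`, `sign_test()`, `repeated_measures_anova()`, `compare_arms()` |
| I/O | `read_play_log()`, `write_play_log()`, `load_config()`, `model_configs()` |

Fitted models and experiment results support `tidy()`, `glance()` and
`autoplot()`. The methods vignette
(`vignettes/adherence-domain-adaptation.Rmd`) documents the model,
numerical choices, the simulator's assumptions, and known limitations.
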