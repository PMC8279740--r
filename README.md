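# mirrorpop

Analysis chain for extracellular single-unit recordings from the macaque
action observation network — parietal area AIP and premotor areas F5 and
F6 — during a Go/No-Go reach-to-grasp task that the monkey either executes
(EXE) or observes an experimenter perform (OBS). The package is aimed at
systems neurophysiologists who need the full pipeline from sorted spikes
and waveform snippets to population-level statistics, plus a synthetic
generator with planted ground truth so every stage can be validated without
recordings.

The chain implements four analyses:

1. **Waveform cell classes.** Average waveforms (1000 spline-interpolated
   points over 2.5 ms, ±3 SD snippet rejection, three exclusion rules)
   are reduced to trough-to-peak duration and repolarization time, and
   clustered with a diagonal-covariance Gaussian mixture (EM from 500
   k-means++ replicates), the number of classes chosen by
   `BIC(K) = −2 log L + (5K − 1) log n` over K = 1..10. Cluster
   separation is the mean diagonal of a confusion matrix built from 10⁴
   simulated draws.
2. **Facilitated/suppressed labeling.** Net activity (200-ms bins stepped
   20 ms, minus the 500-ms pre-cue baseline) is soft-normalized by
   `max |net| + 5 spk/s`; units are labeled by a one-tailed sliding paired
   t test (p < 0.05, uncorrected) requiring ≥ 5 consecutive significant
   bins in −300..+900 ms around the Go signal.
3. **Pseudo-population decoding.** Trials are dealt one-per-condition into
   splits (30 × 2 = 60 data points for Go/No-Go, 10 × 3 = 30 for objects);
   a Poisson naive Bayes classifier
   (`score_k = Σ_u x_u log λ_uk − λ_uk`, uniform priors) is evaluated by
   leave-one-split-out cross-validation, with ANOVA feature preselection
   (p < 0.5) on training folds. Performance is the plug-in mutual
   information of the confusion matrix, normalized by `log2 K` (1 bit for
   Go/No-Go, 1.585 for objects); onsets are first crossings of
   `log2 K / 3`, with SE = SD(onsets) × 65/N_area and two-sample z
   comparisons.
4. **Mutual Modulation Depth.** `MMD_n(t) = EXE_n(t) · OBS_n(t)`, the
   per-bin product of the net soft-normalized activity of the two tasks
   aligned to movement onset (−500..+700 ms, baselined on the 500 ms
   before the Go signal): positive for congruent, negative for opposite
   cross-task modulation, tested against the mean of the first five bins.

## Worked example

```r
library(mirrorpop)

sess <- simulate_session(n_units = 30, n_per_condition = 10, seed = 42,
                         n_snippets = 1200)

# waveform features and QC per unit
feats <- do.call(rbind, lapply(seq_along(sess$snippets), function(i) {
  f <- unit_waveform_features(sess$snippets[[i]]$snippets,
                              sess$snippets[[i]]$sampling_rate,
                              n_spikes_total = 1200, seed = i)
  data.frame(unit_id = names(sess$snippets)[i],
             trough_to_peak_ms = round(f$trough_to_peak_ms, 3),
             repolarization_ms = round(f$repolarization_ms, 3),
             qc_status = f$qc_status)
}))
head(feats, 3)
#>   unit_id trough_to_peak_ms repolarization_ms qc_status
#> 1    u001             0.483             0.295  retained
#> 2    u002             0.483             0.317  retained
#> 3    u003             0.180             0.075  retained

# cell classes by BIC
x <- as.matrix(feats[feats$qc_status == "retained",
                     c("trough_to_peak_ms", "repolarization_ms")])
model <- select_K_by_bic(x, Kmax = 6, seed = 1, n_replicates = 100)
model$K
#> [1] 3
round(model$means, 3)
#>       [,1]  [,2]
#> [1,] 0.198 0.060
#> [2,] 0.344 0.155
#> [3,] 0.494 0.268
separation_accuracy(model, seed = 1)$accuracy
#> [1] 1

# Go/No-Go decoding during execution
pop <- population_from_session(sess, task = "EXE", variable = "condition",
                               alignment = "t_object_presentation",
                               window = c(-0.5, 1.5))
dec <- decode_timecourse(pop, n_subsample = 30, n_iterations = 10,
                         n_runs = 3, seed = 1)
onset_time(dec, n_area = 30)[c("onset_mean", "onset_se")]
#> $onset_mean
#> [1] 1.23
#> $onset_se
#> [1] 0.047

# Mutual Modulation Depth of one unit
u <- sess$ground_truth$unit_id[2]
tr <- mmd_traces(sess$spikes[sess$spikes$unit_id == u, ], sess$trials)
mmd <- mmd_timecourse(tr$exe, tr$obs)
bc <- attr(mmd, "bin_centers")
mean(mmd[bc >= 0 & bc <= 0.5])
#> [1] 0.078
```

Reading the output: the three fitted class means land on the planted
narrow/intermediate/broad waveform classes and the mixture separates them
perfectly (accuracy 1, planted-class agreement 1 on this session).
Go/No-Go information becomes decodable about 1.23 s after object
presentation — the movement epoch, which is where this generator plants
the condition difference. Unit `u002` is modulated only during execution
(`mod_sign_obs = 0`), so its movement-epoch MMD stays near zero (0.078):
the index deliberately discounts modulation confined to one task.

The whole chain can also be driven by configuration:

```r
cfg <- session_config(n_units = 12, n_iterations = 5, n_runs = 2,
                      gmm_replicates = 50)
run_pipeline(cfg, out_dir = "artifacts")   # TSV/JSON artifacts + run.log
```

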