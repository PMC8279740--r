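---
title: "Methods: waveform classes, population decoding, and mutual modulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: waveform classes, population decoding, and mutual modulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mirrorpop` implements the single-unit analysis chain used to compare
parietal (AIP) and premotor (F5, F6) grasping areas of the macaque while the
animal executes (EXE) or observes (OBS) a Go/No-Go reach-to-grasp task. This
vignette is the package's own account of the science: the models and the
choices behind them, what the synthetic generator does and does not emulate,
and what the tests therefore can and cannot show.

## Task structure and alignment events

Every analysis aligns spike times to events of a per-trial table: fixation
onset triggers a cue sound, the target object (ring, small cone, or big
cone) becomes visible 0.8 s after the cue, and after a variable 0.8–1.2 s
delay the sound ceases (the Go/No-Go signal). In Go trials the actor
reaches, grasps, and pulls; No-Go trials have no movement events, which the
trial-table schema enforces as an invariant. Times are seconds from trial
start, with fixation onset placed 0.5–1.0 s into the trial so that the
500-ms pre-cue baseline epoch is always inside the recorded span.

## Average waveforms and the two features

For each unit, up to 1000 spike snippets are selected at random and windowed
to 2.5 ms centered on each snippet's absolute minimum. A single-pass
pointwise ±3 SD rule removes atypical snippets (the mean and SD are computed
once, not iteratively — the simplest reading of the procedure, documented
here as a design choice; at the generator's default band-limited noise this
removes roughly 10% of snippets). Retained snippets are cubic-spline
interpolated to 1000 points over the 2.5-ms window regardless of the
original sampling rate, realigned to the absolute minimum, and averaged.
Units are excluded, in order, when they have (1) fewer than 1000 spikes,
(2) a "multipeak" waveform — more than one local maximum strictly between
the main trough and the largest post-trough peak, or (3) a trough shallower
than the subsequent peak or a pre-trough peak above 20% of the trough depth
(likely axonal waveforms).

Two scalar features summarize each retained average waveform:

* **trough-to-peak duration** — time from the global minimum to the next
  local maximum (strict three-point maxima; plateaus resolve to the earliest
  sample);
* **repolarization time** — time from that maximum to the next inflection
  point, located as the first sign change of the central second difference
  after the peak and refined by linear interpolation. No smoothing is
  applied before differentiation: on the 1000-point interpolated grid the
  spline has already regularized the curve, and the analytic test templates
  (whose post-peak lobe is a Gaussian with SD equal to the repolarization
  time) confirm the locator to within two grid steps.

The ±3 SD rejection runs on aligned raw-resolution snippets, before
interpolation; when a raw snippet's minimum sits too close to an edge the
2.5-ms crop shifts to stay inside the data.

## Cell classes: diagonal Gaussian mixture and BIC

Units are clustered in the two-dimensional feature plane with a Gaussian
mixture whose component covariances are constrained to be diagonal (the two
features correlate across classes but not within them). EM runs from 500
k-means++ initializations, each to convergence (relative log-likelihood
change below 1e-5, the conventional EM stopping rule) or 100 iterations,
keeping the replicate with the highest log-likelihood. The number of
components is scanned from 1 to 10 and chosen by BIC with parameter count
5K − 1 (two means, two variances, and one mixing weight per component, minus
one weight constraint) — the count is stated here because it is a choice,
not a given. Variances are floored at 1e-6 ms² to keep components
nonsingular on small samples, and floored fits are flagged. Classes are
renumbered by ascending mean trough-to-peak, so class 1 is the
narrowest-spiking class. An additional outlier-removal step used by earlier
waveform-clustering work is deliberately not applied: physiologically valid
units are kept.

Cluster separation is quantified by drawing 10^4 labeled points from the
fitted mixture, reassigning them by maximum posterior, and reporting the
row-normalized confusion matrix and the mean of its diagonal. For display,
68% confidence ellipses (the bivariate analog of the standard error) are
axis-aligned by construction. Area-by-class composition is compared with
Pearson chi-square tests (goodness-of-fit against the pooled distribution
and pairwise homogeneity, both uncorrected).

## Facilitated and suppressed units

Activity is binned in 200-ms windows advanced by 20 ms; the value sits at
the window center and only windows fully inside the analysis span are used,
so the −300..+900 ms span around the Go signal yields 51 bins centered
−200..+800 ms. The baseline is the per-trial rate in the 500 ms before cue
onset, computed separately per task. Net activity (bin rate minus baseline)
is soft-normalized by the absolute maximum across conditions plus 5 spk/s,
bounding traces inside (−1, 1) and damping low-rate units.

A unit's direction is the sign of its mean net modulation over the span;
each bin is then tested against the trialwise baseline with a one-tailed
paired t test at p < 0.05, uncorrected, and the unit is labeled facilitated
or suppressed only when at least five consecutive bins are significant.
The pairing is a choice: the source procedure says only that baseline and
bin activity were compared, but the trials are shared between the two
quantities, and pairing matches the paired test used for the MMD analysis.
Bins with zero-variance differences are treated as nonsignificant (the t
statistic is undefined there). On null simulations the consecutive-bin rule
keeps false facilitated/suppressed labels at or below 10%.

Peak latencies of facilitated units are the trace maxima in 100–500 ms
after object presentation and 0–600 ms after the Go signal (earliest bin on
ties). Heatmaps order units by descending mean net normalized activity in
the −300..+900 ms span, independently per task. Firing statistics pool
within-trial interspike intervals; the burst fraction is the proportion of
ISIs below 10 ms — a declared surrogate, since the original burst metric is
not specified in the accessible text.

## Pseudo-population decoding

Decoding treats independently recorded units as one population: per unit,
trials are shuffled within condition and dealt one-per-condition into as
many splits as there are trials per condition (30 × 2 = 60 data points for
Go/No-Go, 10 × 3 = 30 for objects). A Poisson naive Bayes classifier is
trained on all but one split and tested on the held-out split, rotating
through all splits. Because the source names the classifier without
defining it, the scoring rule is fixed here: class-conditional mean counts
per unit and bin, floored at 1e-3 counts, uniform priors over the balanced
conditions, and prediction by the argmax of
`sum_u x_u log(lambda_uk) − lambda_uk` with ties broken uniformly at
random. A brute-force Bayes oracle (full Poisson likelihood enumeration)
validates the implementation over all small instances in the tests.

Before training, features (units) are preselected with a one-way F test
across conditions at p < 0.5, recomputed on the training folds of each
cross-validation rotation only — the source is ambiguous about the data
used, and restricting to training folds avoids test-set leakage. Decoding
performance per bin is the plug-in mutual information of the
(actual, predicted) confusion counts, bounded by log2 K (1 bit for
Go/No-Go, 1.585 for three objects).

Number matching draws 65 units with replacement per iteration (three
quarters of the smallest area, rounded half up), runs 10 full
cross-validation cycles with fresh splits, averages them, and smooths the
curve with a Gaussian kernel; "40 ms" is interpreted as the kernel SD,
truncated at ±3 SD and renormalized at the edges (the width convention is
not stated in the source; the interpretation is recorded in the result's
configuration). The across-iteration mean and SD are reported over 50
iterations. The information onset of an iteration is the first bin whose
MI exceeds one third of the theoretical maximum; the onset SE is the SD of
the per-iteration onsets multiplied by 65/N_area, applied exactly as
printed even though its derivation is not given. Onsets and epoch-averaged
MI (200–700 ms after object presentation) are compared across populations
with two-tailed two-sample z tests, uncorrected. Class-wise decoding draws
a fixed 20 units per class per area (60 in total) per iteration.

## Mutual Modulation Depth

For each unit, EXE and OBS activity in Go trials is aligned to movement
onset over −500..+700 ms (51 bins centered −400..+600 ms — the literal
"bins centered at intermediate values" reading), baselined on the 500 ms
before the Go signal (a reference specific to this analysis, distinct from
the pre-cue baseline), and soft-normalized per task. The index is the
per-bin product `MMD_n(t) = EXE_n(t) · OBS_n(t)`: positive for congruent
modulation, negative for opposite modulation, near zero when either task
shows none, bounded by ±1 and strictly inside the bounds for finite rates
because of the +5 spk/s soft constant.

Group-level increases are tested bin-by-bin against each unit's mean of the
first five bins with a one-tailed paired t test across units, keeping runs
of at least five consecutive significant bins. Two discrepancies in the
source are surfaced rather than resolved: the significance level is 0.01 in
the methods text but 0.05 in the corresponding figure legend (the default
here is 0.01, with the threshold exposed as a parameter), and "the first 5
bins (300 ms of activity)" actually span 280 ms on the 200-ms/20-ms grid
(the five grid bins are taken literally).

## The synthetic generator, and what passing tests show

No recordings accompany the source ("available upon request"), so the
package ships a generator with planted ground truth. It emulates: three
waveform classes with distinct trough-to-peak/repolarization geometry
(means 0.20/0.34/0.48 ms and 0.05/0.17/0.30 ms, within-class SD 0.015 ms —
at least 8 within-class SDs of separation, truncated to the observable
ranges 0.13–0.58 and 0.0025–0.43 ms), band-limited snippet noise (white
noise convolved with a one-sample Gaussian kernel, so the ±3 SD rule
removes about the expected tenth of snippets), epoch-structured
condition-dependent firing via inhomogeneous Poisson processes sampled
exactly by thinning (baseline plus a plateau of planted depth with
half-Gaussian 100-ms ramps — the source implies nothing about true rate
dynamics, so the ramp shape is a named default), object-gain selectivity,
and a mirror-like joint EXE/OBS sign structure (jointly facilitated,
jointly suppressed, opposite, single-task, or unmodulated units). Baseline
rates are gamma-distributed with higher means for narrow-spiking classes.

The waveform template is piecewise-smooth with analytic control of both
features: a half-Gaussian descent, a half-cosine trough-to-peak limb whose
extrema sit exactly at the trough and peak, and a Gaussian post-peak decay
whose SD equals the repolarization time, so the inflection point falls
exactly one repolarization time after the peak. All randomness derives
from one session seed split into per-unit/per-trial streams.

The generator does not emulate: biophysical membrane dynamics, LFPs, eye
movements, reaction-time structure beyond fixed event-time distributions,
noise correlations between units (pseudo-populations assume independence
by construction), non-Poisson spiking statistics (refractoriness,
bursting beyond planted doublet constructions in tests), or drift and
instability of real recordings. Passing tests therefore demonstrate that
each stage recovers what was planted under the stated noise model — not
that the chain is robust to every property of real tissue.

## Numerical choices and problem sizes

Tie-breaks are deterministic where the quantity is a measurement (earliest
bin for peak times and plateau maxima, smallest K on BIC ties, input order
for heatmap ties) and uniformly random only inside the classifier, where
they are seeded. Degenerate inputs error early with named messages (all
snippets rejected, K above the number of distinct points, units with too
few trials for the requested splits, windows outside the decoded span).

Test and example problem sizes are chosen to exercise every code path at
desk scale: sessions of 8–30 units with 4–10 trials per condition-object
cell, decoding populations of 8–14 units with 6–8 iterations and 2–3 runs,
and the full 500-replicate, K = 1..10, n = 355 clustering protocol at its
original scale (it is the one stage cheap enough to run exactly as
specified, and its selection behavior is the package's headline
reproduction). Larger decoding configurations simply scale the same code.

## Known limitations

The plug-in mutual information is positively biased at small test-set
sizes; with the protocol's 60 data points the bias is well below the
onset threshold of log2(K)/3, but results from much smaller populations
should not be read against that threshold. The 65/N_area SE correction is
reproduced as printed, without a derivation. The sliding-test and MMD
procedures use uncorrected per-bin p-values by design — the consecutive-bin
rule is the multiplicity control — so single-bin significance is not
meaningful in isolation.
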