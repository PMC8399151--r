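---
title: "Methods: ensemble detection of obstructive sleep apnea from single-lead ECG"
author: "apneafuse authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble detection of obstructive sleep apnea from single-lead ECG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apneafuse)
```

## The detection problem

Obstructive sleep apnea (OSA) interrupts breathing during sleep; its
cardiovascular footprint is visible in a single ECG lead. Two phenomena make
per-minute screening possible: a cyclic bradycardia–tachycardia oscillation
of the RR interval with a period of roughly 30–60 s during apneic episodes,
and respiratory modulation of QRS morphology (amplitude and area). The
package classifies each labelled minute of a 100 Hz single-lead recording as
`apnea` or `normal` and combines several weak detectors into one decision.

## Preprocessing model

Each minute (6000 samples) passes through five stages.

**R-peak detection.** The multilevel Teager energy operator
$\psi_k[n] = x[n]^2 - x[n-k]\,x[n+k]$ responds to the sharp, high-frequency
QRS complex while suppressing smooth baseline activity. Per lag
$k \in \{1,2,3\}$ (configurable) the energy is smoothed with a Hamming
window of length $4k+1$, matched to the width of features each lag is
sensitive to, and the combined energy is the pointwise maximum over lags.
Candidate peaks are energy local maxima above `mean + threshold_c * sd`;
a 250 ms refractory rule keeps the stronger of two competing peaks
(no physiological rhythm produces R peaks closer than that), and each peak
is refined to the argmax of $|x|$ within ±50 ms. The threshold default is
`threshold_c = 1`: the energy distribution of a spiky signal is heavy-tailed,
so its standard deviation is dominated by the QRS spikes themselves, and
respiratory amplitude modulation (±20 % in amplitude, roughly ±40 % in
energy) spreads true-peak energies widely. One standard deviation above the
mean sits far above the noise floor at the noise levels where detection is
meaningful (validated in the test suite: sensitivity and positive
predictivity both ≥ 0.95 at `noise_sd = 0.05`), while larger multipliers
begin to clip low-amplitude beats.

**Beat series.** From peaks $r_1 < r_2 < \dots$: RRI$_i = (r_{i+1}-r_i)/f_s$
seconds; RAMP$_i$ = mean-removed amplitude at $r_i$; EDR$_i$ = integral of
the absolute mean-removed signal over ±50 ms around $r_i$. RAMP and EDR are
deliberately distinct surrogates (peak height vs QRS area): both are
modulated by respiration but respond differently to morphology changes.

**Quality filter.** A minute is `noise` when its beat count falls outside
20–200 or any raw RRI outside 0.3–2.0 s. These are physiological
plausibility bounds for sinus rhythm (20 bpm would be extreme bradycardia,
200 bpm extreme tachycardia; RRIs outside 0.3–2.0 s imply missed or spurious
detections). Noise minutes are excluded from training and evaluation but are
retained in feature files with an explicit flag.

**Grid resampling.** The beat-indexed series are irregularly sampled; the
classifiers need a fixed shape. RRI and RAMP are median-filtered over 5
beats (wide enough to suppress a single ectopic or missed beat, narrow
enough to keep the 30–60 s apnea oscillation intact), then cubic-spline
interpolated onto a uniform 240-point grid over the minute (one point per
0.25 s; an RRI is anchored at the time of the pair's closing beat).
Extrapolation beyond the first/last beat holds the boundary value — splines
diverge when extrapolated. EDR skips the median filter; its respiratory
ripple is slow. A clear minute with fewer than 4 beats cannot support a
cubic spline and is reclassified as noise. The result is the `240 × 3`
per-minute feature matrix.

**Normalization.** Z-scores per column, $\hat X = (X - \mu_X)/\sigma_X$,
with statistics pooled over the *fitting* split only (default
`normalization_scope = "train"`), so no test-set information leaks into the
features. `"global"` pooling is available as a config flag for comparison.
A zero-variance column maps to zeros with a warning.

## Base classifiers

Three compact architectures operate on the `240 × 3` matrices:

| name | plan |
|---|---|
| `wang` | 2 × [conv1d(k 3, 64) → BN → pool 2] → dense 100 → dense 10 → softmax |
| `sharan` | 3 × [conv1d(k 10, 64/128/256) → pool 2] → dense 64 → dense 256 → softmax |
| `almutairi` | 4 sub-windows of 60 rows → shared 3 × [conv1d(k 3, 64/128/16) → BN → pool 2 → dropout 0.2] → LSTM 64 → dense 64 → softmax |

Convolutions use "same" padding and hidden dense layers ReLU — the usual
choices where a plan does not pin them down; they keep the shape arithmetic
stable (240 → 120 → 60 after two pools). Training uses Adam (step size
0.001), softmax cross-entropy on one-hot two-class targets (identical to
binary cross-entropy for $k=2$), batch size 64, 100 epochs by default; all
of these are exposed in the training contract. The networks run on the
package's own neural-network engine (im2col convolutions over BLAS matrix
products, exact batch-norm and LSTM backpropagation); the test suite pins
every layer's gradients against central finite differences at $10^{-7}$
tolerance, and parameter counts against hand shape-arithmetic.

Seeds drive weight initialization, shuffling and dropout, so a fixed seed
reproduces a fit bit-for-bit on one platform; across BLAS builds small
floating-point drift is possible, which is why behavioural tests assert
accuracies with tolerances rather than exact losses.

## Fusion rules

Let $p_{ij}$ be classifier $j$'s probability for class $i$.

1. **Majority voting** counts argmax votes. With 3 classifiers and 2
   classes a tie is impossible; for even ensembles a vote tie is resolved by
   the sum rule restricted to the tied classes.
2. **Sum rule**: $\mathrm{CS}_i = \sum_j p_{ij}$.
3. **Choquet fuzzy fusion.** Per sample, classifier $j$ receives a fuzzy
   density from its prediction entropy, $g_j = 1 - H_2(p_{\cdot j})$
   ($H_2$ in bits; for $k>2$ classes the entropy is divided by $\log_2 k$ so
   the density stays in $[0,1]$ — for the two-class problem this is exactly
   "entropy subtracted from its maximum of 1"). Densities are computed *per
   sample*: the point of the rule is that a classifier that is confident on
   this minute carries more weight on this minute. The Sugeno λ-measure
   extends the densities to classifier subsets via
   $g(A \cup B) = g(A) + g(B) + \lambda\,g(A)\,g(B)$, with λ the unique
   root of $1 + \lambda = \prod_j (1 + \lambda g_j)$ on $(-1,\infty)$,
   found by bisection to $|f(\lambda)| \le 10^{-12}$ (positive when
   densities sum below 1, negative above, 0 at exactly 1 — the additive
   case). Class scores are Choquet integrals over the sorted scores,
   $\mathrm{CS}_i = \sum_j s_{\pi_j} [g(A_{\pi_j}) - g(A_{\pi_{j-1}})]$,
   ties in the sort broken by classifier index.

   With `normalize_densities = TRUE` (default) the densities are divided by
   their sum. That choice makes the measure additive (λ = 0) and the
   Choquet integral collapses to an entropy-weighted arithmetic mean — a
   perfectly sensible rule, but one where the λ machinery is inert. The
   flag therefore also admits `FALSE`, keeping the raw confidences and a
   genuinely non-additive measure. Both paths are tested, including against
   a brute-force subset-enumeration implementation of the integral.
   Degenerate samples (all classifiers exactly uniform) fall back to equal
   densities; a sample with a single informative classifier has no valid λ
   for raw densities and falls back to the normalized additive measure.
4. **MLP stacker.** A one-hidden-layer perceptron (16 ReLU units) on the
   flattened $k \cdot l$ score vector, trained with the same contract as the
   base models. Unlike the fixed rules it can learn non-monotone score
   patterns (the suite demonstrates an XOR-structured pattern no weighted
   mean can express).

Tie-breaking is deterministic everywhere: lowest class index, then lowest
classifier index.

## Evaluation machinery

Confusion counts treat apnea as the positive class (clinical convention:
a missed apnea minute is the costly error). The five metrics are accuracy,
precision, recall, F1 and specificity; a zero-denominator metric is
reported as `NaN` with a note, never silently as 0, because a silent zero
would corrupt fold averages. Protocols: two-fold swap (train A / test B,
swap, average), unstratified k-fold with a seeded shuffle (stratification
available by flag), and plain holdout. `run_experiment()` drives the whole
grid — every base model and every fusion rule by every metric.

## The synthetic generator

`generate_record()` emulates exactly the statistical structure the pipeline
assumes: a fixed Mexican-hat QRS template (width ≈ 0.1 s) placed at beat
times; normal minutes with RR = 60/`base_hr` plus Gaussian jitter
(`hrv_sd`, default 0.02 s); apnea minutes with the RR additionally
multiplied by $1 + s\,\sin(2\pi t/T)$ (`apnea_rr_swing` s, default 0.25;
period `T` = 45 s inside the 30–60 s band reported for cyclical heart-rate
variation); R amplitudes modulated at the respiratory rate (15 breaths/min,
depth 0.2); additive Gaussian noise; and optional corrupted minutes of
high-amplitude broadband noise that keep their class label, existing solely
to exercise the quality filter. Defaults are ordinary resting-adult values.

What it does *not* emulate: P/T waves, baseline wander, electrode motion
artefacts, arrhythmias, inter-patient variability, or any coupling between
apnea and amplitude modulation. Passing tests on this generator therefore
demonstrate that the pipeline's machinery is correct and that the detectors
can learn the cyclic-RR signature; they say nothing about clinical
performance on real recordings, which must be established on real data.
`generate_score_matrices()` plays the same role one level up: synthetic
classifier outputs with known marginal accuracies (Dirichlet rows
concentrated on the drawn class) for testing fusion in isolation.

## Problem sizes and numerical choices

The test suite runs the full stack at desk scale: the end-to-end acceptance
check trains all three models for 10 epochs on 600 synthetic training
minutes (swing 0.4) and evaluates on 600 held-out minutes — large enough
that every base model clears 90 % test accuracy and small enough to run in
minutes on one core. Unit tests use 6–100 minutes and 1–6 epochs. Key
tolerances: λ-bisection to $|f| \le 10^{-12}$; Choquet oracle equivalence to
$10^{-9}$; gradient checks to $10^{-7}$; z-score moments to $10^{-6}$;
detector timing to ±20 ms at 100 Hz. Stochastic training assertions use a
retry-once policy with a second fixed seed.

## Known limitations

* The WFDB reader covers the subset of the format family that the target
  database layout uses (single- and dual-signal formats 16 and 212, MIT
  annotation streams); exotic formats are rejected with a clear error.
* The neural engine is single-threaded BLAS-bound R; it is sized for
  hundreds-of-minutes experiments, not for training on the full clinical
  corpus at 100 epochs.
* Minute labels are assumed reliable; label noise handling is out of scope.
* The stacker is trained on in-sample base-model scores. At desk scale with
  well-separated classes this is adequate, but on real data an out-of-fold
  scheme would reduce stacker overfitting; the function interface accepts
  any score/label pairing, so such a scheme can be built on top.
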