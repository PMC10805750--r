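---
title: "ECG-to-PPG translation: models, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ECG-to-PPG translation: models, parameters, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ecg2ppg)
```

This vignette is the package's own account of the science it implements:
what each model assumes, which tunable parameters matter, where the design
was genuinely open and what we chose, and what the passing test suite does
— and does not — demonstrate about real data.

## The translation model

The core object is a conditional generative model `G` mapping a 1-D ECG
segment to the synchronized PPG segment. `G` is a U-Net: `depth` encoder
levels of stride-2 convolutions (channels doubling per level from
`base_filters`), a bottleneck convolution, and a mirrored decoder of
nearest-neighbour upsampling plus convolution, with skip connections
concatenating each encoder level's activations onto the matching decoder
level. Skips matter here for a physiological reason: beat *timing* is
positional information that the bottleneck alone would blur, and the whole
point of the translation is that the pulse train inherits the R-peak train.
The output head is a convolution to one channel under `tanh`, matching the
per-record min-max normalization of all signals to [-1, 1].

The critic `D` is Markovian: a stack of stride-2 convolutions over the
channel-wise concatenation (ECG, PPG) ending in a one-channel map of patch
logits, so each score judges only a local stretch of waveform. This biases
training pressure toward local pulse realism rather than global segment
statistics, and makes the discriminator translation-covariant up to edges.

Training alternates one discriminator step with one generator step per
example. The generator objective is the adversarial term plus
`lambda_rec` times the mean absolute error against the reference PPG.
The loss composition is the standard conditional-translation convention;
`lambda_rec = 100` (default) makes the L1 term dominant early, which is
what stabilizes training at small scale, while the adversarial term
sharpens pulse shape. Both the objective (`bce` or `lsgan`) and
`lambda_rec` are configurable in `train_config()`. Optimization is Adam at
`2e-4` for both networks with `beta1 = 0.5` (the customary GAN setting —
high momentum on noisy adversarial gradients destabilizes training),
batch size 1 by default.

Because the generator is fully convolutional, any input whose length is a
multiple of `2^depth` is valid; `generate_ppg()` reflect-pads a segment to
the next such multiple and crops the output back. (Padding to the next
multiple — 3008 for a 3000-sample segment at depth 5 — is equivalent to,
and more general than, fixing one padded length in advance.)

All three networks (generator, discriminator, classifier) are implemented
in-package: compiled single-threaded 1-D convolution kernels with
hand-derived backward passes, checked against central-difference numerical
gradients in the test suite to ~1e-9 (convolutions are exact; the only
slack is leaky-ReLU kink crossing). Single-threaded kernels and seeded R
RNG make every training run bit-reproducible, which the tests assert.

## The waveform simulator: what it emulates, what it does not

The simulator stands in for paired clinical recordings so that every
downstream stage is testable. Its defaults define the study conditions and
are not tuned per experiment.

* **Rhythm.** Sinus rhythm: RR intervals `60/mean_hr` modulated
  sinusoidally at the respiratory frequency (`sr_rsa_freq = 0.25` Hz,
  depth `0.08` of the mean RR) plus 2% Gaussian jitter — an SDNN of
  roughly 35–50 ms, the textbook healthy-adult range. AF: i.i.d.
  log-normal RR with mean `60/mean_hr` and coefficient of variation
  `af_cv = 0.2`, reproducing the two signatures that matter for this
  problem — high beat-to-beat irregularity and absent serial correlation
  (tests assert lag-1 autocorrelation below 0.1). Per-record mean rates
  are drawn from 55–85 (SR) and 65–110 (AF) beats/min.
* **ECG morphology.** Each beat is a sum of five Gaussian bumps
  (P, Q, R, S, T) at *fixed latencies in seconds* around the R peak
  (P −160 ms, Q −35 ms, S +35 ms, T +280 ms; widths 12–70 ms), with the T
  latency pulled in to `0.55·RR` on short beats (rate-dependent QT
  shortening). Fixed latencies — rather than fractions of the RR interval
  — are deliberate: they keep consecutive R-R differences exactly equal to
  the generating RR series (a fractional scheme mixes adjacent intervals
  and shrinks the apparent CV by ~25%), and they are how real conduction
  behaves: the complex rides at fixed timing, the baseline stretches.
* **PPG morphology.** One systolic Gaussian (width 90 ms) plus a dicrotic
  wave (amplitude 0.25, +280 ms, width 110 ms) per beat, delayed from the
  R peak by a pulse transit time drawn once per record from 0.18–0.28 s —
  per-record, not per-beat, since beat-level PTT dynamics are invisible to
  every statistic the pipeline computes.
* **Noise.** Additive white Gaussian, `noise_sd = 0.02` against a unit R
  peak, then per-record min-max scaling to [-1, 1].

Not emulated: motion artifacts, ectopic beats, reflectance-vs-transmission
morphology differences, baseline wander, and mixed-rhythm records (the
annotation machinery supports AF bursts inside SR, but no default cohort
generates them). Consequently a green test suite shows that the
*architecture and pipeline* transfer rhythm and morphology under clean
conditions; it does not certify performance on ambulatory wrist data.

## Preprocessing choices

* **Pan–Tompkins** as published: zero-phase 5–15 Hz Butterworth band-pass,
  five-point derivative, squaring, 150-ms moving-window integration,
  adaptive signal/noise thresholds with a 200-ms refractory period and a
  2-s learning phase. Detections are refined to the band-passed extremum
  and then to sub-sample precision by parabolic interpolation; peaks whose
  waveform is truncated by the record edge are dropped. The last two
  refinements exist because the QC statistic below is computed on
  *intervals*: at 100 Hz, integer-sample quantization alone costs ~0.01 of
  interval correlation on low-variability sinus records.
* **PPG peaks**: local maxima above 55% of the signal range (excluding the
  dicrotic wave) with a `60/max_hr` distance floor, on a zero-phase 10-Hz
  low-passed copy — the systolic peak is broad, so unfiltered noise
  dominates its location.
* **QC screen**: a record is kept when the Pearson correlation between its
  R-R and pulse-interval sequences exceeds 0.96 and the mean detected heart
  rate is at least 30 beats/min (a lower detected rate on a continuous
  recording means the channel defeated the detector, not bradycardia).
  Correlation is computed on interval sequences, not peak-index arrays —
  index arrays are trivially near-collinear and would pass anything.
* **Resampling** is rational-factor and zero-phase: zero-stuff by `p`,
  FIR low-pass (`fir1`, applied forward-backward), decimate by `q`, with
  reflect margins cropped away. The off-the-shelf polyphase routine leaves
  an uncompensated ~1-sample group delay, which a peak-timing pipeline
  cannot tolerate.
* **Slicing**: a 30-s parent with a 15-s window and 1-s stride admits 16
  windows by the sliding-window formula; compatibility mode (default)
  drops the final one so each parent yields 15 slices and 770 parents
  yield exactly 11,550 — the counting convention of the experiment this
  package reproduces. All splitting downstream is by whole parents, so
  slices that overlap by 14/15 can never straddle a train/test boundary.

## Embedding and the Degree of Overlap

The t-SNE implementation follows the printed equations exactly: Gaussian
conditionals with per-point bandwidths calibrated by bisection to the
target perplexity (default 30, tolerance 1e-4), symmetrized joint
affinities `(p(i|j)+p(j|i))/2n`, Student-t low-dimensional kernel, and the
`4·Σ (p−q)·w·(y_i−y_j)` gradient — verified against numerical
differentiation of the KL cost. Optimization uses the reference recipe
(learning rate 200, momentum 0.5→0.8 at iteration 250, early exaggeration
×4 for 50 iterations, per-coordinate gains). The final 50 iterations
switch to plain gradient descent with step halving, which makes the
recorded cost non-increasing while the embedding settles — momentum
overshoot otherwise leaves ~1e-4 wiggle that would falsify the monotone
contract for no benefit.

Two populations are always embedded *jointly* (one t-SNE on the
concatenated matrices, then split); separate embeddings would live in
incomparable coordinate systems and make any overlap number meaningless.
Densities are product-Gaussian KDEs evaluated at the cell centers of a
shared 100×100 lattice with Silverman bandwidths and 3-bandwidth margins,
normalized to cell masses, and compared by the Bhattacharyya coefficient
`DO = Σ √(P₁·P₂)` — 1 for identical distributions, 0 for disjoint ones,
invariant to relabeling cells. The KDE is implemented in-package so the
two densities share one lattice and one bandwidth by construction.
Exact O(n²) t-SNE suffices at desk scale; populations are capped at 2000
points by seeded subsampling.

## The classifier experiment

The classifier is exactly the published recipe: six convolution layers
with 4, 8, 16, 32, 64, 128 filters, kernel 3, leaky ReLU α = 0.15,
truncated-normal(0.05) weights with zero biases, global average pooling
into a 2-way softmax, cross-entropy, Adam at 0.001. Stride-2 convolutions
(pooling is unstated in the recipe) reduce the 1500-sample input to 24
positions before pooling. Two practical notes:

* That initialization scale shrinks activations by ~10⁴ across six layers,
  so small-dataset runs spend their first few hundred Adam steps escaping
  a flat region of the loss. Epochs and batch size are unstated in the
  recipe; the experiment defaults here (8 epochs, batch 8) give every
  composition scheme enough optimizer steps to train at desk scale.
* The composition schemes are: D1 all-generated AF + SR; D2 half generated
  + half real AF + SR; D3 all real AF + SR; D4 half real AF + half SR.
  Halves are seeded samples of whole parents; D1–D3 trim the SR pool (by
  whole parents) to the AF count so classes stay balanced. A leakage guard
  refuses any experiment where a parent contributes slices to both a
  training pool and the test set.

AUROC uses the rank (Mann–Whitney) formula with midrank ties — the test
suite checks it against brute-force pair concordance — and its 95% CI is a
seeded stratified bootstrap (2000 resamples by default; the CI method is a
package choice, as the source experiment does not state one).

## Problem sizes and what the stochastic tests show

The suite trains one translation model at the conditions it is scored
under — 500 paired 30-s segments (250 simulated records × 60 s, half AF),
U-Net depth 3 with 8 base filters, 6 epochs — about two minutes of CPU
here. On 12 held-out AF records the correlation between the generated
pulse-interval series and the source R-R series averages ≈ 0.998 against
an acceptance bar of 0.8: at clean desk scale, rhythm transfer is
essentially perfect, and the bar exists to catch structural regressions,
not to estimate clinical performance. The composition experiment uses
pools of 1,200 slices per arm and a 600-slice disjoint test set; the
resulting ordering (mixed > all-generated > half-real, all AUROC > 0.98)
mirrors the motivating real-data finding qualitatively. The printed
real-data numbers themselves (accuracies near 0.96, DO = 0.937, HR
correlation 0.94) depend on clinical databases and are deliberately not
asserted anywhere.

## Known limitations

* Simulated waveforms are far cleaner than clinical PPG; absolute metric
  values (PRD ≈ 25%, CC ≈ 0.96 in the README example) should be read as
  desk-scale ceilings, not forecasts.
* The generator reproduces the *average* pulse transit time of its
  training distribution; per-subject PTT is not recoverable from ECG alone
  and interval statistics are unaffected by a constant delay.
* i.i.d. log-normal AF ignores the weak short-range structure real AF can
  show; anything sensitive to RR autocorrelation beyond lag 0 should not
  rely on the default generator.
* The 3-SD outlier rule in `summarize_metrics()` is a convention; the
  outlier counts it reports are not comparable to counts produced by an
  unknown flagging rule.
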