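---
title: "Estimating Auditory Classification Images: models, simulation and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating Auditory Classification Images: models, simulation and inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aciglm)
```

## The problem

A listener categorizing a phoneme in noise relies on a handful of
acoustic cues — for /da/ vs /ga/, chiefly the onset configuration of the
second and third formant transitions (distant onsets for /da/, converged
onsets for /ga/), with a secondary cue at the first-formant onset. The
Auditory Classification Image (ACI) makes this listening strategy
visible: by presenting thousands of trials in fresh white noise and
regressing the trial-by-trial responses on the noisy stimulus
representations, one obtains a time–frequency weight map showing where
noise energy pushes the listener toward one response or the other. It is
the behavioral sibling of the spectro-temporal receptive field.

This package implements the full chain — stimulus generation, adaptive
experiment, cochleogram front-end, penalized estimation, and group
statistics — with a simulated linear observer at its heart, so that every
stage can be validated against a known ground truth without human data.

## The decision model and its estimator

The linear observer answers 'ga' on trial $i$ with probability
$$p_i = \mathrm{logit}^{-1}\left(\langle S_i, \beta\rangle + c\right),$$
where $S_i$ is the cochleogram of the full stimulus (target + noise),
$\beta$ the internal template, and $c$ a static response bias. Working on
the stimulus cochleogram (rather than separating noise and target
predictors) respects the nonlinearity of the front-end: target and noise
do not combine linearly after compression.

The estimate is the maximum a posteriori solution of the penalized
logistic likelihood
$$\hat\beta,\hat c = \arg\min\; -\sum_i \left[r_i\log p_i + (1-r_i)\log(1-p_i)\right] + \tfrac{\lambda}{2}\,\beta^\top K\beta .$$

**Smoothness prior.** $K = D^\top D$ with $D$ the discrete 2-D Laplacian
on the time–frequency grid with reflecting (Neumann) boundaries. This
penalizes curvature, i.e. performs data-driven low-pass filtering of the
template. The Laplacian annihilates constant maps, so $K$ alone would
leave a flat offset of $\beta$ unpenalized even as $\lambda \to \infty$;
since a constant offset of the template is indistinguishable in role from
the bias $c$, we add a vanishing ridge ($10^{-6} I$) so that the penalty
is positive definite and the large-$\lambda$ limit cleanly drives
$\beta \to 0$ and $c \to \mathrm{logit}(\bar r)$. At any selected
$\lambda$ the ridge contribution is negligible.

**Optimizer.** Newton iterations (penalized IRLS) with
Jacobi-preconditioned conjugate-gradient inner solves on the
$(p+1)$-dimensional system (bias unpenalized), step halving to enforce a
monotone objective, gradient-norm tolerance $10^{-6}(1+|f|)$, iteration
cap 200. Predictors are centered internally; the bias is mapped back to
the raw scale, so the reported $(\hat\beta,\hat c)$ solve the original
problem. With $\lambda = 0$ the solution matches `glm(family = binomial)`
to ~$10^{-9}$ relative error on well-conditioned instances (asserted at
$10^{-4}$ in the tests). Deviance computations clip probabilities to
$[10^{-12}, 1-10^{-12}]$.

**Trial balancing.** The adaptive procedure fixes performance near 79 %
correct, so correct trials outnumber errors ~4:1, which distorts the MAP
estimate. Randomly chosen correct trials are discarded until the counts
match; a 10,000-trial run retains ≈ 4,200 trials. Balancing happens
before cross-validation fold assignment, and folds are stratified by
response.

**Penalty selection.** One shared $\lambda$ for all listeners, chosen to
minimize the mean 10-fold cross-validated deviance across listeners over
a log-spaced grid (default 15 values spanning $10^{-4}$–$10^{2}$). Ties
break toward the smoother value; a minimum at a grid edge is flagged with
a warning.

## The synthetic experiment

**Targets.** Four VCCV non-words (/alda/, /alga/, /arda/, /arga/) are
produced by a parametric source–filter synthesizer: a 120 Hz pulse-train
glottal source through a cascade of three time-varying formant
resonators. All four targets share a 680 ms duration and a second-syllable
onset at exactly 328 ms (the closure gap is digital silence, so the onset
is measurable to the sample). The /da/–/ga/ contrast is carried by the
F2/F3 transition onsets — 1400/2550 Hz for /da/ (distant), 1950/2050 Hz
for /ga/ (converged) — over a shared steady /a/ (700/1220/2600 Hz); the
first-syllable coda is a voiced lateral ("l" context) or band-limited
frication ("r" context). This is deliberately a stylized stimulus: it
carries the cue structure the method targets, not the full variability of
recorded speech.

**Noise and mixing.** Maskers are i.i.d. Gaussian, RMS-normalized, and
identified by `(seed, index)` rather than stored. Mixing at SNR
$s$ uses $\gamma(t + \lambda n)$, $\lambda = 10^{-s/20}$, with $\gamma$
restoring unit RMS, so the requested broadband SNR holds exactly. An
optional raised-cosine noise fade-in (default 50 ms when enabled) is a
listener-comfort feature; it is prepended outside the analysis window and
verified to leave the cochleogram unchanged.

**Staircase.** 3-down-1-up with the printed schedule: initial SNR
−11 dB, step 2 dB decaying ×0.9 at every SNR change (up or down) to a
0.2 dB floor, step reset at each session start, sessions chained through
the final SNR. The decay-at-every-change reading is one of several
consistent with the verbal description; it is the one implemented. A
safety clamp at −40/+10 dB guards degenerate observers and is never
reached by realistic ones. The fixed point of the rule is
$P(\text{correct}) = 0.5^{1/3} \approx 79.4\,\%$, independent of the
observer's psychometric slope.

**Observers.** The simulated listener answers through the same logistic
decision model the estimator assumes, with three parameters: a template
(by default the unit-norm difference between the mean 'ga' and mean 'da'
clean-target cochleograms, optionally jittered per listener), a gain, and
a centering constant. Internal noise is represented by the gain — a
higher gain means a steeper, more deterministic mapping from stimulus
evidence to response — keeping the generating model in the estimator's
likelihood family, which makes parameter recovery well-posed. Because
cochleograms are non-negative energy maps, the raw dot product carries a
large class-independent offset; the centering constant (the midpoint of
the class-conditional mean decision variables over a reference stimulus
ensemble) anchors the decision variable at the category boundary.
`calibrate_gain()` fixes the gain by bisection so the *expected* accuracy
on the reference ensemble (computed analytically from the response
probabilities, hence monotone in gain) hits a target, by default 79 % at
the calibration SNR. A separate SNR-driven psychometric observer
(logistic in SNR with a 0.5 guessing floor, as a two-choice task cannot
fall below chance) serves the staircase-convergence checks, where no
cochleograms are needed.

## The front-end

The published grid is fixed — 15.6 ms frames, 54 channels geometrically
spaced over 96–7760 Hz — but the cochlear model behind it (Lyon's, with
quality factor 8 and "overlapping = 40 %") is not specified to the level
of reimplementation. The default front-end is therefore a documented
stand-in honoring the grid and the quality factor: per channel, a cascade
of four identical two-pole resonators (an all-pole gammatone
approximation) whose pole damping is set so the measured −3 dB bandwidth
equals $f_c/8$; half-wave rectification; second-order Butterworth
envelope smoothing (64 Hz cutoff); power-law compression with exponent
0.3; frame averaging with trailing partial frames dropped (a 680 ms input
gives exactly 43 × 54). The "overlapping = 40 %" remark is recorded in
the filterbank object but not interpreted. The front-end is deterministic
and order-preserving under amplitude scaling (scaling the waveform by $k$
scales the output by $k^{0.3}$), and the estimation machinery is
agnostic to it: any module producing a time × frequency energy matrix can
stand in.

Two numerical choices matter for throughput and are part of the
front-end's definition: resonator states below $10^{-25}$ are flushed to
zero (silent stretches otherwise leave subnormal tails in the IIR
state), and compression plus frame accumulation are evaluated on a
decimated sample grid — the smoothed envelope is band-limited to 64 Hz,
so sampling it every $\min(\text{frame}/8,\ f_s/(16 \cdot 64))$ samples
loses nothing at frame resolution.

## Group-level inference

Individual templates are z-scored (sample standard deviation over pixels;
bias excluded) before averaging, putting listeners on a common scale.
Three inferential tools operate on stacks of z-maps:

- **Pixelwise FDR maps** — one-sample t against zero per pixel,
  Benjamini–Hochberg mask at $q$ (default 0.01), non-significant pixels
  zeroed in the displayed mean map.
- **Cluster-based permutation test** — two-sample pooled t per pixel;
  pixels with $|t|$ above the two-sided $\alpha$ quantile (default 0.05)
  are grouped by 4-connectivity (configurable to 8); cluster mass is the
  sum of $|t|$; the null is the maximum cluster mass over random
  relabelings (default 1000); the p-value includes the observed statistic
  in the null count, so it is never exactly zero. The mass statistic and
  4-connectivity are documented defaults: the literature's standard
  cluster correction does not pin either down.
- **Weight sets** — on the pooled maps (all listeners, both groups),
  pixels with one-sample $p < 10^{-10}$ forming 4-connected components of
  at least 7 pixels become named sets, annotated with size, sign of the
  mean weight, centroid and extent mapped through the grid metadata
  (frame centers in ms, channel center frequencies in Hz). ROI group
  comparisons then t-test each set's mean weight between groups,
  reported uncorrected (as is conventional for such set tables) with a
  Bonferroni column alongside.

Prediction analyses score fitted models by deviance
($-2\log$-likelihood) and by the fraction of held-out trials whose
predicted-probability side of 0.5 matches the response (ties at exactly
0.5 count as incorrect — a conservative convention). Auto-prediction is
10-fold cross-validation within a listener; cross-prediction applies the
same fold machinery with the test partitions taken from another
listener's balanced table, keeping the two deviances on one scale (equal
balanced table sizes are assumed). Specificity is the auto-prediction
deviance minus the mean cross-prediction deviance of the same listener's
data under the other listeners' models — negative when one's own model
predicts best. Sensitivity and criterion follow standard signal detection
theory with 'ga' as the signal; extreme rates are corrected by the
$1/(2N)$ rule before taking normal quantiles. Sensitivity is computed on
the full (unbalanced) runs — balancing forces hit and false-alarm rates
to 0.5 by construction.

## Problem sizes and what the tests show

The test suite and the bundled analysis run at reduced scale, chosen so
the full chain exercises every code path at sub-minute granularity:
320 ms targets at 16 kHz, a 12-channel 150–5000 Hz filterbank with 20 ms
frames (a 16 × 12 grid), and simulated listeners calibrated at −6 dB —
the stylized reduced-band targets carry less discriminable detail than
full-band speech, so the 79 %-correct operating point sits at a milder
SNR than the −12 dB of the full-scale configuration (where the default
54-channel front-end supports 79 % at −12 dB). Parameter recovery is
checked on a 10,000-trial run (≈ 4,100 balanced): the fitted template
correlates with the generating one at $r > 0.9$ at the cross-validated
penalty, increasing with trial count. Type-I error of the cluster test is
verified at ≈ 5 % over 500 null replicates on a 12 × 12 grid, and FDR
control over 200 null replicates. The end-to-end study (two groups of
simulated listeners, one amplifying the core negative /ga/ cue lobe
2.5×) shows the cluster test and ROI analysis recovering the injected
difference, and reruns are checksum-identical from the same seed.

What passing these tests does *not* show: that the method's assumptions
hold for human listeners. Real listeners are non-stationary (learning,
lapses), their internal noise need not be logistic, their effective
front-end differs from any fixed filterbank, and recorded speech carries
covariance structure the formant synthesizer does not emulate. The
simulations validate the estimator and the inference chain, not the
psychology.

## Design choices made where the specification of the method is open

- Step decay is applied at every SNR change (not per trial, not per
  reversal); other readings of the verbal rule exist.
- The exact penalty family and boundary handling of the smoothness prior
  are documented defaults (squared Neumann Laplacian + vanishing ridge).
- Z-scoring uses the sample standard deviation.
- Cross-prediction deviance assumes equal balanced test-set sizes; no
  further normalization is applied.
- The SDT extreme-rate correction is the $1/(2N)$ convention.
- Serialization is delimited text plus JSON sidecars throughout (trial
  logs schema-compatible with deposited experiment logs: one row per
  trial with session, trial, target, noise reference, SNR, response,
  correctness).

## Known limitations

- The front-end approximates, and does not replicate, Lyon's cochlea
  model; absolute cochleogram values are not comparable across
  front-ends, though the estimation grid and all downstream statistics
  are.
- The formant synthesizer produces stylized tokens; transfer of any
  quantitative result to recorded speech must be established separately.
- `fit_aci` on the full 43 × 54 grid with 4,000+ trials is CPU-bound
  (seconds per fit); penalty selection across many listeners at full
  scale is the dominant cost of a study.
- Only the two-alternative (binary response) design is supported.
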