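---
title: "Methods: multiscale information flow between maternal and fetal heart rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiscale information flow between maternal and fetal heart rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dyadflow)
```

## The problem and the measurement model

A pregnant mother and her fetus have interacting cardiovascular systems:
maternal respiration, blood-gas changes and autonomic fluctuations all reach
the fetal circulation. `dyadflow` quantifies that interaction from
simultaneous maternal and fetal RR-interval series along two complementary
axes:

* **temporal information transfer** — how much the maternal heart-rate past
  improves prediction of the fetal heart-rate future beyond the fetal past
  (transfer entropy, directional and lag-resolved), and
* **state-dependent complexity modulation** — how fetal signal complexity
  (entropy rate, sample entropy) changes during specific maternal or fetal
  heart-rate states (acceleration/deceleration epochs).

All quantities are evaluated across time scales τ: the signal is low-pass
filtered by a moving average of width τ and embedded at lag τ, so each τ
isolates dynamics at that scale. Summaries (`max`, `AUC` = mean) are taken
over τ ∈ [0.5, 2.5] s, the band dominated by fast vagal regulation: the
lower edge is about one fetal cardiac cycle (0.43 s at 140 bpm), the upper
edge the cardiac baroreflex loop, well below Mayer-wave scales (~10 s).

## Pipeline and estimators

**RR → HR.** Instantaneous HR is the piecewise-constant `60/RRI` held over
each beat interval and sampled on an even grid (default 20 Hz). A zero-order
hold is used rather than interpolation: raw heart rate genuinely is
piecewise constant between beats, and the scheme introduces no spurious
smoothness at sub-beat scales. Samples outside the beat range, in
poor-quality seconds (per-second quality mask), or in valid runs shorter
than 10 s are flagged invalid; estimators only embed windows lying entirely
inside one valid run. Dyads whose fetal HR sits below 100 bpm for more than
5% of valid samples are excluded (the signature of the maternal heart
recorded twice); the 5% default is a configurable choice, not an established
threshold.

**Filtering.** Centered moving average of `round(τ·fs)` samples; output
samples are valid only when the full window is valid. A centered (not
causal) window avoids phase shift between the maternal and fetal filtered
signals, which matters because epochs of one signal condition estimates on
the other. The analysis is offline, so non-causality costs nothing.

**Epochs.** At each scale, the forward difference of the filtered signal
labels each sample accel (`d > μ`), decel (`d < −μ`) or neither, with μ = 0
by default; run endpoints are `neither`. Both event-based and
time-point-based fractions are reported: event fractions follow the
`N_accel/(N_accel+N_decel)` definition, while time-point fractions are the
natural response for the mixed-model stage and sum to slightly less than 1
(exact-zero derivatives and endpoints form a third category).

**Entropy estimators.** The base estimator is Kozachenko–Leonenko k-NN
differential entropy with the Chebyshev norm and k = 5; transfer entropy is
the KSG/Frenzel–Pompe conditional mutual information
`I(dst_{t+L}; src_t | dst_t)` with the same k. Three numerical safeguards
matter on this kind of data:

* *Jitter*: HR values are quantized (1 ms beat timing), and k-NN estimators
  need distinct distances; a deterministic uniform jitter of amplitude
  10⁻⁶ σ per coordinate is always applied (fixed seed; estimates are
  reproducible).
* *Theiler exclusion*: embedding vectors closer in time than one embedding
  lag are never counted as neighbours of each other. Without this, serial
  correlation of the filtered signals masquerades as recurrence and biases
  every estimate, including the surrogate-corrected TE.
* *Spacing discipline*: candidate vectors are subsampled to a minimum
  temporal gap of half the Theiler window (then evenly thinned to
  `max_vectors`, default 1000). Conditioned vector sets are temporally
  clumped inside epochs; without a common spacing rule their k-NN bias
  differs from the unconditioned estimates and conditioned-vs-unconditioned
  comparisons are distorted. The cap keeps the O(n²) neighbour search fast;
  beyond ~1000 well-separated vectors the variance reduction is marginal.

**Embedding choice.** ER and TE use a single past lag of length τ
(embedding dimension 1) and a future horizon of τ. This is the minimal
embedding consistent with the m = 1 convention of the sample-entropy
parameters and is exposed as a configuration knob (`sampen_m`, and the lag
follows τ by construction); higher-order embeddings multiply the state
dimension and are not justified at the vector counts available per epoch.

**Conditioning.** Five paradigms: none, mHR-accel, mHR-decel, fHR-accel,
fHR-decel. A conditioned estimate uses only embedding vectors whose sample
coordinates (t and t+L; all m+1 template points for SE) carry the required
label of the conditioning signal. The coordinates may fall in *different*
events of the same type: epochs at scale τ last on the order of τ/2, shorter
than the lag τ itself, so requiring the whole window to sit inside a single
event would leave conditioned sets empty at every interesting scale. This
was measured directly (zero usable vectors at τ = 2.5 s on 900 s of signal)
and is the package's deliberate design choice for the conditioning scheme.

**Surrogates.** Corrected TE subtracts the mean raw TE over 20 circular
time shifts of the source (offsets uniform, at least 10 τ). Circular shifts
preserve both marginals and the destination's autocorrelation while
destroying source–destination alignment; the subtraction removes the
finite-sample bias of the raw estimator. The epoch-conditioning frame stays
fixed under shifting — it is part of the analysis design, not of the
coupling under test. The surrogate *mean* (not a percentile) is subtracted,
making corrected values usable as magnitudes rather than significance
calls.

**Features.** {ER, SE} × {mHR, fHR} × 5 paradigms × {max, AUC} (40) plus
netTE × 5 paradigms × {max, AUC} (10) = 50 features per dyad. AUC is the
mean over grid points in the closed band (equal to the area under the curve
up to the 2 s band width); trapezoidal integration differs negligibly on a
log grid this dense and the mean is used. Estimates with fewer than 100
usable vectors are reported missing with a reason, never imputed.

## The synthetic cohort generator

Clinical recordings of this type are not publicly available, so the
generator is a first-class module: every downstream claim is tested against
cohorts whose ground truth is known. Each heart is a continuous-time target
HR process — mean (80 bpm maternal, ~140 bpm fetal) + sinusoidal components
(respiratory ~0.25 Hz and Mayer ~0.1 Hz maternal; fetal-breathing-band
0.8 Hz and a slow drift fetal) + a sum of AR(1) processes with log-spaced
correlation times (0.5–32 s, equal variance shares) approximating the 1/f
spectrum of real HRV, plus a fast (0.3 s) symmetric component that sets the
sub-second information floor — integrated to beat times by
integrate-and-fire on the cumulative cardiac phase and quantized to the
1 ms timing resolution of a 1000 Hz ECG.

Three mechanisms create the structures the analysis is designed to detect:

* **Coupling**: the fetal target HR receives
  `c · (m̄(t−δ) − mean)`, where `m̄` is the maternal HR averaged over a
  trailing window δ (default δ = 1.5 s, the middle of the vagal band).
* **State-contingent variance**: inside ground-truth maternal deceleration
  epochs (sign of the derivative of the maternal target HR smoothed at
  2.5 s — deliberately independent of the estimated epochs) the entire
  fetal fluctuation variance is multiplied by ρ ∈ (0, 1].
* **Slew asymmetry**: the slow stochastic part of each heart passes through
  an asymmetric rate limiter (upward slew capped at ~1 bpm/s, downward
  free), so ascents take longer than descents. This reproduces the
  empirical predominance of accelerations over decelerations in time-point
  fractions (fetal ≈ 50/47, maternal ≈ 51/49 at τ = 2.5 s with the
  defaults).

Defaults were fixed once, as the package's own study conditions: coupling
gain c = 0.6 puts the band-mean net TE of a 20–40 min recording around
0.02–0.05 nats, comfortably above the per-dyad estimator noise
(~0.01 nats), so that a one-way coupled dyad shows positive band net TE in
≥ 90% of realizations. The cohort effect map (stress +0.12 on c, male ×
stressed −0.15, gain SD 0.1, cortisol–gain correlation 0.3 on the log
scale) is a free modelling choice — the reference analysis reports effects
on model coefficients, not in generator units — and is documented as such.
Outcome scores (Bayley composites and subscales) are pure noise by default,
matching the finding that no feature–outcome association survives FDR
correction.

What the generator does *not* emulate: ECG waveforms and their artifacts,
fetal movement and behavioural states, gestational-age trends, and any
nonstationarity beyond the quality-mask dropouts. Passing tests therefore
demonstrate that the estimators recover the modelled mechanisms at
realistic signal scales — not that real recordings contain them.

## Statistics stage

* **Net-TE positivity**: the Gaussian-fit p is `P(mean ≤ 0)` under
  `N(mean, sd/√n)` fitted to the cohort feature; the one-sided one-sample
  t-test is reported alongside and the two agree to ~0.02 for n ≥ 50.
* **Outliers**: iterative leave-one-out z-scores (each point judged against
  the mean/SD of the others), default threshold |z| > 10. Leave-one-out is
  what makes extreme z values (≫ √n) observable at all.
* **Mixed models**: REML with a per-dyad random intercept via
  `lmerTest` (Satterthwaite p-values). Three presets mirror the standard
  layouts: accel/decel time-point fractions (4 obs/dyad), ER features
  (20 obs/dyad), net-TE features (10 obs/dyad). Reference levels are fixed:
  fetal signal, fetal-accel conditioning, max metric, female, control — so
  the `conditioning = none` coefficient is the baseline against which
  `coupling_strength()` forms |β_cond|/β_none. Gestational age, maternal
  age and BMI can be appended as covariates (the sensitivity workflow).
* **Correlation battery**: per feature–outcome pair, Shapiro–Wilk on both
  variables (α = 0.05) selects Pearson (both normal) or Spearman; two-sided
  uncorrected p plus BH q across the battery; strata (stress group, sex,
  sex × stress) re-run as separate BH families and flagged post hoc.
  Pairwise-complete observations; pairs with n < 5 are skipped; missing
  features are never imputed.

## Problem sizes used in the tests

The acceptance-style checks run on study conditions chosen so each
mechanism is comfortably detectable: estimator oracles at n = 10⁴–2·10⁴
points; null-TE centering on 30 uncoupled dyads of 5 min; net-TE
positivity on 10 coupled dyads at the nominal 40 min recording length; the
ρ = 0.4 conditioned-ER contrast on 50 dyads of 15 min; mixed-model
recovery on simulated long tables at the full n = 118 design over 20–40
seeds; the sampling-rate comparison (4 vs 20 Hz) on 20 dyads of 40 min
with the embedding-vector cap raised to 2000, so per-dyad estimator noise
sits well below the between-dyad coupling spread; FDR calibration on eight
60-dyad null cohorts. Reduced surrogate counts (10 instead of 20) are used
where corrected values are averaged over many dyads.

## Known limitations

* The single-lag embedding cannot separate direct coupling from common
  slow drivers; the surrogate correction removes estimator bias, not
  confounding.
* Conditioned estimates at large τ rest on few vectors; below 100 vectors
  they are reported missing, and on 10-minute recordings the fHR/mHR-decel
  paradigms at τ > 5 s are routinely missing by design.
* The Gaussian-fit positivity p assumes approximate normality of the
  cohort feature distribution; the paired t-test column is the robust
  companion.
* Sample entropy with m = 1 measures amplitude-conditional predictability
  only; it is deliberately insensitive to phase structure a larger m would
  capture (a sine has nonzero SE at m = 1).
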