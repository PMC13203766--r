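# dyadflow

Multiscale, event-conditioned information flow between maternal and fetal
heart rates.

During the third trimester the fetal heart does not beat in isolation: the
maternal heart rate (mHR) carries information about the fetal heart rate
(fHR) a second or two into the future, and the fetal signal becomes more
regular while the mother's heart rate decelerates. `dyadflow` implements the
full analysis pipeline for quantifying these two coupling channels from
RR-interval recordings of mother–fetus dyads, for researchers in fetal
physiology, stress programming, and heart-rate-variability methods.

## What it computes

For each dyad, both RR series are converted to evenly sampled instantaneous
heart rate (zero-order hold, default `fs` = 20 Hz), low-pass filtered by a
centered moving average at each time scale τ, and partitioned into
acceleration/deceleration epochs by the sign of the filtered derivative
(μ = 0). On this multiscale representation the package estimates, in nats:

- **Entropy rate** `h(τ) = H(x_t, x_{t+τ}) − H(x_t)` — the rate of new
  information generation, via the Kozachenko–Leonenko k-nearest-neighbour
  estimator (Chebyshev norm, k = 5, Theiler exclusion);
- **Sample entropy** `SE = −ln(A/B)` with m = 1, tolerance r = 0.2 σ,
  templates spaced at the scale lag;
- **Transfer entropy** `TE_src→dst(τ) = I(dst_{t+τ}; src_t | dst_t)` by the
  KSG conditional-mutual-information scheme, bias-corrected by circular
  time-shift surrogates, and its directional balance
  `netTE = TE_m→f − TE_f→m`.

Every metric runs under five conditioning paradigms (none, mHR-accel,
mHR-decel, fHR-accel, fHR-decel); curves are reduced to their maximum and
mean over the vagal band τ ∈ [0.5, 2.5] s, yielding 50 features per dyad
(20 ER + 20 SE + 10 net TE). A cohort statistics stage provides net-TE
positivity tests (Gaussian-fit and one-sided t), REML mixed models with
per-dyad random intercepts and the coupling-strength ratio
|β_conditioned|/β_baseline, and a normality-driven Pearson/Spearman
correlation battery with Benjamini–Hochberg FDR control and stratification.

Because clinical recordings of this kind are not public, the package ships a
synthetic dyad generator (`sim_config()`, `generate_dyad()`,
`generate_cohort()`) with known ground truth: oscillatory + 1/f-like
stochastic heart rates integrated to beat times, unidirectional
maternal→fetal coupling at a configurable lag, deceleration-contingent
fetal variance reduction, slew-rate acceleration asymmetry, and 1 ms beat
quantization.

## A worked example

```r
library(dyadflow)

d <- generate_dyad(sim_config(duration_s = 600), seed = 5)
p <- preprocess_dyad(d, fs = 20)

fm <- hr_moving_average(p$mhr, 2.5)   # maternal HR at tau = 2.5 s
ff <- hr_moving_average(p$fhr, 2.5)
epoch_stats(label_epochs(ff))[, c("accel_frac_time", "decel_frac_time")]
#> # A tibble: 1 × 2
#>   accel_frac_time decel_frac_time
#>             <dbl>           <dbl>
#> 1           0.529           0.444

net_transfer_entropy(fm, ff, entropy_params(n_surrogates = 10))
#> # A tibble: 1 × 6
#>   net_te  te_mf    te_fm n_vectors_mf n_vectors_fm reason
#>    <dbl>  <dbl>    <dbl>        <int>        <int> <chr>
#> 1 0.0349 0.0291 -0.00579          366          366 <NA>
```

The fetal heart spends more time accelerating than decelerating (52.9% vs
44.4% of samples at this scale), and the surrogate-corrected transfer
entropy is clearly positive only in the maternal→fetal direction: a net
flow of information from mother to fetus, here ~0.035 nats at τ = 2.5 s.
`coupling_strength(-0.123, 0.206)` reproduces the 60% ratio between the
maternal-deceleration conditioning effect and the no-conditioning baseline
from the mixed-model stage. `run_pipeline(run_config(...))` chains all
stages — simulation, preprocessing, epochs, features, statistics — from one
seeded config.

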