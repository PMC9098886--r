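---
title: "Lung-sound features in a reduced EMD subspace: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lung-sound features in a reduced EMD subspace: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdcl)
```

## The problem

Lung sounds are nonlinear, nonstationary acoustic signals. Normal
(vesicular) breathing is broadband noise concentrated roughly between 100
and 1000 Hz with a steep drop below about 200 Hz; pathology superimposes
adventitious sounds on it — tonal wheezes during expiration, brief damped
crackle transients during inspiration. Classifying respiration cycles by
diagnosis requires features that capture both spectral envelope and its
temporal dynamics, yet the usual static cepstral features (MFCCs) discard
temporal dependency and live in a high-dimensional hyperspectral space that
can hurt classifiers.

`sdcl` implements a feature that addresses both points: **shifted delta
cepstral coefficients computed in a reduced subspace** (SDC-L). The signal
is first decomposed by empirical mode decomposition (EMD) into intrinsic
mode functions (IMFs); only the first `K` IMFs — the high-frequency,
information-bearing modes — are kept and summed back into a "low subspace"
signal; MFCCs of that reconstruction are then differenced into shifted
delta cepstra. The number `K` is not a tuning knob: it is chosen by a
bootstrap hypothesis test on time–frequency surfaces.

## Empirical mode decomposition

EMD writes a signal as `x(t) = Σ_{k=1..K} y_k(t) + r_K(t)`, where each IMF
`y_k` satisfies two properties: its numbers of extrema and zero crossings
differ by at most one, and the mean of its upper and lower envelopes is
locally near zero. IMFs are found by *sifting*: repeatedly subtracting the
mean of the two natural-cubic-spline envelopes through the maxima and
minima. The decomposition is exactly additive by construction, so the
completeness identity holds to machine precision.

Numerical choices (each one the conventional EMD default, exposed in
`emd_config()`):

* **Envelope interpolation** — natural cubic splines through the extrema.
* **Boundary handling** — the two extrema nearest each end are mirrored
  across it before spline fitting, suppressing end swings.
* **Inner stopping rule** — sifting stops when the Cauchy criterion
  `Σ(h_prev − h)² / Σ h_prev² < 0.2` *and* the candidate actually satisfies
  both IMF defining properties (extrema/zero-crossing balance within one,
  envelope-mean peak below 10% of the candidate's peak); at most 50 sifts
  per IMF. Requiring the defining properties, not just the Cauchy
  criterion, guarantees that everything the decomposition emits passes
  `is_imf()` — with the Cauchy rule alone, low-order noise modes routinely
  retain envelope bias.
* **Degenerate input** — a signal with fewer than two maxima or two minima
  is monotone-like and is a residue by definition; this terminates the
  outer loop.
* **IMF cap** — `ceiling(log2(N))`, the dyadic bound expected for
  broadband signals (EMD acts as a dyadic filter bank, each successive IMF
  roughly an octave lower).

## The stopping rule: choosing K by hypothesis testing

After each new IMF `k` is found, the reconstruction from the first `k − 1`
IMFs is compared against the reconstruction from the first `k`. Each
reconstruction is mapped to a **time–frequency surface**: the log-magnitude
short-time Fourier transform on a time × frequency grid, smoothed by a
separable Gaussian Nadaraya–Watson kernel so that it estimates a smooth
regression function `m(x)`, `x ∈ R²`. The two surfaces are compared with
the L2 statistic

`T_N = Σ_{i<k} ∫ (m_i(x) − m_k(x))² ω(x) dx`,

discretised as a grid sum times the cell area, with uniform weight
`ω ≡ 1` (the simplest smooth positive weight; any member of that family
can be supplied). The general multi-surface sum is implemented; the scan
uses it pairwise.

The null distribution of `T_N` is obtained by a **wild bootstrap**: the
pooled surface `m0` (the mean of the two smoothed surfaces) plays the role
of the common regression function; per-cell residuals (raw observation
minus `m0`) are multiplied by independent Rademacher signs, the perturbed
raw surfaces are re-smoothed, and the statistic is recomputed `B` times.
The p-value uses the add-one convention `(1 + #{T* ≥ T})/(B + 1)`, so it is
never exactly zero. A rejection means the new IMF materially changes the
surface and the scan continues; the first non-rejection stops it at
`K = k − 1`. If the `k`-th IMF is numerically negligible the two
reconstructions coincide, `T = 0 ≤ T*`, and the p-value is 1 — the scan
stops cleanly without a special case.

Design notes:

* **Residual inflation.** The pooled smooth absorbs a fraction
  `h = (S_t)_ii (S_f)_jj / 2` of each raw cell, shrinking its residual;
  residuals are divided by `sqrt(1 − h)` (the HC2 correction familiar from
  wild bootstrapping regressions). Without it the test is measurably
  anti-conservative.
* **Multiplier.** Rademacher signs by default; Mammen's two-point
  distribution is available via `multiplier = "mammen"`.
* **Independence caveat.** The wild bootstrap treats grid cells as
  independent observations. With overlapping frames or a tapered window,
  neighbouring STFT cells are positively correlated and the test
  over-rejects — which, inside the stopping rule, biases `K` upward. The
  calibration checks in the test-suite therefore use non-overlapping
  rectangular-window frames (`surface_config(fft_length = 128, hop = 128,
  window = "rect")`), where cells for white noise are exactly independent;
  the measured type-I error at `α = 0.05` then sits near nominal. The
  package default for feature work remains the 256/128 Hann configuration,
  which is the better *surface estimate* even if its test is conservative
  about calibration guarantees.
* **No multiplicity correction** is applied across the scan — each test is
  read marginally, and the scan typically terminates after one or two
  tests.
* **Smoothing bandwidth** — 2 grid cells per axis. As the bandwidth tends
  to zero the smoother tends to the identity and the statistic degenerates
  to a raw sum of squared differences.

On a designed two-band signal (tones at 350 Hz and 40 Hz, three octaves
apart, in light noise at SD 0.05) the first two IMFs carry the tones and
the scan selects `K = 2` essentially always; on a clean single tone it
selects `K = 1` with a p-value of 1 at the first step.

## Cepstral features

* **Mel scale**: `mel(f) = 2595·log10(1 + f/700)` — the log10 convention
  that pairs with the constant 2595.
* **MFCC chain**: Hann window → power spectrum → triangular mel filterbank
  (centres equally spaced in mel between `fmin` and `fmax`, peak 1) → log
  with floor `1e-10` → orthonormal DCT-II → first 13 coefficients,
  *including* the energy (0th) coefficient. Defaults: frame 2048 samples,
  hop 512 samples, 128 mel filters. Frame parameters are expressed in
  samples, not milliseconds, so recordings of different rates need no
  resampling; a 512-*sample* hop yields enough frames per respiration
  cycle for the delta operators to be meaningful, whereas a 512 ms hop
  would give only two or three frames per cycle.
* **Delta cepstra**: `δ[t] = C[t+d] − C[t−d]` with edge replication at the
  sequence boundaries, so output length equals input length.
* **SDC**: `K_blocks` delta blocks computed at positions shifted by `P`
  frames and concatenated; with one block it reduces exactly to the delta
  operator. The **adjusted** form replaces the two-point difference by the
  local least-squares slope `Σ_u u·C[t+jP+u] / Σ_u u²` over `2d+1` frames
  — on a frame-wise linear sequence it recovers the slope exactly. The
  defaults `d = 2, P = 2, K_blocks = 2` reflect the usual "both parameters
  set to 2" convention with the block count kept explicit and
  configurable.
* **SDC-L** is *defined* as the composition
  `sdc_adjusted(mfcc(reconstruct(emd(x), K)))` and the exported `sdc_l()`
  is tested to be bitwise identical to that composition — there is no
  shortcut path that could drift.

Variable-length cycles are pooled to fixed-length vectors for classifiers;
`mean`, `mean+sd` and `flatten-truncate` schemes are provided. For delta
features the `mean_sd` scheme is the informative default in the evaluation
harness: delta trajectories fluctuate around zero, so their per-coefficient
dispersion carries most of the class information.

## Denoising

The stationary/nonstationary separation iteratively hard-thresholds detail
coefficients of a Daubechies (db8) decomposition: coefficients whose
magnitude exceeds `3 × MAD/0.6745` within their level are declared
nonstationary; the remainder reconstructs the stationary estimate and the
pass repeats (at most 10 times, stopping when the nonstationary energy
changes by under 1%). Approximation coefficients are never thresholded —
they carry the broadband background the filter is meant to keep. The
transform uses **periodization** rather than symmetric extension: the
analysis operator is then exactly orthonormal, so
`stationary + nonstationary ≡ input` holds at machine precision, which is
the invariant everything downstream relies on. High-pass filtering is
deliberately *not* used for heart-sound removal, since lung sounds can
extend down to roughly 20 Hz.

Note one interaction: crackles *are* nonstationary transients, so the
denoiser removes much of their energy from the stationary branch. In a
pipeline that classifies crackle-bearing cycles, either run the denoiser in
`passthrough` mode or accept that crackle cues survive mainly through what
the thresholds miss.

## Synthetic data: what it emulates and what it does not

The generator provides seeded, fully reproducible stand-ins for annotated
respiratory recordings, with three classes rather than a clinical label
set — enough to exercise every pipeline stage and multiclass metrics
without pretending to model specific diseases:

* **vesicular** — Gaussian noise band-passed to 100–1000 Hz
  (forward–backward Butterworth, hence zero-phase), an extra first-order
  roll-off below 200 Hz, modulated by a raised-cosine
  inspiration/expiration envelope (inspiration occupying 40% of the cycle
  and louder by a factor 1/0.6);
* **wheeze** — the vesicular base plus a 400 Hz tone with 1% vibrato at
  4 Hz, active during expiration, at +5 dB relative to the base;
* **crackle** — the vesicular base plus Poisson-placed ~5 ms damped
  700 Hz bursts during inspiration, 8 expected events per cycle.

Defaults: 4 kHz sampling (a common digital-stethoscope rate), 10 s
recordings, 2.5 s cycles — values a respiratory-acoustics practitioner
would call typical for adult resting breathing. Crackle placement is
Poisson rather than regular so that repeated-seed statistics are testable
against the Poisson mean.

What the generator does **not** emulate: heart-sound contamination, sensor
and ambient noise heterogeneity, inter-patient variability, polyphonic
wheezes, or any disease-specific acoustics. Passing the end-to-end
separability check therefore demonstrates that the feature pipeline
preserves and exposes the class-defining structure it is given — not that
comparable accuracy would be reached on clinical corpora.

## Evaluation harness

Metrics come from the standard confusion-matrix formulas (accuracy as
trace over total; per-class one-vs-rest precision, recall and F1) with
**support-weighted** aggregation as the default: with imbalanced classes
weighted averaging is the scheme under which aggregate precision can
exceed accuracy, the pattern typical of published lung-sound results.
Classifiers plug in through a minimal `fit`/`predict` contract; thin
adapters for linear/RBF SVM, k-NN, random forest, LDA and a
single-hidden-layer network ship with the package. The train/test split is
a single stratified hold-out (20% by default) — per-cycle, so cycles of
one recording can land on both sides; with real multi-recording patients
this would risk leakage and a grouped split should be used instead.

## Problem sizes and determinism

Every stochastic routine is a pure function of its seed: generators,
splits, classifier fits and the bootstrap all run under an
internally-scoped RNG, and `run_pipeline()` reproduces its JSON report
byte-for-byte from (config, seed). The shipped verification suite works at
desk scale, chosen to make each property measurable in seconds to minutes:
EMD completeness and the IMF predicate on 100 random signals of lengths
512–4096; the dyadic IMF bound on 30 white-noise draws; test size on 200
null pairs and power on 100 shifted pairs at `B = 199`; K-selection on 20
seeded two-band signals; and a 3 × 20-recording synthetic corpus (240
cycles) for end-to-end separability. The bootstrap size for production
K-selection defaults to `B = 1000`; the scan cost is dominated by it, which
is why the pipeline exposes a fixed `k` once a corpus-level `K` has been
established.

## Known limitations

* The sifting envelope scheme (natural splines, mirrored end extrema) is
  one of several reasonable conventions; IMFs near the signal ends remain
  the least trustworthy part of any EMD.
* The wild-bootstrap calibration guarantee degrades with correlated
  surface cells (overlapping or tapered frames); see above.
* The adjusted-SDC edge frames reuse replicated boundary cepstra and are
  biased toward zero slope; pooled statistics dilute but do not remove
  this.
* `load_diagnoses()` filters *patients* by class size; recording-level
  bookkeeping (how many recordings each retained patient contributes) is
  the caller's concern.
* The synthetic classes are acoustic caricatures; see the synthetic-data
  section for what conclusions they do and do not support.
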