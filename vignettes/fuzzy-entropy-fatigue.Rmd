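---
title: "Fuzzy-entropy features for EEG driver-fatigue detection: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy-entropy features for EEG driver-fatigue detection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuzzyeeg)
```

## The problem

Fatigue degrades a driver's vigilance, and frontal-channel EEG carries a
measurable signature of that state change. `fuzzyeeg` implements a complete,
reproducible desk-scale version of a fatigue-detection pipeline built on a
single nonlinear feature — fuzzy entropy — computed per short epoch on two
frontal-pole electrodes (FP1, FP2), followed by an RBF-kernel SVM evaluated
by stratified 10-fold cross-validation with per-subject accuracy reporting.

Because no public recordings accompany this problem setting, the package
ships a first-class synthetic cohort generator whose statistical structure
matches what the analysis assumes: two sessions (normal, fatigue) per
subject, with fatigue epochs exhibiting *higher* fuzzy entropy than normal
epochs. Every stage is testable end to end with no external data.

## Fuzzy entropy

For a series $\{x_i\}_{i=1}^N$, sliding windows of length $m$ are formed and
each is centered by its own mean:

$$Y_i^m = (x_i, \ldots, x_{i+m-1}) - \overline{(x_i, \ldots, x_{i+m-1})}.$$

Local (per-window) mean removal makes the measure insensitive to slow
baseline shifts — and exactly invariant under a constant offset of the whole
series. Windows are compared by the Chebyshev distance
$d_{ij} = \max_k |Y_{i,k} - Y_{j,k}|$, and distance is mapped to a
similarity degree by a decaying exponential with gradient $n$ and tolerance
$r$. The per-dimension average similarity is

$$\varphi^m(n, r) = \frac{1}{N-m} \sum_{i=1}^{N-m}
  \Big[ \frac{1}{N-m-1} \sum_{j \ne i} D_{ij}^m \Big],$$

and the entropy is the log-ratio across dimensions:

$$\mathrm{FuzzyEn}(m, n, r, N) =
  \ln \varphi^m(n, r) - \ln \varphi^{m+1}(n, r).$$

A regular signal keeps its similarity when the embedding dimension grows
($\varphi^{m+1} \approx \varphi^m$, entropy near 0); noise loses similarity
and scores high.

### Window count

Definitions of the embedding stage in the literature differ on whether
$N-m+1$ or $N-m$ windows enter the sums. We use exactly $N-m$ windows at
*both* dimension $m$ and dimension $m+1$, the convention that makes the two
$\varphi$ averages directly comparable (each is an average over the same
index range). This is the dominant convention in fuzzy-entropy
implementations.

### Similarity form

Two exponential similarity forms are implemented:

* `as_printed` (default): $D_{ij} = \exp(-d_{ij}^n / r)$;
* `normalized`: $D_{ij} = \exp(-(d_{ij}/r)^n)$, the form most common in the
  wider fuzzy-entropy literature.

They coincide at $n = 1$ and differ otherwise. The practical consequence is
scale behavior: with $r \propto \mathrm{SD}(x)$, the normalized form is
exactly invariant under rescaling $x \mapsto a x$, while the as-printed
form's exponent scales as $a^{\,n-1}$ and its value genuinely depends on the
measurement units. The test suite demonstrates both behaviors. No published
numeric entropy value disambiguates which form the original analysis used,
so both are available behind one switch and the default follows the printed
definition. For classification this matters little: features are computed
on a per-epoch basis at a fixed unit (microvolts) and standardized per
training fold before the SVM.

### Parameters

| Parameter | Default | Meaning |
|---|---|---|
| `m` | 2 | embedding (window) length, samples |
| `n` | 4 | similarity gradient; larger = sharper membership boundary |
| `r_factor` | 0.2 | tolerance as a fraction of the series SD |
| `form` | `as_printed` | exponential similarity variant |

The tolerance $r = 0.2 \times \mathrm{SD}$ is recomputed per epoch per
channel using the population SD (divide by $N$), because the entropy is
computed independently per electrode per trial. Too large a tolerance blurs
distinctions (information loss); too small a tolerance amplifies noise
sensitivity.

Degenerate inputs are defined, not exceptional: a constant series has
SD $= 0$ and returns entropy 0 with a warning (a flat signal carries no
complexity); an affine ramp has all centered windows identical at both
dimensions and returns exactly 0. A series must satisfy $N \ge m + 3$ so
that at least two windows exist at dimension $m + 1$.

### Fast path and reference path

The $O((N-m)^2)$ pairwise kernel is implemented in C++ (`Rcpp`), visiting
each unordered pair once and skipping `exp()` calls whose argument is below
the double underflow threshold. An intentionally naive, loop-by-loop R
transcription (`fuzzy_entropy_oracle()`) is part of the public API; the test
suite holds the two routes together to $10^{-10}$ over random series of
lengths 20–200. The fast path at $N = 1000$ costs ~15 ms per epoch on one
core.

## Preprocessing chain

The acquisition band is 0.05–200 Hz with a 50 Hz mains notch, matched in
software so the package can be applied to arbitrary input:

* **Band-pass**: 4th-order Butterworth high-pass (0.05 Hz) and low-pass
  (200 Hz) in cascade. A 0.05 Hz cutoff at 1000 Hz sampling puts the
  normalized cutoff at $10^{-4}$, where the polynomial transfer-function
  form is numerically ill-conditioned; the filters are therefore designed
  analytically as second-order sections (bilinear transform per biquad).
* **Zero phase**: every filter runs forward and backward, so features never
  inherit a group delay; the test suite verifies a 0-sample cross-correlation
  lag on an in-band tone.
* **Edge handling**: odd-reflection padding plus step-matched initial
  state (filtering $x - x_1$ and restoring the DC gain response), which
  removes the startup transient a zero initial state would inject — without
  it, a 0.05 Hz high-pass needs tens of seconds to settle.
* **Notch**: order-2 Butterworth band-stop, bandwidth
  $f_0/Q = 50/30$ Hz. Measured: ≥ 40 dB attenuation at 50 Hz, < 0.01 dB
  loss at 10 Hz.
* **Epoching**: fixed windows, default 1.0 s (1000 samples at 1000 Hz),
  non-overlapping, trailing remainder dropped. One second keeps the
  quadratic entropy kernel cheap while giving stable estimates; both length
  and overlap are configurable.
* **Artifact rejection**: an epoch is dropped iff any sample exceeds
  ±100 µV (configurable). Peak-amplitude rejection is deterministic,
  standard for frontal channels dominated by blink artifacts, and easy to
  audit; no samples are ever modified. Methods that estimate and subtract
  ocular components (ICA, regression) are deliberately out of scope.

No resampling is performed; data stays at its native rate.

## Features and classifier

One fuzzy-entropy value per channel per epoch, joined side by side
(`fuzzyen_FP1`, `fuzzyen_FP2`), labelled 0 = normal, 1 = fatigue. An epoch
time missing on any channel after artifact rejection is dropped entirely —
rows stay complete without imputation. Both channels are fed jointly to one
classifier.

The classifier is an RBF-kernel SVM (`e1071`, libsvm). Hyperparameters are
deliberately parameter-free and fixed: $C = 1$; kernel width
$\gamma = 1/(p \cdot \overline{\mathrm{Var}})$ with $p$ the feature count
and $\overline{\mathrm{Var}}$ the mean training-fold feature variance
(≈ $1/p$ after standardization). Both are overridable; there is no grid
search by default, so a run is exactly reproducible from its seed.

Evaluation is stratified 10-fold cross-validation. Features are
standardized with the mean and SD of each training fold only — the test
fold never influences the scaler, and a test asserts this. By default folds
are built *within each subject* (accuracy tables are conventionally
per-subject); a pooled, subject-blind mode is available. The cohort summary
is the mean of per-subject means, with dispersion across subjects reported
and labelled explicitly as an SD.

The continuous "fatigue level" in $[0, 1]$ is the Platt-scaled probability
of the fatigue class from the fitted SVM: a monotone transform of the
margin, 0.5 at the decision boundary.

## Synthetic cohort generator

Each session is an alpha-band sinusoid plus white Gaussian noise,
optionally plus a 50 Hz mains component:

$$x(t) = A \sin(2\pi f_\alpha t + \phi) + \sigma \varepsilon(t)
       + A_{50} \sin(2\pi \cdot 50 t),$$

with $f_\alpha = 10$ Hz and the pair $(A, \sigma)$ set per state from an
oscillation-to-noise amplitude ratio (SNR $= A/\sigma$), scaled so each
session has 15 µV RMS (peaks comfortably inside ±50 µV, so the ±100 µV
artifact threshold behaves sensibly). Fuzzy entropy of such a mixture is
monotone in the noise fraction — verified empirically as a strict
monotonicity test across $\sigma \in \{0, 0.5, 1, 2\}$ — which makes the
SNR an analytically motivated control knob for state separation.

The fatigue state uses the *lower* SNR, so fatigue epochs are noisier and
carry higher entropy: the direction the downstream analysis assumes (some
EEG-complexity literature reports the opposite direction; the generator
follows the convention of this pipeline's setting, and swapping the two
SNRs swaps the direction, which a test asserts).

Defaults, fixed once by pilot calibration with `calibrate_separation()`
and not revisited:

* 12 subjects × 2 sessions × 2 channels at 1000 Hz, 60 s per session
  (60 one-second epochs per state per channel);
* `snr_normal = 4`, `snr_fatigue = 1`: standardized entropy separation
  $d \gg 1.5$, giving the clearly separable benchmark on which the full
  pipeline reaches a cohort mean accuracy ≥ 0.95;
* `subject_jitter = 0.1`: one log-normal multiplier per subject on both
  SNRs, so subjects differ realistically while within-subject separation is
  preserved;
* `mains_amp = 0` by default; setting it nonzero plants a 50 Hz line that
  the notch must remove (a test checks ≥ 30 dB suppression end to end).

Every (subject, state, channel) stream derives its own sub-seed from the
cohort seed, so cohorts are byte-identical under a fixed seed and
individual streams are reproducible in isolation.

**What the generator does not emulate.** Real EEG has 1/f broadband
structure, nonstationary rhythms, eye-blink and EMG artifacts with
characteristic shapes, electrode drift and inter-channel correlation. The
generator's sinusoid-plus-white-noise model captures none of these beyond
amplitude scale; it is a *statistical* stand-in that realizes exactly the
property the method relies on (a state-dependent complexity difference) and
exercises every pipeline stage (band energy at 10 Hz, optional mains for
the notch, µV amplitudes for the artifact rule). Passing the benchmark
therefore shows the pipeline is correct and well calibrated — it does not
show that real driving EEG is this separable, and accuracy figures on
synthetic cohorts should be read as a ceiling, not a field estimate.

## Test and benchmark problem sizes

The packaged checks run at sizes chosen to give stable statistics on a
single core: the separable benchmark uses the full default cohort (12
subjects × 60 s sessions); the chance-level null calibration uses 30
independent equal-SNR cohorts of 12 subjects × 20 s sessions (480
classified epochs each), with the acceptance band set at three single-run
binomial SDs around 0.5 — conservative, since the 30-run mean is much
tighter; oracle-equivalence checks use 102 random series of length 20–200;
monotonicity checks use medians over 30 seeds.

## Numerical choices

* Population SD (divide by $N$) for the tolerance, matching per-epoch
  feature extraction; sample-vs-population choice shifts $r$ by
  $\sqrt{(N-1)/N}$, negligible at $N = 1000$ but pinned down for exact
  reproducibility.
* `exp()` is skipped when its argument exceeds 745 (result below double
  underflow); this is exact at double precision.
* Similarity ties in the Chebyshev max need no tie-break — only the max
  value enters.
* Filters validate cutoffs against Nyquist per recording; a violating spec
  is a configuration error, not a silent clip.
* The SD = 0 (constant epoch) case returns entropy 0 with a warning rather
  than erroring, so one flat epoch cannot abort a batch run.

## Limitations

* The as-printed similarity form ties entropy values to the measurement
  unit; compare entropy magnitudes across datasets only with the
  normalized form or a fixed unit convention.
* Per-subject 10-fold CV requires ≥ 10 epochs per class per subject;
  subjects missing a class are skipped (and reported), not imputed.
* The EDF writer/reader supports the classic 16-bit format with one-second
  records — sufficient for round-tripping this package's recordings, not a
  general EDF+ implementation.
* Hyperparameters are fixed, not tuned; on real data a nested
  cross-validated search over $(C, \gamma)$ would be the natural extension.
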