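---
title: "Decoding compound hand motions from surface EMG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding compound hand motions from surface EMG: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semgdecode)
```

## The problem

Myoelectric prosthesis control wants more than isolated gestures: a useful
hand must distinguish *compound* motions — which grasp is being made, at what
wrist angle, and with how much force — because the same gesture produces
different muscle activity in different postures and at different loads.
`semgdecode` implements a window-based pattern-recognition pipeline for a
60-class compound-motion problem: 4 grasping gestures (fist, pinch, poke,
palm) x 5 wrist angles (flexion, extension, ulnar, radial, neutrality) x 3
strength levels (holding 0 g, 480 g or 960 g), recorded as eight channels of
surface EMG at 1000 Hz, one 60 s sustained hold per motion.

Each compound motion has an integer ID in 1..60. With 1-based factor indices
$(g, w, s)$ the mapping is $\mathrm{id} = 20(s-1) + 5(g-1) + w$: IDs 1-20
are the unloaded block, 21-40 the 480 g block, 41-60 the 960 g block, and
each gesture owns a run of five consecutive wrist angles. The package keeps
this algebra in `compound_id()` / `decompose_id()` and its two label
encodings (`encode_onehot()`, 60-dim; `encode_multilabel()`, 4+5+3 = 12-dim)
as first-class, exhaustively tested operations, because every later stage —
the classifier chain in particular — leans on it.

## Pipeline

1. **Conditioning** (`preprocess_trial()`): per channel over the whole
   trial, least-squares linear detrend, then a 2nd-order IIR notch at 50 Hz,
   then a 20-250 Hz Butterworth bandpass, in that order, before any
   windowing.
2. **Windowing** (`slice_windows()`): disjoint 150 ms windows (150 samples
   x 8 channels) in trial order; a 60 s trial yields exactly 400 windows.
3. **Features** (`extract_windows()`): per channel, seven time-domain
   features — MAV, RMS, sample variance, the 4th coefficient of an AR(4)
   fit, waveform length, zero crossings, slope sign changes — concatenated
   channel-major into at most $8 \times 7 = 56$ dimensions.
4. **Split** (`chronological_split()`): per motion mode, the first 90% of
   windows in trial time train, the rest test, so test windows always come
   from later in the hold than every training window; each side is then
   shuffled with a fixed seed.
5. **Decoding** (`train_integrated()`, `train_chain()`): either one
   classifier over all 60 classes, or a triple-parallel chain of three
   classifiers (strength 3-class, gesture 4-class, wrist 5-class) whose
   argmax decisions are composed back into a compound ID.
6. **Evaluation** (`evaluate_decoder()` and the sweeps): overall and
   per-mode accuracy, 60x60 confusion matrix, factor and strength+gesture
   accuracies, and mean +/- *population* standard deviation across
   subjects.

## Numerical and design choices

**Notch design.** The notch is a constrained biquad: zeros exactly on the
unit circle at 50 Hz, poles pulled inside to set the width. The -3 dB
bandwidth defaults to 2 Hz (Q = 25) — narrow enough that the 100 Hz gain
stays within 0.003 dB while 50 Hz is nulled. The width is a `filter_spec()`
field because no single value is canonical in the EMG literature.

**Bandpass order.** "4th-order Butterworth bandpass" is read in the
`butter(4, c(20, 250)/(fs/2))` convention: a degree-8 transfer function
with four poles per skirt. That design attenuates 5 Hz by ~50 dB and 400 Hz
by ~41 dB; a degree-4 bandpass (two poles per skirt) would only manage ~24
and ~9 dB, too little to suppress drift remnants and out-of-band carrier.

**Causal by default.** The filters run as single forward passes because the
decoding scenario is real-time (window plus processing must fit a sub-200 ms
budget); `phase_mode = "zero-phase"` (forward-backward) exists for offline
parity checks. Linearity of the whole chain, stability of every design
(poles strictly inside the unit circle), and the attenuation contracts are
asserted in the test suite.

**Detrending.** "Detrend" is implemented as least-squares linear detrend per
channel over the full trial, with mean-removal available via
`filter_spec(detrend = "constant")`. Preprocessing happens trial-level,
before windowing, and a recording refuses a second pass.

**AR coefficient.** The ARC feature is the *last* coefficient of an order-4
Yule-Walker fit (Levinson-Durbin on biased autocovariances of the
mean-removed window), under the sign convention
$x_i = -\sum_k a_k x_{i-k} + e_i$. One coefficient per channel is what makes
the full vector 56-dimensional. The in-package recursion is vectorised
across all windows for throughput and is cross-checked in tests against
`stats::ar(method = "yule-walker")` and against Levinson-Durbin on
theoretical autocovariances of known processes.

**Slope sign changes.** The threshold is $\omega = 0.05\,\mathrm{sd}(x)$ of
the *current window* (per-window is the only std unambiguously in scope; the
choice is recorded here because trial-level or global alternatives exist).
The rule counts interior products $(x_i - x_{i-1})(x_i - x_{i+1}) \ge
\omega$, with the extra convention that zero products never count: a
constant window has $\omega = 0$ and all-zero products, and counting those
would call every sample of a flat line a slope change. For any non-constant
window the convention coincides with the thresholded product exactly. Note
that SSC is not scale-invariant: the product scales quadratically with
amplitude but the threshold linearly; the package implements the formula as
stated rather than a normalised variant.

**Standardization.** Features are z-scored with training-set statistics
before SVM/KNN fitting (the Gaussian-kernel widths 0.56 / 2.2 / 8.9 are
preset scales defined on standardized inputs); zero-variance dimensions pass
through unscaled with a warning, and applying training statistics to test
data is the only supported direction.

**Classifier families.** SVMs (libsvm via `e1071`) use one-vs-one multiclass
decomposition, box constraint 1, and the kernels
$(1 + x'y)^2$, $(1 + x'y)^3$, and $\exp(-\lVert x-y\rVert^2/\gamma)$ with
$\gamma \in \{0.56, 2.2, 8.9\}$. Trees are Gini-split `rpart` fits grown
fully and pruned back to at most 100/20/4 leaves via the complexity table.
Bagged trees are 30 bootstrap trees with all features available at every
split (`randomForest` with `mtry = p`), seeded explicitly. KNN prediction is
computed in-package so that cosine, Minkowski-3 and inverse-squared-distance
weighted variants share one implementation with deterministic tie-breaking
(distance ties by training-row order, vote ties by class index). "Weighted
KNN" is interpreted as Euclidean distance with inverse-squared-distance
voting weights — the preset the name denotes — since the published distance
formula contains an unexplained matrix. Kernel naive Bayes and the
boosted/subspace/RUSBoosted ensembles have no installed backend and are
rejected by `model_spec()` with an explicit message rather than silently
approximated.

**Chain composition.** The chain's compound decision is
`compound_id(gesture, wrist, strength)` of the three factor argmaxes, so its
compound accuracy can never exceed any single factor accuracy, and under
independence its expectation is the product of the three factor accuracies
(`chain_theoretical_accuracy()`). Whether all three factor classifiers share
one family or use the best family per factor is a configuration choice; both
are supported.

**Aggregation convention.** Per-subject accuracies are summarised as mean
+/- population standard deviation (denominator $N$). The convention is
pinned by the published reference tables shipped with the package
(`ref_factor_accuracy()`, `ref_chain_accuracy()`): aggregating the printed
per-subject values with `aggregate_mean_popstd()` reproduces the printed
summary rows to their printed precision (within one unit in the last digit,
the residue of aggregating already-rounded inputs), whereas the sample-std
convention does not (e.g. 0.705 instead of 0.674 for the strength column).
Per-mode accuracy for a mode with no test windows is reported as missing,
never as zero. Display rounding is left to the caller; stored values are
unrounded.

**Split boundary.** The train side takes `floor(f * n + 0.5)` windows (round
half toward train). At the protocol's values (400 windows, f = 0.9) this is
exactly 360 + 40 and no ambiguity arises; the rule matters only for unusual
fractions.

## The synthetic generator

No public recordings exist for this protocol, so the package ships a
class-conditional generator (`simulate_trial()`,
`simulate_subject_dataset()`) that emulates the acquisition setup well
enough to exercise every pipeline stage:

- **Amplitude structure.** Channel $c$ of motion $(g, w, s)$ has expected
  amplitude $\text{gain}_c \cdot \text{strength}_s \cdot (\text{base}_c +
  G_{g,c} + W_{w,c})$. The default gesture and wrist matrices give each
  factor level a dominant channel subset (mimicking electrodes targeted at
  distinct forearm muscles); construction verifies all 60 expected profiles
  are pairwise distinct. Strength gains default to (1.0, 1.4, 1.8) for the
  0/480/960 g loads — a plausible, clearly separable amplitude growth.
- **Carrier.** Per channel, unit-variance white noise band-limited to
  20-450 Hz, the EMG-like stochastic interference pattern.
- **Nuisances.** A 50 Hz sinusoid (amplitude 0.5, random phase per channel
  per trial) keeps the mains line visible above the carrier spectrum so the
  notch has work to do; a sub-hertz sinusoid (amplitude 0.5, random
  frequency 0.05-0.8 Hz) exercises detrending and the bandpass low edge; a
  white noise floor (sd 0.05) sits under everything.
- **Subjects.** Per-subject, per-channel log-normal gains (log-sd 0.15)
  emulate electrode placement and physiology differences.
- **Determinism.** All randomness flows from one master seed through a
  documented stream-split by (subject, compound ID), so a dataset is a pure
  function of (config, model, subject, seed), trials of one subject share
  their gains, and regeneration is bitwise identical.

**What it does not emulate** — and hence what passing tests do and do not
show. There is no motor-unit physiology, no fatigue, no electrode shift, no
within-trial nonstationarity, and, importantly, *no class-dependent spectral
structure*: every class rides the same 20-450 Hz carrier, so all
discriminative information lives in the eight amplitudes. Consequences worth
knowing:

- The 60 classes are cleanly separable by design, and a quadratic SVM on the
  default configuration reaches >99% compound test accuracy at desk scale
  (2 subjects, 30 s trials, i.e. 200 windows per mode — the problem size
  used by the shipped end-to-end checks; accuracies at that scale are what
  the acceptance script reports). Passing this says the pipeline is wired
  correctly, not that real sEMG would decode this well.
- Amplitude-proportional features (MAV, RMS, VAR, WL) carry essentially all
  the class signal, so MAV alone already saturates the decoder and
  feature-count sweeps on synthetic data plateau at one feature — on real
  recordings the spectral/temporal features earn their keep, here they
  cannot. Feature-set conclusions must not be read off this generator.
- No per-class amplitude statistics were published for the real protocol, so
  none of the generator constants is calibrated to real data; they were
  fixed once for separability and are configurable, not fitted.

## Problem sizes and determinism of the shipped checks

The unit and property tests run on seconds-long trials; the end-to-end
checks use 2 synthetic subjects with 30 s trials (200 windows per mode,
10 800 training windows per subject), chosen as the smallest scale at which
all 60 classes have a meaningful chronological test tail. Deterministic
families (SVM, discriminants, KNN, pruned trees) are refit-reproducible and
row-order invariant; bagged trees take an explicit seed. The full pipeline
rerun under a fixed seed reproduces feature tables byte-identically.

## Known limitations

- The generator's amplitude-only class structure (above) is the main gap
  between synthetic and real difficulty.
- Kernel naive Bayes and the boosted/subspace ensemble rows of the
  classifier catalogue are rejected rather than implemented.
- QDA can fail on degenerate training covariances; the package propagates
  the failure instead of silently regularising.
- No majority-vote smoothing across consecutive windows, overlapping
  windows, or online/streaming segmentation; trials are offline 60 s holds.
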