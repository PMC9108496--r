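---
title: "Methods: region-specific EEG emotion recognition and dynamic functional connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: region-specific EEG emotion recognition and dynamic functional connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(emofc)
```

# The problem

`emofc` implements a complete analysis chain for classifying two
music-evoked emotional states — high valence-arousal (HVA) and low
valence-arousal (LVA) — from 32-channel scalp EEG recorded under a
block paradigm: each subject hears 12 music clips (6 per state), every
trial being 5 s rest, 20 s stimulation, 5 s rest, sampled at 500 Hz on
a 10-20 montage whose mastoid electrodes (M1, M2) serve as references,
leaving 30 analysis channels.

Because no public recording of this exact paradigm is available, the
package ships a synthetic-data generator as a first-class, tested
module. Every downstream stage — preprocessing, image encoding, the
convolutional classifier, channel selection, and functional
connectivity — is exercised end-to-end on simulated cohorts whose
ground truth is known analytically.

# The synthetic generator

Each channel is a zero-mean Gaussian process synthesized in the
frequency domain with a one-sided power spectral density

$$S(f) = \max(f, 1)^{-\alpha} + \sum_b r_b\,\max(f_b, 1)^{-\alpha}\,w_b(f),$$

a $1/f^{\alpha}$ background (default $\alpha = 1$) plus band-limited
oscillatory bumps $w_b$ with raised-cosine edges — by default an alpha
band (8–12 Hz, relative density 1) and a beta band (13–30 Hz, relative
density 0.5) — softly rolled off above 45 Hz. Channels are scaled to
10 µV standard deviation, a realistic resting scalp amplitude.
Frequency-domain synthesis gives exact control of the population
spectrum at any record length.

Two kinds of class structure are planted in the stimulation windows:

* **Coherence.** Channels named in `coherent_pairs` share a common
  band-shaped source: $x_c = w_c s + \sqrt{1 - w_c^2}\, n_c$ with $s$
  and $n_c$ independent draws of the *same* spectrum. The population
  magnitude coherence of two such channels is $w_a w_b$ at every
  frequency, so a per-class target $t$ is planted exactly by solving
  $w_a w_b = t$ (least squares in log-weights for general pair graphs).
  The defaults plant the three prefrontal pairs (Fp1–Fpz, Fp1–Fp2,
  Fpz–Fp2) at 0.25 under HVA and 0.30 under LVA — the direction and
  order of magnitude of the reported finding that low valence-arousal
  states show stronger prefrontal coupling.
* **Oscillatory power.** HVA trials multiply the oscillatory bump
  density on `discriminative_channels` (default: the 8 frontal
  channels) by `amplitude_effect` (default 1.5). This leaves the
  $1/f$ background untouched, so the contrast is a change of spectral
  *shape* as well as power.

What the generator does **not** model: volume conduction and spatially
correlated background (non-planted channel pairs are exactly
independent, which real EEG never is), inter-subject variability beyond
independent noise realizations, non-stationarity within a trial, and —
unless the optional ocular artifact is enabled — any artifact at all.
Passing tests therefore demonstrate that the algorithms recover known
structure under clean conditions; they say nothing about robustness to
real-world confounds.

# Preprocessing

The chain is notch → bandpass → common average reference → optional
artifact regression → segmentation with baseline correction.

* **Notch (49–51 Hz).** Zero-phase Butterworth band-stop (order 2 per
  edge, applied forward–backward). Measured response: −165 dB at
  50 Hz, −0.01 dB at 45 Hz.
* **Bandpass (1–40 Hz).** Zero-phase Hamming windowed-sinc FIR with a
  1.8 Hz transition, the filter family EEGLAB-style pipelines use. A
  recursive design was rejected because no reasonable Butterworth order
  at these cutoffs can keep the 2–38 Hz ripple under 1 dB while
  attenuating 0.1 Hz and 60 Hz by 30 dB; the FIR meets all four
  constraints with a large margin (−64 dB at 0.1 Hz, −80 dB at 60 Hz).
  Both filters carry an edge transient of roughly the filter memory
  (~1 s); recordings are filtered continuously before segmentation, so
  trial windows never touch the edges.
* **CAR.** The instantaneous mean of the 30 analysis channels is
  subtracted from each of them; M1/M2 are excluded and left untouched.
  Note that CAR mixes a small fraction (1/30) of every channel into
  every other — on synthetic data with strong planted channels this
  measurably leaks class signal into "clean" channels, which is one
  reason the channel-search studies below segment raw simulated data.
* **Artifact removal (optional).** The ICA-based ocular cleaning of the
  original pipeline is out of scope; a regression stage is provided
  instead: each channel's least-squares projection onto a recorded
  artifact reference is removed. It is exact for the additive artifact
  the generator can plant.
* **Segmentation.** One 20-s stimulation epoch per event; each
  channel's mean over the 5-s pre-stimulus rest is subtracted (the only
  pre-stimulus interval the protocol offers). Events without a complete
  baseline or stimulation window are skipped with a warning, never
  zero-padded.

# Image encoding

The preprocessed signal is sampled per second: each second of a trial
contributes one channels × 20 matrix holding 20 uniformly spaced
samples per channel (plain stride decimation, stride $f_s/20$; the
1–40 Hz bandpass limits content beforehand, and residual aliasing of
the 10–40 Hz range is accepted as part of the representation). Under
the default protocol this yields exactly
$15 \times 6 \times 20 = 1800$ samples per class.

Each matrix is min–max scaled to 8-bit pixels,

$$Y_{ij} = \operatorname{round}\!\left(\frac{(X_{ij} - \min X)\,255}{\max X - \min X}\right),$$

with rounding half away from zero, the global minimum mapping to 0 and
the maximum to 255, replicated to three identical planes for the
RGB-shaped classifier input. The scaling is applied element-wise over
the whole matrix (a per-image global normalization, not per-channel):
summation signs sometimes attached to this formula would collapse the
image to a single number and contradict its use as a pixel array, so
they are read as typographical. One practical consequence, found the
hard way and now tested: when classifying a channel *subset*, the
subset must be cut **before** encoding — slicing rows of an encoded
image lets out-of-subset channels leak class information through the
shared normalization constant.

# The classifier

The image classifier is a depthwise-separable CNN in the Xception
style, implemented in the package itself (C++ convolution kernels, an
Adam + softmax cross-entropy trainer in R) — deliberately compact, with
exact unit-tested gradients and fully deterministic single-threaded
training under a seed. Two scales are built by one architecture
engine:

* `mini` (default): a 3×3 stem convolution and two separable residual
  blocks (16 and 32 filters), global average pooling and a 2-way
  softmax. It accepts native image sizes (e.g. 8 × 20) and is the
  model used by every test.
* `full`: the 14-module architecture — a preprocessing module of 3
  standard convolutions plus 13 residual modules containing 33
  depthwise-separable convolutions (3 entry blocks × 2, 8 middle
  blocks × 3, an exit block × 2 and a tail block × 1), minimum input
  71 × 71 reached by nearest-neighbour upscaling (which invents no
  intensity values). It is constructible and trainable through the
  same code path but is not exercised by the default tests: at desk
  scale its cost buys nothing the mini scale does not already test.

Training defaults (Adam, learning rate 1e-3, 30 epochs, batch 32) are
configuration, not dogma; the Monte-Carlo studies below use fewer
epochs and a higher rate, chosen once for those study sizes.

Evaluation follows a fivefold rotation: per class, samples are split
into 5 near-equal parts; fold $f$ tests on part $f$, validates on the
next part and trains on the remaining three — 1080/360/360 per class at
the full budget. Every sample is tested exactly once. Metrics
(accuracy, sensitivity, specificity, precision, F1, with HVA as the
positive class) are reported per fold and summarized as mean ± SD.
Undefined metrics (zero denominators) are reported as `NA`, never 0.
Sample-level fold assignment reproduces the original procedure and its
known subject leakage; `split_by = "subject"` or `"trial"` provide the
rigorous alternatives, and the trial-level split is what the
channel-search studies use (with 2 synthetic subjects, sample-level
splits let the CNN recognize *trials* by their background noise, which
a pilot showed inflates signal-free subsets to ~0.7 accuracy).

Support-vector and random-forest baselines (radial-kernel `e1071::svm`,
`randomForest` with 200 trees) operate on flattened pixel vectors under
the same fold and metric contracts.

# Sequential backward channel selection

Starting from the 8 frontal channels (Fp1, Fpz, Fp2, F7, F3, Fz, F4,
F8), every leave-one-out subset of the current set is scored by a
pluggable evaluator (by default mean fivefold CV accuracy with a fixed
fold seed, so all subsets are compared on identical folds); the best
becomes current, down to 2 channels — exactly
$8+7+6+5+4+3 = 33$ evaluations, each recorded in a grid of current
subset × removed channel. "Randomly selected seven channels" in the
source procedure is read as exhaustive leave-one-out, which is the only
reading consistent with a complete removal-accuracy grid. The best
subset is the argmax over *all* evaluated subsets, which may occur at
any level. Ties are broken by removing the channel with the larger
montage index.

The correctness of the search is established at three levels:

1. the evaluation count and grid shape are asserted exactly;
2. under a noiseless containment oracle (accuracy = 1 iff the subset
   contains the planted channels) the search provably retains a planted
   3-channel set, and the test asserts it;
3. a stochastic study runs the real mini-CNN evaluator on simulated
   cohorts with one planted discriminative channel (F7, alpha-band
   contrast, effect 12) from a 5-channel start, comparing the greedy
   result against exhaustive search over all 26 subsets of size ≥ 2.

The third study is deliberately reduced from the full 8-channel grid,
for two reasons found empirically. First, classifier evidence
saturates: one strongly informative channel already reaches the
accuracy ceiling, and extra informative channels add $\sqrt{m}$-style
diminishing returns smaller than evaluator noise, so nothing forces a
noisy argmax to retain *all* of a multi-channel planted set — that
containment property is exactly what the noiseless-oracle test (2)
checks without noise. Second, exhaustive search over the 8-channel
lattice costs 247 CV evaluations per seed, far beyond a sensible test
budget. With one planted channel the optimality structure is
unambiguous (subsets containing F7 dominate), and both greedy and
exhaustive searches retained it in 5/5 piloted seeds.

# Coherence functional connectivity

For two channels of one trial, the signal is cut into Hann-tapered
segments (1 s, 50% overlap; 39 segments of a 20-s trial), and with
segment spectra $A(f,k)e^{i\varphi(f,k)}$ the magnitude coherence is

$$\mathrm{Coh}_{xy}(f) =
\frac{\left|\frac1n\sum_k A_x A_y e^{i(\varphi_x - \varphi_y)}\right|}
{\sqrt{\left(\frac1n\sum_k A_x^2\right)\left(\frac1n\sum_k A_y^2\right)}},$$

the magnitude (not squared) of the averaged cross-spectrum normalized
by averaged auto-spectra, then averaged over 1–40 Hz (the full filtered
band; no narrower band is singled out) to one scalar per pair. The
estimator is bounded in [0, 1] (Cauchy–Schwarz), equals 1 for
amplitude-scaled copies, is invariant to per-channel rescaling, and
for independent signals sits at a positive bias floor of about
$\sqrt{\pi/(4K)}$ for $K$ segments — which is why single-segment
coherence (identically 1) is refused. A brute-force DFT implementation
with explicit complex arithmetic serves as the independent oracle in
tests, agreeing to 1e-10.

Per-trial 8 × 8 frontal matrices (unit diagonal, symmetric by
construction) feed two analyses:

* **State comparison.** Per subject and state, upper-triangle
  coherences are Fisher-transformed ($z = \mathrm{atanh}\,r$ — applied
  to coherence in keeping with the source analysis, although coherence
  is not a correlation), averaged over pairs and trials, and compared
  across subjects by a paired t-test. Coherence at 1 is clipped to
  $1 - 10^{-12}$; identical states return $t = 0$, $p = 1$ rather than
  0/0. Under the default plant (Δ = 0.05 on three prefrontal pairs,
  15 subjects), the LVA > HVA contrast was detected at $p < 0.05$ in
  100% of 100 piloted replicates.
* **Dynamic features.** For each subject and state, the first $k$
  per-trial matrices (chronological within class) are concatenated
  column-wise — an $8 \times 8k$ matrix for $k \le 6$ — and pixel
  encoded like any other image. Classification accuracy as a function
  of $k$ is the dynamic-connectivity curve; under a stable planted
  contrast, per-image signal grows roughly as $\sqrt{k}$, and the
  acceptance study (30 synthetic subjects, 10 seeds) requires $k = 6$
  to be at least as accurate as $k = 1$ in 8 of 10 seeds.

# Desk-scale study sizes

The Monte-Carlo studies in the test suite and acceptance script use
sizes chosen once for a single-CPU desk run: the data-budget check runs
the full 15-subject, 500 Hz protocol; the simulation-based coherence
studies use 128 Hz (coherence targets are rate-invariant, and 128 Hz
keeps the 1–40 Hz band comfortably below Nyquist) and a frontal-only
montage where only frontal channels are analysed; the channel-search
study uses 2 subjects × 12 trials with the first 6 s of each trial; the
dynamic-FC study uses 30 subjects. Each choice is a study condition,
not a tuning knob: thresholds and tolerances come from the contracts
stated above.

# Numerical choices and degenerate inputs

* Rounding to pixels is half-away-from-zero (base R's `round` is
  half-even).
* A constant sample matrix encodes to all zeros with a warning.
* Mixing weights are clamped below 1; coherence targets must lie in
  [0, 1).
* Seeds fan out from one base seed by a fixed integer derivation
  (`derive_seed`), so subjects, stages and folds are independently
  reproducible and any single piece can be re-run in isolation.
* The EDF writer quantizes to 16 bits over each channel's physical
  range; exact round-trips use the float64 array container with its
  JSON sidecar.

# Known limitations

The generator's independence between non-planted channels makes the
"no contrast on other channels" tests stricter than real EEG would
allow. The CNN is a faithful but compact reimplementation — no GPU, no
data augmentation, no pretrained weights — so its absolute accuracies
on the synthetic task are not comparable to published figures obtained
on real recordings with the full-size network; no claim about
real-data accuracy is made or tested anywhere in the package. The
mastoid-exclusion reading (30 analysis channels = 32 − {M1, M2}) is an
assumption the montage documentation records.
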