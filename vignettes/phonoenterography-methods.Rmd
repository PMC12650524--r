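---
title: "Methods: detection, phenotyping and temporal modeling of bowel sounds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detection, phenotyping and temporal modeling of bowel sounds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pegsound)
```

## The problem

A phonoenterogram (PEG) is an audio recording of abdominal sounds captured
by a surface microphone or digital stethoscope, typically at 44.1 kHz /
16-bit over a couple of minutes per session. Bowel sounds mark contractile
activity of the gastrointestinal tract, but auscultation is subjective and
hard to standardize. `pegsound` implements a fully unsupervised pipeline
that (i) detects prominent bowel-sound (PBS) events, (ii) encodes each
event acoustically, (iii) groups events into acoustic phenotypes, and (iv)
summarizes how phenotypes follow one another in time. No manual labels are
needed at any stage.

## Event detection

Detection operates on a short-time energy (STE) envelope: mean squared
amplitude over 25 ms frames advanced every 5 ms (both configurable; the
envelope granularity trades temporal precision against noise robustness).
A *dynamic threshold* of mean + 2 SD of the envelope, computed over the
whole recording, marks prominent activity; the SD uses the population
(denominator *N*) convention, switchable to sample SD. Local envelope
maxima above the threshold become candidate events, each carrying a fixed
200 ms feature window (100 ms either side of the peak). Candidates whose
peaks lie closer than 100 ms form conflict chains. Two resolutions are
implemented:

* `discard` — every member of a chain is removed (the strictest reading of
  "closely spaced events are discarded");
* `strongest` — the highest-energy member of the chain is kept.

The package default for the standalone `proximity_filter()` is `discard`;
the *pipeline* default is `strongest`. The reason is measurable: noise-like
short events produce more than one envelope maximum within 100 ms, so
chain-discard silently deletes a whole acoustic class and caps recall far
below the high-nineties regime this detector otherwise reaches. Keeping
one representative per chain preserves exactly one detection per
physical event.

Event *boundaries* (used for dwell times, not for features) come from a
hysteresis rule: from the peak, the onset is the last frame before it whose
energy falls below half the threshold, and the offset the first such frame
after it, floored at the 200 ms window. This reconciles the fixed feature
window with multi-second sustained sounds. The half-threshold fraction is
a tunable with no canonical value; 0.5 makes boundaries insensitive to
small envelope ripple near the threshold.

Detections are scored against reference onsets by greedy one-to-one
matching in order of increasing time difference with a ±100 ms tolerance;
precision = matched/detected, recall = matched/reference, F1 their
harmonic mean.

## Acoustic encoding (279 features per event)

Each 200 ms window is encoded as:

* **260 MFCCs** — the window is cut into exactly 13 frames of 25 ms; the
  hop is derived from the frame count, not vice versa, because the
  20 × 13 = 260 block size is load-bearing downstream. Per frame: Hann
  window, power spectrum, 26-filter mel bank spanning 0–Nyquist, log
  energies, orthonormal DCT-II, first 20 coefficients. No pre-emphasis or
  liftering.
* **13 Δ-MFCCs** — first-order regression deltas (half-window 2 frames) of
  coefficients 1–13, computed on interior frames only (no edge padding)
  and averaged over time. On a coefficient ramp of slope *s* per frame
  every delta equals *s* exactly, which fixes the convention unambiguously.
* **6 spectral descriptors** of the whole window: power-weighted centroid
  and bandwidth (Hz), spectral flatness (geometric/arithmetic mean of the
  power spectrum), 85th-percentile roll-off frequency, time-domain RMS,
  and Shannon entropy of the normalized power spectrum divided by
  log(#bins).

Features are pooled over all recordings and z-scored per column
(population SD; constant columns are zeroed and flagged). A second
centering pass is folded into the stored means so that standardized
columns have exactly zero mean even for near-constant columns, where naive
centering amplifies floating-point residue.

## Embedding and clustering

Standardized features are reduced to exactly 30 principal components
(deterministic sign convention: the largest-magnitude loading of each
component is positive). Thirty components are always retained; the
pipeline warns — but does not stop — if they explain less than 95% of the
variance. The scores are then embedded into a 10-dimensional manifold with
UMAP (cosine metric, 35 neighbors, minimum distance 0.01), run
single-threaded with a fixed seed so coordinates are reproducible
run-to-run on one platform.

Three clustering algorithms operate on the embedding:

* **k-means** (k = 5): own k-means++ seeding, Lloyd iterations, 20
  restarts, best inertia kept. Labels are canonicalized (descending
  cluster size, centroid order on ties) so output is a pure function of
  (input, seed).
* **Ward agglomerative**: Euclidean `ward.D2` linkage, deterministic.
* **Spectral**: symmetric kNN graph with self-tuning Gaussian weights
  (local scale = distance to the n-th neighbor), symmetric-normalized
  Laplacian, bottom-k eigenvectors, row normalization, then the k-means
  above. Binary 0/1 weights were rejected because any bridge edge forced
  by graph-connectivity requirements then weighs as much as a structural
  edge, which breaks textbook cases such as concentric rings.

Cluster quality uses three internal indices implemented from their
defining formulas and cross-checked in the test suite against brute-force
implementations and third-party packages: silhouette
(*s* = (b−a)/max(a,b) per sample, singletons scoring 0),
Calinski–Harabasz (tr(B)/tr(W) × (N−k)/(k−1), +∞ flagged when tr(W)=0)
and Davies–Bouldin (mean over clusters of the worst
(s_i+s_j)/d(c_i,c_j) ratio, +∞ flagged for coincident centroids).
Indices are computed in the embedding space, i.e. the same metric space
the clustering sees.

Robustness checks: a permutation test of the silhouette (300 label
permutations preserving cluster sizes; the smallest attainable p is
1/301), bootstrap model selection (200 resamples, k = 3–7, metric means ±
SDs per k), leave-one-subject-out stability (recluster without each
subject, compare retained labels to the full solution via ARI), a UMAP
hyperparameter grid (neighbors {15, 25, 35, 50} × min_dist {0.001, 0.01,
0.1}; the exact lattice is a package choice within the stated ranges) with
ARI against the baseline configuration, and seed-repeat membership
variability under optimal label matching. The ARI itself is implemented
from the contingency-table formula.

## Temporal model

Labeled events form per-file sequences ordered by onset. The model is a
first-order Markov chain over the K = 5 phenotypes: transition counts are
pooled over consecutive within-file pairs (never across files), and
probabilities come from row normalization with ε = 10⁻⁹ in the
denominator, so a state with no outgoing transitions yields an all-zero
row rather than a division error (and deliberately *not* a uniform row —
absence of evidence is reported as absence). Dwell times (offset − onset)
are summarized per state with sample (N−1) SDs; inter-event gaps (next
onset − previous offset) are pooled globally within files. Overlapping
consecutive events would produce negative gaps; these are kept and flagged
by default (the upstream proximity filter makes them rare) with a
configurable drop.

`simulate_markov()` inverts the model: it draws a state chain from a
transition matrix and dwell/gap durations from truncated-normal laws,
which gives closed-form oracles (truncated-normal moments) for recovery
tests.

## The synthetic generator

Clinical PEG recordings are generally not shareable, so the package ships
a generator whose defaults *are* the validation study conditions used by
the test suite and the acceptance script: 8 subjects × 2 recordings ×
2 minutes at 44.1 kHz, SNR 15 dB, events sequenced by the published
5-state transition matrix (row-renormalized) with truncated-normal dwell
laws at the published per-phenotype means/SDs (0.60/0.14, 0.08/0.02,
3.61/2.50, 1.25/0.33, 0.25/0.08 s) and gap law 0.90/0.46 s truncated at
zero. This yields ≈ 55–65 events per 2-minute recording (≈ 28–30 per
minute), in line with reported event yields for healthy adults.

The five morphologies are synthetic stand-ins — no quantitative acoustic
parameters of the real morphology classes are available — designed under
three constraints:

1. **Sharp attacks.** Every class reaches its energy maximum 10–30 ms
   after onset, so the detected peak matches the annotated onset within
   the ±100 ms tolerance and the 200 ms feature window samples the event
   body rather than the surround.
2. **Sub-threshold secondary structure.** Within-event ripple (burst
   trains, amplitude modulation, decay tails) stays below the dynamic
   threshold, so each event contributes exactly one retained peak.
3. **Separable but connected classes.** Classes differ by carrier
   structure (multiple-burst ~450 Hz burst trains; random-continuous
   700–1600 Hz noise; single-burst ~180 Hz damped tone; harmonic ~120 Hz
   fundamental plus three harmonics with slow AM; multi-modal a ~300 Hz
   tone superposed with a 900–1400 Hz noise band) while continuous
   per-event variation (attack 10–30 ms, sustain ×0.75–1.25, decay
   ×0.8–1.25, carrier jitter, amplitude 0.5–1.0) gives each class a
   connected, unimodal spread. Without that spread the classes degenerate
   to near point masses whose cosine-space geometry UMAP tears into
   arbitrary clumps — an instructive failure mode, but not a useful test
   fixture.

The default background is a *comb* floor: a 5 ms Gaussian noise template,
drawn once per dataset and tiled, i.e. a stationary broadband line
spectrum (200 Hz spacing) standing in for a steady room/sensor floor
shared across sessions. The reason is structural: with i.i.d. white noise,
the log-mel features of background-dominated frames fluctuate
independently in every frame and column regardless of SNR (log-spectral
fluctuation is scale invariant), which makes the feature matrix full-rank
and caps what any 30 components can explain at about 86% on these data.
Because the line spacing exceeds the 25 ms analysis window's main lobe,
the comb's short-time spectrum is the same in every frame, so background
frames are uninformative constants, as they would be after the denoising
real pipelines apply. i.i.d. white and 1/f pink noise remain available as
`noise_color` options for detector-level experiments.

What the generator does **not** emulate: physiological variability across
subjects (all subjects share the same morphology distributions —
deliberate, so leave-one-subject-out folds have a well-defined right
answer), sensor transfer functions, motion artifacts, respiratory or
cardiac interference, and non-stationary ambient noise. Passing tests on
synthetic data therefore demonstrate the pipeline's correctness and
internal consistency, not clinical performance.

## Numerical choices and degenerate inputs

* Times are seconds everywhere; all sample counts are derived at runtime
  from the recording's rate, so non-44.1 kHz input is accepted.
* Frame lengths use half-up rounding (a 25 ms frame at 44.1 kHz is 1103
  samples, not banker's-rounded 1102).
* The dynamic threshold has a relative floor of mean × (1 + 10⁻¹²) so
  float ripple on an exactly flat envelope never counts as structure.
* All-zero recordings normalize to themselves with a warning; all-zero
  segments yield zero descriptors with a `silent` flag; empty event sets
  flow through the pipeline as empty tables, not errors.
* Every stochastic operation takes an explicit seed; derived child seeds
  stay below 2³¹.

## Problem sizes

The default validation study (16 two-minute recordings, ≈ 900 events)
runs the full pipeline in seconds and the complete robustness battery
(300 permutations, 200 bootstrap resamples across k = 3–7, 8 LOSO folds,
a 12-point UMAP grid) in about two minutes on a single CPU. Unit tests
use smaller fixtures (8 kHz, tens of seconds) where the property under
test does not depend on the full study conditions.

## Known limitations

* Morphology names attach to clusters only through post-hoc dwell/spectral
  heuristics on synthetic data; on real data clusters are indices and any
  naming is advisory.
* The detector assumes a roughly stationary noise floor per recording; a
  single per-recording threshold will underperform on recordings with
  drifting noise levels.
* The Markov model is first-order and pooled across subjects by design;
  longer-range dependencies (e.g. postprandial cascades) are out of scope.
* The 95%-variance property of 30 principal components is a property of
  data whose background is stationary; it is checked and warned about, not
  enforced.
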