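# pegsound

Unsupervised detection, phenotyping and temporal modeling of bowel sounds
from phonoenterogram (PEG) recordings.

A phonoenterogram is an audio recording of abdominal sounds (digital
stethoscope or surface microphone, typically 44.1 kHz / 16-bit, ~2 min per
session). Bowel sounds reflect gastrointestinal motility, but routine
auscultation is subjective. `pegsound` provides an annotation-free analysis
chain for researchers working with such recordings:

1. **Detection** — a short-time energy envelope (25 ms frames, 5 ms hop)
   with a dynamic threshold (mean + 2 SD) marks prominent bowel-sound
   events; each event carries a 200 ms feature window around its energy
   peak, and events closer than 100 ms are resolved (discard or
   keep-strongest). Detections are scored against reference onsets with
   ±100 ms greedy one-to-one matching (precision / recall / F1).
2. **Acoustic encoding** — each event becomes a 279-dimensional vector:
   20 MFCCs × 13 frames (260), 13 time-averaged Δ-MFCCs, and six spectral
   descriptors (centroid, bandwidth, flatness, roll-off, RMS, entropy),
   z-scored per column over the pooled dataset.
3. **Embedding and clustering** — PCA to 30 components, UMAP to a
   10-dimensional manifold (cosine metric, 35 neighbors, min_dist 0.01),
   then k-means (k = 5, 20 k-means++ restarts), Ward agglomerative or
   spectral clustering, scored by silhouette `S = (b − a)/max(a, b)`,
   Calinski–Harabasz `CH = [tr(B)/tr(W)]·[(N − k)/(k − 1)]` and
   Davies–Bouldin `DB = (1/k) Σᵢ maxⱼ≠ᵢ (sᵢ + sⱼ)/d(cᵢ, cⱼ)`, plus a
   robustness battery (permutation test, bootstrap k-selection,
   leave-one-subject-out stability, UMAP sensitivity grid, seed repeats).
4. **Temporal modeling** — events ordered within each file form a
   first-order Markov chain over the K = 5 phenotypes:
   `P_ij = N_ij / (Σ_j' N_ij' + ε)` with ε = 10⁻⁹, per-state dwell-time
   statistics `d_n = t_n^end − t_n^start` (sample SD), and global
   inter-event gaps `g_n = t_{n+1}^start − t_n^end`.
5. **Synthesis** — a generator produces ground-truth-labeled synthetic
   PEG recordings with five acoustic morphologies (multiple-burst,
   random-continuous, single-burst, harmonic, multi-modal), Markov-driven
   sequencing and configurable noise, so the entire pipeline is testable
   without clinical data.

## Worked example

```r
library(pegsound)

# a synthetic study: 8 subjects x 2 recordings x 2 min @ 44.1 kHz, SNR 15 dB
spec    <- synthetic_spec(seed = 1)
dataset <- generate_dataset(spec)

run <- run_pipeline(dataset, config = pipeline_config(seed = 1))
print(run)
#> <peg_run> 940 events | algorithm kmeans (k = 5)
#>   S = 0.936 | CH = 38587.4 | DB = 0.099
#>   vs truth: recall 0.997, precision 0.993, ARI 0.995
```

The printout says: 940 prominent events were detected across the 32
minutes of audio (~29 events/min); k-means on the 10-D embedding found
five clusters with strong internal validity (silhouette 0.94, high CH,
low DB); and, because the generator supplies ground truth, the detections
were matched to true events (recall 99.7%, precision 99.3%) and the
cluster labels agree with the true morphology classes almost perfectly
(ARI 0.995).

Temporal structure of the labeled sequence:

```r
run$temporal$probabilities   # 5x5 row-stochastic transition matrix
run$temporal$dwell           # per-state mean and SD dwell times (s)
run$temporal$gaps            # pooled inter-event gap statistics
```

A command-line interface wrapping the same functions is installed at
`inst/cli/pegsound` (subcommands: `simulate`, `detect`, `evaluate`,
`features`, `embed`, `sensitivity`, `cluster`, `robustness`, `temporal`,
`simulate-markov`, `run-all`).

## Scientific scope

The acoustic morphology templates are synthetic stand-ins (no quantitative
acoustic parameters of real bowel-sound classes are published); passing
tests demonstrate pipeline correctness and internal consistency, not
clinical performance. See the methods vignette
(`vignettes/phonoenterography-methods.Rmd`) for the model, parameter
rationale, and limitations.
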