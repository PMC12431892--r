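# microdyn

EEG microstate analysis with an emphasis on temporal dynamics, for
researchers studying large-scale brain states — resting-state cognition,
sleep, anesthesia, disorders of consciousness — from multichannel EEG.

Scalp potential topographies stay semi-stable for ~50–100 ms and then switch
abruptly; these *microstates* are classically summarized by four canonical
maps (A: left-right oblique, B: right-left oblique, C: anterior-posterior,
D: frontocentral). `microdyn` derives the maps and, beyond the usual static
summaries, quantifies the *dynamics* of the map sequence, in particular the
asymmetry of its transitions via entropy production

$$EP = \sum_{ij} P_{ij} \,\ln\frac{P_{ij}}{P_{ji}},$$

which is zero under detailed balance (time-reversible dynamics) and positive
when transitions between maps are directionally biased.

The package provides:

* **preprocessing** — zero-phase 0.5–45 Hz Butterworth band-pass,
  stimulus-locked epoching, iterative bad-channel detection (amplitude and
  variance Z-score criteria), inverse-distance interpolation, bad-epoch
  rejection with participant-level exclusion, edge-channel trimming and
  average referencing;
* **GFP peak extraction** — global field power, strict local maxima with
  minimal peak distance, two-criterion amplitude filtering, subsampling;
* **clustering** — polarity-invariant modified k-means (restart selection
  by global explained variance) and the three-level bootstrap group
  clustering (participant maps → bootstrap-balanced group clusterings →
  final maps), plus canonical A–D template matching;
* **segmentation** — global-map-dissimilarity back-fitting of maps to every
  sample, with window smoothing;
* **markers** — coverage and coverage entropy, GEV per map, mean microstate
  duration (MMD), duration variance (MDV), transition matrices, entropy
  production;
* **group statistics** — pairwise Mann-Whitney U with per-marker Bonferroni
  correction and a Spearman ordinal trend test;
* **a synthetic-data generator** — planted topographies and Markov
  dynamics with a signed oscillatory envelope, so every stage is testable
  by parameter recovery;
* tidy outputs (tibbles), `tidy()`/`glance()` methods, `autoplot()` for
  maps and segmentations, `plot_markers()` for cohort views, and
  `run_pipeline()` to orchestrate a whole cohort from one configuration.

## Worked example

Simulate one participant with four planted maps and a rotationally biased
transition matrix (stay probability 0.95 → 80 ms mean runs; the cyclic
successor favored 7:1 among leaving transitions), then run the analysis:

```r
library(microdyn)

lay  <- grid_layout(64)
maps <- make_topographies(lay, k = 4, seed = 1)
P    <- make_transition_matrix(4, stay_prob = 0.95, asymmetry = 6)
sim  <- simulate_participant(lay, P, n_epochs = 20, epoch_len = 375,
                             amplitude = 10, noise_sd = 1, maps = maps,
                             seed = 3)

ep    <- rereference_and_trim(sim$epochs)   # drop edge ring, average ref
peaks <- gfp_peak_set(ep, seed = 1)
peaks
#> <peak_set> 1449 peak topographies x 36 channels

ms <- mod_kmeans(peaks, k = 4, n_init = 100, seed = 2)
ms
#> <mapset> 4 maps x 36 channels, training GEV = 0.359

seg <- backfit(ep, ms) |> smooth_segmentation(ep, ms)
microstate_markers(ep, seg, ms, participant = "sim01", group = "HC")[,
  c("coverage_entropy", "gev_total", "mmd", "mdv", "ep")]
#>   coverage_entropy gev_total     mmd      mdv     ep
#> 1           1.3852    0.4087 76.3359 5976.762 0.1153
```

The markers read as follows: coverage entropy 1.385 nats is essentially the
uniform maximum ln 4 ≈ 1.386 — all four maps are occupied equally, as
planted. The recovered mean duration 76 ms sits close to the planted 80 ms
(noise occasionally splits a run). Entropy production 0.115 nats is clearly
positive — the planted rotational bias (exact EP 0.259 nats on the planted
matrix) survives back-fitting, diluted by symmetric noise-induced
transitions. And the recovered maps match the planted ones almost exactly:

```r
truth <- mapset(sim$truth$true_maps$maps[, !lay$edge])
attr(order_canonical(ms, truth), "match_correlation")
#> [1] 0.991 0.997 0.996 0.998
```

For cohorts, `run_pipeline()` takes a configuration (see
`default_config()`, YAML overrides via `load_config()`) or a manifest of
recorded files, and returns the marker table, final maps, pairwise tests
and trend tests, writing CSVs plus a provenance record when an output
directory is given.

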