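---
title: "Microstate dynamics: models, markers and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microstate dynamics: models, markers and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microdyn)
```

## The model

Scalp EEG topographies do not change continuously: over windows of roughly
50–100 ms the spatial configuration of the potential field stays semi-stable,
then switches abruptly. These periods are *microstates*. Across healthy
adults four prototypic maps recur — two oblique left-right / right-left
dipolar patterns (A and B), an anterior-posterior gradient (C), and a
frontocentral maximum (D) — and their temporal statistics (how long each map
dominates, how balanced the occupancies are, how asymmetric the transitions
are) carry information about the underlying large-scale network dynamics,
including in disorders of consciousness, sleep and psychiatric conditions.

`microdyn` implements the full analysis chain:

1. **Preprocessing**: zero-phase 0.5–45 Hz band-pass, epoching around
   stimulus onsets (−200 to +1344 ms by default, both endpoint samples
   included, 387 samples at 250 Hz), iterative bad-channel detection,
   interpolation, bad-epoch rejection, edge-channel trimming and average
   referencing.
2. **GFP peak extraction**: global field power (the per-sample spatial
   standard deviation), strict within-epoch local maxima at a minimal
   distance of 2 samples, filtered by two amplitude criteria, subsampled to
   at most 100,000 maps.
3. **Clustering**: polarity-invariant modified k-means with 100 random
   restarts selected by global explained variance (GEV), and a three-level
   bootstrap scheme for group maps (k1 = 10 maps per participant; 2000
   bootstrap draws of the smallest group size from every group, each
   clustered to k = 4; a final clustering of the 4 × 2000 maps to 4).
4. **Segmentation**: back-fitting of the group maps to every sample by
   global map dissimilarity (GMD), followed by window smoothing.
5. **Markers**: coverage and its Shannon entropy, GEV per map, mean
   microstate duration (MMD), duration variance (MDV), the transition
   matrix, and entropy production.
6. **Group statistics**: pairwise two-sided Mann-Whitney U tests with
   per-marker Bonferroni correction, and a Spearman ordinal trend across
   ordered groups.

### Polarity invariance

A topography and its sign flip are physiologically the same state (the
oscillatory generators reverse polarity every half cycle). Assignment
therefore maximizes the *squared* spatial correlation, the prototype update
is the dominant eigenvector of the assigned topographies' outer-product sum
(the first principal axis, which is sign-blind), and GMD is minimized over
polarity. The stored sign of a map is a display convention only (largest
absolute loading positive).

### Entropy production

For a row-stochastic transition matrix \(P\), the entropy production

\[ EP = \sum_{ij} P_{ij} \,\ln\frac{P_{ij}}{P_{ji}} \]

is zero exactly when \(P\) is symmetric on its support (detailed balance:
the chain is statistically the same run forwards and backwards) and positive
when some transitions are directionally biased. Diagonal terms cancel, so
including or excluding self-transitions changes the normalization of the
off-diagonal probabilities but not the zero/non-zero structure; both
variants are available (`transition_matrix(include_self = )`). We use the
natural logarithm throughout (nats), for EP and for coverage entropy alike.

Finite-sample estimates raise a practical problem: a pair observed in one
direction only would make the plug-in EP infinite. Such one-sided pairs are
excluded from the sum and counted in a diagnostics attribute (with a
warning); an epsilon-regularized variant that adds one pseudo-count spread
over all cells is available via `entropy_production(tm, regularize = TRUE)`.

## The synthetic-data generator

Every stage is validated by parameter recovery on simulated recordings with
known ground truth, built as

\[ x(t) = A \,\sin(2\pi f t)\, m_{L(t)} + \varepsilon(t), \qquad
   \varepsilon \sim \mathcal N(0, \sigma^2) \]

where \(L(t)\) is a first-order Markov chain with a planted transition
matrix, \(m_k\) are planted unit-norm topographies, and the signed
oscillatory envelope (default \(f = 10\) Hz) makes the GFP peak twice per
cycle while alternating the instantaneous polarity — so the simulation
exercises exactly the structure the clustering assumes (stable topographies
at GFP peaks) and forces the polarity-invariant path.

Defaults (the simulated study conditions): 64 channels on a regular
head-plane grid with a flagged peripheral ring, 250 Hz sampling, epochs of
375 samples (1.5 s), envelope amplitude 10 µV against sensor noise of 2 µV
(an amplitude signal-to-noise ratio of 5), and stay probabilities around
0.90–0.95 giving mean run lengths of 40–80 ms — the range reported for
resting EEG. The channel count is a parameter; 64 keeps desk-scale runs
fast, and nothing in the code assumes a particular montage size.

Design choices that were genuinely open:

* **Canonical map geometry.** The A/B pair uses oblique dipolar axes
  \(x \pm 0.6\,y\) (about 31° from the left-right axis) rather than full
  45° diagonals. At 45° the A-C correlation is \(1/\sqrt2 \approx 0.71\),
  and with the seeded perturbation a pair can approach 0.8 — at which point
  a single prototype halfway between two planted maps explains the data
  almost as well as the pair, and four-map recovery becomes genuinely
  unidentifiable. At 31° all base pairs sit near \(|r| \approx 0.5\):
  clearly distinct yet realistically overlapping. A seeded smooth
  perturbation (relative amplitude 0.25) is blended into every map so
  different seeds give different map sets; the generator enforces all
  pairwise \(|r| < 0.8\) by construction.
* **State changes at any sample.** The Markov chain switches at the sample
  level, unsynchronized with the envelope. This is the simplest model that
  yields geometric run lengths with a known mean \(1/(1-p_{\text{stay}})\)
  samples and variance \((1-q)/q^2\), \(q = 1 - p_{\text{stay}}\) — the
  analytic anchors for the duration markers.
* **What the generator does not emulate**: forward-modeled cortical
  sources, spatially correlated sensor noise, blinks and muscle artifact,
  1/f background spectra. Passing recovery tests therefore demonstrates the
  correctness of the algorithms under the stated model, not robustness to
  every pathology of real recordings; the preprocessing thresholds are
  tested on constructed fixtures instead.

## Numerical and procedural choices

* **Filter realization.** The band is applied as a forward-backward
  (zero-phase) 4th-order Butterworth via `signal::filtfilt`, so topographies
  are not latency-shifted. Each channel is demeaned first: a DC offset lies
  outside the pass band but would otherwise decay only through slow edge
  transients of the 0.5 Hz high-pass.
* **Bad-channel criteria.** The amplitude criterion (peak absolute voltage
  above 100 µV in more than half the epochs; a peak-to-peak switch is
  provided) is computed once on the input. The variance Z-score criterion
  (Z > 4 relative to the currently good channels) is recomputed four times,
  removing freshly flagged channels each round. Note a small-montage
  subtlety: a variance Z-score among \(n\) channels cannot exceed
  \(\sqrt{n-1}\), so Z = 4 is only reachable with \(n \ge 17\).
* **Interpolation.** Inverse-distance weighting (exponent 2) over the 6
  nearest good channels on the 2-D layout, expanded to include ties at the
  cutoff distance so the neighborhood stays symmetric on regular grids —
  a deliberately simple, documented surrogate for spherical-spline
  interpolation; both the neighbor count and exponent are arguments.
* **GFP peak filters** use the mean, SD and percentile of the *full* GFP
  series (all samples, not only peaks). The upper criterion removes peaks
  more than 1 SD above the mean — unusually strong topographies are more
  often artifact than signal at this stage; it can be disabled with
  `sd_mult = Inf`. Plateau maxima count from their first sample; thinning
  below the minimal peak distance keeps the larger peak, earlier on ties.
* **Convergence.** Modified k-means stops when the relative change of the
  residual variance falls below 1e-6 or after 300 iterations; empty
  clusters are re-seeded from a random topography. With a fixed seed the
  whole clustering is bit-reproducible.
* **Restart counts.** The final-stage clustering uses the full 100 random
  restarts. Participant-level (k1 = 10) and bootstrap-level clusterings
  default to 20 restarts: these stages are re-run hundreds to thousands of
  times and their errors average out in the next level, so the extra
  restarts buy little. Both are configurable.
* **Bootstrap sampling** draws the same number of participants (default:
  the smallest group size) from *every* group in each iteration,
  neutralizing unbalanced cohorts; a pooled-cohort variant sits behind
  `per_group = FALSE`.
* **Smoothing.** The window smoother iteratively relabels each sample to
  minimize its unexplained variance minus `penalty` times the number of
  same-label neighbors within `half_window` samples (defaults 3 samples =
  12 ms at 250 Hz, penalty 5). Costs are normalized by the mean squared
  sample norm, making the penalty scale-free. Zero penalty returns the
  back-fit labels unchanged; iteration stops at a fixed point (or 1000
  sweeps). Samples with near-zero GFP, where GMD is undefined, inherit the
  previous sample's label (first labeled neighbor for a leading run). Ties
  in the GMD argmin break toward the lowest map index. Epochs are smoothed
  independently and runs never cross epoch boundaries.
* **Durations.** MMD/MDV pool run durations over maps (per-map variants are
  also emitted) and use the population (divide-by-n) variance.
  Boundary-truncated runs are included — short epochs interrupt long
  microstates, and dropping truncated runs would bias short-epoch designs;
  per-map tables let users filter differently.
* **Mann-Whitney U** reports the first-sample U convention (min-U is also
  returned), exact p for combined n ≤ 20 without ties, normal approximation
  with continuity and tie correction otherwise. Bonferroni families are the
  pairwise comparisons of one marker (m = 6 for four groups), not all
  markers jointly. The ordinal trend test codes groups
  UWS = 0 < MCS = 1 < EMCS = 2 < HC = 3 by default.

## What the tests establish

The test suite validates each stage against independent oracles (full
permutation enumeration for Mann-Whitney, direct per-sample evaluation for
GEV and GMD, explicit pair counting for transitions, exhaustive permutation
search for template matching) and the whole chain by parameter recovery:
three-level clustering of an 8-participant cohort at amplitude SNR 5
recovers planted maps with mean \(|r| > 0.95\) (50 bootstraps at this desk
scale); plug-in entropy production converges to the analytic
\(0.2\ln 3\) for the two-state test chain and to zero for symmetric chains;
planted geometric durations are recovered in mean and variance; and a
20-repetition experiment with two 10-participant cohorts (80 ms symmetric
vs 40 ms rotationally asymmetric dynamics) yields Bonferroni-corrected
MMD and EP differences at p < 0.05 in at least 90% of repetitions. Problem
sizes (participants, epochs, bootstrap counts) are desk-scale choices made
once for these simulations; every one of them is a parameter of the
corresponding function.

## Known limitations

* The spherical-spline interpolation of dense geodesic nets is replaced by
  2-D inverse-distance weighting; for real 256-channel data a dedicated
  spline implementation would be preferable.
* The exact peripheral-channel list of a given net must be supplied through
  the layout's `edge` flags; no montage database ships with the package.
* EP estimates on short recordings are biased upward (plug-in estimator);
  compare groups at matched recording lengths, or use the regularized
  variant.
* k is fixed by the user (4 throughout the examples); no automatic model
  selection is provided.
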