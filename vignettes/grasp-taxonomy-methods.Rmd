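---
title: "Building quantitative hand-grasp taxonomies: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building quantitative hand-grasp taxonomies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grasptaxa)
```

## The problem

Hand-grasp taxonomies organize grasp types by similarity. Historically they
were drawn by expert judgement; this package instead derives them from
measurements: multi-subject recordings of forearm surface electromyography
(sEMG, 12 channels at 2 kHz) and of hand posture (a 22-sensor data glove at
about 25 Hz), collected while subjects repeatedly perform a fixed set of
grasps (six repetitions of 5 s movement alternating with 3 s rest, the
Ninapro DB2 protocol).

The construction has four stages, each exposed as package functions:

1. **Preprocessing** (`hampel_powerline_filter()`, `synchronize()`,
   `segment_windows()`): 50 Hz line-noise removal on the EMG, linear
   interpolation of all modalities onto the 2 kHz grid of the fastest
   device using per-sample timestamps, and windowing (200 ms windows,
   100 ms overlap) strictly inside each (grasp, repetition) segment.
2. **Features** (`window_features()`, `build_feature_table()`): five
   time-domain families per window and channel — RMS, MAV, IAV, WL and the
   TD set \{MAV, MAVS, ZC, SSC, WL\}.
3. **Distances and trees** (`grasp_distances()`, `agglomerate()`,
   `to_phylo()`): one-way MANOVA machinery turns each subject's feature
   table into a G×G Mahalanobis distance matrix between grasp means under
   the pooled within-group covariance; agglomerative clustering turns the
   matrix into a dendrogram, which is stripped of heights to give an
   unordered rooted unweighted tree.
4. **Supertrees and comparison** (`build_supertree()`, `spr_distance()`,
   `tree_edit_distance()`, `robinson_foulds()`): subject trees are merged
   per modality×family, then per modality, then into one general taxonomy,
   each time minimizing the total rooted subtree-prune-and-regraft (SPR)
   distance via maximum agreement forests; taxonomies are compared by tree
   edit distance.

## The statistical model behind the distances

Windows are grouped by movement. With `x_i` the feature vector of window
`i`, `m_g` the mean of grasp `g`, `N` windows and `G` grasps, the pooled
within-group covariance is

$$W = \frac{1}{N-G}\sum_g \sum_{i\in g}(x_i-m_g)(x_i-m_g)^\top,
\qquad d(g,h)=\sqrt{(m_g-m_h)^\top W^{-1}(m_g-m_h)}.$$

The distance is dimensionless and invariant under invertible affine maps of
the feature space, which is what makes families as different in scale as
IAV (a sum) and MAV (a mean) comparable. Two consequences shape the
pipeline:

- **IAV and MAV give identical taxonomies.** All windows share one length
  `T` (trailing partial windows are dropped), so IAV = T·MAV exactly, the
  map is affine, and every IAV distance matrix — hence every IAV tree —
  equals its MAV counterpart. This identity is asserted end-to-end in the
  tests and is the quantity the acceptance script recomputes.
- **Degenerate components need care.** Smooth glove trajectories have zero
  crossings identically zero, so for the TD family `W` can be singular. We
  then add a ridge $\lambda\,\mathrm{tr}(W)/p\,I$ (default
  $\lambda=10^{-6}$, configurable) and record the event on the result
  object; a `W` that is identically zero falls back to the identity metric.
  Pooling runs over all windows of all repetitions — repetitions are never
  averaged first — to keep the full within-group degrees of freedom.

Distances (not squared distances) are clustered. The linkage is
configurable with **average (UPGMA) as the default**: UPGMA is the standard
bridge from a distance matrix to an ultrametric tree, matching the
convention that all leaves sit at the same depth; single and complete are
provided for sensitivity analyses (`analysis/05_compare.R` runs all
three). Because supertree results depend on merge order, ties between
equally distant cluster pairs are broken lexicographically by smallest leaf
label — an explicit convention so the whole map from matrix to taxonomy is
deterministic and reproducible to the byte.

## Supertrees

The rooted SPR distance between two trees on one leaf set equals the size
of their maximum agreement forest minus one (after augmenting both trees
with an artificial root leaf). `spr_distance()` computes it exactly by
iterative deepening over the number of cut edges with the classic
three-way cherry branching, O(3^k); above `k_max` (default 12) it returns
a greedy upper bound flagged `exact = FALSE` so fallbacks are auditable.
`build_supertree()` seeds with the input tree of minimal total SPR
distance (ties: lowest index) and hill-climbs over the full SPR
neighbourhood, accepting the best improving move (first-best on ties,
canonical enumeration order) until no move improves.

All trees here share one complete leaf set, so the incomplete-overlap
supertree problem — and the clustering decomposition it motivates in the
general algorithm — collapses to a no-op; the implementation is written
for the shared-leaf-set case and validates it up front.

The tree edit distance uses the exact ordered-tree dynamic programme
(delete / insert / rename, unit costs by default, internal nodes carry a
shared null label). Since the taxonomies are *unordered*, trees are first
canonicalized by sorting children by smallest descendant leaf label. This
canonicalization is the single most consequential convention for
reproducing any printed edit-distance value; it is applied uniformly at
tree construction, so all reported numbers share it.

## The synthetic cohort and what it does (not) show

Real recordings cannot be bundled, so the package ships a generator whose
defaults are the study conditions: 6 repetitions, 5 s movement / 3 s rest,
2 kHz × 12 EMG channels, 25 Hz × 22 glove sensors. Its purpose is
parameter recovery: every downstream stage can be checked against a known
ground truth, the *planted tree*.

Per-grasp profiles — a log-amplitude vector over EMG channels and a
(positive) posture vector over glove sensors — evolve by Brownian motion
along the planted tree with per-edge standard deviation `profile_scale`
(default 0.5, giving realistic two- to three-fold amplitude ratios between
distant grasps). EMG is amplitude-modulated Gaussian noise: the minimal
model under which RMS, MAV, IAV and WL all track activation. Glove
channels hold the grasp posture with a broadband multiplicative
micro-movement (`tremor_sd`, default 0.05) that gives waveform-length
features their posture-proportional signal. Label onsets coincide with the
*held* grasp: activation ramps (100 ms raised cosine) and the reach
trajectory (logistic, completing ~0.4 s before label onset) sit just
outside the labelled block, as re-labelled movement annotations do on real
recordings. Variability has four dials: `subject_sd` (between-subject
profile perturbation, default 0.1), `rep_sd` (between-repetition
multiplicative jitter, default 0.05 — the intra-subject variability the
supertree stage exists to absorb), `tremor_sd`, and `noise_sd` (additive
sensor noise, default 0.05 mV). An optional 50 Hz sinusoid
(`powerline_amp`) exercises the Hampel filter.

**Planted-structure certification.** A single Brownian draw can, by
chance, realize profile geometry that contradicts the planted topology —
in which case "ground truth" would be meaningless. `generate_profiles()`
therefore certifies each modality's draw: average-linkage clustering of
the realized profile distances must reproduce the planted tree, and must
keep reproducing it under multiplicative perturbation of the profiles
(30 perturbations of 8%), so accepted draws carry a margin against the
estimation noise of a finite recording. EMG is certified under the
channel-normalized metric (its within-group variability is
amplitude-proportional, so that is the metric the pooled-covariance
whitening induces); the glove under both the raw and normalized metrics
(its variability mixes additive noise and multiplicative tremor). Draws
are rejected and redrawn deterministically from derived seeds; the number
of attempts is reported.

What passing recovery tests shows: the full chain — filtering,
synchronization, windowing, features, MANOVA distances, UPGMA, SPR
supertrees — transmits a planted similarity structure faithfully when
within-group variability is well behaved. What it does not show: real
sEMG has MUAP structure, channel crosstalk, electrode shifts, fatigue
drift and force variation that this amplitude model does not emulate, and
real grasp similarity need not be tree-like at all. Recovering the planted
tree validates the machinery, not the physiology.

## Problem sizes and numerical choices

The test suite and the acceptance script run on desk-scale cohorts chosen
as the smallest sizes that exercise every stage at full protocol fidelity:
the IAV/MAV identity and the acceptance quantity use 5 subjects × 8 grasps
× 6 repetitions at the full 5 s/3 s timing; recovery experiments use 3
subjects with 2 s movements (window counts per repetition drop from 49 to
19, which leaves all identities intact); oracle comparisons use ≤6-leaf
trees where exhaustive enumeration (all 945 rooted binary topologies, all
agreement partitions, all edit mappings) is feasible. The recovery
experiments set `rep_sd = 0.01`: the pooled covariance of a repetition-level
effect is estimated from only `G × R` blocks, and at realistic `rep_sd` this
low-degree-of-freedom component adds metric noise that is a property of the
estimator, not of the topology signal under test. The noise ladder for the
degradation test (`noise_sd` 0 → 1 → 4 against unit-scale signals) spans
clean to noise-dominated and is averaged over three cohort seeds.

Other numerical conventions: the Hampel filter operates on 1 s FFT blocks,
cleaning ±1 Hz around 50 Hz when a bin exceeds the local median by 3 MAD
(neighbourhood ±10 Hz, harmonics optional and off by default — the paper
trail for real Delsys recordings motivates the fundamental only); labels
are resampled nearest-neighbour, never interpolated; zero-crossing and
slope-sign-change thresholds default to 0 (pure sign counts) and are
configurable; the Mahalanobis ridge and its trigger are recorded on every
distance object; Newick output is canonical, making byte-identical outputs
the definition of pipeline determinism.

## Known limitations

- Exact unordered tree edit distance is NP-hard; the ordered-after-
  canonicalization distance used here is the reproducible surrogate, and
  values are only comparable under the same canonicalization.
- Edit distances over *weighted* dendrograms (used for some published
  variability tables) have no specified cost model and are out of scope;
  the inter-/intra-subject tables this package produces are form-level
  analogues computed on unweighted trees.
- `spr_distance()` is exponential in the distance; beyond `k_max` it
  degrades to a flagged greedy bound. For the tree sizes of this analysis
  (≤20 leaves, coherent inputs) the exact search is the practical path.
- The generator's certification can fail for large grasp sets with weak
  profile divergence (it gives up after a bounded number of draws with an
  informative error); the demo analyses use an eight-grasp cohort.
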