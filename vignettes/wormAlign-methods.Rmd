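---
title: "Identifying C. elegans neurons: straightening, atlases and generalized-mean alignment"
author: "wormAlign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying C. elegans neurons: straightening, atlases and generalized-mean alignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormAlign)
```

# The problem

Whole-nervous-system imaging of *Caenorhabditis elegans* produces, per
animal, a sparse 3D point cloud of a few hundred neuron nuclei, often
with a discrete color index per neuron when a multi-fluorophore barcode
strain (e.g. NeuroPAL) is used. Assigning a biological identity to each
point means matching the cloud against a reference atlas of named
canonical positions. Three obstacles make this hard: worms are imaged in
arbitrary bent postures; neuron positions vary between individuals in a
spatially *correlated* way (neighboring neurons shift together); and
experimental clouds are cropped (head-only imaging) or incomplete (dim
nuclei drop out).

wormAlign implements the three stages of a pipeline addressing these
obstacles, plus the simulation machinery to measure how well they work:

1. **Canonicalization** — a posture-invariant straightening of each worm
   built from inscribed tangent circles.
2. **Atlas construction** — robust pooling of canonicalized labeled
   clouds into a median-position atlas with spread statistics.
3. **Generalized-mean (GM) alignment** — matching an unlabeled cloud to
   an atlas by minimizing a power-mean distance loss, optionally through
   a smooth Gaussian-mixture deformation field ("GM Realistic"), then
   greedy color-constrained identity assignment.

# Canonicalization by inscribed circles

Worms are imaged under a coverslip and lie essentially flat, so the
straightening map is modeled in 2D, leaving z untouched until a final
isotropic rescale. The input is a binary hull mask (the binarized
largest-area z-slice). The boundary is traced at the 0.5 level with
sub-pixel interpolation, resampled to uniform arc length, and smoothed
with a circular Gaussian of about one pixel so the two body edges are
C^1 — the construction below needs edge tangents.

The outline is split at the head and tail tips into two opposite edge
curves $\mathbf r_-(s)$ and $\mathbf r_+(s')$, $s, s' \in [0,1]$, each
cubic-spline-fitted against normalized arc length. For a candidate
radius $t$ the circle tangent to the minus edge at $s$ has center
$\mathbf r_-(s) + \hat{\mathbf n}_-(s)\,t$ with
$\hat{\mathbf n}_- = (-\dot r_y, \dot r_x)/|\dot{\mathbf r}|$ the inward
normal, and its signed gap to the opposite edge is

$$ d(s, s', t) = \left| \mathbf r_-(s) + \hat{\mathbf n}_-(s) t -
   \mathbf r_+(s') \right| - t. $$

Minimizing over $s'$ (dense 1024-point grid plus local refinement) and
solving $\min_{s'} d = 0$ for $t$ by bracketed root-finding (tolerance
$10^{-3}$ µm) yields the inscribed tangent circle at every interior $s$.
The circle centers trace the body midline; 1000 circles (configurable)
are resampled equally spaced in cumulative midline arc length. Each
circle $k$ then defines a rigid xy map sending its center to $(L_k, 0)$,
$L_k$ its cumulative arc length, and rotating the local midline tangent
onto $+x$. A neuron is mapped by every circle whose xy projection
contains it and the images are averaged (a neuron inside no circle uses
the nearest-center circle). Finally all coordinates are isotropically
rescaled so the midline spans x ∈ [0, 800] µm. Because adjacent centers
map to $(L_k, 0)$ and $(L_{k+1}, 0)$, inter-center distances are
preserved exactly: the map is an isometry along the midline, which is
what protects the dense head and tail from the volume distortion that
plain skeleton-based straightening (provided as
`straightenPointsBasic()` for comparison) suffers at bends.

## Numerical choices

Several steps have no unique textbook answer; the package's choices are:

* **Tip detection.** The head/tail pair is the boundary point pair of
  maximal Euclidean separation (iteratively refined from a decimated
  farthest-pair search), then snapped to local curvature maxima. The
  curvature used for snapping is computed on a heavily smoothed copy of
  the contour so pixel-staircase noise on straight stretches cannot
  outscore the genuine tip caps. Shapes whose tip separation is below
  1.3 times their equal-area-disk diameter (e.g. a disk) are rejected as
  having no stable tips.
* **Cap handling.** Inside a rounded tip the tangency problem follows a
  second branch of small circles shrinking toward the tip; the body
  midline proper ends at the tip-cap center. The chain is trimmed where
  the solved radius falls well below the nearby stable body radius, and
  each end is then clipped or extended by the residual radius deficit
  (a cap-branch circle of radius $t$ sits $h - t$ from the cap center).
* **Chain smoothing.** Sub-pixel noise in the solved centers would
  inflate the cumulative arc length (a random-walk excess of roughly
  $\sigma^2/\Delta$ per segment); the center polyline is smoothed with
  a short Gaussian before resampling. At body bend radii far above the
  smoothing span the geometric bias this introduces is negligible.
* **Orientation.** The mask alone cannot tell head from tail; the first
  tip (smallest x, then y) maps to x = 0 and `flipAP` flips the choice.
  On fixtures, tests score both orientations and take the better one.

On the package's synthetic bent-worm fixtures (constant-width tube bent
along a circular arc, for which the canonical position of every neuron
is known in closed form) the full pipeline recovers ground truth to
well under 1 µm mean error at 1.5 µm pixels, for bend angles from 0 to
a U-turn.

# Atlas construction

`buildAtlas()` pools canonicalized labeled clouds by componentwise
*median* — robust to outliers and, unlike the mean, resistant to the
overall shrinking that averaging bent-posture residuals produces. The
per-axis spread is reported as the median absolute deviation (with the
usual 1.4826 consistency constant); the paper-level statistic is
deliberately not used by alignment, only exposed in the atlas file.
Neurons present in only a subset of worms are kept with their
contributing-worm count (`minCount` filters them if desired). The two
CAN cells are excluded at the data level by the fixture generator's
default name list, mirroring the fact that panneuronal identification
strains do not label CAN; nothing in the algorithms treats them
specially.

`mergeSubatlas()` folds a higher-resolution head or tail sub-atlas into
the whole-body frame with a closed-form least-squares rigid transform
(Kabsch/SVD with a reflection guard; no scale, since the sub-atlas is
already in canonical units), replacing only the region entries and
leaving midbody entries bitwise untouched. At least three non-collinear
shared neurons are required, otherwise the transform is
underdetermined and the operation errors.

# Generalized-mean alignment

For labeled positions $\mathbf r^{(1)}_i$ (the atlas) with colors
$c^{(1)}_i$ and unlabeled positions $\mathbf r^{(2)}_j$ with colors
$c^{(2)}_j$, the loss is

$$ \ell = \sum_{j=1}^{n_2} \left(
   \frac{\sum_i \delta_{c_i^{(1)} c_j^{(2)}}
         \,|\mathbf r^{(1)}_i - \mathbf r^{(2)}_j|^{\gamma}}
        {\sum_i \delta_{c_i^{(1)} c_j^{(2)}}} \right)^{1/\gamma},
   \qquad \gamma < 0. $$

Each unlabeled neuron contributes the $\gamma$-power mean of its
distances to all same-color atlas entries. With $\gamma < 0$ the
smallest distances dominate — as $\gamma \to -\infty$ the loss becomes
the sum of per-point minimum distances, a pure (and brittle)
nearest-neighbor objective — while a finite $\gamma$ lets slightly
farther candidates still pull, which is what lets the descent escape
poor pairings early on. The default $\gamma = -6$ balances the two
regimes; $\gamma = 2$ would instead give the root-mean-square objective
of a Gaussian-mixture likelihood, i.e. the CPD-like regime. Colorless
clouds are treated as a single color class.

Two numerical guards matter:

* **Distance floor.** With $\gamma < 0$ a vanishing distance blows up
  the loss. Distances enter as $\sqrt{d^2 + \epsilon^2}$
  ($\epsilon = 10^{-3}$ µm): a *smooth* floor, differentiable through
  $d = 0$, so exactly matched pairs neither diverge nor pin the
  optimization at a kink.
* **Stabilized powers.** The per-point minimum distance is factored out
  of the power mean so that exponents as extreme as $\gamma = -50$
  stay in floating-point range; the implementation agrees with a naive
  double-loop evaluation to $10^{-9}$ relative on random instances.

`alignGM()` runs full-batch gradient descent directly on the unlabeled
positions with a backtracking line search (step halved until the loss
does not increase), so its loss trace is monotonically non-increasing
by construction.

## The realistic deformation parameterization

Treating every neuron as a free particle ignores that inter-individual
positional variation is spatially coherent. "GM Realistic" instead
parameterizes the moving positions through a Gaussian-mixture
deformation field

$$ \mathbf f(\mathbf r) = \sum_{n=1}^N \mathbf d_n
   \exp\!\left(-\frac{|\mathbf r - (\mathbf r_n + \mathbf s)|^2}
   {2\sigma^2}\right), $$

with $6N + 1$ parameters (shared influence radius $\sigma$, per-bump
displacements $\mathbf d_n$ and centers $\mathbf r_n$) plus a redundant
global shift $\mathbf s$ added to the bump centers for numerical
stability. All of them are optimized, $\sigma$ in log space to stay
positive. Nearby neurons share displacement, so only smooth tissue-like
deformations are reachable — this is the regularization that makes the
method robust to cropping and dropout, where a free-particle objective
happily tears the cloud apart.

Design choices made here:

* **Optimizer.** The field parameters are fitted with limited-memory
  quasi-Newton descent (L-BFGS-B) on the analytic gradient. The shared
  $\sigma$ couples every neuron to every parameter; plain first-order
  steps traverse that stiff coupling too slowly to localize the field
  (they leave a single-bump test field essentially unrecovered), while
  quasi-Newton curvature estimates recover it to sub-micron residuals
  in a few hundred evaluations. The free-position variant keeps plain
  backtracking descent, where it converges in tens of iterations. The
  returned trace is the best-so-far loss over objective evaluations.
* **Initialization.** Bump centers start on an even grid over the
  unlabeled cloud's bounding box (axis counts proportional to box edge
  lengths, nearest feasible total to the requested N = 100);
  $\sigma_0$ = ¼ of the bounding-box diagonal; displacements start
  either at zero or at the least-squares constant field reproducing the
  atlas-minus-cloud centroid offset — whichever has the lower starting
  loss. The centroid candidate removes a rigid offset in one step, but
  is actively harmful when the two clouds have very different supports
  (a head-only cloud against a whole-body atlas shifts toward the
  atlas centroid, far from any correct pairing), hence the guarded
  two-candidate rule rather than an unconditional centroid shift.
* **Regularization.** An explicit penalty on $\sum_n \|\mathbf d_n\|^2$
  is not applied by default; the parameterization itself (shared
  $\sigma$, finite N) is the regularizer.

## Identity assignment

`assignIds()` builds the matrix of pairwise Euclidean distances between
transformed unlabeled neurons and atlas entries, repeatedly takes the
globally smallest element, assigns that identity, and deletes its row
and column; ties break to the lowest row, then column, for determinism.
With colors, candidates are restricted to same-color pairs, so each
color class is matched independently; every class yields
min(n₁, n₂) pairs and leftovers are reported as unmatched. On
well-separated instances this greedy rule coincides with the optimal
assignment (verified against brute-force enumeration in the tests); it
is used instead of a Hungarian solver because it is what the
identification accuracy below is defined over, and because its
worst-case deviation only occurs in ambiguous configurations where no
assignment rule is reliable.

# The simulation benchmark

`synthWorm()` generates the study substrate: a constant-width (or
tapered) tube of spine length 1000 µm and half-width 40 µm bent along a
circular arc, rasterized at 1.5 µm pixels, with 300 neurons placed 55%
in the head (first 15% of arc length), 15% in the midbody and 30% in
the tail — emulating the dense head/tail ganglia and sparse ventral
cord of the real animal — at radial offsets within 75% of the local
half-width. The bundled name list is the standard 302 adult
hermaphrodite complement with CAN L/R excluded by default (300 names).
What the generator does *not* emulate: left/right symmetry pairs,
position correlations between specific neuron classes, detection noise
in nucleus centroids, and real color-barcode statistics (colors are
assigned uniformly at random by name). Passing benchmarks on these
fixtures therefore demonstrates the geometric and algorithmic
properties of the pipeline, not performance on any particular
microscope's data.

Perturbation generators mirror the benchmark conditions: a shared rigid
jitter uniform in ±5 µm per axis; axis cropping; uniform dropout;
"biological noise" as a random Gaussian-mixture field with N = 100
centers drawn uniformly in the cloud's bounding box and displacement
vectors of fixed magnitude 6.1 µm in isotropic random directions at a
swept influence radius σ. The benchmark description fixes the
displacement *amplitude* while separately sweeping σ as the spatial
influence radius, so the fixed-magnitude reading is the default; a
`gaussianMagnitude` flag restores a literal Gaussian draw (sd σ) for
users who want the alternative reading. Deformation centers are drawn
over the axis-aligned bounding box as the simplest faithful reading of
"within the volume of the point cloud."

`runExperiment()` repeats each scenario `nReps` times (40 by default,
per-replicate seed = base seed + replicate index), aligns with each
registered method, assigns identities and scores accuracy = fraction of
unlabeled neurons assigned their true name (unmatched counts as wrong).
Replicate counts and sizes used by the package's own test suite and
acceptance script are scaled to desk hardware: 40 replicates for the
dropout plateau, 5 thresholds × 10 replicates for cropping, 2–5
replicates elsewhere; these sizes were chosen as the package's own
reproduction conditions. `tuneHyperparameters()` provides the random
search plus coordinate-wise halving local search used to pick method
parameters; external registration baselines (e.g. a coherent point
drift implementation) can be registered by name via
`registerAligner()` but are not bundled.

# Worked example

```{r example, eval = FALSE}
w <- synthWorm(nNeurons = 300, bendAngle = pi / 2, seed = 1)
res <- canonicalizeWorm(w$mask, w$cloud, nCircles = 1000)
atlas <- buildAtlas(list(res$cloud))

## a second worm: deformed, jittered, colorless
obs <- bioNoise(res$cloud, bioNoiseSpec(sigma = 20, seed = 2))$cloud
obs <- rigidJitter(obs, maxShift = 5, seed = 3)$cloud
fit <- alignGMRealistic(pointCloud(coords(obs)), atlas)
asn <- assignIds(fit$cloud, atlas)
accuracy(asn, neuronIds(res$cloud))
```

# Known limitations

* The straightening is 2D: worms must lie flat, and strongly
  self-occluding postures (bend angles approaching a full turn, or
  bend radii under the body width) are rejected rather than handled.
* The head/tail choice is not identifiable from the mask; callers must
  supply the orientation (or flip with `flipAP`).
* Greedy assignment is order-dependent in dense ambiguous regions; it
  matches the optimal assignment only when pairings are well separated.
* The GM loss is non-convex; the deformation parameterization and the
  guarded initialization remove the failure modes exercised by the
  benchmarks (cropping, dropout, coherent deformation up to the tested
  σ and a ±5 µm rigid jitter), but a grossly mis-posed initial overlap
  (e.g. a 180°-rotated cloud) is outside their basin.
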