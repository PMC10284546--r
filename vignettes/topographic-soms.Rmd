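---
title: "Topographic mapping of feature spaces with self-organizing maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topographic mapping of feature spaces with self-organizing maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somtopo)
```

## The problem

High-dimensional feature embeddings — the penultimate layer of an object-
recognition network is the motivating case — carry a rich similarity
structure: animate things cluster away from inanimate things, large-scale
axes such as animacy and real-world size dominate the variance, and tight
focal clusters (faces, scenes) nest inside those broad zones. Biological
visual cortex expresses a comparable structure *spatially*, as smooth maps
on a 2D sheet. `somtopo` bridges the two descriptions: it embeds a 2D grid
into the feature space so that the grid hugs the data manifold, and then
asks, with the statistics used in functional imaging, whether the resulting
sheet reproduces the macroscale preference zones and the mesoscale
selectivity patches seen in cortex.

The package has four layers:

1. **Map fitting** (`som()`): a Kohonen self-organizing map trained over a
   feature matrix.
2. **Spatial maps** (`activation_map()`, `preference_map()`,
   `dprime_map()`, `si_map()`): per-unit responses and condition contrasts.
3. **Overlap statistics** (`roc_overlap()`, `permutation_test()`,
   `morans_i()`, `rdm()`, `mds_embed()`): quantifying how mesoscale
   selectivity sits inside macroscale organization, plus
   representational-geometry summaries.
4. **Synthetic data** (`generate_object_space()`,
   `generate_planar_manifold()`): seeded generators with planted structure,
   so the full pipeline is testable with no external data.

## The model

A map is a `W x H` grid of units, each owning a tuning vector in the
`F`-dimensional input space; the full set is the *codebook*. Fitting
alternates two steps over the data. For an input `x`, the *best matching
unit* (BMU) is the unit whose tuning vector minimizes the Euclidean
distance to `x`. Every unit `u` is then pulled toward the input:

    tuning_u <- tuning_u + L_t * eta_t(u, bmu) * (x - tuning_u)

where `L_t = L0 (1 - t/T)` is the linearly decaying learning rate
(`L0 = 0.3`, `T = 100` epochs by default) and
`eta_t = exp(-d(u, bmu)^2 / (2 sigma_t^2))` is a Gaussian neighborhood in
*grid* coordinates, with radius `sigma_t = max(sigma0 (1 - t/T), eps)`
decaying linearly from `sigma0` (by default half the larger grid dimension,
so 10 on a 20 x 20 map) to the floor `eps = 1e-6`. Early epochs with a wide
neighborhood commit the map's global layout; late epochs with a narrow one
refine local detail. An `"exponential"` radius schedule
(`sigma0 * (min(sigma0, 1)/sigma0)^(t/T)`, geometric decay to radius 1) is
available behind `radius_schedule` for comparison; the linear schedule is
the default and the reference behaviour.

**Initialization.** The codebook starts as a regular lattice on the sample
principal plane: a subsample (default 400 rows) is mean-centered, its top
two eigenpairs computed, and unit `(w, h)` placed at

    mean + a_w sqrt(l1) v1 + b_h sqrt(l2) v2

with `a_w`, `b_h` linearly spaced on `[-1, 1]`. The grid shape itself is
chosen so `W/H` tracks `sqrt(l1/l2)` — the map's aspect ratio matches the
data's aspect on the plane, since the grid axes are scaled by the square
roots of the eigenvalues. With ~400 units and an aspect near 1 this yields
the familiar 20 x 20 grid. Candidate factor pairs keep both sides at least
2 and the unit count within 25% of the request; ties prefer the exact count
and then the squarer shape.

**Batch semantics.** Data are presented in batches (default 32). BMUs for a
batch are found against the codebook as it stood at the start of the batch,
then the per-image updates are applied sequentially in batch order. This
keeps the BMU assignment within a batch order-independent while remaining a
per-image (not averaged) update. A pure online variant — BMU recomputed
after every single update — converges to the same organization under the
decaying schedules but differs bit-wise; the batch-frozen rule is the one
implemented and the one the archive format reproduces.

**Diagnostics.** `quantization_error()` (mean distance of each sample to
its BMU tuning) is recorded per epoch and should fall well below its value
at initialization; `similarity_by_distance()` computes the mean pairwise
Pearson correlation of tuning vectors by grid distance, which must decay
with distance on a well-ordered map; `plot(fit, type = "qe")` and
`type = "similarity"` display both.

## From codebook to cortex-style maps

The response of a unit to a probe image is the **raw dot product** of its
tuning vector with the image's feature vector — the tuning vector acts as a
linear filter. No centering or norm correction is applied; selectivity
metrics that are invariant to global positive scaling make the raw choice
safe, and normalization variants are deliberately out of scope.

- `condition_stats()` computes, per unit and condition, the mean and
  unbiased (n−1) variance of activations. The unbiased estimator is a
  convention choice; at the localizer-scale n (tens of images per
  condition) the difference from the population estimator is negligible,
  but it must be fixed for reproducibility.
- `preference_map()` assigns each unit the condition with the highest mean
  activation; the strength is the winner's margin over the runner-up (for
  two conditions, the absolute difference of the two means). Exact ties are
  resolved by condition order and flagged rather than hidden.
- `dprime_map()` computes `d' = (m_t - m_r) / sqrt((v_t + v_r)/2)` for a
  target condition against all remaining images (optionally excluding named
  conditions from the rest pool); `si_map()` computes the mean-normalized
  `SI = (m_t - m_r)/(m_t + m_r)`, bounded in [-1, 1] for nonnegative
  responses. Units with a zero denominator get an explicit `NA` plus an
  `undefined` flag — never a silent 0, because a zero *score* is a
  meaningful "not selective" statement while a zero *denominator* is a
  degenerate measurement.
- `nonuniformity_score()` softmax-normalizes a selectivity map (temperature
  1, natural logs) into a distribution `P` over units and returns
  `sqrt(KL(P||Q)/2 + KL(Q||P)/2)` against the uniform `Q`. This symmetrized
  form is the package's reference statistic; note it is *not* the textbook
  Jensen–Shannon distance (which diverges against the mixture
  `M = (P+Q)/2` and is bounded by `sqrt(log 2)`) — the textbook form is
  available via `type = "js"`. The symmetrized form is unbounded as a
  single unit comes to dominate, which is the intended behaviour for
  flagging focal hot spots. Softmax probabilities are floored at the
  smallest positive double so the log terms stay finite under extreme score
  ranges.

## Overlap between selectivity and preference zones

`roc_overlap()` asks whether the most selective units for a category
concentrate inside one preference zone. Units are sorted by selectivity
(descending; ties broken by the same row-major order used everywhere), and
for thresholds at 1%, 2%, ..., 100% of units (`k = ceiling(pct * n)`), the
proportion of all zone-a-preferring and all zone-b-preferring units inside
the top-`k` set is recorded. Plotting zone-a fill against zone-b fill
traces a curve from (0,0) to (1,1); the trapezoidal area under it (origin
prepended) is the AUC. Chance is 0.5, and the orientation convention —
zone-b fill on the x axis — makes AUC > 0.5 mean "selective units live in
zone a". The area between curve and diagonal is also reported
(`auc_above_chance = auc - 0.5`) for readers who prefer that convention.

`permutation_test()` shuffles the selectivity scores across units, keeping
the preference map fixed, and reports the plain proportion of null AUCs
strictly greater than the observed one (default 1000 shuffles). The plain
proportion can return exactly 0; `smoothed = TRUE` switches to the add-one
estimate `(b+1)/(n+1)` for calibration-sensitive uses.

`rdm()` (pairwise `1 - Pearson` dissimilarity) and `mds_embed()` summarize
the representational geometry of a stimulus set. `mds_embed()` delegates to
classical (Torgerson) scaling via `stats::cmdscale()` and reports Kruskal
stress-1; classical scaling is deterministic, exact for Euclidean input,
and entirely standard plumbing — the `seed` argument exists only for call
compatibility with stochastic embedders.

`morans_i()` (rook or queen adjacency, binary weights) measures large-scale
spatial clustering of a per-unit quantity, such as the binary animacy
preference labels. It is the package's desk-scale stand-in for eyeballing a
map figure. The appropriate null is the spatial permutation null — shuffle
the per-unit labels across grid positions — whose dispersion is set purely
by grid geometry: the 95th percentile of `|I|` is roughly `2/sqrt(n_units)`
(about 0.12 on a 12 x 12 map, 0.07 at ~400 units). Observed values near 0.9
therefore sit more than an order of magnitude outside the null. Shuffling
the *image* labels instead and re-deriving the map is not a useful null
here: a preference map computed from label noise is still spatially smooth,
because neighboring units share tuning — its clustering reflects the map's
smoothness, not the planted organization.

## The synthetic object space

`generate_object_space()` emulates the statistics the analysis assumes of a
rectified CNN embedding, not the embedding itself:

- Two random orthonormal directions span a latent factor plane; random
  rather than axis-aligned so nothing can pass tests by coordinate
  accident.
- Each category centroid is `base + a g_a u_anim + s g_s u_size + offset`
  with signs from its animacy/size attributes, plus an isotropic centroid
  offset; each image adds isotropic noise; negative entries are clipped to
  0 (after noise, so means shift slightly — accepted as realistic for a
  rectified code).
- Defaults, fixed once as the package's reference study conditions:
  256 dimensions (desk-scale; the motivating embeddings are 4096-D and
  dimensionality is a config knob), 60 images per category, 14 regular
  categories round-robin over the four animacy-by-size cells plus two focal
  clusters — "faces" (animate, small) and "scenes" (inanimate, big) with
  tightness 0.25 — for 960 samples balanced 480/480 on each factor. Factor
  gains 4 (animacy) and 3 (size) against centroid spread 1 and image noise
  0.5 make the two factors the dominant but not exclusive variance, with
  per-factor sign separability above 99%; base level 3 keeps the rectified
  cloud almost entirely positive (sub-1% clipping).

What the generator does **not** emulate: sparsity and heavy-tailed
activation statistics of real rectified embeddings, category manifolds with
non-Gaussian shape, and any image-level structure (there are no images).
Passing tests on this generator therefore demonstrates that the pipeline
recovers planted manifold structure, not that any particular network
organizes its feature space this way.

`generate_planar_manifold()` is the minimal fixture for the ordering
property: points uniform on a rectangle, embedded by a random orthonormal
pair, with optional tiny jitter. After training, grid distances and tuning
distances over unit pairs should correlate strongly (Spearman rho near 1).

## Numerical and design choices

- Grid coordinates are 0-based `(w, h)`, row-major with `h` fastest, in
  memory and in every serialized artifact. All tie-breaks (BMU, top unit,
  ROC sort) use this one order.
- Grid distance is the true Euclidean `sqrt((w-i)^2 + (h-j)^2)` on grid
  coordinates, and the neighborhood denominator is `2 sigma_t^2`.
- All units are updated every step (no neighborhood cutoff); since
  `L_t eta <= 1`, no unit can overshoot past the input, and every update
  weakly decreases every unit's distance to the presented image.
- The radius floor prevents a division by zero as `sigma_t -> 0` in the
  final epochs; at `eps = 1e-6` the neighborhood is effectively a delta on
  the BMU.
- Training runs in compiled code with feature vectors stored contiguously;
  results are bit-reproducible given a seed, and the codebook archive
  (full-precision text + JSON sidecar with config, seed, and traces) is
  byte-identical across same-seed runs. Timestamps live only in the
  separate run manifest.
- Degenerate inputs error early and by name: zero-variance init samples,
  conditions with fewer than two images, constant feature vectors in
  `rdm()`, undefined selectivity entering `nonuniformity_score()` or
  `roc_overlap()`.

## Worked example

```{r, eval = TRUE}
os <- generate_object_space(seed = 1)
fit <- som(os$features, grid = c(12, 12), epochs = 30, seed = 1)
fit

pref <- preference_map(condition_stats(fit, os$features, os$labels, "animacy"))
pref
morans_i(pref$preferred == "animate")

sel <- dprime_map(fit, os$features, os$labels, target = "faces")
roc <- roc_overlap(sel, pref, "animate", "inanimate")
roc
permutation_test(sel, pref, "animate", "inanimate", n_perm = 500, seed = 1)
```

The problem sizes here (960 samples, 256 dimensions, 144 units, 30 epochs)
are the package's desk-scale reference conditions; the same code runs
unchanged on larger embeddings and maps.

## Known limitations

- The map is planar and rectangular; no toroidal wrap, no growing or
  neural-gas variants, and no warping onto a cortical mesh.
- Activations are raw dot products; response normalization schemes are out
  of scope.
- The ROC overlap treats units as exchangeable under permutation; it does
  not correct for spatial autocorrelation of the selectivity map itself
  (no spin-test analogue), so its p-values quantify overlap given the
  observed smoothness, not smoothness-corrected significance.
- Feature extraction from pretrained networks is an extension point (the
  CLI reserves an `extract` subcommand); the package consumes feature
  matrices, it does not produce them.
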