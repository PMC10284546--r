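# somtopo

Topographic mapping of high-dimensional feature spaces with
self-organizing maps.

## What it is for

Deep-network embeddings describe *what* visual tuning looks like in a
high-dimensional feature space; cortex lays comparable tuning out *where*
on a 2D sheet. `somtopo` is for researchers who want to bridge the two: it
trains a Kohonen self-organizing map (SOM) whose grid of units embeds into
a feature space and hugs its data manifold, then analyzes the trained sheet
with the statistics used on functional-imaging maps — condition preference
maps, d′/selectivity-index maps, spatial clustering, and ROC-based overlap
between mesoscale selectivity patches and macroscale preference zones.

A seeded synthetic "object space" generator plants an
animacy-by-real-world-size organization plus tight focal ("face"-like and
"scene"-like) clusters in a nonnegative high-dimensional cloud, so the
entire pipeline is exercised end to end without any pretrained network or
image download.

## The model in brief

Each of the `W x H` map units owns a tuning vector in the `F`-dimensional
input space (the *codebook*, `W x H x F`). For every input `x` the best
matching unit (BMU) minimizes the Euclidean distance over units, and all
units move toward the input,

```
tuning <- tuning + L_t * eta_t * (x - tuning)
L_t    = L0 (1 - t/T)                        # learning rate, L0 = 0.3
eta_t  = exp(-d_grid(u, BMU)^2 / (2 s_t^2))  # Gaussian neighborhood
s_t    = max(s0 (1 - t/T), 1e-6)             # radius, s0 = half the map
```

with `t` the epoch index and `T = 100` epochs by default. The codebook is
initialized as a lattice on the sample principal plane (axes scaled by the
square roots of the top two eigenvalues, grid aspect matched to their
ratio). From a trained map, unit activations to probe images are raw dot
products; preference maps take the condition with the highest mean
activation per unit; selectivity maps compute
`d' = (m_t - m_r) / sqrt((v_t + v_r)/2)` or `SI = (m_t - m_r)/(m_t + m_r)`
for a target category against the rest; and `roc_overlap()` sweeps the
top-1%...100% most selective units, measuring how fast they fill one
preference zone versus another (AUC, chance 0.5) with a permutation null
(`permutation_test()`, 1000 shuffles by default).

## Worked example

```r
library(somtopo)

os  <- generate_object_space(seed = 1)            # 960 x 256, planted 2x2 factors
fit <- som(os$features, grid = c(12, 12), epochs = 30, seed = 1)
fit
#> Self-organizing map: 12 x 12 grid (144 units), 256 feature dimensions
#>   trained 30 epochs on 960 samples (batch 32, L0 = 0.3, sigma0 = 6, linear radius)
#>   quantization error: 7.69 (initial 15.94, ratio 0.482)

pref <- preference_map(condition_stats(fit, os$features, os$labels, "animacy"))
pref
#> two-way preference map (12 x 12) over 'animacy': animate vs inanimate
#>   units preferring: animate 71, inanimate 73
morans_i(pref$preferred == "animate")
#> [1] 0.8938839

sel <- dprime_map(fit, os$features, os$labels, target = "faces")
roc <- roc_overlap(sel, pref, "animate", "inanimate")
roc
#> ROC overlap: dprime-selectivity for 'faces' vs animate/inanimate preference zones (144 units)
#>   AUC = 0.909 (chance 0.5; area above diagonal 0.409)
permutation_test(sel, pref, "animate", "inanimate", n_perm = 500, seed = 1)
#> Permutation test (500 shuffles): observed AUC = 0.909, p = 0
#>   null AUC mean 0.500, 95% of null in [0.411, 0.597]
```

Reading the numbers: the quantization error halves during training (the
sheet has moved onto the data manifold); Moran's I near 0.9 says the
animate/inanimate preference labels form large contiguous zones rather
than salt-and-pepper (the spatial permutation null for this grid stays
within about ±0.12); the face-selectivity AUC of 0.909 says the most
face-selective units fill the animate-preferring zone far faster than the
inanimate zone, and no shuffled map among 500 reached it — the planted
focal cluster is recovered *inside* its macroscale zone.

`plot(fit, type = "qe")`, `plot(pref)`, `plot(sel)`, and `plot(roc)` give
the corresponding figures; `rdm()` + `mds_embed()` summarize the stimulus
geometry. See the vignette in `vignettes/topographic-soms.Rmd` for the full
methods account.

## Command line

A thin wrapper over the same functions is installed with the package:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "somtopo", package = "somtopo"))')
Rscript $CLI synth --out-features f.csv --out-labels l.csv --seed 1
Rscript $CLI train --features f.csv --out map --seed 1
Rscript $CLI prefmap --codebook map --features f.csv --labels l.csv \
        --group animacy --out pref.csv
Rscript $CLI selectivity --codebook map --features f.csv --labels l.csv \
        --target faces --out sel.csv
Rscript $CLI roc --selectivity sel.csv --preference pref.csv \
        --zone-a animate --zone-b inanimate --seed 1 --out roc.json
```

Every artifact is plain text (full-precision CSV grids, JSON sidecars and
manifests); same-seed runs reproduce codebook archives byte-for-byte.

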