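# scatterseg

Model-free classification and segmentation of scanning SAXS/WAXS maps in R.

Scanning small- and wide-angle X-ray scattering experiments raster a
focused beam over a sample and record one azimuthally integrated curve
I(q) per scan pixel — easily 10^3–10^6 curves per map. Every pixel's curve
is a cumulative signature of all phases along the beam path: mineral
mixtures in rock, collagen/lipid/calcification in tissue. `scatterseg`
classifies such curve stacks **without structural models, prior sample
knowledge or human intervention**, segments the scan map into regions of
similar scattering, extracts one representative curve per region, and maps
how strongly every pixel correlates with each representative. A synthetic
phantom generator with known phase composition makes the whole chain
verifiable end to end.

Intended users: beamline scientists and scanning-SAXS/WAXS practitioners
who need a first, unbiased segmentation of a large map before committing
to physical modeling.

## Method

Given r curves on a shared q grid (in nm⁻¹):

1. **Normalize** each curve by its mean intensity over the measured q
   range (shape, not magnitude, should drive the classification), then
   **log-resample** the q axis by a factor of 10 (bin edges uniform in
   log q, bin value = mean of members) to suppress high-frequency
   counting noise. Result: the analysis matrix **M1** (r × c).
2. **Feature extraction**: for every curve, estimate dI/d(log q) and
   d²I/d(log q)² by Savitzky–Golay-style local polynomial fits and keep
   only the intensities at inflection points — bins where either
   derivative changes sign (Bragg peaks and slope changes). The union of
   detected bins over all curves defines the feature positions q_d; the
   sparse matrix **M2** (r × d, d < c) holds each curve's intensity at its
   own detections and zeros elsewhere. Curves with no inflections stay as
   all-zero rows.
3. **PCA** on M2; the number of components m is the smallest count whose
   cumulative explained variance reaches 95% (the L-curve knee is reported
   as a diagnostic).
4. **k-means** on the m-dimensional scores for every candidate cluster
   count n in 2..8; the **silhouette criterion** (Euclidean metric, mean
   over all points of s(i) = (b(i) − a(i)) / max(a(i), b(i))) selects the
   n that maximizes the mean silhouette. Each scan pixel inherits its
   curve's cluster: the **segmentation map**.
5. **Representative signals** S_1..S_n per cluster, by two rules: the
   member closest to its centroid (cluster core), or the mean of the 10%
   of members with the largest summed Euclidean distance to *all*
   centroids — the least-mixed signals, avoiding cluster interfaces.
6. **Correlation maps**: Pearson's ρ between every pixel's curve and each
   S_k; per map, values below the image median are zeroed, and any three
   maps compose into an RGB image showing phase gradients and mixtures.

## Worked example

The built-in demonstration phantom is a 32 × 32 scan over q = 0.5–25 nm⁻¹
with four phases (lamellar lipid-like with its peak near 1.47 nm⁻¹,
collagen-like low-q, mineral-like wide-angle, and an amorphous halo) in
hard quadrants, 10^5 expected counts per curve:

```r
library(scatterseg)
res <- run_phantom_demo(seed = 42, output_dir = "demo_out")
#> select_m: threshold rule gives m=3, L-curve knee at 4; using the threshold
res$selected_n
#> [1] 4
res$accuracy
#> [1] 1
round(res$rep_correlations, 4)
#>     lamellar collagen_like mineral_like amorphous
#> S_1   1.0000       -0.0167      -0.1849   -0.2380
#> S_2  -0.0152        1.0000      -0.1470   -0.2211
#> S_3  -0.1853       -0.1470       1.0000   -0.2518
#> S_4  -0.2398       -0.2207      -0.2527    1.0000
```

The silhouette criterion selects four clusters, the segmentation map
matches the constructed quadrants on every scored pixel, and each
furthest-10% representative correlates essentially perfectly with exactly
one true phase spectrum. `demo_out/` holds the full bundle: the L-curve
table, the silhouette-vs-n table, the label map (PNG + CSV sidecar), the
representative-signal table, per-cluster correlation maps and the RGB
composite, plus a reproducibility manifest.

The same pipeline runs from the shell:

```sh
Rscript inst/cli/scatterseg simulate --out phantom --seed 5
Rscript inst/cli/scatterseg run config.cfg     # flat key=value config
Rscript inst/cli/scatterseg report out_dir
```

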