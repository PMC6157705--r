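---
title: "Methods: model-free segmentation of scanning SAXS/WAXS maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: model-free segmentation of scanning SAXS/WAXS maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scatterseg)
```

## The problem and the model

A scanning SAXS/WAXS measurement yields one azimuthally integrated curve
I(q) per scan pixel. Each curve is the incoherent sum of the scattering of
all phases in the illuminated volume, so a map of r pixels is an r × c_raw
matrix of mixed-phase signatures. `scatterseg` segments such maps by
similarity of curve *shape* alone. The chain is: mean-intensity
normalization → logarithmic rebinning → inflection-point feature
extraction → PCA → silhouette-selected k-means → per-cluster
representative signals → Pearson correlation maps.

The central modeling assumptions are:

* **Linearity.** Phase contributions add linearly in intensity
  (incoherent addition). Interfaces therefore produce curves on the line
  segment between the pure-phase curves, which is why clusters of mixed
  pixels are contiguous in feature space rather than separated.
* **Isotropy.** Curves are azimuthally integrated; any anisotropic
  (orientation-dependent) structure has been averaged out upstream.
* **Shape over magnitude.** Thickness and flux variations scale a curve
  without changing its shape; dividing each curve by its own mean over
  the measured q range removes this nuisance axis. The common alternative
  — normalizing by the transmission map — is available
  (`normalize_transmission()`) but off by default, because the classifier
  compares shapes.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `resample_factor` | 10 | — | log-q rebinning ratio; c = ceiling(c_raw/10) working channels |
| `deriv_window` | 5 | bins | Savitzky–Golay-style window for d/d(log q) |
| `deriv_polyorder` | 2 | — | local polynomial order (2 = lowest order with curvature) |
| `prominence_floor` | 0.05 | fraction | sign changes whose neighborhood derivative magnitude is below this fraction of the row maximum are treated as noise |
| `variance_threshold` | 0.95 | fraction | cumulative explained variance that fixes the PC count m |
| `n_min`..`n_max` | 2..8 | — | candidate cluster counts scanned by the silhouette criterion |
| `kmeans_restarts` | 20 | — | k-means++-seeded Lloyd restarts per candidate n |
| `rep_fraction` | 0.10 | fraction | share of each cluster averaged by the furthest-points rule |

Rebinning uses **mean aggregation, not decimation**, because its purpose
is noise suppression; a constant curve is reproduced exactly, and a bin's
center is the geometric mean of its edges (the natural center of a
log-uniform bin).

## Numerical choices

* **Order of preprocessing.** Normalization precedes rebinning: the row
  mean is taken over the measured (raw) q range. The two operations
  nearly commute (rebinning is mean-preserving per bin but bins hold
  different numbers of channels), so a convention is required; this one
  keeps "mean over the measured range" literal.
* **Derivatives in log q.** The working grid is log-uniform and slope
  features of scattering curves are power-law exponents, which are
  constants in log q. Endpoints use shrinking one-sided windows; fits use
  the actual log-q offsets, so a mildly non-uniform grid is handled
  without interpolation.
* **Prominence guard.** A zero crossing's flanking samples are themselves
  near zero, so the noise guard compares the *largest derivative
  magnitude within 5 bins of the crossing* against
  `prominence_floor × max|d|` of the row. Judging only the two flanking
  samples would discard genuine inflections on densely sampled curves.
* **Crossing-to-bin assignment.** The crossing is placed at the linear
  interpolation of the flanking derivative values and assigned to the
  nearer bin; a bin where both derivatives cross counts once.
* **Feature columns.** Requiring M2 to be one fixed r × d matrix with
  zero fill implies a shared column set; the columns
  are the union over rows of detected bins on the common working grid,
  and entries are copied verbatim from M1 (never re-interpolated). If
  d ≥ c the run warns that the prominence floor is too permissive.
* **Empty rebin bins** (possible when the raw grid is not log-uniform)
  are filled by linear interpolation between neighboring bin values and
  reported.
* **k-means.** Lloyd iterations with k-means++-style seeding,
  20 restarts, centroid-shift tolerance 1e-6, at most 300 iterations; the
  within-cluster sum of squares is asserted nonincreasing at every
  iteration. A restart that empties a cluster is discarded; a candidate n
  whose restarts all fail is skipped and logged. Ties in the silhouette
  maximum resolve toward the smaller n (parsimony).
* **Silhouette.** Computed on the m retained PC scores (clustering
  operates there), over all points (no subsampling); singleton clusters
  and points with a = b = 0 score 0. The O(r²) distance matrix is
  computed once and shared across candidate n.
* **Furthest-points rule.** "Largest distances from the centroids" is
  implemented as the *sum* of Euclidean distances to all n centroids,
  in PC space, because the rule's purpose is to avoid the mixed-signal
  interfaces between clusters, and the summed distance pushes away from
  every cluster core simultaneously. Distance to the own centroid only is
  available via `distance = "own"`. The selected members' normalized
  curves are averaged unweighted.
* **Median thresholding.** Each cluster's correlation map is thresholded
  at its own median over finite pixels (strictly smaller values are
  zeroed; the median itself survives, and applying the threshold twice
  changes nothing). A single global median across all n maps is available
  via `scope = "global"`; the per-map reading keeps the n maps
  individually half-sparse regardless of their absolute correlation
  levels. Thresholding is applied to all maps before any RGB channel
  selection.
* **RGB composition.** Channel-wise max normalization (each channel
  divided by its own maximum after clipping negatives) so that spatial
  structure survives weak absolute correlations.
* **Degenerate inputs.** All-zero curves are excluded from clustering but
  retained in maps with label 0; zero-variance curves yield a missing
  (not zero) correlation; rank-0 feature matrices and empty feature
  unions abort with diagnostics.
* **Containers.** Curve stacks travel as delimited text (q column plus
  one column per pixel, grid geometry in comment headers, full double
  precision so round trips are bit-identical) or as an RDS named-array
  container. Label maps are PNG images with CSV sidecars; 0-based pixel
  indices, 1-based labels, label 0 meaning unassigned. The default raster
  is row-major; `snake` (reversed odd rows, as in continuous scans)
  is a flag on `scan_grid()`.

## The synthetic phantom

`default_phantom_spec()` builds a 32 × 32 quadrant map over
q = 0.5–25 nm⁻¹ (1000 raw channels) with 10^5 expected counts per curve
and four phases: lamellar lipid-like (sharp line near 1.47 nm⁻¹ — the
4.26 nm bilayer repeat — plus its second order), collagen-like low-q,
mineral-like wide-angle (two Bragg lines), and a broad amorphous halo;
each sits on its own power-law + flat background so that both feature
types the method keys on (peaks: first-derivative zeros; slope changes:
second-derivative zeros) occur. Noise is Poisson on expected counts —
scattering detection is photon counting, and a Gaussian approximation
would misrepresent the low-intensity tails that dominate high-q channels.

Design choices worth stating explicitly:

* **Peak placement.** Peak centers sit at centers of the default working
  channels and widths span ≥ 2 channels. A peak whose derivative
  crossings fall near channel *edges* is detected in one channel for some
  noise realizations and the neighboring channel for others; because M2
  holds intensity-or-zero entries, such jitter manufactures artificial
  substructure inside a phase. Real Bragg lines have no reason to align
  with anyone's binning — this is a deliberate idealization that makes
  the phantom's four phases *well separated*, which is the regime the
  recovery tests are about.
* **Mixing maps.** `blob_weight_map()` builds contiguous nearest-seed
  regions with a linear cross-fade of `mix_width` pixels at boundaries;
  `quadrant_weight_map()` pins the seeds to quadrant centers. Truth labels
  are per-pixel argmax weights; interface pixels with maximum weight
  below 0.5 are flagged mixed and excluded from accuracy scoring.
* **What the phantom does not emulate:** anisotropic azimuthal structure,
  nonlinear (multiple-scattering) contributions, detector artifacts,
  instrument geometry, and realistic peak-shape physics (Lorentzian
  tails, strain broadening). Passing the recovery tests therefore shows
  the pipeline is correct under its own assumptions, not that those
  assumptions hold for any particular instrument or sample.

## Problem sizes in the test suite

The suite exercises the full pipeline on the default 32 × 32 phantom
(1024 curves × 1000 channels), the cluster-count recovery property on 20
independent noise realizations of it, oracle equivalence of the
silhouette on 100 random instances up to r = 200 points, and of the
Pearson statistic on 1000 random vector pairs. These sizes were chosen to
make every probabilistic claim testable in a routine `R CMD check`-scale
run while keeping the per-phase pixel statistics (256 pixels/phase)
representative of a small real scan.

## Known limitations

* The feature step keys on inflection points; two phases whose curves
  differ only in regions without derivative sign changes (e.g. pure
  power laws with different exponents) produce identical all-zero feature
  rows and cannot be separated downstream.
* The silhouette criterion favors compact, isolated clusters; gradual
  phase gradients (large `mix_width`) blur the optimum over neighboring
  n, which the high-noise demo documents rather than hides.
* Representatives are mixtures whenever no pure-phase region is large
  enough to form an isolated cluster; the package reports them as such
  and performs no spectral unmixing.
* Correlation maps use Pearson's ρ on the working (normalized, rebinned)
  curves; ρ is blind to nonlinear dependence between signals.
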