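---
title: "Field-scale LiDAR canopy phenotyping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Field-scale LiDAR canopy phenotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canopy3d)
```

# The problem

Backpack and vehicle LiDAR can map a cereal trial of several hundred
plots in minutes, producing tens of millions of 3D returns. Turning that
cloud into per-plot traits requires a chain of steps — outlier removal,
terrain flattening, rasterization into a canopy height model (CHM),
automated plot segmentation, and trait extraction — each with parameters
that must be fixed and tested. `canopy3d` implements that chain for
rectangular drilled trials, together with a spectral canopy-structure
index and a trait-ranking layer for comparing varieties across nitrogen
treatments.

# Pipeline stages and their models

## Statistical outlier removal

For each point the mean Euclidean distance to its `n_neighbors` nearest
neighbours (default 50) is computed; writing `avg` and `std` for the mean
and standard deviation of these per-point means over the whole cloud, a
point is an outlier when its mean exceeds `avg + k * std`. `k` defaults
to 1, the convention of the statistical-outlier-removal literature.

Two practical notes, both visible in the synthetic experiments. First,
the rule is scale-free but *density-sensitive*: at desk-scale simulation
densities (hundreds of points per m² rather than the ~15,000 per m² of a
real backpack scan) the neighbourhood radius is several centimeters, and
at `k = 1` the filter eats a border strip of genuine returns around
every plot, because border points have half-space neighbourhoods. The
trial-scale runs therefore use `k = 3`, which still catches the
multi-meter-offset ghost returns the filter exists for while leaving
plot borders intact; `k` remains a run parameter. Second, the flagged
set is checked against a brute-force O(n²) oracle exactly, not
statistically.

## Ground classification and normalization

Ground filtering seeds a coarse grid (cell size = `radius`, default 2 m)
with each cell's lowest point, region-grows acceptance from the lowest
seed under a `max_slope_deg` constraint (so cells whose minimum is a
canopy point are rejected and re-interpolated from accepted neighbours),
and labels a point ground when it lies within `height_threshold`
(default 10 cm) of the bilinearly interpolated seed surface. Heights are
then normalized: ground points are assigned exactly zero and each
above-ground point's z becomes its height in centimeters above a
fine-grid (0.25 m) surface interpolated through the classified ground
points. The operation is idempotent and flattens a 2-degree slope to
residuals below 1 cm in the tests.

## TIN rasterization and the CHM

Unevenly dense points are interpolated with a triangulated irregular
network: a Delaunay triangulation (Bowyer–Watson, implemented in C++
because no Delaunay package is available to the package) evaluated
piecewise-linearly at raster cell centers, 1 cm per pixel by default.
Rasterization first decimates the above-ground points to the highest
return per cell. One cap matters: triangles with an edge longer than
`max_edge` (default 0.2 m) are not interpolated across. Within-plot
drill-row gaps (0.15 m) are bridged; the 0.3 m bare inter-plot gaps are
not, which is what keeps plot boundaries visible in the CHM. The raster
convention is fixed once: row 1 is the northern edge, the origin is the
top-left corner, and pixel centers sit at half-integer offsets.

Grayscale encoding is the linear map taking 0 cm to 0 and 160 cm to 255
with round-half-up, clamped above (landrace-tall canopies saturate
rather than error). No-data encodes as 0 with a validity mask carried
separately.

## Plot segmentation

The segmentation follows threshold → directional Sobel edges →
Hough-style line accumulation → merging → lattice. Binarization ORs a
global Otsu threshold with a moving-box local threshold so a brightness
gradient across the field does not split the mask. Because the CHM has
been aligned, the line search is restricted to the axis directions: edge
pixels whose gradient is strictly axis-dominant vote for intercepts, the
accumulator is pooled over a 5-pixel window (a TIN-derived mask boundary
is ragged at the point-spacing scale), peaks need both an absolute vote
floor (`min_line_votes`, default 0.4 of the perpendicular dimension) and
half of the strongest peak, and surviving peaks are refined to the vote
centroid. The centroid of a mask transition sits half a pixel outside
the outermost plot pixel, and the lattice builder uses exactly that
convention when cutting rectangles between merged line bands.

Line merging chains intercepts within `merge_distance` and represents
each chain by its vote-weighted mean, retaining the band extent. The
default merge distance is the inter-plot gap plus 5 px of raggedness
headroom (35 px at 1 cm/px): the two Sobel transition centroids flanking
a 30 cm gap sit 31–33 px apart in practice, so the nominal gap width
alone would fail to merge them. When a field layout is supplied and an
orientation disagrees with it, evenly spaced baselines over the mask
extent replace that orientation, which restores the full grid on
lodging-degraded masks.

Sampling windows are refined per plot: local grayscale entropy
(16-bin histogram in a 9 px window) weights a centroid, and the plot
rectangle, shrunk 10% per side, is recentered there and clipped to the
plot. Zero-texture plots (failed emergence) fall back to the geometric
center with a flag.

## Traits

* **Height** — the mean of the highest `ceiling(0.10 n)` points (H10);
  the count uses the ceiling and sorting resolves ties by index.
* **Coverage** — the highest 50% of points are projected overhead at
  1 cm/px; the occupancy image is box-filtered at 51 px and thresholded
  at half the median filtered level over occupied cells. A box filter of
  a region indicator crosses half its interior level exactly at the
  region boundary, so within-canopy gaps close without inflating the
  outline.
* **3D surface area** — points are voxelized at 5 cm, down-sampled to
  per-voxel centroids, and meshed with a 3D alpha shape (Delaunay
  tetrahedra with circumradius at most `alpha`, default twice the voxel
  size; boundary faces summed). A height-constant canopy is a planar
  sheet whose tetrahedra are all degenerate, so it is meshed as a
  two-sided surface (about twice its footprint) — the thin-slab
  two-sidedness also means a flat dense canopy reports between one and
  two footprints of area. The normalized index divides by the cohort
  maximum of the run, the only self-contained choice; the cohort is
  configurable.
* **3DVI / 3DPI** — binary voxel occupancy over the plot bounding
  volume, and the sum over 5 cm height bins of each bin's occupied-cell
  fraction. Occupancy is binary, so both are invariant to uniform
  density changes. These definitions are declared here, not inferred
  from prior biomass literature.

## The spectral canopy-structure index

A plot's CHM sub-image is Fourier-transformed; `log(1 + |F|)` is
centered so the DC component sits at the middle cell. The grid is put on
a 0–255 scale by a *fixed* calibration — division by the theoretical DC
maximum of an image of that size — rather than a per-image min–max
stretch. This choice (the sampling scale was genuinely open) matters:
per-image stretching makes amplitudes incomparable across plots and can
even reverse the ordering of two plots that differ only in texture
variance, whereas the fixed calibration preserves monotonicity of
spectral energy, which the end-to-end tests rely on.

Amplitudes are sampled at 201 integer steps along the main diagonal
through the DC cell (span −100..100; images too small to host the span
have their available diagonal linearly resampled onto it, keeping the
integration domain fixed across plot sizes; averaging both diagonals is
an option). A Gaussian `A exp(-(x-mu)²/2sigma²)` is least-squares fitted
(Levenberg–Marquardt on the residual function; failures are flagged and
the raw curve retained). Three scalars follow:

* **AUC** — the trapezoidal sum over the fitted curve (exact for
  constant and linear integrands; matches the Gaussian error-function
  closed form to 1e-3 on the test grid). Fitted-curve integration is the
  default, raw-curve integration an option.
* **Apex curvature** — parametric curvature from central differences
  over the sample index, reported at the sample nearest the fitted
  center; for a Gaussian apex this equals `A/sigma²`. A denser canopy
  gives a flatter apex.
* **3DCI** — min–max normalization of a cohort's AUCs against widened
  bounds: `MinValue = 0.593 * min`, `MaxValue = 1.294 * max`, so outputs
  are strictly inside (0, 1) and invariant to positive rescaling. The
  default cohort is all plots of one run.

## Nitrogen-response classes and the performance matrix

With `d = (low, medium, high)` treatment means of the index and a
similarity tolerance `tau` (default 0.02, exposed): Class 1 = all
pairwise gaps exceed `tau` and `d` decreases; Class 2 = low ≈ medium,
high drops; Class 3 = medium ≈ high, below low; Class 4 = medium is the
minimum and high rebounds; otherwise unclassified with diagnostics.

The performance matrix expresses each trait as a percentage deviation
from its trimmed mean (10% per tail by default) and bands it into ranks
1–5 at −15/−7.5/+7.5/+15%, lower-inclusive. Height is penalized
symmetrically (very short *and* very tall rank low). Default weights are
GN 0.25, SN 0.25, structural index 0.2, surface 0.2, height 0.1 — yield
components weighted most, height least; the weight-to-trait assignment
is configurable because only the weight vector itself is canonical.

# The synthetic-field generator

Every stage is tested against generated fields with known truth, because
real trial clouds are not shippable. The generator emulates: a plot grid
with the trial geometry (2 × 3 m plots, 6 drill rows at 0.15 m, 0.30 m
gaps, 9 × 18 plots per treatment block); a sloped plane with Gaussian
ground roughness; canopy returns as a mixture of row-concentrated points
(Gaussian scatter, sd 3 cm, around drill-row centerlines) and uniform
inter-row fill, reflecting canopy closure by the heading stage while
keeping the stripe-periodic return density; per-point plant height
`mean_height + N(0, height_sd)`, the single spike-texture dial; and
optional high-altitude ghost returns for the denoiser. Ground truth
(mean and top-decile height, 2 cm-grid coverage, plot corners) is
recomputed from the generated points, not echoed from the inputs.

Default simulation scale is 800 canopy returns and 200 ground returns
per m² — one to two orders of magnitude below a real backpack scan, and
chosen so a full 162-plot treatment block (about one million points)
generates, normalizes, rasterizes at 1 cm/px and segments in about a
minute. What the generator does *not* model: multi-return pulses,
intensity, occlusion, wind motion, lodging geometry beyond mask
corruption, and within-plot agronomic gradients. Passing tests therefore
demonstrate the pipeline's geometric and statistical correctness under
controlled conditions, not sensor realism.

# Numerical choices and degenerate inputs

* Delaunay predicates run in doubles on centered coordinates; duplicate
  points are dropped and collinear input is an error. The triangulation
  is property-tested (empty circumcircle, Euler count).
* The 3D alpha shape dithers voxel centroids by a deterministic
  sub-micron hash before tetrahedralization; exactly coplanar inputs
  take the two-sided planar branch instead.
* Grayscale rounding is round-half-up, fixed so 80 cm encodes to 128.
* Boundary points count as inside an ROI; the clip and its complement
  partition the cloud exactly.
* Band boundaries of the rank matrix are lower-inclusive at exactly
  ±7.5% and ±15%; the similarity checks of the response classifier use
  closed intervals at `tau`.
* Constant spectra, zero-texture plots, empty plots, all-ground and
  all-canopy clouds each have a defined, flagged result rather than an
  error where the pipeline can continue.

# Known limitations

Only rectangular, axis-alignable plot grids are supported; staggered
designs are out of scope. The denoiser's density sensitivity at low
simulation densities is documented above. The spectral index's absolute
values depend on the sampling calibration, so indices should only be
compared within a cohort normalized together. Trait absolute accuracy at
desk-scale densities is limited by point spacing (about 2 px of boundary
uncertainty at 800 points per m²).
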