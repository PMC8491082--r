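# canopy3d

Per-plot canopy trait analysis for field-scale LiDAR point clouds of
cereal trials.

A backpack or vehicle LiDAR scan of a drilled wheat trial produces
millions of 3D returns covering hundreds of plots. `canopy3d` turns such
a cloud into a per-plot trait table through a six-stage pipeline:

1. **Outlier removal** — a point is dropped when its mean distance to
   its 50 nearest neighbours exceeds `avg + k·std` of the per-point
   means over the cloud.
2. **Ground classification and flattening** — coarse-grid lowest-point
   seeding with slope-constrained region growing; ground points are set
   to z = 0 and canopy points to centimeters above the locally
   interpolated ground surface.
3. **Canopy height model (CHM)** — TIN (Delaunay) interpolation of the
   above-ground points at 1 cm/pixel, encoded to 8-bit gray with the
   calibration 0 cm → 0, 160 cm → 255.
4. **Plot segmentation** — adaptive thresholding, directional Sobel
   edges, Hough-style line voting restricted to the axis directions,
   line merging at the gap scale, and an entropy-weighted refinement of
   each plot's sampling window.
5. **Traits** — plot height as the mean of the highest 10% of points
   (H₁₀); canopy coverage from the overhead projection of the highest
   50% (H₅₀) under an adaptive threshold; 3D canopy surface area from a
   voxel-down-sampled alpha-shape mesh; voxel occupancy indices
   (3DVI/3DPI) as biomass proxies.
6. **Spectral canopy structure (3DCI)** — the plot CHM's centered 2D DFT
   log-magnitude is sampled along its diagonal, a Gaussian
   `A·exp(−(x−μ)²/2σ²)` is fitted, and the trapezoidal area under the
   curve is min–max normalized over the cohort with widened bounds
   (0.593·min, 1.294·max), giving an index in (0, 1) that grows with
   canopy spatial variation; the curve's apex curvature (`A/σ²` for the
   fitted Gaussian) indexes canopy density.

On top sit a nitrogen-response classifier (four canonical patterns of
the index across low/medium/high fertilization) and a weighted
performance matrix that bands trait deviations from trimmed means into
ranks 1–5 (±7.5%/±15% bands; height penalized symmetrically) and scores
varieties with weights GN 0.25, SN 0.25, 3DCI 0.2, surface 0.2,
height 0.1.

A synthetic-field generator (`generateField`) produces labeled clouds of
drilled trial blocks on sloped, rough terrain with known per-plot truth,
so the entire pipeline is testable without field data.

## Worked example

```r
library(canopy3d)

# a 3 x 3 block of 2 x 3 m plots, 80 cm canopy, 2-degree slope
fld <- generateField(fieldLayout(n_plot_rows = 3, n_plot_cols = 3),
                     canopySpec(mean_height = 80, height_sd = 3,
                                point_density = 800),
                     terrainSpec(slope_x = 0.035,
                                 ground_roughness_sd = 0.5),
                     seed = 7, ground_density = 200)

dn  <- denoiseCloud(fld$cloud, k = 3)
nm  <- normalizeHeights(classifyGround(dn$clean))
chm <- rasterizeChm(nm)
img <- encodeGrayscale(chm)
grid <- segmentPlots(img, origin = chmOrigin(chm))
grid
#> PlotGrid with 9 plots (3 rows x 3 cols)

traits <- computeTraits(nm, grid)
round(traits$height_h10, 1)
#> [1] 85.3 85.3 85.4 85.3 85.2 85.1 85.2 85.3 85.1
round(traits$coverage, 2)
#> [1] 0.93 0.93 0.94 0.95 0.96 0.96 0.94 0.99 0.93
```

Every plot of this uniform synthetic block is recovered (9 masks, each
boundary within 2 px of the generator truth), H₁₀ sits about 1.7
standard deviations above the 80 cm mean height as expected for a
top-decile statistic of this sample size, and the closed canopy drives
the coverage index toward saturation (the refined sampling windows clip
plot borders, so values sit just below 1). `dciForPlots(img, grid)` appends the spectral curve traits (AUC,
apex curvature, cohort-normalized 3DCI) to the table, and
`runPipeline()` drives the same stages from a LAS file plus YAML config,
writing the trait CSV, plot-grid CSV, CHM PNG, processed LAS and a JSON
run log.

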