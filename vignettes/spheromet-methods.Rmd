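---
title: "Whole-well spheroid morphometry: models, assumptions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-well spheroid morphometry: models, assumptions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spheromet)
```

## The measurement problem

Tumor cells grown in low-attachment 3D culture form spheroids — roughly
spherical multicellular aggregates that are a standard in vitro model for
drug and immune-effector cytotoxicity screening. Under a brightfield
microscope a spheroid appears as a dark, approximately circular body against
the brighter well bottom. Quantifying a treatment's effect means measuring
*every* spheroid in a well: the well is imaged as a grid of partly
overlapping tiles, the tiles are stitched into one calibrated mosaic, each
spheroid is annotated as a circular region of interest (ROI), and per-ROI
morphometry (perimeter, area, volume, cell number) feeds the group
statistics.

`spheromet` implements that workflow end to end, replacing manual ROI
drawing with a deterministic detector, and couples it to a synthetic
well-image generator so that every stage can be validated against known
ground truth — no laboratory data is required for any test in this package.

## The circular-ROI data model

A spheroid is represented by a single circle with radius $r$ fitted on the
2D projection. All downstream quantities are closed forms on $r$:

* perimeter $P = 2\pi r$,
* projected area $A = \pi r^2$,
* volume $V = \tfrac{4}{3}\pi r^3$ (the sphere on the maximal fitted
  radius — a bona fide 3D measure from a 2D image),
* cell number $N = V / V_{\mathrm{cell}}$, with
  $V_{\mathrm{cell}} = \tfrac{4}{3}\pi (d_{\mathrm{cell}}/2)^3$.

The cell-number model assumes cell volumes add with no void space; it is
implemented exactly as stated and not corrected for packing fraction. The
single-cell diameter `cell_diameter_um` is a **required** parameter of
`cell_model()` with no default: it must come from a measurement of the cell
line at hand, and reported counts scale with its cube. With 250 µm spheroids
and plausible cell diameters of 13–22 µm the model spans roughly
1,400–7,000 cells per spheroid, so order-of-magnitude agreement with
published per-spheroid counts is all this model can promise.

Only spheroids with diameter **strictly greater than 50 µm** enter any
summary (`filter_by_diameter()`), the conventional cutoff that excludes
single cells and small debris aggregates; a spheroid of exactly 50 µm is
excluded.

## Synthetic wells: what the generator emulates

`sim_config()` + `generate_ground_truth()` + `render_tiles()` produce a
well that has the statistical structure the analysis assumes:

* **Diameters** are log-normal with median 250 µm and `sdlog` 0.35,
  truncated to [50, 600] µm. This matches day-6 spheroids of about 250 µm
  with a heterogeneous spread up to several hundred µm; the distribution
  family itself is our choice (no published family exists for these
  cultures).
* **Geometry**: a 6,000 × 6,000 µm field at 2.5 µm/px (2,400² px), imaged
  as a 3 × 3 tile grid with 25% overlap — inside the usual 15–35%
  acquisition-software range — with integer offset jitter of at most 2 px
  per tile (tile 1 is the anchor). Commercial stages are accurate, so
  jitter is small but nonzero to make registration non-trivial. These are
  self-consistent desk-scale defaults, not a reproduction of any particular
  instrument's frame geometry.
* **Intensity**: 16-bit, background at 60% of the dynamic range, spheroids
  at 25% (dark-on-bright, as in brightfield), optional darker half-radius
  core (crypt-like morphology), optional rough boundary (a radial sinusoid
  perturbation of up to 20% of the radius; annotations always record the
  nominal circle), additive Gaussian noise of sd 300 counts per tile.
* **Treatments** (`treatment_effect()`): a volume fold applied to radii as
  $f^{1/3}$, and a `kill_fraction` of spheroids destroyed and re-rendered
  as scattered sub-threshold fragments (there is no published appearance
  model for degraded spheroids; fragments are our stand-in).
* **Readouts** (`generate_assay_readouts()`): RLU and OD595 both linear in
  viable cell number. ATP per cell defaults to 2,000 amol (≈2 fmol, the
  textbook mammalian value) in a 200 µl well; both proportionality
  constants are configurable because no instrument constants are published.
  Co-cultured effector cells can be made to add ATP but not OD,
  reproducing (as a direction, not a magnitude) the known upward bias of
  ATP-based viability in co-cultures.

What the generator does **not** emulate: optics (point-spread function,
defocus, vignetting), illumination gradients across tiles, multi-z stacks,
non-circular spheroid shapes beyond the rough-boundary perturbation, and
growth over time. Tests passing on synthetic wells therefore validate the
geometry, calibration and statistics of the pipeline — not its robustness
to real-world optical artifacts.

All randomness flows from one explicit integer seed per well
(`seed` for placement, `seed + 1` for rendering, `seed + 2` for readouts);
identical configuration always reproduces bit-identical tiles and tables.

## Stitching

Tiles are composited at their nominal grid offsets, or, with `refine =
TRUE`, at offsets estimated from the image content: the translation of each
neighbouring pair is found as the integer-pixel peak of normalized
cross-correlation on the shared overlap strip (search window ±5 px), and
the pairwise estimates are reconciled by least squares on the offset graph,
anchored at the first tile. Pairs whose correlation peak is below 0.3 —
typically a featureless strip in a sparse well — are dropped from the graph
with a warning and fall back to nominal. Overlapping pixels are blended by
linear feathering (each tile weighted by the product of its ramp distances
to its borders), which is deterministic and reproduces nominal compositing
bit-exactly when the fitted offsets equal nominal.

Rotation and scale registration and flat-field correction are out of scope;
the acquisition geometry is assumed translation-only with uniform
illumination.

## Detection

The detector automates circular-ROI annotation while honouring the circular
data model (it deliberately does not do free-form segmentation):

1. global Otsu threshold on the mosaic histogram (dark objects on a bright
   background are bimodal by construction); a mosaic with foreground
   fraction above 0.4 is declared non-bimodal and yields a warning and no
   detections;
2. connected-component labelling;
3. each component's circularity $4\pi A / P^2$ is computed with a
   corner-corrected chain-code perimeter estimator
   ($0.980 N_{\mathrm{even}} + 1.406 N_{\mathrm{odd}} - 0.091
   N_{\mathrm{corner}}$), accurate to <1% on rasterized disks of the sizes
   of interest, so the default floor of 0.8 cleanly separates single disks
   (≈1.0) from fused pairs (≈0.75);
4. circular components become one ROI via centroid + area-equivalent
   radius $\sqrt{A/\pi}$ (sub-0.1 px accurate on rendered disks, and less
   biased than a least-squares fit to quantized boundary pixels);
5. non-circular components go to `split_fused()`: seeds are local maxima of
   the interior Euclidean distance transform with minimum separation of
   half the minimum spheroid diameter; each seed's circle (radius = the
   distance-transform value) is refined by a least-squares circle fit
   (`fit_circle()`) to the boundary arc nearest that seed, with the seed
   circle kept as fallback when the arc fit is implausible;
6. circles with diameter ≤ 50 µm (or > 700 µm) are discarded, and
   duplicates suppressed by circle intersection-over-union > 0.6, keeping
   the larger circle (the measurement convention uses the maximal radius);
7. ROIs are sorted by descending radius with ids assigned in that order —
   detection is fully deterministic.

Components clipped by the image border are kept only if a circle fit to
their non-border boundary has RMS residual below 5% of the radius; how edge
objects *should* be treated is genuinely open, and this choice simply
refuses unreliable extrapolation.

`fit_circle()` itself returns the exact circumscribed circle for three
points (the classic three-point circle tool) and the algebraic (Kasa)
least-squares circle with RMS residual for more.

## Calibration and viability readouts

`fit_atp_curve()` fits an ordinary least-squares line through the standards
(RLU vs µM ATP, or RLU vs known cell number). The intercept is fitted
freely — whether such curves should be forced through the origin is
unstated in common practice, and a free intercept doubles as the blank, so
no separate blank well is required. Fits with non-positive slope are
rejected as calibration failures. `rlu_to_atp()` / `cells_from_atp()`
invert the line, flooring at zero below blank.

`crystal_violet_summary()` summarises replicate OD595 values per arm and
reports fractional viability as mean(treated)/mean(control), which is
invariant to instrument gain.

## Statistics

Group comparisons use the classical two-tailed unpaired Student's t test
with pooled variance, implemented in closed form (Welch's variant is
available behind `welch = TRUE`); the test suite cross-checks it against
`stats::t.test` and against numerical integration of the t density.
Summaries report mean, SD (n−1) and SEM = SD/√n per arm; single-observation
groups are flagged rather than dropped. Fold-changes are ratios of means
(ratio of medians available as an option — which convention published
fold-statements use is usually ambiguous). P values are reported raw, with
no multiple-testing correction, and the report footer says so.
Measurements from replicate wells are pooled at the spheroid level.

Degenerate inputs are handled explicitly: zero pooled variance with equal
means gives p = 1; with unequal means, an essentially-zero p flagged
`degenerate`.

### Multi-arm experiments and effect recovery

`simulate_treatment_arms()` generates one well per arm from the *same*
configuration and seed, so each arm applies its effect to the same base
population — a paired design in which the treatment is a transformation of
the population the control well would have had. Under this design the
recovered fold of mean volumes is exact up to filter-boundary losses; with
fully independent draws per arm the fold estimate at n = 150 spheroids/arm
carries ≈15% sampling CV, which is worth remembering when planning real
replicate counts. The validation suite recovers a generated volume fold of
1/3 within [0.30, 0.37] and flags the control-vs-combination contrast at
p < 0.001 across 100 simulated experiments, and the four generated arm
means rank in the generated order.

## Numerical and problem-size choices

Default test and validation wells use a 2,400² px mosaic with 150
spheroids, 3 × 3 tiles and ±2 px jitter; Monte-Carlo checks use 100
replicates (1,000 for coverage, 10,000 for the type-I error of the t test).
These sizes make the whole validation suite run in about two minutes while
keeping every estimate's Monte-Carlo error well inside the asserted
tolerances. Intensities are 16-bit integers end to end; rasters are `[y, x]`
matrices with the pixel-centre convention (pixel `(0,0)` at top-left, x
rightward, y downward, centres at half-integers), and all public
coordinates are in µm via `calibration_profile()`.

## Known limitations

* The detector is specified for dark-on-bright, roughly circular objects;
  heavily non-convex aggregates ("unshaped" colonies that never compact
  into spheroids) are outside the data model.
* The volumes-add cell-number model ignores packing fraction and cell-size
  dispersion; treat absolute counts as model-based estimates.
* Registration is translation-only at integer pixels; sub-pixel stage
  errors, rotation and illumination gradients are not modelled or
  corrected.
* ATP-based viability in co-cultures is biased by effector-cell ATP; the
  package reproduces the direction of that bias in simulation and reports
  OD-based viability as the unbiased alternative.
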