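---
title: "Quantifying nuclear blebbing from lamin-stained images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nuclear blebbing from lamin-stained images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucmorph)
```

## The problem

Cells carrying lamin defects — most prominently fibroblasts from
Hutchinson–Gilford progeria patients, but also aged cells from healthy donors
— show *nuclear blebbing*: protrusions and invaginations of the nuclear
envelope. The conventional readout is a manual blind count of "blebbed"
nuclei, which is slow, binary, and observer-dependent. `nucmorph` implements
an automated alternative: it extracts each nucleus boundary from an
anti-lamin A/C immunofluorescence image at sub-pixel resolution, computes the
signed curvature along the boundary, and condenses blebbing into a continuous
per-nucleus statistic, the **mean negative curvature (MNC)** — the absolute
value of the mean of all concave (negative) boundary curvatures, with convex
curvature excluded. Populations are then compared with heat maps, shape-metric
clustering, and one-tailed unequal-variance (Welch) t-tests.

## The extraction pipeline

Boundary extraction follows a fixed sequence, with every numeric parameter
exposed in `pipeline_config()` and defaulting to the method's published
operating point:

1. **Adaptive equalization** (`equalize_adaptive`): contrast-limited adaptive
   histogram equalization on an 8 × 8 tile grid with clip limit 0.02 and a
   Rayleigh target distribution (shape parameter 0.4, our choice; the method
   names the distribution but not its parameter). Tile mappings are blended
   bilinearly. The Rayleigh inverse CDF is scaled so the top of the histogram
   maps exactly to the top of the intensity range.
2. **Otsu binarization** (`binarize_otsu`) of the equalized image, using a
   256-bin histogram over the representable range regardless of bit depth.
   Binarizing the equalized rather than the raw image follows the stated
   processing order; the raw-image alternative would be more robust on
   frames dominated by empty background (see *Limitations*).
3. **Region cleaning** (`clean_regions`): 8-connected labeling, hole filling
   (4-connected background), removal of regions touching the frame border or
   smaller than 800 px².
4. **Hull construction** (`build_hulls`): each region is eroded by a disk of
   radius 3 and dilated by radius 6 (disks rasterized as center-distance ≤ r);
   the convex hull of this smoothed, enlarged region is the *outer* limit for
   the boundary search. A further erosion by radius 2 — applied to the
   smoothed region, per the method's stated order — gives the *inner* hull
   used to initialize the active contour.
5. **Near-binarization** (`near_binarize`): the raw frame is contrast-stretched
   (1% saturation at both ends), pixels outside the outer hull are zeroed, the
   crop is stretched again, an Otsu threshold T is computed but *not* applied;
   pixels below 0.7 T go to the minimum intensity, above 1.3 T to the maximum,
   the mid-range is stretched linearly, and gray-scale holes (intensity basins
   enclosed by brighter pixels) are filled by morphological reconstruction.
   This turns the rim-stained nucleus into a near-uniform bright blob with a
   single strong edge at its periphery.
6. **GVF snake** (`compute_gvf`, `evolve_snake`): the gradient vector flow
   field of the near-binarized crop (80 diffusion iterations, regularization
   mu = 0.2 — the standard value of the cited formulation, which leaves mu
   unstated here) provides the external force, normalized to unit vectors. The
   inner hull is interpolated and deformed semi-implicitly,
   `x <- (K + gamma I)^-1 (gamma x + kappa F)`, with tension alpha = 0.02,
   rigidity beta = 0.05, step size gamma = 1 and force weight kappa = 0.6, in
   batches of 75 deformations with re-interpolation between batches (vertex
   spacing kept within [d_min, d_max] = [0.5, 2] px). Evolution stops when the
   enclosed area changes by at most 10 px² between batches, or at 50,025 total
   deformations (667 batches — consistent with reading "deformed 75 times" as
   75 vertex updates per convergence check). Vertices escaping the outer hull
   are projected back onto it after each batch. The final contour is resampled
   to constant side length d_min = 0.5 px; because pure arc-length resampling
   leaves chords shorter than the arc step at sharp bleb corners, the resample
   is iterated (corner-cutting at the 0.5 px scale, two orders of magnitude
   below the curvature-fit scale) until all sides are within 10% of d_min.

Interactive curation is replaced by `curate()`: contours containing any point
of a user-supplied exclusion list are dropped.

## Shape measures

`signed_curvature()` fits, at every boundary point, the circle through that
point and the two points 25 boundary points away (12.5 px of arc at the
0.5 px output spacing); curvature is the reciprocal circumradius, positive
where the boundary turns left (convex, for the counter-clockwise contours the
package produces) and negative in concavities; collinear triples give 0. The
25-point offset sets the smoothing scale of the analysis: dents shallower
than roughly `1 - cos(12.5 / R)` of the local radius are smoothed away, and
MNC values are therefore comparable only between analyses using the same
pixel size and offset.

`metric_table()` assembles the 15-measure panel per nucleus: MNC, the
standard deviation of negative curvatures, the largest negative-curvature
magnitude, mean positive curvature, invagination count (maximal cyclic runs
of strictly negative curvature; zeros interrupt runs), area, perimeter,
equivalent diameter, convex-hull area and perimeter, solidity (area /
hull area), tortuosity (perimeter / hull perimeter — not defined by the
original method; chosen because it is dimensionless, scale-invariant, ≥ 1,
and co-clusters with the blebbing measures), eccentricity of the
moment-equivalent ellipse (from exact polygon moment integrals, so a circle
gives 0 and a degenerate collinear contour exactly 1), and the mean and
standard deviation of the staining intensity inside the polygon.

Profiles are aligned by `rotate_to_start()` so index 0 is the boundary point
farthest from the centroid, and `heatmap_matrix()` stretches each profile to
a common length (200 rows by default) by normalized arc position, clips
curvature magnitudes at ±0.15 px⁻¹ for display (the cut-off is applied only
in visualization, never before computing MNC), and orders nuclei left to
right by increasing MNC.

`welch_t_one_tailed()` performs the group test exactly as the original
analysis: a one-tailed two-sample t-test assuming unequal variances, raw
p-values with no multiple-comparison correction. `metric_clustering()`
computes the Pearson correlation matrix of the measures (Spearman behind a
flag) and clusters them with average linkage on the distance 1 − |r|.

## Synthetic data: what it emulates and what it does not

No images from the original study are available, so validation rests on the
`synthetic_nuclei` generator. A nucleus outline is a star-convex polar curve:
an ellipse (axis ratio 1–1.4 by default) carrying `bleb_count` wrapped-
Gaussian inward dents of relative depth `bleb_depth` and angular width 0.15
rad. `render()` paints the outline as a lamin-like rim image — a 3 px rim at
intensity 40,000 extending inward from the boundary, interior at 35% of the
rim, background 2,000, Gaussian noise (sd 1,500), 16-bit — with a 1 px linear
ramp centered on the true boundary, so the image gradient peaks exactly on
the ground-truth contour. Distances are radial (exact for these star-convex
shapes). Default sizes (radius 22–30 px) correspond roughly to a 15 µm
fibroblast nucleus imaged with a 40× objective and 2 × 2 binning, and are
comfortably above the 800 px² region filter.

Per-nucleus RNG substreams are derived from the population seed and the
nucleus index, so enlarging a population never reshuffles existing nuclei.
Blebs are modeled as invaginations because MNC measures concavity; outward
protrusions (which score as blebs through their flanking concavities) can be
obtained by negating the depth at generation time in a custom `shape_spec`.

The generator does **not** emulate optics (no point-spread function, no
photobleaching), intensity heterogeneity along the rim, touching or
overlapping nuclei, or structured cytoplasmic background. Passing the
package's tests therefore demonstrates that the implementation recovers known
geometry from rim-like images under Gaussian noise — not that segmentation
is robust to every real-world artifact; on real data the curation step
remains important.

## Validation experiments and problem sizes

The test suite validates, at the published parameter values:

- analytic anchors — eccentricity 0 for a circle and exactly 1 for a line
  segment; curvature 1/R within 1% on circles of radius 20–80 px; the
  discrete turning number Σ κΔs within 2% of 2π on smooth shapes;
- definitions — MNC of {−0.1, −0.3, +0.2, +0.5} = 0.2; MNC 0 for convex
  contours; invagination count k for k-lobed flowers r = R(1 + a cos kθ),
  k = 2..6 at a = 0.25 (at a = 0.2 the k = 2 valley has exactly zero
  curvature — analytically degenerate — and counts as no invagination under
  the zero-is-non-negative convention);
- recovery — disk radii within 2% and areas within 3% on noiseless and
  5%-noise rims; the 800 px² / border region filter;
- population behavior — two 100-nucleus populations whose mean bleb depth
  differs two-fold (uniform depths 0.05–0.15 vs 0.10–0.30) give one-tailed
  Welch p < 0.001 on extracted MNC in ≥ 90% of 20 replicates; identical
  shape distributions at 1, 4 and 9 nuclei per frame (36 nuclei each, 10
  replicates) give pairwise p > 0.05 in ≥ 90% of comparisons; in a population
  where size and bleb depth vary independently, MNC, the negative-curvature
  spread and tortuosity cluster apart from area and perimeter;
- determinism — a pipeline rerun on identical inputs produces a byte-identical
  `metrics.csv`; extraction contains no randomness.

These sizes (hundreds to a few thousand synthetic nuclei per experiment) keep
the full suite to a few minutes while leaving the statistical checks
well-powered.

## Numerical choices and edge cases

- Connectivity: 8-connected foreground, 4-connected background (holes).
- Coordinates: (x, y) = (column, row), 0-based, pixel centers at integers;
  matrices are indexed `[y + 1, x + 1]`.
- Orientation: contours are normalized to counter-clockwise (positive
  shoelace area); curvature signs follow from the cross product of the
  flanking chords.
- A constant image is returned unchanged by the contrast stretch and rejected
  by Otsu; a nucleus whose hull interior has no contrast is skipped with a
  warning; a snake collapsing below a 1.5 px perimeter rejects the nucleus.
- Degenerate (zero-area) contours fall back to point-set moments for
  eccentricity (giving exactly 1 for collinear points) with a warning.
- Ties in the farthest-point rotation break to the lowest original index.
- Physical calibration: `metrics$pixel_size` rescales lengths, areas and
  curvatures; all defaults are pure pixel units, as in the original analysis.

## Limitations

- CLAHE amplifies background noise in tiles containing no nucleus. On frames
  whose area is mostly empty background, the Otsu threshold can land inside
  the (equalized) background distribution; thresholded noise then percolates
  into large regions that touch the border and can swallow genuine nuclei.
  Dense fields, lower-noise acquisitions, or binarizing the raw image instead
  (the documented alternative to the stated processing order) avoid this.
- MNC depends on pixel size and on the 25-point curvature offset; compare
  only within one imaging and analysis configuration. Solidity is the
  scale-robust alternative among the correlated measures.
- Touching or overlapping nuclei are not split; the intended workflow removes
  them via the exclusion list, as in the original interactive curation.
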