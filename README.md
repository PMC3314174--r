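# nucmorph

Automated, high-throughput quantification of nuclear shape from fluorescence
microscopy images of lamin-stained nuclei.

Abnormal nuclear shape ("nuclear blebbing") is the cellular hallmark of
Hutchinson–Gilford progeria syndrome and appears in normally aged cells; drug
studies (farnesyltransferase inhibitors, rapamycin and its analogs) score
treatment efficacy by how much blebbing decreases. The traditional readout —
manual blind counting of blebbed vs normal nuclei — is binary, slow and
observer-dependent. `nucmorph` replaces it with a continuous, unbiased
measurement for whole cell populations.

## What it computes

For each nucleus the package extracts the boundary from an anti-lamin A/C
immunofluorescence image with a gradient-vector-flow (GVF) active contour:
CLAHE (8×8 tiles, clip limit 0.02, Rayleigh target) → Otsu binarization →
hole filling and removal of border-touching or < 800 px² regions → per-region
convex hulls (erode r=3 / dilate r=6 for the outer limit, a further erode r=2
for the snake initialization) → near-binarization (pixels < 0.7·T to the
minimum, > 1.3·T to the maximum, T the Otsu threshold; mid-range stretched;
gray-scale holes filled) → GVF snake (80 GVF iterations; d_min 0.5, d_max 2;
α 0.02, β 0.05, γ 1, κ 0.6; 75 deformations per convergence check against a
10 px² area tolerance, at most 50,025 deformations), output as a closed
polygon with sides of constant length d_min.

The signed boundary curvature κ is estimated at every boundary point by
fitting a circle through the point and the two points 25 boundary points away
(κ = 1/R, convex positive, concave negative). Blebbing is summarized by the
**mean negative curvature**

    MNC = | mean { κ_i : κ_i < 0 } |        (0 if the boundary is convex)

together with a 15-measure panel (area, perimeter, invagination count,
eccentricity of the moment-equivalent ellipse, solidity = area / convex-hull
area, tortuosity, intensity statistics, …). Population-level outputs are
MNC-sorted curvature heat maps, average-linkage clustering of the measures on
the distance 1 − |r|, and one-tailed unequal-variance (Welch) t-tests between
groups.

A synthetic-nucleus generator (`shape_spec`, `render`,
`generate_population`) produces lamin-rim-like 16-bit images with analytic
ground truth, so the whole pipeline is testable without microscopy data.

## Worked example

Two synthetic populations whose mean bleb depth differs three-fold:

```r
library(nucmorph)

deep <- list(radius = c(22, 30), axis_ratio = c(1, 1.4),
             bleb_count = c(2L, 5L), depth = c(0.15, 0.3), width = 0.15)
shallow <- modifyList(deep, list(depth = c(0, 0.1)))

blebbed <- generate_population(30, seed = 7, nuclei_per_frame = 4, shape_dist = deep)
smooth  <- generate_population(30, seed = 8, nuclei_per_frame = 4, shape_dist = shallow)

mnc_of <- function(pop) unlist(lapply(pop$frames, function(fr) {
  cc <- extract_nuclei(fr)
  vapply(cc, function(ct) mean_negative_curvature(signed_curvature(ct, 25)), numeric(1))
}))

a <- mnc_of(smooth); b <- mnc_of(blebbed)
welch_t_one_tailed(a, b, "less")
```

prints (`p = 5.73e-13`; one blebbed nucleus of 30 is lost to the region
filter):

```
smooth:  n = 30, mean MNC = 0.0005 px^-1
blebbed: n = 29, mean MNC = 0.0290 px^-1
one-tailed Welch: t = -12.01, df = 28.5, p = 5.73e-13
```

MNC is in 1/pixel: the smooth population's concavities are nearly absent,
while the blebbed population averages ~0.03 px⁻¹ — concave arcs with a ~34 px
radius of curvature. Per-nucleus metrics for one extracted boundary:

```r
cnt <- sample_shape(shape_spec(25, bleb_count = 3, bleb_depth = 0.25, center = c(45, 45)))
img <- render(cnt, render_spec(seed = 1), frame_size = c(90, 90))
cc  <- extract_nuclei(img)
metric_table(cc[[1]], signed_curvature(cc[[1]], 25), img)
#>      mnc  invaginations  area      perimeter  eccentricity  solidity  tortuosity
#>   0.0298              3  1844.68     165.12         0.0747    0.9497      1.0471
```

The three rendered invaginations are recovered, solidity < 1 and
tortuosity > 1 reflect the dents, and the near-circular base shape gives a
small eccentricity.

An end-to-end run over a directory of TIFF/PNG frames (group labels from
subdirectory names) writes `contours.json`, `metrics.csv`, `heatmap.csv/png`,
`summary.csv` and `stats.json`:

```r
run_pipeline("images/", "results/")
```

or from the shell via the thin CLI wrapper
`Rscript inst/cli/nucmorph.R run --input images/ --out results/` (subcommands:
`simulate`, `extract`, `metrics`, `heatmap`, `compare`, `cluster`, `run`).

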