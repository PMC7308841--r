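# phenocloud

Desk-scale tools for evaluating structure-from-motion (SfM) plant
phenotyping: from an organ-segmented 3D point cloud of a potted plant,
`phenocloud` extracts the classic morphometric trait set and scores it
against reference measurements with weighted goodness-of-fit statistics. A
built-in synthetic plant generator with exact ground truth replaces the
camera/SfM front end, so the entire pipeline can be exercised and validated
without a turntable, a camera, or photogrammetry software.

## Who it is for

Researchers building or validating low-cost image-based phenotyping
platforms (turntable + RGB camera + multi-view reconstruction) who need a
reproducible way to (a) turn segmented plant clouds into trait tables and
(b) quantify how acquisition choices — how many images, at what resolution —
propagate into per-trait reconstruction error.

## The traits and how they are computed

For a cloud partitioned into principal stem, petioles/branches and single
leaves (gravity-aligned, z-up, metres):

- **Plant height `PH`** and **branch insertion heights `BH`** (cm): the
  straight-line Euclidean distance
  `H = sqrt((x_i - x_1)^2 + (y_i - y_1)^2 + (z_i - z_1)^2)` from the lowest
  point of the whole cloud (`p1`) to the highest stem point (`p3`) or the
  lowest point of each branch (`p4_j`).
- **Stem diameters `BD`, `HD`, `AD`** (mm): points inside a ring of fixed
  radius centred at `p1`, the mid-height stem point `p2`, and `p3` are
  selected; the diameter is `min(rangeX, rangeY)` of the selection (a
  `half_range` mode preserving the literal halved formula is available).
- **Branch inclination `BI`** (deg): angle between the branch's oriented
  principal axis and the zenith (a literal plane-based mode is available).
- **Leaf inclination `LI`** (deg): angle between the normal of the
  total-least-squares plane through the leaf and the zenith, in [0, 90].
- **Leaf area `LA`** (cm²): area of the 2D convex hull of the leaf points
  projected onto their fitted plane (interior voids included).

Observed-vs-predicted trait tables are scored per trait with R², the
relative RMSE `rRMSE = RMSE / mean(O) x 100`, and
`AIC = 2k - 2 ln(L̂)` under a Gaussian residual likelihood; every index is
down-weighted by the missing-value fraction, `Sw = S (1 - mv/n)`, and the
weighted rRMSE is banded as excellent (≤ 10%), good (≤ 20%), fair (≤ 30%)
or poor.

Supporting steps are included: ASCII PLY/XYZ cloud I/O, marker-based metric
rescaling, supervised colour-threshold background masking of RGB images,
and k-nearest-neighbour statistical outlier removal.

## Worked example

```r
library(phenocloud)

spec <- synthetic_plant_spec("tomato_like", seed = 3)
gp   <- generate_plant(spec, density = 150)   # points per cm^2
rec  <- extract_traits(gp$plant)
rec
#> <trait_record 'plant'>
#>   PH  (cm) : 36.04
#>   BH  (cm) : 12.81, 19.11, 21.79, 24.52, 29.88
#>   D   (mm) : BD 9.61 | HD 7.04 | AD 4.61
#>   BI (deg) : 57.55, 47.08, 46.77, 47.52, 50.02
#>   LI (deg) : 20.62, 5.56, 20.25, 27.45, 25.77
#>   LA (cm2) : 36.96, 22.34, 35.25, 54.54, 49.13
gp$truth
#> <trait_record 'tomato_like_seed3'>
#>   PH  (cm) : 36.05
#>   BH  (cm) : 12.76, 19.10, 21.72, 24.52, 29.87
#>   D   (mm) : BD 9.63 | HD 6.98 | AD 4.58
#>   BI (deg) : 57.50, 47.06, 46.65, 47.52, 49.98
#>   LI (deg) : 20.61, 5.62, 20.15, 27.38, 25.80
#>   LA (cm2) : 37.07, 22.48, 35.39, 54.62, 49.27
```

At dense noiseless sampling every trait of this 36 cm herb is recovered to
within a few tenths of a percent of its construction value. Degrading the
cloud the way poorer acquisition would, and scoring against truth:

```r
g <- evaluate_grid("tomato_like", quantities = c(30, 45, 90),
                   qualities = c("L", "M", "H"), reps = 10, seed = 2024)
subset(g, quantity == 30 & quality == "L",
       select = c(trait, rrmse, band))
#>    trait      rrmse      band
#>       BH  1.0254769 excellent
#>       BI  0.4141188 excellent
#>        D 50.3775630      poor
#>       LA 16.4411764      good
#>       LI  0.8808650 excellent
#>       PH  1.0645104 excellent
```

Heights and inclinations survive the sparsest/noisiest setting almost
untouched, leaf areas degrade to "good", and the small stem diameters —
estimated from coordinate ranges of thin ring selections — collapse to
"poor": the characteristic ordering of SfM trait reconstruction difficulty.

A command-line wrapper over the same functions is installed as
`exec/phenocloud` (subcommands `simulate`, `degrade`, `mask`, `filter`,
`extract`, `evaluate`, `grid`).

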