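---
title: "Morphometric trait extraction from plant point clouds: models, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometric trait extraction from plant point clouds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenocloud)
```

## Scope and assumptions

`phenocloud` operates downstream of multi-view reconstruction: its input is
a dense, organ-segmented point cloud of a single potted plant. Three
contracts are assumed rather than estimated:

- **Gravity alignment.** Clouds are z-up; the zenith is `(0, 0, 1)`. All
  inclination angles are referenced to this global vertical. Automatic
  gravity estimation is deliberately out of scope — on a turntable platform
  the vertical is fixed by the ground-control markers.
- **Metric scale.** `rescale_with_markers()` reduces scaling to the minimal
  sufficient contract: one designated marker pair with a known metric
  separation. Additional pairs with known distances are accepted purely as
  a consistency check (a warning fires when implied scales disagree by more
  than 1%, the level at which scale error becomes visible next to the
  few-percent trait errors this package measures).
- **Segmentation as input.** Organ membership (stem, indexed
  petioles/branches, indexed leaves) is supplied, not inferred. Invalid
  partitions (overlaps, out-of-range indices, empty stem) raise errors and
  are never silently repaired, because a repaired segmentation would
  silently shift every downstream trait.

## Trait definitions and their consequences

**Heights.** `PH` and `BH` are *straight-line Euclidean* distances from the
lowest cloud point, not vertical drops. A stem tilted 10° from vertical
with a 45 cm axis reports 45 cm, not 44.3 cm. This follows the height
simulation convention of turntable SfM studies; no verticality correction
is applied, and none should be added without changing the reference
protocol (a tape measure along the stem follows the same convention).
Note that `p1` is the lowest point of the *whole* cloud: a leaf drooping
below the stem base legitimately becomes the height origin.

**Stem diameters.** Ring selections default to a horizontal *slab*
(`|z - centroid_z| <= r`), which preserves the horizontal cross-section
whose x/y coordinate ranges define the estimate; a spherical `ball` mode is
available. The default radius is 5 mm and is meant to be set per species —
thick enough to catch a few hundred points at working densities, thin
enough that stem taper inside the slab stays below the sampling error.
The diameter itself is `min(rangeX, rangeY)`. The halved variant
`min(rangeX/2, rangeY/2)` is retained as `mode = "half_range"` because the
formula is sometimes printed that way; on a fully sampled circular
cross-section the halved form returns the radius, which synthetic cylinder
tests flag immediately, so `"range"` is the default and the choice is
recorded in the extraction configuration. Two properties of the range
estimator matter for interpretation: it is axis-aligned (not invariant
under rotation about z, unlike every other trait), and under additive
noise it is an extreme-value statistic whose positive bias grows with both
noise and point count. This is why diameters are structurally the weakest
trait in every experiment below.

**Inclinations.** Leaf inclination is the zenith angle of the
total-least-squares plane normal, folded into [0, 90] so the normal's sign
is immaterial. Branch inclination defaults to the *oriented principal
axis* of the branch points — well defined for elongated organs — with the
orientation fixed from the branch end nearest the stem centroid toward the
far end, giving angles in [0, 180] (a drooping branch reads > 90°). The
literal plane-based reading (90° minus the plane-normal zenith angle) is
kept as `mode = "plane"`. Plane fits are SVD-based; the normal sign is
fixed (non-negative z, then x, then y) for reproducibility. Fits whose
second singular value vanishes (collinear organs) are degenerate and yield
explicit missing values.

**Leaf area.** Leaf points are projected onto their fitted plane and the
2D convex hull area is reported. The hull *includes interior voids* by
construction — holes in the reconstruction do not reduce the area — and
correspondingly overestimates lobed or strongly concave laminae; a
non-convex (alpha-shape) variant is a documented non-goal. Whether to hull
in 3D or in the projected plane is genuinely open in the source protocols;
the projected 2D hull is implemented as the geometrically meaningful area
of a lamina, and for a curled blade it measures the *projected outline*,
consistent between ground truth and extraction.

**Missing values.** Per-organ failures (too few ring points, degenerate
fits, emptied organs after degradation) become `NA`s with logged reasons,
never aborted records. The count feeds the `Sw` weighting so an incomplete
reconstruction is penalised rather than silently truncated.

## Goodness-of-fit conventions

`r_squared()` defaults to `1 - SS_res/SS_tot`; the bare ratio (perfect fit
= 0) is preserved as `mode = "literal"` and the two always sum to one.
`aic()` needs a likelihood that the observed-vs-predicted setting does not
itself supply; the standard choice is implemented: Gaussian residuals at
the maximum-likelihood variance, `-2 ln(L̂) = n ln(2π σ̂²) + n`, with
`k = 1` (the residual variance) by default, both recorded in the output. A
zero-residual series returns an explicit `-Inf` sentinel with a warning.
The `Sw = S(1 - mv/n)` adjustment is applied multiplicatively to all three
indexes, including AIC, as the literal reading of the weighting protocol;
since AIC is lower-is-better, `weight_aic = FALSE` exempts it. Accuracy
bands close boundaries exactly as printed: 10.0 is excellent, 30.0 is fair.

## What the synthetic generator emulates

Three canopy archetypes cover the platform's test species geometrically:

- `maize_like` — erect monocot: single tapered stem, sessile ribbon leaves
  with a curl parameter (the tangent's zenith angle grows linearly along
  the blade by `curl x 90°`);
- `tomato_like` — petiolate herb: petioles at 40–70° from the zenith, each
  bearing one mildly curled ribbon leaf;
- `olive_like` — woody evergreen: taller stem, long branches, small *flat*
  elliptical leaves (curl fixed at 0).

Default dimensions are drawn per seed from ranges typical of young potted
plants of these habits (herbaceous heights of tens of cm, a ~1 m woody
plant, basal ≥ half ≥ apical stem diameter). Surfaces are sampled
uniformly per unit area, with lamina margins sampled at the matching
linear density — a reconstructed leaf has a silhouette edge, and a hull
over interior-only samples would be biased low by more than the area
tolerance being verified.

Ground truth is *analytic* wherever construction permits (heights from the
ideal extreme surface points, diameters from the control cross-sections,
inclinations of straight organs and flat leaves, elliptical areas `πab`).
Curled laminae have no closed-form plane-fit angle, so their `LI`/`LA`
truth comes from a deterministic fine regular mesh at 10x the sampling
density, flagged `"oracle"` with the mesh density recorded. One genuine
instability is worth knowing: a narrow, strongly curled blade whose
cross-blade extent matches its curl sag has nearly tied second and third
principal axes, and its fitted "plane" — in truth and extraction alike —
is then sensitive to sampling. This mirrors the real difficulty of
assigning an inclination to curled monocot leaves and is why flat-leaf
archetypes anchor the strict recovery tolerances.

**Degradation.** Image *quality* (the platform's 4.88/6.52/9.77 µm/pixel
levels) is emulated by the `H`/`M`/`L` presets as jointly lower sampling
density (160/80/40 points cm⁻²) and larger isotropic point noise
(0.3/0.6/1.0 mm): poorer pixel resolution costs both feature density and
depth precision, and tying the two together keeps the emulation's error
ordering aligned with the physical one (density alone would let the
extreme-value diameter bias *shrink* with fewer points). Image *quantity*
(90/45/30 images) acts in `degrade()` as visibility culling — a point
survives iff its outward normal faces at least one of `n_views` equally
spaced azimuths at a 15° camera depression angle — and, in the grid
experiment, additionally scales density by `sqrt(v/90)` (pairwise feature
matches) and noise by `sqrt(90/v)` (rays per triangulated point). With
three or more equally spaced views the half-space visibility rule alone
covers almost every outward normal, so without the density/precision
channels the view factor would be inert; all three channels are ordinal
emulations, not photogrammetric calibrations, since the true mapping from
image count and µm/pixel to cloud quality is scene-dependent.

These presets and the generator defaults are fixed design choices; they
define the study conditions under which the package's accuracy statements
hold and are not tuned per experiment.

**What passing tests do and do not show.** The synthetic plants have exact
segmentations, no occlusion by pot or neighbouring organs, no SfM drift or
doming, iid isotropic noise, and no radiometric effects. Recovery numbers
therefore validate the *extraction and scoring algorithms*, and the grid
reproduces the *qualitative* orderings (heights and straight-organ angles
easiest, small-diameter rings hardest, errors growing as inputs degrade) —
they say nothing quantitative about any real camera rig. One known
divergence: with straight synthetic petioles, inclination is recovered
essentially exactly, so angle traits score even better here than heights,
whereas real curled organs put more error into angles.

## Numerical choices

- Ties (lowest point, nearest-to-mid-z stem point, k-NN distances) break
  by smallest point index; all RNG flows through per-stage seeds derived
  from one user seed, so every artefact is a pure function of its inputs.
- `p2` is an existing stem point nearest the mid-height, not an
  interpolated point, so it can serve as a ring centroid on the cloud.
- The outlier filter computes exact k-NN mean distances in row blocks
  (never materialising the n x n matrix); the removal threshold
  `mu + alpha*sigma` uses the cloud-wide moments, defaults `k = 8`,
  `alpha = 2` — the de facto convention of photogrammetry suites.
- Colour thresholding is plain Euclidean distance in RGB against a
  user-supplied reference colour (the "supervision"), with 8-connected
  speckle cleanup; against a red panel, foliage separates in RGB without a
  colour-space transform, and the exact space/threshold of any given
  platform is configuration, not algorithm.
- Segmentation JSON uses 0-based indices for interoperability with
  point-cloud editors; everything in R is 1-based internally.

## Problem sizes used in the shipped experiments

The recovery suite runs 20 plants per archetype at 150 points cm⁻²
(roughly 50k–130k points per plant); the grid experiment uses 10
replicates of the herb archetype generated at 200 points cm⁻² and degraded
into nine cells. These sizes put sampling error well below the documented
tolerances (5% rRMSE for heights/angles, 2% for flat-leaf areas, 5% for
noiseless cylinder diameters) while keeping a full validation run on a
single CPU in minutes.

## Known limitations

- No automatic segmentation, marker detection, or gravity estimation.
- Convex-hull areas overestimate concave laminae by design.
- The range-based diameter is axis-aligned and noise-biased; it is
  faithful to the platform protocol being emulated, not a recommendation.
  A robust alternative (e.g. cross-section circle fitting) would change
  the trait definition and is out of scope.
- Binary PLY and mesh I/O are not supported; clouds are ASCII by design to
  keep artefacts inspectable and diffable.
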