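---
title: "Signet ring cell morphometry: models, conventions and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signet ring cell morphometry: models, conventions and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of what it computes and why the
defaults are what they are. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The measurement model

Input is a pair of instance label images of identical shape — one for
cells, one for nuclei — or a 4-class semantic mask (background / cell /
nuclei / instance boundary) that `semantic_to_instances()` converts first.
All coordinates in the package are 1-based (row, col) matrix indices, the
native R convention; CSV outputs carry the same convention.

Four per-cell properties are measured:

* **SC**, cell area: the raw pixel count of the instance mask. No smoothing
  or hole filling is applied — the mask is the measurement.
* **SN**, nucleus area: pixel count of the nucleus instance assigned to the
  cell. Assignment picks, independently for each cell, the nucleus with the
  largest pixel intersection with that cell (ties to the smallest nucleus
  id; intersections on the raw label images, no dilation). One nucleus may
  therefore serve several cells; cells intersecting no nucleus keep SC and
  EP but have missing SN and NCR.
* **EP**, ellipticity: the aspect ratio of the minimum-area rotated
  bounding box of the cell mask, oriented so that EP = short/long lies in
  (0, 1] with 1 the most round. The direction of the ratio is a convention
  this package fixes explicitly (the bounded orientation makes cutoffs and
  regressions better behaved); the opposite convention is its reciprocal.
* **NCR**: SN / SC.

### The minimum-area rectangle

`min_area_rect()` computes the convex hull of the pixel centers
(`grDevices::chull`) and applies rotating calipers: the minimal enclosing
rectangle has a side collinear with some hull edge, so scanning the hull
edges is exact. The oracle tests confirm agreement with a brute-force
rotation sweep to 1e-6 relative area.

Pixel convention: the rectangle is fitted to pixel *centers*, and each
reported side is then increased by 1 px to restore the ±0.5 px extent of
the pixels themselves. Under this convention an axis-aligned `w x h` block
reports sides exactly `(w, h)`, a single pixel reports `(1, 1)`, and a
collinear (1-px-wide) mask reports short side 1. Degenerate masks therefore
never produce zero-width rectangles, and EP is always defined.

### Semantic-mask conversion

Cell instances are connected components of the cell-or-nuclei pixels with
the boundary class removed — the boundary class is precisely what separates
touching cells. Components use 8-connectivity by default (histologic blobs
are compact; 4-connectivity is available). Component labels are renumbered
in row-major order of each component's first pixel, making labeling a pure
function of the input. Nuclei pixels inside a component form that
component's nucleus instance and share its label.

Boundary pixels are then reattributed to the geodesically nearest instance
(multi-source breadth-first search through the boundary region; ties within
a BFS round go to the smallest label), so cell areas are not biased
downward by the boundary class. This reattribution is a stated choice of
this package — segmentation pipelines differ here, and `assign_boundary =
FALSE` leaves boundary pixels unassigned instead.

## Per-slide aggregation

`summarize_slide()` reports the arithmetic mean and the sample SD
(denominator n−1) of each property; the SD is the slide's *atypia* measure,
i.e. within-slide morphological heterogeneity. SN/NCR statistics pool
nucleus-assigned cells only, with the assigned count reported alongside, so
missing nuclei reduce the SN/NCR sample rather than distorting it. The SD
flavor matters only at tiny n; at the 500-cell inclusion threshold the
n vs n−1 difference is negligible. A slide is `included` when it holds at
least `min_cells` cells (default 500, the usual stability rule for
selecting sections); the flag is informational — filtering is the caller's
decision, and the pipeline's `compare` step filters on it.

Slides are the aggregation unit. Cohorts that hold several sections per
case can pool by any key simply by relabeling `slide_id` before
aggregation.

## The cohort statistics battery

* Two-group comparisons: Welch t-test by default (slide-level variances
  differ routinely between groups), pooled-variance optional, and the
  Mann–Whitney U with normal approximation (tie-safe). Note that rank
  tests cannot reach p < 0.01 below about 7 observations per group — at
  n = 3 + 3 the smallest attainable two-sided p is 0.1.
* Multi-group: Kruskal–Wallis with tie correction; Tukey HSD on the
  one-way ANOVA fit supplies pairwise adjusted p-values. No further
  multiplicity correction is applied by default.
* **Youden cutoff**: candidates are the midpoints between consecutive
  distinct scores plus the two all-positive/all-negative extremes, under
  the one-directional rule "positive if score ≥ cutoff";
  J = sensitivity + specificity − 1 is maximized, ties to the smallest
  cutoff. Being one-directional, a variable whose sample effect runs the
  other way has max J = 0 and dichotomizes degenerately; `forest_table()`
  excludes such variables with a logged reason rather than silently
  flipping the direction.
* **Logistic regression**: `binary_logit_hr()` reports exp(coefficient)
  with Wald 95% CIs. The column is called `HR` because that is the label
  this style of forest plot conventionally prints, but the quantity is an
  odds ratio from a logistic model — no time-to-event analysis is involved.
  The default method is maximum likelihood; complete or quasi-complete
  separation is detected (per-SD coefficient magnitude, plus glm's own
  warnings) and flagged as an infinite/zero HR with a warning rather than
  an error. `method = "firth"` fits Firth's bias-reduced penalized
  likelihood, which stays finite under separation; on a saturated 2x2
  table it equals the Haldane (+0.5 per cell) corrected odds ratio, which
  the tests use as its closed-form oracle.
* **Forest tables** default to the Firth method. The reason is structural:
  dichotomizing at an in-sample optimal cutoff concentrates the two groups
  on opposite sides of the threshold, so with cohorts of tens of slides the
  resulting 2x2 table frequently has an empty cell, where the ML odds
  ratio diverges and its Wald p-value is useless. Firth keeps every row
  finite and testable; the classical fit remains available.
* **Ordinal regression**: `ordinal_logit()` fits the cumulative-logit
  proportional-odds model logit P(Y ≤ j | x) = ζ_j − x′β by Newton
  iterations on the analytic gradient (Hessian by numerical
  differentiation), converging to |gradient| < 1e-9. It is implemented in
  package because the obvious library routine declines 2-level outcomes,
  and the 2-level case — where the model *is* binary logistic — is a
  required consistency check: the tests verify coefficient agreement with
  `glm` to 1e-6, and agreement with `MASS::polr` at 4 levels.
* In-sample cutoffs: Youden cutoffs are derived on the same cohort they
  are tested on, which biases J and the dichotomized effect optimistically.
  This mirrors common practice for descriptive forest plots; confirmatory
  use needs a held-out split, which the building blocks support but the
  pipeline does not automate.

Significance language in the pipeline uses α = 0.05, configurable.

## The synthetic scene generator

`generate_scene()` emulates the geometry a segmentation network would
output for a signet-ring field, not its appearance: non-overlapping
elliptical cells, each holding one eccentric nucleus, rasterized into
paired label masks with exact ground truth.

Sampling laws: cell areas are lognormal (positive and right-skewed, as
histologic areas are), parameterized directly by their natural-scale mean
and SD; aspect ratio and NCR are Gaussian clipped into (0.1, 1] and
(0.01, 0.9). Defaults describe a plausible ×40 field at 0.238 µm/px: mean
cell area 2000 px (~113 µm², a ~12 µm cell), aspect 0.75 ± 0.08, NCR
0.15 ± 0.04. The published atypia SDs of ellipticity (~0.10) sit inside the
range the generator can produce, but the generator's defaults are chosen
for testability, not fidelity to any cohort — the underlying per-cell
distributions of real cohorts are not available.

Placement is rejection sampling: a candidate position is rejected if any
pixel is already occupied ("overlap" = any shared pixel); after 1000
failed draws for one cell, generation stops with an error naming the
achieved count. Auto-sizing targets cells covering ~10% of the image,
comfortably below where rejection sampling starts to jam. The nucleus is a
scaled copy of the cell ellipse (area ratio = sampled NCR) displaced along
the major axis by `nucleus_eccentricity` times the free margin
`a(1 − sqrt(NCR))`, so the nucleus is contained by construction and the
sampled NCR survives rasterization unbiased; displacing by a fraction of
`a` itself and clipping to the cell would shrink SN below its sampled
value. An optional crescent mode carves a central mucin-vacuole ellipse
out of the nucleus.

Reproducibility: each slide of a cohort draws from its own RNG stream
derived from (master seed, slide index), so cohorts are reproducible slide
by slide and identical seeds give bit-identical masks.

`generate_cohort()` adds the cohort layer: named groups with their own
distributions and covariate labels, and optional per-slide Gaussian jitter
of named parameters (`slide_jitter`). Jitter is off by default — group
effect sizes in the truth tables then equal the configured values exactly —
but the demo cohort enables it (aspect-ratio SD jittered with SD 0.03
against a 0.06 vs 0.12 group shift, a standardized effect of ~2) because
real patients vary: without between-slide heterogeneity every within-group
slide summary is nearly identical and any group effect separates
completely, which no finite-sample estimator reports sensibly. Realized
per-slide parameters are recorded in `slide_params`. `render = FALSE`
skips rasterization and returns truth-level draws from the same sampling
law, which is what the replicate-heavy power and type-I simulations use.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: H&E texture and staining variation, touching or
overlapping cells (the boundary class is exercised with hand-built
fixtures instead), segmentation errors (false merges/splits, ragged
contours), non-elliptical cell outlines, and spatial clustering of tumor
cells. Results on synthetic cohorts validate the *measurement and
statistics machinery*, not any claim about biology.

## Heatmaps and FROC

`gaussian_map()` floors full-resolution centers onto the thumbnail grid,
accumulates multiple cells per pixel, and convolves with an isotropic
Gaussian (default SD 2 thumbnail px — a value chosen for legibility, as no
standard exists), truncated at 4σ, unit mass, zero-padded borders. The
displayed map is max-normalized to [0, 1] so maps are display-comparable;
the raw density (interior mass = number of cells) is kept alongside for
quantitative use. Overlays are plain per-pixel convex blends of the
colormapped intensity over the thumbnail.

`froc_curve()` sweeps all distinct confidences. Matching is
"center-in-mask": detections are points, a detection is a true positive if
it lands in an unclaimed ground-truth instance, claiming greedily in
confidence order (so the matching at any threshold is a prefix of the
global one — verified against a per-threshold re-match oracle). False
positives are counted on benign images only, and "normal region" is
interpreted as *benign image*: the operating points are mean FPs per benign
image at 1, 2, 4, 8, 16, 32. For each target the largest recall with mean
FPs ≤ target is taken (conservative, exactly achievable on finite data, no
interpolation), and the FROC score is the mean of the six recalls.

## Numerical choices and degenerate inputs

* Empty masks error in the per-instance operations; empty scenes, empty
  detection sets and all-zero maps are valid and return empty/zero results.
* A single-cell slide has an undefined sample SD: reported as `NA` with a
  warning. All-missing NCR likewise.
* Histogram bins are equal-width over the observed range; a degenerate
  range is widened by ±0.5 so counts are always conserved.
* t-tests on zero-variance data short-circuit to (statistic 0, p 1)
  rather than erroring; Kruskal–Wallis likewise.
* 16-bit TIFF holds up to 65535 labels; PNG is refused beyond 255 labels;
  float TIFFs are rejected on read with a pointer to integer formats.
* Ties: nucleus assignment → smallest nucleus id; Youden → smallest
  cutoff; boundary reattribution → smallest label; detection matching →
  confidence, then row, then column.

## Validation problem sizes

The acceptance battery runs at sizes chosen to finish comfortably on one
CPU: 200 convex polygons for the rectangle oracle; 100 random ellipses for
area/EP recovery; 30 slides × 1000 cells (rasterized, generated one slide
at a time) for SC parameter recovery; 50 replicate cohorts of 20 + 20
slides for power and 100 replicates of 10 + 10 for type-I error at the
truth level; 200 replicates of n = 500 for CI coverage; and the bundled
demo cohort (2 groups × 10 slides × 500 cells) end to end.

## Known limitations

* **EP on small rasterized ellipses is not a sharp estimator of b/a.** The
  rectangle search is exact (it matches a brute-force sweep to 1e-6), but
  the *definition* is noisy under discretization: for a tilted ellipse
  with aspect ratio q in roughly (0.8, 0.95), the enclosing-rectangle area
  varies across angles by less than pixel discretization perturbs it (at
  semi-axes 10–40 px), so the minimizing angle is noise-driven and the
  measured EP can land anywhere between q and 1. Typical |EP − b/a| on
  random ellipses is ~0.02, but worst cases reach ~0.15–0.2. The
  corresponding acceptance check asserts a 0.05 bound and fails honestly
  on those draws; at the ~2000 px scale of whole cells the effect shrinks
  but does not vanish for near-circular cells.
* The nucleus-per-cell rule is per-cell; no global one-to-one matching is
  attempted, and shared nuclei are not deduplicated in aggregates.
* The FROC "normal region" equates to a benign image; sub-image regions
  would need their own bookkeeping.
* In-sample Youden cutoffs are optimistic (see above).
* The pipeline's chained steps regenerate their inputs from the seed
  rather than reading intermediate artifacts; for external masks, call the
  module functions (`read_masks()`, `extract_features()`, ...) directly.
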