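---
title: "Methods: image quantification and dose-response statistics for DDR reporter screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image quantification and dose-response statistics for DDR reporter screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddrscreen)
```

This vignette documents the models, parameters and numerical choices
behind `ddrscreen`, in the spirit of a methods section: what each stage
assumes, which knobs matter, and what the synthetic-data validation does
and does not demonstrate about real screen data.

## The measurement model

A DDR reporter screen produces, per well, three fluorescence channels:
Hoechst marks nuclei (the segmentation channel), GFP reports p53-pathway
activation (p53, p21 or BTG2 fused to GFP), and propidium iodide marks
dead or dying cells. 2D cultures are imaged as single planes; 3D spheroid
cultures as z-stacks of 9–11 planes at a 30 µm step. Compounds are tested
at 8 concentrations in geometric (log-equidistant) series spanning two to
three decades, with three biological replicates and solvent-control
wells.

## 2D quantification

`segment_nuclei()` implements a watershed segmentation: Gaussian
smoothing (`smoothing_sigma = 2` px), a locally adaptive foreground mask
(pixel above its 31×31 local mean by `offset_frac = 0.05` of the dynamic
range), then a watershed on the Euclidean distance transform of the mask
to split touching nuclei, and removal of objects under `min_area = 30`
px. The local-mean mask adapts to uneven illumination; the distance
transform splits touching convex objects at their waist. Two nuclei whose
centres are closer than about 1.7× their half-max radius produce a single
intensity summit and a convex joint mask; such pairs are intrinsically
unresolvable by any intensity- or shape-based criterion and count as one
object. The default watershed tolerance (1 px of distance-map depth)
trades over-segmentation of elongated nuclei against under-segmentation
of tight pairs.

`segment_cytoplasm()` is the "Distance N" construction: every nuclear
object is expanded by exactly `expansion = 6` px of Euclidean distance
(the screen protocol's value), contested pixels go to the nucleus with
the nearest nuclear pixel, and ties resolve to the lower label — a
deterministic, order-independent rule. The nuclear pixels are then
removed, leaving a ring per cell. The expansion is implemented as an
exact offset scan (all integer displacements with `dx² + dy² ≤ 36`,
visited in order of distance), so the result equals a brute-force
nearest-nucleus assignment, which the test suite verifies directly.

`measure_cells()` reports the mean GFP over nuclear pixels and over the
cytoplasm ring per cell. Which compartment is the primary readout depends
on the reporter's localisation: nuclear for p53 and p21, cytoplasmic for
BTG2; `quantify_monolayer(reporter = ...)` selects accordingly. A cell is
PI-positive when at least 10% of its nuclear area overlaps the
thresholded PI signal; the boundary is inclusive, and the overlap is
measured over nuclear area (the convention is configurable in effect by
supplying a different mask). PI thresholding defaults to Otsu's method on
the PI channel because the original protocol does not state a threshold;
a fixed value can be passed instead. Objects touching the image border
are kept by default (`exclude_border = FALSE`).

## 3D quantification

Spheroids are quantified on 2D maximum-intensity projections of each
channel: `max_project()` takes the pointwise maximum over planes, which
for a solid spheroid reproduces its equatorial cross-section. The
Hoechst projection is thresholded (Otsu by default), holes are filled —
spheroid cores can be dim in projection — and components under
`min_area = 200` px are dropped as debris. Per spheroid, the GFP mean and
the PI-positive area fraction are reported; `summarize_spheroids()` also
returns the unweighted well mean, so both per-spheroid and per-well
conventions are available. True volumetric segmentation is deliberately
out of scope: the projection approach matches how such screens are
routinely analysed and is validated against spheres of known geometry.

## The point of departure (PoD)

Responses (by default fold changes relative to the solvent-control mean)
are fitted by loess — locally weighted linear regression, tricube
weights, degree 1, `span = 0.5` — against log10 concentration. Solvent
controls sit at concentration zero, whose log is undefined; they are
excluded from the fit and used only to define the control band. The PoD
is the lowest concentration at which the fitted curve leaves the band
`control mean ± 2 · control SD`, in either direction. Numerically, the
fitted curve is evaluated on a 512-point log-spaced grid over the tested
range and the crossing is interpolated linearly in log10 between the
bracketing grid points; with 512 points the interpolation error is
orders of magnitude below one dilution step, which is the resolution at
which PoDs are scientifically meaningful. If the curve is already outside
the band at the lowest tested concentration the PoD is censored there
(reported with `censored = TRUE`); if it never leaves the band there is
no PoD. No value is ever extrapolated beyond the tested range.

Two interpretive choices deserve note:

* **The span.** The protocol this package follows describes the loess
  span as "2/4", which we read as 0.5. `loess_config(span = ...)` exposes
  it; with 24 points (8 concentrations × 3 replicates) a span of 0.5 uses
  the 12 nearest points per local fit. Wider spans stiffen the curve and
  move PoDs of steep responses slightly upward; the recovery simulations
  below can be re-run at any span.
* **The band SD.** The band half-width is 2× the SD of the
  solvent-control replicate values (`sd_method = "control"`). An
  alternative reading — the residual SD of the loess fit — is available
  as `sd_method = "residual"`. The control-SD reading is the default
  because the band is meant to describe solvent-well variability, not
  lack of fit.

The number of solvent-control wells matters more than is obvious: the
band is `mean ± 2·SD` of those wells, and with few wells the SD estimate
is noisy, so flat (null) conditions are called "active" too often when
the SD happens downward. The plate-design default is 16 control wells per
condition — one full column of a 384-well plate, the standard screening
layout — at which the false-positive PoD rate on simulated null curves
is about 1–2%, versus roughly 9% with only 6 wells.

## Absolute IC50

Viability readouts (e.g. ATP luminescence) are expressed as percent of
solvent control and fitted with a four-parameter log-logistic curve whose
top plateau is fixed at 100%. The fit runs on log10 concentration
(parameters: bottom plateau, log10 midpoint, Hill slope) for numerical
conditioning, with a short ladder of slope starting values. The absolute
IC50 is the concentration where the fitted curve equals 50% of control —
not the curve's own inflection — solved in closed form from the fitted
parameters. A crossing outside the tested range is reported as censored
(`"above"` or `"below"`, with the range bound), mirroring the ">highest
tested" convention of potency reporting; a curve whose fitted bottom
stays above 50% has no absolute IC50 at all. Crossings within a 10⁻⁶
relative tolerance of a range boundary are snapped onto it, so a true
IC50 exactly at the highest tested concentration is recovered rather
than lost to floating-point jitter.

## Relative expression

`delta_delta_ct()` implements the comparative-Ct method: ΔCt = target Ct
− housekeeping Ct (GAPDH by default) per sample, ΔΔCt relative to a
reference sample, fold change 2^−ΔΔCt. Technical replicate Ct values are
averaged before ΔCt. Undetected wells propagate as flagged missing
values; imputing a Ct ceiling would silently turn "not detected" into
"strongly repressed", so it is never done.

## Profile comparison and clustering

GFP responses are min–max normalised within each culture model — the
models differ in optics and expression scale, so only within-model
rescaling makes their profiles comparable — and assembled into a
condition × feature matrix. Euclidean distances are computed between
condition profiles; for reporter-level comparisons the three reporters'
distance matrices are averaged element-wise. Hierarchical clustering
supports both complete linkage and Ward's criterion (`ward.D2`), because
screening reports use either and the two can order merges differently;
neither is privileged, and the default is complete linkage. Undefined
PoDs entering a clustering are encoded as one dilution step (10^(1/3))
above the highest tested concentration, so insensitive conditions
cluster together instead of being dropped; these sentinel positions are
flagged. Constant (zero-range) collections min–max normalise to all
zeros with a degenerate flag rather than an error.

## The synthetic-data module

The generators provide the ground truth that the analysis is tested
against:

* **Monolayers** — nuclei are anisotropic Gaussian blobs (semi-axes 5–9
  px at 512×512, a typical 20× field scale) whose half-maximum contour
  defines the ground-truth elliptical mask; centers are placed by
  rejection sampling with a minimum spacing (default 2× the maximum
  radius, so objects may touch but not coincide), and a packing failure
  after 10 000 attempts per nucleus is an error, never silent
  truncation. PI-positive nuclei are painted at a fixed bright level;
  a partial-paint mode fills an exact ceiling-rounded pixel count from
  the nucleus centre outward, which is what makes boundary tests of the
  10% rule exact. Intensities live on a 16-bit scale (0–65535),
  matching common microscopy TIFF dialects.
* **Spheroids** — solid spheres whose per-plane cross-sections follow
  the sphere equation; the PI core is concentric, so its projected area
  fraction is known exactly. Defaults (9 planes, 30 µm step, 2.5 µm/px,
  radii 35–60 px) give spheroids of 175–300 µm diameter spanning 6–10
  planes, typical of Matrigel-grown HepG2 spheroids.
* **Plates** — well-level responses follow a Hill curve
  `baseline · (1 ± (max_fold_change − 1) · hill(c))` with additive
  Gaussian noise; the analytically true onset (where the noiseless
  effect equals the 2-SD band half-width) is returned per condition, so
  PoD recovery can be scored without circularity. Either the onset or
  the EC50 may be specified and the other is derived.

What the generators deliberately do **not** emulate: point-spread
functions and optical aberrations, photobleaching, uneven illumination,
autofluorescence, cell-cycle or pharmacokinetic structure in the
response curves, and segmentation-hostile morphologies (apoptotic
fragmentation, mitotic figures). Passing the synthetic validation
therefore demonstrates that the algorithms are correct implementations
of their definitions and recover known truth under realistic noise — not
that they are robust to every artefact of real microscopy. On real data
the segmentation parameters (`smoothing_sigma`, `offset_frac`,
`min_area`) should be inspected against a few fields by eye.

## Validation scale and determinism

The shipped checks (test suite and `scripts/acceptance.R`) use: 200
simulated curves each for PoD recovery (3 replicates, noise SD 10% of
baseline, onsets log-uniform across the full 8-point range) and for null
behaviour; absolute-IC50 recovery at all 8 design concentrations,
noiseless and at 5% noise; 20 dense 512×512 monolayers of 100–300
nuclei for segmentation scoring; and brute-force oracles for the
cytoplasm expansion (quadratic nearest-pixel scan) and complete-linkage
heights (naive agglomeration on ≤ 8 leaves). These sizes keep the whole
validation under a couple of minutes on one CPU while leaving the
statistical margins wide; all generators take an explicit integer seed
and are bitwise reproducible, with the caller's RNG state restored
afterwards.

## Known limitations

* The watershed re-implementation is defined against synthetic ground
  truth, not against any particular legacy macro; parameter defaults are
  tuned for Hoechst-like nuclear staining at 20× and will need
  adjustment for other magnifications.
* PoD values inherit loess's edge variance: estimates near the lowest
  and highest tested concentrations are the least stable, which is why
  censoring at the range edges is reported explicitly.
* The absolute IC50 assumes viability declines toward a plateau; biphasic
  viability curves (e.g. hormesis) violate the log-logistic form and
  should be inspected before trusting the crossing.
* `hclust` supplies the agglomeration; on inputs with exactly tied
  distances its internal tie-breaking, not a lexicographic rule,
  determines the merge order. Results are deterministic but row-order
  invariance is only guaranteed for tie-free distance matrices.
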