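---
title: "Measuring Circle-of-Willis artery diameters from labeled segmentations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring Circle-of-Willis artery diameters from labeled segmentations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cowmeter)
```

## The measurement model

Given a labeled 3D segmentation of the Circle of Willis (CW) — an integer
volume where each artery segment carries its own code — the package produces
one diameter per artery in three steps:

1. **Local thickness.** On the binary union of all artery labels, every
   foreground voxel $p$ receives
   $$\mathrm{LT}(p) = \max\{\, 2\,d(c) : c \in \mathrm{FG},\ \lVert p - c\rVert \le d(c) \,\},$$
   where $d$ is the spacing-aware Euclidean distance from a voxel center to
   the nearest background voxel center. $\mathrm{LT}(p)$ is the diameter of
   the largest sphere that fits inside the vasculature and contains $p$.
   Thickness is computed on the *union* mask deliberately: where two
   arteries touch, the inscribed sphere may span both, which is exactly how
   contact between vessels inflates real measurements.

2. **Centerlines.** Each label is thinned independently to a one-voxel-wide
   skeleton by topology-preserving curve thinning (six directional
   sub-iterations in a fixed up/down/north/south/east/west order, sequential
   deletion with recheck). A voxel is deleted only when it is *simple* in
   the Bertrand–Malandain sense — exactly one 26-connected foreground
   component in its punctured $3^3$ neighborhood and exactly one 6-connected
   background component in its 18-neighborhood touching a face neighbor —
   and is not a curve endpoint. This guarantees that the per-label skeleton
   preserves the label's 26-connected component count. We chose this
   simple-point formulation over the octree-table medial-axis variant common
   in image libraries because its correctness conditions can be verified
   directly; the topological guarantee is the same, and the procedure is
   deterministic.

3. **Averaging.** The artery diameter is the unweighted arithmetic mean of
   local thickness over the label's centerline voxels, including
   junction-adjacent ones. Optional restriction of the average is
   deliberately not applied: the whole-length mean is the declared contract,
   and junction inflation is part of what the validation framework
   quantifies.

Two inclusion rules follow the measurement conventions of automated CW
morphometry. A posterior communicating artery (PCom) is only reported when
it is 26-adjacent to both the same-side ICA and the same-side PCA (P1, or
P2 when present): a gap of even one voxel voids the measurement
(`PCOM_DISCONNECTED`). A vessel whose median centerline thickness is at or
below two voxels wide is flagged `TOO_THIN` but still reported — below two
voxels across, the inscribed-sphere estimate cannot resolve sub-voxel width,
so such values carry a warning rather than being censored.

## Discrete conventions

All distances are center-to-center; sphere membership is evaluated at voxel
centers with an inclusive boundary ($\lVert p - c\rVert \le d(c)$). The
efficient implementation paints spheres in order of decreasing radius and
skips voxels that already hold a larger value; it is *exactly* equivalent to
the exhaustive definition, and `localThicknessOracle()` (a brute-force
triple loop) is kept in the package so the equivalence is testable
bit-for-bit rather than asserted. The two routes share the same distance
map; the distance transform itself is validated separately against a
brute-force nearest-background search.

Nearest-neighbor resampling uses the voxel-center convention
(center of index $i$, 0-based, sits at $\mathrm{origin} + (i + 0.5)h$), the
output grid shares the input's world origin and covers its bounding box, and
equidistant ties resolve to the lower input index. Only isotropic targets
are supported; the five study sizes are 0.2083, 0.3125, 0.4, 0.5 and
0.625 mm. Grids with no background at all have unbounded thickness and are
rejected; empty masks yield empty (all-zero) results rather than errors.

## What the phantoms emulate

`makeCowPhantom()` builds a stylized, planar CW from straight tubes: two
ICAs joined by PComs to the P1 segments branching off the basilar tip, with
M1 and A1 branching from each ICA top — 11 measured arteries, mutually
connected exactly as the inclusion rules expect. Defaults are the study
conditions:

* **Diameters.** Per-artery means ICA 4.26, ACA A1 2.12, MCA M1 2.71,
  PCom 1.59, PCA P1 1.96, BA 2.77 mm with population SDs 0.62, 0.69, 0.33,
  0.81, 0.75, 0.51 mm, drawn independently per side, truncated to
  $\mu \pm 2.5\sigma$ and at 0.8 mm below (non-physical and out-of-layout
  values excluded).
* **Partial volume.** A real bright-blood segmentation includes any voxel
  the vessel meaningfully touches, so the generator labels a voxel as
  vessel when its center lies within half a voxel of the true surface
  (`partial_volume = 0.5`). This is the mechanism that makes estimated
  diameters grow with voxel size: the dilation is proportional to $h$,
  giving the characteristic positive bias at coarse grids (about $+1$ voxel
  in diameter) on top of a quantization term. With pure center-in
  rasterization (`pv_frac = 0`, the geometric primitive used by
  `rasterize()` and by the analytic-volume tests) the local-thickness
  estimator is nearly unbiased and shows *no* systematic voxel-size trend —
  a useful fact in itself: the voxel-size sensitivity of real measurements
  is a property of the segmentation, not of the thickness transform.
* **Grid alignment.** Each phantom receives a seeded uniform sub-voxel world
  offset: anatomy sits at an arbitrary position relative to a scan grid, and
  a fixed alignment shared by a whole ensemble would make per-size
  quantization a systematic artifact rather than averaged noise.
* **Variants.** `fetal_pca_left`/`_right` removes the P1 segment, enlarges
  the same-side PCom (mean 2.2 mm) and continues it into a PCA P2 tube —
  the fetal configuration — so the PCom connectivity rule still holds.
  `absent_pcom_left`/`_right` removes the PCom.
* **Rater.** `simulateRater()` adds Gaussian noise (default SD 0.5 mm,
  typical intra-rater variability), truncates at 0.1 mm, and records
  per-artery missingness.

The voxel-size study over an ensemble (`cwEnsembleStudy()`, default 20
phantoms) rasterizes each phantom's segmentation *at each voxel size*,
emulating a pipeline in which the image is resampled before segmentation, so
partial-volume inclusion scales with the measurement grid.
`resolutionStudy()` is the complementary tool-level operation: it resamples
one given label map by nearest neighbor and measures at each size. The two
answer different questions — resampling a fixed fine segmentation keeps its
(fixed) dilation and therefore shows no bias growth; only per-size
segmentation reproduces the resolution dependence seen with real images.

What the phantoms do **not** emulate: curved and tortuous vessel paths
(centerlines are straight or arc polylines), intensity artifacts, real
CNN segmentation errors (mislabels, fragmentation), and genuinely
three-dimensional "kissing" configurations. On the last point: for two
parallel equal tubes, the largest inscribed sphere of the merged mask is
capped by the union's minimum width, which equals the single-tube diameter
— merging parallel tubes therefore cannot strictly inflate this estimator,
only quantization luck can move it either way. The dramatic diameter
blow-ups reported for the carotid siphon require loop clusters that enclose
a pocket the segmentation fills in all three dimensions. Passing phantom
tests therefore show correctness of the transform, the centerlines, the
rules and the statistics under controlled geometry, not robustness to every
real-world failure mode.

## The agreement toolkit

Validation against a reference rater uses: detection confusion counts per
artery (both-present = TP, both-missing = TN, reference-only = FN,
automation-only = FP; a key *absent* from one table is an error, distinct
from a recorded missing value); ROC sweeps with the estimated diameter as
the presence score; paired differences (automation − reference, so
overestimation is positive); percentages within 0.5 and 1 mm; a one-sided
Wilcoxon signed-rank test of $|d|$ against each margin (exact, tie-aware
null by a generating-function recursion for $n \le 25$; normal approximation
with tie and continuity correction above — testing whether discrepancies lie
*within* the tolerance); Bonferroni correction with an explicitly declared
family size (default #arteries × #resolutions × #margins — the analysis
family is printed because conventions differ); Spearman correlation
(exact permutation p for $n \le 10$, t-approximation otherwise); ordinary
least squares of reference on automation (reference on the y-axis); and the
Shapiro–Wilk normality check (base R's Royston implementation). The
Wilcoxon-margin construction and the diameter-as-ROC-score choice are
declared conventions of this package; where a one- or two-sided reading is
ambiguous in the field, the one-sided "within margin" alternative is used
because that is the clinically relevant direction.

## Numerical choices and problem sizes

The distance transform is the exact separable parabola-envelope algorithm
with anisotropic spacing; envelope degeneracies (a parabola undercutting the
whole envelope, which occurs with interior unreachable regions) are handled
explicitly. Nearest-neighbor ties go to the lower index; sphere-painting
order (decreasing radius, then linear index) is fixed for determinism;
`measureAll()` is fully deterministic. All randomness in phantoms and raters
flows from explicit seeds.

Tests and the acceptance script use desk-scale problem sizes chosen to keep
the full suite in the minutes range: oracle equivalence on ≥50 random masks
up to $12^3$; tube recovery at the finest study size; a 20-phantom ensemble
across all five sizes (the CW field of view is 35 × 23 × 17 mm, about 1.4M
voxels at 0.2083 mm); and $n = 631$ simulated participants for the
detection and recovery statistics, matching the cohort size the validation
design mirrors.

## Known limitations

* The diameter is an unweighted mean over centerline voxels, not a
  length-weighted mean along an ordered path; for nearly straight segments
  the two agree closely.
* Skeleton spurs are retained (no pruning by default); short spurs at tube
  ends contribute a few voxels with slightly smaller thickness values, and
  concave bites where a higher-priority label claims junction voxels can
  produce branched skeletons.
* Directional thinning erodes rounded vessel ends faster than walls, so the
  centerline of a segment is shorter than the segment by roughly its
  diameter per end; segments shorter than about 2.5 diameters reduce to a
  few mid-lumen voxels. The diameter estimate is still taken at mid-lumen
  positions, but it then averages over few samples.
* Only isotropic resampling targets are supported.
* The thinning result, while topology-preserving and deterministic, is not
  guaranteed to be sub-voxel centered on strongly anisotropic grids;
  the pipeline resamples to isotropic grids before measuring.
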