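---
title: "Micro-CT phenotyping of floral nectar traits: models and methods"
author: "nectarct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Micro-CT phenotyping of floral nectar traits: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nectarct)
```

## The measurement problem

Nectar-related floral traits — the volume and surface of the nectary
gland, the level of secreted nectar inside the corolla, flower width, and
the space available to a visiting pollinator — are three-dimensional
quantities. Classical 2D imaging measures proxies (e.g. the gland's
cross-section in one cut plane) that can be badly misleading: an annular
gland wrapped around the style shows up as two small lobes in any single
longitudinal section, while a dome-shaped gland of very different volume
can show an equal section area. `nectarct` works directly on reconstructed
micro-CT slice stacks, where tissue is bright and air dark, and makes each
of these traits an explicit, reproducible computation.

All volumes use the voxel-counting rule

$$V = N \cdot s^3 \cdot 10^{-9}\ \mathrm{mm^3},$$

with $N$ the voxel count and $s$ the isotropic spacing in µm; 1 mm³ equals
1 µL, and at the working resolution of $s = 5$ µm one voxel is
$5^3 = 125$ µm³ $= 1.25\times10^{-7}$ µL.

## Conventions

* Arrays are indexed `[z, y, x]`, 1-based with inclusive ranges. `z` is
  the flower axis; slice `z = 1` is the flower base (peduncle end). Stacks
  scanned tip-first must be flipped (`reorient()`, or `--flip-z` in the
  CLI converter).
* Only axis-aligned flips and permutations are offered: an interpolating
  rotation would resample intensities and bias the voxel counts that are
  the primary measurand.
* 6-connectivity (shared faces) is the single connectivity convention,
  used for surface faces, connected components and fills.
* Cropping operations record a slice offset (`z_offset`) so every height
  reported downstream stays in the coordinates of the original stack.
* Empty height-map columns carry the sentinel `NA`.

## Segmentation model

The gland cannot be separated from surrounding tissue by intensity alone:
its upper surface is exposed to air, but its base merges into the
receptacle. The pipeline therefore reconstructs the gland between two
surfaces:

1. **Volume of interest.** The user supplies the first and last slice in
   which the gland is observed (`select_voi`). Restricting the stack this
   way is what lets the height projection see the gland rather than the
   floor below it.
2. **Threshold.** Tissue/air separation at a grey threshold
   (`threshold_tissue`); the default is Otsu's method on the 16-bit
   histogram of the VOI, computed globally (one threshold per VOI, not
   per slice). The value used is always recorded. A constant-intensity
   VOI is an error directing the user to a fixed threshold.
3. **Height projection.** Each lateral position gets the z index of its
   topmost tissue voxel, measured from the base upward
   (`height_zproject`). The direction of "height" is a convention; it is
   fixed base-up to match the axis convention above.
4. **Watershed.** The height map is partitioned into compartments grown
   from its regional maxima (`watershed_compartments`, backed by
   `EBImage::watershed`). Maxima shallower than `h_min` (default 2
   voxels) are merged into their dominant neighbour, so minor surface
   texture does not split the gland. The flooding is deterministic.
5. **Compartment selection and external contour.** Strategies:
   `centermost` (footprint centroid nearest the lateral image centre —
   the gland sits at the centre of the flower), `largest`, or explicit
   label ids (several ids are merged, covering a gland segmented as two
   apparent lobes). The external contour is the set of footprint pixels
   adjacent to the border-connected outside; boundaries of interior holes
   (e.g. around the style) are excluded.

   *Concentric anatomy caveat:* in a flower, the corolla wall, an annular
   gland and the central style all have footprint centroids at the image
   centre, making `centermost` degenerate. The practical recipe, used
   throughout the package's own validation, is to crop laterally to the
   inside of the corolla tube (`lateral_box` of `segment_nectary`) and
   then select `centermost` for dome-type (male) glands or `largest` for
   annular (female) glands.
6. **Lower surface.** At each contour pixel the gland's lowest tissue z
   anchors a Dirichlet boundary condition; interior values are filled by
   discrete harmonic (Laplace) interpolation on the footprint's
   4-neighbour graph, solved as a sparse linear system, rounded to
   integer z, and clamped to not exceed the upper surface. Harmonic
   interpolation was chosen because it is deterministic and
   parameter-free, reproduces a constant base exactly (maximum
   principle) and any planar base exactly, and degrades gracefully for
   gently curved bases. Interior holes in the footprint receive natural
   (no-flux) boundary handling.
7. **Gland mask and quantities.** Voxel $(z,y,x)$ belongs to the gland
   iff its column is in the footprint and
   $\mathrm{lower}(y,x) \le z \le \mathrm{upper}(y,x)$. Volume follows
   the voxel-count rule. Surface is the gland's area in contact with
   *air* — the complement of the full tissue mask, not merely of the
   gland — so area pressed against other organs is not counted. Two
   estimators are provided: `exposed_faces` (default; counts
   gland–air voxel faces, additive, with an exact brute-force oracle) and
   `surface_voxels` (counts gland voxels touching air — the literal
   "pixels kept" reading). Absolute voxelized surfaces overestimate a
   smooth continuum area (a Manhattan surface cannot converge to the
   Euclidean one), so surfaces are comparable between flowers measured
   with the same estimator, and the estimator tag is part of the output.
   Faces at the boundary of the field of view are not counted.

## Nectar level reconstruction

A capillary-measured nectar volume $V$ (µL) is turned into a 3D nectar
mask by visiting air voxels in deterministic (z, then y, then x) order
from the flower base and keeping them until the accumulated volume
reaches $V$ (`fill_to_volume`). Properties guaranteed by construction and
asserted in tests:

* never under-filled, overshoot $<$ one voxel volume
  ($\mathrm{achieved} - V \in [0, s^3 10^{-9})$);
* masks nest monotonically with increasing target;
* refilling to an achieved volume is idempotent;
* in a convex chamber the filled surface is level within one slice.

By default only air 6-connected to the component touching the base seed
slice is eligible — nectar pools in the basal chamber, not in
disconnected pockets. The literal all-air scan is available
(`restrict_to_base_component = FALSE`). Whether the measured volume
should be corrected for residual nectar left in the flower is a study
design question; the tool reconstructs exactly the volume it is given.

## Morphometrics

`cross_section_area` takes two perpendicular longitudinal sections of
one-voxel thickness through the flower centre, operationalized as the
lateral centroid of the gland mask so off-centre crops behave; a message
is emitted when centroid and image centre disagree by more than 5 voxels.
Each section counts all gland lobes in its plane (an annular gland
contributes two), and the mean of the two section areas is reported. For
the axially symmetric phantoms the two sections are equal by
construction, which makes this operation testable by symmetry.

`flower_width` defaults to the maximum lateral extent of the tissue
footprint over all slices (`max_extent`); the anatomical level of a width
measurement is genuinely ambiguous (rim vs. widest bulge), so an `at_z`
mode measures a single slice instead, and neither is claimed to be more
correct.

`measure_flower` composes segmentation and morphometrics into one
per-flower record (width mm, cross-section mm², gland surface mm², gland
volume mm³, nectar µL) with full provenance (threshold, parameters,
estimator tags) attached.

## Statistical stage

`compare_groups` implements the two-group decision procedure used for
sex comparisons of floral traits: Shapiro–Wilk normality screening of
each group, then Levene's test for variance homogeneity, then Student's
t (equal variances) or Welch's t (unequal). Levene's test uses the
mean-centred form (the original statistic; switchable to median-centred
Brown–Forsythe). A significant Shapiro test flags
`nonparametric_needed = TRUE` rather than silently switching to a rank
test — no nonparametric fallback is invented, and the t result is still
reported for inspection. Stars use strict bins: `***` $p<0.001$, `**`
$p<0.01$, `*` $p<0.05$, otherwise `N.S.` ($p = 0.05$ exactly is not
significant).

`linear_fit` is closed-form simple OLS with Pearson $r$, $R^2 = r^2$,
and a two-sided $p$ from $t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ df; an
exact permutation $p$ is available for the small cohorts typical of
flower studies (of order 10 per sex). No multiple-testing correction is
applied across trait panels; this mirrors common practice in the field
and is noted here explicitly. `correlate_cohort` filters by sex group,
drops and counts incomplete records, and delegates to `linear_fit`.

## Bee accessibility

The visitation module superimposes three masks — flower tissue,
reconstructed nectar, bee head — under integer translations and axis
flips (`superimpose`), labelling bee–tissue conflicts as overlap.
`max_insertion_depth` is a deterministic proxy for the manual placement a
human would do with rendering software: the head is laterally centred on
the corolla-opening centroid and slid down the flower axis in one-voxel
steps from the rim (detected as the topmost slice whose tissue footprint
encloses air); the deepest collision-free step is reported, and it equals
an exhaustive-placement search by construction (asserted against one in
tests). Insertion depth $s$ means the head's lowest voxel sits $s$ slices
below the rim. `nectar_reachability` then compares the head-bottom to
nectar-top distance with the proboscis length. This is an explicit,
reproducible accessibility criterion defined by this package — a
deliberate formalization, not a reproduction of any manual pose; rotation
search is omitted because the centred descent does not need it.

## The phantom generator: what it emulates, what it does not

`make_flower_phantom` builds an idealized melon-flower anatomy: solid
basal receptacle slab, hollow corolla tube, and either a hemispherical
dome nectary at the centre (male) or an annular nectary around a central
style, separated from it by a narrow groove (female). The geometry is
axially symmetric, dome bases sit on a half-voxel boundary (midpoint
sampling, which removes the leading discretization bias of the
voxelized half-ball), and ground truth — exact masks, voxel-count and
continuum volumes, face-count surface, width, central section areas — is
defined on the ideal geometry *before* degradation. The degradation
model is Gaussian blur (a partial-volume surrogate), additive Gaussian
noise, then 16-bit quantization; all three are explicit parameters with
quiet defaults (no blur, no noise), and generation is deterministic given
a seed.

The phantom reproduces the features the pipeline's correctness depends
on: tissue-brighter-than-air contrast, a gland whose base is not
separable by thresholding, the 2D-lobes-vs-3D-annulus discrepancy of
female anatomy, and an air cavity connected from base chamber to corolla
opening. It deliberately omits scanner physics (beam hardening, ring
artifacts, scatter), trichome-level detail, petal curvature and
off-axis flowers. Passing tests on phantoms therefore demonstrate
algorithmic correctness under a realistic geometry, not robustness to
every artifact of real acquisitions; on real data the recorded threshold
and parameter provenance are the audit trail.

`make_synthetic_cohort` emulates the statistical structure of a
nectar-secretion study: gland volume uniform on 0.5–3 mm³, nectar volume
linear in gland volume (default slope 3 µL/mm³, intercept 0.5 µL) plus
Gaussian noise. The default noise SD of 1.34 µL is derived from
$\sigma_e = \beta\,\sigma_x\sqrt{1/\rho^2 - 1}$ to give a population
correlation $\rho \approx 0.85$, the magnitude typical of gland–nectar
correlations in unisexual flowers; companion morphometrics follow
dimensional scalings ($\propto V^{2/3}$ for areas, $V^{1/3}$ for width)
with mild multiplicative noise. Negative simulated volumes are clipped
at zero and flagged.

## Numerical choices and degenerate inputs

* Otsu on a constant image, an empty compartment labeling, a contour
  with no tissue beneath it, an empty mask in a morphometric, and an
  inverted VOI are errors with directed messages, not silent results.
* Watershed flood ties and the fill's partial-slice tie are both resolved
  by deterministic scan order; the fill's sub-voxel overshoot is
  reported, never redistributed.
* The lower surface is clamped to the upper surface after rounding, so
  the gland mask is always well-formed.
* The air/tissue threshold is shared between the segmentation and fill
  stages by default, making the two partitions exactly complementary.
* Volume ratios, not absolute calibration, drive the fold-change
  validation: the male/female phantom pair is constructed with an
  analytic volume ratio of exactly 2.7 and the pipeline must recover it
  within 5%.

## Problem sizes used in validation

The test suite and the acceptance script validate the noiseless
segmentation at a 256³-voxel stack (dome radius 55 voxels) and the
degraded variant (blur σ = 1 voxel, noise SD 5% of the tissue–air
contrast) at 160³; calibration solids use radius/edge 10–20 voxels; the
type-I error simulation uses 2,000 replicates of n = 15 per group; the
cohort recovery uses n = 200. These sizes were chosen so that every
quantity's discretization error is comfortably below its tolerance while
the whole validation remains quick to run.

## Known limitations

* Absolute surface areas are estimator- and resolution-dependent
  (voxelized surfaces overestimate smooth ones); only like-for-like
  comparisons are meaningful.
* Harmonic lower-surface interpolation is exact for planar gland bases
  and approximate for curved ones (validated to ≤ 2 voxels mean absolute
  error on a thick-shell phantom); strongly concave bases would be
  smoothed.
* The accessibility search is translation-only along the axis with
  lateral centring; a tilted or rotated approach is out of scope.
* Tomographic reconstruction, artifact correction and multi-scan
  merging are upstream of this package: it starts from reconstructed
  slices.
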