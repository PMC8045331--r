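---
title: "Directional CTV margins from expert contour ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directional CTV margins from expert contour ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctvMargins)
```

## The problem

Consensus contouring studies ask a panel of experts to contour the clinical
target volume (CTV) around a fixed gross tumor volume (GTV) on a set of
representative cases, and distill margin recommendations from the resulting
ensemble. When tumor spread is anisotropic — bounded by anatomical barriers
or favoring particular tissue routes, as for non-spine bone metastases with
distinct intraosseous and extraosseous routes — a single isotropic margin
misrepresents the ensemble, and overlap scores such as Dice cannot say *in
which direction* experts disagree. `ctvMargins` implements a
direction-resolved alternative: margins and interobserver variability are
measured along clinician-specified 3D directions.

## The metrics

**Directional margin.** For a direction $\mathbf{d}$ (a unit vector in
patient coordinates), expansion vectors
$\{\mathbf{v}_i\}_{i=1}^{N}$ are cast parallel to $\mathbf{d}$ from the GTV
surface to the CTV surface, discarding rays that pass through the GTV
interior on the way. The directional margin is the median length

$$M(\mathbf{d}) = \mathrm{MEDIAN}\left(\{\lvert\mathbf{v}_i\rvert\}_{i=1}^N\right).$$

The median is the standard order-statistic convention (mean of the two
central values for even $N$).

**Margin deviation.** With $K$ expert CTVs for the same GTV, the per-expert
margins $M(\mathbf{d})_j$ yield the direction-resolved interobserver
variability

$$\mathrm{CV}(\mathbf{d}) =
  \mathrm{STD}\left(\{M(\mathbf{d})_j\}_{j=1}^K\right) /
  \mathrm{MEAN}\left(\{M(\mathbf{d})_j\}_{j=1}^K\right),$$

computed with the sample ($K-1$) standard deviation — a deliberate choice
for small panels (typically $K \approx 9$). If every expert margin is zero
the CV is defined as 0. An expert whose CTV excludes part of the GTV surface
contributes clamped zero-length vectors there rather than being dropped, so
every expert always yields a margin and $K$ is preserved.

**Consensus margin.** In a study, $M(\mathbf{d})$ against the STAPLE
consensus CTV is the *consensus margin*; pooled across cases per
route-of-spread class, its median and range summarize the study.

## Geometry and conventions

* Patient coordinates are **LPS** (+x Left, +y Posterior, +z Superior), the
  dominant radiotherapy convention. NIfTI affines (RAS) are converted on
  read and write; NRRD files declare their space and are converted
  likewise.
* Masks live on voxel grids with physical spacing, origin, and an
  orthonormal axis-direction matrix. Two masks must agree in all four
  within $10^{-6}$ mm to be comparable; a mismatch is an error, never a
  silent resample — this guards against misregistered GTV/CTV pairs.
* The mask surface is the set of foreground voxels with a 6-connected
  background (or out-of-grid) neighbor; their physical centers anchor the
  rays. A marching-cubes surface would not change medians materially at
  clinical voxel sizes and would complicate the voxel-native pipeline.
* Sub-voxel inside/outside queries use trilinear interpolation of the 0/1
  voxel values with "inside" defined as occupancy $\ge 0.5$; nodes beyond
  the grid contribute 0, so the field decays continuously to background
  within one voxel of the boundary. This localizes mask boundaries at
  millimeter precision from voxelized input.
* Planar contours rasterize by the even-odd rule on voxel centers
  (strict containment), so holes subtract, matching common mask
  rasterization behavior.

## The ray caster

From every GTV surface voxel center, a ray is marched along $\mathbf{d}$ in
steps of $0.1 \times \min(\text{spacing})$:

1. The GTV exit crossing (occupancy falling below 0.5) is bracketed and
   refined by 30 bisection steps; this crossing — not the voxel center — is
   the vector start, so lengths are boundary-to-boundary and carry no
   half-voxel anchor bias. The fixed iteration count resolves crossings to
   $\sim 10^{-7}$ voxel, and because the whole computation is carried out in
   index space parameterized by physical arclength, margins are *bitwise*
   invariant under whole-voxel translations and exactly equivariant under
   power-of-two spacing rescalings.
2. Marching continues to the CTV exit crossing, refined the same way — the
   vector end.
3. The ray is **rejected** if any sample strictly beyond the start plus a
   0.05 mm grace zone re-enters the GTV before the end (interior crossing),
   or lies inside an optional barrier mask. The grace zone absorbs
   interpolation jitter right at the departure point, which would otherwise
   cause false rejections on curved surfaces.
4. If the start already lies outside the CTV, the vector is **clamped** to
   length 0 and still counted: a tighter-than-GTV expert contour means "no
   expansion here", not a missing observation.
5. Marching is capped at the grid's physical diagonal; rays whose GTV exit
   cannot be bracketed within the cap (grazing a tangent surface) are
   dropped and logged in the diagnostics rather than failing the whole
   direction.

All rejection, clamp and failure counts are retained in the
`ExpansionVectorSet` so that a margin is never detached from its evidence.
A warning is raised when fewer than 10 vectors survive (configurable via
`castControl()`), since medians of very few rays are unstable; zero
surviving vectors is an error that the study layer records per direction
without aborting the case.

## What the directional margin measures on curved surfaces

A property worth understanding before interpreting results: expansion
vectors are *chords parallel to* $\mathbf{d}$, not surface-normal offsets.
On flat faces perpendicular to $\mathbf{d}$ (the slab phantom, cortical
plates) every chord equals the physical expansion and $M(\mathbf{d})$
recovers it exactly. On curved surfaces, chords anchored obliquely to
$\mathbf{d}$ are systematically *longer* than the normal expansion: for a
sphere of radius $r$ expanded isotropically by $m$, the chord from a surface
point at polar angle $\theta$ from $\mathbf{d}$ has length

$$L(\theta) = \sqrt{(r+m)^2 - r^2\sin^2\theta} - r\cos\theta \ \ge\ m,$$

increasing in $\theta$, and the surface-measure median sits at
$\theta = 60^\circ$: for $r = 10$, $m = 5$ that is $7.25$ mm, not $5$ mm
(the package measures $\approx 6.9$ mm; near-tangent chords are trimmed by
interior rejection on the voxelized surface). This is inherent to the
definition — the full chord-length distribution over the surface is the
object of interest, and the median deliberately summarizes it including
oblique spread. Consequently the phantom suite treats flat-faced phantoms
as exact ground truth and reports the curved-phantom medians as what they
are: medians of chord-length distributions, with the analytic form above as
the reference. Users comparing $M(\mathbf{d})$ against an intended
expansion magnitude should do so on surface regions roughly normal to
$\mathbf{d}$ — which is how directions are chosen clinically (along a
suspected route of spread, away from the surface it emanates from).

## STAPLE conventions

The consensus CTV is estimated with the STAPLE EM algorithm: voxel-wise
posteriors of the latent true segmentation given per-rater sensitivity
$p_j$ and specificity $q_j$, iterated with maximum-likelihood re-estimation
of $(p_j, q_j)$. Implementation choices, each configurable:

* scalar foreground prior, fixed at the mean foreground fraction across
  raters (spatially varying priors are out of scope);
* $p_j = q_j = 0.99999$ initialization, avoiding the label-swapped fixed
  point;
* consensus mask at posterior $\ge 0.5$ (`threshold`);
* computation restricted to the union bounding box dilated by one voxel —
  otherwise the arbitrarily large background inflates specificity and
  drags the prior toward zero;
* convergence when the mean absolute posterior change falls below `tol`
  ($10^{-6}$), within `maxIter` (100).

These are common defaults; original-publication settings for any given
study can be matched through the parameters.

## The phantom generator

`makePhantom()` builds GTV/CTV pairs from analytic solids (sphere, box,
slab, U-shape) with the CTV defined by thresholding the *analytic* distance
function — never by morphological dilation — so the applied expansion is
exact in millimeters and independent of grid resolution. Expansion rules:
isotropic (exact Euclidean), per-axis (sphere to ellipsoid, box growth), and
signed per-direction growth (the asymmetric slab mirrors the worked
7 mm / 2 mm example). A half-space barrier clips the expansion and flags
affected directions in the truth table. `makeExpertEnsemble()` draws
per-expert margins from a normal distribution truncated at zero
(negative draws redrawn) and expands the same analytic shape — emulating a
panel that agrees on the route of spread but disagrees on magnitude.

The default validation grid is 0.5 mm isotropic, finer than typical
planning CT (about 1.2 mm in-plane, 1–3 mm slices), with anisotropic-grid
cases exercised in the tests. What the phantoms deliberately do *not*
emulate: imaging appearance, realistic bone anatomy, and spatially
correlated expert disagreement (experts differ only in margin magnitude).
Passing phantom tests therefore demonstrates the geometry and statistics of
the pipeline, not robustness to segmentation noise in real contours.

Test problem sizes were chosen to exercise every code path at desk scale:
grids up to about $70^3$ voxels, ensembles of 9 experts over 20 seeds, and
200-ray brute-force cross-checks against a dense fixed-step marcher
(0.005 voxel steps, agreement within 0.05 mm).

## The study pipeline

`runStudy()` consumes a YAML/JSON configuration naming per-case mask files
and directions (labels like `"SA"` parsed in LPS, or explicit vectors),
computes the STAPLE consensus when none is supplied, evaluates consensus
margin and margin deviation per direction, and writes per-case JSON, a
study CSV and a summary JSON. Route-of-spread classes attach per direction,
not per case, so one case can contribute both intraosseous and extraosseous
data; cross-case medians pool one datum per direction. Failed directions
are excluded from summaries but counted and reported — silent exclusion
would bias medians invisibly. Reports store full precision; presentation
rounds to 0.1 mm and 0.01 CV. Outputs are byte-identical across reruns on
identical inputs.

## Known limitations

* Only a subset of the GTV surface may be clinically relevant for a given
  direction; without a barrier mask, vectors from irrelevant surface
  regions enter the median. Supplying segmented anatomical barriers
  excludes rays crossing them.
* The chord-obliquity property above inflates medians on strongly curved
  surfaces relative to the normal expansion.
* Grids must match exactly between masks; resampling is out of scope.
* Non-orthonormal (sheared) voxel grids are rejected on input.
* DICOM RT-STRUCT is not parsed; planar contours are accepted in a neutral
  JSON format any converter can emit.
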