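---
title: "Measuring surgical-margin and cutting accuracy on bone meshes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring surgical-margin and cutting accuracy on bone meshes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pelvicut)
```

## The measurement problem

A guided bone tumor resection is planned as a small set of target
cutting planes placed around the tumor with a safe margin of healthy
bone. After surgery, the only objective record of what was actually cut
is the post-operative 3D bone model. Turning that model into accuracy
numbers requires four steps, each of which this package implements:
place and validate the planes, align the post-operative model with the
pre-operative one, identify the achieved cut surfaces, and measure them
against the plan and the tumor.

Everything operates on triangle meshes in millimetres. Tumor models
must be watertight; bone models are closed surfaces in the phantoms but
open shells are accepted wherever only distances are needed.

## Metrics and conventions

Every cutting plane is oriented so that its **normal points toward the
specimen (tumor) side** — the side the cut removes. With that
convention a single signed quantity carries the clinical meaning:

* **SM**, the achieved surgical margin, is the minimum signed distance
  from the achieved cut plane to the tumor surface. The signed distance
  is linear over each triangle, so its minimum over the tumor is
  attained at a vertex and the vertex minimum is exact — no surface
  sampling is involved. Positive SM is clear margin; negative SM means
  the plane passes through the tumor. The clinical series this package
  reproduces contained no intralesional cut, so the negative branch of
  the convention is ours.
* **ESM = SM − desired margin.** Negative values mean the cut came
  closer to the tumor than planned.
* **L**, the location accuracy, follows the ISO 1101 idea of a location
  tolerance: the maximum absolute distance between the achieved cut and
  the target plane, measured along the target plane's normal. L is
  evaluated over the extracted cut-surface points — the physical cut
  footprint — because the maximum distance of an infinite tilted plane
  is unbounded. A plane parallel-offset by d gives L = d; a tilt by
  angle t about an axis through the footprint centroid gives
  L = r sin t, with r the footprint's largest lever arm about that
  axis.
* **Kerf.** The saw blade destroys a band of bone as thick as the
  blade. When the guide sits on the tumor side of the plane, the
  remaining-bone cut face ends up displaced by the blade thickness away
  from the tumor, so the raw L must be corrected by subtracting the
  blade thickness (floored at zero). The blade thickness has no
  default: it is a property of the instrument actually used and must be
  supplied.
* **Margin classes** follow the UICC convention: R0 (in sano) for
  SM > 1 mm, R1 (possible microscopic residuals) for 0 ≤ SM ≤ 1 mm, and
  a geometric "intralesional" class for SM < 0. Histologic R2 depends
  on the state of the specimen, not on geometry, so it is out of reach
  of a mesh-based evaluation and never emitted.

## Planning

`tangent_plane_at_margin(tumor, direction, margin)` constructs the
supporting plane of the tumor perpendicular to a chosen approach
direction and offsets it by the margin; by construction
`planned_margin()` returns the requested margin exactly, which makes
the pair a convenient invariant (`plan-then-measure` is the identity).
Interactive plane placement, as a surgeon would do in a visualization
tool, is deliberately replaced by this deterministic constructor: the
package's business is measurement, and a reproducible constructor makes
every downstream test exact. `build_strategy()` enforces the clinical
envelope — 1 to 6 planes, unique labels, planned margin not short of
the desired one — and warns below 3 mm, the smallest margin used
clinically. A plane may carry no margin at all (e.g. an extra-articular
resection plane not referenced to the tumor); evaluation then reports L
only.

`cutting_depth()` computes the guide calibration value: the farthest
bone crossing along a direction line within the cutting plane,
implemented as a 2D ray–polygon intersection against the plane section
of the bone.

## The synthetic phantom and what it does (not) emulate

No patient imaging ships with this package, so every end-to-end claim
is demonstrated on synthetic phantoms with known ground truth. The bone
is a thick-walled ellipsoidal shell (outer surface 120 × 80 × 60 mm,
endosteal surface scaled by 0.55) with two smooth outward prominences
(default 12 and 8 mm high, at seeded directions at least 60° apart).
The prominences matter: an ellipsoid is symmetric under half-turns
about its axes, which real pelvic bone is not, and without them rigid
registration of a partially resected model would face a four-fold pose
ambiguity that real anatomy never poses. The ellipsoidal tumor
(24 × 20 × 18 mm by default) must fit strictly inside the outer bone
surface; it may protrude into the medullary cavity, as intraosseous
tumors do. Mesh resolution is set by a target edge length (4 mm by
default, icosphere subdivision chosen accordingly).

`simulate_resection()` perturbs each target plane by a translation
along its normal (SD `sigma_t`) and a tilt about a random in-plane axis
through the cut footprint centroid (SD `sigma_theta`), then removes the
specimen plus a kerf band of configurable thickness. The defaults —
`sigma_t` = 1.0 mm, `sigma_theta` = 1.5°, kerf = 0.9 mm — are a
calibration chosen to land the simulated per-plane accuracy on the
scale reported for guided pelvic resections (ESM within roughly
±2 mm, L of 1–3 mm); they are a plausible guide-positioning error
model, not measured ground truth. `apply_scan_noise()` then moves the
remaining bone into an arbitrary rigid scanner frame and jitters every
vertex coordinate i.i.d. Gaussian, emulating segmentation error.

Geometrically, the remaining bone is *not* built by repeated clipping:
the complement of the specimen (an intersection of half-spaces) is a
union, not an intersection, so the mesh is assembled from its boundary
pieces — the kept part of the original surface plus one planar cut face
per plane, trimmed by the other planes' half-spaces. Shell
cross-sections are annuli; their cut faces are triangulated by rings
that morph from the outer boundary loop to the hole loop and are
zipped conformally to both, so no fictitious surface is generated
across the medullary cavity and no T-junctions arise. Cut faces carry
interior vertices spaced ~3 mm apart plus a rim ring 0.8 mm inside the
boundary, so the extracted footprint reaches close to the physical rim
(this bounds the lever-arm loss in L to about 2%). Where two cut faces
meet, their triangulations are independent: the result is geometrically
closed (enclosed volumes are exact, and `remaining + specimen = bone`
holds to 1e-6 relative) but not edge-manifold along those seams.

What the phantom does **not** emulate: anatomical pelvic shape and
cortical/trabecular structure, soft tissue, segmentation bias (only
zero-mean jitter), metal artefacts, or post-operative bone formation.
Passing tests therefore demonstrate that the *measurement chain* is
correct and well-conditioned at realistic noise levels — not that any
specific clinical accuracy will be achieved on real data.

## Registration

The post-operative model lacks the resected specimen, carries new cut
surfaces that have no pre-operative counterpart, and sits in an
arbitrary frame. `icp_register()` is built around those three facts:

* **Pre-alignment** matches centroids and principal axes. Principal
  axes of a resected model are unreliable in both sign and order, so
  all proper axis permutations with comparable eigenvalues and all
  proper sign combinations are generated as candidate starts (up to
  24); each gets a short burn-in and the two most promising are refined
  fully.
* **Correspondences** go from a fixed, seeded, *area-weighted* sample
  of moving vertices to the closest point on the fixed surface (nearest
  vertex, refined over its one-ring triangles). Area weighting matters
  because the synthetic cut faces are triangulated more densely than
  the original surface; sampling by vertex count would over-represent
  exactly the surface that has no counterpart.
* **Rejection and trimming.** Correspondences whose surface normals
  disagree by more than 60° are rejected outright — a cut-face point
  pairing with old bone surface fails this at any pose. The remainder
  is trimmed fractionally: the kept fraction (between 0.5 and
  1 − `trim`) is chosen each iteration to minimize RMS divided by the
  cube of the kept fraction, so the effective overlap tunes itself and
  a wrong pose cannot look good by aggressive trimming alone.
* **Updates** solve the point-to-plane least squares (fast on smooth,
  sliding-prone bone) with a point-to-point (Kabsch) fallback; each
  iteration keeps whichever update actually lowers the point-to-surface
  residual, which makes the iteration unconditionally stable. The
  trimmed RMS is non-increasing across iterations and is always
  reported together with a convergence flag — the quantitative stand-in
  for the visual inspection a human operator would perform.

On the default phantom with 0.3 mm scan jitter, random displacements up
to 30°/50 mm are recovered with median errors well under 0.5° and
0.5 mm (the registration study in `analysis/04_registration_study.R`
and the acceptance script recompute this).

## Cut-surface extraction

Post-operative vertices farther than `novelty_threshold` (default
0.5 mm) from the pre-operative surface are "new" surface. New points
whose normals are compatible with some target plane are partitioned
into planar clusters by a seeded consensus search (random minimal
planes scored by inliers within `inlier_threshold`, default 0.3 mm,
with normal compatibility within 35°), each cluster refit by total
least squares and matched to the target plane with the most similar
normal (within 25°) and the smallest centroid distance. Coplanar
fragments claiming the same target are merged when their union still
fits one plane; small debris clusters are dropped; two comparable
non-coplanar clusters for one target raise an error naming the sizes,
and a target with no cluster is reported missing rather than failing
the whole evaluation. The thresholds sit above the manufacturing
tolerance of printed guides (0.2 mm) and below the mesh edge length;
both are configurable.

Two measurement consequences are worth knowing. First, points within
the novelty threshold of the old surface — the outermost rim of the
cut — can never be recovered, which slightly shortens the lever arm
over which L is evaluated; the rim ring in the synthetic cut faces
keeps this loss small, and the same effect exists for a human operator
reading a post-operative CT. Second, SM is measured from the fitted
plane of the *physical cut face*, which under a kerf sits displaced
away from the tumor; only L carries a kerf correction, mirroring how
the measurements are made clinically.

## Statistics and reporting

Per-plane records aggregate as mean, SD, 95% confidence interval and
labelled extremes (`summarize_metric()`). The CI uses Student-t
quantiles with the sample SD: with fewer than ten planes per series the
t interval is materially wider than a normal one, and it is the choice
that reproduces the published series' printed intervals exactly at
0.1 mm display precision — the packaged per-plane table
(`read_series_cuts()`) gives ESM mean −0.8 mm (95% CI −1.8 to 0.1) and
L mean 2.5 mm (95% CI 1.8 to 3.2), recomputed by
`analysis/01_series_statistics.R`. Display rounding is half away from
zero at 0.1 mm; JSON reports keep full precision. One inconsistency in
the source series is handled by computing rather than transcribing: the
per-plane table implies a maximum positive ESM of +0.7 mm, which is
what the package reports.

## Numerical choices and degenerate inputs

* Plane clipping classifies vertices with a 1e-9 mm tolerance; cut
  chords are chained into loops and capped; capping requires loops that
  are star-shaped about their centroid (disks) or a single hole per
  outer loop (annuli) — the shapes produced by convex-ish solids and
  shells. Sequentially re-clipping an already clipped solid can create
  C-shaped sections that violate this, which is exactly why the
  simulator assembles resection boundaries from trimmed planar patches
  instead.
* Enclosed volume uses the divergence theorem on signed tetrahedra and
  is exact for closed, consistently oriented surfaces; clipping both
  sides of any watertight mesh conserves volume to 1e-6 relative (an
  acceptance check).
* Plane fitting is total least squares via SVD; collinear point sets
  are an error. Normal signs are always resolved toward the matched
  target so the SM sign convention survives fitting.
* Ties and randomness: every stochastic step (phantom prominences, cut
  noise, scan jitter, ICP sampling, consensus search) flows through an
  explicit integer seed; nothing reads or leaves global RNG state
  behind (`with_seed()`).
* Degenerate registration inputs (rank-deficient vertex distributions)
  fall back to centroid-only alignment with a warning; ICP returns its
  best transform with `converged = FALSE` rather than throwing.

## Problem sizes

The packaged analyses and tests run phantoms at 4–5 mm mesh resolution
(roughly 3,000–8,000 vertices per model), strategies of 1–6 planes, 20
seeds for the registration study and 10 seeded cases for the simulated
accuracy summary. These sizes were chosen so that every study in
`analysis/` reruns from scratch in minutes on a single core while
leaving the mesh chord error an order of magnitude below the 0.1 mm
reporting precision of the metrics.

## Known limitations

* The phantom is parametric, not anatomical; its registration
  difficulty (smooth, nearly symmetric shell) is in some respects
  *harder* than real bone, its segmentation noise model (i.i.d.
  jitter) easier.
* The evaluation measures plane-shaped cuts only; curved or stepped
  osteotomies would need a different achieved-surface model.
* Histology is out of scope: margin classes are geometric proxies.
* Soft-tissue margins, which drove one recurrence in the reference
  series, are invisible to a bone-mesh analysis.
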