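---
title: "Measuring and describing vascular-tree geometry from 3-D angiographic volumes"
author: "vasctree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and describing vascular-tree geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vasctree)
```

# The measurement problem

Contrast-enhanced CT angiography (CTA) renders arteries as bright tubular
structures in a 3-D grid of Hounsfield Units (HU). Morphometric studies of
arterial divisions — for instance of the middle cerebral artery (MCA), whose
first division (M1 trunk into M2 branches) is a predilection site for
aneurysms — need, per vessel tree:

* cross-section metrics (minimal, maximal and average diameter, area) in
  planes perpendicular to the local vessel axis;
* centerlines: ordered point sequences maximally distant from the vessel
  wall, with local radius and cumulative arc length;
* a description of each division (bifurcation) zone: the split point, the
  division plane, the branching angle BA between the two branch directional
  vectors, the vessel angles VA between trunk and each branch, and
  coplanarity indices CoI;
* smooth mathematical curves approximating the centerlines, from which
  curvature $\kappa$ and torsion $\tau$ profiles and their arc statistics
  ($K_{max}$, $K_{av}$, $T_{av}$) are derived.

`vasctree` implements this measurement chain end to end, together with
synthetic phantoms carrying analytic ground truth, so that every stage can
be validated quantitatively without clinical data.

# Synthetic phantoms

All phantoms are painted into a cubic volume (default 100 mm at 0.6 mm
isotropic resolution, the typical CTA scale) with a *spatial brush*: a cube
of half-width $1.5R$ around each stroke center whose voxels receive

$$HU(r) = C + C\left(\tfrac12 - \frac{1}{1 + e^{-a (r - R)}}\right),$$

composed with the current volume by per-voxel maximum. The profile equals
$C$ exactly at the tube boundary $r = R$, tends to $1.5C$ on the axis and to
$C/2$ far away; the background is initialized at the far-field value $C/2$
so thresholding behaves identically on and off the structure. The default
parameters $C = 150$ HU and $a = 10$ are the validation conditions used for
all phantoms. The brush stride along a swept curve is $0.25\times$ the voxel
size, which guarantees stroke overlap so the max-composed tube shows no
ridging; a support of $1.5R$ *half-width* is used because the sigmoid tail
(about $3/a$ beyond $R$) is visibly truncated by smaller supports at low
slopes.

Three families are available:

* **Torus** (`makeTorus`): a tube of diameter $D$ swept along a circle of
  radius $R_1$ in the central z-plane. Ground truth: the circle itself,
  curvature $1/R_1$, torsion 0.
* **Helix** (`makeHelix`): the axis $(R_1\cos t, R_1\sin t, bt)$ with
  $b = R_2/(2\pi)$, i.e. the "spiral addition" $R_2$ is interpreted as the
  axial rise per full turn — this makes $R_2$ a length commensurate with the
  self-overlap rejection rule $R_2 \ge 2D$ (successive turns clear each
  other). Curvature $R_1/(R_1^2+b^2)$ and torsion $b/(R_1^2+b^2)$ are
  exposed as ground truth. At most one turn is swept, clipped to the volume.
* **Artificial bifurcation zone** (`makeBifurcation`): a straight trunk
  (diameter $D_T$, length 20 mm) along $+z$ ending at an apex from which two
  straight branches (diameters $D_1$, $D_2$, length 15 mm) deviate by $A_1$,
  $A_2$ degrees on opposite sides within the nominal division plane, each
  tilted out of that plane by $A_{1pl}$, $A_{2pl}$. Trunk and branch lengths
  are package choices (unconstrained by the validated geometry) sized so
  that zone points at radius-scaled spacing fit on each vessel. True angles
  and coplanarity indices are computed from the construction direction
  vectors; the true division-plane normal is the normal of the plane spanned
  by the two branch directions, through the apex.

Parameter grids mirror the validation design: `diameterValidationGrid()` enumerates the
torus grid $D \in [1,5]$ mm step 0.25, $R_1 \in [5,30]$ mm step 1 and the
helix grid (additionally $R_2 \in [5,9]$ mm step 1, $D$ from 1.5 mm), with
combinations violating $R_1 < 2D$ or $R_2 < 2D$ rejected — 412 torus and
1086 helix specs survive. `sampleABZ()` draws bifurcation parameters
uniformly within anatomically motivated ranges (`abzRanges()`); uniform
is a package choice, the source distribution being unstated.

## The aneurysm sphere

`makeBifurcation` can paint a spherical aneurysm of diameter $D_{an}$ past
the apex on the trunk axis. A full-contrast sphere of the anatomical
diameters (2–6 mm) engulfs the junction — it swallows both branch axes
within ~2 mm of the apex — and bends the literal point-0/1 direction
vectors by tens of degrees, an order of magnitude beyond the accuracy this
class of pipeline is documented to reach; the meaning of the accompanying
"aneurysm weight" parameter `wAn` is not recoverable and is stored without
geometric effect. The zone validation experiment therefore runs on
aneurysm-free zones by default (`includeAneurysm = FALSE`), while the
aneurysm machinery (type-1 curve labels, `selectTrueDivision`) is exercised
on constructed curves.

# Preprocessing

Within a user-selected volume of interest (VOI), the volume is resampled to
an auxiliary resolution of 0.2 mm with a separable cubic-convolution kernel
(Keys, $a=-0.5$), which reproduces constant and linear fields exactly.
Segmentation is plain thresholding with a lower level in [100, 150] HU; 150
— the exact painted boundary value — is the phantom default, lower values
suit clinical arterial-phase data. The Euclidean distance map is computed
exactly (Felzenszwalb–Huttenlocher separable transform) in physical
millimetres, honoring anisotropic spacing; each foreground voxel holds the
distance to the nearest background voxel center, a convention that is
standard, reproducible, and carries a documented half-voxel bias at the
boundary. The maxima of this map along a vessel approximate the maximal
inscribed-ball radius and drive everything downstream.

# Cross-section analysis

A measuring plane through a seed point is oriented perpendicular to the
vessel either from a supplied axis estimate or by minimizing the measured
section area over two tilt angles (golden-section refinement, ~1°
tolerance): an oblique cut of a tube always measures a larger area, so the
perpendicular plane is the local minimum. On a *curved* tube the
area-minimizing plane tilts slightly into the bend — by about $D/(2R)$
radians for tube diameter $D$ and bend radius $R$ — so area-based
orientation carries that small intrinsic bias on strongly curved vessels.
In the plane:

1. the *vessel core* is the connected in-plane component with values in
   $[C_{min}, C_{max}]$ containing the click; its intensity-weighted
   centroid is the geometric center $P_{sc}$;
2. from $P_{sc}$, rays march outward in $n$ directions (step $2\pi/n$,
   default $n=36$) sampling the volume tricubically every 0.1 mm; the
   border is the first position where the profile drops below $O_{dv}$,
   with the crossing located by linear interpolation between samples;
3. with neighbor detection on, a local minimum followed within 2 mm by a
   rise above $\max(M_{min}, \text{valley} + 15\,\mathrm{HU})$ marks an
   adjacent vessel and the border is pulled back to that valley (the
   15 HU rise tolerance rejects the ~10 HU ringing that cubic
   interpolation produces at the sharp tube edge);
4. border radii are smoothed by a circular moving average (window 5);
5. extreme diameters are the shortest/longest chords between opposite rays
   ($i$ paired with $i + n/2$ — the only pairing that yields diameters),
   the area is the closed triangle fan around $P_{sc}$, and the average
   diameter is $\Delta d = \sqrt{4 P_{pp} / \pi}$.

The validation thresholds are $M_{min}=150$, $O_{dv}=160$, $C_{min}=170$,
$C_{max}=1500$. Note that $O_{dv} = 160 > C$ places the detected border
slightly *inside* the true radius (by $\ln(1.31)/a \approx 0.027$ mm at
$a=10$), a small systematic negative bias visible in the diameter
validation.

# Centerline tracking

Tracking crawls between two user-indicated cross-sections over local maxima
of the distance map. One step from point $P$ with direction $\hat d$:

* step length $\Delta d = M(P) \cdot f$, where $M$ is the distance-map
  value and $f$ the crawl rate (default 0.5; values in $[0.5, 1]$ are
  sensible, outside that range the configuration warns — large $f$ can jump
  between abutting vessels, small $f$ produces rough curves);
* the next point is the local maximum of the distance map within the plane
  perpendicular to $\hat d$ at $\Delta d$ ahead, found by a deterministic
  shrinking pattern search (tolerance $10^{-3}$ mm) restricted to a disc
  of radius $\min(\Delta d \tan dA, M(P))$;
* the new direction is the normalized displacement.

The printed aperture value "3/2π" admits two readings; the package default
is $dA = 1.5\pi$ (an effectively unconstrained turn, with the disc still
capped by the local radius so the search cannot leave the current vessel),
because the conservative reading $3/(2\pi) \approx 27°$ per step forces the
curve to turn over several millimetres and breaks steep-branch divisions;
both readings are available via `trackingConfig(dA = )`. The seed direction
is the principal axis of the local foreground, signed toward the endpoint,
and the seed point is refined to the in-plane ridge maximum. Tracking stops
within $\max(\text{local radius} \cdot f, 0.4\,\mathrm{mm})$ of the
endpoint. Out-and-back excursions (a later point returning within $0.3
\times$ radius of an earlier one) are pruned: a centerline between two
sections must not self-approach, but a large adjacent structure can briefly
capture the crawler.

Cumulative arc length is the running chord sum
$\L_i = \sum_{n\le i} |p_{n-1} p_n|$. Tree topology labels follow the
level/branch scheme: levels are 0-based rising distally, branches on a
level are numbered from 1 by declining cross-section area (ties broken by
input order).

# Division zones

Given two curves tracked from a common start through the two branches
(internally each curve is tracked from its branch endpoint *down* into the
trunk and reversed — at a merge the ridge continuation is unambiguous,
at a fork it is not):

* the **split point** $T_0$ is found from the last positions (in flow
  order) on each curve that lie within $d = 0.2$ mm — the auxiliary
  resolution — of the other curve, taking their component-wise midpoint
  (a literal coordinate-wise geometric mean would not be translation
  invariant). The distance test runs on densely resampled curves, not just
  tracked vertices, and a refinement pass re-tracks ±(4, 6) mm around the
  preliminary split with a 0.25 mm capped step so the split is resolved at
  the $d$ scale;
* **Tr points** march from the split up the trunk against the flow,
  **Br points** down each branch with the flow, at an arc spacing of
  `pointSpacingFactor` × local radius per step. The default factor is 3:
  near a division the painted tubes blend over roughly
  $(r_T + r_{br})/\sin VA$, i.e. 2–3 radii along each vessel, and
  direction vectors sampled inside that blend do not reflect the vessel
  axes (with factor 1, fat shallow branches measured 20–40° wrong);
* two placement guards operationalize "past the common zone" on blended
  junctions: a branch's point 0 must both clear the whole opposite curve
  by $d$ *and* have its local inscribed radius settled to ≤ 1.15× the
  branch's own distal caliber; the trunk's point 0 is pulled back to the
  most distal point whose local direction agrees within 10° with the
  straight proximal run. Without these guards the hyper-deterministic
  tracked curves coincide along the blend ridge for several millimetres
  and the literal rule places zone points off the vessel axes;
* the **division plane** passes through the three 0-points, its normal
  signed toward the trunk flow; **BA** is the angle between the branch
  directional vectors ($Br_0 \to Br_1$), **VA** between the downstream
  trunk vector ($Tr_1 \to Tr_0$) and each branch;
* the **coplanarity index** is $CoI = 1 - \angle(VDV, DPN)/(\pi/2)$ with
  the angle folded to $[0, \pi/2]$: 1 for a vessel parallel to the plane
  normal, 0 for a vessel lying in the division plane. Because clinical
  values near 0.9 suggest the opposite convention may be in use elsewhere,
  `coplanarityIndex(..., convention = "in-plane")` exposes the
  complement; the package asserts nothing about intent.
* with an aneurysm present, the curve into the sac is labeled type 1 and
  `selectTrueDivision` flags the zone whose split point lies furthest from
  the trunk origin as the aneurysm departure, returning the remaining zone
  as the actual division.

The dominant branch is the one with the larger mean radius over its Br
points, consistent with area-ranked topology numbering.

# Spline geometry

Centerlines are approximated by splines of degree-6 Bézier segments with
C3 joints — C3 is required for a continuous torsion function, and degree 6
is the minimal degree that supports C3 joints with per-segment freedom left
over. The centerline is resampled at an arc spacing proportional to the
local radius (wide vessels need fewer control points; the number of
segments decreases monotonically with radius), grouped into segments of at
most 20 resampled points (joints can additionally be forced at division
split points via `breakArcs`), and fitted per coordinate by
equality-constrained least squares: endpoint interpolation plus C0–C3
constraints tying the last four control points of each segment to the
first four of the next (with proper chord-span scaling). Chord-length
parameterization is used for fitting; the arc-length map is built
afterwards by dense quadrature of $\|r'\|$ (tolerance well below
$10^{-4}$ mm relative).

Curvature and torsion are computed analytically from the spline
derivatives,

$$\kappa = \frac{|r' \times r''|}{|r'|^3}, \qquad
  \tau = \frac{(r' \times r'') \cdot r'''}{|r' \times r''|^2},$$

both parameterization invariant. Where $\kappa$ falls below $10^{-6}$
rad/mm the Frénet frame is undefined and torsion is reported as 0 —
discrete frames fail on straight stretches, a documented limitation of
this representation. Arc statistics over a stated range (default step
0.05 mm) report $K_{max}$, $K_{av}$ and $T_{av}$; $T_{av}$ averages
$|\tau|$, since the reference statistics are positive and the sign
convention of the source is unstated.

# Validation experiments and what they show

Three experiments reproduce the synthetic validation design end to end;
all are seeded and reproducible bit for bit.

**Diameter accuracy** (`runDiameterExperiment`): for every phantom in the
grid, 10 random sites on the analytic centerline are measured with the
plane oriented from the analytic tangent; per-model RMS uses the true
value as reference, $RMS_D = \sqrt{\mathrm{mean}\,(m_D - D)^2}$, and SD is
the sample standard deviation ($k-1$ denominator). At 0.6 mm voxels the
torus-grid mean $RMS_D$ lands at ~0.12 mm (an order below the voxel size)
with sub-voxel accuracy for $D \ge 1.5$ mm and a visible breakdown at
$D = 1$ mm — two voxels, the Nyquist-style limit of the sampling. A
`stride` argument thins the grid for quick runs; the full grid is the
reference configuration.

**Centerline accuracy** (`runCenterlineExperiment`): 25 torus and 11 helix
models drawn from the centerline-validation ranges, two tracked curves per
model between random sections 25–40 mm apart, each curve scored by its RMS
distance to the analytic axis. Group means land near 0.04–0.05 mm, i.e.
at or below the ~0.06 mm reference level — about a tenth of the voxel
size. At this noise floor the torus/helix difference (~0.01 mm, 1/50
voxel) is statistically detectable though scientifically negligible; the
torus group benefits from its lattice-aligned central plane.

**Zone accuracy** (`runZoneExperiment`): 70 random aneurysm-free zones,
full pipeline, absolute errors against construction truth. Branch
correspondence and dominance come from the construction (the branch built
with the larger diameter), so angle errors are not contaminated by label
flips. Mean absolute angle errors land well below 3.4°, the dominant
branch below 1.9° mean / 7° max, and the worst non-dominant errors around
10–15° on shallow fat branches — the same profile as the reference
implementation. The trunk coplanarity error (~0.03 mean) is of the same
order as the branch CoI errors rather than an order below; resolving the
division plane from three sub-millimetre lever arms at 0.2 mm auxiliary
resolution does not support the published 0.0085 level, which we could
not reproduce under any placement rule we examined.

A resolution-scaling smoke test (0.6 mm vs 0.3 mm voxels) confirms that
zone errors shrink with finer voxels.

## What passing these tests does and does not show

The phantoms are noiseless, the profile is an ideal sigmoid, the
background is uniform, and vessels are circular tubes: passing validates
the geometry pipeline (segmentation bias, interpolation, ridge tracking,
zone construction, spline analysis) under controlled conditions. It does
not demonstrate robustness to CT noise, beam hardening, motion artifacts,
venous contamination, non-circular lumina or pathological wall geometry —
all outside the scope of the synthetic design. Problem sizes used in the
automated tests (70 zones, 36 centerline models, a stride-2 diameter grid)
are the package's validation configuration; the full diameter grid is
available through `diameterValidationGrid(stride = 1)`.

# Numerical choices, in one place

* Tricubic kernel: Keys $a=-0.5$ (interpolating; exact on linear fields);
  boundary handling by index clamping.
* EDT: exact squared-distance lower-envelope transform; inside-only,
  distances to background voxel centers.
* Pattern search for in-plane maxima: 3×3 stencil, halving step, stop at
  $5\times10^{-4}$ mm; deterministic, robust on the non-smooth cone ridges
  of distance maps.
* Ray marching: 0.1 mm step, linear crossing interpolation, 15 HU valley
  rise tolerance, 2 mm look-ahead.
* Crawl: $f = 0.5$, $dA = 1.5\pi$ (see above), stop radius
  $\max(f \cdot M, 0.4)$ mm, excursion pruning at $0.3\times$ radius.
* Zone: $d = 0.2$ mm, point spacing 3× local radius, 4 points per vessel,
  caliber-settling and trunk-kink guards as described.
* Spline: degree 6, C3, ≤ 20 resampled points per segment, ridge
  regularization $10^{-10}$ on the normal equations, $\kappa$ floor
  $10^{-6}$ rad/mm.
* Volumes: phantom background $C/2$; volume center at the grid center
  $(n-1)\,s/2$; all geometry in physical mm, 0-based voxel indexing,
  physical = origin + index × spacing.

# Known limitations

* Shallow ($< 20°$), thick branches blend with the trunk over many
  millimetres; zone vectors are then measured at the blend boundary and
  non-dominant angle errors can reach ~10–15°.
* The trunk coplanarity index is measured no better than the branch ones
  (see above).
* Trifurcations are out of scope; so are DICOM ingestion, contrast-phase
  judgment, and interactive editing of curve control points (the
  curve-type label slot exists; the GUI does not).
* NIfTI geometry round-trips at float32 precision (the format's header
  stores spacing as single precision).
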