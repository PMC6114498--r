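# vasctree

Semi-automatic measurement and mathematical description of vascular-tree
geometry from 3-D angiographic-style volumes (Hounsfield-unit grids), aimed
at morphometric studies of arterial divisions — e.g. the first division of
the middle cerebral artery, where branching angles, coplanarity and
centerline curvature/torsion are candidate correlates of aneurysm
development.

The package implements the full measurement chain:

* **Synthetic phantoms with analytic ground truth** — torus, helix and
  artificial-bifurcation-zone volumes painted with the sigmoid cross-profile
  `HU(r) = C + C(1/2 − 1/(1 + e^{−a(r−R)}))` (boundary value `C`, slope
  `a`), composed by per-voxel maximum.
* **Preprocessing** — VOI extraction, tricubic resampling to a 0.2 mm
  auxiliary grid, HU thresholding, and an exact anisotropic Euclidean
  distance map whose ridge maxima approximate the local inscribed-ball
  radius.
* **Cross-sections** — plane orientation perpendicular to the vessel (area
  minimization), intensity-weighted geometric center, ray-cast border with
  neighbor-vessel valley detection, circular smoothing, and the metrics
  `d_min`, `d_max`, area `P_pp` and `d_avg = sqrt(4 P_pp / π)`.
* **Centerlines** — crawl tracking over local in-plane maxima of the
  distance map with radius-proportional steps (`Δd = M(P)·f`), cumulative
  arc length `Ł_i = Σ |p_{n−1} p_n|`, and level/branch topology labels.
* **Bifurcation zones** — split point from the d = 0.2 mm proximity rule,
  trunk/branch zone points, division plane, branching angle BA, vessel
  angles VA, and coplanarity indices `CoI = 1 − ∠(VDV, DPN)/(π/2)`.
* **Spline geometry** — degree-6 Bézier splines with C3 joints (continuous
  torsion), radius-adaptive control-point allocation, curvature
  `κ = |r′×r″|/|r′|³`, torsion `τ = ((r′×r″)·r‴)/|r′×r″|²`, and the arc
  statistics `Kmax`, `Kav`, `Tav`.
* **Validation experiments** — reproducible end-to-end accuracy studies of
  diameters, centerline positioning and bifurcation-zone angles on the
  phantoms.

See `vignettes/vascular-geometry.Rmd` for the methods account.

## Worked example

Build a torus phantom (tube diameter 4 mm swept at radius 20 mm, 0.6 mm
voxels), preprocess it, measure a cross-section and track a centerline:

```r
library(vasctree)

ph <- makeTorus(D = 4, R1 = 20)           # volume + analytic ground truth
gt <- ph$truth

## cross-section at arc position 30 mm, plane from the analytic tangent
cs <- measureVessel(ph$volume, gt@centerline(30), gt@geometry$tangent(30))
cs
#> CrossSection: d_min 3.863, d_max 4.047, d_avg 3.911 mm; area 12.013 mm^2 (36 border points)

## preprocess a VOI around the arc and track between two sections
arc <- t(sapply(seq(5, 35, length.out = 50), gt@centerline))
voi <- extractVOI(ph$volume, c(apply(arc, 2, min) - 5, apply(arc, 2, max) + 5))
dm  <- distanceMap(segmentThreshold(resampleTricubic(voi, 0.2), 100))
cl  <- trackCenterline(dm, gt@centerline(5), gt@centerline(35),
                       trackingConfig(), initDirection = gt@geometry$tangent(5))
cl
#> Centerline: 28 points, length 29.28 mm
sqrt(mean(gt@distanceTo(clPoints(cl))^2))   # RMS distance to the true circle
#> [1] 0.02175171

## curvature / torsion of the tracked curve via a C3 Bezier spline
st <- arcStats(fitSpline(cl))
st
#> ArcStats over [0.00, 29.27] mm: Kmax 0.0684, Kav 0.0508, Tav 1.835e-09 rad/mm
```

The measured average diameter (3.91 mm) sits ~2 % below the true 4 mm —
the region-growing stop level (160 HU) lies slightly inside the painted
boundary (150 HU), a documented small negative bias; the tracked
centerline follows the analytic circle to ~0.02 mm (a thirtieth of the
voxel size); the spline's mean curvature reproduces the true 1/20 =
0.05 mm⁻¹ and its torsion vanishes on the planar curve.

A bifurcation phantom goes through the same machinery:

```r
p  <- ABZParams(A1 = 45, A2 = 30, A1pl = 5, A2pl = -5)
ph <- makeBifurcation(p, includeAneurysm = FALSE)
ph$truth@geometry$trueBA     # 75.57 deg, from the construction vectors
```

and `runZoneExperiment(n = 70, seed = 1)` measures such zones end to end,
reporting absolute angle and coplanarity errors against the construction.

A command-line front end over the same functions is installed at
`inst/cli/vasctree.R`:

```sh
Rscript inst/cli/vasctree.R phantom torus --D 4 --R1 20 -o torus.nii.gz
Rscript inst/cli/vasctree.R validate zones --seed 1 --out results/
```

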