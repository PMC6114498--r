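# Shared fixtures, built once per test run. Sizes are kept small: the
# phantoms here are measurement targets, not the full validation volumes.

# straight cylinder of radius `r` along +z through the volume center
cylinderVolume <- function(r = 2, extent = 40, spacing = 0.6, C = 150,
                           a = 10, offset = c(0, 0)) {
  v <- vasctree:::newPhantomVolume(extent, spacing, C)
  ctr <- vasctree:::phantomCenter(v)
  zlen <- (dim(voxelData(v))[3] - 1) * spacing
  seg <- function(t) c(ctr[1] + offset[1], ctr[2] + offset[2], zlen * t)
  vasctree:::paintStrokes(v, vasctree:::curveStrokes(seg, c(0, 1), zlen, spacing),
                          r, C, a)
}

# torus phantom shared by several files (D = 4, R1 = 20)
.torusFix <- new.env()
torusFixture <- function() {
  if (is.null(.torusFix$ph))
    .torusFix$ph <- makeTorus(D = 4, R1 = 20, extent = 52)
  .torusFix$ph
}

# radius at which the sigmoid profile crosses a HU level (inverts huProfile)
huCrossing <- function(level, C = 150, R, a = 10) {
  R - log(1 / (0.5 - (level - C) / C) - 1) / a
}

expect_rel <- function(x, y, tol) expect_lt(abs(x - y) / abs(y), tol)
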