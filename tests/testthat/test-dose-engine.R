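# Analytic dose model: closed forms and physical invariants.
#
# Geometry of the water-box fixtures: gantry 180 places the source at
# y = iso_y + 1000 mm; boxes are built so their posterior surface sits at
# y = 0 (SSD 100) unless stated otherwise. Axes ascend with voxel index.

test_that("on-axis dose in water follows the stated normalization and PDD", {
  ys <- seq(-239, -1, by = 2)
  dens <- voxelVolume(array(1, c(11, length(ys), 11)), c(5, 2, 5),
                      origin = c(-25, -239, -25))
  beam <- open_beam(jaws = c(-10, 10, -10, 10), iso = c(0, 0, 0))
  d <- beamDose(beam, dens, beamModel())
  at <- function(y) d@voxels[6, which.min(abs(ys - y)), 6]
  expect_equal(at(-15), 1.0, tolerance = 1e-3)            # 1 Gy at dmax
  ratio <- at(-101) / at(-15)          # 10.1 cm is the nearest grid depth
  expect_equal(ratio, (101.5 / 110.1)^2 * exp(-0.05 * 8.6), tolerance = 2e-3)
})

test_that("dose beyond a thin slab falls off as inverse square", {
  # 30 mm water slab for build-up, then air: depth stays fixed, r grows
  ys <- seq(-599, -1, by = 2)
  arr <- array(0, c(11, length(ys), 11))
  arr[, ys >= -30, ] <- 1                                 # slab y in [-30, 0]
  dens <- voxelVolume(arr, c(5, 2, 5), origin = c(-25, -599, -25))
  beam <- open_beam(jaws = c(-15, 15, -15, 15), iso = c(0, 0, 0))
  d <- beamDose(beam, dens, beamModel())
  at <- function(y) d@voxels[6, which.min(abs(ys - y)), 6]
  r <- function(y) 1000 - y
  expect_equal(at(-101) / at(-301), (r(-301) / r(-101))^2, tolerance = 2e-3)
  expect_equal(at(-151) / at(-451), (r(-451) / r(-151))^2, tolerance = 2e-3)
})

test_that("on-axis dose decreases monotonically beyond dmax in water", {
  ys <- seq(-299, -1, by = 2)
  dens <- voxelVolume(array(1, c(9, length(ys), 9)), c(5, 2, 5),
                      origin = c(-20, -299, -20))
  d <- beamDose(open_beam(jaws = c(-12, 12, -12, 12)), dens)
  prof <- d@voxels[5, , 5]              # index ascends towards the surface
  beyond <- prof[ys <= -16]             # depths beyond dmax
  expect_true(all(diff(beyond) > 0))    # shallower = higher, strictly
})

test_that("far outside the aperture only leaf transmission remains", {
  ys <- seq(-148.75, -1.25, by = 2.5)
  dens <- voxelVolume(array(1, c(81, length(ys), 11)), c(2.5, 2.5, 5),
                      origin = c(-100, -148.75, -25))
  beam <- open_beam(jaws = c(-3, 3, -10, 10), iso = c(0, 0, 0))
  d <- beamDose(beam, dens, beamModel())
  iy <- which.min(abs(ys + 50))          # ~5 cm deep
  inField <- d@voxels[41, iy, 6]
  outField <- d@voxels[75, iy, 6]        # ~8.5 cm off-axis
  expect_gt(outField / inField, 0.015)
  expect_lt(outField / inField, 0.03)
})

test_that("the 50% beam edge sits at the geometrically projected jaw edge", {
  ys <- seq(-99, 99, by = 2)             # surface y = +100, iso 10 cm deep
  zc <- seq(-120, 120, by = 2)
  dens <- voxelVolume(array(1, c(11, length(ys), length(zc))), c(5, 2, 2),
                      origin = c(-25, -99, -120))
  beam <- open_beam(jaws = c(-6, 6, -5, 5), iso = c(0, 0, 0))
  d <- beamDose(beam, dens, beamModel())
  iy <- which.min(abs(ys - 50))          # plane y = +50 (t = 1050)
  prof <- d@voxels[6, iy, ]
  central <- prof[which.min(abs(zc))]
  zEdge <- 50 * 1050 / 1100              # jaw edge projected to that plane
  f <- approxfun(zc, prof - 0.5 * central)
  cross <- uniroot(f, c(zEdge - 8, zEdge + 8))$root
  expect_lte(abs(cross - zEdge), 1)      # within half a voxel

  # same field shaped by the MLC instead of the jaw
  mlc <- cbind(rep(-2, 20), rep(2, 20))
  beamM <- newBeam("mlc", 180, c(0, 0, 0), jaws_cm = c(-3, 3, -5, 5),
                   mlc = mlc, mlc_edges_cm = seq(-5, 5, by = 0.5))
  dm <- beamDose(beamM, dens, beamModel())
  profM <- dm@voxels[6, iy, ]
  centralM <- profM[which.min(abs(zc))]
  fM <- approxfun(zc, profM - 0.5 * centralM)
  crossM <- uniroot(fM, c(zEdge - 8, zEdge + 8))$root
  expect_lte(abs(crossM - zEdge), 1)
})

test_that("equal-weight opposed laterals give a mirror-symmetric dose", {
  dens <- voxelVolume(array(1, c(41, 21, 21)), c(5, 5, 5),
                      origin = c(-100, -50, -50))
  jaws <- c(-8, 8, -8, 8)
  dL <- beamDose(open_beam(jaws, gantry = 90), dens)
  dR <- beamDose(open_beam(jaws, gantry = 270), dens)
  tot <- sumDose(list(dL, dR), c(1, 1))@voxels
  mirrored <- tot[41:1, , ]
  expect_lt(max(abs(tot - mirrored)) / max(tot), 1e-6)
})

test_that("half-beam blocked field edge crosses 50% at the central axis", {
  xs <- seq(-99, 99, by = 2)             # gantry 90: source at x = +1000
  zc <- seq(-120, 120, by = 2)
  dens <- voxelVolume(array(1, c(length(xs), 21, length(zc))), c(2, 5, 2),
                      origin = c(-99, -50, -120))
  beam <- newBeam("hb", 90, c(0, 0, 0), jaws_cm = c(-8, 8, -15, 15))
  beam <- applyHalfBeamBlock(beam)
  expect_identical(beam@jaws_cm[3], 0)
  d <- beamDose(beam, dens, beamModel())
  ix <- which.min(abs(xs))               # 10 cm deep (x = 0 plane)
  prof <- d@voxels[ix, 11, ]
  plateau <- prof[which.min(abs(zc - 60))]
  f <- approxfun(zc, prof - 0.5 * plateau)
  cross <- uniroot(f, c(-10, 10))$root
  expect_lte(abs(cross), 1)              # non-divergent edge at the axis
})

test_that("sumDose is a pointwise weighted sum with validated inputs", {
  a <- voxelVolume(array(runif(27), c(3, 3, 3)), c(1, 1, 1))
  b <- voxelVolume(array(runif(27), c(3, 3, 3)), c(1, 1, 1))
  expect_identical(sumDose(list(a, b), c(1, 0))@voxels, a@voxels)
  expect_equal(sumDose(list(a, a), c(0.5, 0.5))@voxels, a@voxels)
  lin <- sumDose(list(a, b), c(0.3, 1.7))@voxels
  expect_equal(lin, 0.3 * a@voxels + 1.7 * b@voxels)
  expect_error(sumDose(list(a, b), 1), "same length")
  expect_error(sumDose(list(a, b), c(1, -1)), "non-negative")
  c3 <- voxelVolume(array(0, c(4, 3, 3)), c(1, 1, 1))
  expect_error(sumDose(list(a, c3), c(1, 1)), "grid")
})
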