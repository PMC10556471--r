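# BEV projection, MLC fitting, half-beam block, divergence matching, fields.

test_that("BEV projection reproduces point-source geometry", {
  # single voxel at the isocenter projects to the BEV origin
  m <- array(FALSE, c(11, 11, 11)); m[6, 6, 6] <- TRUE
  beam <- open_beam(iso = c(0, 0, 0))
  fp <- bevProject(m, beam, c(2, 2, 2), c(-10, -10, -10), supersample = 1)
  idx <- which(fp@pixels, arr.ind = TRUE)
  expect_equal(nrow(idx), 1L)
  u <- fp@u0_mm + (idx[1] - 1) * fp@pixel_mm
  v <- fp@v0_mm + (idx[2] - 1) * fp@pixel_mm
  expect_lte(abs(u), fp@pixel_mm / 2)
  expect_lte(abs(v), fp@pixel_mm / 2)

  # 10 cm upstream, 2 cm off-axis: magnified by SAD / (SAD - 10)
  m2 <- array(FALSE, c(41, 41, 41)); m2[31, 31, 21] <- TRUE   # x=+20,y=+100,z=0
  fp2 <- bevProject(m2, beam, c(2, 10, 2), c(-40, -200, -40), pixel_mm = 1,
                    supersample = 1)
  idx2 <- which(fp2@pixels, arr.ind = TRUE)
  u2 <- fp2@u0_mm + (idx2[1] - 1) * fp2@pixel_mm
  expect_lte(abs(u2 - 20 * 100 / 90), fp2@pixel_mm)

  expect_error(bevProject(array(FALSE, c(3, 3, 3)), beam, c(2, 2, 2), c(0, 0, 0)),
               "empty")
})

test_that("a convex mask straddling iso magnifies: footprint area >= midplane section", {
  r <- 30
  sp <- c(3, 3, 3)
  dimg <- c(31, 31, 31); orig <- -sp * (dimg - 1) / 2
  idx <- which(array(TRUE, dimg), arr.ind = TRUE)
  ctr <- sweep(sweep(idx - 1, 2, sp, "*"), 2, orig, "+")
  sphere <- array(sqrt(rowSums(ctr^2)) <= r, dimg)
  fp <- bevProject(sphere, open_beam(), sp, orig, pixel_mm = 4)
  area <- sum(fp@pixels) * fp@pixel_mm^2
  midplane <- sum(sphere[, , 16]) * sp[1] * sp[2]   # voxel-counted section
  expect_gte(area, midplane * 0.98)     # small rasterization slack
})

test_that("MLC fit matches the exhaustive per-track scan", {
  # rectangle aligned to tracks: every open pair sits at the rectangle edges
  px <- matrix(FALSE, 30, 40)
  px[8:23, 11:30] <- TRUE
  fp <- new("BEVFootprint", pixels = px, u0_mm = -29, v0_mm = -39, pixel_mm = 2)
  fit <- fitMLC(fp, 0.5)
  open <- fit$mlc[, 2] > fit$mlc[, 1]
  expect_true(any(open))
  uLo <- (-29 + 7 * 2 - 1) / 10; uHi <- (-29 + 22 * 2 + 1) / 10
  expect_true(all(abs(fit$mlc[open, 1] - uLo) < 1e-9))
  expect_true(all(abs(fit$mlc[open, 2] - uHi) < 1e-9))

  # circular footprint against the naive oracle
  uc <- outer(seq(-29, 29, by = 2), rep(1, 40))
  vc <- outer(rep(1, 30), seq(-39, 39, by = 2))
  circ <- (uc - 3)^2 + (vc + 5)^2 <= 24^2
  fpc <- new("BEVFootprint", pixels = circ, u0_mm = -29, v0_mm = -39, pixel_mm = 2)
  fit <- fitMLC(fpc, 0.5)
  ora <- mlc_oracle(fpc, 0.5)
  expect_equal(fit$edges_cm, ora$edges_cm)
  openO <- !is.na(ora$mlc[, 1])
  expect_equal(unname(fit$mlc[openO, ]), unname(ora$mlc[openO, ]),
               tolerance = 1e-12)
})

test_that("MLC fit equals the oracle and covers the footprint on random shapes", {
  fps <- random_footprints(100)
  expect_mlc_matches_oracle(fps)
  for (fp in fps) {
    fit <- fitMLC(fp, 0.5)
    # coverage: every footprint pixel centre lies inside its track's aperture
    uC <- fp@u0_mm + (seq_len(nrow(fp@pixels)) - 1) * fp@pixel_mm
    vC <- fp@v0_mm + (seq_len(ncol(fp@pixels)) - 1) * fp@pixel_mm
    idx <- which(fp@pixels, arr.ind = TRUE)
    tr <- findInterval(vC[idx[, 2]], fit$edges_cm * 10, rightmost.closed = TRUE)
    expect_true(all(uC[idx[, 1]] >= fit$mlc[tr, 1] * 10 - 1e-9 &
                    uC[idx[, 1]] <= fit$mlc[tr, 2] * 10 + 1e-9))
  }
})

test_that("half-beam block zeroes the inferior jaw and closes blocked leaves", {
  fs <- tiny_fields()
  for (b in fs@brain_beams) {
    expect_identical(b@jaws_cm[3], 0)
    e <- b@mlc_edges_cm
    below <- e[-1] <= 0
    if (any(below))
      expect_true(all(b@mlc[below, 1] == b@mlc[below, 2]))
  }
  expect_error(applyHalfBeamBlock(fs@spine_beams[[1]]), "spine")
})

test_that("divergence matching follows atan(L/SSD)", {
  expect_equal(matchDivergence(0, 100), 0)
  expect_equal(matchDivergence(15, 100), atan(0.15) * 180 / pi, tolerance = 1e-12)
  th <- vapply(seq(0, 20, 2), matchDivergence, numeric(1), ssd_spine_cm = 100)
  expect_true(all(diff(th) > 0))
  # the built brain beams carry opposite-signed collimator angles
  fs <- tiny_fields()
  cols <- vapply(fs@brain_beams, function(b) b@collimator_deg, numeric(1))
  expect_equal(cols[1], -cols[2])
  expect_gt(abs(cols[1]), 0)
})

test_that("two-field skin gap follows the similar-triangle closed form", {
  up <- open_beam(jaws = c(-2, 2, -15, 15))
  lo <- open_beam(jaws = c(-2, 2, -15, 15))
  expect_equal(computeFieldGap(up, lo, 6), 1.8)
  expect_equal(computeFieldGap(up, lo, 0), 0)
  expect_error(computeFieldGap(up, lo, -1), "non-negative")
  # extended field uses its setup SSD
  upE <- open_beam(jaws = c(-2, 2, -18, 18), ssd_setup_cm = 120)
  expect_equal(computeFieldGap(upE, lo, 6), 3 * (36 / 120 + 30 / 100))
})

test_that("field sets realise the pre-check configuration", {
  fs <- tiny_fields()
  expect_equal(fs@config, "SINGLE")
  expect_setequal(vapply(fs@brain_beams, function(b) b@gantry_deg, numeric(1)),
                  c(90, 270))
  expect_equal(fs@spine_beams[[1]]@gantry_deg, 180)
  expect_length(fs@junction_z_mm, 1)
  for (b in c(fs@brain_beams, fs@spine_beams)) {
    expect_equal(b@couch_deg, 0)
    expect_equal(b@energy_mv, 6)
  }

  svE <- structureSet(extended_phantom())
  fsE <- buildFields(svE, runPrecheck(svE))
  expect_equal(fsE@config, "EXTENDED")
  expect_equal(fsE@spine_beams[[1]]@ssd_setup_cm, 120)

  svM <- structureSet(multi_phantom())
  fsM <- buildFields(svM, runPrecheck(svM))
  expect_equal(fsM@config, "MULTIPLE")
  expect_length(fsM@spine_beams, 2)
  expect_length(fsM@junction_z_mm, 2)
})

test_that("brain isocenter rides the junction and stays in the feather interval", {
  sv <- structureSet(tiny_phantom())
  iso <- placeIsocenters(sv, tiny_report())
  expect_equal(iso$brain_iso_mm[3], iso$junction_z_mm[1])
  expect_gte(iso$junction_z_mm[1], iso$feather_interval_mm[1] - 2.6)
  expect_lte(iso$junction_z_mm[1], iso$feather_interval_mm[2] + 2.6)
  narrow <- generatePhantom(tiny_spec(mandible_shoulder_gap_cm = 0.5))
  expect_error(placeIsocenters(structureSet(narrow), runPrecheck(narrow)),
               "rejected")
})

test_that("expanded brain projects inside the union of the brain apertures", {
  sv <- structureSet(tiny_phantom())
  fs <- tiny_fields()
  brainExp <- tiny_targets()$brainExp
  sp <- voxelSpacing(sv); or <- voxelOrigin(sv)
  idx <- which(brainExp, arr.ind = TRUE)
  pts <- sweep(sweep(idx - 1, 2, sp, "*"), 2, or, "+")
  insideAperture <- function(beam) {
    uv <- csiplan:::projectToBEV(pts, beam) / 10
    tr <- findInterval(uv[, 2], beam@mlc_edges_cm, rightmost.closed = TRUE)
    ok <- tr >= 1 & tr <= nrow(beam@mlc)
    ok[ok] <- uv[ok, 1] >= beam@mlc[tr[ok], 1] - 1e-6 &
      uv[ok, 1] <= beam@mlc[tr[ok], 2] + 1e-6 &
      uv[ok, 2] >= beam@jaws_cm[3] - 1e-6 & uv[ok, 2] <= beam@jaws_cm[4] + 1e-6
    ok
  }
  cover <- insideAperture(fs@brain_beams[[1]]) | insideAperture(fs@brain_beams[[2]])
  expect_true(all(cover))
})
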