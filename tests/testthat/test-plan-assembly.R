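# Subfields, iterative weighting, feathering, normalization, compositing.

# brute-force oracle: exhaustive 0.01-step weight grid (single subfield)
grid_oracle_1d <- function(parent, sub, w_max = 1) {
  grid <- seq(0, w_max, by = 0.01)
  spreads <- vapply(grid, function(w) {
    tot <- parent + w * sub; max(tot) - min(tot)
  }, numeric(1))
  grid[which.min(spreads)]
}

test_that("subfield counts follow the field configuration", {
  p1 <- tiny_plan()                        # SINGLE
  for (fs in p1@sub_plans) expect_length(fs@spine_subfields, 1)
  pm <- multi_plan()                       # MULTIPLE: 2 per spine field
  for (fs in pm@sub_plans) expect_length(fs@spine_subfields, 4)
  pe <- extended_plan()                    # EXTENDED
  for (fs in pe@sub_plans) expect_length(fs@spine_subfields, 1)
})

test_that("subfield apertures only shrink their parent's", {
  for (plan in list(tiny_plan(), multi_plan())) {
    fs <- plan@sub_plans[[1]]
    for (sub in fs@spine_subfields) {
      parent <- Find(function(b) startsWith(sub@label, b@label), fs@spine_beams)
      expect_identical(sub@mlc_edges_cm, parent@mlc_edges_cm)
      open <- sub@mlc[, 2] > sub@mlc[, 1] + 1e-9
      expect_true(all(sub@mlc[open, 1] >= parent@mlc[open, 1] - 1e-9))
      expect_true(all(sub@mlc[open, 2] <= parent@mlc[open, 2] + 1e-9))
      # some tracks must actually be closed (hot segments shielded)
      expect_gt(sum(!open), sum(parent@mlc[, 2] <= parent@mlc[, 1] + 1e-9))
    }
  }
})

test_that("weight optimizer matches the exhaustive grid and never hurts", {
  # toy two-segment midline with one hot segment
  parent <- c(rep(10, 6), rep(12, 6))
  sub <- c(rep(4, 6), rep(0.08, 6))        # shields the hot half
  opt <- optimizeSpineWeights(parent, matrix(sub))
  expect_equal(opt$weights, grid_oracle_1d(parent, sub))
  expect_lte(opt$spread, max(parent) - min(parent))

  # already-flat midline: optimum at zero weights
  flat <- optimizeSpineWeights(rep(10, 8), matrix(rep(1, 8)))
  expect_identical(flat$weights, 0)

  # spread never increases, for random cases and 2 subfields
  set.seed(7)
  for (i in 1:10) {
    p <- runif(15, 8, 12)
    M <- matrix(runif(30, 0, 3), 15, 2)
    o <- optimizeSpineWeights(p, M)
    expect_lte(o$spread, max(p) - min(p) + 1e-12)
    expect_true(all(o$weights >= 0))
  }
  expect_error(optimizeSpineWeights(1:3, matrix(1, 4, 1)), "match")
})

test_that("feathering shifts every junction superiorly by k x spacing", {
  sv <- structureSet(tiny_phantom())
  subs <- featherPlan(sv, tiny_report(), spacing_cm = 1.0)
  z <- vapply(subs, function(fs) fs@junction_z_mm[1], numeric(1))
  expect_equal(z - z[1], c(0, 10, 20))

  # spacing 0 gives three identical sub-plans
  same <- featherPlan(sv, tiny_report(), spacing_cm = 0)
  expect_identical(csiplan:::fieldSetToList(same[[1]]),
                   csiplan:::fieldSetToList(same[[2]]))
  expect_identical(csiplan:::fieldSetToList(same[[1]]),
                   csiplan:::fieldSetToList(same[[3]]))

  # both junctions of a MULTIPLE plan are feathered
  pm <- multi_plan()
  zj <- vapply(pm@sub_plans, function(fs) fs@junction_z_mm, numeric(2))
  expect_equal(zj[1, ] - zj[1, 1], c(0, 10, 20))
  expect_equal(zj[2, ] - zj[2, 1], c(0, 10, 20))
})

test_that("each feathered sub-plan abuts brain and spine edges at its junction", {
  ph <- tiny_phantom(); sv <- structureSet(ph)
  dens <- densityVolume(ph)
  iso <- placeIsocenters(sv, tiny_report())
  or <- voxelOrigin(sv); sp <- voxelSpacing(sv)
  zc <- or[3] + (seq_len(dim(dens@voxels)[3]) - 1) * sp[3]
  ixc <- round((iso$brain_iso_mm[1] - or[1]) / sp[1]) + 1
  iyc <- round((iso$y_canal_mm - or[2]) / sp[2]) + 1
  for (k in 1:2) {
    fs <- tiny_plan()@sub_plans[[k]]
    z0 <- fs@junction_z_mm[1]
    bD <- csiplan:::groupDose(fs@brain_beams, dens, beamModel())
    sD <- csiplan:::groupDose(fs@spine_beams, dens, beamModel())
    bProf <- bD@voxels[ixc, iyc, ]       # rises superior of the junction
    sProf <- sD@voxels[ixc, iyc, ]       # falls superior of the junction
    bPlat <- bProf[which.min(abs(zc - (z0 + 40)))]
    sPlat <- sProf[which.min(abs(zc - (z0 - 40)))]
    bCross <- uniroot(approxfun(zc, bProf - 0.5 * bPlat),
                      c(z0 - 15, z0 + 15))$root
    sCross <- uniroot(approxfun(zc, sProf - 0.5 * sPlat),
                      c(z0 - 15, z0 + 15))$root
    expect_lte(abs(bCross - z0), sp[3] / 2 + 1)
    expect_lte(abs(sCross - z0), sp[3] / 2 + 1)
  }
})

test_that("two matched spine fields abut at the declared match depth", {
  ph <- multi_phantom(); sv <- structureSet(ph); dens <- densityVolume(ph)
  rep <- runPrecheck(sv)
  iso <- placeIsocenters(sv, rep)
  fs <- multi_plan()@sub_plans[[1]]
  or <- voxelOrigin(sv); sp <- voxelSpacing(sv)
  z1 <- fs@junction_z_mm[2]
  zc <- or[3] + (seq_len(dim(dens@voxels)[3]) - 1) * sp[3]
  ixc <- round((iso$brain_iso_mm[1] - or[1]) / sp[1]) + 1
  iym <- round((iso$match_y_mm - or[2]) / sp[2]) + 1
  up <- beamDose(fs@spine_beams[[1]], dens)@voxels[ixc, iym, ]
  lo <- beamDose(fs@spine_beams[[2]], dens)@voxels[ixc, iym, ]
  upPlat <- up[which.min(abs(zc - (z1 + 60)))]
  loPlat <- lo[which.min(abs(zc - (z1 - 60)))]
  upCross <- uniroot(approxfun(zc, up - 0.5 * upPlat), c(z1 - 20, z1 + 20))$root
  loCross <- uniroot(approxfun(zc, lo - 0.5 * loPlat), c(z1 - 20, z1 + 20))$root
  expect_lte(abs(upCross - loCross), sp[3] / 2 + 1)
  # and the fields are separated at the skin by the similar-triangle gap
  expect_gt(computeFieldGap(fs@spine_beams[[1]], fs@spine_beams[[2]],
                            iso$match_depth_cm), 0)
})

test_that("normalization solves the uniform-dose closed form and is idempotent", {
  sv <- structureSet(tiny_phantom())
  m <- structureMasks(sv)
  dm <- dim(m$brain); sp <- voxelSpacing(sv)
  mk <- function(mask, level) {
    a <- array(0, dm); a[mask] <- level
    voxelVolume(a, sp, voxelOrigin(sv))
  }
  brainD <- mk(m$brain, 20); spineD <- mk(m$spinal_canal, 20)
  sc <- normalizePlan(brainD, spineD, sv, prescription())
  expect_equal(unname(sc["brain"]), 23.4 * 0.95 / 20, tolerance = 1e-3)
  expect_equal(unname(sc["spine"]), 23.4 * 0.95 / 20, tolerance = 1e-3)
  # after scaling, every brain voxel is at or above 95% of the prescription
  expect_true(all(sc["brain"] * brainD@voxels[m$brain] >= 0.95 * 23.4 - 1e-6))
  # idempotence: re-normalizing the scaled doses returns scalars ~1
  sc2 <- normalizePlan(sumDose(list(brainD), sc["brain"]),
                       sumDose(list(spineD), sc["spine"]), sv, prescription())
  expect_equal(unname(sc2), c(1, 1), tolerance = 2e-3)
  # unreachable coverage is reported against the structure
  expect_error(normalizePlan(mk(m$brain, 1e-6), mk(m$spinal_canal, 1e-6), sv),
               "brain")
})

test_that("composite is the 5-5-3 convex combination of the sub-plans", {
  plan <- tiny_plan()
  expect_equal(plan@fraction_weights, c(5, 5, 3) / 13)
  expect_equal(sum(plan@fraction_weights), 1)

  doses <- plan@sub_plan_doses
  comp <- compositeDose(plan)@voxels
  # convexity: composite between the pointwise min and max of the sub-plans
  mn <- pmin(doses[[1]]@voxels, doses[[2]]@voxels, doses[[3]]@voxels)
  mx <- pmax(doses[[1]]@voxels, doses[[2]]@voxels, doses[[3]]@voxels)
  expect_true(all(comp >= mn - 1e-9 & comp <= mx + 1e-9))
  # conservation: integral dose is the weighted sum of sub-plan integrals
  expect_lt(abs(sum(comp) - sum(vapply(1:3, function(k)
    plan@fraction_weights[k] * sum(doses[[k]]@voxels), numeric(1)))) / sum(comp),
    1e-9)
  # identical sub-plans composite to themselves
  same <- assembleComposite(list(doses[[1]], doses[[1]], doses[[1]]))
  expect_equal(same$dose@voxels, doses[[1]]@voxels)
  expect_error(assembleComposite(doses[1:2]), "3 sub-plan")
})

test_that("junction smoothing: composite deviation bounded by sub-plan deviation", {
  plan <- tiny_plan()
  sv <- structureSet(tiny_phantom())
  rxGy <- plan@prescription@total_dose_gy
  canal <- structureMasks(sv)$spinal_canal
  or <- voxelOrigin(sv); sp <- voxelSpacing(sv)
  zc <- or[3] + (seq_len(dim(canal)[3]) - 1) * sp[3]
  zJ <- range(vapply(plan@sub_plans, function(fs) fs@junction_z_mm[1], numeric(1)))
  near <- canal; near[, , zc < zJ[1] - 20 | zc > zJ[2] + 20] <- FALSE
  comp <- compositeDose(plan)@voxels[near]
  devs <- vapply(plan@sub_plan_doses, function(d)
    max(abs(d@voxels[near] - rxGy)), numeric(1))
  expect_lte(max(abs(comp - rxGy)), max(devs) + 1e-9)
})

test_that("generated plans meet the coverage rules and are deterministic", {
  plan <- tiny_plan()
  sv <- structureSet(tiny_phantom())
  m <- structureMasks(sv)
  d <- compositeDose(plan)
  expect_equal(vAtDirect(d, m$brain, 0.95 * 23.4), 100)          # exact
  expect_gte(vAtDirect(d, m$spinal_canal, 0.95 * 23.4), 95 - 1e-9)

  again <- generatePlan(tiny_phantom())
  expect_identical(compositeDose(again)@voxels, d@voxels)

  narrow <- generatePhantom(tiny_spec(mandible_shoulder_gap_cm = 0.5))
  expect_error(generatePlan(narrow), "feathering space")
})
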