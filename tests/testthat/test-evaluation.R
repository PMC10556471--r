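# DVH curves and the plan-quality metric panel.

toy_dose <- function(values, dims = c(2, 2, 2), spacing = c(2, 2, 2)) {
  voxelVolume(array(values, dims), spacing)
}

test_that("DVH matches hand-computed cumulative fractions", {
  mask <- array(TRUE, c(2, 2, 2))

  # uniform dose: full volume up to the dose, then nothing
  u <- computeDVH(toy_dose(rep(10, 8)), mask, bin_width_gy = 1)
  expect_equal(u$fraction[u$dose_gy <= 10], rep(1, 11))
  expect_equal(u$fraction[u$dose_gy > 10], 0)

  # eight voxels at 1..8 Gy: fraction at edge k is (9-k)/8
  d <- computeDVH(toy_dose(1:8), mask, bin_width_gy = 1)
  expect_equal(d$dose_gy, 0:9)
  expect_equal(d$fraction, c(1, (9 - (1:8)) / 8, 0))

  # monotone non-increasing, mass at the ends
  r <- computeDVH(toy_dose(runif(8, 0, 30)), mask, bin_width_gy = 0.1)
  expect_true(all(diff(r$fraction) <= 0))
  expect_equal(r$fraction[1], 1)
  expect_equal(r$fraction[nrow(r)], 0)

  expect_error(computeDVH(toy_dose(1:8), array(FALSE, c(2, 2, 2))), "empty")
})

test_that("volume-at-dose uses an inclusive threshold and matches counting", {
  mask <- array(TRUE, c(2, 2, 2))
  u <- toy_dose(rep(10, 8))
  expect_equal(vAtDirect(u, mask, 10), 100)        # inclusive at the boundary

  tri <- toy_dose(c(20, 23, 24, 20, 23, 24, 20, 23))
  m3 <- array(FALSE, c(2, 2, 2)); m3[1:3] <- TRUE  # doses {20, 23, 24}
  expect_equal(vAtDirect(tri, m3, 0.95 * 23.4), 100 * 2 / 3, tolerance = 1e-9)

  # DVH lookup agrees with direct counting within one bin width
  set.seed(11)
  for (i in 1:5) {
    d <- toy_dose(runif(60, 0, 30), dims = c(5, 4, 3))
    m <- array(runif(60) < 0.7, c(5, 4, 3)); m[1] <- TRUE
    dvh <- computeDVH(d, m, 0.1)
    for (q in c(5, 12.35, 22.23)) {
      direct <- vAtDirect(d, m, q)
      lookedUp <- vAt(dvh, q)
      within <- abs(vAt(dvh, q - 0.1) - direct) < 1e-9 ||
        abs(lookedUp - direct) < 1e-9 ||
        (lookedUp >= vAtDirect(d, m, q + 0.1) - 1e-9 && lookedUp <= vAtDirect(d, m, q - 0.1) + 1e-9)
      expect_true(within)
    }
  }
})

test_that("dMean scales linearly and never exceeds dMax", {
  d <- toy_dose(runif(8, 1, 9))
  mask <- array(TRUE, c(2, 2, 2))
  expect_equal(dMean(sumDose(list(d), 3), mask), 3 * dMean(d, mask))
  expect_lte(dMean(d, mask), dMax(d, mask))
  expect_error(dMax(d, array(FALSE, c(2, 2, 2))), "empty")
})

test_that("hotspot volume is voxel-volume arithmetic, monotone in the level", {
  dims <- c(4, 4, 4)
  a <- array(20, dims); a[2, 3, 2] <- 1.10 * 23.4
  d <- voxelVolume(a, c(2, 2, 2))
  expect_equal(hotspotVolume(d, rx_gy = 23.4, level_pct = 107), 0.008)
  expect_equal(hotspotVolume(toy_dose(rep(23, 8)), rx_gy = 23.4), 0)
  v <- vapply(c(100, 103, 107, 110, 115), function(l)
    hotspotVolume(d, rx_gy = 23.4, level_pct = l), numeric(1))
  expect_true(all(diff(v) <= 0))
})

test_that("the plan report fills the panel consistently", {
  plan <- tiny_plan()
  sv <- structureSet(tiny_phantom())
  rep <- evaluatePlan(plan, sv)
  m <- rep@metrics
  expect_equal(m$value_pct[m$structure == "brain" & m$metric == "V95"], 100)
  expect_setequal(m$structure[m$metric == "Dmax"],
                  c("brain", "spinal_canal", "brainstem", "cochleae", "eyes",
                    "lenses", "optic_nerves"))
  expect_setequal(m$structure[m$metric == "Dmean"],
                  c("cochleae", "heart", "kidneys", "lacrimal_glands", "lungs",
                    "pituitary", "thyroid"))
  # Dmean <= Dmax wherever both are reported
  both <- intersect(m$structure[m$metric == "Dmean"],
                    m$structure[m$metric == "Dmax"])
  for (s in both)
    expect_lte(m$value_gy[m$structure == s & m$metric == "Dmean"],
               m$value_gy[m$structure == s & m$metric == "Dmax"])
  expect_gte(rep@hotspot_cc, 0)
  expect_true(any(grepl("hotspot", planReportMarkdown(rep))))

  # linearity: doubling the dose doubles every Gy metric
  doubled <- sumDose(list(compositeDose(plan)), 2)
  rep2 <- evaluatePlan(doubled, sv)
  m2 <- rep2@metrics
  gy <- !is.na(m$value_gy)
  expect_equal(m2$value_gy[gy], 2 * m$value_gy[gy], tolerance = 1e-12)

  # a missing structure is flagged absent with a warning, not an error
  sv2 <- sv; sv2@masks$thyroid <- NULL
  expect_warning(rep3 <- evaluatePlan(plan, sv2), "thyroid")
  m3 <- rep3@metrics
  expect_false(m3$present[m3$structure == "thyroid"])
})

test_that("DVH table and plot cover the requested structures", {
  plan <- tiny_plan()
  sv <- structureSet(tiny_phantom())
  tab <- dvhTable(plan, sv, structures = c("brain", "spinal_canal", "heart"))
  expect_setequal(unique(tab$structure), c("brain", "spinal_canal", "heart"))
  expect_true(all(tab$fraction >= 0 & tab$fraction <= 1))
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plotDVH(tab, rx_gy = 23.4))
})
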