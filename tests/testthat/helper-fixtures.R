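# Shared fixtures, memoised so expensive phantoms/plans are built once per run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, force(expr), envir = .fixtures)
  get(key, envir = .fixtures)
}

# coarse single-field phantom used by most geometry/plan tests
tiny_spec <- function(seed = 2L, ...) {
  phantomSpec(canal_length_cm = 28, voxel_spacing_mm = c(5, 5, 5),
              slice_thickness_mm = 5, seed = seed, ...)
}
tiny_phantom <- function() memo("tiny_phantom", generatePhantom(tiny_spec()))
tiny_report <- function() memo("tiny_report", runPrecheck(structureSet(tiny_phantom())))
tiny_targets <- function() memo("tiny_targets", apertureTargets(structureSet(tiny_phantom())))
tiny_fields <- function() memo("tiny_fields",
  buildFields(structureSet(tiny_phantom()), tiny_report(), targets = tiny_targets()))
tiny_plan <- function() memo("tiny_plan", generatePlan(tiny_phantom()))

multi_phantom <- function() memo("multi_phantom",
  generatePhantom(phantomSpec(canal_length_cm = 50, voxel_spacing_mm = c(5, 5, 5),
                              slice_thickness_mm = 5, seed = 3L)))
multi_plan <- function() memo("multi_plan", generatePlan(multi_phantom()))

extended_phantom <- function() memo("extended_phantom",
  generatePhantom(phantomSpec(canal_length_cm = 40, voxel_spacing_mm = c(5, 5, 5),
                              slice_thickness_mm = 5, seed = 3L)))
extended_plan <- function() memo("extended_plan", generatePlan(extended_phantom()))

# default-resolution phantom and plan: the study conditions (canal 30 cm,
# gap 2.5 cm, 3 mm grid); built once, reused by the acceptance tests
default_phantom <- function() memo("default_phantom", generatePhantom(phantomSpec()))
default_plan <- function() memo("default_plan", generatePlan(default_phantom()))

# homogeneous water box with a simple PA or lateral beam, for dose closed forms
water_box <- function(nx = 13, ny = 81, nz = 13, d = 5) {
  voxelVolume(array(1, c(nx, ny, nz)), rep(d, 3),
              origin = -d * (c(nx, ny, nz) - 1) / 2)
}

# open-field beam (no MLC) with given jaws, gantry 180 by default
open_beam <- function(jaws = c(-10, 10, -10, 10), gantry = 180,
                      iso = c(0, 0, 0), ...) {
  newBeam("test", gantry, iso, jaws, ...)
}

# synthetic tube structure set for the measurement unit tests
tube_structures <- function(slices, dz_mm, names = "spinal_canal",
                            nxy = 5L, nz = max(unlist(slices)) + 5L) {
  masks <- lapply(names, function(nm) array(FALSE, c(nxy, nxy, nz)))
  names(masks) <- names
  for (nm in names) {
    rng <- slices[[nm]]
    masks[[nm]][2:4, 2:4, rng[1]:rng[2]] <- TRUE
  }
  labeledVolume(masks, c(2, 2, dz_mm))
}

rel_diff <- function(a, b) abs(a - b) / max(abs(b), 1e-12)

# naive per-track min/max scan, independent of fitMLC's implementation
mlc_oracle <- function(fp, leaf_width_cm = 0.5) {
  wmm <- leaf_width_cm * 10
  px <- fp@pixels
  uC <- fp@u0_mm + (seq_len(nrow(px)) - 1) * fp@pixel_mm
  vC <- fp@v0_mm + (seq_len(ncol(px)) - 1) * fp@pixel_mm
  lo <- floor(min(vC) / wmm); hi <- ceiling(max(vC) / wmm + 1e-9)
  if (hi <= lo) hi <- lo + 1
  edges <- (lo:hi) * wmm
  out <- matrix(NA_real_, length(edges) - 1, 2)
  for (j in seq_len(nrow(out))) {
    us <- c()
    for (ix in seq_len(nrow(px))) for (iv in seq_len(ncol(px))) {
      if (!px[ix, iv]) next
      inTrack <- if (j == nrow(out)) vC[iv] >= edges[j] & vC[iv] <= edges[j + 1]
                 else vC[iv] >= edges[j] & vC[iv] < edges[j + 1]
      if (inTrack) us <- c(us, uC[ix])
    }
    if (length(us)) out[j, ] <- c(min(us) - fp@pixel_mm / 2,
                                  max(us) + fp@pixel_mm / 2)
  }
  list(edges_cm = edges / 10, mlc = out / 10)
}

# random BEV footprints for the aperture-fit property checks
random_footprints <- function(n, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    nu <- sample(10:40, 1); nv <- sample(10:50, 1)
    px <- matrix(runif(nu * nv) < 0.2, nu, nv)
    if (!any(px)) px[sample(nu, 1), sample(nv, 1)] <- TRUE
    new("BEVFootprint", pixels = px, u0_mm = runif(1, -60, 0),
        v0_mm = runif(1, -80, 0), pixel_mm = sample(c(1, 2, 2.5), 1))
  })
}

expect_mlc_matches_oracle <- function(fps) {
  for (fp in fps) {
    fit <- fitMLC(fp, 0.5)
    ora <- mlc_oracle(fp, 0.5)
    openO <- !is.na(ora$mlc[, 1])
    expect_equal(unname(fit$mlc[openO, , drop = FALSE]),
                 unname(ora$mlc[openO, , drop = FALSE]), tolerance = 1e-12)
  }
}
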