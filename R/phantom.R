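## Synthetic pediatric whole-body phantom generator.
##
## The phantom is a stylized assembly of geometric primitives (ellipsoids,
## boxes, tubes) on a regular LPS grid; the planner consumes only masks and
## densities, so image realism is deliberately out of scope. All internal
## layout constants are in cm; grids are stored in mm.

## ---- rasterization helpers (mm coordinates) ----

ellipsoidMask <- function(xs, ys, zs, center, semi) {
  m <- array(FALSE, c(length(xs), length(ys), length(zs)))
  ix <- which(abs(xs - center[1]) <= semi[1])
  iy <- which(abs(ys - center[2]) <= semi[2])
  iz <- which(abs(zs - center[3]) <= semi[3])
  if (!length(ix) || !length(iy) || !length(iz)) return(m)
  dx2 <- ((xs[ix] - center[1]) / semi[1])^2
  dy2 <- ((ys[iy] - center[2]) / semi[2])^2
  dz2 <- ((zs[iz] - center[3]) / semi[3])^2
  m[ix, iy, iz] <- outer(outer(dx2, dy2, "+"), dz2, "+") <= 1
  m
}

boxMask <- function(xs, ys, zs, xr, yr, zr) {
  m <- array(FALSE, c(length(xs), length(ys), length(zs)))
  m[xs >= xr[1] & xs <= xr[2], ys >= yr[1] & ys <= yr[2],
    zs >= zr[1] & zs <= zr[2]] <- TRUE
  m
}

## elliptical cylinder along z
ellipCylZ <- function(xs, ys, zs, cxy, semixy, zr) {
  m <- array(FALSE, c(length(xs), length(ys), length(zs)))
  iz <- which(zs >= zr[1] & zs <= zr[2])
  if (!length(iz)) return(m)
  disc <- outer(((xs - cxy[1]) / semixy[1])^2, ((ys - cxy[2]) / semixy[2])^2, "+") <= 1
  m[, , iz] <- disc
  m
}

tubeZ <- function(xs, ys, zs, cxy, r, zr)
  ellipCylZ(xs, ys, zs, cxy, c(r, r), zr)

## circular cylinder along y (optic nerves)
tubeY <- function(xs, ys, zs, cxz, r, yr) {
  m <- array(FALSE, c(length(xs), length(ys), length(zs)))
  iy <- which(ys >= yr[1] & ys <= yr[2])
  if (!length(iy)) return(m)
  disc <- outer((xs - cxz[1])^2, (zs - cxz[2])^2, "+") <= r^2   # x-z disc
  m[, iy, ] <- aperm(array(disc, c(length(xs), length(zs), length(iy))), c(1, 3, 2))
  m
}

## ---- generator ----

#' Generate a synthetic pediatric CSI phantom
#'
#' Builds a co-registered density volume and 18-structure mask set from a
#' [phantomSpec()]. Geometry is deterministic given the spec (the seed only
#' jitters soft-organ placement by a millimetre or two), and the key planning
#' measurements are recovered by construction: the spinal-canal longitudinal
#' extent equals `canal_length_cm` within one slice, the mandible-shoulder
#' clearance equals `mandible_shoulder_gap_cm` within one voxel, and a larger
#' `head_tilt_deg` raises the mandible (shortening the brain-to-mandible
#' distance, as a chin tuck does).
#'
#' @param spec a [PhantomSpec-class] from [phantomSpec()].
#' @return A [CSIPhantom-class] holding the density [VoxelVolume-class] and
#'   the structure [LabeledVolume-class].
#' @examples
#' ph <- generatePhantom(phantomSpec(canal_length_cm = 25, slice_thickness_mm = 6,
#'                                   voxel_spacing_mm = c(6, 6, 6)))
#' measureSpinalCanalLength(structureSet(ph))
#' @export
generatePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)

  s <- spec@body_height_cm / 120            # torso cross-section scale
  gap <- spec@mandible_shoulder_gap_cm
  L <- spec@canal_length_cm

  ## organ-placement jitter (cm), the only use of the seed
  jit <- withLocalSeed(spec@seed, runif(12, -0.15, 0.15))

  ## longitudinal layout (cm), brain top at z = 0
  d_bm <- max(8, 16.5 - 0.15 * spec@head_tilt_deg)  # brain-to-mandible target
  mand_b <- -d_bm                                    # mandible inferior edge
  sh_top <- mand_b - gap                             # shoulder superior edge
  canal_top <- -14                                   # skull base
  canal_bot <- canal_top - L
  torso_bot <- canal_bot - 6
  z_lo <- torso_bot - 1.5
  z_hi <- 1 + 1.5                                    # head top + margin

  y_canal <- min(8 * s - 4, 4.5)
  x_hi <- max(15.5 * s, 9.5)
  y_lo <- -10.5
  y_hi <- max(8 * s, 6) + 1.5

  dxy <- spec@voxel_spacing_mm[1:2]
  dz <- spec@slice_thickness_mm
  mkAxis <- function(lo, hi, d) {                    # mm voxel centres
    n <- ceiling((hi - lo) * 10 / d)
    lo * 10 + d / 2 + d * (0:(n - 1))
  }
  xs <- mkAxis(-x_hi, x_hi, dxy[1])
  ys <- mkAxis(y_lo, y_hi, dxy[2])
  zs <- mkAxis(z_lo, z_hi, dz)
  cm <- function(v) v * 10                           # cm -> mm

  ## snap measurement-critical boundaries to voxel centres so that the
  ## slice-based measurements recover the spec within one slice
  snapZ <- function(zcm) zs[which.min(abs(zs - zcm * 10))] / 10
  eps <- 0.049 * dz / 10                             # sub-voxel face offset, cm
  brain_top_s <- snapZ(0)
  mand_b_s <- snapZ(mand_b)
  sh_top_s <- snapZ(sh_top)
  canal_top_s <- snapZ(canal_top)
  nCanal <- max(2, round(L * 10 / dz))
  canal_bot_s <- canal_top_s - (nCanal - 1) * dz / 10

  E <- function(cx, cy, cz, a, b, c)
    ellipsoidMask(xs, ys, zs, cm(c(cx, cy, cz)), cm(c(a, b, c)))

  ## body envelope
  head <- E(0, -1, -7, 7.5, 9, 8)
  neck <- ellipCylZ(xs, ys, zs, cm(c(0, -1)), cm(c(6, 7)),
                    cm(c(sh_top - 3, -3)))
  torso <- ellipCylZ(xs, ys, zs, cm(c(0, 0)), cm(c(12 * s, 8 * s)),
                     cm(c(torso_bot, sh_top)))
  zShC <- sh_top_s + eps - 3
  shoulderL <- E(-9.5 * s, 0, zShC, 4.5 * s, 4 * s, 3)
  shoulderR <- E(+9.5 * s, 0, zShC, 4.5 * s, 4 * s, 3)
  shoulderPad <- E(-9.5 * s, 0, zShC, 4.5 * s + 0.5, 4 * s + 0.5, 3.4) |
    E(+9.5 * s, 0, zShC, 4.5 * s + 0.5, 4 * s + 0.5, 3.4)
  body <- head | neck | torso | shoulderPad

  brain <- E(0 + jit[1] * 0.5, -1 + jit[2] * 0.5, brain_top_s + eps - 7,
             6.5, 8, 7)
  mandible <- boxMask(xs, ys, zs, cm(c(-3.5, 3.5)), cm(c(-6, -2)),
                      cm(c(mand_b_s - eps, mand_b_s + 4.5)))
  canal <- tubeZ(xs, ys, zs, cm(c(jit[3] * 0.5, y_canal)), cm(0.7),
                 cm(c(canal_bot_s - eps, canal_top_s + eps)))
  column <- tubeZ(xs, ys, zs, cm(c(jit[3] * 0.5, y_canal)), cm(1.6),
                  cm(c(canal_bot_s - 1, canal_top_s + eps))) & !canal
  brainstem <- tubeZ(xs, ys, zs, cm(c(0, 2)), cm(1.0), cm(c(-14, -9)))

  z_eye <- -9 + jit[4]
  eyes <- E(-2.8, -7 + jit[5], z_eye, 1.2, 1.2, 1.2) |
    E(+2.8, -7 + jit[5], z_eye, 1.2, 1.2, 1.2)
  lenses <- E(-2.8, -7.75 + jit[5], z_eye, 0.4, 0.4, 0.4) |
    E(+2.8, -7.75 + jit[5], z_eye, 0.4, 0.4, 0.4)
  nerves <- tubeY(xs, ys, zs, cm(c(-2.3, z_eye)), cm(0.25), cm(c(-5.7, -2.5))) |
    tubeY(xs, ys, zs, cm(c(2.3, z_eye)), cm(0.25), cm(c(-5.7, -2.5)))
  lacrimal <- E(-3.7, -6.6, -8 + jit[6], 0.5, 0.5, 0.5) |
    E(+3.7, -6.6, -8 + jit[6], 0.5, 0.5, 0.5)
  cochleae <- E(-5.3, -1 + jit[7], -9.5, 0.45, 0.45, 0.45) |
    E(+5.3, -1 + jit[7], -9.5, 0.45, 0.45, 0.45)
  pituitary <- E(0, -2 + jit[8], -12.5, 0.5, 0.5, 0.5)
  cribriform <- boxMask(xs, ys, zs, cm(c(-1.4, 1.4)), cm(c(-6.3, -5.0)),
                        cm(c(-12.3, -11.8)))
  z_thy <- (sh_top + mand_b) / 2
  thyroid <- E(0, -5, z_thy, 1.6, 1.0, min(1.5, max(0.2, gap * 0.45)))

  heart <- E(-1 * s + jit[9], -2.5 * s, sh_top - 13.5, 4 * s, 3.8 * s, 4.5)
  lungs <- (E(-6.2 * s, -0.5 * s + jit[10], sh_top - 9, 3.8 * s, 5.5 * s, 8) |
            E(+6.2 * s, -0.5 * s + jit[10], sh_top - 9, 3.8 * s, 5.5 * s, 8)) & !heart
  z_kid <- max(sh_top - 22, torso_bot + 5.5) + jit[11]
  kidneys <- E(-4.8 * s, 3.2 * s + jit[12], z_kid, 2.4 * s, 1.9 * s, 4) |
    E(+4.8 * s, 3.2 * s + jit[12], z_kid, 2.4 * s, 1.9 * s, 4)

  masks <- list(body = body, brain = brain, brainstem = brainstem,
                spinal_canal = canal, vertebral_column = column,
                cribriform_plate = cribriform, eyes = eyes, lenses = lenses,
                optic_nerves = nerves, lacrimal_glands = lacrimal,
                pituitary = pituitary, cochleae = cochleae,
                mandible = mandible, thyroid = thyroid, lungs = lungs,
                heart = heart, kidneys = kidneys,
                shoulders = shoulderL | shoulderR)
  ## structures may not extend outside the body
  for (nm in setdiff(names(masks), "body")) masks[[nm]] <- masks[[nm]] & body

  dens <- array(0, dim(body))
  dens[body] <- 1.0
  dens[masks$lungs] <- 0.26
  dens[masks$vertebral_column | masks$mandible | masks$shoulders] <- 1.6
  if (spec@include_contrast_kidneys) dens[masks$kidneys] <- 1.05

  spacing <- c(dxy, dz)
  origin <- c(xs[1], ys[1], zs[1])
  new("CSIPhantom",
      density = voxelVolume(dens, spacing, origin),
      structures = labeledVolume(masks, spacing, origin),
      spec = spec)
}

#' Sample a cohort of phantom specs
#'
#' Draws `n` [PhantomSpec-class]s with parameters uniform within the given
#' ranges. Default ranges emulate the anatomical spread of a pediatric CSI
#' population: canal lengths 25-60 cm, head tilt 0-20 degrees,
#' mandible-shoulder gaps 0.5-4 cm and slice thicknesses 1-3 mm.
#'
#' @param n number of specs (>= 1).
#' @param ranges named list of `c(min, max)` ranges; entries override the
#'   defaults for `canal_length_cm`, `head_tilt_deg`,
#'   `mandible_shoulder_gap_cm`, `body_height_cm`, `slice_thickness_mm`.
#' @param seed RNG seed; the i-th spec receives `seed + i` as its own seed.
#' @param voxel_spacing_mm fixed in-plane spacing for all specs.
#' @return list of [PhantomSpec-class] objects.
#' @export
sampleCohort <- function(n, ranges = list(), seed = 1L,
                         voxel_spacing_mm = c(3, 3, 3)) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("n must be a single count >= 1")
  defaults <- list(canal_length_cm = c(25, 60), head_tilt_deg = c(0, 20),
                   mandible_shoulder_gap_cm = c(0.5, 4),
                   body_height_cm = c(100, 150), slice_thickness_mm = c(1, 3))
  bad <- setdiff(names(ranges), names(defaults))
  if (length(bad)) stop("unknown range parameter(s): ", paste(bad, collapse = ", "))
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2L || any(!is.finite(r)) || r[1] > r[2])
      stop(sprintf("range for %s must be a well-ordered c(min, max)", nm))
    defaults[[nm]] <- as.numeric(r)
  }
  draws <- withLocalSeed(as.integer(seed), {
    vapply(seq_len(n), function(i)
      vapply(defaults, function(r) runif(1, r[1], r[2]), numeric(1)),
      numeric(length(defaults)))
  })
  draws <- matrix(draws, nrow = length(defaults),
                  dimnames = list(names(defaults), NULL))
  d <- function(p, i) unname(draws[p, i])
  lapply(seq_len(n), function(i)
    phantomSpec(canal_length_cm = d("canal_length_cm", i),
                head_tilt_deg = d("head_tilt_deg", i),
                mandible_shoulder_gap_cm = d("mandible_shoulder_gap_cm", i),
                body_height_cm = d("body_height_cm", i),
                voxel_spacing_mm = voxel_spacing_mm,
                slice_thickness_mm = d("slice_thickness_mm", i),
                seed = as.integer(seed) + i))
}
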