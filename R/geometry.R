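## Treatment-field construction: isocenter placement, beam's-eye-view (BEV)
## projection, MLC aperture fitting, half-beam block, divergence matching and
## the two-spine-field gap geometry.
##
## Beam frame convention: for a beam at gantry g (IEC, couch 0) the source
## lies at direction d(g) = (sin g, -cos g, 0) from the isocenter; the beam
## axis is w = -d. With collimator 0 the BEV inplane axis ev is patient
## +z (superior) and the crossplane (leaf-travel) axis is eu = ev x w.
## Collimator rotation turns (eu, ev) about w.

#' BEVFootprint: projected occupancy on the isocenter plane
#'
#' @slot pixels logical matrix (u along rows, v along columns).
#' @slot u0_mm,v0_mm centre coordinate of pixel \[1,1\] (mm at iso).
#' @slot pixel_mm pixel spacing (mm).
#' @export
setClass("BEVFootprint",
  representation(pixels = "matrix", u0_mm = "numeric", v0_mm = "numeric",
                 pixel_mm = "numeric"),
  validity = function(object) {
    if (!is.logical(object@pixels)) return("pixels must be logical")
    if (object@pixel_mm <= 0) return("pixel_mm must be > 0")
    TRUE
  }
)

setMethod("show", "BEVFootprint", function(object) {
  cat(sprintf("BEVFootprint %d x %d px (%g mm), u [%.1f, %.1f], v [%.1f, %.1f] mm\n",
              nrow(object@pixels), ncol(object@pixels), object@pixel_mm,
              object@u0_mm, object@u0_mm + (nrow(object@pixels) - 1) * object@pixel_mm,
              object@v0_mm, object@v0_mm + (ncol(object@pixels) - 1) * object@pixel_mm))
})

## unit source direction for a gantry angle (couch 0)
gantryDirection <- function(gantry_deg) {
  g <- gantry_deg * pi / 180
  c(sin(g), -cos(g), 0)
}

#' Beam coordinate frame
#'
#' @param beam a [Beam-class].
#' @return list with unit vectors `eu`, `ev` (BEV axes), `w` (beam axis,
#'   source towards isocenter) and the nominal isocentric source position
#'   `src_mm` (extended-SSD setups shift the source further back; see
#'   [beamSourcePosition()]).
#' @export
beamFrame <- function(beam) {
  d <- gantryDirection(beam@gantry_deg)
  w <- -d
  ev0 <- c(0, 0, 1)
  eu0 <- c(ev0[2] * w[3] - ev0[3] * w[2],
           ev0[3] * w[1] - ev0[1] * w[3],
           ev0[1] * w[2] - ev0[2] * w[1])
  th <- beam@collimator_deg * pi / 180
  list(eu = cos(th) * eu0 + sin(th) * ev0,
       ev = -sin(th) * eu0 + cos(th) * ev0,
       w = w,
       src_mm = beam@isocenter_mm + d * beam@sad_cm * 10)
}

#' Actual source position of a beam
#'
#' Isocentric beams place the source at SAD from the isocenter. Extended-SSD
#' beams (non-NA `ssd_setup_cm`) place it so that the distance from the
#' source to the patient surface on the central axis equals the setup SSD;
#' the surface is located along the central axis in `surface` (a body mask on
#' a [LabeledVolume-class]) or a density [VoxelVolume-class] (threshold 0.05).
#'
#' @param beam a [Beam-class].
#' @param surface optional [LabeledVolume-class] (uses its `body` mask) or
#'   density [VoxelVolume-class], needed for extended-SSD beams.
#' @return numeric(3) source position, patient mm.
#' @export
beamSourcePosition <- function(beam, surface = NULL) {
  fr <- beamFrame(beam)
  if (is.na(beam@ssd_setup_cm)) return(fr$src_mm)
  if (is.null(surface))
    stop("extended-SSD beam needs a surface (body mask or density volume)")
  tSurf <- surfaceOffset(beam, surface)
  beam@isocenter_mm - fr$w * (tSurf + beam@ssd_setup_cm * 10)
}

## distance (mm) from the isocenter to the patient surface towards the source,
## measured on the central axis; 0 if no surface is found
surfaceOffset <- function(beam, surface) {
  fr <- beamFrame(beam)
  if (is(surface, "LabeledVolume")) {
    occ <- getMask(surface, "body")
    sp <- gridSpacing(surface); or <- gridOrigin(surface)
  } else {
    occ <- surface@voxels > 0.05
    sp <- gridSpacing(surface); or <- gridOrigin(surface)
  }
  d <- dim(occ)
  step <- min(sp) / 2
  tt <- seq(0, 600, by = step)
  pts <- t(outer(-fr$w, tt) + beam@isocenter_mm)   # marching towards source
  idx <- round(sweep(sweep(pts, 2, or), 2, sp, "/")) + 1
  keep <- idx[, 1] >= 1 & idx[, 1] <= d[1] & idx[, 2] >= 1 & idx[, 2] <= d[2] &
    idx[, 3] >= 1 & idx[, 3] <= d[3]
  hit <- keep & occ[cbind(pmin(pmax(idx[, 1], 1), d[1]),
                          pmin(pmax(idx[, 2], 1), d[2]),
                          pmin(pmax(idx[, 3], 1), d[3]))]
  if (!any(hit)) return(0)
  max(tt[hit])
}

## project points (n x 3, mm) into BEV iso-plane coordinates (u, v) in mm
projectToBEV <- function(pts, beam, src = NULL) {
  fr <- beamFrame(beam)
  if (is.null(src)) src <- fr$src_mm
  vec <- sweep(pts, 2, src)
  tt <- vec %*% fr$w
  if (any(tt <= 0)) stop("point at or behind the source cannot be projected")
  s <- beam@sad_cm * 10 / tt
  cbind(u = s * (vec %*% fr$eu), v = s * (vec %*% fr$ev))
}

#' Project a structure mask into the beam's eye view
#'
#' Divergent (point-source) projection of every mask-voxel centre through the
#' source onto the isocenter plane, rasterized as a binary footprint.
#'
#' @param mask logical 3D array (non-empty).
#' @param beam a [Beam-class].
#' @param spacing_mm,origin_mm grid geometry of `mask`.
#' @param pixel_mm footprint pixel size at the isocenter plane (default 2 mm).
#' @param src_mm optional explicit source position (extended-SSD beams).
#' @param supersample samples per voxel axis (default 2: voxels are projected
#'   at quarter-voxel offsets so coarse grids still paint every leaf track).
#' @return a [BEVFootprint-class].
#' @export
bevProject <- function(mask, beam, spacing_mm, origin_mm, pixel_mm = 2,
                       src_mm = NULL, supersample = 2) {
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx)) stop("cannot project an empty mask")
  pts <- sweep(sweep(idx - 1, 2, spacing_mm, "*"), 2, origin_mm, "+")
  if (supersample > 1) {
    off <- seq(-0.5, 0.5, length.out = supersample + 2)[2:(supersample + 1)]
    grid <- as.matrix(expand.grid(off, off, off))
    pts <- do.call(rbind, lapply(seq_len(nrow(grid)), function(k)
      sweep(pts, 2, grid[k, ] * spacing_mm, "+")))
  }
  uv <- projectToBEV(pts, beam, src = src_mm)
  u0 <- floor(min(uv[, 1]) / pixel_mm) * pixel_mm
  v0 <- floor(min(uv[, 2]) / pixel_mm) * pixel_mm
  iu <- floor((uv[, 1] - u0) / pixel_mm) + 1
  iv <- floor((uv[, 2] - v0) / pixel_mm) + 1
  px <- matrix(FALSE, max(iu), max(iv))
  px[cbind(iu, iv)] <- TRUE
  new("BEVFootprint", pixels = px, u0_mm = u0 + pixel_mm / 2,
      v0_mm = v0 + pixel_mm / 2, pixel_mm = pixel_mm)
}

#' Fit MLC leaf positions to a BEV footprint
#'
#' Leaf tracks run along the v axis with the given width, aligned so that
#' track boundaries fall on multiples of the leaf width. Within each track
#' the left/right leaf edges are set to the min/max footprint extent
#' (padded by half a pixel so every footprint pixel is covered); tracks with
#' no footprint are closed at the parked position (the leftmost open edge).
#'
#' @param footprint a [BEVFootprint-class].
#' @param leaf_width_cm leaf width at iso (default 0.5 cm).
#' @return list with `mlc` (n x 2 matrix, cm), `edges_cm` (n+1 track
#'   boundaries, cm).
#' @export
fitMLC <- function(footprint, leaf_width_cm = 0.5) {
  if (!any(footprint@pixels)) stop("cannot fit MLC to an empty footprint")
  wmm <- leaf_width_cm * 10
  px <- footprint@pixels
  vC <- footprint@v0_mm + (seq_len(ncol(px)) - 1) * footprint@pixel_mm
  uC <- footprint@u0_mm + (seq_len(nrow(px)) - 1) * footprint@pixel_mm
  lo <- floor(min(vC) / wmm); hi <- ceiling(max(vC) / wmm + 1e-9)
  if (hi <= lo) hi <- lo + 1
  edges <- (lo:hi) * wmm
  n <- length(edges) - 1L
  left <- rep(NA_real_, n); right <- rep(NA_real_, n)
  track <- pmin(pmax(findInterval(vC, edges, rightmost.closed = TRUE), 1L), n)
  half <- footprint@pixel_mm / 2
  for (j in seq_len(n)) {
    cols <- which(track == j)
    if (!length(cols)) next
    rows <- which(rowSums(px[, cols, drop = FALSE]) > 0)
    if (!length(rows)) next
    left[j] <- uC[min(rows)] - half
    right[j] <- uC[max(rows)] + half
  }
  park <- if (all(is.na(left))) 0 else min(left, na.rm = TRUE)
  closed <- is.na(left)
  left[closed] <- park; right[closed] <- park
  list(mlc = cbind(left = left / 10, right = right / 10), edges_cm = edges / 10)
}

#' Apply a half-beam block to a brain field
#'
#' Closes the inferior jaw at the central axis (0.0 at the isocenter plane),
#' so the inferior field edge is non-divergent at the junction plane; MLC
#' pairs entirely on the blocked side are closed.
#'
#' @param beam a lateral brain [Beam-class] (gantry 90 or 270).
#' @param blocked_side which side to block; only `"inferior"` is used in CSI.
#' @return the modified [Beam-class].
#' @export
applyHalfBeamBlock <- function(beam, blocked_side = "inferior") {
  if (beam@gantry_deg == 180)
    stop("half-beam block applies to brain fields, not a spine field")
  blocked_side <- match.arg(blocked_side, c("inferior", "superior"))
  if (blocked_side == "inferior") beam@jaws_cm[3] <- 0 else beam@jaws_cm[4] <- 0
  if (nrow(beam@mlc)) {
    e <- beam@mlc_edges_cm
    blocked <- if (blocked_side == "inferior") e[-1] <= 0 else e[-length(e)] >= 0
    if (any(blocked)) {
      park <- min(beam@mlc[, 1])
      beam@mlc[blocked, 1] <- park
      beam@mlc[blocked, 2] <- park
    }
  }
  validObject(beam)
  beam
}

#' Brain-field collimator angle matching spine-field divergence
#'
#' The brain inferior edge (half-beam blocked, hence non-divergent) is
#' rotated by theta = atan(L_sup / SSD_spine) so that it parallels the
#' diverging superior edge of the spine field, where `L_sup` is the spine
#' field's superior half-length and `SSD_spine` the spine source-to-junction
#' distance.
#'
#' @param L_sup_cm spine-field superior half-length (cm).
#' @param ssd_spine_cm spine source distance at the junction (cm).
#' @return collimator angle theta in degrees (magnitude; the gantry-90 beam
#'   uses +theta, the gantry-270 beam -theta).
#' @export
matchDivergence <- function(L_sup_cm, ssd_spine_cm) {
  atan(L_sup_cm / ssd_spine_cm) * 180 / pi
}

#' Skin gap between two abutting PA spine fields
#'
#' For field edges meeting at depth `d` below the surface, the surface gap is
#' G = (d/2) (L1/SSD1 + L2/SSD2) with L the field lengths and SSD the source
#' to surface distances.
#'
#' @param upper,lower the two PA spine [Beam-class]s.
#' @param match_depth_cm depth of the match point below the skin (>= 0), cm.
#' @return skin gap in cm.
#' @export
computeFieldGap <- function(upper, lower, match_depth_cm) {
  if (!is.finite(match_depth_cm) || match_depth_cm < 0)
    stop("match depth must be non-negative")
  len <- function(b) b@jaws_cm[4] - b@jaws_cm[3]
  ssd <- function(b) if (is.na(b@ssd_setup_cm)) b@sad_cm else b@ssd_setup_cm
  (match_depth_cm / 2) * (len(upper) / ssd(upper) + len(lower) / ssd(lower))
}

## centroid (mm) of a mask, and convenience extents
maskCentroid <- function(mask, spacing, origin) {
  idx <- which(mask, arr.ind = TRUE)
  unname(colMeans(sweep(sweep(idx - 1, 2, spacing, "*"), 2, origin, "+")))
}

sliceZ <- function(sv, i) gridOrigin(sv)[3] + (i - 1) * gridSpacing(sv)[3]

#' Place isocenters and junction planes
#'
#' The brain isocenter sits on the cranio-spinal junction plane (enabling the
#' half-beam match) at the spinal-canal depth; the junction defaults to the
#' midpoint of the mandible-shoulder feather interval minus one junction
#' spacing, so all three feather shifts \{0, +s, +2s\} stay inside the
#' measured space. Spine isocenters are centred on their canal segment; for
#' MULTIPLE configurations the spine-spine match plane is placed just
#' anterior to the canal (0.5 cm) at the mid-canal split.
#'
#' @param sv a [LabeledVolume-class] (or [CSIPhantom-class]).
#' @param report an accepted [CompatibilityReport-class].
#' @param limits a [MachineLimits-class].
#' @param junction_shift_cm superior junction shift applied to every match
#'   plane (used by feathering; default 0).
#' @return list with `junction_z_mm` (length 1 or 2), `brain_iso_mm`,
#'   `spine_iso_mm` (list), `y_canal_mm`, `match_depth_cm` (MULTIPLE only),
#'   `inferior_edge_z_mm` and `feather_interval_mm`.
#' @export
placeIsocenters <- function(sv, report, limits = machineLimits(),
                            junction_shift_cm = 0) {
  if (is(sv, "CSIPhantom")) sv <- structureSet(sv)
  if (!isAccepted(report))
    stop("pre-check rejected this patient: ", paste(report@reasons, collapse = "; "))
  sp <- gridSpacing(sv); or <- gridOrigin(sv)
  mand <- getMask(sv, "mandible"); sh <- getMask(sv, "shoulders")
  canal <- getMask(sv, "spinal_canal")
  zMandB <- sliceZ(sv, occupiedRange(mand, 3L)[1])
  zShT <- sliceZ(sv, occupiedRange(sh, 3L)[2])
  s_mm <- report@junction_spacing_cm * 10
  z0 <- (zMandB + zShT) / 2 - s_mm + junction_shift_cm * 10
  if (z0 > zMandB + sp[3] / 2 + 1e-6 || z0 < zShT - sp[3] / 2 - 1e-6)
    stop("feather shift would exit the mandible-shoulder space")

  cr <- occupiedRange(canal, 3L)
  zCanalBot <- sliceZ(sv, cr[1])
  cen <- maskCentroid(canal, sp, or)
  xC <- cen[1]; yCanal <- cen[2]
  infEdge <- zCanalBot - 7                      # cover canal bottom + margin
  out <- list(junction_z_mm = z0,
              brain_iso_mm = c(xC, yCanal, z0),
              y_canal_mm = yCanal,
              inferior_edge_z_mm = infEdge,
              feather_interval_mm = c(zShT, zMandB))
  if (report@field_config %in% c("SINGLE", "EXTENDED")) {
    out$spine_iso_mm <- list(c(xC, yCanal, (z0 + infEdge) / 2))
  } else {
    ## split mid-span; the spine-spine junction shifts with the feathering too
    z1 <- (z0 - junction_shift_cm * 10 + infEdge) / 2 + junction_shift_cm * 10
    out$junction_z_mm <- c(z0, z1)
    out$spine_iso_mm <- list(c(xC, yCanal, (z0 + z1) / 2),
                             c(xC, yCanal, (z1 + infEdge) / 2))
    ## match point just anterior (0.5 cm) to the canal's anterior surface at z1
    i1 <- pmin(pmax(round((z1 - or[3]) / sp[3]) + 1, cr[1]), cr[2])
    sl <- canal[, , i1]
    yAnt <- or[2] + (min(which(apply(sl, 2, any))) - 1) * sp[2]
    yMatch <- yAnt - 5
    body <- getMask(sv, "body")
    ySkin <- or[2] + (max(which(apply(body[, , i1], 2, any))) - 1) * sp[2]
    out$match_y_mm <- yMatch
    out$match_depth_cm <- max(0.1, (ySkin - yMatch) / 10)
  }
  out
}

## v-coordinate (cm at iso) of a patient point seen from a beam
vCoordOf <- function(point_mm, beam, src) {
  projectToBEV(matrix(point_mm, 1), beam, src = src)[1, 2] / 10
}

#' Build the CSI field set for an accepted patient
#'
#' Constructs the 2 opposed lateral brain fields (gantry 90/270) with
#' half-beam block and divergence-matched collimator, plus the PA spine
#' field(s) per the pre-check configuration: a single isocentric field, a
#' single extended-SSD field, or two matched fields with a skin gap opening
#' at the spine-spine match depth. Brain MLCs conform to the 1 cm uniform
#' brain expansion (plus the laterally-expanded canal segment above the
#' junction, as the brain field treats the upper cervical canal); spine MLCs
#' conform to the 1 cm lateral canal expansion.
#'
#' @param sv a [LabeledVolume-class] or [CSIPhantom-class].
#' @param report an accepted [CompatibilityReport-class].
#' @param limits a [MachineLimits-class].
#' @param junction_shift_cm superior junction shift (feathering).
#' @param targets optional precomputed list from [apertureTargets()] (saves
#'   re-dilating masks when building the three feathered sub-plans).
#' @return a [FieldSet-class] (without subfields; see [makeSubfields()]).
#' @export
buildFields <- function(sv, report, limits = machineLimits(),
                        junction_shift_cm = 0, targets = NULL) {
  if (is(sv, "CSIPhantom")) sv <- structureSet(sv)
  if (!isAccepted(report))
    stop("pre-check rejected this patient: ", paste(report@reasons, collapse = "; "))
  sp <- gridSpacing(sv); or <- gridOrigin(sv)
  if (is.null(targets)) targets <- apertureTargets(sv)
  iso <- placeIsocenters(sv, report, limits, junction_shift_cm)
  z0 <- iso$junction_z_mm[1]
  sad <- limits@sad_cm
  lw <- limits@leaf_width_at_iso_cm
  cfg <- report@field_config

  ## ---- spine field(s) ----
  mkSpine <- function(label, iso_mm, supPoint, infPoint, extended) {
    b <- newBeam(label, 180, iso_mm, jaws_cm = c(-1, 1, -1, 1), sad_cm = sad,
                 ssd_setup_cm = if (extended) limits@extended_ssd_cm else NA_real_)
    src <- beamSourcePosition(b, sv)
    fp <- bevProject(targets$spineTarget, b, sp, or, src_mm = src)
    fit <- fitMLC(fp, lw)
    vSup <- vCoordOf(supPoint, b, src)
    vInf <- vCoordOf(infPoint, b, src)
    open <- fit$mlc[, 2] > fit$mlc[, 1] + 1e-9
    xlo <- min(fit$mlc[open, 1]) - 0.2; xhi <- max(fit$mlc[open, 2]) + 0.2
    b@jaws_cm <- c(xlo, xhi, vInf, vSup)
    b@mlc <- fit$mlc; b@mlc_edges_cm <- fit$edges_cm
    ## close tracks fully outside the jaws
    e <- fit$edges_cm
    out <- e[-1] <= vInf | e[-length(e)] >= vSup
    if (any(out)) { park <- xlo; b@mlc[out, 1] <- park; b@mlc[out, 2] <- park }
    validObject(b)
    list(beam = b, src = src)
  }

  yC <- iso$y_canal_mm
  xC <- iso$brain_iso_mm[1]
  junPoint <- c(xC, yC, z0)
  if (cfg %in% c("SINGLE", "EXTENDED")) {
    spu <- mkSpine("spine", iso$spine_iso_mm[[1]], junPoint,
                   c(xC, yC, iso$inferior_edge_z_mm), cfg == "EXTENDED")
    spines <- list(spu)
  } else {
    z1 <- iso$junction_z_mm[2]
    matchPoint <- c(xC, iso$match_y_mm, z1)
    spu <- mkSpine("spine_upper", iso$spine_iso_mm[[1]], junPoint, matchPoint, FALSE)
    spl <- mkSpine("spine_lower", iso$spine_iso_mm[[2]], matchPoint,
                   c(xC, yC, iso$inferior_edge_z_mm), FALSE)
    spines <- list(spu, spl)
  }

  ## ---- brain fields, divergence-matched to the upper spine field ----
  upper <- spines[[1]]
  Lsup <- upper$beam@jaws_cm[4]
  ssdJ <- sqrt(sum((junPoint - upper$src)^2)) / 10
  theta <- matchDivergence(Lsup, ssdJ)

  zc <- axisCoords(or, sp, gridDim(sv)[3], 3)
  canalAbove <- targets$canalLat
  canalAbove[, , zc <= z0] <- FALSE
  brainTarget <- targets$brainExp | canalAbove
  mkBrain <- function(label, gantry, sign) {
    b <- newBeam(label, gantry, iso$brain_iso_mm, jaws_cm = c(-1, 1, -1, 1),
                 collimator_deg = sign * theta, sad_cm = sad)
    src <- beamSourcePosition(b)
    fp <- bevProject(brainTarget, b, sp, or, src_mm = src)
    fit <- fitMLC(fp, lw)
    b@mlc <- fit$mlc; b@mlc_edges_cm <- fit$edges_cm
    open <- fit$mlc[, 2] > fit$mlc[, 1] + 1e-9
    vHi <- max(fit$edges_cm[-1][open]) + 0.2
    b@jaws_cm <- c(min(fit$mlc[open, 1]) - 0.2, max(fit$mlc[open, 2]) + 0.2,
                   -0.5, vHi)
    applyHalfBeamBlock(b, "inferior")
  }
  brains <- list(mkBrain("brain_L", 90, +1), mkBrain("brain_R", 270, -1))

  new("FieldSet", brain_beams = brains,
      spine_beams = lapply(spines, `[[`, "beam"),
      spine_subfields = list(),
      junction_z_mm = iso$junction_z_mm, config = cfg)
}

#' Precompute MLC aperture target masks
#'
#' The dilations that define the aperture targets: the 1 cm uniform brain
#' expansion and the 1 cm lateral canal expansion. Computing them once and
#' passing the result to [buildFields()] avoids re-dilating for each
#' feathered sub-plan.
#'
#' @param sv a [LabeledVolume-class].
#' @param brain_margin_cm,canal_margin_cm expansion margins (default 1 cm).
#' @return list with `brainExp`, `canalLat`, `spineTarget` masks.
#' @export
apertureTargets <- function(sv, brain_margin_cm = 1, canal_margin_cm = 1) {
  if (is(sv, "CSIPhantom")) sv <- structureSet(sv)
  sp <- gridSpacing(sv)
  brainExp <- expandUniform(getMask(sv, "brain"), brain_margin_cm, sp)
  canalLat <- expandLateral(getMask(sv, "spinal_canal"), canal_margin_cm, sp)
  list(brainExp = brainExp, canalLat = canalLat, spineTarget = canalLat)
}
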