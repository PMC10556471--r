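#' Construct a VoxelVolume
#'
#' @param voxels 3D numeric array.
#' @param spacing voxel spacing in mm, length 3.
#' @param origin mm coordinate of the first voxel centre, length 3.
#' @return A [VoxelVolume-class] object.
#' @export
voxelVolume <- function(voxels, spacing, origin = c(0, 0, 0)) {
  new("VoxelVolume", voxels = voxels, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Construct a LabeledVolume
#'
#' @param masks named list of logical 3D arrays on a shared grid.
#' @param spacing voxel spacing in mm, length 3.
#' @param origin mm coordinate of the first voxel centre, length 3.
#' @return A [LabeledVolume-class] object.
#' @export
labeledVolume <- function(masks, spacing, origin = c(0, 0, 0)) {
  stopifnot(length(masks) >= 1)
  new("LabeledVolume", dim = dim(masks[[1]]), spacing = as.numeric(spacing),
      origin = as.numeric(origin), masks = masks)
}

#' The structure-name vocabulary
#'
#' The 18 structure names the planner and evaluator know about. Paired organs
#' (eyes, lenses, optic nerves, lacrimal glands, cochleae, lungs, kidneys,
#' shoulders) are stored as a single mask holding both sides.
#'
#' @return Character vector of canonical structure names.
#' @export
structureNames <- function() {
  c("body", "brain", "brainstem", "spinal_canal", "vertebral_column",
    "cribriform_plate", "eyes", "lenses", "optic_nerves", "lacrimal_glands",
    "pituitary", "cochleae", "mandible", "thyroid", "lungs", "heart",
    "kidneys", "shoulders")
}

## synonym table: lowercase, punctuation-stripped -> canonical
.structureSynonyms <- c(
  spinalcanal = "spinal_canal", canal = "spinal_canal", cord = "spinal_canal",
  vertebralcolumn = "vertebral_column", spine = "vertebral_column",
  cribriformplate = "cribriform_plate", cribriform = "cribriform_plate",
  eye = "eyes", lens = "lenses",
  opticnerve = "optic_nerves", opticnerves = "optic_nerves",
  lacrimal = "lacrimal_glands", lacrimalgland = "lacrimal_glands",
  lacrimalglands = "lacrimal_glands",
  pituitarygland = "pituitary", cochlea = "cochleae",
  lung = "lungs", kidney = "kidneys", shoulder = "shoulders",
  external = "body", skin = "body")

#' Resolve a structure name against a set of available names
#'
#' Matching is case-insensitive, ignores underscores/spaces/hyphens, and
#' accepts common synonyms ("SpinalCanal", "cord", "Lung", ...).
#'
#' @param name queried name.
#' @param available candidate names (default: the canonical vocabulary).
#' @return The matched element of `available`, or `NA_character_`.
#' @export
matchStructureName <- function(name, available = structureNames()) {
  norm <- function(x) gsub("[^a-z0-9]", "", tolower(x))
  q <- norm(name)
  if (q %in% names(.structureSynonyms)) q <- norm(.structureSynonyms[[q]])
  hit <- which(norm(available) == q)
  if (length(hit)) available[hit[1]] else NA_character_
}

#' Construct a PhantomSpec
#'
#' Defaults describe a typical compatible pediatric patient: 30 cm spinal
#' canal, 2.5 cm mandible-shoulder feathering space, a 3 mm planning grid.
#'
#' @param canal_length_cm spinal-canal longitudinal extent, cm (20-70).
#' @param head_tilt_deg chin-tuck angle, degrees; larger tilt raises the
#'   mandible and shortens the brain-to-mandible distance.
#' @param mandible_shoulder_gap_cm feathering space, cm.
#' @param body_height_cm nominal height, cm.
#' @param voxel_spacing_mm in-plane spacing (x, y), mm; may be length 2 or 3.
#' @param slice_thickness_mm axial spacing, mm (1-3 typical).
#' @param seed integer jitter seed.
#' @param include_contrast_kidneys raise kidney density slightly.
#' @return A [PhantomSpec-class] object.
#' @export
phantomSpec <- function(canal_length_cm = 30, head_tilt_deg = 10,
                        mandible_shoulder_gap_cm = 2.5, body_height_cm = 120,
                        voxel_spacing_mm = c(3, 3, 3), slice_thickness_mm = 3,
                        seed = 1L, include_contrast_kidneys = FALSE) {
  sp <- as.numeric(voxel_spacing_mm)
  if (length(sp) == 2L) sp <- c(sp, slice_thickness_mm)
  sp[3] <- slice_thickness_mm
  obj <- try(new("PhantomSpec", canal_length_cm = canal_length_cm,
                 head_tilt_deg = head_tilt_deg,
                 mandible_shoulder_gap_cm = mandible_shoulder_gap_cm,
                 body_height_cm = body_height_cm, voxel_spacing_mm = sp,
                 slice_thickness_mm = slice_thickness_mm,
                 seed = as.integer(seed),
                 include_contrast_kidneys = isTRUE(include_contrast_kidneys)),
             silent = TRUE)
  if (inherits(obj, "try-error"))
    stop("invalid phantom spec: ", attr(obj, "condition")$message, call. = FALSE)
  obj
}

#' Construct MachineLimits
#'
#' @param max_field_len_at_iso_cm maximum field length at iso (default 36 cm,
#'   leaving junction margin within a 40 cm aperture).
#' @param sad_cm source-axis distance (default 100 cm).
#' @param extended_ssd_cm extended-setup SSD to couch top (default 120 cm).
#' @param leaf_width_at_iso_cm MLC leaf width at iso (default 0.5 cm).
#' @return A [MachineLimits-class] object.
#' @export
machineLimits <- function(max_field_len_at_iso_cm = 36, sad_cm = 100,
                          extended_ssd_cm = 120, leaf_width_at_iso_cm = 0.5) {
  new("MachineLimits", max_field_len_at_iso_cm = max_field_len_at_iso_cm,
      sad_cm = sad_cm, extended_ssd_cm = extended_ssd_cm,
      leaf_width_at_iso_cm = leaf_width_at_iso_cm)
}

#' Construct a Prescription
#'
#' @param total_dose_gy prescription dose (default 23.4 Gy in 13 fractions).
#' @param n_fractions number of fractions.
#' @param feather_fractions fractions per feathered sub-plan (default 5, 5, 3).
#' @param brain_coverage_rule fraction of brain volume required at 95% of Rx.
#' @param spine_coverage_rule fraction of canal volume required at 95% of Rx.
#' @return A [Prescription-class] object.
#' @export
prescription <- function(total_dose_gy = 23.4, n_fractions = 13,
                         feather_fractions = c(5, 5, 3),
                         brain_coverage_rule = 1.00,
                         spine_coverage_rule = 0.95) {
  new("Prescription", total_dose_gy = total_dose_gy, n_fractions = n_fractions,
      feather_fractions = as.numeric(feather_fractions),
      brain_coverage_rule = brain_coverage_rule,
      spine_coverage_rule = spine_coverage_rule)
}

#' Construct BeamModelParams
#'
#' @param mu_eff_cm_inv effective attenuation beyond dmax (default 0.05 /cm).
#' @param dmax_cm build-up depth (default 1.5 cm).
#' @param penumbra_sigma_cm penumbra width at iso (default 0.3 cm).
#' @param leaf_transmission out-of-aperture transmission (default 0.02).
#' @param step_mm ray-marching step; NA means half the minimum voxel dimension.
#' @return A [BeamModelParams-class] object.
#' @export
beamModel <- function(mu_eff_cm_inv = 0.05, dmax_cm = 1.5,
                      penumbra_sigma_cm = 0.3, leaf_transmission = 0.02,
                      step_mm = NA_real_) {
  new("BeamModelParams", mu_eff_cm_inv = mu_eff_cm_inv, dmax_cm = dmax_cm,
      penumbra_sigma_cm = penumbra_sigma_cm,
      leaf_transmission = leaf_transmission, step_mm = step_mm)
}

#' Construct a Beam
#'
#' @param label field name.
#' @param gantry_deg,collimator_deg IEC angles (degrees).
#' @param isocenter_mm isocenter, patient LPS mm.
#' @param jaws_cm numeric(4): x1, x2, y1, y2 at iso (cm).
#' @param mlc n x 2 matrix of (left, right) leaf positions (cm); may be empty.
#' @param mlc_edges_cm leaf-track boundaries along v (cm), length n+1.
#' @param sad_cm source-axis distance (cm).
#' @param ssd_setup_cm extended-setup SSD, or NA for isocentric setup.
#' @param weight beam weight.
#' @return A [Beam-class] object.
#' @export
newBeam <- function(label, gantry_deg, isocenter_mm, jaws_cm,
                    mlc = matrix(numeric(0), 0, 2), mlc_edges_cm = numeric(0),
                    collimator_deg = 0, sad_cm = 100, ssd_setup_cm = NA_real_,
                    weight = 1) {
  new("Beam", label = label, gantry_deg = gantry_deg,
      collimator_deg = collimator_deg, couch_deg = 0,
      isocenter_mm = as.numeric(isocenter_mm), sad_cm = sad_cm,
      ssd_setup_cm = ssd_setup_cm, jaws_cm = as.numeric(jaws_cm), mlc = mlc,
      mlc_edges_cm = as.numeric(mlc_edges_cm), energy_mv = 6, weight = weight)
}

## ---- accessors ----

#' @describeIn VoxelVolume-class the raw voxel array
#' @param x a VoxelVolume
#' @export
setMethod("as.array", "VoxelVolume", function(x) x@voxels)

#' Grid accessors
#'
#' @param object a VoxelVolume, LabeledVolume or CSIPhantom.
#' @return `voxelSpacing` and `voxelOrigin` return numeric(3) in mm;
#'   `structureMasks` the named list of logical masks.
#' @export
setGeneric("voxelSpacing", function(object) standardGeneric("voxelSpacing"))
#' @rdname voxelSpacing
#' @export
setGeneric("voxelOrigin", function(object) standardGeneric("voxelOrigin"))
#' @rdname voxelSpacing
#' @export
setGeneric("structureMasks", function(object) standardGeneric("structureMasks"))

#' @rdname voxelSpacing
setMethod("voxelSpacing", "VoxelVolume", function(object) object@spacing)
#' @rdname voxelSpacing
setMethod("voxelSpacing", "LabeledVolume", function(object) object@spacing)
#' @rdname voxelSpacing
setMethod("voxelSpacing", "CSIPhantom", function(object) object@structures@spacing)
#' @rdname voxelSpacing
setMethod("voxelOrigin", "VoxelVolume", function(object) object@origin)
#' @rdname voxelSpacing
setMethod("voxelOrigin", "LabeledVolume", function(object) object@origin)
#' @rdname voxelSpacing
setMethod("structureMasks", "LabeledVolume", function(object) object@masks)
#' @rdname voxelSpacing
setMethod("structureMasks", "CSIPhantom", function(object) object@structures@masks)

#' Phantom component accessors
#'
#' @param object a [CSIPhantom-class].
#' @return the density [VoxelVolume-class] or structure [LabeledVolume-class].
#' @export
setGeneric("densityVolume", function(object) standardGeneric("densityVolume"))
#' @rdname densityVolume
#' @export
setGeneric("structureSet", function(object) standardGeneric("structureSet"))
#' @rdname densityVolume
setMethod("densityVolume", "CSIPhantom", function(object) object@density)
#' @rdname densityVolume
setMethod("structureSet", "CSIPhantom", function(object) object@structures)

#' Composite dose of a plan
#'
#' @param object a [CompositePlan-class].
#' @return the composite full-course dose as a [VoxelVolume-class].
#' @export
setGeneric("compositeDose", function(object) standardGeneric("compositeDose"))
#' @rdname compositeDose
setMethod("compositeDose", "CompositePlan", function(object) object@composite_dose)

#' Plan acceptance verdict
#'
#' @param object a [CompatibilityReport-class].
#' @return TRUE iff planning may proceed (no rejection reasons).
#' @export
setGeneric("isAccepted", function(object) standardGeneric("isAccepted"))
#' @rdname isAccepted
setMethod("isAccepted", "CompatibilityReport",
          function(object) length(object@reasons) == 0L)

## ---- show methods ----

setMethod("show", "VoxelVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("VoxelVolume %d x %d x %d, spacing %s mm, range [%.3g, %.3g]\n",
              d[1], d[2], d[3], paste(format(object@spacing), collapse = " x "),
              min(object@voxels), max(object@voxels)))
})

setMethod("show", "LabeledVolume", function(object) {
  cat(sprintf("LabeledVolume %d x %d x %d, spacing %s mm\n%d structures: %s\n",
              object@dim[1], object@dim[2], object@dim[3],
              paste(format(object@spacing), collapse = " x "),
              length(object@masks),
              paste(names(object@masks), collapse = ", ")))
})

setMethod("show", "CSIPhantom", function(object) {
  s <- object@spec
  cat(sprintf(paste0("CSIPhantom: canal %.1f cm, tilt %.1f deg, gap %.1f cm, ",
                     "height %.0f cm, slices %.1f mm (seed %d)\n"),
              s@canal_length_cm, s@head_tilt_deg, s@mandible_shoulder_gap_cm,
              s@body_height_cm, s@slice_thickness_mm, s@seed))
  show(object@structures)
})

setMethod("show", "CompatibilityReport", function(object) {
  cat("CSI compatibility pre-check\n")
  m <- object@measurements
  cat(sprintf("  canal length     : %.1f cm -> %s configuration\n",
              m[["canal_length_cm"]], object@field_config))
  cat(sprintf("  feather space    : %.1f cm -> %s\n", m[["feather_space_cm"]],
              if (object@feather_ok)
                sprintf("%.1f cm junction spacing", object@junction_spacing_cm)
              else "REJECTED"))
  cat(sprintf("  brain-to-mandible: %.1f cm -> half-beam %s\n",
              m[["brain_to_mandible_cm"]],
              if (object@half_beam_ok) "ok" else "REJECTED"))
  if (length(object@reasons))
    cat("  reasons:\n", paste0("   - ", object@reasons, collapse = "\n"), "\n")
  else cat("  verdict: accepted\n")
})

setMethod("show", "Beam", function(object) {
  cat(sprintf(paste0("Beam '%s': gantry %g, coll %.2f, %d MV, SAD %g cm%s\n",
                     "  jaws (x1 x2 y1 y2) = %s cm, %d MLC pairs, weight %.4g\n"),
              object@label, object@gantry_deg, object@collimator_deg,
              object@energy_mv, object@sad_cm,
              if (is.na(object@ssd_setup_cm)) ""
              else sprintf(", setup SSD %g cm", object@ssd_setup_cm),
              paste(sprintf("%.2f", object@jaws_cm), collapse = " "),
              nrow(object@mlc), object@weight))
})

setMethod("show", "FieldSet", function(object) {
  cat(sprintf("FieldSet (%s): %d brain + %d spine beams, %d subfields, junction z = %s mm\n",
              object@config, length(object@brain_beams),
              length(object@spine_beams), length(object@spine_subfields),
              paste(sprintf("%.1f", object@junction_z_mm), collapse = ", ")))
})

setMethod("show", "CompositePlan", function(object) {
  rx <- object@prescription
  cat(sprintf("CompositePlan (%s): %.1f Gy / %g fx, feather fractions %s\n",
              object@sub_plans[[1]]@config, rx@total_dose_gy, rx@n_fractions,
              paste(rx@feather_fractions, collapse = "-")))
  cat(sprintf("  normalization scalars (brain, spine) per sub-plan: %s\n",
              paste(apply(object@normalization_scalars, 1, function(r)
                sprintf("(%.3f, %.3f)", r[1], r[2])), collapse = " ")))
  show(object@composite_dose)
})

setMethod("show", "PlanReport", function(object) {
  cat(planReportMarkdown(object), sep = "\n")
})
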