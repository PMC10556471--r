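#' @import methods
NULL

## Patient coordinate convention used throughout: LPS in mm, head-first-supine,
## x = patient left, y = posterior, z = superior (= increasing slice index).
## A volume's `origin` is the coordinate of the centre of voxel [1, 1, 1].

#' VoxelVolume: a scalar field on a regular grid
#'
#' Container for a 3D scalar array (density in g/cc, or absorbed dose in Gy)
#' together with its grid geometry. Axes are LPS; `origin` is the mm
#' coordinate of the centre of the first voxel.
#'
#' @slot voxels 3D numeric array.
#' @slot spacing numeric(3), voxel spacing in mm (x, y, z).
#' @slot origin numeric(3), mm coordinate of voxel \[1,1,1\]'s centre.
#' @export
setClass("VoxelVolume",
  representation(voxels = "array", spacing = "numeric", origin = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(dim(object@voxels)) != 3L) msg <- c(msg, "voxels must be a 3D array")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      msg <- c(msg, "spacing must be 3 positive values (mm)")
    if (length(object@origin) != 3L) msg <- c(msg, "origin must have length 3")
    if (any(!is.finite(object@voxels))) msg <- c(msg, "voxels must be finite")
    if (is.null(msg)) TRUE else msg
  }
)

#' LabeledVolume: a structure set on a shared grid
#'
#' Named binary structure masks (logical arrays) sharing one voxel grid.
#' Planning requires at least `brain`, `spinal_canal`, `mandible`,
#' `shoulders` and `body`; the full vocabulary holds the 18 structures the
#' planner and evaluator know about (see [structureNames()]).
#'
#' @slot dim integer(3) grid dimensions.
#' @slot spacing numeric(3) voxel spacing, mm.
#' @slot origin numeric(3) mm coordinate of the first voxel centre.
#' @slot masks named list of logical 3D arrays, all with dimension `dim`.
#' @export
setClass("LabeledVolume",
  representation(dim = "integer", spacing = "numeric", origin = "numeric",
                 masks = "list"),
  validity = function(object) {
    msg <- NULL
    if (length(object@dim) != 3L) msg <- c(msg, "dim must have length 3")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      msg <- c(msg, "spacing must be 3 positive values (mm)")
    if (length(object@origin) != 3L) msg <- c(msg, "origin must have length 3")
    if (length(object@masks)) {
      if (is.null(names(object@masks)) || any(!nzchar(names(object@masks))))
        msg <- c(msg, "all masks must be named")
      for (nm in names(object@masks)) {
        m <- object@masks[[nm]]
        if (!is.logical(m) || !identical(dim(m), object@dim))
          msg <- c(msg, sprintf("mask '%s' must be a logical array on the shared grid", nm))
      }
    }
    if (is.null(msg)) TRUE else msg
  }
)

#' PhantomSpec: parameters of a synthetic pediatric phantom
#'
#' @slot canal_length_cm target longitudinal extent of the spinal canal (cm),
#'   must lie in \[20, 70\].
#' @slot head_tilt_deg chin-tuck angle (degrees). Larger tilt raises the
#'   mandible's inferior edge and so shortens the brain-to-mandible distance.
#' @slot mandible_shoulder_gap_cm longitudinal clearance between the mandible
#'   inferior edge and the shoulder superior edge (cm) -- the feathering space.
#' @slot body_height_cm nominal patient height (cm), scales torso cross-sections.
#' @slot voxel_spacing_mm numeric(3) grid spacing (x, y, z) in mm; the z value
#'   is overridden by `slice_thickness_mm`.
#' @slot slice_thickness_mm axial slice thickness (mm).
#' @slot seed integer RNG seed controlling small organ-placement jitter.
#' @slot include_contrast_kidneys logical; if TRUE the kidney density is
#'   raised slightly (cosmetic contrast stand-in).
#' @export
setClass("PhantomSpec",
  representation(canal_length_cm = "numeric", head_tilt_deg = "numeric",
                 mandible_shoulder_gap_cm = "numeric", body_height_cm = "numeric",
                 voxel_spacing_mm = "numeric", slice_thickness_mm = "numeric",
                 seed = "integer", include_contrast_kidneys = "logical"),
  validity = function(object) {
    msg <- NULL
    chk1 <- function(x, nm) if (length(slot(object, x)) != 1L || !is.finite(slot(object, x)))
      sprintf("%s must be a single finite value", nm) else NULL
    for (f in c("canal_length_cm", "head_tilt_deg", "mandible_shoulder_gap_cm",
                "body_height_cm", "slice_thickness_mm"))
      msg <- c(msg, chk1(f, f))
    if (is.null(msg)) {
      if (object@canal_length_cm < 20 || object@canal_length_cm > 70)
        msg <- c(msg, "canal_length_cm must lie in [20, 70]")
      if (object@mandible_shoulder_gap_cm < 0)
        msg <- c(msg, "mandible_shoulder_gap_cm must be >= 0")
      if (object@body_height_cm <= 0) msg <- c(msg, "body_height_cm must be > 0")
      if (length(object@voxel_spacing_mm) != 3L || any(object@voxel_spacing_mm <= 0))
        msg <- c(msg, "voxel_spacing_mm must be 3 positive values")
      if (object@slice_thickness_mm <= 0) msg <- c(msg, "slice_thickness_mm must be > 0")
      if (length(object@seed) != 1L || is.na(object@seed))
        msg <- c(msg, "seed must be a single integer")
    }
    if (is.null(msg)) TRUE else msg
  }
)

#' CSIPhantom: generated phantom (density + structure set)
#'
#' @slot density a [VoxelVolume] of mass density (g/cc).
#' @slot structures a co-registered [LabeledVolume] with 18 structure masks.
#' @slot spec the [PhantomSpec] the phantom was generated from.
#' @export
setClass("CSIPhantom",
  representation(density = "VoxelVolume", structures = "LabeledVolume",
                 spec = "PhantomSpec"),
  validity = function(object) {
    if (!identical(dim(object@density@voxels), object@structures@dim))
      "density and structures must share one grid" else TRUE
  }
)

#' MachineLimits: treatment-machine geometry limits
#'
#' @slot max_field_len_at_iso_cm maximum usable field length at isocenter (cm).
#' @slot sad_cm source-to-axis distance (cm).
#' @slot extended_ssd_cm source-to-surface distance for extended spine fields (cm).
#' @slot leaf_width_at_iso_cm MLC leaf width projected to isocenter (cm).
#' @export
setClass("MachineLimits",
  representation(max_field_len_at_iso_cm = "numeric", sad_cm = "numeric",
                 extended_ssd_cm = "numeric", leaf_width_at_iso_cm = "numeric"),
  validity = function(object) {
    msg <- NULL
    v <- c(object@max_field_len_at_iso_cm, object@sad_cm,
           object@extended_ssd_cm, object@leaf_width_at_iso_cm)
    if (length(v) != 4L || any(!is.finite(v)) || any(v <= 0))
      msg <- c(msg, "all machine limits must be single positive values")
    else if (object@extended_ssd_cm < object@sad_cm)
      msg <- c(msg, "extended_ssd_cm must be >= sad_cm")
    if (is.null(msg)) TRUE else msg
  }
)

#' CompatibilityReport: anatomical pre-check verdicts
#'
#' @slot junction_spacing_cm chosen junction spacing, 1.0 or 0.5 cm (NA when
#'   rejected for insufficient feathering space).
#' @slot feather_ok FALSE iff the mandible-shoulder feathering space is < 1 cm.
#' @slot half_beam_ok FALSE iff the brain-to-mandible distance exceeds 20 cm.
#' @slot field_config one of "SINGLE", "EXTENDED", "MULTIPLE".
#' @slot reasons character vector of human-readable rejection reasons (empty
#'   iff planning may proceed).
#' @slot measurements named numeric: canal_length_cm, brain_to_mandible_cm,
#'   feather_space_cm.
#' @export
setClass("CompatibilityReport",
  representation(junction_spacing_cm = "numeric", feather_ok = "logical",
                 half_beam_ok = "logical", field_config = "character",
                 reasons = "character", measurements = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!is.na(object@junction_spacing_cm) &&
        !object@junction_spacing_cm %in% c(1.0, 0.5))
      msg <- c(msg, "junction_spacing_cm must be 1.0, 0.5 or NA")
    if (!object@field_config %in% c("SINGLE", "EXTENDED", "MULTIPLE"))
      msg <- c(msg, "field_config must be SINGLE, EXTENDED or MULTIPLE")
    need <- c("canal_length_cm", "brain_to_mandible_cm", "feather_space_cm")
    if (!all(need %in% names(object@measurements)))
      msg <- c(msg, "measurements must contain canal_length_cm, brain_to_mandible_cm, feather_space_cm")
    if (is.null(msg)) TRUE else msg
  }
)

#' Beam: a single treatment field
#'
#' Angles follow IEC 61217; couch is fixed at 0 and energy at 6 MV. Jaws and
#' MLC leaf positions are expressed in cm in the isocenter plane, in the
#' beam's-eye-view (BEV) frame: `u` is the leaf-travel (crossplane) axis, `v`
#' the inplane axis (patient-superior positive for collimator 0).
#'
#' @slot label field name.
#' @slot gantry_deg gantry angle (90/270 laterals, 180 PA).
#' @slot collimator_deg collimator rotation about the beam axis (degrees).
#' @slot couch_deg always 0.
#' @slot isocenter_mm numeric(3) isocenter in patient LPS mm.
#' @slot sad_cm source-axis distance (cm).
#' @slot ssd_setup_cm nominal source-surface distance for extended-SSD setups
#'   (NA for standard isocentric fields).
#' @slot jaws_cm numeric(4): x1, x2, y1, y2 at the isocenter plane (cm),
#'   asymmetric allowed, x1 <= x2 and y1 <= y2.
#' @slot mlc numeric matrix n x 2 (left, right) leaf positions (cm at iso);
#'   zero rows means an open (jaw-only) field.
#' @slot mlc_edges_cm numeric(n+1) leaf-track boundaries along v (cm at iso).
#' @slot energy_mv always 6.
#' @slot weight non-negative beam weight (1 weight unit = 1 Gy at dmax,
#'   on-axis, SSD 100).
#' @export
setClass("Beam",
  representation(label = "character", gantry_deg = "numeric",
                 collimator_deg = "numeric", couch_deg = "numeric",
                 isocenter_mm = "numeric", sad_cm = "numeric",
                 ssd_setup_cm = "numeric", jaws_cm = "numeric",
                 mlc = "matrix", mlc_edges_cm = "numeric",
                 energy_mv = "numeric", weight = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@couch_deg != 0) msg <- c(msg, "couch_deg is fixed at 0")
    if (object@energy_mv != 6) msg <- c(msg, "energy_mv is fixed at 6")
    if (length(object@jaws_cm) != 4L) msg <- c(msg, "jaws_cm must be (x1, x2, y1, y2)")
    else {
      if (object@jaws_cm[1] > object@jaws_cm[2]) msg <- c(msg, "jaw x1 must be <= x2")
      if (object@jaws_cm[3] > object@jaws_cm[4]) msg <- c(msg, "jaw y1 must be <= y2")
    }
    if (length(object@isocenter_mm) != 3L) msg <- c(msg, "isocenter_mm must have length 3")
    if (nrow(object@mlc)) {
      if (ncol(object@mlc) != 2L) msg <- c(msg, "mlc must have two columns (left, right)")
      else if (any(object@mlc[, 1] > object@mlc[, 2] + 1e-9))
        msg <- c(msg, "each MLC pair must satisfy left <= right")
      if (length(object@mlc_edges_cm) != nrow(object@mlc) + 1L)
        msg <- c(msg, "mlc_edges_cm must have nrow(mlc)+1 entries")
      else if (is.unsorted(object@mlc_edges_cm, strictly = TRUE))
        msg <- c(msg, "mlc_edges_cm must be strictly increasing")
    }
    if (object@weight < 0) msg <- c(msg, "weight must be non-negative")
    if (is.null(msg)) TRUE else msg
  }
)

#' FieldSet: the fields of one CSI sub-plan
#'
#' @slot brain_beams list of the 2 opposed lateral brain beams (gantry 90/270).
#' @slot spine_beams list of 1 (SINGLE/EXTENDED) or 2 (MULTIPLE) PA spine beams.
#' @slot spine_subfields list of reduced-aperture spine subfield beams.
#' @slot junction_z_mm z positions (mm) of the match planes: 1 for
#'   SINGLE/EXTENDED (cranio-spinal), 2 for MULTIPLE (+ spine-spine).
#' @slot config the field configuration this set realises.
#' @export
setClass("FieldSet",
  representation(brain_beams = "list", spine_beams = "list",
                 spine_subfields = "list", junction_z_mm = "numeric",
                 config = "character"),
  validity = function(object) {
    msg <- NULL
    if (length(object@brain_beams) != 2L) msg <- c(msg, "need exactly 2 brain beams")
    g <- vapply(object@brain_beams, function(b) b@gantry_deg, numeric(1))
    if (length(g) == 2L && !setequal(g, c(90, 270)))
      msg <- c(msg, "brain gantries must be {90, 270}")
    if (!length(object@spine_beams) %in% 1:2)
      msg <- c(msg, "need 1 or 2 spine beams")
    gs <- vapply(object@spine_beams, function(b) b@gantry_deg, numeric(1))
    if (any(gs != 180)) msg <- c(msg, "spine gantry must be 180")
    nj <- if (object@config == "MULTIPLE") 2L else 1L
    if (length(object@junction_z_mm) != nj)
      msg <- c(msg, sprintf("expected %d junction plane(s) for %s", nj, object@config))
    if (is.null(msg)) TRUE else msg
  }
)

#' BeamModelParams: parameters of the analytic 6 MV dose model
#'
#' @slot mu_eff_cm_inv effective linear attenuation beyond dmax (1/cm).
#' @slot dmax_cm build-up depth of maximum dose (cm).
#' @slot penumbra_sigma_cm Gaussian penumbra width at the isocenter plane (cm).
#' @slot leaf_transmission fractional fluence outside the aperture.
#' @slot step_mm ray-marching step for radiological depth (mm); defaults to
#'   half the minimum voxel dimension when NA.
#' @export
setClass("BeamModelParams",
  representation(mu_eff_cm_inv = "numeric", dmax_cm = "numeric",
                 penumbra_sigma_cm = "numeric", leaf_transmission = "numeric",
                 step_mm = "numeric"),
  validity = function(object) {
    v <- c(object@mu_eff_cm_inv, object@dmax_cm, object@penumbra_sigma_cm,
           object@leaf_transmission)
    if (any(!is.finite(v)) || any(v <= 0)) return("all dose-model parameters must be positive")
    if (object@leaf_transmission >= 1) return("leaf_transmission must be < 1")
    TRUE
  }
)

#' Prescription: dose prescription and normalization rules
#'
#' @slot total_dose_gy prescription dose (default 23.4 Gy).
#' @slot n_fractions number of fractions (default 13).
#' @slot feather_fractions ordered triple of fractions delivered with each of
#'   the three feathered sub-plans (default 5, 5, 3); must sum to n_fractions.
#' @slot brain_coverage_rule fraction of brain volume that must receive 95% of
#'   the prescription (default 1.00).
#' @slot spine_coverage_rule fraction of spinal-canal volume that must receive
#'   95% of the prescription (default 0.95).
#' @export
setClass("Prescription",
  representation(total_dose_gy = "numeric", n_fractions = "numeric",
                 feather_fractions = "numeric", brain_coverage_rule = "numeric",
                 spine_coverage_rule = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@total_dose_gy <= 0) msg <- c(msg, "total_dose_gy must be > 0")
    if (length(object@feather_fractions) != 3L)
      msg <- c(msg, "feather_fractions must be an ordered triple")
    else if (abs(sum(object@feather_fractions) - object@n_fractions) > 1e-9)
      msg <- c(msg, "feather_fractions must sum to n_fractions")
    for (f in c("brain_coverage_rule", "spine_coverage_rule")) {
      v <- slot(object, f)
      if (v <= 0 || v > 1) msg <- c(msg, sprintf("%s must lie in (0, 1]", f))
    }
    if (is.null(msg)) TRUE else msg
  }
)

#' CompositePlan: three feathered sub-plans and their composite dose
#'
#' @slot sub_plans list of 3 [FieldSet]s (original + 2 junction-shifted).
#' @slot fraction_weights numeric(3), feather fractions / n_fractions.
#' @slot normalization_scalars 3 x 2 matrix of (brain, spine) scalars per sub-plan.
#' @slot subfield_weights optimized spine-subfield weights.
#' @slot composite_dose [VoxelVolume] of full-course composite dose (Gy).
#' @slot sub_plan_doses list of 3 normalized full-course sub-plan dose arrays.
#' @slot prescription the [Prescription] used.
#' @slot report the accepted [CompatibilityReport].
#' @export
setClass("CompositePlan",
  representation(sub_plans = "list", fraction_weights = "numeric",
                 normalization_scalars = "matrix", subfield_weights = "numeric",
                 composite_dose = "VoxelVolume", sub_plan_doses = "list",
                 prescription = "Prescription", report = "CompatibilityReport"),
  validity = function(object) {
    msg <- NULL
    if (length(object@sub_plans) != 3L) msg <- c(msg, "need 3 sub-plans")
    if (length(object@fraction_weights) != 3L ||
        abs(sum(object@fraction_weights) - 1) > 1e-9)
      msg <- c(msg, "fraction_weights must be 3 values summing to 1")
    if (any(object@normalization_scalars <= 0))
      msg <- c(msg, "normalization scalars must be > 0")
    if (is.null(msg)) TRUE else msg
  }
)

#' PlanReport: the quantitative plan-quality panel
#'
#' Holds V95 for the targets, maximum dose for serial structures, mean dose
#' for parallel structures (Gy and % of prescription), and the 107% hotspot
#' volume, mirroring a standard CSI plan evaluation.
#'
#' @slot metrics data.frame with columns structure, metric, value_gy,
#'   value_pct_rx, value_pct (V95 rows), present.
#' @slot hotspot_cc body volume receiving >= 107% of the prescription (cc).
#' @slot rx_gy the prescription dose the percentages refer to.
#' @export
setClass("PlanReport",
  representation(metrics = "data.frame", hotspot_cc = "numeric", rx_gy = "numeric"))
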