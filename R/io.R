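## Format round-tripping: NIfTI volumes, JSON manifests / plans / reports.

#' Write / read a VoxelVolume as NIfTI
#'
#' Grid spacing travels in the NIfTI pixdim; the origin is carried separately
#' in the JSON manifests (the package works in plain LPS mm).
#'
#' @param vol a [VoxelVolume-class].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `writeVolume` the path, invisibly; `readVolume` a
#'   [VoxelVolume-class].
#' @export
writeVolume <- function(vol, path) {
  img <- RNifti::asNifti(vol@voxels)
  RNifti::pixdim(img) <- gridSpacing(vol)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeVolume
#' @param path input path.
#' @param origin grid origin override (mm).
#' @export
readVolume <- function(path, origin = c(0, 0, 0)) {
  img <- RNifti::readNifti(path)
  voxelVolume(array(as.numeric(img), dim(img)), RNifti::pixdim(img), origin)
}

#' Write a phantom to a directory
#'
#' Writes the density volume and one NIfTI mask per structure, plus a JSON
#' manifest mapping structure names to files and carrying the grid geometry
#' and generating spec.
#'
#' @param phantom a [CSIPhantom-class].
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
writePhantom <- function(phantom, dir) {
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  sv <- structureSet(phantom)
  writeVolume(densityVolume(phantom), file.path(dir, "density.nii.gz"))
  files <- list()
  for (nm in names(sv@masks)) {
    f <- file.path("masks", paste0(nm, ".nii.gz"))
    vol <- voxelVolume(array(as.numeric(sv@masks[[nm]]), dim(sv@masks[[nm]])),
                       gridSpacing(sv), gridOrigin(sv))
    writeVolume(vol, file.path(dir, f))
    files[[nm]] <- f
  }
  s <- phantom@spec
  manifest <- list(
    density = "density.nii.gz", structures = files,
    spacing_mm = gridSpacing(sv), origin_mm = gridOrigin(sv),
    orientation = "LPS",
    spec = list(canal_length_cm = s@canal_length_cm,
                head_tilt_deg = s@head_tilt_deg,
                mandible_shoulder_gap_cm = s@mandible_shoulder_gap_cm,
                body_height_cm = s@body_height_cm,
                voxel_spacing_mm = s@voxel_spacing_mm,
                slice_thickness_mm = s@slice_thickness_mm,
                seed = s@seed,
                include_contrast_kidneys = s@include_contrast_kidneys))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a phantom from a manifest
#'
#' @param path manifest.json path, or the directory containing it.
#' @return a [CSIPhantom-class].
#' @export
readPhantom <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.json")
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  dir <- dirname(path)
  origin <- as.numeric(man$origin_mm)
  dens <- readVolume(file.path(dir, man$density), origin)
  masks <- lapply(man$structures, function(f) {
    v <- readVolume(file.path(dir, f), origin)
    array(v@voxels > 0.5, dim(v@voxels))
  })
  names(masks) <- names(man$structures)
  spec <- do.call(phantomSpec, man$spec)
  new("CSIPhantom", density = dens,
      structures = labeledVolume(masks, as.numeric(man$spacing_mm), origin),
      spec = spec)
}

beamToList <- function(b) {
  list(label = b@label, gantry_deg = b@gantry_deg,
       collimator_deg = b@collimator_deg, couch_deg = b@couch_deg,
       isocenter_mm = b@isocenter_mm, sad_cm = b@sad_cm,
       ssd_setup_cm = if (is.na(b@ssd_setup_cm)) NULL else b@ssd_setup_cm,
       jaws_cm = b@jaws_cm,
       mlc_left_cm = b@mlc[, 1], mlc_right_cm = b@mlc[, 2],
       mlc_edges_cm = b@mlc_edges_cm,
       energy_mv = b@energy_mv, weight = b@weight)
}

listToBeam <- function(l) {
  ssd <- l$ssd_setup_cm
  ssd <- if (is.null(ssd) || !length(ssd)) NA_real_ else as.numeric(ssd)
  newBeam(l$label, l$gantry_deg, as.numeric(l$isocenter_mm),
          as.numeric(l$jaws_cm),
          mlc = cbind(as.numeric(l$mlc_left_cm), as.numeric(l$mlc_right_cm)),
          mlc_edges_cm = as.numeric(l$mlc_edges_cm),
          collimator_deg = l$collimator_deg, sad_cm = l$sad_cm,
          ssd_setup_cm = ssd, weight = l$weight)
}

fieldSetToList <- function(fs) {
  list(config = fs@config, junction_z_mm = fs@junction_z_mm,
       coordinate_frame = "LPS, mm; z superior",
       brain_beams = lapply(fs@brain_beams, beamToList),
       spine_beams = lapply(fs@spine_beams, beamToList),
       spine_subfields = lapply(fs@spine_subfields, beamToList))
}

listToFieldSet <- function(l) {
  new("FieldSet", brain_beams = lapply(l$brain_beams, listToBeam),
      spine_beams = lapply(l$spine_beams, listToBeam),
      spine_subfields = lapply(l$spine_subfields, listToBeam),
      junction_z_mm = as.numeric(l$junction_z_mm), config = l$config)
}

#' Write / read a composite plan
#'
#' `plan.json` holds the beams, junctions, weights and normalization scalars;
#' the composite dose is written as NIfTI in Gy.
#'
#' @param plan a [CompositePlan-class].
#' @param dir output directory.
#' @return the plan.json path, invisibly.
#' @export
writePlan <- function(plan, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rx <- plan@prescription
  out <- list(
    prescription = list(total_dose_gy = rx@total_dose_gy,
                        n_fractions = rx@n_fractions,
                        feather_fractions = rx@feather_fractions),
    fraction_weights = plan@fraction_weights,
    normalization_scalars = apply(plan@normalization_scalars, 1, as.list),
    subfield_weights = plan@subfield_weights,
    precheck = list(field_config = plan@report@field_config,
                    junction_spacing_cm = plan@report@junction_spacing_cm,
                    measurements = as.list(plan@report@measurements)),
    sub_plans = lapply(plan@sub_plans, fieldSetToList))
  path <- file.path(dir, "plan.json")
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeVolume(compositeDose(plan), file.path(dir, "composite_dose.nii.gz"))
  invisible(path)
}

#' @rdname writePlan
#' @return `readPlanJSON`: the parsed plan list with `sub_plans` as
#'   [FieldSet-class] objects.
#' @export
readPlanJSON <- function(dir) {
  path <- if (dir.exists(dir)) file.path(dir, "plan.json") else dir
  l <- jsonlite::read_json(path, simplifyVector = FALSE)
  l$fraction_weights <- as.numeric(unlist(l$fraction_weights))
  l$sub_plans <- lapply(l$sub_plans, listToFieldSet)
  l
}

#' Write a plan report (JSON + Markdown) and the DVH table (CSV)
#'
#' @param report a [PlanReport-class].
#' @param dir output directory.
#' @param dvh optional long data.frame from [dvhTable()].
#' @return the report.json path, invisibly.
#' @export
writeReport <- function(report, dir, dvh = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(list(rx_gy = report@rx_gy, hotspot_cc = report@hotspot_cc,
                            metrics = report@metrics),
                       file.path(dir, "report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  writeLines(planReportMarkdown(report), file.path(dir, "report.md"))
  if (!is.null(dvh))
    utils::write.csv(dvh, file.path(dir, "dvh.csv"), row.names = FALSE)
  invisible(file.path(dir, "report.json"))
}
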