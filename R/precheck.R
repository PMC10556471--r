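## Automated anatomical compatibility verification, run before any planning.

#' Decide the junction spacing from the available feathering space
#'
#' Feathering uses three junction positions \{z0, z0+s, z0+2s\}, which span
#' twice the spacing `s`, so a 1 cm junction needs at least 2 cm of
#' mandible-shoulder space and a 0.5 cm junction at least 1 cm. Patients with
#' less than 1 cm of space are flagged and rejected.
#'
#' @param feather_space_cm measured mandible-shoulder clearance, cm (>= 0).
#' @return list with `spacing_cm` (1.0, 0.5, or NA) and `reason`
#'   (`NA_character_` when accepted).
#' @export
determineJunctionSpacing <- function(feather_space_cm) {
  stopifnot(is.finite(feather_space_cm), feather_space_cm >= 0)
  if (feather_space_cm < 1.0)
    return(list(spacing_cm = NA_real_,
                reason = sprintf(paste0("insufficient feathering space: %.2f cm ",
                                        "between mandible and shoulders (< 1 cm)"),
                                 feather_space_cm)))
  list(spacing_cm = if (feather_space_cm >= 2.0) 1.0 else 0.5,
       reason = NA_character_)
}

#' Check half-beam-block compatibility of the brain field
#'
#' The brain field uses a half-beam block at the cranio-spinal junction, so
#' the whole brain must fit in one half field: patients whose
#' brain-to-mandible distance is larger than 20 cm are rejected.
#'
#' @param brain_to_mandible_cm measured distance, cm (>= 0).
#' @return list with `ok` (logical) and `reason` (NA when passing).
#' @export
checkHalfBeam <- function(brain_to_mandible_cm) {
  stopifnot(is.finite(brain_to_mandible_cm), brain_to_mandible_cm >= 0)
  if (brain_to_mandible_cm > 20)
    return(list(ok = FALSE,
                reason = sprintf(paste0("brain-to-mandible distance %.1f cm ",
                                        "exceeds the 20 cm half-beam block limit"),
                                 brain_to_mandible_cm)))
  list(ok = TRUE, reason = NA_character_)
}

#' Select the spine field configuration from canal length
#'
#' A canal fitting one field at isocenter gets a SINGLE PA field; one fitting
#' only at extended SSD (field length scales with SSD/SAD) gets an EXTENDED
#' field; anything longer gets two matched (MULTIPLE) fields.
#'
#' @param canal_length_cm measured canal length, cm (> 0).
#' @param limits a [MachineLimits-class]; the single-field cap is
#'   `max_field_len_at_iso_cm` (default 36 cm) and the extended cap is that
#'   value times `extended_ssd_cm / sad_cm` (default 43.2 cm).
#' @return one of `"SINGLE"`, `"EXTENDED"`, `"MULTIPLE"`.
#' @export
selectFieldConfig <- function(canal_length_cm, limits = machineLimits()) {
  if (!is.finite(canal_length_cm) || canal_length_cm <= 0)
    stop("canal_length_cm must be positive")
  L1 <- limits@max_field_len_at_iso_cm
  L2 <- L1 * limits@extended_ssd_cm / limits@sad_cm
  if (canal_length_cm <= L1) "SINGLE"
  else if (canal_length_cm <= L2) "EXTENDED"
  else "MULTIPLE"
}

#' Run the full anatomical pre-check
#'
#' Measures the structure set and aggregates the three compatibility rules:
#' junction-spacing selection, half-beam-block fit, and spine
#' field-configuration selection. Planning proceeds only when the reasons
#' list is empty.
#'
#' @param sv a [LabeledVolume-class] with brain, mandible, shoulders and
#'   spinal_canal masks (or a [CSIPhantom-class], whose structure set is used).
#' @param limits a [MachineLimits-class].
#' @return a [CompatibilityReport-class].
#' @export
runPrecheck <- function(sv, limits = machineLimits()) {
  if (is(sv, "CSIPhantom")) sv <- structureSet(sv)
  meas <- measureAnatomy(sv)
  js <- determineJunctionSpacing(meas[["feather_space_cm"]])
  hb <- checkHalfBeam(meas[["brain_to_mandible_cm"]])
  config <- selectFieldConfig(meas[["canal_length_cm"]], limits)
  reasons <- c(js$reason, hb$reason)
  reasons <- reasons[!is.na(reasons)]
  new("CompatibilityReport",
      junction_spacing_cm = js$spacing_cm,
      feather_ok = !is.na(js$spacing_cm),
      half_beam_ok = hb$ok,
      field_config = config,
      reasons = as.character(reasons),
      measurements = meas)
}
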