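## Anatomical measurements used by the pre-planning checks, and the margin
## expansions that define MLC aperture targets.

#' Measure the longitudinal extent of the spinal canal
#'
#' Length is the superior-inferior (z) span of the canal mask: the number of
#' occupied slices times the slice thickness. (Curved centerline arc length is
#' deliberately not used; field lengths are set along z.)
#'
#' @param sv a [LabeledVolume-class] containing a non-empty `spinal_canal` mask.
#' @return canal length in cm.
#' @export
measureSpinalCanalLength <- function(sv) {
  m <- getMask(sv, "spinal_canal")
  r <- occupiedRange(m, 3L)
  (r[2] - r[1] + 1L) * gridSpacing(sv)[3] / 10
}

#' Measure the brain-to-mandible distance
#'
#' The absolute z-distance between the most superior slice of the brain and
#' the most inferior slice of the mandible: the anatomical length the brain
#' field must span below a half-beam block. A chin tuck raises the mandible
#' and shortens this distance.
#'
#' @param sv a [LabeledVolume-class] with non-empty `brain` and `mandible` masks.
#' @return distance in cm.
#' @export
measureBrainToMandible <- function(sv) {
  brain <- getMask(sv, "brain")
  mand <- getMask(sv, "mandible")
  zTop <- occupiedRange(brain, 3L)[2]
  zBot <- occupiedRange(mand, 3L)[1]
  abs(zTop - zBot) * gridSpacing(sv)[3] / 10
}

#' Measure the feathering space between mandible and shoulders
#'
#' Longitudinal clearance between the mandible's inferior extent and the
#' shoulders' superior extent; clamped to 0 when they overlap. This is the
#' space available to shift the cranio-spinal junction between sub-plans.
#'
#' @param sv a [LabeledVolume-class] with non-empty `mandible` and `shoulders`
#'   masks.
#' @return gap in cm (>= 0).
#' @export
measureFeatherSpace <- function(sv) {
  mand <- getMask(sv, "mandible")
  sh <- getMask(sv, "shoulders")
  zMand <- occupiedRange(mand, 3L)[1]   # inferior extent of mandible
  zSh <- occupiedRange(sh, 3L)[2]       # superior extent of shoulders
  max(0, (zMand - zSh) * gridSpacing(sv)[3] / 10)
}

#' All pre-check measurements at once
#'
#' @param sv a [LabeledVolume-class] with the required planning structures.
#' @return named numeric: `canal_length_cm`, `brain_to_mandible_cm`,
#'   `feather_space_cm`.
#' @export
measureAnatomy <- function(sv) {
  c(canal_length_cm = measureSpinalCanalLength(sv),
    brain_to_mandible_cm = measureBrainToMandible(sv),
    feather_space_cm = measureFeatherSpace(sv))
}

## dilation by shift-OR over all voxel offsets whose mm length is within the
## margin; ties at exactly the margin are included (deterministic, grid-robust)
.dilateOffsets <- function(mask, offsets) {
  d <- dim(mask)
  out <- array(FALSE, d)
  for (k in seq_len(nrow(offsets))) {
    o <- offsets[k, ]
    sx <- intersect(seq_len(d[1]), seq_len(d[1]) - o[1])
    sy <- intersect(seq_len(d[2]), seq_len(d[2]) - o[2])
    sz <- intersect(seq_len(d[3]), seq_len(d[3]) - o[3])
    if (!length(sx) || !length(sy) || !length(sz)) next
    out[sx + o[1], sy + o[2], sz + o[3]] <-
      out[sx + o[1], sy + o[2], sz + o[3]] | mask[sx, sy, sz]
  }
  out
}

#' Isotropic margin expansion of a mask
#'
#' 3D dilation by `margin_cm`, computed on voxel centres in mm space so that
#' anisotropic grids are handled correctly: a voxel is added iff its centre
#' lies within the margin (inclusive) of some mask-voxel centre.
#'
#' @param mask logical 3D array.
#' @param margin_cm margin (>= 0), cm.
#' @param spacing_mm voxel spacing, mm (length 3).
#' @return logical array of the same dimension.
#' @export
expandUniform <- function(mask, margin_cm, spacing_mm) {
  if (length(margin_cm) != 1L || !is.finite(margin_cm) || margin_cm < 0)
    stop("margin_cm must be a single non-negative value")
  if (margin_cm == 0) return(mask)
  mm <- margin_cm * 10
  n <- floor(mm / spacing_mm + 1e-9)
  offs <- as.matrix(expand.grid(x = -n[1]:n[1], y = -n[2]:n[2], z = -n[3]:n[3]))
  keep <- sqrt((offs[, 1] * spacing_mm[1])^2 + (offs[, 2] * spacing_mm[2])^2 +
               (offs[, 3] * spacing_mm[3])^2) <= mm + 1e-9
  .dilateOffsets(mask, offs[keep, , drop = FALSE])
}

#' Lateral (left-right) margin expansion of a mask
#'
#' Dilation along the patient x-axis only; superior-inferior and
#' anterior-posterior extents are unchanged. This defines the spine-field MLC
#' aperture target around the spinal canal.
#'
#' @inheritParams expandUniform
#' @return logical array of the same dimension.
#' @export
expandLateral <- function(mask, margin_cm, spacing_mm) {
  if (length(margin_cm) != 1L || !is.finite(margin_cm) || margin_cm < 0)
    stop("margin_cm must be a single non-negative value")
  if (margin_cm == 0) return(mask)
  n <- floor(margin_cm * 10 / spacing_mm[1] + 1e-9)
  offs <- cbind(x = -n:n, y = 0L, z = 0L)
  .dilateOffsets(mask, offs)
}
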