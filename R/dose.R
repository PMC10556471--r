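## R surface of the analytic 6 MV dose model.

#' Compute the dose of a single beam
#'
#' Evaluates the analytic broad-beam model on the density grid:
#' `D(v) = weight * ((SAD + dmax)/r)^2 * PDD(d_eff) * F`, with the
#' radiological depth `d_eff` ray-marched along the source ray (density line
#' integral), a linear build-up to the maximum at `dmax` followed by
#' effective exponential attenuation, and an aperture fluence `F` that is 1
#' inside the jaw/MLC opening and `leaf_transmission` outside, with
#' error-function penumbra at the projected edges. One weight unit delivers
#' 1 Gy at dmax on the central axis at SSD 100.
#'
#' @param beam a [Beam-class].
#' @param density a density [VoxelVolume-class] (g/cc; water = 1).
#' @param params a [BeamModelParams-class].
#' @return a dose [VoxelVolume-class] (Gy) on the density grid.
#' @export
beamDose <- function(beam, density, params = beamModel()) {
  stopifnot(is(beam, "Beam"), is(density, "VoxelVolume"))
  validObject(beam)
  sp <- gridSpacing(density)
  step <- if (is.na(params@step_mm)) min(sp) / 2 else params@step_mm
  fr <- beamFrame(beam)
  src <- beamSourcePosition(beam, surface = density)
  arr <- .beamDoseCpp(density@voxels, dim(density@voxels), sp,
                      gridOrigin(density), src, fr$eu, fr$ev, fr$w,
                      beam@sad_cm * 10, beam@jaws_cm * 10,
                      beam@mlc_edges_cm * 10, beam@mlc[, 1] * 10,
                      beam@mlc[, 2] * 10, params@mu_eff_cm_inv / 10,
                      params@dmax_cm * 10, params@penumbra_sigma_cm * 10,
                      params@leaf_transmission, beam@weight, step)
  voxelVolume(arr, sp, gridOrigin(density))
}

#' Weighted sum of dose grids
#'
#' @param doses list of dose [VoxelVolume-class]s on one grid.
#' @param weights non-negative weights, one per grid.
#' @return the pointwise weighted sum as a [VoxelVolume-class].
#' @export
sumDose <- function(doses, weights) {
  if (length(doses) != length(weights))
    stop("doses and weights must have the same length")
  if (any(weights < 0)) stop("weights must be non-negative")
  for (d in doses[-1]) stopifnotSameGrid(doses[[1]], d)
  acc <- array(0, dim(doses[[1]]@voxels))
  for (i in seq_along(doses)) acc <- acc + weights[i] * doses[[i]]@voxels
  voxelVolume(acc, gridSpacing(doses[[1]]), gridOrigin(doses[[1]]))
}

## dose of a field group (list of beams), honouring each beam's weight
groupDose <- function(beams, density, params) {
  if (!length(beams)) {
    return(voxelVolume(array(0, dim(density@voxels)), gridSpacing(density),
                       gridOrigin(density)))
  }
  acc <- array(0, dim(density@voxels))
  for (b in beams) acc <- acc + beamDose(b, density, params)@voxels
  voxelVolume(acc, gridSpacing(density), gridOrigin(density))
}
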