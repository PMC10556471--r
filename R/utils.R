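## Small internal helpers shared across modules.

## voxel-centre coordinates (mm) along one axis of a gridded object
axisCoords <- function(origin, spacing, n, axis) {
  origin[axis] + spacing[axis] * (seq_len(n) - 1)
}

gridCoords <- function(obj) {
  d <- gridDim(obj)
  list(x = axisCoords(gridOrigin(obj), gridSpacing(obj), d[1], 1),
       y = axisCoords(gridOrigin(obj), gridSpacing(obj), d[2], 2),
       z = axisCoords(gridOrigin(obj), gridSpacing(obj), d[3], 3))
}

gridDim <- function(obj) {
  if (is(obj, "VoxelVolume")) dim(obj@voxels) else obj@dim
}
gridSpacing <- function(obj) obj@spacing
gridOrigin <- function(obj) obj@origin

stopifnotSameGrid <- function(a, b) {
  if (!identical(gridDim(a), gridDim(b)) ||
      max(abs(gridSpacing(a) - gridSpacing(b))) > 1e-9 ||
      max(abs(gridOrigin(a) - gridOrigin(b))) > 1e-6)
    stop("volumes are not on the same grid")
  invisible(TRUE)
}

## indices (per axis) of occupied slices of a mask
occupiedRange <- function(mask, axis) {
  keep <- apply(mask, axis, any)
  if (!any(keep)) return(NULL)
  range(which(keep))
}

## voxel volume in cc
voxelVolumeCC <- function(obj) prod(gridSpacing(obj)) / 1000

## fetch a mask by (case-insensitive, synonym-aware) name, with a clear error
getMask <- function(sv, name, required = TRUE) {
  nm <- matchStructureName(name, names(sv@masks))
  if (is.na(nm)) {
    if (required) stop(sprintf("structure '%s' is missing from the structure set", name))
    return(NULL)
  }
  m <- sv@masks[[nm]]
  if (required && !any(m))
    stop(sprintf("structure '%s' has an empty mask", name))
  m
}

## run an expression with a local RNG state (does not disturb the caller's)
withLocalSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
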