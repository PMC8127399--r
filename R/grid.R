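#' Construct an analysis grid
#'
#' Builds a \linkS4class{BrainGrid} covering an MNI bounding box at a given
#' isotropic voxel size. By default the analysis mask is a brain-shaped
#' ellipsoid (centered near the anterior commissure) so that no template
#' download is required; any logical array of matching dimensions, or a
#' NIfTI mask read with \code{\link{readMaskNifti}}, may be supplied instead.
#'
#' @param voxelSize isotropic voxel edge in mm.
#' @param bbox 2x3 matrix of mm bounds (rows = lower/upper, columns x,y,z).
#' @param mask \code{"ellipsoid"}, \code{"all"}, or a logical array with the
#'   grid's dimensions.
#' @param ellipsoidCenter,ellipsoidSemiaxes mm parameters of the default mask.
#' @return A \linkS4class{BrainGrid}.
#' @examples
#' g <- makeBrainGrid(8)
#' g
#' @export
makeBrainGrid <- function(voxelSize = 2,
                          bbox = rbind(c(-90, -126, -72), c(90, 90, 108)),
                          mask = "ellipsoid",
                          ellipsoidCenter = c(0, -18, 8),
                          ellipsoidSemiaxes = c(70, 86, 75)) {
  stopifnot(voxelSize > 0, all(bbox[2, ] >= bbox[1, ]))
  shape <- as.integer(floor((bbox[2, ] - bbox[1, ]) / voxelSize) + 1L)
  affine <- diag(c(rep(voxelSize, 3), 1))
  affine[1:3, 4] <- bbox[1, ]
  if (is.character(mask)) {
    mask <- match.arg(mask, c("ellipsoid", "all"))
    ctr <- gridCenters(shape, affine)
    inside <- if (mask == "all") rep(TRUE, nrow(ctr)) else {
      rowSums(sweep(sweep(ctr, 2, ellipsoidCenter), 2,
                    ellipsoidSemiaxes, "/")^2) <= 1
    }
    maskArr <- array(inside, dim = shape)
  } else {
    stopifnot(is.logical(mask), identical(dim(mask), as.integer(shape)))
    maskArr <- mask
  }
  newBrainGrid(shape, affine, maskArr)
}

newBrainGrid <- function(shape, affine, maskArr) {
  idx <- array(0L, dim = shape)
  idx[maskArr] <- seq_len(sum(maskArr))
  new("BrainGrid", shape = as.integer(shape), affine = affine,
      mask = maskArr, maskIndex = idx)
}

# mm coordinates of all voxel centers, in array (column-major) order
gridCenters <- function(shape, affine) {
  i <- rep.int(seq_len(shape[1]) - 1L, shape[2] * shape[3])
  j <- rep.int(rep(seq_len(shape[2]) - 1L, each = shape[1]), shape[3])
  k <- rep(seq_len(shape[3]) - 1L, each = shape[1] * shape[2])
  cbind(
    affine[1, 1] * i + affine[1, 2] * j + affine[1, 3] * k + affine[1, 4],
    affine[2, 1] * i + affine[2, 2] * j + affine[2, 3] * k + affine[2, 4],
    affine[3, 1] * i + affine[3, 2] * j + affine[3, 3] * k + affine[3, 4])
}

#' Map millimetre coordinates to 0-based voxel indices (and back)
#'
#' @param grid a \linkS4class{BrainGrid}.
#' @param mm numeric matrix (rows = points) or length-3 vector.
#' @return \code{mmToVoxel}: real-valued 0-based voxel indices;
#'   \code{voxelToMm}: mm coordinates of (possibly fractional) indices.
#' @export
mmToVoxel <- function(grid, mm) {
  mm <- rbind(mm)
  inv <- solve(grid@affine)
  t(inv[1:3, 1:3] %*% t(mm) + inv[1:3, 4])
}

#' @rdname mmToVoxel
#' @param ijk 0-based voxel indices (matrix or vector).
#' @export
voxelToMm <- function(grid, ijk) {
  ijk <- rbind(ijk)
  t(grid@affine[1:3, 1:3] %*% t(ijk) + grid@affine[1:3, 4])
}

#' Millimetre coordinates of all mask voxels
#'
#' @param grid a \linkS4class{BrainGrid}.
#' @return numeric matrix, one row per mask voxel in packed order.
#' @export
maskCoordinates <- function(grid) {
  gridCenters(grid@shape, grid@affine)[as.vector(grid@mask), , drop = FALSE]
}

#' Number of voxels in the analysis mask
#' @param grid a \linkS4class{BrainGrid}.
#' @export
nMaskVoxels <- function(grid) sum(grid@mask)

# TRUE for points whose nearest voxel is inside the mask
inMask <- function(grid, mm) {
  ijk <- round(mmToVoxel(grid, mm))
  ok <- ijk[, 1] >= 0 & ijk[, 1] < grid@shape[1] &
    ijk[, 2] >= 0 & ijk[, 2] < grid@shape[2] &
    ijk[, 3] >= 0 & ijk[, 3] < grid@shape[3]
  res <- logical(nrow(ijk))
  if (any(ok)) {
    lin <- 1L + ijk[ok, 1] + grid@shape[1] * (ijk[ok, 2] +
      grid@shape[2] * ijk[ok, 3])
    res[ok] <- grid@mask[lin]
  }
  res
}

#' Expand a packed mask-voxel vector to a full 3-D array
#'
#' @param grid a \linkS4class{BrainGrid}.
#' @param values vector with one element per mask voxel.
#' @param fill value for voxels outside the mask.
#' @export
unpackToArray <- function(grid, values, fill = 0) {
  stopifnot(length(values) == nMaskVoxels(grid))
  arr <- array(fill, dim = grid@shape)
  arr[grid@mask] <- values
  arr
}

#' Read and write NIfTI volumes on a grid
#'
#' \code{writeVolumeNifti} writes a per-mask-voxel vector (or full array) as
#' a NIfTI-1 file with the grid's affine; \code{readMaskNifti} builds a
#' \linkS4class{BrainGrid} from a mask file (nonzero voxels analyzed);
#' \code{readVolumeNifti} reads a volume back as a full array.
#'
#' @param grid a \linkS4class{BrainGrid}.
#' @param values per-mask-voxel vector or array of dimension \code{shape}.
#' @param file path.
#' @export
writeVolumeNifti <- function(grid, values, file) {
  arr <- if (length(values) == nMaskVoxels(grid) &&
             !identical(dim(values), as.integer(grid@shape)))
    unpackToArray(grid, values) else array(values, dim = grid@shape)
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- sqrt(colSums(grid@affine[1:3, 1:3]^2))
  img <- RNifti::`sform<-`(img, structure(grid@affine, code = 2L))
  RNifti::writeNifti(img, file)
  invisible(file)
}

#' @rdname writeVolumeNifti
#' @export
readMaskNifti <- function(file) {
  img <- RNifti::readNifti(file)
  aff <- RNifti::xform(img)
  arr <- array(as.array(img) != 0, dim = dim(img)[1:3])
  newBrainGrid(dim(arr), unclass(aff), arr)
}

#' @rdname writeVolumeNifti
#' @export
readVolumeNifti <- function(file) {
  img <- RNifti::readNifti(file)
  array(as.array(img), dim = dim(img)[1:3])
}
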