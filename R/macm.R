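#' Define a volume of interest
#'
#' A VOI is either a sphere (center + radius) or an explicit voxel mask on
#' the analysis grid, with a polarity tag saying which effect direction it
#' came from.
#'
#' @param name VOI name.
#' @param center mm center (sphere definition).
#' @param radius mm radius (sphere definition).
#' @param mask logical array of grid dimensions, or per-mask-voxel logical
#'   vector (mask definition; overrides center/radius).
#' @param polarity \code{"decreased_in_PD"}, \code{"increased_in_PD"} or any
#'   label.
#' @return VOI object (list).
#' @export
voi <- function(name, center = NULL, radius = NULL, mask = NULL,
                polarity = "decreased_in_PD") {
  if (is.null(mask) && (is.null(center) || is.null(radius)))
    stop("VOI needs either a mask or a center and radius")
  structure(list(name = name, center = center, radius = radius,
                 mask = mask, polarity = polarity), class = "aleMetaVoi")
}

# logical vector over the full grid: voxels belonging to the VOI
voiVoxels <- function(v, grid) {
  if (!is.null(v$mask)) {
    m <- if (length(v$mask) == nMaskVoxels(grid))
      as.vector(unpackToArray(grid, v$mask, fill = FALSE)) else as.vector(v$mask)
    stopifnot(length(m) == prod(grid@shape))
    return(as.logical(m))
  }
  ctr <- gridCenters(grid@shape, grid@affine)
  rowSums(sweep(ctr, 2, v$center)^2) <= v$radius^2
}

#' Retrieve database experiments activating a VOI
#'
#' Selects the experiments reporting at least one focus inside the VOI voxel
#' set (nearest-voxel membership test), mirroring seed-based retrieval from
#' a coactivation database.
#'
#' @param db list of \linkS4class{FociExperiment} in MNI space.
#' @param v a \code{\link{voi}}.
#' @param grid a \linkS4class{BrainGrid}.
#' @return Sub-list of retrieved experiments (possibly empty).
#' @export
retrieveByVoi <- function(db, v, grid) {
  vox <- voiVoxels(v, grid)
  if (!any(vox)) stop("VOI '", v$name, "' is empty on this grid")
  sh <- grid@shape
  hits <- vapply(db, function(e) {
    ijk <- round(mmToVoxel(grid, e@foci))
    ok <- ijk[, 1] >= 0 & ijk[, 1] < sh[1] & ijk[, 2] >= 0 &
      ijk[, 2] < sh[2] & ijk[, 3] >= 0 & ijk[, 3] < sh[3]
    if (!any(ok)) return(FALSE)
    lin <- 1L + ijk[ok, 1] + sh[1] * (ijk[ok, 2] + sh[2] * ijk[ok, 3])
    any(vox[lin])
  }, logical(1))
  db[hits]
}

#' Coactivation profile of a VOI
#'
#' Runs the full ALE chain (modeled activation, union, analytic null,
#' cluster-level FWE) over the database experiments retrieved for the VOI.
#' The significant-coactivation mask is the union of the FWE-significant
#' clusters. Retrieval below \code{minRetrieved} experiments is refused,
#' reusing the eligibility convention that meta-analyses over few
#' experiments are driven by single studies.
#'
#' @param db list of \linkS4class{FociExperiment}.
#' @param v a \code{\link{voi}}.
#' @param grid a \linkS4class{BrainGrid}.
#' @param spec a \linkS4class{KernelSpec}.
#' @param minRetrieved minimum retrieval count (default 21, i.e. > 20).
#' @param ... thresholds passed to \code{\link{clusterFwe}} (formingP,
#'   alpha, nPerm, seed, ...).
#' @return A \linkS4class{MACMProfile}.
#' @export
macmProfile <- function(db, v, grid, spec = kernelSpec(),
                        minRetrieved = 21, ...) {
  retrieved <- retrieveByVoi(db, v, grid)
  if (length(retrieved) < minRetrieved)
    stop("VOI '", v$name, "' retrieved only ", length(retrieved),
         " experiments (minimum ", minRetrieved, ")")
  res <- clusterFwe(retrieved, grid, spec, ...)
  new("MACMProfile", voiName = v$name, polarity = v$polarity,
      nRetrieved = length(retrieved), result = res,
      sigMask = res@clusterLabels > 0L)
}

#' Conjunction of coactivation profiles
#'
#' Voxel-wise intersection of the significant-coactivation masks of several
#' profiles of one polarity: the overlap holds the voxels commonly
#' coactivated with every seed. A minimum-statistic conjunction (voxel-wise
#' minimum z over profiles, returned alongside) is available via
#' \code{minStat = TRUE}.
#'
#' @param profiles list of \linkS4class{MACMProfile} on one grid, length
#'   >= 2.
#' @param minStat also return the voxel-wise minimum z map.
#' @return List with \code{overlap} (logical per mask voxel),
#'   \code{polarity}, and optionally \code{minZ}.
#' @export
macmConjunction <- function(profiles, minStat = FALSE) {
  if (length(profiles) < 2) stop("conjunction needs at least 2 profiles")
  n <- unique(vapply(profiles, function(p) length(p@sigMask), integer(1)))
  if (length(n) != 1) stop("profiles must share one grid")
  pol <- unique(vapply(profiles, function(p) p@polarity, character(1)))
  if (length(pol) != 1)
    warning("conjunction mixes polarities: ", paste(pol, collapse = ", "))
  overlap <- Reduce(`&`, lapply(profiles, function(p) p@sigMask))
  out <- list(overlap = overlap, polarity = pol[1])
  if (minStat)
    out$minZ <- Reduce(pmin, lapply(profiles, function(p) p@result@z))
  out
}

#' Summarize an overlap within an atlas region
#'
#' Restricts a conjunction overlap to one labeled atlas region and reports
#' its size, centroid and mean y coordinate (the rostrocaudal statistic:
#' smaller y = more posterior/caudal).
#'
#' @param overlap logical per mask voxel (from
#'   \code{\link{macmConjunction}}).
#' @param grid a \linkS4class{BrainGrid}.
#' @param atlas atlas object (see \code{\link{makeToyAtlas}} /
#'   \code{\link{readAtlas}}).
#' @param region label id or region name.
#' @param polarity label copied into the output.
#' @return data.frame with one row: polarity, region, within_atlas_voxels,
#'   centroid x/y/z, mean_y (NA coordinates if the intersection is empty).
#' @export
overlapSummary <- function(overlap, grid, atlas, region,
                           polarity = NA_character_) {
  labId <- if (is.character(region)) {
    hit <- atlas$table$label[atlas$table$name == region]
    if (!length(hit))
      stop("region '", region, "' not in atlas; available: ",
           paste(sprintf("%d=%s", atlas$table$label, atlas$table$name),
                 collapse = ", "))
    hit[1]
  } else {
    if (!region %in% atlas$table$label)
      stop("label ", region, " not in atlas; available: ",
           paste(sprintf("%d=%s", atlas$table$label, atlas$table$name),
                 collapse = ", "))
    region
  }
  regionVec <- as.vector(atlas$labels == labId)[as.vector(grid@mask)]
  inter <- overlap & regionVec
  mm <- maskCoordinates(grid)[inter, , drop = FALSE]
  data.frame(
    polarity = polarity,
    region = atlas$table$name[atlas$table$label == labId][1],
    within_atlas_voxels = sum(inter),
    centroid_x = if (nrow(mm)) mean(mm[, 1]) else NA_real_,
    centroid_y = if (nrow(mm)) mean(mm[, 2]) else NA_real_,
    centroid_z = if (nrow(mm)) mean(mm[, 3]) else NA_real_,
    mean_y = if (nrow(mm)) mean(mm[, 2]) else NA_real_,
    stringsAsFactors = FALSE)
}

#' Toy bilateral putamen atlas
#'
#' An integer-labeled atlas on the analysis grid with a single region
#' (label 1, "putamen"): two ellipsoids elongated along the y axis at
#' x = +/-26 mm, spanning roughly y -25 to +11 mm, emulating the
#' anterior-posterior extent of the bilateral putamen for gradient tests.
#'
#' @param grid a \linkS4class{BrainGrid}.
#' @return Atlas object: list with \code{labels} (integer array of grid
#'   dimensions) and \code{table} (data.frame with columns label, name).
#' @export
makeToyAtlas <- function(grid) {
  ctr <- gridCenters(grid@shape, grid@affine)
  inReg <- rep(FALSE, nrow(ctr))
  for (cx in c(-26, 26)) {
    d <- sweep(ctr, 2, c(cx, -7, 4))
    inReg <- inReg | (d[, 1] / 10)^2 + (d[, 2] / 18)^2 + (d[, 3] / 9)^2 <= 1
  }
  labels <- array(0L, dim = grid@shape)
  labels[inReg] <- 1L
  list(labels = labels,
       table = data.frame(label = 1L, name = "putamen",
                          stringsAsFactors = FALSE))
}

#' Read and write labeled atlases
#'
#' Atlases are exchanged as an integer-labeled NIfTI plus a tab-separated
#' label table with columns \code{label} and \code{name}.
#'
#' @param niftiPath label volume path.
#' @param tablePath label table TSV path.
#' @return Atlas object as \code{\link{makeToyAtlas}}.
#' @export
readAtlas <- function(niftiPath, tablePath) {
  labels <- readVolumeNifti(niftiPath)
  storage.mode(labels) <- "integer"
  tab <- utils::read.delim(tablePath, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("label", "name") %in% names(tab)))
  list(labels = labels, table = tab)
}

#' @rdname readAtlas
#' @param atlas atlas object.
#' @param grid a \linkS4class{BrainGrid} (for the affine).
#' @export
writeAtlas <- function(atlas, grid, niftiPath, tablePath) {
  writeVolumeNifti(grid, atlas$labels, niftiPath)
  utils::write.table(atlas$table, tablePath, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(c(niftiPath, tablePath))
}
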