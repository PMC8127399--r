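#' @import methods
NULL

#' Voxel lattice for the analysis
#'
#' A \code{BrainGrid} couples a 3-D voxel lattice to millimetre (MNI) space
#' through an invertible affine, and carries the boolean analysis mask
#' ("gray matter" voxels). Voxel indices are 0-based in the affine convention
#' (NIfTI style); accessors below handle the R 1-based array view.
#'
#' @slot shape integer(3), array dimensions.
#' @slot affine 4x4 matrix mapping homogeneous 0-based voxel indices to mm.
#' @slot mask logical array of dimension \code{shape}; \code{TRUE} = analyzed.
#' @slot maskIndex integer array of dimension \code{shape}; position of each
#'   voxel in the packed mask vector, 0 for voxels outside the mask.
#' @export
setClass("BrainGrid", representation(
  shape = "integer",
  affine = "matrix",
  mask = "array",
  maskIndex = "array"
))

setValidity("BrainGrid", function(object) {
  msg <- character()
  if (length(object@shape) != 3L || any(object@shape < 1L))
    msg <- c(msg, "shape must be 3 positive integers")
  if (!all(dim(object@affine) == c(4L, 4L)))
    msg <- c(msg, "affine must be 4x4")
  else if (abs(det(object@affine[1:3, 1:3])) < 1e-12)
    msg <- c(msg, "affine must be invertible")
  if (!identical(dim(object@mask), as.integer(object@shape)))
    msg <- c(msg, "mask dimensions must equal shape")
  if (!any(object@mask))
    msg <- c(msg, "mask must be non-empty")
  if (length(msg)) msg else TRUE
})

#' Gaussian kernel specification for modeled activation
#'
#' Spatial uncertainty model for reported foci. The per-experiment, per-axis
#' standard deviation is \code{sigma(n) = sqrt(sigmaSubj^2 / n +
#' sigmaTemplate^2)} for an experiment with \code{n} subjects: between-subject
#' variability shrinks with the sample size while between-template
#' (normalization) variability does not. Kernels are truncated at
#' \code{truncationFactor * sigma(n)} and evaluated at voxel centers times a
#' fixed reference voxel volume, so modeled-activation values are
#' probabilities and do not depend on the analysis grid resolution.
#'
#' @slot sigmaSubj numeric, between-subject per-axis sd scale in mm.
#' @slot sigmaTemplate numeric, between-template per-axis sd in mm.
#' @slot truncationFactor numeric, kernel cut-off in units of sigma(n).
#' @slot refVolume numeric, reference voxel volume in mm^3 (default 8 = 2 mm
#'   isotropic voxel).
#' @export
setClass("KernelSpec", representation(
  sigmaSubj = "numeric",
  sigmaTemplate = "numeric",
  truncationFactor = "numeric",
  refVolume = "numeric"
))

setValidity("KernelSpec", function(object) {
  v <- c(object@sigmaSubj, object@sigmaTemplate, object@truncationFactor,
         object@refVolume)
  if (length(v) != 4L || any(!is.finite(v)) || any(v <= 0))
    "all kernel parameters must be positive finite scalars" else TRUE
})

#' One experiment (contrast) with its reported foci
#'
#' An experiment is a single contrast of interest; one study (publication)
#' may contribute several experiments. \code{nSubjects} is the lower of the
#' two group sizes when groups differ.
#'
#' @slot experimentId character scalar.
#' @slot studyId character scalar; groups experiments of one publication.
#' @slot contrast character scalar, contrast label
#'   (e.g. \code{"HC_gt_PDOFF"}; arbitrary labels allowed for database
#'   corpora).
#' @slot nSubjects integer, >= 1.
#' @slot modality character, \code{"fMRI"} or \code{"PET"} (or \code{"NA"}).
#' @slot foci numeric matrix, one row per focus, columns x, y, z in mm.
#' @slot space character, \code{"MNI"} or \code{"TAL"}.
#' @export
setClass("FociExperiment", representation(
  experimentId = "character",
  studyId = "character",
  contrast = "character",
  nSubjects = "integer",
  modality = "character",
  foci = "matrix",
  space = "character"
))

setValidity("FociExperiment", function(object) {
  msg <- character()
  if (length(object@nSubjects) != 1L || is.na(object@nSubjects) ||
      object@nSubjects < 1L)
    msg <- c(msg, "nSubjects must be a positive integer")
  if (!is.numeric(object@foci) || ncol(object@foci) != 3L ||
      nrow(object@foci) < 1L)
    msg <- c(msg, "foci must be a numeric matrix with >= 1 row and 3 columns")
  else if (any(!is.finite(object@foci)))
    msg <- c(msg, "focus coordinates must be finite")
  if (!object@space %in% c("MNI", "TAL"))
    msg <- c(msg, "space must be 'MNI' or 'TAL'")
  if (object@space == "MNI" && nrow(object@foci) >= 1L &&
      any(abs(object@foci) > 120))
    msg <- c(msg, "MNI coordinates must satisfy |x|,|y|,|z| <= 120 mm")
  if (length(msg)) msg else TRUE
})

#' Null distribution of the ALE score under random spatial association
#'
#' Distribution of the ALE score at a single voxel when every experiment's
#' modeled-activation value is drawn independently from that experiment's
#' empirical MA histogram over the mask — i.e. foci placed with no spatial
#' association. \code{kind} is \code{"exact"} (value/probability pairs from
#' full enumeration of the union combination) or \code{"binned"} (histogram
#' convolution on the discretized log-complement score axis).
#'
#' @slot scores numeric, sorted ALE score support (exact values, or lattice
#'   values for the binned representation).
#' @slot probs numeric, probabilities matching \code{scores}, summing to 1.
#' @slot tailProbs numeric, upper-tail cumulative probabilities
#'   (\code{tailProbs[i] = P(score >= scores[i])}).
#' @slot binWidth numeric, lattice step on the log-complement axis
#'   (\code{NA} for exact).
#' @slot nExperiments integer.
#' @slot kind character, \code{"exact"} or \code{"binned"}.
#' @export
setClass("NullModel", representation(
  scores = "numeric",
  probs = "numeric",
  tailProbs = "numeric",
  binWidth = "numeric",
  nExperiments = "integer",
  kind = "character"
))

setValidity("NullModel", function(object) {
  msg <- character()
  if (length(object@scores) != length(object@probs))
    msg <- c(msg, "scores and probs must have equal length")
  if (any(object@probs < -1e-12))
    msg <- c(msg, "probabilities must be nonnegative")
  if (abs(sum(object@probs) - 1) > 1e-9)
    msg <- c(msg, "probabilities must sum to 1")
  if (length(object@scores) &&
      (min(object@scores) < 0 || max(object@scores) >= 1))
    msg <- c(msg, "support must lie in [0, 1)")
  if (!object@kind %in% c("exact", "binned"))
    msg <- c(msg, "kind must be 'exact' or 'binned'")
  if (length(msg)) msg else TRUE
})

#' Result of an ALE meta-analysis with cluster-level inference
#'
#' @slot grid the \linkS4class{BrainGrid} used.
#' @slot ale numeric, ALE score per mask voxel (packed mask order).
#' @slot p numeric, uncorrected voxel-wise p per mask voxel.
#' @slot z numeric, standard-normal equivalents of \code{p}.
#' @slot clusterLabels integer per mask voxel; 0 = not in a significant
#'   cluster.
#' @slot clusters data.frame, one row per significant cluster (label, side,
#'   peak coordinates, peak z, extent, corrected p).
#' @slot contributions list of per-cluster named contribution-fraction
#'   vectors (experiment id -> fraction).
#' @slot detectedBy list of per-cluster character vectors of experiment ids.
#' @slot criticalExtent numeric, permutation critical cluster extent
#'   (voxels).
#' @slot nullMaxExtents integer, permutation distribution of the maximum
#'   cluster extent.
#' @slot null the voxel-wise \linkS4class{NullModel}.
#' @slot settings list of thresholds/seed used.
#' @export
setClass("ALEResult", representation(
  grid = "BrainGrid",
  ale = "numeric",
  p = "numeric",
  z = "numeric",
  clusterLabels = "integer",
  clusters = "data.frame",
  contributions = "list",
  detectedBy = "list",
  criticalExtent = "numeric",
  nullMaxExtents = "integer",
  null = "NullModel",
  settings = "list"
))

#' Meta-analytic connectivity profile of one seed volume
#'
#' @slot voiName character.
#' @slot polarity character, \code{"decreased_in_PD"}, \code{"increased_in_PD"}
#'   or other user label.
#' @slot nRetrieved integer, number of database experiments with a focus in
#'   the VOI.
#' @slot result the \linkS4class{ALEResult} of the coactivation
#'   meta-analysis.
#' @slot sigMask logical per mask voxel, cluster-FWE-significant coactivation.
#' @export
setClass("MACMProfile", representation(
  voiName = "character",
  polarity = "character",
  nRetrieved = "integer",
  result = "ALEResult",
  sigMask = "logical"
))

setMethod("show", "BrainGrid", function(object) {
  cat(sprintf("BrainGrid: %d x %d x %d voxels (%.1f mm), %d mask voxels\n",
              object@shape[1], object@shape[2], object@shape[3],
              abs(object@affine[1, 1]), sum(object@mask)))
})

setMethod("show", "FociExperiment", function(object) {
  cat(sprintf("FociExperiment '%s' (study %s): %s, n=%d, %d foci [%s]\n",
              object@experimentId, object@studyId, object@contrast,
              object@nSubjects, nrow(object@foci), object@space))
})

setMethod("show", "NullModel", function(object) {
  cat(sprintf("NullModel (%s): %d experiments, %d support points, max %.4g\n",
              object@kind, object@nExperiments, length(object@scores),
              if (length(object@scores)) max(object@scores) else NA_real_))
})

setMethod("show", "ALEResult", function(object) {
  cat(sprintf(
    "ALEResult: %d experiments, %d significant cluster(s), critical extent %s\n",
    object@settings$nExperiments, nrow(object@clusters),
    format(object@criticalExtent)))
  if (nrow(object@clusters)) print(object@clusters)
})

setMethod("show", "MACMProfile", function(object) {
  cat(sprintf("MACMProfile '%s' (%s): %d experiments retrieved, %d sig voxels\n",
              object@voiName, object@polarity, object@nRetrieved,
              sum(object@sigMask)))
})
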