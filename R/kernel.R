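# Lancaster pooled MNI/ICBM -> Talairach affine ("icbm2tal", average of the
# SPM- and FSL-template fits). Talairach -> MNI applies its inverse.
ICBM2TAL <- matrix(c(
   0.9357,  0.0029, -0.0072, -1.0423,
  -0.0065,  0.9396, -0.0726, -1.3940,
   0.0103,  0.0752,  0.8967,  3.6475,
   0,       0,       0,       1), nrow = 4, byrow = TRUE)

TAL2ICBM <- solve(ICBM2TAL)

#' Convert Talairach coordinates to MNI space
#'
#' Applies the pooled Lancaster tal2icbm affine (the inverse of the published
#' ICBM-to-Talairach fit) to coordinates reported in Talairach space.
#'
#' @param xyz numeric matrix (rows = points) or length-3 vector of Talairach
#'   coordinates in mm.
#' @return Matrix of MNI coordinates with the same number of rows.
#' @examples
#' tal2mni(c(30, -10, 6))
#' @export
tal2mni <- function(xyz) {
  xyz <- rbind(xyz)
  stopifnot(ncol(xyz) == 3)
  t(TAL2ICBM[1:3, 1:3] %*% t(xyz) + TAL2ICBM[1:3, 4])
}

#' Normalize an experiment's foci to MNI space
#'
#' Experiments flagged Talairach have every focus transformed with
#' \code{\link{tal2mni}}; MNI-flagged input is returned unchanged with a
#' warning (no-op).
#'
#' @param experiment a \linkS4class{FociExperiment}.
#' @return The experiment with \code{space == "MNI"}.
#' @export
toMni <- function(experiment) {
  if (experiment@space == "MNI") {
    warning("experiment '", experiment@experimentId,
            "' is already in MNI space; no transform applied")
    return(experiment)
  }
  experiment@foci <- tal2mni(experiment@foci)
  experiment@space <- "MNI"
  validObject(experiment)
  experiment
}

#' Kernel specification constructor
#'
#' Defaults follow the standard empirical calibration of coordinate-based
#' meta-analysis kernels: a between-subject Euclidean-distance scale of
#' 11.6 mm and a between-template scale of 5.7 mm, converted to per-axis
#' standard deviations by the factor \code{2 * sqrt(2 / pi)}. The resulting
#' per-experiment sd is \code{sqrt(sigmaSubj^2 / n + sigmaTemplate^2)}.
#'
#' @param sigmaSubj per-axis between-subject sd scale, mm.
#' @param sigmaTemplate per-axis between-template sd, mm.
#' @param truncationFactor kernel truncation radius in sigma units.
#' @param refVolume reference voxel volume in mm^3 used to convert the
#'   Gaussian density to a per-voxel probability (8 = 2 mm voxel).
#' @return A \linkS4class{KernelSpec}.
#' @examples
#' kernelSigma(14, kernelSpec())
#' @export
kernelSpec <- function(sigmaSubj = 11.6 / (2 * sqrt(2 / pi)),
                       sigmaTemplate = 5.7 / (2 * sqrt(2 / pi)),
                       truncationFactor = 3.5,
                       refVolume = 8) {
  new("KernelSpec", sigmaSubj = sigmaSubj, sigmaTemplate = sigmaTemplate,
      truncationFactor = truncationFactor, refVolume = refVolume)
}

#' Per-experiment kernel standard deviation
#'
#' \code{sigma(n) = sqrt(sigmaSubj^2 / n + sigmaTemplate^2)}: strictly
#' decreasing in the sample size with limit \code{sigmaTemplate}, so larger
#' experiments are modeled with sharper spatial localization.
#'
#' @param n number of subjects (the lower group size), >= 1.
#' @param spec a \linkS4class{KernelSpec}.
#' @return sd in mm.
#' @export
kernelSigma <- function(n, spec = kernelSpec()) {
  if (any(!is.finite(n)) || any(n < 1))
    stop("n must be >= 1")
  sqrt(spec@sigmaSubj^2 / n + spec@sigmaTemplate^2)
}

#' Modeled-activation (MA) map of one experiment
#'
#' Each focus contributes the probability that the experiment's true
#' activation lies in a reference voxel centered at each grid voxel: an
#' isotropic 3-D Gaussian with sd \code{kernelSigma(n)}, evaluated at the
#' voxel center, multiplied by the reference voxel volume, truncated at
#' \code{truncationFactor * sigma}, and clipped below 1. Overlapping foci
#' within one experiment are combined by the voxel-wise maximum (the
#' nonadditive rule), so duplicated foci do not inflate the map; the legacy
#' additive rule is available via \code{combine = "sum"} for comparisons.
#'
#' @param experiment a \linkS4class{FociExperiment} in MNI space.
#' @param grid a \linkS4class{BrainGrid}.
#' @param spec a \linkS4class{KernelSpec}.
#' @param combine \code{"max"} (default, nonadditive) or \code{"sum"}.
#' @return Numeric vector of MA probabilities, one per mask voxel, in
#'   \code{[0, 1)}.
#' @export
maMap <- function(experiment, grid, spec = kernelSpec(), combine = c("max", "sum")) {
  combine <- match.arg(combine)
  if (experiment@space != "MNI")
    stop("experiment '", experiment@experimentId,
         "' must be normalized to MNI space first (see toMni)")
  sigma <- kernelSigma(experiment@nSubjects, spec)
  arr <- maArray(experiment@foci, sigma, grid, spec, combine)
  arr[grid@mask]
}

# Accumulate focus kernels into a full 3-D array (compiled inner loop;
# kernels evaluated analytically at voxel centers, truncated radially).
maArray <- function(foci, sigma, grid, spec, combine = "max") {
  offdiag <- grid@affine[1:3, 1:3]; diag(offdiag) <- 0
  if (any(abs(offdiag) > 1e-8) || any(diag(grid@affine)[1:3] <= 0))
    stop("kernel evaluation requires an axis-aligned grid affine with ",
         "positive voxel sizes")
  radius <- spec@truncationFactor * sigma
  norm <- spec@refVolume / (2 * pi * sigma^2)^1.5
  arr <- .maAccumulate(grid@shape, diag(grid@affine)[1:3],
                       grid@affine[1:3, 4], foci, sigma, radius, norm,
                       if (combine == "max") 0L else 1L)
  array(arr, dim = grid@shape)
}
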