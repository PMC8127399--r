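#' Draw points uniformly within the analysis mask
#'
#' Continuous-uniform samples over the masked volume, by rejection from the
#' mask bounding box (nearest-voxel membership test). Optionally avoids a
#' set of spherical exclusion zones.
#'
#' @param n number of points.
#' @param grid a \linkS4class{BrainGrid}.
#' @param avoid optional list of \code{list(center=, radius=)} spheres the
#'   samples must not fall in.
#' @return n x 3 matrix of mm coordinates.
#' @export
sampleUniformInMask <- function(n, grid, avoid = NULL) {
  if (n == 0) return(matrix(numeric(0), ncol = 3))
  maskMm <- maskCoordinates(grid)
  lo <- apply(maskMm, 2, min) - 0.5 * abs(diag(grid@affine)[1:3])
  hi <- apply(maskMm, 2, max) + 0.5 * abs(diag(grid@affine)[1:3])
  out <- matrix(NA_real_, n, 3)
  got <- 0L
  while (got < n) {
    m <- max(2L * (n - got), 64L)
    cand <- cbind(stats::runif(m, lo[1], hi[1]),
                  stats::runif(m, lo[2], hi[2]),
                  stats::runif(m, lo[3], hi[3]))
    ok <- inMask(grid, cand)
    if (!is.null(avoid)) {
      for (a in avoid)
        ok <- ok & sqrt(rowSums(sweep(cand, 2, a$center)^2)) > a$radius
    }
    cand <- cand[ok, , drop = FALSE]
    take <- min(nrow(cand), n - got)
    if (take > 0) {
      out[(got + 1):(got + take), ] <- cand[seq_len(take), , drop = FALSE]
      got <- got + take
    }
  }
  out
}

# normal draws around a center, resampled until inside the mask
sampleNormalInMask <- function(n, center, dispersion, grid) {
  out <- matrix(NA_real_, n, 3)
  got <- 0L
  while (got < n) {
    m <- max(2L * (n - got), 16L)
    cand <- matrix(stats::rnorm(m * 3, sd = dispersion), ncol = 3)
    cand <- sweep(cand, 2, center, "+")
    cand <- cand[inMask(grid, cand), , drop = FALSE]
    take <- min(nrow(cand), n - got)
    if (take > 0) {
      out[(got + 1):(got + take), ] <- cand[seq_len(take), , drop = FALSE]
      got <- got + take
    }
  }
  out
}

#' Generate a synthetic foci corpus with planted convergence loci
#'
#' Emulates the statistical structure of a patient-versus-control foci
#' corpus: per-experiment sample sizes and foci counts drawn uniformly from
#' ranges matching the published corpus (n 6-26, 1-34 foci per experiment,
#' study-level mean UPDRS-III in 9-41), with optional planted convergence
#' loci. For each planted locus, \code{round(proportion * nExperiments)}
#' experiments are chosen to converge there; each contributes one focus
#' drawn isotropic-normal around the locus center with the stated
#' dispersion. All remaining foci are uniform in the mask. One study per
#' experiment is generated.
#'
#' @param nExperiments number of experiments.
#' @param grid a \linkS4class{BrainGrid}.
#' @param plantedLoci list of \code{list(center=, proportion=, dispersion=)}.
#' @param fociRange integer range of foci per experiment (default 1-34).
#' @param nSubjectsRange integer range of sample sizes (default 6-26).
#' @param updrsRange range of study-mean UPDRS scores (default 9-41).
#' @param contrast contrast label assigned to all experiments.
#' @param seed integer RNG seed.
#' @return List with \code{experiments} (list of
#'   \linkS4class{FociExperiment}), \code{metadata} (data.frame with
#'   study_id, n_subjects, n_foci, updrs_mean) and \code{groundTruth}
#'   (per-locus center, dispersion and converging experiment ids, plus the
#'   seed).
#' @export
generateCorpus <- function(nExperiments, grid, plantedLoci = list(),
                           fociRange = c(1L, 34L),
                           nSubjectsRange = c(6L, 26L),
                           updrsRange = c(9, 41),
                           contrast = "HC_gt_PD", seed = 1) {
  stopifnot(nExperiments >= 1, fociRange[1] >= 1,
            fociRange[2] >= fociRange[1],
            nSubjectsRange[1] >= 1, nSubjectsRange[2] >= nSubjectsRange[1])
  for (pl in plantedLoci) {
    stopifnot(pl$proportion >= 0, pl$proportion <= 1, pl$dispersion > 0)
    if (pl$proportion > 0 && pl$proportion * nExperiments < 1)
      warning("planted locus proportion ", pl$proportion,
              " selects no experiment at nExperiments = ", nExperiments)
  }
  set.seed(as.integer(seed))
  nSubj <- sample(nSubjectsRange[1]:nSubjectsRange[2], nExperiments,
                  replace = TRUE)
  nFoci <- sample(fociRange[1]:fociRange[2], nExperiments, replace = TRUE)
  updrs <- stats::runif(nExperiments, updrsRange[1], updrsRange[2])

  converge <- vector("list", length(plantedLoci))
  for (li in seq_along(plantedLoci)) {
    k <- round(plantedLoci[[li]]$proportion * nExperiments)
    converge[[li]] <- if (k >= 1) sort(sample.int(nExperiments, k)) else integer(0)
  }
  # every converging experiment needs room for its planted foci
  for (e in seq_len(nExperiments)) {
    need <- sum(vapply(converge, function(cv) e %in% cv, logical(1)))
    if (need > nFoci[e]) nFoci[e] <- need
  }

  experiments <- vector("list", nExperiments)
  for (e in seq_len(nExperiments)) {
    planted <- NULL
    for (li in seq_along(plantedLoci)) {
      if (e %in% converge[[li]]) {
        pl <- plantedLoci[[li]]
        planted <- rbind(planted,
                         sampleNormalInMask(1, pl$center, pl$dispersion, grid))
      }
    }
    nBg <- nFoci[e] - NROW(planted)
    foci <- rbind(planted, sampleUniformInMask(nBg, grid))
    experiments[[e]] <- fociExperiment(
      experimentId = sprintf("synth%03d: %s", e, contrast),
      contrast = contrast, nSubjects = nSubj[e], foci = foci,
      studyId = sprintf("synth%03d", e))
  }
  metadata <- data.frame(
    study_id = sprintf("synth%03d", seq_len(nExperiments)),
    n_subjects = nSubj, n_foci = nFoci, updrs_mean = updrs,
    stringsAsFactors = FALSE)
  groundTruth <- list(
    seed = seed,
    loci = lapply(seq_along(plantedLoci), function(li) list(
      center = plantedLoci[[li]]$center,
      dispersion = plantedLoci[[li]]$dispersion,
      experiments = metadata$study_id[converge[[li]]])))
  list(experiments = experiments, metadata = metadata,
       groundTruth = groundTruth)
}

#' Generate a synthetic coactivation database with planted VOI coupling
#'
#' Builds a healthy-subject database corpus for connectivity modeling: for
#' each (VOI, target) pair, \code{nHitting} experiments carry one focus
#' uniform over the VOI's voxel set (sphere intersected with the mask) and,
#' with probability \code{coupling}, one focus normal around the target
#' center; the remaining experiments and all background foci are uniform in
#' the mask \emph{outside} every VOI voxel set, so VOI retrieval counts
#' equal the planted counts exactly.
#'
#' @param nExperiments total database size.
#' @param grid a \linkS4class{BrainGrid}.
#' @param voiTargetPairs list of \code{list(voi=center mm, target=center mm,
#'   coupling=probability, nHitting=count)}.
#' @param voiRadius VOI sphere radius in mm (default 8).
#' @param targetDispersion sd of target-adjacent foci in mm (default 5).
#' @param backgroundFociRange integer range of background foci per
#'   experiment (default 3-10).
#' @param nSubjectsRange sample-size range (default 10-30, typical of
#'   healthy-subject task studies).
#' @param seed integer RNG seed.
#' @return List with \code{experiments} and \code{groundTruth} (per pair:
#'   hitting experiment ids and which carry a target focus).
#' @export
generateCoactivationDb <- function(nExperiments, grid, voiTargetPairs,
                                   voiRadius = 8, targetDispersion = 5,
                                   backgroundFociRange = c(3L, 10L),
                                   nSubjectsRange = c(10L, 30L), seed = 1) {
  for (p in voiTargetPairs)
    stopifnot(p$coupling >= 0, p$coupling <= 1, p$nHitting >= 0)
  nHit <- vapply(voiTargetPairs, function(p) as.integer(p$nHitting),
                 integer(1))
  if (sum(nHit) > nExperiments)
    stop("planted VOI-hitting experiments exceed database size")
  set.seed(as.integer(seed))
  # membership is voxelized (nearest voxel), exactly as retrieval tests it
  voiVox <- lapply(voiTargetPairs, function(p)
    voiVoxels(voi("plant", center = p$voi, radius = voiRadius), grid))
  anyVoi <- Reduce(`|`, voiVox)
  voxelSizes <- abs(diag(grid@affine)[1:3])
  centersAll <- gridCenters(grid@shape, grid@affine)

  sampleAvoidingVois <- function(n) {
    if (n == 0) return(matrix(numeric(0), ncol = 3))
    out <- matrix(NA_real_, n, 3); got <- 0L
    while (got < n) {
      cand <- sampleUniformInMask(2L * (n - got) + 8L, grid)
      ijk <- round(mmToVoxel(grid, cand))
      lin <- 1L + ijk[, 1] + grid@shape[1] * (ijk[, 2] +
        grid@shape[2] * ijk[, 3])
      cand <- cand[!anyVoi[lin], , drop = FALSE]
      take <- min(nrow(cand), n - got)
      if (take > 0) {
        out[(got + 1):(got + take), ] <- cand[seq_len(take), , drop = FALSE]
        got <- got + take
      }
    }
    out
  }

  assign <- rep(0L, nExperiments)  # 0 = background experiment
  assign[seq_len(sum(nHit))] <- rep(seq_along(voiTargetPairs), nHit)

  experiments <- vector("list", nExperiments)
  gt <- lapply(voiTargetPairs, function(p)
    list(voi = p$voi, target = p$target, hitting = character(0),
         coupled = character(0)))
  for (e in seq_len(nExperiments)) {
    id <- sprintf("db%04d", e)
    nBg <- sample(backgroundFociRange[1]:backgroundFociRange[2], 1)
    foci <- sampleAvoidingVois(nBg)
    if (assign[e] > 0) {
      p <- voiTargetPairs[[assign[e]]]
      # uniform over the VOI's in-mask voxel set plus within-voxel jitter
      inVoi <- which(voiVox[[assign[e]]] & as.vector(grid@mask))
      if (!length(inVoi))
        stop("VOI at ", paste(p$voi, collapse = ","),
             " covers no mask voxel on this grid")
      pick <- inVoi[sample.int(length(inVoi), 1)]
      hit <- centersAll[pick, ] +
        stats::runif(3, -0.5, 0.5) * voxelSizes
      foci <- rbind(foci, hit)
      gt[[assign[e]]]$hitting <- c(gt[[assign[e]]]$hitting, id)
      if (stats::runif(1) < p$coupling) {
        foci <- rbind(foci, sampleNormalInMask(1, p$target,
                                               targetDispersion, grid))
        gt[[assign[e]]]$coupled <- c(gt[[assign[e]]]$coupled, id)
      }
    }
    experiments[[e]] <- fociExperiment(
      experimentId = sprintf("%s: task", id), contrast = "task",
      nSubjects = sample(nSubjectsRange[1]:nSubjectsRange[2], 1),
      foci = foci, studyId = id)
  }
  list(experiments = experiments,
       groundTruth = list(seed = seed, pairs = gt))
}

#' Packaged putamen detection cross-tabulation
#'
#' The published detection counts encoded as an experiment-level table:
#' of 49 experiments comparing controls with patients, 25 activated the
#' putamen in the control group; 21 of those also found decreased putamen
#' activity in the patients and 4 did not; no experiment reported a patient
#' decrease without control activation.
#'
#' @return data.frame with logical columns \code{control_putamen_active} and
#'   \code{pd_putamen_decreased}, one row per experiment.
#' @export
makeDetectionFixture <- function() {
  data.frame(
    experiment_id = sprintf("exp%02d", 1:49),
    control_putamen_active = rep(c(TRUE, TRUE, FALSE), c(21, 4, 24)),
    pd_putamen_decreased = rep(c(TRUE, FALSE, FALSE), c(21, 4, 24)),
    stringsAsFactors = FALSE)
}

#' Write corpus ground truth as JSON
#'
#' @param groundTruth ground-truth component of \code{\link{generateCorpus}}
#'   or \code{\link{generateCoactivationDb}}.
#' @param path output JSON path.
#' @export
writeGroundTruth <- function(groundTruth, path) {
  jsonlite::write_json(groundTruth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
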