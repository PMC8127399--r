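#' Run configuration
#'
#' Assembles and validates the declarative configuration for a pipeline run.
#' All parameters are serialized next to the outputs so a run is fully
#' reproducible from its output directory.
#'
#' @param voxelSize analysis grid voxel edge, mm.
#' @param maskPath optional NIfTI mask path (nonzero = analyzed); when NULL
#'   the shipped ellipsoidal mask is used.
#' @param sigmaSubj,sigmaTemplate,truncationFactor,refVolume kernel
#'   constants, see \code{\link{kernelSpec}}.
#' @param formingP cluster-forming voxel threshold (uncorrected p).
#' @param alpha cluster-level corrected significance level.
#' @param nPerm permutations for the cluster-extent null.
#' @param seed integer RNG seed.
#' @param gateThreshold pools must exceed this experiment count (strict).
#' @param includePet keep PET experiments (set FALSE for the
#'   fMRI-only sensitivity run).
#' @param connectivity cluster connectivity (26, 18 or 6).
#' @param relThreshold detection threshold multiplier, see
#'   \code{\link{clusterFwe}}.
#' @return Named list of settings.
#' @export
runConfig <- function(voxelSize = 4, maskPath = NULL,
                      sigmaSubj = 11.6 / (2 * sqrt(2 / pi)),
                      sigmaTemplate = 5.7 / (2 * sqrt(2 / pi)),
                      truncationFactor = 3.5, refVolume = 8,
                      formingP = 0.001, alpha = 0.05, nPerm = 1000,
                      seed = 1, gateThreshold = 20, includePet = TRUE,
                      connectivity = 26, relThreshold = 0.1) {
  cfg <- list(voxelSize = voxelSize, maskPath = maskPath,
              sigmaSubj = sigmaSubj, sigmaTemplate = sigmaTemplate,
              truncationFactor = truncationFactor, refVolume = refVolume,
              formingP = formingP, alpha = alpha, nPerm = nPerm,
              seed = seed, gateThreshold = gateThreshold,
              includePet = includePet, connectivity = connectivity,
              relThreshold = relThreshold)
  stopifnot(cfg$voxelSize > 0, cfg$formingP > 0, cfg$formingP < 1,
            cfg$alpha > 0, cfg$alpha <= 1, cfg$nPerm >= 100)
  if (!is.null(cfg$maskPath) && !file.exists(cfg$maskPath))
    stop("mask file not found: ", cfg$maskPath)
  cfg
}

configGrid <- function(config) {
  if (!is.null(config$maskPath)) readMaskNifti(config$maskPath)
  else makeBrainGrid(config$voxelSize)
}

configKernel <- function(config) {
  kernelSpec(sigmaSubj = config$sigmaSubj,
             sigmaTemplate = config$sigmaTemplate,
             truncationFactor = config$truncationFactor,
             refVolume = config$refVolume)
}

prepareExperiments <- function(experiments, config) {
  if (!config$includePet)
    experiments <- Filter(function(e) e@modality != "PET", experiments)
  lapply(experiments, function(e)
    if (e@space == "TAL") toMni(e) else e)
}

#' Run an ALE meta-analysis end to end
#'
#' Loads foci (Sleuth path or experiment list), normalizes Talairach
#' coordinates, enforces the experiment-count gate, runs
#' \code{\link{clusterFwe}}, and (when \code{outputDir} is given) writes
#' ALE/p/z/cluster-label NIfTI maps, the cluster table CSV, the
#' configuration JSON and a run log.
#'
#' @param foci Sleuth file path or list of \linkS4class{FociExperiment}.
#' @param config list from \code{\link{runConfig}}.
#' @param outputDir optional output directory (created if needed).
#' @param analysisName name used in output files and the log.
#' @return The \linkS4class{ALEResult}, invisibly when writing outputs.
#' @export
runAle <- function(foci, config = runConfig(), outputDir = NULL,
                   analysisName = "ale") {
  experiments <- if (is.character(foci)) readSleuth(foci) else foci
  experiments <- prepareExperiments(experiments, config)
  n <- length(experiments)
  if (n <= config$gateThreshold)
    stop("pool has ", n, " experiments; the eligibility gate requires more ",
         "than ", config$gateThreshold,
         " experiments per meta-analysis (gate rule: >",
         config$gateThreshold, ")")
  grid <- configGrid(config)
  res <- clusterFwe(experiments, grid, configKernel(config),
                    formingP = config$formingP, alpha = config$alpha,
                    nPerm = config$nPerm, seed = config$seed,
                    connectivity = config$connectivity,
                    relThreshold = config$relThreshold)
  if (!is.null(outputDir)) {
    dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(ext) file.path(outputDir, paste0(analysisName, ext))
    writeVolumeNifti(grid, res@ale, fp("_ale.nii.gz"))
    writeVolumeNifti(grid, res@p, fp("_p.nii.gz"))
    writeVolumeNifti(grid, res@z, fp("_z.nii.gz"))
    writeVolumeNifti(grid, as.numeric(res@clusterLabels),
                     fp("_clusters.nii.gz"))
    utils::write.csv(clusterTable(res), fp("_clusters.csv"),
                     row.names = FALSE)
    jsonlite::write_json(config, fp("_config.json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
    writeLines(c(sprintf("analysis: %s", analysisName),
                 sprintf("experiments: %d", n),
                 sprintf("gate: > %d experiments, passed",
                         config$gateThreshold),
                 sprintf("seed: %d", config$seed),
                 sprintf("significant clusters: %d", nrow(res@clusters)),
                 sprintf("critical extent: %s",
                         format(res@criticalExtent))),
               fp("_log.txt"))
    return(invisible(res))
  }
  res
}

#' Cluster table with per-experiment contributions
#'
#' @param result an \linkS4class{ALEResult}.
#' @param long include per-experiment contribution rows (long form) instead
#'   of the compact per-cluster table.
#' @return data.frame.
#' @export
clusterTable <- function(result, long = FALSE) {
  if (!long) return(result@clusters)
  if (!nrow(result@clusters))
    return(data.frame(label = integer(0), experiment_id = character(0),
                      contribution = numeric(0), detected = logical(0)))
  do.call(rbind, lapply(seq_len(nrow(result@clusters)), function(i) {
    co <- result@contributions[[i]]
    data.frame(label = result@clusters$label[i],
               experiment_id = names(co), contribution = as.numeric(co),
               detected = names(co) %in% result@detectedBy[[i]],
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

#' Run MACM profiles and their conjunction
#'
#' Retrieves database experiments per VOI, computes each coactivation
#' profile (\code{\link{macmProfile}}), intersects same-polarity profiles
#' and summarizes the overlap within an atlas region. With a single VOI no
#' conjunction is computed (profile only, with a warning).
#'
#' @param db Sleuth path or list of \linkS4class{FociExperiment}.
#' @param vois list of \code{\link{voi}} (one polarity per call).
#' @param atlas atlas object (see \code{\link{makeToyAtlas}}).
#' @param region atlas label id or name for the overlap summary.
#' @param config list from \code{\link{runConfig}}.
#' @param outputDir optional output directory.
#' @param minRetrieved minimum retrieval count per VOI.
#' @return List with \code{profiles}, \code{conjunction} (NULL for a single
#'   VOI) and \code{summary} (data.frame or NULL).
#' @export
runMacm <- function(db, vois, atlas, region = "putamen",
                    config = runConfig(), outputDir = NULL,
                    minRetrieved = 21) {
  experiments <- if (is.character(db)) readSleuth(db) else db
  experiments <- prepareExperiments(experiments, config)
  grid <- configGrid(config)
  spec <- configKernel(config)
  profiles <- lapply(vois, function(v)
    macmProfile(experiments, v, grid, spec, minRetrieved = minRetrieved,
                formingP = config$formingP, alpha = config$alpha,
                nPerm = config$nPerm, seed = config$seed,
                connectivity = config$connectivity))
  conj <- NULL; summ <- NULL
  if (length(profiles) >= 2) {
    conj <- macmConjunction(profiles)
    summ <- overlapSummary(conj$overlap, grid, atlas, region,
                           polarity = conj$polarity)
  } else {
    warning("single VOI: profile computed, no conjunction")
  }
  if (!is.null(outputDir)) {
    dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
    for (p in profiles)
      writeVolumeNifti(grid, as.numeric(p@sigMask),
                       file.path(outputDir,
                                 sprintf("macm_%s_sig.nii.gz", p@voiName)))
    if (!is.null(conj)) {
      writeVolumeNifti(grid, as.numeric(conj$overlap),
                       file.path(outputDir, "macm_overlap.nii.gz"))
      utils::write.table(summ, file.path(outputDir, "macm_overlap.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    jsonlite::write_json(config, file.path(outputDir, "macm_config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  list(profiles = profiles, conjunction = conj, summary = summ)
}

#' Human-readable result report
#'
#' Formats the significant-cluster table (side, peak x/y/z, peak z value,
#' extent, corrected cluster p) with per-cluster detection percentages,
#' mirroring the customary presentation of coordinate-based meta-analysis
#' results.
#'
#' @param result an \linkS4class{ALEResult}.
#' @param title heading line.
#' @return Character vector of report lines.
#' @export
renderReport <- function(result, title = "ALE meta-analysis") {
  lines <- c(title,
             strrep("=", nchar(title)),
             sprintf("Experiments: %d; cluster-level threshold p < %.2g FWE",
                     result@settings$nExperiments, result@settings$alpha))
  if (!nrow(result@clusters)) {
    return(c(lines, "No suprathreshold clusters."))
  }
  lines <- c(lines, "",
             sprintf("%-6s %6s %6s %6s %8s %8s %10s %s",
                     "Side", "x", "y", "z", "peak Z", "extent", "cluster p",
                     "detected"))
  nExp <- result@settings$nExperiments
  for (i in seq_len(nrow(result@clusters))) {
    cl <- result@clusters[i, ]
    k <- length(result@detectedBy[[i]])
    lines <- c(lines, sprintf(
      "%-6s %6.0f %6.0f %6.0f %8.2f %8d %10.4f %d/%d (%d%%)",
      cl$side, cl$x, cl$y, cl$z, cl$peak_z, cl$extent, cl$cluster_p,
      k, nExp, reportDetectionPercent(k, nExp)))
  }
  lines
}

#' Empirical family-wise error rate under the null
#'
#' Calibration of the full cluster-level inference chain: generates
#' \code{nRuns} null corpora (foci uniform in the mask, no planted
#' convergence), runs \code{\link{clusterFwe}} on each, and reports the
#' fraction of runs with at least one significant cluster. Under a valid
#' procedure this fraction should not exceed \code{alpha} beyond binomial
#' noise.
#'
#' @param nRuns number of null corpora.
#' @param nExperiments experiments per corpus.
#' @param nFoci foci per experiment.
#' @param grid a \linkS4class{BrainGrid}.
#' @param spec a \linkS4class{KernelSpec}.
#' @param nSubjectsRange per-experiment sample-size range.
#' @param formingP,alpha,nPerm,connectivity inference settings, as
#'   \code{\link{clusterFwe}}.
#' @param seed integer RNG seed (one stream drives all runs).
#' @return List with \code{fwe} (fraction of positive runs), \code{se}
#'   (binomial standard error), \code{nRuns}, \code{alpha} and the per-run
#'   logical vector \code{anySignificant}.
#' @export
fweCalibration <- function(nRuns = 50, nExperiments = 25, nFoci = 10,
                           grid = makeBrainGrid(6), spec = kernelSpec(),
                           nSubjectsRange = c(8L, 25L),
                           formingP = 0.001, alpha = 0.05, nPerm = 200,
                           connectivity = 26, seed = 1) {
  set.seed(as.integer(seed))
  runSeeds <- sample.int(.Machine$integer.max, nRuns)
  anySig <- logical(nRuns)
  for (r in seq_len(nRuns)) {
    corpus <- generateCorpus(nExperiments, grid, plantedLoci = list(),
                             fociRange = c(nFoci, nFoci),
                             nSubjectsRange = nSubjectsRange,
                             seed = runSeeds[r] %% .Machine$integer.max)
    res <- clusterFwe(corpus$experiments, grid, spec,
                      formingP = formingP, alpha = alpha, nPerm = nPerm,
                      seed = runSeeds[r], connectivity = connectivity)
    anySig[r] <- nrow(res@clusters) > 0
  }
  fwe <- mean(anySig)
  list(fwe = fwe, se = sqrt(alpha * (1 - alpha) / nRuns),
       nRuns = nRuns, alpha = alpha, anySignificant = anySig)
}
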