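#' ALE union of modeled-activation maps
#'
#' The ALE score at a voxel is the probability that at least one experiment's
#' true activation lies there under independence:
#' \code{ALE(v) = 1 - prod_e (1 - MA_e(v))}.
#'
#' @param maMaps list of per-mask-voxel MA vectors (equal lengths, one grid),
#'   or a matrix with one column per experiment.
#' @return Numeric vector of ALE scores per mask voxel.
#' @export
aleUnion <- function(maMaps) {
  if (is.matrix(maMaps)) maMaps <- asplit(maMaps, 2)
  if (!length(maMaps)) stop("need at least one MA map")
  n <- unique(lengths(maMaps))
  if (length(n) != 1) stop("MA maps must share one grid")
  prodCompl <- rep(1, n)
  for (m in maMaps) prodCompl <- prodCompl * (1 - m)
  1 - prodCompl
}

#' Analytic null distribution of the ALE score
#'
#' Distribution of the ALE score at a random voxel under random spatial
#' association: each experiment's MA value is drawn independently from that
#' experiment's empirical histogram of MA values over the mask, and the draws
#' are combined by the ALE union. Two representations are used:
#' \describe{
#'   \item{exact}{full enumeration of the union over the experiments'
#'     distinct MA values (value/probability pairs, no discretization);
#'     feasible when the product of distinct-value counts stays small.}
#'   \item{binned}{the union becomes an exact sum on the log-complement axis
#'     \code{L = -log(1 - MA)}, so the combined distribution is the
#'     convolution of the per-experiment L histograms, computed iteratively
#'     on a lattice of step \code{binWidth} (FFT convolution).}
#' }
#' \code{method = "auto"} picks exact while the enumerated support stays
#' below \code{maxExact} values, else binned.
#'
#' @param maMaps list of per-mask-voxel MA vectors.
#' @param binWidth lattice step on the log-complement score axis (close to
#'   ALE units at small scores). Default 1e-5.
#' @param method \code{"auto"}, \code{"exact"} or \code{"binned"}.
#' @param maxExact support cap for the exact path under \code{"auto"}.
#' @return A \linkS4class{NullModel}.
#' @export
aleNullModel <- function(maMaps, binWidth = 1e-5,
                         method = c("auto", "exact", "binned"),
                         maxExact = 2e5) {
  method <- match.arg(method)
  if (is.matrix(maMaps)) maMaps <- asplit(maMaps, 2)
  if (!length(maMaps)) stop("need at least one MA map")
  if (binWidth <= 0) stop("binWidth must be positive")
  nExp <- length(maMaps)

  if (method != "binned") {
    supportSize <- 1
    for (m in maMaps) {
      supportSize <- supportSize * length(unique(m))
      if (supportSize > maxExact) break
    }
    if (method == "exact" || supportSize <= maxExact)
      return(exactNull(maMaps, nExp, binWidth))
    # fall through to binned under "auto"
  }
  binnedNull(maMaps, nExp, binWidth)
}

exactNull <- function(maMaps, nExp, binWidth) {
  # accumulate the complement product q = prod(1 - MA) with the same
  # multiplication order as aleUnion, so scores tie out exactly with
  # observed ALE values
  q <- 1; probs <- 1
  for (m in maMaps) {
    mu <- unique(m)
    mp <- vapply(mu, function(v) mean(m == v), numeric(1))
    comb <- as.vector(outer(q, 1 - mu))
    w <- as.vector(outer(probs, mp))
    o <- order(comb)
    cv <- comb[o]; cw <- w[o]
    first <- !duplicated(cv)
    grp <- cumsum(first)
    q <- cv[first]
    probs <- as.numeric(rowsum(cw, grp))
  }
  scores <- 1 - q              # q decreasing in score; sort ascending
  o <- order(scores)
  scores <- scores[o]; probs <- probs[o]
  tails <- rev(cumsum(rev(probs)))
  new("NullModel", scores = scores, probs = probs, tailProbs = tails,
      binWidth = NA_real_, nExperiments = as.integer(nExp), kind = "exact")
}

binnedNull <- function(maMaps, nExp, binWidth) {
  # distribution of L = -log(1 - MA) on lattice k*binWidth (floor binning)
  acc <- 1  # point mass at L = 0
  nVox <- length(maMaps[[1]])
  for (m in maMaps) {
    k <- floor(-log1p(-m) / binWidth)
    h <- tabulate(k + 1L, nbins = max(k) + 1L) / nVox
    acc <- convolveDensities(acc, h)
  }
  probs <- acc
  probs[probs < 0] <- 0          # FFT noise
  probs <- probs / sum(probs)
  nz <- which(probs > 0)
  lat <- (nz - 1) * binWidth
  scores <- -expm1(-lat)         # back to the ALE axis
  probs <- probs[nz]
  tails <- rev(cumsum(rev(probs)))
  new("NullModel", scores = scores, probs = probs, tailProbs = tails,
      binWidth = binWidth, nExperiments = as.integer(nExp), kind = "binned")
}

convolveDensities <- function(a, b) {
  if (length(a) == 1L) return(a * b)
  if (length(b) == 1L) return(a * b)
  out <- stats::convolve(a, rev(b), type = "open")
  out[abs(out) < 1e-16] <- 0
  out
}

#' Survival function of an ALE null model
#'
#' Right-continuous upper-tail probability \code{P(score >= s)} ("equal or
#' higher values"). For the binned representation the query score is snapped
#' to the same lattice as the null mass so ties are counted consistently.
#'
#' @param null a \linkS4class{NullModel}.
#' @param scores numeric vector of ALE scores.
#' @return Numeric vector of upper-tail probabilities in [0, 1].
#' @export
nullSurvival <- function(null, scores) {
  if (null@kind == "binned") {
    kq <- floor(-log1p(-scores) / null@binWidth)
    kn <- round(-log1p(-null@scores) / null@binWidth)
    pos <- findInterval(kq, kn)  # last null bin <= query bin
    # tail from the first bin >= query bin
    idx <- ifelse(pos >= 1 & kn[pmax(pos, 1)] == kq, pos, pos + 1L)
  } else {
    eps <- 1e-13
    idx <- findInterval(scores - eps, null@scores) + 1L
    # findInterval gives last score <= s-eps; tail starts at the next one,
    # which includes exact ties of s
  }
  out <- numeric(length(scores))
  inRange <- idx <= length(null@tailProbs)
  out[inRange] <- null@tailProbs[idx[inRange]]
  out[scores <= 0] <- 1
  out
}

#' Voxel-wise p and z maps from an ALE map and its null
#'
#' \code{p(v)} is the null survival at the observed score ("proportion of
#' equal or higher values"); \code{z = qnorm(1 - p)}, capped.
#'
#' @param ale per-mask-voxel ALE scores.
#' @param null a \linkS4class{NullModel} built from the same MA maps.
#' @param zMax cap for the z transform (default 10).
#' @return List with components \code{p} and \code{z}.
#' @export
voxelPvalues <- function(ale, null, zMax = 10) {
  p <- nullSurvival(null, ale)
  z <- stats::qnorm(1 - p)
  z[z > zMax] <- zMax
  z[z < -zMax] <- -zMax
  list(p = p, z = z)
}

# smallest ALE score whose null survival is < formingP (cluster-forming
# score cutoff); Inf if no score is extreme enough
formingScoreCutoff <- function(null, formingP) {
  k <- which(null@tailProbs < formingP)
  if (!length(k)) return(Inf)
  null@scores[min(k)]
}

#' Label connected suprathreshold clusters
#'
#' Connected components of a boolean mask-voxel set under 26- (default), 18-
#' or 6-neighborhood connectivity.
#'
#' @param grid a \linkS4class{BrainGrid}.
#' @param supra logical vector per mask voxel.
#' @param connectivity 26, 18 or 6.
#' @return Integer vector per mask voxel; 0 outside clusters, labels are
#'   1..K in decreasing extent order.
#' @export
labelClusters <- function(grid, supra, connectivity = 26) {
  labels <- integer(length(supra))
  vox <- which(supra)
  if (!length(vox)) return(labels)
  # 0-based ijk of suprathreshold mask voxels
  full <- which(as.vector(grid@mask))[vox]
  sh <- grid@shape
  i <- (full - 1L) %% sh[1]
  j <- ((full - 1L) %/% sh[1]) %% sh[2]
  k <- (full - 1L) %/% (sh[1] * sh[2])
  key <- i + sh[1] * (j + sh[2] * k)
  lookup <- stats::setNames(seq_along(vox), key)

  offs <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  offs <- offs[!(offs$di == 0 & offs$dj == 0 & offs$dk == 0), ]
  dist1 <- abs(offs$di) + abs(offs$dj) + abs(offs$dk)
  offs <- switch(as.character(connectivity),
                 "6" = offs[dist1 == 1, ],
                 "18" = offs[dist1 <= 2, ],
                 "26" = offs,
                 stop("connectivity must be 6, 18 or 26"))

  comp <- integer(length(vox))
  nextLabel <- 0L
  for (s in seq_along(vox)) {
    if (comp[s]) next
    nextLabel <- nextLabel + 1L
    queue <- s
    comp[s] <- nextLabel
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      ni <- i[cur] + offs$di; nj <- j[cur] + offs$dj; nk <- k[cur] + offs$dk
      ok <- ni >= 0 & ni < sh[1] & nj >= 0 & nj < sh[2] & nk >= 0 & nk < sh[3]
      nkey <- ni[ok] + sh[1] * (nj[ok] + sh[2] * nk[ok])
      hit <- lookup[as.character(nkey)]
      hit <- hit[!is.na(hit)]
      new <- hit[comp[hit] == 0L]
      if (length(new)) {
        comp[new] <- nextLabel
        queue <- c(queue, new)
      }
    }
  }
  # relabel by decreasing extent
  ext <- tabulate(comp, nextLabel)
  ord <- order(ext, decreasing = TRUE)
  relab <- integer(nextLabel); relab[ord] <- seq_len(nextLabel)
  labels[vox] <- relab[comp]
  labels
}

# uniform relocation of an experiment's foci: mask voxels drawn without
# replacement plus uniform within-voxel jitter, so null foci are continuous-
# uniform over the masked volume like observed ones
relocateFoci <- function(nFoci, grid, maskMm, voxelSizes) {
  pick <- sample.int(nrow(maskMm), nFoci, replace = FALSE)
  jitter <- matrix(stats::runif(nFoci * 3, -0.5, 0.5), ncol = 3)
  maskMm[pick, , drop = FALSE] + sweep(jitter, 2, voxelSizes, "*")
}

#' ALE meta-analysis with cluster-level family-wise error control
#'
#' Runs the full inference chain: per-experiment MA maps, ALE union, analytic
#' voxel-wise null, cluster-forming threshold at \code{formingP}
#' (uncorrected), connected-component labeling, and a permutation null of the
#' maximum cluster extent in which every experiment's foci are relocated
#' uniformly at random within the mask (foci count and sample size preserved)
#' and the map is rethresholded. A cluster is significant when its corrected
#' p — \code{(1 + #\{permutation maxima >= extent\}) / (nPerm + 1)} — is at
#' most \code{alpha}. The critical extent reported is the empirical
#' \code{1 - alpha} quantile of the permutation maxima.
#'
#' @param experiments list of \linkS4class{FociExperiment} in MNI space.
#' @param grid a \linkS4class{BrainGrid}.
#' @param spec a \linkS4class{KernelSpec}.
#' @param formingP cluster-forming voxel threshold, uncorrected p (default
#'   0.001).
#' @param alpha cluster-level corrected significance level (default 0.05).
#' @param nPerm number of permutations, >= 100.
#' @param seed integer RNG seed.
#' @param connectivity cluster connectivity (26, 18 or 6).
#' @param nullMethod passed to \code{\link{aleNullModel}}.
#' @param binWidth null-histogram lattice step.
#' @param relThreshold detection threshold for \code{detected_by}, as a
#'   multiple of the uniform share 1/nExperiments (default 0.1).
#' @param statistic \code{"extent"} (default) or \code{"mass"} (sum of ALE
#'   scores over the cluster) as cluster-level statistic.
#' @return An \linkS4class{ALEResult}.
#' @export
clusterFwe <- function(experiments, grid, spec = kernelSpec(),
                       formingP = 0.001, alpha = 0.05, nPerm = 1000,
                       seed = 1, connectivity = 26,
                       nullMethod = "auto", binWidth = 1e-5,
                       relThreshold = 0.1,
                       statistic = c("extent", "mass")) {
  statistic <- match.arg(statistic)
  if (!length(experiments)) stop("need at least one experiment")
  if (nPerm < 100) stop("nPerm must be >= 100")
  if (formingP <= 0 || formingP >= 1) stop("formingP must be in (0, 1)")
  set.seed(as.integer(seed))

  ids <- vapply(experiments, function(e) e@experimentId, character(1))
  maList <- lapply(experiments, maMap, grid = grid, spec = spec)
  names(maList) <- ids
  ale <- aleUnion(maList)
  null <- aleNullModel(maList, binWidth = binWidth, method = nullMethod)
  pv <- voxelPvalues(ale, null)
  cutoff <- formingScoreCutoff(null, formingP)

  clusterStat <- function(aleVec, labels) {
    if (!any(labels > 0)) return(numeric(0))
    if (statistic == "extent") tabulate(labels)
    else as.numeric(rowsum(aleVec[labels > 0], labels[labels > 0]))
  }

  labels <- labelClusters(grid, ale >= cutoff, connectivity)
  obsStats <- clusterStat(ale, labels)

  maskMm <- maskCoordinates(grid)
  maskIdx <- which(as.vector(grid@mask))
  voxelSizes <- abs(diag(grid@affine)[1:3])
  origin <- grid@affine[1:3, 4]
  sigmas <- vapply(experiments, function(e)
    kernelSigma(e@nSubjects, spec), numeric(1))
  radii <- spec@truncationFactor * sigmas
  norms <- spec@refVolume / (2 * pi * sigmas^2)^1.5
  nFoci <- vapply(experiments, function(e) nrow(e@foci), integer(1))

  permMax <- numeric(nPerm)
  for (b in seq_len(nPerm)) {
    prodCompl <- rep(1, length(maskIdx))
    for (e in seq_along(experiments)) {
      foci <- relocateFoci(nFoci[e], grid, maskMm, voxelSizes)
      maFull <- .maAccumulate(grid@shape, voxelSizes, origin, foci,
                              sigmas[e], radii[e], norms[e], 0L)
      prodCompl <- .complementProduct(prodCompl, maFull, maskIdx)
    }
    permAle <- 1 - prodCompl
    permLabels <- labelClusters(grid, permAle >= cutoff, connectivity)
    st <- clusterStat(permAle, permLabels)
    permMax[b] <- if (length(st)) max(st) else 0
  }
  criticalExtent <- stats::quantile(permMax, 1 - alpha, type = 1, names = FALSE)

  correctedP <- vapply(obsStats, function(s)
    (1 + sum(permMax >= s)) / (nPerm + 1), numeric(1))
  keep <- which(correctedP <= alpha)

  clusterLabels <- integer(length(ale))
  clusters <- data.frame(label = integer(0), side = character(0),
                         x = numeric(0), y = numeric(0), z = numeric(0),
                         peak_z = numeric(0), extent = integer(0),
                         cluster_p = numeric(0), stringsAsFactors = FALSE)
  contributions <- list(); detectedBy <- list()
  if (length(keep)) {
    maskMmAll <- maskMm
    newLab <- 0L
    for (lab in keep) {
      newLab <- newLab + 1L
      vox <- which(labels == lab)
      clusterLabels[vox] <- newLab
      pk <- clusterPeak(vox, pv$z, maskMmAll)
      contrib <- attributeCluster(vox, maList)
      det <- names(contrib)[contrib >= relThreshold / length(maList)]
      clusters <- rbind(clusters, data.frame(
        label = newLab, side = if (pk["x"] > 0) "Right" else "Left",
        x = pk["x"], y = pk["y"], z = pk["z"],
        peak_z = pk["z_value"], extent = length(vox),
        cluster_p = correctedP[lab], stringsAsFactors = FALSE))
      contributions[[newLab]] <- contrib
      detectedBy[[newLab]] <- det
    }
    rownames(clusters) <- NULL
  }

  new("ALEResult", grid = grid, ale = ale, p = pv$p, z = pv$z,
      clusterLabels = clusterLabels, clusters = clusters,
      contributions = contributions, detectedBy = detectedBy,
      criticalExtent = as.numeric(criticalExtent),
      nullMaxExtents = as.integer(round(permMax)),
      null = null,
      settings = list(nExperiments = length(experiments),
                      formingP = formingP, alpha = alpha, nPerm = nPerm,
                      seed = seed, connectivity = connectivity,
                      statistic = statistic, relThreshold = relThreshold,
                      scoreCutoff = cutoff))
}

# peak voxel of a cluster: maximum z, ties broken by smallest lexicographic
# (x, y, z) mm coordinate
clusterPeak <- function(vox, z, maskMm) {
  zi <- z[vox]
  best <- vox[zi == max(zi)]
  if (length(best) > 1) {
    mm <- maskMm[best, , drop = FALSE]
    best <- best[order(mm[, 1], mm[, 2], mm[, 3])][1]
  }
  c(x = maskMm[best, 1], y = maskMm[best, 2], z = maskMm[best, 3],
    z_value = z[best])
}

#' Per-experiment contribution to a cluster
#'
#' Leave-one-out attribution: the contribution of experiment e is the drop in
#' total cluster ALE mass when e is removed,
#' \code{sum_v ALE(v) - sum_v ALE_without_e(v)}, normalized so the fractions
#' sum to 1 over experiments.
#'
#' @param cluster integer vector of mask-voxel indices in the cluster.
#' @param maMaps named list of per-mask-voxel MA vectors (all experiments of
#'   the analysis).
#' @return Named numeric vector of contribution fractions summing to 1.
#' @export
attributeCluster <- function(cluster, maMaps) {
  if (!length(cluster)) stop("empty cluster")
  sub <- lapply(maMaps, function(m) m[cluster])
  prodCompl <- rep(1, length(cluster))
  for (m in sub) prodCompl <- prodCompl * (1 - m)
  aleMass <- sum(1 - prodCompl)
  drops <- vapply(sub, function(m) {
    without <- prodCompl / (1 - m)  # MA clipped < 1 upstream
    aleMass - sum(1 - without)
  }, numeric(1))
  if (sum(drops) <= 0) stop("cluster has no experiment contribution")
  drops / sum(drops)
}
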