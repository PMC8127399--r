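test_that("ALE union follows the complement-product formula", {
  # union of one map is the map itself
  m <- runif(40)
  expect_identical(aleUnion(list(m)), 1 - (1 - m))

  # two maps at 0.5 combine to 0.75
  expect_equal(aleUnion(list(0.5, 0.5)), 0.75)

  # 20 random MA vectors on 50 voxels against a direct product oracle
  set.seed(5)
  maps <- replicate(20, runif(50, 0, 0.05), simplify = FALSE)
  ale <- aleUnion(maps)
  oracle <- 1 - apply(do.call(cbind, lapply(maps, function(m) 1 - m)), 1, prod)
  expect_equal(ale, oracle, tolerance = 1e-14)
  expect_error(aleUnion(list()), "at least one")
})

test_that("union bounds hold: max MA <= ALE <= sum MA", {
  set.seed(6)
  maps <- replicate(8, runif(30, 0, 0.2), simplify = FALSE)
  ale <- aleUnion(maps)
  mx <- do.call(pmax, maps)
  sm <- Reduce(`+`, maps)
  expect_true(all(ale >= mx - 1e-15))
  expect_true(all(ale <= sm + 1e-15))
})

test_that("exact null matches exhaustive enumeration of voxel pairings", {
  # 2 experiments x 30-voxel toy mask: all 30 x 30 pairings
  set.seed(9)
  ma1 <- runif(30, 0, 0.06)
  ma2 <- runif(30, 0, 0.06)
  null <- aleNullModel(list(ma1, ma2), method = "exact")
  expect_equal(null@kind, "exact")
  expect_equal(sum(null@probs), 1, tolerance = 1e-12)

  comb <- as.vector(1 - outer(1 - ma1, 1 - ma2))  # exhaustive oracle
  ale <- aleUnion(list(ma1, ma2))
  pObs <- nullSurvival(null, ale)
  pOracle <- vapply(ale, function(s) mean(comb >= s), numeric(1))
  expect_identical(pObs, pOracle)

  # survival at zero is 1: every null draw is >= 0
  expect_equal(nullSurvival(null, 0), 1)
})

test_that("single-experiment null is that experiment's MA histogram", {
  ma <- c(0, 0, 0.01, 0.02, 0.02, 0.05)
  null <- aleNullModel(list(ma), method = "exact")
  expect_equal(null@scores, c(0, 0.01, 0.02, 0.05))
  expect_equal(null@probs, c(2, 1, 2, 1) / 6)
})

test_that("binned null agrees with the exact null", {
  set.seed(10)
  maps <- replicate(3, runif(50, 0, 0.03), simplify = FALSE)
  exact <- aleNullModel(maps, method = "exact")
  binned <- aleNullModel(maps, method = "binned", binWidth = 1e-5)
  qs <- quantile(aleUnion(maps), c(0.5, 0.9, 0.99))
  pe <- nullSurvival(exact, qs)
  pb <- nullSurvival(binned, qs)
  expect_equal(pb, pe, tolerance = 2e-3)
})

test_that("analytic null agrees with Monte-Carlo voxel sampling", {
  # 5 experiments on a 500-voxel toy: compare survival at the scores whose
  # analytic tail is ~0.05/0.01/0.001 against direct random association
  set.seed(12)
  maps <- replicate(5, runif(500, 0, 0.04) * rbinom(500, 1, 0.4),
                    simplify = FALSE)
  null <- aleNullModel(maps)
  nMc <- 200000
  set.seed(13)
  draws <- matrix(0, nMc, 5)
  for (e in 1:5) draws[, e] <- sample(maps[[e]], nMc, replace = TRUE)
  mcAle <- 1 - apply(1 - draws, 1, prod)
  for (ptarget in c(0.05, 0.01, 0.001)) {
    s <- null@scores[which(null@tailProbs <= ptarget)[1]]
    pAnalytic <- nullSurvival(null, s)
    pMc <- mean(mcAle >= s)
    se <- sqrt(pAnalytic * (1 - pAnalytic) / nMc)
    expect_lt(abs(pMc - pAnalytic), 3 * se + 1e-6)
  }
})

test_that("voxel p-values are a monotone transform of ALE scores", {
  set.seed(14)
  maps <- replicate(3, runif(100, 0, 0.05), simplify = FALSE)
  ale <- aleUnion(maps)
  null <- aleNullModel(maps)
  pv <- voxelPvalues(ale, null)
  expect_equal(which.min(pv$p), which.max(ale))
  o <- order(ale)
  expect_true(all(diff(pv$p[o]) <= 1e-15))
  expect_true(all(pv$z <= 10))
  # z is the normal quantile of 1 - p
  mid <- pv$p > 1e-6 & pv$p < 1 - 1e-6
  expect_equal(pv$z[mid], qnorm(1 - pv$p[mid]))
})

test_that("cluster labeling finds connected components", {
  g <- makeBrainGrid(10, bbox = rbind(c(0, 0, 0), c(50, 50, 0)),
                     mask = "all")  # 6 x 6 x 1 sheet
  supra <- rep(FALSE, nMaskVoxels(g))
  mm <- maskCoordinates(g)
  # component A: an L-shape touching diagonally; component B: far corner
  inA <- (mm[, 1] <= 10 & mm[, 2] <= 10)
  inB <- (mm[, 1] >= 40 & mm[, 2] >= 40)
  supra[inA | inB] <- TRUE
  lab26 <- labelClusters(g, supra, 26)
  expect_equal(sort(unique(lab26[supra])), c(1L, 2L))
  expect_equal(length(unique(lab26[inA])), 1)
  expect_true(all(lab26[!supra] == 0L))
  # 6-connectivity splits diagonal-only contacts
  supra2 <- rep(FALSE, nMaskVoxels(g))
  diagPair <- (mm[, 1] == 0 & mm[, 2] == 0) | (mm[, 1] == 10 & mm[, 2] == 10)
  supra2[diagPair] <- TRUE
  expect_equal(max(labelClusters(g, supra2, 6)), 2L)
  expect_equal(max(labelClusters(g, supra2, 26)), 1L)
})

test_that("attribution fractions are exact for symmetric cases", {
  g <- coarseGrid(8)
  e1 <- makeExperiment(c(20, -20, 20), id = "a")
  ma1 <- maMap(e1, g)
  # single experiment: contribution 1
  vox <- which(ma1 > 0)
  expect_equal(unname(attributeCluster(vox, list(a = ma1))), 1)
  # two identical experiments: 0.5 each
  co <- attributeCluster(vox, list(a = ma1, b = ma1))
  expect_equal(unname(co), c(0.5, 0.5), tolerance = 1e-9)
  expect_error(attributeCluster(integer(0), list(a = ma1)), "empty")
})

test_that("attribution matches an independent leave-one-out recomputation", {
  g <- coarseGrid(8)
  set.seed(15)
  exps <- nullExperiments(5, 4, g, seed = 16)
  maps <- lapply(exps, maMap, grid = g)
  names(maps) <- paste0("e", 1:5)
  ale <- aleUnion(maps)
  vox <- order(ale, decreasing = TRUE)[1:30]
  co <- attributeCluster(vox, maps)
  # oracle: recompute cluster ALE mass without each experiment from scratch
  total <- sum(aleUnion(maps)[vox])
  drops <- vapply(1:5, function(i)
    total - sum(aleUnion(maps[-i])[vox]), numeric(1))
  expect_equal(unname(co), drops / sum(drops), tolerance = 1e-9)
  expect_equal(sum(co), 1)
})

test_that("cluster FWE chain is reproducible and honors its guards", {
  g <- makeBrainGrid(10)
  exps <- nullExperiments(6, 5, g, seed = 21)
  expect_error(clusterFwe(exps, g, nPerm = 50), "nPerm")
  r1 <- clusterFwe(exps, g, nPerm = 100, seed = 3)
  r2 <- clusterFwe(exps, g, nPerm = 100, seed = 3)
  expect_identical(r1@criticalExtent, r2@criticalExtent)
  expect_identical(r1@clusters, r2@clusters)
  expect_identical(r1@nullMaxExtents, r2@nullMaxExtents)
})

test_that("alpha = 1 retains every suprathreshold cluster", {
  g <- makeBrainGrid(10)
  set.seed(22)
  center <- c(-26, -8, 2)
  exps <- c(
    lapply(1:6, function(i) makeExperiment(
      rbind(center + rnorm(3, sd = 3), sampleUniformInMask(3, g)),
      id = sprintf("conv%d", i))),
    nullExperiments(4, 4, g, seed = 23))
  resAll <- clusterFwe(exps, g, formingP = 0.01, alpha = 1, nPerm = 100,
                       seed = 4)
  cutoff <- resAll@settings$scoreCutoff
  labs <- labelClusters(g, resAll@ale >= cutoff)
  expect_equal(nrow(resAll@clusters), max(labs))
})
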