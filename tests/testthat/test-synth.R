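test_that("generated corpora respect their spec and stay in the mask", {
  g <- coarseGrid(8)
  corp <- generateCorpus(12, g, fociRange = c(2L, 9L),
                         nSubjectsRange = c(6L, 26L), seed = 41)
  expect_length(corp$experiments, 12)
  for (e in corp$experiments) {
    expect_true(all(inMaskForTest(g, e@foci)))
    expect_true(nrow(e@foci) >= 2 && nrow(e@foci) <= 9)
    expect_true(e@nSubjects >= 6 && e@nSubjects <= 26)
  }
  expect_true(all(corp$metadata$updrs_mean >= 9 &
                    corp$metadata$updrs_mean <= 41))
})

test_that("zero proportions give a pure null corpus", {
  g <- coarseGrid(8)
  corp <- generateCorpus(
    8, g, plantedLoci = list(list(center = c(28, -10, 4), proportion = 0,
                                  dispersion = 10)),
    fociRange = c(3L, 6L), seed = 42)
  expect_length(corp$groundTruth$loci[[1]]$experiments, 0)
})

test_that("planted convergence counts round to the nearest experiment", {
  g <- coarseGrid(8)
  corp <- generateCorpus(
    49, g, plantedLoci = list(list(center = c(28, -10, 4), proportion = 0.35,
                                   dispersion = 10)),
    fociRange = c(1L, 34L), seed = 43)
  expect_length(corp$groundTruth$loci[[1]]$experiments, 17)
  # converging experiments place a focus near the locus (normal, sd 10)
  conv <- corp$groundTruth$loci[[1]]$experiments
  idx <- match(conv, corp$metadata$study_id)
  d <- vapply(idx, function(i) {
    f <- corp$experiments[[i]]@foci
    min(sqrt(rowSums(sweep(f, 2, c(28, -10, 4))^2)))
  }, numeric(1))
  expect_true(mean(d < 25) > 0.9)
  # a sub-unit proportion that selects no experiment warns
  expect_warning(
    generateCorpus(8, g, plantedLoci = list(
      list(center = c(28, -10, 4), proportion = 0.05, dispersion = 10)),
      seed = 44),
    "selects no experiment")
})

test_that("same seed gives byte-identical Sleuth output", {
  g <- coarseGrid(8)
  f1 <- withr::local_tempfile(fileext = ".txt")
  f2 <- withr::local_tempfile(fileext = ".txt")
  writeSleuth(generateCorpus(10, g, seed = 45)$experiments, f1)
  writeSleuth(generateCorpus(10, g, seed = 45)$experiments, f2)
  expect_identical(readLines(f1), readLines(f2))
  # and a different seed does not
  f3 <- withr::local_tempfile(fileext = ".txt")
  writeSleuth(generateCorpus(10, g, seed = 46)$experiments, f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("corpus statistics track the spec ranges over seeds", {
  g <- coarseGrid(8)
  meanN <- meanF <- numeric(20)
  for (s in 1:20) {
    corp <- generateCorpus(30, g, fociRange = c(1L, 34L),
                           nSubjectsRange = c(6L, 26L), seed = 100 + s)
    meanN[s] <- mean(corp$metadata$n_subjects)
    meanF[s] <- mean(corp$metadata$n_foci)
  }
  expect_lt(abs(mean(meanN) - 16), 1.6)   # within 10% of the range mean
  expect_lt(abs(mean(meanF) - 17.5), 1.75)
})

test_that("coactivation coupling probabilities behave at the extremes", {
  g <- coarseGrid(8)
  pairs <- list(list(voi = c(-36, -22, 50), target = c(26, -12, 2),
                     coupling = 1, nHitting = 15))
  db <- generateCoactivationDb(40, g, pairs, seed = 47)
  gt <- db$groundTruth$pairs[[1]]
  expect_length(gt$hitting, 15)
  expect_setequal(gt$coupled, gt$hitting)

  pairs0 <- list(list(voi = c(-36, -22, 50), target = c(26, -12, 2),
                      coupling = 0, nHitting = 15))
  db0 <- generateCoactivationDb(40, g, pairs0, seed = 48)
  expect_length(db0$groundTruth$pairs[[1]]$coupled, 0)
})

test_that("coupling counts fall in the binomial 99% interval", {
  g <- coarseGrid(8)
  pairs <- list(list(voi = c(-36, -22, 50), target = c(26, -12, 2),
                     coupling = 0.8, nHitting = 50))
  db <- generateCoactivationDb(60, g, pairs, seed = 49)
  k <- length(db$groundTruth$pairs[[1]]$coupled)
  bounds <- qbinom(c(0.005, 0.995), 50, 0.8)
  expect_true(k >= bounds[1] && k <= bounds[2])
})

test_that("tight planted convergence is recovered end to end", {
  # a compact locus (dispersion 6 mm, 35% of 49 experiments) must survive
  # cluster-level FWE with its peak near the planted center
  g <- makeBrainGrid(6)
  for (s in 1:2) {
    corp <- generateCorpus(
      49, g, plantedLoci = list(list(center = c(28, -10, 4),
                                     proportion = 0.35, dispersion = 6)),
      seed = 200 + s)
    res <- clusterFwe(corp$experiments, g, nPerm = 100, seed = 200 + s)
    expect_gte(nrow(res@clusters), 1)
    d <- sqrt((res@clusters$x - 28)^2 + (res@clusters$y + 10)^2 +
                (res@clusters$z - 4)^2)
    expect_lte(min(d), 10)
  }
})

test_that("detection fixture passes its schema invariants", {
  tab <- makeDetectionFixture()
  expect_equal(nrow(tab), 49)
  expect_true(all(!is.na(tab$control_putamen_active)))
  expect_true(all(!is.na(tab$pd_putamen_decreased)))
  expect_equal(sum(tab$control_putamen_active), 25)
  expect_equal(sum(tab$pd_putamen_decreased & !tab$control_putamen_active), 0)
})
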