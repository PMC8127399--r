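test_that("percentages round half away from zero", {
  expect_equal(reportDetectionPercent(17, 49), 35L)
  expect_equal(reportDetectionPercent(18, 49), 37L)
  expect_equal(reportDetectionPercent(11, 49), 22L)
  expect_equal(reportDetectionPercent(13, 41), 32L)
  expect_equal(reportDetectionPercent(0, 49), 0L)
  # exact half rounds up, not to even
  expect_equal(reportDetectionPercent(1, 8), 13L)  # 12.5 -> 13
  expect_equal(reportDetectionPercent(3, 8), 38L)  # 37.5 -> 38
  expect_error(reportDetectionPercent(1, 0), "positive")
  expect_error(reportDetectionPercent(5, 4), "in \\[0, n\\]")
})

test_that("complementary percentages sum to ~100", {
  for (n in c(41, 49)) for (k in 0:n) {
    s <- reportDetectionPercent(k, n) + reportDetectionPercent(n - k, n)
    expect_true(s %in% 99:101)
  }
  # no .5 ties: exact 100
  expect_equal(reportDetectionPercent(21, 25) + reportDetectionPercent(4, 25),
               100L)
})

test_that("detection probability reproduces the packaged cross-tab", {
  tab <- makeDetectionFixture()
  dp <- detectionProbability(tab)
  expect_equal(dp$pctDetected, 84L)
  expect_equal(dp$pctMissed, 16L)
  expect_equal(as.integer(dp$counts["TRUE", "TRUE"]), 21L)
  expect_equal(as.integer(dp$counts["TRUE", "FALSE"]), 4L)
  expect_equal(as.integer(dp$counts["FALSE", "TRUE"]), 0L)
  expect_length(dp$violations, 0)
})

test_that("detection probability guards degenerate tables", {
  none <- data.frame(control_putamen_active = c(FALSE, FALSE),
                     pd_putamen_decreased = c(FALSE, FALSE))
  expect_error(detectionProbability(none), "undefined")
  zero <- data.frame(control_putamen_active = rep(TRUE, 5),
                     pd_putamen_decreased = rep(FALSE, 5))
  dp <- detectionProbability(zero)
  expect_equal(dp$pctDetected, 0L)
  expect_equal(dp$pctMissed, 100L)
  # a decrease without control activation is flagged
  odd <- data.frame(control_putamen_active = c(TRUE, FALSE),
                    pd_putamen_decreased = c(TRUE, TRUE))
  expect_equal(detectionProbability(odd)$violations, 2L)
})

test_that("Spearman correlation handles monotone and tied data", {
  expect_equal(contributionUpdrsCorrelation(1:8, (1:8)^3)$rho, 1)
  expect_equal(contributionUpdrsCorrelation(1:8, -(1:8))$rho, -1)

  # 8-pair toy with one tie against a rank-then-Pearson oracle
  x <- c(0.05, 0.20, 0.20, 0.10, 0.30, 0.01, 0.08, 0.15)
  y <- c(12, 30, 25, 18, 41, 9, 22, 28)
  res <- contributionUpdrsCorrelation(x, y)
  rx <- rank(x); ry <- rank(y)
  oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(res$rho, oracle, tolerance = 1e-12)
  tstat <- oracle * sqrt(6 / (1 - oracle^2))
  expect_equal(res$p, 2 * pt(-abs(tstat), df = 6), tolerance = 1e-12)

  # cross-check against the standard implementation (no ties)
  set.seed(31)
  x2 <- rnorm(12); y2 <- rnorm(12)
  ref <- suppressWarnings(cor.test(x2, y2, method = "spearman"))
  expect_equal(contributionUpdrsCorrelation(x2, y2)$rho,
               unname(ref$estimate), tolerance = 1e-12)
})

test_that("Spearman rho is invariant under strictly monotone transforms", {
  set.seed(32)
  x <- runif(10); y <- runif(10)
  base <- contributionUpdrsCorrelation(x, y)$rho
  expect_equal(contributionUpdrsCorrelation(exp(x), y)$rho, base)
  expect_equal(contributionUpdrsCorrelation(x, y^3 + 2 * y)$rho, base)
})

test_that("Spearman correlation guards its preconditions", {
  expect_error(contributionUpdrsCorrelation(1:3, 1:3), "at least 4")
  expect_error(contributionUpdrsCorrelation(rep(1, 6), 1:6), "zero variance")
  # NA pairs are dropped pairwise
  res <- contributionUpdrsCorrelation(c(1:5, NA), c(2, 4, 6, 8, 10, 1))
  expect_equal(res$n, 5)
  expect_equal(res$rho, 1)
})

test_that("detection tables round-trip through TSV", {
  tab <- makeDetectionFixture()
  f <- withr::local_tempfile(fileext = ".tsv")
  writeDetectionTable(tab, f)
  back <- readDetectionTable(f)
  expect_equal(back$control_putamen_active, tab$control_putamen_active)
  expect_equal(back$pd_putamen_decreased, tab$pd_putamen_decreased)
  expect_equal(detectionProbability(back)$pctDetected, 84L)
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("a\tb\n1\t2", bad)
  expect_error(readDetectionTable(bad), "missing columns")
})

test_that("study contributions aggregate experiment fractions", {
  co <- c("s1|e1" = 0.3, "s1|e2" = 0.2, "s2|e1" = 0.5)
  map <- c("s1|e1" = "s1", "s1|e2" = "s1", "s2|e1" = "s2")
  agg <- studyContributions(co, map)
  expect_equal(as.numeric(agg[c("s1", "s2")]), c(0.5, 0.5))
  expect_error(studyContributions(c(bad = 1), map), "missing study id")
})
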