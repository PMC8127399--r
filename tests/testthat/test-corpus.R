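test_that("Sleuth parsing builds experiments from blocks", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(sleuthText(), f)
  exps <- readSleuth(f)
  expect_length(exps, 2)
  expect_equal(exps[[1]]@nSubjects, 12L)
  expect_equal(nrow(exps[[1]]@foci), 3)
  expect_equal(exps[[1]]@contrast, "HC_gt_PDOFF")
  expect_equal(exps[[1]]@space, "MNI")
  expect_equal(exps[[2]]@nSubjects, 9L)
  expect_equal(exps[[1]]@foci[1, ], c(x = 30, y = -10, z = 6))
})

test_that("Sleuth round-trip preserves counts, subjects and coordinates", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(sleuthText(), f)
  exps <- readSleuth(f)
  f2 <- withr::local_tempfile(fileext = ".txt")
  writeSleuth(exps, f2)
  back <- readSleuth(f2)
  expect_length(back, length(exps))
  for (i in seq_along(exps)) {
    expect_equal(back[[i]]@nSubjects, exps[[i]]@nSubjects)
    expect_lt(max(abs(back[[i]]@foci - exps[[i]]@foci)), 0.01)
  }
})

test_that("Talairach header flags foci TAL without converting", {
  f <- withr::local_tempfile(fileext = ".txt")
  txt <- sub("Reference=MNI", "Reference=Talairach", sleuthText())
  writeLines(txt, f)
  exps <- readSleuth(f)
  expect_true(all(vapply(exps, function(e) e@space, character(1)) == "TAL"))
  expect_equal(exps[[1]]@foci[1, ], c(x = 30, y = -10, z = 6))
})

test_that("Sleuth errors are informative", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("// Reference=MNI", "", "// A: c1", "// Subjects=5",
               "1 2 banana"), f)
  expect_error(readSleuth(f), "line 5")
  writeLines(c("// Reference=MNI", "", "// A: c1", "3 4 5"), f)
  expect_error(readSleuth(f), "Subjects")
  writeLines(character(0), f)
  expect_identical(readSleuth(f), list())
  writeLines(c("3 4 5"), f)
  expect_error(readSleuth(f), "[Rr]eference")
})

test_that("packaged study table yields 39 included studies (36 fMRI, 3 PET)", {
  rec <- pdMotorStudies()
  sel <- applySelection(rec)
  expect_equal(sel$nIncludedStudies, 39)
  expect_equal(nrow(sel$excluded), 0)
  perStudy <- tapply(sel$included$modality, sel$included$study_id,
                     function(x) x[1])
  expect_equal(sum(perStudy == "fMRI"), 36)
  expect_equal(sum(perStudy == "PET"), 3)
})

test_that("selection excludes small patient groups with the right tag", {
  rec <- pdMotorStudies()
  rec$n_pd[rec$study_id == "Sabatini2000"] <- 5
  sel <- applySelection(rec)
  expect_equal(sel$nIncludedStudies, 38)
  expect_true(all(sel$excluded$exclusion_reason == "fewer_than_6_patients"))
  expect_setequal(unique(sel$excluded$study_id), "Sabatini2000")
})

test_that("selection partitions input and empty rules include everything", {
  rec <- pdMotorStudies()
  rec$n_pd[3] <- 4
  rec$n_foci[10] <- NA
  sel <- applySelection(rec)
  expect_equal(nrow(sel$included) + nrow(sel$excluded), nrow(rec))
  expect_equal(nrow(applySelection(rec, rules = list())$excluded), 0)
  # flag columns drive full-text criteria
  rec2 <- pdMotorStudies()
  rec2$roi_based <- FALSE
  rec2$roi_based[rec2$study_id == "Mohl2017"] <- TRUE
  sel2 <- applySelection(rec2)
  expect_true(all(sel2$excluded$exclusion_reason == "roi_based_analysis"))
  expect_error(applySelection(rec, rules = list(bad = 42)), "unknown rule")
})

test_that("selection report lists every study once with status and reason", {
  rec <- pdMotorStudies()
  rec$n_pd[rec$study_id == "Poisson2013"] <- 4
  sel <- applySelection(rec)
  f <- withr::local_tempfile(fileext = ".csv")
  writeSelectionReport(sel, f)
  rep <- read.csv(f, stringsAsFactors = FALSE)
  expect_equal(nrow(rep), 39)
  expect_equal(sum(rep$status == "excluded"), 1)
  expect_equal(rep$reason[rep$status == "excluded"], "fewer_than_6_patients")
})

test_that("contrast pooling reproduces published counts and the strict gate", {
  counts <- c(HC_gt_PDON = 13, PDON_gt_HC = 7, ON_gt_OFF = 10,
              OFF_gt_ON = 5, HC_gt_PDOFF = 36, PDOFF_gt_HC = 34)
  pools <- poolContrasts(counts)
  eligible <- pools$contrast_key[pools$eligible]
  expect_setequal(eligible,
                  c("HC_gt_PDOFF", "PDOFF_gt_HC", "HC_gt_PD", "PD_gt_HC"))
  expect_equal(pools$n_experiments[pools$contrast_key == "HC_gt_PD"], 49)
  expect_equal(pools$n_experiments[pools$contrast_key == "PD_gt_HC"], 41)

  # strict inequality: 20 is not eligible, 21 is
  p20 <- poolContrasts(c(HC_gt_PDOFF = 20),
                       pooling = list(HC_gt_PDOFF = "HC_gt_PDOFF"))
  expect_false(p20$eligible)
  p21 <- poolContrasts(c(HC_gt_PDOFF = 21),
                       pooling = list(HC_gt_PDOFF = "HC_gt_PDOFF"))
  expect_true(p21$eligible)

  # empty input: all pools empty and ineligible
  p0 <- poolContrasts(integer(0))
  expect_true(all(p0$n_experiments == 0))
  expect_false(any(p0$eligible))
})

test_that("pooling conserves experiments over disjoint pooled keys", {
  rec <- pdMotorStudies()
  exps <- expandExperiments(rec)
  pools <- poolContrasts(exps)
  raw <- pools[pools$contrast_key %in%
                 c("HC_gt_PDOFF", "PDOFF_gt_HC", "HC_gt_PDON", "PDON_gt_HC",
                   "ON_gt_OFF", "OFF_gt_ON"), ]
  expect_equal(sum(raw$n_experiments), nrow(exps))
  expect_equal(pools$n_experiments[pools$contrast_key == "HC_gt_PD"],
               sum(raw$n_experiments[raw$contrast_key %in%
                                       c("HC_gt_PDOFF", "HC_gt_PDON")]))
})
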