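# Small grids and corpora shared across tests. Everything is generated in
# code; no binary fixtures.

# a 30-voxel all-in box for exhaustive null enumeration
tinyBoxGrid <- function() {
  makeBrainGrid(10, bbox = rbind(c(0, 0, 0), c(40, 20, 10)), mask = "all")
}

# a small brain-shaped grid for kernel/cluster tests
coarseGrid <- function(voxel = 8) makeBrainGrid(voxel)

# deterministic experiment with given foci
makeExperiment <- function(foci, n = 14, id = "exp1", contrast = "HC_gt_PD",
                           space = "MNI") {
  if (!is.matrix(foci)) foci <- matrix(foci, ncol = 3, byrow = TRUE)
  fociExperiment(experimentId = paste0(id, ": ", contrast),
                 contrast = contrast, nSubjects = n, foci = foci,
                 space = space, studyId = id)
}

# n experiments with uniform foci (null corpus) on a grid
nullExperiments <- function(nExp, nFoci, grid, seed, n = 14) {
  set.seed(seed)
  lapply(seq_len(nExp), function(e)
    makeExperiment(sampleUniformInMask(nFoci, grid), n = n,
                   id = sprintf("null%02d", e)))
}

# nearest-voxel mask membership, via the package internal
inMaskForTest <- function(grid, mm) aleMeta:::inMask(grid, mm)

sleuthText <- function() {
  c("// Reference=MNI",
    "",
    "// Smith, 2010: HC_gt_PDOFF",
    "// Subjects=12",
    "30\t-10\t6",
    "-28 -8 2",
    "0 -6 58",
    "",
    "// Jones, 2012: PDOFF_gt_HC",
    "// Subjects=9",
    "-34 -6 58")
}
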