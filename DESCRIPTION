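Package: aleMeta
Title: Activation Likelihood Estimation Meta-Analysis of Neuroimaging Foci
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coordinate-based meta-analysis of stereotactic activation foci by
    activation likelihood estimation (ALE). Reads and writes Sleuth-format foci
    files, models per-experiment foci as sample-size-dependent Gaussian
    probability distributions on a voxel grid, combines modeled-activation maps
    by the ALE union, derives nonparametric voxel-wise p-values from an
    analytic random-spatial-association null, and controls family-wise error
    at the cluster level by permutation of focus locations. Includes
    study-selection filtering and contrast pooling for patient-versus-control
    corpora, per-experiment cluster attribution with detection-probability and
    severity-correlation follow-ups, meta-analytic connectivity modeling
    (MACM) with conjunction across seed volumes, and a synthetic-corpus
    generator with planted convergence loci for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, Rcpp, RNifti, jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
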