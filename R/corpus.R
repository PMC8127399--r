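#' Create a foci experiment
#'
#' @param experimentId,studyId identifiers; \code{studyId} defaults to the
#'   part of \code{experimentId} before the first colon.
#' @param contrast contrast label (free string; the patient-vs-control labels
#'   \code{HC_gt_PDOFF}, \code{PDOFF_gt_HC}, \code{HC_gt_PDON},
#'   \code{PDON_gt_HC}, \code{ON_gt_OFF}, \code{OFF_gt_ON} are understood by
#'   \code{\link{poolContrasts}}).
#' @param nSubjects number of subjects (lower of the two group sizes).
#' @param foci numeric matrix of x, y, z coordinates in mm (rows = foci).
#' @param space \code{"MNI"} or \code{"TAL"}.
#' @param modality \code{"fMRI"}, \code{"PET"} or \code{"NA"}.
#' @return A \linkS4class{FociExperiment}.
#' @export
fociExperiment <- function(experimentId, contrast, nSubjects, foci,
                           space = "MNI",
                           studyId = sub(":.*$", "", experimentId),
                           modality = "NA") {
  foci <- matrix(as.numeric(foci), ncol = 3,
                 dimnames = list(NULL, c("x", "y", "z")))
  new("FociExperiment", experimentId = as.character(experimentId),
      studyId = as.character(studyId), contrast = as.character(contrast),
      nSubjects = as.integer(nSubjects), modality = modality,
      foci = foci, space = space)
}

#' Read a Sleuth-format foci file
#'
#' Parses the plain-text foci-exchange dialect used by coordinate-based
#' meta-analysis tools: a reference-space header
#' (\code{// Reference=MNI} or \code{// Reference=Talairach}), then one block
#' per experiment consisting of \code{// <label>: <contrast>} and
#' \code{// Subjects=<n>} comment lines followed by one whitespace-separated
#' \code{x y z} line per focus; blank lines separate blocks. Talairach-space
#' foci are flagged \code{TAL} but not converted (see \code{\link{toMni}}).
#'
#' @param path file path.
#' @return List of \linkS4class{FociExperiment} in file order (empty list for
#'   an empty file).
#' @export
readSleuth <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(trimws(lines) != "")
  if (!length(nonblank)) return(list())
  header <- trimws(lines[nonblank[1]])
  m <- regmatches(header, regexec("^//\\s*Reference\\s*=\\s*(\\S+)", header,
                                  ignore.case = TRUE))[[1]]
  if (length(m) < 2)
    stop("first non-blank line must declare the reference space, e.g. '// Reference=MNI'")
  space <- switch(toupper(m[2]),
                  MNI = "MNI", ICBM = "MNI",
                  TALAIRACH = "TAL", TAL = "TAL",
                  stop("unknown reference space: ", m[2]))

  experiments <- list()
  label <- NULL; contrast <- NULL; subjects <- NA_integer_; foci <- NULL
  flush <- function() {
    if (is.null(label)) return()
    if (is.na(subjects))
      stop("experiment '", label, "' is missing a '// Subjects=' header")
    if (is.null(foci))
      stop("experiment '", label, "' has no foci")
    experiments[[length(experiments) + 1L]] <<- fociExperiment(
      experimentId = paste0(label, ": ", contrast), contrast = contrast,
      nSubjects = subjects, foci = do.call(rbind, foci), space = space,
      studyId = label)
    label <<- NULL; contrast <<- NULL; subjects <<- NA_integer_; foci <<- NULL
  }
  for (ln in setdiff(nonblank, nonblank[1])) {
    txt <- trimws(lines[ln])
    if (startsWith(txt, "//")) {
      body <- trimws(sub("^//", "", txt))
      sm <- regmatches(body, regexec("^Subjects\\s*=\\s*(\\d+)$", body,
                                     ignore.case = TRUE))[[1]]
      if (length(sm) == 2) {
        subjects <- as.integer(sm[2])
      } else if (grepl(":", body, fixed = TRUE)) {
        flush()
        label <- trimws(sub(":.*$", "", body))
        contrast <- trimws(sub("^[^:]*:", "", body))
      }
      # other comment lines are ignored
    } else {
      xyz <- suppressWarnings(as.numeric(strsplit(txt, "[ \t]+")[[1]]))
      if (length(xyz) != 3 || any(is.na(xyz)))
        stop("malformed coordinate line ", ln, ": '", lines[ln], "'")
      if (is.null(label))
        stop("coordinate line ", ln, " appears before any experiment header")
      foci[[length(foci) + 1L]] <- xyz
    }
  }
  flush()
  experiments
}

#' Write experiments as a Sleuth-format foci file
#'
#' Inverse of \code{\link{readSleuth}}; all experiments must share one
#' coordinate space.
#'
#' @param experiments list of \linkS4class{FociExperiment}.
#' @param path output file path.
#' @export
writeSleuth <- function(experiments, path) {
  spaces <- unique(vapply(experiments, function(e) e@space, character(1)))
  if (length(spaces) > 1)
    stop("experiments mix coordinate spaces: ", paste(spaces, collapse = ", "))
  space <- if (length(spaces)) spaces else "MNI"
  out <- sprintf("// Reference=%s", if (space == "TAL") "Talairach" else "MNI")
  for (e in experiments) {
    out <- c(out, "",
             sprintf("// %s: %s", e@studyId, e@contrast),
             sprintf("// Subjects=%d", e@nSubjects),
             sprintf("%.2f\t%.2f\t%.2f", e@foci[, 1], e@foci[, 2], e@foci[, 3]))
  }
  writeLines(out, path)
  invisible(path)
}

#' Read the study-metadata table
#'
#' Reads a tab-separated table with one row per experiment, columns
#' \code{study_id, modality, n_pd, n_control, updrs_off_mean, updrs_on_mean,
#' age_pd, age_control, n_foci, contrast_label, task} plus the direction
#' columns \code{reports_a_gt_b} / \code{reports_b_gt_a} (does the experiment
#' report foci for group A > group B and vice versa, where A and B are the
#' first and second group in \code{contrast_label}), and optional boolean
#' exclusion-flag columns used by \code{\link{applySelection}}.
#'
#' @param path TSV path; defaults to the packaged Parkinson's-disease motor
#'   activation corpus (see \code{\link{pdMotorStudies}}).
#' @return data.frame of study records.
#' @export
readStudyTable <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = c("", "NA", "n/a"))
  needed <- c("study_id", "modality", "n_pd", "n_control", "updrs_off_mean",
              "updrs_on_mean", "age_pd", "age_control", "n_foci",
              "contrast_label")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("study table is missing columns: ", paste(missing, collapse = ", "))
  for (col in c("reports_a_gt_b", "reports_b_gt_a"))
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  df
}

#' Packaged study-metadata fixture
#'
#' The experiment-level metadata of the 39 studies (67 experiments) included
#' in the motor-activation meta-analysis of Parkinson's disease: modality,
#' group sizes, UPDRS-III OFF/ON means, ages, foci counts, contrast and task.
#' The two direction-of-effect columns are synthetic: the source table does
#' not print which direction(s) each experiment reported, so they were
#' allocated deterministically (experiments with the fewest foci drop a
#' direction first) under the constraint that the direction totals match the
#' published per-contrast experiment counts (36 HC>PD-OFF, 34 PD-OFF>HC,
#' 13 HC>PD-ON, 7 PD-ON>HC, 10 ON>OFF, 5 OFF>ON).
#'
#' @return data.frame as from \code{\link{readStudyTable}}.
#' @export
pdMotorStudies <- function() {
  readStudyTable(system.file("extdata", "pd_motor_studies.tsv",
                             package = "aleMeta", mustWork = TRUE))
}

#' Default study-selection rules
#'
#' Declarative exclusion predicates mirroring the selection procedure of a
#' patient-versus-control activation meta-analysis: review articles or
#' non-water-PET imaging, nonmotor/passive tasks, task-versus-task-only
#' designs, no eligible group contrast, region-of-interest-restricted
#' analyses, multivariate/covariance analyses, fewer than 6 patients, deep
#' brain stimulation or non-levodopa drug challenge, group age mismatch, and
#' missing coordinates. Criteria that require full-text screening are driven
#' by optional boolean flag columns (absent columns are treated as
#' \code{FALSE}); only the patient-count and missing-coordinate rules operate
#' on numeric fields.
#'
#' Each rule is a one-sided R expression over the record's fields; a record
#' is excluded by the first rule whose expression is \code{TRUE}.
#'
#' @param minPatients minimum number of patients (default 6).
#' @return Named list of rules (tag -> expression string).
#' @export
defaultSelectionRules <- function(minPatients = 6) {
  list(
    review_or_ineligible_modality =
      "isTRUE(is_review) || !(modality %in% c('fMRI', 'PET'))",
    nonmotor_or_passive_task = "isTRUE(nonmotor_task)",
    task_vs_task_only = "isTRUE(task_vs_task_only)",
    no_eligible_contrast = "isTRUE(no_eligible_contrast)",
    roi_based_analysis = "isTRUE(roi_based)",
    multivariate_analysis = "isTRUE(multivariate)",
    fewer_than_6_patients =
      sprintf("!is.na(n_pd) && n_pd < %d", minPatients),
    dbs_or_drug_challenge = "isTRUE(dbs_or_drug_challenge)",
    age_mismatch = "isTRUE(age_mismatch)",
    missing_coordinates = "is.na(n_foci) || n_foci < 1"
  )
}

#' Apply study-selection rules
#'
#' Partitions study records into included and excluded sets. Each excluded
#' record carries the tag of the first matching rule; rule order is the
#' order of \code{rules}. Exclusion is decided per study: a study is
#' excluded if any of its experiment rows triggers a rule.
#'
#' @param records data.frame of study records
#'   (see \code{\link{readStudyTable}}).
#' @param rules named list of exclusion expressions, as
#'   \code{\link{defaultSelectionRules}}; an empty list includes everything.
#' @return List with \code{included} (data.frame), \code{excluded}
#'   (data.frame with an added \code{exclusion_reason} column),
#'   \code{nIncludedStudies} and \code{nExcludedStudies}.
#' @export
applySelection <- function(records, rules = defaultSelectionRules()) {
  stopifnot(is.data.frame(records))
  if (length(rules)) {
    if (is.null(names(rules)) || any(names(rules) == ""))
      stop("selection rules must be a named list (tag -> expression)")
    bad <- !vapply(rules, function(r) is.character(r) && length(r) == 1,
                   logical(1))
    if (any(bad))
      stop("unknown rule format for: ", paste(names(rules)[bad], collapse = ", "),
           " (each rule must be a single expression string)")
  }
  parsed <- lapply(rules, function(r) parse(text = r)[[1]])
  reason <- rep(NA_character_, nrow(records))
  for (i in seq_len(nrow(records))) {
    env <- as.list(records[i, , drop = FALSE])
    # optional flag fields referenced by a rule but absent from the table
    # are treated as not-flagged
    for (v in unique(unlist(lapply(parsed, all.vars))))
      if (is.null(env[[v]])) env[[v]] <- NA
    for (tag in names(parsed)) {
      hit <- tryCatch(
        isTRUE(eval(parsed[[tag]], envir = env, enclos = baseenv())),
        error = function(e) stop("rule '", tag, "' failed: ",
                                 conditionMessage(e), call. = FALSE))
      if (hit) { reason[i] <- tag; break }
    }
  }
  # exclusion propagates to all rows of the same study
  studyReason <- tapply(reason, records$study_id,
                        function(r) if (all(is.na(r))) NA_character_ else
                          r[!is.na(r)][1])
  excludedStudy <- !is.na(studyReason[records$study_id])
  excluded <- records[excludedStudy, , drop = FALSE]
  if (nrow(excluded))
    excluded$exclusion_reason <-
      unname(studyReason[excluded$study_id])
  else excluded$exclusion_reason <- character(0)
  list(included = records[!excludedStudy, , drop = FALSE],
       excluded = excluded,
       nIncludedStudies = length(unique(records$study_id[!excludedStudy])),
       nExcludedStudies = sum(!is.na(studyReason)))
}

#' Write a selection report
#'
#' @param selection result of \code{\link{applySelection}}.
#' @param path CSV path.
#' @export
writeSelectionReport <- function(selection, path) {
  inc <- unique(selection$included$study_id)
  exc <- selection$excluded[!duplicated(selection$excluded$study_id),
                            c("study_id", "exclusion_reason"), drop = FALSE]
  rep <- rbind(
    data.frame(study_id = inc, status = "included", reason = "",
               stringsAsFactors = FALSE),
    if (nrow(exc)) data.frame(study_id = exc$study_id, status = "excluded",
                              reason = exc$exclusion_reason,
                              stringsAsFactors = FALSE))
  utils::write.csv(rep, path, row.names = FALSE)
  invisible(path)
}

# contrast enum for a metadata row and direction
directionContrast <- function(contrastLabel, direction) {
  key <- toupper(gsub("[^A-Za-z]", "", contrastLabel))
  tab <- list(
    HCVSOFF = c(a = "HC_gt_PDOFF", b = "PDOFF_gt_HC"),
    HCVSON = c(a = "HC_gt_PDON", b = "PDON_gt_HC"),
    ONVSOFF = c(a = "ON_gt_OFF", b = "OFF_gt_ON"))
  if (is.null(tab[[key]]))
    stop("unknown contrast label: ", contrastLabel)
  unname(tab[[key]][direction])
}

#' Expand metadata rows into directional experiment records
#'
#' Each metadata row describes one scanned contrast (e.g. HC vs PD-OFF); the
#' direction columns say which directional effects it reported. One
#' directional record is produced per reported direction, with
#' \code{n_subjects} the lower of the two group sizes.
#'
#' @param records data.frame from \code{\link{readStudyTable}}.
#' @return data.frame with columns \code{experiment_id, study_id, contrast,
#'   n_subjects, modality, n_foci}.
#' @export
expandExperiments <- function(records) {
  stopifnot(all(c("reports_a_gt_b", "reports_b_gt_a") %in% names(records)))
  rows <- list()
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    n <- suppressWarnings(min(c(r$n_pd, r$n_control), na.rm = TRUE))
    for (d in c("a", "b")) {
      if (!isTRUE(r[[paste0("reports_", d, "_gt_", setdiff(c("a", "b"), d))]]))
        next
      ctr <- directionContrast(r$contrast_label, d)
      rows[[length(rows) + 1L]] <- data.frame(
        experiment_id = sprintf("%s|%d|%s", r$study_id, i, ctr),
        study_id = r$study_id, contrast = ctr, n_subjects = n,
        modality = r$modality, n_foci = r$n_foci, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Default pooling of raw contrasts
#'
#' Maps each raw directional contrast to itself and, for the
#' patient-versus-control contrasts, additionally into medication-pooled
#' keys (\code{HC_gt_PD} pools \code{HC_gt_PDOFF} with \code{HC_gt_PDON};
#' \code{PD_gt_HC} analogously).
#'
#' @return Named list: pooled key -> character vector of raw contrasts.
#' @export
defaultPooling <- function() {
  raw <- c("HC_gt_PDOFF", "PDOFF_gt_HC", "HC_gt_PDON", "PDON_gt_HC",
           "ON_gt_OFF", "OFF_gt_ON")
  pools <- c(stats::setNames(as.list(raw), raw),
             list(HC_gt_PD = c("HC_gt_PDOFF", "HC_gt_PDON"),
                  PD_gt_HC = c("PDOFF_gt_HC", "PDON_gt_HC")))
  pools
}

#' Pool contrasts and apply the experiment-count gate
#'
#' Groups experiments into contrast pools and flags each pool as eligible
#' for meta-analysis only when it holds strictly more than
#' \code{gateThreshold} experiments (meta-analyses over few experiments are
#' driven by single studies).
#'
#' @param experiments either a data.frame with a \code{contrast} column (as
#'   \code{\link{expandExperiments}}), a list of
#'   \linkS4class{FociExperiment}, or a named integer vector of per-contrast
#'   counts.
#' @param pooling named list mapping pooled keys to raw contrasts
#'   (default \code{\link{defaultPooling}}).
#' @param gateThreshold integer; a pool must exceed this count (strict) to be
#'   eligible. Default 20.
#' @return data.frame with columns \code{contrast_key, n_experiments,
#'   eligible}, one row per pool, in \code{pooling} order.
#' @examples
#' poolContrasts(c(HC_gt_PDOFF = 36, PDOFF_gt_HC = 34, HC_gt_PDON = 13,
#'                 PDON_gt_HC = 7, ON_gt_OFF = 10, OFF_gt_ON = 5))
#' @export
poolContrasts <- function(experiments, pooling = defaultPooling(),
                          gateThreshold = 20L) {
  counts <- if (is.numeric(experiments)) {
    experiments
  } else if (is.data.frame(experiments)) {
    table(experiments$contrast)
  } else {
    table(vapply(experiments, function(e) e@contrast, character(1)))
  }
  counts <- stats::setNames(as.integer(counts), names(counts))
  n <- vapply(pooling, function(raw) sum(counts[raw], na.rm = TRUE),
              integer(1))
  data.frame(contrast_key = names(pooling), n_experiments = as.integer(n),
             eligible = as.integer(n) > gateThreshold,
             stringsAsFactors = FALSE, row.names = NULL)
}
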