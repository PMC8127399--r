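#' Integer percentage, half away from zero
#'
#' Reporting convention for detection counts: \code{round(100 * k / n)} with
#' exact halves rounded away from zero (so 35.5 -> 36), not to even.
#'
#' @param k number of detecting experiments, \code{0 <= k <= n}.
#' @param n total number of experiments, \code{> 0}.
#' @return Integer percent.
#' @examples
#' reportDetectionPercent(17, 49)  # 35
#' @export
reportDetectionPercent <- function(k, n) {
  if (any(n <= 0)) stop("n must be positive")
  if (any(k < 0 | k > n)) stop("k must be in [0, n]")
  x <- 100 * k / n
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' Conditional probability of detecting decreased putamen activation
#'
#' Restricts a detection table to the experiments whose control group
#' activated the putamen and reports the percentage of those that also found
#' decreased putamen activity in the patients (and its complement), plus the
#' full cross-tabulation. Rows reporting a patient decrease without control
#' activation are flagged (none are expected: a decrease is only
#' interpretable where the region engaged at all).
#'
#' @param table data.frame with logical columns \code{control_putamen_active}
#'   and \code{pd_putamen_decreased}, one row per experiment.
#' @return List with \code{pctDetected}, \code{pctMissed} (integer percents,
#'   summing to 100 up to the half-rounding), \code{counts} (2x2 table) and
#'   \code{violations} (row indices with decrease but no control
#'   activation).
#' @export
detectionProbability <- function(table) {
  stopifnot(is.data.frame(table), nrow(table) > 0,
            all(c("control_putamen_active", "pd_putamen_decreased") %in%
                  names(table)))
  ctl <- table$control_putamen_active
  dec <- table$pd_putamen_decreased
  if (any(is.na(ctl)) || any(is.na(dec)))
    stop("detection table must not contain missing values")
  nPos <- sum(ctl)
  if (nPos == 0)
    stop("no experiment activated the putamen in the control group; ",
         "conditional detection probability is undefined")
  k <- sum(ctl & dec)
  counts <- table(control = factor(ctl, c(FALSE, TRUE)),
                  decreased = factor(dec, c(FALSE, TRUE)))
  list(pctDetected = reportDetectionPercent(k, nPos),
       pctMissed = reportDetectionPercent(nPos - k, nPos),
       counts = counts,
       violations = which(dec & !ctl))
}

#' Spearman correlation of cluster contributions with disease severity
#'
#' Correlates per-study contributions to a cluster with study-level mean
#' UPDRS-III scores: mid-ranks (average ranks for ties) are Pearson-
#' correlated and the two-sided p-value uses the t approximation on
#' \code{n - 2} degrees of freedom. No multiplicity correction is applied
#' (the p is reported uncorrected). Studies with a missing UPDRS mean are
#' dropped pairwise before ranking.
#'
#' @param contribution numeric vector of per-study contribution fractions.
#' @param updrs numeric vector of study-level mean UPDRS scores (same
#'   length; NAs dropped pairwise).
#' @return List with \code{rho}, \code{p} and \code{n} (complete pairs).
#' @export
contributionUpdrsCorrelation <- function(contribution, updrs) {
  stopifnot(length(contribution) == length(updrs))
  ok <- is.finite(contribution) & is.finite(updrs)
  x <- contribution[ok]; y <- updrs[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("rho undefined: zero variance in ",
         if (stats::var(x) == 0) "contribution" else "UPDRS")
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Read or write a detection table as TSV
#'
#' Detection tables are exchanged as tab-separated text with one row per
#' experiment and logical columns \code{control_putamen_active} and
#' \code{pd_putamen_decreased}.
#'
#' @param path TSV path.
#' @return \code{readDetectionTable}: data.frame suitable for
#'   \code{\link{detectionProbability}}.
#' @export
readDetectionTable <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("control_putamen_active", "pd_putamen_decreased")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("detection table is missing columns: ",
         paste(missing, collapse = ", "))
  for (col in need) df[[col]] <- as.logical(df[[col]])
  df
}

#' @rdname readDetectionTable
#' @param table detection-table data.frame.
#' @export
writeDetectionTable <- function(table, path) {
  utils::write.table(table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Aggregate experiment contributions to study level
#'
#' A study's contribution to a cluster is the sum of its experiments'
#' contribution fractions (the severity correlation is run per study, not
#' per experiment).
#'
#' @param contrib named contribution-fraction vector (experiment id ->
#'   fraction), as stored in an \linkS4class{ALEResult}.
#' @param studyIds named character vector mapping experiment id -> study id.
#' @return Named numeric vector, one element per study.
#' @export
studyContributions <- function(contrib, studyIds) {
  sid <- studyIds[names(contrib)]
  if (any(is.na(sid)))
    stop("missing study id for experiments: ",
         paste(names(contrib)[is.na(sid)], collapse = ", "))
  tapply(contrib, sid, sum)
}
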