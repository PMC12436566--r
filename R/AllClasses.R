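#' @import methods
NULL

## Canonical S-ICD sensing-vector surrogate roles, in channel order.
.VALID_ROLES <- c("primary", "alternate", "secondary")

## Cohort subgroups (adult congenital heart disease, hypertrophic
## cardiomyopathy, heart failure, structurally normal hearts, prior
## inappropriate S-ICD shock recipients).
.VALID_SUBGROUPS <- c("ACHD", "HCM", "HF", "Normal", "S-ICD")

#' Multi-channel Holter ECG recording
#'
#' Container for a uniformly sampled multi-channel ECG recording whose
#' channels surrogate the three S-ICD sensing vectors (primary, alternate,
#' secondary). Channels are stored as millivolt sample vectors; any subset
#' of the three roles may be present (real Holter studies lose channels),
#' but all present channels must have equal length.
#'
#' @slot samplingRate sampling frequency in Hz.
#' @slot channels named list of numeric millivolt vectors; names are a
#'   subset of \code{c("primary", "alternate", "secondary")}.
#' @slot subjectId subject identifier.
#' @slot subgroup cohort subgroup label (\code{"ACHD"}, \code{"HCM"},
#'   \code{"HF"}, \code{"Normal"} or \code{"S-ICD"}; \code{"unknown"}
#'   allowed for data without metadata).
#'
#' @seealso [readHolterAscii()], [generateRecording()], [segmentRecording()]
#' @export
setClass("ECGRecording",
  slots = c(
    samplingRate = "numeric",
    channels = "list",
    subjectId = "character",
    subgroup = "character"
  )
)

setValidity("ECGRecording", function(object) {
  msg <- character()
  if (length(object@samplingRate) != 1 || !is.finite(object@samplingRate) ||
      object@samplingRate <= 0) {
    msg <- c(msg, "samplingRate must be a single positive number")
  }
  roles <- names(object@channels)
  if (length(object@channels) == 0) {
    msg <- c(msg, "at least one channel must be present")
  }
  if (is.null(roles) || !all(roles %in% .VALID_ROLES)) {
    msg <- c(msg, sprintf("channel roles must be among: %s",
                          paste(.VALID_ROLES, collapse = ", ")))
  }
  if (anyDuplicated(roles)) msg <- c(msg, "duplicate channel roles")
  lens <- lengths(object@channels)
  if (length(lens) > 1 && length(unique(lens)) != 1) {
    msg <- c(msg, "all present channels must have equal length")
  }
  if (!all(vapply(object@channels, is.numeric, logical(1)))) {
    msg <- c(msg, "channel samples must be numeric")
  }
  if (length(msg)) msg else TRUE
})

#' One 10-second window of one ECG channel
#'
#' A single analysis window cut from one channel of an [ECGRecording-class].
#' At the defaults (500 Hz, 10 s) a segment holds exactly 5000 samples.
#' Segment indices are 0-based; segment \eqn{k} covers the half-open time
#' interval \eqn{[10k, 10k+10)} seconds.
#'
#' @slot samples numeric millivolt vector.
#' @slot samplingRate sampling frequency in Hz.
#' @slot channelRole role of the source channel.
#' @slot segmentIndex 0-based index on the segment grid.
#' @slot startTime window start in seconds from recording start.
#'
#' @seealso [segmentRecording()], [preprocessSegment()], [psrImage()]
#' @export
setClass("ECGSegment",
  slots = c(
    samples = "numeric",
    samplingRate = "numeric",
    channelRole = "character",
    segmentIndex = "integer",
    startTime = "numeric"
  )
)

setValidity("ECGSegment", function(object) {
  msg <- character()
  if (length(object@samplingRate) != 1 || object@samplingRate <= 0) {
    msg <- c(msg, "samplingRate must be a single positive number")
  }
  if (length(object@segmentIndex) != 1 || object@segmentIndex < 0) {
    msg <- c(msg, "segmentIndex must be a single non-negative integer")
  }
  if (length(object@startTime) != 1 || object@startTime < 0) {
    msg <- c(msg, "startTime must be a single non-negative number")
  }
  if (length(msg)) msg else TRUE
})

#' Phase-space-reconstruction image of an ECG segment
#'
#' The 2-D delay-map occupancy histogram of one preprocessed segment:
#' pairs \eqn{(x[t], x[t+\tau])} of the amplitude-normalised signal are
#' binned onto a 32 x 32 grid. \code{counts} holds the raw occupancy
#' counts (summing to \eqn{N - \tau}); \code{intensity} is the same grid
#' divided by its maximum count, so values lie in [0, 1] with at least one
#' pixel equal to 1. Rows index the \eqn{x[t]} bin, columns the
#' \eqn{x[t+\tau]} bin.
#'
#' @slot counts integer occupancy matrix (bins x bins).
#' @slot intensity max-normalised matrix in [0, 1].
#' @slot tau embedding delay in samples.
#' @slot channelRole role of the source channel.
#' @slot segmentIndex 0-based segment index.
#'
#' @seealso [psrImage()], [batchImages()]
#' @export
setClass("PSRImage",
  slots = c(
    counts = "matrix",
    intensity = "matrix",
    tau = "integer",
    channelRole = "character",
    segmentIndex = "integer"
  )
)

setValidity("PSRImage", function(object) {
  msg <- character()
  if (!all(dim(object@counts) == dim(object@intensity))) {
    msg <- c(msg, "counts and intensity must have identical dimensions")
  }
  if (any(object@intensity < 0 | object@intensity > 1)) {
    msg <- c(msg, "intensity values must lie in [0, 1]")
  }
  if (length(object@tau) != 1 || object@tau < 1) {
    msg <- c(msg, "tau must be a single integer >= 1")
  }
  if (length(msg)) msg else TRUE
})

#' Per-segment T:R ratio series for one channel
#'
#' One T:R amplitude-ratio estimate per 10-second segment of one channel.
#' Segments where the estimator could not produce a value carry \code{NA}
#' with a reason code; an entirely absent channel is represented by a
#' series with \code{missingChannel = TRUE} and zero-length values.
#'
#' @slot values numeric T:R ratios (\code{NA} allowed), one per segment.
#' @slot channelRole role of the source channel.
#' @slot missingChannel \code{TRUE} when the channel was absent from the
#'   recording.
#' @slot reasonCodes character vector parallel to \code{values}; \code{""}
#'   for valid estimates, otherwise a short code (e.g.
#'   \code{"too_few_beats"}).
#'
#' @seealso [trSeries()], [favourability()], [vectorProlongedPass()]
#' @export
setClass("TRSeries",
  slots = c(
    values = "numeric",
    channelRole = "character",
    missingChannel = "logical",
    reasonCodes = "character"
  )
)

setValidity("TRSeries", function(object) {
  msg <- character()
  if (any(!is.na(object@values) & object@values < 0)) {
    msg <- c(msg, "T:R values must be non-negative")
  }
  if (length(object@reasonCodes) != length(object@values)) {
    msg <- c(msg, "reasonCodes must be parallel to values")
  }
  if (length(object@missingChannel) != 1) {
    msg <- c(msg, "missingChannel must be a single logical")
  }
  if (length(msg)) msg else TRUE
})

#' Cross-validated accuracy report for a T:R regressor
#'
#' Accuracy of predicted against reference T:R ratios. The headline
#' \code{mse}, \code{rmse} and \code{mae} are pooled over all out-of-fold
#' predictions; \code{perFold} holds the same metrics per fold, and
#' \code{foldMeans} their across-fold averages (the two aggregations
#' differ in general; both are reported).
#'
#' @slot mse pooled mean squared error.
#' @slot rmse pooled root mean squared error (\code{sqrt(mse)}).
#' @slot mae pooled mean absolute error.
#' @slot nFolds number of folds (1 for a plain evaluation set).
#' @slot perFold data.frame with columns fold, n, mse, rmse, mae.
#' @slot foldMeans named numeric: across-fold means of mse, rmse, mae.
#'
#' @seealso [evaluateAccuracy()], [trainRegressor()]
#' @export
setClass("AccuracyReport",
  slots = c(
    mse = "numeric",
    rmse = "numeric",
    mae = "numeric",
    nFolds = "integer",
    perFold = "data.frame",
    foldMeans = "numeric"
  )
)

setValidity("AccuracyReport", function(object) {
  msg <- character()
  if (abs(object@rmse - sqrt(object@mse)) > 1e-9) {
    msg <- c(msg, "rmse must equal sqrt(mse)")
  }
  if (object@mae > object@rmse + 1e-12) {
    msg <- c(msg, "mae cannot exceed rmse")
  }
  if (length(msg)) msg else TRUE
})

#' Screening outcome for one patient
#'
#' Per-vector and per-patient pass/fail decisions at each T:R threshold,
#' together with the standard-practice pass probability (fraction of
#' 10-second segments with at least one vector showing T:R below 1:3).
#' A patient passes at a threshold when at least one non-missing vector
#' passes; a vector passes when it never shows an unfavourable T:R for 20
#' consecutive seconds or longer.
#'
#' @slot subjectId subject identifier.
#' @slot subgroup cohort subgroup label.
#' @slot standardPassProbability probability in [0, 1].
#' @slot thresholds numeric T:R cutoffs evaluated.
#' @slot vectorResults data.frame with columns role, threshold, pass,
#'   nFailingRuns, longestRunS, nMissing, missingChannel.
#' @slot patientPass named logical vector, one flag per threshold.
#'
#' @seealso [patientScreen()], [cohortScreen()]
#' @export
setClass("PatientScreening",
  slots = c(
    subjectId = "character",
    subgroup = "character",
    standardPassProbability = "numeric",
    thresholds = "numeric",
    vectorResults = "data.frame",
    patientPass = "logical"
  )
)

setValidity("PatientScreening", function(object) {
  msg <- character()
  p <- object@standardPassProbability
  if (length(p) != 1 || is.na(p) || p < 0 || p > 1) {
    msg <- c(msg, "standardPassProbability must lie in [0, 1]")
  }
  if (length(object@patientPass) != length(object@thresholds)) {
    msg <- c(msg, "one patient pass flag per threshold required")
  }
  if (length(msg)) msg else TRUE
})

#' Outcome-by-subgroup contingency table
#'
#' A 2 x K table of fail/pass counts across cohort subgroups, the shape
#' analysed with the exact Fisher test.
#'
#' @slot counts non-negative integer matrix with rownames
#'   \code{c("fail", "pass")} (or any outcome labels) and subgroup
#'   colnames.
#'
#' @seealso [contingencyTable()], [fisherExactRxC()]
#' @export
setClass("CohortTable", slots = c(counts = "matrix"))

setValidity("CohortTable", function(object) {
  msg <- character()
  cnt <- object@counts
  if (!is.numeric(cnt) || any(cnt < 0) || any(cnt != round(cnt))) {
    msg <- c(msg, "counts must be non-negative integers")
  }
  if (sum(cnt) <= 0) msg <- c(msg, "table total must be positive")
  if (length(msg)) msg else TRUE
})

#' Hypothesis-test result
#'
#' Minimal container for a test statistic and p-value (exact Fisher test
#' or Kruskal-Wallis rank-sum test).
#'
#' @slot statistic test statistic (\code{NA} for the exact Fisher test,
#'   which has no single canonical statistic).
#' @slot pValue p-value in (0, 1].
#' @slot method human-readable method label.
#' @slot n total number of observations.
#'
#' @seealso [fisherExactRxC()], [kruskalWallis()]
#' @export
setClass("TestResult",
  slots = c(
    statistic = "numeric",
    pValue = "numeric",
    method = "character",
    n = "integer"
  )
)

setValidity("TestResult", function(object) {
  p <- object@pValue
  if (length(p) != 1 || is.na(p) || p <= 0 || p > 1 + 1e-12) {
    "pValue must lie in (0, 1]"
  } else TRUE
})
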