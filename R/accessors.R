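#' @title Accessors for SICDscreen classes
#' @description Small accessor generics so user code never touches slots.
#' @param object an object of the documented class.
#' @name accessors
NULL

#' @describeIn accessors sampling frequency in Hz.
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' @describeIn accessors roles of the channels present.
#' @export
setGeneric("channelRoles", function(object) standardGeneric("channelRoles"))

#' @describeIn accessors subject identifier.
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))

#' @describeIn accessors cohort subgroup label.
#' @export
setGeneric("subgroup", function(object) standardGeneric("subgroup"))

#' @describeIn accessors recording duration in seconds.
#' @export
setGeneric("recordingDuration",
           function(object) standardGeneric("recordingDuration"))

#' @describeIn accessors T:R values (for \code{TRSeries}) as a numeric
#'   vector with \code{NA} for missing estimates.
#' @export
setGeneric("trValues", function(object) standardGeneric("trValues"))

#' Extract one channel's samples
#'
#' @param object an [ECGRecording-class].
#' @param role one of \code{"primary"}, \code{"alternate"},
#'   \code{"secondary"}.
#' @return numeric millivolt vector.
#' @export
setGeneric("channelSamples",
           function(object, role) standardGeneric("channelSamples"))

#' @rdname accessors
#' @export
setMethod("samplingRate", "ECGRecording", function(object) object@samplingRate)

#' @rdname accessors
#' @export
setMethod("samplingRate", "ECGSegment", function(object) object@samplingRate)

#' @rdname accessors
#' @export
setMethod("channelRoles", "ECGRecording",
          function(object) names(object@channels))

#' @rdname accessors
#' @export
setMethod("subjectId", "ECGRecording", function(object) object@subjectId)

#' @rdname accessors
#' @export
setMethod("subgroup", "ECGRecording", function(object) object@subgroup)

#' @rdname accessors
#' @export
setMethod("recordingDuration", "ECGRecording", function(object) {
  if (length(object@channels) == 0) return(0)
  length(object@channels[[1]]) / object@samplingRate
})

#' @rdname channelSamples
#' @export
setMethod("channelSamples", "ECGRecording", function(object, role) {
  role <- match.arg(role, .VALID_ROLES)
  if (!role %in% names(object@channels)) {
    stop(sprintf("channel role '%s' is not present in this recording", role))
  }
  object@channels[[role]]
})

#' @rdname accessors
#' @export
setMethod("trValues", "TRSeries", function(object) object@values)

#' @rdname accessors
#' @export
setMethod("channelRoles", "TRSeries", function(object) object@channelRole)

setMethod("show", "ECGRecording", function(object) {
  cat(sprintf(
    "ECGRecording: subject '%s' (%s)\n  %d channel(s) [%s], %.1f s at %g Hz\n",
    object@subjectId, object@subgroup, length(object@channels),
    paste(names(object@channels), collapse = ", "),
    recordingDuration(object), object@samplingRate))
})

setMethod("show", "ECGSegment", function(object) {
  cat(sprintf(
    "ECGSegment: %s #%d, %d samples at %g Hz (t0 = %.0f s)\n",
    object@channelRole, object@segmentIndex, length(object@samples),
    object@samplingRate, object@startTime))
})

setMethod("show", "PSRImage", function(object) {
  cat(sprintf(
    "PSRImage: %dx%d delay map (tau = %d) of %s segment #%d, %d pairs\n",
    nrow(object@counts), ncol(object@counts), object@tau,
    object@channelRole, object@segmentIndex, sum(object@counts)))
})

setMethod("show", "TRSeries", function(object) {
  if (object@missingChannel) {
    cat(sprintf("TRSeries: %s channel missing\n", object@channelRole))
  } else {
    v <- object@values
    cat(sprintf(
      "TRSeries: %s, %d segment(s), %d missing; median T:R = %.3f\n",
      object@channelRole, length(v), sum(is.na(v)),
      stats::median(v, na.rm = TRUE)))
  }
})

setMethod("show", "AccuracyReport", function(object) {
  cat(sprintf(
    paste0("AccuracyReport (%d fold(s)):\n",
           "  pooled      MSE = %.4g  RMSE = %.4g  MAE = %.4g\n",
           "  fold means  MSE = %.4g  RMSE = %.4g  MAE = %.4g\n"),
    object@nFolds, object@mse, object@rmse, object@mae,
    object@foldMeans[["mse"]], object@foldMeans[["rmse"]],
    object@foldMeans[["mae"]]))
})

setMethod("show", "PatientScreening", function(object) {
  cat(sprintf("PatientScreening: subject '%s' (%s)\n", object@subjectId,
              object@subgroup))
  cat(sprintf("  standard pass probability: %.3f\n",
              object@standardPassProbability))
  flags <- ifelse(object@patientPass, "pass", "fail")
  cat("  prolonged screening: ",
      paste(sprintf("%s at %.3g", flags, object@thresholds),
            collapse = ", "), "\n", sep = "")
})

setMethod("show", "CohortTable", function(object) {
  cat("CohortTable (outcome x subgroup):\n")
  print(object@counts)
})

setMethod("show", "TestResult", function(object) {
  if (is.na(object@statistic)) {
    cat(sprintf("%s: p = %.4g (n = %d)\n", object@method, object@pValue,
                object@n))
  } else {
    cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %d)\n", object@method,
                object@statistic, object@pValue, object@n))
  }
})

#' Counts of a cohort contingency table
#'
#' @param object a [CohortTable-class].
#' @return integer matrix of counts.
#' @export
setGeneric("tableCounts", function(object) standardGeneric("tableCounts"))

#' @rdname tableCounts
#' @export
setMethod("tableCounts", "CohortTable", function(object) object@counts)

#' P-value of a test result
#'
#' @param object a [TestResult-class].
#' @return the p-value.
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))

#' @rdname pValue
#' @export
setMethod("pValue", "TestResult", function(object) object@pValue)
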