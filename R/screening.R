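## Eligibility computations: standard-practice pass probability and
## prolonged screening with the 20-s consecutive-failure rule at the
## five proposed T:R thresholds.

#' The proposed T:R screening thresholds
#'
#' Strictly increasing T:R cutoffs in (0, 1]; the defaults are the five
#' proposed ratios 1:3, 1:2, 2:3, 3:4 and 1:1.
#'
#' @param ratios numeric vector of cutoffs.
#' @return validated numeric vector of class \code{ThresholdSet}.
#' @export
thresholdSet <- function(ratios = c(1 / 3, 1 / 2, 2 / 3, 3 / 4, 1)) {
  if (any(diff(ratios) <= 0)) stop("thresholds must be strictly increasing")
  if (any(ratios <= 0 | ratios > 1)) stop("thresholds must lie in (0, 1]")
  structure(ratios, class = "ThresholdSet")
}

#' Per-segment favourability of a T:R series
#'
#' A segment is favourable exactly when its T:R ratio is strictly below
#' the threshold (ties at the threshold are unfavourable). Missing T:R
#' values propagate as \code{NA}.
#'
#' @param series a [TRSeries-class] or numeric vector of T:R values.
#' @param threshold positive T:R cutoff.
#' @return logical vector, one flag per segment.
#' @export
favourability <- function(series, threshold) {
  stopifnot(threshold > 0)
  v <- if (is(series, "TRSeries")) series@values else series
  v < threshold
}

#' Standard-practice pass probability
#'
#' The chance that a patient would pass today's one-off screening if it
#' were performed at a uniformly random time in the recording: the
#' number of 10-s segment indices where at least one vector shows a
#' favourable (strictly below-threshold, default 1:3) T:R ratio, divided
#' by the total number of segments (8640 in 24 h). Invariant to vector
#' order; missing estimates never count as favourable.
#'
#' @param seriesList list of [TRSeries-class] (or numeric vectors) of
#'   equal length; channels flagged missing are ignored.
#' @param threshold T:R cutoff (default 1/3).
#' @return probability in [0, 1].
#' @export
standardPassProbability <- function(seriesList, threshold = 1 / 3) {
  vecs <- Filter(function(s) !(is(s, "TRSeries") && s@missingChannel),
                 seriesList)
  if (length(vecs) == 0) stop("at least one non-missing vector required")
  favs <- lapply(vecs, favourability, threshold = threshold)
  lens <- lengths(favs)
  if (length(unique(lens)) != 1) stop("series must have equal length")
  if (lens[1] == 0) stop("series contain zero segments")
  anyFav <- Reduce(`|`, lapply(favs, function(f) !is.na(f) & f))
  sum(anyFav) / lens[1]
}

#' Prolonged-screening decision for one vector
#'
#' A vector fails a threshold when its T:R ratio is unfavourable for at
#' least \code{minFailDurationS} consecutive seconds -- at the defaults,
#' 2 consecutive 10-s segments, the surrogate for the device's
#' detection-charge-redetection-shock time. Isolated ("silent")
#' unfavourable segments shorter than the cutoff pass. Missing estimates
#' break runs conservatively (treated as favourable for run-building)
#' and are reported so users can audit dropouts. Runs never wrap across
#' the recording boundary.
#'
#' @param series a [TRSeries-class] or numeric vector.
#' @param threshold T:R cutoff.
#' @param minFailDurationS failure cutoff in seconds (default 20).
#' @param segmentDurationS duration of one segment in seconds (default
#'   10); must divide \code{minFailDurationS}.
#' @return list with elements \code{pass}, \code{nFailingRuns} (runs
#'   meeting the failure cutoff), \code{longestRunS} (longest
#'   unfavourable run in seconds) and \code{nMissing}; or a list with
#'   \code{missing = TRUE} for an absent channel.
#' @export
vectorProlongedPass <- function(series, threshold,
                                minFailDurationS = 20,
                                segmentDurationS = 10) {
  if (minFailDurationS %% segmentDurationS != 0) {
    stop("segment duration must divide the failure cutoff")
  }
  if (is(series, "TRSeries") && series@missingChannel) {
    return(list(missing = TRUE, pass = NA, nFailingRuns = NA_integer_,
                longestRunS = NA_real_, nMissing = NA_integer_))
  }
  fav <- favourability(series, threshold)
  nMissing <- sum(is.na(fav))
  unf <- !fav
  unf[is.na(unf)] <- FALSE             # dropouts break runs, never fail
  needed <- minFailDurationS / segmentDurationS
  r <- rle(unf)
  runLens <- r$lengths[r$values]
  longest <- if (length(runLens)) max(runLens) * segmentDurationS else 0
  list(missing = FALSE,
       pass = longest < minFailDurationS,
       nFailingRuns = sum(runLens >= needed),
       longestRunS = longest,
       nMissing = nMissing)
}

#' Screen one patient at every threshold
#'
#' Evaluates each vector independently with the 20-s rule at every
#' threshold; the patient passes a threshold when at least one
#' non-missing vector passes it. Also computes the standard-practice
#' pass probability at 1:3. Pass flags are monotone in the threshold at
#' both the vector and the patient level.
#'
#' @param seriesList named list of [TRSeries-class] (one per vector
#'   role; roles flagged missing are skipped in the decision).
#' @param thresholds a [thresholdSet()] or numeric cutoffs.
#' @param subjectId,subgroup metadata carried into the result.
#' @param minFailDurationS,segmentDurationS see [vectorProlongedPass()].
#' @return a [PatientScreening-class].
#' @export
patientScreen <- function(seriesList, thresholds = thresholdSet(),
                          subjectId = "unknown", subgroup = "unknown",
                          minFailDurationS = 20, segmentDurationS = 10) {
  present <- Filter(function(s) !(is(s, "TRSeries") && s@missingChannel),
                    seriesList)
  if (length(present) == 0) stop("all vectors missing for this patient")
  thr <- as.numeric(thresholds)

  rows <- list()
  for (role in names(seriesList)) {
    s <- seriesList[[role]]
    for (t in thr) {
      res <- vectorProlongedPass(s, t, minFailDurationS, segmentDurationS)
      rows[[length(rows) + 1L]] <- data.frame(
        role = role, threshold = t, pass = res$pass,
        nFailingRuns = res$nFailingRuns, longestRunS = res$longestRunS,
        nMissing = res$nMissing, missingChannel = isTRUE(res$missing))
    }
  }
  vres <- do.call(rbind, rows)
  patientPass <- vapply(thr, function(t) {
    any(vres$pass[vres$threshold == t & !vres$missingChannel],
        na.rm = TRUE)
  }, logical(1))
  names(patientPass) <- sprintf("%.6g", thr)

  new("PatientScreening",
      subjectId = subjectId, subgroup = subgroup,
      standardPassProbability = standardPassProbability(seriesList, 1 / 3),
      thresholds = thr, vectorResults = vres, patientPass = patientPass)
}

#' Screen a cohort
#'
#' Applies [patientScreen()] to each subject and tabulates per-threshold
#' pass counts by subgroup.
#'
#' @param cohort list of per-subject lists, each with elements
#'   \code{series} (named list of [TRSeries-class]), \code{subjectId}
#'   and \code{subgroup} -- or the output of [generateCohort()] plus a
#'   T:R backend run, see [cohortTRSeries()].
#' @param thresholds a [thresholdSet()] or numeric cutoffs.
#' @param minFailDurationS,segmentDurationS see [vectorProlongedPass()].
#' @return list with \code{patients} (list of
#'   [PatientScreening-class]) and \code{summary} (data.frame of
#'   threshold, subgroup, nPass, nFail).
#' @export
cohortScreen <- function(cohort, thresholds = thresholdSet(),
                         minFailDurationS = 20, segmentDurationS = 10) {
  if (length(cohort) == 0) {
    return(list(patients = list(),
                summary = data.frame(threshold = numeric(0),
                                     subgroup = character(0),
                                     nPass = integer(0),
                                     nFail = integer(0))))
  }
  patients <- lapply(cohort, function(subj) {
    patientScreen(subj$series, thresholds,
                  subjectId = subj$subjectId %||% "unknown",
                  subgroup = subj$subgroup %||% "unknown",
                  minFailDurationS = minFailDurationS,
                  segmentDurationS = segmentDurationS)
  })
  thr <- as.numeric(thresholds)
  groups <- unique(vapply(patients, function(p) p@subgroup, character(1)))
  summary <- do.call(rbind, lapply(thr, function(t) {
    do.call(rbind, lapply(groups, function(g) {
      flags <- vapply(patients, function(p) {
        if (p@subgroup != g) return(NA)
        p@patientPass[[sprintf("%.6g", t)]]
      }, logical(1))
      flags <- flags[!is.na(flags)]
      data.frame(threshold = t, subgroup = g,
                 nPass = sum(flags), nFail = sum(!flags))
    }))
  }))
  list(patients = patients, summary = summary)
}

#' Oracle or model T:R series for every subject of a synthetic cohort
#'
#' Convenience bridge from [generateCohort()] output to the screening
#' layer: runs [trSeries()] on each subject's recording and attaches the
#' result as \code{series}.
#'
#' @param cohort output of [generateCohort()].
#' @param backend,model,windowS see [trSeries()].
#' @return the cohort list with a \code{series} element per subject.
#' @export
cohortTRSeries <- function(cohort, backend = "oracle", model = NULL,
                           windowS = 10) {
  lapply(cohort, function(subj) {
    subj$series <- trSeries(subj$recording, backend = backend,
                            model = model, windowS = windowS)
    subj
  })
}

#' Write per-patient screening results as JSON
#'
#' Emits one JSON object per patient with the standard pass probability,
#' per-threshold patient flags and the per-vector result table.
#'
#' @param cohortResult output of [cohortScreen()].
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
writeScreeningJson <- function(cohortResult, path) {
  payload <- lapply(cohortResult$patients, function(p) {
    list(subjectId = p@subjectId, subgroup = p@subgroup,
         standardPassProbability = p@standardPassProbability,
         patientPass = as.list(p@patientPass),
         vectorResults = p@vectorResults)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
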