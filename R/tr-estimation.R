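## Per-segment T:R estimation: a waveform peak-ratio estimator used as
## the labelling oracle, plus accuracy evaluation and whole-recording
## series extraction. The trainable PSR-image regressor lives in
## regressor.R.

#' Waveform-based T:R ratio of one preprocessed segment
#'
#' Mechanises the manual T:R measurement. R peaks are detected by
#' threshold-crossing on a smoothed squared-derivative envelope (with a
#' 250 ms refractory merge); for each beat, the T peak is the
#' absolute-maximum deflection in the window from R + 120 ms to
#' R + 60\% of the local RR interval. Wave amplitudes are measured as
#' deflections from the isoelectric level (the segment median), as in
#' manual calliper measurement; the returned ratio is the median over
#' beats of |T| / |R| and is invariant to uniform amplitude scaling of
#' the segment.
#'
#' Segments without a detectable rhythm (fewer than 3 beats, implausibly
#' many threshold crossings, or R peaks indistinguishable from the
#' noise floor) return \code{NA} carrying a \code{"reason"} attribute.
#'
#' @param segment a preprocessed [ECGSegment-class].
#' @return a single non-negative number, or \code{NA} with attribute
#'   \code{reason} in \code{c("too_few_beats", "no_rhythm", "low_snr")}.
#' @export
oracleTR <- function(segment) {
  stopifnot(is(segment, "ECGSegment"))
  x <- segment@samples
  fs <- segment@samplingRate
  miss <- function(code) structure(NA_real_, reason = code)

  ## squared-derivative envelope, smoothed over ~30 ms
  d <- diff(x)
  k <- max(3L, as.integer(round(0.03 * fs)))
  env <- as.numeric(stats::filter(d^2, rep(1 / k, k), sides = 2))
  env[is.na(env)] <- 0
  thr <- 0.3 * max(env)
  if (thr <= 0) return(miss("low_snr"))

  above <- env > thr
  edges <- diff(c(FALSE, above, FALSE))
  starts <- which(edges == 1)
  ends <- which(edges == -1) - 1L
  if (length(starts) > 60) return(miss("no_rhythm"))
  if (length(starts) < 3) return(miss("too_few_beats"))

  ## R location = absolute-maximum sample inside each crossing region
  peaks <- mapply(function(s, e) s + which.max(abs(x[s:e])) - 1L,
                  starts, ends)
  ## refractory merge: enforce >= 250 ms between peaks, keep the larger
  minGap <- round(0.25 * fs)
  keep <- integer(0)
  for (p in peaks) {
    if (length(keep) && p - keep[length(keep)] < minGap) {
      if (abs(x[p]) > abs(x[keep[length(keep)]])) keep[length(keep)] <- p
    } else {
      keep <- c(keep, p)
    }
  }
  if (length(keep) < 3) return(miss("too_few_beats"))

  rAmp <- abs(x[keep] - stats::median(x))
  if (any(rAmp == 0)) stop("zero R amplitude at a detected peak")
  if (stats::median(rAmp) < 8 * stats::mad(x)) return(miss("low_snr"))

  ratios <- vapply(seq_len(length(keep) - 1L), function(i) {
    r0 <- keep[i]
    rr <- keep[i + 1L] - r0
    w0 <- r0 + round(0.12 * fs)
    w1 <- r0 + round(0.6 * rr)
    if (w1 <= w0 || w1 > length(x)) return(NA_real_)
    ## local isoelectric level: median over this RR interval (robust to
    ## residual drift that a global reference would smear across beats)
    iso <- stats::median(x[r0:keep[i + 1L]])
    max(abs(x[w0:w1] - iso)) / abs(x[r0] - iso)
  }, numeric(1))
  ratios <- ratios[!is.na(ratios)]
  if (length(ratios) < 2) return(miss("too_few_beats"))
  stats::median(ratios)
}

#' Accuracy metrics for predicted T:R ratios
#'
#' Pooled mean squared error, its square root and mean absolute error,
#' plus the same metrics per fold and fold-averaged (pooled and
#' fold-averaged aggregations differ in general; both are reported).
#'
#' @param predictions numeric predictions.
#' @param labels numeric reference values, same length.
#' @param folds optional integer fold assignment per observation; when
#'   omitted, everything is one fold.
#' @return an [AccuracyReport-class].
#' @examples
#' evaluateAccuracy(c(0.2, 0.6), c(0.3, 0.4))  # MAE 0.15, MSE 0.025
#' @export
evaluateAccuracy <- function(predictions, labels, folds = NULL) {
  if (length(predictions) == 0 || length(predictions) != length(labels)) {
    stop("predictions and labels must be non-empty and of equal length")
  }
  if (anyNA(predictions) || anyNA(labels)) {
    stop("predictions and labels must be finite")
  }
  if (is.null(folds)) folds <- rep(1L, length(labels))
  err <- predictions - labels
  mse <- mean(err^2)
  perFold <- do.call(rbind, lapply(sort(unique(folds)), function(f) {
    e <- err[folds == f]
    data.frame(fold = f, n = length(e), mse = mean(e^2),
               rmse = sqrt(mean(e^2)), mae = mean(abs(e)))
  }))
  new("AccuracyReport",
      mse = mse, rmse = sqrt(mse), mae = mean(abs(err)),
      nFolds = length(unique(folds)), perFold = perFold,
      foldMeans = c(mse = mean(perFold$mse), rmse = mean(perFold$rmse),
                    mae = mean(perFold$mae)))
}

#' Per-segment T:R series for every channel of a recording
#'
#' Cuts the recording into the 10-s grid, conditions every segment and
#' estimates its T:R ratio with the requested backend: the waveform
#' oracle ([oracleTR()]) or a trained PSR-image regressor
#' ([predictTR()]). All three vector roles are always reported; roles
#' absent from the recording yield a series flagged
#' \code{missingChannel}.
#'
#' @param recording an [ECGRecording-class].
#' @param backend \code{"oracle"} or \code{"model"}.
#' @param model a model from [trainRegressor()] (required for
#'   \code{backend = "model"}).
#' @param windowS segment window in seconds.
#' @param tau,bins PSR imaging parameters (model backend only).
#' @return named list of [TRSeries-class], one per role in
#'   \code{c("primary", "alternate", "secondary")}.
#' @export
trSeries <- function(recording, backend = c("oracle", "model"),
                     model = NULL, windowS = 10, tau = 10, bins = 32) {
  backend <- match.arg(backend)
  if (backend == "model" && is.null(model)) {
    stop("backend = 'model' requires a trained model")
  }
  segs <- segmentRecording(recording, windowS)
  out <- lapply(.VALID_ROLES, function(role) {
    if (!role %in% names(segs)) {
      return(new("TRSeries", values = numeric(0), channelRole = role,
                 missingChannel = TRUE, reasonCodes = character(0)))
    }
    chanSegs <- segs[[role]]
    vals <- numeric(length(chanSegs))
    reasons <- character(length(chanSegs))
    for (i in seq_along(chanSegs)) {
      pre <- preprocessSegment(chanSegs[[i]])
      v <- if (backend == "oracle") {
        oracleTR(pre)
      } else {
        predictTR(model, psrImage(pre, tau = tau, bins = bins))
      }
      vals[i] <- as.numeric(v)
      reasons[i] <- attr(v, "reason") %||% ""
    }
    new("TRSeries", values = vals, channelRole = role,
        missingChannel = FALSE, reasonCodes = reasons)
  })
  names(out) <- .VALID_ROLES
  out
}
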