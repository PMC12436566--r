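## Phase-space-reconstruction imaging: each 10-s segment becomes a 32x32
## occupancy image of its delay map (x[t], x[t+tau]).

#' Phase-space-reconstruction image of one segment
#'
#' Builds the 2-D occupancy histogram of the delay pairs
#' \eqn{(x[t], x[t+\tau])}, \eqn{t = 0 \ldots N-\tau-1}, after min-max
#' amplitude normalisation of the segment to [0, 1]. The histogram uses
#' \code{bins} equal-width bins per axis on [0, 1] (right-closed final
#' bin: a value of exactly 1 falls in the last bin), so the raw counts
#' sum to \eqn{N - \tau}. Intensities are the counts divided by the
#' maximum cell count. The image is invariant to positive rescaling of
#' the segment, and time reversal maps it to its transpose.
#'
#' A constant (zero amplitude range) segment cannot be normalised; it
#' maps, with a warning, to an image with a single centre-diagonal pixel
#' set to 1.
#'
#' @param segment an [ECGSegment-class] (typically the output of
#'   [preprocessSegment()]).
#' @param tau embedding delay in samples (default 10, i.e. 20 ms at
#'   500 Hz); must satisfy \code{1 <= tau < length(segment)}.
#' @param bins bins per axis (default 32).
#' @return a [PSRImage-class].
#' @examples
#' seg <- new("ECGSegment", samples = sin(seq(0, 20 * pi, length.out = 5000)),
#'            samplingRate = 500, channelRole = "primary",
#'            segmentIndex = 0L, startTime = 0)
#' img <- psrImage(seg)
#' sum(img@counts)  # 5000 - 10 pairs
#' @export
psrImage <- function(segment, tau = 10, bins = 32) {
  stopifnot(is(segment, "ECGSegment"))
  x <- segment@samples
  n <- length(x)
  tau <- as.integer(tau)
  if (tau < 1) stop("tau must be >= 1")
  if (n <= tau) stop("segment length must exceed tau")

  rng <- range(x)
  if (diff(rng) == 0) {
    warning("constant segment: zero amplitude range, emitting a single ",
            "centre-diagonal pixel")
    counts <- matrix(0L, bins, bins)
    mid <- as.integer(ceiling(bins / 2))
    counts[mid, mid] <- n - tau
    intensity <- matrix(0, bins, bins)
    intensity[mid, mid] <- 1
  } else {
    u <- (x - rng[1]) / diff(rng)
    ix <- pmin(as.integer(floor(u * bins)), bins - 1L)  # bin 0..bins-1
    rowBin <- ix[1:(n - tau)]
    colBin <- ix[(tau + 1):n]
    counts <- matrix(tabulate(rowBin + bins * colBin + 1L,
                              nbins = bins * bins), bins, bins)
    storage.mode(counts) <- "integer"
    intensity <- counts / max(counts)
  }
  new("PSRImage", counts = counts, intensity = intensity, tau = tau,
      channelRole = segment@channelRole,
      segmentIndex = segment@segmentIndex)
}

#' PSR images for every segment of a recording
#'
#' Cuts the recording into the 10-s grid, applies the full conditioning
#' chain ([preprocessSegment()]) and [psrImage()] to every segment of
#' every present channel, preserving segment order.
#'
#' @param recording an [ECGRecording-class].
#' @param tau embedding delay in samples.
#' @param bins bins per axis.
#' @param windowS segment window in seconds.
#' @return named list (per channel role) of lists of
#'   [PSRImage-class] objects; a 24-h 3-channel recording yields
#'   3 x 8640 images.
#' @export
batchImages <- function(recording, tau = 10, bins = 32, windowS = 10) {
  segs <- segmentRecording(recording, windowS)
  lapply(segs, function(chanSegs) {
    lapply(chanSegs, function(s) psrImage(preprocessSegment(s), tau, bins))
  })
}

#' Write a PSR image as a CSV matrix
#'
#' Dumps the 32 x 32 intensity matrix for inspection, with the delay
#' recorded in a comment header.
#'
#' @param image a [PSRImage-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writePSRImageCsv <- function(image, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(sprintf("# tau=%d role=%s segment=%d", image@tau,
                     image@channelRole, image@segmentIndex), con)
  utils::write.table(image@intensity, con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
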