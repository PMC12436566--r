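## ASCII Holter sample-table I/O and segmentation.
##
## Dialect: header lines `# fs=<Hz>`, `# channels=<role,role,...>`,
## `# subject=<id>`, `# subgroup=<label>`, then whitespace-separated rows,
## one sample time-point per row, one column per channel, values in mV.

.parseHeader <- function(lines) {
  kv <- list()
  for (ln in lines) {
    body <- trimws(sub("^#", "", ln))
    eq <- regexpr("=", body, fixed = TRUE)
    if (eq > 0) {
      key <- trimws(substr(body, 1, eq - 1))
      kv[[key]] <- trimws(substr(body, eq + 1, nchar(body)))
    }
  }
  kv
}

#' Read an ASCII Holter sample table
#'
#' Parses the package's self-describing ASCII dialect (see Details) into
#' an [ECGRecording-class]. Parsing is locale-independent (dot decimal
#' separator). Channels absent from the file (e.g. a lost secondary
#' electrode) are simply absent from the returned recording.
#'
#' @details The format is plain text: comment headers
#' \verb{# fs=<Hz>}, \verb{# channels=<role,role,...>},
#' \verb{# subject=<id>}, \verb{# subgroup=<label>}, followed by
#' whitespace-separated data rows, one time-point per row and one column
#' per declared channel, in millivolts.
#'
#' @param path file path.
#' @return an [ECGRecording-class].
#' @seealso [writeHolterAscii()], [segmentRecording()]
#' @export
readHolterAscii <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || all(!nzchar(trimws(lines)))) {
    stop("empty Holter ASCII file: ", path)
  }
  isHeader <- grepl("^\\s*#", lines)
  kv <- .parseHeader(lines[isHeader])
  if (is.null(kv$fs)) stop("missing '# fs=<Hz>' header in ", path)
  fs <- as.numeric(kv$fs)
  if (!is.finite(fs) || fs <= 0) stop("invalid sampling rate in header")
  if (is.null(kv$channels)) stop("missing '# channels=' header in ", path)
  roles <- trimws(strsplit(kv$channels, ",", fixed = TRUE)[[1]])
  bad <- setdiff(roles, .VALID_ROLES)
  if (length(bad)) {
    stop("unknown channel role(s) in header: ", paste(bad, collapse = ", "))
  }

  dataIdx <- which(!isHeader & nzchar(trimws(lines)))
  if (length(dataIdx) == 0) stop("no data rows in ", path)
  fields <- strsplit(trimws(lines[dataIdx]), "\\s+")
  nf <- lengths(fields)
  if (any(nf != length(roles))) {
    badLine <- dataIdx[which(nf != length(roles))[1]]
    stop(sprintf("ragged row at line %d: expected %d column(s), found %d",
                 badLine, length(roles), nf[which(nf != length(roles))[1]]))
  }
  vals <- suppressWarnings(as.numeric(unlist(fields, use.names = FALSE)))
  if (anyNA(vals)) stop("non-numeric sample value in ", path)
  mat <- matrix(vals, ncol = length(roles), byrow = TRUE)
  channels <- lapply(seq_along(roles), function(j) mat[, j])
  names(channels) <- roles
  new("ECGRecording", samplingRate = fs, channels = channels,
      subjectId = kv$subject %||% "unknown",
      subgroup = kv$subgroup %||% "unknown")
}

#' Write an ECG recording as an ASCII Holter sample table
#'
#' Writes the dialect documented in [readHolterAscii()], lossless to at
#' least 6 significant digits (values are printed with 9).
#'
#' @param recording an [ECGRecording-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeHolterAscii <- function(recording, path) {
  stopifnot(is(recording, "ECGRecording"))
  if (length(recording@channels) == 0) stop("recording has no channels")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    sprintf("# fs=%.10g", recording@samplingRate),
    sprintf("# channels=%s", paste(names(recording@channels),
                                   collapse = ",")),
    sprintf("# subject=%s", recording@subjectId),
    sprintf("# subgroup=%s", recording@subgroup)
  ), con)
  mat <- do.call(cbind, recording@channels)
  utils::write.table(format(mat, digits = 9, scientific = FALSE,
                            trim = TRUE),
                     con, sep = " ", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Cut a recording into the 10-second segment grid
#'
#' Splits every present channel into consecutive non-overlapping windows
#' of \code{windowS} seconds. Trailing samples that do not fill a whole
#' window are dropped (the screening denominator assumes whole 10-s
#' segments). Indices are 0-based; segment \eqn{k} covers
#' \eqn{[k \cdot windowS, (k+1) \cdot windowS)} seconds, identically
#' across channels.
#'
#' @param recording an [ECGRecording-class].
#' @param windowS window length in seconds (default 10).
#' @return named list (one element per channel role) of lists of
#'   [ECGSegment-class] objects. A 24-h recording yields 8640 segments
#'   per channel at the default window.
#' @export
segmentRecording <- function(recording, windowS = 10) {
  stopifnot(is(recording, "ECGRecording"), windowS > 0)
  fs <- recording@samplingRate
  nPerSeg <- round(windowS * fs)
  out <- lapply(names(recording@channels), function(role) {
    x <- recording@channels[[role]]
    nSeg <- length(x) %/% nPerSeg
    if (nSeg == 0) {
      warning("window (", windowS, " s) longer than recording; ",
              "no segments produced")
      return(list())
    }
    lapply(seq_len(nSeg), function(k) {
      i0 <- (k - 1L) * nPerSeg
      new("ECGSegment",
          samples = x[(i0 + 1L):(i0 + nPerSeg)],
          samplingRate = fs, channelRole = role,
          segmentIndex = k - 1L, startTime = (k - 1) * windowS)
    })
  })
  names(out) <- names(recording@channels)
  out
}

#' Export a set of T:R series as CSV
#'
#' Writes rows \code{segment_index,role,tr} for every non-missing channel
#' (missing estimates are written as empty fields).
#'
#' @param seriesList named list of [TRSeries-class].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeTRSeriesCsv <- function(seriesList, path) {
  rows <- do.call(rbind, lapply(seriesList, function(s) {
    if (s@missingChannel) return(NULL)
    data.frame(segment_index = seq_along(s@values) - 1L,
               role = s@channelRole, tr = s@values)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
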