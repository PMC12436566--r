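# Shared helpers: hand-built segments and recordings with analytically
# known structure, used as independent references by the module tests.

# Wrap a numeric vector as an ECGSegment.
makeSegment <- function(x, fs = 500, role = "primary", index = 0L) {
  new("ECGSegment", samples = as.numeric(x), samplingRate = fs,
      channelRole = role, segmentIndex = as.integer(index),
      startTime = 10 * index)
}

# A clean 10-s beat-train segment with exact T:R ratio `tr`.
cleanSegment <- function(tr, heartRate = 60, fs = 500, durationS = 10) {
  tpl <- beatTemplate(heartRate = heartRate, trRatio = tr)
  beat <- generateBeat(tpl, fs)
  makeSegment(rep(beat, length.out = durationS * fs), fs = fs)
}

# The default additive noise battery, deterministic given the phases.
addNoise <- function(segment, wander = 0.2, wanderHz = 0.33,
                     mains = 0.05, whiteSD = 0.02,
                     phases = c(0.4, 1.3), whiteSeed = 11L) {
  x <- segment@samples
  fs <- segment@samplingRate
  tt <- (seq_along(x) - 1) / fs
  x <- x + wander * sin(2 * pi * wanderHz * tt + phases[1]) +
    mains * sin(2 * pi * 50 * tt + phases[2])
  if (whiteSD > 0) {
    set.seed(whiteSeed)
    x <- x + rnorm(length(x), 0, whiteSD)
  }
  makeSegment(x, fs = segment@samplingRate)
}

# A TRSeries with the given values (helper for screening-layer tests).
makeSeries <- function(values, role = "primary", missing = FALSE) {
  new("TRSeries", values = as.numeric(values), channelRole = role,
      missingChannel = missing,
      reasonCodes = rep("", if (missing) 0 else length(values)))
}

# Root-mean-square.
rms <- function(x) sqrt(mean(x^2))

# Brute-force run oracle: longest run of TRUE in a logical vector by
# scanning every contiguous window.
bruteLongestRun <- function(flags) {
  n <- length(flags)
  longest <- 0L
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (all(flags[i:j])) longest <- max(longest, j - i + 1L) else break
    }
  }
  longest
}
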