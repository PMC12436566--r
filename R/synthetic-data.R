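## Synthetic Holter generator.
##
## Study-like recordings are 24 h, 3 channels at 500 Hz with a slowly
## drifting, per-segment T:R amplitude ratio. Beats are sums of Gaussian
## bumps (P, Q, R, S, T) so that the R and T peak amplitudes -- and hence
## the ground-truth T:R ratio -- are controlled analytically. Gaussian
## tails wrap around the cardiac cycle, making beat tiling seamless.

#' Parametric PQRST beat template
#'
#' Describes one cardiac cycle as a sum of Gaussian bumps, one per wave
#' (P, Q, R, S, T). Amplitudes are in millivolts, centres in seconds
#' relative to the R peak, widths are Gaussian standard deviations in
#' seconds. The template's nominal T:R ratio is the T amplitude divided by
#' the R amplitude; the recording generator rescales the T bump per
#' segment to realise a target T:R trajectory.
#'
#' @param heartRate heart rate in beats/min (fixed per recording), in
#'   \[30, 180\].
#' @param rAmplitude R peak amplitude in mV (> 0).
#' @param trRatio nominal T:R ratio in \[0, 2\].
#' @param components optional data.frame overriding the default wave set;
#'   columns \code{label}, \code{amplitude}, \code{center}, \code{width}.
#' @return a \code{BeatTemplate} list with elements \code{components} and
#'   \code{heartRate}.
#' @examples
#' tpl <- beatTemplate(heartRate = 60, rAmplitude = 1, trRatio = 0.25)
#' beat <- generateBeat(tpl, samplingRate = 500)
#' length(beat)  # 500 samples: one 1-s cycle
#' @export
beatTemplate <- function(heartRate = 60, rAmplitude = 1.0, trRatio = 0.25,
                         components = NULL) {
  stopifnot(is.numeric(heartRate), length(heartRate) == 1)
  if (heartRate < 30 || heartRate > 180) {
    stop("heartRate must lie in [30, 180] beats/min")
  }
  if (rAmplitude <= 0) stop("R amplitude must be positive")
  if (trRatio < 0 || trRatio > 2) stop("trRatio must lie in [0, 2]")
  if (is.null(components)) {
    components <- data.frame(
      label     = c("P",     "Q",     "R",   "S",    "T"),
      amplitude = c(0.10 * rAmplitude, -0.06 * rAmplitude, rAmplitude,
                    -0.10 * rAmplitude, trRatio * rAmplitude),
      center    = c(-0.200, -0.035, 0.000, 0.035, 0.250),
      width     = c(0.025, 0.010, 0.012, 0.012, 0.050),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(all(c("label", "amplitude", "center", "width") %in%
                  names(components)))
  if (any(components$width <= 0)) stop("component widths must be positive")
  rAmp <- components$amplitude[components$label == "R"]
  if (length(rAmp) != 1 || rAmp <= 0) {
    stop("template must contain exactly one R component with amplitude > 0")
  }
  structure(list(components = components, heartRate = heartRate),
            class = "BeatTemplate")
}

## Signed value of the wrapped Gaussian component sum at times t (seconds,
## relative to the R peak), for one cardiac cycle of length cyc seconds.
.beatValue <- function(t, components, cyc) {
  out <- numeric(length(t))
  for (i in seq_len(nrow(components))) {
    delta <- (t - components$center[i] + cyc / 2) %% cyc - cyc / 2
    out <- out + components$amplitude[i] *
      exp(-delta^2 / (2 * components$width[i]^2))
  }
  out
}

#' Synthesise one cardiac cycle from a beat template
#'
#' Renders the template as a sampled waveform of exactly
#' \code{round(samplingRate * 60 / heartRate)} samples, with the R peak at
#' a fixed 40\% phase of the cycle. Component tails wrap around the cycle
#' so that repeated beats tile continuously. The template is rejected when
#' overlapping components distort the R or T peak by more than 1\% of the
#' R amplitude, which would break the analytic T:R guarantee.
#'
#' @param template a [beatTemplate()].
#' @param samplingRate sampling frequency in Hz.
#' @return numeric millivolt waveform of one cycle.
#' @export
generateBeat <- function(template, samplingRate = 500) {
  stopifnot(inherits(template, "BeatTemplate"), samplingRate > 0)
  comp <- template$components
  cyc <- 60 / template$heartRate
  n <- round(samplingRate * cyc)
  tR <- 0.4 * cyc                      # R peak position within the cycle
  t <- (seq_len(n) - 1) / samplingRate - tR
  wave <- .beatValue(t, comp, cyc)

  rAmp <- comp$amplitude[comp$label == "R"]
  tAmp <- if ("T" %in% comp$label) comp$amplitude[comp$label == "T"] else 0
  atR <- .beatValue(0, comp, cyc)
  atT <- if ("T" %in% comp$label) {
    .beatValue(comp$center[comp$label == "T"], comp, cyc)
  } else 0
  if (abs(atR - rAmp) > 0.01 * rAmp || abs(atT - tAmp) > 0.01 * rAmp) {
    stop("overlapping components distort the R or T peak by more than 1% ",
         "of the R amplitude; adjust centers or widths")
  }
  wave
}

#' Target T:R ratio trajectory over the segment grid
#'
#' The per-segment target is a circadian sinusoid around a baseline plus
#' independent Gaussian jitter, clamped to (0, 2]. Alternatively an
#' explicit per-segment target vector can be supplied.
#'
#' @param baseline baseline T:R ratio.
#' @param circadianAmplitude amplitude of the slow sinusoidal drift.
#' @param circadianPeriod period of the drift in seconds (default one day).
#' @param jitterSD standard deviation of per-segment Gaussian jitter.
#' @param targets optional explicit per-segment targets (overrides the
#'   drift model; still clamped to (0, 2]).
#' @return a \code{TRTrajectory} list.
#' @export
trTrajectory <- function(baseline = 0.3, circadianAmplitude = 0.1,
                         circadianPeriod = 86400, jitterSD = 0.03,
                         targets = NULL) {
  stopifnot(baseline > 0, circadianAmplitude >= 0, circadianPeriod > 0,
            jitterSD >= 0)
  if (!is.null(targets) && any(targets <= 0 | targets > 2)) {
    stop("explicit targets must lie in (0, 2]")
  }
  structure(list(baseline = baseline,
                 circadianAmplitude = circadianAmplitude,
                 circadianPeriod = circadianPeriod,
                 jitterSD = jitterSD,
                 targets = targets),
            class = "TRTrajectory")
}

#' Additive noise model for a synthetic channel
#'
#' Baseline wander (slow sinusoid), 50 Hz power-line interference and
#' white broadband noise, the three disturbances the conditioning chain
#' is designed to remove. The power-line frequency is fixed at 50 Hz.
#'
#' @param wanderAmplitude baseline wander amplitude in mV.
#' @param wanderFrequency wander frequency in Hz (typically 0.2--0.5).
#' @param powerlineAmplitude 50 Hz interference amplitude in mV.
#' @param whiteNoiseSD white noise standard deviation in mV.
#' @return a \code{NoiseModel} list.
#' @export
noiseModel <- function(wanderAmplitude = 0.2, wanderFrequency = 0.33,
                       powerlineAmplitude = 0.05, whiteNoiseSD = 0.02) {
  stopifnot(wanderAmplitude >= 0, wanderFrequency > 0,
            powerlineAmplitude >= 0, whiteNoiseSD >= 0)
  structure(list(wanderAmplitude = wanderAmplitude,
                 wanderFrequency = wanderFrequency,
                 powerlineFrequency = 50,
                 powerlineAmplitude = powerlineAmplitude,
                 whiteNoiseSD = whiteNoiseSD),
            class = "NoiseModel")
}

#' Simulation configuration for one synthetic recording
#'
#' Bundles duration, sampling rate, seed, subject metadata and the
#' per-channel beat template, T:R trajectory and noise model. The
#' duration must be a positive multiple of 10 s so that the ground-truth
#' trajectory and the 10-s segment grid coincide exactly.
#'
#' @param duration recording length in seconds (positive multiple of 10;
#'   86400 for a study-like 24-h recording).
#' @param samplingRate sampling frequency in Hz (study value 500).
#' @param seed integer RNG seed; the same seed and configuration yield a
#'   bit-identical recording.
#' @param subjectId subject identifier.
#' @param subgroup cohort subgroup label.
#' @param channels named list (names among \code{"primary"},
#'   \code{"alternate"}, \code{"secondary"}) of lists with elements
#'   \code{template}, \code{trajectory}, \code{noise}. Defaults to three
#'   identical channels with package-default template, trajectory and
#'   noise.
#' @return a \code{SimConfig} list.
#' @export
simConfig <- function(duration = 86400, samplingRate = 500, seed = 1L,
                      subjectId = "subject-1", subgroup = "Normal",
                      channels = NULL) {
  if (duration <= 0 || abs(duration %% 10) > 1e-9) {
    stop("duration must be a positive multiple of 10 seconds")
  }
  stopifnot(samplingRate > 0, length(seed) == 1)
  if (is.null(channels)) {
    one <- function() list(template = beatTemplate(),
                           trajectory = trTrajectory(),
                           noise = noiseModel())
    channels <- list(primary = one(), alternate = one(), secondary = one())
  }
  if (!all(names(channels) %in% .VALID_ROLES)) {
    stop("channel names must be among primary, alternate, secondary")
  }
  structure(list(duration = duration, samplingRate = samplingRate,
                 seed = as.integer(seed), subjectId = subjectId,
                 subgroup = subgroup, channels = channels),
            class = "SimConfig")
}

## Realise the per-segment targets of a trajectory (RNG state is consumed
## for the jitter draws; clamped to (0, 2]).
.realizeTrajectory <- function(traj, nSeg) {
  if (!is.null(traj$targets)) {
    if (length(traj$targets) != nSeg) {
      stop("explicit trajectory targets must have one value per segment")
    }
    return(pmin(pmax(traj$targets, 1e-3), 2))
  }
  segMid <- (seq_len(nSeg) - 0.5) * 10
  base <- traj$baseline +
    traj$circadianAmplitude * sin(2 * pi * segMid / traj$circadianPeriod)
  jit <- if (traj$jitterSD > 0) stats::rnorm(nSeg, 0, traj$jitterSD) else 0
  pmin(pmax(base + jit, 1e-3), 2)
}

#' Generate one synthetic Holter recording with known T:R ground truth
#'
#' Synthesises each channel as a tiling of template beats whose T-wave
#' amplitude is rescaled per 10-s segment to the realised trajectory
#' target (a beat belongs to the segment containing its R peak), then
#' adds baseline wander, 50 Hz interference and white noise. The
#' ground-truth T:R series is defined on the clean (pre-noise) signal, so
#' changing the noise model never changes the truth. All trajectory
#' realisations are drawn before any noise.
#'
#' @param config a [simConfig()].
#' @return list with elements \code{recording} (an
#'   [ECGRecording-class]) and \code{truth} (named list of
#'   [TRSeries-class], one per channel, holding the realised per-segment
#'   targets).
#' @examples
#' cfg <- simConfig(duration = 60, seed = 7)
#' out <- generateRecording(cfg)
#' out$recording
#' trValues(out$truth$primary)
#' @export
generateRecording <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  fs <- config$samplingRate
  total <- round(config$duration * fs)
  nSeg <- round(config$duration / 10)
  roles <- names(config$channels)

  set.seed(config$seed)
  ## 1. Realise all trajectories first (truth is independent of noise).
  truthTargets <- lapply(config$channels, function(ch) {
    .realizeTrajectory(ch$trajectory, nSeg)
  })

  ## 2. Synthesise clean signals and add noise.
  samples <- vector("list", length(roles))
  names(samples) <- roles
  for (role in roles) {
    ch <- config$channels[[role]]
    comp <- ch$template$components
    cyc <- 60 / ch$template$heartRate
    ncyc <- round(fs * cyc)
    nBeats <- ceiling(total / ncyc)
    tR <- 0.4 * cyc
    tCycle <- (seq_len(ncyc) - 1) / fs - tR

    base <- .beatValue(tCycle, comp[comp$label != "T", , drop = FALSE], cyc)
    tShape <- if ("T" %in% comp$label) {
      .beatValue(tCycle, transform(comp[comp$label == "T", , drop = FALSE],
                                   amplitude = 1), cyc)
    } else numeric(ncyc)
    rAmp <- comp$amplitude[comp$label == "R"]

    ## segment owning each beat = segment containing its R peak
    beatR <- ((seq_len(nBeats) - 1) * ncyc) / fs + tR
    beatSeg <- pmin(floor(beatR / 10), nSeg - 1) + 1
    tAmpPerBeat <- truthTargets[[role]][beatSeg] * rAmp

    x <- rep(base, nBeats)[seq_len(total)] +
      rep(tAmpPerBeat, each = ncyc)[seq_len(total)] *
      rep(tShape, nBeats)[seq_len(total)]

    nm <- ch$noise
    if (nm$wanderAmplitude > 0 || nm$powerlineAmplitude > 0) {
      tt <- (seq_len(total) - 1) / fs
      if (nm$wanderAmplitude > 0) {
        x <- x + nm$wanderAmplitude *
          sin(2 * pi * nm$wanderFrequency * tt + stats::runif(1, 0, 2 * pi))
      }
      if (nm$powerlineAmplitude > 0) {
        x <- x + nm$powerlineAmplitude *
          sin(2 * pi * nm$powerlineFrequency * tt +
                stats::runif(1, 0, 2 * pi))
      }
    }
    if (nm$whiteNoiseSD > 0) x <- x + stats::rnorm(total, 0, nm$whiteNoiseSD)
    samples[[role]] <- x
  }

  rec <- new("ECGRecording", samplingRate = fs, channels = samples,
             subjectId = config$subjectId, subgroup = config$subgroup)
  truth <- lapply(roles, function(role) {
    new("TRSeries", values = truthTargets[[role]], channelRole = role,
        missingChannel = FALSE, reasonCodes = rep("", nSeg))
  })
  names(truth) <- roles
  list(recording = rec, truth = truth)
}

## Subgroup-default trajectory parameters. Free parameters of the
## generator (the source cohort is not deposited); the S-ICD subgroup --
## patients with prior T-wave-oversensing shocks -- is drawn with high
## T:R baselines, structurally normal hearts with low ones.
.SUBGROUP_DEFAULTS <- list(
  "ACHD"   = list(baseline = 0.38, amp = 0.12, jitter = 0.05),
  "HCM"    = list(baseline = 0.32, amp = 0.10, jitter = 0.04),
  "HF"     = list(baseline = 0.33, amp = 0.12, jitter = 0.05),
  "Normal" = list(baseline = 0.20, amp = 0.05, jitter = 0.02),
  "S-ICD"  = list(baseline = 0.55, amp = 0.20, jitter = 0.06)
)

#' Generate a synthetic cohort of recordings
#'
#' One recording per subject. Each subject draws a heart rate and a
#' subject-level T:R baseline around the subgroup default, then a full
#' recording via [generateRecording()]. Deterministic given
#' \code{baseSeed}: subject \eqn{i} uses seed \code{baseSeed + i}.
#'
#' @param nPerSubgroup named integer vector or list of subject counts per
#'   subgroup, e.g. \code{c(ACHD = 6, HCM = 7, HF = 14, Normal = 7,
#'   "S-ICD" = 3)} (the study cohort shape, n = 37).
#' @param baseSeed integer base seed.
#' @param duration per-recording duration in seconds (multiple of 10;
#'   86400 for study-like recordings).
#' @param samplingRate sampling frequency in Hz.
#' @param noise a [noiseModel()] shared by all channels.
#' @return list of per-subject lists with elements \code{recording},
#'   \code{truth}, \code{subjectId}, \code{subgroup}.
#' @export
generateCohort <- function(nPerSubgroup, baseSeed = 1L, duration = 86400,
                           samplingRate = 500, noise = noiseModel()) {
  counts <- unlist(nPerSubgroup)
  if (any(counts < 0)) stop("subgroup counts must be non-negative")
  badGroups <- setdiff(names(counts), .VALID_SUBGROUPS)
  if (length(badGroups)) {
    stop("unknown subgroup label(s): ", paste(badGroups, collapse = ", "))
  }
  out <- list()
  idx <- 0L
  for (grp in names(counts)) {
    def <- .SUBGROUP_DEFAULTS[[grp]]
    for (k in seq_len(counts[[grp]])) {
      idx <- idx + 1L
      subjSeed <- as.integer(baseSeed) + idx
      ## subject-level draws, separated from the recording's own stream
      set.seed(subjSeed * 2L + 1L)
      hr <- round(stats::runif(1, 55, 85))
      subjBase <- max(0.05, def$baseline + stats::rnorm(1, 0, 0.05))
      ## modest per-channel variation in baseline ratio
      chanBase <- pmax(0.05, subjBase + stats::rnorm(3, 0, 0.03))
      chans <- lapply(chanBase, function(b) {
        list(template = beatTemplate(heartRate = hr, trRatio = min(b, 2)),
             trajectory = trTrajectory(baseline = b,
                                       circadianAmplitude = def$amp,
                                       jitterSD = def$jitter),
             noise = noise)
      })
      names(chans) <- .VALID_ROLES
      cfg <- simConfig(duration = duration, samplingRate = samplingRate,
                       seed = subjSeed,
                       subjectId = sprintf("%s-%02d", grp, k),
                       subgroup = grp, channels = chans)
      rec <- generateRecording(cfg)
      out[[idx]] <- list(recording = rec$recording, truth = rec$truth,
                         subjectId = cfg$subjectId, subgroup = grp)
    }
  }
  out
}

#' Read a simulation configuration from a YAML file
#'
#' Accepts a YAML key-value file with top-level keys matching the
#' [simConfig()] arguments (\code{duration}, \code{samplingRate},
#' \code{seed}, \code{subjectId}, \code{subgroup}) and an optional
#' \code{channels} mapping with per-channel \code{trRatio},
#' \code{heartRate} and noise fields.
#'
#' @param path YAML file path.
#' @return a \code{SimConfig}.
#' @export
readSimConfig <- function(path) {
  y <- yaml::read_yaml(path)
  channels <- NULL
  if (!is.null(y$channels)) {
    channels <- lapply(y$channels, function(ch) {
      nm <- do.call(noiseModel, ch$noise %||% list())
      list(template = beatTemplate(heartRate = ch$heartRate %||% 60,
                                   trRatio = ch$trRatio %||% 0.25),
           trajectory = do.call(trTrajectory, ch$trajectory %||% list()),
           noise = nm)
    })
  }
  simConfig(duration = y$duration %||% 86400,
            samplingRate = y$samplingRate %||% 500,
            seed = y$seed %||% 1L,
            subjectId = y$subjectId %||% "subject-1",
            subgroup = y$subgroup %||% "Normal",
            channels = channels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
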