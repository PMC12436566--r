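test_that("synthesised beats have the template's cycle length and peak placement", {
  tpl <- beatTemplate(heartRate = 60, rAmplitude = 1, trRatio = 0.25)
  beat <- generateBeat(tpl, samplingRate = 500)
  expect_length(beat, 500)
  expect_equal(which.max(beat), 0.4 * 500 + 1)   # R peak at 40% phase

  beat72 <- generateBeat(beatTemplate(heartRate = 72), samplingRate = 500)
  expect_length(beat72, round(500 * 60 / 72))
})

test_that("the synthesised T:R ratio equals the nominal template ratio within 1%", {
  for (tr in c(0.1, 0.25, 0.4, 0.8, 1.5)) {
    tpl <- beatTemplate(heartRate = 60, rAmplitude = 1, trRatio = tr)
    beat <- generateBeat(tpl, 500)
    rIdx <- 0.4 * 500 + 1
    rAmp <- beat[rIdx]
    # T peak: absolute maximum in a window around R + 250 ms
    tWin <- (rIdx + 50):(rIdx + 200)
    tAmp <- max(beat[tWin])
    expect_equal(tAmp / rAmp, tr, tolerance = 0.01)
  }
})

test_that("a zero-amplitude T wave yields a degenerate but valid beat", {
  tpl <- beatTemplate(heartRate = 60, rAmplitude = 1, trRatio = 0)
  beat <- generateBeat(tpl, 500)
  rIdx <- 0.4 * 500 + 1
  tWin <- (rIdx + 50):(rIdx + 200)
  expect_lt(max(abs(beat[tWin])), 0.02)  # only Gaussian tails remain
})

test_that("templates whose components distort the R or T peak are rejected", {
  comp <- data.frame(label = c("R", "T"),
                     amplitude = c(1, 0.5),
                     center = c(0, 0.02),    # T almost on top of R
                     width = c(0.012, 0.05))
  tpl <- beatTemplate(heartRate = 60, components = comp)
  expect_error(generateBeat(tpl, 500), "distort")
})

test_that("template validation rejects out-of-range physiology", {
  expect_error(beatTemplate(heartRate = 20), "30")
  expect_error(beatTemplate(heartRate = 200), "30")
  expect_error(beatTemplate(rAmplitude = 0), "positive")
  expect_error(beatTemplate(trRatio = 2.5), "2")
  expect_error(trTrajectory(baseline = -0.1))
  expect_error(trTrajectory(targets = c(0.5, 0)), "targets")
  expect_error(noiseModel(wanderAmplitude = -1))
})

test_that("a recording has exactly duration x sampling-rate samples per channel and one truth value per segment", {
  cfg <- simConfig(duration = 60, samplingRate = 500, seed = 5)
  out <- generateRecording(cfg)
  for (role in channelRoles(out$recording)) {
    expect_length(out$recording@channels[[role]], 60 * 500)
    expect_length(trValues(out$truth[[role]]), 6)
  }
  expect_error(simConfig(duration = 25), "multiple of 10")
})

test_that("recordings are bit-identical under the same seed and configuration", {
  a <- generateRecording(simConfig(duration = 30, seed = 42))
  b <- generateRecording(simConfig(duration = 30, seed = 42))
  expect_identical(a$recording@channels, b$recording@channels)
  expect_identical(lapply(a$truth, trValues), lapply(b$truth, trValues))
  c <- generateRecording(simConfig(duration = 30, seed = 43))
  expect_false(identical(a$recording@channels$primary,
                         c$recording@channels$primary))
})

test_that("noise never changes the ground-truth T:R series", {
  quiet <- function() list(template = beatTemplate(),
                           trajectory = trTrajectory(),
                           noise = noiseModel(wanderAmplitude = 0,
                                              powerlineAmplitude = 0,
                                              whiteNoiseSD = 0))
  loud <- function() list(template = beatTemplate(),
                          trajectory = trTrajectory(),
                          noise = noiseModel(wanderAmplitude = 0.5,
                                             whiteNoiseSD = 0.05))
  a <- generateRecording(simConfig(duration = 40, seed = 9,
                                   channels = list(primary = quiet())))
  b <- generateRecording(simConfig(duration = 40, seed = 9,
                                   channels = list(primary = loud())))
  expect_identical(trValues(a$truth$primary), trValues(b$truth$primary))
  expect_false(identical(a$recording@channels$primary,
                         b$recording@channels$primary))
})

test_that("ground truth matches T and R amplitudes measured on the clean signal within 1%", {
  ch <- list(template = beatTemplate(heartRate = 60),
             trajectory = trTrajectory(baseline = 0.4,
                                       circadianAmplitude = 0,
                                       jitterSD = 0),
             noise = noiseModel(wanderAmplitude = 0, powerlineAmplitude = 0,
                                whiteNoiseSD = 0))
  out <- generateRecording(simConfig(duration = 20, seed = 3,
                                     channels = list(primary = ch)))
  x <- out$recording@channels$primary
  truth <- trValues(out$truth$primary)
  # beats are 1 s long with R at 40%: measure each beat's peaks directly
  for (seg in 0:1) {
    segx <- x[(seg * 5000 + 1):((seg + 1) * 5000)]
    rIdx <- 0.4 * 500 + 1
    beat <- segx[1:500]
    measured <- max(beat[(rIdx + 50):(rIdx + 200)]) / beat[rIdx]
    expect_equal(measured, truth[seg + 1], tolerance = 0.01)
  }
})

test_that("the oracle recovers a constant noise-free trajectory within 0.02 everywhere", {
  ch <- list(template = beatTemplate(heartRate = 72),
             trajectory = trTrajectory(baseline = 0.4,
                                       circadianAmplitude = 0, jitterSD = 0),
             noise = noiseModel(wanderAmplitude = 0, powerlineAmplitude = 0,
                                whiteNoiseSD = 0))
  out <- generateRecording(simConfig(duration = 40, seed = 2,
                                     channels = list(primary = ch)))
  est <- trSeries(out$recording, backend = "oracle")$primary
  expect_true(all(abs(trValues(est) - 0.4) < 0.02))
})

test_that("cohort generation honours subgroup counts and the base seed", {
  counts <- c(ACHD = 2, Normal = 1, "S-ICD" = 1)
  coh <- generateCohort(counts, baseSeed = 7, duration = 20)
  expect_length(coh, 4)
  expect_identical(vapply(coh, `[[`, character(1), "subgroup"),
                   c("ACHD", "ACHD", "Normal", "S-ICD"))
  coh2 <- generateCohort(counts, baseSeed = 7, duration = 20)
  expect_identical(coh[[1]]$recording@channels, coh2[[1]]$recording@channels)
  expect_length(generateCohort(c(ACHD = 0), baseSeed = 1, duration = 20), 0)
  expect_error(generateCohort(c(Unknown = 2), baseSeed = 1, duration = 20),
               "subgroup")
})

test_that("a YAML configuration round-trips into an equivalent simulation", {
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(duration = 30, samplingRate = 500, seed = 12,
                        subjectId = "s-7", subgroup = "HCM",
                        channels = list(primary = list(
                          heartRate = 66, trRatio = 0.3,
                          noise = list(wanderAmplitude = 0.1)))),
                   path)
  cfg <- readSimConfig(path)
  expect_equal(cfg$duration, 30)
  expect_equal(cfg$subgroup, "HCM")
  expect_equal(cfg$channels$primary$template$heartRate, 66)
  expect_equal(cfg$channels$primary$noise$wanderAmplitude, 0.1)
  out <- generateRecording(cfg)
  expect_length(out$recording@channels$primary, 30 * 500)
})
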