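test_that("slow-potential band-pass has the specified frequency response", {
  expect_equal(bandpassMRCP(matrix(0, 1, 250 * 25), 250),
               matrix(0, 1, 250 * 25))
  g1 <- sineGain(function(x) bandpassMRCP(matrix(x, 1), 250)[1, ], 1, 250,
                 durS = 60)
  expect_lt(abs(g1 - 1), 0.05)
  g20 <- sineGain(function(x) bandpassMRCP(matrix(x, 1), 250)[1, ], 20, 250,
                  durS = 60)
  expect_lt(g20, 0.02)
  expect_error(bandpassMRCP(matrix(0, 1, 100), 250), "short")
})

test_that("oscillation band-pass keeps 30 Hz and rejects 90 Hz", {
  g30 <- sineGain(function(x) bandpassOsc(matrix(x, 1), 250)[1, ], 30, 250,
                  durS = 60)
  expect_lt(abs(g30 - 1), 0.05)
  g90 <- sineGain(function(x) bandpassOsc(matrix(x, 1), 250)[1, ], 90, 250,
                  durS = 60)
  expect_lt(g90, 0.10)
})

test_that("both band-pass paths are linear", {
  set.seed(7)
  x <- matrix(rnorm(2 * 250 * 30), 2)
  y <- matrix(rnorm(2 * 250 * 30), 2)
  # the 0.05 Hz corner is numerically ill-conditioned, so exact linearity
  # degrades to ~1e-5 relative
  for (f in list(bandpassMRCP, bandpassOsc)) {
    lhs <- f(2 * x - 3 * y, 250)
    rhs <- 2 * f(x, 250) - 3 * f(y, 250)
    expect_equal(lhs, rhs, tolerance = 1e-4)
  }
})

test_that("epoch extraction slices exactly, at the right samples, with QC flags", {
  p <- defaultGroupProfiles()$HC
  ses <- generateSession(p, "S", nTrials = 2, seed = 13, interTrialS = 12,
                         preRollS = 12, postRollS = 8)$session
  rate <- eegRate(ses)
  # ramp signal: epoch values must equal session values exactly
  ramp <- matrix(rep(seq_len(ncol(eegData(ses))) / rate, each = 17), 17,
                 byrow = FALSE)
  onsets <- data.frame(trial = 1:3,
                       onset_time_s = c(10, 25, NA),
                       detected = c(TRUE, TRUE, FALSE),
                       threshold_used = 1, cue_go_time_s = c(9, 24, 38))
  ep <- extractEpochs(ses, ramp, onsets)
  expect_equal(nTrials(ep), 2)
  skipped <- attr(ep, "skipped")
  expect_equal(nrow(skipped), 1)
  expect_match(skipped$reason, "not detected")

  # onset at 10.0 s covers 6.0-14.0 s; t = 0 is the 1001st sample
  expect_equal(length(epochTimes(ep)), 2000)
  expect_equal(which(epochTimes(ep) == 0), 1001)
  sliced <- epochChannel(ep, "Cz", 1)
  expect_identical(sliced, ramp[11, (6 * rate + 1):(14 * rate)])

  # onset too close to the record edge is flagged, not an error
  onEdge <- data.frame(trial = 1, onset_time_s = 2, detected = TRUE,
                       threshold_used = 1, cue_go_time_s = 1.5)
  epEdge <- extractEpochs(ses, ramp, onEdge)
  expect_equal(nTrials(epEdge), 0)
  expect_match(attr(epEdge, "skipped")$reason, "edge")
})

test_that("oscillation outlier rules flag pre-cue and opposite-leg activity", {
  times <- epochAxis()
  n <- length(times)
  set.seed(8)
  baseEnv <- function() 5 + abs(rnorm(n, 0, 0.3))
  burst <- function(at, dur = 0.5, amp = 300)
    ifelse(times >= at & times < at + dur, amp, 0)
  mkEnv <- function(extraTa = 0, extraSol = 0, extraCon = 0)
    makeEpochSet(matrix(0, n, 3),
                 taEnv = sapply(1:3, function(i)
                   baseEnv() + burst(0) + if (i == 2) extraTa else 0),
                 solEnv = sapply(1:3, function(i)
                   baseEnv() + burst(0.1) + if (i == 2) extraSol else 0),
                 taConEnv = sapply(1:3, function(i)
                   baseEnv() + if (i == 3) extraCon else 0))
  onsets <- data.frame(trial = 1:3, onset_time_s = c(20, 32, 44),
                       detected = TRUE, threshold_used = 1,
                       cue_go_time_s = c(19.5, 31.5, 43.5))

  clean <- rejectOscillationOutliers(mkEnv(), onsets)
  expect_equal(nTrials(clean$kept), 3)
  expect_equal(nrow(clean$report), 0)
  expect_match(clean$note, "head-motion")

  pre <- rejectOscillationOutliers(
    mkEnv(extraTa = burst(-3, amp = 400)), onsets)
  expect_equal(nTrials(pre$kept), 2)
  expect_match(pre$report$reason, "pre-cue activity")

  con <- rejectOscillationOutliers(
    mkEnv(extraCon = burst(1, amp = 400)), onsets)
  expect_false(3 %in% con$kept@trialIndex)
  expect_match(con$report$reason, "opposite-leg activity")
})

icaTestSession <- function(seed, blinks = 0) {
  p <- groupProfile("HC", blink_rate_per_min = blinks,
                    blink_amplitude_uv = 150,
                    band_carrier_sd = c(theta = 1.5, low_beta = 1.5,
                                        high_beta = 1.5))
  generateSession(p, "S", nTrials = 3, seed = seed, interTrialS = 12,
                  preRollS = 15, postRollS = 10)$session
}

test_that("ICA cleaning removes injected blinks from frontal channels", {
  p <- groupProfile("HC", band_carrier_sd = c(theta = 1.5, low_beta = 1.5,
                                              high_beta = 1.5))
  g <- generateSession(p, "S", nTrials = 3, seed = 17, interTrialS = 12,
                       preRollS = 15, postRollS = 10)
  bl <- injectBlinks(g$session, ratePerMin = 12, amplitudeUv = 150,
                     seed = 99)
  expect_gt(nrow(bl$blinks), 3)
  eeg <- bandpassOsc(eegData(bl$session), 250)
  res <- removeArtifactComponents(eeg, 250, seed = 1)
  expect_equal(dim(res$cleaned), dim(eeg))
  expect_gte(sum(res$report$rejected), 1)

  inBlink <- rep(FALSE, ncol(eeg))
  for (tb in bl$blinks$time_s) {
    idx <- round(tb * 250):(round(tb * 250) + 75)
    inBlink[idx[idx <= length(inBlink)]] <- TRUE
  }
  vBefore <- var(eeg["FP1", inBlink])
  vAfter <- var(res$cleaned["FP1", inBlink])
  expect_lt(vAfter, 0.2 * vBefore)
})

test_that("ICA cleaning is specific: blink-free data lose no components", {
  rejected <- vapply(1:6, function(s) {
    ses <- icaTestSession(seed = 100 + s)
    eeg <- bandpassOsc(eegData(ses), 250)
    res <- removeArtifactComponents(eeg, 250, seed = s)
    sum(res$report$rejected)
  }, 0)
  expect_gte(sum(rejected == 0), 5)
})

test_that("cleaning already-clean data again rejects nothing", {
  ses <- icaTestSession(seed = 23)
  bl <- injectBlinks(ses, 12, 150, seed = 7)
  eeg <- bandpassOsc(eegData(bl$session), 250)
  first <- removeArtifactComponents(eeg, 250, seed = 1)
  second <- removeArtifactComponents(first$cleaned, 250, seed = 2)
  expect_equal(sum(second$report$rejected), 0)
})
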