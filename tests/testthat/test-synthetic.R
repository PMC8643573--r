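test_that("generation is bit-identical under a fixed seed", {
  p <- defaultGroupProfiles()$PD_mildFOG
  a <- generateSession(p, "S", nTrials = 2, seed = 11, interTrialS = 12,
                       preRollS = 12, postRollS = 8)
  b <- generateSession(p, "S", nTrials = 2, seed = 11, interTrialS = 12,
                       preRollS = 12, postRollS = 8)
  expect_identical(eegData(a$session), eegData(b$session))
  expect_identical(emgData(a$session), emgData(b$session))
  expect_identical(a$truth, b$truth)
  c <- generateSession(p, "S", nTrials = 2, seed = 12, interTrialS = 12,
                       preRollS = 12, postRollS = 8)
  expect_false(identical(eegData(a$session), eegData(c$session)))
})

test_that("cohorts have the requested structure and valid cue grids", {
  gen <- generateCohort(defaultGroupProfiles()[c("HC", "PD_noFOG")],
                        nSubjectsPerGroup = 2, nTrials = 3, seed = 5,
                        interTrialS = 11, preRollS = 12, postRollS = 8)
  expect_length(gen$sessions, 4)
  for (ses in gen$sessions) {
    expect_true(validObject(ses))
    cues <- cueTimes(ses)
    expect_equal(nrow(cues), 3)
    expect_equal(cues$go_s - cues$ready_s, rep(2, 3))
    expect_equal(eegRate(ses), 250)
    expect_equal(emgRate(ses), 1000)
  }
  tr <- gtTrials(gen$truth)
  expect_equal(nrow(tr), 12)
  expect_true(all(tr$true_onset_s > tr$go_s))
  expect_error(generateCohort(nSubjectsPerGroup = 0, seed = 1),
               "positive")
})

test_that("the grand-average Cz trough recovers the injected peak negativity", {
  p <- groupProfile("HC", peak_negativity_uv = -16, mrcp_peak_time_s = 0.4,
                    band_carrier_sd = c(theta = 0, low_beta = 0,
                                        high_beta = 0),
                    eeg_pink_sd = 0, eeg_white_sd = 2)
  g <- generateSession(p, "S", nTrials = 40, seed = 21, interTrialS = 10)
  ep <- extractEpochs(g$session, eegData(g$session),
                      detectSessionOnsets(g$session))
  ga <- grandAverage(ep, "Cz", smoothS = 0.04)
  trough <- min(ga$mean[ga$times >= -1 & ga$times <= 1.5])
  expect_lt(abs(trough - (-16)), 1)
})

test_that("blink injection is a no-op at zero rate or amplitude", {
  ses <- generateSession(defaultGroupProfiles()$HC, "S", nTrials = 2,
                         seed = 2, interTrialS = 12, preRollS = 12,
                         postRollS = 8)$session
  expect_identical(injectBlinks(ses, 0, 150, seed = 1)$session, ses)
  expect_identical(injectBlinks(ses, 10, 0, seed = 1)$session, ses)
})

test_that("blink counts follow the requested Poisson rate", {
  ses <- generateSession(defaultGroupProfiles()$HC, "S", nTrials = 2,
                         seed = 2, interTrialS = 12, preRollS = 12,
                         postRollS = 8)$session
  durMin <- ncol(eegData(ses)) / eegRate(ses) / 60
  counts <- vapply(1:50, function(s)
    nrow(injectBlinks(ses, 10, 150, seed = s)$blinks), 1L)
  lambda <- 50 * 10 * durMin
  # total count within the 99% Poisson interval
  expect_gt(sum(counts), qpois(0.005, lambda))
  expect_lt(sum(counts), qpois(0.995, lambda))
  # blinks raise frontal much more than central power
  bl <- injectBlinks(ses, 10, 150, seed = 1)
  dFP <- var(eegData(bl$session)["FP1", ]) - var(eegData(ses)["FP1", ])
  dCz <- var(eegData(bl$session)["Cz", ]) - var(eegData(ses)["Cz", ])
  expect_gt(dFP, 20 * max(dCz, 1e-9))
})

test_that("scheduled band modulation changes band power by the requested fraction", {
  # pure low-beta profile: Welch-style in-band power in the scheduled
  # window vs the baseline window, matched 1-s segments
  p <- groupProfile("HC", peak_negativity_uv = 0, ns1_slope_uv_per_s = 0,
                    ns2_slope_uv_per_s = 0, rebound_rate_uv_per_s = 0,
                    oscillation_schedule = list(
                      list(band = "low_beta", pct = -40, window = c(-1, 0))),
                    band_carrier_sd = c(theta = 0, low_beta = 4,
                                        high_beta = 0))
  g <- generateSession(p, "S", nTrials = 60, seed = 31, interTrialS = 10)
  cz <- eegData(g$session)["Cz", ]
  tE <- (seq_along(cz) - 1) / 250
  bandPower <- function(seg) {
    s <- Mod(stats::fft(seg))^2
    f <- (seq_along(seg) - 1) * 250 / length(seg)
    mean(s[f >= 13 & f <= 20])
  }
  onsets <- g$truth$trials$true_onset_s
  win <- vapply(onsets, function(on) bandPower(cz[tE >= on - 1 & tE < on]), 0)
  bas <- vapply(onsets, function(on) bandPower(cz[tE >= on - 4 & tE < on - 3]), 0)
  pct <- 100 * (mean(win) - mean(bas)) / mean(bas)
  expect_lt(abs(pct - (-40)), 10)   # 60 trials; the 200-trial bound is 5
})
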