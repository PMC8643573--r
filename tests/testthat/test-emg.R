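test_that("tkeo matches its defining formula and algebraic identities", {
  # brute-force evaluation of psi[n] = x[n]^2 - x[n-1] x[n+1]
  set.seed(1)
  x <- rnorm(50)
  direct <- numeric(50)
  for (n in 2:49) direct[n] <- x[n]^2 - x[n - 1] * x[n + 1]
  expect_equal(tkeo(x), direct)

  expect_equal(tkeo(rep(3.7, 100)), rep(0, 100))

  imp <- numeric(21); imp[11] <- 1
  psi <- tkeo(imp)
  expect_equal(psi[11], 1)
  expect_equal(psi[10], 0 - imp[9] * imp[11])   # 0
  expect_equal(psi[12], 0)

  expect_error(tkeo(c(1, 2)), "3 samples")
})

test_that("tkeo is homogeneous of degree two", {
  set.seed(2)
  x <- rnorm(200)
  for (a in c(-2, 0.5, 3))
    expect_equal(tkeo(a * x), a^2 * tkeo(x), tolerance = 1e-12)
})

test_that("tkeo of a sinusoid equals the closed form A^2 sin^2(omega)", {
  A <- 2; w <- 0.1
  n <- 0:999
  psi <- tkeo(A * sin(w * n))
  expect_lt(max(abs(psi[2:999] - A^2 * sin(w)^2)), 1e-6)
})

test_that("EMG band-pass passes 60 Hz, rejects 2 Hz, zero phase", {
  expect_equal(bandpassEMG(numeric(1000), 1000), numeric(1000))
  expect_lt(abs(sineGain(function(x) bandpassEMG(x, 1000), 60, 1000) - 1),
            0.01)
  expect_lt(sineGain(function(x) bandpassEMG(x, 1000), 2, 1000), 0.05)
  expect_error(bandpassEMG(numeric(100), 200), "too low")
  # zero-phase: filtering a reversed signal equals reversing the filtered
  # signal (away from the boundary transients)
  set.seed(3)
  x <- rnorm(2000)
  a <- bandpassEMG(rev(x), 1000)
  b <- rev(bandpassEMG(x, 1000))
  mid <- 301:1700
  expect_lt(max(abs(a[mid] - b[mid])), 1e-6)
})

test_that("decimation keeps in-band sinusoids and rejects aliases", {
  expect_equal(downsampleEMG(rep(2.5, 1000)), rep(2.5, 250),
               tolerance = 1e-9)
  t <- seq(0, 10, by = 1e-3)
  y <- downsampleEMG(sin(2 * pi * 10 * t))
  expect_lt(abs(max(abs(y[100:2000])) - 1), 0.02)
  y4 <- downsampleEMG(sin(2 * pi * 400 * t))
  expect_lt(max(abs(y4[100:2000])), 0.01)
  expect_equal(length(downsampleEMG(numeric(1001))), ceiling(1001 / 4))
  expect_error(downsampleEMG(numeric(100), 1000, 300), "integer")
})

test_that("auto threshold is zero on zero baselines and energy-equivariant", {
  expect_equal(autoThreshold(numeric(100))$threshold, 0)
  set.seed(4)
  psi <- smoothEnergy(tkeo(rnorm(5000)), 1000)
  expect_equal(autoThreshold(4 * psi)$threshold,
               4 * autoThreshold(psi)$threshold, tolerance = 1e-12)
  expect_error(autoThreshold(numeric(0)), "empty")
})

test_that("onset detection finds step onsets and reports misses as QC", {
  n <- 8000; rate <- 1000
  zero <- detectOnset(numeric(n), 2, rate, threshold = 1)
  expect_false(zero$detected)
  expect_true(is.na(zero$onset_time_s))

  e <- numeric(n); e[4001:n] <- 10
  det <- detectOnset(e, 2, rate, threshold = 1, minHoldS = 0.05)
  expect_true(det$detected)
  expect_lt(abs(det$onset_time_s - 4.0), 1 / rate + 1e-9)
  expect_gte(det$onset_time_s, det$cue_go_time_s)
})

test_that("session onset detection stays within 20 ms at 6 dB and is quiet on noise", {
  # 6 dB: the burst carrier SD over the initial plateau (0.8 x peak x
  # sqrt(pi/2) scaling) is twice the baseline SD of 2
  p <- groupProfile("HC", emg_peak_uv = 4, emg_noise_sd = 2,
                    band_carrier_sd = c(theta = 0, low_beta = 0,
                                        high_beta = 0),
                    eeg_pink_sd = 0, eeg_white_sd = 0)
  g <- generateSession(p, "S", nTrials = 30, seed = 41, interTrialS = 10)
  on <- detectSessionOnsets(g$session)
  expect_true(all(on$detected))
  err <- 1000 * (on$onset_time_s - g$truth$trials$true_onset_s)
  expect_lte(median(abs(err)), 20)
})

test_that("onset error variance decreases with SNR", {
  vars <- vapply(c(1, 2, 4), function(ratio) {
    p <- groupProfile("HC", emg_peak_uv = ratio * 2, emg_noise_sd = 2,
                      band_carrier_sd = c(theta = 0, low_beta = 0,
                                          high_beta = 0),
                      eeg_pink_sd = 0, eeg_white_sd = 0)
    g <- generateSession(p, "S", nTrials = 25, seed = 43, interTrialS = 10)
    on <- detectSessionOnsets(g$session)
    stats::var(on$onset_time_s - g$truth$trials$true_onset_s, na.rm = TRUE)
  }, 0)
  expect_true(all(diff(vars) < 0))
})

test_that("EMG features read the envelope peak and TA-SOL lag", {
  times <- epochAxis()
  tri <- pmax(0, 500 * (1 - abs(times - 0.4) / 0.3))
  ep <- makeEpochSet(matrix(0, length(times), 1), taEnv = tri,
                     solEnv = c(numeric(30), tri[1:(length(times) - 30)]))
  f <- emgFeatures(ep, 1)
  expect_equal(f$peak_amplitude_uv, 500)
  expect_equal(f$peak_time_ms, 400)
  expect_lt(abs(f$onset_lag_ta_sol_ms - 120), 20)

  epZero <- makeEpochSet(matrix(0, length(times), 1), taEnv = tri)
  fz <- emgFeatures(epZero, 1)
  expect_equal(fz$peak_amplitude_uv, 500)
  expect_true(is.na(fz$onset_lag_ta_sol_ms))

  flat <- makeEpochSet(matrix(0, length(times), 1))
  expect_true(is.na(emgFeatures(flat, 1)$peak_amplitude_uv))
})
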