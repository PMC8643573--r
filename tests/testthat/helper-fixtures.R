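# In-code fixtures: epoch sets and sessions built deterministically.

epochAxis <- function(rate = 250, preS = 4, postS = 4) {
  n <- (preS + postS) * rate
  (seq_len(n) - preS * rate - 1) / rate
}

# Build a TrialEpochSet from a time x trials matrix for one channel
# (default Cz); remaining channels get `fillValue`, EMG envelopes get
# `taEnv`/`solEnv` (time x trials) on the dominant-right side.
makeEpochSet <- function(czData, times = epochAxis(), channel = "Cz",
                         taEnv = NULL, solEnv = NULL, taConEnv = NULL,
                         fillValue = 0, group = "HC") {
  czData <- as.matrix(czData)
  nTr <- ncol(czData)
  mont <- defaultMontage()
  nCh <- length(channelNames(mont))
  eeg <- array(fillValue, c(nCh, length(times), nTr))
  eeg[match(channel, channelNames(mont)), , ] <- czData
  env <- array(0, c(4, length(times), nTr))
  if (!is.null(taEnv)) env[2, , ] <- as.matrix(taEnv)        # TA_right
  if (!is.null(solEnv)) env[4, , ] <- as.matrix(solEnv)      # SOL_right
  if (!is.null(taConEnv)) env[1, , ] <- as.matrix(taConEnv)  # TA_left
  dimnames(eeg) <- list(channelNames(mont), NULL, NULL)
  dimnames(env) <- list(c("TA_left", "TA_right", "SOL_left", "SOL_right"),
                        NULL, NULL)
  new("TrialEpochSet", subjectId = "test", group = group,
      trialIndex = seq_len(nTr), onsetTimes = rep(0, nTr), times = times,
      eeg = eeg, emgEnvelopes = env,
      qcFlags = rep(list(character()), nTr),
      dominantFoot = "right", montage = mont)
}

# Template trials with additive white noise, as time x trials matrix.
templateTrials <- function(nTrials, noiseSd = 0, peak = -16, ns1 = -3,
                           ns2 = -12, rebound = 3, peakTime = 0.4,
                           times = epochAxis(), seed = 1) {
  set.seed(seed)
  tmpl <- mrcpTemplate(times, peak, ns1, ns2, rebound, peakTime)
  sapply(seq_len(nTrials), function(i) tmpl + rnorm(length(times), 0, noiseSd))
}

# Independent single-channel oscillation trials: band carrier with a gain
# step inside `window`, plus pink background. Returns time x trials.
oscTrials <- function(nTrials, rate = 250, low = 9, high = 26, carrierSd = 4,
                      pct = 0, window = c(-1, 0), pinkSd = 2,
                      times = epochAxis(rate), seed = 1) {
  set.seed(seed)
  gain <- ifelse(times >= window[1] & times < window[2],
                 sqrt(1 + pct / 100), 1)
  sapply(seq_len(nTrials), function(i)
    gain * bandCarrier(length(times), rate, low, high, carrierSd) +
      pinkNoise(length(times), pinkSd))
}

# Amplitude of a sinusoid after passing through `fun`, measured on the
# interior half of the signal (frequency-response oracle).
sineGain <- function(fun, freq, rate, durS = 20) {
  t <- seq(0, durS, by = 1 / rate)
  y <- fun(sin(2 * pi * freq * t))
  mid <- y[(length(y) %/% 4):(3 * length(y) %/% 4)]
  max(abs(mid))
}
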