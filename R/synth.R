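# Synthetic cohort generator: every downstream stage is validated against
# the injected ("ground truth") parameters recorded here.

BAND_RANGES <- list(theta = c(4, 8), low_beta = c(13, 20),
                    high_beta = c(21, 35), beta = c(12, 35))

#' 1/f ("pink") noise
#'
#' Colored noise with amplitude spectrum proportional to f^(-1/2)
#' (power ~ 1/f), the minimal realistic background EEG spectrum, scaled to a
#' target standard deviation. Consumes the current RNG stream.
#'
#' @param n number of samples.
#' @param sd target standard deviation.
#' @return numeric vector of length n.
#' @export
pinkNoise <- function(n, sd = 1) {
  if (sd == 0) return(numeric(n))
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  k <- c(1, seq_len(n - 1))           # avoid DC blow-up
  k <- pmin(k, n - k + 1)             # fold to two-sided frequency index
  X <- X / sqrt(k)
  X[1] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  sd * y / stats::sd(y)
}

#' Band-limited Gaussian noise carrier
#'
#' White noise band-passed with a 4th-order zero-phase Butterworth filter and
#' rescaled to a target SD; the carrier for injected oscillatory activity.
#'
#' @param n samples; @param rate sampling rate Hz.
#' @param low,high band corners (Hz).
#' @param sd target standard deviation.
#' @export
bandCarrier <- function(n, rate, low, high, sd = 1) {
  if (sd == 0) return(numeric(n))
  bf <- signal::butter(4, c(low, high) / (rate / 2), type = "pass")
  y <- signal::filtfilt(bf, stats::rnorm(n))
  sd * y / stats::sd(y)
}

#' Piecewise-linear MRCP template
#'
#' The injected slow potential: zero until 3 s before the negative trough, a
#' lead-in ramp, an NS1 segment of slope \code{ns1} over [trough-1.4,
#' trough-0.4] s, an NS2 segment of slope \code{ns2} over the final 0.4 s
#' reaching \code{peak} (microvolts, negative), then recovery at
#' \code{rebound} microvolts/s for 1.5 s and a linear return to zero at 3 s
#' after the trough. Being piecewise linear, the MRCP features have exact
#' analytic values on it.
#'
#' @param times time axis in s, relative to movement onset.
#' @param peak trough amplitude in microvolts (negative).
#' @param ns1,ns2 pre-movement slopes in microvolts/s (negative).
#' @param rebound recovery slope in microvolts/s (positive).
#' @param peakTime trough time relative to onset (s).
#' @return numeric vector over \code{times}.
#' @export
mrcpTemplate <- function(times, peak = -16, ns1 = -3, ns2 = -12,
                         rebound = 3, peakTime = 0.35) {
  v2 <- peak - 0.4 * ns2          # value 0.4 s before the trough
  v1 <- v2 - 1.0 * ns1            # value 1.4 s before the trough
  v4 <- peak + 1.5 * rebound
  knots <- peakTime + c(-3, -1.4, -0.4, 0, 1.5, 3)
  vals <- c(0, v1, v2, peak, v4, 0)
  stats::approx(knots, vals, xout = times, yleft = 0, yright = 0)$y
}

#' Piecewise-linear EMG burst envelope
#'
#' Rises steeply to 80% of the peak within \code{riseS} (abrupt recruitment
#' at movement onset), climbs to the peak at \code{peakTimeS}, and decays
#' linearly to zero at \code{endS} after onset.
#'
#' @param times time axis (s) relative to burst onset.
#' @param peakUv envelope peak in microvolts.
#' @param riseS initial rise time (s).
#' @param peakTimeS time of the envelope peak after onset (s).
#' @param endS burst end after onset (s).
#' @export
burstEnvelope <- function(times, peakUv = 500, riseS = 0.02,
                          peakTimeS = 0.4, endS = 1.5) {
  knots <- c(0, riseS, peakTimeS, endS)
  vals <- peakUv * c(0, 0.8, 1, 0)
  stats::approx(knots, vals, xout = times, yleft = 0, yright = 0)$y
}

#' Group generation profile
#'
#' The injected structure of one participant group: MRCP shape, per-band
#' oscillatory power schedule, EMG burst parameters and artifact settings.
#' Percent changes are realized exactly: inside a scheduled window the band
#' carrier is multiplied by sqrt(1 + pct/100), so the expected band power
#' change equals the requested percentage by construction.
#'
#' @param name group label (HC, PD_noFOG, PD_mildFOG, PD_severeFOG).
#' @param peak_negativity_uv MRCP trough (microvolts, negative).
#' @param ns1_slope_uv_per_s,ns2_slope_uv_per_s pre-movement slopes.
#' @param rebound_rate_uv_per_s post-trough recovery slope.
#' @param mrcp_peak_time_s trough time after movement onset (s).
#' @param oscillation_schedule list of entries, each
#'   \code{list(band = "low_beta", pct = -40, window = c(-1, 1))}; bands are
#'   theta (4-8 Hz), low_beta (13-20), high_beta (21-35); windows are in s
#'   relative to onset; negative pct = desynchronization.
#' @param band_carrier_sd named vector of baseline carrier SDs (microvolts)
#'   for theta, low_beta, high_beta.
#' @param eeg_pink_sd,eeg_white_sd background EEG noise SDs (microvolts).
#' @param emg_peak_uv EMG-TA envelope peak (microvolts).
#' @param emg_onset_delay_mean_s,emg_onset_delay_sd_s movement-onset delay
#'   after the 'go' cue (s).
#' @param ta_sol_lag_mean_s,ta_sol_lag_sd_s SOL burst onset lag after TA (s).
#' @param emg_noise_sd EMG baseline noise SD (microvolts).
#' @param emg_peak_time_s,emg_rise_s,emg_burst_end_s burst envelope shape.
#' @param blink_rate_per_min,blink_amplitude_uv eye-blink artifact settings.
#' @return a list of class \code{GroupProfile}.
#' @export
groupProfile <- function(name,
                         peak_negativity_uv = -16,
                         ns1_slope_uv_per_s = -3,
                         ns2_slope_uv_per_s = -12,
                         rebound_rate_uv_per_s = 3,
                         mrcp_peak_time_s = 0.35,
                         oscillation_schedule = list(),
                         band_carrier_sd = c(theta = 1.5, low_beta = 1.5,
                                             high_beta = 1.5),
                         eeg_pink_sd = 2, eeg_white_sd = 0.5,
                         emg_peak_uv = 500,
                         emg_onset_delay_mean_s = 0.5,
                         emg_onset_delay_sd_s = 0.1,
                         ta_sol_lag_mean_s = 0.05,
                         ta_sol_lag_sd_s = 0.02,
                         emg_noise_sd = 5,
                         emg_peak_time_s = 0.4,
                         emg_rise_s = 0.02,
                         emg_burst_end_s = 1.5,
                         blink_rate_per_min = 0,
                         blink_amplitude_uv = 150) {
  stopifnot(name %in% GROUP_LEVELS,
            emg_onset_delay_sd_s >= 0, ta_sol_lag_sd_s >= 0)
  for (entry in oscillation_schedule)
    if (!entry$band %in% c("theta", "low_beta", "high_beta"))
      stop("unknown band in oscillation schedule: ", entry$band)
  p <- as.list(environment())
  class(p) <- "GroupProfile"
  p
}

#' Default group profiles
#'
#' Four profiles whose injected MRCP features and band schedules
#' qualitatively mirror the clinical contrasts the pipeline is meant to
#' resolve: healthy controls with the strongest early negativity and beta
#' desynchronization, freezers with flattened NS1, attenuated (mild) or
#' absent (severe) low-beta ERD, and added pre-movement theta
#' synchronization, plus a delayed soleus onset in severe freezers. These
#' are test parameters for the generator, not claims about any cohort.
#'
#' @return named list of \code{GroupProfile}s.
#' @export
defaultGroupProfiles <- function() {
  list(
    HC = groupProfile("HC",
      peak_negativity_uv = -16.1, ns1_slope_uv_per_s = -3.0,
      ns2_slope_uv_per_s = -12.8, rebound_rate_uv_per_s = 3.4,
      emg_peak_uv = 946.5,
      oscillation_schedule = list(
        list(band = "low_beta", pct = -40, window = c(-1, 1)),
        list(band = "high_beta", pct = -30, window = c(-2, 1.5)),
        list(band = "low_beta", pct = 20, window = c(2.5, 4)))),
    PD_noFOG = groupProfile("PD_noFOG",
      peak_negativity_uv = -10.5, ns1_slope_uv_per_s = -1.7,
      ns2_slope_uv_per_s = -10.5, rebound_rate_uv_per_s = 2.8,
      emg_peak_uv = 737.3,
      oscillation_schedule = list(
        list(band = "low_beta", pct = -20, window = c(-1, 1)),
        list(band = "high_beta", pct = -15, window = c(-2, 1.5)))),
    PD_mildFOG = groupProfile("PD_mildFOG",
      peak_negativity_uv = -13.6, ns1_slope_uv_per_s = -1.0,
      ns2_slope_uv_per_s = -13.2, rebound_rate_uv_per_s = 1.2,
      emg_peak_uv = 825.5,
      oscillation_schedule = list(
        list(band = "theta", pct = 15, window = c(-2, 0)),
        list(band = "low_beta", pct = -5, window = c(-1, 1)),
        list(band = "high_beta", pct = -20, window = c(-2, 1.5)))),
    PD_severeFOG = groupProfile("PD_severeFOG",
      peak_negativity_uv = -13.7, ns1_slope_uv_per_s = -0.6,
      ns2_slope_uv_per_s = -18.6, rebound_rate_uv_per_s = 2.5,
      emg_peak_uv = 512,
      ta_sol_lag_mean_s = 0.15, ta_sol_lag_sd_s = 0.05,
      oscillation_schedule = list(
        list(band = "theta", pct = 25, window = c(-2, 0.5)),
        list(band = "high_beta", pct = -10, window = c(0, 1.5))))
  )
}

mrcpSpatialWeights <- function(montage) {
  w <- c(FP1 = 0.1, FP2 = 0.1, AF3 = 0.15, AF4 = 0.15,
         F3 = 0.3, Fz = 0.6, F4 = 0.3, FC1 = 0.8, FC2 = 0.8,
         C3 = 0.55, Cz = 1.0, C4 = 0.55, CP1 = 0.5, CP2 = 0.5,
         P3 = 0.25, Pz = 0.4, P4 = 0.25)
  w[channelNames(montage)]
}

#' Generate one synthetic session
#'
#' One subject's raw recording: 17-channel EEG at 250 Hz (1/f + white
#' background, band-limited oscillation carriers with scheduled ERD/ERS
#' envelopes, a spatially weighted piecewise-linear MRCP per trial, optional
#' blink artifacts) and 4-channel EMG at 1000 Hz (baseline noise plus
#' amplitude-modulated 20-120 Hz bursts on the dominant leg starting at the
#' true onset, soleus lagging tibialis anterior). Fully deterministic under
#' a fixed seed.
#'
#' @param profile a \code{GroupProfile}.
#' @param subjectId subject identifier.
#' @param nTrials number of cue pairs (>= 1).
#' @param seed integer seed.
#' @param dominantFoot "left" or "right".
#' @param interTrialS spacing between 'ready' cues (s, >= 10).
#' @param preRollS recording before the first 'ready' cue (s).
#' @param postRollS recording after the last trial (s).
#' @param eegRate,emgRate sampling rates (Hz).
#' @param montage the \linkS4class{Montage}.
#' @return list with elements \code{session} (\linkS4class{RawSession}) and
#'   \code{truth} (data.frames \code{trials}, \code{blinks}).
#' @export
generateSession <- function(profile, subjectId = "S01", nTrials = 15,
                            seed = 1, dominantFoot = "right",
                            interTrialS = 15, preRollS = 20, postRollS = 10,
                            eegRate = 250, emgRate = 1000,
                            montage = defaultMontage()) {
  if (nTrials < 1) stop("nTrials must be >= 1")
  if (interTrialS < 10) stop("inter-trial spacing must be >= 10 s")
  set.seed(seed)
  durS <- ceiling(preRollS + (nTrials - 1) * interTrialS + 2 + postRollS)
  nE <- durS * eegRate
  nM <- durS * emgRate
  tE <- (seq_len(nE) - 1) / eegRate
  tM <- (seq_len(nM) - 1) / emgRate

  ready <- preRollS + (seq_len(nTrials) - 1) * interTrialS
  go <- ready + 2
  delay <- pmax(0.05, stats::rnorm(nTrials, profile$emg_onset_delay_mean_s,
                                   profile$emg_onset_delay_sd_s))
  onset <- go + delay
  solLag <- pmax(0, stats::rnorm(nTrials, profile$ta_sol_lag_mean_s,
                                 profile$ta_sol_lag_sd_s))

  # shared MRCP time course, scaled per channel below
  mrcpSig <- numeric(nE)
  for (i in seq_len(nTrials))
    mrcpSig <- mrcpSig + mrcpTemplate(
      tE - onset[i], peak = profile$peak_negativity_uv,
      ns1 = profile$ns1_slope_uv_per_s, ns2 = profile$ns2_slope_uv_per_s,
      rebound = profile$rebound_rate_uv_per_s,
      peakTime = profile$mrcp_peak_time_s)

  # per-band gain schedule (shared across channels; carriers independent)
  gains <- list()
  for (band in names(BAND_RANGES)[1:3]) {
    g <- rep(1, nE)
    # pad the scheduled window by ~2.5 time-SDs of a five-cycle wavelet at
    # the band centre, so a wavelet reading of the nominal window sees
    # modulated carrier across its full temporal smearing
    fc <- mean(BAND_RANGES[[band]])
    tPad <- 2.5 * 5 / (2 * pi * fc)
    for (entry in profile$oscillation_schedule) {
      if (entry$band != band) next
      for (i in seq_len(nTrials)) {
        idx <- which(tE >= onset[i] + entry$window[1] - tPad &
                     tE < onset[i] + entry$window[2] + tPad)
        g[idx] <- g[idx] * sqrt(1 + entry$pct / 100)
      }
    }
    gains[[band]] <- g
  }

  w <- mrcpSpatialWeights(montage)
  nCh <- length(channelNames(montage))
  eeg <- matrix(0, nCh, nE)
  for (ch in seq_len(nCh)) {
    x <- pinkNoise(nE, profile$eeg_pink_sd) +
      stats::rnorm(nE, sd = profile$eeg_white_sd) +
      w[ch] * mrcpSig
    for (band in names(gains)) {
      bsd <- profile$band_carrier_sd[[band]]
      if (is.null(bsd) || bsd == 0) next
      rng <- BAND_RANGES[[band]]
      # pad the carrier band by ~2.5 spectral SDs of a five-cycle wavelet at
      # each edge, so a wavelet analysis of the nominal band sees modulated
      # carrier across its full integration bandwidth
      lowC <- max(0.5, rng[1] * (1 - 2.5 / 5))
      highC <- min(0.95 * eegRate / 2, rng[2] * (1 + 2.5 / 5))
      x <- x + gains[[band]] * bandCarrier(nE, eegRate, lowC, highC, bsd)
    }
    eeg[ch, ] <- x
  }

  emg <- matrix(stats::rnorm(4 * nM, sd = profile$emg_noise_sd), 4, nM)
  rownames(emg) <- EMG_CHANNELS
  side <- dominantFoot
  taRow <- if (side == "left") "TA_left" else "TA_right"
  solRow <- if (side == "left") "SOL_left" else "SOL_right"
  envScale <- sqrt(pi / 2)   # rectified-mean of unit-SD Gaussian = sqrt(2/pi)
  taEnv <- numeric(nM); solEnv <- numeric(nM)
  for (i in seq_len(nTrials)) {
    taEnv <- taEnv + burstEnvelope(tM - onset[i], profile$emg_peak_uv,
                                   profile$emg_rise_s,
                                   profile$emg_peak_time_s,
                                   profile$emg_burst_end_s)
    solEnv <- solEnv + burstEnvelope(tM - onset[i] - solLag[i],
                                     0.8 * profile$emg_peak_uv,
                                     profile$emg_rise_s,
                                     profile$emg_peak_time_s,
                                     profile$emg_burst_end_s)
  }
  emg[taRow, ] <- emg[taRow, ] +
    envScale * taEnv * bandCarrier(nM, emgRate, 20, 120, 1)
  emg[solRow, ] <- emg[solRow, ] +
    envScale * solEnv * bandCarrier(nM, emgRate, 20, 120, 1)

  session <- rawSession(subjectId, profile$name, side, eeg, emg,
                        data.frame(ready_s = ready, go_s = go),
                        eegRate, emgRate, montage)
  blinks <- data.frame(subject_id = character(), time_s = numeric())
  if (profile$blink_rate_per_min > 0 && profile$blink_amplitude_uv != 0) {
    bl <- injectBlinks(session, profile$blink_rate_per_min,
                       profile$blink_amplitude_uv,
                       seed = seed + 1L)
    session <- bl$session
    if (nrow(bl$blinks))
      blinks <- data.frame(subject_id = subjectId, time_s = bl$blinks$time_s)
  }

  trials <- data.frame(
    subject_id = subjectId, group = profile$name,
    trial = seq_len(nTrials),
    ready_s = ready, go_s = go, true_onset_s = onset,
    peak_negativity_uv = profile$peak_negativity_uv,
    ns1_uv_per_s = profile$ns1_slope_uv_per_s,
    ns2_uv_per_s = profile$ns2_slope_uv_per_s,
    rebound_uv_per_s = profile$rebound_rate_uv_per_s,
    mrcp_peak_time_s = profile$mrcp_peak_time_s,
    emg_peak_uv = profile$emg_peak_uv,
    emg_peak_time_s = profile$emg_peak_time_s,
    ta_sol_lag_s = solLag,
    seed = seed)
  list(session = session, truth = list(trials = trials, blinks = blinks))
}

#' Inject stereotyped eye blinks
#'
#' Adds ~0.3 s raised-cosine low-frequency transients with a
#' frontal-dominant spatial pattern (maximal at FP1/FP2) at Poisson-process
#' times. With rate or amplitude zero the session is returned unchanged.
#'
#' @param session a \linkS4class{RawSession}.
#' @param ratePerMin expected blinks per minute (>= 0).
#' @param amplitudeUv blink peak at FP1/FP2 (microvolts).
#' @param seed integer seed.
#' @return list with \code{session} (modified copy) and \code{blinks}
#'   (data.frame of blink times).
#' @export
injectBlinks <- function(session, ratePerMin, amplitudeUv = 150, seed = 1) {
  if (ratePerMin < 0) stop("blink rate must be >= 0")
  blinks <- data.frame(time_s = numeric())
  if (ratePerMin == 0 || amplitudeUv == 0)
    return(list(session = session, blinks = blinks))
  set.seed(seed)
  rate <- eegRate(session)
  n <- ncol(eegData(session))
  durS <- n / rate
  count <- stats::rpois(1, ratePerMin / 60 * durS)
  if (count == 0) return(list(session = session, blinks = blinks))
  times <- sort(stats::runif(count, 0.5, durS - 0.5))
  width <- 0.3
  wSpat <- c(FP1 = 1, FP2 = 1, AF3 = 0.6, AF4 = 0.6,
             F3 = 0.3, Fz = 0.3, F4 = 0.3, FC1 = 0.12, FC2 = 0.12,
             C3 = 0.05, Cz = 0.05, C4 = 0.05, CP1 = 0.03, CP2 = 0.03,
             P3 = 0.02, Pz = 0.02, P4 = 0.02)
  wSpat <- wSpat[channelNames(montage(session))]
  eeg <- eegData(session)
  shape <- amplitudeUv * sin(pi * seq(0, 1, length.out = round(width * rate)))^2
  for (tb in times) {
    i0 <- round(tb * rate) + 1
    idx <- i0:(i0 + length(shape) - 1)
    ok <- idx >= 1 & idx <= n
    eeg[, idx[ok]] <- eeg[, idx[ok]] + outer(wSpat, shape[ok])
  }
  out <- session
  out@eeg <- eeg
  list(session = out, blinks = data.frame(time_s = times))
}

#' Generate a multi-subject cohort with ground truth
#'
#' Generates \code{nSubjectsPerGroup} sessions for every profile, each with
#' \code{nTrials} ready/go cue pairs, and assembles the
#' \linkS4class{GroundTruth} record of all injected parameters.
#' Deterministic at the cohort level: the same seed reproduces every session
#' bit-exactly.
#'
#' @param profiles list of \code{GroupProfile}s (default
#'   [defaultGroupProfiles()]).
#' @param nSubjectsPerGroup subjects per profile (>= 1).
#' @param nTrials trials per subject (>= 1; 15 emulates one recording
#'   session).
#' @param seed integer cohort seed.
#' @param dominantFootProb probability a subject is right-foot dominant.
#' @param ... passed to [generateSession()] (timing, rates, montage).
#' @return list with \code{sessions} (list of \linkS4class{RawSession}) and
#'   \code{truth} (\linkS4class{GroundTruth}).
#' @export
generateCohort <- function(profiles = defaultGroupProfiles(),
                           nSubjectsPerGroup = 3, nTrials = 15, seed = 1,
                           dominantFootProb = 0.8, ...) {
  if (nSubjectsPerGroup < 1 || nTrials < 1)
    stop("counts must be positive")
  set.seed(seed)
  nTot <- length(profiles) * nSubjectsPerGroup
  subSeeds <- sample.int(.Machine$integer.max - 1L, nTot)
  feet <- ifelse(stats::runif(nTot) < dominantFootProb, "right", "left")
  sessions <- list()
  trialTabs <- list(); blinkTabs <- list(); schedTabs <- list()
  k <- 0
  for (profile in profiles) {
    for (s in seq_len(nSubjectsPerGroup)) {
      k <- k + 1
      sid <- sprintf("%s_%02d", profile$name, s)
      g <- generateSession(profile, subjectId = sid, nTrials = nTrials,
                           seed = subSeeds[k], dominantFoot = feet[k], ...)
      sessions[[sid]] <- g$session
      trialTabs[[k]] <- g$truth$trials
      blinkTabs[[k]] <- g$truth$blinks
      if (length(profile$oscillation_schedule))
        schedTabs[[k]] <- do.call(rbind, lapply(
          profile$oscillation_schedule, function(e)
            data.frame(subject_id = sid, band = e$band, pct = e$pct,
                       window_start_s = e$window[1],
                       window_end_s = e$window[2])))
    }
  }
  truth <- new("GroundTruth",
               trials = do.call(rbind, trialTabs),
               schedules = if (length(schedTabs))
                 do.call(rbind, schedTabs) else
                 data.frame(subject_id = character(), band = character(),
                            pct = numeric(), window_start_s = numeric(),
                            window_end_s = numeric()),
               blinks = do.call(rbind, blinkTabs),
               profiles = profiles, seed = as.integer(seed))
  list(sessions = sessions, truth = truth)
}
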