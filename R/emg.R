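# EMG conditioning, Teager-Kaiser energy, movement-onset detection and
# EMG burst features.

#' Band-pass filter EMG (20-120 Hz, zero phase)
#'
#' Second-order Butterworth band-pass with 20 and 120 Hz corners applied
#' forward and backward (zero phase). Output length equals input length.
#'
#' @param x numeric vector.
#' @param rateHz sampling rate; must exceed 240 Hz so the upper corner is
#'   below Nyquist.
#' @export
bandpassEMG <- function(x, rateHz) {
  if (rateHz <= 240) stop("sampling rate too low for the 120 Hz corner")
  bf <- signal::butter(2, c(20, 120) / (rateHz / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Anti-aliased decimation
#'
#' Integer-ratio downsampling (default 1000 Hz -> 250 Hz) with the
#' anti-aliasing low-pass of \code{signal::decimate}.
#'
#' @param x numeric vector.
#' @param fromHz,toHz source and target rates; fromHz must be an integer
#'   multiple of toHz.
#' @export
downsampleEMG <- function(x, fromHz = 1000, toHz = 250) {
  q <- fromHz / toHz
  if (abs(q - round(q)) > 1e-9) stop("rate ratio must be an integer")
  # mean-centre so the anti-aliasing filter's edge transient does not act
  # on the DC offset
  m <- mean(x)
  as.numeric(signal::decimate(x - m, round(q), ftype = "iir")) + m
}

#' Teager-Kaiser energy operator
#'
#' The discrete operator \eqn{\psi[n] = x[n]^2 - x[n-1] x[n+1]}, computed for
#' interior samples with the endpoints set to zero. For a sinusoid
#' \eqn{A\sin(\omega n)} it is the constant \eqn{A^2 \sin^2\omega}; it is
#' homogeneous of degree two, \eqn{\psi(a x) = a^2 \psi(x)}, and vanishes on
#' constants.
#'
#' @param x numeric vector, length >= 3.
#' @return numeric vector the same length as \code{x}.
#' @export
tkeo <- function(x) {
  n <- length(x)
  if (n < 3) stop("tkeo needs at least 3 samples")
  psi <- numeric(n)
  psi[2:(n - 1)] <- x[2:(n - 1)]^2 - x[1:(n - 2)] * x[3:n]
  psi
}

#' Moving-average smoothing of an energy series
#'
#' Centered moving average over \code{windowS} seconds (default 50 ms), used
#' to suppress isolated spikes in the Teager-Kaiser energy before
#' thresholding.
#'
#' @param energy numeric vector.
#' @param rateHz sampling rate (Hz).
#' @param windowS window length (s).
#' @export
smoothEnergy <- function(energy, rateHz, windowS = 0.05) {
  w <- max(1, round(windowS * rateHz))
  as.numeric(stats::filter(energy, rep(1 / w, w), sides = 2)) ->
    sm
  sm[is.na(sm)] <- energy[is.na(sm)]
  sm
}

#' Robust automatic energy threshold
#'
#' Replaces per-subject manual threshold selection with a reproducible rule:
#' threshold = median + k * MAD of the pre-cue baseline of the smoothed
#' energy series (k = 8 by default). Both statistics are affinely
#' equivariant, so scaling the signal by \code{a} scales the threshold by
#' \code{a^2}, consistent with the energy operator's homogeneity.
#'
#' @param energyBaseline smoothed energy samples from the pre-'ready'
#'   baseline (>= 0.5 s of data recommended).
#' @param k multiplier on the MAD (default 8).
#' @return list with \code{threshold}, \code{median}, \code{mad}.
#' @export
autoThreshold <- function(energyBaseline, k = 8) {
  if (!length(energyBaseline)) stop("empty baseline")
  med <- stats::median(energyBaseline)
  md <- stats::mad(energyBaseline)
  list(threshold = med + k * md, median = med, mad = md)
}

#' Detect movement onset in an energy series
#'
#' Finds the first time after the 'go' cue at which the smoothed energy
#' stays above the threshold for at least \code{minHoldS}, then backtracks
#' to the preceding up-crossing of the baseline median so that the reported
#' onset marks where the energy left baseline rather than where it cleared
#' the (deliberately conservative) threshold. An absent crossing is a QC
#' outcome (\code{detected = FALSE}), not an error.
#'
#' @param energy smoothed energy series (e.g. [smoothEnergy()] of
#'   [tkeo()]).
#' @param goTimeS 'go' cue time (s from series start).
#' @param rateHz sampling rate (Hz).
#' @param threshold detection threshold (energy units, > 0 unless the
#'   baseline is identically zero).
#' @param minHoldS minimum supra-threshold duration (s, default 50 ms).
#' @param searchEndS end of the search window (s; default 4 s after go).
#' @param refine optional backtracking refinement: a list with
#'   \code{energy} (a lightly smoothed energy series on the same axis) and
#'   \code{level} (its baseline level, e.g. median + 2 MAD). From the
#'   conservative crossing the onset is walked back while the refined
#'   energy stays above the level, so the reported onset marks where the
#'   energy left baseline rather than where it cleared the 8-MAD
#'   threshold.
#' @return data.frame row: \code{onset_time_s}, \code{detected},
#'   \code{threshold_used}, \code{cue_go_time_s}.
#' @export
detectOnset <- function(energy, goTimeS, rateHz, threshold,
                        minHoldS = 0.05, searchEndS = goTimeS + 4,
                        refine = NULL) {
  i0 <- max(1L, round(goTimeS * rateHz) + 1L)
  i1 <- min(length(energy), round(searchEndS * rateHz) + 1L)
  hold <- max(1L, round(minHoldS * rateHz))
  seg <- energy[i0:i1]
  above <- seg > threshold
  # run length of consecutive TRUEs ending at each sample
  run <- Reduce(function(acc, a) if (a) acc + 1L else 0L, above,
                accumulate = TRUE)
  hit <- which(run >= hold)
  if (!length(hit))
    return(data.frame(onset_time_s = NA_real_, detected = FALSE,
                      threshold_used = threshold, cue_go_time_s = goTimeS))
  onsetIdx <- i0 + (hit[1] - hold)      # first sample of the hold run
  if (!is.null(refine)) {
    while (onsetIdx > i0 && refine$energy[onsetIdx - 1] > refine$level)
      onsetIdx <- onsetIdx - 1
  }
  data.frame(onset_time_s = (onsetIdx - 1) / rateHz, detected = TRUE,
             threshold_used = threshold, cue_go_time_s = goTimeS)
}

#' Detect all movement onsets of a session
#'
#' Full per-subject onset pipeline on the dominant-leg TA channel at the
#' native 1000 Hz EMG rate: 20-120 Hz band-pass, Teager-Kaiser energy,
#' 50 ms moving-average smoothing, one automatic threshold per subject from
#' the concatenated pre-'ready' baselines (median + k MAD), then per-trial
#' detection after each 'go' cue.
#'
#' @param session a \linkS4class{RawSession}.
#' @param k MAD multiplier for [autoThreshold()].
#' @param minHoldS minimum supra-threshold hold (s).
#' @param baselineS length of the pre-'ready' baseline per trial (s).
#' @param thresholdOverride optional manual threshold replacing the
#'   automatic one.
#' @return data.frame, one row per trial: \code{subject_id}, \code{trial},
#'   \code{onset_time_s}, \code{detected}, \code{threshold_used},
#'   \code{cue_go_time_s}.
#' @export
detectSessionOnsets <- function(session, k = 8, minHoldS = 0.05,
                                baselineS = 2, thresholdOverride = NULL) {
  rate <- emgRate(session)
  ta <- if (dominantFoot(session) == "left") "TA_left" else "TA_right"
  x <- emgData(session)[ta, ]
  raw <- tkeo(bandpassEMG(x, rate))
  energy <- smoothEnergy(raw, rate)
  fine <- smoothEnergy(raw, rate, windowS = 0.01)
  cues <- cueTimes(session)
  basIdx <- unlist(lapply(cues$ready_s, function(r) {
    j0 <- max(1L, round((r - baselineS) * rate) + 1L)
    j1 <- max(1L, round(r * rate))
    j0:j1
  }))
  thr <- autoThreshold(energy[basIdx], k = k)
  fineLevel <- stats::median(fine[basIdx]) + 2 * stats::mad(fine[basIdx])
  threshold <- if (is.null(thresholdOverride)) thr$threshold else
    thresholdOverride
  rows <- lapply(seq_len(nrow(cues)), function(i) {
    det <- detectOnset(energy, cues$go_s[i], rate, threshold,
                       minHoldS = minHoldS,
                       refine = list(energy = fine, level = fineLevel))
    cbind(subject_id = subjectId(session), trial = i, det)
  })
  do.call(rbind, rows)
}

#' Rectified low-pass EMG envelope
#'
#' Band-passes (20-120 Hz), full-wave rectifies and low-passes (6 Hz,
#' zero-phase 2nd-order Butterworth) an EMG channel. This is the envelope on
#' which burst peak amplitude (microvolts) and peak time are measured;
#' normalization to the TA peak is a plotting concern only.
#'
#' @param x raw EMG vector.
#' @param rateHz sampling rate (Hz).
#' @param bandpassed set TRUE if \code{x} is already 20-120 Hz filtered.
#' @export
emgEnvelope <- function(x, rateHz, bandpassed = FALSE) {
  if (!bandpassed) x <- bandpassEMG(x, rateHz)
  lf <- signal::butter(2, 6 / (rateHz / 2), type = "low")
  env <- as.numeric(signal::filtfilt(lf, abs(x)))
  pmax(env, 0)
}

#' EMG burst features of one epoch
#'
#' Peak amplitude (microvolts) and peak time (ms from onset) of the
#' dominant-leg TA envelope within [0, 4] s after movement onset, and the
#' SOL-minus-TA burst onset lag (ms) from each muscle's own crossing of half
#' its peak-to-baseline excursion. Flat envelopes yield missing features
#' rather than errors.
#'
#' @param epochs a \linkS4class{TrialEpochSet}.
#' @param trial trial position within the set.
#' @return data.frame row: \code{peak_amplitude_uv}, \code{peak_time_ms},
#'   \code{onset_lag_ta_sol_ms}.
#' @export
emgFeatures <- function(epochs, trial) {
  times <- epochTimes(epochs)
  side <- dominantFoot(epochs)
  ta <- epochs@emgEnvelopes[if (side == "left") "TA_left" else "TA_right", ,
                            trial]
  sol <- epochs@emgEnvelopes[if (side == "left") "SOL_left" else "SOL_right",
                             , trial]
  win <- times >= 0 & times <= 4
  if (max(ta[win]) - min(ta[win]) < 1e-9)
    return(data.frame(peak_amplitude_uv = NA_real_, peak_time_ms = NA_real_,
                      onset_lag_ta_sol_ms = NA_real_))
  pk <- which.max(ta * win)
  peakUv <- ta[pk]
  peakMs <- times[pk] * 1000

  burstOnset <- function(env) {
    # first crossing of half the excursion above the pre-go baseline level
    base <- stats::median(env[times < -0.5])
    half <- base + 0.5 * (max(env[win]) - base)
    if (max(env[win]) - base < 1e-9) return(NA_real_)
    idx <- which(env > half & times >= -0.5 & times <= 4)
    if (!length(idx)) return(NA_real_)
    times[idx[1]]
  }
  lagMs <- 1000 * (burstOnset(sol) - burstOnset(ta))
  data.frame(peak_amplitude_uv = peakUv, peak_time_ms = peakMs,
             onset_lag_ta_sol_ms = lagMs)
}
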