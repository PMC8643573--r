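# Single-trial MRCP features, outlier rule, grand averages, coefficient of
# variation, and topographic time-series values.
#
# Amplitudes at offsets (peak - 1.4 s etc.) are read at the nearest sample;
# at 250 Hz the 4 ms resolution is far below the feature time scales.

nearestIdx <- function(times, t) which.min(abs(times - t))

# outlier rule applied to the epoch-wide minimum over the 'Go' window:
# the feature search window [-1, 1.5] s lies inside the rejection window
# [-1.5, 2] s, so the rule must look at the unrestricted trough location
isOutlierTrial <- function(x, times) {
  pk <- peakNegativity(x, times, window = c(-2, 4))
  flagOutlier(pk$time_ms)
}

#' Peak negativity of one epoch channel
#'
#' The lowest value in the closed search window \eqn{[-1, 1.5]} s relative
#' to movement onset, with ties broken by the earliest time.
#'
#' @param x numeric vector, one channel of one epoch.
#' @param times epoch time axis (s, relative to onset).
#' @param window search window (s), default c(-1, 1.5).
#' @return list with \code{amplitude_uv} and \code{time_ms}.
#' @export
peakNegativity <- function(x, times, window = c(-1, 1.5)) {
  sel <- which(times >= window[1] & times <= window[2])
  i <- sel[which.min(x[sel])]        # which.min takes the first minimum
  list(amplitude_uv = x[i], time_ms = times[i] * 1000)
}

#' Early pre-movement slope NS1
#'
#' Amplitude difference between 0.4 s and 1.4 s before the peak negativity,
#' divided by 1 s; negative when the potential grows more negative toward
#' the peak.
#'
#' @param x epoch channel vector; @param times time axis (s).
#' @param peakTimeS peak-negativity time in s (relative to onset).
#' @return slope in microvolts/s.
#' @export
ns1 <- function(x, times, peakTimeS) {
  (x[nearestIdx(times, peakTimeS - 0.4)] -
     x[nearestIdx(times, peakTimeS - 1.4)]) / 1.0
}

#' Late pre-movement slope NS2
#'
#' Difference between the peak amplitude and the amplitude 0.4 s before the
#' peak, divided by 0.4 s.
#'
#' @inheritParams ns1
#' @param peakAmplitudeUv the peak-negativity amplitude (microvolts).
#' @export
ns2 <- function(x, times, peakTimeS, peakAmplitudeUv) {
  (peakAmplitudeUv - x[nearestIdx(times, peakTimeS - 0.4)]) / 0.4
}

#' Post-peak rebound rate
#'
#' Amplitude 1.5 s after the peak minus the peak amplitude, divided by
#' 1.5 s; positive for recovery toward baseline. If the epoch does not
#' extend 1.5 s past the peak the feature is missing (NA), not an error.
#'
#' @inheritParams ns2
#' @export
reboundRate <- function(x, times, peakTimeS, peakAmplitudeUv) {
  target <- peakTimeS + 1.5
  if (target > max(times) + 1e-9) return(NA_real_)
  (x[nearestIdx(times, target)] - peakAmplitudeUv) / 1.5
}

#' MRCP outlier rule
#'
#' A trial is an outlier when its peak-negativity time falls outside the
#' closed interval \eqn{[-1.5, 2]} s relative to movement onset.
#'
#' @param peakTimeMs peak time in ms.
#' @return logical.
#' @export
flagOutlier <- function(peakTimeMs) {
  peakTimeMs < -1500 | peakTimeMs > 2000
}

#' MRCP-to-EMG latency
#'
#' Peak-negativity time minus EMG-TA envelope peak time, in ms; negative
#' when the cortical peak precedes the muscular peak.
#'
#' @param peakTimeMs MRCP peak time (ms).
#' @param emgPeakTimeMs EMG-TA envelope peak time (ms).
#' @export
latencyMrcpEmg <- function(peakTimeMs, emgPeakTimeMs) {
  peakTimeMs - emgPeakTimeMs
}

#' Single-trial MRCP + EMG feature table
#'
#' Computes the five MRCP features (peak negativity, peak time, NS1, NS2,
#' rebound rate) on the requested channel, the EMG burst features, the
#' MRCP-EMG latency and the outlier flag for every trial of an epoch set.
#'
#' @param epochs a \linkS4class{TrialEpochSet} from the slow-potential path.
#' @param channel feature channel (default "Cz", over M1).
#' @return data.frame, one row per trial.
#' @export
mrcpFeatures <- function(epochs, channel = "Cz") {
  times <- epochTimes(epochs)
  rows <- lapply(seq_len(nTrials(epochs)), function(j) {
    x <- epochChannel(epochs, channel, j)
    pk <- peakNegativity(x, times)
    peakS <- pk$time_ms / 1000
    emg <- emgFeatures(epochs, j)
    data.frame(
      subject_id = subjectId(epochs), group = groupLabel(epochs),
      trial = epochs@trialIndex[j], channel = channel,
      peak_negativity_uv = pk$amplitude_uv,
      peak_time_ms = pk$time_ms,
      ns1_uv_per_s = ns1(x, times, peakS),
      ns2_uv_per_s = ns2(x, times, peakS, pk$amplitude_uv),
      rebound_uv_per_s = reboundRate(x, times, peakS, pk$amplitude_uv),
      emg_peak_uv = emg$peak_amplitude_uv,
      emg_peak_time_ms = emg$peak_time_ms,
      ta_sol_lag_ms = emg$onset_lag_ta_sol_ms,
      latency_mrcp_emg_ms = latencyMrcpEmg(pk$time_ms, emg$peak_time_ms),
      outlier = isOutlierTrial(x, times))
  })
  do.call(rbind, rows)
}

#' Grand-average waveform
#'
#' Pointwise mean and SD across the non-outlier trials of one channel.
#'
#' @param epochs a \linkS4class{TrialEpochSet}.
#' @param channel channel label.
#' @param excludeOutliers drop trials failing the peak-time rule.
#' @param smoothS optional moving-average window (s) applied to the mean
#'   waveform. Reading a pointwise minimum off a noisy average is biased
#'   downward (an extreme-value effect); a light smoothing (e.g. 0.04 s)
#'   removes most of that bias when features are taken from the average.
#' @return list with \code{times}, \code{mean}, \code{sd}, \code{n}.
#' @export
grandAverage <- function(epochs, channel = "Cz", excludeOutliers = TRUE,
                         smoothS = 0) {
  m <- epochChannel(epochs, channel)
  if (excludeOutliers && ncol(m) > 0) {
    keep <- !vapply(seq_len(ncol(m)), function(j)
      isOutlierTrial(m[, j], epochTimes(epochs)), TRUE)
    m <- m[, keep, drop = FALSE]
  }
  n <- ncol(m)
  mu <- rowMeans(m)
  times <- epochTimes(epochs)
  if (smoothS > 0) {
    rate <- 1 / diff(times[1:2])
    mu <- smoothEnergy(mu, rate, smoothS)
  }
  list(times = times, mean = mu,
       sd = if (n > 1) apply(m, 1, stats::sd) else numeric(nrow(m)) * 0,
       n = n)
}

#' Coefficient of variation of a channel's trial ensemble
#'
#' Temporal-consistency index: the across-trial SD divided by the
#' across-trial mean, aggregated as the mean of
#' SD(t) / max(|mean(t)|, epsilon) over the 'Go' window \eqn{[-2, 4)} s.
#' The epsilon floor (default 0.1 microvolt) prevents blow-up where the
#' mean waveform crosses zero. Alternative conventions (CoV of per-trial
#' peak amplitudes or of peak times) are available via \code{method}.
#'
#' @param epochs a \linkS4class{TrialEpochSet} (>= 2 non-outlier trials).
#' @param channel channel label.
#' @param method "waveform" (default), "peak_amplitude" or "peak_time".
#' @param eps floor on |mean| in microvolts (waveform method).
#' @param window aggregation window in s (waveform method).
#' @return a single non-negative number.
#' @export
coefficientOfVariation <- function(epochs, channel = "Cz",
                                   method = c("waveform", "peak_amplitude",
                                              "peak_time"),
                                   eps = 0.1, window = c(-2, 4)) {
  method <- match.arg(method)
  times <- epochTimes(epochs)
  m <- epochChannel(epochs, channel)
  keep <- !vapply(seq_len(ncol(m)), function(j)
    isOutlierTrial(m[, j], times), TRUE)
  m <- m[, keep, drop = FALSE]
  if (ncol(m) < 2) stop("need >= 2 non-outlier trials")
  if (method == "waveform") {
    sel <- times >= window[1] & times < window[2]
    mu <- rowMeans(m[sel, , drop = FALSE])
    s <- apply(m[sel, , drop = FALSE], 1, stats::sd)
    return(mean(s / pmax(abs(mu), eps)))
  }
  pk <- vapply(seq_len(ncol(m)), function(j) {
    p <- peakNegativity(m[, j], times)
    if (method == "peak_amplitude") p$amplitude_uv else p$time_ms
  }, 0)
  stats::sd(pk) / max(abs(mean(pk)), 1e-12)
}

#' Topographic time-series table
#'
#' Grand-average amplitude of every channel at the requested time points
#' (default 13 points from -2 to 4 s in 0.5 s steps); scalp-map rendering is
#' a thin plotting layer over this table.
#'
#' @param epochs a \linkS4class{TrialEpochSet}.
#' @param times time points (s relative to onset).
#' @param excludeOutliers drop trials failing the peak-time rule (applied
#'   per the feature channel Cz).
#' @return numeric matrix channels x time points.
#' @export
topoSeries <- function(epochs, times = seq(-2, 4, by = 0.5),
                       excludeOutliers = TRUE) {
  axis <- epochTimes(epochs)
  chans <- channelNames(epochs)
  keep <- rep(TRUE, nTrials(epochs))
  if (excludeOutliers && nTrials(epochs) > 0) {
    cz <- epochChannel(epochs, "Cz")
    keep <- !vapply(seq_len(ncol(cz)), function(j)
      isOutlierTrial(cz[, j], axis), TRUE)
  }
  out <- matrix(NA_real_, length(chans), length(times),
                dimnames = list(chans, sprintf("%+.1fs", times)))
  for (ci in seq_along(chans)) {
    m <- epochChannel(epochs, chans[ci])[, keep, drop = FALSE]
    mu <- rowMeans(m)
    out[ci, ] <- mu[vapply(times, function(t) nearestIdx(axis, t), 1L)]
  }
  out
}
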