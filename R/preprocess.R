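# EEG preprocessing: the two band-pass paths (slow potentials and
# oscillations), automated artifact-component removal, onset-locked
# epoching, and oscillation-path trial QC.

bandpassEEG <- function(eeg, rateHz, low, high, order = 3, minLenS = 20) {
  if (rateHz < 250) stop("EEG sampling rate must be >= 250 Hz")
  if (ncol(eeg) / rateHz < minLenS)
    stop("record too short for the ", low, " Hz corner (need >= ",
         minLenS, " s)")
  bf <- signal::butter(order, c(low, high) / (rateHz / 2), type = "pass")
  out <- eeg
  for (i in seq_len(nrow(eeg)))
    out[i, ] <- signal::filtfilt(bf, eeg[i, ])
  out
}

#' Band-pass EEG for the slow-potential (MRCP) path
#'
#' Zero-phase (forward-backward) third-order Butterworth band-pass with
#' 0.05 and 5 Hz corners, applied per channel.
#'
#' @param eeg channels x samples matrix.
#' @param rateHz sampling rate (>= 250 Hz); the record must be at least
#'   20 s long for the 0.05 Hz corner to be meaningful.
#' @return filtered matrix of the same shape.
#' @export
bandpassMRCP <- function(eeg, rateHz) bandpassEEG(eeg, rateHz, 0.05, 5)

#' Band-pass EEG for the oscillation path
#'
#' As [bandpassMRCP()] with corners 0.05 and 50 Hz.
#' @inheritParams bandpassMRCP
#' @export
bandpassOsc <- function(eeg, rateHz) bandpassEEG(eeg, rateHz, 0.05, 50)

componentSpectralRatio <- function(src, rateHz) {
  n <- length(src)
  spec <- Mod(stats::fft(src - mean(src)))^2
  f <- (seq_len(n) - 1) * rateHz / n
  hi <- spec[f >= 25 & f <= 50]
  lo <- spec[f >= 1 & f <= 10]
  (mean(hi) * 1) / max(mean(lo), 1e-12)
}

#' Remove artifact components with automated criteria
#'
#' Runs extended-infomax ICA on the (filtered) EEG and removes components
#' meeting either automated criterion: (a) absolute correlation with the
#' mean of the frontal channels (FP1, FP2) above \code{blinkCor} -- the
#' blink proxy; or (b) mean spectral power in 25-50 Hz relative to 1-10 Hz
#' above \code{emgRatio} -- broadband muscle activity. These reproducible
#' rules stand in for expert visual labeling of component maps. On
#' non-convergence the original data are passed through with a warning
#' status in the report.
#'
#' @param eeg channels x samples matrix (>= 60 s of data recommended).
#' @param rateHz sampling rate (Hz).
#' @param frontalChannels row indices (or labels, if eeg has rownames) of
#'   FP1/FP2.
#' @param blinkCor blink-correlation cutoff (default 0.8).
#' @param emgRatio high/low spectral power ratio cutoff (default 2).
#' @param seed seed for the ICA.
#' @param ... passed to [extendedInfomax()].
#' @return list with \code{cleaned} (matrix, same shape), \code{report}
#'   (data.frame: component, blink_cor, emg_ratio, rejected, reason) and
#'   \code{status} ("ok" or "not_converged").
#' @export
removeArtifactComponents <- function(eeg, rateHz,
                                     frontalChannels = c("FP1", "FP2"),
                                     blinkCor = 0.8, emgRatio = 2,
                                     seed = 1, ...) {
  if (is.character(frontalChannels))
    frontalChannels <- match(frontalChannels, rownames(eeg))
  if (anyNA(frontalChannels)) stop("frontal channels not found in eeg rows")
  fit <- extendedInfomax(eeg, seed = seed, ...)
  frontal <- colMeans(eeg[frontalChannels, , drop = FALSE])
  nComp <- nrow(fit$sources)
  blink <- vapply(seq_len(nComp), function(i)
    abs(stats::cor(fit$sources[i, ], frontal)), 0)
  ratio <- vapply(seq_len(nComp), function(i)
    componentSpectralRatio(fit$sources[i, ], rateHz), 0)
  rejected <- blink > blinkCor | ratio > emgRatio
  reason <- ifelse(blink > blinkCor, "blink",
                   ifelse(ratio > emgRatio, "emg", ""))
  report <- data.frame(component = seq_len(nComp), blink_cor = blink,
                       emg_ratio = ratio, rejected = rejected,
                       reason = reason)
  if (!fit$converged) {
    return(list(cleaned = eeg, report = report, status = "not_converged"))
  }
  keep <- !rejected
  cleaned <- fit$mixing[, keep, drop = FALSE] %*%
    fit$sources[keep, , drop = FALSE] + rowMeans(eeg)
  dimnames(cleaned) <- dimnames(eeg)
  list(cleaned = cleaned, report = report, status = "ok")
}

#' Cut onset-locked epochs
#'
#' Slices \eqn{[-4, 4)} s epochs (2000 samples at 250 Hz, t = 0 exactly at
#' the sample nearest the detected onset) out of a preprocessed EEG matrix,
#' and attaches the four EMG envelopes downsampled onto the same axis.
#' Undetected trials and trials too close to a record edge are skipped with
#' a QC flag; slicing never alters sample values.
#'
#' @param session the \linkS4class{RawSession} the EEG was derived from
#'   (supplies EMG, metadata and the montage).
#' @param eeg preprocessed channels x samples matrix at the EEG rate.
#' @param onsets data.frame from [detectSessionOnsets()].
#' @param preS,postS epoch extent before/after onset (s).
#' @return a \linkS4class{TrialEpochSet} containing the usable trials; the
#'   \code{qcFlags} attribute \code{"skipped"} records dropped trials with
#'   reasons.
#' @export
extractEpochs <- function(session, eeg, onsets, preS = 4, postS = 4) {
  rate <- eegRate(session)
  nPre <- round(preS * rate); nPost <- round(postS * rate)
  times <- (seq_len(nPre + nPost) - nPre - 1) / rate
  emgRateHz <- emgRate(session)
  env <- t(vapply(seq_len(nrow(emgData(session))), function(i)
    emgEnvelope(emgData(session)[i, ], emgRateHz),
    numeric(ncol(emgData(session)))))
  q <- round(emgRateHz / rate)

  keepIdx <- integer(); skipped <- list()
  eegList <- list(); envList <- list(); onsetKeep <- numeric()
  for (i in seq_len(nrow(onsets))) {
    if (!isTRUE(onsets$detected[i])) {
      skipped[[length(skipped) + 1]] <-
        data.frame(trial = onsets$trial[i], reason = "onset not detected")
      next
    }
    c0 <- round(onsets$onset_time_s[i] * rate) + 1L
    idx <- (c0 - nPre):(c0 + nPost - 1L)
    if (idx[1] < 1 || idx[length(idx)] > ncol(eeg)) {
      skipped[[length(skipped) + 1]] <-
        data.frame(trial = onsets$trial[i], reason = "too close to record edge")
      next
    }
    m0 <- round(onsets$onset_time_s[i] * emgRateHz) + 1L
    midx <- seq(m0 - nPre * q, by = q, length.out = nPre + nPost)
    if (midx[1] < 1 || midx[length(midx)] > ncol(env)) {
      skipped[[length(skipped) + 1]] <-
        data.frame(trial = onsets$trial[i], reason = "too close to record edge")
      next
    }
    keepIdx <- c(keepIdx, onsets$trial[i])
    onsetKeep <- c(onsetKeep, onsets$onset_time_s[i])
    eegList[[length(eegList) + 1]] <- eeg[, idx, drop = FALSE]
    envList[[length(envList) + 1]] <- env[, midx, drop = FALSE]
  }
  nT <- length(keepIdx)
  nCh <- nrow(eeg)
  eegArr <- array(0, c(nCh, length(times), nT))
  envArr <- array(0, c(4, length(times), nT))
  for (j in seq_len(nT)) {
    eegArr[, , j] <- eegList[[j]]
    envArr[, , j] <- envList[[j]]
  }
  dimnames(eegArr) <- list(channelNames(montage(session)), NULL, NULL)
  dimnames(envArr) <- list(EMG_CHANNELS, NULL, NULL)
  out <- new("TrialEpochSet",
             subjectId = subjectId(session), group = groupLabel(session),
             trialIndex = as.integer(keepIdx), onsetTimes = onsetKeep,
             times = times, eeg = eegArr, emgEnvelopes = envArr,
             qcFlags = rep(list(character()), nT),
             dominantFoot = dominantFoot(session),
             montage = montage(session))
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(trial = integer(), reason = character())
  out
}

#' Reject oscillation-path outlier trials
#'
#' Flags trials with excessive pre-'go' muscle activity in either
#' dominant-leg muscle, or a contralateral-TA burst during the motor task
#' ([0, 4] s). Thresholds are median + k MAD of each envelope's own
#' cross-trial baseline. A head-motion criterion would need a motion
#' channel, which the data model does not carry; it is skipped with a note
#' in the report.
#'
#' @param epochs a \linkS4class{TrialEpochSet}.
#' @param onsets the onset table (supplies the go-to-onset delay per trial).
#' @param k MAD multiplier for the envelope thresholds.
#' @return list with \code{kept} (a \linkS4class{TrialEpochSet}),
#'   \code{report} (data.frame: trial, reason) and \code{note}.
#' @export
rejectOscillationOutliers <- function(epochs, onsets, k = 8) {
  times <- epochTimes(epochs)
  side <- dominantFoot(epochs)
  taDom <- if (side == "left") "TA_left" else "TA_right"
  solDom <- if (side == "left") "SOL_left" else "SOL_right"
  taCon <- if (side == "left") "TA_right" else "TA_left"
  n <- nTrials(epochs)
  goDelay <- onsets$onset_time_s - onsets$cue_go_time_s
  goDelay <- goDelay[match(epochs@trialIndex, onsets$trial)]

  envBase <- function(chan) {
    # cross-trial baseline level of this envelope in the far pre-cue window
    b <- epochs@emgEnvelopes[chan, times < -3, , drop = FALSE]
    c(stats::median(b), stats::mad(b))
  }
  flags <- rep(list(character()), n)
  for (chan in c(taDom, solDom)) {
    st <- envBase(chan)
    thr <- st[1] + k * st[2]
    for (j in seq_len(n)) {
      pre <- times < -goDelay[j] & times >= -3   # before the 'go' cue
      if (any(epochs@emgEnvelopes[chan, pre, j] > thr))
        flags[[j]] <- union(flags[[j]], "pre-cue activity")
    }
  }
  stCon <- envBase(taCon)
  thrCon <- stCon[1] + k * stCon[2]
  for (j in seq_len(n)) {
    task <- times >= 0 & times <= 4
    if (any(epochs@emgEnvelopes[taCon, task, j] > thrCon))
      flags[[j]] <- union(flags[[j]], "opposite-leg activity")
  }
  rejected <- vapply(flags, length, 1L) > 0
  report <- do.call(rbind, c(list(
    data.frame(trial = integer(), reason = character())),
    lapply(which(rejected), function(j)
      data.frame(trial = epochs@trialIndex[j],
                 reason = paste(flags[[j]], collapse = "; ")))))
  kept <- subsetEpochs(epochs, !rejected)
  list(kept = kept, report = report,
       note = "head-motion criterion skipped: no motion channel in data model")
}

subsetEpochs <- function(epochs, keep) {
  new("TrialEpochSet",
      subjectId = epochs@subjectId, group = epochs@group,
      trialIndex = epochs@trialIndex[keep],
      onsetTimes = epochs@onsetTimes[keep],
      times = epochs@times,
      eeg = epochs@eeg[, , keep, drop = FALSE],
      emgEnvelopes = epochs@emgEnvelopes[, , keep, drop = FALSE],
      qcFlags = epochs@qcFlags[keep],
      dominantFoot = epochs@dominantFoot, montage = epochs@montage)
}
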