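#' @import methods
NULL

GROUP_LEVELS <- c("HC", "PD_noFOG", "PD_mildFOG", "PD_severeFOG")
EMG_CHANNELS <- c("TA_left", "TA_right", "SOL_left", "SOL_right")

#' Scalp montage
#'
#' Describes the 17-channel 10-20 EEG montage used throughout the package:
#' channel order, 2-D scalp positions, the small-Laplacian neighbour sets and
#' the left/right mirror pairs used when recordings from left-foot-dominant
#' participants are flipped.
#'
#' @slot channelNames ordered character vector of the 17 EEG labels.
#' @slot positions numeric matrix (channels x 2) of 2-D scalp coordinates.
#' @slot laplacianNeighbors named list mapping a centre label to exactly four
#'   neighbour labels.
#' @slot lateralPairs character matrix (pairs x 2) of (left, right) labels.
#' @export
setClass("Montage", representation(
  channelNames = "character",
  positions = "matrix",
  laplacianNeighbors = "list",
  lateralPairs = "matrix"
))

MONTAGE_CHANNELS <- c("FP1", "FP2", "AF3", "AF4", "F3", "Fz", "F4",
                      "FC1", "FC2", "C3", "Cz", "C4", "CP1", "CP2",
                      "P3", "Pz", "P4")

setValidity("Montage", function(object) {
  msg <- character()
  if (!setequal(object@channelNames, MONTAGE_CHANNELS))
    msg <- c(msg, "channel set must equal the 17-channel 10-20 montage")
  if (nrow(object@positions) != length(object@channelNames))
    msg <- c(msg, "positions must have one row per channel")
  for (centre in names(object@laplacianNeighbors)) {
    nb <- object@laplacianNeighbors[[centre]]
    if (length(nb) != 4L)
      msg <- c(msg, sprintf("laplacian neighbours of %s must number 4", centre))
    if (!all(nb %in% object@channelNames))
      msg <- c(msg, sprintf("laplacian neighbours of %s outside montage", centre))
  }
  if (!all(c("Cz", "FC1", "FC2") %in% names(object@laplacianNeighbors)))
    msg <- c(msg, "laplacian neighbours must be defined for Cz, FC1, FC2")
  if (ncol(object@lateralPairs) != 2L)
    msg <- c(msg, "lateralPairs must have two columns")
  if (!all(object@lateralPairs %in% object@channelNames))
    msg <- c(msg, "lateral pair labels outside montage")
  if (length(msg)) msg else TRUE
})

#' Raw EEG + EMG session
#'
#' A continuous multirate recording: 17-channel scalp EEG (rows ordered as the
#' montage) with 4-channel bilateral leg EMG and the ready/go auditory-cue
#' times, plus subject metadata (group, dominant foot).
#'
#' @slot subjectId character scalar.
#' @slot group one of HC, PD_noFOG, PD_mildFOG, PD_severeFOG.
#' @slot dominantFoot "left" or "right".
#' @slot eeg numeric matrix, channels x samples, microvolts.
#' @slot eegRate sampling rate of the EEG in Hz (250 by default).
#' @slot emg numeric matrix, 4 x samples (TA_left, TA_right, SOL_left,
#'   SOL_right), microvolts.
#' @slot emgRate sampling rate of the EMG in Hz (1000 by default).
#' @slot cues data.frame with columns ready_s and go_s, one row per trial.
#' @slot montage the \linkS4class{Montage} the EEG rows follow.
#' @export
setClass("RawSession", representation(
  subjectId = "character",
  group = "character",
  dominantFoot = "character",
  eeg = "matrix",
  eegRate = "numeric",
  emg = "matrix",
  emgRate = "numeric",
  cues = "data.frame",
  montage = "Montage"
))

setValidity("RawSession", function(object) {
  msg <- character()
  if (!object@group %in% GROUP_LEVELS)
    msg <- c(msg, sprintf("group must be one of %s",
                          paste(GROUP_LEVELS, collapse = ", ")))
  if (!object@dominantFoot %in% c("left", "right"))
    msg <- c(msg, "dominantFoot must be 'left' or 'right'")
  if (nrow(object@eeg) != length(object@montage@channelNames))
    msg <- c(msg, "eeg must have one row per montage channel")
  if (!is.null(rownames(object@eeg)) &&
      !identical(rownames(object@eeg), object@montage@channelNames))
    msg <- c(msg, "eeg row names must follow montage order")
  if (nrow(object@emg) != 4L)
    msg <- c(msg, "emg must have 4 rows (TA_left, TA_right, SOL_left, SOL_right)")
  if (!all(c("ready_s", "go_s") %in% names(object@cues)))
    msg <- c(msg, "cues needs columns ready_s, go_s")
  if (nrow(object@cues) > 0) {
    gap <- object@cues$go_s - object@cues$ready_s
    if (any(abs(gap - 2) > 1 / object@eegRate + 1e-9))
      msg <- c(msg, "every go cue must follow its ready cue by 2 s (within one EEG sample)")
    if (nrow(object@cues) > 1 && any(diff(object@cues$ready_s) < 10))
      msg <- c(msg, "inter-trial spacing must be at least 10 s")
  }
  if (length(msg)) msg else TRUE
})

#' Onset-locked trial epochs
#'
#' EEG epochs cut around the EMG-derived movement onset. The time axis is
#' half-open \eqn{[-4, 4)} s at the EEG rate (2000 samples at 250 Hz) with
#' t = 0 exactly at the detected onset; the analysis window reported to users
#' is the 'Go' sub-window \eqn{[-2, 4)} s. EMG envelopes for all four leg
#' muscles are carried on the same axis.
#'
#' @slot subjectId character scalar.
#' @slot group group label of the subject.
#' @slot trialIndex integer vector, original trial numbers.
#' @slot onsetTimes numeric vector of onset times in session seconds.
#' @slot times numeric vector, epoch time axis in s relative to onset.
#' @slot eeg numeric array channels x time x trials.
#' @slot emgEnvelopes numeric array 4 x time x trials (rectified low-passed
#'   envelopes for TA_left, TA_right, SOL_left, SOL_right).
#' @slot qcFlags list (one character vector per kept or rejected trial) of
#'   rejection reasons; empty vector = clean trial.
#' @slot dominantFoot "left" or "right".
#' @slot montage the \linkS4class{Montage}.
#' @export
setClass("TrialEpochSet", representation(
  subjectId = "character",
  group = "character",
  trialIndex = "integer",
  onsetTimes = "numeric",
  times = "numeric",
  eeg = "array",
  emgEnvelopes = "array",
  qcFlags = "list",
  dominantFoot = "character",
  montage = "Montage"
))

setValidity("TrialEpochSet", function(object) {
  msg <- character()
  n <- length(object@trialIndex)
  if (dim(object@eeg)[3] != n || length(object@onsetTimes) != n ||
      length(object@qcFlags) != n)
    msg <- c(msg, "trial dimensions disagree")
  if (dim(object@eeg)[2] != length(object@times))
    msg <- c(msg, "eeg time dimension must match times")
  if (length(object@times) && min(abs(object@times)) > 1e-9)
    msg <- c(msg, "time axis must include 0 exactly at onset")
  if (length(msg)) msg else TRUE
})

#' Time-frequency power map
#'
#' Morlet-wavelet power of a single channel over an epoch: frequencies x
#' times, in signal-units squared. \code{edgeValid} marks the samples at
#' least 2.5 wavelet cycles away from both epoch edges, where the convolution
#' is free of edge leakage.
#'
#' @slot channel character scalar.
#' @slot freqs numeric vector of analysis frequencies (Hz).
#' @slot times numeric vector, epoch time axis (s).
#' @slot power numeric matrix frequencies x times, non-negative.
#' @slot edgeValid logical matrix frequencies x times.
#' @export
setClass("TFRMap", representation(
  channel = "character",
  freqs = "numeric",
  times = "numeric",
  power = "matrix",
  edgeValid = "matrix"
))

setValidity("TFRMap", function(object) {
  msg <- character()
  if (any(object@power < 0)) msg <- c(msg, "power must be non-negative")
  if (!all(dim(object@power) == c(length(object@freqs), length(object@times))))
    msg <- c(msg, "power must be freqs x times")
  if (length(msg)) msg else TRUE
})

#' Baseline-normalized ERD/ERS map
#'
#' Percent power change relative to the per-frequency mean over the baseline
#' window (default \eqn{[-4, -2]} s): negative values are event-related
#' desynchronization, positive values synchronization. The mean over the
#' baseline columns of every frequency row is zero by construction. An
#' optional boolean significance mask (bootstrap or permutation) can be
#' attached.
#'
#' @slot channel character scalar.
#' @slot freqs numeric vector (Hz).
#' @slot times numeric vector (s).
#' @slot erd numeric matrix frequencies x times, percent change.
#' @slot baselineWindow numeric length-2 vector (s).
#' @slot significanceMask logical matrix (0 x 0 when absent).
#' @slot nTrials number of trials averaged.
#' @export
setClass("ERDMap", representation(
  channel = "character",
  freqs = "numeric",
  times = "numeric",
  erd = "matrix",
  baselineWindow = "numeric",
  significanceMask = "matrix",
  nTrials = "integer"
))

#' Ground truth of a synthetic cohort
#'
#' Injected parameters of every generated trial (true onsets, MRCP slopes and
#' trough, EMG burst peak and TA-SOL lag), the per-band oscillation schedules,
#' blink times, and the RNG seed, for recovery testing of every downstream
#' stage.
#'
#' @slot trials data.frame, one row per generated trial.
#' @slot schedules data.frame of oscillation schedule entries per subject.
#' @slot blinks data.frame of injected blink times per subject.
#' @slot profiles list of the GroupProfile lists used.
#' @slot seed integer RNG seed of the cohort.
#' @export
setClass("GroundTruth", representation(
  trials = "data.frame",
  schedules = "data.frame",
  blinks = "data.frame",
  profiles = "list",
  seed = "integer"
))

setMethod("show", "Montage", function(object) {
  cat("Montage:", length(object@channelNames), "channels\n")
  cat(" ", paste(object@channelNames, collapse = " "), "\n")
  cat("  Laplacian centres:",
      paste(names(object@laplacianNeighbors), collapse = ", "), "\n")
})

setMethod("show", "RawSession", function(object) {
  cat("RawSession", object@subjectId,
      sprintf("(%s, %s foot dominant)\n", object@group, object@dominantFoot))
  cat(sprintf("  EEG: %d ch x %d samples @ %g Hz (%.1f s)\n",
              nrow(object@eeg), ncol(object@eeg), object@eegRate,
              ncol(object@eeg) / object@eegRate))
  cat(sprintf("  EMG: %d ch x %d samples @ %g Hz\n",
              nrow(object@emg), ncol(object@emg), object@emgRate))
  cat(sprintf("  cues: %d ready/go pairs\n", nrow(object@cues)))
})

setMethod("show", "TrialEpochSet", function(object) {
  clean <- sum(vapply(object@qcFlags, length, 1L) == 0L)
  cat("TrialEpochSet", object@subjectId,
      sprintf("(%s): %d trials (%d clean), %d channels, [%.3g, %.3g) s\n",
              object@group, length(object@trialIndex), clean,
              dim(object@eeg)[1], min(object@times),
              max(object@times) + diff(object@times[1:2])))
})

setMethod("show", "TFRMap", function(object) {
  cat(sprintf("TFRMap %s: %d freqs (%g-%g Hz) x %d times [%.3g, %.3g] s\n",
              object@channel, length(object@freqs), min(object@freqs),
              max(object@freqs), length(object@times), min(object@times),
              max(object@times)))
})

setMethod("show", "ERDMap", function(object) {
  cat(sprintf("ERDMap %s: %d freqs x %d times, baseline [%g, %g] s, %d trials",
              object@channel, length(object@freqs), length(object@times),
              object@baselineWindow[1], object@baselineWindow[2],
              object@nTrials))
  if (length(object@significanceMask))
    cat(sprintf(", %.1f%% significant",
                100 * mean(object@significanceMask)))
  cat("\n")
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d trials, %d subjects, seed %d\n",
              nrow(object@trials), length(unique(object@trials$subject_id)),
              object@seed))
})
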