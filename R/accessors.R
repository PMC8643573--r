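#' Accessors for the data containers
#'
#' Accessor generics for the package's S4 containers. Slots should not be
#' reached into directly; these are the supported surface.
#'
#' @param object a package object (\linkS4class{Montage},
#'   \linkS4class{RawSession}, \linkS4class{TrialEpochSet},
#'   \linkS4class{TFRMap}, \linkS4class{ERDMap} or
#'   \linkS4class{GroundTruth}).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setGeneric("channelPositions", function(object) standardGeneric("channelPositions"))
#' @rdname accessors
#' @export
setGeneric("laplacianNeighbors", function(object) standardGeneric("laplacianNeighbors"))
#' @rdname accessors
#' @export
setGeneric("lateralPairs", function(object) standardGeneric("lateralPairs"))
#' @rdname accessors
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setGeneric("groupLabel", function(object) standardGeneric("groupLabel"))
#' @rdname accessors
#' @export
setGeneric("dominantFoot", function(object) standardGeneric("dominantFoot"))
#' @rdname accessors
#' @export
setGeneric("eegData", function(object) standardGeneric("eegData"))
#' @rdname accessors
#' @export
setGeneric("eegRate", function(object) standardGeneric("eegRate"))
#' @rdname accessors
#' @export
setGeneric("emgData", function(object) standardGeneric("emgData"))
#' @rdname accessors
#' @export
setGeneric("emgRate", function(object) standardGeneric("emgRate"))
#' @rdname accessors
#' @export
setGeneric("cueTimes", function(object) standardGeneric("cueTimes"))
#' @rdname accessors
#' @export
setGeneric("montage", function(object) standardGeneric("montage"))
#' @rdname accessors
#' @export
setGeneric("epochTimes", function(object) standardGeneric("epochTimes"))
#' @rdname accessors
#' @export
setGeneric("epochData", function(object) standardGeneric("epochData"))
#' @rdname accessors
#' @export
setGeneric("emgEnvelopes", function(object) standardGeneric("emgEnvelopes"))
#' @rdname accessors
#' @export
setGeneric("onsetTimes", function(object) standardGeneric("onsetTimes"))
#' @rdname accessors
#' @export
setGeneric("qcFlags", function(object) standardGeneric("qcFlags"))
#' @rdname accessors
#' @export
setGeneric("nTrials", function(object) standardGeneric("nTrials"))
#' @rdname accessors
#' @export
setGeneric("tfrPower", function(object) standardGeneric("tfrPower"))
#' @rdname accessors
#' @export
setGeneric("tfrFreqs", function(object) standardGeneric("tfrFreqs"))
#' @rdname accessors
#' @export
setGeneric("tfrTimes", function(object) standardGeneric("tfrTimes"))
#' @rdname accessors
#' @export
setGeneric("edgeValid", function(object) standardGeneric("edgeValid"))
#' @rdname accessors
#' @export
setGeneric("erdValues", function(object) standardGeneric("erdValues"))
#' @rdname accessors
#' @export
setGeneric("baselineWindow", function(object) standardGeneric("baselineWindow"))
#' @rdname accessors
#' @export
setGeneric("significanceMask", function(object) standardGeneric("significanceMask"))
#' @rdname accessors
#' @export
setGeneric("gtTrials", function(object) standardGeneric("gtTrials"))
#' @rdname accessors
#' @export
setGeneric("gtSchedules", function(object) standardGeneric("gtSchedules"))
#' @rdname accessors
#' @export
setGeneric("gtBlinks", function(object) standardGeneric("gtBlinks"))

#' @rdname accessors
setMethod("channelNames", "Montage", function(object) object@channelNames)
#' @rdname accessors
setMethod("channelPositions", "Montage", function(object) object@positions)
#' @rdname accessors
setMethod("laplacianNeighbors", "Montage", function(object) object@laplacianNeighbors)
#' @rdname accessors
setMethod("lateralPairs", "Montage", function(object) object@lateralPairs)

#' @rdname accessors
setMethod("subjectId", "RawSession", function(object) object@subjectId)
#' @rdname accessors
setMethod("groupLabel", "RawSession", function(object) object@group)
#' @rdname accessors
setMethod("dominantFoot", "RawSession", function(object) object@dominantFoot)
#' @rdname accessors
setMethod("eegData", "RawSession", function(object) object@eeg)
#' @rdname accessors
setMethod("eegRate", "RawSession", function(object) object@eegRate)
#' @rdname accessors
setMethod("emgData", "RawSession", function(object) object@emg)
#' @rdname accessors
setMethod("emgRate", "RawSession", function(object) object@emgRate)
#' @rdname accessors
setMethod("cueTimes", "RawSession", function(object) object@cues)
#' @rdname accessors
setMethod("montage", "RawSession", function(object) object@montage)
#' @rdname accessors
setMethod("channelNames", "RawSession", function(object) object@montage@channelNames)

#' @rdname accessors
setMethod("subjectId", "TrialEpochSet", function(object) object@subjectId)
#' @rdname accessors
setMethod("groupLabel", "TrialEpochSet", function(object) object@group)
#' @rdname accessors
setMethod("dominantFoot", "TrialEpochSet", function(object) object@dominantFoot)
#' @rdname accessors
setMethod("epochTimes", "TrialEpochSet", function(object) object@times)
#' @rdname accessors
setMethod("epochData", "TrialEpochSet", function(object) object@eeg)
#' @rdname accessors
setMethod("emgEnvelopes", "TrialEpochSet", function(object) object@emgEnvelopes)
#' @rdname accessors
setMethod("onsetTimes", "TrialEpochSet", function(object) object@onsetTimes)
#' @rdname accessors
setMethod("qcFlags", "TrialEpochSet", function(object) object@qcFlags)
#' @rdname accessors
setMethod("nTrials", "TrialEpochSet", function(object) length(object@trialIndex))
#' @rdname accessors
setMethod("montage", "TrialEpochSet", function(object) object@montage)
#' @rdname accessors
setMethod("channelNames", "TrialEpochSet", function(object) object@montage@channelNames)

#' @rdname accessors
setMethod("tfrPower", "TFRMap", function(object) object@power)
#' @rdname accessors
setMethod("tfrFreqs", "TFRMap", function(object) object@freqs)
#' @rdname accessors
setMethod("tfrTimes", "TFRMap", function(object) object@times)
#' @rdname accessors
setMethod("edgeValid", "TFRMap", function(object) object@edgeValid)

#' @rdname accessors
setMethod("erdValues", "ERDMap", function(object) object@erd)
#' @rdname accessors
setMethod("tfrFreqs", "ERDMap", function(object) object@freqs)
#' @rdname accessors
setMethod("tfrTimes", "ERDMap", function(object) object@times)
#' @rdname accessors
setMethod("baselineWindow", "ERDMap", function(object) object@baselineWindow)
#' @rdname accessors
setMethod("significanceMask", "ERDMap", function(object) {
  if (length(object@significanceMask)) object@significanceMask else NULL
})
#' @rdname accessors
setMethod("nTrials", "ERDMap", function(object) object@nTrials)

#' @rdname accessors
setMethod("gtTrials", "GroundTruth", function(object) object@trials)
#' @rdname accessors
setMethod("gtSchedules", "GroundTruth", function(object) object@schedules)
#' @rdname accessors
setMethod("gtBlinks", "GroundTruth", function(object) object@blinks)

#' Extract one channel of an epoch
#'
#' @param epochs a \linkS4class{TrialEpochSet}.
#' @param channel channel label.
#' @param trial trial position (1-based within the set); if NULL, a matrix
#'   time x trials is returned.
#' @return numeric vector (one trial) or matrix time x trials.
#' @export
epochChannel <- function(epochs, channel, trial = NULL) {
  idx <- match(channel, channelNames(epochs))
  if (is.na(idx)) stop("unknown channel: ", channel)
  if (is.null(trial))
    matrix(epochs@eeg[idx, , ], length(epochs@times), dim(epochs@eeg)[3])
  else epochs@eeg[idx, , trial]
}
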