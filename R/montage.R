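#' Default 17-channel 10-20 montage
#'
#' The standard montage for this pipeline: FP1, FP2, AF3, AF4, F3, Fz, F4,
#' FC1, FC2, C3, Cz, C4, CP1, CP2, P3, Pz, P4, with approximate 2-D scalp
#' coordinates (unit head radius, nose up), small-Laplacian neighbour sets
#' for Cz, FC1 and FC2, and the mirror pairs swapped for left-foot-dominant
#' participants.
#'
#' The true orthogonal Laplacian neighbours of FC1/FC2 (FCz, FC5/FC6, CPz...)
#' are not part of the 17-channel montage, so the closest available members
#' are used: Cz -> C3, C4, Fz, Pz; FC1 -> F3, Fz, C3, Cz; FC2 -> F4, Fz, C4,
#' Cz. The sets are plain list entries and can be replaced before analysis.
#'
#' @param laplacianNeighbors optional replacement neighbour list.
#' @return a \linkS4class{Montage}.
#' @examples
#' m <- defaultMontage()
#' channelNames(m)
#' laplacianNeighbors(m)$Cz
#' @export
defaultMontage <- function(laplacianNeighbors = NULL) {
  pos <- rbind(
    FP1 = c(-0.31, 0.95), FP2 = c(0.31, 0.95),
    AF3 = c(-0.35, 0.75), AF4 = c(0.35, 0.75),
    F3 = c(-0.45, 0.52), Fz = c(0, 0.50), F4 = c(0.45, 0.52),
    FC1 = c(-0.28, 0.25), FC2 = c(0.28, 0.25),
    C3 = c(-0.50, 0.00), Cz = c(0, 0.00), C4 = c(0.50, 0.00),
    CP1 = c(-0.28, -0.25), CP2 = c(0.28, -0.25),
    P3 = c(-0.45, -0.52), Pz = c(0, -0.50), P4 = c(0.45, -0.52)
  )
  colnames(pos) <- c("x", "y")
  if (is.null(laplacianNeighbors))
    laplacianNeighbors <- list(
      Cz  = c("C3", "C4", "Fz", "Pz"),
      FC1 = c("F3", "Fz", "C3", "Cz"),
      FC2 = c("F4", "Fz", "C4", "Cz")
    )
  pairs <- rbind(
    c("FP1", "FP2"), c("AF3", "AF4"), c("F3", "F4"),
    c("FC1", "FC2"), c("C3", "C4"), c("CP1", "CP2"), c("P3", "P4")
  )
  colnames(pairs) <- c("left", "right")
  new("Montage", channelNames = rownames(pos), positions = pos,
      laplacianNeighbors = laplacianNeighbors, lateralPairs = pairs)
}

#' Construct a raw session
#'
#' @param subjectId subject identifier.
#' @param group one of HC, PD_noFOG, PD_mildFOG, PD_severeFOG.
#' @param dominantFoot "left" or "right".
#' @param eeg channels x samples matrix (microvolts), rows in montage order.
#' @param emg 4 x samples matrix (TA_left, TA_right, SOL_left, SOL_right).
#' @param cues data.frame with columns ready_s, go_s.
#' @param eegRate,emgRate sampling rates in Hz.
#' @param montage a \linkS4class{Montage}.
#' @return a \linkS4class{RawSession}.
#' @export
rawSession <- function(subjectId, group, dominantFoot, eeg, emg, cues,
                       eegRate = 250, emgRate = 1000,
                       montage = defaultMontage()) {
  rownames(eeg) <- channelNames(montage)
  rownames(emg) <- EMG_CHANNELS
  new("RawSession", subjectId = subjectId, group = group,
      dominantFoot = dominantFoot, eeg = eeg, eegRate = eegRate,
      emg = emg, emgRate = emgRate,
      cues = as.data.frame(cues), montage = montage)
}

#' Swap left/right EEG channels for left-foot-dominant sessions
#'
#' For participants whose dominant (moving) foot is the left one, the lateral
#' EEG channels are mirror-swapped (FP1<->FP2, AF3<->AF4, F3<->F4, FC1<->FC2,
#' C3<->C4, CP1<->CP2, P3<->P4) so that the hemisphere contralateral to the
#' moving foot is on the same side for every subject. Midline channels are
#' untouched; right-dominant sessions are returned unchanged. Applying the
#' function twice restores the original session.
#'
#' @param session a \linkS4class{RawSession}.
#' @return a \linkS4class{RawSession} with lateral channels swapped if
#'   \code{dominantFoot(session) == "left"}.
#' @export
flipLateralChannels <- function(session) {
  if (dominantFoot(session) != "left") return(session)
  m <- montage(session)
  eeg <- eegData(session)
  for (i in seq_len(nrow(lateralPairs(m)))) {
    l <- lateralPairs(m)[i, 1]; r <- lateralPairs(m)[i, 2]
    tmp <- eeg[l, ]
    eeg[l, ] <- eeg[r, ]
    eeg[r, ] <- tmp
  }
  out <- session
  out@eeg <- eeg
  out
}
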