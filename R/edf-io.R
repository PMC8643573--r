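# Minimal EDF/EDF+ I/O for the 17 EEG + 4 EMG channel layout.
# EDF stores each signal as 16-bit integers in fixed-duration data records;
# per-signal sample counts per record encode the (possibly different)
# sampling rates, which is how the 250 Hz EEG and 1000 Hz EMG share a file.

padTo <- function(x, width) formatC(as.character(x), width = width,
                                    flag = "-")

edfNum <- function(x, width = 8) {
  s <- formatC(x, width = width, format = "g", digits = 6)
  s <- gsub(" ", "", s)
  padTo(s, width)
}

#' Write a session to EDF with sidecar annotation and metadata files
#'
#' Writes the EEG (250 Hz) and EMG (1000 Hz) channels to a 16-bit EDF file
#' with 1-second data records, the ready/go cue annotations to a sidecar
#' tab-separated file (columns \code{event}, \code{time_s}) and the subject
#' metadata (subject_id, group, dominant_foot) to a sidecar YAML file.
#' Signals are padded with zeros to a whole number of records. Quantization
#' is 16-bit over a symmetric physical range chosen per channel from the
#' data, so a read-back differs from the input by at most half a
#' quantization step per sample.
#'
#' @param session a \linkS4class{RawSession}.
#' @param path output EDF path.
#' @param annotationsPath cue annotation TSV (default: path with .tsv).
#' @param metadataPath subject metadata YAML (default: path with .yaml).
#' @return invisibly, the EDF path.
#' @seealso [readSession()]
#' @export
writeSession <- function(session, path,
                         annotationsPath = sub("\\.edf$", ".tsv", path),
                         metadataPath = sub("\\.edf$", ".yaml", path)) {
  validObject(session)
  eeg <- eegData(session); emg <- emgData(session)
  rates <- c(rep(eegRate(session), nrow(eeg)), rep(emgRate(session), nrow(emg)))
  labels <- c(rownames(eeg), rownames(emg))
  nSig <- length(labels)
  dur <- max(ncol(eeg) / eegRate(session), ncol(emg) / emgRate(session))
  nRec <- as.integer(ceiling(dur - 1e-9))

  sigList <- vector("list", nSig)
  physMin <- physMax <- numeric(nSig)
  for (i in seq_len(nSig)) {
    x <- if (i <= nrow(eeg)) eeg[i, ] else emg[i - nrow(eeg), ]
    n <- nRec * rates[i]
    if (length(x) < n) x <- c(x, numeric(n - length(x)))
    # round the range to the 6 significant digits the header field carries,
    # so writer and reader use the same scaling
    r <- signif(max(max(abs(x)) * (1 + 1e-6), 1), 6)
    physMin[i] <- -r; physMax[i] <- r
    dig <- round((x - physMin[i]) / (2 * r) * 65535 - 32768)
    sigList[[i]] <- matrix(as.integer(pmin(32767, pmax(-32768, dig))),
                           nrow = rates[i], ncol = nRec)
  }

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    padTo("0", 8),
    padTo(subjectId(session), 80),
    padTo("Startdate X", 80),
    "01.01.00", "00.00.00",
    padTo(256 * (nSig + 1), 8),
    padTo("", 44),
    padTo(nRec, 8),
    padTo(1, 8),
    padTo(nSig, 4)
  )
  sigHdr <- paste0(
    paste(padTo(labels, 16), collapse = ""),
    paste(rep(padTo("", 80), nSig), collapse = ""),
    paste(rep(padTo("uV", 8), nSig), collapse = ""),
    paste(vapply(physMin, edfNum, ""), collapse = ""),
    paste(vapply(physMax, edfNum, ""), collapse = ""),
    paste(rep(padTo("-32768", 8), nSig), collapse = ""),
    paste(rep(padTo("32767", 8), nSig), collapse = ""),
    paste(rep(padTo("", 80), nSig), collapse = ""),
    paste(padTo(rates, 8), collapse = ""),
    paste(rep(padTo("", 32), nSig), collapse = "")
  )
  writeChar(paste0(hdr, sigHdr), con, eos = NULL, useBytes = TRUE)
  # interleave: per record, each signal's block of samples
  blocks <- do.call(rbind, sigList)
  writeBin(as.integer(blocks), con, size = 2, endian = "little")

  cues <- cueTimes(session)
  ann <- data.frame(
    event = rep(c("ready", "go"), each = nrow(cues)),
    time_s = c(cues$ready_s, cues$go_s)
  )
  ann <- ann[order(ann$time_s), ]
  utils::write.table(ann, annotationsPath, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  yaml::write_yaml(list(subject_id = subjectId(session),
                        group = groupLabel(session),
                        dominant_foot = dominantFoot(session)),
                   metadataPath)
  invisible(path)
}

#' Read a session from EDF plus sidecar annotations and metadata
#'
#' Reads an EDF file written by [writeSession()] (or any EDF carrying the
#' full 17-channel montage plus the four leg EMG channels), the cue
#' annotation TSV and the metadata YAML, and reassembles a
#' \linkS4class{RawSession} with EEG rows reordered to montage order.
#' Sampling rates are taken from the file header. A missing montage channel
#' raises a montage-mismatch error naming the channel.
#'
#' @param path EDF path.
#' @param annotationsPath cue annotation TSV (default: path with .tsv).
#' @param metadataPath subject metadata YAML (default: path with .yaml).
#' @param montage the expected \linkS4class{Montage}.
#' @return a \linkS4class{RawSession}.
#' @export
readSession <- function(path,
                        annotationsPath = sub("\\.edf$", ".tsv", path),
                        metadataPath = sub("\\.edf$", ".yaml", path),
                        montage = defaultMontage()) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) {
    s <- readChar(con, n, useBytes = TRUE)
    if (nchar(s, type = "bytes") < n) stop("format error: truncated EDF header")
    trimws(s)
  }
  version <- rd(8)
  if (version != "0") stop("format error: not an EDF file (version '",
                           version, "')")
  rd(80); rd(80); rd(8); rd(8)
  rd(8)  # header bytes
  rd(44)
  nRec <- as.integer(rd(8))
  recDur <- as.numeric(rd(8))
  nSig <- as.integer(rd(4))
  rdv <- function(w) vapply(seq_len(nSig), function(i) rd(w), "")
  labels <- rdv(16)
  rdv(80); rdv(8)
  physMin <- as.numeric(rdv(8)); physMax <- as.numeric(rdv(8))
  digMin <- as.numeric(rdv(8)); digMax <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8))  # samples per record
  rdv(32)

  total <- sum(spr) * nRec
  raw <- readBin(con, integer(), n = total, size = 2, endian = "little")
  if (length(raw) < total) stop("format error: truncated EDF data")
  blocks <- matrix(raw, nrow = sum(spr), ncol = nRec)
  ends <- cumsum(spr); starts <- ends - spr + 1
  signals <- lapply(seq_len(nSig), function(i) {
    dig <- as.numeric(blocks[starts[i]:ends[i], ])
    (dig - digMin[i]) / (digMax[i] - digMin[i]) *
      (physMax[i] - physMin[i]) + physMin[i]
  })
  names(signals) <- labels
  rates <- spr / recDur

  missing <- setdiff(channelNames(montage), labels)
  if (length(missing))
    stop("montage mismatch: missing channel ", paste(missing, collapse = ", "))
  missingEmg <- setdiff(EMG_CHANNELS, labels)
  if (length(missingEmg))
    stop("montage mismatch: missing channel ",
         paste(missingEmg, collapse = ", "))

  eegIdx <- match(channelNames(montage), labels)
  emgIdx <- match(EMG_CHANNELS, labels)
  eeg <- do.call(rbind, signals[eegIdx])
  emg <- do.call(rbind, signals[emgIdx])

  ann <- utils::read.table(annotationsPath, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  ready <- ann$time_s[ann$event == "ready"]
  go <- ann$time_s[ann$event == "go"]
  meta <- yaml::read_yaml(metadataPath)

  rawSession(subjectId = meta$subject_id, group = meta$group,
             dominantFoot = meta$dominant_foot,
             eeg = eeg, emg = emg,
             cues = data.frame(ready_s = sort(ready), go_s = sort(go)),
             eegRate = rates[eegIdx[1]], emgRate = rates[emgIdx[1]],
             montage = montage)
}
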