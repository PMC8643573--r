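# Surface small-Laplacian filtering, Morlet time-frequency decomposition,
# baseline-normalized ERD/ERS maps and band summaries.

#' Frequency-band presets
#'
#' Band definitions used for ERD/ERS summaries. The default preset has
#' theta 4-8 Hz, low-beta 13-20 Hz, high-beta 21-35 Hz and broad beta
#' 12-35 Hz; the alternative \code{"split1221"} preset draws the low/high
#' beta boundary at 21 Hz with low-beta starting at 12 Hz.
#'
#' @param preset "default" or "split1221".
#' @return data.frame with columns name, low_hz, high_hz.
#' @export
bandDefinitions <- function(preset = c("default", "split1221")) {
  preset <- match.arg(preset)
  if (preset == "default")
    data.frame(name = c("theta", "low_beta", "high_beta", "beta"),
               low_hz = c(4, 13, 21, 12), high_hz = c(8, 20, 35, 35))
  else
    data.frame(name = c("theta", "low_beta", "high_beta", "beta"),
               low_hz = c(4, 12, 21, 12), high_hz = c(8, 21, 35, 35))
}

#' Surface small-Laplacian filter
#'
#' Subtracts the average of the four surrounding electrodes from the centre
#' electrode, attenuating volume-conducted activity common to the
#' neighbourhood. The neighbour sets come from the montage (defined for Cz,
#' FC1, FC2 by default).
#'
#' @param epochs a \linkS4class{TrialEpochSet} (or a channels x samples
#'   matrix with rownames).
#' @param center centre channel label.
#' @param montage a \linkS4class{Montage}; defaults to the epochs' montage.
#' @return matrix time x trials (or a vector for matrix input).
#' @export
smallLaplacian <- function(epochs, center, montage = NULL) {
  if (is(epochs, "TrialEpochSet")) {
    if (is.null(montage)) montage <- epochs@montage
    nb <- laplacianNeighbors(montage)[[center]]
    if (is.null(nb)) stop("no Laplacian neighbours defined for ", center)
    if (!all(nb %in% channelNames(epochs)))
      stop("montage error: missing neighbour of ", center)
    ctr <- epochChannel(epochs, center)
    nbm <- Reduce(`+`, lapply(nb, function(ch) epochChannel(epochs, ch))) / 4
    return(ctr - nbm)
  }
  if (is.null(montage)) stop("montage required for matrix input")
  nb <- laplacianNeighbors(montage)[[center]]
  if (is.null(nb)) stop("no Laplacian neighbours defined for ", center)
  if (!all(c(center, nb) %in% rownames(epochs)))
    stop("montage error: missing neighbour of ", center)
  epochs[center, ] - colMeans(epochs[nb, , drop = FALSE])
}

#' Morlet-wavelet time-frequency power
#'
#' Convolves a signal with complex Morlet wavelets (default five cycles, so
#' the Gaussian envelope SD is n_cycles / (2 pi f)) on a 1-50 Hz grid and
#' returns squared magnitude as power. Wavelets are L2 (energy) normalized.
#' Samples within 2.5 cycles of either epoch edge are marked invalid in
#' \code{edgeValid} rather than silently reported; at the default epoch
#' length the reported 'Go' window is edge-valid for f >= 2 Hz.
#'
#' @param x numeric vector (one channel, one epoch).
#' @param rateHz sampling rate (Hz).
#' @param freqs analysis frequencies (Hz), default 1-50 Hz in 1 Hz steps.
#' @param nCycles wavelet cycles (default 5).
#' @param times optional time axis for the output (length of x).
#' @param decim keep every decim-th time sample of the power map.
#' @param channel channel label stored in the result.
#' @return a \linkS4class{TFRMap}.
#' @export
morletTFR <- function(x, rateHz, freqs = 1:50, nCycles = 5, times = NULL,
                      decim = 1, channel = "") {
  n <- length(x)
  if (is.null(times)) times <- (seq_len(n) - 1) / rateHz
  if (n < nCycles * rateHz / min(freqs))
    stop("signal shorter than ", nCycles, " cycles of ", min(freqs), " Hz")
  keep <- seq(1, n, by = decim)
  nf <- length(freqs)
  pow <- matrix(0, nf, length(keep))
  valid <- matrix(TRUE, nf, length(keep))
  maxHalf <- ceiling(5 * nCycles / (2 * pi * min(freqs)) * rateHz)
  nfft <- stats::nextn(n + 2 * maxHalf + 1, 2)
  X <- stats::fft(c(x, numeric(nfft - n)))
  for (fi in seq_len(nf)) {
    f <- freqs[fi]
    sigmaT <- nCycles / (2 * pi * f)
    half <- ceiling(5 * sigmaT * rateHz)
    tw <- (-half:half) / rateHz
    w <- exp(-tw^2 / (2 * sigmaT^2)) * exp(2i * pi * f * tw)
    w <- w / sqrt(sum(Mod(w)^2) / rateHz)      # unit energy
    nw <- length(w)
    W <- stats::fft(c(w, complex(real = numeric(nfft - nw))))
    conv <- stats::fft(X * W, inverse = TRUE) / nfft
    centre <- conv[half + seq_len(n)]          # align wavelet centre
    p <- Mod(centre)^2
    pow[fi, ] <- p[keep]
    margin <- 2.5 / f
    valid[fi, ] <- times[keep] >= times[1] + margin &
      times[keep] <= times[n] - margin
  }
  new("TFRMap", channel = channel, freqs = as.numeric(freqs),
      times = times[keep], power = pow, edgeValid = valid)
}

powerArray <- function(maps) {
  if (is.array(maps) && length(dim(maps)) == 3) return(maps)
  arr <- array(0, c(dim(tfrPower(maps[[1]])), length(maps)))
  for (j in seq_along(maps)) arr[, , j] <- tfrPower(maps[[j]])
  arr
}

# basMask: nf x nt 0/1 matrix of columns entering each row's baseline mean
erdFromMean <- function(P, basMask) {
  B <- rowSums(P * basMask) / rowSums(basMask)
  if (any(B <= 0))
    stop("zero baseline power at frequency row ",
         paste(which(B <= 0), collapse = ", "))
  100 * (P - B) / B
}

# baseline columns per frequency: the baseline window intersected with the
# edge-valid region of that frequency row (falling back to the full window
# when a row has no valid baseline sample)
baselineMask <- function(times, baselineWindow, edgeValid = NULL,
                         freqsN = NULL) {
  basCols <- times >= baselineWindow[1] & times <= baselineWindow[2]
  if (!any(basCols)) stop("baseline window outside the epoch")
  nf <- if (is.null(edgeValid)) freqsN else nrow(edgeValid)
  m <- matrix(rep(basCols, each = nf), nf, length(times))
  if (!is.null(edgeValid)) {
    mv <- m * edgeValid
    ok <- rowSums(mv) > 0
    m[ok, ] <- mv[ok, ]
  }
  m
}

#' ERD/ERS map from trial power maps
#'
#' Averages power across trials, then expresses each frequency row as
#' percent change relative to its mean over the baseline window (default
#' \eqn{[-4, -2]} s): ERD\%(f,t) = 100 (P(f,t) - B(f)) / B(f). Negative
#' values are desynchronization. Averaging before normalizing follows the
#' single-baseline formulation; the mean of each row over the baseline
#' columns is zero by construction, and the map is invariant to rescaling
#' all trial powers by a common factor.
#'
#' @param maps list of \linkS4class{TFRMap}s sharing grids, or a 3-D array
#'   freqs x times x trials.
#' @param times,freqs grids (taken from the first map when \code{maps} is a
#'   list).
#' @param baselineWindow baseline interval in s (default c(-4, -2)).
#' @param channel label for the output.
#' @param edgeValid optional logical freqs x times matrix (taken from the
#'   first map when \code{maps} is a list): baseline means per frequency
#'   row use only edge-valid columns, so the attenuated samples next to
#'   the epoch edge do not deflate the baseline.
#' @return an \linkS4class{ERDMap}.
#' @export
erdErs <- function(maps, times = NULL, freqs = NULL,
                   baselineWindow = c(-4, -2), channel = "",
                   edgeValid = NULL) {
  if (!is.array(maps)) {
    if (!length(maps)) stop("need at least one trial")
    if (is.null(times)) times <- tfrTimes(maps[[1]])
    if (is.null(freqs)) freqs <- tfrFreqs(maps[[1]])
    if (channel == "") channel <- maps[[1]]@channel
    if (is.null(edgeValid)) edgeValid <- maps[[1]]@edgeValid
  }
  arr <- powerArray(maps)
  basMask <- baselineMask(times, baselineWindow, edgeValid,
                          freqsN = dim(arr)[1])
  P <- apply(arr, c(1, 2), mean)
  erd <- erdFromMean(P, basMask)
  new("ERDMap", channel = channel, freqs = as.numeric(freqs),
      times = times, erd = erd,
      baselineWindow = as.numeric(baselineWindow),
      significanceMask = matrix(logical(), 0, 0),
      nTrials = dim(arr)[3])
}

#' Band x window summary of an ERD map
#'
#' Mean percent change over the band's frequency rows and the window's time
#' columns (band edges inclusive, window half-open at the right).
#'
#' @param erd an \linkS4class{ERDMap}.
#' @param band a row of [bandDefinitions()] (or list with low_hz, high_hz).
#' @param window time interval in s.
#' @return a single percentage.
#' @export
bandSummary <- function(erd, band, window) {
  rows <- tfrFreqs(erd) >= band$low_hz & tfrFreqs(erd) <= band$high_hz
  cols <- tfrTimes(erd) >= window[1] & tfrTimes(erd) < window[2]
  if (!any(rows) || !any(cols)) stop("empty band or window selection")
  mean(erdValues(erd)[rows, cols])
}

#' Export an ERD map in long format
#'
#' @param erd an \linkS4class{ERDMap}.
#' @param path optional TSV output path.
#' @return data.frame (channel, freq_hz, time_s, erd_pct, significant).
#' @export
erdLongFormat <- function(erd, path = NULL) {
  mask <- significanceMask(erd)
  df <- data.frame(
    channel = erd@channel,
    freq_hz = rep(tfrFreqs(erd), times = length(tfrTimes(erd))),
    time_s = rep(tfrTimes(erd), each = length(tfrFreqs(erd))),
    erd_pct = as.numeric(erdValues(erd)),
    significant = if (is.null(mask)) NA else as.logical(mask))
  if (!is.null(path))
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  df
}

#' Plot an ERD/ERS map
#'
#' Image plot (time x frequency, percent change; blue desynchronization,
#' red synchronization) with significant areas outlined by contour when a
#' mask is attached.
#'
#' @param x an \linkS4class{ERDMap}.
#' @param y unused.
#' @param xlim time range to display (default the 'Go' window).
#' @param ... passed to \code{graphics::image}.
#' @export
setMethod("plot", signature(x = "ERDMap", y = "missing"),
  function(x, y, xlim = c(-2, 4), ...) {
    sel <- tfrTimes(x) >= xlim[1] & tfrTimes(x) <= xlim[2]
    z <- t(erdValues(x)[, sel, drop = FALSE])
    r <- max(abs(z))
    pal <- grDevices::colorRampPalette(c("blue", "white", "red"))(64)
    graphics::image(tfrTimes(x)[sel], tfrFreqs(x), z, col = pal,
                    zlim = c(-r, r), xlab = "time (s)",
                    ylab = "frequency (Hz)",
                    main = sprintf("%s ERD/ERS (%%)", x@channel), ...)
    mask <- significanceMask(x)
    if (!is.null(mask))
      graphics::contour(tfrTimes(x)[sel], tfrFreqs(x),
                        t(mask[, sel, drop = FALSE]) * 1, levels = 0.5,
                        add = TRUE, drawlabels = FALSE)
    invisible(x)
  })
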