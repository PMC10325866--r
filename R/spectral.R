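#' Canonical frequency-band scheme
#'
#' delta 1-4, theta 4-8, alpha 8-12, beta 12-25, high_beta 25-30 and gamma
#' 30-40 Hz. Adjacent band edges are resolved half-open: a band covers
#' [low, high), except the last band which is closed at its upper edge, so
#' the six bands partition the 1-Hz bins 1..40 without double counting
#' (bin k belongs to the band with low <= k < high; bin 4 is theta,
#' bin 40 is gamma).
#'
#' @return data.frame(name, low, high) in Hz
#' @export
bandScheme <- function() {
  data.frame(
    name = c("delta", "theta", "alpha", "beta", "high_beta", "gamma"),
    low = c(1, 4, 8, 12, 25, 30),
    high = c(4, 8, 12, 25, 30, 40),
    stringsAsFactors = FALSE
  )
}

#' Integer 1-Hz bins belonging to one band of a scheme
#' @param scheme band scheme data.frame
#' @param band band name
#' @return integer vector of bin centers (Hz)
#' @export
bandBins <- function(scheme, band) {
  i <- match(band, scheme$name)
  if (is.na(i)) stop("unknown band: ", band)
  if (i == nrow(scheme)) scheme$low[i]:scheme$high[i]
  else scheme$low[i]:(scheme$high[i] - 1L)
}

# ---- Welch auto/cross spectral engine ---------------------------------------

#' Welch auto- and cross-spectra over accepted segments
#'
#' Segment-averaged modified periodograms: 2-s Hann windows at 50% overlap,
#' per-window demeaning, windows fitted within each segment so spectra never
#' straddle a segment boundary. One-sided densities on the native 0.5-Hz
#' grid.
#'
#' @param sigmat channels x samples matrix, uV
#' @param fs sampling rate, Hz
#' @param segments data.frame(start, end) in seconds; NULL = whole signal
#' @param winSec,overlap window length (s) and overlap fraction
#' @param cross also accumulate the full cross-spectral array
#' @return list(freq, auto (channels x nf, uV^2/Hz), cross (nf x nch x nch
#'   complex, or NULL), nWindows, skippedSegments)
#' @export
welchCsd <- function(sigmat, fs, segments = NULL, winSec = 2,
                     overlap = 0.5, cross = TRUE) {
  nch <- nrow(sigmat); ns <- ncol(sigmat)
  if (is.null(segments))
    segments <- data.frame(start = 0, end = ns / fs)
  L <- round(winSec * fs)
  step <- max(1L, round(L * (1 - overlap)))
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / (L + 1)) # Hann
  U <- sum(w^2)
  nf <- L %/% 2 + 1
  freq <- (seq_len(nf) - 1) / L * fs
  scale <- 2 / (fs * U)
  scale1 <- rep(scale, nf); scale1[1] <- scale / 2
  if (L %% 2 == 0) scale1[nf] <- scale / 2

  auto <- matrix(0, nch, nf)
  xspec <- if (cross) array(0 + 0i, dim = c(nf, nch, nch)) else NULL
  nwin <- 0L
  skipped <- 0L
  for (k in seq_len(nrow(segments))) {
    from <- floor(segments$start[k] * fs) + 1L
    to <- min(ns, round(segments$end[k] * fs))
    if (to - from + 1L < L) { skipped <- skipped + 1L; next }
    starts <- seq(from, to - L + 1L, by = step)
    for (s0 in starts) {
      seg <- sigmat[, s0:(s0 + L - 1L), drop = FALSE]
      seg <- seg - rowMeans(seg)
      X <- stats::mvfft(t(seg * rep(w, each = nch)))[seq_len(nf), , drop = FALSE]
      auto <- auto + t(Re(X * Conj(X)))
      if (cross) {
        Xc <- Conj(X)
        for (i in seq_len(nch))
          xspec[, i, ] <- xspec[, i, ] + X[, i] * Xc
      }
      nwin <- nwin + 1L
    }
  }
  if (nwin == 0L) stop("no window fits the provided segments")
  auto <- auto / nwin * rep(scale1, each = nch)
  if (cross) xspec <- xspec / nwin * scale1
  list(freq = freq, auto = auto, cross = xspec, nWindows = nwin,
       skippedSegments = skipped)
}

.segmentsOf <- function(segments) {
  if (is(segments, "SegmentSet")) {
    if (!segments@accepted)
      stop("segment set was rejected: ", segments@reason)
    segments@segments
  } else segments
}

#' Welch power spectrum in 1-Hz bins
#'
#' Averaged modified periodograms (2-s Hann windows, 50% overlap) over the
#' accepted segments, at the native 0.5-Hz resolution, aggregated to 1-Hz
#' bins: bin k (uV^2) collects the spectral mass at 0.5-Hz grid frequencies
#' k - 0.5 and k. Segments shorter than one window are skipped (counted in
#' the \code{skippedSegments} attribute).
#'
#' @param recording an [EEGRecording-class]
#' @param segments a [SegmentSet-class] or data.frame(start, end) in seconds;
#'   NULL analyses the whole recording
#' @param maxBin highest 1-Hz bin to report (default 40)
#' @param csd optional precomputed [welchCsd()] result (shared with the
#'   coherence computation to avoid re-estimating the spectra)
#' @return channels x bins matrix of absolute power (uV^2), with attributes
#'   \code{freq}/\code{psd} carrying the native grid and
#'   \code{skippedSegments}.
#' @export
powerSpectrum <- function(recording, segments = NULL, maxBin = 40,
                          csd = NULL) {
  fs <- samplingRate(recording)
  seg <- if (is.null(segments)) NULL else .segmentsOf(segments)
  cs <- if (is.null(csd))
    welchCsd(signalMatrix(recording), fs, seg, cross = FALSE) else csd
  bins <- seq_len(maxBin)
  out <- matrix(0, nrow(cs$auto), length(bins),
                dimnames = list(channelLabels(recording), bins))
  for (k in bins) {
    idx <- which(abs(cs$freq - (k - 0.5)) < 1e-9 | abs(cs$freq - k) < 1e-9)
    out[, k] <- rowSums(cs$auto[, idx, drop = FALSE]) * 0.5
  }
  attr(out, "freq") <- cs$freq
  attr(out, "psd") <- cs$auto
  attr(out, "skippedSegments") <- cs$skippedSegments
  out
}

#' Aggregate 1-Hz bin powers to band powers
#'
#' Band power is the sum of its member bins under the half-open [low, high)
#' convention of [bandScheme()] (last band closed).
#'
#' @param binPowers channels x bins matrix from [powerSpectrum()]
#' @param scheme band scheme data.frame
#' @return channels x bands matrix (uV^2)
#' @export
bandPower <- function(binPowers, scheme = bandScheme()) {
  have <- as.integer(colnames(binPowers))
  need <- seq(min(scheme$low), max(scheme$high))
  if (!all(need %in% have))
    stop("bin powers must cover 1-Hz bins ",
         min(scheme$low), "..", max(scheme$high))
  out <- vapply(scheme$name, function(b) {
    idx <- match(bandBins(scheme, b), have)
    rowSums(binPowers[, idx, drop = FALSE])
  }, numeric(nrow(binPowers)))
  if (is.null(dim(out)))
    out <- matrix(out, 1, length(scheme$name),
                  dimnames = list(rownames(binPowers), scheme$name))
  out
}

#' Electrode-averaged mean power per band
#'
#' Unweighted arithmetic mean across the full 12-channel montage.
#'
#' @param bandPowers channels x bands matrix from [bandPower()]
#' @param nChannels required montage size (default 12)
#' @return named numeric vector, one mean power per band (uV^2)
#' @export
meanPower <- function(bandPowers, nChannels = 12) {
  if (nrow(bandPowers) != nChannels)
    stop("mean power requires the full ", nChannels, "-channel montage, got ",
         nrow(bandPowers), " channels")
  colMeans(bandPowers)
}

#' Band-power table for one subject x epoch
#'
#' Convenience wrapper producing one tidy row block: per-channel bin and band
#' powers plus the electrode-averaged means.
#'
#' @inheritParams powerSpectrum
#' @param scheme band scheme
#' @param subject,epoch identifiers stamped on the rows
#' @param csd optional precomputed [welchCsd()] result
#' @return list with elements \code{bins} (channels x 40), \code{bands}
#'   (channels x 6), \code{mean} (named band vector), \code{table}
#'   (tidy data.frame)
#' @export
bandPowerTable <- function(recording, segments = NULL, scheme = bandScheme(),
                           subject = subjectId(recording), epoch = NA,
                           csd = NULL) {
  bins <- powerSpectrum(recording, segments, csd = csd)
  bands <- bandPower(bins, scheme)
  mp <- meanPower(bands, nChannels = nrow(bins))
  tab <- data.frame(subject = subject, epoch = epoch,
                    channel = rep(rownames(bands), ncol(bands)),
                    band = rep(colnames(bands), each = nrow(bands)),
                    power = as.vector(bands), stringsAsFactors = FALSE)
  list(bins = bins, bands = bands, mean = mp, table = tab)
}
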