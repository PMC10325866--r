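#' Segment selection criteria
#'
#' The semiautomatic artifact-free selection criteria: accepted windows may
#' not exceed 1.25x the exemplar's per-channel maximal amplitude, the
#' accepted set must reach split-half and test-retest reliability of at
#' least 0.9, at least 30 s must survive for the epoch to enter analysis,
#' and selection aims for about 2 min of signal built from a 10-s exemplar.
#'
#' @param amplitudeFactor multiplier on the exemplar per-channel max
#' @param splitHalfMin,testRetestMin minimal reliabilities in (0, 1]
#' @param minTotalS minimal accepted signal, s
#' @param targetTotalS selection target, s
#' @param exemplarTotalS exemplar length, s
#' @return criteria list
#' @export
selectionCriteria <- function(amplitudeFactor = 1.25, splitHalfMin = 0.9,
                              testRetestMin = 0.9, minTotalS = 30,
                              targetTotalS = 120, exemplarTotalS = 10) {
  stopifnot(amplitudeFactor > 1,
            splitHalfMin > 0, splitHalfMin <= 1,
            testRetestMin > 0, testRetestMin <= 1,
            minTotalS <= targetTotalS)
  list(amplitudeFactor = amplitudeFactor, splitHalfMin = splitHalfMin,
       testRetestMin = testRetestMin, minTotalS = minTotalS,
       targetTotalS = targetTotalS, exemplarTotalS = exemplarTotalS)
}

#' Linear-phase FIR bandpass with group-delay compensation
#'
#' Window-designed FIR bandpass (default 111 coefficients, 0.5-40 Hz, the
#' digital front-end the analysis assumes), applied with exact group-delay
#' compensation so filtering introduces no net shift. The tap count must be
#' odd (type-I linear phase).
#'
#' @param recording an [EEGRecording-class]
#' @param low,high band edges, Hz
#' @param nTaps number of filter coefficients (odd)
#' @return the filtered recording
#' @export
bandpassFir <- function(recording, low = 0.5, high = 40, nTaps = 111) {
  fs <- samplingRate(recording)
  if (nTaps %% 2 == 0)
    stop("nTaps must be odd (type-I linear-phase FIR)")
  if (!(low > 0 && low < high && high < fs / 2))
    stop("need 0 < low < high < samplingRate/2")
  h <- .firTaps(low, high, nTaps, fs)
  gd <- (nTaps - 1) / 2
  sig <- signalMatrix(recording)
  n <- ncol(sig)
  # FFT convolution, trimmed by the group delay for zero net shift
  L <- stats::nextn(n + nTaps - 1)
  H <- stats::fft(c(h, rep(0, L - nTaps)))
  X <- stats::mvfft(rbind(t(sig), matrix(0, L - n, nrow(sig))))
  y <- Re(stats::mvfft(X * H, inverse = TRUE)) / L
  out <- t(y[(gd + 1):(gd + n), , drop = FALSE])
  dimnames(out) <- dimnames(sig)
  initialize(recording, signal = out)
}

# window-designed bandpass taps with an exact spectral null at DC: a short
# filter with a 0.5 Hz lower edge otherwise passes a large fraction of any
# constant offset, so the residual DC gain is removed by a Hamming-weighted
# tap correction (Hamming sidelobes keep the passband perturbation < 1%)
.firTaps <- function(low, high, nTaps, fs) {
  h <- signal::fir1(nTaps - 1, c(low, high) / (fs / 2), type = "pass")
  w <- 0.54 - 0.46 * cos(2 * pi * seq(0, nTaps - 1) / (nTaps - 1))
  h - sum(h) * w / sum(w)
}

#' Frequency response of the analysis FIR filter
#'
#' Utility to evaluate the designed bandpass at arbitrary frequencies, e.g.
#' to verify stopband attenuation.
#'
#' @param f frequencies, Hz
#' @inheritParams bandpassFir
#' @param fs sampling rate, Hz
#' @return complex response at \code{f}
#' @export
firResponse <- function(f, low = 0.5, high = 40, nTaps = 111, fs = 250) {
  h <- .firTaps(low, high, nTaps, fs)
  sapply(f, function(ff) {
    z <- exp(-1i * 2 * pi * ff / fs * (0:(nTaps - 1)))
    sum(h * z)
  })
}

#' Carve the analysis epochs out of a recording
#'
#' Produces one named slice per epoch window (baseline plus the three
#' post-administration windows by default). Post windows are measured from
#' the administration time. Windows not fully covered by the recording are
#' flagged missing rather than silently truncated.
#'
#' @param recording an [EEGRecording-class] with adminTime set (unless
#'   explicit \code{epochs} are supplied)
#' @param epochs optional data.frame(epoch, start, end), s absolute
#' @return named list; each element has \code{recording} (slice with
#'   slice-local markers; NULL when missing), \code{start}, \code{end}
#'   (absolute s) and \code{missing}
#' @export
extractEpochs <- function(recording, epochs = NULL) {
  if (is.null(epochs)) {
    at <- adminTime(recording)
    if (is.na(at)) stop("administration time not set and no epochs supplied")
    epochs <- epochWindows(at)
  }
  dur <- recordingDuration(recording)
  fs <- samplingRate(recording)
  sig <- signalMatrix(recording)
  mk <- recordingMarkers(recording)
  out <- list()
  for (i in seq_len(nrow(epochs))) {
    s <- epochs$start[i]; e <- epochs$end[i]
    if (s < 0 || e > dur + 1e-9) {
      out[[epochs$epoch[i]]] <- list(recording = NULL, start = s, end = e,
                                     missing = TRUE)
      next
    }
    idx <- (floor(s * fs) + 1L):round(e * fs)
    mloc <- mk[mk$end > s & mk$start < e, , drop = FALSE]
    if (nrow(mloc)) {
      mloc$start <- pmax(mloc$start, s) - s
      mloc$end <- pmin(mloc$end, e) - s
      rownames(mloc) <- NULL
    }
    slice <- EEGRecording(sig[, idx, drop = FALSE],
                          samplingRate = fs,
                          layout = electrodeLayout(recording),
                          markers = mloc,
                          subject = subjectId(recording),
                          group = treatmentGroup(recording),
                          adminTime = NA_real_)
    out[[epochs$epoch[i]]] <- list(recording = slice, start = s, end = e,
                                   missing = FALSE)
  }
  out
}

#' Split-half and test-retest reliability of a per-second amplitude series
#'
#' Symmetric power-agreement ratios: with m_h the mean squared amplitude of
#' half h, reliability = 1 - |m_1 - m_2| / (m_1 + m_2), in [0, 1].
#' Split-half compares interleaved (odd/even second) halves; test-retest the
#' first and second temporal halves. An all-zero series is degenerate and
#' returns 1 for both (flagged). This is a documented stand-in for the
#' unpublished vendor metrics sharing their >= 0.9 threshold semantics.
#'
#' @param values per-second amplitude series (e.g. per-second RMS), length
#'   >= 4
#' @return list(splitHalf, testRetest, degenerate)
#' @export
reliability <- function(values) {
  if (length(values) < 4) stop("need at least 4 one-second blocks")
  m <- values^2
  agree <- function(m1, m2) {
    if (m1 + m2 == 0) return(1)
    1 - abs(m1 - m2) / (m1 + m2)
  }
  odd <- seq(1, length(m), by = 2)
  half <- seq_len(floor(length(m) / 2))
  list(
    splitHalf = agree(mean(m[odd]), mean(m[-odd])),
    testRetest = agree(mean(m[half]), mean(m[-half])),
    degenerate = all(m == 0)
  )
}

#' Semiautomatic artifact-free segment selection within one epoch
#'
#' Deterministic stand-in for exemplar-guided manual selection:
#' \enumerate{
#'   \item usable seconds are the 1-s blocks fully inside behavioral
#'     inactivity and outside handling/sleep-suspect/artifact intervals;
#'   \item the exemplar is the 10 s of usable signal with the lowest
#'     across-channel peak amplitude;
#'   \item usable seconds whose per-channel peak amplitude stays within
#'     \code{amplitudeFactor} times the exemplar's per-channel maximum are
#'     accepted chronologically until the 120-s target is reached or
#'     material is exhausted;
#'   \item split-half/test-retest reliability of the accepted per-second RMS
#'     must reach 0.9, dropping the worst-offending seconds until both pass;
#'   \item epochs retaining less than 30 s are rejected.
#' }
#'
#' @param epoch an element of [extractEpochs()] output, or an
#'   [EEGRecording-class] (then treated as starting at t = 0)
#' @param criteria a [selectionCriteria()] list
#' @param epochName epoch label stamped on the result
#' @return a [SegmentSet-class]; segment times are absolute recording time
#' @export
selectSegments <- function(epoch, criteria = selectionCriteria(),
                           epochName = NULL) {
  if (is(epoch, "EEGRecording"))
    epoch <- list(recording = epoch, start = 0,
                  end = recordingDuration(epoch), missing = FALSE)
  if (isTRUE(epoch$missing) || is.null(epoch$recording))
    return(.rejectedSet(epoch, epochName, "epoch window missing"))
  rec <- epoch$recording
  fs <- samplingRate(rec)
  sig <- signalMatrix(rec)
  dur <- floor(recordingDuration(rec))
  mk <- recordingMarkers(rec)

  inact <- intervalUnion(mk[mk$label == "inactive", c("start", "end")])
  excl <- intervalUnion(mk[mk$label %in%
                             c("active", "handling", "sleep_suspect",
                               "artifact"), c("start", "end")])
  usableIv <- intervalDiff(inact, excl)
  if (intervalLength(usableIv) == 0)
    return(.rejectedSet(epoch, epochName, "no inactive interval"))

  secs <- seq_len(dur)
  usable <- vapply(secs, function(k) {
    any(usableIv$start <= (k - 1) + 1e-9 & usableIv$end >= k - 1e-9)
  }, logical(1))
  usec <- secs[usable]
  if (length(usec) < criteria$exemplarTotalS)
    return(.rejectedSet(epoch, epochName,
                        "insufficient inactive signal for exemplar"))

  # per-second per-channel peak amplitude and pooled RMS
  peaks <- t(vapply(usec, function(k) {
    blk <- sig[, ((k - 1) * fs + 1):(k * fs), drop = FALSE]
    apply(abs(blk), 1, max)
  }, numeric(nrow(sig))))
  rms <- vapply(usec, function(k) {
    blk <- sig[, ((k - 1) * fs + 1):(k * fs), drop = FALSE]
    sqrt(mean(blk^2))
  }, numeric(1))

  ord <- order(apply(peaks, 1, max), usec)
  exemplar <- ord[seq_len(criteria$exemplarTotalS)]
  exMax <- apply(peaks[exemplar, , drop = FALSE], 2, max)

  ok <- apply(peaks, 1, function(p)
    all(p <= criteria$amplitudeFactor * exMax + 1e-12))
  cand <- which(ok)
  cand <- cand[seq_len(min(length(cand), criteria$targetTotalS))]

  # reliability pruning: drop the second with the most deviant power until
  # both criteria pass or the minimum length is hit
  keep <- cand
  repeat {
    if (length(keep) < max(4, criteria$minTotalS)) break
    rel <- reliability(rms[keep])
    if (rel$splitHalf >= criteria$splitHalfMin &&
        rel$testRetest >= criteria$testRetestMin) break
    dev <- abs(rms[keep]^2 - stats::median(rms[keep]^2))
    keep <- keep[-which.max(dev)]
  }
  if (length(keep) >= 4) {
    rel <- reliability(rms[keep])
    relOk <- rel$splitHalf >= criteria$splitHalfMin &&
      rel$testRetest >= criteria$testRetestMin
  } else relOk <- FALSE

  if (length(keep) < criteria$minTotalS)
    return(.rejectedSet(epoch, epochName, sprintf(
      "only %d s survive selection (minimum %d s)",
      length(keep), criteria$minTotalS)))
  if (!relOk)
    return(.rejectedSet(epoch, epochName, "reliability criteria not met"))

  segs <- .secondsToSegments(sort(usec[keep]), epoch$start)
  new("SegmentSet", subject = subjectId(rec),
      epoch = if (is.null(epochName)) NA_character_ else epochName,
      segments = segs, totalS = sum(segs$end - segs$start),
      accepted = TRUE, reason = "")
}

.secondsToSegments <- function(secs, offset) {
  if (!length(secs)) return(.emptyIntervals())
  brk <- c(0, which(diff(secs) > 1), length(secs))
  do.call(rbind, lapply(seq_len(length(brk) - 1), function(i) {
    s <- secs[(brk[i] + 1):brk[i + 1]]
    data.frame(start = offset + min(s) - 1, end = offset + max(s))
  }))
}

.rejectedSet <- function(epoch, epochName, reason) {
  subj <- if (!is.null(epoch$recording)) subjectId(epoch$recording)
          else NA_character_
  new("SegmentSet", subject = subj,
      epoch = if (is.null(epochName)) NA_character_ else epochName,
      segments = .emptyIntervals(), totalS = 0,
      accepted = FALSE, reason = reason)
}
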