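# Phase-lagged coherence, baseline-relative connectivity change, the
# per-subject global functional connectivity (GFC) scalar, and the KDE
# characterization of pooled connectivity-change distributions.

#' Phase-lagged coherence per electrode pair and band
#'
#' From Welch cross- and auto-spectra over the accepted segments, the lagged
#' coherence at each frequency bin is
#' \deqn{LC(f) = Im(S_{xy})^2 / (S_{xx} S_{yy} - Re(S_{xy})^2),}
#' which removes the zero-lag (volume-conduction / common-reference)
#' component: any instantaneous linear mixture of independent sources has
#' LC = 0. Values are in [0, 1]. Band values aggregate the bins of each
#' band's 1-Hz bins (native 0.5-Hz grid) weighted by the geometric mean of
#' the two auto-spectra, so bins with negligible power do not dominate.
#' Degenerate bins (denominator below 1e-12, e.g. zero auto-power) yield 0.
#'
#' @param recording an [EEGRecording-class]
#' @param segments a [SegmentSet-class] or data.frame(start, end); NULL =
#'   whole recording
#' @param scheme band scheme
#' @param subject,epoch identifiers stamped on the rows
#' @param csd optional precomputed [welchCsd()] result (with cross spectra)
#' @return data.frame(subject, epoch, ch1, ch2, band, lc) over all unordered
#'   channel pairs
#' @export
laggedCoherence <- function(recording, segments = NULL,
                            scheme = bandScheme(),
                            subject = subjectId(recording), epoch = NA,
                            csd = NULL) {
  seg <- if (is.null(segments)) NULL else .segmentsOf(segments)
  cs <- if (is.null(csd))
    welchCsd(signalMatrix(recording), samplingRate(recording), seg,
             cross = TRUE) else csd
  if (is.null(cs$cross)) stop("csd lacks cross spectra")
  labels <- channelLabels(recording)
  pairs <- .channelPairs(labels)
  bandIdx <- lapply(scheme$name, function(b) {
    fg <- as.vector(rbind(bandBins(scheme, b) - 0.5, bandBins(scheme, b)))
    match(fg, cs$freq)
  })
  names(bandIdx) <- scheme$name
  out <- expand.grid(pair = seq_len(nrow(pairs)), band = scheme$name,
                     stringsAsFactors = FALSE)
  out$lc <- NA_real_
  for (r in seq_len(nrow(out))) {
    i <- match(pairs$ch1[out$pair[r]], labels)
    j <- match(pairs$ch2[out$pair[r]], labels)
    idx <- bandIdx[[out$band[r]]]
    sxy <- cs$cross[idx, i, j]
    sxx <- cs$auto[i, idx]
    syy <- cs$auto[j, idx]
    den <- sxx * syy - Re(sxy)^2
    lcf <- ifelse(den < 1e-12, 0, Im(sxy)^2 / den)
    w <- sqrt(sxx * syy)
    out$lc[r] <- if (sum(w) <= 0) 0 else sum(w * lcf) / sum(w)
  }
  data.frame(subject = subject, epoch = epoch,
             ch1 = pairs$ch1[out$pair], ch2 = pairs$ch2[out$pair],
             band = out$band, lc = pmin(1, pmax(0, out$lc)),
             stringsAsFactors = FALSE)
}

#' Baseline-relative lagged-coherence change
#'
#' Per-cell Box-Cox (lambda = 0) ratio to the subject's own baseline:
#' change = log(LC_epoch / LC_baseline). Cells where either epoch's
#' coherence falls below \code{floor} are masked (NA) rather than producing
#' extreme logs.
#'
#' @param table coherence data.frame for one subject x epoch
#'   (from [laggedCoherence()])
#' @param baseline coherence data.frame of the same subject's baseline
#' @param floor coherence floor below which cells are masked
#' @return \code{table} with an added \code{change} column
#' @export
coherenceChange <- function(table, baseline, floor = 1e-3) {
  key <- function(d) paste(d$ch1, d$ch2, d$band)
  i <- match(key(table), key(baseline))
  if (anyNA(i)) stop("baseline table does not cover all pair x band cells")
  lc0 <- baseline$lc[i]
  out <- table
  out$change <- ifelse(out$lc < floor | lc0 < floor, NA_real_,
                       log(out$lc / lc0))
  out
}

#' Global functional connectivity (GFC) scalar
#'
#' The per-subject, per-epoch mean of the baseline-relative lagged-coherence
#' changes across all electrode pairs and frequency bands. Undefined
#' (flagged) when fewer than \code{minCoverage} of the pair x band cells are
#' unmasked.
#'
#' @param changes data.frame from [coherenceChange()]
#' @param minCoverage minimal fraction of unmasked cells
#' @return list(gfc, changeSamples, coverage, defined, subject, epoch)
#' @export
gfc <- function(changes, minCoverage = 0.5) {
  samples <- changes$change[!is.na(changes$change)]
  coverage <- length(samples) / nrow(changes)
  defined <- coverage >= minCoverage
  list(gfc = if (defined) mean(samples) else NA_real_,
       changeSamples = samples, coverage = coverage, defined = defined,
       subject = changes$subject[1], epoch = changes$epoch[1])
}

#' Gaussian kernel density of pooled connectivity changes
#'
#' Fixed-bandwidth Gaussian KDE (kernel standard deviation 0.5, the kernel
#' width used for the qualitative GFC pattern) of change values concatenated
#' across subjects, electrode pairs and frequency bands, evaluated on a
#' fixed grid spanning the observed range plus a 4-bandwidth margin (wide
#' enough that the curve integrates to 1 within 1e-3 even for a single
#' sample).
#'
#' @param samples pooled change values (>= 1, finite)
#' @param bandwidth Gaussian kernel standard deviation
#' @param n grid length
#' @param range optional c(lo, hi) grid range override (before margin)
#' @return data.frame(grid, density)
#' @export
kdeDistribution <- function(samples, bandwidth = 0.5, n = 512,
                            range = NULL) {
  samples <- samples[is.finite(samples)]
  if (!length(samples)) stop("no finite samples for the KDE")
  if (is.null(range)) range <- c(min(samples), max(samples))
  grid <- seq(range[1] - 4 * bandwidth, range[2] + 4 * bandwidth,
              length.out = n)
  dens <- vapply(grid, function(g)
    mean(stats::dnorm(g - samples, sd = bandwidth)), numeric(1))
  data.frame(grid = grid, density = dens)
}

#' Mode of a KDE curve
#' @param kde data.frame(grid, density)
#' @return grid location of the maximal density
#' @export
kdeMode <- function(kde) kde$grid[which.max(kde$density)]
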