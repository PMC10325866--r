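# Synthetic multichannel rodent-EEG generator with analytically known ground
# truth. Channels are sums of band-limited noise sources (4th-order
# Butterworth bandpass magnitude, applied in the frequency domain, zero
# phase), partially shared across coupled electrode pairs with a pure sample
# delay, plus a 1/f background and white sensor noise. Because every
# component has a closed-form spectrum, band powers and lagged coherences of
# the generative model are computed exactly from the mixing weights and lags
# rather than estimated from the realized signal.

#' Epoch analysis windows
#'
#' Ten minutes of baseline immediately before administration and three
#' post-administration windows at 20-30, 50-60 and 80-90 min by default
#' (all configurable for scaled-down studies).
#'
#' @param adminTime administration time, s from recording start
#' @param baselineLen baseline window length, s
#' @param offsets named numeric vector of post-administration window start
#'   offsets, s after administration
#' @param epochLen post window length, s
#' @return data.frame(epoch, start, end), seconds, absolute recording time
#' @examples
#' epochWindows(600) # E1 runs 1800..2400 s
#' @export
epochWindows <- function(adminTime = 600, baselineLen = 600,
                         offsets = c(E1 = 1200, E2 = 3000, E3 = 4800),
                         epochLen = 600) {
  data.frame(
    epoch = c("baseline", names(offsets)),
    start = c(max(0, adminTime - baselineLen), adminTime + offsets),
    end = c(adminTime, adminTime + offsets + epochLen),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Default pairwise coupling structure
#'
#' Cortical EEG is coherent across much of the montage, so the default
#' couples every homologous left/right pair (shared-variance fraction 0.4)
#' and the ipsilateral fronto-parieto-temporal chains F-C, C-P3, P3-P5,
#' P5-T5 and T3-P3 with their right-hemisphere homologues (fraction 0.18),
#' in all six bands, with band-specific conduction delays shrinking from
#' 16 ms (delta) to 4 ms (gamma). Per-channel shared fractions stay below 1
#' so every channel keeps a private source. This gives 16 coupled pairs
#' (96 of the 396 pair x band cells) carrying true lagged coherence - a
#' coarse caricature of interhemispheric plus anterior-posterior coupling.
#'
#' @param layout electrode layout
#' @return data.frame(ch1, ch2, band, weight, lagMs)
#' @export
defaultCoupling <- function(layout = defaultLayout()) {
  hp <- homologousPairs(layout)
  chains <- data.frame(
    ch1 = c("F3", "C3", "P3", "P5", "T3", "F4", "C4", "P4", "P6", "T4"),
    ch2 = c("C3", "P3", "P5", "T5", "P3", "C4", "P4", "P6", "T6", "P4"),
    stringsAsFactors = FALSE)
  lag <- c(delta = 16, theta = 14, alpha = 12, beta = 6, high_beta = 5,
           gamma = 4)
  do.call(rbind, lapply(names(lag), function(b) rbind(
    data.frame(ch1 = hp$ch1, ch2 = hp$ch2, band = b, weight = 0.4,
               lagMs = lag[[b]], stringsAsFactors = FALSE),
    data.frame(ch1 = chains$ch1, ch2 = chains$ch2, band = b, weight = 0.18,
               lagMs = lag[[b]], stringsAsFactors = FALSE))))
}

#' Simulation configuration
#'
#' Bundles all generative parameters. Defaults mirror a full-length session:
#' 100 min at 250 Hz, administration at 600 s, band RMS amplitudes tapering
#' from 40 uV (delta) to 8 uV (gamma), 10 uV 1/f background, 2 uV white
#' sensor noise, the [defaultCoupling()] structure, and active-behavior
#' episodes carrying >40 Hz EMG noise plus large movement transients.
#'
#' @param samplingRate Hz
#' @param duration total length, s
#' @param adminTime administration time, s
#' @param epochs epoch window data.frame (see [epochWindows()])
#' @param bandAmplitudes named per-band RMS amplitude, uV
#' @param coupling data.frame(ch1, ch2, band, weight, lagMs); weight is the
#'   shared-source variance fraction in [0, 1], lag a pure delay in ms
#' @param pinkAmplitude,whiteAmplitude RMS of the 1/f background and of the
#'   per-channel white noise, uV
#' @param drugEffect named list, one entry per post-baseline epoch:
#'   \code{list(powerGain = , couplingGain = )}; powerGain is a scalar or
#'   per-band named vector multiplying band *power*, couplingGain in [0, 1]
#'   multiplies every shared-variance fraction
#' @param activitySchedule data.frame(start, end) of active-behavior
#'   episodes, s (everything else is inactive)
#' @param emgAmplitude RMS of EMG-like >40 Hz noise added during activity, uV
#' @param artifactAmplitude movement-transient amplitude, uV
#' @param transientsPerMin expected movement transients per active minute
#' @param scheme band scheme (defines the bands amplitudes refer to)
#' @param quantize logical: apply 16-bit quantization to the output
#' @param halfRange,bits quantizer dynamic half-range (uV) and bit depth
#' @return validated config list of class \code{qeegSimConfig}
#' @export
simulationConfig <- function(samplingRate = 250, duration = 6000,
                             adminTime = 600,
                             epochs = epochWindows(adminTime),
                             bandAmplitudes = c(delta = 40, theta = 30,
                                                alpha = 20, beta = 12,
                                                high_beta = 9, gamma = 8),
                             coupling = defaultCoupling(),
                             pinkAmplitude = 10, whiteAmplitude = 2,
                             drugEffect = list(),
                             activitySchedule = NULL,
                             emgAmplitude = 30, artifactAmplitude = 300,
                             transientsPerMin = 2,
                             scheme = bandScheme(),
                             quantize = TRUE, halfRange = 500, bits = 16) {
  if (is.null(activitySchedule))
    activitySchedule <- .emptyIntervals()
  cfg <- list(samplingRate = samplingRate, duration = duration,
              adminTime = adminTime, epochs = epochs,
              bandAmplitudes = bandAmplitudes, coupling = coupling,
              pinkAmplitude = pinkAmplitude, whiteAmplitude = whiteAmplitude,
              drugEffect = drugEffect, activitySchedule = activitySchedule,
              emgAmplitude = emgAmplitude,
              artifactAmplitude = artifactAmplitude,
              transientsPerMin = transientsPerMin, scheme = scheme,
              quantize = quantize, halfRange = halfRange, bits = bits)
  class(cfg) <- "qeegSimConfig"
  validateSimulationConfig(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Rejects durations shorter than the epoch schedule, negative gains or lags,
#' zero-lag couplings with nonzero weight (invisible to the lagged metric),
#' per-channel shared-variance fractions above 1, and lags at or beyond the
#' band's center period, for which the intended coherence target is
#' ill-posed (phase wrap); such configs are flagged, never silently clipped.
#'
#' @param cfg a config list from [simulationConfig()]
#' @return the config, invisibly; errors when invalid
#' @export
validateSimulationConfig <- function(cfg) {
  stopifnot(cfg$samplingRate > 0, cfg$duration > 0)
  if (max(cfg$epochs$end) > cfg$duration + 1e-9)
    stop("duration (", cfg$duration,
         " s) is shorter than the epoch schedule (ends at ",
         max(cfg$epochs$end), " s)")
  if (!all(cfg$scheme$name %in% names(cfg$bandAmplitudes)))
    stop("bandAmplitudes must name every band of the scheme")
  if (any(cfg$bandAmplitudes < 0) || cfg$pinkAmplitude < 0 ||
      cfg$whiteAmplitude < 0)
    stop("amplitudes must be >= 0")
  cp <- cfg$coupling
  if (nrow(cp)) {
    stopifnot(all(cp$weight >= 0), all(cp$weight <= 1), all(cp$lagMs >= 0))
    if (any(cp$weight > 0 & cp$lagMs <= 0))
      stop("couplings with nonzero weight need lag > 0: ",
           "zero-lag coupling carries no lagged coherence")
    i <- match(cp$band, cfg$scheme$name)
    if (anyNA(i)) stop("coupling band not in scheme")
    period <- 2 / (cfg$scheme$low[i] + cfg$scheme$high[i])
    bad <- cp$lagMs / 1000 >= period
    if (any(bad))
      stop("coupling lag >= band center period for ",
           paste(sprintf("%s-%s/%s", cp$ch1[bad], cp$ch2[bad], cp$band[bad]),
                 collapse = ", "),
           ": lagged-coherence target ill-posed")
    # per channel x band total shared fraction must leave room for a
    # private source
    key <- c(paste(cp$ch1, cp$band), paste(cp$ch2, cp$band))
    tot <- tapply(c(cp$weight, cp$weight), key, sum)
    if (any(tot > 1 + 1e-12))
      stop("total shared variance fraction > 1 for ",
           paste(names(tot)[tot > 1 + 1e-12], collapse = ", "))
  }
  for (e in names(cfg$drugEffect)) {
    de <- cfg$drugEffect[[e]]
    if (!is.null(de$powerGain) && any(de$powerGain < 0))
      stop("powerGain must be >= 0")
    if (!is.null(de$couplingGain) &&
        (de$couplingGain < 0 || de$couplingGain > 1))
      stop("couplingGain must be in [0, 1]")
    if (!e %in% cfg$epochs$epoch) stop("drugEffect epoch not in schedule: ", e)
  }
  invisible(cfg)
}

# ---- analytic component spectra ---------------------------------------------

# squared magnitude of the analog 4th-order Butterworth bandpass prototype
.butterBandMag2 <- function(f, low, high, order = 4) {
  q <- ifelse(f <= 0, Inf, (f^2 - low * high) / (pmax(f, 1e-12) * (high - low)))
  ifelse(is.infinite(q), 0, 1 / (1 + q^(2 * order)))
}

.highpassMag2 <- function(f, fc, order = 4) {
  r <- (f / fc)^(2 * order)
  r / (1 + r)
}

# 1/f magnitude-squared shape, flattened below f0 to keep it integrable
.pinkMag2 <- function(f, f0 = 0.5) 1 / pmax(abs(f), f0)

# synthesize k independent unit-variance noise columns with the given
# two-sided magnitude shape; the shape's normalization links it to a
# one-sided PSD: S(f) = (2/fs) * mag2(f) / mean(mag2)
.shapedNoiseMatrix <- function(n, fs, mag2fun, k = 1) {
  f <- (seq_len(n) - 1) / n * fs
  f <- pmin(f, fs - f)
  m2 <- mag2fun(f)
  m <- sqrt(m2 / mean(m2))
  # the filter kernel is real (m is even-symmetric), so two independent
  # real series can ride one complex FFT: Re/Im of the result are the two
  # filtered series
  kk <- ceiling(k / 2)
  z <- matrix(stats::rnorm(n * kk), n, kk) +
    1i * matrix(stats::rnorm(n * kk), n, kk)
  y <- stats::mvfft(stats::mvfft(z) * m, inverse = TRUE) / n
  x <- matrix(0, n, 2 * kk)
  x[, seq(1, 2 * kk, by = 2)] <- Re(y)
  x[, seq(2, 2 * kk, by = 2)] <- Im(y)
  x[, seq_len(k), drop = FALSE]
}

.shapedNoise <- function(n, fs, mag2fun) {
  list(x = .shapedNoiseMatrix(n, fs, mag2fun, 1)[, 1])
}

# circular delay by d samples (consistent with the circularly stationary
# frequency-domain synthesis, so the cross-spectrum is exactly e^{-i w d/fs})
.delaySamples <- function(x, d) {
  n <- length(x)
  d <- d %% n
  if (d == 0) x else c(x[(n - d + 1):n], x[1:(n - d)])
}

# per-epoch multiplicative gains resolved from the drugEffect list:
# baseline = 1; post epochs take their configured gains (default 1)
.epochGains <- function(cfg) {
  bands <- cfg$scheme$name
  eps <- cfg$epochs$epoch
  pg <- matrix(1, length(bands), length(eps), dimnames = list(bands, eps))
  cg <- stats::setNames(rep(1, length(eps)), eps)
  for (e in names(cfg$drugEffect)) {
    de <- cfg$drugEffect[[e]]
    if (!is.null(de$powerGain)) {
      g <- de$powerGain
      if (is.null(names(g)) && length(g) == 1) g <- stats::setNames(rep(g, length(bands)), bands)
      pg[names(g), e] <- g
    }
    if (!is.null(de$couplingGain)) cg[e] <- de$couplingGain
  }
  list(power = pg, coupling = cg)
}

# gain-constant stretches of the recording: gains are step functions that
# switch at each post-administration epoch start and hold until the next one
# (value 1 before the first post window); each stretch is stationary, so the
# signal is synthesized per stretch
.gainSegments <- function(cfg) {
  n <- round(cfg$duration * cfg$samplingRate)
  post <- cfg$epochs[cfg$epochs$epoch != "baseline", ]
  post <- post[order(post$start), ]
  if (nrow(post) == 0)
    return(data.frame(i0 = 1L, i1 = n, epoch = "baseline"))
  b <- pmin(n + 1L, round(post$start * cfg$samplingRate) + 1L)
  out <- data.frame(i0 = c(1L, b), i1 = c(b - 1L, n),
                    epoch = c("baseline", post$epoch),
                    stringsAsFactors = FALSE)
  out[out$i1 >= out$i0, ]
}

# ---- ground truth ------------------------------------------------------------

# analytic one-sided total PSD (uV^2/Hz) at frequencies f for one epoch
.analyticPsd <- function(cfg, f, epoch, norms) {
  g <- .epochGains(cfg)
  s <- rep(0, length(f))
  for (b in cfg$scheme$name) {
    i <- match(b, cfg$scheme$name)
    m2 <- .butterBandMag2(f, cfg$scheme$low[i], cfg$scheme$high[i])
    s <- s + cfg$bandAmplitudes[b]^2 * g$power[b, epoch] *
      (2 / cfg$samplingRate) * m2 / norms$band[b]
  }
  s <- s + cfg$pinkAmplitude^2 * (2 / cfg$samplingRate) *
    .pinkMag2(f) / norms$pink
  s + cfg$whiteAmplitude^2 * (2 / cfg$samplingRate)
}

# normalization constants of the shaped components: two-sided mean of the
# magnitude-squared shape on a fixed fine grid, so realization (any segment
# length) and analytic truth use the identical spectra
.componentNorms <- function(cfg) {
  M <- 65536L
  f <- (seq_len(M) - 1) / M * cfg$samplingRate
  f <- pmin(f, cfg$samplingRate - f)
  band <- sapply(seq_len(nrow(cfg$scheme)), function(i)
    mean(.butterBandMag2(f, cfg$scheme$low[i], cfg$scheme$high[i])))
  names(band) <- cfg$scheme$name
  list(band = band, pink = mean(.pinkMag2(f)))
}

#' Analytic ground truth of a simulation configuration
#'
#' Band powers and pairwise lagged coherences of the generative model per
#' epoch, derived in closed form from the component spectra, mixing weights
#' and (sample-rounded) delays - never from a realized signal. Powers are
#' evaluated on the same 0.5-Hz grid and 1-Hz binning the Welch analysis
#' uses; lagged coherence is aggregated over band bins with geometric-mean
#' auto-power weights, matching [laggedCoherence()]. Truth describes the
#' stationary inactive-state process (activity-period EMG and transients are
#' excluded by design).
#'
#' @param cfg simulation config
#' @param layout electrode layout
#' @return list with \code{bandPower} (channels x bands x epochs array,
#'   uV^2), \code{laggedCoherence} (data.frame ch1, ch2, band, epoch, lc)
#'   and \code{activitySchedule}
#' @export
groundTruth <- function(cfg, layout = defaultLayout()) {
  norms <- .componentNorms(cfg)
  g <- .epochGains(cfg)
  fs <- cfg$samplingRate
  eps <- cfg$epochs$epoch
  bands <- cfg$scheme$name
  chans <- layout$label

  bp <- array(0, dim = c(length(chans), length(bands), length(eps)),
              dimnames = list(chans, bands, eps))
  for (e in eps) {
    for (b in bands) {
      fgrid <- as.vector(rbind(bandBins(cfg$scheme, b) - 0.5,
                               bandBins(cfg$scheme, b)))
      bp[, b, e] <- sum(.analyticPsd(cfg, fgrid, e, norms)) * 0.5
    }
  }

  pairs <- .channelPairs(chans)
  lc <- expand.grid(pair = seq_len(nrow(pairs)), band = bands, epoch = eps,
                    stringsAsFactors = FALSE)
  lc <- data.frame(ch1 = pairs$ch1[lc$pair], ch2 = pairs$ch2[lc$pair],
                   band = lc$band, epoch = lc$epoch, lc = 0,
                   stringsAsFactors = FALSE)
  cp <- cfg$coupling
  if (nrow(cp)) {
    for (r in seq_len(nrow(lc))) {
      hit <- which((cp$ch1 == lc$ch1[r] & cp$ch2 == lc$ch2[r]) |
                   (cp$ch1 == lc$ch2[r] & cp$ch2 == lc$ch1[r]))
      if (!length(hit)) next
      bb <- lc$band[r]; e <- lc$epoch[r]
      fgrid <- as.vector(rbind(bandBins(cfg$scheme, bb) - 0.5,
                               bandBins(cfg$scheme, bb)))
      stot <- .analyticPsd(cfg, fgrid, e, norms)
      sxy <- rep(0 + 0i, length(fgrid))
      for (k in hit) {
        bi <- match(cp$band[k], bands)
        m2 <- .butterBandMag2(fgrid, cfg$scheme$low[bi], cfg$scheme$high[bi])
        sb <- cfg$bandAmplitudes[cp$band[k]]^2 * g$power[cp$band[k], e] *
          (2 / fs) * m2 / norms$band[cp$band[k]]
        tau <- round(cp$lagMs[k] / 1000 * fs) / fs
        sgn <- if (cp$ch1[k] == lc$ch1[r]) 1 else -1
        sxy <- sxy + cp$weight[k] * g$coupling[e] * sb *
          exp(-1i * 2 * pi * fgrid * tau * sgn)
      }
      den <- stot * stot - Re(sxy)^2
      lcf <- ifelse(den < 1e-12, 0, Im(sxy)^2 / den)
      w <- stot
      lc$lc[r] <- sum(w * lcf) / sum(w)
    }
  }
  list(bandPower = bp, laggedCoherence = lc,
       activitySchedule = cfg$activitySchedule)
}

# ---- quantization ------------------------------------------------------------

#' Quantizer step size
#'
#' The recording model's least-significant-bit size, defined as
#' \code{halfRange / 2^bits}. With the default +/-500 uV half-range and
#' 16-bit depth this is 0.00762939 uV = 7.63 nV per bit, the acquisition
#' resolution the pipeline emulates (about 131 bits/uV). Note the more
#' common full-range/2^bits convention would give twice this step; the
#' half-range convention is the one consistent with the emulated hardware's
#' printed resolution.
#'
#' @param halfRange dynamic half-range, uV
#' @param bits bit depth (>= 2)
#' @return step size, uV per bit
#' @export
quantStep <- function(halfRange = 500, bits = 16) {
  stopifnot(halfRange > 0, bits >= 2)
  halfRange / 2^bits
}

#' Uniform quantization of a microvolt series
#'
#' Values are clipped at +/- halfRange and rounded to integer multiples of
#' [quantStep()]. Multiply the counts by the step to reconstruct microvolts;
#' the reconstruction error is at most step/2 over the unclipped range.
#'
#' @param x numeric vector or matrix, uV
#' @param halfRange dynamic half-range, uV
#' @param bits bit depth
#' @return integer count series/matrix with attribute \code{step} (uV/bit)
#' @export
quantizeSignal <- function(x, halfRange = 500, bits = 16) {
  step <- quantStep(halfRange, bits)
  counts <- round(pmin(pmax(x, -halfRange), halfRange) / step)
  attr(counts, "step") <- step
  counts
}

# ---- recording synthesis -----------------------------------------------------

#' Generate a synthetic recording with known ground truth
#'
#' Realizes the generative model of [simulationConfig()]: per band, each
#' channel mixes a private band-limited source with the delayed shared
#' sources of its couplings (variance fractions preserved so auto-spectra are
#' coupling-invariant), epoch-wise drug gains are applied as step functions,
#' a 1/f background and white sensor noise are added, active-behavior
#' episodes receive >40 Hz EMG noise and large movement transients, and the
#' result is 16-bit quantized. Same seed and config give a bit-identical
#' recording.
#'
#' @param cfg simulation config
#' @param layout electrode layout
#' @param seed integer seed (mandatory: the generator is deterministic)
#' @param subject,group annotations stamped on the recording
#' @return list(recording = [EEGRecording-class], truth = [groundTruth()]
#'   output)
#' @export
generateRecording <- function(cfg, layout = defaultLayout(), seed,
                              subject = "S1", group = NA_character_) {
  validateSimulationConfig(cfg)
  validateLayout(layout)
  set.seed(as.integer(seed))
  fs <- cfg$samplingRate
  n <- round(cfg$duration * fs)
  nch <- nrow(layout)
  chans <- layout$label
  g <- .epochGains(cfg)

  # frequency-domain synthesis per gain-constant stretch: sources are drawn
  # as complex Gaussian spectral coefficients shaped by the component
  # magnitude (restricted to the band's numerical support), mixed into
  # channel spectra (delays = exact phase ramps), and inverse-transformed
  # once per channel
  norms <- .componentNorms(cfg)
  segs <- .gainSegments(cfg)
  sig <- matrix(0, nch, n, dimnames = list(chans, NULL))
  for (si in seq_len(nrow(segs))) {
    m <- segs$i1[si] - segs$i0[si] + 1L
    e <- segs$epoch[si]
    kidx <- seq_len(m) - 1
    ffold <- kidx / m * fs
    ffold <- pmin(ffold, fs - ffold)
    X <- matrix(0 + 0i, m, nch)
    cg <- g$coupling[e]
    for (bi in seq_len(nrow(cfg$scheme))) {
      b <- cfg$scheme$name[bi]
      m2 <- .butterBandMag2(ffold, cfg$scheme$low[bi], cfg$scheme$high[bi])
      sup <- which(m2 > 1e-4 * max(m2))
      if (!length(sup)) next
      mag <- sqrt(m2[sup] / norms$band[b])
      amp <- cfg$bandAmplitudes[b] * sqrt(g$power[b, e])
      cp <- cfg$coupling[cfg$coupling$band == b, , drop = FALSE]
      wsum <- rep(0, nch)
      if (nrow(cp)) for (k in seq_len(nrow(cp))) {
        ns <- length(sup)
        S <- complex(real = stats::rnorm(ns), imaginary = stats::rnorm(ns)) /
          sqrt(2) * mag
        w <- cp$weight[k] * cg
        d <- round(cp$lagMs[k] / 1000 * fs)
        i1c <- match(cp$ch1[k], chans); i2c <- match(cp$ch2[k], chans)
        X[sup, i1c] <- X[sup, i1c] + (amp * sqrt(w)) * S
        X[sup, i2c] <- X[sup, i2c] + (amp * sqrt(w)) * S *
          exp(-2i * pi * d / m * kidx[sup])
        wsum[i1c] <- wsum[i1c] + w
        wsum[i2c] <- wsum[i2c] + w
      }
      ns <- length(sup)
      Gp <- matrix(complex(real = stats::rnorm(ns * nch),
                           imaginary = stats::rnorm(ns * nch)),
                   ns, nch) / sqrt(2) * mag
      coef <- amp * sqrt(pmax(0, 1 - wsum))
      X[sup, ] <- X[sup, ] + Gp * rep(coef, each = ns)
    }
    if (cfg$pinkAmplitude > 0) {
      magp <- sqrt(.pinkMag2(ffold) / norms$pink)
      Gp <- matrix(complex(real = stats::rnorm(m * nch),
                           imaginary = stats::rnorm(m * nch)),
                   m, nch) / sqrt(2) * magp
      X <- X + cfg$pinkAmplitude * Gp
    }
    sig[, segs$i0[si]:segs$i1[si]] <-
      t(Re(stats::mvfft(X, inverse = TRUE))) * sqrt(2 / m)
  }
  if (cfg$whiteAmplitude > 0)
    sig <- sig + cfg$whiteAmplitude * matrix(stats::rnorm(n * nch), nch, n)

  # behavioral activity: EMG leakage above 40 Hz plus movement transients
  act <- intervalClip(intervalUnion(cfg$activitySchedule), 0, cfg$duration)
  if (nrow(act) && (cfg$emgAmplitude > 0 || cfg$artifactAmplitude > 0)) {
    hpf <- function(f) .highpassMag2(f, 40)
    for (ai in seq_len(nrow(act))) {
      i0 <- floor(act$start[ai] * fs) + 1L
      i1 <- min(n, round(act$end[ai] * fs))
      len <- i1 - i0 + 1L
      if (len < 2L) next
      if (cfg$emgAmplitude > 0)
        for (ci in seq_len(nch))
          sig[ci, i0:i1] <- sig[ci, i0:i1] +
            cfg$emgAmplitude * .shapedNoise(len, fs, hpf)$x
      if (cfg$artifactAmplitude > 0) {
        nt <- stats::rpois(1, cfg$transientsPerMin * len / fs / 60)
        if (nt > 0) {
          t0 <- sort(stats::runif(nt, act$start[ai], act$end[ai]))
          for (tt in t0) {
            idx <- max(1L, round((tt - 0.15) * fs)):min(n, round((tt + 0.15) * fs))
            tv <- idx / fs - tt
            pulse <- exp(-(tv / 0.05)^2) * sin(2 * pi * 3 * tv + pi / 2)
            amp <- cfg$artifactAmplitude * stats::runif(1, 0.7, 1.3)
            chscale <- stats::runif(nch, 0.5, 1)
            sig[, idx] <- sig[, idx] + outer(chscale, amp * pulse)
          }
        }
      }
    }
  }

  if (cfg$quantize) {
    q <- quantizeSignal(sig, cfg$halfRange, cfg$bits)
    sig <- q * attr(q, "step")
    dimnames(sig) <- list(chans, NULL)
  }

  inact <- intervalDiff(data.frame(start = 0, end = cfg$duration), act)
  markers <- rbind(
    if (nrow(act)) data.frame(start = act$start, end = act$end,
                              label = "active") else NULL,
    if (nrow(inact)) data.frame(start = inact$start, end = inact$end,
                                label = "inactive") else NULL
  )
  markers <- markers[order(markers$start), , drop = FALSE]
  rownames(markers) <- NULL

  rec <- EEGRecording(sig, samplingRate = fs, layout = layout,
                      markers = markers, subject = subject, group = group,
                      adminTime = cfg$adminTime)
  list(recording = rec, truth = groundTruth(cfg, layout))
}
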