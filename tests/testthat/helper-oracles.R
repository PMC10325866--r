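# Independent oracles and small fixtures used across the suite. Everything
# here is written from first definitions, independent of the package's own
# computational paths.

# ---- compact simulation fixtures --------------------------------------------

# stationary single-epoch config: one baseline window covering the whole
# recording, no drug effect, no behavioral activity
quietConfig <- function(duration = 120, coupling = defaultCoupling(),
                        activitySchedule = NULL, ...) {
  simulationConfig(
    duration = duration, adminTime = duration,
    epochs = data.frame(epoch = "baseline", start = 0, end = duration),
    coupling = coupling, activitySchedule = activitySchedule, ...)
}

# four compressed epochs of `len` seconds each, administration after baseline
compressedConfig <- function(len = 60, ...) {
  simulationConfig(
    duration = 4 * len, adminTime = len,
    epochs = data.frame(epoch = c("baseline", "E1", "E2", "E3"),
                        start = len * (0:3), end = len * (1:4)), ...)
}

# plain white-noise 12-channel recording (no band structure)
whiteRecording <- function(duration = 120, sd = 10, fs = 250, seed = 1) {
  set.seed(seed)
  lay <- defaultLayout()
  n <- duration * fs
  sig <- matrix(rnorm(12 * n, sd = sd), 12, n,
                dimnames = list(lay$label, NULL))
  EEGRecording(sig, samplingRate = fs, layout = lay,
               markers = data.frame(start = 0, end = duration,
                                    label = "inactive"))
}

# ---- mixed RM-ANOVA oracle: explicit least-squares cell-means fit -----------

# Sequential sums of squares by explicit projection onto nested model
# spaces, built from raw indicator matrices and base qr() only.
oracleRmAnova <- function(design) {
  design$subject <- factor(design$subject, levels = unique(design$subject))
  design$group <- factor(design$group, levels = unique(design$group))
  design$time <- factor(design$time, levels = unique(design$time))
  y <- design$value
  k <- nlevels(design$group); t <- nlevels(design$time)
  N <- nlevels(design$subject)
  ind <- function(f) {
    m <- stats::model.matrix(~ f - 1)
    colnames(m) <- levels(f); m
  }
  proj <- function(X, v) {
    q <- qr(X)
    qr.fitted(q, v)
  }
  Xs <- ind(design$subject)
  Xg <- ind(design$group)
  Xt <- ind(design$time)
  Xc <- stats::model.matrix(~ design$group:design$time - 1)

  one <- matrix(1, length(y), 1)
  grand <- proj(one, y)
  # between-subject stratum
  fitS <- proj(Xs, y)
  fitG <- proj(Xg, y)
  ssTreat <- sum((fitG - grand)^2)
  ssSubj <- sum((fitS - fitG)^2)
  # within stratum
  r <- y - fitS
  fitT <- proj(Xt, r)
  ssTime <- sum(fitT^2)
  fitC <- proj(Xc, r)
  ssInt <- sum(fitC^2) - ssTime
  ssErr <- sum((r - fitC)^2)

  ngs <- length(unique(design$subject))
  dfs <- c(treat = k - 1, subj = N - k, time = t - 1,
           int = (k - 1) * (t - 1), err = (N - k) * (t - 1))
  list(F = c(treatment = (ssTreat / dfs["treat"]) / (ssSubj / dfs["subj"]),
             time = (ssTime / dfs["time"]) / (ssErr / dfs["err"]),
             interaction = (ssInt / dfs["int"]) / (ssErr / dfs["err"])),
       ss = c(treat = ssTreat, subj = ssSubj, time = ssTime, int = ssInt,
              err = ssErr))
}

# textbook element-wise Greenhouse-Geisser formula with explicit centering
oracleGgEpsilon <- function(S) {
  t <- nrow(S)
  sbar <- mean(S)
  sdd <- mean(diag(S))
  srow <- rowMeans(S)
  num <- t^2 * (sdd - sbar)^2
  den <- (t - 1) * (sum(S^2) - 2 * t * sum(srow^2) + t^2 * sbar^2)
  num / den
}

# random small balanced mixed design
randomDesign <- function(seed, k = 2, t = 3, n = 5) {
  set.seed(seed)
  subj <- paste0("s", seq_len(k * n))
  grp <- rep(paste0("g", seq_len(k)), each = n)
  data.frame(subject = rep(subj, each = t),
             group = rep(grp, each = t),
             time = rep(paste0("t", seq_len(t)), k * n),
             value = rnorm(k * n * t), stringsAsFactors = FALSE)
}

# ---- analytic lagged-coherence oracle for the delayed-shared-source model ---

# Closed-form cross-spectrum of x = sqrt(w) s(t) + sqrt(1-w) p1,
# y = sqrt(w) s(t - tau) + sqrt(1-w) p2 where s, p1, p2 are unit-variance
# band-limited noises with 4th-order Butterworth bandpass magnitude, on top
# of a shared-shape background. All spectra evaluated from the analog
# Butterworth prototype directly.
oracleLaggedCoherence <- function(f, w, tauS, low, high, sTot, sBand) {
  sxy <- w * sBand * exp(-1i * 2 * pi * f * tauS)
  den <- sTot^2 - Re(sxy)^2
  lcf <- ifelse(den <= 0, 0, Im(sxy)^2 / den)
  sum(sTot * lcf) / sum(sTot)
}

butterMag2 <- function(f, low, high, order = 4) {
  q <- (f^2 - low * high) / (pmax(f, 1e-12) * (high - low))
  1 / (1 + q^(2 * order))
}

# brute-force interval bookkeeping on a fine grid (for behavior tests)
gridIntervalSeconds <- function(iv, window, step = 0.01) {
  ts <- seq(window[1], window[2] - step, by = step) + step / 2
  inAny <- rep(FALSE, length(ts))
  for (i in seq_len(nrow(iv)))
    inAny <- inAny | (ts >= iv$start[i] & ts < iv$end[i])
  sum(inAny) * step
}
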