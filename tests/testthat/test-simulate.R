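test_that("default layout places the 12 sites at the published coordinates", {
  lay <- defaultLayout()
  expect_equal(nrow(lay), 12)
  expect_equal(lay$anterior[lay$label == "F3"], 5.0)
  expect_equal(lay$lateral[lay$label == "F3"], -2.0)
  expect_equal(lay$anterior[lay$label == "F4"], 5.0)
  expect_equal(lay$lateral[lay$label == "F4"], 2.0)
  hp <- homologousPairs(lay)
  expect_equal(nrow(hp), 6)
  expect_false(anyDuplicated(paste(lay$anterior, lay$lateral)) > 0)
  bad <- lay; bad$lateral[2] <- -2.0 # F4 collides with F3
  expect_error(validateLayout(bad), "distinct")
})

test_that("quantizer reproduces the 7.63 nV/bit acquisition resolution", {
  step <- quantStep(500, 16)
  expect_equal(round(step * 1000, 2), 7.63) # nV per bit
  q <- quantizeSignal(rep(0, 100), 500, 16)
  expect_true(all(q == 0))
  ramp <- seq(-500, 500, length.out = 20001)
  q <- quantizeSignal(ramp, 500, 16)
  recon <- q * attr(q, "step")
  inRange <- abs(ramp) <= 500 - step
  expect_lte(max(abs(recon[inRange] - ramp[inRange])), step / 2 + 1e-12)
  # clipping at the dynamic range
  q2 <- quantizeSignal(c(-1e4, 1e4), 500, 16)
  expect_equal(as.numeric(q2 * attr(q2, "step")), c(-500, 500))
})

test_that("same seed and config give a bit-identical recording", {
  cfg <- quietConfig(duration = 20)
  r1 <- generateRecording(cfg, seed = 99)
  r2 <- generateRecording(cfg, seed = 99)
  expect_identical(signalMatrix(r1$recording), signalMatrix(r2$recording))
  r3 <- generateRecording(cfg, seed = 100)
  expect_false(identical(signalMatrix(r1$recording),
                         signalMatrix(r3$recording)))
})

test_that("ground truth: no coupling means zero lagged coherence, no drug
           effect means epoch-constant power", {
  cfg <- compressedConfig(len = 20, coupling = defaultCoupling()[0, ])
  tr <- groundTruth(cfg)
  expect_true(all(tr$laggedCoherence$lc == 0))
  expect_true(all(tr$bandPower >= 0))
  # identical gains across epochs
  for (e in c("E1", "E2", "E3"))
    expect_equal(tr$bandPower[, , e], tr$bandPower[, , "baseline"])
  # drug effect moves exactly the configured epochs
  cfg2 <- compressedConfig(len = 20,
                           drugEffect = list(E1 = list(powerGain = 0.5)))
  tr2 <- groundTruth(cfg2)
  expect_equal(tr2$bandPower[, , "E1"] / tr2$bandPower[, , "baseline"] < 1,
               matrix(TRUE, 12, 6, dimnames = dimnames(tr2$bandPower[, , 1])))
  expect_equal(tr2$bandPower[, , "E3"], tr2$bandPower[, , "baseline"])
  expect_true(all(tr2$laggedCoherence$lc >= 0 &
                    tr2$laggedCoherence$lc <= 1))
})

test_that("empirical band power recovers the analytic truth within 10%", {
  relerr <- numeric(0)
  for (seed in 1:20) {
    cfg <- quietConfig(duration = 120)
    r <- generateRecording(cfg, seed = seed)
    bp <- bandPower(powerSpectrum(r$recording))
    mp <- meanPower(bp)
    relerr <- c(relerr, mp / r$truth$bandPower[1, , "baseline"] - 1)
  }
  expect_lt(max(abs(relerr)), 0.1)
})

test_that("doubling a band amplitude quadruples its power", {
  # isolate the alpha source so neighboring-band spectral leakage does not
  # dilute the scaling law
  amps <- c(delta = 0, theta = 0, alpha = 20, beta = 0, high_beta = 0,
            gamma = 0)
  amps2 <- amps; amps2["alpha"] <- 2 * amps["alpha"]
  cfg1 <- quietConfig(duration = 120, bandAmplitudes = amps,
                      pinkAmplitude = 0, whiteAmplitude = 0)
  cfg2 <- quietConfig(duration = 120, bandAmplitudes = amps2,
                      pinkAmplitude = 0, whiteAmplitude = 0)
  t1 <- groundTruth(cfg1)$bandPower[1, "alpha", 1]
  t2 <- groundTruth(cfg2)$bandPower[1, "alpha", 1]
  expect_equal(t2 / t1, 4, tolerance = 1e-6)
  e1 <- meanPower(bandPower(powerSpectrum(
    generateRecording(cfg1, seed = 5)$recording)))["alpha"]
  e2 <- meanPower(bandPower(powerSpectrum(
    generateRecording(cfg2, seed = 6)$recording)))["alpha"]
  expect_equal(unname(e2 / e1), 4, tolerance = 0.1)
})

test_that("estimated lagged coherence matches the generative closed form", {
  # alpha-band shared source, w = 0.8, 12 ms lag on F3-T3, 120 s
  cp <- data.frame(ch1 = "F3", ch2 = "T3", band = "alpha", weight = 0.8,
                   lagMs = 12, stringsAsFactors = FALSE)
  cfg <- quietConfig(duration = 120, coupling = cp)
  errs <- numeric(0)
  for (seed in 1:5) {
    r <- generateRecording(cfg, seed = seed)
    lc <- laggedCoherence(r$recording)
    est <- lc$lc[lc$ch1 == "F3" & lc$ch2 == "T3" & lc$band == "alpha"]
    # independent closed-form evaluation from the analog Butterworth
    # prototype on the analysis grid
    fgrid <- as.vector(rbind(bandBins(bandScheme(), "alpha") - 0.5,
                             bandBins(bandScheme(), "alpha")))
    fs <- 250
    dense <- (seq_len(65536) - 1) / 65536 * fs
    dense <- pmin(dense, fs - dense)
    sc <- bandScheme()
    sTot <- rep(2^2 * 2 / fs, length(fgrid)) # white floor
    for (i in seq_len(nrow(sc))) {
      m2 <- butterMag2(fgrid, sc$low[i], sc$high[i])
      nrm <- mean(butterMag2(dense, sc$low[i], sc$high[i]))
      amp <- cfg$bandAmplitudes[sc$name[i]]
      sTot <- sTot + amp^2 * (2 / fs) * m2 / nrm
    }
    sTot <- sTot + 10^2 * (2 / fs) * (1 / pmax(fgrid, 0.5)) /
      mean(1 / pmax(dense, 0.5))
    sAlpha <- 20^2 * (2 / fs) * butterMag2(fgrid, 8, 12) /
      mean(butterMag2(dense, 8, 12))
    tau <- round(0.012 * fs) / fs
    oracle <- oracleLaggedCoherence(fgrid, 0.8, tau, 8, 12, sTot, sAlpha)
    errs <- c(errs, abs(est - oracle))
  }
  expect_lt(max(errs), 0.05)
})

test_that("invalid simulation configs are rejected, not clipped", {
  # default schedule ends at 6000 s
  expect_error(simulationConfig(duration = 100),
               "shorter than the epoch schedule")
  cpl <- data.frame(ch1 = "F3", ch2 = "F4", band = "alpha", weight = 0.5,
                    lagMs = 0)
  expect_error(quietConfig(duration = 60, coupling = cpl), "lag > 0")
  cpl$lagMs <- 150 # alpha center period is 100 ms
  expect_error(quietConfig(duration = 60, coupling = cpl), "ill-posed")
  over <- data.frame(ch1 = c("F3", "F3"), ch2 = c("F4", "C3"),
                     band = "alpha", weight = 0.6, lagMs = 10)
  expect_error(quietConfig(duration = 60, coupling = over),
               "shared variance")
  expect_error(simulationConfig(samplingRate = -1), "samplingRate")
})
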