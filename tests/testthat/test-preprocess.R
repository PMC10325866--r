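sineRecording <- function(freq, amp = 1, duration = 10, dc = 0, fs = 250) {
  lay <- defaultLayout()
  t <- seq_len(duration * fs) / fs
  x <- amp * sin(2 * pi * freq * t) + dc
  sig <- matrix(rep(x, each = 12), 12, length(t),
                dimnames = list(lay$label, NULL))
  EEGRecording(sig, samplingRate = fs, layout = lay)
}

test_that("analysis FIR: passband unity, stopband attenuation, DC removal", {
  rec <- sineRecording(10)
  out <- bandpassFir(rec)
  core <- 500:2000 # avoid edge transients
  expect_equal(sd(signalMatrix(out)[1, core]) /
                 sd(signalMatrix(rec)[1, core]), 1, tolerance = 0.01)
  # 60 Hz attenuated at least as much as the designed response promises
  rec60 <- sineRecording(60)
  out60 <- bandpassFir(rec60)
  h60 <- abs(firResponse(60))
  expect_lt(sd(signalMatrix(out60)[1, core]) /
              sd(signalMatrix(rec60)[1, core]), h60 * 1.5)
  # 100 uV DC offset leaves < 1 uV residual mean
  recDC <- sineRecording(10, dc = 100)
  outDC <- bandpassFir(recDC)
  expect_lt(abs(mean(signalMatrix(outDC)[1, core])), 1)
  expect_error(bandpassFir(rec, nTaps = 110), "odd")
  expect_error(bandpassFir(rec, low = 0, high = 40), "0 < low")
})

test_that("filtering introduces no net time shift (group delay compensated)", {
  fs <- 250
  t <- seq_len(5 * fs) / fs
  x <- sin(2 * pi * 5 * t)
  lay <- defaultLayout()
  sig <- matrix(rep(x, each = 12), 12, length(t),
                dimnames = list(lay$label, NULL))
  out <- signalMatrix(bandpassFir(EEGRecording(sig)))[1, ]
  core <- 300:900
  lagCor <- sapply(-3:3, function(d)
    cor(x[core], out[core + d]))
  expect_equal(c(-3:3)[which.max(lagCor)], 0)
})

test_that("epoch windows follow the administration time", {
  w <- epochWindows(600)
  expect_equal(w$start[w$epoch == "E1"], 1800)
  expect_equal(w$end[w$epoch == "E1"], 2400)
  expect_equal(w$start[w$epoch == "baseline"], 0)
  expect_equal(w$epoch, c("baseline", "E1", "E2", "E3"))
  expect_true(all(w$start[-1] >= w$end[-4])) # ordered, non-overlapping
})

test_that("epochs beyond the recording are flagged missing, not truncated", {
  cfg <- compressedConfig(len = 30)
  rec <- generateRecording(cfg, seed = 8)$recording
  eps <- extractEpochs(rec, cfg$epochs)
  expect_true(all(!vapply(eps, `[[`, TRUE, "missing")))
  tooFar <- rbind(cfg$epochs,
                  data.frame(epoch = "E4", start = 120, end = 150))
  eps2 <- extractEpochs(rec, tooFar)
  expect_true(eps2$E4$missing)
  expect_false(eps2$E3$missing)
  seg <- selectSegments(eps2$E4, epochName = "E4")
  expect_false(isAccepted(seg))
  expect_match(seg@reason, "missing")
})

test_that("reliability is a symmetric power-agreement ratio", {
  expect_equal(reliability(rep(2, 10))$splitHalf, 1)
  expect_equal(reliability(rep(2, 10))$testRetest, 1)
  # second half 10x the first: 1 - 99/101
  v <- c(rep(1, 10), rep(10, 10))
  expect_equal(reliability(v)$testRetest, 1 - 99 / 101, tolerance = 1e-12)
  expect_true(reliability(rep(0, 8))$degenerate)
  expect_equal(reliability(rep(0, 8))$splitHalf, 1)
  expect_error(reliability(c(1, 2, 3)), "at least 4")
  # stationary per-second RMS series almost always clears 0.9
  set.seed(42)
  ok <- replicate(200, {
    v <- sqrt(vapply(seq_len(120), function(i) mean(rnorm(250)^2), 1))
    r <- reliability(v)
    r$splitHalf > 0.9 && r$testRetest > 0.9
  })
  expect_gte(mean(ok), 0.99)
})

test_that("segment selection: clean epochs give ~2 min, artifact-laden
           epochs are rejected", {
  # 10 min of fully inactive stationary signal: the 120-s target is reached
  cfg <- quietConfig(duration = 600)
  rec <- generateRecording(cfg, seed = 21)$recording
  seg <- selectSegments(rec, epochName = "baseline")
  expect_true(isAccepted(seg))
  expect_equal(totalSeconds(seg), 120)
  st <- segmentTable(seg)
  expect_true(all(st$start >= 0 & st$end <= 600))

  # transients of 10x RMS on all but 20 s: rejected for < 30 s
  lay <- defaultLayout()
  set.seed(7)
  n <- 60 * 250
  sig <- matrix(rnorm(12 * n, sd = 10), 12, n,
                dimnames = list(lay$label, NULL))
  rms <- sqrt(mean(sig^2))
  for (s in setdiff(seq_len(60), 20:39)) {
    at <- (s - 1) * 250 + sample(30:220, 3)
    sig[, at] <- sig[, at] + 10 * rms
  }
  dirty <- EEGRecording(sig, layout = lay,
                        markers = data.frame(start = 0, end = 60,
                                             label = "inactive"))
  seg2 <- selectSegments(dirty, epochName = "E1")
  expect_false(isAccepted(seg2))
  expect_match(seg2@reason, "minimum")
})

test_that("selection avoids active intervals and is deterministic and
           monotone in the amplitude factor", {
  secondsOf <- function(seg) {
    st <- segmentTable(seg)
    unlist(lapply(seq_len(nrow(st)), function(i)
      seq(st$start[i], st$end[i] - 1)))
  }
  for (seed in 1:5) {
    cfg <- quietConfig(duration = 180,
                       activitySchedule = data.frame(start = c(30, 100),
                                                     end = c(60, 130)))
    rec <- generateRecording(cfg, seed = seed)$recording
    seg <- selectSegments(rec, epochName = "b")
    segB <- selectSegments(rec, epochName = "b")
    expect_identical(segmentTable(seg), segmentTable(segB))
    s <- secondsOf(seg)
    expect_false(any(s %in% c(30:59, 100:129)))
    strict <- selectSegments(rec, selectionCriteria(amplitudeFactor = 1.05),
                             epochName = "b")
    expect_true(all(secondsOf(strict) %in% s))
    expect_lte(totalSeconds(strict), totalSeconds(seg))
  }
  # no inactive interval at all
  cfgA <- quietConfig(duration = 60,
                      activitySchedule = data.frame(start = 0, end = 60))
  recA <- generateRecording(cfgA, seed = 1)$recording
  segA <- selectSegments(recA, epochName = "b")
  expect_false(isAccepted(segA))
})
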