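test_that("lagged coherence is blind to zero-lag coupling", {
  # identical signals on every channel: Im(Sxy) = 0 exactly
  lay <- defaultLayout()
  set.seed(10)
  x <- rnorm(120 * 250, sd = 10)
  sig <- matrix(rep(x, each = 12), 12, length(x),
                dimnames = list(lay$label, NULL))
  lc <- laggedCoherence(EEGRecording(sig))
  expect_true(all(lc$lc == 0))

  # instantaneous mixture of independent band-limited sources
  cfg <- quietConfig(duration = 120, coupling = defaultCoupling()[0, ])
  rec <- generateRecording(cfg, seed = 11)$recording
  set.seed(12)
  A <- diag(12) + matrix(runif(144, 0, 0.5), 12, 12)
  mixed <- initialize(rec, signal = {
    m <- A %*% signalMatrix(rec)
    dimnames(m) <- dimnames(signalMatrix(rec)); m
  })
  lc2 <- laggedCoherence(mixed)
  expect_lt(max(lc2$lc), 0.05)
})

test_that("lagged coherence is invariant under channel rescaling", {
  cfg <- quietConfig(duration = 60)
  rec <- generateRecording(cfg, seed = 13)$recording
  sc <- signalMatrix(rec) * seq(0.5, 6, length.out = 12)
  dimnames(sc) <- dimnames(signalMatrix(rec))
  lc1 <- laggedCoherence(rec)
  lc2 <- laggedCoherence(initialize(rec, signal = sc))
  expect_equal(lc1$lc, lc2$lc, tolerance = 1e-9)
})

test_that("coherence change is the log ratio to baseline with floor masking", {
  base <- data.frame(subject = "s", epoch = "baseline",
                     ch1 = c("F3", "F3", "C3"), ch2 = c("F4", "C3", "C4"),
                     band = "alpha", lc = c(0.4, 0.2, 5e-4))
  now <- base; now$epoch <- "E1"; now$lc <- c(0.4, 0.1, 0.3)
  ch <- coherenceChange(now, base)
  expect_equal(ch$change[1], 0)
  expect_equal(ch$change[2], -log(2))
  expect_true(is.na(ch$change[3])) # baseline below floor -> masked
  now2 <- now; now2$lc[1] <- 1e-5
  expect_true(is.na(coherenceChange(now2, base)$change[1]))
  expect_error(coherenceChange(now[1:2, ], base[3, ]), "cover")
})

test_that("GFC is the mean of unmasked changes, with a coverage guard", {
  ch <- data.frame(subject = "s", epoch = "E1", ch1 = "a", ch2 = "b",
                   band = "x", lc = 0.1,
                   change = rep(-0.2, 10))[rep(1, 10), ]
  ch$change <- -0.2
  g <- gfc(ch)
  expect_equal(g$gfc, -0.2)
  ch$change <- rep(c(0.1, -0.1), 5)
  expect_equal(gfc(ch)$gfc, 0)
  ch$change[1:6] <- NA
  g3 <- gfc(ch)
  expect_false(g3$defined)
  expect_true(is.na(g3$gfc))
  expect_equal(g3$coverage, 0.4)
})

test_that("baseline against itself gives GFC exactly zero", {
  cfg <- quietConfig(duration = 40)
  rec <- generateRecording(cfg, seed = 14)$recording
  lc <- laggedCoherence(rec, epoch = "baseline")
  ch <- coherenceChange(lc, lc)
  expect_true(all(ch$change[!is.na(ch$change)] == 0))
  expect_equal(gfc(ch)$gfc, 0)
})

test_that("KDE: single-kernel case, normalization, translation
           equivariance", {
  k1 <- kdeDistribution(0)
  expect_equal(k1$density, dnorm(k1$grid, 0, 0.5), tolerance = 1e-12)
  set.seed(15)
  x <- rnorm(400, sd = 1.3)
  k <- kdeDistribution(x)
  expect_true(all(k$density >= 0))
  integ <- sum(diff(k$grid) * (head(k$density, -1) + tail(k$density, -1)) / 2)
  expect_gte(integ, 0.999); expect_lte(integ, 1.001)
  kL <- kdeDistribution(x - 0.5)
  expect_equal(kL$grid, k$grid - 0.5)
  expect_equal(kL$density, k$density)
  expect_equal(kdeMode(kL), kdeMode(k) - 0.5)
  expect_error(kdeDistribution(numeric(0)), "no finite samples")
})

test_that("null study: group-mean GFC is statistically indistinguishable
           from zero", {
  cfg <- studyConfig(simulation = list(
    duration = 240, adminTime = 60, activityFraction = 0,
    epochs = data.frame(epoch = c("baseline", "E1", "E2", "E3"),
                        start = c(0, 60, 120, 180),
                        end = c(60, 120, 180, 240)),
    groups = list(SAL = list(n = 4), SHAM = list(n = 4))), seed = 20)
  # activityFraction = 0 makes every behavior ratio exactly zero, so the
  # behavior ANOVA legitimately warns about an undefined F
  expect_warning(res <- runStudy(cfg), "zero error variance")
  g <- res$tables$gfc$gfc
  expect_lte(abs(mean(g)), 2 * sd(g) / sqrt(length(g)))
})
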