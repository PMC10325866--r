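test_that("activity ratio sums clipped interval lengths, excluding
           handling", {
  mk <- data.frame(start = numeric(0), end = numeric(0),
                   label = character(0))
  r0 <- activityRatio(mk, c(0, 600))
  expect_equal(r0$ratio, 0) # unmarked time counts as inactive
  expect_equal(r0$inactive_s, 600)

  mk2 <- data.frame(start = 0, end = 300, label = "active")
  expect_equal(activityRatio(mk2, c(0, 600))$ratio, 0.5)

  # three overlapping handling intervals: active + inactive = 600 - handled
  mk3 <- data.frame(
    start = c(50, 80, 100, 0, 200, 420),
    end = c(110, 130, 160, 70, 390, 600),
    label = c("handling", "handling", "handling", "active", "active",
              "active"))
  a <- activityRatio(mk3, c(0, 600))
  handled <- gridIntervalSeconds(
    mk3[mk3$label == "handling", c("start", "end")], c(0, 600))
  expect_equal(a$active_s + a$inactive_s, 600 - handled, tolerance = 0.02)
  expect_equal(a$excluded_s, handled, tolerance = 0.02)
  # brute-force active seconds: active minus handled, on a fine grid
  stopifnot(requireNamespace("stats"))
  ts <- seq(0.005, 599.995, by = 0.01)
  act <- (ts >= 0 & ts < 70) | (ts >= 200 & ts < 390) | (ts >= 420)
  hnd <- (ts >= 50 & ts < 160)
  expect_equal(a$active_s, sum(act & !hnd) * 0.01, tolerance = 0.02)

  expect_error(activityRatio(mk, c(10, 10)), "positive length")
})

test_that("activity shares sum to one per group and epoch", {
  s <- data.frame(subject = rep(1:4, 2), group = rep(c("a", "b"), each = 4),
                  epoch = "E1", ratio = runif(8))
  sh <- activityShareTable(s)
  expect_equal(sh$active_share + sh$inactive_share, rep(1, nrow(sh)))
})

test_that("behavior ANOVA detects a treatment shift and controls the null", {
  simSummaries <- function(shift) {
    do.call(rbind, lapply(1:16, function(i) {
      g <- if (i <= 8) "SAL" else "CLO"
      base <- rnorm(1, 400, 40)
      eff <- if (g == "CLO") shift else 0
      data.frame(subject = paste0("s", i), group = g,
                 epoch = c("baseline", "E1", "E2", "E3"),
                 inactive_s = base + c(0, rep(eff, 3)) + rnorm(4, 0, 30))
    }))
  }
  set.seed(30)
  hits <- replicate(20, {
    an <- behaviorAnova(simSummaries(120))
    effectP(an, "treatment") < 0.05 || effectP(an, "treatment:time") < 0.05
  })
  expect_gte(mean(hits), 0.8)

  set.seed(31)
  rej <- replicate(200, {
    an <- behaviorAnova(simSummaries(0))
    effectP(an, "treatment:time") < 0.05
  })
  # binomial 95% CI around 0.05 at 200 reps
  expect_gte(mean(rej), 0.05 - 1.96 * sqrt(0.05 * 0.95 / 200))
  expect_lte(mean(rej), 0.05 + 1.96 * sqrt(0.05 * 0.95 / 200))
})

test_that("constant behavioral data is flagged degenerate", {
  s <- data.frame(subject = rep(1:6, each = 4),
                  group = rep(c("a", "b"), each = 12),
                  epoch = rep(c("baseline", "E1", "E2", "E3"), 6),
                  inactive_s = 500)
  expect_warning(an <- behaviorAnova(s), "zero error variance")
  expect_true(is.na(anovaEffects(an)$F[1]))
})
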