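coarse <- gridSpec(resolution = 1, margin = 1)

test_that("thin-plate spline reproduces constants, affine fields and the
           electrode values exactly", {
  lay <- defaultLayout()
  m <- splineInterpolate(rep(3.5, 12), lay, coarse)
  expect_equal(range(m$values, na.rm = TRUE), c(3.5, 3.5), tolerance = 1e-9)

  v <- 2 + 0.7 * lay$anterior # affine in the anterior coordinate
  m2 <- splineInterpolate(v, lay, coarse)
  expct <- outer(m2$x, rep(1, length(m2$y))) * 0.7 + 2
  expect_lt(max(abs(m2$values - expct), na.rm = TRUE), 1e-6)

  set.seed(50)
  r <- rnorm(12)
  B <- qeegpipe:::.tpsBasis(cbind(lay$anterior, lay$lateral),
                            cbind(lay$anterior, lay$lateral))
  expect_lt(max(abs(B %*% r - r)), 1e-6)

  dup <- cbind(lay$anterior, lay$lateral); dup[2, ] <- dup[1, ]
  expect_error(qeegpipe:::.tpsBasis(dup, dup), "duplicate")
  expect_error(splineInterpolate(c(r[-1], NA), lay, coarse), "finite")
})

test_that("interpolation is linear in the data and respects left-right
           symmetry", {
  lay <- defaultLayout()
  set.seed(51)
  u <- rnorm(12); v <- rnorm(12)
  mu <- splineInterpolate(u, lay, coarse)$values
  mv <- splineInterpolate(v, lay, coarse)$values
  mc <- splineInterpolate(2 * u - 3 * v, lay, coarse)$values
  expect_lt(max(abs(mc - (2 * mu - 3 * mv)), na.rm = TRUE), 1e-9)

  # swapping homologous electrode values mirrors the map in the lateral axis
  mirror <- u[c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9, 12, 11)]
  mm <- splineInterpolate(mirror, lay, coarse)$values
  expect_lt(max(abs(mm - mu[, ncol(mu):1]), na.rm = TRUE), 1e-9)
})

test_that("pointwise statistics: null gives ~alpha false positives, a
           frontal effect is localized frontally", {
  lay <- defaultLayout()
  mkData <- function(effect, nsub = 6) {
    do.call(rbind, lapply(seq_len(2 * nsub), function(i) {
      g <- if (i <= nsub) "A" else "B"
      v <- rnorm(12)
      if (g == "B") v <- v + effect
      data.frame(subject = paste0("s", i), group = g, time = "E1",
                 channel = lay$label, value = v)
    }))
  }
  set.seed(52)
  fracs <- replicate(60, {
    tm <- pointwiseSignificance(mkData(rep(0, 12)), lay, coarse)
    mean(tm$pvalues < 0.05, na.rm = TRUE)
  })
  expect_gt(mean(fracs), 0.01)
  expect_lt(mean(fracs), 0.11)

  set.seed(53)
  reps <- replicate(20, {
    eff <- ifelse(lay$label %in% c("F3", "F4"), 3, 0)
    tm <- pointwiseSignificance(mkData(eff), lay, coarse)
    atF <- mapValueAt(tm, lay$anterior[1:2], lay$lateral[1:2])
    sF <- tm$significance[cbind(
      sapply(lay$anterior[1:2], function(a) which.min(abs(tm$x - a))),
      sapply(lay$lateral[1:2], function(l) which.min(abs(tm$y - l))))]
    sT <- tm$significance[cbind(
      sapply(lay$anterior[11:12], function(a) which.min(abs(tm$x - a))),
      sapply(lay$lateral[11:12], function(l) which.min(abs(tm$y - l))))]
    c(frontal = all(is.finite(atF)) && all(sF >= 1),
      temporalFP = mean(sT > 0))
  })
  # the injected frontal effect is detected at the F3/F4 grid points ...
  expect_gte(mean(reps["frontal", ]), 0.9)
  # ... while the null posterior-temporal points reject near the alpha rate
  # (exact non-significance of every null point in every replicate has
  # probability ~0.95^2 per replicate even for a perfect implementation)
  expect_lte(mean(reps["temporalFP", ]), 0.15)

  one <- mkData(rep(0, 12), nsub = 1)
  expect_error(pointwiseSignificance(one, lay, coarse), "2 subjects")
})

test_that("multi-epoch pointwise maps use the mixed-ANOVA machinery", {
  lay <- defaultLayout()
  set.seed(54)
  d <- do.call(rbind, lapply(1:8, function(i) {
    g <- if (i <= 4) "A" else "B"
    do.call(rbind, lapply(c("E1", "E2"), function(tt) {
      v <- rnorm(12, sd = 0.3) +
        ifelse(g == "B" & tt == "E2" & lay$anterior > 0, 4, 0)
      data.frame(subject = paste0("s", i), group = g, time = tt,
                 channel = lay$label, value = v)
    }))
  }))
  tm <- pointwiseSignificance(d, lay, coarse, effect = "treatment:time")
  sF <- tm$significance[which.min(abs(tm$x - 5)), which.min(abs(tm$y - 2))]
  expect_gte(sF, 1)
  png <- file.path(tempdir(), "map.png")
  plotTopoMap(tm, png)
  expect_true(file.exists(png) && file.size(png) > 0)
})
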