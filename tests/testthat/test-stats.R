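test_that("Box-Cox ratio transform: lambda = 0 is the log ratio", {
  expect_equal(boxcoxRatio(3, 3), 0)
  expect_equal(boxcoxRatio(2, 1), log(2))
  expect_equal(boxcoxRatio(c(2, 4), c(1, 2)), c(log(2), log(2)))
  # lambda -> 0 limit approaches the log branch: the analytic gap is
  # lambda * log(r)^2 / 2
  expect_lt(abs(boxcoxRatio(3, 1, lambda = 1e-4) - log(3)),
            2e-4 * log(3)^2)
  expect_lt(abs(boxcoxRatio(3, 1, lambda = 1e-8) - log(3)), 1e-6)
  expect_error(boxcoxRatio(-1, 2), "positive")
  expect_error(boxcoxRatio(1, 0), "positive")
})

test_that("Shapiro-Wilk check distinguishes normal from exponential
           samples", {
  set.seed(40)
  pn <- replicate(100, normalityCheck(rnorm(500))$p)
  pe <- replicate(100, normalityCheck(rexp(500))$p)
  expect_gte(mean(pn > 0.05), 0.9)
  expect_gte(mean(pe < 0.05), 0.95)
  expect_true(normalityCheck(rep(1, 10))$degenerate)
  expect_error(normalityCheck(c(1, 2)), "at least 3")
})

test_that("GG epsilon: compound symmetry gives 1, degeneracy the lower
           bound, random matrices match the definitional formula", {
  cs <- matrix(0.3, 3, 3); diag(cs) <- 1
  expect_equal(ggEpsilon(cs), 1)
  # rank-1 centered covariance: maximal non-sphericity, eps = 1/(t-1)
  v <- c(1, -1, 0)
  S <- outer(v, v) + matrix(1, 3, 3)
  expect_equal(ggEpsilon(S), 0.5)
  set.seed(41)
  for (i in 1:20) {
    A <- matrix(rnorm(9), 3, 3)
    S <- crossprod(A) + diag(3)
    expect_equal(ggEpsilon(S),
                 min(1, max(0.5, oracleGgEpsilon(S))), tolerance = 1e-10)
  }
  expect_warning(ggEpsilon(matrix(1, 3, 3)), "degenerate")
})

test_that("mixed ANOVA reproduces the published df structure", {
  # 4 treatment arms x 3 analysis epochs
  set.seed(42)
  d <- randomDesign(1, k = 4, t = 3, n = 8)
  an <- rmAnova(d)
  eff <- anovaEffects(an)
  expect_equal(eff$df_num[eff$effect == "treatment:time"], 6)
  expect_equal(eff$df_den[eff$effect == "treatment:time"],
               (32 - 4) * (3 - 1))
  # N = 34 unbalanced (8 + 8 + 9 + 9): error df 60
  d2 <- rbind(randomDesign(2, k = 2, t = 3, n = 8),
              within(randomDesign(3, k = 2, t = 3, n = 9), {
                subject <- paste0(subject, "x")
                group <- paste0(group, "x")
              }))
  an2 <- rmAnova(d2)
  eff2 <- anovaEffects(an2)
  expect_equal(an2@nSubjects, 34L)
  expect_equal(eff2$df_num[3], 6)
  expect_equal(eff2$df_den[3], 60)
})

test_that("F values agree with the explicit least-squares oracle and with
           aov", {
  for (seed in 1:50) {
    k <- sample(2:4, 1); t <- sample(2:4, 1); n <- sample(3:6, 1)
    set.seed(seed)
    d <- randomDesign(seed * 7, k = k, t = t, n = n)
    an <- rmAnova(d, runPosthoc = FALSE)
    orc <- oracleRmAnova(d)
    eff <- anovaEffects(an)
    expect_equal(eff$F, unname(orc$F), tolerance = 1e-8)
    # exact SS decomposition: strata sum to the total sum of squares
    ssTot <- sum((d$value - mean(d$value))^2)
    expect_equal(sum(orc$ss), ssTot, tolerance = 1e-8)
    expect_equal(sum(eff$ss) + attr(eff, "ssSubj") + attr(eff, "ssErr"),
                 ssTot, tolerance = 1e-8)
  }
  # independent cross-check against stats::aov on one design
  d <- randomDesign(99, k = 3, t = 3, n = 5)
  an <- rmAnova(d)
  fit <- summary(stats::aov(value ~ group * time + Error(subject / time),
                            data = transform(d, group = factor(group),
                                             time = factor(time),
                                             subject = factor(subject))))
  aovF <- c(fit[["Error: subject"]][[1]]["group", "F value"],
            fit[["Error: subject:time"]][[1]][c("time", "group:time"),
                                              "F value"])
  expect_equal(anovaEffects(an)$F, unname(aovF), tolerance = 1e-8)
})

test_that("Bonferroni post-hocs are gated by the interaction and clipped
           at 1", {
  set.seed(43)
  d <- randomDesign(5, k = 3, t = 2, n = 6) # null: interaction almost surely ns
  an <- rmAnova(d, alpha = 1e-6) # gate practically closed
  expect_equal(nrow(anovaPosthoc(an)), 0)
  ph <- bonferroniPosthoc(d, gate = FALSE)
  m <- nrow(ph)
  expect_equal(m, 2 * 3) # t(k)(k-1)/2 = 2 x 3 comparisons
  expect_equal(ph$p_bonferroni, pmin(1, ph$p * m))
  expect_true(all(ph$p_bonferroni <= 1))
  # strong interaction opens the gate
  d2 <- randomDesign(6, k = 2, t = 3, n = 6)
  d2$value <- d2$value * 0.1 +
    ifelse(d2$group == "g2" & d2$time == "t3", 5, 0)
  an2 <- rmAnova(d2)
  expect_true(an2@interactionSignificant)
  expect_gt(nrow(anovaPosthoc(an2)), 0)
})

test_that("GFC inference rule picks the documented branch", {
  mkDesign <- function(groupShift, interaction) {
    set.seed(44)
    d <- randomDesign(8, k = 2, t = 3, n = 8)
    d$value <- d$value * 0.2
    if (groupShift) d$value <- d$value + ifelse(d$group == "g2", 3, 0)
    if (interaction)
      d$value <- d$value + ifelse(d$group == "g2" & d$time == "t1", 4, 0)
    d
  }
  dG <- mkDesign(TRUE, FALSE)
  infG <- gfcInference(rmAnova(dG), dG)
  expect_equal(infG$branch, "global")
  expect_true(all(c("group1", "group2", "p_bonferroni") %in%
                    names(infG$posthoc)))
  dI <- mkDesign(FALSE, TRUE)
  infI <- gfcInference(rmAnova(dI), dI)
  expect_equal(infI$branch, "interaction")
  dN <- mkDesign(FALSE, FALSE)
  infN <- gfcInference(rmAnova(dN), dN)
  expect_equal(infN$branch, "none")
  expect_equal(nrow(infN$posthoc), 0)
})

test_that("design validation: duplicates, incomplete subjects, size
           minimums", {
  d <- randomDesign(9, k = 2, t = 3, n = 3)
  expect_error(rmAnova(rbind(d, d[1, ])), "duplicated")
  d2 <- d[-1, ] # subject s1 incomplete -> dropped with message
  expect_message(an <- rmAnova(d2), "incomplete")
  expect_equal(an@nSubjects, 5L)
  expect_error(rmAnova(d[d$group == "g1", ]), "2 treatment groups")
  expect_error(rmAnova(d[d$time == "t1", ]), "within-subject levels")
})
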