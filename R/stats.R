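# Box-Cox ratio normalization, mixed repeated-measures ANOVA with
# Greenhouse-Geisser correction, Bonferroni post-hocs and the GFC inference
# rule. The ANOVA is implemented from first principles (explicit projection
# sums of squares) so it can be validated against independent oracles.

#' Box-Cox ratio transform
#'
#' Normalizes a measure by the subject's own baseline: the lambda = 0 branch
#' is log(value / baseline); for lambda != 0 it is
#' ((value/baseline)^lambda - 1) / lambda. Inputs must be positive (mask
#' non-positive cells upstream).
#'
#' @param value,baseline positive numerics (vectorized)
#' @param lambda Box-Cox exponent (0 = log ratio, the default used
#'   throughout the pipeline)
#' @return transformed values
#' @export
boxcoxRatio <- function(value, baseline, lambda = 0) {
  if (any(value <= 0) || any(baseline <= 0))
    stop("boxcoxRatio requires positive value and baseline")
  r <- value / baseline
  # expm1 keeps the general branch accurate as lambda -> 0
  if (lambda == 0) log(r) else expm1(lambda * log(r)) / lambda
}

#' Shapiro-Wilk normality check
#'
#' Reported, not used to gate the parametric analysis. Constant samples are
#' degenerate and flagged instead of erroring.
#'
#' @param x numeric sample, 3 <= n <= 5000
#' @return list(statistic, p, degenerate)
#' @export
normalityCheck <- function(x) {
  if (length(x) < 3) stop("Shapiro-Wilk needs at least 3 observations")
  if (length(x) > 5000) stop("Shapiro-Wilk limited to 5000 observations")
  if (stats::var(x) == 0)
    return(list(statistic = NA_real_, p = NA_real_, degenerate = TRUE))
  sw <- stats::shapiro.test(x)
  list(statistic = unname(sw$statistic), p = sw$p.value, degenerate = FALSE)
}

#' Greenhouse-Geisser epsilon
#'
#' Sphericity correction factor estimated from the t x t within-subject
#' covariance: with A the double-centered covariance and lambda_i its
#' eigenvalues, epsilon = (sum lambda)^2 / ((t-1) sum lambda^2), clamped to
#' [1/(t-1), 1]. Equals 1 exactly under compound symmetry.
#'
#' @param S symmetric positive semidefinite t x t covariance matrix
#' @return epsilon, or NA (with a warning) for a rank-0 centered covariance
#' @export
ggEpsilon <- function(S) {
  t <- nrow(S)
  stopifnot(t >= 2, ncol(S) == t)
  if (max(abs(S - t(S))) > 1e-8 * max(1, max(abs(S))))
    stop("covariance must be symmetric")
  C <- diag(t) - 1 / t
  A <- C %*% S %*% C
  trA <- sum(diag(A))
  trA2 <- sum(A * A) # = tr(A^2) for symmetric A
  scale <- sum(abs(diag(S))) + 1e-300
  if (trA <= 1e-9 * scale || trA2 <= (1e-9 * scale)^2) {
    warning("degenerate (rank-0) double-centered covariance")
    return(NA_real_)
  }
  min(1, max(1 / (t - 1), trA^2 / ((t - 1) * trA2)))
}

.checkDesign <- function(design) {
  stopifnot(all(c("subject", "group", "time", "value") %in% names(design)))
  design$subject <- as.character(design$subject)
  design$group <- factor(design$group, levels = unique(design$group))
  design$time <- factor(design$time, levels = unique(design$time))
  tlev <- levels(design$time)
  # drop subjects with incomplete cells
  cnt <- table(design$subject)
  bad <- names(cnt)[cnt != length(tlev)]
  keyDup <- anyDuplicated(paste(design$subject, design$time))
  if (keyDup) stop("duplicated subject x time cells")
  if (length(bad)) {
    message("dropping ", length(bad),
            " subject(s) with incomplete within-subject cells: ",
            paste(bad, collapse = ", "))
    design <- design[!design$subject %in% bad, ]
  }
  if (anyNA(design$value)) {
    badNA <- unique(design$subject[is.na(design$value)])
    message("dropping ", length(badNA), " subject(s) with missing values")
    design <- design[!design$subject %in% badNA, ]
  }
  design$group <- droplevels(design$group)
  design
}

#' Mixed repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Between-subject factor \code{group} (treatment, k levels), within-subject
#' factor \code{time} (t levels), one value per subject x time. Sums of
#' squares are computed by explicit projections: the between-subject stratum
#' partitions t x (subject-mean deviations) into treatment and
#' subject-within-group error; the within stratum partitions the
#' subject-centered residuals sequentially into time, treatment:time and the
#' subject x time error. Degrees of freedom follow the mixed-design
#' contract: treatment (k-1, N-k); time (t-1, (N-k)(t-1)); treatment:time
#' ((k-1)(t-1), (N-k)(t-1)). Within-effect p values are additionally
#' corrected by multiplying both dfs by the Greenhouse-Geisser epsilon
#' estimated from the pooled within-group covariance. Unbalanced group sizes
#' are accepted; subjects with incomplete cells are dropped with a message.
#'
#' @param design data.frame(subject, group, time, value)
#' @param alpha significance level for the decision flags and the post-hoc
#'   gate
#' @param runPosthoc run Bonferroni post-hocs when the interaction is
#'   significant
#' @return an [RmAnovaResult-class]
#' @export
rmAnova <- function(design, alpha = 0.05, runPosthoc = TRUE) {
  design <- .checkDesign(design)
  glev <- levels(design$group)
  tlev <- levels(design$time)
  k <- length(glev); t <- length(tlev)
  if (k < 2) stop("need at least 2 treatment groups")
  if (t < 2) stop("need at least 2 within-subject levels")
  subj <- unique(design$subject)
  N <- length(subj)
  Y <- matrix(NA_real_, N, t, dimnames = list(subj, tlev))
  Y[cbind(match(design$subject, subj), match(design$time, tlev))] <-
    design$value
  grp <- design$group[match(subj, design$subject)]
  ng <- table(grp)
  if (any(ng < 2)) stop("need at least 2 subjects per group")

  grand <- mean(Y)
  msub <- rowMeans(Y)
  mgrp <- tapply(msub, grp, mean)
  ssTreat <- t * sum(as.numeric(ng) * (mgrp - grand)^2)
  ssSubj <- t * sum((msub - mgrp[grp])^2)

  R <- Y - msub # within-subject residuals
  tmean <- colMeans(R)
  ssTime <- N * sum(tmean^2)
  cellMean <- apply(R, 2, function(col) tapply(col, grp, mean))
  # cellMean: k x t (or vector when k==1); project R on group x time cells
  ssCells <- sum(as.numeric(ng) * rowSums(cellMean^2))
  ssInt <- ssCells - ssTime
  ssErr <- sum(R^2) - ssCells

  dfTreat <- k - 1; dfSubj <- N - k
  dfTime <- t - 1; dfInt <- (k - 1) * (t - 1); dfErr <- (N - k) * (t - 1)
  msSubj <- ssSubj / dfSubj
  msErr <- ssErr / dfErr

  # pooled within-group covariance of the repeated measures
  Sw <- matrix(0, t, t)
  for (g in glev) {
    Yg <- Y[grp == g, , drop = FALSE]
    Sw <- Sw + crossprod(scale(Yg, center = TRUE, scale = FALSE))
  }
  Sw <- Sw / (N - k)
  eps <- suppressWarnings(ggEpsilon(Sw))

  degenerateBetween <- msSubj <= 0
  degenerateWithin <- msErr <= 0
  fTreat <- if (degenerateBetween) NA_real_ else (ssTreat / dfTreat) / msSubj
  fTime <- if (degenerateWithin) NA_real_ else (ssTime / dfTime) / msErr
  fInt <- if (degenerateWithin) NA_real_ else (ssInt / dfInt) / msErr
  if (degenerateBetween || degenerateWithin)
    warning("zero error variance: F undefined for one or more effects")

  pv <- function(f, d1, d2) if (is.na(f)) NA_real_ else
    stats::pf(f, d1, d2, lower.tail = FALSE)
  pgg <- function(f, d1, d2) if (is.na(f) || is.na(eps)) NA_real_ else
    stats::pf(f, d1 * eps, d2 * eps, lower.tail = FALSE)

  eff <- data.frame(
    effect = c("treatment", "time", "treatment:time"),
    df_num = c(dfTreat, dfTime, dfInt),
    df_den = c(dfSubj, dfErr, dfErr),
    ss = c(ssTreat, ssTime, ssInt),
    ms = c(ssTreat / dfTreat, ssTime / dfTime, ssInt / dfInt),
    F = c(fTreat, fTime, fInt),
    gg_epsilon = c(NA_real_, eps, eps),
    p_uncorrected = c(pv(fTreat, dfTreat, dfSubj),
                      pv(fTime, dfTime, dfErr),
                      pv(fInt, dfInt, dfErr)),
    stringsAsFactors = FALSE
  )
  eff$p_gg <- c(eff$p_uncorrected[1],
                pgg(fTime, dfTime, dfErr),
                pgg(fInt, dfInt, dfErr))
  attr(eff, "ssSubj") <- ssSubj
  attr(eff, "ssErr") <- ssErr

  res <- new("RmAnovaResult", effects = eff,
             posthoc = data.frame(), alpha = alpha,
             interactionSignificant = isTRUE(eff$p_gg[3] < alpha),
             treatmentSignificant = isTRUE(eff$p_gg[1] < alpha),
             nSubjects = as.integer(N), nGroups = as.integer(k),
             nTimes = as.integer(t))
  if (runPosthoc)
    res@posthoc <- bonferroniPosthoc(design, res, alpha = alpha)
  res
}

#' Bonferroni-corrected pairwise post-hoc comparisons
#'
#' Executed only when the treatment:time interaction is significant
#' (GG-corrected p < alpha), unless \code{gate = FALSE}. All pairwise
#' between-group contrasts at each time level are tested with pooled-variance
#' two-sample t tests; raw p values are multiplied by the number of
#' comparisons performed and clipped at 1.
#'
#' @param design data.frame(subject, group, time, value)
#' @param anova the [RmAnovaResult-class] gating the family
#' @param alpha gate level
#' @param gate apply the significant-interaction gate
#' @return data.frame(time, group1, group2, diff, t, df, p, p_bonferroni);
#'   empty when gated out
#' @export
bonferroniPosthoc <- function(design, anova = NULL, alpha = 0.05,
                              gate = TRUE) {
  empty <- data.frame(time = character(0), group1 = character(0),
                      group2 = character(0), diff = numeric(0),
                      t = numeric(0), df = numeric(0), p = numeric(0),
                      p_bonferroni = numeric(0), stringsAsFactors = FALSE)
  if (gate) {
    if (is.null(anova)) stop("gated post-hocs need the ANOVA result")
    if (!anova@interactionSignificant) return(empty)
  }
  design <- .checkDesign(design)
  glev <- levels(design$group)
  tlev <- levels(design$time)
  rows <- list()
  for (tv in tlev) {
    d <- design[design$time == tv, ]
    for (i in seq_len(length(glev) - 1)) for (j in (i + 1):length(glev)) {
      x <- d$value[d$group == glev[i]]
      y <- d$value[d$group == glev[j]]
      tt <- .pooledT(x, y)
      rows[[length(rows) + 1]] <- data.frame(
        time = tv, group1 = glev[i], group2 = glev[j],
        diff = mean(x) - mean(y), t = tt$t, df = tt$df, p = tt$p,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  m <- nrow(out)
  out$p_bonferroni <- pmin(1, out$p * m)
  out
}

.pooledT <- function(x, y) {
  nx <- length(x); ny <- length(y)
  df <- nx + ny - 2
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / df
  if (sp2 <= 0) return(list(t = NA_real_, df = df, p = NA_real_))
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = tstat, df = df, p = 2 * stats::pt(-abs(tstat), df))
}

#' GFC inference rule
#'
#' Decision logic for the global-connectivity effect: a significant
#' treatment:time interaction triggers per-time post-hocs; otherwise a
#' significant treatment main effect is interpreted as an overall
#' (time-collapsed) GFC effect and tested by global pairwise group
#' comparisons; otherwise no effect is declared. The record states which
#' branch fired.
#'
#' @param anova [RmAnovaResult-class] computed on GFC values
#' @param design the data.frame the ANOVA was computed from
#' @param alpha significance level
#' @return list(branch = one of "interaction", "global", "none", posthoc)
#' @export
gfcInference <- function(anova, design, alpha = 0.05) {
  pInt <- effectP(anova, "treatment:time")
  pTreat <- effectP(anova, "treatment")
  if (isTRUE(pInt < alpha)) {
    ph <- bonferroniPosthoc(design, anova, alpha = alpha, gate = FALSE)
    return(list(branch = "interaction", posthoc = ph))
  }
  if (isTRUE(pTreat < alpha)) {
    design <- .checkDesign(design)
    agg <- stats::aggregate(value ~ subject + group, design, mean)
    glev <- levels(agg$group)
    rows <- list()
    for (i in seq_len(length(glev) - 1)) for (j in (i + 1):length(glev)) {
      x <- agg$value[agg$group == glev[i]]
      y <- agg$value[agg$group == glev[j]]
      tt <- .pooledT(x, y)
      rows[[length(rows) + 1]] <- data.frame(
        group1 = glev[i], group2 = glev[j], diff = mean(x) - mean(y),
        t = tt$t, df = tt$df, p = tt$p, stringsAsFactors = FALSE)
    }
    ph <- do.call(rbind, rows)
    ph$p_bonferroni <- pmin(1, ph$p * nrow(ph))
    return(list(branch = "global", posthoc = ph))
  }
  list(branch = "none", posthoc = data.frame())
}
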