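# Behavioral activity quantification per epoch and the treatment test on
# inactivity durations.

#' Activity/inactivity summary of one epoch window
#'
#' Sums active and inactive interval lengths clipped to the window.
#' Handling, artifact and sleep-suspect intervals are excluded from both
#' sums; time not covered by any marker counts as inactive (markers flag
#' activity onsets/offsets). The ratio is active / (active + inactive).
#'
#' @param markers data.frame(start, end, label), seconds
#' @param window c(start, end) of the epoch, seconds (positive length)
#' @param subject,epoch identifiers stamped on the row
#' @return one-row data.frame(subject, epoch, active_s, inactive_s,
#'   excluded_s, ratio)
#' @export
activityRatio <- function(markers, window, subject = NA, epoch = NA) {
  stopifnot(length(window) == 2)
  if (window[2] <= window[1]) stop("epoch window must have positive length")
  wlen <- window[2] - window[1]
  excl <- intervalUnion(intervalClip(
    markers[markers$label %in% c("handling", "artifact", "sleep_suspect"),
            c("start", "end")], window[1], window[2]))
  act <- intervalUnion(intervalClip(
    markers[markers$label == "active", c("start", "end")],
    window[1], window[2]))
  act <- intervalDiff(act, excl)
  excluded_s <- intervalLength(excl)
  active_s <- intervalLength(act)
  inactive_s <- wlen - excluded_s - active_s
  data.frame(subject = subject, epoch = epoch, active_s = active_s,
             inactive_s = inactive_s, excluded_s = excluded_s,
             ratio = active_s / (active_s + inactive_s),
             stringsAsFactors = FALSE)
}

#' RM-ANOVA on behavioral inactivity durations
#'
#' Treatment (between) x epoch (within) mixed ANOVA on per-epoch inactivity,
#' keeping the baseline as a fourth within-level (the behavioral analysis
#' compares baseline against the treatment intervals directly, unlike the
#' baseline-normalized qEEG responses). Delegates to [rmAnova()].
#'
#' @param summaries data.frame with columns subject, group, epoch and the
#'   response column
#' @param measure response column name (default \code{inactive_s})
#' @param alpha significance level
#' @return an [RmAnovaResult-class]
#' @export
behaviorAnova <- function(summaries, measure = "inactive_s", alpha = 0.05) {
  stopifnot(measure %in% names(summaries))
  design <- data.frame(subject = summaries$subject, group = summaries$group,
                       time = summaries$epoch, value = summaries[[measure]],
                       stringsAsFactors = FALSE)
  rmAnova(design, alpha = alpha)
}

#' Group x epoch activity shares (pie-chart values)
#'
#' Average share of time spent active vs inactive per group and epoch;
#' the two shares sum to 1.
#'
#' @param summaries rows from [activityRatio()] plus a \code{group} column
#' @return data.frame(group, epoch, active_share, inactive_share)
#' @export
activityShareTable <- function(summaries) {
  agg <- stats::aggregate(ratio ~ group + epoch, summaries, mean)
  data.frame(group = agg$group, epoch = agg$epoch,
             active_share = agg$ratio, inactive_share = 1 - agg$ratio,
             stringsAsFactors = FALSE)
}
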