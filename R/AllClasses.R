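#' @import methods
NULL

MARKER_LABELS <- c("active", "inactive", "handling", "sleep_suspect", "artifact")

#' EEGRecording: multichannel scalp EEG with layout, markers and annotations
#'
#' The central data container of the package: a channels x samples matrix in
#' microvolts together with the electrode layout, the sampling rate,
#' behavioral/artifact markers and study annotations (subject id, treatment
#' group, administration time).
#'
#' @slot signal numeric matrix, channels x samples, in microvolts; rownames
#'   are channel labels and must match the layout.
#' @slot samplingRate sampling rate in Hz (250 by default throughout).
#' @slot layout data.frame with columns \code{label}, \code{anterior},
#'   \code{lateral} (skull coordinates in mm, anterior positive, right
#'   lateral positive), as returned by [defaultLayout()].
#' @slot markers data.frame with columns \code{start}, \code{end} (seconds
#'   from recording start) and \code{label} (one of \code{active},
#'   \code{inactive}, \code{handling}, \code{sleep_suspect},
#'   \code{artifact}).
#' @slot subject subject identifier.
#' @slot group treatment-group label (e.g. \code{SAL}, \code{PSI}).
#' @slot adminTime drug administration time in seconds from recording start
#'   (\code{NA_real_} when not applicable).
#'
#' @export
setClass("EEGRecording",
  representation(
    signal = "matrix",
    samplingRate = "numeric",
    layout = "data.frame",
    markers = "data.frame",
    subject = "character",
    group = "character",
    adminTime = "numeric"
  ),
  prototype(
    samplingRate = 250,
    markers = data.frame(start = numeric(0), end = numeric(0),
                         label = character(0)),
    subject = NA_character_,
    group = NA_character_,
    adminTime = NA_real_
  )
)

setValidity("EEGRecording", function(object) {
  msg <- character(0)
  if (!is.numeric(object@signal))
    msg <- c(msg, "signal must be a numeric matrix (channels x samples)")
  if (length(object@samplingRate) != 1 || object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a single positive number")
  if (is.null(rownames(object@signal)))
    msg <- c(msg, "signal must have channel labels as rownames")
  if (!all(c("label", "anterior", "lateral") %in% names(object@layout)))
    msg <- c(msg, "layout needs columns label, anterior, lateral")
  if (!identical(rownames(object@signal), as.character(object@layout$label)))
    msg <- c(msg, "signal rownames must equal layout$label (same order)")
  mk <- object@markers
  if (!all(c("start", "end", "label") %in% names(mk))) {
    msg <- c(msg, "markers needs columns start, end, label")
  } else if (nrow(mk) > 0) {
    dur <- ncol(object@signal) / object@samplingRate
    if (any(mk$end < mk$start))
      msg <- c(msg, "marker intervals may not have negative length")
    if (any(mk$start < 0) || any(mk$end > dur + 1e-9))
      msg <- c(msg, "markers must lie within [0, duration]")
    if (!all(mk$label %in% MARKER_LABELS))
      msg <- c(msg, paste("marker labels must be one of:",
                          paste(MARKER_LABELS, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct an EEGRecording
#'
#' @param signal channels x samples numeric matrix in microvolts; rownames
#'   must be the channel labels in layout order.
#' @param samplingRate sampling rate in Hz.
#' @param layout electrode layout data.frame (see [defaultLayout()]).
#' @param markers marker data.frame (start, end, label).
#' @param subject,group,adminTime study annotations.
#' @return an [EEGRecording-class] object.
#' @export
EEGRecording <- function(signal, samplingRate = 250, layout = defaultLayout(),
                         markers = NULL, subject = NA_character_,
                         group = NA_character_, adminTime = NA_real_) {
  if (is.null(markers))
    markers <- data.frame(start = numeric(0), end = numeric(0),
                          label = character(0))
  new("EEGRecording", signal = signal, samplingRate = samplingRate,
      layout = layout, markers = markers,
      subject = as.character(subject), group = as.character(group),
      adminTime = as.numeric(adminTime))
}

#' @describeIn EEGRecording signal matrix accessor (channels x samples, uV)
#' @param x,object an EEGRecording
#' @export
signalMatrix <- function(x) x@signal

#' @describeIn EEGRecording sampling rate in Hz
#' @export
samplingRate <- function(x) x@samplingRate

#' @describeIn EEGRecording channel labels in layout order
#' @export
channelLabels <- function(x) rownames(x@signal)

#' @describeIn EEGRecording electrode layout data.frame
#' @export
electrodeLayout <- function(x) x@layout

#' @describeIn EEGRecording marker data.frame
#' @export
recordingMarkers <- function(x) x@markers

#' @describeIn EEGRecording duration in seconds
#' @export
recordingDuration <- function(x) ncol(x@signal) / x@samplingRate

#' @describeIn EEGRecording subject identifier
#' @export
subjectId <- function(x) x@subject

#' @describeIn EEGRecording treatment-group label
#' @export
treatmentGroup <- function(x) x@group

#' @describeIn EEGRecording administration time (s)
#' @export
adminTime <- function(x) x@adminTime

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf(
    "EEGRecording: %d channels x %d samples (%.1f s @ %g Hz)\n",
    nrow(object@signal), ncol(object@signal),
    ncol(object@signal) / object@samplingRate, object@samplingRate))
  cat(sprintf("  subject: %s  group: %s  adminTime: %s s\n",
              object@subject, object@group, format(object@adminTime)))
  cat(sprintf("  channels: %s\n",
              paste(rownames(object@signal), collapse = " ")))
  cat(sprintf("  markers: %d intervals (%s)\n", nrow(object@markers),
              paste(unique(object@markers$label), collapse = ", ")))
})

#' SegmentSet: accepted artifact-free inactivity segments within one epoch
#'
#' @slot subject subject id.
#' @slot epoch epoch name (baseline, E1, E2, E3).
#' @slot segments data.frame(start, end) in seconds, absolute recording time;
#'   non-overlapping, sorted.
#' @slot totalS total accepted signal in seconds.
#' @slot accepted logical; FALSE when the epoch failed the selection criteria.
#' @slot reason rejection reason ("" when accepted).
#' @export
setClass("SegmentSet",
  representation(subject = "character", epoch = "character",
                 segments = "data.frame", totalS = "numeric",
                 accepted = "logical", reason = "character"))

setValidity("SegmentSet", function(object) {
  seg <- object@segments
  msg <- character(0)
  if (!all(c("start", "end") %in% names(seg)))
    return("segments needs columns start, end")
  if (nrow(seg) > 0) {
    if (any(seg$end <= seg$start)) msg <- c(msg, "zero/negative segment")
    if (is.unsorted(seg$start)) msg <- c(msg, "segments must be sorted")
    if (nrow(seg) > 1 && any(seg$start[-1] < seg$end[-nrow(seg)] - 1e-9))
      msg <- c(msg, "segments must be non-overlapping")
  }
  tot <- sum(seg$end - seg$start)
  if (abs(tot - object@totalS) > 1e-6)
    msg <- c(msg, "totalS does not match segments")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SegmentSet", function(object) {
  cat(sprintf("SegmentSet: subject %s, epoch %s: %.0f s in %d segments [%s]\n",
              object@subject, object@epoch, object@totalS,
              nrow(object@segments),
              if (object@accepted) "accepted"
              else paste("REJECTED:", object@reason)))
})

#' @describeIn SegmentSet total accepted seconds
#' @param x a SegmentSet
#' @export
totalSeconds <- function(x) x@totalS

#' @describeIn SegmentSet whether the epoch passed selection
#' @export
isAccepted <- function(x) x@accepted

#' @describeIn SegmentSet the segment table (start, end in s)
#' @export
segmentTable <- function(x) x@segments

#' RmAnovaResult: mixed repeated-measures ANOVA with GG correction
#'
#' Holds the three-effect table (treatment, time, treatment:time), the
#' Greenhouse-Geisser epsilon, Bonferroni post-hoc comparisons and the
#' decision flags used by the GFC inference rule.
#'
#' @slot effects data.frame with columns effect, df_num, df_den, ss, ms, F,
#'   gg_epsilon, p_uncorrected, p_gg.
#' @slot posthoc data.frame of pairwise comparisons (may be empty).
#' @slot alpha significance level used for the flags.
#' @slot interactionSignificant logical flag (treatment:time, GG-corrected p).
#' @slot treatmentSignificant logical flag (between-subject main effect).
#' @slot nSubjects,nGroups,nTimes design dimensions.
#' @export
setClass("RmAnovaResult",
  representation(effects = "data.frame", posthoc = "data.frame",
                 alpha = "numeric", interactionSignificant = "logical",
                 treatmentSignificant = "logical", nSubjects = "integer",
                 nGroups = "integer", nTimes = "integer"))

setMethod("show", "RmAnovaResult", function(object) {
  cat(sprintf(
    "Mixed RM-ANOVA: %d subjects, %d groups, %d within-levels (alpha = %g)\n",
    object@nSubjects, object@nGroups, object@nTimes, object@alpha))
  eff <- object@effects
  eff$F <- signif(eff$F, 4)
  eff$p_uncorrected <- signif(eff$p_uncorrected, 3)
  eff$p_gg <- signif(eff$p_gg, 3)
  print(eff[, c("effect", "df_num", "df_den", "F", "gg_epsilon",
                "p_uncorrected", "p_gg")], row.names = FALSE)
  if (nrow(object@posthoc))
    cat(sprintf("  %d Bonferroni post-hoc comparisons\n",
                nrow(object@posthoc)))
})

#' @describeIn RmAnovaResult the effect table
#' @param x an RmAnovaResult
#' @export
anovaEffects <- function(x) x@effects

#' @describeIn RmAnovaResult the post-hoc comparison table
#' @export
anovaPosthoc <- function(x) x@posthoc

#' @describeIn RmAnovaResult GG-corrected p for one effect
#' @param effect one of "treatment", "time", "treatment:time"
#' @export
effectP <- function(x, effect) {
  i <- match(effect, x@effects$effect)
  if (is.na(i)) stop("unknown effect: ", effect)
  x@effects$p_gg[i]
}
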