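# Minimal EDF (European Data Format) writer/reader: ASCII header plus
# int16 little-endian data records, one 1-s record per second. Markers,
# study annotations and the exact sample count travel in a YAML sidecar
# (EDF+ annotation support is inconsistent across readers). No installed
# package reads EDF, hence the self-contained implementation; it follows the
# published EDF field layout and round-trips within one quantization step.

.edfPad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

#' Write a recording as EDF plus a YAML sidecar
#'
#' The EDF carries the signal (int16, physical range +/- physRange uV); the
#' sidecar (same path with extension \code{.yaml}) carries subject, group,
#' administration time, sampling rate, exact sample count (the final EDF
#' record is zero-padded to a whole second) and the marker intervals.
#'
#' @param recording an [EEGRecording-class]
#' @param path output path (conventionally \code{.edf})
#' @param physRange physical half-range, uV
#' @return the path, invisibly
#' @export
writeRecording <- function(recording, path, physRange = 500) {
  sig <- signalMatrix(recording)
  fs <- samplingRate(recording)
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer needs an integer Hz rate")
  fs <- as.integer(round(fs))
  nch <- nrow(sig); ns <- ncol(sig)
  nrec <- as.integer(ceiling(ns / fs))
  pad <- nrec * fs - ns
  if (pad > 0) sig <- cbind(sig, matrix(0, nch, pad))

  digMax <- 32767L
  dig <- round(pmin(pmax(sig, -physRange), physRange) / physRange * digMax)

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edfPad("0", 8),
    .edfPad(paste("subject", subjectId(recording)), 80),
    .edfPad(paste("qeegpipe recording group", treatmentGroup(recording)), 80),
    .edfPad("01.01.00", 8), .edfPad("00.00.00", 8),
    .edfPad(256 + 256 * nch, 8), .edfPad("", 44),
    .edfPad(nrec, 8), .edfPad("1", 8), .edfPad(nch, 4))
  sighdr <- paste0(
    paste(vapply(rownames(sig), .edfPad, "", width = 16), collapse = ""),
    paste(rep(.edfPad("AgAgCl cortical electrode", 80), nch), collapse = ""),
    paste(rep(.edfPad("uV", 8), nch), collapse = ""),
    paste(rep(.edfPad(-physRange, 8), nch), collapse = ""),
    paste(rep(.edfPad(physRange, 8), nch), collapse = ""),
    paste(rep(.edfPad(-digMax, 8), nch), collapse = ""),
    paste(rep(.edfPad(digMax, 8), nch), collapse = ""),
    paste(rep(.edfPad("HP:0.15Hz LP:70Hz", 80), nch), collapse = ""),
    paste(rep(.edfPad(fs, 8), nch), collapse = ""),
    paste(rep(.edfPad("", 32), nch), collapse = ""))
  writeChar(paste0(hdr, sighdr), con, eos = NULL)
  for (r in seq_len(nrec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    writeBin(as.integer(t(dig[, idx])), con, size = 2, endian = "little")
  }

  mk <- recordingMarkers(recording)
  side <- list(
    subject = subjectId(recording),
    group = treatmentGroup(recording),
    adminTime = if (is.na(adminTime(recording))) NULL
                else adminTime(recording),
    samplingRate = fs,
    nSamples = ns,
    physRange = physRange,
    reference = attr(electrodeLayout(recording), "reference"),
    ground = attr(electrodeLayout(recording), "ground"),
    markers = lapply(seq_len(nrow(mk)), function(i)
      list(start = mk$start[i], end = mk$end[i], label = mk$label[i]))
  )
  yaml::write_yaml(side, .sidecarPath(path))
  invisible(path)
}

.sidecarPath <- function(path) paste0(sub("\\.edf$", "", path), ".yaml")

#' Read a recording written by [writeRecording()]
#'
#' Channel order is normalized to the layout order. A channel required by
#' the layout but absent from the file is a hard error naming the channel,
#' as is a sampling-rate mismatch with \code{expectedRate}.
#'
#' @param path EDF path (sidecar expected alongside)
#' @param layout electrode layout defining the required channels and order
#' @param expectedRate required sampling rate in Hz, or NULL to accept the
#'   file's rate
#' @return an [EEGRecording-class]
#' @export
readRecording <- function(path, layout = defaultLayout(),
                          expectedRate = 250) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(wd) trimws(readChar(con, wd))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8) # header bytes
  rd(44)
  nrec <- as.integer(rd(8))
  recDur <- as.numeric(rd(8))
  nch <- as.integer(rd(4))
  labels <- vapply(seq_len(nch), function(i) rd(16), "")
  for (i in seq_len(nch)) rd(80)
  for (i in seq_len(nch)) rd(8) # dim
  physMin <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), 0)
  physMax <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), 0)
  digMin <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), 0)
  digMax <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(nch)) rd(80)
  spr <- vapply(seq_len(nch), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(nch)) rd(32)
  if (length(unique(spr)) != 1)
    stop("mixed per-channel sampling rates are not supported")
  fs <- spr[1] / recDur

  side <- yaml::read_yaml(.sidecarPath(path))
  if (!is.null(expectedRate) && abs(fs - expectedRate) > 1e-9)
    stop("sampling rate mismatch: file has ", fs, " Hz, expected ",
         expectedRate)
  missing <- setdiff(layout$label, labels)
  if (length(missing))
    stop("recording is missing channel(s): ", paste(missing, collapse = ", "))

  sig <- matrix(0, nch, nrec * spr[1])
  for (r in seq_len(nrec)) {
    blk <- readBin(con, integer(), n = nch * spr[1], size = 2,
                   endian = "little")
    sig[, ((r - 1) * spr[1] + 1):(r * spr[1])] <-
      matrix(blk, nch, spr[1], byrow = TRUE)
  }
  scale <- (physMax - physMin) / (digMax - digMin)
  sig <- sig * scale + (physMax - scale * digMax)
  rownames(sig) <- labels
  ns <- if (!is.null(side$nSamples)) side$nSamples else ncol(sig)
  sig <- sig[layout$label, seq_len(ns), drop = FALSE]

  mk <- if (length(side$markers))
    do.call(rbind, lapply(side$markers, function(m)
      data.frame(start = m$start, end = m$end, label = m$label,
                 stringsAsFactors = FALSE)))
  else data.frame(start = numeric(0), end = numeric(0), label = character(0))

  EEGRecording(sig, samplingRate = fs, layout = layout, markers = mk,
               subject = if (is.null(side$subject)) NA else side$subject,
               group = if (is.null(side$group)) NA else side$group,
               adminTime = if (is.null(side$adminTime)) NA_real_
                           else side$adminTime)
}
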