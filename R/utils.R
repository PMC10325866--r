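# Interval arithmetic on data.frames with columns start, end (seconds).
# Used by marker handling, epoch extraction and the behavior module.

.emptyIntervals <- function() data.frame(start = numeric(0), end = numeric(0))

#' Normalize a set of intervals: sort, drop empties, merge overlaps
#' @param iv data.frame(start, end)
#' @return merged data.frame(start, end)
#' @keywords internal
intervalUnion <- function(iv) {
  iv <- iv[iv$end > iv$start, c("start", "end"), drop = FALSE]
  if (nrow(iv) == 0) return(.emptyIntervals())
  iv <- iv[order(iv$start, iv$end), , drop = FALSE]
  out_s <- iv$start[1]; out_e <- iv$end[1]
  ns <- numeric(0); ne <- numeric(0)
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv$start[i] <= out_e) {
      out_e <- max(out_e, iv$end[i])
    } else {
      ns <- c(ns, out_s); ne <- c(ne, out_e)
      out_s <- iv$start[i]; out_e <- iv$end[i]
    }
  }
  data.frame(start = c(ns, out_s), end = c(ne, out_e))
}

#' Intersect a set of intervals with one window
#' @keywords internal
intervalClip <- function(iv, lo, hi) {
  if (nrow(iv) == 0) return(.emptyIntervals())
  s <- pmax(iv$start, lo); e <- pmin(iv$end, hi)
  keep <- e > s
  data.frame(start = s[keep], end = e[keep])
}

#' Set difference: iv minus sub (both interval data.frames)
#' @keywords internal
intervalDiff <- function(iv, sub) {
  iv <- intervalUnion(iv); sub <- intervalUnion(sub)
  if (nrow(iv) == 0) return(.emptyIntervals())
  if (nrow(sub) == 0) return(iv)
  out <- .emptyIntervals()
  for (i in seq_len(nrow(iv))) {
    cur_s <- iv$start[i]; cur_e <- iv$end[i]
    pieces_s <- numeric(0); pieces_e <- numeric(0)
    pos <- cur_s
    ov <- intervalClip(sub, cur_s, cur_e)
    if (nrow(ov)) {
      for (j in seq_len(nrow(ov))) {
        if (ov$start[j] > pos) {
          pieces_s <- c(pieces_s, pos); pieces_e <- c(pieces_e, ov$start[j])
        }
        pos <- max(pos, ov$end[j])
      }
    }
    if (pos < cur_e) { pieces_s <- c(pieces_s, pos); pieces_e <- c(pieces_e, cur_e) }
    out <- rbind(out, data.frame(start = pieces_s, end = pieces_e))
  }
  out
}

#' Total length of a set of intervals
#' @keywords internal
intervalLength <- function(iv) {
  iv <- intervalUnion(iv)
  if (nrow(iv) == 0) 0 else sum(iv$end - iv$start)
}

#' Deterministic per-subject seed substream
#'
#' Fans a global study seed out to per-subject seeds so that adding or
#' removing subjects does not shift other subjects' synthetic data.
#' Result is always a positive integer below 2^31.
#'
#' @param seed global integer seed
#' @param index 1-based subject index (or any small integer tag)
#' @return integer seed
#' @export
subSeed <- function(seed, index) {
  s <- (as.double(seed) %% 2147483647) * 48271 + as.double(index) * 16807
  as.integer(s %% 2147483629 + 1)
}

# all unordered channel pairs of a layout, in fixed order
.channelPairs <- function(labels) {
  n <- length(labels)
  i <- rep(seq_len(n - 1), times = (n - 1):1)
  j <- unlist(lapply(seq_len(n - 1), function(k) (k + 1):n))
  data.frame(ch1 = labels[i], ch2 = labels[j], stringsAsFactors = FALSE)
}
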