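#' Default 12-electrode rat cortical layout
#'
#' Skull coordinates (mm relative to bregma; anterior positive, right lateral
#' positive) of the 12 recording sites over frontal association (F3/F4),
#' primary motor (C3/C4), medial parietal association (P3/P4), lateral
#' parietal association (P5/P6), secondary auditory (T3/T4) and temporal
#' association (T5/T6) cortex. Odd labels are left hemisphere (negative
#' lateral). The reference sits above the olfactory bulb and the ground
#' subcutaneously over the occiput; both are carried as attributes, not as
#' signal channels.
#'
#' @return data.frame with columns \code{label}, \code{anterior},
#'   \code{lateral} and attributes \code{reference}, \code{ground}.
#' @examples
#' lay <- defaultLayout()
#' stopifnot(nrow(lay) == 12)
#' @export
defaultLayout <- function() {
  lay <- data.frame(
    label = c("F3", "F4", "C3", "C4", "P3", "P4",
              "P5", "P6", "T3", "T4", "T5", "T6"),
    anterior = c(5.0, 5.0, 2.2, 2.2, -3.8, -3.8,
                 -4.5, -4.5, -3.6, -3.6, -8.3, -8.3),
    lateral = c(-2.0, 2.0, -3.2, 3.2, -2.5, 2.5,
                -4.5, 4.5, -7.2, 7.2, -5.8, 5.8),
    stringsAsFactors = FALSE
  )
  attr(lay, "reference") <- "REF_olfactory_bulb"
  attr(lay, "ground") <- "GND_occipital"
  validateLayout(lay)
  lay
}

#' Validate an electrode layout
#'
#' Checks the invariants assumed downstream: exactly 12 scalp channels, all
#' coordinates distinct, and left/right homologous pairs (consecutive rows)
#' sharing the anterior coordinate with mirrored lateral coordinates.
#'
#' @param layout a layout data.frame
#' @return the layout, invisibly; errors when invalid
#' @export
validateLayout <- function(layout) {
  stopifnot(all(c("label", "anterior", "lateral") %in% names(layout)))
  if (nrow(layout) != 12)
    stop("layout must have exactly 12 scalp channels, got ", nrow(layout))
  key <- paste(layout$anterior, layout$lateral)
  if (anyDuplicated(key))
    stop("layout coordinates must be pairwise distinct")
  odd <- seq(1, 11, by = 2)
  if (any(layout$anterior[odd] != layout$anterior[odd + 1]) ||
      any(layout$lateral[odd] != -layout$lateral[odd + 1]))
    stop("homologous pairs must share anterior and mirror lateral coords")
  invisible(layout)
}

#' Homologous left/right electrode pairs of a layout
#' @param layout a layout data.frame
#' @return data.frame(ch1, ch2), six rows for the default layout
#' @export
homologousPairs <- function(layout) {
  odd <- seq(1, nrow(layout) - 1, by = 2)
  data.frame(ch1 = layout$label[odd], ch2 = layout$label[odd + 1],
             stringsAsFactors = FALSE)
}
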