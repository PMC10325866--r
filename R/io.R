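# Result serialization and study configuration.

#' Write pipeline result tables as CSV
#'
#' Deterministic naming (the list names, lower-cased, non-alphanumerics
#' collapsed to underscores) and deterministic content: rerunning with the
#' same inputs yields byte-identical files. Empty data.frames produce
#' header-only CSVs.
#'
#' @param tables named list of data.frames
#' @param outputDir output directory (created when absent)
#' @return named character vector of file paths
#' @export
writeResults <- function(tables, outputDir) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  ok <- dir.exists(outputDir) || dir.create(outputDir, recursive = TRUE,
                                            showWarnings = FALSE)
  if (!ok || file.access(outputDir, 2) != 0)
    stop("output directory is not writable: ", outputDir)
  paths <- character(0)
  for (nm in names(tables)) {
    fn <- file.path(outputDir, paste0(
      gsub("[^a-z0-9]+", "_", tolower(nm)), ".csv"))
    utils::write.csv(tables[[nm]], fn, row.names = FALSE)
    paths[nm] <- fn
  }
  paths
}

#' Assemble and validate a study configuration
#'
#' Exactly one of \code{manifest} (a data.frame subject/group/path pointing
#' at EDF recordings) or \code{simulation} (a specification understood by
#' [runStudy()]) must be present.
#'
#' @param simulation simulation block: list(groups = named list of
#'   list(n, powerGain, couplingGain), plus optional overrides of
#'   [simulationConfig()] arguments such as duration, adminTime, epochs)
#' @param manifest data.frame(subject, group, path)
#' @param alpha significance level in (0, 1)
#' @param criteria segment [selectionCriteria()]
#' @param scheme band scheme
#' @param coherenceFloor masking floor for log-ratio coherence changes
#' @param seed global study seed (fans out per subject via [subSeed()])
#' @param topomaps build per-band topographic maps (2-group designs)
#' @param writeRecordings write per-subject EDF + sidecar files
#' @param epochs optional analysis epoch windows data.frame(epoch, start,
#'   end) overriding the per-recording default (simulation schedule, or
#'   [epochWindows()] from the administration time); windows a recording
#'   does not cover are flagged missing and analysed epochs are reduced
#'   with a note
#' @param equalizeWindows analyse the same number of Welch windows in every
#'   accepted epoch of a subject (default TRUE): the lagged-coherence
#'   estimator's null bias depends on the window count, so unequal epoch
#'   durations would bias baseline-relative coherence ratios
#' @return validated config list of class \code{qeegStudyConfig}
#' @export
studyConfig <- function(simulation = NULL, manifest = NULL, alpha = 0.05,
                        criteria = selectionCriteria(),
                        scheme = bandScheme(), coherenceFloor = 1e-3,
                        seed = 1, topomaps = FALSE,
                        writeRecordings = FALSE, epochs = NULL,
                        equalizeWindows = TRUE) {
  if (is.null(simulation) == is.null(manifest))
    stop("exactly one of simulation or manifest must be given")
  stopifnot(alpha > 0, alpha < 1)
  if (!is.null(manifest))
    stopifnot(all(c("subject", "group", "path") %in% names(manifest)),
              !anyDuplicated(manifest$subject))
  if (!is.null(epochs) && !is.data.frame(epochs))
    epochs <- do.call(rbind, lapply(epochs, as.data.frame))
  cfg <- list(simulation = simulation, manifest = manifest, alpha = alpha,
              criteria = criteria, scheme = scheme,
              coherenceFloor = coherenceFloor, seed = seed,
              topomaps = topomaps, writeRecordings = writeRecordings,
              epochs = epochs, equalizeWindows = equalizeWindows)
  class(cfg) <- "qeegStudyConfig"
  cfg
}

#' Read a study configuration from YAML
#'
#' @param path YAML file; top-level keys mirror the [studyConfig()]
#'   arguments (criteria/scheme entries override the defaults field-wise)
#' @return a \code{qeegStudyConfig}
#' @export
readStudyConfig <- function(path) {
  y <- yaml::read_yaml(path)
  crit <- do.call(selectionCriteria,
                  if (is.null(y$criteria)) list() else y$criteria)
  manifest <- if (!is.null(y$manifest)) {
    do.call(rbind, lapply(y$manifest, function(m)
      data.frame(subject = m$subject, group = m$group, path = m$path,
                 stringsAsFactors = FALSE)))
  }
  studyConfig(
    simulation = y$simulation, manifest = manifest,
    alpha = if (is.null(y$alpha)) 0.05 else y$alpha,
    criteria = crit,
    coherenceFloor = if (is.null(y$coherenceFloor)) 1e-3
                     else y$coherenceFloor,
    seed = if (is.null(y$seed)) 1 else y$seed,
    topomaps = isTRUE(y$topomaps),
    writeRecordings = isTRUE(y$writeRecordings),
    epochs = y$epochs)
}
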