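# Full-study orchestration: simulate or ingest recordings, preprocess,
# select segments, compute spectra / coherence / GFC / behavior, run the
# band-wise statistics and write deterministic outputs.

#' Deterministic pseudo-random activity schedule
#'
#' Alternating inactive gaps and active episodes (uniform 5-15 s episodes,
#' exponential gaps tuned to the target active fraction), reproducible from
#' the seed.
#'
#' @param duration recording length, s
#' @param seed integer seed
#' @param fraction target fraction of time spent active
#' @param episode c(min, max) episode length, s
#' @return data.frame(start, end) of active episodes
#' @export
defaultActivitySchedule <- function(duration, seed, fraction = 0.2,
                                    episode = c(5, 15)) {
  if (fraction <= 0) return(.emptyIntervals())
  set.seed(as.integer(seed))
  meanEp <- mean(episode)
  meanGap <- meanEp * (1 - fraction) / fraction
  t <- 0; s <- numeric(0); e <- numeric(0)
  repeat {
    t <- t + stats::rexp(1, 1 / meanGap)
    len <- stats::runif(1, episode[1], episode[2])
    if (t + len >= duration) break
    s <- c(s, t); e <- c(e, t + len)
    t <- t + len
  }
  data.frame(start = s, end = e)
}

# resolve the simulation block of a study config into per-subject
# simulationConfig objects
.simSubjects <- function(config) {
  sim <- config$simulation
  stopifnot(!is.null(sim$groups))
  base <- sim[setdiff(names(sim), c("groups", "activityFraction"))]
  if (!is.null(base$epochs) && !is.data.frame(base$epochs))
    base$epochs <- do.call(rbind, lapply(base$epochs, as.data.frame))
  frac <- if (is.null(sim$activityFraction)) 0.2 else sim$activityFraction
  subjects <- list()
  idx <- 0
  for (g in names(sim$groups)) {
    spec <- sim$groups[[g]]
    n <- spec$n
    postEpochs <- setdiff(
      (if (!is.null(base$epochs)) base$epochs$epoch
       else epochWindows(if (is.null(base$adminTime)) 600
                         else base$adminTime)$epoch), "baseline")
    drug <- list()
    for (e in postEpochs) {
      pg <- if (!is.null(spec$powerGain)) {
        v <- spec$powerGain
        if (!is.null(names(v)) && e %in% names(v)) v[[e]] else
          if (is.null(names(v))) v else NULL
      }
      cg <- if (!is.null(spec$couplingGain)) {
        v <- spec$couplingGain
        if (!is.null(names(v)) && e %in% names(v)) v[[e]] else
          if (is.null(names(v))) v else NULL
      }
      if (!is.null(pg) || !is.null(cg))
        drug[[e]] <- list(powerGain = if (is.null(pg)) NULL else unlist(pg),
                          couplingGain = if (is.null(cg)) NULL
                                         else as.numeric(cg))
    }
    for (i in seq_len(n)) {
      idx <- idx + 1
      sseed <- subSeed(config$seed, idx)
      args <- base
      args$drugEffect <- drug
      args$activitySchedule <- defaultActivitySchedule(
        if (is.null(base$duration)) 6000 else base$duration,
        subSeed(sseed, 2), fraction = frac)
      cfg <- do.call(simulationConfig, args)
      subjects[[idx]] <- list(subject = sprintf("%s_%02d", g, i), group = g,
                              cfg = cfg, seed = sseed)
    }
  }
  subjects
}

# number of 2-s/50%-overlap Welch windows a segment set can host
.windowCapacity <- function(seg, winSec = 2, step = 1) {
  len <- seg$end - seg$start
  sum(ifelse(len >= winSec, floor((len - winSec) / step) + 1, 0))
}

# truncate a segment set so it hosts exactly targetWin windows: the
# lagged-coherence estimator's null bias scales with 1/nWindows, so
# baseline-relative coherence ratios are only unbiased when every epoch of
# a subject contributes the same number of windows
.trimSegmentsToWindows <- function(seg, targetWin, winSec = 2, step = 1) {
  keep <- seg[0, c("start", "end")]
  acc <- 0
  for (i in seq_len(nrow(seg))) {
    len <- seg$end[i] - seg$start[i]
    cap <- if (len >= winSec) floor((len - winSec) / step) + 1 else 0
    if (acc + cap < targetWin) {
      keep <- rbind(keep, seg[i, c("start", "end")])
      acc <- acc + cap
    } else {
      need <- targetWin - acc
      if (need > 0)
        keep <- rbind(keep, data.frame(
          start = seg$start[i], end = seg$start[i] + winSec +
            (need - 1) * step))
      return(keep)
    }
  }
  keep
}

# process one recording through filter -> epochs -> selection -> spectra ->
# coherence; returns per-subject tidy tables
.processRecording <- function(rec, config) {
  subj <- subjectId(rec); grp <- treatmentGroup(rec)
  filt <- bandpassFir(rec)
  eps <- if (!is.null(config$epochs)) {
    config$epochs
  } else if (!is.null(config$simulation$epochs)) {
    e <- config$simulation$epochs
    if (!is.data.frame(e)) e <- do.call(rbind, lapply(e, as.data.frame))
    e
  } else epochWindows(adminTime(rec))
  slices <- extractEpochs(filt, eps)

  selRows <- list(); mpRows <- list(); bpRows <- list(); cohRows <- list()
  behRows <- list(); bandsBySubject <- list()
  coh <- list(); segsByEpoch <- list()
  for (en in names(slices)) {
    sl <- slices[[en]]
    seg <- selectSegments(sl, config$criteria, epochName = en)
    selRows[[en]] <- data.frame(
      subject = subj, group = grp, epoch = en, total_s = totalSeconds(seg),
      accepted = isAccepted(seg),
      reason = if (isAccepted(seg)) "" else seg@reason,
      stringsAsFactors = FALSE)
    win <- c(sl$start, sl$end)
    if (!sl$missing)
      behRows[[en]] <- cbind(
        activityRatio(recordingMarkers(rec),
                      c(0, win[2] - win[1]) + win[1],
                      subject = subj, epoch = en),
        group = grp)
    if (!isAccepted(seg)) next
    segLocal <- segmentTable(seg)
    segLocal$start <- segLocal$start - sl$start
    segLocal$end <- segLocal$end - sl$start
    segsByEpoch[[en]] <- segLocal
  }
  # equalize the Welch window count across this subject's accepted epochs
  # (the coherence estimator's null bias depends on the window count, so
  # baseline-relative ratios need equal effective data per epoch)
  if (length(segsByEpoch) > 1 && !isFALSE(config$equalizeWindows)) {
    target <- min(vapply(segsByEpoch, .windowCapacity, numeric(1)))
    segsByEpoch <- lapply(segsByEpoch, .trimSegmentsToWindows, target)
  }
  for (en in names(segsByEpoch)) {
    sl <- slices[[en]]
    segLocal <- segsByEpoch[[en]]
    cs <- welchCsd(signalMatrix(sl$recording), samplingRate(sl$recording),
                   segLocal, cross = TRUE)
    bp <- bandPowerTable(sl$recording, segLocal, config$scheme,
                         subject = subj, epoch = en, csd = cs)
    mpRows[[en]] <- data.frame(subject = subj, group = grp, epoch = en,
                               band = names(bp$mean),
                               mean_power = as.numeric(bp$mean),
                               stringsAsFactors = FALSE)
    bpRows[[en]] <- cbind(bp$table, group = grp)
    bandsBySubject[[en]] <- bp$bands
    coh[[en]] <- laggedCoherence(sl$recording, segLocal, config$scheme,
                                 subject = subj, epoch = en, csd = cs)
    cohRows[[en]] <- cbind(coh[[en]], group = grp)
  }

  gfcRows <- list(); chRows <- list()
  if (!is.null(coh$baseline)) {
    for (en in setdiff(names(coh), "baseline")) {
      ch <- coherenceChange(coh[[en]], coh$baseline,
                            floor = config$coherenceFloor)
      gres <- gfc(ch)
      gfcRows[[en]] <- data.frame(subject = subj, group = grp, epoch = en,
                                  gfc = gres$gfc, coverage = gres$coverage,
                                  defined = gres$defined,
                                  stringsAsFactors = FALSE)
      chRows[[en]] <- cbind(ch, group = grp)
    }
  }
  list(selection = do.call(rbind, selRows),
       meanPower = do.call(rbind, mpRows),
       bandPower = do.call(rbind, bpRows),
       coherence = do.call(rbind, cohRows),
       changes = do.call(rbind, chRows),
       gfc = do.call(rbind, gfcRows),
       behavior = do.call(rbind, behRows),
       bands = bandsBySubject)
}

#' Run a full study from one configuration
#'
#' Simulates (or loads) every subject's recording, runs preprocessing,
#' artifact-free inactivity selection, spectral power, lagged coherence,
#' GFC and behavior quantification, then band-wise Box-Cox-normalized mixed
#' RM-ANOVAs with GG correction and Bonferroni post-hocs, the GFC inference
#' rule, per-group KDE curves of pooled connectivity changes, and (optional)
#' topographic maps. Rerunning with an identical config and seed reproduces
#' identical outputs.
#'
#' @param config a [studyConfig()]
#' @param outputDir when non-NULL, all tables are written there as CSV
#'   (plus PNG topomaps and a run manifest JSON)
#' @param mapSpec [gridSpec()] used for topographic maps
#' @return results bundle: tidy tables, per-band [RmAnovaResult-class]
#'   objects, the GFC inference record, KDE table, notes, and written file
#'   paths
#' @export
runStudy <- function(config, outputDir = NULL, mapSpec = gridSpec()) {
  stopifnot(inherits(config, "qeegStudyConfig"))
  notes <- character(0)
  recs <- list()
  if (!is.null(config$simulation)) {
    subjects <- .simSubjects(config)
    for (s in subjects)
      recs[[s$subject]] <- generateRecording(
        s$cfg, seed = s$seed, subject = s$subject, group = s$group)$recording
  } else {
    for (i in seq_len(nrow(config$manifest)))
      recs[[config$manifest$subject[i]]] <- readRecording(
        config$manifest$path[i])
  }
  if (!is.null(outputDir) && config$writeRecordings) {
    rdir <- file.path(outputDir, "recordings")
    dir.create(rdir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(recs))
      writeRecording(recs[[nm]], file.path(rdir, paste0(nm, ".edf")))
  }

  per <- lapply(recs, .processRecording, config = config)
  bind <- function(field) do.call(rbind, c(lapply(per, `[[`, field),
                                           list(make.row.names = FALSE)))
  tabs <- list(
    selection = bind("selection"), mean_power = bind("meanPower"),
    band_power = bind("bandPower"), coherence = bind("coherence"),
    gfc = bind("gfc"), behavior = bind("behavior"))

  alpha <- config$alpha
  bands <- config$scheme$name
  postEpochs <- setdiff(unique(tabs$selection$epoch), "baseline")

  # Box-Cox (lambda = 0) normalized mean-power responses per band
  mp <- tabs$mean_power
  anovaPower <- list(); posthocPower <- list()
  designsPower <- list()
  for (b in bands) {
    d <- mp[mp$band == b, ]
    base <- d[d$epoch == "baseline", ]
    d <- d[d$epoch != "baseline", ]
    i <- match(d$subject, base$subject)
    ok <- !is.na(i) & base$mean_power[i] > 0 & d$mean_power > 0
    design <- data.frame(subject = d$subject[ok], group = d$group[ok],
                         time = d$epoch[ok],
                         value = boxcoxRatio(d$mean_power[ok],
                                             base$mean_power[i][ok]),
                         stringsAsFactors = FALSE)
    design <- .completeEpochs(design, postEpochs, paste("power", b), notes)
    notes <- attr(design, "notes")
    an <- suppressMessages(rmAnova(design, alpha = alpha))
    anovaPower[[b]] <- an
    designsPower[[b]] <- design
    ph <- anovaPosthoc(an)
    if (nrow(ph)) posthocPower[[b]] <- cbind(band = b, ph)
  }

  # per-band mean connectivity change, and the GFC scalar
  anovaCoherence <- list()
  ch <- tabs$gfc
  if (!is.null(per[[1]]$changes)) {
    allch <- do.call(rbind, c(lapply(per, `[[`, "changes"),
                              list(make.row.names = FALSE)))
    for (b in bands) {
      d <- allch[allch$band == b & !is.na(allch$change), ]
      agg <- stats::aggregate(change ~ subject + group + epoch, d, mean)
      design <- data.frame(subject = agg$subject, group = agg$group,
                           time = agg$epoch, value = agg$change,
                           stringsAsFactors = FALSE)
      design <- .completeEpochs(design, postEpochs, paste("coherence", b),
                                notes)
      notes <- attr(design, "notes")
      anovaCoherence[[b]] <- suppressMessages(rmAnova(design, alpha = alpha))
    }
  } else allch <- NULL

  gfcDesign <- data.frame(subject = ch$subject, group = ch$group,
                          time = ch$epoch, value = ch$gfc,
                          stringsAsFactors = FALSE)
  gfcDesign <- gfcDesign[!is.na(gfcDesign$value), ]
  gfcDesign <- .completeEpochs(gfcDesign, postEpochs, "gfc", notes)
  notes <- attr(gfcDesign, "notes")
  anovaGfc <- suppressMessages(rmAnova(gfcDesign, alpha = alpha))
  inference <- gfcInference(anovaGfc, gfcDesign, alpha = alpha)

  anovaBehavior <- suppressMessages(behaviorAnova(tabs$behavior,
                                                  alpha = alpha))
  tabs$activity_shares <- activityShareTable(tabs$behavior)

  # pooled per-group KDE of connectivity changes
  kdeTab <- NULL
  if (!is.null(allch)) {
    tabs$coherence_change <- allch
    samp <- allch$change[!is.na(allch$change)]
    rng <- c(min(samp), max(samp))
    groups <- unique(allch$group)
    kdeTab <- NULL
    for (g in groups) {
      k <- kdeDistribution(allch$change[allch$group == g &
                                          !is.na(allch$change)],
                           range = rng)
      if (is.null(kdeTab)) kdeTab <- data.frame(grid = k$grid)
      kdeTab[[paste0("density_", g)]] <- k$density
    }
  }

  flat <- function(lst) do.call(rbind, lapply(names(lst), function(b)
    cbind(band = b, anovaEffects(lst[[b]]))))
  tabs$anova_gfc <- anovaEffects(anovaGfc)
  tabs$anova_behavior <- anovaEffects(anovaBehavior)
  tabs$posthoc_power <- if (length(posthocPower))
    do.call(rbind, c(posthocPower, list(make.row.names = FALSE)))
  else data.frame()
  tabs$gfc_inference <- data.frame(branch = inference$branch)
  if (!is.null(kdeTab)) tabs$kde_gfc <- kdeTab
  for (b in bands) {
    tabs[[paste0("anova_power_", b)]] <- anovaEffects(anovaPower[[b]])
    if (!is.null(anovaCoherence[[b]]))
      tabs[[paste0("anova_coherence_", b)]] <-
        anovaEffects(anovaCoherence[[b]])
  }

  maps <- NULL
  if (isTRUE(config$topomaps)) {
    bpt <- tabs$band_power
    baseKey <- paste(bpt$subject, bpt$channel, bpt$band)
    base <- bpt[bpt$epoch == "baseline", ]
    i <- match(baseKey, paste(base$subject, base$channel, base$band))
    bpt$logratio <- ifelse(bpt$power > 0 & base$power[i] > 0,
                           log(bpt$power / base$power[i]), NA)
    bpt <- bpt[bpt$epoch != "baseline" & !is.na(bpt$logratio), ]
    maps <- list()
    for (b in bands) {
      d <- bpt[bpt$band == b, ]
      maps[[b]] <- pointwiseSignificance(
        data.frame(subject = d$subject, group = d$group, time = d$epoch,
                   channel = d$channel, value = d$logratio,
                   stringsAsFactors = FALSE),
        layout = electrodeLayout(recs[[1]]), spec = mapSpec)
    }
  }

  files <- NULL
  if (!is.null(outputDir)) {
    files <- writeResults(tabs, outputDir)
    if (!is.null(maps))
      for (b in names(maps)) {
        plotTopoMap(maps[[b]], file.path(outputDir,
                                         paste0("topomap_", b, ".png")),
                    main = paste(b, maps[[b]]$contrast))
        utils::write.csv(
          data.frame(anterior = rep(maps[[b]]$x, length(maps[[b]]$y)),
                     lateral = rep(maps[[b]]$y, each = length(maps[[b]]$x)),
                     value = as.vector(maps[[b]]$values),
                     significance = as.vector(maps[[b]]$significance)),
          file.path(outputDir, paste0("topomap_", b, ".csv")),
          row.names = FALSE)
      }
    manifest <- list(seed = config$seed, alpha = alpha,
                     package = as.character(utils::packageVersion("qeegpipe")),
                     nSubjects = length(recs), notes = notes,
                     configDigest = .configDigest(config))
    jsonlite::write_json(manifest, file.path(outputDir, "run_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }

  list(tables = tabs, anova = list(power = anovaPower,
                                   coherence = anovaCoherence,
                                   gfc = anovaGfc, behavior = anovaBehavior),
       designs = list(power = designsPower, gfc = gfcDesign),
       inference = inference, kde = kdeTab, maps = maps, notes = notes,
       files = files, seed = config$seed)
}

# keep only within-levels observed for at least 2 subjects per group, so a
# study whose recordings do not cover a late window still analyses the
# available epochs (with a note) instead of dropping every subject
.completeEpochs <- function(design, postEpochs, label, notes) {
  groups <- unique(design$group)
  keep <- character(0)
  for (e in intersect(postEpochs, unique(design$time))) {
    d <- design[design$time == e, ]
    cnt <- table(factor(d$group, levels = groups))
    if (nrow(d) && min(cnt) >= 2) keep <- c(keep, e)
  }
  if (!setequal(keep, postEpochs))
    notes <- c(notes, sprintf(
      "%s: analysing epochs {%s}; {%s} unavailable", label,
      paste(keep, collapse = ","),
      paste(setdiff(postEpochs, keep), collapse = ",")))
  design <- design[design$time %in% keep, ]
  attr(design, "notes") <- notes
  design
}

.configDigest <- function(config) {
  raw <- serialize(config, NULL, version = 2)
  # order-dependent 64-bit FNV-style fold; enough to tag a run manifest
  h <- 1099511628211
  for (b in as.integer(raw[seq(1, length(raw), by = 7)]))
    h <- (h * 31 + b) %% 9007199254740993
  sprintf("%.0f", h)
}
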