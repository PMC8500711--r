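## Peri-event time histograms, baseline Z-scoring, functional classification
## of BA units, and the pyramidal/interneuron split.

PETH_BASELINE <- c(-5, -1.5)

#' Z-scored peri-event time histogram
#'
#' Spike counts in `bin`-second bins over `window` around each event,
#' averaged over events and converted to Hz. Each bin's Z score is taken
#' against the baseline bins (those starting in \[-5, -1.5) s): Z =
#' (rate - baseline mean) / baseline SD. The baseline SD is floored at the
#' SD expected from Poisson counting at the baseline mean rate
#' (`sqrt(mean / (bin * nEvents))`), which keeps the Z calibrated when the
#' 7-bin empirical SD is degenerate or spuriously small; set
#' `sdFloor = "zero_only"` to apply the floor only when the empirical SD is
#' exactly zero.
#'
#' @param train a [SpikeTrain-class].
#' @param eventTimes event times (s); must be non-empty (filter threat
#'   events with [filterSurgeEvents()] first).
#' @param bin bin width (s), default 0.5.
#' @param window time window around the event (s), default c(-5, 10).
#' @param eventKind label stored on the result.
#' @param sdFloor "always" (default) or "zero_only".
#' @return a [PethResult-class].
#' @export
computePeth <- function(train, eventTimes, bin = 0.5, window = c(-5, 10),
                        eventKind = "event", sdFloor = c("always", "zero_only")) {
  sdFloor <- match.arg(sdFloor)
  if (!length(eventTimes)) stop("computePeth needs at least one event")
  edges <- seq(window[1], window[2], by = bin)
  nb <- length(edges) - 1L
  counts <- numeric(nb)
  tt <- spikeTimes(train)
  for (te in eventTimes) {
    rel <- tt[tt >= te + window[1] & tt < te + window[2]] - te
    idx <- findInterval(rel, edges)
    idx <- idx[idx >= 1L & idx <= nb]
    if (length(idx)) counts <- counts + tabulate(idx, nb)
  }
  nEv <- length(eventTimes)
  rate <- counts / (bin * nEv)
  starts <- edges[-length(edges)]
  baseIdx <- which(starts >= PETH_BASELINE[1] - 1e-9 &
                   starts < PETH_BASELINE[2] - 1e-9)
  bm <- mean(rate[baseIdx])
  bs <- stats::sd(rate[baseIdx])
  poisSd <- sqrt(bm / (bin * nEv))
  floored <- FALSE
  if (sdFloor == "always") {
    if (bs < poisSd) { bs <- poisSd; floored <- TRUE }
  } else if (bs == 0) { bs <- poisSd; floored <- TRUE }
  z <- if (bs > 0) (rate - bm) / bs else rep(0, nb)
  new("PethResult", cellId = cellId(train), eventKind = eventKind,
      binEdges = edges, rate = rate, z = z, nEvents = as.integer(nEv),
      baselineMean = bm, baselineSd = bs, sdFloored = floored)
}

pethWindowBins <- function(peth, lo, hi) {
  # bins whose start lies in [lo, hi)
  starts <- peth@binEdges[-length(peth@binEdges)]
  which(starts >= lo - 1e-9 & starts < hi - 1e-9)
}

windowResponse <- function(peth, lo, hi, zThreshold = 3) {
  idx <- pethWindowBins(peth, lo, hi)
  z <- peth@z[idx]
  if (!length(z)) return(list(responsive = FALSE, sign = "none"))
  if (any(z > zThreshold)) list(responsive = TRUE, sign = "excited")
  else if (any(z < -zThreshold)) list(responsive = TRUE, sign = "inhibited")
  else list(responsive = FALSE, sign = "none")
}

#' Functional classification of a BA unit
#'
#' A cell is robot-responsive when any PETH bin exceeds |Z| = 3 in the
#' robot-approaching window (bins inside \[-1.5, 0) s before the surge) or
#' the robot-triggered window (bins inside \[0, 3) s after it); pellet
#' responsiveness uses the \[-1.5, 2) s window around pellet procurement.
#' Classes: Robot (robot-only), Pellet (pellet-only), RobotPellet (both) or
#' NonResponsive. The response sign (excited/inhibited) and the robot
#' sub-window (approaching/triggered) are retained.
#'
#' @param pethRobot [PethResult-class] aligned on robot surges (or
#'   photostimulations), or NULL when unavailable.
#' @param pethPellet [PethResult-class] aligned on pellet procurement, or
#'   NULL.
#' @param zThreshold significance threshold (default 3).
#' @return data.frame row: cell_id, class, sign, robot_subwindow, partial.
#' @export
classifyBaCell <- function(pethRobot, pethPellet, zThreshold = 3) {
  if (is.null(pethRobot) && is.null(pethPellet))
    stop("at least one PETH is required")
  cid <- if (!is.null(pethRobot)) pethRobot@cellId else pethPellet@cellId
  partial <- is.null(pethRobot) || is.null(pethPellet)
  robApp <- if (!is.null(pethRobot))
    windowResponse(pethRobot, -1.5, 0, zThreshold)
    else list(responsive = FALSE, sign = "none")
  robTrig <- if (!is.null(pethRobot))
    windowResponse(pethRobot, 0, 3, zThreshold)
    else list(responsive = FALSE, sign = "none")
  pel <- if (!is.null(pethPellet))
    windowResponse(pethPellet, -1.5, 2, zThreshold)
    else list(responsive = FALSE, sign = "none")
  robotResp <- robApp$responsive || robTrig$responsive
  robotSign <- if (robTrig$responsive) robTrig$sign
               else if (robApp$responsive) robApp$sign else "none"
  cls <- if (robotResp && pel$responsive) "RobotPellet"
         else if (robotResp) "Robot"
         else if (pel$responsive) "Pellet"
         else "NonResponsive"
  sign <- switch(cls, Robot = robotSign, Pellet = pel$sign,
                 RobotPellet = robotSign, NonResponsive = "none")
  sub <- if (!robotResp) "none"
         else if (robTrig$responsive && robApp$responsive) "both"
         else if (robTrig$responsive) "triggered" else "approaching"
  data.frame(cell_id = cid, class = cls, sign = sign,
             robot_subwindow = sub, partial = partial,
             stringsAsFactors = FALSE)
}

meanSilhouette <- function(d, cl) {
  d <- as.matrix(d)
  s <- vapply(seq_along(cl), function(i) {
    own <- which(cl == cl[i]); own <- own[own != i]
    oth <- which(cl != cl[i])
    if (!length(own)) return(0)  # singleton: no within-cluster evidence
    a <- mean(d[i, own]); b <- mean(d[i, oth])
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

#' Pyramidal / interneuron split of BA units
#'
#' Agglomerative two-cluster split (Ward linkage on standardized spike
#' width and mean firing rate); the cluster with the larger mean spike
#' width is labeled pyramidal. The two-cluster solution is accepted only
#' when it is genuinely separated (mean silhouette width above
#' `minSilhouette`); a homogeneous population - and any population of
#' fewer than 4 cells or with degenerate features - is labeled all
#' pyramidal with a warning (interneurons are excluded from downstream
#' analyses anyway).
#'
#' @param features data.frame with columns cell_id, spike_width (ms),
#'   mean_rate (Hz).
#' @param minSilhouette minimum mean silhouette width to accept the split
#'   (default 0.5).
#' @return data.frame with cell_id and unit_type.
#' @export
splitPyramidalInterneuron <- function(features, minSilhouette = 0.5) {
  stopifnot(all(c("cell_id", "spike_width", "mean_rate") %in% names(features)))
  out <- data.frame(cell_id = features$cell_id, unit_type = "pyramidal",
                    stringsAsFactors = FALSE)
  n <- nrow(features)
  if (n < 4L) {
    warning("fewer than 4 cells; all labeled pyramidal")
    return(out)
  }
  f <- as.matrix(features[, c("spike_width", "mean_rate")])
  sds <- apply(f, 2, stats::sd)
  if (any(sds == 0)) {
    if (all(sds == 0)) {
      warning("identical features; all labeled pyramidal")
      return(out)
    }
    sds[sds == 0] <- 1
  }
  z <- scale(f, scale = sds)
  d <- stats::dist(z)
  cl <- stats::cutree(stats::hclust(d, method = "ward.D2"), k = 2)
  if (meanSilhouette(d, cl) < minSilhouette) {
    warning("no separated two-cluster structure; all labeled pyramidal")
    return(out)
  }
  meanWidth <- tapply(features$spike_width, cl, mean)
  pyr <- as.integer(names(meanWidth)[which.max(meanWidth)])
  out$unit_type <- ifelse(cl == pyr, "pyramidal", "interneuron")
  out
}

#' Classify every BA unit of a cohort
#'
#' Computes robot PETHs from the (surge-filtered) threat-session events and
#' pellet PETHs from the pre_threat-session procurements, classifies each BA
#' unit, and adds the pyramidal/interneuron label.
#'
#' @param cohort list with a `sessions` element (see [makeCohort()]).
#' @param sdFloor passed to [computePeth()].
#' @return data.frame: cell_id, class, sign, robot_subwindow, unit_type,
#'   mean_rate.
#' @export
classifyBaCohort <- function(cohort, sdFloor = "always") {
  ss <- cohort$sessions
  baIds <- names(ss$threat@trains)[vapply(ss$threat@trains, region,
                                          character(1)) == "BA"]
  if (!length(baIds)) return(data.frame())
  evT <- filterSurgeEvents(ss$threat@events)@events
  robotTimes <- evT$time[evT$kind %in% c("robot_surge", "stim_on")]
  evP <- ss$pre_threat@events@events
  pelletTimes <- evP$time[evP$kind == "pellet_procured"]
  rows <- lapply(baIds, function(id) {
    pr <- if (length(robotTimes))
      computePeth(ss$threat@trains[[id]], robotTimes, eventKind = "robot",
                  sdFloor = sdFloor) else NULL
    pp <- if (length(pelletTimes))
      computePeth(ss$pre_threat@trains[[id]], pelletTimes,
                  eventKind = "pellet", sdFloor = sdFloor) else NULL
    classifyBaCell(pr, pp)
  })
  cls <- do.call(rbind, rows)
  feat <- data.frame(
    cell_id = baIds,
    spike_width = vapply(baIds, function(id)
      spikeWidth(ss$threat@trains[[id]]), numeric(1)),
    mean_rate = vapply(baIds, function(id)
      nSpikes(ss$threat@trains[[id]]) / sessionDuration(ss$threat),
      numeric(1)))
  if (all(is.na(feat$spike_width))) {
    cls$unit_type <- "pyramidal"
  } else {
    ut <- splitPyramidalInterneuron(feat[!is.na(feat$spike_width), ])
    cls$unit_type <- ut$unit_type[match(cls$cell_id, ut$cell_id)]
    cls$unit_type[is.na(cls$unit_type)] <- "pyramidal"
  }
  cls$mean_rate <- feat$mean_rate[match(cls$cell_id, feat$cell_id)]
  cls
}
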