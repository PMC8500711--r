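#' Per-frame speed from tracking
#'
#' Central differences of (x, y) on the interior frames, one-sided
#' differences at the endpoints.
#'
#' @param tracking a [Tracking-class] with at least 2 frames.
#' @return numeric vector of speeds (cm/s), one per frame.
#' @export
computeSpeed <- function(tracking) {
  n <- length(tracking@t)
  if (n < 2L) stop("computeSpeed needs at least 2 frames")
  t <- tracking@t; x <- tracking@x; y <- tracking@y
  v <- numeric(n)
  if (n > 2L) {
    i <- 2:(n - 1L)
    v[i] <- sqrt((x[i + 1L] - x[i - 1L])^2 + (y[i + 1L] - y[i - 1L])^2) /
      (t[i + 1L] - t[i - 1L])
  }
  v[1L] <- sqrt((x[2L] - x[1L])^2 + (y[2L] - y[1L])^2) / (t[2L] - t[1L])
  v[n] <- sqrt((x[n] - x[n - 1L])^2 + (y[n] - y[n - 1L])^2) / (t[n] - t[n - 1L])
  v
}

#' Behavioral summary of a session
#'
#' Success rate is the fraction of attempted trials (trials with a
#' gate_open) ending in pellet procurement. The outbound latency of a trial
#' runs from the gate opening to the pellet procurement, or - in threat
#' sessions - to the first robot surge / photostimulation when no pellet was
#' procured. Trials with a gate_open but no outcome get an NA latency;
#' trials without a gate_open are skipped with a warning.
#'
#' @param session a [Session-class].
#' @return a [BehaviorSummary-class].
#' @export
behaviorMetrics <- function(session) {
  ev <- session@events@events
  trials <- sort(unique(ev$trial))
  lat <- numeric(0)
  nAttempt <- 0L; nSuccess <- 0L
  for (tr in trials) {
    sub <- ev[ev$trial == tr, ]
    gate <- sub$time[sub$kind == "gate_open"]
    if (!length(gate)) {
      warning("trial ", tr, " has no gate_open event; skipped")
      next
    }
    nAttempt <- nAttempt + 1L
    pellet <- sub$time[sub$kind == "pellet_procured"]
    if (length(pellet)) {
      nSuccess <- nSuccess + 1L
      lat <- c(lat, pellet[1L] - gate[1L])
    } else {
      surge <- sub$time[sub$kind %in% c("robot_surge", "stim_on")]
      lat <- c(lat, if (length(surge)) min(surge) - gate[1L] else NA_real_)
    }
  }
  trk <- session@tracking
  dist <- if (length(trk@t) > 1L)
    sum(sqrt(diff(trk@x)^2 + diff(trk@y)^2)) else 0
  spd <- if (length(trk@t) > 1L) mean(computeSpeed(trk)) else 0
  new("BehaviorSummary",
      successRate = if (nAttempt) nSuccess / nAttempt else NA_real_,
      outboundLatency = lat,
      meanLatency = if (any(!is.na(lat))) mean(lat, na.rm = TRUE) else NA_real_,
      distanceTraveled = dist, meanSpeed = spd)
}

#' Drop threat events that follow another one too closely
#'
#' Robot surges (and photostimulations) occurring within `refractory`
#' seconds of the previously kept event of the same kind are excluded, so
#' event-locked analyses never overlap. The boundary is inclusive: a gap of
#' exactly `refractory` seconds is kept. Other event kinds pass through
#' unchanged.
#'
#' @param events an [EventLog-class].
#' @param refractory minimum gap in seconds (default 10).
#' @return a filtered [EventLog-class].
#' @export
filterSurgeEvents <- function(events, refractory = 10) {
  ev <- events@events
  keep <- rep(TRUE, nrow(ev))
  for (k in c("robot_surge", "stim_on")) {
    idx <- which(ev$kind == k)
    if (length(idx) < 2L) next
    tt <- ev$time[idx]
    o <- order(tt)
    lastKept <- -Inf
    for (j in o) {
      if (tt[j] - lastKept >= refractory - 1e-12) lastKept <- tt[j]
      else keep[idx[j]] <- FALSE
    }
  }
  new("EventLog", events = ev[keep, , drop = FALSE])
}

#' Build 2.5 s analysis epochs around threat or pellet events
#'
#' `pre_*` windows are the half-open interval \[t - width, t) before the
#' event, `post_*` windows \[t, t + width) after it. Surge labels use
#' robot_surge and stim_on events, pellet labels use pellet_procured. The
#' event log is expected to have passed [filterSurgeEvents()] already.
#'
#' @param events an [EventLog-class].
#' @param label one of "pre_surge", "post_surge", "pre_pellet", "post_pellet".
#' @param width window width in seconds (default 2.5).
#' @return an [EpochSet-class] (possibly with zero windows).
#' @export
makeEpochs <- function(events, label, width = 2.5) {
  label <- match.arg(label, EPOCH_LABELS)
  ev <- events@events
  kinds <- if (grepl("surge", label)) c("robot_surge", "stim_on")
           else "pellet_procured"
  sub <- ev[ev$kind %in% kinds, , drop = FALSE]
  sub <- sub[order(sub$time), , drop = FALSE]
  if (!nrow(sub))
    return(new("EpochSet", label = label,
               windows = matrix(numeric(0), ncol = 2,
                                dimnames = list(NULL, c("start", "end"))),
               trial = integer(0), width = width))
  start <- if (startsWith(label, "pre")) sub$time - width else sub$time
  w <- cbind(start = start, end = start + width)
  new("EpochSet", label = label, windows = w, trial = as.integer(sub$trial),
      width = width)
}

#' Foraging limit of a threat session
#'
#' The maximum corridor position (x, cm) visited during the threat session.
#' Place-field analyses of all three sessions are truncated at this limit,
#' and cells whose pre-threat peak lies beyond it are excluded from
#' stability analysis, so maps are always compared over territory the animal
#' covered in every session.
#'
#' @param threatSession the threat-phase [Session-class].
#' @return the limit in cm.
#' @export
foragingLimit <- function(threatSession) {
  if (!length(threatSession@tracking@x)) return(NA_real_)
  max(threatSession@tracking@x)
}
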