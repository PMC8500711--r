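#' @import methods
NULL

TIME_RESOLUTION <- 1e-4  # spike times are meaningful to 0.1 ms

EVENT_KINDS <- c("gate_open", "pellet_procured", "robot_surge", "stim_on",
                 "trial_end")
EPOCH_LABELS <- c("pre_surge", "post_surge", "pre_pellet", "post_pellet")
PHASES <- c("pre_threat", "threat", "post_threat")

#' SpikeTrain: sorted spike times for one unit
#'
#' Holds the spike times (seconds) of a single recorded unit together with
#' its identity: the cell id, the region it was recorded from (basal
#' amygdala \code{"BA"} or dorsal hippocampus \code{"dHPC"}), and optionally
#' the mean extracellular spike width in ms (used for the
#' pyramidal/interneuron split).
#'
#' Validity: times must be sorted ascending with no duplicates at 0.1 ms
#' resolution, and non-negative.
#'
#' @slot cellId character scalar.
#' @slot region \code{"BA"} or \code{"dHPC"}.
#' @slot times numeric vector of spike times in seconds.
#' @slot spikeWidth spike width in ms (\code{NA_real_} if unknown).
#' @slot sessionId id of the session the train belongs to.
#' @export
setClass("SpikeTrain",
  representation(cellId = "character", region = "character",
                 times = "numeric", spikeWidth = "numeric",
                 sessionId = "character"),
  prototype(spikeWidth = NA_real_, sessionId = NA_character_))

setValidity("SpikeTrain", function(object) {
  msg <- character()
  if (length(object@cellId) != 1L) msg <- c(msg, "cellId must be length 1")
  if (!(object@region %in% c("BA", "dHPC")))
    msg <- c(msg, "region must be 'BA' or 'dHPC'")
  tt <- object@times
  if (length(tt)) {
    if (anyNA(tt) || any(!is.finite(tt)))
      msg <- c(msg, sprintf("cell %s: non-finite spike times", object@cellId))
    else {
      if (is.unsorted(tt))
        msg <- c(msg, sprintf("cell %s: spike times not sorted", object@cellId))
      if (any(tt < 0))
        msg <- c(msg, sprintf("cell %s: negative spike times", object@cellId))
      if (length(tt) > 1L && any(diff(tt) < TIME_RESOLUTION / 2))
        msg <- c(msg, sprintf("cell %s: duplicate spike times at 0.1 ms resolution",
                              object@cellId))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Tracking: animal position samples at a uniform frame rate
#'
#' Position of the animal along the corridor. Convention: x is the corridor
#' axis in cm with the nest interior at x < 0, the gateway at x = 0 and the
#' pellet at x = 125; y is the lateral offset in cm. Frames are uniform at
#' \code{frameRate} (default 30 frames/s); the frame interval must be
#' constant to within 1%.
#'
#' @slot t numeric timestamps (s).
#' @slot x,y numeric positions (cm).
#' @slot frameRate frames per second.
#' @export
setClass("Tracking",
  representation(t = "numeric", x = "numeric", y = "numeric",
                 frameRate = "numeric"),
  prototype(frameRate = 30))

setValidity("Tracking", function(object) {
  msg <- character()
  n <- length(object@t)
  if (length(object@x) != n || length(object@y) != n)
    msg <- c(msg, "t, x, y must have equal length")
  if (anyNA(object@x) || any(!is.finite(object@x)))
    msg <- c(msg, "x must be finite")
  if (n > 1L) {
    dt <- diff(object@t)
    if (any(dt <= 0)) msg <- c(msg, "timestamps must be strictly increasing")
    else {
      med <- stats::median(dt)
      if (max(abs(dt - med)) > 0.01 * med)
        msg <- c(msg, "frame interval not constant within 1%")
    }
  }
  if (length(msg)) msg else TRUE
})

#' EventLog: trial-tagged behavioral events
#'
#' A table of behavioral events: \code{trial} (integer >= 1), \code{kind}
#' (one of gate_open, pellet_procured, robot_surge, stim_on, trial_end) and
#' \code{time} in seconds. Within each trial at most one gate_open and one
#' pellet_procured may occur and times must be sorted.
#'
#' @slot events data.frame with columns trial, kind, time.
#' @export
setClass("EventLog", representation(events = "data.frame"))

setValidity("EventLog", function(object) {
  ev <- object@events
  msg <- character()
  need <- c("trial", "kind", "time")
  if (!all(need %in% names(ev)))
    return("events must have columns trial, kind, time")
  if (nrow(ev)) {
    if (any(!ev$kind %in% EVENT_KINDS))
      msg <- c(msg, paste("unknown event kind:",
                          paste(setdiff(unique(ev$kind), EVENT_KINDS), collapse = ", ")))
    if (any(ev$trial < 1)) msg <- c(msg, "trial indices must be >= 1")
    for (tr in unique(ev$trial)) {
      sub <- ev[ev$trial == tr, ]
      if (is.unsorted(sub$time))
        msg <- c(msg, sprintf("trial %d: event times not sorted", tr))
      for (k in c("gate_open", "pellet_procured"))
        if (sum(sub$kind == k) > 1L)
          msg <- c(msg, sprintf("trial %d: more than one %s event", tr, k))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Session: one recording session (tracking + events + spike trains)
#'
#' A single behavioral phase of a recording day: \code{pre_threat},
#' \code{threat} or \code{post_threat}. Threat sessions (and only threat
#' sessions) contain robot_surge or stim_on events.
#'
#' @slot sessionId character scalar.
#' @slot phase one of pre_threat, threat, post_threat.
#' @slot tracking a [Tracking-class].
#' @slot events an [EventLog-class].
#' @slot trains named list of [SpikeTrain-class] objects.
#' @slot duration session length in seconds.
#' @export
setClass("Session",
  representation(sessionId = "character", phase = "character",
                 tracking = "Tracking", events = "EventLog",
                 trains = "list", duration = "numeric"))

setValidity("Session", function(object) {
  msg <- character()
  if (!(object@phase %in% PHASES))
    msg <- c(msg, "phase must be pre_threat, threat or post_threat")
  d <- object@duration
  if (length(object@tracking@t) && max(object@tracking@t) > d + 1e-9)
    msg <- c(msg, "tracking extends beyond session duration")
  ev <- object@events@events
  if (nrow(ev) && max(ev$time) > d + 1e-9)
    msg <- c(msg, "events extend beyond session duration")
  for (tr in object@trains) {
    if (!is(tr, "SpikeTrain")) { msg <- c(msg, "trains must be SpikeTrain objects"); break }
    if (length(tr@times) && max(tr@times) > d + 1e-9)
      msg <- c(msg, sprintf("cell %s: spikes beyond session duration", tr@cellId))
  }
  threatEv <- nrow(ev) && any(ev$kind %in% c("robot_surge", "stim_on"))
  if (object@phase == "threat" && !threatEv)
    msg <- c(msg, "threat session without robot_surge/stim_on events")
  if (object@phase != "threat" && threatEv)
    msg <- c(msg, sprintf("%s session contains threat events", object@phase))
  if (length(msg)) msg else TRUE
})

#' EpochSet: per-trial 2.5 s analysis windows around an event
#'
#' Windows of fixed width (2.5 s by default) immediately before or after
#' robot surges / pellet procurements; half-open \code{[start, end)}.
#'
#' @slot label one of pre_surge, post_surge, pre_pellet, post_pellet.
#' @slot windows numeric matrix with columns start, end (one row per event).
#' @slot trial integer trial index per window.
#' @slot width window width in s.
#' @export
setClass("EpochSet",
  representation(label = "character", windows = "matrix",
                 trial = "integer", width = "numeric"),
  prototype(width = 2.5))

setValidity("EpochSet", function(object) {
  msg <- character()
  if (!(object@label %in% EPOCH_LABELS))
    msg <- c(msg, "label must be one of pre_surge, post_surge, pre_pellet, post_pellet")
  w <- object@windows
  if (nrow(w)) {
    if (ncol(w) != 2L) msg <- c(msg, "windows must have 2 columns")
    else {
      if (max(abs((w[, 2] - w[, 1]) - object@width)) > 1e-9)
        msg <- c(msg, sprintf("all windows must have width %g s", object@width))
      o <- order(w[, 1])
      if (nrow(w) > 1L && any(w[o, 1][-1] < w[o, 2][-nrow(w)] - 1e-12))
        msg <- c(msg, "windows overlap")
    }
    if (length(object@trial) != nrow(w))
      msg <- c(msg, "trial must have one entry per window")
  }
  if (length(msg)) msg else TRUE
})

#' BehaviorSummary: per-session behavioral metrics
#'
#' @slot successRate fraction of attempted trials with pellet procurement.
#' @slot outboundLatency per-trial gate-to-outcome latency (s), NA when the
#'   trial had neither a procurement nor a surge.
#' @slot meanLatency mean of the defined latencies (s).
#' @slot distanceTraveled total path length (cm).
#' @slot meanSpeed mean frame speed (cm/s).
#' @export
setClass("BehaviorSummary",
  representation(successRate = "numeric", outboundLatency = "numeric",
                 meanLatency = "numeric", distanceTraveled = "numeric",
                 meanSpeed = "numeric"))

#' RateMap: occupancy-normalized firing-rate map on a pixel grid
#'
#' 2-D pixel grid over the corridor, truncated at the foraging limit.
#' \code{rate} is the Gaussian-smoothed count map divided by the equally
#' smoothed occupancy map, defined on visited pixels only; \code{rateRaw}
#' is the unsmoothed count/occupancy ratio used for spatial information.
#'
#' @slot xBreaks,yBreaks pixel edges (cm).
#' @slot occupancy seconds per pixel (unsmoothed).
#' @slot spikeCount spikes per pixel (unsmoothed).
#' @slot rate smoothed firing rate (Hz), NA on unvisited pixels.
#' @slot rateRaw unsmoothed firing rate (Hz), NA on unvisited pixels.
#' @slot visited logical mask of visited pixels.
#' @slot peakRate peak of \code{rate} over visited pixels (Hz).
#' @slot peakX x coordinate (pixel center, cm) of the peak pixel.
#' @slot pixelSize pixel edge length (cm).
#' @export
setClass("RateMap",
  representation(xBreaks = "numeric", yBreaks = "numeric",
                 occupancy = "matrix", spikeCount = "matrix",
                 rate = "matrix", rateRaw = "matrix", visited = "matrix",
                 peakRate = "numeric", peakX = "numeric",
                 pixelSize = "numeric"))

setValidity("RateMap", function(object) {
  msg <- character()
  if (any(object@occupancy < 0)) msg <- c(msg, "occupancy must be >= 0")
  if (any(object@spikeCount < 0)) msg <- c(msg, "spike counts must be >= 0")
  dims <- dim(object@occupancy)
  for (s in c("spikeCount", "rate", "rateRaw", "visited"))
    if (!identical(dim(slot(object, s)), dims))
      msg <- c(msg, sprintf("%s dimensions differ from occupancy", s))
  if (length(msg)) msg else TRUE
})

#' PethResult: Z-scored peri-event time histogram
#'
#' Spike counts around events in 500 ms bins over [-5, +10] s, averaged over
#' events and converted to Hz, then Z-scored against the baseline bins
#' [-5, -1.5) s.
#'
#' @slot cellId,eventKind identity of the cell and the aligning event.
#' @slot binEdges bin edges (s relative to the event).
#' @slot rate mean firing rate per bin (Hz).
#' @slot z per-bin Z score relative to baseline.
#' @slot nEvents number of events averaged.
#' @slot baselineMean,baselineSd baseline statistics (Hz).
#' @slot sdFloored TRUE when the Poisson floor was binding for the baseline SD.
#' @export
setClass("PethResult",
  representation(cellId = "character", eventKind = "character",
                 binEdges = "numeric", rate = "numeric", z = "numeric",
                 nEvents = "integer", baselineMean = "numeric",
                 baselineSd = "numeric", sdFloored = "logical"))

#' CcgResult: shift-predictor-corrected cross-correlogram for one pair
#'
#' BA-referenced cross-correlogram restricted to one epoch label, in 10 ms
#' bins spanning +/-500 ms (bin edges at multiples of 10 ms, so no bin
#' straddles lag 0). The corrected correlogram is raw minus the mean
#' shift-predictor; Z per bin is computed from the mean and SD of the
#' corrected correlogram. A pair is significant when the peak Z exceeds 3,
#' the peak bin lies within +/-100 ms, and both epoch firing rates exceed
#' 0.1 Hz. Direction: a significant peak in [-100, 0) ms means the dHPC cell
#' leads (dHPC->BA); in (0, +100] ms the BA cell leads (BA->dHPC).
#'
#' @slot baCell,hpcCell,epochLabel pair identity.
#' @slot binEdges lag-bin edges (s).
#' @slot raw,predictor,corrected,z per-bin correlogram quantities.
#' @slot peakZ,peakLagMs peak Z and the center (ms) of the peak bin.
#' @slot significant logical.
#' @slot direction "dHPC->BA", "BA->dHPC" or "none".
#' @slot baRate,hpcRate epoch firing rates (Hz).
#' @slot flag "ok", "rate_fail", "degenerate" or "no_epochs".
#' @export
setClass("CcgResult",
  representation(baCell = "character", hpcCell = "character",
                 epochLabel = "character", binEdges = "numeric",
                 raw = "numeric", predictor = "numeric",
                 corrected = "numeric", z = "numeric",
                 peakZ = "numeric", peakLagMs = "numeric",
                 significant = "logical", direction = "character",
                 baRate = "numeric", hpcRate = "numeric", flag = "character"))

#' PsdResult: spike-train power spectrum and band fractions
#'
#' Welch-averaged power spectral density of a binned (2 ms), demeaned spike
#' train over a set of analysis windows, with band fractions expressed as a
#' percentage of the total power in [1, 50) Hz. Theta is 6-10 Hz.
#'
#' @slot freq frequency grid (Hz).
#' @slot power power density per frequency.
#' @slot bandFraction named numeric: percent of in-range power per band
#'   (delta, theta, beta, gamma).
#' @slot nSegments number of Welch segments averaged.
#' @slot windows the analysis windows used (matrix start, end).
#' @export
setClass("PsdResult",
  representation(freq = "numeric", power = "numeric",
                 bandFraction = "numeric", nSegments = "integer",
                 windows = "matrix"))

setValidity("PsdResult", function(object) {
  bf <- object@bandFraction
  if (any(bf < -1e-9)) return("band fractions must be >= 0")
  if (sum(bf) > 100 + 1e-6) return("band fractions exceed 100% of in-range power")
  TRUE
})

#' SimConfig: parameters of the synthetic foraging cohort
#'
#' Describes a simulated recording day: corridor geometry, trial structure,
#' the dHPC place-cell population (Gaussian place fields on the corridor
#' axis), the BA population (baseline Poisson firing with event-locked
#' multiplicative modulation) and the list of pairwise synchrony injections.
#' See [simConfig()] for field semantics and defaults.
#'
#' @slot nTrials trials per phase.
#' @slot pelletX pellet position (cm).
#' @slot triggerOffset robot trigger distance from the pellet (cm).
#' @slot surgeTravel robot surge travel (cm; event timing cosmetic only).
#' @slot frameRate tracking frame rate (Hz).
#' @slot nestDepth nest interior depth (cm; nest spans [-nestDepth, 0)).
#' @slot outboundSpeed,returnSpeed,fleeSpeed locomotion speeds (cm/s).
#' @slot nestDwell nest dwell per trial (s).
#' @slot pauseProb,pauseDuration threat-phase outbound pause parameters.
#' @slot successProbThreat probability a threat trial still ends in procurement.
#' @slot yNoise lateral position noise bound (cm).
#' @slot placeCells data.frame of dHPC cell parameters.
#' @slot baCells data.frame of BA cell parameters.
#' @slot synchrony data.frame of pairwise co-firing injections.
#' @slot refractory simulated absolute refractory period (s).
#' @slot seed integer RNG seed for the cohort.
#' @export
setClass("SimConfig",
  representation(nTrials = "integer", pelletX = "numeric",
                 triggerOffset = "numeric", surgeTravel = "numeric",
                 frameRate = "numeric", nestDepth = "numeric",
                 outboundSpeed = "numeric", returnSpeed = "numeric",
                 fleeSpeed = "numeric", nestDwell = "numeric",
                 pauseProb = "numeric", pauseDuration = "numeric",
                 successProbThreat = "numeric", yNoise = "numeric",
                 placeCells = "data.frame", baCells = "data.frame",
                 synchrony = "data.frame", refractory = "numeric",
                 seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@outboundSpeed <= 0 || object@returnSpeed <= 0 || object@fleeSpeed <= 0)
    msg <- c(msg, "speeds must be positive")
  pc <- object@placeCells
  if (nrow(pc)) {
    if (any(pc$peak_rate < 0) || any(pc$baseline_rate < 0))
      msg <- c(msg, "place-cell rates must be >= 0")
    if (any(pc$sigma <= 0)) msg <- c(msg, "place-field sigma must be > 0")
  }
  ba <- object@baCells
  if (nrow(ba) && any(ba$baseline_rate < 0))
    msg <- c(msg, "BA baseline rates must be >= 0")
  sy <- object@synchrony
  if (nrow(sy)) {
    if (any(abs(sy$lag_ms) > 100)) msg <- c(msg, "synchrony lag must be within +/-100 ms")
    if (any(sy$excess < 0)) msg <- c(msg, "synchrony excess must be >= 0")
  }
  if (length(msg)) msg else TRUE
})
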