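#' Accessors for riskforage objects
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param x an object.
#' @return the corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("cellId", function(x) standardGeneric("cellId"))
#' @rdname accessors
#' @export
setGeneric("region", function(x) standardGeneric("region"))
#' @rdname accessors
#' @export
setGeneric("spikeTimes", function(x) standardGeneric("spikeTimes"))
#' @rdname accessors
#' @export
setGeneric("nSpikes", function(x) standardGeneric("nSpikes"))
#' @rdname accessors
#' @export
setGeneric("spikeWidth", function(x) standardGeneric("spikeWidth"))
#' @rdname accessors
#' @export
setGeneric("sessionId", function(x) standardGeneric("sessionId"))
#' @rdname accessors
#' @export
setGeneric("sessionPhase", function(x) standardGeneric("sessionPhase"))
#' @rdname accessors
#' @export
setGeneric("tracking", function(x) standardGeneric("tracking"))
#' @rdname accessors
#' @export
setGeneric("events", function(x) standardGeneric("events"))
#' @rdname accessors
#' @export
setGeneric("trains", function(x) standardGeneric("trains"))
#' @rdname accessors
#' @export
setGeneric("sessionDuration", function(x) standardGeneric("sessionDuration"))
#' @rdname accessors
#' @export
setGeneric("epochWindows", function(x) standardGeneric("epochWindows"))
#' @rdname accessors
#' @export
setGeneric("epochLabel", function(x) standardGeneric("epochLabel"))
#' @rdname accessors
#' @export
setGeneric("rateMatrix", function(x, smoothed = TRUE) standardGeneric("rateMatrix"))
#' @rdname accessors
#' @export
setGeneric("occupancyMatrix", function(x) standardGeneric("occupancyMatrix"))
#' @rdname accessors
#' @export
setGeneric("peakRate", function(x) standardGeneric("peakRate"))
#' @rdname accessors
#' @export
setGeneric("peakX", function(x) standardGeneric("peakX"))
#' @rdname accessors
#' @export
setGeneric("pethZ", function(x) standardGeneric("pethZ"))
#' @rdname accessors
#' @export
setGeneric("pethRate", function(x) standardGeneric("pethRate"))
#' @rdname accessors
#' @export
setGeneric("binEdges", function(x) standardGeneric("binEdges"))
#' @rdname accessors
#' @export
setGeneric("isSignificant", function(x) standardGeneric("isSignificant"))
#' @rdname accessors
#' @export
setGeneric("pairDirection", function(x) standardGeneric("pairDirection"))
#' @rdname accessors
#' @export
setGeneric("bandFractions", function(x) standardGeneric("bandFractions"))

setMethod("cellId", "SpikeTrain", function(x) x@cellId)
setMethod("region", "SpikeTrain", function(x) x@region)
setMethod("spikeTimes", "SpikeTrain", function(x) x@times)
setMethod("nSpikes", "SpikeTrain", function(x) length(x@times))
setMethod("spikeWidth", "SpikeTrain", function(x) x@spikeWidth)
setMethod("sessionId", "SpikeTrain", function(x) x@sessionId)
setMethod("sessionId", "Session", function(x) x@sessionId)
setMethod("sessionPhase", "Session", function(x) x@phase)
setMethod("tracking", "Session", function(x) x@tracking)
setMethod("events", "Session", function(x) x@events@events)
setMethod("events", "EventLog", function(x) x@events)
setMethod("trains", "Session", function(x) x@trains)
setMethod("sessionDuration", "Session", function(x) x@duration)
setMethod("epochWindows", "EpochSet", function(x) x@windows)
setMethod("epochLabel", "EpochSet", function(x) x@label)
setMethod("rateMatrix", "RateMap",
          function(x, smoothed = TRUE) if (smoothed) x@rate else x@rateRaw)
setMethod("occupancyMatrix", "RateMap", function(x) x@occupancy)
setMethod("peakRate", "RateMap", function(x) x@peakRate)
setMethod("peakX", "RateMap", function(x) x@peakX)
setMethod("pethZ", "PethResult", function(x) x@z)
setMethod("pethRate", "PethResult", function(x) x@rate)
setMethod("binEdges", "PethResult", function(x) x@binEdges)
setMethod("binEdges", "CcgResult", function(x) x@binEdges)
setMethod("isSignificant", "CcgResult", function(x) x@significant)
setMethod("pairDirection", "CcgResult", function(x) x@direction)
setMethod("bandFractions", "PsdResult", function(x) x@bandFraction)

setMethod("show", "SpikeTrain", function(object) {
  cat(sprintf("SpikeTrain '%s' (%s): %d spikes", object@cellId,
              object@region, length(object@times)))
  if (length(object@times))
    cat(sprintf(" over [%.3f, %.3f] s", min(object@times), max(object@times)))
  cat("\n")
})

setMethod("show", "Tracking", function(object) {
  cat(sprintf("Tracking: %d frames at %g Hz", length(object@t), object@frameRate))
  if (length(object@t))
    cat(sprintf(", x in [%.1f, %.1f] cm", min(object@x), max(object@x)))
  cat("\n")
})

setMethod("show", "EventLog", function(object) {
  ev <- object@events
  cat(sprintf("EventLog: %d events across %d trials\n", nrow(ev),
              length(unique(ev$trial))))
  if (nrow(ev)) print(table(ev$kind))
})

setMethod("show", "Session", function(object) {
  cat(sprintf("Session '%s' (%s): %.1f s, %d units (%d BA, %d dHPC), %d events\n",
              object@sessionId, object@phase, object@duration,
              length(object@trains),
              sum(vapply(object@trains, function(tr) tr@region == "BA", logical(1))),
              sum(vapply(object@trains, function(tr) tr@region == "dHPC", logical(1))),
              nrow(object@events@events)))
})

setMethod("show", "EpochSet", function(object) {
  cat(sprintf("EpochSet '%s': %d windows of %.1f s\n", object@label,
              nrow(object@windows), object@width))
})

setMethod("show", "BehaviorSummary", function(object) {
  cat(sprintf("BehaviorSummary: success rate %.2f, mean outbound latency %.2f s,\n  distance %.0f cm, mean speed %.1f cm/s\n",
              object@successRate, object@meanLatency,
              object@distanceTraveled, object@meanSpeed))
})

setMethod("show", "RateMap", function(object) {
  cat(sprintf("RateMap: %d x %d pixels (%g cm), peak %.2f Hz at x = %.1f cm\n",
              nrow(object@occupancy), ncol(object@occupancy),
              object@pixelSize, object@peakRate, object@peakX))
})

setMethod("show", "PethResult", function(object) {
  cat(sprintf("PethResult '%s' ~ %s: %d events, peak |Z| = %.2f\n",
              object@cellId, object@eventKind, object@nEvents,
              max(abs(object@z), na.rm = TRUE)))
})

setMethod("show", "CcgResult", function(object) {
  cat(sprintf("CcgResult %s ~ %s [%s]: peak Z = %.2f at %+.0f ms, %s%s\n",
              object@baCell, object@hpcCell, object@epochLabel,
              object@peakZ, object@peakLagMs,
              if (object@significant) "significant" else "not significant",
              if (object@direction == "none") "" else paste0(" (", object@direction, ")")))
})

setMethod("show", "PsdResult", function(object) {
  cat(sprintf("PsdResult: %d segments, theta fraction %.2f%%\n",
              object@nSegments, object@bandFraction[["theta"]]))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf("SimConfig: %d trials/phase, %d dHPC place cells, %d BA cells, %d synchrony injections, seed %d\n",
              object@nTrials, nrow(object@placeCells), nrow(object@baCells),
              nrow(object@synchrony), object@seed))
})
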