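#' Construct a SpikeTrain
#'
#' @param cellId unit id.
#' @param region "BA" or "dHPC".
#' @param times spike times in seconds (sorted ascending).
#' @param spikeWidth mean spike width in ms (optional).
#' @param sessionId id of the owning session (optional).
#' @return a [SpikeTrain-class].
#' @export
spikeTrain <- function(cellId, region, times, spikeWidth = NA_real_,
                       sessionId = NA_character_) {
  new("SpikeTrain", cellId = as.character(cellId), region = region,
      times = as.numeric(times), spikeWidth = spikeWidth,
      sessionId = sessionId)
}

#' Construct a Tracking object
#'
#' @param t timestamps (s), uniform spacing.
#' @param x corridor-axis position (cm; nest interior < 0, pellet at 125).
#' @param y lateral position (cm).
#' @param frameRate frames per second (default 30).
#' @return a [Tracking-class].
#' @export
trackingData <- function(t, x, y, frameRate = 30) {
  new("Tracking", t = as.numeric(t), x = as.numeric(x), y = as.numeric(y),
      frameRate = frameRate)
}

#' Construct an EventLog
#'
#' @param trial integer trial index per event.
#' @param kind event kind (gate_open, pellet_procured, robot_surge, stim_on,
#'   trial_end).
#' @param time event time (s).
#' @return an [EventLog-class].
#' @export
eventLog <- function(trial = integer(), kind = character(), time = numeric()) {
  new("EventLog", events = data.frame(trial = as.integer(trial),
                                      kind = as.character(kind),
                                      time = as.numeric(time)))
}

#' Construct a Session
#'
#' @param sessionId session id.
#' @param phase "pre_threat", "threat" or "post_threat".
#' @param tracking a [Tracking-class].
#' @param events an [EventLog-class].
#' @param trains list of [SpikeTrain-class]; names are set to the cell ids.
#' @param duration session length (s); default the last tracking timestamp.
#' @return a [Session-class].
#' @export
session <- function(sessionId, phase, tracking, events, trains,
                    duration = NULL) {
  if (is.null(duration))
    duration <- if (length(tracking@t)) max(tracking@t) else 0
  names(trains) <- vapply(trains, cellId, character(1))
  new("Session", sessionId = sessionId, phase = phase, tracking = tracking,
      events = events, trains = trains, duration = duration)
}

## ---- file formats ---------------------------------------------------------
## spikes.csv:   cell_id, region, time_s, spike_width_ms
## tracking.csv: t_s, x_cm, y_cm
## events.csv:   trial, kind, time_s
## manifest:     DCF text with session_id, phase, duration_s, frame_rate_hz

fmt_num <- function(x, digits) {
  out <- formatC(x, format = "f", digits = digits)
  out[is.na(x)] <- "NA"
  out
}

write_table_stable <- function(df, path) {
  con <- file(path, open = "wb")  # binary mode: LF endings on every platform
  on.exit(close(con))
  writeLines(paste(names(df), collapse = ","), con)
  if (nrow(df)) {
    cols <- lapply(df, as.character)
    writeLines(do.call(paste, c(cols, sep = ",")), con)
  }
  invisible(NULL)
}

#' Write a Session to a directory of plain-text tables
#'
#' Writes `spikes.csv`, `tracking.csv`, `events.csv` and a `manifest` file
#' (DCF key: value text). Numeric formatting is fixed (times at 0.1 ms,
#' positions at 0.001 cm) so identical sessions produce byte-identical files.
#'
#' @param session a [Session-class].
#' @param dirPath output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
writeSession <- function(session, dirPath) {
  stopifnot(is(session, "Session"))
  if (!dir.exists(dirPath) &&
      !dir.create(dirPath, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create directory: ", dirPath)
  trs <- session@trains
  spk <- data.frame(
    cell_id = rep(vapply(trs, cellId, character(1)),
                  vapply(trs, nSpikes, integer(1))),
    region = rep(vapply(trs, region, character(1)),
                 vapply(trs, nSpikes, integer(1))),
    time_s = fmt_num(unlist(lapply(trs, spikeTimes), use.names = FALSE), 4),
    spike_width_ms = rep(fmt_num(vapply(trs, spikeWidth, numeric(1)), 3),
                         vapply(trs, nSpikes, integer(1))))
  if (!length(trs))
    spk <- data.frame(cell_id = character(), region = character(),
                      time_s = character(), spike_width_ms = character())
  write_table_stable(spk, file.path(dirPath, "spikes.csv"))
  trk <- session@tracking
  write_table_stable(
    data.frame(t_s = fmt_num(trk@t, 6), x_cm = fmt_num(trk@x, 3),
               y_cm = fmt_num(trk@y, 3)),
    file.path(dirPath, "tracking.csv"))
  ev <- session@events@events
  write_table_stable(
    data.frame(trial = as.integer(ev$trial), kind = ev$kind,
               time_s = fmt_num(ev$time, 4)),
    file.path(dirPath, "events.csv"))
  # spike width catalog: cells with zero spikes still need identity on disk
  cells <- data.frame(
    cell_id = vapply(trs, cellId, character(1)),
    region = vapply(trs, region, character(1)),
    spike_width_ms = fmt_num(vapply(trs, spikeWidth, numeric(1)), 3))
  if (!length(trs))
    cells <- data.frame(cell_id = character(), region = character(),
                        spike_width_ms = character())
  write_table_stable(cells, file.path(dirPath, "cells.csv"))
  man <- matrix(c(session@sessionId, session@phase,
                  fmt_num(session@duration, 6),
                  fmt_num(trk@frameRate, 3)), nrow = 1)
  colnames(man) <- c("session_id", "phase", "duration_s", "frame_rate_hz")
  write.dcf(man, file.path(dirPath, "manifest"))
  invisible(dirPath)
}

#' Read a Session from a directory written by [writeSession()]
#'
#' Validates the result: spike times must be sorted, non-negative and within
#' the session duration; event invariants (sorted within trial, at most one
#' gate_open / pellet_procured per trial) are enforced.
#'
#' @param dirPath directory containing spikes.csv, tracking.csv, events.csv,
#'   cells.csv and manifest.
#' @return a [Session-class].
#' @export
readSession <- function(dirPath) {
  need <- c("spikes.csv", "tracking.csv", "events.csv", "cells.csv", "manifest")
  missing <- need[!file.exists(file.path(dirPath, need))]
  if (length(missing))
    stop("session directory ", dirPath, " is missing: ",
         paste(missing, collapse = ", "))
  man <- read.dcf(file.path(dirPath, "manifest"))
  spk <- utils::read.csv(file.path(dirPath, "spikes.csv"),
                         colClasses = c("character", "character",
                                        "numeric", "numeric"))
  trk <- utils::read.csv(file.path(dirPath, "tracking.csv"))
  ev <- utils::read.csv(file.path(dirPath, "events.csv"),
                        colClasses = c("integer", "character", "numeric"))
  cells <- utils::read.csv(file.path(dirPath, "cells.csv"),
                           colClasses = c("character", "character", "numeric"))
  sid <- unname(man[1, "session_id"])
  trainList <- lapply(seq_len(nrow(cells)), function(i) {
    tt <- spk$time_s[spk$cell_id == cells$cell_id[i]]
    spikeTrain(cells$cell_id[i], cells$region[i], tt,
               spikeWidth = cells$spike_width_ms[i], sessionId = sid)
  })
  session(sid, unname(man[1, "phase"]),
          trackingData(trk$t_s, trk$x_cm, trk$y_cm,
                       frameRate = as.numeric(man[1, "frame_rate_hz"])),
          eventLog(ev$trial, ev$kind, ev$time_s),
          trainList, duration = as.numeric(man[1, "duration_s"]))
}
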