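## Spike-train power spectra (Welch) and theta-band (6-10 Hz) fractions
## around threat / stimulation events.

PSD_BANDS <- list(delta = c(1, 4), theta = c(6, 10), beta = c(12, 30),
                  gamma = c(30, 50))
PSD_TOTAL_RANGE <- c(1, 50)

hannWindow <- function(n) 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))

#' Welch power spectrum of a binned spike train
#'
#' Spikes inside each analysis window are binned at `binWidth` (2 ms
#' default) and mean-subtracted per window; the windows are cut into
#' `segLength`-second segments with `overlap` fractional overlap, each
#' segment is tapered (`Hann` by default) and its periodogram computed, and
#' the periodograms are averaged. Power is normalized so that, with a
#' rectangular taper and no overlap, the one-sided spectrum sums to the
#' variance of the binned train (a Parseval identity). Band fractions are
#' percentages of the total power over \[1, 50) Hz, with half-open bands:
#' delta \[1,4), theta \[6,10), beta \[12,30), gamma \[30,50).
#'
#' @param train a [SpikeTrain-class] (or numeric spike-time vector).
#' @param windows numeric matrix (start, end) of analysis windows (s);
#'   total length must be at least 5 s.
#' @param binWidth spike-count bin (s), default 0.002.
#' @param segLength Welch segment length (s), default 2.5.
#' @param overlap fractional segment overlap, default 0.5.
#' @param taper "hann" (default) or "rect".
#' @return a [PsdResult-class].
#' @export
spikePsd <- function(train, windows, binWidth = 0.002, segLength = 2.5,
                     overlap = 0.5, taper = c("hann", "rect")) {
  taper <- match.arg(taper)
  if (is.null(dim(windows))) windows <- matrix(windows, ncol = 2, byrow = TRUE)
  if (!nrow(windows) || sum(windows[, 2] - windows[, 1]) < 5 - 1e-9)
    stop("spikePsd needs windows totalling at least 5 s")
  tt <- if (is(train, "SpikeTrain")) spikeTimes(train) else as.numeric(train)
  nSeg <- round(segLength / binWidth)
  w <- if (taper == "hann") hannWindow(nSeg) else rep(1, nSeg)
  sumw2 <- sum(w^2)
  step <- max(1L, round(nSeg * (1 - overlap)))
  half <- nSeg %/% 2
  freq <- seq_len(half) / (nSeg * binWidth)  # DC dropped (demeaned)
  acc <- numeric(half); count <- 0L
  for (i in seq_len(nrow(windows))) {
    lo <- windows[i, 1]; hi <- windows[i, 2]
    nb <- floor((hi - lo) / binWidth)
    if (nb < nSeg) next
    sel <- tt[tt >= lo - 1e-9 & tt < lo + nb * binWidth - 1e-9]
    counts <- tabulate(floor((sel - lo + 1e-9) / binWidth) + 1L, nb)
    x <- counts - mean(counts)
    starts <- seq(1L, nb - nSeg + 1L, by = step)
    for (s0 in starts) {
      seg <- x[s0:(s0 + nSeg - 1L)]
      X <- stats::fft(seg * w)
      p2 <- Mod(X)^2 / (nSeg * sumw2)      # two-sided, sums to variance
      p1 <- 2 * p2[2:(half + 1L)]          # one-sided (DC dropped)
      if (nSeg %% 2 == 0) p1[half] <- p2[half + 1L]  # Nyquist not doubled
      acc <- acc + p1
      count <- count + 1L
    }
  }
  if (!count) stop("no complete Welch segment fits in the windows")
  power <- acc / count
  inRange <- freq >= PSD_TOTAL_RANGE[1] & freq < PSD_TOTAL_RANGE[2]
  total <- sum(power[inRange])
  bf <- vapply(PSD_BANDS, function(b) {
    idx <- freq >= b[1] & freq < b[2]
    if (total > 0) 100 * sum(power[idx]) / total else 0
  }, numeric(1))
  new("PsdResult", freq = freq, power = power, bandFraction = bf,
      nSegments = as.integer(count), windows = windows)
}

#' Theta-band fractions per place-cell class and session
#'
#' For every included, classified place cell, spike power spectra are
#' computed in event-centered windows (+/-2.5 s around robot surges in the
#' threat session; +/-2.5 s around pellet procurement in pre/post sessions;
#' use `stimWindow = c(0, 5)` semantics via `eventWindow` for
#' photostimulation designs) and the theta (6-10 Hz) fraction is reported
#' per cell and session.
#'
#' @param placeRecords `records` data.frame from [placeCellRecords()].
#' @param cohort list with `sessions`.
#' @param eventWindow window around each event (s), default c(-2.5, 2.5).
#' @param minTotal minimum total window length required per cell (s).
#' @return data.frame: cell_id, class, session, theta_fraction, n_windows.
#' @export
thetaByCellType <- function(placeRecords, cohort, eventWindow = c(-2.5, 2.5),
                            minTotal = 5) {
  ss <- cohort$sessions
  rec <- placeRecords[placeRecords$included & !is.na(placeRecords$class), ]
  if (!nrow(rec)) {
    warning("no included, classified place cells")
    return(data.frame())
  }
  rows <- list(); k <- 0L
  for (phase in PHASES) {
    s <- ss[[phase]]
    ev <- filterSurgeEvents(s@events)@events
    kinds <- if (phase == "threat") c("robot_surge", "stim_on")
             else "pellet_procured"
    centers <- ev$time[ev$kind %in% kinds]
    w <- cbind(centers + eventWindow[1], centers + eventWindow[2])
    w <- w[w[, 1] >= 0 & w[, 2] <= s@duration, , drop = FALSE]
    if (!nrow(w) || sum(w[, 2] - w[, 1]) < minTotal) next
    for (i in seq_len(nrow(rec))) {
      k <- k + 1L
      psd <- spikePsd(s@trains[[rec$cell_id[i]]], w)
      rows[[k]] <- data.frame(
        cell_id = rec$cell_id[i], class = rec$class[i], session = phase,
        theta_fraction = psd@bandFraction[["theta"]], n_windows = nrow(w),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  for (cl in unique(rec$class))
    if (!is.null(out) && !cl %in% out$class)
      warning("class ", cl, " has no theta results")
  out
}
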