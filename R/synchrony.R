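## Epoch-restricted BA-referenced cross-correlograms with shift-predictor
## correction, peak-Z significance within +/-100 ms, and lead/lag
## directionality.

CCG_BIN <- 0.010
CCG_RANGE <- 0.500
CCG_TEST_WINDOW <- 0.100
CCG_RATE_FLOOR <- 0.1

ccgEdges <- function(bin = CCG_BIN, range = CCG_RANGE) {
  # edges at integer multiples of the bin width: lag 0 is an edge, so no
  # bin straddles zero
  seq(-range, range, by = bin)
}

#' Group a spike train by epoch windows
#'
#' Spikes are assigned to the half-open window \[start, end) containing
#' them; spikes outside every window are dropped. The window starts are
#' kept alongside so the shift predictor can align trials.
#'
#' @param train a [SpikeTrain-class] (or numeric spike-time vector).
#' @param epochs an [EpochSet-class] with at least one window.
#' @return object of class `epoch_spikes`: list with `times` (list of
#'   per-window spike vectors), `start` (window starts) and `trial`.
#' @export
epochSpikes <- function(train, epochs) {
  w <- epochs@windows
  if (!nrow(w)) stop("epochSpikes needs a non-empty EpochSet")
  tt <- if (is(train, "SpikeTrain")) spikeTimes(train) else as.numeric(train)
  times <- lapply(seq_len(nrow(w)), function(i)
    tt[tt >= w[i, 1] & tt < w[i, 2]])
  structure(list(times = times, start = w[, 1], trial = epochs@trial,
                 width = epochs@width),
            class = "epoch_spikes")
}

asEpochSpikes <- function(x) {
  if (inherits(x, "epoch_spikes")) return(x)
  if (is.list(x))  # plain per-trial lists: treat times as window-relative
    return(structure(list(times = lapply(x, as.numeric),
                          start = rep(0, length(x)),
                          trial = seq_along(x), width = NA_real_),
                     class = "epoch_spikes"))
  stop("expected an epoch_spikes object or a list of per-trial spike vectors")
}

lagHistogram <- function(tgt, ref, edges) {
  # spike times live on a 0.1 ms grid and edges on a 10 ms grid, so a 1 ns
  # epsilon resolves float jitter at bin boundaries without moving any true
  # lag across an edge
  nb <- length(edges) - 1L
  if (!length(tgt) || !length(ref)) return(numeric(nb))
  lags <- as.vector(outer(tgt, ref, "-"))
  lags <- lags[lags >= edges[1] - 1e-9 & lags < edges[length(edges)] - 1e-9]
  idx <- floor((lags - edges[1] + 1e-9) / (edges[2] - edges[1])) + 1L
  idx[idx < 1L] <- 1L
  idx[idx > nb] <- nb
  tabulate(idx, nb)
}

#' Raw cross-correlogram
#'
#' For each reference (BA) spike, lags of same-trial target (dHPC) spikes
#' are histogrammed into `bin`-wide bins over +/-`range`; counts are summed
#' over trials. Bins are half-open \[lo, hi).
#'
#' @param refByTrial,tgtByTrial `epoch_spikes` objects from [epochSpikes()]
#'   or plain lists of per-trial spike-time vectors (aligned trials).
#' @param bin bin width (s), default 0.010.
#' @param range maximum |lag| (s), default 0.500.
#' @return numeric vector of counts with the bin edges as attribute
#'   `edges`.
#' @export
rawCcg <- function(refByTrial, tgtByTrial, bin = CCG_BIN, range = CCG_RANGE) {
  ref <- asEpochSpikes(refByTrial); tgt <- asEpochSpikes(tgtByTrial)
  if (length(ref$times) != length(tgt$times))
    stop("reference and target have different trial counts")
  edges <- ccgEdges(bin, range)
  counts <- numeric(length(edges) - 1L)
  for (i in seq_along(ref$times))
    counts <- counts + lagHistogram(tgt$times[[i]], ref$times[[i]], edges)
  structure(counts, edges = edges)
}

# per-trial-pair lag histograms, window-start-aligned: H[, i, j] is the
# histogram of (tgt trial j, shifted into ref trial i's window) vs ref trial i
crossTrialHistograms <- function(ref, tgt, edges) {
  n <- length(ref$times)
  nb <- length(edges) - 1L
  refRel <- lapply(seq_len(n), function(i) ref$times[[i]] - ref$start[i])
  tgtRel <- lapply(seq_len(n), function(j) tgt$times[[j]] - tgt$start[j])
  H <- array(0, c(nb, n, n))
  for (i in seq_len(n)) for (j in seq_len(n))
    H[, i, j] <- lagHistogram(tgtRel[[j]], refRel[[i]], edges)
  H
}

# uniform random permutation of 1..n with no fixed point
sampleDerangement <- function(n) {
  if (n < 2L) stop("derangement needs n >= 2")
  repeat {
    p <- sample.int(n)
    if (!any(p == seq_len(n))) return(p)
  }
}

#' Shift-predictor cross-correlogram
#'
#' The event-locked (stimulus-induced) component of a cross-correlogram,
#' estimated by trial shuffling: each shuffle pairs reference trial i with
#' target trial pi(i) for a uniform fixed-point-free permutation pi, lags
#' being computed after aligning the two windows' starts. The predictor is
#' the mean raw CCG over `nShuffles` shuffles; subtracting it from the raw
#' CCG removes correlation that is merely locked to the event.
#'
#' @inheritParams rawCcg
#' @param nShuffles number of trial shuffles (default 100).
#' @param seed RNG seed.
#' @return numeric vector of mean shuffled counts, edges as attribute.
#' @export
shiftPredictor <- function(refByTrial, tgtByTrial, nShuffles = 100,
                           seed = 1L, bin = CCG_BIN, range = CCG_RANGE) {
  ref <- asEpochSpikes(refByTrial); tgt <- asEpochSpikes(tgtByTrial)
  n <- length(ref$times)
  if (n != length(tgt$times)) stop("trial counts differ")
  if (n < 2L) stop("shift predictor needs at least 2 trials")
  edges <- ccgEdges(bin, range)
  H <- crossTrialHistograms(ref, tgt, edges)
  pred <- withSeed(seed, {
    acc <- numeric(dim(H)[1])
    for (s in seq_len(nShuffles)) {
      p <- sampleDerangement(n)
      for (i in seq_len(n)) acc <- acc + H[, i, p[i]]
    }
    acc / nShuffles
  })
  structure(pred, edges = edges)
}

epochRate <- function(train, epochs) {
  w <- epochs@windows
  if (!nrow(w)) return(NA_real_)
  tt <- if (is(train, "SpikeTrain")) spikeTimes(train) else as.numeric(train)
  nIn <- sum(vapply(seq_len(nrow(w)), function(i)
    sum(tt >= w[i, 1] & tt < w[i, 2]), numeric(1)))
  nIn / sum(w[, 2] - w[, 1])
}

#' Significance and directionality of a corrected cross-correlogram
#'
#' corrected = raw - predictor; per-bin Z uses the mean and SD of the
#' corrected correlogram over all +/-500 ms bins (set
#' `zNormalization = "outside_window"` to exclude the +/-100 ms test window
#' from the normalization). The peak is the maximum-Z bin (ties toward the
#' smallest |lag|). The pair is significant when peak Z > 3, the peak bin
#' lies within the +/-100 ms testing window, and both epoch firing rates
#' exceed 0.1 Hz. A significant peak in \[-100, 0) ms is a dHPC-leading
#' pair (direction "dHPC->BA"); in \[0, +100) ms a BA-leading pair
#' ("BA->dHPC").
#'
#' @param raw,predictor vectors from [rawCcg()] / [shiftPredictor()].
#' @param baRate,hpcRate epoch firing rates (Hz) of the two cells.
#' @param baCell,hpcCell,epochLabel identity stored on the result.
#' @param zThreshold peak-Z threshold (default 3).
#' @param zNormalization "all_bins" (default) or "outside_window".
#' @return a [CcgResult-class].
#' @export
ccgSignificance <- function(raw, predictor, baRate, hpcRate,
                            baCell = "BA", hpcCell = "dHPC",
                            epochLabel = "pre_surge", zThreshold = 3,
                            zNormalization = c("all_bins", "outside_window")) {
  zNormalization <- match.arg(zNormalization)
  edges <- attr(raw, "edges")
  if (is.null(edges)) edges <- ccgEdges()
  corrected <- as.numeric(raw) - as.numeric(predictor)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  normIdx <- if (zNormalization == "all_bins") seq_along(corrected)
             else which(abs(centers) > CCG_TEST_WINDOW)
  m <- mean(corrected[normIdx]); s <- stats::sd(corrected[normIdx])
  flag <- "ok"
  if (is.na(s) || s == 0) {
    z <- rep(0, length(corrected)); flag <- "degenerate"
  } else z <- (corrected - m) / s
  ord <- order(-z, abs(centers))
  peakIdx <- ord[1L]
  peakZ <- z[peakIdx]
  inWindow <- edges[peakIdx] >= -CCG_TEST_WINDOW - 1e-12 &&
              edges[peakIdx + 1L] <= CCG_TEST_WINDOW + 1e-12
  rateOk <- !is.na(baRate) && !is.na(hpcRate) &&
            baRate > CCG_RATE_FLOOR && hpcRate > CCG_RATE_FLOOR
  if (!rateOk && flag == "ok") flag <- "rate_fail"
  sig <- flag == "ok" && peakZ > zThreshold && inWindow
  dir <- if (!sig) "none"
         else if (edges[peakIdx + 1L] <= 0 + 1e-12) "dHPC->BA" else "BA->dHPC"
  new("CcgResult", baCell = baCell, hpcCell = hpcCell,
      epochLabel = epochLabel, binEdges = edges, raw = as.numeric(raw),
      predictor = as.numeric(predictor), corrected = corrected, z = z,
      peakZ = peakZ, peakLagMs = centers[peakIdx] * 1000,
      significant = sig, direction = dir,
      baRate = baRate, hpcRate = hpcRate, flag = flag)
}

# one pair in one epoch set: raw + predictor from shared trial histograms
ccgPair <- function(baTrain, hpcTrain, epochs, nShuffles = 100, seed = 1L,
                    bin = CCG_BIN, range = CCG_RANGE, zThreshold = 3,
                    zNormalization = "all_bins") {
  if (!nrow(epochs@windows))
    return(new("CcgResult", baCell = cellId(baTrain),
               hpcCell = cellId(hpcTrain), epochLabel = epochs@label,
               binEdges = ccgEdges(bin, range),
               raw = numeric(length(ccgEdges(bin, range)) - 1L),
               predictor = numeric(length(ccgEdges(bin, range)) - 1L),
               corrected = numeric(length(ccgEdges(bin, range)) - 1L),
               z = numeric(length(ccgEdges(bin, range)) - 1L),
               peakZ = NA_real_, peakLagMs = NA_real_, significant = FALSE,
               direction = "none", baRate = NA_real_, hpcRate = NA_real_,
               flag = "no_epochs"))
  ref <- epochSpikes(baTrain, epochs)
  tgt <- epochSpikes(hpcTrain, epochs)
  edges <- ccgEdges(bin, range)
  n <- length(ref$times)
  if (n >= 2L) {
    H <- crossTrialHistograms(ref, tgt, edges)
    raw <- numeric(length(edges) - 1L)
    for (i in seq_len(n)) raw <- raw + H[, i, i]
    pred <- withSeed(seed, {
      acc <- numeric(length(edges) - 1L)
      for (s in seq_len(nShuffles)) {
        p <- sampleDerangement(n)
        for (i in seq_len(n)) acc <- acc + H[, i, p[i]]
      }
      acc / nShuffles
    })
  } else {
    raw <- rawCcg(ref, tgt, bin, range)
    pred <- rep(NA_real_, length(edges) - 1L)
  }
  res <- ccgSignificance(structure(raw, edges = edges), pred,
                         epochRate(baTrain, epochs),
                         epochRate(hpcTrain, epochs),
                         baCell = cellId(baTrain), hpcCell = cellId(hpcTrain),
                         epochLabel = epochs@label, zThreshold = zThreshold,
                         zNormalization = zNormalization)
  if (n < 2L) { res@significant <- FALSE; res@flag <- "no_epochs" }
  res
}

#' Screen all BA x dHPC pairs across epoch labels
#'
#' Evaluates the shift-predictor-corrected cross-correlogram of every BA
#' reference / dHPC target pair in every requested epoch set and returns a
#' long table of results, one row per (ba_cell, hpc_cell, epoch).
#'
#' @param baTrains,hpcTrains lists of [SpikeTrain-class] objects.
#' @param epochSets list of [EpochSet-class] objects (one per label).
#' @param nShuffles shuffles for the predictor.
#' @param seed base RNG seed; each pair/epoch gets a derived stream.
#' @param zNormalization passed to [ccgSignificance()].
#' @param keepCcgs also return the full [CcgResult-class] objects.
#' @return data.frame with columns ba_cell, hpc_cell, epoch, peak_z,
#'   peak_lag_ms, significant, direction, ba_rate, hpc_rate, flag (and
#'   attribute `ccgs` when `keepCcgs`).
#' @export
pairScreen <- function(baTrains, hpcTrains, epochSets, nShuffles = 100,
                       seed = 1L, zNormalization = "all_bins",
                       keepCcgs = FALSE) {
  rows <- list(); ccgs <- list(); k <- 0L
  for (ep in epochSets) for (ba in baTrains) for (hpc in hpcTrains) {
    k <- k + 1L
    res <- ccgPair(ba, hpc, ep, nShuffles = nShuffles,
                   seed = childSeed(seed, paste0("ccg_", cellId(ba), "_",
                                                 cellId(hpc), "_", ep@label)),
                   zNormalization = zNormalization)
    rows[[k]] <- data.frame(
      ba_cell = res@baCell, hpc_cell = res@hpcCell, epoch = res@epochLabel,
      peak_z = res@peakZ, peak_lag_ms = res@peakLagMs,
      significant = res@significant, direction = res@direction,
      ba_rate = res@baRate, hpc_rate = res@hpcRate, flag = res@flag,
      stringsAsFactors = FALSE)
    if (keepCcgs) ccgs[[k]] <- res
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (keepCcgs) attr(out, "ccgs") <- ccgs
  out
}

#' Epoch sets of a session, surge-filtered
#'
#' Convenience wrapper: applies [filterSurgeEvents()] and builds the epoch
#' sets for the given labels.
#'
#' @param session a [Session-class].
#' @param labels epoch labels (default the labels whose events the session
#'   contains).
#' @param refractory surge exclusion gap (s).
#' @return named list of [EpochSet-class] objects.
#' @export
sessionEpochs <- function(session, labels = NULL, refractory = 10) {
  filt <- filterSurgeEvents(session@events, refractory)
  if (is.null(labels)) {
    kinds <- unique(filt@events$kind)
    labels <- c(if (any(kinds %in% c("robot_surge", "stim_on")))
                  c("pre_surge", "post_surge"),
                if ("pellet_procured" %in% kinds)
                  c("pre_pellet", "post_pellet"))
  }
  eps <- lapply(labels, function(lb) makeEpochs(filt, lb))
  names(eps) <- labels
  eps
}
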