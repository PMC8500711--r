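## Place-field rate maps, inclusion criteria, nest/proximal/distal classes,
## and the two map-stability metrics: pixel-by-pixel spatial correlation
## (Fisher Z') and peak distance along the corridor axis.

defaultGrid <- function(pixelSize, xRange, yRange) {
  list(x = seq(xRange[1], xRange[2] + pixelSize - 1e-9, by = pixelSize),
       y = seq(yRange[1], yRange[2] + pixelSize - 1e-9, by = pixelSize))
}

binIndex <- function(v, breaks) {
  idx <- findInterval(v, breaks, rightmost.closed = TRUE)
  idx[v < breaks[1] | v > breaks[length(breaks)]] <- NA_integer_
  idx[idx == length(breaks)] <- length(breaks) - 1L  # right edge inclusive
  idx
}

#' Occupancy map on a pixel grid
#'
#' Frame-duration-weighted time per pixel, restricted to frames with
#' x <= xLimit (the foraging limit); nest pixels (x < 0) are included.
#'
#' @param tracking a [Tracking-class].
#' @param pixelSize pixel edge (cm), default 4.
#' @param xLimit truncation of the corridor axis (cm).
#' @param xRange,yRange grid extents (cm); defaults cover the nest and the
#'   corridor up to `xLimit` and +/-10 cm laterally.
#' @return list with `occupancy` matrix (x by y, seconds), `xBreaks`,
#'   `yBreaks`.
#' @export
computeOccupancy <- function(tracking, pixelSize = 4, xLimit = 125,
                             xRange = c(-48, xLimit), yRange = c(-10, 10)) {
  stopifnot(pixelSize > 0)
  g <- defaultGrid(pixelSize, xRange, yRange)
  dt <- 1 / tracking@frameRate
  use <- tracking@x <= xLimit
  if (!any(use)) stop("no tracking frames within the foraging limit")
  ix <- binIndex(tracking@x[use], g$x)
  iy <- binIndex(tracking@y[use], g$y)
  occ <- matrix(0, length(g$x) - 1L, length(g$y) - 1L)
  ok <- !is.na(ix) & !is.na(iy)
  tab <- table(factor(ix[ok], levels = seq_len(nrow(occ))),
               factor(iy[ok], levels = seq_len(ncol(occ))))
  occ[] <- as.numeric(tab) * dt
  list(occupancy = occ, xBreaks = g$x, yBreaks = g$y)
}

gaussKernel1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- ceiling(3 * sigma)
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k / sum(k)
}

smooth2d <- function(m, sigma) {
  if (sigma <= 0) return(m)
  k <- gaussKernel1d(sigma)
  r <- (length(k) - 1L) / 2L
  pad <- function(v, n) c(rep(0, n), v, rep(0, n))
  # separable convolution with zero padding
  out <- apply(m, 2, function(col) {
    p <- pad(col, r)
    vapply(seq_along(col), function(i) sum(p[i:(i + 2 * r)] * rev(k)),
           numeric(1))
  })
  out <- t(apply(out, 1, function(row) {
    p <- pad(row, r)
    vapply(seq_along(row), function(i) sum(p[i:(i + 2 * r)] * rev(k)),
           numeric(1))
  }))
  out
}

#' Firing-rate map of one unit
#'
#' Spike positions are interpolated from tracking at the spike times, binned
#' on the occupancy grid, and both the count and occupancy maps are smoothed
#' with the same Gaussian kernel before taking their ratio; rates are
#' defined on visited pixels only. The peak is the maximum-rate visited
#' pixel; ties break toward smaller x. The unsmoothed ratio is kept for
#' spatial information.
#'
#' @param train a [SpikeTrain-class].
#' @param tracking a [Tracking-class].
#' @param pixelSize pixel edge (cm), default 4.
#' @param smoothingSigma Gaussian sigma in pixels (default 1; 0 = off).
#' @param xLimit foraging limit (cm).
#' @param xRange,yRange grid extents, as in [computeOccupancy()].
#' @param minOccupancy minimum dwell (s) for a pixel to count as visited
#'   (default 0.2, i.e. six 30 Hz frames); rates on barely-sampled pixels
#'   are dominated by estimation noise and would bias the Skaggs
#'   information upward.
#' @return a [RateMap-class].
#' @export
computeRateMap <- function(train, tracking, pixelSize = 4,
                           smoothingSigma = 1, xLimit = 125,
                           xRange = c(-48, xLimit), yRange = c(-10, 10),
                           minOccupancy = 0.2) {
  occ <- computeOccupancy(tracking, pixelSize, xLimit, xRange, yRange)
  tt <- spikeTimes(train)
  cnt <- matrix(0, nrow(occ$occupancy), ncol(occ$occupancy))
  if (length(tt)) {
    sx <- stats::approx(tracking@t, tracking@x, tt, rule = 2)$y
    sy <- stats::approx(tracking@t, tracking@y, tt, rule = 2)$y
    use <- sx <= xLimit
    ix <- binIndex(sx[use], occ$xBreaks)
    iy <- binIndex(sy[use], occ$yBreaks)
    ok <- !is.na(ix) & !is.na(iy)
    tab <- table(factor(ix[ok], levels = seq_len(nrow(cnt))),
                 factor(iy[ok], levels = seq_len(ncol(cnt))))
    cnt[] <- as.numeric(tab)
  }
  visited <- occ$occupancy >= pmax(minOccupancy, .Machine$double.eps)
  rateRaw <- matrix(NA_real_, nrow(cnt), ncol(cnt))
  rateRaw[visited] <- cnt[visited] / occ$occupancy[visited]
  sCnt <- smooth2d(cnt, smoothingSigma)
  sOcc <- smooth2d(occ$occupancy, smoothingSigma)
  rate <- matrix(NA_real_, nrow(cnt), ncol(cnt))
  rate[visited] <- sCnt[visited] / sOcc[visited]
  xCenters <- occ$xBreaks[-length(occ$xBreaks)] + pixelSize / 2
  if (any(visited) && any(rate[visited] > 0)) {
    pk <- max(rate[visited])
    cand <- which(rate == pk & visited, arr.ind = TRUE)
    best <- cand[order(cand[, 1], cand[, 2])[1L], , drop = FALSE]
    peakX <- xCenters[best[1, 1]]
  } else { pk <- 0; peakX <- NA_real_ }
  new("RateMap", xBreaks = occ$xBreaks, yBreaks = occ$yBreaks,
      occupancy = occ$occupancy, spikeCount = cnt, rate = rate,
      rateRaw = rateRaw, visited = visited, peakRate = pk, peakX = peakX,
      pixelSize = pixelSize)
}

#' Skaggs spatial information of a rate map
#'
#' `I = sum_i p_i lambda_i log2(lambda_i / lambda_bar)` in bits/s, where
#' `p_i` is the occupancy fraction of pixel i, `lambda_i` its unsmoothed
#' firing rate and `lambda_bar = sum p_i lambda_i` the occupancy-weighted
#' mean rate. Zero-rate pixels contribute 0; an all-silent map returns 0.
#'
#' @param map a [RateMap-class].
#' @return spatial information in bits/s.
#' @export
spatialInformation <- function(map) {
  v <- map@visited
  if (!any(v) || sum(map@occupancy[v]) <= 0)
    stop("spatialInformation needs positive total occupancy")
  p <- map@occupancy[v] / sum(map@occupancy[v])
  lam <- map@rateRaw[v]
  lbar <- sum(p * lam)
  if (lbar <= 0) return(0)
  pos <- lam > 0
  sum(p[pos] * lam[pos] * log2(lam[pos] / lbar))
}

#' Place-cell inclusion criteria
#'
#' A unit qualifies when (i) its minimum inter-spike interval across the
#' supplied sessions is at least 1 ms (refractory criterion), (ii) its
#' smoothed peak firing rate exceeds 2 Hz in any session, and (iii) its
#' spatial information exceeds 1.0 bits/s in any session. (Waveform
#' stability, assessed at spike sorting, is assumed.)
#'
#' @param trains list of the cell's [SpikeTrain-class] per session.
#' @param maps list of the cell's [RateMap-class] per session.
#' @return list with `included` (logical) and per-criterion `flags`.
#' @export
qualifiesAsPlaceCell <- function(trains, maps) {
  minIsi <- suppressWarnings(min(vapply(trains, function(tr) {
    tt <- spikeTimes(tr)
    if (length(tt) > 1L) min(diff(tt)) else Inf
  }, numeric(1))))
  refractoryOk <- minIsi >= 0.001 - 1e-12
  peakOk <- any(vapply(maps, peakRate, numeric(1)) > 2)
  infoOk <- any(vapply(maps, spatialInformation, numeric(1)) > 1.0)
  list(included = refractoryOk && peakOk && infoOk,
       flags = c(refractory = refractoryOk, peak_rate = peakOk,
                 spatial_info = infoOk))
}

#' Classify a place cell by its pre-threat peak location
#'
#' Nest cells peak inside the nest (x < 0), proximal cells in the foraging
#' area between 0 and 25 cm (closed interval), distal cells beyond 25 cm.
#'
#' @param peakX pre-threat (or pre-stimulation) peak location (cm).
#' @return "nest", "proximal" or "distal".
#' @export
classifyPlaceCell <- function(peakX) {
  if (is.na(peakX)) return(NA_character_)
  if (peakX < 0) "nest" else if (peakX <= 25) "proximal" else "distal"
}

Z_CLIP <- 1 - 1e-7

#' Pixel-by-pixel spatial correlation of two rate maps
#'
#' Pearson correlation over pixels visited in both maps, converted to a
#' Fisher Z' score (atanh of r clipped to +/- (1 - 1e-7)). Smoothed rates
#' are correlated by default.
#'
#' @param mapA,mapB [RateMap-class] objects on the same grid.
#' @param smoothed correlate smoothed (default) or raw rates.
#' @param minPixels minimum number of common visited pixels (default 10).
#' @return list with `r`, `zPrime` and `nPixels`; `r` is NA (with a
#'   warning) when fewer than `minPixels` pixels are common.
#' @export
spatialCorrelation <- function(mapA, mapB, smoothed = TRUE, minPixels = 10) {
  if (!identical(mapA@xBreaks, mapB@xBreaks) ||
      !identical(mapA@yBreaks, mapB@yBreaks))
    stop("maps are on different grids")
  common <- mapA@visited & mapB@visited
  n <- sum(common)
  if (n < minPixels) {
    warning(sprintf("only %d common visited pixels (< %d); correlation undefined",
                    n, minPixels))
    return(list(r = NA_real_, zPrime = NA_real_, nPixels = n))
  }
  a <- rateMatrix(mapA, smoothed)[common]
  b <- rateMatrix(mapB, smoothed)[common]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    return(list(r = NA_real_, zPrime = NA_real_, nPixels = n))
  r <- stats::cor(a, b)
  list(r = r, zPrime = atanh(max(-Z_CLIP, min(Z_CLIP, r))), nPixels = n)
}

#' Distance between the firing peaks of two maps
#'
#' Absolute difference of the peak x locations (cm) - the corridor-axis
#' remapping metric.
#'
#' @param mapA,mapB [RateMap-class] objects.
#' @return distance in cm, or NA when either peak is undefined.
#' @export
peakDistance <- function(mapA, mapB) {
  if (is.na(mapA@peakX) || is.na(mapB@peakX)) return(NA_real_)
  abs(mapA@peakX - mapB@peakX)
}

#' Per-cell place-field results for a cohort
#'
#' Runs the full place-field pipeline over the three sessions of a cohort:
#' the threat-session foraging limit truncates all maps; inclusion criteria
#' are applied across sessions; classes come from the pre-threat peak; and
#' stability (r, Fisher Z', peak distance) is computed for the pre-vs-threat,
#' threat-vs-post and pre-vs-post session pairs. Cells whose pre-threat peak
#' (computed without truncation) lies beyond the foraging limit are flagged
#' and excluded from stability analysis.
#'
#' @param cohort list with a `sessions` element as returned by
#'   [makeCohort()] (or assembled from [readSession()] outputs named
#'   pre_threat/threat/post_threat).
#' @param pixelSize,smoothingSigma map parameters (see [computeRateMap()]).
#' @param smoothedCorrelation correlate smoothed maps (default TRUE).
#' @return list with `records` (data.frame, one row per dHPC unit) and
#'   `maps` (per-cell per-session [RateMap-class] list).
#' @export
placeCellRecords <- function(cohort, pixelSize = 4, smoothingSigma = 1,
                             smoothedCorrelation = TRUE) {
  ss <- cohort$sessions
  stopifnot(all(PHASES %in% names(ss)))
  limit <- foragingLimit(ss$threat)
  hpcIds <- names(ss$pre_threat@trains)[vapply(ss$pre_threat@trains, region,
                                               character(1)) == "dHPC"]
  xRange <- c(-48, max(limit, 0))
  rows <- list(); maps <- list()
  for (id in hpcIds) {
    trainsBy <- lapply(ss, function(s) s@trains[[id]])
    mapsBy <- lapply(PHASES, function(ph)
      computeRateMap(trainsBy[[ph]], ss[[ph]]@tracking, pixelSize,
                     smoothingSigma, xLimit = limit, xRange = xRange))
    names(mapsBy) <- PHASES
    qual <- qualifiesAsPlaceCell(trainsBy[PHASES], mapsBy)
    # pre-threat peak without truncation, for the beyond-limit exclusion
    fullPre <- computeRateMap(trainsBy$pre_threat, ss$pre_threat@tracking,
                              pixelSize, smoothingSigma, xLimit = 125,
                              xRange = c(-48, 125))
    beyond <- !is.na(fullPre@peakX) && fullPre@peakX > limit
    peakPre <- mapsBy$pre_threat@peakX
    cls <- if (qual$included && !beyond) classifyPlaceCell(peakPre)
           else NA_character_
    stab <- list(pre_vs_threat = c("pre_threat", "threat"),
                 threat_vs_post = c("threat", "post_threat"),
                 pre_vs_post = c("pre_threat", "post_threat"))
    st <- lapply(stab, function(pair) {
      sc <- spatialCorrelation(mapsBy[[pair[1]]], mapsBy[[pair[2]]],
                               smoothed = smoothedCorrelation)
      c(r = sc$r, z_prime = sc$zPrime,
        peak_distance = peakDistance(mapsBy[[pair[1]]], mapsBy[[pair[2]]]))
    })
    rows[[id]] <- data.frame(
      cell_id = id, included = qual$included && !beyond,
      flag_refractory = qual$flags[["refractory"]],
      flag_peak_rate = qual$flags[["peak_rate"]],
      flag_spatial_info = qual$flags[["spatial_info"]],
      flag_beyond_limit = beyond,
      class = cls, peak_x_pre = peakPre,
      peak_rate_pre = mapsBy$pre_threat@peakRate,
      peak_rate_threat = mapsBy$threat@peakRate,
      peak_rate_post = mapsBy$post_threat@peakRate,
      info_pre = spatialInformation(mapsBy$pre_threat),
      info_threat = spatialInformation(mapsBy$threat),
      info_post = spatialInformation(mapsBy$post_threat),
      r_pre_threat = st$pre_vs_threat[["r"]],
      z_pre_threat = st$pre_vs_threat[["z_prime"]],
      pd_pre_threat = st$pre_vs_threat[["peak_distance"]],
      r_threat_post = st$threat_vs_post[["r"]],
      z_threat_post = st$threat_vs_post[["z_prime"]],
      pd_threat_post = st$threat_vs_post[["peak_distance"]],
      r_pre_post = st$pre_vs_post[["r"]],
      z_pre_post = st$pre_vs_post[["z_prime"]],
      pd_pre_post = st$pre_vs_post[["peak_distance"]],
      stringsAsFactors = FALSE)
    maps[[id]] <- mapsBy
  }
  records <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  list(records = records, maps = maps, foragingLimit = limit)
}
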