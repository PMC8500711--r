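# Small deterministic fixtures used across test files.

# Poisson spike train rounded to the 0.1 ms storage resolution
poissonTrain <- function(id, rate, duration, seed, region = "BA") {
  set.seed(seed)
  n <- rpois(1, rate * duration)
  tt <- unique(sort(round(runif(n, 0, duration), 4)))
  spikeTrain(id, region, tt)
}

# a tiny 3-trial pre_threat-like session with two cells
tinySession <- function(seed = 1L) {
  cfg <- simConfig(
    nTrials = 3L, nestDwell = 4,
    placeCells = data.frame(cell_id = "hpc_a", center_x = 60, sigma = 10,
                            peak_rate = 10, baseline_rate = 0.5,
                            threat_shift = 0, theta_mod = 0),
    baCells = data.frame(cell_id = "ba_a", baseline_rate = 4,
                         event_kind = "pellet", gain = 3, latency = 0.1,
                         decay = 1, spike_width = 0.4),
    seed = seed)
  traj <- simulateTrajectory(cfg, "pre_threat")
  dur <- max(traj$tracking@t) + 1
  trains <- list(
    simulatePlaceTrain(cfg@placeCells[1, ], traj$tracking, "pre_threat",
                       seed = 11L, sessionId = "tiny"),
    simulateBaTrain(cfg@baCells[1, ], traj$events, dur, seed = 12L,
                    sessionId = "tiny"))
  session("tiny", "pre_threat", traj$tracking, traj$events, trains,
          duration = dur)
}

# event log of n regularly spaced surges
surgeLog <- function(n = 10, spacing = 30, first = 20) {
  eventLog(seq_len(n), rep("robot_surge", n),
           seq(first, by = spacing, length.out = n))
}

expect_sessions_equal <- function(a, b) {
  expect_identical(sessionId(a), sessionId(b))
  expect_identical(sessionPhase(a), sessionPhase(b))
  expect_equal(sessionDuration(a), sessionDuration(b))
  expect_equal(tracking(a)@t, tracking(b)@t)
  expect_equal(tracking(a)@x, tracking(b)@x)
  expect_equal(tracking(a)@y, tracking(b)@y)
  expect_equal(events(a), events(b))
  expect_identical(sort(names(trains(a))), sort(names(trains(b))))
  for (nm in names(trains(a))) {
    expect_equal(spikeTimes(trains(a)[[nm]]), spikeTimes(trains(b)[[nm]]))
    expect_identical(region(trains(a)[[nm]]), region(trains(b)[[nm]]))
  }
}

# RateMap built directly from occupancy seconds and raw rates (1-D row of
# pixels); used for closed-form spatial-information and correlation checks
handMap <- function(occ, rates, pixelSize = 4) {
  occ <- matrix(occ, nrow = length(occ))
  rates <- matrix(rates, nrow = length(rates))
  visited <- occ > 0
  xBreaks <- seq(0, by = pixelSize, length.out = nrow(occ) + 1L)
  cnt <- rates * occ
  pk <- if (any(visited)) max(rates[visited]) else 0
  pkx <- if (any(visited) && pk > 0)
    xBreaks[which(rates == pk & visited)[1L]] + pixelSize / 2 else NA_real_
  new("RateMap", xBreaks = xBreaks, yBreaks = c(0, pixelSize),
      occupancy = occ, spikeCount = cnt, rate = rates, rateRaw = rates,
      visited = visited, peakRate = pk, peakX = pkx, pixelSize = pixelSize)
}
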