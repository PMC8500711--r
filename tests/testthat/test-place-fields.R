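test_that("occupancy conserves time and spreads evenly under constant speed", {
  # animal sitting in one pixel
  t <- seq(0, 10 - 1 / 30, by = 1 / 30)
  still <- trackingData(t, rep(10, length(t)), rep(0, length(t)))
  occ <- computeOccupancy(still, pixelSize = 4, xLimit = 125,
                          xRange = c(0, 124), yRange = c(-2, 2))
  expect_equal(sum(occ$occupancy), 10, tolerance = 1e-9)
  expect_equal(max(occ$occupancy), 10, tolerance = 1e-9)
  # uniform sweep: occupancy uniform over interior traversed pixels
  ts <- seq(0, 5, by = 1 / 30)
  sweep <- trackingData(ts, 20 * ts, rep(0, length(ts)))
  os <- computeOccupancy(sweep, pixelSize = 4, xLimit = 125,
                         xRange = c(0, 100), yRange = c(-2, 2))
  col <- rowSums(os$occupancy)
  interior <- col[3:23]
  expect_true(max(abs(interior - mean(interior))) / mean(interior) < 0.2)
  expect_equal(sum(os$occupancy), 5 + 1 / 30, tolerance = 1e-9)
  expect_error(computeOccupancy(still, xLimit = 5, xRange = c(0, 124)),
               "no tracking")
})

test_that("rate maps are count/occupancy with the peak on visited pixels", {
  t <- seq(0, 10 - 1 / 30, by = 1 / 30)
  still <- trackingData(t, rep(10, length(t)), rep(0, length(t)))
  tr <- spikeTrain("c", "dHPC", seq(0.25, 9.75, length.out = 20))
  m <- computeRateMap(tr, still, pixelSize = 4, smoothingSigma = 0,
                      xLimit = 125, xRange = c(0, 124), yRange = c(-2, 2))
  expect_equal(peakRate(m), 2, tolerance = 1e-9)  # 20 spikes / 10 s
  expect_equal(peakX(m), 10)
  # conservation on the unsmoothed map
  expect_equal(sum(m@spikeCount) / sum(m@occupancy),
               20 / 10, tolerance = 1e-9)
  # empty train: all-zero map
  m0 <- computeRateMap(spikeTrain("z", "dHPC", numeric(0)), still,
                       xLimit = 125, xRange = c(0, 124), yRange = c(-2, 2))
  expect_equal(peakRate(m0), 0)
  expect_true(is.na(peakX(m0)))
})

test_that("simulated field centers are recovered by the rate-map peak", {
  cfg <- simConfig(seed = 31L)
  traj <- simulateTrajectory(cfg, "pre_threat")
  p <- list(cell_id = "c", center_x = 80, sigma = 10, peak_rate = 15,
            baseline_rate = 0.5, threat_shift = 0, theta_mod = 0)
  tr <- simulatePlaceTrain(p, traj$tracking, "pre_threat", seed = 41L)
  m <- computeRateMap(tr, traj$tracking, xLimit = 125)
  expect_lte(abs(peakX(m) - 80), 4)  # within one pixel
  # a threat shift moves the recovered peak by the shifted amount
  p$threat_shift <- 30
  trShift <- simulatePlaceTrain(p, traj$tracking, "threat", seed = 42L)
  mShift <- computeRateMap(trShift, traj$tracking, xLimit = 125)
  expect_lte(abs(peakX(mShift) - 110), 4)
  # each peak is quantized to the 4 cm grid, so the distance can be off by
  # up to one pixel per map
  expect_lte(abs(peakDistance(m, mShift) - 30), 8)
})

test_that("Skaggs information matches closed forms and is non-negative", {
  expect_equal(spatialInformation(handMap(c(2, 2, 2), c(3, 3, 3))), 0)
  expect_equal(spatialInformation(handMap(c(1, 1), c(0, 2))), 1.0)
  expect_equal(spatialInformation(handMap(rep(1, 4), c(0, 0, 0, 4))), 2.0)
  # non-negativity on random maps
  set.seed(10)
  for (i in 1:20) {
    occ <- runif(12, 0.1, 5)
    rates <- rexp(12, 1 / 3)
    expect_gte(spatialInformation(handMap(occ, rates)), 0)
  }
  expect_error(spatialInformation(handMap(c(0, 0), c(1, 1))), "occupancy")
})

test_that("inclusion criteria flag refractory, peak-rate and info failures", {
  t <- seq(0, 10 - 1 / 30, by = 1 / 30)
  still <- trackingData(t, rep(10, length(t)), rep(0, length(t)))
  grid <- list(pixelSize = 4, xLimit = 125, xRange = c(0, 124),
               yRange = c(-2, 2))
  mk <- function(tr) do.call(computeRateMap,
                             c(list(tr, still, smoothingSigma = 0), grid))
  good <- spikeTrain("g", "dHPC", seq(0.25, 9.75, length.out = 50))
  # an informative high-rate map from a second "session" visiting 2 pixels
  t2 <- seq(0, 10 - 1 / 30, by = 1 / 30)
  half <- trackingData(t2, c(rep(10, 150), rep(50, 150)), rep(0, 300))
  burst <- spikeTrain("g", "dHPC", seq(0.2, 4.8, length.out = 40))
  mapBurst <- do.call(computeRateMap,
                      c(list(burst, half, smoothingSigma = 0), grid))
  q <- qualifiesAsPlaceCell(list(good, burst), list(mk(good), mapBurst))
  expect_true(q$included)
  # sub-ms ISI violates the refractory criterion
  bad <- spikeTrain("b", "dHPC", c(1, 1.0004, seq(2, 9, by = 0.2)))
  qb <- qualifiesAsPlaceCell(list(bad), list(mk(bad)))
  expect_false(qb$included)
  expect_false(qb$flags[["refractory"]])
  # peak below 2 Hz excluded
  weak <- spikeTrain("w", "dHPC", seq(0.5, 9.5, length.out = 15))
  qw <- qualifiesAsPlaceCell(list(weak), list(mk(weak)))
  expect_false(qw$flags[["peak_rate"]])
})

test_that("peak position maps to nest/proximal/distal classes", {
  expect_identical(classifyPlaceCell(-10), "nest")
  expect_identical(classifyPlaceCell(12), "proximal")
  expect_identical(classifyPlaceCell(0), "proximal")
  expect_identical(classifyPlaceCell(25), "proximal")
  expect_identical(classifyPlaceCell(80), "distal")
  expect_true(is.na(classifyPlaceCell(NA_real_)))
})

test_that("spatial correlation and Fisher Z' behave as on paper", {
  m <- handMap(rep(1, 12), c(1, 5, 2, 8, 3, 1, 0.5, 2, 4, 6, 1, 3))
  sc <- spatialCorrelation(m, m)
  expect_equal(sc$r, 1)
  expect_equal(sc$zPrime, atanh(1 - 1e-7))
  expect_equal(peakDistance(m, m), 0)
  # hand Pearson on three pixels (minimum-pixel check relaxed)
  a <- handMap(rep(1, 3), c(1, 2, 3))
  b <- handMap(rep(1, 3), c(3, 2, 1))
  scab <- spatialCorrelation(a, b, minPixels = 3)
  expect_equal(scab$r, -1)
  expect_equal(atanh(0.5), 0.5493, tolerance = 1e-4)
  # z' strictly increasing in r
  rs <- seq(-0.95, 0.95, by = 0.05)
  expect_true(all(diff(atanh(rs)) > 0))
  # too few common pixels: undefined with a warning
  expect_warning(und <- spatialCorrelation(a, b), "common visited")
  expect_true(is.na(und$r))
  expect_error(spatialCorrelation(m, a), "different grids")
})

test_that("cells peaking beyond the foraging limit are excluded", {
  cfg <- defaultSimConfig(seed = 17L, nDistalShift = 0L, nDistalStable = 1L,
                          nNest = 1L, nProximal = 1L)
  cfg@placeCells <- rbind(cfg@placeCells,
                          data.frame(cell_id = "hpc_beyond", center_x = 112,
                                     sigma = 6, peak_rate = 14,
                                     baseline_rate = 0.5, threat_shift = 0,
                                     theta_mod = 0))
  coh <- makeCohort(cfg)
  pr <- placeCellRecords(coh)
  rec <- pr$records
  expect_true(rec$flag_beyond_limit[rec$cell_id == "hpc_beyond"])
  expect_false(rec$included[rec$cell_id == "hpc_beyond"])
  expect_false(any(rec$flag_beyond_limit[rec$cell_id != "hpc_beyond"]))
})
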