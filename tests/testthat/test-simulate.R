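test_that("trajectories respect the trial script in each phase", {
  cfg <- defaultSimConfig(seed = 9L, nDistalShift = 1L, nDistalStable = 1L,
                          nNest = 1L, nProximal = 1L)
  pre <- simulateTrajectory(cfg, "pre_threat")
  ev <- events(pre$events)
  expect_equal(sum(ev$kind == "gate_open"), 10L)
  expect_equal(sum(ev$kind == "pellet_procured"), 10L)
  expect_equal(sum(ev$kind == "robot_surge"), 0L)
  thr <- simulateTrajectory(cfg, "threat")
  evT <- events(thr$events)
  expect_equal(sum(evT$kind == "pellet_procured"), 0L)  # default: all fail
  expect_equal(sum(evT$kind == "robot_surge"), 10L)
  # surge fired at x ~ pellet - trigger offset (within one frame of travel)
  surgeX <- approx(thr$tracking@t, thr$tracking@x,
                   evT$time[evT$kind == "robot_surge"], rule = 2)$y
  expect_true(all(abs(surgeX - 100) < 2))
  # determinism: same seed twice gives identical output
  pre2 <- simulateTrajectory(cfg, "pre_threat")
  expect_identical(pre$tracking@x, pre2$tracking@x)
  expect_identical(events(pre$events), events(pre2$events))
  expect_error(simulateTrajectory(simConfig(outboundSpeed = -1), "threat"),
               "positive")
})

test_that("place-train thinning matches the intended intensity", {
  cfg <- simConfig(seed = 5L)
  traj <- simulateTrajectory(cfg, "pre_threat", seed = 55L)
  p <- list(cell_id = "c", center_x = 60, sigma = 10, peak_rate = 15,
            baseline_rate = 1, threat_shift = 0, theta_mod = 0)
  tr <- simulatePlaceTrain(p, traj$tracking, "pre_threat", seed = 7L)
  # empirical count within 3 SE of the time-averaged intensity
  x <- traj$tracking@x
  lam <- p$baseline_rate + (p$peak_rate - p$baseline_rate) *
    exp(-(x - p$center_x)^2 / (2 * p$sigma^2))
  expected <- mean(lam) * max(traj$tracking@t)
  expect_lt(abs(nSpikes(tr) - expected), 3 * sqrt(expected))
  # uniform intensity (peak = baseline) carries no spatial information; the
  # plug-in Skaggs estimator has a positive sampling bias of roughly
  # n_pixels/(2 ln2 T) bits/s, so the near-zero limit needs enough dwell
  # time (60 trials here) to be visible
  pu <- list(cell_id = "u", center_x = 60, sigma = 10, peak_rate = 8,
             baseline_rate = 8, threat_shift = 0, theta_mod = 0)
  trajLong <- simulateTrajectory(simConfig(nTrials = 60L, seed = 5L),
                                 "pre_threat", seed = 56L)
  tru <- simulatePlaceTrain(pu, trajLong$tracking, "pre_threat", seed = 8L)
  m <- computeRateMap(tru, trajLong$tracking, xLimit = 125)
  expect_lt(spatialInformation(m), 0.1)
  # and at 10 trials it is still far below a place-tuned cell's information
  tru10 <- simulatePlaceTrain(pu, traj$tracking, "pre_threat", seed = 8L)
  m10 <- computeRateMap(tru10, traj$tracking, xLimit = 125)
  tuned <- simulatePlaceTrain(p, traj$tracking, "pre_threat", seed = 9L)
  mTuned <- computeRateMap(tuned, traj$tracking, xLimit = 125)
  expect_lt(spatialInformation(m10), spatialInformation(mTuned) / 3)
  # determinism
  tr2 <- simulatePlaceTrain(p, traj$tracking, "pre_threat", seed = 7L)
  expect_identical(spikeTimes(tr), spikeTimes(tr2))
  # refractory period respected
  expect_true(all(diff(spikeTimes(tr)) >= 0.002 - 1e-12))
})

test_that("BA trains carry the event-locked modulation they were given", {
  ev <- surgeLog(40, spacing = 30)
  dur <- 40 * 30 + 20
  exc <- list(cell_id = "e", baseline_rate = 3, event_kind = "robot",
              gain = 5, latency = 0.1, decay = 1.5, spike_width = 0.4)
  tr <- simulateBaTrain(exc, ev, dur, seed = 3L)
  tt <- spikeTimes(tr)
  evT <- events(ev)$time
  inResp <- sum(vapply(evT, function(e) sum(tt >= e & tt < e + 1.5),
                       numeric(1)))
  inBase <- sum(vapply(evT, function(e) sum(tt >= e - 3 & tt < e - 1.5),
                       numeric(1)))
  expect_gt(inResp, 2 * inBase)  # strong excitation after events
  # homogeneous when event_kind is none
  non <- list(cell_id = "n", baseline_rate = 3, event_kind = "none",
              gain = 1, latency = 0.1, decay = 1.5, spike_width = 0.4)
  trn <- simulateBaTrain(non, ev, dur, seed = 4L)
  expect_lt(abs(nSpikes(trn) - 3 * dur), 3 * sqrt(3 * dur))
})

test_that("injectSynchrony adds coincidences only where asked", {
  ev <- surgeLog(10)
  ep <- makeEpochs(filterSurgeEvents(ev), "pre_surge")
  ba <- poissonTrain("ba", 5, 320, seed = 21L)
  hpc <- poissonTrain("hpc", 5, 320, seed = 22L, region = "dHPC")
  out <- injectSynchrony(ba, hpc, ep, lagMs = 30, excess = 0.3, seed = 9L)
  refIn <- riskforage::epochSpikes(ba, ep)
  nRef <- sum(lengths(refIn$times))
  added <- nSpikes(out) - nSpikes(hpc)
  expect_lt(abs(added - 0.3 * nRef), 3 * sqrt(0.3 * nRef))
  # added spikes cluster at the requested lag (within jitter)
  newSpk <- setdiff(spikeTimes(out), spikeTimes(hpc))
  nearRef <- vapply(newSpk, function(s) min(abs(s - 0.030 - spikeTimes(ba))),
                    numeric(1))
  expect_true(all(nearRef <= 0.0051))
  # excess 0 leaves the train untouched
  same <- injectSynchrony(ba, hpc, ep, lagMs = 30, excess = 0, seed = 9L)
  expect_identical(spikeTimes(same), spikeTimes(hpc))
})

test_that("cohorts are deterministic and round-trip through disk", {
  cfg <- defaultSimConfig(seed = 13L, nDistalShift = 1L, nDistalStable = 1L,
                          nNest = 2L, nProximal = 1L)
  coh1 <- makeCohort(cfg)
  coh2 <- makeCohort(cfg)
  for (ph in names(coh1$sessions))
    expect_sessions_equal(coh1$sessions[[ph]], coh2$sessions[[ph]])
  d <- file.path(tempdir(), "cohort_rt")
  writeSession(coh1$sessions$threat, d)
  expect_sessions_equal(readSession(d), coh1$sessions$threat)
  unlink(d, recursive = TRUE)
  # adding a cell does not perturb existing cells' spikes
  cfg2 <- cfg
  cfg2@placeCells <- rbind(cfg2@placeCells,
                           data.frame(cell_id = "hpc_extra", center_x = 70,
                                      sigma = 10, peak_rate = 12,
                                      baseline_rate = 0.8, threat_shift = 0,
                                      theta_mod = 0))
  coh3 <- makeCohort(cfg2)
  for (id in cfg@placeCells$cell_id)
    expect_identical(spikeTimes(trains(coh3$sessions$pre_threat)[[id]]),
                     spikeTimes(trains(coh1$sessions$pre_threat)[[id]]))
})
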