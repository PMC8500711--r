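## Synthetic foraging cohort: scripted trajectory, event log, and coupled
## inhomogeneous-Poisson spike trains with known ground truth. The simulator
## is an artifact of this package (the study records real neurons); its
## distributions are chosen for parameter-recovery testing, not biophysics.

RNG_MOD <- 2147483647

# deterministic per-component seed derived from the cohort seed and a tag;
# doubles are exact here, result always < 2^31
childSeed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag))) %% RNG_MOD
  as.integer(((seed %% RNG_MOD) * 16807 + h) %% RNG_MOD)
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# enforce an absolute refractory period on a sorted spike vector
applyRefractory <- function(times, refractory) {
  if (length(times) < 2L) return(times)
  keep <- logical(length(times))
  last <- -Inf
  for (i in seq_along(times)) {
    if (times[i] - last >= refractory - 1e-12) { keep[i] <- TRUE; last <- times[i] }
  }
  times[keep]
}

#' Build a simulation configuration
#'
#' Describes a synthetic recording day on the nest-corridor apparatus:
#' a nest (x in \[-nestDepth, 0)), a gateway at x = 0 and a pellet at
#' `pelletX` = 125 cm. Each phase has `nTrials` trials; in the threat phase
#' a robot surge fires the first time the animal passes
#' `pelletX - triggerOffset` (default 100 cm) and the animal flees, so
#' pellet procurement only happens with probability `successProbThreat`
#' (default 0).
#'
#' `placeCells` rows describe dHPC units with Gaussian place fields on the
#' corridor axis: columns `cell_id`, `center_x` (cm), `sigma` (cm),
#' `peak_rate`, `baseline_rate` (Hz), `threat_shift` (cm added to the center
#' during the threat phase) and `theta_mod` (sinusoidal 8 Hz rate-modulation
#' depth applied during the threat phase; 0 = none).
#'
#' `baCells` rows describe BA units: `cell_id`, `baseline_rate` (Hz),
#' `event_kind` ("robot", "pellet", "both", "none"), `gain` (multiplicative,
#' > 1 excited, < 1 inhibited), `latency` and `decay` (s), `spike_width`
#' (ms, for the pyramidal/interneuron split).
#'
#' `synchrony` rows inject pairwise co-firing: `ba_cell`, `hpc_cell`,
#' `epoch` (an epoch label), `lag_ms` (dHPC spike lag relative to the BA
#' spike; within +/-100 ms) and `excess` (probability per BA spike of an
#' inserted coincident dHPC spike).
#'
#' @param nTrials trials per phase (default 10).
#' @param pelletX pellet position, cm.
#' @param triggerOffset robot trigger distance from the pellet, cm.
#' @param surgeTravel robot travel per surge, cm (timing cosmetic only).
#' @param frameRate tracking frame rate, Hz.
#' @param nestDepth nest interior depth, cm.
#' @param outboundSpeed,returnSpeed,fleeSpeed locomotion speeds, cm/s.
#' @param nestDwell time spent in the nest before each trial, s.
#' @param pauseProb probability of one mid-corridor pause per threat trial.
#' @param pauseDuration pause length, s.
#' @param successProbThreat probability a threat trial still ends in
#'   procurement.
#' @param yNoise bound on lateral position noise, cm.
#' @param placeCells,baCells,synchrony data.frames as described above.
#' @param refractory simulated absolute refractory period, s.
#' @param seed cohort RNG seed.
#' @return a [SimConfig-class].
#' @export
simConfig <- function(nTrials = 10L, pelletX = 125, triggerOffset = 25,
                      surgeTravel = 23, frameRate = 30, nestDepth = 45,
                      outboundSpeed = 25, returnSpeed = 35, fleeSpeed = 60,
                      nestDwell = 15, pauseProb = 0.3, pauseDuration = 1,
                      successProbThreat = 0, yNoise = 5,
                      placeCells = emptyPlaceCells(),
                      baCells = emptyBaCells(),
                      synchrony = emptySynchrony(),
                      refractory = 0.002, seed = 1L) {
  new("SimConfig", nTrials = as.integer(nTrials), pelletX = pelletX,
      triggerOffset = triggerOffset, surgeTravel = surgeTravel,
      frameRate = frameRate, nestDepth = nestDepth,
      outboundSpeed = outboundSpeed, returnSpeed = returnSpeed,
      fleeSpeed = fleeSpeed, nestDwell = nestDwell, pauseProb = pauseProb,
      pauseDuration = pauseDuration, successProbThreat = successProbThreat,
      yNoise = yNoise, placeCells = placeCells, baCells = baCells,
      synchrony = synchrony, refractory = refractory, seed = as.integer(seed))
}

emptyPlaceCells <- function()
  data.frame(cell_id = character(), center_x = numeric(), sigma = numeric(),
             peak_rate = numeric(), baseline_rate = numeric(),
             threat_shift = numeric(), theta_mod = numeric())

emptyBaCells <- function()
  data.frame(cell_id = character(), baseline_rate = numeric(),
             event_kind = character(), gain = numeric(), latency = numeric(),
             decay = numeric(), spike_width = numeric())

emptySynchrony <- function()
  data.frame(ba_cell = character(), hpc_cell = character(),
             epoch = character(), lag_ms = numeric(), excess = numeric())

#' Simulate the trajectory and event log of one phase
#'
#' Per trial: a nest dwell (bounded random walk inside the nest), a
#' gate_open, a constant-speed outbound run, then either a pellet
#' procurement and return (pre/post phases, and threat trials that succeed)
#' or a robot surge at the trigger line followed by a flight back to the
#' nest. Threat-phase outbound runs may include one brief pause. Positions
#' are rounded to 0.001 cm, frame times to 1e-6 s and event times to 0.1 ms,
#' so sessions round-trip exactly through the CSV files.
#'
#' @param config a [SimConfig-class].
#' @param phase "pre_threat", "threat" or "post_threat".
#' @param seed RNG seed for this trajectory (default derived from the
#'   config seed and the phase).
#' @return list with elements `tracking` ([Tracking-class]) and `events`
#'   ([EventLog-class]).
#' @export
simulateTrajectory <- function(config, phase,
                               seed = childSeed(config@seed,
                                                paste0("traj_", phase))) {
  phase <- match.arg(phase, PHASES)
  if (config@outboundSpeed <= 0) stop("outbound speed must be positive")
  fr <- config@frameRate
  dt <- 1 / fr
  withSeed(seed, {
    xs <- numeric(0)
    evTrial <- integer(0); evKind <- character(0); evFrame <- integer(0)
    xNest <- -config@nestDepth / 2
    frame <- 0L  # frames emitted so far; frame k has time k/fr
    for (tr in seq_len(config@nTrials)) {
      # nest dwell: bounded random walk
      nd <- round(config@nestDwell * fr)
      steps <- stats::rnorm(nd, 0, 0.6)
      xw <- numeric(nd)
      for (i in seq_len(nd)) {
        xNest <- min(-2, max(-config@nestDepth + 2, xNest + steps[i]))
        xw[i] <- xNest
      }
      xs <- c(xs, xw); frame <- frame + nd
      evTrial <- c(evTrial, tr); evKind <- c(evKind, "gate_open")
      evFrame <- c(evFrame, frame)
      # outbound run
      succeed <- phase != "threat" || stats::runif(1) < config@successProbThreat
      trigger <- config@pelletX - config@triggerOffset
      pauseAt <- if (phase == "threat" && stats::runif(1) < config@pauseProb)
        stats::runif(1, 10, trigger - 20) else Inf
      x <- xNest
      surged <- FALSE
      repeat {
        x <- x + config@outboundSpeed * dt
        if (is.finite(pauseAt) && x >= pauseAt) {
          np <- round(config@pauseDuration * fr)
          xs <- c(xs, rep(x, np)); frame <- frame + np
          pauseAt <- Inf
        }
        if (phase == "threat" && !surged && x >= trigger) {
          surged <- TRUE
          xs <- c(xs, x); frame <- frame + 1L
          evTrial <- c(evTrial, tr); evKind <- c(evKind, "robot_surge")
          evFrame <- c(evFrame, frame)
          if (!succeed) break
          next
        }
        if (x >= config@pelletX) {
          x <- config@pelletX
          xs <- c(xs, x); frame <- frame + 1L
          evTrial <- c(evTrial, tr); evKind <- c(evKind, "pellet_procured")
          evFrame <- c(evFrame, frame)
          np <- round(0.5 * fr)  # grabs the pellet
          xs <- c(xs, rep(x, np)); frame <- frame + np
          break
        }
        xs <- c(xs, x); frame <- frame + 1L
      }
      # return (or flight) to the nest
      vBack <- if (phase == "threat" && !succeed) config@fleeSpeed
               else config@returnSpeed
      while (x > xNest) {
        x <- max(xNest, x - vBack * dt)
        xs <- c(xs, x); frame <- frame + 1L
      }
      evTrial <- c(evTrial, tr); evKind <- c(evKind, "trial_end")
      evFrame <- c(evFrame, frame)
    }
    n <- length(xs)
    t <- round(seq_len(n) / fr, 6)
    # smooth bounded lateral noise
    y <- numeric(n)
    innov <- stats::rnorm(n, 0, 0.5)
    acc <- 0
    for (i in seq_len(n)) {
      acc <- 0.9 * acc + innov[i]
      y[i] <- max(-config@yNoise, min(config@yNoise, acc))
    }
    trk <- trackingData(t, round(xs, 3), round(y, 3), frameRate = fr)
    ev <- eventLog(evTrial, evKind, round(evFrame / fr, 4))
    list(tracking = trk, events = ev)
  })
}

# per-frame firing intensity of a Gaussian place field along the corridor
placeIntensity <- function(params, x, t, phase) {
  center <- params$center_x +
    if (phase == "threat") params$threat_shift else 0
  lam <- params$baseline_rate + (params$peak_rate - params$baseline_rate) *
    exp(-(x - center)^2 / (2 * params$sigma^2))
  depth <- if (phase == "threat" && !is.null(params$theta_mod))
    params$theta_mod else 0
  if (depth > 0) lam <- lam * (1 + depth * sin(2 * pi * 8 * t))
  lam
}

#' Simulate a place-modulated dHPC spike train
#'
#' Inhomogeneous Poisson spikes by thinning, with intensity
#' `baseline + (peak - baseline) * exp(-(x(t) - center)^2 / (2 sigma^2))`;
#' during the threat phase the center is displaced by `threat_shift` and an
#' optional 8 Hz sinusoidal modulation of depth `theta_mod` is applied. A
#' 2 ms refractory period is enforced so simulated units satisfy the place
#' cell inclusion criteria that real sorted units satisfy.
#'
#' @param params one row of the `placeCells` data.frame (see [simConfig()]),
#'   as a list or 1-row data.frame.
#' @param tracking a [Tracking-class] for the phase.
#' @param phase the session phase.
#' @param seed RNG seed.
#' @param refractory refractory period (s).
#' @param sessionId id recorded on the train.
#' @return a [SpikeTrain-class] (region "dHPC").
#' @export
simulatePlaceTrain <- function(params, tracking, phase = "pre_threat",
                               seed = 1L, refractory = 0.002,
                               sessionId = NA_character_) {
  params <- as.list(params)
  stopifnot(params$peak_rate >= params$baseline_rate,
            params$baseline_rate >= 0)
  dur <- max(tracking@t)
  depth <- if (phase == "threat" && !is.null(params$theta_mod))
    params$theta_mod else 0
  lamMax <- params$peak_rate * (1 + max(0, depth)) + 1e-9
  times <- withSeed(seed, {
    n <- stats::rpois(1, lamMax * dur)
    cand <- sort(stats::runif(n, 0, dur))
    x <- stats::approx(tracking@t, tracking@x, cand, rule = 2)$y
    lam <- placeIntensity(params, x, cand, phase)
    cand[stats::runif(n) < lam / lamMax]
  })
  times <- applyRefractory(unique(round(times, 4)), refractory)
  spikeTrain(params$cell_id, "dHPC", times, sessionId = sessionId)
}

# event-locked multiplicative modulation; one exponential kernel per event,
# combined with max() so overlapping events cannot blow the rate up
baModulation <- function(t, eventTimes, gain, latency, decay) {
  if (!length(eventTimes)) return(rep(1, length(t)))
  m <- rep(0, length(t))
  for (te in eventTimes) {
    dtv <- t - te - latency
    m <- pmax(m, ifelse(dtv >= 0, exp(-dtv / decay), 0))
  }
  if (gain >= 1) 1 + (gain - 1) * m else 1 - (1 - gain) * m
}

#' Simulate an event-responsive BA spike train
#'
#' Baseline Poisson firing with multiplicative event-locked modulation: from
#' `latency` seconds after each selected event the rate is multiplied by a
#' factor decaying from `gain` back to 1 with time constant `decay`. Excited
#' cells have gain > 1, inhibited cells 0 <= gain < 1; `event_kind` selects
#' which events modulate ("robot" = robot_surge/stim_on, "pellet" =
#' pellet_procured, "both", or "none" for a homogeneous train).
#'
#' @param params one row of the `baCells` data.frame (see [simConfig()]).
#' @param events an [EventLog-class].
#' @param duration session duration (s).
#' @param seed RNG seed.
#' @param refractory refractory period (s).
#' @param sessionId id recorded on the train.
#' @return a [SpikeTrain-class] (region "BA").
#' @export
simulateBaTrain <- function(params, events, duration, seed = 1L,
                            refractory = 0.002, sessionId = NA_character_) {
  params <- as.list(params)
  stopifnot(params$baseline_rate >= 0, params$gain >= 0)
  ev <- events@events
  kinds <- switch(params$event_kind,
                  robot = c("robot_surge", "stim_on"),
                  pellet = "pellet_procured",
                  both = c("robot_surge", "stim_on", "pellet_procured"),
                  none = character(0),
                  stop("unknown event_kind: ", params$event_kind))
  evTimes <- ev$time[ev$kind %in% kinds]
  lamMax <- params$baseline_rate * max(1, params$gain) + 1e-9
  times <- withSeed(seed, {
    n <- stats::rpois(1, lamMax * duration)
    cand <- sort(stats::runif(n, 0, duration))
    lam <- params$baseline_rate *
      baModulation(cand, evTimes, params$gain, params$latency, params$decay)
    cand[stats::runif(n) < lam / lamMax]
  })
  times <- applyRefractory(unique(round(times, 4)), refractory)
  width <- if (!is.null(params$spike_width)) params$spike_width else NA_real_
  spikeTrain(params$cell_id, "BA", times, spikeWidth = width,
             sessionId = sessionId)
}

#' Inject epoch-restricted pairwise co-firing
#'
#' For every BA reference spike falling inside one of the epoch windows,
#' with probability `excess` a dHPC spike is inserted at the reference time
#' plus `lagMs` milliseconds plus a uniform +/-5 ms jitter. The merged train
#' is re-sorted; inserted spikes closer than the refractory period to an
#' existing spike (or landing outside the session) are dropped.
#'
#' @param baTrain reference [SpikeTrain-class].
#' @param hpcTrain target [SpikeTrain-class] to receive extra spikes.
#' @param epochs an [EpochSet-class].
#' @param lagMs lag of inserted spikes (ms; positive = dHPC after BA).
#' @param excess expected inserted coincidences per in-epoch BA spike.
#' @param seed RNG seed.
#' @param refractory minimum gap to an existing spike (s).
#' @param duration session duration; inserted spikes beyond it are dropped.
#' @return the modified dHPC [SpikeTrain-class].
#' @export
injectSynchrony <- function(baTrain, hpcTrain, epochs, lagMs, excess,
                            seed = 1L, refractory = 0.002, duration = Inf) {
  stopifnot(abs(lagMs) <= 100, excess >= 0)
  if (excess == 0 || !nrow(epochs@windows)) return(hpcTrain)
  w <- epochs@windows
  refT <- spikeTimes(baTrain)
  inEpoch <- vapply(refT, function(s)
    any(s >= w[, 1] & s < w[, 2]), logical(1))
  refT <- refT[inEpoch]
  if (!length(refT)) return(hpcTrain)
  newSpk <- withSeed(seed, {
    sel <- stats::runif(length(refT)) < excess
    refT[sel] + lagMs / 1000 + stats::runif(sum(sel), -0.005, 0.005)
  })
  newSpk <- round(newSpk[newSpk >= 0 & newSpk <= duration], 4)
  old <- spikeTimes(hpcTrain)
  # drop inserted spikes violating the refractory period against the train
  keep <- vapply(newSpk, function(s)
    !length(old) || min(abs(old - s)) >= refractory, logical(1))
  merged <- sort(unique(c(old, newSpk[keep])))
  merged <- applyRefractory(merged, refractory)
  spikeTrain(cellId(hpcTrain), region(hpcTrain), merged,
             spikeWidth = spikeWidth(hpcTrain),
             sessionId = sessionId(hpcTrain))
}

#' Simulate a full three-session cohort with ground truth
#'
#' Builds the pre_threat, threat and post_threat sessions of one synthetic
#' recording day, sharing cell identities, and returns them with the ground
#' truth (true place-cell classes and field centers, true BA response
#' classes, and the injected-synchrony list). Surge-epoch synchrony is
#' injected in the threat session, pellet-epoch synchrony in the pre_threat
#' session. Per-cell RNG streams are derived from the cohort seed, so adding
#' a cell never perturbs the others.
#'
#' @param config a [SimConfig-class].
#' @return list with `sessions` (named list pre_threat/threat/post_threat)
#'   and `groundTruth` (list of data.frames `place`, `ba`, `synchrony`).
#' @export
makeCohort <- function(config) {
  validObject(config)
  sessions <- list()
  for (phase in PHASES) {
    traj <- simulateTrajectory(config, phase)
    dur <- max(traj$tracking@t) + 1
    sid <- sprintf("sim%d_%s", config@seed, phase)
    trains <- list()
    pc <- config@placeCells
    for (i in seq_len(nrow(pc)))
      trains[[pc$cell_id[i]]] <- simulatePlaceTrain(
        pc[i, ], traj$tracking, phase,
        seed = childSeed(config@seed, paste0("pc_", pc$cell_id[i], "_", phase)),
        refractory = config@refractory, sessionId = sid)
    ba <- config@baCells
    for (i in seq_len(nrow(ba)))
      trains[[ba$cell_id[i]]] <- simulateBaTrain(
        ba[i, ], traj$events, dur,
        seed = childSeed(config@seed, paste0("ba_", ba$cell_id[i], "_", phase)),
        refractory = config@refractory, sessionId = sid)
    # epoch-restricted synchrony: surge epochs live in the threat session,
    # pellet epochs in the pre_threat session
    sy <- config@synchrony
    if (nrow(sy)) {
      filt <- filterSurgeEvents(traj$events)
      for (i in seq_len(nrow(sy))) {
        hostPhase <- if (grepl("surge", sy$epoch[i])) "threat" else "pre_threat"
        if (hostPhase != phase) next
        ep <- makeEpochs(filt, sy$epoch[i])
        trains[[sy$hpc_cell[i]]] <- injectSynchrony(
          trains[[sy$ba_cell[i]]], trains[[sy$hpc_cell[i]]], ep,
          sy$lag_ms[i], sy$excess[i],
          seed = childSeed(config@seed, paste0("syn_", i, "_", phase)),
          refractory = config@refractory, duration = dur)
      }
    }
    sessions[[phase]] <- session(sid, phase, traj$tracking, traj$events,
                                 trains, duration = dur)
  }
  pc <- config@placeCells
  truePlace <- cbind(pc, true_class = ifelse(pc$center_x < 0, "nest",
                              ifelse(pc$center_x <= 25, "proximal", "distal")))
  ba <- config@baCells
  trueBa <- cbind(ba, true_class = c(robot = "Robot", pellet = "Pellet",
                                     both = "RobotPellet",
                                     none = "NonResponsive")[ba$event_kind])
  list(sessions = sessions,
       groundTruth = list(place = truePlace, ba = trueBa,
                          synchrony = config@synchrony))
}

#' Default "paper-like" cohort configuration
#'
#' The study conditions the analyses are validated against: 10 trials per
#' phase, pellet at 125 cm, robot trigger 25 cm before it; a dHPC population
#' of nest, proximal and distal place cells (Gaussian fields, peak 12 Hz,
#' baseline 0.8 Hz, sigma 10 cm); BA cells that are robot-excited,
#' pellet-excited or non-responsive (baseline 4 Hz, gain 5); surge-epoch
#' synchrony (lag +30 ms, excess 0.3) linking robot-responsive BA cells to
#' half of the distal cells - and only those distal cells remap during the
#' threat phase (field displaced 30 cm toward the nest, so the shifted field
#' stays inside the threat-session foraging limit). Nest cells are paired
#' half with robot cells and half with nonRobot cells and all stay stable,
#' giving the expected null contrast in the nest group.
#'
#' @param seed cohort seed.
#' @param nDistalShift,nDistalStable distal cells with / without remapping.
#' @param nNest,nProximal counts of the other dHPC classes.
#' @param thetaModThreat 8 Hz modulation depth given to distal cells during
#'   the threat phase (default 0).
#' @return a [SimConfig-class].
#' @export
defaultSimConfig <- function(seed = 1L, nDistalShift = 10L, nDistalStable = 10L,
                             nNest = 10L, nProximal = 4L, thetaModThreat = 0) {
  nestC <- seq(-38, -8, length.out = nNest)
  proxC <- seq(5, 22, length.out = nProximal)
  nDist <- nDistalShift + nDistalStable
  distC <- seq(38, 92, length.out = nDist)
  # interleave remapping and pairing assignments across field positions so
  # neither is confounded with distance from the nest
  distShiftIdx <- seq_len(nDist) %% 2 == 1
  if (sum(distShiftIdx) != nDistalShift)
    distShiftIdx <- seq_len(nDist) <= nDistalShift
  pc <- data.frame(
    cell_id = c(sprintf("hpc_nest%02d", seq_len(nNest)),
                sprintf("hpc_prox%02d", seq_len(nProximal)),
                sprintf("hpc_dist%02d", seq_len(nDist))),
    center_x = c(nestC, proxC, distC),
    sigma = 10, peak_rate = 12, baseline_rate = 0.8,
    threat_shift = c(rep(0, nNest + nProximal),
                     ifelse(distShiftIdx, -30, 0)),
    theta_mod = c(rep(0, nNest + nProximal), rep(thetaModThreat, nDist)))
  ba <- data.frame(
    cell_id = c("ba_rob01", "ba_rob02",
                "ba_pel01", "ba_pel02", "ba_non01", "ba_non02"),
    baseline_rate = 4,
    event_kind = c("robot", "robot", "pellet", "pellet", "none", "none"),
    gain = c(5, 5, 4, 4, 1, 1), latency = 0.1, decay = 1.5,
    spike_width = c(0.42, 0.38, 0.41, 0.37, 0.39, 0.43))
  distShift <- sprintf("hpc_dist%02d", which(distShiftIdx))
  distStable <- sprintf("hpc_dist%02d", which(!distShiftIdx))
  nestIds <- sprintf("hpc_nest%02d", seq_len(nNest))
  nestRobotIdx <- seq_len(nNest) %% 2 == 1
  robotBa <- c("ba_rob01", "ba_rob02")
  nonRobotBa <- c("ba_pel01", "ba_pel02", "ba_non01", "ba_non02")
  sy <- data.frame(
    ba_cell = c(rep_len(robotBa, length(distShift)),
                rep_len(nonRobotBa, length(distStable)),
                rep_len(robotBa, sum(nestRobotIdx)),
                rep_len(nonRobotBa, sum(!nestRobotIdx))),
    hpc_cell = c(distShift, distStable, nestIds[nestRobotIdx],
                 nestIds[!nestRobotIdx]),
    epoch = "pre_surge", lag_ms = 30, excess = 0.3)
  simConfig(placeCells = pc, baCells = ba, synchrony = sy, seed = seed)
}
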