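# independent brute-force CCG: explicit double loop over all spike pairs
bruteCcg <- function(refList, tgtList, bin = 0.01, range = 0.5) {
  edges <- seq(-range, range, by = bin)
  counts <- numeric(length(edges) - 1L)
  for (tr in seq_along(refList)) {
    for (r in refList[[tr]]) for (s in tgtList[[tr]]) {
      lag <- s - r
      if (lag >= -range && lag < range) {
        b <- floor((lag + range) / bin) + 1L
        counts[b] <- counts[b] + 1
      }
    }
  }
  counts
}

test_that("epoch grouping keeps spikes in half-open windows", {
  ev <- eventLog(1L, "robot_surge", 100)
  ep <- makeEpochs(ev, "pre_surge")
  es <- epochSpikes(spikeTrain("c", "BA", c(97.5, 97.6, 100.0, 101.0)), ep)
  expect_equal(es$times[[1]], c(97.5, 97.6))  # start kept, end dropped
  esEmpty <- epochSpikes(spikeTrain("c", "BA", numeric(0)), ep)
  expect_length(esEmpty$times[[1]], 0)
  expect_error(epochSpikes(spikeTrain("c", "BA", 1),
                           makeEpochs(eventLog(), "pre_surge")), "non-empty")
})

test_that("rawCcg bins single lags where the arithmetic says", {
  edges <- seq(-0.5, 0.5, by = 0.01)
  r1 <- rawCcg(list(c(1.00)), list(c(1.02)))
  expect_equal(sum(r1), 1)
  expect_equal(which(r1 == 1), which(abs(edges - 0.02) < 1e-9))  # [+20, +30) ms
  r2 <- rawCcg(list(c(1.0, 2.0)), list(c(0.95)))
  expect_equal(sum(r2), 1)  # the -1.05 s lag is out of range
  expect_equal(which(r2 == 1), which(abs(edges - -0.05) < 1e-12))
  expect_error(rawCcg(list(1, 2), list(1)), "trial counts")
})

test_that("rawCcg equals the brute-force double loop exactly", {
  set.seed(14)
  for (rep in 1:25) {
    nTrials <- sample(1:5, 1)
    refL <- lapply(seq_len(nTrials), function(i)
      sort(runif(sample(0:60, 1), 0, 2.5)))
    tgtL <- lapply(seq_len(nTrials), function(i)
      sort(runif(sample(0:60, 1), 0, 2.5)))
    expect_equal(as.numeric(rawCcg(refL, tgtL)), bruteCcg(refL, tgtL))
    # antisymmetry: reversing roles mirrors the CCG about lag 0
    fwd <- as.numeric(rawCcg(refL, tgtL))
    bwd <- as.numeric(rawCcg(tgtL, refL))
    # bins [lo, hi) mirror onto (-hi, -lo]; compare via brute force on -lags
    neg <- bruteCcg(lapply(tgtL, function(x) -x), lapply(refL, function(x) -x))
    expect_equal(fwd, neg)
    expect_equal(sum(fwd), sum(bruteCcg(refL, tgtL)))
    expect_true(sum(abs(sort(fwd) - sort(bwd))) <= sum(fwd))  # same mass
  }
})

test_that("the shift predictor nulls stimulus-locked correlation", {
  # identical pattern on every trial: predictor ~ raw, corrected ~ 0
  pat <- seq(0.1, 2.4, by = 0.1)
  ev <- surgeLog(8)
  ep <- makeEpochs(filterSurgeEvents(ev), "post_surge")
  starts <- epochWindows(ep)[, 1]
  ref <- spikeTrain("ba", "BA", round(as.vector(outer(pat, starts, "+")), 4))
  tgt <- spikeTrain("hp", "dHPC",
                    round(as.vector(outer(pat + 0.03, starts, "+")), 4))
  refE <- epochSpikes(ref, ep); tgtE <- epochSpikes(tgt, ep)
  raw <- rawCcg(refE, tgtE)
  pred <- shiftPredictor(refE, tgtE, nShuffles = 100, seed = 5L)
  expect_lt(max(abs(raw - pred)) / max(raw), 0.15)
  res <- ccgSignificance(raw, pred, 8, 8)
  expect_false(isSignificant(res))
  # determinism of the predictor
  pred2 <- shiftPredictor(refE, tgtE, nShuffles = 100, seed = 5L)
  expect_identical(as.numeric(pred), as.numeric(pred2))
  expect_error(shiftPredictor(list(1), list(1)), "2 trials")
  # independent trains: corrected is centered on zero
  set.seed(33)
  refI <- lapply(1:10, function(i) sort(runif(12, 0, 2.5)))
  tgtI <- lapply(1:10, function(i) sort(runif(12, 0, 2.5)))
  rawI <- rawCcg(refI, tgtI)
  predI <- shiftPredictor(refI, tgtI, seed = 6L)
  corr <- rawI - predI
  expect_lt(abs(mean(corr)), 2 * sd(corr) / sqrt(length(corr)))
})

test_that("significance needs peak Z > 3 inside +/-100 ms and 0.1 Hz rates", {
  edges <- seq(-0.5, 0.5, by = 0.01)
  nb <- length(edges) - 1L
  base <- rep(10, nb)
  # peak at +150 ms only: outside the testing window
  far <- base; far[which(abs(edges - 0.15) < 1e-9)] <- 40
  resFar <- ccgSignificance(structure(far, edges = edges),
                            structure(base, edges = edges), 5, 5)
  expect_false(isSignificant(resFar))
  expect_equal(resFar@peakLagMs, 155)
  # same peak at +30 ms: significant, BA leading
  nearC <- base; nearC[which(abs(edges - 0.03) < 1e-9)] <- 40
  resNear <- ccgSignificance(structure(nearC, edges = edges),
                             structure(base, edges = edges), 5, 5)
  expect_true(isSignificant(resNear))
  expect_gt(resNear@peakZ, 3)
  expect_identical(pairDirection(resNear), "BA->dHPC")
  # peak in [-40, -30) ms: dHPC leading
  nearL <- base; nearL[which(abs(edges - -0.04) < 1e-12)] <- 40
  resL <- ccgSignificance(structure(nearL, edges = edges),
                          structure(base, edges = edges), 5, 5)
  expect_identical(pairDirection(resL), "dHPC->BA")
  # sub-floor firing rate excludes the pair
  resRate <- ccgSignificance(structure(nearC, edges = edges),
                             structure(base, edges = edges), 5, 0.05)
  expect_false(isSignificant(resRate))
  expect_identical(resRate@flag, "rate_fail")
  # flat corrected CCG is degenerate, not significant
  resDeg <- ccgSignificance(structure(base, edges = edges),
                            structure(base, edges = edges), 5, 5)
  expect_false(isSignificant(resDeg))
  expect_identical(resDeg@flag, "degenerate")
})

test_that("pairScreen enumerates every pair in every epoch", {
  ses <- makeCohort(defaultSimConfig(seed = 23L, nDistalShift = 1L,
                                     nDistalStable = 1L, nNest = 1L,
                                     nProximal = 0L))$sessions$threat
  eps <- sessionEpochs(ses, c("pre_surge", "post_surge"))
  isBa <- vapply(trains(ses), region, character(1)) == "BA"
  tab <- pairScreen(trains(ses)[isBa], trains(ses)[!isBa], eps,
                    nShuffles = 20, seed = 1L)
  expect_identical(nrow(tab), sum(isBa) * sum(!isBa) * 2L)
  expect_true(all(tab$epoch %in% c("pre_surge", "post_surge")))
  # reproducible under the same seed
  tab2 <- pairScreen(trains(ses)[isBa], trains(ses)[!isBa], eps,
                     nShuffles = 20, seed = 1L)
  expect_identical(tab$peak_z, tab2$peak_z)
})
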