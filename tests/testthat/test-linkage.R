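mkRecords <- function(ids, classes, z, pd = NULL, px = NULL) {
  n <- length(ids)
  data.frame(cell_id = ids, included = TRUE, class = classes,
             peak_x_pre = if (is.null(px)) seq(30, 90, length.out = n) else px,
             z_pre_threat = z,
             pd_pre_threat = if (is.null(pd)) rep(10, n) else pd,
             z_pre_post = z, pd_pre_post = rep(5, n),
             stringsAsFactors = FALSE)
}

mkPairs <- function(ba, hpc, sig, epoch = "pre_surge") {
  data.frame(ba_cell = ba, hpc_cell = hpc, epoch = epoch, peak_z = 5,
             peak_lag_ms = 30, significant = sig, direction = "BA->dHPC",
             ba_rate = 4, hpc_rate = 2, flag = "ok", stringsAsFactors = FALSE)
}

mkBaCls <- function() {
  data.frame(cell_id = c("rob1", "pel1", "non1", "rp1", "int1"),
             class = c("Robot", "Pellet", "NonResponsive", "RobotPellet",
                       "Robot"),
             sign = c("excited", "excited", "none", "excited", "excited"),
             robot_subwindow = "triggered", partial = FALSE,
             unit_type = c(rep("pyramidal", 4), "interneuron"),
             mean_rate = 4, stringsAsFactors = FALSE)
}

test_that("pairing labels follow the Robot-dominance rule", {
  rec <- mkRecords(c("h1", "h2", "h3", "h4", "h5", "h6"),
                   c("distal", "distal", "distal", "nest", "nest", "proximal"),
                   z = c(0.2, 1.5, 2.0, 2.1, 2.2, 2.3))
  pairs <- rbind(
    mkPairs("rob1", "h1", TRUE),            # Robot partner
    mkPairs("pel1", "h2", TRUE),            # nonRobot partner
    mkPairs("rob1", "h3", TRUE),            # both kinds -> dominance
    mkPairs("non1", "h3", TRUE),
    mkPairs("rob1", "h4", FALSE),           # not significant -> unpaired
    mkPairs("rp1", "h5", TRUE),             # RobotPellet excluded
    mkPairs("int1", "h6", TRUE))            # interneuron excluded
  lk <- buildLinkage(pairs, mkBaCls(), rec)
  lab <- setNames(lk$paired_pre_surge, lk$cell_id)
  expect_identical(lab[["h1"]], "Robot")
  expect_identical(lab[["h2"]], "nonRobot")
  expect_identical(lab[["h3"]], "Robot")
  expect_identical(lab[["h4"]], "unpaired")
  expect_identical(lab[["h5"]], "unpaired")
  expect_identical(lab[["h6"]], "unpaired")
  expect_identical(unname(lk$group[lk$cell_id == "h6"]), "nest_proximal")
  # exclusive mode drops dual-paired cells
  lkx <- buildLinkage(pairs, mkBaCls(), rec, mode = "exclusive")
  expect_true(is.na(lkx$paired_pre_surge[lkx$cell_id == "h3"]))
  # unknown BA ids are an error naming the orphan
  bad <- rbind(pairs, mkPairs("ghost", "h1", TRUE))
  expect_error(buildLinkage(bad, mkBaCls(), rec), "ghost")
})

test_that("stability contrasts respond to group labels symmetrically", {
  set.seed(71)
  ids <- sprintf("d%02d", 1:20)
  z <- c(rnorm(10, 0.2, 0.3), rnorm(10, 2.0, 0.3))
  rec <- mkRecords(ids, rep("distal", 20), z)
  pairs <- mkPairs(c(rep("rob1", 10), rep("pel1", 10)), ids, TRUE)
  lk <- buildLinkage(pairs, mkBaCls(), rec)
  ct <- suppressWarnings(stabilityByPairing(lk))
  expect_identical(ct$group, "distal")
  expect_lt(ct$p, 0.05)
  expect_lt(ct$estimate, 0)  # Robot-paired less stable
  # swapping the group labels flips the effect sign
  pairsSwap <- mkPairs(c(rep("pel1", 10), rep("rob1", 10)), ids, TRUE)
  lkSwap <- buildLinkage(pairsSwap, mkBaCls(), rec)
  ctSwap <- suppressWarnings(stabilityByPairing(lkSwap))
  expect_equal(ctSwap$estimate, -ct$estimate, tolerance = 1e-9)
  # too-small groups are skipped with a warning (one per skipped group)
  tiny <- lk[c(1:2, 11:20), ]
  w <- capture_warnings(stabilityByPairing(tiny))
  expect_true(any(grepl("too few", w)))
})

test_that("position regressions report slope, r and p per metric", {
  set.seed(72)
  n <- 40
  px <- seq(-30, 90, length.out = n)
  z <- 2 - 0.02 * px + rnorm(n, 0, 0.1)
  pd <- 2 + 0.3 * px + rnorm(n, 0, 3)
  rec <- mkRecords(sprintf("c%02d", 1:n), rep("distal", n), z, pd = pd,
                   px = px)
  reg <- stabilityVsPosition(rec)
  expect_lt(reg$slope[reg$metric == "z_pre_threat"], 0)
  expect_gt(reg$slope[reg$metric == "pd_pre_threat"], 0)
  expect_true(all(reg$p < 0.05))
  # duplicating every row leaves the slope unchanged
  reg2 <- stabilityVsPosition(rbind(rec, rec))
  expect_equal(reg2$slope, reg$slope, tolerance = 1e-9)
  # degenerate predictor errors out
  recFlat <- rec; recFlat$peak_x_pre <- 50
  expect_error(stabilityVsPosition(recFlat), "degenerate")
})

test_that("the speed control sees forced dependence and nothing else", {
  coh <- makeCohort(defaultSimConfig(seed = 37L, nDistalShift = 0L,
                                     nDistalStable = 6L, nNest = 6L,
                                     nProximal = 0L))
  pr <- placeCellRecords(coh)
  rec <- pr$records[pr$records$included, ]
  lk <- data.frame(cell_id = rec$cell_id, class = rec$class,
                   group = ifelse(rec$class == "distal", "distal",
                                  "nest_proximal"),
                   peak_x_pre = rec$peak_x_pre,
                   z_pre_threat = rec$z_pre_threat,
                   stringsAsFactors = FALSE)
  sc <- speedControl(lk, coh)
  expect_true(all(abs(sc$r) <= 1))
  # stable cohort: no strong speed-stability coupling expected
  expect_true(all(sc$p > 0.01))
  # forced dependence: overwrite z with a deterministic function of speed
  spd <- vapply(seq_len(nrow(lk)), function(i) {
    trk <- tracking(coh$sessions$threat)
    sel <- abs(trk@x - lk$peak_x_pre[i]) <= 15
    mean(computeSpeed(trk)[sel])
  }, numeric(1))
  trkP <- tracking(coh$sessions$pre_threat)
  spdP <- vapply(seq_len(nrow(lk)), function(i) {
    sel <- abs(trkP@x - lk$peak_x_pre[i]) <= 15
    mean(computeSpeed(trkP)[sel])
  }, numeric(1))
  lk2 <- lk; lk2$z_pre_threat <- (spd - spdP) / spdP
  sc2 <- speedControl(lk2, coh)
  expect_true(all(abs(sc2$r) > 0.999))
})

test_that("rate comparisons detect only genuine rate differences", {
  ids <- sprintf("d%02d", 1:12)
  rec <- mkRecords(ids, c(rep("distal", 6), rep("nest", 6)),
                   z = rep(1, 12))
  pairs <- mkPairs(rep("rob1", 12), ids, TRUE)
  pairs$hpc_rate <- rep(2, 12)  # equal rates
  lk <- buildLinkage(pairs, mkBaCls(), rec)
  rc <- suppressWarnings(rateComparisons(lk, pairs, mkBaCls()))
  hpcRow <- rc[rc$contrast == "robot_paired_distal_vs_nest_proximal_rate", ]
  expect_equal(hpcRow$mean_a, hpcRow$mean_b)
  # a 3x rate difference is flagged
  pairs2 <- pairs
  set.seed(4)
  pairs2$hpc_rate <- c(rnorm(6, 6, 0.3), rnorm(6, 2, 0.3))
  rc2 <- suppressWarnings(rateComparisons(lk, pairs2, mkBaCls()))
  row2 <- rc2[rc2$contrast == "robot_paired_distal_vs_nest_proximal_rate", ]
  expect_lt(row2$p, 0.05)
})

test_that("every included place cell appears exactly once in the linkage", {
  coh <- makeCohort(defaultSimConfig(seed = 19L, nDistalShift = 2L,
                                     nDistalStable = 2L, nNest = 3L,
                                     nProximal = 1L))
  an <- suppressWarnings(analyzeCohort(coh, seed = 19L, nShuffles = 30))
  inc <- an$placeRecords$records$cell_id[an$placeRecords$records$included]
  expect_setequal(an$linkage$cell_id, inc)
  expect_identical(anyDuplicated(an$linkage$cell_id), 0L)
  # pairing labels are reproducible from the pair table alone
  lk2 <- buildLinkage(an$pairTable, an$baClasses, an$placeRecords$records)
  expect_identical(lk2$paired_pre_surge, an$linkage$paired_pre_surge)
})
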