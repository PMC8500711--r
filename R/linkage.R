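## Linking BA-dHPC synchrony, BA functional class and place-field stability:
## the headline contrasts plus the position-regression, speed and firing-rate
## controls.

ROBOT_SET <- "Robot"
NONROBOT_SET <- c("Pellet", "NonResponsive")

#' Join synchrony, BA classes and place-field stability
#'
#' One row per included dHPC place cell. For each epoch label, the cell is
#' labeled `Robot` if it has at least one significant pair with a
#' robot-responsive pyramidal BA cell in that epoch, `nonRobot` if its only
#' significant partners are Pellet or non-responsive cells, `unpaired`
#' otherwise (dominance rule: a cell paired with both kinds counts as
#' Robot-paired; `mode = "exclusive"` drops such cells to NA instead).
#' RobotPellet BA cells and interneurons are excluded from pairing. Nest
#' and proximal cells are merged into the nest_proximal group.
#'
#' @param pairTable output of [pairScreen()].
#' @param baClasses output of [classifyBaCohort()].
#' @param placeRecords `records` from [placeCellRecords()].
#' @param mode "dominant" (default) or "exclusive".
#' @return data.frame (the linkage table): cell_id, class, group, stability
#'   metrics, pre-threat peak, and one paired_<epoch> column per epoch.
#' @export
buildLinkage <- function(pairTable, baClasses, placeRecords,
                         mode = c("dominant", "exclusive")) {
  mode <- match.arg(mode)
  orphans <- setdiff(pairTable$ba_cell, baClasses$cell_id)
  if (length(orphans))
    stop("BA cells missing from the classification: ",
         paste(orphans, collapse = ", "))
  rec <- placeRecords[placeRecords$included & !is.na(placeRecords$class), ]
  eligible <- baClasses[baClasses$unit_type == "pyramidal" &
                        baClasses$class != "RobotPellet", ]
  epochs <- unique(pairTable$epoch)
  sig <- pairTable[pairTable$significant, ]
  out <- rec[, c("cell_id", "class", "peak_x_pre",
                 "z_pre_threat", "pd_pre_threat",
                 "z_pre_post", "pd_pre_post")]
  out$group <- ifelse(out$class == "distal", "distal", "nest_proximal")
  for (ep in epochs) {
    lab <- paste0("paired_", ep)
    out[[lab]] <- vapply(out$cell_id, function(cid) {
      partners <- sig$ba_cell[sig$hpc_cell == cid & sig$epoch == ep]
      partners <- intersect(partners, eligible$cell_id)
      if (!length(partners)) return("unpaired")
      cls <- eligible$class[match(partners, eligible$cell_id)]
      hasRobot <- any(cls %in% ROBOT_SET)
      hasNon <- any(cls %in% NONROBOT_SET)
      if (hasRobot && hasNon)
        return(if (mode == "dominant") "Robot" else NA_character_)
      if (hasRobot) "Robot" else "nonRobot"
    }, character(1))
  }
  rownames(out) <- NULL
  out
}

# normality pre-test (Lilliefors / Kolmogorov-Smirnov) chooses the test:
# t-test when both groups look normal (or are too small to assess),
# Wilcoxon rank-sum otherwise
chooseTest <- function(a, b, alpha = 0.05) {
  normal <- function(v) {
    if (length(v) < 5L || stats::sd(v) == 0) return(TRUE)
    nortest::lillie.test(v)$p.value > alpha
  }
  if (normal(a) && normal(b)) "t" else "wilcox"
}

twoGroupTest <- function(a, b, alternative = "two.sided") {
  if (stats::sd(c(a, b)) == 0)
    return(list(p = 1, method = "t", estimate = mean(a) - mean(b)))
  method <- chooseTest(a, b)
  res <- if (method == "t")
    stats::t.test(a, b, alternative = alternative)
  else
    suppressWarnings(stats::wilcox.test(a, b, alternative = alternative))
  list(p = res$p.value, method = method,
       estimate = mean(a) - mean(b))
}

#' Stability contrast between Robot-paired and nonRobot-paired cells
#'
#' For each place-cell group (nest_proximal, distal), compares the chosen
#' stability metric between cells paired with robot-responsive BA cells and
#' cells paired with nonRobot BA cells in the given epoch. The test
#' (Welch t vs Wilcoxon rank-sum) is chosen by a Kolmogorov-Smirnov
#' (Lilliefors) normality pre-test. Groups with fewer than `minN` cells are
#' skipped with a warning.
#'
#' @param linkage table from [buildLinkage()].
#' @param epoch epoch label (default "pre_surge").
#' @param metric "z_pre_threat" (default), "pd_pre_threat", etc.
#' @param minN minimum cells per contrasted group (default 3).
#' @param alternative "two.sided" (default), or "less"/"greater" for the
#'   directional hypothesis that Robot-paired cells have a lower/higher
#'   metric than nonRobot-paired cells.
#' @return data.frame: group, n_robot, n_nonrobot, estimate
#'   (Robot - nonRobot mean difference), p, method.
#' @export
stabilityByPairing <- function(linkage, epoch = "pre_surge",
                               metric = "z_pre_threat", minN = 3L,
                               alternative = "two.sided") {
  lab <- paste0("paired_", epoch)
  stopifnot(lab %in% names(linkage), metric %in% names(linkage))
  rows <- list()
  for (grp in c("nest_proximal", "distal")) {
    sub <- linkage[linkage$group == grp & !is.na(linkage[[lab]]), ]
    a <- sub[[metric]][sub[[lab]] == "Robot"]
    b <- sub[[metric]][sub[[lab]] == "nonRobot"]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < minN || length(b) < minN) {
      warning("group ", grp, ": too few cells (", length(a), " Robot, ",
              length(b), " nonRobot); contrast skipped")
      next
    }
    tst <- twoGroupTest(a, b, alternative = alternative)
    rows[[grp]] <- data.frame(group = grp, n_robot = length(a),
                              n_nonrobot = length(b),
                              estimate = tst$estimate, p = tst$p,
                              method = tst$method, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Stability as a function of field position
#'
#' Ordinary least-squares regressions of the two stability metrics on the
#' pre-threat peak firing location: Fisher Z' (expected to fall with
#' distance from the nest under threat) and peak distance (expected to
#' rise).
#'
#' @param records the linkage table or `records` data.frame; needs columns
#'   peak_x_pre and the two metrics.
#' @param zMetric,pdMetric column names (defaults pre-vs-threat).
#' @param minN minimum number of cells (default 10).
#' @return data.frame with one row per metric: metric, slope, r, p, n.
#' @export
stabilityVsPosition <- function(records, zMetric = "z_pre_threat",
                                pdMetric = "pd_pre_threat", minN = 10L) {
  fit1 <- function(metric) {
    d <- records[!is.na(records[[metric]]) & !is.na(records$peak_x_pre), ]
    if (nrow(d) < minN) stop("fewer than ", minN, " cells for ", metric)
    if (stats::sd(d$peak_x_pre) == 0) stop("degenerate x variance")
    fit <- stats::lm(d[[metric]] ~ d$peak_x_pre)
    ct <- stats::cor.test(d$peak_x_pre, d[[metric]])
    data.frame(metric = metric, slope = unname(stats::coef(fit)[2]),
               r = unname(ct$estimate), p = ct$p.value, n = nrow(d),
               stringsAsFactors = FALSE)
  }
  rbind(fit1(zMetric), fit1(pdMetric), make.row.names = FALSE)
}

#' Speed-change control correlation
#'
#' For each cell, the mean running speed within its field region (pre-threat
#' peak +/- `halfWidth` cm) is computed for the pre-threat and threat
#' sessions; the relative change (threat - pre)/pre is correlated (Pearson)
#' with the pre-vs-threat Fisher Z' per place-cell group. A remapping effect
#' that survives this control is not explained by locomotion changes.
#'
#' @param linkage table from [buildLinkage()].
#' @param cohort list with `sessions`.
#' @param halfWidth half-width of the field region (cm), default 15 (about
#'   one field sigma).
#' @return data.frame: group, r, p, n.
#' @export
speedControl <- function(linkage, cohort, halfWidth = 15) {
  ss <- cohort$sessions
  spd <- lapply(ss[c("pre_threat", "threat")], function(s)
    list(v = computeSpeed(s@tracking), x = s@tracking@x))
  relChange <- vapply(seq_len(nrow(linkage)), function(i) {
    px <- linkage$peak_x_pre[i]
    m <- vapply(spd, function(sv) {
      sel <- abs(sv$x - px) <= halfWidth
      if (!any(sel)) return(NA_real_)
      mean(sv$v[sel])
    }, numeric(1))
    if (is.na(m[1]) || is.na(m[2]) || m[1] == 0) return(NA_real_)
    (m[2] - m[1]) / m[1]
  }, numeric(1))
  rows <- list()
  for (grp in c("nest_proximal", "distal")) {
    sel <- linkage$group == grp & !is.na(relChange) &
      !is.na(linkage$z_pre_threat)
    if (sum(sel) < 3L) next
    ct <- stats::cor.test(relChange[sel], linkage$z_pre_threat[sel])
    rows[[grp]] <- data.frame(group = grp, r = unname(ct$estimate),
                              p = ct$p.value, n = sum(sel),
                              stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Firing-rate confound controls
#'
#' Epoch firing-rate contrasts: (i) Robot-paired distal vs Robot-paired
#' nest_proximal dHPC cells, and (ii) robot-responsive BA cells grouped by
#' the class of the dHPC cells they pair with. Comparable rates across
#' groups rule out a pure rate confound behind a stability difference.
#'
#' @param linkage table from [buildLinkage()].
#' @param pairTable output of [pairScreen()].
#' @param baClasses output of [classifyBaCohort()].
#' @param epoch epoch label (default "pre_surge").
#' @param minN minimum cells per group.
#' @return data.frame: contrast, n_a, n_b, mean_a, mean_b, p, method.
#' @export
rateComparisons <- function(linkage, pairTable, baClasses,
                            epoch = "pre_surge", minN = 3L) {
  lab <- paste0("paired_", epoch)
  sub <- pairTable[pairTable$epoch == epoch, ]
  hpcRate <- tapply(sub$hpc_rate, sub$hpc_cell, mean)
  rows <- list()
  robotPaired <- linkage$cell_id[!is.na(linkage[[lab]]) &
                                 linkage[[lab]] == "Robot"]
  a <- hpcRate[intersect(robotPaired,
                         linkage$cell_id[linkage$group == "distal"])]
  b <- hpcRate[intersect(robotPaired,
                         linkage$cell_id[linkage$group == "nest_proximal"])]
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) >= minN && length(b) >= minN) {
    tst <- twoGroupTest(a, b)
    rows[["hpc"]] <- data.frame(
      contrast = "robot_paired_distal_vs_nest_proximal_rate",
      n_a = length(a), n_b = length(b), mean_a = mean(a), mean_b = mean(b),
      p = tst$p, method = tst$method, stringsAsFactors = FALSE)
  } else warning("dHPC rate contrast skipped: too few cells")
  # robot-responsive BA cells by partner class
  robotBa <- baClasses$cell_id[baClasses$class == "Robot" &
                               baClasses$unit_type == "pyramidal"]
  sig <- sub[sub$significant & sub$ba_cell %in% robotBa, ]
  sig$partner_group <- linkage$group[match(sig$hpc_cell, linkage$cell_id)]
  aB <- sig$ba_rate[sig$partner_group == "distal"]
  bB <- sig$ba_rate[sig$partner_group == "nest_proximal"]
  aB <- aB[!is.na(aB)]; bB <- bB[!is.na(bB)]
  if (length(aB) >= minN && length(bB) >= minN) {
    tst <- twoGroupTest(aB, bB)
    rows[["ba"]] <- data.frame(
      contrast = "robot_ba_rate_by_partner_class",
      n_a = length(aB), n_b = length(bB), mean_a = mean(aB),
      mean_b = mean(bB), p = tst$p, method = tst$method,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Run the full analysis pipeline on a cohort
#'
#' Place-field records, BA classification, the pair screen over the four
#' epoch labels, the linkage table and the headline contrasts, in one call.
#' All randomness (the shift predictor) is governed by `seed`.
#'
#' @param cohort list with `sessions` (see [makeCohort()]).
#' @param seed RNG seed for the shift predictors.
#' @param nShuffles shuffles per predictor.
#' @param epoch epoch label used for the linkage contrasts.
#' @return list: placeRecords, baClasses, pairTable, linkage, contrast
#'   (stability by pairing), regression (stability vs position), behavior
#'   (per-session [BehaviorSummary-class]).
#' @export
analyzeCohort <- function(cohort, seed = 1L, nShuffles = 100,
                          epoch = "pre_surge") {
  pr <- placeCellRecords(cohort)
  ba <- classifyBaCohort(cohort)
  ss <- cohort$sessions
  eps <- c(sessionEpochs(ss$threat, c("pre_surge", "post_surge")),
           sessionEpochs(ss$pre_threat, c("pre_pellet", "post_pellet")))
  epochPhase <- c(pre_surge = "threat", post_surge = "threat",
                  pre_pellet = "pre_threat", post_pellet = "pre_threat")
  pairs <- list()
  for (lb in names(eps)) {
    s <- ss[[epochPhase[[lb]]]]
    isBa <- vapply(s@trains, region, character(1)) == "BA"
    pairs[[lb]] <- pairScreen(s@trains[isBa], s@trains[!isBa],
                              eps[lb], nShuffles = nShuffles,
                              seed = childSeed(seed, paste0("screen_", lb)))
  }
  pairTable <- do.call(rbind, c(pairs, list(make.row.names = FALSE)))
  linkage <- buildLinkage(pairTable, ba, pr$records)
  contrast <- suppressWarnings(stabilityByPairing(linkage, epoch = epoch))
  regression <- tryCatch(stabilityVsPosition(linkage),
                         error = function(e) NULL)
  behavior <- lapply(ss, behaviorMetrics)
  list(placeRecords = pr, baClasses = ba, pairTable = pairTable,
       linkage = linkage, contrast = contrast, regression = regression,
       behavior = behavior)
}

#' Write the pipeline's result tables to a directory
#'
#' Deterministic CSV output (fixed column order, fixed numeric formatting):
#' running the pipeline twice with the same seed yields byte-identical
#' files.
#'
#' @param analysis list from [analyzeCohort()].
#' @param dirPath output directory.
#' @return the directory, invisibly.
#' @export
writeResults <- function(analysis, dirPath) {
  if (!dir.exists(dirPath) &&
      !dir.create(dirPath, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create directory: ", dirPath)
  fmtDf <- function(df) {
    for (nm in names(df)) if (is.numeric(df[[nm]]))
      df[[nm]] <- fmt_num(df[[nm]], 6)
    df
  }
  write_table_stable(fmtDf(analysis$placeRecords$records),
                     file.path(dirPath, "place_cells.csv"))
  write_table_stable(fmtDf(analysis$baClasses),
                     file.path(dirPath, "ba_classes.csv"))
  write_table_stable(fmtDf(analysis$pairTable),
                     file.path(dirPath, "pairs.csv"))
  write_table_stable(fmtDf(analysis$linkage),
                     file.path(dirPath, "linkage.csv"))
  if (!is.null(analysis$contrast))
    write_table_stable(fmtDf(analysis$contrast),
                       file.path(dirPath, "contrast.csv"))
  if (!is.null(analysis$regression))
    write_table_stable(fmtDf(analysis$regression),
                       file.path(dirPath, "regression.csv"))
  invisible(dirPath)
}
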