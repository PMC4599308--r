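scoresFromSh <- function(sh) {
  data.frame(column_index = seq_along(sh) - 1L,
             query_residue_index = seq_along(sh),
             query_aa = "A", n_H = 5L, n_M = 5L,
             entropy_H = 1, entropy_M = 1, sh = sh,
             stringsAsFactors = FALSE)
}

annotationsFromClasses <- function(classes) {
  annotateResidueClasses(data.frame(
    residue_index = seq_along(classes), amino_acid = "A",
    asa = ifelse(classes == "buried", 0, 50),
    bsa = ifelse(classes == "interface", 10, 0),
    stringsAsFactors = FALSE))
}

test_that("the two-state predictor includes the cutoff boundary", {
  sc <- scoresFromSh(c(0.15, 0.2, 0.25))
  expect_equal(predictInterface(sc, 0.2), c(1L, 2L))
  expect_equal(predictInterface(sc, 0), integer(0))
  expect_equal(predictInterface(sc, 1), 1:3)
})

test_that("confusion counts follow the worked large-group arithmetic", {
  # 262 residues: 31 interface, the rest non-interface; 85 predicted of
  # which 21 are true interface sites
  classes <- c(rep("interface", 31), rep("surface", 131),
               rep("buried", 100))
  ann <- annotationsFromClasses(classes)
  predicted <- c(1:21, 32:95)       # 21 interface + 64 others
  k <- confusionCounts(predicted, ann)
  expect_equal(k, c(tp = 21L, fp = 64L, tn = 167L, fn = 10L))

  expect_equal(confusionCounts(integer(0), ann)[c("tp", "fp")],
               c(tp = 0L, fp = 0L))
  perfect <- confusionCounts(1:31, ann)
  expect_equal(perfect[["fp"]], 0L)
  expect_equal(perfect[["fn"]], 0L)
  expect_error(confusionCounts(500L, ann), "outside the annotated")
})

test_that("the surface-only universe drops buried residues", {
  ann <- annotationsFromClasses(c("interface", "surface", "buried",
                                  "buried"))
  k <- confusionCounts(c(1L, 3L), ann, universe = "surface_only")
  expect_equal(sum(k), 2L)          # buried residues leave the universe
  expect_equal(k[["tp"]], 1L)
})

test_that("metrics reproduce the worked recall/FPR/precision numbers", {
  m <- predictionMetrics(c(tp = 21, fp = 64, tn = 167, fn = 10))
  expect_equal(unname(m["recall"]), 21 / 31)
  expect_equal(unname(m["precision"]), 21 / 85)
  expect_equal(unname(m["fpr"]), 64 / 231)
  expect_true(is.na(predictionMetrics(
    c(tp = 0, fp = 0, tn = 5, fn = 0))[["precision"]]))
  expect_true(is.na(predictionMetrics(
    c(tp = 0, fp = 0, tn = 5, fn = 0))[["recall"]]))
})

test_that("prediction equal to the positive set gives recall 1 and FPR 0", {
  set.seed(15)
  classes <- c("interface",
               sample(c("interface", "surface", "buried"), 39, TRUE))
  ann <- annotationsFromClasses(classes)
  pos <- ann$residue_index[ann$position_class == "interface"]
  m <- predictionMetrics(confusionCounts(pos, ann))
  expect_equal(unname(m["recall"]), 1)
  expect_equal(unname(m["fpr"]), 0)
})

test_that("AUC endpoints: perfect separation and all-tied scores", {
  classes <- c(rep("interface", 3), rep("surface", 4))
  ann <- annotationsFromClasses(classes)
  expect_equal(rocAuc(scoresFromSh(c(0.0, 0.1, 0.1, 0.5, 0.6, 0.7, 0.9)),
                      ann), 1)
  expect_equal(rocAuc(scoresFromSh(rep(0.3, 7)), ann), 0.5)
  # degenerate: single class present
  annPos <- annotationsFromClasses(rep("interface", 3))
  expect_true(is.na(rocAuc(scoresFromSh(c(0.1, 0.2, 0.3)), annPos)))
})

test_that("rank-sum AUC equals exhaustive pair counting and trapezoid area", {
  # fixed 6-residue mixed ranking with a tie across classes
  sh6 <- c(0.05, 0.30, 0.30, 0.10, 0.50, 0.90)
  cls6 <- c("interface", "interface", "surface", "surface", "interface",
            "surface")
  ann6 <- annotationsFromClasses(cls6)
  auc6 <- rocAuc(scoresFromSh(sh6), ann6)
  expect_equal(auc6, aucPairCount(sh6, cls6 == "interface"))
  expect_equal(auc6, aucTrapezoid(sh6, cls6 == "interface"))

  set.seed(13)
  for (i in 1:30) {
    n <- sample(5:12, 1)
    sh <- round(stats::runif(n), 2)          # rounding forces ties
    cls <- sample(c("interface", "surface", "buried"), n, TRUE)
    if (length(unique(cls == "interface")) < 2) next
    ann <- annotationsFromClasses(cls)
    auc <- rocAuc(scoresFromSh(sh), ann)
    expect_equal(auc, aucPairCount(sh, cls == "interface"))
    expect_equal(auc, aucTrapezoid(sh, cls == "interface"),
                 tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(14)
  sh <- stats::runif(20)
  cls <- c(rep("interface", 6), rep("surface", 14))
  ann <- annotationsFromClasses(cls)
  a1 <- rocAuc(scoresFromSh(sh), ann)
  a2 <- rocAuc(scoresFromSh(sh^3), ann)          # monotone on [0,1]
  a3 <- rocAuc(scoresFromSh(0.1 + 0.8 * sh), ann)
  expect_equal(a1, a2)
  expect_equal(a1, a3)
})

test_that("group evaluation ties prediction, confusion and AUC together", {
  sim <- simulatePairGroup(simSpec(seed = 8))
  sc <- scoreGroup(sim$alignment)
  rep <- evaluateGroup(sc, sim$annotations, groupId = "g8")
  k <- confusion(rep)
  expect_equal(sum(k), nrow(sim$annotations))
  m <- predictionMetrics(k)
  expect_equal(unname(performance(rep)[c("recall", "fpr", "precision")]),
               unname(m))
  expect_equal(performance(rep)[["auc"]], rocAuc(sc, sim$annotations))
})

test_that("aggregation averages defined AUCs and counts undefined ones", {
  mk <- function(auc, id) new("EvalReport", groupId = id,
    counts = c(tp = 1L, fp = 1L, tn = 1L, fn = 1L), recall = 0.5,
    fpr = 0.5, precision = 0.5, auc = auc, nEvaluated = 4L)
  s <- aggregateReports(list(mk(0.6, "a"), mk(0.8, "b")))
  expect_equal(s$mean_auc, 0.7)
  expect_equal(s$n_undefined_auc, 0L)

  s2 <- aggregateReports(list(mk(0.6, "a"), mk(NA_real_, "b")))
  expect_equal(s2$mean_auc, 0.6)
  expect_equal(s2$n_undefined_auc, 1L)

  cmA <- data.frame(position_class = c("interface", "surface"),
                    n = c(5L, 5L), mean_entropy_H = c(1, 2),
                    mean_sh = c(0.2, 0.4), stringsAsFactors = FALSE)
  cmB <- data.frame(position_class = "interface", n = 5L,
                    mean_entropy_H = 3, mean_sh = 0.4,
                    stringsAsFactors = FALSE)
  s3 <- aggregateReports(list(mk(0.6, "a"), mk(0.8, "b")),
                         classMeans = list(cmA, cmB))
  cm <- s3$class_means
  expect_equal(cm$mean_sh[cm$position_class == "interface"], 0.3)
  expect_equal(cm$n_groups[cm$position_class == "surface"], 1L)
  # aggregated mean AUC is bounded by per-group extremes
  expect_gte(s3$mean_auc, 0.6)
  expect_lte(s3$mean_auc, 0.8)
})

test_that("class-difference t-test matches the pooled-variance formula", {
  a <- c(0.31, 0.35, 0.29, 0.40, 0.33)
  b <- c(0.38, 0.42, 0.36, 0.45, 0.41)
  got <- classDifferenceTest(a, b)
  # direct evaluation of the pooled two-sample formula and t CDF
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
    (length(a) + length(b) - 2)
  tHand <- (mean(a) - mean(b)) /
    sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  pHand <- 2 * stats::pt(-abs(tHand), df = length(a) + length(b) - 2)
  expect_equal(got$statistic, tHand, tolerance = 1e-12)
  expect_equal(got$p.value, pHand, tolerance = 1e-12)

  same <- classDifferenceTest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)

  degen <- classDifferenceTest(c(0, 0, 0), c(1, 1, 1))
  expect_equal(degen$p.value, 0)

  expect_error(classDifferenceTest(1, c(1, 2)), "at least two")
})
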