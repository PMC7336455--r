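test_that("score-group comparison matches a hand/base t-test", {
  resp <- c(-42, -35, -50, -28, -39, -44)
  non <- c(10, 22, 5, 18, 30, 12)
  scores <- setNames(c(resp, non), paste0("p", 1:12))
  out <- binaryOutcome(names(scores), rep(c(1, 0), each = 6))
  res <- compareScoreGroups(scores, out)
  or <- t.test(resp, non, var.equal = TRUE)
  expect_equal(res$statistic, unname(or$statistic), tolerance = 1e-12)
  expect_equal(res$p_value, or$p.value, tolerance = 1e-12)
  expect_equal(unname(res$group_means), c(mean(resp), mean(non)))

  # identical distributions -> p ~ 1; full separation -> tiny p
  same <- setNames(rep(c(1, 2, 3), 4), paste0("q", 1:12))
  outS <- binaryOutcome(names(same), rep(c(1, 0), 6))
  expect_gt(compareScoreGroups(same, outS)$p_value, 0.5)
  expect_lt(res$p_value, 1e-6)

  expect_error(compareScoreGroups(scores,
                                  binaryOutcome(names(scores),
                                                c(1, rep(0, 11)))),
               "at least 2")
})

test_that("rank AUC equals the exhaustive pair-count oracle", {
  scores <- setNames(c(1, 2, 3, 4), paste0("s", 1:4))
  out1 <- binaryOutcome(names(scores), c(1, 1, 0, 0))
  expect_equal(aucScore(scores, out1)$auc, 1)
  out2 <- binaryOutcome(names(scores), c(1, 0, 1, 0))
  expect_equal(aucScore(scores, out2)$auc, 0.75)

  set.seed(60)
  for (rep in 1:25) {
    n <- sample(5:12, 1)
    sc <- setNames(round(rnorm(n), 1), paste0("s", 1:n))  # rounded -> ties
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    out <- binaryOutcome(names(sc), y)
    expect_equal(aucScore(sc, out)$auc, aucPairOracle(sc, y),
                 tolerance = 1e-12)
    # orientation flip complements
    expect_equal(aucScore(sc, out)$auc +
                 aucScore(-sc, out)$auc, 1, tolerance = 1e-12)
    # invariance under strictly monotone transforms
    expect_equal(aucScore(sc, out)$auc,
                 aucScore(exp(sc / 2) + 5, out)$auc, tolerance = 1e-12)
  }
})

test_that("AUC agrees with the pROC reference implementation", {
  set.seed(71)
  sc <- setNames(rnorm(40), paste0("s", 1:40))
  y <- rbinom(40, 1, 0.5); y[1:2] <- c(0, 1)
  out <- binaryOutcome(names(sc), y)
  ours <- aucScore(sc, out, responderLow = TRUE)$auc
  ref <- suppressMessages(
    as.numeric(pROC::auc(pROC::roc(y, as.numeric(sc),
                                   direction = ">", quiet = TRUE))))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("the bootstrap CI is seeded, covers the point estimate, and degenerates sanely", {
  set.seed(83)
  sc <- setNames(c(rnorm(30, -20, 10), rnorm(30, 15, 10)), paste0("s", 1:60))
  out <- binaryOutcome(names(sc), rep(c(1, 0), each = 30))
  a1 <- aucScore(sc, out, ci = TRUE, seed = 7, nBoot = 500)
  a2 <- aucScore(sc, out, ci = TRUE, seed = 7, nBoot = 500)
  expect_identical(a1, a2)
  expect_lte(a1$ci_lower, a1$auc)
  expect_gte(a1$ci_upper, a1$auc)
  expect_gt(a1$ci_lower, 0.5)  # clear signal excludes chance
  expect_error(aucScore(sc, out, ci = TRUE), "seed")
})

test_that("median split puts ties at the median into the low stratum", {
  sc <- setNames(as.numeric(1:6), paste0("s", 1:6))
  st <- stratifyScores(sc)
  expect_setequal(names(st)[st == "low"], paste0("s", 1:3))
  expect_setequal(names(st)[st == "high"], paste0("s", 4:6))

  tied <- setNames(c(1, 2, 4, 4, 4, 6, 7), paste0("t", 1:7))  # median = 4
  stT <- stratifyScores(tied)
  expect_setequal(names(stT)[stT == "low"], paste0("t", 1:5))
  expect_setequal(names(stT)[stT == "high"], paste0("t", 6:7))

  expect_error(stratifyScores(setNames(rep(2, 5), paste0("u", 1:5))),
               "identical")
})

test_that("tertiles balance 1..9 into three ordered strata monotone in score", {
  sc <- setNames(as.numeric(1:9), paste0("s", 1:9))
  st <- stratifyScores(sc, mode = "tertiles")
  expect_equal(unname(table(st)), c(3L, 3L, 3L), ignore_attr = TRUE)
  expect_true(all(sc[st == "low"] < sc[st == "intermediate"]))
  expect_true(all(sc[st == "intermediate"] < sc[st == "high"]))
  # partition: disjoint and covering
  expect_identical(sort(names(st)), sort(names(sc)))
})

test_that("log-rank matches the manual hypergeometric-increment oracle", {
  # 8 subjects, two strata, fixed times and events
  time <- c(2, 4, 5, 7, 8, 10, 12, 15)
  event <- c(1, 1, 0, 1, 1, 1, 0, 1)
  grp <- factor(c("low", "high", "low", "high", "low", "high", "low",
                  "high"), levels = c("low", "high"), ordered = TRUE)
  names(grp) <- paste0("s", 1:8)
  out <- survivalOutcome(names(grp), time, event)
  res <- survivalCompare(grp, out)
  or <- logrankOracle(time, event, as.character(grp))
  expect_equal(res$logrank_chisq, or$chisq, tolerance = 1e-10)
  expect_equal(res$logrank_p, or$p, tolerance = 1e-10)
  # with two strata the trend test reduces to the log-rank test
  expect_equal(res$trend_p, res$logrank_p, tolerance = 1e-10)
})

test_that("survival comparison: null and dominance regimes behave", {
  ids <- paste0("s", 1:16)
  st <- setNames(factor(rep(c("low", "high"), 8),
                        levels = c("low", "high"), ordered = TRUE), ids)
  # identical event times in both strata -> p ~ 1
  outNull <- survivalOutcome(ids, rep(c(3, 6, 9, 12), each = 4),
                             rep(1, 16))
  expect_gt(survivalCompare(st, outNull)$logrank_p, 0.9)

  # all low-stratum events precede high-stratum events
  stD <- setNames(factor(rep(c("low", "high"), each = 8),
                         levels = c("low", "high"), ordered = TRUE), ids)
  outDom <- survivalOutcome(ids, c(1:8 / 2, 20 + 1:8), rep(1, 16))
  resD <- survivalCompare(stD, outDom)
  expect_lt(resD$logrank_p, 1e-4)
  expect_lt(resD$median_survival["low"], resD$median_survival["high"])

  expect_error(survivalCompare(st, survivalOutcome(ids, rep(5, 16),
                                                   rep(0, 16))),
               "no events")
})

test_that("validateCohort dispatches on outcome kind with consistent fields", {
  sim <- smallSim(seed = 30)
  fit <- trainGem(sim$pdx, sim$activity, seed = 8)
  sc <- predictScores(fit, sim$patientVal)
  vb <- validateCohort(sc, sim$outcomeBinary, label = "bin", seed = 1,
                       nBoot = 200)
  expect_s4_class(vb, "ValidationReport")
  expect_identical(vb@outcomeKind, "binary_response")
  expect_false(is.na(vb@auc))
  expect_length(vb@survivalTests, 0)

  vs <- validateCohort(sc, sim$outcomeSurvival, label = "surv",
                       strata = "tertiles")
  expect_identical(vs@outcomeKind, "survival")
  expect_true(is.na(vs@auc))
  expect_true(all(c("logrank_p", "trend_p", "median_survival", "curves")
                  %in% names(vs@survivalTests)))

  f <- withr::local_tempfile(fileext = ".json")
  writeValidationReport(vb, f)
  parsed <- jsonlite::read_json(f)
  expect_equal(parsed$auc, vb@auc, tolerance = 1e-12)
})

test_that("group-test p and AUC point the same way on planted signal", {
  sim <- simulateStudy(simConfig(nFeatures = 200, nSensitivity = 30,
                                 nConcordant = 20, nPdx = 24,
                                 nPatientsVal = 120, moduleSize = 20,
                                 seed = 91))
  bm <- discoverBiomarkers(sim$pdx, sim$activity)
  cc <- runCCEA(sim$pdx, sim$patientRef, bm)
  fit <- trainGem(sim$pdx, sim$activity, features = cc, seed = 13)
  sc <- predictScores(fit, sim$patientVal)
  tt <- compareScoreGroups(sc, sim$outcomeBinary)
  a <- aucScore(sc, sim$outcomeBinary, ci = TRUE, seed = 3, nBoot = 500)
  expect_lt(tt$p_value, 0.05)
  expect_gt(a$ci_lower, 0.5)

  cox <- coxScoreAssociation(sc, sim$outcomeSurvival)
  expect_gt(cox$hr, 1)  # higher score (growth) -> higher hazard
})
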