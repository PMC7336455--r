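test_that("pairwise correlations match a brute-force double loop", {
  set.seed(31)
  mat <- toyExpr(rnorm(24), 4, 6)
  C <- pairwiseCorrelations(mat)
  for (i in 1:4) for (j in 1:4)
    expect_equal(C[i, j], cor(mat[i, ], mat[j, ]), tolerance = 1e-12)
  expect_equal(diag(C), rep(1, 4), ignore_attr = TRUE)
  expect_identical(C, t(C))
})

test_that("pairwise correlations: identical, anti-correlated and constant rows", {
  base <- c(1, 3, 2, 5, 4, 6)
  mat <- rbind(a = base, b = base, c = -base, d = rep(7, 6))
  colnames(mat) <- paste0("s", 1:6)
  C <- pairwiseCorrelations(mat)
  expect_equal(C["a", "b"], 1)
  expect_equal(C["a", "c"], -1)
  expect_identical(attr(C, "degenerate"), "d")
  expect_equal(unname(C["d", "a"]), 0)
  expect_error(pairwiseCorrelations(mat[, 1:2]), "3 samples")
})

test_that("ccec equals the independently coded moment-form Lin CCC", {
  set.seed(101)
  worst <- 0
  for (rep in 1:1000) {
    m <- sample(4:49, 1)            # n features = m + 1, n in 5..50
    u <- runif(m, -1, 1)
    v <- runif(m, -1, 1)
    pair <- embedCorrPair(u, v)
    worst <- max(worst, abs(ccec(pair$U, pair$V, 1) - linCCCOracle(u, v)))
  }
  expect_lt(worst, 1e-12)
})

test_that("ccec analytic limits: self-concordance, symmetry, precision bound", {
  set.seed(55)
  for (rep in 1:50) {
    m <- sample(4:20, 1)
    u <- runif(m, -1, 1); v <- runif(m, -1, 1)
    pair <- embedCorrPair(u, v)
    expect_equal(ccec(pair$U, pair$U, 1), 1)                    # c(U,U) = 1
    expect_equal(ccec(pair$U, pair$V, 1), ccec(pair$V, pair$U, 1),
                 tolerance = 1e-14)                              # symmetry
    expect_lte(abs(ccec(pair$U, pair$V, 1)), abs(cor(u, v)) + 1e-14)
  }
})

test_that("ccec is invariant to a joint permutation of the partner features", {
  set.seed(77)
  u <- runif(9, -1, 1); v <- runif(9, -1, 1)
  pair <- embedCorrPair(u, v)
  perm <- c(1, sample(2:10))        # keep g in place, permute partners
  expect_equal(ccec(pair$U[perm, perm], pair$V[perm, perm], 1),
               ccec(pair$U, pair$V, 1), tolerance = 1e-14)
})

test_that("a reflected partner vector yields a negative ccec", {
  set.seed(12)
  u <- runif(10, -0.9, 0.9)
  v <- 2 * mean(u) - u              # reflection about the u mean
  pair <- embedCorrPair(u, v)
  cc <- ccec(pair$U, pair$V, 1)
  expect_lt(cc, 0)
  expect_equal(cc, linCCCOracle(u, v), tolerance = 1e-14)
})

test_that("ccec degenerate and error cases", {
  u <- rep(0.5, 5); v <- rep(0.5, 5)
  pair <- embedCorrPair(u, v)
  expect_equal(ccec(pair$U, pair$V, 1), 0)   # 0/0 convention
  expect_error(ccec(diag(2), diag(2), 1), "at least 3")
})

test_that("ccec p-value has the stated closed form and monotonicities", {
  expect_equal(ccecPvalue(0, 10), 1)
  # 2*(1 - Phi(atanh(c) * sqrt(m - 2))), written in the numerically
  # stable lower-tail form
  expect_equal(ccecPvalue(0.5, 103),
               2 * pnorm(atanh(0.5) * sqrt(101), lower.tail = FALSE),
               tolerance = 1e-14)
  expect_equal(ccecPvalue(1, 10), 0)
  cs <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(ccecPvalue(cs, 20)) < 0))       # decreasing in |c|
  ms <- c(5, 10, 20, 50, 200)
  expect_true(all(diff(ccecPvalue(0.4, ms)) < 0))      # decreasing in m
  expect_error(ccecPvalue(0.2, 2), "m >= 3")
})

test_that("self-cohort CCEA gives perfect concordance and full selection", {
  sim <- smallSim(seed = 8)
  bm <- discoverBiomarkers(sim$pdx, sim$activity)
  cc <- runCCEA(sim$pdx, sim$pdx, bm)
  expect_true(all(abs(cc$ccec[!cc$degenerate] - 1) < 1e-12))
  expect_true(all(cc$selected[!cc$degenerate]))
})

test_that("CCEA enriches planted concordant features and nests in min_ccec", {
  sim <- smallSim(seed = 14)
  bm <- discoverBiomarkers(sim$pdx, sim$activity)
  cc0 <- runCCEA(sim$pdx, sim$patientRef, bm)
  conc <- sim$truth$concordant_feature_ids
  sel <- selectedFeatures(cc0)
  inSel <- sum(sel %in% conc); outSel <- sum(!sel %in% conc)
  notSel <- setdiff(featureIds(cc0), sel)
  inNot <- sum(notSel %in% conc); outNot <- sum(!notSel %in% conc)
  odds <- (inSel + 0.5) / (outSel + 0.5) * (outNot + 0.5) / (inNot + 0.5)
  expect_gt(odds, 4)

  cc3 <- runCCEA(sim$pdx, sim$patientRef, bm, minCcec = 0.3)
  expect_true(all(selectedFeatures(cc3) %in% sel))   # threshold nesting
  expect_true(all(cc3$ccec[cc3$selected] > 0.3))

  ccStrict <- runCCEA(sim$pdx, sim$patientRef, bm, fdr = 0.01)
  expect_true(all(selectedFeatures(ccStrict) %in% sel))  # fdr nesting
})

test_that("CCEA rejects tiny candidate sets and never selects degenerate features", {
  sim <- smallSim(seed = 2)
  expect_error(runCCEA(sim$pdx, sim$patientRef, c("g00001", "g00002")),
               "at least 4")
  # plant a constant feature among the candidates
  pdxM <- assayMat(sim$pdx); refM <- assayMat(sim$patientRef)
  pdxM["g00005", ] <- 3
  cc <- runCCEA(pdxM, refM, c("g00001", "g00002", "g00003", "g00005"))
  row <- as.data.frame(cc)[cc$feature_id == "g00005", ]
  expect_true(row$degenerate)
  expect_false(row$selected)
  expect_equal(row$ccec, 0)
})

test_that("permutation p-values broadly agree with the z-transform on signal", {
  sim <- smallSim(seed = 4)
  bm <- discoverBiomarkers(sim$pdx, sim$activity)
  cz <- runCCEA(sim$pdx, sim$patientRef, bm)
  cp <- runCCEA(sim$pdx, sim$patientRef, bm, pMethod = "permutation",
                nPerm = 200, seed = 99)
  expect_identical(cz$ccec, cp$ccec)
  # strongly concordant features are significant under both nulls
  strong <- cz$ccec > 0.6 & !cz$degenerate
  if (any(strong)) expect_true(all(cp$p_value[strong] < 0.05))
})
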