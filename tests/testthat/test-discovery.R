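test_that("activity sign split: shrinkage strict, zero goes to grown", {
  act <- setNames(c(-10, -0.5, 3, 40), paste0("s", 1:4))
  sp <- splitByActivity(act)
  expect_setequal(sp$shrunken, c("s1", "s2"))
  expect_setequal(sp$grown, c("s3", "s4"))

  sp <- splitByActivity(setNames(c(5, 10), c("a", "b")))
  expect_length(sp$shrunken, 0)
  expect_length(sp$grown, 2)

  sp <- splitByActivity(setNames(c(0, -1, 2, 3), paste0("s", 1:4)))
  expect_true("s1" %in% sp$grown)
})

test_that("test-method rule: small groups fall back to correlation", {
  expect_identical(chooseTestMethod(3, 10), "t_test")
  expect_identical(chooseTestMethod(2, 4), "t_test")   # default minGroupSize 2
  expect_identical(chooseTestMethod(0, 13), "correlation")
  expect_identical(chooseTestMethod(1, 12), "correlation")
  expect_identical(chooseTestMethod(2, 4, minGroupSize = 3), "correlation")
  expect_error(chooseTestMethod(1, 2), "at least 4")
})

test_that("vectorized t-test matches base t.test (pooled and Welch)", {
  A <- c(2.1, 2.9, 2.5); B <- c(3.9, 4.1, 4.3, 3.7)
  mat <- rbind(g1 = c(A, B), g2 = rnorm(7, 5))
  colnames(mat) <- paste0("s", 1:7)
  shr <- paste0("s", 1:3); gro <- paste0("s", 4:7)

  res <- tTestPerFeature(mat, shr, gro)
  or <- t.test(B, A, var.equal = TRUE)  # oriented grown - shrunken, 5 df
  expect_equal(res$statistic[1], unname(or$statistic), tolerance = 1e-12)
  expect_equal(res$p_value[1], or$p.value, tolerance = 1e-12)

  resW <- tTestPerFeature(mat, shr, gro, varEqual = FALSE)
  orW <- t.test(B, A, var.equal = FALSE)
  expect_equal(resW$statistic[1], unname(orW$statistic), tolerance = 1e-12)
  expect_equal(resW$p_value[1], orW$p.value, tolerance = 1e-12)
})

test_that("degenerate t-test features: identical groups and zero-variance separation", {
  mat <- rbind(same = rep(1:3, 2), sep = c(0, 0, 0, 5, 5, 5))
  mat["same", ] <- c(1, 2, 3, 1, 2, 3)
  colnames(mat) <- paste0("s", 1:6)
  res <- tTestPerFeature(mat, paste0("s", 1:3), paste0("s", 4:6))
  expect_equal(res$statistic[res$feature_id == "same"], 0)
  expect_equal(res$p_value[res$feature_id == "same"], 1)
  sep <- res[res$feature_id == "sep", ]
  expect_true(sep$degenerate)
  expect_equal(sep$p_value, 0)
  expect_true(is.infinite(sep$statistic))
})

test_that("per-feature correlation matches cor.test and flags constants", {
  set.seed(42)
  act <- setNames(rnorm(8, 0, 25), paste0("s", 1:8))
  mat <- rbind(self = act, anti = -rank(act), flat = rep(2, 8),
               noise = rnorm(8))
  colnames(mat) <- names(act)

  pe <- correlationPerFeature(mat, act, flavor = "pearson")
  expect_equal(pe$statistic[pe$feature_id == "self"], 1)
  sp <- correlationPerFeature(mat, act, flavor = "spearman")
  expect_equal(sp$statistic[sp$feature_id == "anti"], -1)
  expect_equal(sp$p_value[sp$feature_id == "anti"], 0)

  orc <- cor.test(mat["noise", ], act, method = "spearman")
  noise <- sp[sp$feature_id == "noise", ]
  expect_equal(noise$statistic, unname(orc$estimate), tolerance = 1e-12)
  # two-sided t approximation with n - 2 df
  tor <- noise$statistic * sqrt(6 / (1 - noise$statistic^2))
  expect_equal(noise$p_value, 2 * pt(-abs(tor), 6), tolerance = 1e-12)

  flat <- sp[sp$feature_id == "flat", ]
  expect_true(flat$degenerate)
  expect_equal(flat$p_value, 1)
})

test_that("discovery selects a planted perfect signal with the smallest q", {
  set.seed(7)
  n <- 12
  mat <- matrix(rnorm(40 * n), 40, n,
                dimnames = list(sprintf("g%02d", 1:40), paste0("s", 1:n)))
  act <- setNames(rnorm(n, 0, 30), colnames(mat))
  mat["g05", ] <- act / 15
  res <- discoverBiomarkers(mat, act)
  expect_s4_class(res, "BiomarkerResults")
  expect_identical(featureIds(res), rownames(mat))  # input order kept
  expect_true("g05" %in% selectedFeatures(res))
  expect_equal(res$feature_id[which.min(res$q_value)], "g05")
  expect_equal(res$q_value, p.adjust(res$p_value, "BH"))
})

test_that("nominal fallback selects exactly the p < 0.05 features when FDR is empty", {
  set.seed(1204)
  n <- 10
  mat <- matrix(rnorm(20 * n), 20, n,
                dimnames = list(sprintf("g%02d", 1:20), paste0("s", 1:n)))
  act <- setNames(rnorm(n, 0, 20), colnames(mat))
  res <- discoverBiomarkers(mat, act)
  expect_false(any(res$q_value < 0.05))  # null panel: FDR empty
  expect_identical(alphaMode(res), "nominal")
  expect_setequal(selectedFeatures(res),
                  res$feature_id[res$p_value < 0.05])
  # fallback is a no-op when disabled
  res2 <- discoverBiomarkers(mat, act, nominalFallback = FALSE)
  expect_identical(alphaMode(res2), "fdr")
  expect_length(selectedFeatures(res2), 0)
})

test_that("t-test and correlation branches agree in direction on monotone data", {
  set.seed(9)
  n <- 14
  act <- setNames(seq(-40, 40, length.out = n) + rnorm(n, 0, 2),
                  paste0("s", 1:n))
  mat <- rbind(up = as.numeric(act) / 10 + rnorm(n, 0, 0.3),
               down = -as.numeric(act) / 10 + rnorm(n, 0, 0.3))
  colnames(mat) <- names(act)
  tt <- discoverBiomarkers(mat, act, method = "t_test")
  sp <- discoverBiomarkers(mat, act, method = "spearman")
  expect_identical(sign(tt$statistic), sign(sp$statistic))
  expect_equal(unname(tt$direction[tt$feature_id == "up"]), 1)
  expect_equal(unname(tt$direction[tt$feature_id == "down"]), -1)
})

test_that("BH q-values are invariant to feature order", {
  set.seed(5)
  mat <- matrix(rnorm(30 * 10), 30, 10,
                dimnames = list(sprintf("g%02d", 1:30), paste0("s", 1:10)))
  act <- setNames(rnorm(10, 0, 10), colnames(mat))
  r1 <- discoverBiomarkers(mat, act)
  perm <- sample(nrow(mat))
  r2 <- discoverBiomarkers(mat[perm, ], act)
  m <- match(r1$feature_id, r2$feature_id)
  expect_equal(r1$q_value, r2$q_value[m], tolerance = 1e-14)
  expect_true(all(r1$q_value >= 0 & r1$q_value <= 1))
})

test_that("biomarker tables survive a CSV round trip", {
  sim <- smallSim(seed = 21)
  res <- discoverBiomarkers(sim$pdx, sim$activity)
  f <- withr::local_tempfile(fileext = ".csv")
  writeBiomarkerTable(res, f)
  back <- readBiomarkerTable(f)
  expect_identical(alphaMode(back), alphaMode(res))
  expect_identical(selectedFeatures(back), selectedFeatures(res))
  expect_equal(back$q_value, res$q_value, tolerance = 1e-6)
})
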