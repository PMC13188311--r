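test_that("PPV and NPV are the exact ratios, NA when undefined", {
  expect_equal(ppvNpv(confusionCounts(TP = 1, FP = 0, TN = 1, FN = 0)),
               c(PPV = 1, NPV = 1))
  expect_equal(ppvNpv(confusionCounts(TP = 3, FP = 1, TN = 4, FN = 1)),
               c(PPV = 0.75, NPV = 0.8))
  expect_equal(ppvNpv(confusionCounts(TP = 0, FP = 5, TN = 2, FN = 3))[["PPV"]], 0)
  pn <- ppvNpv(confusionCounts(TP = 0, FP = 0, TN = 2, FN = 1))
  expect_true(is.na(pn[["PPV"]]))
  expect_equal(pn[["NPV"]], 2 / 3)
  pn2 <- ppvNpv(confusionCounts(TP = 4, FP = 1, TN = 0, FN = 0))
  expect_true(is.na(pn2[["NPV"]]))
})

test_that("pairs are tallied against TABS truth per the fixed orientation", {
  labels <- c(a = "1-1", b = "1-1", c = "2-1")
  pairs <- data.frame(i = c("a", "a", "b"), j = c("b", "c", "c"),
                      value = c(0.99, 0.99, 0.5))
  cc <- confusionAtThreshold(pairs, labels, 0.97, "similarity")
  expect_equal(unclass(cc)[c("TP", "FP", "TN", "FN")],
               c(TP = 1L, FP = 1L, TN = 1L, FN = 0L))
  # single-pair cases forced by the definitions
  one <- function(lab_j, val) {
    confusionAtThreshold(data.frame(i = "a", j = "b", value = val),
                         c(a = "1", b = lab_j), 0.97, "similarity")
  }
  expect_equal(sum(one("1", 0.99) * c(1, 0, 0, 0)), 1)  # TP
  expect_equal(sum(one("1", 0.50) * c(0, 0, 0, 1)), 1)  # FN
  expect_equal(sum(one("2", 0.99) * c(0, 1, 0, 0)), 1)  # FP
  # distance metrics invert the prediction side
  dcc <- confusionAtThreshold(data.frame(i = "a", j = "b", value = 0.3),
                              c(a = "1", b = "1"), 0.5, "distance")
  expect_equal(dcc[["TP"]], 1L)
  expect_error(confusionAtThreshold(pairs, labels[1:2], 0.9, "similarity"),
               "without TABS labels")
})

test_that("threshold sweeps are monotone and conserve pair counts", {
  set.seed(77)
  sys <- TabsSystem(c(3L, 3L), SymmetryGroup(list(c(2L, 1L)), nBits = 2))
  ens <- syntheticEnsemble(sys, 24)
  grid <- seq(0, 1, length.out = 41)
  sw <- sweepThresholds(ens$scores, ens$labels, grid, "similarity")
  expect_equal(nrow(sw), 41)
  npairs <- nrow(ens$scores)
  expect_true(all(sw$TP + sw$FP + sw$TN + sw$FN == npairs))
  # predicted-"same" count shrinks as a similarity threshold rises
  expect_true(all(diff(sw$TP + sw$FP) <= 0))
  expect_true(all(diff(sw$TN + sw$FN) >= 0))
  # a threshold below all similarities predicts everything "same"
  sw0 <- sweepThresholds(ens$scores, ens$labels, -1, "similarity")
  expect_equal(sw0$TN + sw0$FN, 0)
  expect_true(is.na(sw0$NPV))
})

test_that("an indicator metric of TABS equality gives perfect agreement", {
  set.seed(78)
  sys <- randomTabsSystem(nBitsRange = c(2L, 4L),
                          multiplicityRange = c(2L, 3L), nGenerators = 1)
  ens <- syntheticEnsemble(sys, 20)
  ind <- ens$scores
  same <- ens$labels[ind$i] == ens$labels[ind$j]
  ind$value <- as.numeric(same)
  sw <- sweepThresholds(ind, ens$labels, 0.5, "similarity")
  if (any(same) && any(!same)) {
    expect_equal(sw$PPV, 1)
    expect_equal(sw$NPV, 1)
  }
})

test_that("optimal threshold maximizes min(PPV, NPV) with stated ties", {
  tab <- data.frame(threshold = c(0.2, 0.5, 0.8),
                    PPV = c(0.6, 0.9, 0.9), NPV = c(0.8, 1.0, 0.7))
  expect_equal(optimalThreshold(tab, "similarity"), 0.5)
  # ties break toward the larger threshold for similarity ...
  tie <- data.frame(threshold = c(0.4, 0.6), PPV = c(1, 1), NPV = c(1, 1))
  expect_equal(optimalThreshold(tie, "similarity"), 0.6)
  # ... and the smaller one for distances
  expect_equal(optimalThreshold(tie, "distance"), 0.4)
  # criterion options
  tab2 <- data.frame(threshold = 1:2, PPV = c(0.9, 0.7), NPV = c(0.5, 0.9))
  expect_equal(optimalThreshold(tab2, "similarity", "min"), 2)
  expect_equal(optimalThreshold(tab2, "similarity", "product"), 2)
  expect_equal(optimalThreshold(tab2, "similarity", "fixed-npv"), 2)
  und <- data.frame(threshold = 1, PPV = NA_real_, NPV = 0.5)
  expect_error(optimalThreshold(und, "similarity"), "no threshold")
})

test_that("flexibility categories use the 500 / 10,000 boundaries", {
  expect_equal(flexibilityCategory(1), "low")
  expect_equal(flexibilityCategory(499), "low")
  expect_equal(flexibilityCategory(500), "medium")
  expect_equal(flexibilityCategory(9999), "medium")
  expect_equal(flexibilityCategory(10000), "high")
  expect_equal(flexibilityCategory(bigInteger("221073919720733357899776")),
               "high")
  expect_error(flexibilityCategory(0), ">= 1")
})

test_that("pair-score CSV adapter reads both column dialects", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(conf_i = "a", conf_j = "b", value = 0.5), path,
            row.names = FALSE)
  df <- readPairScores(path)
  expect_identical(names(df), c("i", "j", "value"))
  write.csv(data.frame(i = "a", j = "b", value = 0.5), path,
            row.names = FALSE)
  expect_equal(readPairScores(path)$value, 0.5)
})
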