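test_that("alignment precision/recall/F1 count bipartite edges", {
  expect_equal(alignmentPRF("MMXY", "MMXY"),
               c(precision = 1, recall = 1, f1 = 1))
  # disjoint edge sets
  expect_equal(alignmentPRF("MXY", "XYM")[["f1"]], 0)
  # 4 predicted, 4 true, 2 shared
  pred <- "MMMMXY"   # edges (1,1) (2,2) (3,3) (4,4), consumes 5x5
  truth <- "MMXMMY"  # edges (1,1) (2,2) (4,3) (5,4), consumes 5x5
  pr <- alignmentPRF(pred, truth)
  expect_equal(unname(pr["precision"]), 2 / 4)
  expect_equal(unname(pr["recall"]), 2 / 4)
  expect_equal(unname(pr["f1"]), 0.5)
  # precision and recall swap under argument exchange
  pr2 <- alignmentPRF(truth, pred)
  expect_equal(unname(pr["precision"]), unname(pr2["recall"]))
  expect_equal(unname(pr["recall"]), unname(pr2["precision"]))
  expect_error(alignmentPRF("MM", "MMM"), "different sequence lengths")
})

test_that("retrieval sensitivity counts label overlap in the top n", {
  hits <- data.frame(
    query_id = rep(c("q1", "q2", "q3", "q4"), each = 2),
    hit_id = c("a", "b", "a", "c", "b", "c", "c", "b"),
    rank = rep(1:2, 4))
  ann <- list(q1 = "F1", q2 = "F1", q3 = "F2", q4 = "F3",
              a = "F1", b = "F2", c = c("F1", "F3"))
  # q1 -> a (F1) yes; q2 -> a yes; q3 -> b (F2) yes; q4 -> c (F3) yes
  expect_equal(retrievalSensitivity(hits, ann, n = 1), 100)
  ann$q4 <- "F9"
  expect_equal(retrievalSensitivity(hits, ann, n = 2), 75)
  expect_error(retrievalSensitivity(hits, ann, n = 3), "fewer than n")
  expect_error(retrievalSensitivity(hits, ann[-1], n = 1), "unannotated")
})

test_that("average precision matches an independent reference", {
  # values computed with scikit-learn's average_precision_score
  expect_equal(averagePrecision(c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4, 0.3, 0.2),
                                c(1, 0, 1, 1, 0, 0, 1, 0)),
               0.7470238095238095)
  expect_equal(averagePrecision(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)),
               0.8333333333333333)
  expect_equal(averagePrecision(c(5, 4, 3), c(1, 1, 1)), 1)
})

test_that("triplet AUPR separates separated blobs and is chance-level on noise", {
  gl <- generateLabeledVectors(n_classes = 4, per_class = 25, d = 12,
                               separation = 4, seed = 2)
  expect_equal(tripletAUPR(gl$vectors, gl$labels, 800, seed = 1), 1,
               tolerance = 0.01)
  set.seed(3)
  V <- matrix(rnorm(200 * 8), 200, 8)
  lab <- sample(5, 200, replace = TRUE)
  aupr <- tripletAUPR(V, lab, 2000, seed = 4)
  expect_gt(aupr, 0.45); expect_lt(aupr, 0.55)
  # determinism under seed
  expect_identical(tripletAUPR(V, lab, 500, seed = 9),
                   tripletAUPR(V, lab, 500, seed = 9))
  expect_error(tripletAUPR(V[1:3, ], c("a", "b", "c"), 10, seed = 1),
               "impossible")
})

test_that("adjusted mutual information matches an independent reference", {
  # value computed with scikit-learn's adjusted_mutual_info_score
  expect_equal(adjustedMutualInformation(c(1, 1, 1, 2, 2, 3, 3, 3, 3, 2),
                                         c(1, 1, 2, 2, 2, 3, 3, 1, 3, 2)),
               0.47728999000145694, tolerance = 1e-12)
  # invariant to label renaming; 1 for identical partitions
  expect_equal(adjustedMutualInformation(c(1, 1, 2, 2, 3, 3),
                                         c(3, 3, 1, 1, 2, 2)), 1)
  set.seed(5)
  a <- sample(4, 400, replace = TRUE)
  b <- sample(4, 400, replace = TRUE)
  expect_lt(abs(adjustedMutualInformation(a, b)), 0.05)
})

test_that("cluster-adjusted MI separates blobs and nulls shuffle", {
  gl <- generateLabeledVectors(n_classes = 5, per_class = 30, d = 16,
                               separation = 3, seed = 7)
  expect_gte(clusterAdjustedMI(gl$vectors, gl$labels, 5, seed = 1), 0.95)
  set.seed(8)
  V <- matrix(rnorm(500 * 8), 500, 8)
  lab <- sample(5, 500, replace = TRUE)
  expect_lt(abs(clusterAdjustedMI(V, lab, 5, seed = 2)), 0.05)
  expect_error(clusterAdjustedMI(matrix(1, 20, 4), rep(1:4, 5), 4),
               "degenerate")
})
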