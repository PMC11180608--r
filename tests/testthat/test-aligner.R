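test_that("cross-entropy alignment loss matches hand computation", {
  # perfect binary prediction: loss at the clamp floor
  estar <- matrix(c(1, 0, 0, 1), 2, 2)
  expect_lt(alignmentLoss(estar, estar), 1e-10)
  # maximal-entropy prediction: log 2 per cell
  expect_equal(alignmentLoss(estar, matrix(0.5, 2, 2)), log(2))
  expect_equal(alignmentLoss(matrix(c(1, 0, 0, 0), 2, 2),
                             matrix(0.5, 2, 2)), log(2))
  # one confident match, others near zero
  e <- matrix(0.1, 2, 2); e[1, 1] <- 0.9
  es <- matrix(0, 2, 2); es[1, 1] <- 1
  expect_equal(alignmentLoss(es, e), -(log(0.9) + 3 * log(0.9)) / 4)
  # sum reduction is cells times the mean
  expect_equal(alignmentLoss(es, e, reduction = "sum"),
               4 * alignmentLoss(es, e))
  expect_error(alignmentLoss(matrix(0, 2, 2), matrix(0.5, 2, 3)),
               "shape mismatch")
})

test_that("loss gradient w.r.t. e matches finite differences", {
  set.seed(3)
  e <- matrix(runif(12, 0.05, 0.95), 3, 4)
  estar <- groundTruthMatrix("MMMY", 3, 4)
  g <- embedalign:::.alignment_loss_grad(estar, e)
  h <- 1e-6
  for (k in sample(12, 6)) {
    ep <- e; ep[k] <- ep[k] + h
    em <- e; em[k] <- em[k] - h
    fd <- (alignmentLoss(estar, ep) - alignmentLoss(estar, em)) / (2 * h)
    expect_equal(g[k], fd, tolerance = 1e-5)
  }
})

test_that("ground-truth matrices respect the path invariants", {
  m <- groundTruthMatrix("MXMYM")
  expect_equal(dim(m), c(4L, 4L))
  expect_true(all(rowSums(m) <= 1) && all(colSums(m) <= 1))
  expect_equal(sum(m), 3)
  expect_error(groundTruthMatrix("MM", p = 3, q = 2), "consumes")
  expect_error(alignmentPath("MZ"), "invalid state")
})

test_that("training filters use the exact printed boundaries", {
  recs <- data.frame(
    states = c(paste0(strrep("M", 5), strrep("X", 11), strrep("M", 5)),
               paste0(strrep("M", 5), strrep("X", 10), strrep("M", 5)),
               strrep("M", 12),
               paste0(strrep("M", 3), strrep("X", 6), strrep("Y", 6),
                      strrep("M", 3))),
    tm = c(0.9, 0.60, 0.59, 0.95))
  fl <- filterTrainingAlignments(recs)
  expect_equal(unname(fl$report["excluded_gap_run"]), 1L)  # the 11-run only
  expect_equal(unname(fl$report["excluded_low_tm"]), 1L)   # tm = 0.59 only
  # mixed X/Y runs of 6+6 do not form a 12-run
  expect_true(recs$states[4] %in% fl$kept$states)
  expect_true(recs$states[2] %in% fl$kept$states)  # 10-run at tm 0.60 kept
  expect_error(filterTrainingAlignments(data.frame(states = "MQM", tm = 1)),
               "malformed")
})

test_that("gap runs of exactly 10 survive and of exactly 11 never do", {
  set.seed(41)
  for (r in 1:20) {
    runlen <- sample(c(10, 11), 1)
    gapchar <- sample(c("X", "Y"), 1)
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    states <- paste0(strrep("M", n1), strrep(gapchar, runlen),
                     strrep("M", n2))
    fl <- filterTrainingAlignments(data.frame(states = states, tm = 0.8))
    expect_equal(nrow(fl$kept), as.integer(runlen == 10))
  }
})

test_that("alignPair returns a structurally valid decoded alignment", {
  model <- newAligner(d = 16, n_layers = 2, width = 8, seed = 2)
  res <- alignPair("AAA", "AAA", model)
  st <- strsplit(pathStates(res$path), "")[[1]]
  expect_equal(sum(st != "Y"), 3)
  expect_equal(sum(st != "X"), 3)
  expect_s4_class(res$expected, "ExpectedAlignment")
  expect_type(res$low_confidence, "logical")
  expect_length(res$gapped, 2)
  expect_equal(nchar(res$gapped[1]), nchar(res$gapped[2]))
})

test_that("alignment rendering produces consistent gapped text", {
  path <- alignmentPath("MMXYM")
  r <- renderAlignment("ACDE", "AGWE", path)
  expect_equal(r$gapped[1], "ACD-E")
  expect_equal(r$gapped[2], "AG-WE")
  lines <- strsplit(r$text, "\n")[[1]]
  expect_equal(lines[1], "ACD-E")
  expect_equal(lines[2], "||  |")
  expect_equal(lines[3], "AG-WE")
  expect_error(renderAlignment("ACD", "AGWE", path), "does not match")
})

test_that("a single repeated training example is memorised", {
  # indel-free pair: the all-match target is exactly representable by the
  # visitation marginals, so the loss can reach its floor
  corp <- generatePairCorpus(generatorConfig(
    seed = 8, n_families = 1, members_per_family = 2,
    length_range = c(20, 30), divergence_range = c(0.05, 0.1),
    indel_rate = 0, unrelated_frac = 0))
  rec <- corp$alignments[1, ]
  recs <- rec[rep(1, 8), ]
  fit <- trainAligner(recs, corp$sequences,
                      newAligner(d = 16, n_layers = 1, width = 8, seed = 3),
                      epochs = 60, lr = 8e-3, batch_size = 1,
                      val_frac = 0.15, patience = 60, seed = 2)
  expect_lt(min(fit$log$train_loss), 0.01)
})

test_that("aligner training is reproducible under a fixed seed", {
  corp <- generatePairCorpus(generatorConfig(
    seed = 9, n_families = 3, members_per_family = 3,
    divergence_range = c(0.02, 0.15), unrelated_frac = 0))
  args <- list(records = corp$alignments, sequences = corp$sequences,
               model = newAligner(d = 16, n_layers = 1, width = 6, seed = 1),
               epochs = 2, lr = 5e-4, batch_size = 4, val_frac = 0.2,
               seed = 13)
  f1 <- do.call(trainAligner, args)
  set.seed(31); rnorm(2)
  f2 <- do.call(trainAligner, args)
  expect_identical(f1$log, f2$log)
})

test_that("training contract errors are informative", {
  expect_error(trainAligner(data.frame(id_a = character(),
                                       id_b = character(),
                                       states = character()),
                            c(a = "ACD")), "empty training set")
  expect_error(trainAligner(data.frame(id_a = "a", id_b = "zz",
                                       states = "M"),
                            c(a = "A")), "missing sequence id")
})
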