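toy_cfg <- encoderConfig(n_layers = 1, n_heads = 2, d_in = 16, ff_dim = 24,
                         out_dim = 8, dropout = 0.1, seed = 5)

test_that("inference encoding is deterministic with the configured shape", {
  model <- newEncoder(toy_cfg)
  emb <- embedResidues("MKVLAW")
  z1 <- encodeProtein(emb, model)
  z2 <- encodeProtein(emb, model)
  expect_identical(z1, z2)
  expect_length(z1, 8)
  expect_error(encodeProtein(matrix(0, 4, 7), model), "dimension mismatch")
})

test_that("encoding a sequence alone or within a batch gives the same vector", {
  model <- newEncoder(toy_cfg)
  seqs <- c(a = "MKVLAW", b = "ACDEFGHIK", c = "WYVMKV")
  lone <- encodeProtein(embedResidues(seqs[["a"]]), model)
  batch <- encodeSequences(seqs, model)
  expect_equal(vectorMatrix(batch)["a", ], lone, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("predicted TM-score is the clamped cosine similarity", {
  expect_equal(as.numeric(predictTm(c(1, 1), c(1, 1))), 1)
  expect_equal(as.numeric(predictTm(c(1, 0), c(0, 1))), 0)
  expect_equal(as.numeric(predictTm(c(1, 1), c(1, 0))), 1 / sqrt(2))
  expect_equal(as.numeric(predictTm(c(1, 2, 3), c(3, 1, 2))),
               as.numeric(predictTm(c(3, 1, 2), c(1, 2, 3))))
  # raw cosine kept; clamped report for negative cosines
  p <- predictTm(c(1, 0), c(-1, 0))
  expect_equal(as.numeric(p), 0)
  expect_equal(attr(p, "raw"), -1)
  expect_error(predictTm(c(0, 0), c(1, 0)), "zero-norm")
  expect_error(predictTm(c(1, 0), c(1, 0, 0)), "dimensions differ")
})

test_that("encoder backward pass matches finite differences", {
  cfg <- encoderConfig(n_layers = 1, n_heads = 2, d_in = 8, ff_dim = 10,
                       out_dim = 6, dropout = 0, seed = 7)
  model <- newEncoder(cfg)
  ea <- asNamespace("embedalign")
  xa <- matrix(rnorm(40), 5, 8); xb <- matrix(rnorm(56), 7, 8)
  label <- 0.35
  fa <- ea$.encoder_fwd(xa, model); fb <- ea$.encoder_fwd(xb, model)
  cs <- ea$.cosine_fwd(fa$z, fb$z)
  dz <- cs$bwd(sign(cs$cos - label))
  g <- ea$nn_tree_add(fa$bwd(dz$dza), fb$bwd(dz$dzb))
  lossfn <- function(params) {
    m <- model; m$params <- params
    abs(ea$.cosine_fwd(ea$.encoder_fwd(xa, m)$z,
                       ea$.encoder_fwd(xb, m)$z)$cos - label)
  }
  flat <- ea$.flatten_params(model$params)
  gflat <- ea$.flatten_params(g)
  h <- 1e-5
  set.seed(9)
  for (nm in names(flat)) {
    arr <- flat[[nm]]
    for (ii in sample(length(arr), min(2, length(arr)))) {
      ap <- arr; ap[ii] <- ap[ii] + h
      am <- arr; am[ii] <- am[ii] - h
      fd <- (lossfn(ea$.assign_path(model$params, nm, ap)) -
             lossfn(ea$.assign_path(model$params, nm, am))) / (2 * h)
      expect_equal(gflat[[nm]][ii], fd, tolerance = 1e-3)
    }
  }
})

test_that("training degenerates correctly: identical pairs and zero lr", {
  corp <- generatePairCorpus(generatorConfig(seed = 3, n_families = 4,
                                             members_per_family = 2))
  ids <- names(corp$sequences)
  # all pairs (s, s) with label 1: recoverable to near-zero loss
  pairs <- data.frame(id_a = ids, id_b = ids, label = 1)
  fit <- trainTwinEncoder(pairs, corp$sequences,
                    encoderConfig(d_in = 16, out_dim = 8, dropout = 0,
                                  seed = 2),
                    epochs = 3, lr = 1e-3, batch_size = 4, val_frac = 0.25,
                    seed = 6)
  expect_lt(tail(fit$log$train_loss, 1), 0.01)

  # zero learning rate leaves parameters and losses unchanged
  m0 <- newEncoder(toy_cfg)
  fit0 <- trainTwinEncoder(corp$pairs, corp$sequences, toy_cfg, epochs = 3,
                     lr = 0, batch_size = 4, val_frac = 0.25, seed = 6)
  expect_identical(fit0$model$params, m0$params)
  expect_equal(length(unique(round(fit0$log$val_loss, 12))), 1L)
})

test_that("training is reproducible under a fixed seed", {
  corp <- generatePairCorpus(generatorConfig(seed = 4, n_families = 4,
                                             members_per_family = 3))
  args <- list(pairs = corp$pairs, sequences = corp$sequences,
               config = toy_cfg, epochs = 2, lr = 1e-3, batch_size = 8,
               val_frac = 0.2, seed = 11)
  f1 <- do.call(trainTwinEncoder, args)
  set.seed(777); runif(3) # disturb the ambient RNG
  f2 <- do.call(trainTwinEncoder, args)
  expect_identical(f1$log, f2$log)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("training input contracts are enforced", {
  expect_error(trainTwinEncoder(data.frame(id_a = "a", id_b = "b", label = 0.5),
                          c(a = "ACD"), toy_cfg),
               "missing sequence id")
  expect_error(trainTwinEncoder(data.frame(id_a = c("a", "a"), id_b = c("b", "b"),
                                     label = c(0.5, 1.2)),
                          c(a = "ACD", b = "ACD"), toy_cfg),
               "labels")
})
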