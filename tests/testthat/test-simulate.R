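test_that("corpora are bit-identical under the same config and seed", {
  cfg <- generatorConfig(seed = 12, n_families = 5, members_per_family = 3)
  a <- generatePairCorpus(cfg)
  set.seed(999); runif(10)
  b <- generatePairCorpus(cfg)
  expect_identical(a, b)
  # and differ under another seed
  c2 <- generatePairCorpus(generatorConfig(seed = 13, n_families = 5,
                                           members_per_family = 3))
  expect_false(identical(a$sequences, c2$sequences))
})

test_that("every planted alignment replays to the emitted sequence lengths", {
  corp <- generatePairCorpus(generatorConfig(seed = 21, n_families = 8,
                                             members_per_family = 3))
  for (i in seq_len(nrow(corp$alignments))) {
    st <- strsplit(corp$alignments$states[i], "")[[1]]
    expect_equal(sum(st != "Y"),
                 nchar(corp$sequences[[corp$alignments$id_a[i]]]))
    expect_equal(sum(st != "X"),
                 nchar(corp$sequences[[corp$alignments$id_b[i]]]))
    # and satisfies the ground-truth matrix invariants
    m <- groundTruthMatrix(corp$alignments$states[i])
    expect_true(all(rowSums(m) <= 1) && all(colSums(m) <= 1))
  }
})

test_that("zero divergence yields identical sequences and an all-match path", {
  corp <- generatePairCorpus(generatorConfig(
    seed = 5, n_families = 4, members_per_family = 2,
    divergence_range = c(0, 0), unrelated_frac = 0))
  for (i in seq_len(nrow(corp$pairs))) {
    sa <- corp$sequences[[corp$pairs$id_a[i]]]
    sb <- corp$sequences[[corp$pairs$id_b[i]]]
    expect_identical(sa, sb)
    expect_equal(corp$alignments$states[i], strrep("M", nchar(sa)))
    expect_gte(corp$pairs$label[i], 1 - 3 * 0.02)
  }
})

test_that("planted labels decay monotonically with divergence", {
  corp <- generatePairCorpus(generatorConfig(
    seed = 31, n_families = 60, members_per_family = 4,
    divergence_range = c(0.02, 0.5), unrelated_frac = 0))
  p <- corp$pairs
  bins <- cut(p$divergence, breaks = seq(0, 1, by = 0.2))
  mlab <- tapply(p$label, bins, mean)
  mlab <- mlab[!is.na(mlab)]
  expect_gte(length(mlab), 4)
  expect_true(all(diff(mlab) < 0))
  # labels track exp(-lambda * divergence) up to the noise floor
  expect_lt(median(abs(p$label - exp(-2 * p$divergence))), 3 * 0.02)
})

test_that("cross-family pairs are labelled as unrelated", {
  corp <- generatePairCorpus(generatorConfig(seed = 41, n_families = 10,
                                             members_per_family = 3,
                                             unrelated_frac = 0.5))
  unrel <- corp$pairs[!corp$pairs$related, ]
  expect_gt(nrow(unrel), 5)
  expect_true(all(unrel$label <= 0.2))
  expect_lt(mean(unrel$label), 0.2)
})

test_that("labelled blob vectors grade from separable to chance with separation", {
  amis <- vapply(c(0.3, 1.5, 4), function(sep) {
    gl <- generateLabeledVectors(n_classes = 4, per_class = 25, d = 8,
                                 separation = sep, seed = 3)
    clusterAdjustedMI(gl$vectors, gl$labels, 4, seed = 1)
  }, numeric(1))
  expect_true(all(diff(amis) > 0))
  expect_lt(amis[1], 0.3)
  expect_gt(amis[3], 0.9)
  # one member per class cannot support triplet sampling
  gl1 <- generateLabeledVectors(n_classes = 3, per_class = 1, d = 4, seed = 1)
  expect_error(tripletAUPR(gl1$vectors, gl1$labels, 10), "impossible")
})

test_that("corpus files are written in the documented formats", {
  corp <- generatePairCorpus(generatorConfig(seed = 6, n_families = 3,
                                             members_per_family = 2))
  dir <- tempfile()
  writeCorpus(corp, dir)
  expect_identical(readFastaSequences(file.path(dir, "sequences.fasta")),
                   corp$sequences)
  pairs <- read.table(file.path(dir, "pairs.tsv"), header = TRUE, sep = "\t")
  expect_equal(nrow(pairs), nrow(corp$pairs))
  ann <- read.table(file.path(dir, "annotations.tsv"), header = TRUE,
                    sep = "\t")
  expect_setequal(ann$id, names(corp$sequences))
})
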