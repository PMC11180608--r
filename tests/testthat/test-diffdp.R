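test_that("smoothed max reproduces log-sum-exp with softmax weights", {
  r <- smoothMax(c(0, 0, 0))
  expect_equal(r$value, log(3))
  expect_equal(r$weights, rep(1 / 3, 3))

  r <- smoothMax(c(1, 2))
  expect_equal(r$value, 2 + log(1 + exp(-1)))

  # hard-max limit as temperature -> 0
  r <- smoothMax(c(5, 0, 0), SmoothingConfig(temperature = 1e-4))
  expect_equal(r$value, 5, tolerance = 1e-8)
  expect_equal(r$weights, c(1, 0, 0), tolerance = 1e-8)

  # value bounds: max(x) <= value <= max(x) + t*log(n)
  set.seed(1)
  for (i in 1:20) {
    x <- rnorm(sample(2:6, 1))
    tau <- runif(1, 0.1, 2)
    r <- smoothMax(x, SmoothingConfig(temperature = tau))
    expect_gte(r$value, max(x))
    expect_lte(r$value, max(x) + tau * log(length(x)) + 1e-12)
    expect_equal(sum(r$weights), 1)
  }

  # -Inf branches are inadmissible; all -Inf is an error
  r <- smoothMax(c(1, -Inf))
  expect_equal(r$weights, c(1, 0))
  expect_error(smoothMax(c(-Inf, -Inf)), "no admissible")
  expect_error(smoothMax(numeric(0)), "empty")
})

test_that("forward pass matches hand-computed values in both border modes", {
  # single admissible path under path-strict borders
  fw <- nwForward(ScoreMatrices(matrix(2), matrix(-1)), cfg_strict)
  expect_equal(alignmentValue(fw), 2)
  expect_equal(as.numeric(argmaxWeights(fw)[1, 1, ]), c(1, 0, 0))

  # three monotone paths of score 0 each
  fw <- nwForward(ScoreMatrices(matrix(0, 2, 2), matrix(0, 2, 2)), cfg_strict)
  expect_equal(alignmentValue(fw), log(3))

  # printed borders: origin carries weight e^1, the two side starts e^0
  fw <- nwForward(ScoreMatrices(matrix(0), matrix(0)), cfg_printed)
  expect_equal(alignmentValue(fw), log(exp(1) + 2))

  expect_error(nwForward(ScoreMatrices(matrix(0, 2, 2), matrix(0, 2, 3))))
  expect_error(SmoothingConfig(temperature = 0))
})

test_that("argmax weight triples are probability vectors", {
  set.seed(42)
  for (i in 1:10) {
    sm <- rand_scores(sample(5, 1), sample(5, 1))
    for (cfg in list(cfg_strict, cfg_printed)) {
      w <- argmaxWeights(nwForward(sm, cfg))
      sums <- apply(w, c(1, 2), sum)
      expect_equal(as.numeric(sums), rep(1, length(sums)), tolerance = 1e-12)
      expect_true(all(w >= 0))
    }
  }
})

test_that("expected alignment matches hand-derived marginals", {
  # 1x1: the only path visits the only cell
  e <- nwExpectedAlignment(nwForward(rand_scores(1, 1, seed = 3), cfg_strict))
  expect_equal(expectedMatrix(e), matrix(1))

  # 2x2 all-zero scores: corners forced, off-diagonal cells on 1 of 3 paths
  e <- nwExpectedAlignment(nwForward(
    ScoreMatrices(matrix(0, 2, 2), matrix(0, 2, 2)), cfg_strict))
  m <- expectedMatrix(e)
  expect_equal(m, t(m))
  expect_equal(m[1, 1], 1)
  expect_equal(m[2, 2], 1)
  expect_equal(m[1, 2], 1 / 3)
})

test_that("forward value and marginals agree with exhaustive enumeration", {
  set.seed(7)
  for (i in 1:15) {
    sm <- rand_scores(sample(5, 1), sample(5, 1))
    for (cfg in list(cfg_strict, cfg_printed,
                     SmoothingConfig(0.6, "path_strict", mu_on_gaps = FALSE))) {
      fw <- nwForward(sm, cfg)
      or <- enumeratePathsOracle(sm, cfg)
      expect_equal(alignmentValue(fw), or$value, tolerance = 1e-10)
      expect_equal(expectedMatrix(nwExpectedAlignment(fw)), or$marginals,
                   tolerance = 1e-10)
    }
  }
  expect_error(enumeratePathsOracle(rand_scores(7, 7)), "too large")
})

test_that("expected alignment equals the value gradient w.r.t. match scores", {
  set.seed(11)
  for (cfg in list(cfg_strict, cfg_printed)) {
    sm <- rand_scores(3, 4)
    e <- expectedMatrix(nwExpectedAlignment(nwForward(sm, cfg)))
    fd <- fd_dvalue_dmu(sm, cfg)
    expect_equal(e, fd, tolerance = 1e-4)
  }
})

test_that("directional derivatives match finite differences and are linear", {
  set.seed(13)
  h <- 1e-5
  for (cfg in list(cfg_strict, cfg_printed)) {
    sm <- rand_scores(3, 4)
    zmu <- matrix(rnorm(12), 3, 4); zg <- matrix(rnorm(12), 3, 4)
    fw <- nwForward(sm, cfg)
    dd <- nwDirectional(sm, zmu, zg, fw)

    fwp <- nwForward(ScoreMatrices(matchScores(sm) + h * zmu,
                                   gapScores(sm) + h * zg), cfg)
    fwm <- nwForward(ScoreMatrices(matchScores(sm) - h * zmu,
                                   gapScores(sm) - h * zg), cfg)
    expect_equal(dd$vdot,
                 (alignmentValue(fwp) - alignmentValue(fwm)) / (2 * h),
                 tolerance = 1e-4)
    ep <- expectedMatrix(nwExpectedAlignment(fwp))
    em <- expectedMatrix(nwExpectedAlignment(fwm))
    expect_equal(dd$edot, (ep - em) / (2 * h), tolerance = 1e-4)

    # zero perturbation
    z0 <- matrix(0, 3, 4)
    d0 <- nwDirectional(sm, z0, z0, fw)
    expect_equal(d0$vdot, 0)
    expect_equal(d0$edot, z0)

    # linearity in Z
    z1m <- matrix(rnorm(12), 3, 4); z1g <- matrix(rnorm(12), 3, 4)
    z2m <- matrix(rnorm(12), 3, 4); z2g <- matrix(rnorm(12), 3, 4)
    dc <- nwDirectional(sm, 2 * z1m + 3 * z2m, 2 * z1g + 3 * z2g, fw)
    d1 <- nwDirectional(sm, z1m, z1g, fw)
    d2 <- nwDirectional(sm, z2m, z2g, fw)
    expect_equal(dc$vdot, 2 * d1$vdot + 3 * d2$vdot, tolerance = 1e-8)
    expect_equal(dc$edot, 2 * d1$edot + 3 * d2$edot, tolerance = 1e-8)
  }
  expect_error(nwDirectional(rand_scores(2, 2), matrix(0, 3, 3),
                             matrix(0, 3, 3)), "shape")
})

test_that("training adjoint matches finite differences of an e-loss", {
  set.seed(17)
  h <- 1e-5
  for (cfg in list(cfg_strict, cfg_printed)) {
    sm <- rand_scores(3, 3)
    eb <- matrix(rnorm(9), 3, 3)
    vb <- rnorm(1)
    ad <- nwBackprop(sm, eb, vb, nwForward(sm, cfg))
    num <- function(mu, gap) {
      f <- nwForward(ScoreMatrices(mu, gap), cfg)
      sum(eb * expectedMatrix(nwExpectedAlignment(f))) +
        vb * alignmentValue(f)
    }
    for (i in 1:3) for (j in 1:3) {
      mp <- matchScores(sm); mp[i, j] <- mp[i, j] + h
      mm <- matchScores(sm); mm[i, j] <- mm[i, j] - h
      expect_equal(ad$dmu[i, j],
                   (num(mp, gapScores(sm)) - num(mm, gapScores(sm))) / (2 * h),
                   tolerance = 1e-4)
      gp <- gapScores(sm); gp[i, j] <- gp[i, j] + h
      gm <- gapScores(sm); gm[i, j] <- gm[i, j] - h
      expect_equal(ad$dgap[i, j],
                   (num(matchScores(sm), gp) - num(matchScores(sm), gm)) / (2 * h),
                   tolerance = 1e-4)
    }
  }
})

test_that("adjoint and directional derivative agree through Hessian symmetry", {
  # <Hessian Z1, Z2> computed two ways: edot(Z1) contracted with the mu-block
  # of Z2 equals the adjoint of ebar = Z2_mu contracted with Z1
  set.seed(19)
  sm <- rand_scores(4, 3)
  z1m <- matrix(rnorm(12), 4, 3); z1g <- matrix(rnorm(12), 4, 3)
  z2m <- matrix(rnorm(12), 4, 3)
  fw <- nwForward(sm, cfg_strict)
  dd <- nwDirectional(sm, z1m, z1g, fw)
  ad <- nwBackprop(sm, ebar = z2m, vbar = 0, forward = fw)
  expect_equal(sum(dd$edot * z2m),
               sum(ad$dmu * z1m) + sum(ad$dgap * z1g), tolerance = 1e-10)
})

test_that("hard decode recovers the optimal path with fixed tie-breaking", {
  mu <- matrix(0.1, 3, 3); diag(mu) <- 5
  hd <- nwHardDecode(ScoreMatrices(mu, matrix(-1, 3, 3)))
  expect_equal(hd$score, 15)
  expect_equal(pathStates(hd$path), "MMM")
  expect_equal(pathEdges(hd$path), cbind(i = 1:3, j = 1:3))

  # 1x1 grid is always a single match
  expect_equal(pathStates(nwHardDecode(rand_scores(1, 1, seed = 2))$path), "M")

  # all-tied path scores resolve match > insert > delete, i.e. the
  # diagonal (textbook variant: every monotone path scores 0 here)
  hd <- nwHardDecode(ScoreMatrices(matrix(0, 3, 3), matrix(0, 3, 3)),
                     mu_on_gaps = FALSE)
  expect_equal(pathStates(hd$path), "MMM")

  # replaying the returned path reproduces the returned score exactly
  set.seed(23)
  for (i in 1:10) {
    sm <- rand_scores(sample(5, 1), sample(5, 1))
    hd <- nwHardDecode(sm)
    st <- strsplit(pathStates(hd$path), "")[[1]]
    ii <- 0; jj <- 0; sc <- 0
    for (s in st) {
      if (s == "M") { ii <- ii + 1; jj <- jj + 1
        sc <- sc + matchScores(sm)[ii, jj]
      } else if (s == "X") { ii <- ii + 1
        sc <- sc + matchScores(sm)[ii, jj] + gapScores(sm)[ii, jj]
      } else { jj <- jj + 1
        sc <- sc + matchScores(sm)[ii, jj] + gapScores(sm)[ii, jj]
      }
    }
    expect_equal(sc, hd$score, tolerance = 1e-12)
  }
})

test_that("smoothed value decreases to the hard score as temperature -> 0", {
  set.seed(29)
  for (i in 1:5) {
    sm <- rand_scores(4, 4)
    hs <- nwHardDecode(sm)$score
    taus <- c(1, 0.1, 0.01)
    vals <- vapply(taus, function(tau)
      alignmentValue(nwForward(sm, SmoothingConfig(tau, "path_strict"))),
      numeric(1))
    expect_true(all(diff(vals) < 0))
    or <- enumeratePathsOracle(sm, cfg_strict)
    for (k in seq_along(taus)) {
      expect_gte(vals[k], hs)
      expect_lte(vals[k] - hs, taus[k] * log(or$n_paths) + 1e-12)
    }
    # hard decode equals the enumeration argmax path
    expect_equal(pathStates(nwHardDecode(sm)$path), or$best_states)
    expect_equal(nwHardDecode(sm)$score, or$best_score, tolerance = 1e-12)
  }
})

test_that("batch evaluation is bitwise identical to lone evaluation", {
  set.seed(31)
  sl <- lapply(1:6, function(i) rand_scores(sample(2:6, 1), sample(2:6, 1)))
  bt <- nwBatch(sl, cfg_strict)
  for (i in seq_along(sl)) {
    fw <- nwForward(sl[[i]], cfg_strict)
    expect_identical(bt$forward[[i]]@value, fw@value)
    expect_identical(bt$forward[[i]]@weights, fw@weights)
    expect_identical(expectedMatrix(bt$expected[[i]]),
                     expectedMatrix(nwExpectedAlignment(fw)))
  }
})

test_that("expected-alignment TSV serialisation round-trips", {
  e <- nwExpectedAlignment(nwForward(rand_scores(3, 2, seed = 5), cfg_strict))
  f <- tempfile(fileext = ".tsv")
  writeExpectedAlignmentTsv(e, f)
  df <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(nrow(df), 6)
  expect_equal(matrix(df$e_ij, 3, 2), expectedMatrix(e))
})
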