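# shared fixtures: random score matrices and small configured models

rand_scores <- function(p, q, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ScoreMatrices(matrix(rnorm(p * q), p, q),
                matrix(rnorm(p * q, mean = -1), p, q))
}

cfg_strict <- SmoothingConfig(border_mode = "path_strict")
cfg_printed <- SmoothingConfig(border_mode = "as_printed")

# finite-difference gradient of the terminal value w.r.t. mu
fd_dvalue_dmu <- function(scores, config, h = 1e-5) {
  p <- nrow(matchScores(scores)); q <- ncol(matchScores(scores))
  out <- matrix(0, p, q)
  for (i in seq_len(p)) for (j in seq_len(q)) {
    mp <- matchScores(scores); mp[i, j] <- mp[i, j] + h
    mm <- matchScores(scores); mm[i, j] <- mm[i, j] - h
    out[i, j] <-
      (alignmentValue(nwForward(ScoreMatrices(mp, gapScores(scores)), config)) -
       alignmentValue(nwForward(ScoreMatrices(mm, gapScores(scores)), config))) /
      (2 * h)
  }
  out
}

toy_heads <- function(d = 6, seed = 1) {
  newScoringHeads(d = d, n_layers = 2, width = 5, kernel = 3, seed = seed)
}
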