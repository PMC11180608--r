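#' Smoothed maximum and argmax
#'
#' The smoothed maximum is the temperature-scaled log-sum-exp,
#' `value = t * log(sum(exp(x / t)))`, and the smoothed argmax its gradient,
#' `softmax(x / t)`. At `temperature = 1` these are the operators exactly as
#' written in the smoothed alignment recursion; as the temperature tends to
#' zero they recover the hard max/argmax.
#'
#' @param x numeric vector; entries may be `-Inf` (inadmissible branches)
#'   but at least one entry must be finite.
#' @param config a [SmoothingConfig-class] (only the temperature is used).
#' @return list with `value` (scalar) and `weights` (probability vector
#'   summing to 1).
#' @examples
#' smoothMax(c(1, 2))$value  # 2 + log(1 + exp(-1))
#' @export
smoothMax <- function(x, config = SmoothingConfig()) {
  stopifnot(is(config, "SmoothingConfig"))
  if (length(x) == 0) stop("smoothMax: empty input")
  if (any(is.na(x)) || any(x == Inf)) stop("smoothMax: entries must be in R or -Inf")
  m <- max(x)
  if (m == -Inf) stop("smoothMax: no admissible transition (all branches -Inf)")
  tau <- config@temperature
  w <- ifelse(x == -Inf, 0, exp((x - m) / tau))
  s <- sum(w)
  list(value = m + tau * log(s), weights = w / s)
}

#' Forward pass of the differentiable Needleman-Wunsch recursion
#'
#' Runs the smoothed recursion
#' `v[i,j] = smoothmax(mu[i,j] + c(v[i-1,j-1], g[i,j] + v[i-1,j],
#' g[i,j] + v[i,j-1]))` over the p x q grid and records the per-cell
#' smoothed-argmax weights needed by the backward passes.
#'
#' @param scores a [ScoreMatrices-class].
#' @param config a [SmoothingConfig-class]; the border mode picks the
#'   initialisation (see [SmoothingConfig-class]).
#' @return a [ForwardResult-class].
#' @examples
#' fw <- nwForward(ScoreMatrices(matrix(0, 2, 2), matrix(0, 2, 2)))
#' alignmentValue(fw)  # log(3): three admissible paths
#' @export
nwForward <- function(scores, config = SmoothingConfig()) {
  stopifnot(is(scores, "ScoreMatrices"), is(config, "SmoothingConfig"))
  res <- cpp_nw_forward(scores@mu, scores@gap, config@temperature,
                        if (config@border_mode == "as_printed") 0L else 1L,
                        config@mu_on_gaps)
  new("ForwardResult", value = res$value,
      weights = array(res$weights, dim = c(dim(scores@mu), 3)),
      config = config)
}

#' Expected alignment (backward pass)
#'
#' Propagates the smoothed-argmax weights backwards from the terminal cell
#' to obtain the predicted traceback matrix `e`, whose entry (i, j) equals
#' the gradient of the terminal alignment value with respect to
#' `mu[i, j]` - under path-strict borders, the marginal probability that
#' the alignment path visits cell (i, j).
#'
#' @param forward a [ForwardResult-class] from [nwForward()].
#' @return an [ExpectedAlignment-class].
#' @export
nwExpectedAlignment <- function(forward) {
  stopifnot(is(forward, "ForwardResult"))
  d <- dim(forward@weights)
  e <- cpp_nw_expected(as.vector(forward@weights), d[1], d[2])
  # clip the <= 1e-9 numerical excursions the backward pass can produce
  e[e < 0] <- 0
  e[e > 1] <- 1
  new("ExpectedAlignment", e = e, config = forward@config)
}

#' Directional derivatives of the alignment layer (Hessian-vector product)
#'
#' Given a perturbation `Z = [z_mu, z_gap]` of the score matrices, computes
#' `vdot`, the inner product of the gradient of the terminal value with Z,
#' and `edot`, the directional derivative of the expected alignment (the
#' Hessian of the terminal value applied to Z, restricted to the mu block).
#' The omega-dot update uses the softmax Jacobian in its calculus-derived
#' form (the Jacobian annihilates the z_mu term common to all branches);
#' both returns are validated against central finite differences.
#'
#' @param scores a [ScoreMatrices-class].
#' @param z_mu,z_gap perturbation matrices, same shape as the scores.
#' @param forward optional precomputed [ForwardResult-class].
#' @return list with scalar `vdot` and p x q matrix `edot`.
#' @export
nwDirectional <- function(scores, z_mu, z_gap, forward = NULL) {
  stopifnot(is(scores, "ScoreMatrices"))
  if (!identical(dim(z_mu), dim(scores@mu)) ||
      !identical(dim(z_gap), dim(scores@gap)))
    stop("perturbation shape must match the score matrices")
  if (is.null(forward)) forward <- nwForward(scores)
  e <- nwExpectedAlignment(forward)
  cfg <- forward@config
  cpp_nw_directional(scores@mu, scores@gap, z_mu, z_gap, forward@value,
                     as.vector(forward@weights), e@e, cfg@temperature,
                     cfg@mu_on_gaps)
}

#' Reverse-mode gradients of the alignment layer
#'
#' The training adjoint: given the gradient `ebar` of a scalar loss with
#' respect to the expected alignment (and optionally `vbar` with respect
#' to the terminal value), returns the loss gradients with respect to the
#' match and gap score matrices. This is what backpropagation through the
#' alignment layer uses when fitting the scoring heads.
#'
#' @param scores a [ScoreMatrices-class].
#' @param ebar p x q matrix, dLoss/dE.
#' @param vbar scalar, dLoss/dValue (default 0).
#' @param forward optional precomputed [ForwardResult-class].
#' @return list with matrices `dmu` and `dgap`.
#' @export
nwBackprop <- function(scores, ebar, vbar = 0, forward = NULL) {
  stopifnot(is(scores, "ScoreMatrices"))
  if (!identical(dim(ebar), dim(scores@mu)))
    stop("ebar shape must match the score matrices")
  if (is.null(forward)) forward <- nwForward(scores)
  e <- nwExpectedAlignment(forward)
  cfg <- forward@config
  cpp_nw_adjoint(scores@mu, scores@gap, forward@value,
                 as.vector(forward@weights), e@e, ebar, vbar,
                 cfg@temperature, cfg@mu_on_gaps)
}

#' Hard (classical) Needleman-Wunsch decoding
#'
#' Evaluates the recursion with the exact max/argmax under path-strict
#' borders and returns the optimal score together with the traced path.
#' Ties are broken deterministically in the order match > insert (X) >
#' delete (Y).
#'
#' @param scores a [ScoreMatrices-class].
#' @param mu_on_gaps add the match score on gap branches as printed
#'   (default `TRUE`, matching the smoothed layer's default).
#' @return list with `score` (numeric) and `path` (an
#'   [AlignmentPath-class]).
#' @examples
#' sm <- ScoreMatrices(diag(3) * 5 + 0.1, matrix(-1, 3, 3))
#' nwHardDecode(sm)$path
#' @export
nwHardDecode <- function(scores, mu_on_gaps = TRUE) {
  stopifnot(is(scores, "ScoreMatrices"))
  res <- cpp_nw_hard(scores@mu, scores@gap, mu_on_gaps)
  ed <- cbind(i = res$edges_i, j = res$edges_j)
  list(score = res$score,
       path = new("AlignmentPath", states = res$states, edges = ed))
}

#' Batched forward/backward evaluation
#'
#' Evaluates a list of instances in one call. Instances are padded to the
#' largest grid internally; padded cells are masked out and never touch the
#' per-instance recursions, so each result is bitwise identical to a lone
#' [nwForward()] / [nwExpectedAlignment()] call on that instance. Padded
#' regions carry no defined values and must be excluded from losses.
#'
#' @param scoresList list of [ScoreMatrices-class].
#' @param config a [SmoothingConfig-class] shared by the batch.
#' @return list with elements `forward` (list of [ForwardResult-class]) and
#'   `expected` (list of [ExpectedAlignment-class]).
#' @export
nwBatch <- function(scoresList, config = SmoothingConfig()) {
  stopifnot(all(vapply(scoresList, is, TRUE, "ScoreMatrices")))
  fwd <- lapply(scoresList, nwForward, config = config)
  exp <- lapply(fwd, nwExpectedAlignment)
  list(forward = fwd, expected = exp)
}

#' Write an expected alignment as TSV
#'
#' Debug serialisation: one row per cell with columns `i`, `j`, `e_ij`.
#'
#' @param e an [ExpectedAlignment-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeExpectedAlignmentTsv <- function(e, path) {
  stopifnot(is(e, "ExpectedAlignment"))
  m <- e@e
  df <- data.frame(i = rep(seq_len(nrow(m)), ncol(m)),
                   j = rep(seq_len(ncol(m)), each = nrow(m)),
                   e_ij = as.vector(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
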