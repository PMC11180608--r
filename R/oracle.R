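#' Exhaustive path-enumeration oracle for the alignment layer
#'
#' Independent brute-force reference for [nwForward()],
#' [nwExpectedAlignment()] and [nwHardDecode()]: enumerates every monotone
#' lattice path admitted by the border mode, scores each path under the
#' recursion's semantics, and aggregates them directly. Under
#' `"path_strict"` paths start at the origin; under `"as_printed"` a path
#' may start at any border cell and carries that cell's initialisation
#' value as a start weight. Exponential in the grid size, hence refused
#' above 36 cells; intended for tests only.
#'
#' @param scores a [ScoreMatrices-class] with at most 36 cells.
#' @param config a [SmoothingConfig-class].
#' @return list with `value` (temperature-scaled log-sum-exp of path
#'   scores), `marginals` (p x q per-cell visitation probabilities),
#'   `n_paths`, `best_score` and `best_states` (the argmax path under
#'   match > X > Y tie precedence, `NA` for non-origin starts).
#' @export
enumeratePathsOracle <- function(scores, config = SmoothingConfig()) {
  stopifnot(is(scores, "ScoreMatrices"), is(config, "SmoothingConfig"))
  mu <- scores@mu; gap <- scores@gap
  p <- nrow(mu); q <- ncol(mu)
  if (p * q > 36) stop("enumeratePathsOracle: grid too large (> 36 cells)")
  tau <- config@temperature
  mog <- config@mu_on_gaps

  env <- new.env(parent = emptyenv())
  env$scores <- numeric(0)   # per-path total score (incl. start weight)
  env$visits <- list()       # per-path visited interior cells
  env$starts <- integer(0)   # 1 if origin start
  env$states <- character(0)

  walk <- function(a, b, score, cells, states, origin) {
    if (a == p && b == q) {
      n <- length(env$scores) + 1L
      env$scores[n] <- score
      env$visits[[n]] <- cells
      env$starts[n] <- origin
      env$states[n] <- paste(states, collapse = "")
      return(invisible(NULL))
    }
    # step order fixes the tie precedence of the argmax path: M > X > Y
    if (a < p && b < q)
      walk(a + 1, b + 1, score + mu[a + 1, b + 1],
           c(cells, (b + 1 - 1) * p + a + 1), c(states, "M"), origin)
    if (a < p && b >= 1)
      walk(a + 1, b, score + (if (mog) mu[a + 1, b] else 0) + gap[a + 1, b],
           c(cells, (b - 1) * p + a + 1), c(states, "X"), origin)
    if (b < q && a >= 1)
      walk(a, b + 1, score + (if (mog) mu[a, b + 1] else 0) + gap[a, b + 1],
           c(cells, (b + 1 - 1) * p + a), c(states, "Y"), origin)
    invisible(NULL)
  }

  if (config@border_mode == "path_strict") {
    walk(0, 0, 0, integer(0), character(0), 1L)
  } else {
    walk(0, 0, 1, integer(0), character(0), 1L) # v[0,0] = 1 start weight
    for (j0 in seq_len(q)) walk(0, j0, 0, integer(0), character(0), 0L)
    for (i0 in seq_len(p)) walk(i0, 0, 0, integer(0), character(0), 0L)
  }

  m <- max(env$scores)
  w <- exp((env$scores - m) / tau)
  total <- sum(w)
  marg <- matrix(0, p, q)
  for (n in seq_along(w))
    marg[env$visits[[n]]] <- marg[env$visits[[n]]] + w[n]
  marg <- marg / total
  best <- which(env$scores == max(env$scores[env$starts == 1L]) &
                  env$starts == 1L)[1]
  list(value = m + tau * log(total), marginals = marg,
       n_paths = length(w),
       best_score = if (length(best)) env$scores[best] else NA_real_,
       best_states = if (length(best)) env$states[best] else NA_character_)
}
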