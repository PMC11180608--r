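#' @import methods
NULL

#' Smoothing configuration for the differentiable alignment kernel
#'
#' Holds the temperature of the smoothed max/argmax operators and the border
#' initialisation mode of the dynamic-programming recursion.
#'
#' @slot temperature positive scale of the smoothed operators: branch scores
#'   are divided by it before the log-sum-exp and the result multiplied back.
#'   `temperature = 1` reproduces the operators exactly as the recursion is
#'   usually written.
#' @slot border_mode `"as_printed"` initialises `v[0,0] = 1` and the other
#'   border cells to 0; `"path_strict"` initialises `v[0,0] = 0` and the
#'   other border cells to `-Inf`, under which the terminal value is the
#'   temperature-scaled log-sum-exp over all monotone paths from the origin.
#' @slot mu_on_gaps logical; if `TRUE` (the default, matching the recursion
#'   as printed) the match score of a cell is added on the insert and delete
#'   branches as well; `FALSE` gives the textbook variant.
#' @export
setClass("SmoothingConfig",
  representation(temperature = "numeric", border_mode = "character",
                 mu_on_gaps = "logical"),
  prototype(temperature = 1, border_mode = "path_strict", mu_on_gaps = TRUE))

setValidity("SmoothingConfig", function(object) {
  if (length(object@temperature) != 1 || !is.finite(object@temperature) ||
      object@temperature <= 0)
    return("temperature must be a single positive finite number")
  if (!object@border_mode %in% c("as_printed", "path_strict"))
    return("border_mode must be 'as_printed' or 'path_strict'")
  if (length(object@mu_on_gaps) != 1 || is.na(object@mu_on_gaps))
    return("mu_on_gaps must be TRUE or FALSE")
  TRUE
})

#' Construct a SmoothingConfig
#'
#' @param temperature positive smoothing temperature (default 1).
#' @param border_mode `"as_printed"` or `"path_strict"` (see
#'   [SmoothingConfig-class]).
#' @param mu_on_gaps add the match score on gap branches as printed
#'   (default `TRUE`).
#' @return a [SmoothingConfig-class] object.
#' @examples
#' SmoothingConfig(temperature = 0.5, border_mode = "path_strict")
#' @export
SmoothingConfig <- function(temperature = 1, border_mode = "path_strict",
                            mu_on_gaps = TRUE) {
  new("SmoothingConfig", temperature = temperature,
      border_mode = border_mode, mu_on_gaps = mu_on_gaps)
}

#' Paired match and gap score matrices
#'
#' The parameter block of the differentiable alignment layer: `mu[i, j]` is
#' the log-odds of residue i of the query aligning to residue j of the
#' target, `gap[i, j]` the log-odds of an insertion or deletion at that
#' cell. When produced by the scoring heads, `mu` is strictly positive
#' (softplus) and `gap` strictly negative (log-sigmoid).
#'
#' @slot mu p x q numeric matrix of match scores.
#' @slot gap p x q numeric matrix of gap scores.
#' @export
setClass("ScoreMatrices", representation(mu = "matrix", gap = "matrix"))

setValidity("ScoreMatrices", function(object) {
  if (!identical(dim(object@mu), dim(object@gap)))
    return("mu and gap must have identical dimensions")
  if (nrow(object@mu) < 1 || ncol(object@mu) < 1)
    return("score matrices must be at least 1 x 1")
  if (!all(is.finite(object@mu)) || !all(is.finite(object@gap)))
    return("mu and gap must be finite")
  TRUE
})

#' Construct a ScoreMatrices object
#'
#' @param mu p x q numeric matrix of match scores.
#' @param gap p x q numeric matrix of gap scores.
#' @return a [ScoreMatrices-class] object.
#' @examples
#' ScoreMatrices(matrix(1, 2, 3), matrix(-1, 2, 3))
#' @export
ScoreMatrices <- function(mu, gap) {
  new("ScoreMatrices", mu = as.matrix(mu), gap = as.matrix(gap))
}

#' Forward pass of the smoothed alignment recursion
#'
#' @slot value (p+1) x (q+1) matrix of smoothed alignment values; row and
#'   column 1 hold the border initialisation (maths index 0).
#' @slot weights p x q x 3 array of smoothed-argmax weights, channel order
#'   match / insert (X) / delete (Y); each interior triple sums to 1.
#' @slot config the [SmoothingConfig-class] used.
#' @export
setClass("ForwardResult",
  representation(value = "matrix", weights = "array",
                 config = "SmoothingConfig"))

setValidity("ForwardResult", function(object) {
  d <- dim(object@weights)
  if (length(d) != 3 || d[3] != 3)
    return("weights must be a p x q x 3 array")
  if (!identical(dim(object@value), c(d[1] + 1L, d[2] + 1L)))
    return("value must be (p+1) x (q+1)")
  TRUE
})

#' Expected alignment (predicted traceback matrix)
#'
#' Entry (i, j) is the gradient of the terminal alignment value with
#' respect to the match score `mu[i, j]`; under path-strict borders it is
#' the marginal probability that the alignment path visits cell (i, j)
#' under the Gibbs distribution over monotone paths.
#'
#' @slot e p x q numeric matrix with entries in `[0, 1]`.
#' @slot config the [SmoothingConfig-class] of the producing forward pass.
#' @export
setClass("ExpectedAlignment",
  representation(e = "matrix", config = "SmoothingConfig"))

setValidity("ExpectedAlignment", function(object) {
  if (any(object@e < -1e-9) || any(object@e > 1 + 1e-9))
    return("expected-alignment entries must lie in [0, 1]")
  TRUE
})

#' A hard (decoded) alignment path
#'
#' @slot states character scalar over the alphabet M (residues aligned),
#'   X (query residue against a gap), Y (target residue against a gap).
#' @slot edges integer matrix with columns `i`, `j`: the 1-based matched
#'   residue pairs, strictly increasing in both coordinates.
#' @export
setClass("AlignmentPath",
  representation(states = "character", edges = "matrix"))

setValidity("AlignmentPath", function(object) {
  st <- strsplit(object@states, "")[[1]]
  if (length(st) && !all(st %in% c("M", "X", "Y")))
    return("states must be over {M, X, Y}")
  ed <- object@edges
  if (nrow(ed)) {
    if (ncol(ed) != 2) return("edges must have two columns")
    if (nrow(ed) > 1 &&
        (any(diff(ed[, 1]) <= 0) || any(diff(ed[, 2]) <= 0)))
      return("edges must be strictly increasing in both coordinates")
  }
  if (sum(st == "M") != nrow(ed))
    return("number of M states must equal number of edges")
  TRUE
})

#' Construct an AlignmentPath from a state string
#'
#' @param states string over M/X/Y.
#' @return an [AlignmentPath-class]; the edge set is derived by replaying
#'   the states from the origin.
#' @examples
#' alignmentPath("MMXY")
#' @export
alignmentPath <- function(states) {
  st <- strsplit(states, "")[[1]]
  i <- 0L; j <- 0L
  ed <- matrix(0L, sum(st == "M"), 2, dimnames = list(NULL, c("i", "j")))
  n <- 0L
  for (s in st) {
    if (s == "M") { i <- i + 1L; j <- j + 1L; n <- n + 1L; ed[n, ] <- c(i, j) }
    else if (s == "X") i <- i + 1L
    else if (s == "Y") j <- j + 1L
    else stop("invalid state '", s, "'")
  }
  new("AlignmentPath", states = states, edges = ed)
}

#' A set of per-protein vectors with cosine-similarity semantics
#'
#' Rows are structure-aware protein vectors; the cosine similarity of two
#' rows is the model's prediction of the pair's TM-score.
#'
#' @slot vectors n x d numeric matrix, one row per protein.
#' @slot ids character vector of unique sequence identifiers.
#' @slot model_hash hash of the encoder checkpoint that produced them.
#' @export
setClass("ProteinVectorSet",
  representation(vectors = "matrix", ids = "character",
                 model_hash = "character"))

setValidity("ProteinVectorSet", function(object) {
  if (nrow(object@vectors) != length(object@ids))
    return("one id per vector row required")
  if (anyDuplicated(object@ids)) return("ids must be unique")
  if (!all(is.finite(object@vectors))) return("vectors must be finite")
  TRUE
})

#' Construct a ProteinVectorSet
#' @param vectors n x d numeric matrix.
#' @param ids character identifiers, one per row.
#' @param model_hash hash of the producing model (default `"unknown"`).
#' @return a [ProteinVectorSet-class].
#' @export
ProteinVectorSet <- function(vectors, ids, model_hash = "unknown") {
  vectors <- as.matrix(vectors)
  rownames(vectors) <- ids
  new("ProteinVectorSet", vectors = vectors, ids = as.character(ids),
      model_hash = model_hash)
}

#' An indexed, persistable vector database searched by cosine similarity
#'
#' @slot vectors n x d matrix of L2-normalised vectors.
#' @slot ids unique identifiers, one per row.
#' @slot backend `"exact"` or `"approximate"` (inverted-file coarse
#'   quantiser).
#' @slot manifest named list: model_hash, embedder id, build parameters,
#'   seed.
#' @slot centroids k x d matrix of coarse centroids (approximate backend
#'   only; 0 x d otherwise).
#' @slot assignments integer vector (column-major `assign_per_row x n`)
#'   mapping each row to its nearest centroids (approximate backend only).
#' @export
setClass("VectorIndex",
  representation(vectors = "matrix", ids = "character", backend = "character",
                 manifest = "list", centroids = "matrix",
                 assignments = "integer"))

setValidity("VectorIndex", function(object) {
  if (!object@backend %in% c("exact", "approximate"))
    return("backend must be 'exact' or 'approximate'")
  if (nrow(object@vectors) != length(object@ids))
    return("one id per vector row required")
  if (anyDuplicated(object@ids)) return("ids must be unique")
  nrm <- sqrt(rowSums(object@vectors^2))
  if (any(abs(nrm - 1) > 1e-6)) return("rows must be L2-normalised")
  TRUE
})

setMethod("show", "ScoreMatrices", function(object) {
  cat(sprintf("ScoreMatrices: %d x %d (mu in [%.3g, %.3g], gap in [%.3g, %.3g])\n",
              nrow(object@mu), ncol(object@mu), min(object@mu), max(object@mu),
              min(object@gap), max(object@gap)))
})

setMethod("show", "ForwardResult", function(object) {
  d <- dim(object@weights)
  cat(sprintf("ForwardResult: %d x %d grid, temperature %g, border '%s', value %.6g\n",
              d[1], d[2], object@config@temperature, object@config@border_mode,
              object@value[d[1] + 1, d[2] + 1]))
})

setMethod("show", "ExpectedAlignment", function(object) {
  cat(sprintf("ExpectedAlignment: %d x %d, mass %.4g, border '%s'\n",
              nrow(object@e), ncol(object@e), sum(object@e),
              object@config@border_mode))
})

setMethod("show", "AlignmentPath", function(object) {
  cat(sprintf("AlignmentPath: %d states (%d matches)\n  %s\n",
              nchar(object@states), nrow(object@edges),
              if (nchar(object@states) > 60)
                paste0(substr(object@states, 1, 57), "...")
              else object@states))
})

setMethod("show", "ProteinVectorSet", function(object) {
  cat(sprintf("ProteinVectorSet: %d proteins x %d dims (model %s)\n",
              nrow(object@vectors), ncol(object@vectors), object@model_hash))
})

setMethod("show", "VectorIndex", function(object) {
  cat(sprintf("VectorIndex: %d vectors x %d dims, backend '%s'\n",
              nrow(object@vectors), ncol(object@vectors), object@backend))
})

# ---- accessors ------------------------------------------------------------

#' @rdname accessors
#' @param x an object from this package.
#' @return the underlying slot value.
#' @export
setGeneric("matchScores", function(x) standardGeneric("matchScores"))
#' @rdname accessors
#' @export
setGeneric("gapScores", function(x) standardGeneric("gapScores"))
#' @rdname accessors
#' @export
setGeneric("alignmentValue", function(x) standardGeneric("alignmentValue"))
#' @rdname accessors
#' @export
setGeneric("argmaxWeights", function(x) standardGeneric("argmaxWeights"))
#' @rdname accessors
#' @export
setGeneric("expectedMatrix", function(x) standardGeneric("expectedMatrix"))
#' @rdname accessors
#' @export
setGeneric("pathStates", function(x) standardGeneric("pathStates"))
#' @rdname accessors
#' @export
setGeneric("pathEdges", function(x) standardGeneric("pathEdges"))
#' @rdname accessors
#' @export
setGeneric("vectorMatrix", function(x) standardGeneric("vectorMatrix"))
#' @rdname accessors
#' @export
setGeneric("vectorIds", function(x) standardGeneric("vectorIds"))

#' Accessors for the package's S4 containers
#' @name accessors
#' @rdname accessors
#' @export
setMethod("matchScores", "ScoreMatrices", function(x) x@mu)
#' @rdname accessors
#' @export
setMethod("gapScores", "ScoreMatrices", function(x) x@gap)
#' @rdname accessors
#' @export
setMethod("alignmentValue", "ForwardResult", function(x) {
  d <- dim(x@weights); x@value[d[1] + 1, d[2] + 1]
})
#' @rdname accessors
#' @export
setMethod("argmaxWeights", "ForwardResult", function(x) x@weights)
#' @rdname accessors
#' @export
setMethod("expectedMatrix", "ExpectedAlignment", function(x) x@e)
#' @rdname accessors
#' @export
setMethod("pathStates", "AlignmentPath", function(x) x@states)
#' @rdname accessors
#' @export
setMethod("pathEdges", "AlignmentPath", function(x) x@edges)
#' @rdname accessors
#' @export
setMethod("vectorMatrix", "ProteinVectorSet", function(x) x@vectors)
#' @rdname accessors
#' @export
setMethod("vectorIds", "ProteinVectorSet", function(x) x@ids)
#' @rdname accessors
#' @export
setMethod("vectorMatrix", "VectorIndex", function(x) x@vectors)
#' @rdname accessors
#' @export
setMethod("vectorIds", "VectorIndex", function(x) x@ids)
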