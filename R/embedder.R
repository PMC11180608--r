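#' @include AllClasses.R
NULL

.ea_cache <- new.env(parent = emptyenv())

.AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# fixed random projection for the toy embedder; keyed by dimension, seeded
# by a constant so the backend is deterministic across sessions
.toy_projection <- function(d) {
  key <- paste0("proj_", d)
  if (is.null(.ea_cache[[key]])) {
    nn_seed_rng(760817L + d)
    .ea_cache[[key]] <- matrix(stats::rnorm(21L * d), 21L, d)
  }
  .ea_cache[[key]]
}

#' Per-residue embeddings for a protein sequence
#'
#' Pluggable embedder front end. The built-in `"toy"` backend is fully
#' deterministic and needs no pretrained weights: each residue is one-hot
#' encoded over the 20 standard amino acids plus one unknown channel
#' (X/B/Z/U and any other letter), projected through a fixed seeded random
#' matrix, and averaged over a +/-`window` local context so neighbouring
#' positions correlate. External protein language models can be plugged in
#' by registering a backend function (`registerEmbedder()`).
#'
#' @param sequence amino-acid string (length >= 1).
#' @param backend embedder id; `"toy"` is built in.
#' @param d embedding dimension of the toy backend (default 16).
#' @param window half-width of the toy context window (default 2).
#' @param max_length refuse sequences longer than this (default 1000;
#'   raise explicitly for longer inputs).
#' @return numeric matrix `nchar(sequence) x d`.
#' @examples
#' dim(embedResidues("ACDEFG"))
#' @export
embedResidues <- function(sequence, backend = "toy", d = 16L, window = 2L,
                          max_length = 1000L) {
  if (!is.character(sequence) || length(sequence) != 1 || nchar(sequence) < 1)
    stop("sequence must be a non-empty string")
  if (nchar(sequence) > max_length)
    stop("sequence longer than max_length (", max_length,
         "); raise max_length to override")
  if (backend == "toy") {
    chars <- strsplit(toupper(sequence), "")[[1]]
    idx <- match(chars, .AA_ALPHABET)
    idx[is.na(idx)] <- 21L  # unknown channel
    proj <- .toy_projection(d)
    raw <- proj[idx, , drop = FALSE]
    n <- length(idx)
    out <- matrix(0, n, d)
    for (i in seq_len(n)) {
      lo <- max(1L, i - window); hi <- min(n, i + window)
      out[i, ] <- colMeans(raw[lo:hi, , drop = FALSE])
    }
    out
  } else if (!is.null(.ea_cache[[paste0("backend_", backend)]])) {
    .ea_cache[[paste0("backend_", backend)]](sequence)
  } else {
    stop("unknown embedder backend '", backend, "'")
  }
}

#' Register an external embedder backend
#'
#' @param name backend id used in `backend = name`.
#' @param fn function(sequence) returning a length x d matrix.
#' @return invisibly, the previous registration (or NULL).
#' @export
registerEmbedder <- function(name, fn) {
  key <- paste0("backend_", name)
  prev <- .ea_cache[[key]]
  .ea_cache[[key]] <- fn
  invisible(prev)
}

#' Embed every sequence of a named set
#'
#' @param sequences named character vector of sequences.
#' @param ... passed to [embedResidues()].
#' @return named list of embedding matrices.
#' @export
embedSequences <- function(sequences, ...) {
  stopifnot(!is.null(names(sequences)))
  lapply(stats::setNames(as.list(sequences), names(sequences)),
         embedResidues, ...)
}

#' Read protein sequences from FASTA
#'
#' Multi-record, wrapped lines; trailing `*` stop characters are stripped.
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
readFastaSequences <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- gsub("\\*", "", as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  seqs
}

#' Write protein sequences to FASTA
#'
#' @param sequences named character vector.
#' @param path output path.
#' @param width line-wrap width (default 60).
#' @return the path, invisibly.
#' @export
writeFastaSequences <- function(sequences, path, width = 60L) {
  ss <- Biostrings::BStringSet(sequences)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}
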