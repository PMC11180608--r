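#' Two-stage search-then-align pipeline
#'
#' Stage 1 (retrieval): encode each query with the twin encoder and return
#' its k nearest database entries by predicted TM-score (cosine). Stage 2
#' (alignment): align the query against each hit sequence with the trained
#' aligner. Either stage can be run alone (`aligner = NULL` skips stage 2).
#'
#' @param queries named character vector of query sequences.
#' @param db a [VectorIndex-class] over the target collection.
#' @param sequences named character vector resolving the database ids to
#'   sequences (needed for stage 2).
#' @param encoder a trained `ea_encoder` compatible with the database.
#' @param aligner a trained `ea_aligner`, or NULL for retrieval only.
#' @param k neighbours per query.
#' @param backend embedder backend id used for the queries.
#' @param force skip the model-hash compatibility check.
#' @return list with `hits` (data.frame `query_id`, `hit_id`, `rank`,
#'   `predicted_tm`) and `alignments` (named list of [alignPair()] results,
#'   keys `query_id|hit_id`; empty if `aligner` is NULL).
#' @export
pipelineSearchAlign <- function(queries, db, sequences = NULL, encoder,
                                aligner = NULL, k = 10L, backend = "toy",
                                force = FALSE) {
  stopifnot(inherits(encoder, "ea_encoder"))
  qvs <- tryCatch(
    encodeSequences(queries, encoder, backend = backend),
    error = function(e) stop("retrieval stage (encoding) failed: ",
                             conditionMessage(e)))
  hits <- tryCatch(
    queryDatabase(db, qvs, k = k, force = force),
    error = function(e) stop("retrieval stage (search) failed: ",
                             conditionMessage(e)))
  alignments <- list()
  if (!is.null(aligner)) {
    stopifnot(inherits(aligner, "ea_aligner"))
    if (is.null(sequences))
      stop("alignment stage needs the database sequences")
    for (r in seq_len(nrow(hits))) {
      qid <- hits$query_id[r]; hid <- hits$hit_id[r]
      if (!hid %in% names(sequences))
        stop("alignment stage failed: no sequence for hit id '", hid, "'")
      alignments[[paste(qid, hid, sep = "|")]] <- tryCatch(
        alignPair(queries[[qid]], sequences[[hid]], aligner),
        error = function(e) stop("alignment stage failed for ", qid, " vs ",
                                 hid, ": ", conditionMessage(e)))
    }
  }
  list(hits = hits, alignments = alignments)
}
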