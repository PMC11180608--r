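# Indexed vector database searched by cosine similarity. The exact backend
# is the ground truth (normalised inner products against every row); the
# approximate backend is an inverted-file index over a coarse k-means
# quantiser probing the nprobe nearest cells.

.IDX_MAGIC <- "EAVD"

#' Build a vector database
#'
#' Rows are L2-normalised at build time so cosine similarity is an inner
#' product. The approximate backend clusters the normalised rows into
#' `round(sqrt(n))` k-means cells (seeded, hence rebuildable
#' bit-identically) and searches only the cells nearest to the query.
#'
#' @param vectors numeric matrix (rows = proteins) or
#'   [ProteinVectorSet-class].
#' @param ids identifiers, one per row (taken from the vector set if
#'   omitted).
#' Each database row is assigned to its two nearest cells
#' (multi-assignment), which keeps recall high even on corpora with weak
#' cluster structure.
#'
#' @param backend `"exact"` (default) or `"approximate"`.
#' @param nprobe cells probed per query by the approximate backend
#'   (default: half the cells, at least 4).
#' @param model_hash hash of the encoder that produced the vectors.
#' @param embedder embedder id recorded in the manifest.
#' @param seed k-means seed.
#' @return a [VectorIndex-class].
#' @export
buildDatabase <- function(vectors, ids = NULL, backend = c("exact", "approximate"),
                          nprobe = NULL, model_hash = NULL, embedder = "toy",
                          seed = 1L) {
  backend <- match.arg(backend)
  if (is(vectors, "ProteinVectorSet")) {
    ids <- ids %||% vectors@ids
    model_hash <- model_hash %||% vectors@model_hash
    vectors <- vectors@vectors
  }
  model_hash <- model_hash %||% "unknown"
  vectors <- as.matrix(vectors)
  if (is.null(ids)) stop("ids required")
  if (anyDuplicated(ids)) stop("duplicate ids")
  if (nrow(vectors) != length(ids)) stop("one id per row required")
  if (nrow(vectors) < 1) stop("need at least one vector")
  nrm <- sqrt(rowSums(vectors^2))
  if (any(nrm == 0)) stop("zero-norm vector cannot be indexed")
  vn <- vectors / nrm
  centroids <- matrix(numeric(0), 0, ncol(vn))
  assignments <- integer(0)
  k_cells <- 0L
  assign_per_row <- 0L
  if (backend == "approximate") {
    k_cells <- max(1L, round(sqrt(nrow(vn))))
    if (k_cells >= nrow(vn)) k_cells <- max(1L, nrow(vn) %/% 2L)
    if (k_cells < 1L) k_cells <- 1L
    nn_seed_rng(seed)
    km <- stats::kmeans(vn, centers = k_cells, nstart = 3, iter.max = 30)
    centroids <- km$centers
    assign_per_row <- min(2L, k_cells)
    simsC <- vn %*% t(centroids)
    assignments <- apply(simsC, 1,
                         function(s) order(-s)[seq_len(assign_per_row)])
    assignments <- as.integer(assignments) # assign_per_row x n, column-major
  }
  nprobe <- as.integer(nprobe %||% max(4L, ceiling(k_cells / 2)))
  manifest <- list(model_hash = model_hash, embedder = embedder,
                   backend = backend, seed = seed,
                   n = nrow(vn), dim = ncol(vn),
                   k_cells = k_cells, nprobe = nprobe,
                   assign_per_row = assign_per_row)
  new("VectorIndex", vectors = vn, ids = as.character(ids),
      backend = backend, manifest = manifest, centroids = centroids,
      assignments = as.integer(assignments))
}

.write_f32 <- function(mat, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(.IDX_MAGIC, con, nchars = 4, eos = NULL)
  writeBin(as.integer(c(nrow(mat), ncol(mat), 1L)), con, size = 4,
           endian = "little")
  writeBin(as.numeric(t(mat)), con, size = 4, endian = "little")
  invisible(path)
}

.read_f32 <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 4, useBytes = TRUE)
  if (!identical(magic, .IDX_MAGIC)) stop("not a vector file: ", path)
  hdr <- readBin(con, "integer", 3, size = 4, endian = "little")
  dat <- readBin(con, "numeric", hdr[1] * hdr[2], size = 4,
                 endian = "little")
  matrix(dat, hdr[1], hdr[2], byrow = TRUE)
}

#' Persist a vector database to a directory
#'
#' Layout: `vectors.f32` (16-byte header - 4-byte magic, little-endian
#' int32 n, dim, version - then row-major little-endian float32),
#' `ids.txt` (one id per line, UTF-8), `manifest.txt` (tab-separated
#' key-value pairs), plus `centroids.f32` and `assignments.txt` for the
#' approximate backend.
#'
#' @param db a [VectorIndex-class].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeDatabase <- function(db, dir) {
  stopifnot(is(db, "VectorIndex"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .write_f32(db@vectors, file.path(dir, "vectors.f32"))
  writeLines(db@ids, file.path(dir, "ids.txt"), useBytes = TRUE)
  mf <- vapply(db@manifest, function(v) paste(v, collapse = ","), "")
  writeLines(paste(names(mf), mf, sep = "\t"),
             file.path(dir, "manifest.txt"))
  if (db@backend == "approximate") {
    .write_f32(db@centroids, file.path(dir, "centroids.f32"))
    writeLines(as.character(db@assignments),
               file.path(dir, "assignments.txt"))
  }
  invisible(dir)
}

#' Load a persisted vector database
#'
#' @param dir directory written by [writeDatabase()].
#' @return a [VectorIndex-class]. Vectors are float32-exact round trips of
#'   what was stored.
#' @export
loadDatabase <- function(dir) {
  vn <- .read_f32(file.path(dir, "vectors.f32"))
  ids <- readLines(file.path(dir, "ids.txt"))
  mf_lines <- strsplit(readLines(file.path(dir, "manifest.txt")), "\t")
  manifest <- stats::setNames(lapply(mf_lines, function(x) {
    v <- utils::type.convert(strsplit(x[2], ",")[[1]], as.is = TRUE)
    v
  }), vapply(mf_lines, `[`, "", 1))
  backend <- manifest$backend
  centroids <- matrix(numeric(0), 0, ncol(vn))
  assignments <- integer(0)
  if (identical(backend, "approximate")) {
    centroids <- .read_f32(file.path(dir, "centroids.f32"))
    assignments <- as.integer(readLines(file.path(dir, "assignments.txt")))
  }
  # float32 storage perturbs norms in the 1e-8 range; renormalise exactly
  vn <- vn / sqrt(rowSums(vn^2))
  new("VectorIndex", vectors = vn, ids = ids, backend = backend,
      manifest = manifest, centroids = centroids,
      assignments = assignments)
}

#' Query a vector database
#'
#' Returns the k nearest database entries by cosine similarity for each
#' query. The exact backend scans all rows (ground truth); the approximate
#' backend scans only the `nprobe` k-means cells nearest to the query.
#' Ties are broken deterministically by id order.
#'
#' @param db a [VectorIndex-class].
#' @param queries numeric matrix (rows = queries) or
#'   [ProteinVectorSet-class]; a bare numeric vector is treated as one
#'   query.
#' @param k number of neighbours (1 <= k <= database size).
#' @param query_ids ids for the result table (default `Q1..Qn` or the
#'   vector-set ids).
#' @param exclude_self drop a hit whose id equals the query id
#'   (leave-self-out evaluation).
#' @param force skip the model-hash compatibility check.
#' @return data.frame with `query_id`, `hit_id`, `rank`, `predicted_tm`.
#' @export
queryDatabase <- function(db, queries, k, query_ids = NULL,
                          exclude_self = FALSE, force = FALSE) {
  stopifnot(is(db, "VectorIndex"))
  if (is(queries, "ProteinVectorSet")) {
    if (!force && !identical(db@manifest$model_hash, "unknown") &&
        !identical(queries@model_hash, db@manifest$model_hash))
      stop("model_hash mismatch between query vectors and database ",
           "(use force = TRUE to override)")
    query_ids <- query_ids %||% queries@ids
    queries <- queries@vectors
  }
  if (is.null(dim(queries))) queries <- matrix(queries, 1)
  if (ncol(queries) != ncol(db@vectors))
    stop("query dimension ", ncol(queries), " does not match database ",
         ncol(db@vectors))
  n <- nrow(db@vectors)
  if (k < 1 || k > n) stop("k must be between 1 and the database size ", n)
  query_ids <- query_ids %||% paste0("Q", seq_len(nrow(queries)))
  qn <- queries / sqrt(rowSums(queries^2))
  id_rank <- rank(db@ids, ties.method = "first") # lexicographic tie-break
  out <- vector("list", nrow(qn))
  for (qi in seq_len(nrow(qn))) {
    if (db@backend == "exact") {
      cand <- seq_len(n)
    } else {
      a <- db@manifest$assign_per_row
      asg <- matrix(db@assignments, nrow = a)
      csim <- as.numeric(db@centroids %*% qn[qi, ])
      nprobe <- min(db@manifest$nprobe, length(csim))
      probe <- order(-csim)[seq_len(nprobe)]
      cand <- which(colSums(matrix(asg %in% probe, nrow = a)) > 0)
      # expand probes until enough candidates survive self-exclusion
      while (length(cand) < k + as.integer(exclude_self) &&
             nprobe < length(csim)) {
        nprobe <- min(length(csim), nprobe * 2L)
        probe <- order(-csim)[seq_len(nprobe)]
        cand <- which(colSums(matrix(asg %in% probe, nrow = a)) > 0)
      }
    }
    sims <- as.numeric(db@vectors[cand, , drop = FALSE] %*% qn[qi, ])
    ord <- cand[order(-sims, id_rank[cand])]
    if (exclude_self) ord <- ord[db@ids[ord] != query_ids[qi]]
    top <- head(ord, k)
    out[[qi]] <- data.frame(
      query_id = query_ids[qi], hit_id = db@ids[top],
      rank = seq_along(top),
      predicted_tm = as.numeric(db@vectors[top, , drop = FALSE] %*% qn[qi, ]))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write search hits as TSV
#'
#' Columns `query_id`, `hit_id`, `rank`, `predicted_tm` (6 decimal places).
#'
#' @param hits data.frame from [queryDatabase()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeHits <- function(hits, path) {
  hits$predicted_tm <- sprintf("%.6f", hits$predicted_tm)
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
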