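# Evaluation statistics: alignment precision/recall over bipartite match
# edges, retrieval sensitivity, triplet-scoring AUPR and cluster-adjusted
# mutual information.

#' Alignment precision, recall and F1 over match edges
#'
#' An alignment is a bipartite graph whose edges are the matched residue
#' pairs; precision and recall compare the predicted edge set with the
#' ground-truth edge set. An empty predicted edge set yields precision 0
#' (documented convention) and F1 0.
#'
#' @param predicted,truth [AlignmentPath-class] objects (or state strings)
#'   over the same sequence pair.
#' @return named numeric vector `precision`, `recall`, `f1`.
#' @examples
#' alignmentPRF("MMXY", "MMXY")  # perfect: 1 1 1
#' @export
alignmentPRF <- function(predicted, truth) {
  if (is.character(predicted)) predicted <- alignmentPath(predicted)
  if (is.character(truth)) truth <- alignmentPath(truth)
  lens <- function(p) {
    st <- strsplit(p@states, "")[[1]]
    c(sum(st != "Y"), sum(st != "X"))
  }
  if (!identical(lens(predicted), lens(truth)))
    stop("paths consume different sequence lengths")
  key <- function(ed) paste(ed[, 1], ed[, 2])
  ep <- key(predicted@edges); et <- key(truth@edges)
  inter <- length(intersect(ep, et))
  precision <- if (length(ep) == 0) 0 else inter / length(ep)
  recall <- if (length(et) == 0) 0 else inter / length(et)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, f1 = f1)
}

#' Retrieval sensitivity at top n
#'
#' The percentage of queries for which at least one of the query's
#' annotation labels appears among the union of labels of its top-n hits.
#'
#' @param hits data.frame with columns `query_id`, `hit_id`, `rank`.
#' @param annotations named list mapping every id to a character vector of
#'   labels (or a data.frame with columns `id`, `label`).
#' @param n retrieval depth; every query must have at least n hits.
#' @return percentage in `[0, 100]`.
#' @export
retrievalSensitivity <- function(hits, annotations, n) {
  stopifnot(all(c("query_id", "hit_id", "rank") %in% names(hits)))
  if (is.data.frame(annotations))
    annotations <- split(as.character(annotations$label),
                         as.character(annotations$id))
  need <- unique(c(hits$query_id, hits$hit_id))
  missing_ann <- setdiff(need, names(annotations))
  if (length(missing_ann))
    stop("unannotated id(s): ", paste(head(missing_ann, 5), collapse = ", "))
  queries <- unique(hits$query_id)
  succ <- vapply(queries, function(qid) {
    hq <- hits[hits$query_id == qid, ]
    if (max(hq$rank) < n || nrow(hq) < n)
      stop("query '", qid, "' has fewer than n = ", n, " hits")
    top <- hq$hit_id[hq$rank <= n]
    any(annotations[[qid]] %in% unlist(annotations[top]))
  }, logical(1))
  100 * mean(succ)
}

#' Step-wise average precision (AUPR)
#'
#' Area under the precision-recall curve computed as step-wise average
#' precision (no linear interpolation): the sum over positives, in
#' decreasing score order, of precision at that cut times the recall
#' increment.
#'
#' @param scores numeric prediction scores (higher = more positive).
#' @param labels logical or 0/1 vector of true classes.
#' @return AUPR in `[0, 1]`.
#' @export
averagePrecision <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), any(labels))
  ord <- order(-scores)
  lab <- labels[ord]
  tp <- cumsum(lab)
  prec <- tp / seq_along(lab)
  sum(prec[lab]) / sum(lab)
}

#' Triplet-scoring AUPR of labelled vectors
#'
#' Samples triplets in which two members share a label and the third is
#' drawn from a different label; the same-label pair forms the positive
#' class and the anchor-negative pair the negative class (balanced by
#' construction). Pairs are scored by cosine similarity and the step-wise
#' AUPR of that classifier is returned. Sampling: anchor uniform over
#' points whose label has at least 2 members; positive uniform over the
#' anchor's label (excluding the anchor); negative uniform over all points
#' with a different label; with replacement across triplets.
#'
#' @param vectors numeric matrix (rows = items) or
#'   [ProteinVectorSet-class].
#' @param labels vector of item labels.
#' @param n_triplets number of sampled triplets (default 2000).
#' @param seed sampling seed.
#' @return AUPR in `[0, 1]`.
#' @export
tripletAUPR <- function(vectors, labels, n_triplets = 2000L, seed = 1L) {
  if (is(vectors, "ProteinVectorSet")) vectors <- vectors@vectors
  labels <- as.character(labels)
  stopifnot(nrow(vectors) == length(labels))
  tab <- table(labels)
  eligible <- which(labels %in% names(tab)[tab >= 2])
  if (!length(eligible) || length(tab) < 2)
    stop("triplet sampling impossible: need >= 2 labels and a label with >= 2 members")
  nrm <- sqrt(rowSums(vectors^2))
  if (any(nrm == 0)) stop("zero-norm vector")
  vn <- vectors / nrm
  nn_seed_rng(seed)
  anchors <- sample(eligible, n_triplets, replace = TRUE)
  scores <- numeric(2L * n_triplets); cls <- logical(2L * n_triplets)
  for (t in seq_len(n_triplets)) {
    a <- anchors[t]
    same <- setdiff(which(labels == labels[a]), a)
    diff_ <- which(labels != labels[a])
    pos <- if (length(same) == 1) same else sample(same, 1)
    neg <- if (length(diff_) == 1) diff_ else sample(diff_, 1)
    scores[2 * t - 1] <- sum(vn[a, ] * vn[pos, ]); cls[2 * t - 1] <- TRUE
    scores[2 * t] <- sum(vn[a, ] * vn[neg, ]); cls[2 * t] <- FALSE
  }
  averagePrecision(scores, cls)
}

#' Adjusted mutual information between two labelings
#'
#' Mutual information adjusted for chance against the permutation model
#' (hypergeometric expected MI), normalised by the arithmetic mean of the
#' two entropies. Invariant to label renaming; ~0 for independent
#' labelings, 1 for identical partitions.
#'
#' @param a,b label vectors of equal length.
#' @return AMI (can be slightly negative by chance).
#' @export
adjustedMutualInformation <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  ct <- table(a, b)
  ai <- unname(rowSums(ct)); bj <- unname(colSums(ct))
  # mutual information (nats)
  mi <- 0
  for (i in seq_along(ai)) for (j in seq_along(bj)) {
    nij <- ct[i, j]
    if (nij > 0) mi <- mi + (nij / n) * log(n * nij / (ai[i] * bj[j]))
  }
  hu <- -sum((ai / n) * log(ai / n))
  hv <- -sum((bj / n) * log(bj / n))
  if (hu == 0 && hv == 0) return(1)
  # expected MI under the hypergeometric permutation null
  emi <- 0
  for (i in seq_along(ai)) {
    for (j in seq_along(bj)) {
      lo <- max(1, ai[i] + bj[j] - n); hi <- min(ai[i], bj[j])
      if (lo > hi) next
      for (nij in lo:hi) {
        term <- (nij / n) * log(n * nij / (ai[i] * bj[j]))
        lp <- lgamma(ai[i] + 1) + lgamma(bj[j] + 1) +
          lgamma(n - ai[i] + 1) + lgamma(n - bj[j] + 1) -
          lgamma(n + 1) - lgamma(nij + 1) - lgamma(ai[i] - nij + 1) -
          lgamma(bj[j] - nij + 1) - lgamma(n - ai[i] - bj[j] + nij + 1)
        emi <- emi + term * exp(lp)
      }
    }
  }
  denom <- (hu + hv) / 2 - emi
  if (abs(denom) < .Machine$double.eps) return(0)
  unname((mi - emi) / denom)
}

# normalized spectral clustering on a nonnegative affinity matrix
.spectral_cluster <- function(affinity, k, seed = 1L) {
  n <- nrow(affinity)
  d <- rowSums(affinity)
  if (any(d == 0)) stop("degenerate affinity: isolated item")
  dm <- 1 / sqrt(d)
  L <- affinity * (dm %o% dm)
  eig <- eigen(L, symmetric = TRUE)
  U <- eig$vectors[, seq_len(k), drop = FALSE]
  rn <- sqrt(rowSums(U^2))
  if (any(rn == 0)) stop("degenerate spectral embedding")
  U <- U / rn
  nn_seed_rng(seed)
  stats::kmeans(U, centers = k, nstart = 10, iter.max = 50)$cluster
}

#' Cluster-adjusted mutual information of labelled vectors
#'
#' Spectral clustering (cosine affinity shifted to nonnegative,
#' `(1 + cos)/2`, symmetric normalised Laplacian embedding, seeded k-means)
#' into `n_clusters`, scored by adjusted mutual information against the
#' true labels.
#'
#' @param vectors numeric matrix or [ProteinVectorSet-class].
#' @param labels true labels.
#' @param n_clusters number of clusters (default 5).
#' @param seed k-means seed.
#' @return AMI between cluster assignments and labels.
#' @export
clusterAdjustedMI <- function(vectors, labels, n_clusters = 5L, seed = 1L) {
  if (is(vectors, "ProteinVectorSet")) vectors <- vectors@vectors
  stopifnot(nrow(vectors) == length(labels), nrow(vectors) >= n_clusters)
  nrm <- sqrt(rowSums(vectors^2))
  if (any(nrm == 0)) stop("zero-norm vector")
  vn <- vectors / nrm
  cs <- vn %*% t(vn)
  if (max(cs) - min(cs) < 1e-12)
    stop("degenerate affinity: all vectors identical")
  aff <- (1 + cs) / 2
  cl <- .spectral_cluster(aff, n_clusters, seed)
  adjustedMutualInformation(cl, labels)
}
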