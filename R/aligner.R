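# The sequence-to-alignment model: embedder + scoring heads + the
# differentiable alignment layer, trained with a cross-entropy loss between
# the expected alignment and a ground-truth match matrix.

#' Binary ground-truth alignment matrix from a path
#'
#' @param path an [AlignmentPath-class] (or state string).
#' @param p,q sequence lengths; defaults are taken from the path replay.
#' @return p x q binary matrix with a 1 at every matched residue pair (at
#'   most one per row and column, jointly increasing).
#' @export
groundTruthMatrix <- function(path, p = NULL, q = NULL) {
  if (is.character(path)) path <- alignmentPath(path)
  st <- strsplit(path@states, "")[[1]]
  np <- sum(st != "Y"); nq <- sum(st != "X")
  p <- p %||% np; q <- q %||% nq
  if (p != np || q != nq)
    stop("path consumes ", np, " x ", nq, " residues, expected ", p, " x ", q)
  m <- matrix(0, p, q)
  ed <- path@edges
  if (nrow(ed)) m[ed] <- 1
  m
}

#' Cross-entropy alignment loss
#'
#' The negative mean (or sum) over cells of
#' `estar * log(e) + (1 - estar) * log(1 - e)`, where `estar` is the binary
#' ground-truth match matrix and `e` the expected alignment. The printed
#' form of this objective is a log-likelihood; it is negated here (and
#' averaged by default so learning rates are length-independent) to make a
#' minimisable loss. Entries of `e` are clamped to
#' `[1e-12, 1 - 1e-12]` before the logs.
#'
#' @param estar binary matrix (or [AlignmentPath-class]/state string).
#' @param e an [ExpectedAlignment-class] or numeric matrix.
#' @param reduction `"mean"` (default) or `"sum"`.
#' @return scalar loss.
#' @examples
#' alignmentLoss(matrix(c(1, 0, 0, 0), 2), matrix(0.5, 2, 2))  # log 2
#' @export
alignmentLoss <- function(estar, e, reduction = c("mean", "sum")) {
  reduction <- match.arg(reduction)
  if (is(e, "ExpectedAlignment")) e <- e@e
  if (is(estar, "AlignmentPath") || is.character(estar))
    estar <- groundTruthMatrix(estar, nrow(e), ncol(e))
  if (!identical(dim(estar), dim(e))) stop("shape mismatch between estar and e")
  ec <- pmin(pmax(e, 1e-12), 1 - 1e-12)
  ll <- estar * log(ec) + (1 - estar) * log1p(-ec)
  if (reduction == "mean") -mean(ll) else -sum(ll)
}

# gradient of alignmentLoss w.r.t. e (same clamping; zero outside the clamp)
.alignment_loss_grad <- function(estar, e, reduction = "mean") {
  ec <- pmin(pmax(e, 1e-12), 1 - 1e-12)
  g <- -(estar / ec - (1 - estar) / (1 - ec))
  g[e < 1e-12 | e > 1 - 1e-12] <- 0
  if (reduction == "mean") g / length(e) else g
}

#' Create an untrained aligner model
#'
#' @param d residue-embedding dimension (toy default 16).
#' @param n_layers,width,kernel scoring-head architecture, see
#'   [newScoringHeads()].
#' @param backend embedder backend id.
#' @param smoothing a [SmoothingConfig-class] for the alignment layer.
#' @param seed initialisation seed.
#' @return an object of class `ea_aligner`.
#' @export
newAligner <- function(d = 16L, n_layers = 2L, width = 32L, kernel = 5L,
                       backend = "toy",
                       smoothing = SmoothingConfig(border_mode = "path_strict"),
                       seed = 1L) {
  structure(list(heads = newScoringHeads(d, n_layers, width, kernel, seed),
                 backend = backend, d = d, smoothing = smoothing),
            class = "ea_aligner")
}

#' @export
print.ea_aligner <- function(x, ...) {
  cat("Aligner model (embedder backend '", x$backend, "', d ", x$d, ")\n",
      sep = "")
  print(x$heads)
  invisible(x)
}

#' Align a pair of sequences
#'
#' Computes learned match/gap scores for the pair, runs the smoothed
#' forward and backward passes to obtain the expected alignment, decodes a
#' hard path by classical dynamic programming on the same scores, and
#' renders the alignment as text. If no row of the expected alignment
#' reaches `conf_threshold`, the result is flagged low-confidence.
#'
#' @param seq_a,seq_b amino-acid strings.
#' @param model an `ea_aligner`.
#' @param conf_threshold low-confidence flag threshold on the maximum row
#'   marginal (default 0.5).
#' @return list with `expected` ([ExpectedAlignment-class]), `path`
#'   ([AlignmentPath-class]), `score`, `text` (three-row blocks),
#'   `gapped` (two gapped sequences), `low_confidence`.
#' @export
alignPair <- function(seq_a, seq_b, model, conf_threshold = 0.5) {
  stopifnot(inherits(model, "ea_aligner"))
  hx <- embedResidues(seq_a, backend = model$backend, d = model$d)
  hy <- embedResidues(seq_b, backend = model$backend, d = model$d)
  scores <- computeScores(hx, hy, model$heads)
  fw <- nwForward(scores, model$smoothing)
  e <- nwExpectedAlignment(fw)
  hd <- nwHardDecode(scores, mu_on_gaps = model$smoothing@mu_on_gaps)
  low_conf <- all(apply(e@e, 1, max) < conf_threshold)
  rend <- renderAlignment(seq_a, seq_b, hd$path)
  list(expected = e, path = hd$path, score = hd$score,
       text = rend$text, gapped = rend$gapped, low_confidence = low_conf)
}

#' Render an alignment path as text
#'
#' @param seq_a,seq_b the aligned sequences.
#' @param path an [AlignmentPath-class] over them.
#' @param width block width for the three-row text (default 60).
#' @return list with `gapped` (character vector of the two gapped
#'   sequences) and `text` (three-row blocks: gapped query, match line with
#'   `|` at matches, gapped target).
#' @export
renderAlignment <- function(seq_a, seq_b, path, width = 60L) {
  st <- strsplit(path@states, "")[[1]]
  a <- strsplit(seq_a, "")[[1]]; b <- strsplit(seq_b, "")[[1]]
  if (sum(st != "Y") != length(a) || sum(st != "X") != length(b))
    stop("path length does not match the sequences")
  ga <- character(length(st)); gb <- character(length(st))
  ml <- character(length(st))
  ia <- 0L; ib <- 0L
  for (k in seq_along(st)) {
    if (st[k] == "M") {
      ia <- ia + 1L; ib <- ib + 1L
      ga[k] <- a[ia]; gb[k] <- b[ib]; ml[k] <- "|"
    } else if (st[k] == "X") {
      ia <- ia + 1L
      ga[k] <- a[ia]; gb[k] <- "-"; ml[k] <- " "
    } else {
      ib <- ib + 1L
      ga[k] <- "-"; gb[k] <- b[ib]; ml[k] <- " "
    }
  }
  ga <- paste(ga, collapse = ""); gb <- paste(gb, collapse = "")
  ml <- paste(ml, collapse = "")
  blocks <- character(0)
  for (s in seq(1, nchar(ga), by = width)) {
    e <- min(s + width - 1, nchar(ga))
    blocks <- c(blocks, substr(ga, s, e), substr(ml, s, e), substr(gb, s, e),
                "")
  }
  list(gapped = c(ga, gb), text = paste(blocks, collapse = "\n"))
}

#' Filter training alignments
#'
#' Drops records whose state string contains a run of more than 10
#' consecutive gap states, or whose TM-score label is below 0.6. Runs of X
#' and Y are counted separately (a run mixing X and Y breaks the run). The
#' boundaries are exact: a run of exactly 10 gaps and a label of exactly
#' 0.6 are both retained.
#'
#' @param records data.frame with columns `states` and `tm` (and any id
#'   columns, preserved).
#' @param max_gap_run longest retained gap run (default 10).
#' @param min_tm smallest retained TM-score label (default 0.6).
#' @return list with `kept` (filtered data.frame) and `report` (counts per
#'   exclusion reason; a record failing both filters is counted under both).
#' @export
filterTrainingAlignments <- function(records, max_gap_run = 10L,
                                     min_tm = 0.6) {
  stopifnot(all(c("states", "tm") %in% names(records)))
  bad_states <- grepl("[^MXY]", records$states) | nchar(records$states) == 0
  if (any(bad_states))
    stop("malformed alignment state string in record(s): ",
         paste(head(which(bad_states), 5), collapse = ", "))
  run_len <- function(states) {
    r <- rle(strsplit(states, "")[[1]])
    gaps <- r$lengths[r$values %in% c("X", "Y")]
    if (length(gaps)) max(gaps) else 0L
  }
  runs <- vapply(records$states, run_len, integer(1), USE.NAMES = FALSE)
  gap_fail <- runs > max_gap_run
  tm_fail <- records$tm < min_tm
  keep <- !(gap_fail | tm_fail)
  list(kept = records[keep, , drop = FALSE],
       report = c(total = nrow(records), kept = sum(keep),
                  excluded_gap_run = sum(gap_fail),
                  excluded_low_tm = sum(tm_fail)))
}

# loss + head gradients for one training record (embeddings precomputed)
.aligner_record_grad <- function(model, hx, hy, estar) {
  sf <- .compute_scores_fwd(hx, hy, model$heads)
  fw <- nwForward(sf$scores, model$smoothing)
  e <- nwExpectedAlignment(fw)
  loss <- alignmentLoss(estar, e)
  ebar <- .alignment_loss_grad(estar, e@e)
  dd <- nwBackprop(sf$scores, ebar, vbar = 0, forward = fw)
  grads <- sf$bwd(dd$dmu, dd$dgap)
  list(loss = loss, grads = grads)
}

#' Train the aligner on ground-truth alignments
#'
#' Minimises the cross-entropy alignment loss with Adam. Records should
#' already satisfy the training filters (apply
#' [filterTrainingAlignments()] first). Per epoch the held-out split is
#' scored by loss and by decoded edge precision/recall; training stops
#' early once the validation loss has not improved for `patience` epochs,
#' and the best-validation parameters are returned.
#'
#' @param records data.frame with columns `id_a`, `id_b`, `states` (the
#'   ground-truth state string aligning `id_a` to `id_b`).
#' @param sequences named character vector resolving every id.
#' @param model an `ea_aligner` to start from (default toy).
#' @param epochs maximum epochs (default 20).
#' @param lr Adam learning rate (reference 5e-4).
#' @param batch_size minibatch size (default 8 for desk-scale runs).
#' @param val_frac held-out fraction (default 0.1).
#' @param patience early-stopping patience in epochs (default 5).
#' @param seed seed for split and shuffling.
#' @param verbose print per-epoch metrics.
#' @return list with `model`, `log` (epoch, train_loss, val_loss,
#'   val_precision, val_recall) and `best_epoch`.
#' @export
trainAligner <- function(records, sequences, model = newAligner(),
                         epochs = 20L, lr = 5e-4, batch_size = 8L,
                         val_frac = 0.1, patience = 5L, seed = 1L,
                         verbose = FALSE) {
  stopifnot(all(c("id_a", "id_b", "states") %in% names(records)))
  if (nrow(records) == 0) stop("empty training set after filtering")
  missing_ids <- setdiff(unique(c(records$id_a, records$id_b)),
                         names(sequences))
  if (length(missing_ids))
    stop("missing sequence id(s): ", paste(head(missing_ids, 5), collapse = ", "))

  embs <- embedSequences(sequences[unique(c(records$id_a, records$id_b))],
                         backend = model$backend, d = model$d)
  estars <- lapply(seq_len(nrow(records)), function(i)
    groundTruthMatrix(records$states[i],
                      nchar(sequences[[records$id_a[i]]]),
                      nchar(sequences[[records$id_b[i]]])))

  nn_seed_rng(seed)
  n <- nrow(records)
  n_val <- max(1L, round(val_frac * n))
  val_idx <- sample(n, n_val)
  tr_idx <- setdiff(seq_len(n), val_idx)
  if (!length(tr_idx)) stop("empty training split")

  eval_val <- function(mod) {
    losses <- numeric(length(val_idx)); prec <- numeric(length(val_idx))
    rec <- numeric(length(val_idx))
    for (k in seq_along(val_idx)) {
      i <- val_idx[k]
      sc <- computeScores(embs[[records$id_a[i]]], embs[[records$id_b[i]]],
                          mod$heads)
      fw <- nwForward(sc, mod$smoothing)
      losses[k] <- alignmentLoss(estars[[i]], nwExpectedAlignment(fw))
      hd <- nwHardDecode(sc, mu_on_gaps = mod$smoothing@mu_on_gaps)
      pr <- alignmentPRF(hd$path, alignmentPath(records$states[i]))
      prec[k] <- pr["precision"]; rec[k] <- pr["recall"]
    }
    c(loss = mean(losses), precision = stats::median(prec),
      recall = stats::median(rec))
  }

  opt <- nn_adam_init(model$heads[c("M", "G")])
  best <- list(heads = model$heads, val = Inf, epoch = 0L)
  log <- NULL
  stall <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample(tr_idx)
    ep_loss <- numeric(0)
    for (start in seq(1, length(ord), by = batch_size)) {
      batch <- ord[start:min(start + batch_size - 1, length(ord))]
      grads <- NULL; bl <- 0
      for (i in batch) {
        rg <- .aligner_record_grad(model, embs[[records$id_a[i]]],
                                   embs[[records$id_b[i]]], estars[[i]])
        bl <- bl + rg$loss
        g <- nn_tree_map(function(x) x / length(batch), rg$grads)
        grads <- if (is.null(grads)) g else nn_tree_add(grads, g)
      }
      if (lr > 0) {
        st <- nn_adam_step(model$heads[c("M", "G")], grads, opt, lr = lr)
        model$heads$M <- st$params$M
        model$heads$G <- st$params$G
        opt <- st$state
      }
      ep_loss <- c(ep_loss, bl / length(batch))
    }
    ev <- eval_val(model)
    log <- rbind(log, data.frame(epoch = ep, train_loss = mean(ep_loss),
                                 val_loss = ev["loss"],
                                 val_precision = ev["precision"],
                                 val_recall = ev["recall"]))
    if (verbose)
      message(sprintf("epoch %d train %.4f val %.4f P %.3f R %.3f", ep,
                      mean(ep_loss), ev["loss"], ev["precision"],
                      ev["recall"]))
    if (ev["loss"] < best$val - 1e-6) {
      best <- list(heads = model$heads, val = ev["loss"], epoch = ep)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) break
    }
  }
  model$heads <- best$heads
  rownames(log) <- NULL
  list(model = model, log = log, best_epoch = best$epoch)
}
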