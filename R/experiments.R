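# Desk-scale recovery experiments: the package's own end-to-end validation
# runs on synthetic corpora. Both are seeded, CPU-only and sized to finish
# in minutes; the methods vignette discusses what they do and do not show.

#' TM-score recovery experiment (twin encoder)
#'
#' Generates a fold-enriched synthetic corpus (9 families x 14 members,
#' member divergences U(0.02, 0.5), 20% unrelated cross-family pairs,
#' label noise sd 0.02), trains the toy twin encoder on 425 pairs and
#' evaluates on 75 held-out pairs of the same corpus (the left-out-pairs
#' protocol: held-out pairs may share proteins with training pairs, as in
#' chain-pair training sets). Reports the held-out median absolute error
#' between predicted and planted similarity and the Spearman correlation
#' of predictions with planted divergence on the related held-out pairs.
#'
#' @param seed integer seed controlling corpus, initialisation and
#'   training.
#' @param epochs training epochs (default 100).
#' @param n_pairs total pair budget (default 500: 425 train / 75 held out).
#' @return list with `median_abs_error`, `spearman_divergence`,
#'   `retrieval_sensitivity_top1` (leave-self-out family retrieval over
#'   the corpus, in percent), `n_heldout`, `model`, `log`.
#' @export
experimentTmScoreRecovery <- function(seed = 1L, epochs = 100L,
                                      n_pairs = 500L) {
  corp <- generatePairCorpus(generatorConfig(
    seed = seed + 1000L, n_families = 9L, members_per_family = 14L,
    divergence_range = c(0.02, 0.5), unrelated_frac = 0.2))
  pairs <- corp$pairs
  nn_seed_rng(seed + 5L)
  pairs <- pairs[sample(nrow(pairs), min(n_pairs, nrow(pairs))), ]
  n_held <- round(0.15 * nrow(pairs))
  held <- sample(nrow(pairs), n_held)
  train <- setdiff(seq_len(nrow(pairs)), held)

  fit <- trainTwinEncoder(pairs[train, ], corp$sequences,
                    encoderConfig(n_layers = 1L, n_heads = 2L, d_in = 16L,
                                  ff_dim = 128L, out_dim = 64L,
                                  dropout = 0.05, seed = seed + 2L),
                    epochs = epochs, lr = 5e-3, lr_decay = 0.98,
                    batch_size = 32L, val_frac = 0.1, seed = seed + 3L)

  embs <- embedSequences(corp$sequences, d = 16L)
  zs <- lapply(embs, encodeProtein, model = fit$model)
  pred <- mapply(function(a, b) as.numeric(predictTm(zs[[a]], zs[[b]])),
                 pairs$id_a[held], pairs$id_b[held])
  err <- abs(pred - pairs$label[held])
  rel <- pairs$related[held]
  rho <- stats::cor(pred[rel], pairs$divergence[held][rel],
                    method = "spearman")

  # leave-self-out family retrieval over the whole corpus
  vs <- ProteinVectorSet(do.call(rbind, zs), names(zs))
  db <- buildDatabase(vs)
  hits <- queryDatabase(db, vs, k = 2L, exclude_self = TRUE)
  hits <- hits[hits$rank == 1L, ]
  ann <- split(corp$annotations$label, corp$annotations$id)
  sens <- retrievalSensitivity(hits, ann, n = 1L)

  list(median_abs_error = stats::median(err),
       spearman_divergence = rho,
       retrieval_sensitivity_top1 = sens,
       n_heldout = length(held), model = fit$model, log = fit$log)
}

#' Alignment recovery experiment (trainable aligner)
#'
#' Generates low-divergence homolog pairs (the regime retained by the
#' TM >= 0.6 training filter), applies the training filters, trains the
#' toy aligner on 300 ground-truth alignments and reports the held-out
#' median decoded-edge precision and recall at the best-validation epoch.
#'
#' @param seed integer seed.
#' @param epochs maximum epochs (default 60).
#' @param n_records training alignments (default 300).
#' @return list with `median_precision`, `median_recall`, `filter_report`,
#'   `model`, `log`.
#' @export
experimentAlignmentRecovery <- function(seed = 1L, epochs = 60L,
                                        n_records = 300L) {
  corp <- generatePairCorpus(generatorConfig(
    seed = seed + 2000L, n_families = 60L, members_per_family = 4L,
    divergence_range = c(0.01, 0.13), unrelated_frac = 0))
  recs <- merge(corp$alignments, corp$pairs[, c("id_a", "id_b")],
                by = c("id_a", "id_b"))
  fl <- filterTrainingAlignments(recs)
  recs <- utils::head(fl$kept, n_records)
  fit <- trainAligner(recs, corp$sequences,
                      newAligner(d = 16L, n_layers = 2L, width = 32L,
                                 kernel = 5L, seed = seed + 4L),
                      epochs = epochs, lr = 1e-3, batch_size = 8L,
                      val_frac = 0.12, patience = 10L, seed = seed + 6L)
  best <- fit$log[fit$log$epoch == fit$best_epoch, ]
  list(median_precision = best$val_precision,
       median_recall = best$val_recall,
       filter_report = fl$report, model = fit$model, log = fit$log)
}
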