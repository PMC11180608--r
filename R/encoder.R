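# Twin encoder phi: transformer encoder layers over residue embeddings,
# mask-aware mean pooling, dropout and a small fully connected head. Two
# proteins are encoded with the same weights and the cosine similarity of
# their vectors is the model's TM-score prediction; training minimises the
# L1 distance between that cosine and the pair label.

#' Encoder configuration
#'
#' @param n_layers number of transformer encoder layers (reference models use
#'   2 or 4; toy default 1).
#' @param n_heads attention heads per layer (reference 4; toy default 2).
#' @param d_in input residue-embedding dimension (reference 1024; toy 16).
#' @param ff_dim feedforward width inside each layer (reference 2048).
#' @param out_dim protein-vector dimension (reference 512; toy default 8).
#' @param dropout dropout rate on the pooled vector during training
#'   (disabled at inference).
#' @param seed RNG seed for parameter initialisation.
#' @return a list of class `ea_encoder_config`.
#' @export
encoderConfig <- function(n_layers = 1L, n_heads = 2L, d_in = 16L,
                          ff_dim = 32L, out_dim = 8L, dropout = 0.1,
                          seed = 1L) {
  stopifnot(n_layers >= 1, n_heads >= 1, d_in %% n_heads == 0,
            ff_dim >= 1, out_dim >= 1, dropout >= 0, dropout < 1)
  structure(list(n_layers = n_layers, n_heads = n_heads, d_in = d_in,
                 ff_dim = ff_dim, out_dim = out_dim, dropout = dropout,
                 seed = seed),
            class = "ea_encoder_config")
}

#' Create a twin protein encoder
#'
#' @param config an [encoderConfig()].
#' @return an object of class `ea_encoder` holding the parameter tree and
#'   the configuration.
#' @export
newEncoder <- function(config = encoderConfig()) {
  stopifnot(inherits(config, "ea_encoder_config"))
  nn_seed_rng(config$seed)
  d <- config$d_in
  layers <- lapply(seq_len(config$n_layers), function(i) {
    list(mha = nn_mha_init(d, config$n_heads),
         ln1 = nn_layernorm_init(d),
         ff1 = nn_dense_init(d, config$ff_dim),
         ff2 = nn_dense_init(config$ff_dim, d),
         ln2 = nn_layernorm_init(d))
  })
  head <- list(fc1 = nn_dense_init(d, config$out_dim),
               fc2 = nn_dense_init(config$out_dim, config$out_dim))
  structure(list(params = list(layers = layers, head = head),
                 config = config),
            class = "ea_encoder")
}

#' @export
print.ea_encoder <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Twin encoder: %d transformer layer(s), %d heads, d_in %d, out_dim %d\n",
    cfg$n_layers, cfg$n_heads, cfg$d_in, cfg$out_dim))
  invisible(x)
}

# forward with optional dropout mask on the pooled vector; returns z and a
# backward closure yielding the full parameter-gradient tree
.encoder_fwd <- function(x, model, drop_mask = NULL) {
  cfg <- model$config
  pl <- model$params$layers
  n <- length(pl)
  bwds <- vector("list", n)
  for (li in seq_len(n)) {
    p <- pl[[li]]
    at <- nn_mha_fwd(x, p$mha, cfg$n_heads)
    l1 <- nn_layernorm_fwd(x + at$out, p$ln1)
    f1 <- nn_dense_fwd(l1$out, p$ff1)
    rl <- nn_relu_fwd(f1$out)
    f2 <- nn_dense_fwd(rl$out, p$ff2)
    l2 <- nn_layernorm_fwd(l1$out + f2$out, p$ln2)
    bwds[[li]] <- list(at = at, l1 = l1, f1 = f1, rl = rl, f2 = f2, l2 = l2)
    x <- l2$out
  }
  t_len <- nrow(x)
  pooled <- colMeans(x)
  if (!is.null(drop_mask)) pooled <- pooled * drop_mask
  hp <- model$params$head
  h1 <- nn_dense_fwd(matrix(pooled, 1), hp$fc1)
  hr <- nn_relu_fwd(h1$out)
  h2 <- nn_dense_fwd(hr$out, hp$fc2)
  z <- as.numeric(h2$out)
  bwd <- function(dz) {
    g2 <- h2$bwd(matrix(dz, 1))
    gr <- hr$bwd(g2$dx)
    g1 <- h1$bwd(gr$dx)
    head_grads <- list(fc1 = g1$grads, fc2 = g2$grads)
    dpooled <- as.numeric(g1$dx)
    if (!is.null(drop_mask)) dpooled <- dpooled * drop_mask
    g <- matrix(rep(dpooled / t_len, each = t_len), t_len)
    layer_grads <- vector("list", n)
    for (li in rev(seq_len(n))) {
      bb <- bwds[[li]]
      gl2 <- bb$l2$bwd(g)
      gf2 <- bb$f2$bwd(gl2$dx)
      grl <- bb$rl$bwd(gf2$dx)
      gf1 <- bb$f1$bwd(grl$dx)
      gl1 <- bb$l1$bwd(gl2$dx + gf1$dx)
      gat <- bb$at$bwd(gl1$dx)
      layer_grads[[li]] <- list(mha = gat$grads, ln1 = gl1$grads,
                                ff1 = gf1$grads, ff2 = gf2$grads,
                                ln2 = gl2$grads)
      g <- gl1$dx + gat$dx
    }
    list(layers = layer_grads, head = head_grads)
  }
  list(z = z, bwd = bwd)
}

#' Encode a protein into a structure-aware vector
#'
#' Deterministic inference pass (dropout disabled). The cosine similarity of
#' two such vectors from the same model approximates the pair's TM-score.
#'
#' @param emb residue-embedding matrix (`length x d_in`).
#' @param model an `ea_encoder`.
#' @return numeric vector of length `out_dim`.
#' @export
encodeProtein <- function(emb, model) {
  stopifnot(inherits(model, "ea_encoder"))
  if (ncol(emb) != model$config$d_in)
    stop("embedding dimension mismatch: encoder expects d_in = ",
         model$config$d_in)
  .encoder_fwd(as.matrix(emb), model)$z
}

#' Encode a set of sequences into a ProteinVectorSet
#'
#' @param sequences named character vector of sequences.
#' @param model an `ea_encoder`.
#' @param backend embedder backend id (default `"toy"`).
#' @return a [ProteinVectorSet-class].
#' @export
encodeSequences <- function(sequences, model, backend = "toy") {
  embs <- embedSequences(sequences, backend = backend,
                         d = model$config$d_in)
  vecs <- t(vapply(embs, encodeProtein, numeric(model$config$out_dim),
                   model = model))
  ProteinVectorSet(vecs, names(sequences), model_hash = modelHash(model))
}

#' Predicted TM-score of a protein pair
#'
#' Cosine similarity of the two protein vectors; symmetric in its
#' arguments. The reported value is clamped to `[0, 1]` (a TM-score range);
#' the raw cosine is attached as attribute `"raw"`.
#'
#' @param za,zb numeric protein vectors from the same model.
#' @return clamped cosine similarity with attribute `raw`.
#' @examples
#' predictTm(c(1, 1), c(1, 0))  # 1/sqrt(2)
#' @export
predictTm <- function(za, zb) {
  if (length(za) != length(zb)) stop("vector dimensions differ")
  na <- sqrt(sum(za^2)); nb <- sqrt(sum(zb^2))
  if (na == 0 || nb == 0) stop("zero-norm protein vector")
  raw <- sum(za * zb) / (na * nb)
  structure(min(1, max(0, raw)), raw = raw)
}

#' Content hash of a model's parameters
#'
#' @param model any model object from this package.
#' @return md5 string of the serialised parameter tree.
#' @export
modelHash <- function(model) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(model$params %||% model, f, version = 2)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# cosine forward/backward on raw vectors
.cosine_fwd <- function(za, zb) {
  na <- sqrt(sum(za^2)); nb <- sqrt(sum(zb^2))
  cs <- sum(za * zb) / (na * nb)
  list(cos = cs, bwd = function(dc) {
    list(dza = dc * (zb / (na * nb) - cs * za / na^2),
         dzb = dc * (za / (na * nb) - cs * zb / nb^2))
  })
}

#' Train the twin encoder on labelled sequence pairs
#'
#' Minimises the mean L1 distance between the cosine similarity of the two
#' protein vectors and the pair label (a TM-score in `[0, 1]`) with Adam.
#' The best-validation-loss parameters are retained. Fully seeded: two runs
#' with identical inputs and seed give identical loss curves.
#'
#' @param pairs data.frame with columns `id_a`, `id_b`, `label` (in
#'   `[0, 1]`).
#' @param sequences named character vector resolving every pair id.
#' @param config an [encoderConfig()].
#' @param epochs training epochs (default 20).
#' @param lr Adam learning rate (reference 1e-4; raise for toy runs).
#' @param lr_decay multiplicative learning-rate decay per epoch (default 1,
#'   no decay).
#' @param batch_size minibatch size (reference 32).
#' @param val_frac fraction of pairs held out for validation (default 0.1).
#' @param backend embedder backend (default `"toy"`).
#' @param seed seed controlling the split, shuffling and dropout.
#' @param verbose print per-epoch losses.
#' @return list with `model` (the best checkpoint), `log` (per-epoch
#'   train/validation loss data.frame) and `best_epoch`.
#' @export
trainTwinEncoder <- function(pairs, sequences, config = encoderConfig(),
                       epochs = 20L, lr = 1e-4, lr_decay = 1,
                       batch_size = 32L, val_frac = 0.1, backend = "toy",
                       seed = 1L, verbose = FALSE) {
  stopifnot(all(c("id_a", "id_b", "label") %in% names(pairs)))
  missing_ids <- setdiff(unique(c(pairs$id_a, pairs$id_b)), names(sequences))
  if (length(missing_ids))
    stop("missing sequence id(s): ", paste(head(missing_ids, 5), collapse = ", "))
  if (nrow(pairs) < 2) stop("need at least two pairs")
  if (any(pairs$label < 0 | pairs$label > 1))
    stop("labels must lie in [0, 1]")

  model <- newEncoder(config)
  embs <- embedSequences(sequences[unique(c(pairs$id_a, pairs$id_b))],
                         backend = backend, d = config$d_in)

  nn_seed_rng(seed)
  n <- nrow(pairs)
  n_val <- max(1L, round(val_frac * n))
  val_idx <- sample(n, n_val)
  if (length(val_idx) >= n) stop("empty training split")
  tr_idx <- setdiff(seq_len(n), val_idx)

  pair_loss <- function(params, row, drop = FALSE) {
    m <- model; m$params <- params
    mask <- NULL
    if (drop && config$dropout > 0)
      mask <- stats::rbinom(config$d_in, 1, 1 - config$dropout) /
        (1 - config$dropout)
    fa <- .encoder_fwd(embs[[row$id_a]], m, mask)
    mask_b <- NULL
    if (drop && config$dropout > 0)
      mask_b <- stats::rbinom(config$d_in, 1, 1 - config$dropout) /
        (1 - config$dropout)
    fb <- .encoder_fwd(embs[[row$id_b]], m, mask_b)
    cs <- .cosine_fwd(fa$z, fb$z)
    list(loss = abs(cs$cos - row$label), fa = fa, fb = fb, cs = cs)
  }

  eval_split <- function(params, idx) {
    errs <- vapply(idx, function(i)
      pair_loss(params, pairs[i, ])$loss, numeric(1))
    mean(errs)
  }

  opt <- nn_adam_init(model$params)
  best <- list(params = model$params, val = Inf, epoch = 0L)
  log <- data.frame(epoch = integer(), train_loss = numeric(),
                    val_loss = numeric())
  lr_ep <- lr
  for (ep in seq_len(epochs)) {
    if (ep > 1) lr_ep <- lr_ep * lr_decay
    ord <- sample(tr_idx)
    ep_losses <- numeric(0)
    for (start in seq(1, length(ord), by = batch_size)) {
      batch <- ord[start:min(start + batch_size - 1, length(ord))]
      grads <- NULL
      bl <- 0
      for (i in batch) {
        pl <- pair_loss(model$params, pairs[i, ], drop = TRUE)
        bl <- bl + pl$loss
        dcos <- sign(pl$cs$cos - pairs$label[i]) / length(batch)
        dz <- pl$cs$bwd(dcos)
        g <- nn_tree_add(pl$fa$bwd(dz$dza), pl$fb$bwd(dz$dzb))
        grads <- if (is.null(grads)) g else nn_tree_add(grads, g)
      }
      if (lr > 0) {
        st <- nn_adam_step(model$params, grads, opt, lr = lr_ep)
        model$params <- st$params
        opt <- st$state
      }
      ep_losses <- c(ep_losses, bl / length(batch))
    }
    vl <- eval_split(model$params, val_idx)
    log <- rbind(log, data.frame(epoch = ep, train_loss = mean(ep_losses),
                                 val_loss = vl))
    if (vl < best$val) best <- list(params = model$params, val = vl, epoch = ep)
    if (verbose)
      message(sprintf("epoch %d train %.4f val %.4f", ep,
                      mean(ep_losses), vl))
  }
  model$params <- best$params
  list(model = model, log = log, best_epoch = best$epoch)
}
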