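# Match/gap scoring heads: two independent convolutional sequence-to-sequence
# maps M and G over residue embeddings. Match scores are
# softplus(M(Hx) M(Hy)^T) (strictly positive), gap scores
# log-sigmoid(G(Hx) G(Hy)^T) (strictly negative).

#' Create convolutional scoring heads
#'
#' Builds the match head M and gap head G: each a stack of 1-D convolutions
#' (same padding, stride 1) with ReLU between layers, mapping a `t x d`
#' embedding matrix to a transformed `t x d` matrix. M and G share the
#' architecture but not the parameters. Initialisation is reproducible
#' under the seed.
#'
#' @param d embedding dimension consumed and produced by each head.
#' @param n_layers number of convolution layers (reference configuration 8;
#'   toy default 2).
#' @param width channel width of the intermediate layers (reference 1024;
#'   toy default 32).
#' @param kernel receptive-field size of each convolution (default 5).
#' @param seed RNG seed for the parameter initialisation.
#' @return an object of class `ea_scoring_heads`.
#' @examples
#' heads <- newScoringHeads(d = 8, n_layers = 2, width = 16, seed = 1)
#' @export
newScoringHeads <- function(d, n_layers = 2L, width = 32L, kernel = 5L,
                            seed = 1L) {
  stopifnot(n_layers >= 1, width >= 1, kernel >= 1, d >= 1)
  nn_seed_rng(seed)
  make_stack <- function() {
    dims <- if (n_layers == 1) cbind(d, d)
            else cbind(c(d, rep(width, n_layers - 1)),
                       c(rep(width, n_layers - 1), d))
    lapply(seq_len(n_layers),
           function(i) nn_conv1d_init(kernel, dims[i, 1], dims[i, 2]))
  }
  structure(list(M = make_stack(), G = make_stack(),
                 config = list(d = d, n_layers = n_layers, width = width,
                               kernel = kernel, seed = seed)),
            class = "ea_scoring_heads")
}

#' @export
print.ea_scoring_heads <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Scoring heads: %d conv layers, width %d, kernel %d, d %d\n",
              cfg$n_layers, cfg$width, cfg$kernel, cfg$d))
  invisible(x)
}

# forward through one conv stack; returns out + bwd over (dx, layer grads)
.head_stack_fwd <- function(x, layers) {
  n <- length(layers)
  bwds <- vector("list", 2L * n)
  h <- x
  for (i in seq_len(n)) {
    cv <- nn_conv1d_fwd(h, layers[[i]])
    bwds[[2L * i - 1L]] <- cv$bwd
    h <- cv$out
    if (i < n) {
      rl <- nn_relu_fwd(h)
      bwds[[2L * i]] <- rl$bwd
      h <- rl$out
    }
  }
  list(out = h, bwd = function(g) {
    grads <- vector("list", n)
    for (i in rev(seq_len(n))) {
      if (i < n) g <- bwds[[2L * i]](g)$dx
      cb <- bwds[[2L * i - 1L]](g)
      grads[[i]] <- cb$grads
      g <- cb$dx
    }
    list(dx = g, grads = grads)
  })
}

# full differentiable scoring: returns ScoreMatrices plus a backward closure
# mapping (dmu, dgap) to head gradients (used by the aligner trainer)
.compute_scores_fwd <- function(hx, hy, heads) {
  mx <- .head_stack_fwd(hx, heads$M); my <- .head_stack_fwd(hy, heads$M)
  gx <- .head_stack_fwd(hx, heads$G); gy <- .head_stack_fwd(hy, heads$G)
  mu_raw <- mx$out %*% t(my$out)
  gap_raw <- gx$out %*% t(gy$out)
  scores <- ScoreMatrices(nn_softplus(mu_raw), nn_logsigmoid(gap_raw))
  bwd <- function(dmu, dgap) {
    dmu_raw <- dmu * nn_sigmoid(mu_raw)
    dgap_raw <- dgap * (1 - nn_sigmoid(gap_raw))
    bm_x <- mx$bwd(dmu_raw %*% my$out)
    bm_y <- my$bwd(t(dmu_raw) %*% mx$out)
    bg_x <- gx$bwd(dgap_raw %*% gy$out)
    bg_y <- gy$bwd(t(dgap_raw) %*% gx$out)
    list(M = nn_tree_add(bm_x$grads, bm_y$grads),
         G = nn_tree_add(bg_x$grads, bg_y$grads))
  }
  list(scores = scores, bwd = bwd)
}

#' Compute match and gap score matrices from residue embeddings
#'
#' `mu = softplus(M(hx) %*% t(M(hy)))` and
#' `gap = logsigmoid(G(hx) %*% t(G(hy)))`, so every match score is strictly
#' positive and every gap score strictly negative for arbitrary parameters,
#' which penalises gaps, rewards matches and keeps the alignment layer
#' identifiable.
#'
#' @param hx,hy residue-embedding matrices (`p x d`, `q x d`).
#' @param heads an `ea_scoring_heads` object with matching `d`.
#' @return a [ScoreMatrices-class] of shape `p x q`.
#' @export
computeScores <- function(hx, hy, heads) {
  stopifnot(inherits(heads, "ea_scoring_heads"))
  if (ncol(hx) != heads$config$d || ncol(hy) != heads$config$d)
    stop("embedding dimension mismatch: heads expect d = ", heads$config$d)
  .compute_scores_fwd(hx, hy, heads)$scores
}
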