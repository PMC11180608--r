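# Minimal neural-network layer library with closure-style reverse mode.
#
# Every forward function returns list(out = ..., bwd = function(dout) ...)
# where bwd returns list(dx = ..., grads = named list matching the layer's
# parameters). Gradients of every layer are covered by finite-difference
# checks in the test suite. All parameter containers are plain named lists
# of numeric arrays so the Adam update can walk them generically.

nn_seed_rng <- function(seed, envir = parent.frame()) {
  # seed the RNG for the calling function's scope and restore the ambient
  # RNG state when the caller exits
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    restore <- bquote(assign(".Random.seed", .(old), envir = globalenv()))
  } else {
    restore <- quote(suppressWarnings(
      rm(".Random.seed", envir = globalenv())))
  }
  do.call(on.exit, list(restore, add = TRUE), envir = envir)
  set.seed(seed)
  invisible(NULL)
}

nn_init_matrix <- function(nin, nout, scale = sqrt(2 / (nin + nout))) {
  matrix(stats::rnorm(nin * nout, sd = scale), nin, nout)
}

# ---- elementwise activations ----------------------------------------------

nn_softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
nn_sigmoid <- function(x) 1 / (1 + exp(-x))
nn_logsigmoid <- function(x) -nn_softplus(-x)

nn_relu_fwd <- function(x) {
  mask <- x > 0
  list(out = x * mask, bwd = function(g) list(dx = g * mask))
}

# ---- dense ----------------------------------------------------------------

nn_dense_init <- function(nin, nout) {
  list(W = nn_init_matrix(nin, nout), b = numeric(nout))
}

nn_dense_fwd <- function(x, p) {
  out <- sweep(x %*% p$W, 2, p$b, `+`)
  list(out = out, bwd = function(g) {
    list(dx = g %*% t(p$W), grads = list(W = crossprod(x, g), b = colSums(g)))
  })
}

# ---- 1-D convolution over the sequence axis --------------------------------
# x: t x cin; W: k x cin x cout (same padding, stride 1); b: cout

nn_conv1d_init <- function(k, cin, cout) {
  list(W = array(stats::rnorm(k * cin * cout, sd = sqrt(2 / (k * cin + cout))),
                 dim = c(k, cin, cout)),
       b = numeric(cout))
}

nn_conv1d_fwd <- function(x, p) {
  k <- dim(p$W)[1]; cin <- dim(p$W)[2]; cout <- dim(p$W)[3]
  t_len <- nrow(x)
  off <- (k - 1L) %/% 2L
  out <- matrix(rep(p$b, each = t_len), t_len, cout)
  for (dk in seq_len(k)) {
    sh <- dk - 1L - off  # row t of out reads row t + sh of x
    src <- seq_len(t_len) + sh
    ok <- src >= 1 & src <= t_len
    if (!any(ok)) next
    out[ok, ] <- out[ok, , drop = FALSE] +
      x[src[ok], , drop = FALSE] %*% p$W[dk, , ]
  }
  list(out = out, bwd = function(g) {
    dx <- matrix(0, t_len, cin)
    dW <- array(0, dim = c(k, cin, cout))
    for (dk in seq_len(k)) {
      sh <- dk - 1L - off
      src <- seq_len(t_len) + sh
      ok <- src >= 1 & src <= t_len
      if (!any(ok)) next
      dW[dk, , ] <- crossprod(x[src[ok], , drop = FALSE], g[ok, , drop = FALSE])
      dx[src[ok], ] <- dx[src[ok], , drop = FALSE] +
        g[ok, , drop = FALSE] %*% t(p$W[dk, , ])
    }
    list(dx = dx, grads = list(W = dW, b = colSums(g)))
  })
}

# ---- layer norm (per row, over features) ------------------------------------

nn_layernorm_init <- function(d) list(gamma = rep(1, d), beta = numeric(d))

nn_layernorm_fwd <- function(x, p, eps = 1e-5) {
  d <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  va <- rowMeans(xc^2)
  istd <- 1 / sqrt(va + eps)
  xhat <- xc * istd
  out <- sweep(sweep(xhat, 2, p$gamma, `*`), 2, p$beta, `+`)
  list(out = out, bwd = function(g) {
    gg <- sweep(g, 2, p$gamma, `*`)
    # standard layernorm backward per row
    s1 <- rowMeans(gg)
    s2 <- rowMeans(gg * xhat)
    dx <- (gg - s1 - xhat * s2) * istd
    list(dx = dx,
         grads = list(gamma = colSums(g * xhat), beta = colSums(g)))
  })
}

# ---- softmax over rows ------------------------------------------------------

nn_softmax_rows_fwd <- function(x) {
  m <- apply(x, 1, max)
  e <- exp(x - m)
  s <- e / rowSums(e)
  list(out = s, bwd = function(g) {
    dot <- rowSums(g * s)
    list(dx = s * (g - dot))
  })
}

# ---- multi-head self-attention ---------------------------------------------
# d model dims split across h heads (d %% h == 0)

nn_mha_init <- function(d, n_heads) {
  stopifnot(d %% n_heads == 0)
  list(Wq = nn_init_matrix(d, d), Wk = nn_init_matrix(d, d),
       Wv = nn_init_matrix(d, d), Wo = nn_init_matrix(d, d),
       bo = numeric(d))
}

nn_mha_fwd <- function(x, p, n_heads) {
  d <- ncol(x); dh <- d / n_heads; t_len <- nrow(x)
  Q <- x %*% p$Wq; K <- x %*% p$Wk; V <- x %*% p$Wv
  heads <- vector("list", n_heads)
  O <- matrix(0, t_len, d)
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1) * dh + 1):(h * dh)
    qs <- Q[, idx, drop = FALSE]; ks <- K[, idx, drop = FALSE]
    vs <- V[, idx, drop = FALSE]
    sc <- qs %*% t(ks) / sqrt(dh)
    sm <- nn_softmax_rows_fwd(sc)
    O[, idx] <- sm$out %*% vs
    heads[[h]] <- list(idx = idx, qs = qs, ks = ks, vs = vs, sm = sm)
  }
  proj <- sweep(O %*% p$Wo, 2, p$bo, `+`)
  list(out = proj, bwd = function(g) {
    dO <- g %*% t(p$Wo)
    gr <- list(Wq = matrix(0, d, d), Wk = matrix(0, d, d),
               Wv = matrix(0, d, d), Wo = crossprod(O, g), bo = colSums(g))
    dQ <- matrix(0, t_len, d); dK <- matrix(0, t_len, d)
    dV <- matrix(0, t_len, d)
    for (h in seq_len(n_heads)) {
      hh <- heads[[h]]; idx <- hh$idx
      dOh <- dO[, idx, drop = FALSE]
      dA <- dOh %*% t(hh$vs)
      dV[, idx] <- t(hh$sm$out) %*% dOh
      dsc <- hh$sm$bwd(dA)$dx / sqrt(dh)
      dQ[, idx] <- dsc %*% hh$ks
      dK[, idx] <- t(dsc) %*% hh$qs
    }
    gr$Wq <- crossprod(x, dQ); gr$Wk <- crossprod(x, dK)
    gr$Wv <- crossprod(x, dV)
    dx <- dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv)
    list(dx = dx, grads = gr)
  })
}

# ---- generic parameter-tree utilities ---------------------------------------

nn_tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- mapply(function(x, y) nn_tree_map2(f, x, y), a, b, SIMPLIFY = FALSE)
    out
  } else f(a, b)
}

nn_tree_map <- function(f, a) {
  if (is.list(a)) lapply(a, nn_tree_map, f = f) else f(a)
}

nn_zeros_like <- function(a) nn_tree_map(function(x) x * 0, a)

nn_tree_add <- function(a, b) nn_tree_map2(`+`, a, b)

# ---- Adam -------------------------------------------------------------------

nn_adam_init <- function(params) {
  list(m = nn_zeros_like(params), v = nn_zeros_like(params), t = 0L)
}

nn_adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                         beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- nn_tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                          state$m, grads)
  state$v <- nn_tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2,
                          state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- nn_tree_map2(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                      state$m, state$v)
  params <- nn_tree_map2(`-`, params, upd)
  list(params = params, state = state)
}
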