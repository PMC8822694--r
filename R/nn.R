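## Neural-network primitives: initialization, layer forward/backward passes
## and the Adam optimizer. Everything is plain R matrix code; gradients are
## validated against finite differences in the test suite. All functions
## here are internal.

.xavier <- function(nin, nout) {
  l <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -l, l), nin, nout)
}

.relu <- function(x) x * (x > 0)

## Row-wise bias add without sweep()'s aperm overhead.
.add_bias <- function(z, b) z + rep(b, each = nrow(z))

.sigmoid <- function(x) 1 / (1 + exp(-x))

## Sinusoidal positional encoding, n positions (0-based) x H dims.
.pe_matrix <- function(n, H) {
  pos <- seq_len(n) - 1
  n_pair <- ceiling(H / 2)
  freq <- 1 / 10000^(2 * (seq_len(n_pair) - 1) / H)
  ang <- outer(pos, freq)
  pe <- matrix(0, n, H)
  pe[, seq(1L, H, by = 2L)] <- sin(ang[, seq_len(length(seq(1L, H, by = 2L))),
                                       drop = FALSE])
  even <- seq(2L, H, by = 2L)
  if (length(even)) pe[, even] <- cos(ang[, seq_len(length(even)), drop = FALSE])
  pe
}

## ---- dense ----------------------------------------------------------------

.dense_fwd <- function(x, W, b, activation = "linear") {
  z <- .add_bias(x %*% W, b)
  y <- if (activation == "relu") .relu(z) else z
  list(y = y, x = x, z = z, activation = activation)
}

## Returns list(dx, dW, db)
.dense_bwd <- function(dy, cache, W) {
  if (cache$activation == "relu") dy <- dy * (cache$z > 0)
  list(dx = tcrossprod(dy, W), dW = crossprod(cache$x, dy),
       db = colSums(dy))
}

## ---- layer norm -----------------------------------------------------------

.ln_fwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  sd <- sqrt(rowMeans(xc^2) + eps)
  xhat <- xc / sd
  y <- .add_bias(xhat * rep(g, each = nrow(x)), b)
  list(y = y, xhat = xhat, sd = sd)
}

.ln_bwd <- function(dy, cache, g) {
  xhat <- cache$xhat
  dxhat <- dy * rep(g, each = nrow(dy))
  dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) / cache$sd
  list(dx = dx, dg = colSums(dy * xhat), db = colSums(dy))
}

## ---- multi-head self-attention --------------------------------------------

## X: n x H, mask: logical n (valid key positions). Returns output, per-head
## attention matrices and a cache for the backward pass.
.attn_fwd <- function(X, p, prefix, nh, mask, dropout = 0, train = FALSE) {
  H <- ncol(X)
  dk <- H %/% nh
  Q <- .add_bias(X %*% p[[paste0(prefix, ".Wq")]], p[[paste0(prefix, ".bq")]])
  K <- .add_bias(X %*% p[[paste0(prefix, ".Wk")]], p[[paste0(prefix, ".bk")]])
  V <- .add_bias(X %*% p[[paste0(prefix, ".Wv")]], p[[paste0(prefix, ".bv")]])
  n <- nrow(X)
  A <- vector("list", nh)
  Ad <- vector("list", nh)   # attention after dropout (used for values)
  O <- matrix(0, n, H)
  for (h in seq_len(nh)) {
    cols <- ((h - 1L) * dk + 1L):(h * dk)
    S <- tcrossprod(Q[, cols, drop = FALSE], K[, cols, drop = FALSE]) / sqrt(dk)
    if (!all(mask)) S[, !mask] <- -Inf
    S <- S - apply(S, 1L, max)
    E <- exp(S)
    Ah <- E / rowSums(E)
    A[[h]] <- Ah
    if (train && dropout > 0) {
      dm <- matrix(stats::runif(n * n) >= dropout, n, n) / (1 - dropout)
      Ad[[h]] <- Ah * dm
    } else {
      Ad[[h]] <- Ah
    }
    O[, cols] <- Ad[[h]] %*% V[, cols, drop = FALSE]
  }
  out <- .add_bias(O %*% p[[paste0(prefix, ".Wo")]],
                   p[[paste0(prefix, ".bo")]])
  list(y = out, cache = list(X = X, Q = Q, K = K, V = V, A = A, Ad = Ad,
                             O = O, nh = nh, dk = dk))
}

.attn_bwd <- function(dy, cache, p, prefix, gadd) {
  X <- cache$X; nh <- cache$nh; dk <- cache$dk
  Wo <- p[[paste0(prefix, ".Wo")]]
  gadd(paste0(prefix, ".Wo"), crossprod(cache$O, dy))
  gadd(paste0(prefix, ".bo"), colSums(dy))
  dO <- tcrossprod(dy, Wo)
  dQ <- matrix(0, nrow(X), ncol(X))
  dK <- matrix(0, nrow(X), ncol(X))
  dV <- matrix(0, nrow(X), ncol(X))
  for (h in seq_len(nh)) {
    cols <- ((h - 1L) * dk + 1L):(h * dk)
    Ah <- cache$A[[h]]; Adh <- cache$Ad[[h]]
    dAd <- tcrossprod(dO[, cols, drop = FALSE], cache$V[, cols, drop = FALSE])
    dV[, cols] <- crossprod(Adh, dO[, cols, drop = FALSE])
    dA <- dAd * (Adh / ifelse(Ah > 0, Ah, 1))   # undo dropout scaling
    dS <- Ah * (dA - rowSums(dA * Ah))
    dQ[, cols] <- dS %*% cache$K[, cols, drop = FALSE] / sqrt(dk)
    dK[, cols] <- crossprod(dS, cache$Q[, cols, drop = FALSE]) / sqrt(dk)
  }
  dX <- matrix(0, nrow(X), ncol(X))
  for (nm in c("q", "k", "v")) {
    d <- switch(nm, q = dQ, k = dK, v = dV)
    W <- p[[paste0(prefix, ".W", nm)]]
    gadd(paste0(prefix, ".W", nm), crossprod(X, d))
    gadd(paste0(prefix, ".b", nm), colSums(d))
    dX <- dX + tcrossprod(d, W)
  }
  dX
}

## ---- transformer block (post-norm) ----------------------------------------

.block_fwd <- function(X, p, prefix, cfg, mask, train = FALSE) {
  att <- .attn_fwd(X, p, prefix, cfg$n_heads, mask, cfg$dropout, train)
  a_out <- att$y
  m1 <- NULL
  if (train && cfg$dropout > 0) {
    m1 <- matrix(stats::runif(length(a_out)) >= cfg$dropout,
                 nrow(a_out)) / (1 - cfg$dropout)
    a_out <- a_out * m1
  }
  ln1 <- .ln_fwd(X + a_out, p[[paste0(prefix, ".ln1.g")]],
                 p[[paste0(prefix, ".ln1.b")]])
  ff1 <- .dense_fwd(ln1$y, p[[paste0(prefix, ".ff1.W")]],
                    p[[paste0(prefix, ".ff1.b")]], "relu")
  ff2 <- .dense_fwd(ff1$y, p[[paste0(prefix, ".ff2.W")]],
                    p[[paste0(prefix, ".ff2.b")]], "linear")
  f_out <- ff2$y
  m2 <- NULL
  if (train && cfg$dropout > 0) {
    m2 <- matrix(stats::runif(length(f_out)) >= cfg$dropout,
                 nrow(f_out)) / (1 - cfg$dropout)
    f_out <- f_out * m2
  }
  ln2 <- .ln_fwd(ln1$y + f_out, p[[paste0(prefix, ".ln2.g")]],
                 p[[paste0(prefix, ".ln2.b")]])
  list(y = ln2$y,
       attention = att$cache$A,
       cache = list(att = att$cache, m1 = m1, m2 = m2, ln1 = ln1,
                    ff1 = ff1, ff2 = ff2, ln2 = ln2))
}

.block_bwd <- function(dy, cache, p, prefix, gadd) {
  b2 <- .ln_bwd(dy, cache$ln2, p[[paste0(prefix, ".ln2.g")]])
  gadd(paste0(prefix, ".ln2.g"), b2$dg)
  gadd(paste0(prefix, ".ln2.b"), b2$db)
  dR2 <- b2$dx
  df_out <- if (is.null(cache$m2)) dR2 else dR2 * cache$m2
  d2 <- .dense_bwd(df_out, cache$ff2, p[[paste0(prefix, ".ff2.W")]])
  gadd(paste0(prefix, ".ff2.W"), d2$dW)
  gadd(paste0(prefix, ".ff2.b"), d2$db)
  d1 <- .dense_bwd(d2$dx, cache$ff1, p[[paste0(prefix, ".ff1.W")]])
  gadd(paste0(prefix, ".ff1.W"), d1$dW)
  gadd(paste0(prefix, ".ff1.b"), d1$db)
  dL1 <- dR2 + d1$dx
  b1 <- .ln_bwd(dL1, cache$ln1, p[[paste0(prefix, ".ln1.g")]])
  gadd(paste0(prefix, ".ln1.g"), b1$dg)
  gadd(paste0(prefix, ".ln1.b"), b1$db)
  dR1 <- b1$dx
  da_out <- if (is.null(cache$m1)) dR1 else dR1 * cache$m1
  dX_att <- .attn_bwd(da_out, cache$att, p, prefix, gadd)
  dR1 + dX_att
}

## ---- optimizer -------------------------------------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

## Adam state lives in two flat vectors over the concatenated parameters;
## per-tensor bookkeeping in R is far more expensive than the arithmetic.
.adam_init <- function(params) {
  sizes <- vapply(params, length, integer(1L))
  ends <- cumsum(sizes)
  n <- ends[length(ends)]
  list(m = numeric(n), v = numeric(n), t = 0L,
       starts = ends - sizes + 1L, ends = ends, sizes = sizes)
}

## Tensors with no gradient entry are frozen for the step: their weights
## and their moment estimates are left untouched (a BR epoch must leave
## the DTI stage bit-identical even when earlier DTI epochs built up
## momentum there).
## lr_scale: optional per-tensor learning-rate multipliers (named vector;
## tensors not listed use 1), for discriminative fine-tuning rates.
.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, clip = 1, lr_scale = NULL) {
  pn <- names(params)
  n <- state$ends[length(state$ends)]
  g <- numeric(n)
  have <- logical(length(pn))
  for (i in seq_along(pn)) {
    gi <- grads[[pn[i]]]
    if (!is.null(gi)) {
      g[state$starts[i]:state$ends[i]] <- gi
      have[i] <- TRUE
    }
  }
  if (is.finite(clip) && clip > 0) {
    gn <- sqrt(sum(g * g))
    if (gn > clip) g <- g * (clip / gn)
  }
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  if (all(have)) {
    state$m <- beta1 * state$m + (1 - beta1) * g
    state$v <- beta2 * state$v + (1 - beta2) * g * g
    upd <- lr * (state$m / bc1) / (sqrt(state$v / bc2) + eps)
  } else {
    act <- unlist(lapply(which(have), function(i)
      state$starts[i]:state$ends[i]), use.names = FALSE)
    ga <- g[act]
    ma <- beta1 * state$m[act] + (1 - beta1) * ga
    va <- beta2 * state$v[act] + (1 - beta2) * ga * ga
    state$m[act] <- ma
    state$v[act] <- va
    upd <- numeric(n)
    upd[act] <- lr * (ma / bc1) / (sqrt(va / bc2) + eps)
  }
  if (!is.null(lr_scale)) {
    for (nm in names(lr_scale)) {
      i <- match(nm, pn)
      if (!is.na(i) && have[i]) {
        rng <- state$starts[i]:state$ends[i]
        upd[rng] <- upd[rng] * lr_scale[[nm]]
      }
    }
  }
  flat <- unlist(params, use.names = FALSE) - upd
  for (i in seq_along(pn)) {
    if (!have[i]) next
    x <- flat[state$starts[i]:state$ends[i]]
    dim(x) <- dim(params[[pn[i]]])
    params[[pn[i]]] <- x
  }
  list(params = params, state = state)
}

## Gradient accumulator backed by an environment; returns list(add, get).
.grad_env <- function() {
  e <- new.env(parent = emptyenv())
  add <- function(name, val) {
    cur <- e[[name]]
    e[[name]] <- if (is.null(cur)) val else cur + val
  }
  get_all <- function() as.list(e)
  list(add = add, get = get_all)
}
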