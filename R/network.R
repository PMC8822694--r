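## The detection network: residue embedding -> multi-window 1D convolution
## -> per-grid max pooling -> projection; compound fingerprint -> token;
## token + grids + positional encoding -> BR transformer blocks -> per-grid
## anchor-wise (c, w, p) detection head; -> DTI transformer blocks -> DTI
## head on the compound token.

#' Initialize a model
#'
#' Creates a model object with Xavier-initialized weights. Uses R's global
#' RNG; call [set.seed()] first for reproducibility.
#'
#' @param cfg A [hots_config()].
#' @return A `hots_model` list with elements `params` (named weight list)
#'   and `cfg`.
#' @export
hots_init_model <- function(cfg = hots_config()) {
  stopifnot(inherits(cfg, "hots_config"))
  p <- list()
  d <- cfg$embed_dim
  p$emb <- if (cfg$embed_init == "onehot") diag(length(AA_ALPHABET))
           else matrix(stats::rnorm(length(AA_ALPHABET) * d, sd = 0.1),
                       length(AA_ALPHABET), d)
  for (j in seq_along(cfg$conv_windows)) {
    k <- cfg$conv_windows[j]; f <- cfg$conv_filters[j]
    p[[paste0("conv", j, ".W")]] <- .xavier(k * d, f)
    p[[paste0("conv", j, ".b")]] <- numeric(f)
  }
  f_total <- sum(cfg$conv_filters)
  p$proj.W <- .xavier(f_total, cfg$H); p$proj.b <- numeric(cfg$H)
  p$comp.W <- .xavier(cfg$fp_bits, cfg$H); p$comp.b <- numeric(cfg$H)
  for (prefix in .block_prefixes(cfg)) {
    H <- cfg$H; fH <- cfg$ff_ratio * H
    for (nm in c("q", "k", "v", "o")) {
      p[[paste0(prefix, ".W", nm)]] <- .xavier(H, H)
      p[[paste0(prefix, ".b", nm)]] <- numeric(H)
    }
    p[[paste0(prefix, ".ln1.g")]] <- rep(1, H)
    p[[paste0(prefix, ".ln1.b")]] <- numeric(H)
    p[[paste0(prefix, ".ff1.W")]] <- .xavier(H, fH)
    p[[paste0(prefix, ".ff1.b")]] <- numeric(fH)
    p[[paste0(prefix, ".ff2.W")]] <- .xavier(fH, H)
    p[[paste0(prefix, ".ff2.b")]] <- numeric(H)
    p[[paste0(prefix, ".ln2.g")]] <- rep(1, H)
    p[[paste0(prefix, ".ln2.b")]] <- numeric(H)
  }
  A <- length(cfg$anchors)
  p$det.W1 <- .xavier(cfg$H, cfg$H); p$det.b1 <- numeric(cfg$H)
  p$det.W2 <- .xavier(cfg$H, 3L * A); p$det.b2 <- numeric(3L * A)
  p$dti.W1 <- .xavier(cfg$H, cfg$H); p$dti.b1 <- numeric(cfg$H)
  p$dti.W2 <- .xavier(cfg$H, 1L); p$dti.b2 <- numeric(1L)
  structure(list(params = p, cfg = cfg), class = "hots_model")
}

.block_prefixes <- function(cfg) {
  c(if (cfg$n_br_blocks) paste0("br", seq_len(cfg$n_br_blocks)),
    if (cfg$n_dti_blocks) paste0("dti", seq_len(cfg$n_dti_blocks)))
}

#' @export
print.hots_model <- function(x, ...) {
  npar <- sum(vapply(x$params, length, integer(1L)))
  cat("BR/DTI detection model: ", format(npar, big.mark = ","),
      " parameters\n", sep = "")
  print(x$cfg)
  invisible(x)
}

## ---- protein encoder -------------------------------------------------------

## Because the convolution input rows are embedding rows selected by
## residue code, the window-k convolution is evaluated through per-shift
## lookup tables E_t = emb %*% W_t (one extra zero row for padding):
## Z = b + sum_t E_t[code at shifted position, ]. The tables cost
## k * d * f flops to build and turn the convolution into row gathers;
## .conv_lut() builds them once per optimizer step.
.conv_lut <- function(p, cfg) {
  d <- cfg$embed_dim
  n_codes <- nrow(p$emb)
  lapply(seq_along(cfg$conv_windows), function(j) {
    k <- cfg$conv_windows[j]
    W <- p[[paste0("conv", j, ".W")]]
    lapply(seq_len(k), function(t)
      rbind(p$emb %*% W[((t - 1L) * d + 1L):(t * d), , drop = FALSE],
            0))                                    # row n_codes+1 = padding
  })
}

## seq_int: integer codes 1..21. Returns grid encodings + cache.
.encode_protein_fwd <- function(p, cfg, seq_int, pad_to_grids = NULL,
                                need_cache = TRUE, lut = NULL) {
  L <- length(seq_int)
  if (L > cfg$max_len) {
    warning("sequence of length ", L, " truncated to max_len = ",
            cfg$max_len)
    seq_int <- seq_int[seq_len(cfg$max_len)]
    L <- cfg$max_len
  }
  if (is.null(lut)) lut <- .conv_lut(p, cfg)
  pad_code <- nrow(p$emb) + 1L
  kmax <- max(cfg$conv_windows)
  codes <- c(rep(pad_code, kmax - 1L), seq_int, rep(pad_code, kmax - 1L))
  convs <- vector("list", length(cfg$conv_windows))
  caches <- vector("list", length(cfg$conv_windows))
  for (j in seq_along(cfg$conv_windows)) {
    k <- cfg$conv_windows[j]
    f <- cfg$conv_filters[j]
    pl <- (k - 1L) %/% 2L
    ## output position i covers input positions i-pl .. i-pl+k-1 (0 padded)
    off <- kmax - 1L - pl
    Z <- matrix(rep(p[[paste0("conv", j, ".b")]], each = L), L, f)
    for (t in seq_len(k)) {
      Z <- Z + lut[[j]][[t]][codes[off + t - 1L + seq_len(L)], ,
                             drop = FALSE]
    }
    convs[[j]] <- .relu(Z)
    if (need_cache) caches[[j]] <- list(Z = Z, pl = pl, k = k, off = off)
  }
  C <- do.call(cbind, convs)                        # L x F_total
  spec <- grid_spec(L, cfg$grid_size)
  n_real <- spec$n_grids
  n_grids <- if (is.null(pad_to_grids)) n_real else max(pad_to_grids, n_real)
  Ft <- ncol(C)
  gs <- cfg$grid_size
  ## one-shot per-grid max pooling: pad C to n_real * gs rows with -Inf,
  ## view each (grid, filter) pair as one column, argmax with max.col
  Cp <- matrix(-Inf, n_real * gs, Ft)
  Cp[seq_len(L), ] <- C
  dim(Cp) <- c(gs, n_real * Ft)
  am <- max.col(t(Cp), ties.method = "first")       # within-grid row
  pooled <- Cp[cbind(am, seq_along(am))]
  P <- matrix(0, n_grids, Ft)
  P[seq_len(n_real), ] <- matrix(pooled, n_real, Ft)
  grid_rep <- rep(seq_len(n_real) - 1L, times = Ft)
  amax_real <- matrix(grid_rep * gs + am, n_real, Ft) # global row in C
  proj <- .dense_fwd(P, p$proj.W, p$proj.b, "relu")
  mask <- c(rep(TRUE, n_real), rep(FALSE, n_grids - n_real))
  cache <- NULL
  if (need_cache) {
    ## residue-code indicator of the padded sequence; the conv backward
    ## pools gradients per code with one crossprod per shift
    Mp <- matrix(0, length(codes), pad_code)
    Mp[cbind(seq_along(codes), codes)] <- 1
    cache <- list(seq_int = seq_int, convs = caches, codes = codes,
                  Mp = Mp, kmax = kmax, L = L, Ft = Ft, amax = amax_real,
                  proj = proj, n_real = n_real)
  }
  list(G = proj$y, mask = mask, spec = spec, n_grids = n_grids,
       cache = cache)
}

.encode_protein_bwd <- function(dG, p, cfg, cache, gadd) {
  pr <- .dense_bwd(dG, cache$proj, p$proj.W)
  gadd("proj.W", pr$dW); gadd("proj.b", pr$db)
  dP <- pr$dx
  L <- cache$L; Ft <- cache$Ft
  dC <- matrix(0, L, Ft)
  ## (argmax row, filter) pairs are unique, so a single indexed assignment
  ## scatters the pooled gradients without collisions
  cells <- cbind(as.vector(cache$amax),
                 rep(seq_len(Ft), each = cache$n_real))
  dC[cells] <- as.vector(dP[seq_len(cache$n_real), , drop = FALSE])
  d <- cfg$embed_dim
  n_codes <- nrow(p$emb)
  demb <- matrix(0, n_codes, d)
  col0 <- 0L
  for (j in seq_along(cfg$conv_windows)) {
    f <- cfg$conv_filters[j]
    cc <- cache$convs[[j]]
    W <- p[[paste0("conv", j, ".W")]]
    dZ <- dC[, (col0 + 1L):(col0 + f), drop = FALSE] * (cc$Z > 0)
    col0 <- col0 + f
    dW <- matrix(0, cc$k * d, f)
    for (t in seq_len(cc$k)) {
      ## per-code gradient sums at this shift: S = Mp_slice' dZ, then
      ## dW_t = emb' S and demb += S W_t'
      rows <- cc$off + t - 1L + seq_len(L)
      S <- crossprod(cache$Mp[rows, seq_len(n_codes), drop = FALSE], dZ)
      wr <- ((t - 1L) * d + 1L):(t * d)
      dW[wr, ] <- crossprod(p$emb, S)
      demb <- demb + tcrossprod(S, W[wr, , drop = FALSE])
    }
    gadd(paste0("conv", j, ".W"), dW)
    gadd(paste0("conv", j, ".b"), colSums(dZ))
  }
  gadd("emb", demb)
  invisible(NULL)
}

## ---- full forward ----------------------------------------------------------

## sample: list(seq_int, fp). mode: "br", "dti" or "both".
.hots_fwd <- function(p, cfg, seq_int, fp, mode = "both", train = FALSE,
                      pad_to_grids = NULL, need_cache = train, lut = NULL) {
  enc <- .encode_protein_fwd(p, cfg, seq_int, pad_to_grids,
                             need_cache = need_cache, lut = lut)
  comp <- .dense_fwd(matrix(fp, 1L), p$comp.W, p$comp.b, "relu")
  n <- enc$n_grids
  X0 <- rbind(comp$y, enc$G) + .pe_matrix(n + 1L, cfg$H)
  mask <- c(TRUE, enc$mask)
  X <- X0
  br_caches <- vector("list", cfg$n_br_blocks)
  attention <- list()
  for (b in seq_len(cfg$n_br_blocks)) {
    blk <- .block_fwd(X, p, paste0("br", b), cfg, mask, train)
    X <- blk$y
    br_caches[[b]] <- blk$cache
    attention[[paste0("br", b)]] <- blk$attention
  }
  X_br <- X
  out <- list(n_grids = n, mask = enc$mask, spec = enc$spec,
              attention = attention)

  det_cache <- NULL
  if (mode %in% c("br", "both")) {
    Xg <- X_br[-1L, , drop = FALSE]
    d1 <- .dense_fwd(Xg, p$det.W1, p$det.b1, "relu")
    d2 <- .dense_fwd(d1$y, p$det.W2, p$det.b2, "linear")
    A <- length(cfg$anchors)
    S <- .sigmoid(d2$y)
    out$det <- list(c = S[, seq_len(A), drop = FALSE],
                    w = S[, A + seq_len(A), drop = FALSE],
                    p = S[, 2L * A + seq_len(A), drop = FALSE],
                    valid = enc$mask)
    det_cache <- list(d1 = d1, d2 = d2, S = S)
  }

  dti_cache <- NULL
  if (mode %in% c("dti", "both")) {
    if (cfg$dti_mode == "full") {
      Xd <- X_br; dmask <- mask
    } else {
      Xd <- X_br[1L, , drop = FALSE]; dmask <- TRUE
    }
    dti_blk_caches <- vector("list", cfg$n_dti_blocks)
    for (b in seq_len(cfg$n_dti_blocks)) {
      blk <- .block_fwd(Xd, p, paste0("dti", b), cfg, dmask, train)
      Xd <- blk$y
      dti_blk_caches[[b]] <- blk$cache
      attention[[paste0("dti", b)]] <- blk$attention
    }
    h1 <- .dense_fwd(Xd[1L, , drop = FALSE], p$dti.W1, p$dti.b1, "relu")
    h2 <- .dense_fwd(h1$y, p$dti.W2, p$dti.b2, "linear")
    out$p_dti <- .sigmoid(h2$y[1L, 1L])
    out$z_dti <- h2$y[1L, 1L]
    out$attention <- attention
    dti_cache <- list(blocks = dti_blk_caches, h1 = h1, h2 = h2)
  }

  if (need_cache) {
    out$cache <- list(enc = enc, comp = comp, br = br_caches,
                      det = det_cache, dti = dti_cache, mask = mask,
                      X_br = X_br, mode = mode)
  }
  out
}

## Backward pass. dZdet: (n_grids x 3A) gradient w.r.t. the detection head
## pre-sigmoid outputs (or NULL); dz_dti: scalar gradient w.r.t. the DTI
## pre-sigmoid logit (or NULL). Returns the named gradient list.
## Pass a shared `ge` accumulator to sum gradients over a batch without
## per-sample list merging; with ge = NULL the gradient list is returned.
.hots_bwd <- function(p, cfg, fwd, dZdet = NULL, dz_dti = NULL, ge = NULL) {
  own_env <- is.null(ge)
  if (own_env) ge <- .grad_env()
  gadd <- ge$add
  cache <- fwd$cache
  n <- fwd$n_grids
  dX_br <- matrix(0, n + 1L, cfg$H)

  if (!is.null(dz_dti)) {
    dh2 <- matrix(dz_dti, 1L, 1L)
    b2 <- .dense_bwd(dh2, cache$dti$h2, p$dti.W2)
    gadd("dti.W2", b2$dW); gadd("dti.b2", b2$db)
    b1 <- .dense_bwd(b2$dx, cache$dti$h1, p$dti.W1)
    gadd("dti.W1", b1$dW); gadd("dti.b1", b1$db)
    nd <- if (cfg$dti_mode == "full") n + 1L else 1L
    dXd <- matrix(0, nd, cfg$H)
    dXd[1L, ] <- b1$dx
    for (b in rev(seq_len(cfg$n_dti_blocks))) {
      dXd <- .block_bwd(dXd, cache$dti$blocks[[b]], p, paste0("dti", b), gadd)
    }
    if (cfg$dti_mode == "full") {
      dX_br <- dX_br + dXd
    } else {
      dX_br[1L, ] <- dX_br[1L, ] + dXd[1L, ]
    }
  }

  if (!is.null(dZdet)) {
    d2 <- .dense_bwd(dZdet, cache$det$d2, p$det.W2)
    gadd("det.W2", d2$dW); gadd("det.b2", d2$db)
    d1 <- .dense_bwd(d2$dx, cache$det$d1, p$det.W1)
    gadd("det.W1", d1$dW); gadd("det.b1", d1$db)
    dX_br[-1L, ] <- dX_br[-1L, , drop = FALSE] + d1$dx
  }

  dX <- dX_br
  for (b in rev(seq_len(cfg$n_br_blocks))) {
    dX <- .block_bwd(dX, cache$br[[b]], p, paste0("br", b), gadd)
  }
  ## positional encoding is additive: gradient passes through unchanged
  dtok <- dX[1L, , drop = FALSE]
  cb <- .dense_bwd(dtok, cache$comp, p$comp.W)
  gadd("comp.W", cb$dW); gadd("comp.b", cb$db)
  dG <- dX[-1L, , drop = FALSE]
  .encode_protein_bwd(dG, p, cfg, cache$enc$cache, gadd)
  if (own_env) ge$get() else invisible(NULL)
}
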