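# Independent brute-force oracles used across the suite. These are
# deliberately written as naive enumerations / dynamic programs, separate
# from the package's implementations.

# IoU by enumerating integer positions (integer intervals only).
oracle_iou <- function(a, b) {
  pa <- seq(a[1], a[2] - 1)
  pb <- seq(b[1], b[2] - 1)
  length(intersect(pa, pb)) / length(union(pa, pb))
}

# Window expansion + merge by enumerating covered positions.
oracle_expand <- function(residues, L, e = 9) {
  covered <- sort(unique(unlist(lapply(residues - 1, function(r0) {
    lo <- max(0, r0 - floor((e - 1) / 2))
    hi <- min(L - 1, r0 + ceiling((e - 1) / 2))
    lo:hi
  }))))
  # split into runs of consecutive positions
  runs <- split(covered, cumsum(c(1, diff(covered) != 1)))
  t(vapply(runs, function(r) c(min(r), max(r) + 1), numeric(2)))
}

# Pooled AP: independent greedy matching + numeric integration of the
# interpolated precision over a fine recall grid.
oracle_ap <- function(predictions, truths, iou_threshold = 0.5,
                      grid_n = 4000) {
  ord <- order(-predictions$confidence, predictions$complex_id,
               predictions$start)
  preds <- predictions[ord, , drop = FALSE]
  used <- rep(FALSE, nrow(truths))
  tp <- numeric(nrow(preds))
  for (k in seq_len(nrow(preds))) {
    best <- 0; best_t <- 0
    for (t in seq_len(nrow(truths))) {
      if (used[t] || truths$complex_id[t] != preds$complex_id[k]) next
      i <- max(0, min(preds$end[k], truths$end[t]) -
                 max(preds$start[k], truths$start[t]))
      u <- (preds$end[k] - preds$start[k]) +
        (truths$end[t] - truths$start[t]) - i
      v <- i / u
      if (v > best) { best <- v; best_t <- t }
    }
    if (best >= iou_threshold) { used[best_t] <- TRUE; tp[k] <- 1 }
  }
  prec <- cumsum(tp) / seq_along(tp)
  rec <- cumsum(tp) / nrow(truths)
  rgrid <- seq(0, 1, length.out = grid_n + 1)[-1]
  pint <- vapply(rgrid, function(r) {
    ok <- which(rec >= r - 1e-12)
    if (length(ok) == 0) 0 else max(prec[ok[1]:length(prec)])
  }, numeric(1))
  mean(pint)
}

# Top-n success by integer position counting.
oracle_topn <- function(predictions, truths, extra = 0) {
  out <- vapply(unique(truths$complex_id), function(cx) {
    tr <- truths[truths$complex_id == cx, , drop = FALSE]
    pr <- predictions[predictions$complex_id == cx, , drop = FALSE]
    pr <- pr[order(-pr$confidence, pr$start), , drop = FALSE]
    pr <- utils::head(pr, 1 + extra)
    hits <- vapply(seq_len(nrow(tr)), function(t) {
      tpos <- seq(tr$start[t], tr$end[t] - 1)
      any(vapply(seq_len(nrow(pr)), function(k) {
        ov <- max(0, min(pr$end[k], tr$end[t]) -
                    max(pr$start[k], tr$start[t]))
        ov / (tr$end[t] - tr$start[t]) >= 0.5
      }, logical(1)))
    }, logical(1))
    mean(hits)
  }, numeric(1))
  mean(out)
}

# Affine-gap Smith-Waterman (Gotoh) with BLOSUM62, gap open 10 / extend
# 0.5, matching the convention that a length-g gap costs open + g * ext.
oracle_sw <- function(a, b, gap_open = 10, gap_ext = 0.5) {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  blosum <- as.matrix(e$BLOSUM62)
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  M <- matrix(0, n + 1, m + 1)   # match/mismatch ending
  X <- matrix(-Inf, n + 1, m + 1) # gap in b (vertical)
  Y <- matrix(-Inf, n + 1, m + 1) # gap in a (horizontal)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      X[i, j] <- max(M[i - 1, j] - gap_open - gap_ext,
                     X[i - 1, j] - gap_ext)
      Y[i, j] <- max(M[i, j - 1] - gap_open - gap_ext,
                     Y[i, j - 1] - gap_ext)
      s <- blosum[A[i - 1], B[j - 1]]
      M[i, j] <- max(0, M[i - 1, j - 1] + s, X[i - 1, j - 1] + s,
                     Y[i - 1, j - 1] + s)
      if (M[i, j] > best) best <- M[i, j]
    }
  }
  best
}

oracle_sw_norm <- function(a, b, ...) {
  oracle_sw(a, b, ...) / sqrt(oracle_sw(a, a, ...) * oracle_sw(b, b, ...))
}

random_protein <- function(L) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y"), L,
               replace = TRUE), collapse = "")
}
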