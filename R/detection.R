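## Detection mechanics: ground-truth target assignment, decoding of raw
## (c, w, p) outputs back to sequence intervals, focal loss and the
## combined detection loss.

#' Construct a detection tensor
#'
#' Per grid `g` and anchor `i`, a detection tensor holds centre offsets
#' `c` in `[0, 1)` (fraction of the grid), log-width ratios `w` in
#' `[0, 1)` and confidences `p`. For targets, `p` is the 0/1
#' responsibility indicator; for model outputs all three are sigmoid
#' activations in `(0, 1)`.
#'
#' @param c,w,p Numeric `n_grids x n_anchors` matrices.
#' @param resp Logical responsibility matrix (targets only; `NULL` for
#'   outputs).
#' @param valid Logical per-grid validity (padding mask).
#' @return A `hots_detection` list.
#' @export
detection_tensor <- function(c, w, p, resp = NULL, valid = rep(TRUE, nrow(p))) {
  stopifnot(is.matrix(c), is.matrix(w), is.matrix(p),
            all(dim(c) == dim(w)), all(dim(c) == dim(p)),
            length(valid) == nrow(p))
  structure(list(c = c, w = w, p = p, resp = resp, valid = valid),
            class = "hots_detection")
}

#' Encode ground-truth binding regions as detection targets
#'
#' Each BR is assigned to the grid containing its centre. The anchor is
#' the one whose clipped log-ratio target `w = clip(log(W / r_i), 0,
#' 1 - width_eps)` gives the decodable width `r_i * exp(w)` of maximal IoU
#' with the true width (same-centre IoU, i.e. the min/max width ratio).
#' The centre target is `(centre - s_g) / grid_size`. When two BRs fall in
#' the same grid the wider one is assigned first; later BRs take their
#' next-best free anchor in that grid, or are dropped with a warning.
#'
#' @param brs 2-column `(start, end)` matrix of ground-truth regions
#'   (0-based half-open), or an empty matrix.
#' @param spec A [grid_spec()] covering the (padded) sequence.
#' @param anchors Anchor widths `r_i`.
#' @param width_eps Upper clip margin for the width target.
#' @return A `hots_detection` target tensor: `resp` marks the single
#'   responsible `(grid, anchor)` cell per encoded BR, `p` is its numeric
#'   0/1 copy, and `c`/`w` are defined where responsible.
#' @export
encode_targets <- function(brs, spec, anchors, width_eps = 1e-3) {
  stopifnot(inherits(spec, "hots_grid_spec"))
  if (!is.matrix(brs)) brs <- matrix(brs, ncol = 2L, byrow = TRUE)
  n <- spec$n_grids; A <- length(anchors)
  ct <- matrix(0, n, A); wt <- matrix(0, n, A)
  resp <- matrix(FALSE, n, A)
  if (nrow(brs) > 0L) {
    .check_interval(brs)
    widths <- brs[, 2L] - brs[, 1L]
    for (b in order(widths, decreasing = TRUE)) {
      center <- (brs[b, 1L] + brs[b, 2L]) / 2
      W <- widths[b]
      upper <- n * spec$grid_size
      if (center < 0 || center >= upper) {
        stop("BR centre ", center, " outside the padded sequence [0, ",
             upper, ")")
      }
      g <- as.integer(floor(center / spec$grid_size)) + 1L
      wtg <- pmin(pmax(log(W / anchors), 0), 1 - width_eps)
      dec_w <- anchors * exp(wtg)
      a_iou <- pmin(dec_w, W) / pmax(dec_w, W)   # same-centre IoU
      assigned <- FALSE
      ## ties (several anchors decode W exactly) go to the least-stretched
      ## anchor, i.e. the smallest width target
      for (i in order(-a_iou, wtg)) {
        if (!resp[g, i]) {
          resp[g, i] <- TRUE
          ct[g, i] <- (center - spec$starts[g]) / spec$grid_size
          wt[g, i] <- wtg[i]
          assigned <- TRUE
          break
        }
      }
      if (!assigned) {
        warning("BR [", brs[b, 1L], ", ", brs[b, 2L], ") dropped: all ",
                A, " anchors of grid ", g - 1L, " already responsible")
      }
    }
  }
  detection_tensor(ct, wt, p = resp * 1, resp = resp)
}

#' Decode raw detection outputs into predicted intervals
#'
#' Applies the reconstruction formulas `centre = s_g + grid_size * c` and
#' `width = r_i * exp(w)` to every `(grid, anchor)` cell whose confidence
#' passes `conf_threshold`, then optionally suppresses near-duplicate
#' predictions with greedy non-maximum suppression (higher-confidence
#' interval kept when IoU >= `nms_iou`).
#'
#' @param outputs A `hots_detection` output tensor (entries in `(0, 1)`).
#' @param spec The [grid_spec()] the outputs were computed on.
#' @param anchors Anchor widths.
#' @param conf_threshold Minimum confidence to decode (default 0.5).
#' @param nms_iou IoU threshold for suppression (default 0.5).
#' @param nms Apply non-maximum suppression (default `TRUE`).
#' @return A data frame sorted by descending confidence with columns
#'   `start`, `end`, `center`, `width`, `confidence`, `grid` (0-based),
#'   `anchor` (index into `anchors`).
#' @export
decode <- function(outputs, spec, anchors, conf_threshold = 0.5,
                   nms_iou = 0.5, nms = TRUE) {
  stopifnot(inherits(outputs, "hots_detection"),
            inherits(spec, "hots_grid_spec"))
  A <- length(anchors); n <- nrow(outputs$p)
  keep <- which(outputs$p >= conf_threshold & outputs$valid, arr.ind = TRUE)
  empty <- data.frame(start = numeric(), end = numeric(), center = numeric(),
                      width = numeric(), confidence = numeric(),
                      grid = integer(), anchor = integer())
  if (nrow(keep) == 0L) return(empty)
  g <- keep[, 1L]; i <- keep[, 2L]
  center <- spec$starts[g] + spec$grid_size * outputs$c[keep]
  width <- anchors[i] * exp(outputs$w[keep])
  out <- data.frame(start = center - width / 2, end = center + width / 2,
                    center = center, width = width,
                    confidence = outputs$p[keep],
                    grid = as.integer(g - 1L), anchor = as.integer(i))
  out <- out[order(-out$confidence, out$start), , drop = FALSE]
  if (nms && nrow(out) > 1L) {
    kept <- logical(nrow(out))
    for (r in seq_len(nrow(out))) {
      ok <- TRUE
      for (s in which(kept)) {
        if (iou(c(out$start[r], out$end[r]),
                c(out$start[s], out$end[s])) >= nms_iou) {
          ok <- FALSE; break
        }
      }
      kept[r] <- ok
    }
    out <- out[kept, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Focal loss
#'
#' `FL(p_t) = -(1 - p_t)^gamma * log(p_t)` with `p_t = p` for positives
#' and `1 - p` for negatives. At `gamma = 0` this is binary cross-entropy;
#' larger `gamma` down-weights well-classified (easy) examples, countering
#' the scarcity of binding-region cells among grid-anchor cells.
#'
#' @param p Predicted probabilities (vectorized; clamped to
#'   `[1e-7, 1 - 1e-7]`).
#' @param y Binary labels (0/1, recycled against `p`).
#' @param gamma Focusing exponent, `>= 0`.
#' @return Non-negative loss values, same length as `p`.
#' @export
#' @examples
#' focal_loss(0.9, 1, gamma = 2) # (0.1)^2 * -log(0.9)
focal_loss <- function(p, y, gamma = 2) {
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma < 0)
    stop("'gamma' must be a single number >= 0")
  if (!all(y %in% c(0, 1))) stop("'y' must be binary (0/1)")
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  pt <- ifelse(y == 1, p, 1 - p)
  -(1 - pt)^gamma * log(pt)
}

#' Combined detection loss
#'
#' `L = lambda_reg * (|c_true - c_pred| + |w_true - w_pred|) +
#' lambda_conf * FL(p_t)`. The L1 regression terms are averaged over
#' responsible cells only; the focal confidence term is averaged over all
#' valid (unmasked) grid-anchor cells, with labels taken from the target's
#' responsibility flags.
#'
#' @param targets Target `hots_detection` (from [encode_targets()]).
#' @param outputs Output `hots_detection` (model predictions).
#' @param lambda_reg,lambda_conf Term weights.
#' @param gamma Focal exponent.
#' @return Scalar loss, with attributes `regression` and `focal` holding
#'   the two unweighted components.
#' @export
br_loss <- function(targets, outputs, lambda_reg = 1, lambda_conf = 1,
                    gamma = 2) {
  stopifnot(inherits(targets, "hots_detection"),
            inherits(outputs, "hots_detection"),
            all(dim(targets$p) == dim(outputs$p)))
  valid <- targets$valid & outputs$valid
  vmat <- matrix(valid, nrow(targets$p), ncol(targets$p))
  resp <- targets$resp & vmat
  if (any(resp)) {
    reg <- mean(abs(targets$c[resp] - outputs$c[resp]) +
                  abs(targets$w[resp] - outputs$w[resp]))
  } else {
    reg <- 0
  }
  fl <- mean(focal_loss(outputs$p[vmat], (targets$resp * 1)[vmat], gamma))
  total <- lambda_reg * reg + lambda_conf * fl
  attr(total, "regression") <- reg
  attr(total, "focal") <- fl
  total
}

## Gradient of br_loss w.r.t. the detection head's pre-sigmoid outputs,
## as an n x 3A matrix in the head's column layout [c | w | p].
.br_loss_grad_z <- function(targets, outputs, cfg) {
  A <- ncol(targets$p)
  n <- nrow(targets$p)
  valid <- targets$valid & outputs$valid
  vmat <- matrix(valid, n, A)
  resp <- targets$resp & vmat
  n_resp <- sum(resp)
  n_valid <- sum(vmat)
  dZ <- matrix(0, n, 3L * A)
  if (n_resp > 0L) {
    for (blk in 1:2) {
      pred <- if (blk == 1L) outputs$c else outputs$w
      tgt <- if (blk == 1L) targets$c else targets$w
      g <- matrix(0, n, A)
      g[resp] <- sign(pred[resp] - tgt[resp]) * pred[resp] *
        (1 - pred[resp]) * cfg$lambda_reg / n_resp
      dZ[, (blk - 1L) * A + seq_len(A)] <- g
    }
  }
  p <- pmin(pmax(outputs$p, 1e-7), 1 - 1e-7)
  gam <- cfg$gamma
  gpos <- gam * p * (1 - p)^gam * log(p) - (1 - p)^(gam + 1)
  gneg <- p^(gam + 1) - gam * (1 - p) * p^gam * log(1 - p)
  gp <- ifelse(targets$resp, gpos, gneg) * cfg$lambda_conf / n_valid
  gp[!vmat] <- 0
  dZ[, 2L * A + seq_len(A)] <- gp
  dZ
}
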