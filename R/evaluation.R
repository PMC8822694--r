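## Detection and classification metrics: pooled interpolated average
## precision, top-n / top-(n+2) success rates, DTI classification metrics
## and the normalized Smith-Waterman similarity audit.

#' Interpolated average precision of binding-region detection
#'
#' Pools all predictions across complexes, sorts them by descending
#' confidence (ties broken by complex id then start, for reproducibility)
#' and greedily marks each prediction a true positive when its IoU with an
#' as-yet-unmatched ground-truth region of the same complex reaches
#' `iou_threshold` (the best-IoU unmatched truth is consumed). Precision
#' and recall are computed at every rank, precision is interpolated with
#' `p_interp(r) = max over r' >= r of p(r')`, and AP is the area under the
#' interpolated precision-recall curve (an interpolated AUPR).
#'
#' @param predictions Data frame with columns `complex_id`, `start`,
#'   `end`, `confidence`.
#' @param truths Data frame with columns `complex_id`, `start`, `end`;
#'   must be non-empty.
#' @param iou_threshold True-positive IoU threshold (default 0.5).
#' @param curve Also return the PR-curve points.
#' @return AP in `[0, 1]`; with `curve = TRUE`, a list with `ap` and
#'   `curve` (data frame `recall`, `precision`, `precision_interp`).
#' @export
average_precision <- function(predictions, truths, iou_threshold = 0.5,
                              curve = FALSE) {
  if (is.null(truths) || nrow(truths) == 0L)
    stop("'truths' must contain at least one ground-truth region")
  if (is.null(predictions) || nrow(predictions) == 0L) {
    return(if (curve) list(ap = 0, curve = NULL) else 0)
  }
  ord <- order(-predictions$confidence, predictions$complex_id,
               predictions$start)
  preds <- predictions[ord, , drop = FALSE]
  n_truth <- nrow(truths)
  matched <- logical(n_truth)
  tp <- logical(nrow(preds))
  for (k in seq_len(nrow(preds))) {
    cand <- which(truths$complex_id == preds$complex_id[k] & !matched)
    if (length(cand) == 0L) next
    ious <- vapply(cand, function(t)
      iou(c(preds$start[k], preds$end[k]),
          c(truths$start[t], truths$end[t])), numeric(1L))
    best <- which.max(ious)
    if (ious[best] >= iou_threshold) {
      matched[cand[best]] <- TRUE
      tp[k] <- TRUE
    }
  }
  cum_tp <- cumsum(tp)
  precision <- cum_tp / seq_along(tp)
  recall <- cum_tp / n_truth
  p_interp <- rev(cummax(rev(precision)))
  ap <- sum(diff(c(0, recall)) * p_interp)
  if (!curve) return(ap)
  list(ap = ap, curve = data.frame(recall = recall, precision = precision,
                                   precision_interp = p_interp))
}

#' Top-n / top-(n+2) success rate
#'
#' For each complex the `n + extra` highest-confidence predictions are
#' selected (`n` = the complex's number of interacting-ligand records,
#' default 1). A ground-truth region counts as hit when a selected
#' prediction covers at least half of its positions (overlap divided by
#' truth width -- a coverage criterion, deliberately not IoU). The
#' complex-level score is the fraction of its truth regions hit and the
#' reported rate is the mean over complexes; `per_complex_any = TRUE`
#' instead scores a complex 1 when any truth is hit.
#'
#' @param predictions,truths Data frames with `complex_id`, `start`,
#'   `end` (+ `confidence` for predictions).
#' @param extra Extra predictions beyond n (0 for top-n, 2 for
#'   top-(n+2)).
#' @param n_ligands Optional named vector giving n per complex id
#'   (defaults to 1 for every complex).
#' @param coverage Minimum covered fraction of a truth region (default
#'   0.5).
#' @param per_complex_any Score complexes by any-hit instead of the
#'   per-truth fraction.
#' @return Success rate in `[0, 1]`.
#' @export
topn_success <- function(predictions, truths, extra = 0L, n_ligands = NULL,
                         coverage = 0.5, per_complex_any = FALSE) {
  if (is.null(truths) || nrow(truths) == 0L)
    stop("'truths' must contain at least one ground-truth region")
  complexes <- unique(truths$complex_id)
  scores <- vapply(complexes, function(cx) {
    tr <- truths[truths$complex_id == cx, , drop = FALSE]
    n <- if (!is.null(n_ligands) && !is.na(n_ligands[cx])) n_ligands[cx] else 1L
    pr <- predictions[predictions$complex_id == cx, , drop = FALSE]
    take <- min(nrow(pr), n + extra)
    hit <- rep(FALSE, nrow(tr))
    if (take > 0L) {
      pr <- pr[order(-pr$confidence, pr$start), , drop = FALSE][seq_len(take), ]
      for (t in seq_len(nrow(tr))) {
        ov <- pmax(0, pmin(pr$end, tr$end[t]) - pmax(pr$start, tr$start[t]))
        hit[t] <- any(ov / (tr$end[t] - tr$start[t]) >= coverage)
      }
    }
    if (per_complex_any) as.numeric(any(hit)) else mean(hit)
  }, numeric(1L))
  mean(scores)
}

#' DTI classification metrics
#'
#' AUROC (rank-based), AUPR (average precision over the
#' confidence-sorted list) and threshold-0.5 accuracy, precision, recall,
#' specificity and F1.
#'
#' @param scores Predicted probabilities.
#' @param labels Binary labels (at least one of each class).
#' @return List of metrics.
#' @export
dti_metrics <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("'scores' and 'labels' must have equal length")
  if (!all(labels %in% c(0, 1)) || length(unique(labels)) < 2L)
    stop("'labels' must contain both classes (0 and 1)")
  auroc <- as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = scores, quiet = TRUE,
    direction = "<", levels = c(0, 1))))
  ord <- order(-scores)
  y <- labels[ord]
  prec_at_k <- cumsum(y) / seq_along(y)
  aupr <- sum(prec_at_k[y == 1]) / sum(y)
  pred <- as.integer(scores >= 0.5)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0); fn <- sum(pred == 0 & labels == 1)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- tp / (tp + fn)
  f1 <- if (!is.na(precision) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  list(auroc = auroc, aupr = aupr,
       accuracy = (tp + tn) / length(labels),
       precision = precision, recall = recall,
       specificity = tn / (tn + fp), f1 = f1,
       n = length(labels), n_pos = sum(labels == 1))
}

#' Normalized Smith-Waterman similarity
#'
#' Local-alignment score normalized by the geometric mean of the two
#' self-alignment scores: `SW(a, b) / sqrt(SW(a, a) * SW(b, b))`.
#' Symmetric; 1 for identical sequences. Default scoring is BLOSUM62 with
#' gap opening 10 and gap extension 0.5.
#'
#' @param a,b Amino-acid strings (non-empty).
#' @param substitution_matrix Substitution matrix name or matrix.
#' @param gap_opening,gap_extension Gap penalties (positive costs).
#' @return Similarity in `(0, 1]`.
#' @export
sw_norm <- function(a, b, substitution_matrix = "BLOSUM62",
                    gap_opening = 10, gap_extension = 0.5) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  sw <- function(x, y) {
    Biostrings::score(Biostrings::pairwiseAlignment(
      Biostrings::AAString(x), Biostrings::AAString(y), type = "local",
      substitutionMatrix = substitution_matrix,
      gapOpening = gap_opening, gapExtension = gap_extension))
  }
  sab <- sw(a, b)
  sab / sqrt(sw(a, a) * sw(b, b))
}

#' Best-training-match similarity report
#'
#' For every test protein, the maximum [sw_norm()] similarity to any
#' training protein -- the audit used to stratify test performance by
#' train/test similarity.
#'
#' @param test_proteins,train_proteins Named character vectors of
#'   sequences.
#' @param ... Passed to [sw_norm()].
#' @return Data frame `test_id`, `best_train_id`, `sw_norm`.
#' @export
similarity_report <- function(test_proteins, train_proteins, ...) {
  stopifnot(length(test_proteins) > 0L, length(train_proteins) > 0L)
  rows <- lapply(names(test_proteins), function(tid) {
    sims <- vapply(train_proteins, function(tr)
      sw_norm(test_proteins[[tid]], tr, ...), numeric(1L))
    b <- which.max(sims)
    data.frame(test_id = tid, best_train_id = names(train_proteins)[b],
               sw_norm = sims[b], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
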