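## Binding-region construction: residue-level binding information (BI) is
## expanded to fixed-length windows and merged into contiguous binding
## regions (BRs); jittered BRs augment detection training.

#' Merge a set of intervals
#'
#' Overlapping or touching (gap 0) intervals are merged; touching windows
#' form one contiguous subsequence and are therefore treated as a single
#' region. Result is sorted by start and pairwise disjoint.
#'
#' @param x 2-column numeric matrix of `(start, end)` rows (0-based
#'   half-open).
#' @return Sorted, disjoint 2-column matrix.
#' @export
merge_intervals <- function(x) {
  if (!is.matrix(x)) x <- matrix(x, ncol = 2L, byrow = TRUE)
  if (nrow(x) == 0L) return(x)
  .check_interval(x)
  x <- x[order(x[, 1L], x[, 2L]), , drop = FALSE]
  out <- matrix(NA_real_, nrow(x), 2L)
  cur <- x[1L, ]
  k <- 0L
  for (i in seq_len(nrow(x))[-1L]) {
    if (x[i, 1L] <= cur[2L]) {          # overlap or touch: extend
      cur[2L] <- max(cur[2L], x[i, 2L])
    } else {
      k <- k + 1L; out[k, ] <- cur; cur <- x[i, ]
    }
  }
  k <- k + 1L; out[k, ] <- cur
  out <- out[seq_len(k), , drop = FALSE]
  colnames(out) <- c("start", "end")
  out
}

#' Expand binding residues into merged binding regions
#'
#' Each binding residue (1-based index) becomes a window of
#' `expansion_length` residues centred on it (left-biased for even
#' lengths: the residue sits at offset `floor((e - 1) / 2)` inside its
#' window). Windows are clipped to the sequence and overlapping or touching
#' windows are merged, yielding the contiguous binding regions used as
#' detection ground truth.
#'
#' @param residues Integer vector of 1-based binding-residue indices
#'   (non-empty, within `[1, protein_length]`).
#' @param protein_length Sequence length.
#' @param expansion_length Window length each residue is expanded to
#'   (default 9).
#' @return Sorted, disjoint 2-column matrix of 0-based half-open
#'   `(start, end)` regions covering every input residue.
#' @export
#' @examples
#' expand_and_merge(c(50, 53), protein_length = 300) # one region [45, 57)
expand_and_merge <- function(residues, protein_length,
                             expansion_length = 9L) {
  expansion_length <- as.integer(expansion_length)
  if (is.na(expansion_length) || expansion_length < 1L)
    stop("'expansion_length' must be >= 1")
  residues <- as.integer(residues)
  if (length(residues) == 0L || anyNA(residues))
    stop("'residues' must be a non-empty vector of residue indices")
  bad <- residues[residues < 1L | residues > protein_length]
  if (length(bad)) {
    stop("binding residue ", bad[1L], " outside the sequence (1-",
         protein_length, ")")
  }
  r0 <- unique(residues) - 1L                     # to 0-based
  left <- pmax(0L, r0 - (expansion_length - 1L) %/% 2L)
  right <- pmin(protein_length, r0 + (expansion_length - 1L + 1L) %/% 2L + 1L)
  merge_intervals(cbind(start = as.numeric(left), end = as.numeric(right)))
}

#' Randomly jitter a binding region under an IoU constraint
#'
#' Draws a shifted and rescaled copy of `region` whose IoU with the
#' original is at least `iou_min`; such jittered regions are fed to the
#' detector during training as augmentation. The shift is uniform in
#' plus/minus `ceiling(width / 2)` and the width is scaled by a uniform
#' factor in `[2/3, 3/2]`, rejection-sampled against the IoU constraint
#' and the sequence bounds. Uses R's global RNG; seed with [set.seed()] for
#' reproducibility.
#'
#' @param region Interval (length-2 numeric, 0-based half-open).
#' @param protein_length Sequence length (jittered region stays inside
#'   `[0, protein_length)`).
#' @param iou_min Minimum IoU with the input region (default 0.7, in
#'   `(0, 1)`).
#' @param max_tries Rejection budget; on exhaustion the unjittered region
#'   is returned with a warning.
#' @return A length-2 numeric `(start, end)` interval.
#' @export
jitter_br <- function(region, protein_length, iou_min = 0.7,
                      max_tries = 200L) {
  .check_interval(region)
  if (!is.numeric(iou_min) || iou_min <= 0 || iou_min >= 1)
    stop("'iou_min' must be in (0, 1)")
  w <- region[2L] - region[1L]
  ctr <- (region[1L] + region[2L]) / 2
  half_shift <- ceiling(w / 2)
  for (i in seq_len(max_tries)) {
    shift <- stats::runif(1L, -half_shift, half_shift)
    scale <- stats::runif(1L, 2 / 3, 3 / 2)
    nw <- w * scale
    ns <- ctr + shift - nw / 2
    ne <- ctr + shift + nw / 2
    if (ns < 0 || ne > protein_length || ne - ns < 1) next
    cand <- c(ns, ne)
    if (iou(cand, unclass(region)[1:2]) >= iou_min) {
      return(c(start = unname(ns), end = unname(ne)))
    }
  }
  warning("jitter_br: no candidate met IoU >= ", iou_min, " after ",
          max_tries, " draws; returning the unjittered region")
  c(start = unname(region[1L]), end = unname(region[2L]))
}

#' Fraction of a sequence covered by a set of disjoint regions
#'
#' @param regions 2-column `(start, end)` matrix, assumed disjoint.
#' @param protein_length Sequence length.
#' @return Covered fraction in `[0, 1]`.
#' @export
region_coverage <- function(regions, protein_length) {
  if (!is.matrix(regions)) regions <- matrix(regions, ncol = 2L, byrow = TRUE)
  if (nrow(regions) == 0L) return(0)
  sum(pmin(regions[, 2L], protein_length) - pmax(regions[, 1L], 0)) /
    protein_length
}
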