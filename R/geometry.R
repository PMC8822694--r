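## Interval arithmetic, grid partitioning and IoU shared by all modules.
## Coordinates are 0-based half-open [start, end) internally; 1-based
## inclusive residue indices are converted at the I/O boundary.

#' Construct a sequence interval
#'
#' Intervals are 0-based half-open `[start, end)` spans on a protein
#' sequence; `end` is exclusive, so the width is `end - start`. Starts and
#' ends may be real-valued (decoded predictions are continuous), but must
#' satisfy `start < end`.
#'
#' @param start Start position (0-based, inclusive).
#' @param end End position (exclusive). Must be strictly greater than
#'   `start`.
#' @return A numeric vector `c(start, end)` of class `hots_interval`.
#' @export
#' @examples
#' interval(10, 20)
interval <- function(start, end) {
  if (!is.numeric(start) || !is.numeric(end) || length(start) != 1L ||
      length(end) != 1L || is.na(start) || is.na(end)) {
    stop("'start' and 'end' must be single non-missing numbers")
  }
  if (start < 0) stop("interval start must be >= 0, got ", start)
  if (start >= end) {
    stop("invalid interval: start (", start, ") must be < end (", end, ")")
  }
  structure(c(start = start, end = end), class = "hots_interval")
}

## Decoded predictions may spill past the sequence boundaries, so only
## start < end is required here; the interval() constructor is stricter.
.check_interval <- function(x, what = "interval") {
  if (is.matrix(x)) {
    if (ncol(x) != 2L) stop(what, " matrix must have 2 columns (start, end)")
    bad <- which(!(x[, 1L] < x[, 2L]) | is.na(x[, 1L]) | is.na(x[, 2L]))
    if (length(bad)) {
      stop("invalid ", what, " at row ", bad[1L], ": start=",
           x[bad[1L], 1L], ", end=", x[bad[1L], 2L])
    }
    return(invisible(x))
  }
  if (length(x) != 2L || anyNA(x) || x[1L] >= x[2L]) {
    stop("invalid ", what, ": need start < end, got (",
         paste(format(x), collapse = ", "), ")")
  }
  invisible(x)
}

#' @rdname interval
#' @param x An interval (length-2 numeric) or a 2-column matrix of
#'   intervals.
#' @export
interval_width <- function(x) {
  if (is.matrix(x)) unname(x[, 2L] - x[, 1L]) else unname(x[2L] - x[1L])
}

#' @rdname interval
#' @export
interval_center <- function(x) {
  if (is.matrix(x)) unname((x[, 1L] + x[, 2L]) / 2)
  else unname((x[1L] + x[2L]) / 2)
}

#' Intersection over union of two sequence intervals
#'
#' The overlap of the two spans divided by the length of their union,
#' measured as `|a| + |b| - |a intersect b|`. IoU is symmetric, equals 1
#' for identical intervals and 0 for disjoint ones. Intervals are treated
#' as continuous spans, so real-valued (decoded) intervals need no rounding
#' before evaluation.
#'
#' @param a,b Intervals as length-2 numeric vectors `c(start, end)`, or
#'   2-column matrices with one interval per row (vectorized row-wise; the
#'   two matrices are recycled to a common number of rows).
#' @return IoU value(s) in `[0, 1]`.
#' @export
#' @examples
#' iou(interval(10, 20), interval(15, 25)) # 5 / 15
iou <- function(a, b) {
  if (is.matrix(a) || is.matrix(b)) {
    if (!is.matrix(a)) a <- matrix(a, ncol = 2L, byrow = TRUE)
    if (!is.matrix(b)) b <- matrix(b, ncol = 2L, byrow = TRUE)
    .check_interval(a); .check_interval(b)
    n <- max(nrow(a), nrow(b))
    ia <- rep_len(seq_len(nrow(a)), n); ib <- rep_len(seq_len(nrow(b)), n)
    inter <- pmax(0, pmin(a[ia, 2L], b[ib, 2L]) - pmax(a[ia, 1L], b[ib, 1L]))
    union <- (a[ia, 2L] - a[ia, 1L]) + (b[ib, 2L] - b[ib, 1L]) - inter
    return(inter / union)
  }
  .check_interval(a); .check_interval(b)
  inter <- max(0, min(a[2L], b[2L]) - max(a[1L], b[1L]))
  inter / (unname(a[2L] - a[1L]) + unname(b[2L] - b[1L]) - inter)
}

#' Partition a sequence into fixed-size grids
#'
#' Tiles positions `[0, n_grids * grid_size)` with non-overlapping grids of
#' `grid_size` residues; `n_grids = ceiling(protein_length / grid_size)`,
#' so the last grid may extend past the sequence end (those positions are
#' padding). Grid `g` (0-based) starts at `s_g = g * grid_size`.
#'
#' @param protein_length Sequence length in residues (positive integer).
#' @param grid_size Residues per grid (positive integer).
#' @return A `hots_grid_spec` list with `grid_size`, `n_grids`, `starts`
#'   (0-based start index of each grid) and `protein_length`.
#' @export
#' @examples
#' grid_spec(101, 25) # 5 grids starting at 0, 25, 50, 75, 100
grid_spec <- function(protein_length, grid_size) {
  protein_length <- as.integer(protein_length)
  grid_size <- as.integer(grid_size)
  if (is.na(protein_length) || protein_length < 1L)
    stop("'protein_length' must be a positive integer")
  if (is.na(grid_size) || grid_size < 1L)
    stop("'grid_size' must be a positive integer")
  n_grids <- as.integer(ceiling(protein_length / grid_size))
  structure(
    list(grid_size = grid_size, n_grids = n_grids,
         starts = (seq_len(n_grids) - 1L) * grid_size,
         protein_length = protein_length),
    class = "hots_grid_spec")
}

#' @export
print.hots_grid_spec <- function(x, ...) {
  cat("Grid spec: ", x$n_grids, " grids of ", x$grid_size,
      " residues over a length-", x$protein_length, " sequence\n", sep = "")
  invisible(x)
}

#' Map a sequence position to its grid index
#'
#' @param position 0-based residue position(s); must lie in
#'   `[0, n_grids * grid_size)`.
#' @param spec A [grid_spec()].
#' @return 0-based grid index, `floor(position / grid_size)`.
#' @export
grid_of <- function(position, spec) {
  stopifnot(inherits(spec, "hots_grid_spec"))
  upper <- spec$n_grids * spec$grid_size
  if (any(position < 0 | position >= upper)) {
    bad <- position[position < 0 | position >= upper][1L]
    stop("position ", bad, " outside the padded range [0, ", upper, ")")
  }
  as.integer(floor(position / spec$grid_size))
}
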