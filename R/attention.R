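## Attention analysis: where does the compound token attend? Per-complex
## maximum attention over BR vs non-BR grids, Gumbel fits, a two-sample
## Kolmogorov-Smirnov comparison and Circos-style edge-list export.

## Euler-Mascheroni constant (Gumbel mean = mu + gamma * beta).
.EULER_GAMMA <- 0.5772156649015329

#' Label grids as BR / non-BR
#'
#' A grid is a BR grid iff its span overlaps any ground-truth binding
#' region of the complex.
#'
#' @param brs 2-column `(start, end)` truth matrix (0-based half-open).
#' @param spec A [grid_spec()].
#' @return Logical vector of length `n_grids`.
#' @export
br_grid_labels <- function(brs, spec) {
  stopifnot(inherits(spec, "hots_grid_spec"))
  if (!is.matrix(brs)) brs <- matrix(brs, ncol = 2L, byrow = TRUE)
  vapply(seq_len(spec$n_grids), function(g) {
    gs <- spec$starts[g]; ge <- gs + spec$grid_size
    any(brs[, 1L] < ge & brs[, 2L] > gs)
  }, logical(1L))
}

#' Collect per-complex maximum compound-token attention for BR and non-BR
#' grids
#'
#' For each (protein, compound) complex the compound-token query row of
#' the chosen transformer block is reduced by the maximum over heads, and
#' the maximum attention over BR-labelled grids and over non-BR grids is
#' recorded (one value each per complex; complexes lacking one class
#' contribute to the other side only).
#'
#' @param model A trained `hots_model`.
#' @param corpus A `hots_corpus` with ground-truth BRs.
#' @param block Block name or index into the BR stack (default 1, the
#'   first BR block).
#' @return List with numeric vectors `br` and `nonbr`.
#' @export
collect_max_attention <- function(model, corpus, block = 1L) {
  stopifnot(inherits(model, "hots_model"))
  samples <- .br_samples(corpus)
  block_name <- if (is.character(block)) block else paste0("br", block)
  br_vals <- numeric(0); nonbr_vals <- numeric(0)
  for (sm in samples) {
    fwd <- .hots_fwd(model$params, model$cfg, sm$seq_int, sm$fp,
                     mode = "dti", train = FALSE, need_cache = TRUE)
    heads <- fwd$attention[[block_name]]
    if (is.null(heads)) stop("no attention recorded for block ", block_name)
    ## compound-token query row, grid keys only (drop the token column)
    tok_rows <- matrix(vapply(heads, function(A) A[1L, -1L],
                              numeric(fwd$n_grids)), nrow = fwd$n_grids)
    att <- apply(tok_rows, 1L, max)          # max over heads per grid
    labels <- br_grid_labels(sm$brs, fwd$spec)
    valid <- fwd$mask          # per-grid validity (no token entry)
    if (any(labels & valid))
      br_vals <- c(br_vals, max(att[labels & valid]))
    if (any(!labels & valid))
      nonbr_vals <- c(nonbr_vals, max(att[!labels & valid]))
  }
  list(br = br_vals, nonbr = nonbr_vals)
}

#' Fit a Gumbel distribution by the method of moments
#'
#' `beta = s * sqrt(6) / pi`, `mu = mean - gamma_Euler * beta`, the
#' closed-form moment fit for the extreme-value distribution of
#' per-complex attention maxima.
#'
#' @param samples Numeric vector (n >= 10).
#' @return A `hots_gumbel` list with `mu`, `beta`, `n` and `degenerate`
#'   (TRUE when the sample variance is zero).
#' @export
fit_gumbel <- function(samples) {
  samples <- samples[is.finite(samples)]
  if (length(samples) < 10L)
    stop("need at least 10 samples to fit a Gumbel distribution, got ",
         length(samples))
  s <- stats::sd(samples)
  if (s == 0) {
    warning("zero-variance sample: degenerate Gumbel fit")
    return(structure(list(mu = mean(samples), beta = 0,
                          n = length(samples), degenerate = TRUE),
                     class = "hots_gumbel"))
  }
  beta <- s * sqrt(6) / pi
  structure(list(mu = mean(samples) - .EULER_GAMMA * beta, beta = beta,
                 n = length(samples), degenerate = FALSE),
            class = "hots_gumbel")
}

#' @export
print.hots_gumbel <- function(x, ...) {
  cat(sprintf("Gumbel fit (moments): mu = %.4f, beta = %.4f, n = %d%s\n",
              x$mu, x$beta, x$n,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Draw from a Gumbel distribution by inverse-CDF sampling
#'
#' @param n Number of draws.
#' @param mu Location.
#' @param beta Scale (> 0).
#' @return Numeric vector.
#' @export
rgumbel <- function(n, mu = 0, beta = 1) {
  stopifnot(beta > 0)
  mu - beta * log(-log(stats::runif(n)))
}

#' Two-sample Kolmogorov-Smirnov comparison of attention maxima
#'
#' @param br_samples,nonbr_samples Numeric vectors (n >= 5 each).
#' @return List with `statistic` (D) and `p_value`.
#' @export
ks_compare <- function(br_samples, nonbr_samples) {
  if (length(br_samples) < 5L || length(nonbr_samples) < 5L)
    stop("both samples need n >= 5")
  kt <- suppressWarnings(stats::ks.test(br_samples, nonbr_samples))
  list(statistic = unname(kt$statistic), p_value = kt$p.value)
}

#' Export an attention matrix as a Circos-style edge list
#'
#' Sectors are the compound token followed by the protein grids in
#' sequence order, classed `compound`, `BR` or `non-BR`. Edges are all
#' query-to-key pairs whose weight reaches the retention cutoff: keeping
#' `keep_fraction` of the attention mass range means discarding weights
#' below the `(1 - keep_fraction)` quantile (ties at the cutoff are
#' retained). Edge weights are the raw attention values, unrenormalized.
#'
#' @param attention A `(1 + n_grids) x (1 + n_grids)` row-stochastic
#'   attention matrix (one head).
#' @param br_labels Logical per-grid BR flags (length `n_grids`).
#' @param keep_fraction Fraction of weights retained (default 0.9).
#' @param valid Optional validity mask of length `1 + n_grids`.
#' @return A `hots_edge_list`: `sectors` (data frame `id`, `class`) and
#'   `edges` (data frame `source`, `target`, `weight`).
#' @export
export_circos <- function(attention, br_labels, keep_fraction = 0.9,
                          valid = rep(TRUE, nrow(attention))) {
  stopifnot(is.matrix(attention), nrow(attention) == ncol(attention),
            length(br_labels) == nrow(attention) - 1L,
            keep_fraction > 0, keep_fraction <= 1)
  n <- nrow(attention) - 1L
  ids <- c("compound", sprintf("grid%03d", seq_len(n) - 1L))
  classes <- c("compound", ifelse(br_labels, "BR", "non-BR"))
  w <- attention[valid, valid, drop = FALSE]
  cutoff <- stats::quantile(w, probs = 1 - keep_fraction, names = FALSE)
  keep <- which(attention >= cutoff & outer(valid, valid), arr.ind = TRUE)
  edges <- data.frame(source = ids[keep[, 1L]], target = ids[keep[, 2L]],
                      weight = attention[keep])
  edges <- edges[order(-edges$weight), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(sectors = data.frame(id = ids, class = classes),
                 edges = edges, cutoff = cutoff),
            class = "hots_edge_list")
}

#' @export
print.hots_edge_list <- function(x, ...) {
  cat("Attention edge list: ", nrow(x$edges), " edges over ",
      nrow(x$sectors), " sectors (cutoff ", format(x$cutoff, digits = 4),
      ")\n", sep = "")
  invisible(x)
}

#' Write an attention edge list as JSON
#'
#' @param x A `hots_edge_list`.
#' @param path Output file.
#' @export
write_circos_json <- function(x, path) {
  stopifnot(inherits(x, "hots_edge_list"))
  jsonlite::write_json(list(sectors = x$sectors, edges = x$edges),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Full attention separation report
#'
#' Convenience wrapper: collects per-complex BR/non-BR attention maxima,
#' fits both Gumbel distributions and runs the two-sample KS test.
#'
#' @inheritParams collect_max_attention
#' @return List with `br_fit`, `nonbr_fit`, `ks`, and the raw `samples`.
#' @export
attention_report <- function(model, corpus, block = 1L) {
  samples <- collect_max_attention(model, corpus, block)
  list(br_fit = fit_gumbel(samples$br),
       nonbr_fit = fit_gumbel(samples$nonbr),
       ks = ks_compare(samples$br, samples$nonbr),
       samples = samples)
}
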