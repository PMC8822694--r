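## User-facing wrappers around the network internals.

#' Encode a protein sequence as grid encodings
#'
#' Embeds residues, applies the multi-window 1D convolutions, pools the
#' per-grid maxima of every filter and projects to `H` dimensions per
#' grid. Grids beyond the (optionally padded) sequence are masked.
#'
#' @param model A `hots_model`.
#' @param sequence Amino-acid string (or integer codes from
#'   [encode_sequence()]).
#' @param pad_to_grids Optionally pad with fully masked grids up to this
#'   count (for fixed-size batching).
#' @return List with `encoding` (`n_grids x H` matrix), `mask` (logical
#'   per-grid validity) and `spec` (the [grid_spec()]).
#' @export
encode_protein <- function(model, sequence, pad_to_grids = NULL) {
  stopifnot(inherits(model, "hots_model"))
  seq_int <- if (is.character(sequence)) encode_sequence(sequence)
             else as.integer(sequence)
  enc <- .encode_protein_fwd(model$params, model$cfg, seq_int, pad_to_grids,
                             need_cache = FALSE)
  list(encoding = enc$G, mask = enc$mask, spec = enc$spec)
}

#' Encode a compound fingerprint as a compound token
#'
#' Deterministic dense map from a 2048-bit binary fingerprint to an
#' H-dimensional token; identical fingerprints give identical tokens.
#'
#' @param model A `hots_model`.
#' @param fingerprint Numeric/integer vector of exactly `cfg$fp_bits`
#'   binary entries.
#' @return Numeric vector of length `H`.
#' @export
encode_compound <- function(model, fingerprint) {
  stopifnot(inherits(model, "hots_model"))
  if (length(fingerprint) != model$cfg$fp_bits)
    stop("fingerprint must have exactly ", model$cfg$fp_bits, " bits, got ",
         length(fingerprint))
  if (!all(fingerprint %in% c(0, 1)))
    stop("fingerprint entries must be binary (0/1)")
  out <- .dense_fwd(matrix(as.numeric(fingerprint), 1L),
                    model$params$comp.W, model$params$comp.b, "relu")
  drop(out$y)
}

#' Assemble the compound-grids feature
#'
#' Places the compound token at position 0 and the grid encodings at
#' positions 1..n, then adds the fixed sinusoidal positional encoding, so
#' the feature has length `1 + ceiling(protein_length / grid_size)`.
#'
#' @param token Compound token (length-`H` vector).
#' @param grids Output of [encode_protein()] (or an `n_grids x H` matrix).
#' @param mask Per-grid validity (defaults to the mask in `grids`).
#' @return List with `feature` (`(1 + n_grids) x H`) and `mask` (length
#'   `1 + n_grids`; the token is always valid).
#' @export
assemble <- function(token, grids, mask = NULL) {
  G <- if (is.list(grids)) grids$encoding else grids
  if (is.null(mask)) mask <- if (is.list(grids)) grids$mask else
    rep(TRUE, nrow(G))
  if (length(token) != ncol(G))
    stop("token length (", length(token), ") must equal the grid encoding ",
         "dimension (", ncol(G), ")")
  X <- rbind(matrix(token, 1L), G)
  list(feature = X + .pe_matrix(nrow(X), ncol(X)),
       mask = c(TRUE, mask))
}

#' Run the full network on one protein-compound pair
#'
#' Forward pass through encoder, BR transformer blocks and detection head
#' (`mode = "br"`), optionally continuing through the DTI blocks and DTI
#' head (`mode = "dti"` or `"both"`). Attention weights of every block and
#' head are always recorded.
#'
#' @param model A `hots_model`.
#' @param sequence Amino-acid string or integer codes.
#' @param fingerprint Binary fingerprint vector of length `cfg$fp_bits`.
#' @param mode `"both"` (default), `"br"` or `"dti"`.
#' @param pad_to_grids Optional fixed grid count (padding masked).
#' @return List with `det` (a `hots_detection` output tensor, when BR ran),
#'   `p_dti` (when DTI ran), `spec`, `mask` and `attention` (nested list:
#'   block name -> head -> `(1 + n_grids)^2` row-stochastic matrix).
#' @export
hots_forward <- function(model, sequence, fingerprint,
                         mode = c("both", "br", "dti"),
                         pad_to_grids = NULL) {
  stopifnot(inherits(model, "hots_model"))
  mode <- match.arg(mode)
  seq_int <- if (is.character(sequence)) encode_sequence(sequence)
             else as.integer(sequence)
  if (length(fingerprint) != model$cfg$fp_bits)
    stop("fingerprint must have exactly ", model$cfg$fp_bits, " bits")
  fwd <- .hots_fwd(model$params, model$cfg, seq_int,
                   as.numeric(fingerprint), mode = mode, train = FALSE,
                   pad_to_grids = pad_to_grids, need_cache = FALSE)
  out <- list(spec = fwd$spec, mask = fwd$mask, attention = fwd$attention)
  if (!is.null(fwd$det)) {
    out$det <- detection_tensor(fwd$det$c, fwd$det$w, fwd$det$p,
                                valid = fwd$det$valid)
  }
  if (!is.null(fwd$p_dti)) out$p_dti <- fwd$p_dti
  out
}
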