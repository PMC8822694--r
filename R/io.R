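## File formats: FASTA proteins, fingerprint/BI/BR/DTI TSV dialects,
## JSON manifests and text model checkpoints. All residue indices are
## 1-based inclusive on disk and 0-based half-open in memory, converted
## here at the boundary (BR tables are stored 0-based half-open,
## BED-like, and documented as such).

#' Read a protein FASTA file
#'
#' @param path FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1L), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1L])
  }
  if (any(set@ranges@width == 0L)) {
    stop("empty sequence for FASTA record ",
         ids[which(set@ranges@width == 0L)[1L]])
  }
  out <- toupper(as.character(set))
  names(out) <- ids
  out
}

#' Write proteins to FASTA
#'
#' @param proteins Named character vector.
#' @param path Output file.
#' @export
write_fasta <- function(proteins, path) {
  set <- Biostrings::AAStringSet(proteins)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read / write a fingerprint table
#'
#' TSV with columns `compound_id` and `fingerprint` (a string of 0/1
#' characters, one per bit).
#'
#' @param path TSV file.
#' @param fp_bits Expected fingerprint length.
#' @return Binary matrix with one row per compound.
#' @export
read_fingerprints <- function(path, fp_bits = 2048L) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!all(c("compound_id", "fingerprint") %in% names(tab)))
    stop("fingerprint table needs columns compound_id, fingerprint")
  if (anyDuplicated(tab$compound_id))
    stop("duplicate compound_id: ",
         tab$compound_id[duplicated(tab$compound_id)][1L])
  bad <- which(nchar(tab$fingerprint) != fp_bits |
                 grepl("[^01]", tab$fingerprint))
  if (length(bad))
    stop("row ", bad[1L], ": fingerprint must be ", fp_bits,
         " characters of 0/1")
  m <- t(vapply(strsplit(tab$fingerprint, ""),
                function(x) as.integer(x), integer(fp_bits)))
  rownames(m) <- tab$compound_id
  m
}

#' @rdname read_fingerprints
#' @param compounds Binary matrix (rownames = compound ids).
#' @export
write_fingerprints <- function(compounds, path) {
  utils::write.table(
    data.frame(compound_id = rownames(compounds),
               fingerprint = apply(compounds, 1L, paste, collapse = "")),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a binding-information (BI) table
#'
#' TSV with columns `protein_id`, `ligand_id`, `residues`
#' (comma-separated 1-based residue indices). When `proteins` is
#' supplied, ids and residue ranges are validated against it.
#'
#' @param path TSV file.
#' @param proteins Optional named character vector for validation.
#' @return Data frame `protein_id`, `ligand_id`, `residues`.
#' @export
read_bi <- function(path, proteins = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!all(c("protein_id", "ligand_id", "residues") %in% names(tab)))
    stop("BI table needs columns protein_id, ligand_id, residues")
  for (r in seq_len(nrow(tab))) {
    res <- suppressWarnings(as.integer(strsplit(tab$residues[r], ",")[[1L]]))
    if (length(res) == 0L || anyNA(res))
      stop("row ", r, ": malformed residue list '", tab$residues[r], "'")
    if (any(res < 1L))
      stop("row ", r, ": residue indices are 1-based; got ", min(res))
    if (!is.null(proteins)) {
      if (!tab$protein_id[r] %in% names(proteins))
        stop("row ", r, ": unknown protein_id '", tab$protein_id[r], "'")
      L <- nchar(proteins[[tab$protein_id[r]]])
      if (any(res > L))
        stop("row ", r, ": residue ", max(res), " beyond length ", L,
             " of ", tab$protein_id[r])
    }
  }
  tab
}

#' Read / write a binding-region table
#'
#' TSV with columns `protein_id`, `ligand_id`, `start`, `end`; intervals
#' are 0-based half-open (BED-like).
#'
#' @param path TSV file.
#' @return Data frame.
#' @export
read_brs <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("protein_id", "ligand_id", "start", "end") %in% names(tab)))
    stop("BR table needs columns protein_id, ligand_id, start, end")
  bad <- which(!(tab$start < tab$end) | tab$start < 0)
  if (length(bad))
    stop("row ", bad[1L], ": invalid interval [", tab$start[bad[1L]], ", ",
         tab$end[bad[1L]], ")")
  tab
}

#' @rdname read_brs
#' @param brs Data frame with the BR columns.
#' @export
write_brs <- function(brs, path) {
  utils::write.table(brs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a DTI label table
#'
#' TSV with columns `compound_id`, `protein_id`, `label` (0/1).
#'
#' @param path TSV file.
#' @return Data frame.
#' @export
read_dti <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("compound_id", "protein_id", "label") %in% names(tab)))
    stop("DTI table needs columns compound_id, protein_id, label")
  bad <- which(!tab$label %in% c(0L, 1L))
  if (length(bad))
    stop("row ", bad[1L], ": DTI label must be 0 or 1, got ",
         tab$label[bad[1L]])
  tab
}

#' @rdname read_dti
#' @param dti Data frame with the DTI columns.
#' @export
write_dti <- function(dti, path) {
  utils::write.table(dti, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a corpus to a directory
#'
#' Writes `proteins.fasta`, `fingerprints.tsv`, `bi.tsv`, `brs.tsv`,
#' `dti.tsv`, `motifs.tsv` and `manifest.json`.
#'
#' @param corpus A `hots_corpus`.
#' @param dir Output directory (created if missing).
#' @export
write_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "hots_corpus"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(corpus$proteins, file.path(dir, "proteins.fasta"))
  write_fingerprints(corpus$compounds, file.path(dir, "fingerprints.tsv"))
  utils::write.table(corpus$bi, file.path(dir, "bi.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_brs(corpus$brs, file.path(dir, "brs.tsv"))
  write_dti(corpus$dti, file.path(dir, "dti.tsv"))
  utils::write.table(corpus$motifs, file.path(dir, "motifs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(corpus$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a corpus directory written by [write_corpus()]
#'
#' @param dir Corpus directory.
#' @return A `hots_corpus`.
#' @export
read_corpus <- function(dir) {
  proteins <- read_fasta(file.path(dir, "proteins.fasta"))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  fp_bits <- manifest$fp_bits %||% 2048L
  compounds <- read_fingerprints(file.path(dir, "fingerprints.tsv"), fp_bits)
  bi <- read_bi(file.path(dir, "bi.tsv"), proteins)
  brs <- read_brs(file.path(dir, "brs.tsv"))
  dti <- read_dti(file.path(dir, "dti.tsv"))
  for (tab in list(bi, brs)) {
    dangling <- setdiff(tab$protein_id, names(proteins))
    if (length(dangling)) stop("unknown protein_id '", dangling[1L], "'")
    dangling <- setdiff(tab$ligand_id, rownames(compounds))
    if (length(dangling)) stop("unknown ligand_id '", dangling[1L], "'")
  }
  dangling <- setdiff(dti$compound_id, rownames(compounds))
  if (length(dangling)) stop("unknown compound_id '", dangling[1L], "'")
  motifs_path <- file.path(dir, "motifs.tsv")
  motifs <- if (file.exists(motifs_path))
    utils::read.delim(motifs_path, stringsAsFactors = FALSE) else NULL
  structure(list(proteins = proteins, compounds = compounds,
                 motifs = motifs, bi = bi, brs = brs, dti = dti,
                 manifest = manifest),
            class = "hots_corpus")
}

#' Save / load a model checkpoint
#'
#' Text checkpoint: a JSON document with the configuration embedded and
#' every weight array flattened with its dimensions.
#'
#' @param model A `hots_model`.
#' @param path Checkpoint file (JSON).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "hots_model"))
  payload <- list(
    format = "hots-checkpoint-1",
    cfg = unclass(model$cfg),
    params = lapply(model$params, function(x)
      list(dim = dim(x) %||% length(x), values = as.numeric(x))))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @return `load_model` returns the reconstructed `hots_model`.
#' @export
load_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "hots-checkpoint-1"))
    stop("not a model checkpoint: ", path)
  cfgl <- payload$cfg
  cfg <- hots_config(H = cfgl$H, embed_dim = cfgl$embed_dim,
                     conv_windows = cfgl$conv_windows,
                     conv_filters = cfgl$conv_filters,
                     grid_size = cfgl$grid_size, anchors = cfgl$anchors,
                     n_br_blocks = cfgl$n_br_blocks,
                     n_dti_blocks = cfgl$n_dti_blocks,
                     n_heads = cfgl$n_heads, ff_ratio = cfgl$ff_ratio,
                     max_len = cfgl$max_len, gamma = cfgl$gamma,
                     lambda_reg = cfgl$lambda_reg,
                     lambda_conf = cfgl$lambda_conf,
                     dropout = cfgl$dropout, dti_mode = cfgl$dti_mode,
                     width_eps = cfgl$width_eps, fp_bits = cfgl$fp_bits)
  params <- lapply(payload$params, function(x) {
    if (length(x$dim) == 2L) matrix(x$values, x$dim[1L], x$dim[2L])
    else as.numeric(x$values)
  })
  structure(list(params = params, cfg = cfg), class = "hots_model")
}
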