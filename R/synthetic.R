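## Planted-motif synthetic corpus: proteins with mutated motif copies whose
## presence causally determines binding, matched compounds whose
## fingerprints carry motif-linked bit patterns, ground-truth BRs and
## 2:1-negative DTI labels. Used by every test in the package.

## Best sliding-window identity of `motif` (character vector) in `s`
## (character vector). Returns list(identity, start) with 1-based start.
.motif_best_match <- function(s, motif) {
  k <- length(motif)
  L <- length(s)
  if (L < k) return(list(identity = 0, start = NA_integer_))
  nw <- L - k + 1L
  m <- matrix(FALSE, nw, k)
  for (j in seq_len(k)) m[, j] <- s[j:(j + nw - 1L)] == motif[j]
  hits <- rowSums(m)
  b <- which.max(hits)
  list(identity = hits[b] / k, start = b)
}

.pairwise_identity <- function(a, b) {
  ## best identity of the shorter sliding along the longer
  if (length(a) > length(b)) { tmp <- a; a <- b; b <- tmp }
  .motif_best_match(b, a)$identity
}

#' Generate a planted-motif synthetic corpus
#'
#' Background residues are drawn uniformly from the 20 standard amino
#' acids. Each protein receives `motifs_per_protein` distinct motifs; each
#' (protein, motif) record plants 1-3 mutated copies at non-overlapping
#' positions, and those positions are the record's ground-truth binding
#' residues (BI). Ground-truth BRs are the BI expanded and merged with
#' [expand_and_merge()]. Every motif is linked to one compound whose
#' fingerprint sets a disjoint 32-bit pattern plus Bernoulli noise bits.
#' Positive DTIs are the planted (compound, protein) pairs; negatives are
#' sampled uniformly at `neg_ratio`:1 from pairs whose protein carries no
#' copy of the compound's motif (screened at < 70% best-window identity,
#' the same conservation floor guaranteed for planted copies, so motif
#' presence and the DTI label agree exactly).
#'
#' @param n_proteins Number of proteins.
#' @param length_range Protein length range (uniform integer draw).
#' @param n_motifs Number of distinct motifs/compounds.
#' @param motifs_per_protein Distinct motifs planted per protein.
#' @param seed RNG seed (the corpus is a deterministic function of the
#'   arguments).
#' @param motif_length_range Consensus length range (default 10-14).
#' @param sub_rate Per-position substitution rate of planted copies;
#'   substitutions are capped at 30% of the motif length so every copy
#'   keeps >= 70% identity to its consensus.
#' @param bits_per_motif Linked fingerprint bits per motif (disjoint
#'   blocks).
#' @param noise_bit_rate Bernoulli rate for extra fingerprint bits outside
#'   every linked block.
#' @param neg_ratio Negative:positive DTI ratio (default 2).
#' @param expansion_length BR expansion window (default 9).
#' @param fp_bits Fingerprint length (default 2048).
#' @return A `hots_corpus` list: `proteins` (named character vector),
#'   `compounds` (binary matrix, one row per compound), `motifs` (data
#'   frame), `bi` (protein_id, ligand_id, residues as comma-separated
#'   1-based indices), `brs` (protein_id, ligand_id, start, end; 0-based
#'   half-open), `dti` (compound_id, protein_id, label) and `manifest`.
#' @export
generate_corpus <- function(n_proteins = 100L, length_range = c(200L, 400L),
                            n_motifs = 8L, motifs_per_protein = 2L,
                            seed = 1L, motif_length_range = c(10L, 14L),
                            sub_rate = 0.05, bits_per_motif = 32L,
                            noise_bit_rate = 0.02, neg_ratio = 2L,
                            expansion_length = 9L, fp_bits = 2048L) {
  stopifnot(n_proteins >= 1L, n_motifs >= 1L, motifs_per_protein >= 1L,
            motifs_per_protein <= n_motifs,
            length_range[1L] <= length_range[2L],
            motif_length_range[1L] >= 6L, motif_length_range[2L] <= 15L,
            n_motifs * bits_per_motif <= fp_bits)
  set.seed(seed)
  aa20 <- AA_ALPHABET[1:20]

  ## motif consensi: pairwise identity < 50%
  motif_seqs <- vector("list", n_motifs)
  for (m in seq_len(n_motifs)) {
    for (try in 1:100) {
      len <- sample(motif_length_range[1L]:motif_length_range[2L], 1L)
      cand <- sample(aa20, len, replace = TRUE)
      ok <- TRUE
      for (prev in seq_len(m - 1L)) {
        if (.pairwise_identity(cand, motif_seqs[[prev]]) >= 0.5) {
          ok <- FALSE; break
        }
      }
      if (ok) { motif_seqs[[m]] <- cand; break }
      if (try == 100L) stop("could not draw ", n_motifs,
                            " motifs below 50% pairwise identity")
    }
  }
  motif_ids <- sprintf("M%02d", seq_len(n_motifs))
  compound_ids <- sprintf("C%02d", seq_len(n_motifs))

  ## compounds: disjoint linked bit blocks + noise outside all blocks
  compounds <- matrix(0L, n_motifs, fp_bits,
                      dimnames = list(compound_ids, NULL))
  linked_end <- n_motifs * bits_per_motif
  for (m in seq_len(n_motifs)) {
    block <- ((m - 1L) * bits_per_motif + 1L):(m * bits_per_motif)
    compounds[m, block] <- 1L
    if (linked_end < fp_bits) {
      noise <- which(stats::runif(fp_bits - linked_end) < noise_bit_rate)
      compounds[m, linked_end + noise] <- 1L
    }
  }

  proteins <- character(n_proteins)
  protein_ids <- sprintf("P%04d", seq_len(n_proteins))
  names(proteins) <- protein_ids
  bi_rows <- list()
  br_rows <- list()
  planted <- matrix(FALSE, n_proteins, n_motifs,
                    dimnames = list(protein_ids, motif_ids))

  for (i in seq_len(n_proteins)) {
    L <- sample(length_range[1L]:length_range[2L], 1L)
    s <- sample(aa20, L, replace = TRUE)
    occupied <- logical(L)
    chosen <- sample(n_motifs, motifs_per_protein)
    for (m in chosen) {
      motif <- motif_seqs[[m]]
      len <- length(motif)
      n_copies <- sample(1:3, 1L)
      residues <- integer(0)
      for (cp in seq_len(n_copies)) {
        placed <- FALSE
        for (try in 1:50) {
          st <- sample.int(L - len + 1L, 1L)
          span <- st:(st + len - 1L)
          ## keep a 1-residue gap so copies stay distinct regions
          guard <- max(1L, st - 1L):min(L, st + len)
          if (any(occupied[guard])) next
          copy <- motif
          n_sub <- min(stats::rbinom(1L, len, sub_rate),
                       floor(0.3 * len))
          if (n_sub > 0L) {
            pos <- sample.int(len, n_sub)
            for (q in pos) {
              copy[q] <- sample(setdiff(aa20, copy[q]), 1L)
            }
          }
          s[span] <- copy
          occupied[span] <- TRUE
          residues <- c(residues, span)
          placed <- TRUE
          break
        }
        if (!placed) break  # crowded sequence: accept fewer copies
      }
      if (length(residues) == 0L) {
        ## crowded sequence: deterministically take the first fully free
        ## stretch so the record count stays exact
        runs <- rle(occupied)
        ends <- cumsum(runs$lengths)
        ok <- which(!runs$values & runs$lengths >= len)
        if (length(ok) == 0L)
          stop("protein too crowded to place motif of length ", len)
        st <- ends[ok[1L]] - runs$lengths[ok[1L]] + 1L
        span <- st:(st + len - 1L)
        s[span] <- motif
        occupied[span] <- TRUE
        residues <- span
      }
      residues <- sort(residues)
      planted[i, m] <- TRUE
      bi_rows[[length(bi_rows) + 1L]] <- data.frame(
        protein_id = protein_ids[i], ligand_id = compound_ids[m],
        residues = paste(residues, collapse = ","),
        stringsAsFactors = FALSE)
      reg <- expand_and_merge(residues, L, expansion_length)
      br_rows[[length(br_rows) + 1L]] <- data.frame(
        protein_id = protein_ids[i], ligand_id = compound_ids[m],
        start = reg[, 1L], end = reg[, 2L], stringsAsFactors = FALSE)
    }
    proteins[i] <- paste(s, collapse = "")
  }

  bi <- do.call(rbind, bi_rows)
  brs <- do.call(rbind, br_rows)
  rownames(brs) <- NULL

  ## DTI labels: planted pairs positive; negatives screened against
  ## spurious motif matches at the 70% identity floor
  pos <- data.frame(compound_id = bi$ligand_id, protein_id = bi$protein_id,
                    label = 1L, stringsAsFactors = FALSE)
  cand <- which(!planted, arr.ind = TRUE)
  keep <- logical(nrow(cand))
  seq_chars <- lapply(proteins, function(x) strsplit(x, "")[[1L]])
  for (r in seq_len(nrow(cand))) {
    sc <- seq_chars[[cand[r, 1L]]]
    keep[r] <- .motif_best_match(sc, motif_seqs[[cand[r, 2L]]])$identity < 0.7
  }
  cand <- cand[keep, , drop = FALSE]
  n_neg <- neg_ratio * nrow(pos)
  if (nrow(cand) < n_neg) {
    warning("only ", nrow(cand), " clean negative pairs available (wanted ",
            n_neg, ")")
    n_neg <- nrow(cand)
  }
  pick <- cand[sample.int(nrow(cand), n_neg), , drop = FALSE]
  neg <- data.frame(compound_id = compound_ids[pick[, 2L]],
                    protein_id = protein_ids[pick[, 1L]],
                    label = 0L, stringsAsFactors = FALSE)
  dti <- rbind(pos, neg)
  rownames(dti) <- NULL

  structure(list(
    proteins = proteins,
    compounds = compounds,
    motifs = data.frame(motif_id = motif_ids, compound_id = compound_ids,
                        consensus = vapply(motif_seqs, paste,
                                           character(1L), collapse = ""),
                        stringsAsFactors = FALSE),
    bi = bi, brs = brs, dti = dti,
    manifest = list(seed = seed, n_proteins = n_proteins,
                    length_range = length_range, n_motifs = n_motifs,
                    motifs_per_protein = motifs_per_protein,
                    motif_length_range = motif_length_range,
                    sub_rate = sub_rate, bits_per_motif = bits_per_motif,
                    noise_bit_rate = noise_bit_rate, neg_ratio = neg_ratio,
                    expansion_length = expansion_length,
                    fp_bits = fp_bits)),
    class = "hots_corpus")
}

#' @export
print.hots_corpus <- function(x, ...) {
  cat("Synthetic planted-motif corpus: ", length(x$proteins), " proteins, ",
      nrow(x$compounds), " compounds, ", nrow(x$bi), " binding records, ",
      sum(x$dti$label == 1L), " positive / ", sum(x$dti$label == 0L),
      " negative DTIs (seed ", x$manifest$seed, ")\n", sep = "")
  invisible(x)
}

## Subset a corpus to a set of protein ids.
.subset_corpus <- function(corpus, ids) {
  out <- corpus
  out$proteins <- corpus$proteins[ids]
  out$bi <- corpus$bi[corpus$bi$protein_id %in% ids, , drop = FALSE]
  out$brs <- corpus$brs[corpus$brs$protein_id %in% ids, , drop = FALSE]
  out$dti <- corpus$dti[corpus$dti$protein_id %in% ids, , drop = FALSE]
  rownames(out$bi) <- rownames(out$brs) <- rownames(out$dti) <- NULL
  out
}

#' Split a corpus into training and validation sets by protein
#'
#' Proteins are partitioned (no protein appears on both sides), mirroring
#' a leakage-free 9:1 train:validation split.
#'
#' @param corpus A `hots_corpus`.
#' @param fraction Training fraction in (0, 1), default 0.9.
#' @param seed RNG seed for the protein permutation.
#' @return List with `train` and `validation` corpora.
#' @export
train_validation_split <- function(corpus, fraction = 0.9, seed = 1L) {
  stopifnot(inherits(corpus, "hots_corpus"),
            fraction > 0, fraction < 1)
  ids <- names(corpus$proteins)
  n_train <- round(length(ids) * fraction)
  if (n_train < 1L || n_train >= length(ids))
    stop("too few proteins (", length(ids), ") for a ", fraction, " split")
  set.seed(seed)
  perm <- sample(ids)
  list(train = .subset_corpus(corpus, sort(perm[seq_len(n_train)])),
       validation = .subset_corpus(corpus, sort(perm[-seq_len(n_train)])))
}
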