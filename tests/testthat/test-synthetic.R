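# The planted-motif corpus generator: determinism, counting, label
# consistency with an independent motif-scan oracle, and BR invariants.

# Independent sliding-window scan: best fraction of identical positions of
# `motif` anywhere in `protein` (both plain strings).
scan_identity <- function(protein, motif) {
  p <- strsplit(protein, "")[[1]]
  m <- strsplit(motif, "")[[1]]
  k <- length(m)
  if (length(p) < k) return(0)
  best <- 0
  for (s in seq_len(length(p) - k + 1)) {
    id <- sum(p[s:(s + k - 1)] == m) / k
    if (id > best) best <- id
  }
  best
}

test_that("the corpus is a deterministic function of the seed", {
  c1 <- tiny_corpus(n = 10, seed = 5)
  c2 <- tiny_corpus(n = 10, seed = 5)
  expect_identical(c1, c2)
  c3 <- tiny_corpus(n = 10, seed = 6)
  expect_false(identical(c1$proteins, c3$proteins))
})

test_that("record counts follow n_proteins x motifs_per_protein", {
  corpus <- generate_corpus(n_proteins = 40, length_range = c(150, 250),
                            n_motifs = 6, motifs_per_protein = 2, seed = 9)
  expect_equal(nrow(corpus$bi), 80)
  expect_equal(sum(corpus$dti$label == 1), 80)
  expect_equal(sum(corpus$dti$label == 0), 160)   # 2:1 negatives
  expect_equal(length(corpus$proteins), 40)
  expect_equal(nrow(corpus$compounds), 6)
})

test_that("generated BRs are disjoint, sorted and cover their BI residues", {
  corpus <- tiny_corpus(n = 15, seed = 21)
  key <- paste(corpus$brs$protein_id, corpus$brs$ligand_id)
  for (k in unique(key)) {
    rows <- corpus$brs[key == k, , drop = FALSE]
    expect_true(all(diff(rows$start) > 0))
    if (nrow(rows) > 1)
      expect_true(all(rows$end[-nrow(rows)] < rows$start[-1]))
  }
  for (r in seq_len(nrow(corpus$bi))) {
    res <- as.integer(strsplit(corpus$bi$residues[r], ",")[[1]]) - 1
    rows <- corpus$brs[corpus$brs$protein_id == corpus$bi$protein_id[r] &
                         corpus$brs$ligand_id == corpus$bi$ligand_id[r], ]
    expect_true(all(vapply(res, function(x)
      any(rows$start <= x & x < rows$end), logical(1))))
  }
})

test_that("BR truth covers a small fraction of each protein", {
  corpus <- generate_corpus(n_proteins = 30, length_range = c(200, 400),
                            n_motifs = 8, motifs_per_protein = 2, seed = 13)
  cov <- vapply(names(corpus$proteins), function(pid) {
    rows <- corpus$brs[corpus$brs$protein_id == pid, , drop = FALSE]
    merged <- merge_intervals(cbind(rows$start, rows$end))
    region_coverage(merged, nchar(corpus$proteins[[pid]]))
  }, numeric(1))
  expect_true(all(cov < 0.5))
  expect_gt(mean(cov), 0.02)   # motifs are actually planted
})

test_that("an independent motif scan reproduces every DTI label", {
  corpus <- generate_corpus(n_proteins = 40, length_range = c(150, 300),
                            n_motifs = 6, motifs_per_protein = 2, seed = 31)
  consensus <- setNames(corpus$motifs$consensus, corpus$motifs$compound_id)
  for (r in seq_len(nrow(corpus$dti))) {
    id <- scan_identity(corpus$proteins[[corpus$dti$protein_id[r]]],
                        consensus[[corpus$dti$compound_id[r]]])
    expect_identical(id >= 0.7, corpus$dti$label[r] == 1L)
  }
})

test_that("motif consensi stay below 50% pairwise identity and linked bits are disjoint", {
  corpus <- generate_corpus(n_proteins = 5, length_range = c(150, 200),
                            n_motifs = 8, motifs_per_protein = 2, seed = 3)
  cons <- corpus$motifs$consensus
  for (i in seq_along(cons)) for (j in seq_len(i - 1)) {
    expect_lt(max(scan_identity(cons[i], cons[j]),
                  scan_identity(cons[j], cons[i])), 0.5)
  }
  linked <- corpus$compounds[, 1:(8 * 32)]
  expect_true(all(colSums(linked) == 1))   # each linked bit in one compound
})

test_that("the train/validation split separates proteins without leakage", {
  corpus <- tiny_corpus(n = 20, seed = 41)
  sp <- train_validation_split(corpus, 0.9, seed = 1)
  expect_equal(length(sp$train$proteins), 18)
  expect_equal(length(sp$validation$proteins), 2)
  expect_length(intersect(names(sp$train$proteins),
                          names(sp$validation$proteins)), 0)
  expect_true(all(sp$train$dti$protein_id %in% names(sp$train$proteins)))
  expect_true(all(sp$validation$brs$protein_id %in%
                    names(sp$validation$proteins)))
  sp2 <- train_validation_split(corpus, 0.9, seed = 1)
  expect_identical(sp, sp2)
  expect_error(train_validation_split(corpus, 0.99), "too few")
})
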