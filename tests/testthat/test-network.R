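# Architecture behaviour: encoder geometry, masking, attention
# normalization, compound token determinism and forward invariants.

test_that("grid and feature counts follow the ceiling formula", {
  cfg <- tiny_config()
  set.seed(1); m <- hots_init_model(cfg)
  seqs <- c(9, 10, 11, 95, 101)
  for (L in seqs) {
    enc <- encode_protein(m, random_protein(L))
    expect_equal(nrow(enc$encoding), ceiling(L / cfg$grid_size))
    asm <- assemble(encode_compound(m, random_fp()), enc)
    expect_equal(nrow(asm$feature), 1 + ceiling(L / cfg$grid_size))
  }
})

test_that("a constant sequence yields identical interior grid encodings", {
  cfg <- tiny_config()
  set.seed(2); m <- hots_init_model(cfg)
  enc <- encode_protein(m, strrep("A", 60))
  G <- enc$encoding
  # all grids fully inside the sequence see identical inputs
  for (g in 2:5) expect_equal(G[g, ], G[2, ], tolerance = 1e-12)
})

test_that("convolution is local: permuting a grid interior leaves other grids unchanged", {
  cfg <- hots_config(H = 16L, embed_dim = 8L, conv_windows = 3L,
                     conv_filters = 6L, grid_size = 10L, anchors = c(5, 9),
                     n_br_blocks = 1L, n_dti_blocks = 1L, n_heads = 2L,
                     ff_ratio = 2L, max_len = 500L, dropout = 0)
  set.seed(3); m <- hots_init_model(cfg)
  s <- strsplit(random_protein(50), "")[[1]]
  # permute positions 13..18 (0-based 12..17): interior of grid 1, more
  # than one receptive-field radius away from its boundaries
  s2 <- s
  s2[13:18] <- s[c(15, 17, 13, 18, 16, 14)]
  g1 <- encode_protein(m, paste(s, collapse = ""))$encoding
  g2 <- encode_protein(m, paste(s2, collapse = ""))$encoding
  expect_false(isTRUE(all.equal(g1[2, ], g2[2, ])))  # the permuted grid moves
  expect_equal(g1[-2, ], g2[-2, ], tolerance = 1e-12)
})

test_that("compound tokens are deterministic functions of the fingerprint", {
  cfg <- tiny_config()
  set.seed(4); m <- hots_init_model(cfg)
  fp <- random_fp()
  expect_identical(encode_compound(m, fp), encode_compound(m, fp))
  # all-zero fingerprint maps to the bias image
  z <- encode_compound(m, rep(0, 2048))
  expect_equal(z, pmax(m$params$comp.b, 0))
  # a single flipped bit changes the token
  fp2 <- fp; fp2[17] <- 1 - fp2[17]
  expect_false(isTRUE(all.equal(encode_compound(m, fp),
                                encode_compound(m, fp2))))
  expect_error(encode_compound(m, rep(0, 100)), "2048")
  expect_error(encode_compound(m, rep(0.5, 2048)), "binary")
})

test_that("assembly places the token first and adds the positional encoding", {
  cfg <- tiny_config()
  set.seed(5); m <- hots_init_model(cfg)
  enc <- encode_protein(m, random_protein(40))
  tok <- encode_compound(m, random_fp())
  asm <- assemble(tok, enc)
  pe0 <- hots:::.pe_matrix(1, cfg$H)[1, ]
  expect_equal(asm$feature[1, ], tok + pe0)
  expect_true(asm$mask[1])
  expect_error(assemble(tok[-1], enc), "dimension")
})

test_that("detection outputs and DTI scores stay inside the sigmoid range", {
  cfg <- tiny_config()
  set.seed(6); m <- hots_init_model(cfg)
  for (i in 1:5) {
    out <- hots_forward(m, random_protein(sample(30:120, 1)), random_fp())
    expect_true(all(out$det$c > 0 & out$det$c < 1))
    expect_true(all(out$det$w > 0 & out$det$w < 1))
    expect_true(all(out$det$p > 0 & out$det$p < 1))
    expect_true(out$p_dti > 0 && out$p_dti < 1)
  }
})

test_that("attention rows are stochastic over valid keys in every block and head", {
  cfg <- hots_config(H = 16L, embed_dim = 8L, conv_windows = c(3L, 5L),
                     conv_filters = 4L, grid_size = 10L, anchors = c(5, 9),
                     n_br_blocks = 2L, n_dti_blocks = 2L, n_heads = 2L,
                     ff_ratio = 2L, max_len = 500L, dropout = 0)
  set.seed(7); m <- hots_init_model(cfg)
  out <- hots_forward(m, random_protein(55), random_fp(),
                      pad_to_grids = 8L)
  expect_equal(length(out$attention), 4L)
  for (blk in out$attention) for (A in blk) {
    expect_true(all(A >= 0))
    expect_equal(rowSums(A), rep(1, nrow(A)), tolerance = 1e-5)
    # masked keys receive no attention from any query
    expect_true(all(A[, !c(TRUE, out$mask)] == 0))
  }
})

test_that("padded grids do not influence predictions", {
  cfg <- tiny_config()
  set.seed(8); m <- hots_init_model(cfg)
  s <- random_protein(47)
  fp <- random_fp()
  a <- hots_forward(m, s, fp)
  b <- hots_forward(m, s, fp, pad_to_grids = 9L)
  expect_equal(a$p_dti, b$p_dti, tolerance = 1e-12)
  n <- a$spec$n_grids
  expect_equal(a$det$p, b$det$p[seq_len(n), , drop = FALSE],
               tolerance = 1e-12)
})

test_that("the forward pass is deterministic for fixed weights and inputs", {
  cfg <- tiny_config()
  set.seed(9); m <- hots_init_model(cfg)
  s <- random_protein(64); fp <- random_fp()
  expect_identical(hots_forward(m, s, fp)$p_dti,
                   hots_forward(m, s, fp)$p_dti)
})

test_that("different proteins give different DTI scores for one compound", {
  cfg <- tiny_config()
  set.seed(10); m <- hots_init_model(cfg)
  fp <- random_fp()
  p1 <- hots_forward(m, random_protein(80), fp)$p_dti
  p2 <- hots_forward(m, random_protein(80), fp)$p_dti
  expect_false(identical(p1, p2))
})

test_that("unknown residues are mapped to X with a warning; long sequences truncate", {
  cfg <- tiny_config()
  set.seed(11); m <- hots_init_model(cfg)
  expect_warning(ix <- encode_sequence("ACDB"), "mapped to X")
  expect_equal(ix[4], 21L)
  expect_error(encode_sequence(""), "non-empty")
  long <- random_protein(cfg$max_len + 40)
  expect_warning(enc <- encode_protein(m, long), "truncated")
  expect_equal(nrow(enc$encoding), cfg$max_len / cfg$grid_size)
})

test_that("checkpoint round trip preserves predictions", {
  cfg <- tiny_config()
  set.seed(12); m <- hots_init_model(cfg)
  path <- tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  s <- random_protein(70); fp <- random_fp()
  expect_equal(hots_forward(m, s, fp)$p_dti,
               hots_forward(m2, s, fp)$p_dti, tolerance = 1e-12)
  unlink(path)
})
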