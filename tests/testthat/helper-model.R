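# Small configurations and corpora shared across tests.

tiny_config <- function(dropout = 0, max_len = 500L, ...) {
  hots_config(H = 16L, embed_dim = 8L, conv_windows = c(3L, 5L),
              conv_filters = 4L, grid_size = 10L, anchors = c(5, 9),
              n_br_blocks = 1L, n_dti_blocks = 1L, n_heads = 2L,
              ff_ratio = 2L, max_len = max_len, dropout = dropout, ...)
}

# The desk-scale model used for end-to-end runs: hidden size and block
# counts per the small-model study conditions, with a lean encoder.
small_config <- function(...) {
  hots_config(H = 32L, embed_dim = 21L, embed_init = "onehot",
              conv_filters = 16L, n_br_blocks = 1L, n_dti_blocks = 1L,
              dropout = 0.1, ...)
}

tiny_corpus <- function(n = 20, seed = 11, ...) {
  generate_corpus(n_proteins = n, length_range = c(120L, 200L),
                  n_motifs = 4L, motifs_per_protein = 1L, seed = seed, ...)
}

random_fp <- function(p = 0.05, bits = 2048) {
  as.numeric(stats::runif(bits) < p)
}
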