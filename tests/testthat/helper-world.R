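# Shared fixtures: a reduced synthetic world and small model configurations.
# The reduced world uses short molecules, light atom masses and shrunken
# spectral grids so whole training runs stay cheap; see the methods vignette
# for the rationale behind these sizes.

tiny_world <- function(seed = 7, ...) {
  toy_world_config(
    max_len = 8,
    atom_masses = c(A = 3, B = 4, C = 5, D = 3, E = 6, F = 4, G = 7, H = 8),
    grid_points = c(IR = 32L, NMR = 32L, MS = 64L),
    seed = seed,
    ...
  )
}

tiny_vocab <- function(world = tiny_world()) vocabulary(c(world$alphabet, "."))

tiny_model_config <- function(vocab, sources = c("R", "IR", "NMR", "MS"),
                              d_emb = 16, n_heads = 2, ffn_width = 32,
                              dropout = 0, cells = c(1, 1), ...) {
  deductive_model_config(
    sources = sources, vocab = vocab,
    d_emb = d_emb, n_heads = n_heads, ffn_width = ffn_width,
    dropout = dropout,
    reactant_cells = cells, spectral_cells = cells,
    d_seq = c(R = 12, IR = 32, NMR = 32, MS = 64),
    max_decode = 8, ...
  )
}

# Reduced training configuration used by the end-to-end accuracy checks:
# d_emb 32, 2 heads, 1+1 reactant and 2+2 spectral attention cells.
toy_train_model_config <- function(vocab, sources = c("R", "IR", "NMR", "MS")) {
  deductive_model_config(
    sources = sources, vocab = vocab,
    d_emb = 32, n_heads = 2, ffn_width = 64, dropout = 0.1,
    reactant_cells = c(1, 1), spectral_cells = c(2, 2),
    d_seq = c(R = 12, IR = 32, NMR = 32, MS = 64),
    max_decode = 8
  )
}

spectrum_key <- function(sp) {
  nz <- which(sp$intensities > 0)
  paste(nz, signif(sp$intensities[nz], 10), collapse = ",")
}
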