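# Closed-form parameter-count oracle, summed layer by layer. Attention
# projections carry no biases (the concatenated heads feed the residual
# directly); feed-forward linears, output heads and the deduction layer carry
# biases; every layer norm has gain + bias; encoder/decoder stacks end in a
# final layer norm.
count_oracle <- function(cfg) {
  d <- cfg$d_emb; f <- cfg$ffn_width; V <- cfg$out_vocab
  attn <- 3 * d * d
  ffn <- d * f + f + f * d + d
  enc_cell <- 2 * (2 * d) + attn + ffn
  dec_cell <- 3 * (2 * d) + 2 * attn + ffn
  total <- V * d                                    # shared target embedding
  for (s in cfg$sources) {
    cells <- if (s == "R") cfg$reactant_cells else cfg$spectral_cells
    vin <- if (s == "R") V else cfg$spectral_vocab[[s]]
    total <- total + vin * d + cells[1] * enc_cell + 2 * d      # encoder
    total <- total + cells[2] * dec_cell + 2 * d + d * V + V    # decoder+head
  }
  total + V * length(cfg$sources) * V + V            # deduction layer
}

test_that("positional embeddings follow the trigonometric form", {
  p0 <- positional_embedding(0, 8)
  expect_equal(p0[c(1, 3, 5, 7)], rep(0, 4))   # sin entries
  expect_equal(p0[c(2, 4, 6, 8)], rep(1, 4))   # cos entries
  p1 <- positional_embedding(1, 8, n = 1e4)
  expect_equal(p1[1], sin(1), tolerance = 1e-12)
  expect_equal(p1[1], 0.84147, tolerance = 1e-5)
  for (k in c(3, 17, 500)) {
    expect_true(all(abs(positional_embedding(k, 16)) <= 1))
  }
  expect_error(positional_embedding(1, 7), "even")
  expect_error(positional_embedding(-1, 8), ">= 0")
})

test_that("scaled dot-product attention honors masks and degenerate rows", {
  set.seed(1)
  K <- matrix(rnorm(12), 4, 3); V <- matrix(rnorm(8), 4, 2)
  Q <- matrix(rnorm(3), 1, 3)
  # one unmasked key: output equals that key's value row
  out <- scaled_dot_attention(Q, K, V, mask = c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(as.numeric(out), V[3, ])
  # identical keys: uniform mean of values
  K2 <- matrix(rep(K[1, ], 4), 4, 3, byrow = TRUE)
  out2 <- scaled_dot_attention(Q, K2, V)
  expect_equal(as.numeric(out2), colMeans(V), tolerance = 1e-12)
  # masked keys get exactly zero weight
  out3 <- scaled_dot_attention(Q, K, V, mask = c(TRUE, TRUE, FALSE, FALSE))
  w12 <- exp(Q %*% t(K[1:2, ]) / sqrt(3))
  expect_equal(as.numeric(out3),
               as.numeric((w12 / sum(w12)) %*% V[1:2, ]), tolerance = 1e-12)
  expect_error(scaled_dot_attention(Q, K, V, mask = rep(FALSE, 4)),
               "all keys masked")
})

test_that("encoder output has the configured shape and is deterministic", {
  v <- tiny_vocab()
  cfg <- tiny_model_config(v)
  m <- deductive_model(cfg, seed = 2)
  toks <- pad_encode(tokenize_structure("AB.BA>GG", v), v, 12)
  M1 <- encoder_forward(m, "R", toks)
  M2 <- encoder_forward(m, "R", toks)
  expect_equal(dim(M1), c(12L, 16L))
  expect_identical(unclass(M1), unclass(M2))     # eval mode, bit-identical
  w <- tiny_world()
  sp <- discretize(normalize_spectrum(simulate_spectrum("ABC", "MS", w)))
  Ms <- encoder_forward(m, "MS", sp)
  expect_equal(dim(Ms), c(64L, 16L))
  expect_error(encoder_forward(m, "MS", rep(0L, 10)), "length")
})

test_that("pad positions are masked out of encoder attention", {
  # same weights, two pad amounts: content rows must agree
  v <- tiny_vocab()
  cfg_long <- deductive_model_config(sources = "R", vocab = v, d_emb = 16,
                                     n_heads = 2, ffn_width = 32, dropout = 0,
                                     reactant_cells = c(2, 1),
                                     spectral_cells = c(1, 1),
                                     d_seq = c(R = 12), max_decode = 8)
  cfg_short <- cfg_long; cfg_short$d_seq <- c(R = 5)
  m_long <- deductive_model(cfg_long, seed = 3)
  m_short <- deductive_model(cfg_short, seed = 3)   # identical init weights
  expect_identical(model_state(m_long), model_state(m_short))
  toks <- tokenize_structure("ABCDA", v)
  M_long <- encoder_forward(m_long, "R", pad_encode(toks, v, 12))
  M_short <- encoder_forward(m_short, "R", pad_encode(toks, v, 5))
  expect_equal(unclass(M_long)[1:5, ], unclass(M_short)[1:5, ],
               tolerance = 1e-5)
})

test_that("decoder distributions are normalized and causally masked", {
  v <- tiny_vocab()
  cfg <- tiny_model_config(v, sources = c("R", "MS"))
  m <- deductive_model(cfg, seed = 4)
  toks <- pad_encode(tokenize_structure("AB.BA", v), v, 12)
  M <- encoder_forward(m, "R", toks)
  prefix <- c(v$start_id, match(c("A", "B"), v$tokens))
  p <- decoder_next_probs(m, "R", M, prefix)
  expect_length(p, v$size)
  expect_true(all(p >= 0))
  expect_equal(sum(p), 1, tolerance = 1e-6)
  # causality: appending tokens must not change earlier positions
  full <- specdeduce:::sn_decoder_probs(m$ptr, 0L, unclass(M),
                                        attr(M, "key_ok"),
                                        c(prefix, match("C", v$tokens)) - 1L)
  expect_equal(full[3, ], p, tolerance = 1e-6)
  expect_error(decoder_next_probs(m, "R", M, prefix[-1]), "start token")
  expect_error(decoder_next_probs(m, "R", M, c(prefix, rep(1L, 10))),
               "max_decode")
})

test_that("the target embedding is shared across transformers", {
  v <- tiny_vocab()
  m <- deductive_model(tiny_model_config(v), seed = 5)
  nms <- names(model_state(m))
  expect_equal(sum(nms == "tgt_emb"), 1L)
  expect_false(any(grepl("dec.emb", nms)))   # no per-source target embedding
})

test_that("the deduction layer fuses, normalizes, and respects zeroing", {
  v <- tiny_vocab()
  m <- deductive_model(tiny_model_config(v, sources = c("R", "MS")), seed = 6)
  P <- matrix(runif(2 * v$size), 2)
  P <- P / rowSums(P)
  f <- deduce(m, P)
  expect_equal(sum(f), 1, tolerance = 1e-6)
  expect_error(deduce(m, P[1, , drop = FALSE]), "one row per")
  expect_error(deduce(m, P, zero = c("R", "MS")), "all sources")
  expect_error(deduce(m, P, zero = "IR"), "unknown source")

  # zero deduction weights: the fused output is softmax(bias), input-free
  st <- model_state(m)
  st$ded.W[] <- 0
  set.seed(8); st$ded.b[] <- rnorm(v$size)
  m0 <- deductive_model(m$config, seed = 6, state = st)
  f1 <- deduce(m0, P)
  f2 <- deduce(m0, matrix(runif(2 * v$size), 2))
  expect_equal(f1, f2, tolerance = 1e-6)
  expect_equal(f1, as.numeric(exp(st$ded.b) / sum(exp(st$ded.b))),
               tolerance = 1e-5)
})

test_that("an identity-block deduction preserves input rank order", {
  v <- tiny_vocab()
  m <- deductive_model(tiny_model_config(v, sources = "R"), seed = 7)
  st <- model_state(m)
  st$ded.W <- diag(v$size) * 3
  st$ded.b[] <- 0
  m1 <- deductive_model(m$config, seed = 7, state = st)
  p <- runif(v$size); p <- p / sum(p)
  f <- deduce(m1, matrix(p, 1))
  expect_equal(order(f), order(p))   # softmax of a monotone map
})

test_that("parameter counts match the closed-form oracle", {
  v <- tiny_vocab()
  cfg <- tiny_model_config(v, sources = c("R", "IR", "MS"))
  expect_equal(count_parameters(cfg), count_oracle(cfg))
  # doubling the feed-forward width changes exactly the two ffn linears
  cfg2 <- tiny_model_config(v, sources = c("R", "IR", "MS"), ffn_width = 64)
  d <- cfg$d_emb
  n_cells <- sum(cfg$reactant_cells) + 2 * sum(cfg$spectral_cells)
  delta <- n_cells * (d * 32 + 32 + 32 * d)   # extra 32 hidden units
  expect_equal(count_parameters(cfg2) - count_parameters(cfg), delta)
})

test_that("the full four-source configuration lands near 30 M weights", {
  cfg <- deductive_model_config()           # paper-scale defaults
  n <- count_parameters(cfg)
  expect_equal(n, count_oracle(cfg))
  expect_gte(n, 25e6)
  expect_lte(n, 35e6)
})

test_that("analytic gradients agree with finite differences", {
  # directional derivatives along random directions: pooling the whole
  # gradient keeps the check far above single-precision forward noise
  v <- tiny_vocab()
  w <- tiny_world()
  cfg <- tiny_model_config(v, sources = c("R", "MS"))
  m <- deductive_model(cfg, seed = 11)
  recs <- generate_reactions(w, 3)
  e <- encode_record(recs[[1]], v, cfg)
  g <- specdeduce:::sn_grads(m$ptr, unname(e$inputs), e$tin, e$tout)
  st <- model_state(m)
  set.seed(12)
  for (trial in 1:4) {
    dir <- lapply(st, function(x) {
      d <- x
      d[] <- rnorm(length(x))
      d
    })
    nrm <- sqrt(sum(vapply(dir, function(d) sum(d^2), numeric(1))))
    eps <- 5e-3
    stp <- mapply(function(x, d) x + eps * d / nrm, st, dir, SIMPLIFY = FALSE)
    stm <- mapply(function(x, d) x - eps * d / nrm, st, dir, SIMPLIFY = FALSE)
    specdeduce:::sn_set_state(m$ptr, stp)
    lp <- specdeduce:::sn_loss(m$ptr, unname(e$inputs), e$tin, e$tout)
    specdeduce:::sn_set_state(m$ptr, stm)
    lm <- specdeduce:::sn_loss(m$ptr, unname(e$inputs), e$tin, e$tout)
    specdeduce:::sn_set_state(m$ptr, st)
    num <- (lp - lm) / (2 * eps)
    ana <- sum(mapply(function(gr, d) sum(gr * d / nrm), g$grads[names(st)],
                      dir))
    expect_lt(abs(num - ana), 1e-4 + 0.02 * (abs(num) + abs(ana)))
  }
})
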