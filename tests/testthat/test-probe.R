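test_that("decisiveness flags match an explicit enumeration oracle", {
  v <- tiny_vocab(); w <- tiny_world(seed = 51)
  cfg <- tiny_model_config(v, sources = c("R", "MS"))
  m <- deductive_model(cfg, seed = 17)
  # hand-built deduction weights: the fused output reads only the R block,
  # so MS can never be decisive and zeroing R collapses to the uniform argmax
  st <- model_state(m)
  st$ded.W[] <- 0
  st$ded.W[seq_len(v$size), ] <- diag(v$size) * 5
  st$ded.b[] <- 0
  m <- deductive_model(cfg, seed = 17, state = st)
  e <- encode_record(generate_reactions(w, 2)[[1]], v, cfg)
  dec <- decisiveness(m, e$inputs, v)
  expect_named(dec$decisive, c("R", "MS"))
  expect_false(dec$decisive[["MS"]])
  # enumeration oracle: with R zeroed the fused logits are all equal, so the
  # top-1 falls to the first token; R is decisive wherever the intact top-1
  # is any other token
  tin0 <- c(cfg$start_id - 1L, as.integer(dec$reference) - 1L)
  tf <- specdeduce:::sn_teacher(m$ptr, unname(e$inputs[c("R", "MS")]), tin0)
  intact_top1 <- apply(tf$fused, 1, which.max)
  expect_equal(unname(dec$decisive_at["R", ]), intact_top1 != 1L)
  expect_equal(dec$decisive[["R"]], any(intact_top1 != 1L))
})

test_that("zeroing a non-decisive source leaves the fused top-1 unchanged", {
  v <- tiny_vocab(); w <- tiny_world(seed = 52)
  cfg <- tiny_model_config(v)
  m <- deductive_model(cfg, seed = 19)
  e <- encode_record(generate_reactions(w, 2)[[1]], v, cfg)
  dec <- decisiveness(m, e$inputs, v)
  tin0 <- c(cfg$start_id - 1L, as.integer(dec$reference) - 1L)
  tf <- specdeduce:::sn_teacher(m$ptr, unname(e$inputs[cfg$sources]), tin0)
  for (t in seq_len(ncol(dec$decisive_at))) {
    P <- do.call(rbind, lapply(tf$per_source, function(x) x[t, ]))
    top1 <- which.max(tf$fused[t, ])
    for (s in cfg$sources) {
      if (!dec$decisive_at[s, t])
        expect_equal(which.max(deduce(m, P, zero = s)), top1)
    }
  }
})

test_that("ablation feeds neutral inputs and reports consistent drops", {
  v <- tiny_vocab(); w <- tiny_world(seed = 53)
  cfg <- tiny_model_config(v, sources = c("R", "MS"))
  m <- deductive_model(cfg, seed = 23)
  recs <- generate_reactions(w, 4)
  rep_ <- input_ablation(m, recs, v, beam = 3)
  intact <- attr(rep_, "intact")
  expect_equal(rep_$drop1, intact["top1"] - rep_$top1, ignore_attr = TRUE)
  expect_equal(rep_$drop5, intact["top5"] - rep_$top5, ignore_attr = TRUE)
  expect_setequal(rep_$source, c("R", "MS"))
  expect_error(input_ablation(m, recs, v, sources = "NMR"), "not in model")
  # an all-padding reactant sequence is accepted (uniform-attention fallback)
  e <- encode_record(recs[[1]], v, cfg)
  abl <- specdeduce:::ablated_inputs(m, e$inputs, "R")
  expect_true(all(abl$R == cfg$pad_id - 1L))
  expect_silent(beam_search(m, abl, v, beam = 2))
  abl2 <- specdeduce:::ablated_inputs(m, e$inputs, "MS")
  expect_true(all(abl2$MS == 0L))
})

test_that("spectral noise perturbs only non-zero positions by the fixed factors", {
  w <- tiny_world()
  sp <- simulate_spectrum("ABCD", "NMR", w)
  expect_identical(add_noise(sp, 0), sp)
  set.seed(5)
  noised <- add_noise(sp, 0.1)
  zero <- sp$intensities == 0
  expect_identical(noised$intensities[zero], sp$intensities[zero])
  ratio <- noised$intensities[!zero] / sp$intensities[!zero]
  # each altered value is v, 0.9 v, or 1.1 v (the peak at 1 clips back to 1)
  ok <- vapply(seq_along(ratio), function(i) {
    isTRUE(all.equal(ratio[i], 0.9)) || isTRUE(all.equal(ratio[i], 1.1)) ||
      isTRUE(all.equal(ratio[i], 1)) ||
      isTRUE(all.equal(noised$intensities[!zero][i], 1))
  }, logical(1))
  expect_true(all(ok))
  expect_true(all(noised$intensities <= 1))
  expect_error(add_noise(sp, -0.2), ">= 0")
})

test_that("zero-level noising leaves encoded datasets bit-identical", {
  v <- tiny_vocab(); w <- tiny_world(seed = 54)
  cfg <- tiny_model_config(v)
  recs <- generate_reactions(w, 5)
  noised <- noise_records(recs, 0, seed = 3)
  expect_identical(encode_dataset(noised, v, cfg), encode_dataset(recs, v, cfg))
})
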