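test_that("the learning-rate schedule ramps linearly then decays", {
  # closed form evaluated independently: peak = d^-1/2 * s_warm^-1/2
  expect_equal(lr_schedule(37500, 256, 37500), 256^-0.5 * 37500^-0.5,
               tolerance = 1e-12)
  expect_equal(lr_schedule(37500, 256, 37500), 3.2275e-4, tolerance = 1e-4)
  expect_equal(lr_schedule(37500 / 2, 256, 37500),
               lr_schedule(37500, 256, 37500) / 2, tolerance = 1e-12)
  s <- seq(37501, 80000, by = 500)
  expect_true(all(diff(lr_schedule(s, 256, 37500)) < 0))
  expect_error(lr_schedule(0, 256, 37500), ">= 1")
})

test_that("spectral dropout replaces whole spectra and never the reactants", {
  w <- tiny_world()
  r <- generate_reactions(w, 2)[[1]]
  expect_identical(spectral_dropout(r, 0), r)
  set.seed(1)
  dropped <- spectral_dropout(r, 1)
  for (m in c("IR", "NMR", "MS"))
    expect_equal(dropped$spectra[[m]]$intensities,
                 numeric(length(r$spectra[[m]]$intensities)))
  expect_identical(dropped$reactants, r$reactants)
  # empirical joint drop rate near p^3
  set.seed(2)
  all3 <- replicate(4000, {
    d <- spectral_dropout(r, 0.1)
    all(vapply(d$spectra, function(s) all(s$intensities == 0), logical(1)))
  })
  expect_lt(abs(mean(all3) - 0.001), 0.002)
  expect_error(spectral_dropout(r, -0.1), "p >= 0")
})

test_that("training loss covers content and end positions only", {
  v <- tiny_vocab(); w <- tiny_world()
  cfg <- tiny_model_config(v, sources = c("R", "MS"))
  m <- deductive_model(cfg, seed = 3)
  r <- generate_reactions(w, 1)[[1]]
  e <- encode_record(r, v, cfg)
  # hand-weighted oracle: sum of -log fused prob at each content/end position
  tf <- specdeduce:::sn_teacher(m$ptr, unname(e$inputs), e$tin)
  by_hand <- -sum(log(tf$fused[cbind(seq_along(e$tout), e$tout + 1L)]))
  expect_equal(specdeduce:::sn_loss(m$ptr, unname(e$inputs), e$tin, e$tout),
               by_hand, tolerance = 1e-10)
  expect_length(e$tout, nchar(r$target) + 1L)   # tokens plus end, no padding
})

test_that("one optimization step reduces the loss on a fixed batch", {
  v <- tiny_vocab(); w <- tiny_world(seed = 21)
  cfg <- tiny_model_config(v, sources = c("R", "MS"))
  m <- deductive_model(cfg, seed = 5)
  recs <- generate_reactions(w, 8)
  enc <- encode_dataset(recs, v, cfg)
  before <- mean(vapply(seq_along(recs), function(i) {
    e <- encode_record(recs[[i]], v, cfg)
    specdeduce:::sn_loss(m$ptr, unname(e$inputs), e$tin, e$tout) / length(e$tout)
  }, numeric(1)))
  fit <- train_model(m, list(train = enc, validation = enc), v,
                     train_config(batch_size = 32, max_epochs = 1,
                                  s_warm = 10, seed = 1))
  expect_lte(fit$history$train_loss[1], before + 1e-6)
  expect_lte(fit$history$val_loss[1], before + 1e-6)
})

test_that("early stopping waits exactly `patience` non-improving epochs", {
  v <- tiny_vocab(); w <- tiny_world(seed = 22)
  cfg <- tiny_model_config(v, sources = "R")
  m <- deductive_model(cfg, seed = 6)
  recs <- generate_reactions(w, 6)
  enc <- encode_dataset(recs, v, cfg)
  # lr_scale 0 freezes the weights, so validation loss never improves
  fit <- train_model(m, list(train = enc, validation = enc), v,
                     train_config(max_epochs = 30, patience = 1, s_warm = 10,
                                  lr_scale = 0, seed = 1))
  expect_equal(nrow(fit$history), 2L)   # best at epoch 1, one extra epoch
  expect_equal(fit$best_epoch, 1L)
})

test_that("identical seeds reproduce the training trajectory exactly", {
  v <- tiny_vocab(); w <- tiny_world(seed = 23)
  cfg <- tiny_model_config(v, sources = c("R", "IR"), dropout = 0.1)
  recs <- generate_reactions(w, 10)
  enc <- encode_dataset(recs, v, cfg)
  run <- function() {
    m <- deductive_model(cfg, seed = 9)
    train_model(m, list(train = enc, validation = enc), v,
                train_config(max_epochs = 4, s_warm = 10, seed = 31,
                             spectral_drop_p = 0.1))$history
  }
  expect_identical(run(), run())
})

test_that("degenerate training inputs are rejected", {
  v <- tiny_vocab()
  cfg <- tiny_model_config(v, sources = "R")
  m <- deductive_model(cfg, seed = 10)
  expect_error(train_model(m, list(train = list(), validation = list()), v,
                           train_config(max_epochs = 1)),
               "empty training split")
})
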