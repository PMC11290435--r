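test_that("mass spectra place the molecular ion and fragment peaks by mass", {
  cfg <- toy_world_config()           # default masses: A = 10
  sp <- simulate_spectrum("AA", "MS", cfg)
  expect_s3_class(sp, "spectrum")
  expect_length(sp$intensities, 999)
  expect_equal(sp$intensities[20], 1.0)          # molecular ion at total mass
  expect_gt(sp$intensities[10], 0)               # fragment at the prefix mass
  expect_equal(sum(sp$intensities > 0), 2)

  empty <- simulate_spectrum("", "MS", cfg)
  expect_equal(empty$intensities, numeric(999))
})

test_that("simulated spectra are deterministic and on the standard grids", {
  cfg <- toy_world_config()
  for (m in c("IR", "NMR", "MS")) {
    a <- simulate_spectrum("ABCD", m, cfg)
    b <- simulate_spectrum("ABCD", m, cfg)
    expect_identical(a$intensities, b$intensities)
    expect_equal(length(a$intensities),
                 c(IR = 900L, NMR = 993L, MS = 999L)[[m]])
    expect_equal(max(a$intensities), 1)          # non-empty molecules peak at 1
  }
})

test_that("invalid molecules and modalities are rejected", {
  cfg <- toy_world_config()
  expect_error(simulate_spectrum("AXZ", "MS", cfg), "unknown symbol")
  expect_error(simulate_spectrum("AA", "UV", cfg), "unknown modality")
  expect_error(simulate_spectrum(strrep("A", 25), "MS", cfg), "max_len")
})

test_that("generated corpora respect the null ratio and the discard rule", {
  w <- tiny_world(seed = 41)
  recs <- generate_reactions(w, 100)
  is_null <- vapply(recs, `[[`, logical(1), "is_null")
  n_real <- sum(!is_null); n_null <- sum(is_null)
  expect_equal(n_real, 100)
  # real:null within 10% of 2:1
  expect_true(abs(n_null - 50) <= 10)
  # no null target collides with any real product
  real_products <- unique(vapply(recs[!is_null], `[[`, character(1), "target"))
  null_targets <- vapply(recs[is_null], `[[`, character(1), "target")
  expect_length(intersect(null_targets, real_products), 0)
  # null targets are members of their reactant sets, with the target's spectra
  r <- recs[is_null][[1]]
  expect_true(r$target %in% r$reactants)
  expect_identical(r$spectra$MS$intensities,
                   simulate_spectrum(r$target, "MS", w)$intensities)

  expect_identical(generate_reactions(w, 0), list())
  expect_error(generate_reactions(w, -1), ">= 0")
  w2 <- tiny_world(); w2$rewrite_rules <- character(0)
  expect_error(generate_reactions(w2, 5), "non-empty")
})

test_that("the same seed reproduces the corpus exactly", {
  a <- generate_reactions(tiny_world(seed = 5), 40)
  b <- generate_reactions(tiny_world(seed = 5), 40)
  expect_identical(a, b)
  c <- generate_reactions(tiny_world(seed = 6), 40)
  expect_false(identical(a, c))
})

test_that("a third of reactant sets map to two or more targets", {
  recs <- generate_reactions(tiny_world(seed = 13), 300)
  keys <- vapply(recs, function(r) paste(r$reactants, collapse = "."),
                 character(1))
  targets <- vapply(recs, `[[`, character(1), "target")
  per_set <- tapply(targets, keys, function(x) length(unique(x)))
  expect_gte(mean(per_set >= 2), 0.30)
})

test_that("spectral triples identify molecules up to a <1% collision rate", {
  w <- tiny_world(seed = 17)
  recs <- generate_reactions(w, 300)
  mols <- unique(c(unlist(lapply(recs, `[[`, "reactants")),
                   vapply(recs, `[[`, character(1), "target")))
  keys <- vapply(mols, function(m) {
    paste(vapply(c("IR", "NMR", "MS"), function(mod)
      spectrum_key(simulate_spectrum(m, mod, w)), character(1)),
      collapse = "|")
  }, character(1))
  collisions <- sum(duplicated(keys))
  expect_lt(collisions / length(mols), 0.01)
})

test_that("records survive a JSONL round trip", {
  w <- tiny_world(seed = 3)
  recs <- generate_reactions(w, 5)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_reactions_jsonl(recs, path)
  back <- read_reactions_jsonl(path)
  expect_length(back, length(recs))
  expect_equal(back[[1]]$target, recs[[1]]$target)
  expect_equal(back[[1]]$reactants, recs[[1]]$reactants)
  expect_equal(back[[1]]$spectra$MS$intensities,
               recs[[1]]$spectra$MS$intensities)
})
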