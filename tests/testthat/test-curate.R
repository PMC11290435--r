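rec <- function(reactants, target, reagent = NULL, is_null = FALSE)
  list(reactants = reactants, reagent = reagent, target = target,
       is_null = is_null)

test_that("null generation enumerates reactants and applies the discard rule", {
  # {A.B -> C, D -> A}: the candidate A.B -> A dies because A is a real product
  reals <- list(rec(c("A", "B"), "C"), rec("D", "A"))
  nulls <- make_null_reactions(reals)
  got <- vapply(nulls, function(r)
    paste(paste(r$reactants, collapse = "."), r$target, sep = "->"),
    character(1))
  expect_setequal(got, c("A.B->B", "D->D"))
  expect_true(all(vapply(nulls, `[[`, logical(1), "is_null")))

  # a single real reaction yields one null per reactant
  nulls2 <- make_null_reactions(list(rec(c("E", "F"), "G")))
  expect_setequal(vapply(nulls2, `[[`, character(1), "target"), c("E", "F"))

  # every reactant also a real product -> the discard rule fires everywhere
  nulls3 <- make_null_reactions(list(rec("A", "B"), rec("B", "A")))
  expect_length(nulls3, 0)

  expect_identical(make_null_reactions(list()), list())
  expect_error(make_null_reactions(list(rec("A", "A", is_null = TRUE))),
               "only real")
})

test_that("null targets and real products stay disjoint on generated corpora", {
  w <- tiny_world(seed = 29)
  recs <- generate_reactions(w, 150)
  reals <- Filter(function(r) !r$is_null, recs)
  nulls <- make_null_reactions(reals, w)
  expect_length(
    intersect(vapply(nulls, `[[`, character(1), "target"),
              vapply(reals, `[[`, character(1), "target")), 0)
  # regenerated spectra belong to the null target
  n1 <- nulls[[1]]
  expect_identical(n1$spectra$IR$intensities,
                   simulate_spectrum(n1$target, "IR", w)$intensities)
})

test_that("target-aware splitting keeps target groups intact", {
  recs10 <- lapply(1:10, function(i) rec("A", paste0(strrep("B", i))))
  sp <- split_by_target(recs10, seed = 2)
  expect_equal(vapply(list(sp$train, sp$validation, sp$test), length,
                      integer(1)), c(8L, 1L, 1L))

  # 7 records over 3 targets: records sharing a target co-locate
  recs7 <- c(lapply(1:3, function(i) rec("A", "X")),
             lapply(1:2, function(i) rec("B", "Y")),
             lapply(1:2, function(i) rec("C", "Z")))
  sp7 <- split_by_target(recs7, seed = 5)
  for (part in list(sp7$train, sp7$validation, sp7$test)) {
    tg <- vapply(part, `[[`, character(1), "target")
    expect_true(all(table(tg) == c(X = 3, Y = 2, Z = 2)[unique(tg)]))
  }

  expect_error(split_by_target(recs7[1:5]), "at least 3")
})

test_that("splits are seed-deterministic, leak-free, and near 80:10:10", {
  recs <- generate_reactions(tiny_world(seed = 37), 667)  # ~1000 records
  a <- split_by_target(recs, seed = 9)
  b <- split_by_target(recs, seed = 9)
  expect_identical(lapply(a$train, `[[`, "target"),
                   lapply(b$train, `[[`, "target"))
  tg <- function(part) unique(vapply(part, `[[`, character(1), "target"))
  expect_length(intersect(tg(a$train), tg(a$test)), 0)
  expect_length(intersect(tg(a$train), tg(a$validation)), 0)
  expect_length(intersect(tg(a$validation), tg(a$test)), 0)
  g <- length(unique(vapply(recs, `[[`, character(1), "target")))
  expect_lte(abs(length(tg(a$test)) - round(0.1 * g)), 1)
  expect_lte(abs(length(tg(a$validation)) - round(0.1 * g)), 1)
  expect_equal(length(recs),
               length(a$train) + length(a$validation) + length(a$test))
})

test_that("reagent variants compose the documented input strings", {
  r <- rec(c("A", "B"), "C", reagent = "R")
  expect_equal(reaction_input_string(r, TRUE), "A.B>R")
  expect_equal(reaction_input_string(r, FALSE), "A.B.R")
  expect_equal(reaction_input_string(rec("A", "C"), TRUE), "A")
  recs <- apply_reagent_variant(list(r), with_separator = TRUE)
  expect_equal(recs[[1]]$input, "A.B>R")
})

test_that("reagent target swaps replace targets and spectra, excluding seen reagents", {
  w <- tiny_world()
  r1 <- rec(c("AB", "BA"), "CC", reagent = "GG")
  r2 <- rec(c("AB", "CA"), "DD", reagent = "HH")
  out <- swap_target_to_reagent(list(r1, r2), training_targets = "HH",
                                world = w, seed = 1)
  expect_length(out, 1)                       # HH was a training target
  expect_equal(out[[1]]$target, "GG")
  expect_identical(out[[1]]$spectra$MS$intensities,
                   simulate_spectrum("GG", "MS", w)$intensities)
  expect_length(swap_target_to_reagent(list(r1), character(0), w,
                                       max_per_reagent = 0), 0)
  # cap respected
  many <- lapply(1:5, function(i) rec(c(strrep("A", i)), "BB", reagent = "GG"))
  capped <- swap_target_to_reagent(many, character(0), w,
                                   max_per_reagent = 3, seed = 2)
  expect_length(capped, 3)
})
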