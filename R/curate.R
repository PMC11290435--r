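# Corpus curation: null-reaction augmentation, target-aware splitting,
# reagent-separator variants, and reagent target swaps.

#' Generate null-reaction candidates from real reactions
#'
#' For every real reaction and each of its distinct reactants, a candidate
#' null record is formed whose target is that reactant (the
#' starting-material outcome) and whose spectra are regenerated for that
#' reactant. Candidates whose target matches *any* real product in the input
#' set are discarded (avoiding information leakage between the null and real
#' tasks), and duplicates (same reactant set and target) are collapsed.
#'
#' @param reals List of real reaction records (`is_null = FALSE`).
#' @param world A [toy_world_config()] used to regenerate target spectra, or
#'   `NULL` to skip spectra (structure-only curation).
#' @return List of null reaction records.
#' @examples
#' w <- toy_world_config()
#' reals <- list(
#'   list(reactants = c("AB", "BA"), reagent = NULL, target = "CC",
#'        is_null = FALSE),
#'   list(reactants = "DD", reagent = NULL, target = "AB", is_null = FALSE)
#' )
#' # "AB" is a real product, so the null candidate AB.BA -> AB is discarded
#' sapply(make_null_reactions(reals, w), `[[`, "target")
#' @export
make_null_reactions <- function(reals, world = NULL) {
  if (length(reals) == 0) return(list())
  if (any(vapply(reals, function(r) isTRUE(r$is_null), logical(1))))
    stop("make_null_reactions expects only real reactions")
  real_products <- unique(vapply(reals, `[[`, character(1), "target"))
  out <- list()
  seen <- character(0)
  for (r in reals) {
    for (reactant in unique(r$reactants)) {
      if (reactant %in% real_products) next       # discard rule
      key <- paste(paste(r$reactants, collapse = "."), reactant, sep = "->")
      if (key %in% seen) next                     # collapse duplicates
      seen <- c(seen, key)
      rec <- list(reactants = r$reactants, reagent = r$reagent,
                  target = reactant, is_null = TRUE)
      if (!is.null(world))
        rec$spectra <- simulate_all_spectra(reactant, world)
      out[[length(out) + 1L]] <- rec
    }
  }
  out
}

#' Split records into train/validation/test by prediction target
#'
#' All records sharing a target string are partitioned to the same split, so
#' validation and test targets are unseen during training. Balancing is by
#' number of target groups; the same seed always yields the same assignment.
#'
#' @param records List of reaction records.
#' @param fractions Numeric triple summing to 1 (default `c(0.8, 0.1, 0.1)`).
#' @param seed Integer seed for the group shuffle.
#' @return A `dataset_splits` object with `train`, `validation`, `test`.
#' @export
split_by_target <- function(records, fractions = c(0.8, 0.1, 0.1), seed = 1) {
  stopifnot(length(fractions) == 3, abs(sum(fractions) - 1) < 1e-8)
  targets <- vapply(records, `[[`, character(1), "target")
  groups <- unique(targets)
  if (length(groups) < 3)
    stop("need at least 3 distinct targets to form 3 splits")
  g <- length(groups)
  assign_split <- with_local_seed(seed, {
    shuffled <- sample(groups)
    n_test <- max(1L, round(fractions[3] * g))
    n_val <- max(1L, round(fractions[2] * g))
    split_of <- rep("train", g)
    split_of[seq_len(n_test)] <- "test"
    split_of[n_test + seq_len(n_val)] <- "validation"
    stats::setNames(split_of, shuffled)
  })
  member <- assign_split[targets]
  structure(
    list(train = records[member == "train"],
         validation = records[member == "validation"],
         test = records[member == "test"],
         fractions = fractions, seed = seed),
    class = "dataset_splits"
  )
}

#' @export
print.dataset_splits <- function(x, ...) {
  cat("<dataset_splits> train ", length(x$train), " / validation ",
      length(x$validation), " / test ", length(x$test), "\n", sep = "")
  invisible(x)
}

#' Compose the model input string for a reaction record
#'
#' With the separator variant, reactants are joined by `"."` and the reagent
#' (if any) appended after `">"`; without it, the reagent is merged into the
#' reactant list with no marker.
#'
#' @param record A reaction record.
#' @param with_separator Logical; distinguish the reagent with `">"`.
#' @return Character scalar.
#' @examples
#' r <- list(reactants = c("AB", "BA"), reagent = "GG")
#' reaction_input_string(r, TRUE)
#' reaction_input_string(r, FALSE)
#' @export
reaction_input_string <- function(record, with_separator = TRUE) {
  base <- paste(record$reactants, collapse = ".")
  if (is.null(record$reagent) || !length(record$reagent)) return(base)
  if (with_separator) paste0(base, ">", record$reagent)
  else paste(c(record$reactants, record$reagent), collapse = ".")
}

#' Apply the reagent-separator variant to a record set
#'
#' Attaches the composed `input` string to every record.
#'
#' @inheritParams reaction_input_string
#' @param records List of reaction records.
#' @return The records, each with an `input` field.
#' @export
apply_reagent_variant <- function(records, with_separator = TRUE) {
  lapply(records, function(r) {
    r$input <- reaction_input_string(r, with_separator)
    r
  })
}

#' Swap prediction targets for reagents
#'
#' Builds a reagent-identification evaluation set: for each distinct reagent
#' that never appears as a training target, up to `max_per_reagent` records
#' carrying it are selected at random and their target and spectra are
#' replaced by the reagent's.
#'
#' @param records List of reaction records carrying reagents.
#' @param training_targets Character vector of target strings seen in
#'   training (reagents overlapping these are excluded).
#' @param world A [toy_world_config()] used to simulate the reagent spectra.
#' @param max_per_reagent Maximum records retained per reagent.
#' @param seed Integer seed.
#' @return List of swapped records (`swapped = TRUE`).
#' @export
swap_target_to_reagent <- function(records, training_targets, world,
                                   max_per_reagent = 3, seed = 1) {
  if (max_per_reagent <= 0) return(list())
  has_reagent <- vapply(records, function(r) !is.null(r$reagent), logical(1))
  records <- records[has_reagent]
  if (!length(records)) return(list())
  reagents <- unique(vapply(records, `[[`, character(1), "reagent"))
  reagents <- setdiff(reagents, training_targets)
  with_local_seed(seed, {
    out <- list()
    for (rg in reagents) {
      idx <- which(vapply(records, function(r) identical(r$reagent, rg),
                          logical(1)))
      take <- if (length(idx) > max_per_reagent)
        sample(idx, max_per_reagent) else idx
      for (i in take) {
        r <- records[[i]]
        r$target <- rg
        r$spectra <- simulate_all_spectra(rg, world)
        r$is_null <- FALSE
        r$swapped <- TRUE
        out[[length(out) + 1L]] <- r
      }
    }
    out
  })
}
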