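# Probing tools: per-transformer decisiveness, input ablation, and spectral
# noising.

#' Per-transformer decisiveness along a decoding
#'
#' Walks the intact model's reference decoding token-by-token; at each
#' position, each source's probability vector is zeroed in turn before the
#' deduction layer. A source is *decisive at a position* if that changes the
#' fused top-1 token, and *decisive for the record* if decisive at one or
#' more positions. Evaluation is counterfactual along the fixed intact
#' decoding path (the path is not re-decoded after zeroing).
#'
#' @param model A [deductive_model()].
#' @param inputs Encoded inputs for one record (from [encode_record()]).
#' @param vocab A [vocabulary()].
#' @param reference Optional 1-based token-id vector of the reference
#'   decoding body (defaults to the intact model's beam top-1).
#' @param beam Beam width for the reference decoding.
#' @return A `decisiveness` object: named logical `decisive` flags, decisive
#'   positions per source, and the reference token ids.
#' @export
decisiveness <- function(model, inputs, vocab, reference = NULL, beam = 5) {
  stopifnot(inherits(model, "deductive_model"))
  sources <- model$config$sources
  if (is.null(reference)) {
    pred <- beam_search(model, inputs, vocab, beam = beam)
    reference <- pred$token_ids[[1]]
  }
  tin0 <- c(model$config$start_id - 1L, as.integer(reference) - 1L)
  tf <- sn_teacher(model$ptr, unname(inputs[sources]), tin0)
  n_pos <- length(tin0)
  decisive_at <- matrix(FALSE, length(sources), n_pos,
                        dimnames = list(sources, NULL))
  for (t in seq_len(n_pos)) {
    P <- do.call(rbind, lapply(tf$per_source, function(m) m[t, ]))
    top1 <- which.max(tf$fused[t, ])
    for (si in seq_along(sources)) {
      f2 <- deduce(model, P, zero = sources[si])
      decisive_at[si, t] <- which.max(f2) != top1
    }
  }
  structure(
    list(decisive = apply(decisive_at, 1, any),
         positions = apply(decisive_at, 1, which, simplify = FALSE),
         decisive_at = decisive_at,
         reference = reference),
    class = "decisiveness"
  )
}

#' Dataset-level decisive fractions
#'
#' Fraction of records for which each transformer is decisive for at least
#' one token of its decoding.
#'
#' @param model A [deductive_model()].
#' @param records Reaction records.
#' @param vocab A [vocabulary()].
#' @param with_separator Reagent-separator variant.
#' @param beam Beam width for reference decodings.
#' @return A `decisiveness_report`: per-source fractions and the per-record
#'   flag matrix.
#' @export
decisiveness_report <- function(model, records, vocab, with_separator = TRUE,
                                beam = 5) {
  sources <- model$config$sources
  flags <- matrix(FALSE, length(records), length(sources),
                  dimnames = list(NULL, sources))
  for (i in seq_along(records)) {
    e <- encode_record(records[[i]], vocab, model$config, with_separator)
    flags[i, ] <- decisiveness(model, e$inputs, vocab, beam = beam)$decisive
  }
  structure(list(fractions = colMeans(flags), flags = flags,
                 n = length(records)),
            class = "decisiveness_report")
}

#' @export
print.decisiveness_report <- function(x, ...) {
  cat("<decisiveness_report> n =", x$n, "\n")
  print(round(x$fractions, 3))
  invisible(x)
}

ablated_inputs <- function(model, inputs, source) {
  cfg <- model$config
  if (source == "R") {
    inputs[["R"]] <- rep(cfg$pad_id - 1L, cfg$d_seq[["R"]])
  } else {
    inputs[[source]] <- rep(0L, cfg$d_seq[[source]])
  }
  inputs
}

#' Accuracy reduction under input ablation
#'
#' Recomputes beam-search top-1/top-5 accuracy with one source's input
#' replaced by its neutral element -- an all-padding sequence for the
#' reactant transformer, an all-zero-intensity-token spectrum for a spectral
#' transformer -- and reports the drop against the intact model on the same
#' records.
#'
#' @param model A [deductive_model()].
#' @param records Reaction records.
#' @param vocab A [vocabulary()].
#' @param sources Sources to ablate (default: all configured).
#' @param beam Beam width.
#' @param with_separator Reagent-separator variant.
#' @return An `ablation_report` data frame with intact and ablated top-1 /
#'   top-5 accuracies and their drops per source.
#' @export
input_ablation <- function(model, records, vocab,
                           sources = model$config$sources, beam = 5,
                           with_separator = TRUE) {
  bad <- setdiff(sources, model$config$sources)
  if (length(bad)) stop("source not in model: ", paste(bad, collapse = ", "))
  targets <- vapply(records, `[[`, character(1), "target")
  encoded <- lapply(records, encode_record, vocab = vocab,
                    config = model$config, with_separator = with_separator)
  run <- function(tweak) {
    preds <- lapply(encoded, function(e)
      beam_search(model, tweak(e$inputs), vocab, beam = beam))
    c(top1 = top_n_accuracy(preds, targets, 1),
      top5 = top_n_accuracy(preds, targets, min(5, beam)))
  }
  intact <- run(identity)
  rows <- lapply(sources, function(s) {
    acc <- run(function(inp) ablated_inputs(model, inp, s))
    data.frame(source = s, top1 = acc["top1"], top5 = acc["top5"],
               drop1 = intact["top1"] - acc["top1"],
               drop5 = intact["top5"] - acc["top5"], row.names = NULL)
  })
  out <- do.call(rbind, rows)
  attr(out, "intact") <- intact
  class(out) <- c("ablation_report", "data.frame")
  out
}

#' Perturb a spectrum with fixed-percentage intensity noise
#'
#' For each non-zero grid position, one of three outcomes is chosen
#' uniformly: increase the intensity by `level`, decrease it by `level`, or
#' leave it unchanged. Zero positions are untouched, and the result is
#' clipped back to `[0, 1]` (no re-normalization). Uses the session RNG.
#'
#' @param sp A normalized [spectrum()].
#' @param level Fractional perturbation (e.g. 0.1 or 0.2); 0 is the
#'   identity.
#' @return The noised `spectrum`.
#' @export
add_noise <- function(sp, level) {
  stopifnot(inherits(sp, "spectrum"))
  if (level < 0) stop("noise level must be >= 0")
  if (level == 0) return(sp)
  nz <- which(sp$intensities > 0)
  if (length(nz)) {
    f <- sample(c(1 + level, 1 - level, 1), length(nz), replace = TRUE)
    sp$intensities[nz] <- pmin(pmax(sp$intensities[nz] * f, 0), 1)
  }
  sp
}

#' Apply spectral noise across a record set
#'
#' @param records Reaction records.
#' @param level Fractional perturbation level (>= 0).
#' @param scope Modalities to noise: `"all"` or a subset of
#'   `c("IR", "NMR", "MS")`.
#' @param seed Integer seed.
#' @return Records with noised spectra.
#' @export
noise_records <- function(records, level, scope = "all", seed = 1) {
  if (identical(scope, "all")) scope <- c("IR", "NMR", "MS")
  with_local_seed(seed, {
    lapply(records, function(r) {
      for (m in intersect(scope, names(r$spectra)))
        r$spectra[[m]] <- add_noise(r$spectra[[m]], level)
      r
    })
  })
}
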