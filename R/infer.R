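# Beam-search decoding and top-n evaluation.

# Precompute encoder memories for one encoded record.
prepare_memories <- function(model, inputs) {
  memories <- list(); key_oks <- list()
  for (i in seq_along(model$config$sources)) {
    s <- model$config$sources[i]
    res <- sn_encode(model$ptr, i - 1L, inputs[[s]])
    memories[[i]] <- res$memory
    key_oks[[i]] <- res$key_ok
  }
  list(memories = memories, key_oks = key_oks)
}

#' Beam-search decoding
#'
#' Decoding starts from a dummy string holding only the start token. At each
#' step every live beam proposes its `beam` most probable extensions; the
#' `beam` highest cumulative-log-probability candidates are kept from the
#' pooled set (finished beams persist in the pool with frozen scores). Under
#' the default `"top1"` finish rule a beam finishes when the end token is its
#' single most probable next token (its log-probability is then added) or
#' when the decoded body reaches `max_len`; `"append"` is the conventional
#' rule where the end token competes as an ordinary extension. Candidate
#' score ties break by pool order (beam index, then token id), so decoding
#' is deterministic.
#'
#' @param model A [deductive_model()], or a function `function(prefix_ids)`
#'   returning a probability vector over the vocabulary for a 1-based prefix
#'   (used for hand-specified probability tables).
#' @param inputs Encoded inputs for one record (named 0-based id vectors, as
#'   from [encode_record()]); ignored for function models.
#' @param vocab The [vocabulary()] used to map ids back to strings.
#' @param beam Beam width (>= 1).
#' @param max_len Maximum decoded body length (defaults to the model's
#'   `max_decode`, or 67 for function models).
#' @param finish_rule `"top1"` or `"append"`.
#' @return A `prediction`: ranked decoded strings (no special tokens) with
#'   log-probability scores, plus per-step candidate-pool diagnostics.
#' @export
beam_search <- function(model, inputs = NULL, vocab, beam = 5, max_len = NULL,
                        finish_rule = c("top1", "append")) {
  finish_rule <- match.arg(finish_rule)
  if (beam < 1) stop("beam width must be >= 1")
  is_net <- inherits(model, "deductive_model")
  if (is_net) {
    if (is.null(max_len)) max_len <- model$config$max_decode
    mem <- prepare_memories(model, inputs)
    step_fun <- function(prefix1)
      sn_step(model$ptr, mem$memories, mem$key_oks,
              as.integer(prefix1) - 1L)$fused
  } else if (is.function(model)) {
    if (is.null(max_len)) max_len <- 67L
    step_fun <- model
  } else stop("model must be a deductive_model or a probability function")

  start_id <- vocab$start_id; end_id <- vocab$end_id
  blocked <- c(vocab$pad_id, vocab$start_id)
  if (finish_rule == "top1") blocked <- c(blocked, end_id)

  beams <- list(list(ids = start_id, lp = 0, finished = FALSE))
  pool_sizes <- integer(0)
  repeat {
    live <- which(!vapply(beams, `[[`, logical(1), "finished"))
    if (!length(live)) break
    pool <- beams[-live]
    n_proposed <- 0L
    for (b in live) {
      bm <- beams[[b]]
      p <- step_fun(bm$ids)
      if (finish_rule == "top1" && which.max(p) == end_id) {
        bm$finished <- TRUE
        bm$lp <- bm$lp + log(p[end_id])
        pool[[length(pool) + 1L]] <- bm
        next
      }
      ord <- order(p, decreasing = TRUE)
      ord <- setdiff(ord, blocked)
      cand <- utils::head(ord, beam)
      cand <- sort(cand)                       # token-id order within a beam
      n_proposed <- n_proposed + length(cand)
      for (tok in cand) {
        nb <- list(ids = c(bm$ids, tok), lp = bm$lp + log(p[tok]),
                   finished = FALSE)
        if (finish_rule == "append" && tok == end_id) {
          nb$ids <- bm$ids
          nb$finished <- TRUE
        } else if (length(nb$ids) - 1L >= max_len) {
          nb$finished <- TRUE                  # length cap, no end bonus
        }
        pool[[length(pool) + 1L]] <- nb
      }
    }
    if (n_proposed > 0L) pool_sizes <- c(pool_sizes, n_proposed)
    lps <- vapply(pool, `[[`, numeric(1), "lp")
    beams <- pool[utils::head(order(-lps), beam)]   # stable: ties by pool order
  }
  lps <- vapply(beams, `[[`, numeric(1), "lp")
  ord <- order(-lps)
  beams <- beams[ord]
  strings <- vapply(beams, function(b)
    paste(vocab$tokens[b$ids[-1]], collapse = ""), character(1))
  structure(
    list(strings = strings,
         logprob = vapply(beams, `[[`, numeric(1), "lp"),
         token_ids = lapply(beams, function(b) b$ids[-1]),
         pool_sizes = pool_sizes),
    class = "prediction"
  )
}

#' @export
print.prediction <- function(x, ...) {
  for (i in seq_along(x$strings))
    cat(sprintf("%d. %-20s %8.3f\n", i,
                ifelse(nzchar(x$strings[i]), x$strings[i], "<empty>"),
                x$logprob[i]))
  invisible(x)
}

#' Beam-search predictions for a record set
#'
#' @param model A [deductive_model()].
#' @param records Reaction records (or an `encoded_reactions` set is not
#'   supported here; records carry the spectra needed for encoding).
#' @param vocab A [vocabulary()].
#' @param beam Beam width.
#' @param with_separator Reagent-separator variant.
#' @param finish_rule Passed to [beam_search()].
#' @return List of `prediction` objects, one per record.
#' @export
predict_products <- function(model, records, vocab, beam = 5,
                             with_separator = TRUE, finish_rule = "top1") {
  lapply(records, function(r) {
    e <- encode_record(r, vocab, model$config, with_separator)
    beam_search(model, e$inputs, vocab, beam = beam, finish_rule = finish_rule)
  })
}

#' Top-n string-match accuracy
#'
#' Fraction of records whose target string appears among the first `n`
#' ranked predictions (exact string match).
#'
#' @param predictions List of `prediction` objects.
#' @param targets Character vector of target strings, aligned with
#'   `predictions`.
#' @param n Rank cutoff.
#' @return Fraction in `[0, 1]`.
#' @export
top_n_accuracy <- function(predictions, targets, n) {
  if (!length(predictions)) stop("empty prediction set")
  stopifnot(length(predictions) == length(targets), n >= 1)
  hits <- mapply(function(p, t) t %in% utils::head(p$strings, n),
                 predictions, targets)
  mean(hits)
}
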