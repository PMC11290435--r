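# The deductive super-network: configuration, construction, and the exported
# forward operations (positional embedding, attention reference, encoder,
# per-source decoder distributions, and the linear deduction layer).

#' Configure a deductive super-network
#'
#' One encoder-decoder transformer per evidence source (`"R"` for the
#' reactant/reagent string; `"IR"`, `"NMR"`, `"MS"` for spectra), all decoding
#' against a shared target-token embedding, fused by a single linear
#' deduction layer over the concatenated per-source next-token probability
#' vectors. Defaults are the full-scale configuration: 256-wide embeddings,
#' 8 heads (key/query/value widths totalling 256 across heads, 32 per head),
#' 2048-wide feed-forwards, 4+4 attention cells for the reactant transformer
#' and 2+2 for each spectral transformer, a 288-token output vocabulary, and
#' input lengths 276/900/993/999.
#'
#' @param sources Ordered subset of `c("R", "IR", "NMR", "MS")`.
#' @param vocab Optional [vocabulary()]; sets `out_vocab` and the special
#'   token ids.
#' @param d_emb Embedding width.
#' @param n_heads Attention heads; must divide `d_emb`.
#' @param ffn_width Feed-forward hidden width.
#' @param dropout Dropout rate applied after each feed-forward linear during
#'   training.
#' @param layernorm_eps Layer-norm epsilon.
#' @param reactant_cells,spectral_cells Integer pairs `c(encoder, decoder)`
#'   attention-cell counts.
#' @param out_vocab Output token inventory size (ignored when `vocab` given).
#' @param d_seq Named per-source input lengths.
#' @param spectral_vocab Named intensity-token inventory sizes.
#' @param pos_n Positional-embedding frequency constant.
#' @param max_decode Maximum decoded body length.
#' @param pad_id,start_id,end_id 1-based special token indices (defaults
#'   follow the [vocabulary()] layout: the last three entries).
#' @return A `deductive_model_config`.
#' @export
deductive_model_config <- function(sources = c("R", "IR", "NMR", "MS"),
                                   vocab = NULL,
                                   d_emb = 256, n_heads = 8, ffn_width = 2048,
                                   dropout = 0.1, layernorm_eps = 1e-6,
                                   reactant_cells = c(4, 4),
                                   spectral_cells = c(2, 2),
                                   out_vocab = 288,
                                   d_seq = c(R = 276, IR = 900, NMR = 993,
                                             MS = 999),
                                   spectral_vocab = c(IR = 100, NMR = 101,
                                                      MS = 101),
                                   pos_n = 1e4, max_decode = 67,
                                   pad_id = NULL, start_id = NULL,
                                   end_id = NULL) {
  if (!length(sources) || !all(sources %in% c("R", "IR", "NMR", "MS")) ||
      anyDuplicated(sources))
    stop("sources must be a non-empty distinct subset of R, IR, NMR, MS")
  if (d_emb %% 2 != 0) stop("d_emb must be even")
  if (d_emb %% n_heads != 0)
    stop("n_heads must divide d_emb (per-head value width = d_emb / n_heads)")
  if (!is.null(vocab)) {
    stopifnot(inherits(vocab, "vocabulary"))
    out_vocab <- vocab$size
    pad_id <- vocab$pad_id; start_id <- vocab$start_id; end_id <- vocab$end_id
  }
  if (is.null(pad_id)) pad_id <- out_vocab - 2L
  if (is.null(start_id)) start_id <- out_vocab - 1L
  if (is.null(end_id)) end_id <- out_vocab
  missing_seq <- setdiff(sources, names(d_seq))
  if (length(missing_seq))
    stop("d_seq missing entries for: ", paste(missing_seq, collapse = ", "))
  structure(
    list(sources = sources, d_emb = as.integer(d_emb),
         n_heads = as.integer(n_heads), ffn_width = as.integer(ffn_width),
         dropout = dropout, layernorm_eps = layernorm_eps,
         reactant_cells = as.integer(reactant_cells),
         spectral_cells = as.integer(spectral_cells),
         out_vocab = as.integer(out_vocab),
         d_seq = d_seq, spectral_vocab = spectral_vocab,
         pos_n = pos_n, max_decode = as.integer(max_decode),
         pad_id = as.integer(pad_id), start_id = as.integer(start_id),
         end_id = as.integer(end_id)),
    class = "deductive_model_config"
  )
}

config_to_c <- function(config) {
  srcs <- lapply(config$sources, function(s) {
    spectral <- s != "R"
    cells <- if (spectral) config$spectral_cells else config$reactant_cells
    list(name = s,
         vocab_in = as.integer(if (spectral) config$spectral_vocab[[s]]
                               else config$out_vocab),
         d_seq = as.integer(config$d_seq[[s]]),
         n_enc = cells[1], n_dec = cells[2],
         spectral = spectral)
  })
  list(d_emb = config$d_emb, n_heads = config$n_heads,
       ffn_width = config$ffn_width, out_vocab = config$out_vocab,
       max_decode = config$max_decode, dropout = config$dropout,
       ln_eps = config$layernorm_eps, pos_n = config$pos_n,
       pad_id = config$pad_id - 1L, start_id = config$start_id - 1L,
       end_id = config$end_id - 1L, sources = srcs)
}

#' Instantiate a deductive super-network
#'
#' @param config A [deductive_model_config()].
#' @param seed Integer seed for weight initialization (Glorot uniform).
#' @param state Optional named weight list from [model_state()] to restore.
#' @return A `deductive_model` (holds the compiled network).
#' @export
deductive_model <- function(config, seed = 1, state = NULL) {
  stopifnot(inherits(config, "deductive_model_config"))
  ptr <- sn_new(config_to_c(config), as.integer(seed))
  model <- structure(list(config = config, ptr = ptr, seed = seed),
                     class = "deductive_model")
  if (!is.null(state)) sn_set_state(ptr, state)
  model
}

#' @export
print.deductive_model <- function(x, ...) {
  cfg <- x$config
  cat("<deductive_model> sources ", paste(cfg$sources, collapse = "+"),
      ", d_emb ", cfg$d_emb, ", heads ", cfg$n_heads, ", ",
      format(count_parameters(x), big.mark = ","), " trainable weights\n",
      sep = "")
  invisible(x)
}

#' Extract / restore model weights
#'
#' @param model A [deductive_model()].
#' @return Named list of weight matrices (restore via the `state` argument of
#'   [deductive_model()]).
#' @export
model_state <- function(model) {
  stopifnot(inherits(model, "deductive_model"))
  sn_state(model$ptr)
}

#' Count trainable parameters
#'
#' Exact count of trainable scalars: input and shared target embeddings,
#' attention projections, feed-forward linears (with biases), layer norms,
#' per-transformer output heads, and the deduction layer.
#'
#' @param x A `deductive_model` or `deductive_model_config`.
#' @param ... Unused.
#' @return Numeric scalar count.
#' @export
count_parameters <- function(x, ...) UseMethod("count_parameters")

#' @export
count_parameters.deductive_model <- function(x, ...) sn_num_params(x$ptr)

#' @export
count_parameters.deductive_model_config <- function(x, ...) {
  sn_num_params(deductive_model(x, seed = 0)$ptr)
}

#' Trigonometric positional embedding
#'
#' Entry `2i` (0-based) is `sin(k / n^(2i/d))`, entry `2i + 1` is
#' `cos(k / n^(2i/d))`.
#'
#' @param k Position (0-based, >= 0).
#' @param d Even embedding width.
#' @param n Frequency constant (default 1e4).
#' @return Numeric vector of length `d`.
#' @export
positional_embedding <- function(k, d, n = 1e4) {
  if (d %% 2 != 0) stop("embedding width d must be even")
  if (k < 0) stop("position k must be >= 0")
  i <- seq_len(d / 2) - 1
  w <- k / n^(2 * i / d)
  out <- numeric(d)
  out[2 * i + 1] <- sin(w)
  out[2 * i + 2] <- cos(w)
  out
}

#' Scaled dot-product attention (reference implementation)
#'
#' `softmax(Q K' / sqrt(d_k)) V` with optional key masking and causal
#' masking; masked entries receive `-Inf` before the softmax so their
#' attention weight is exactly zero. This plain-R single-head version is the
#' reference for the compiled multi-head engine.
#'
#' @param Q,K,V Matrices with rows as positions; `Q` and `K` share the key
#'   width, `K` and `V` share the number of rows.
#' @param mask Optional logical vector over key positions (`TRUE` = usable).
#' @param causal Logical; restrict each query to keys at its own or earlier
#'   positions.
#' @return Matrix of attention outputs, one row per query.
#' @export
scaled_dot_attention <- function(Q, K, V, mask = NULL, causal = FALSE) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  stopifnot(ncol(Q) == ncol(K), nrow(K) == nrow(V))
  S <- Q %*% t(K) / sqrt(ncol(K))
  if (!is.null(mask)) {
    stopifnot(length(mask) == nrow(K))
    S[, !mask] <- -Inf
  }
  if (causal) S[upper.tri(S)] <- -Inf
  out <- matrix(0, nrow(Q), ncol(V))
  for (i in seq_len(nrow(S))) {
    r <- S[i, ]
    if (all(!is.finite(r)))
      stop("all keys masked for query ", i, " (degenerate attention row)")
    r <- r - max(r[is.finite(r)])
    w <- ifelse(is.finite(r), exp(r), 0)
    out[i, ] <- (w / sum(w)) %*% V
  }
  out
}

source_index <- function(model, source) {
  i <- match(source, model$config$sources)
  if (is.na(i)) stop("source ", source, " not in model (",
                     paste(model$config$sources, collapse = ", "), ")")
  i
}

# Convert user-facing input objects to 0-based id vectors for one source.
input_ids0 <- function(model, source, x) {
  cfg <- model$config
  ids0 <- if (inherits(x, "token_sequence")) {
    x$ids - 1L
  } else if (inherits(x, "discretized_spectrum")) {
    if (x$modality != source)
      stop("spectrum modality ", x$modality, " does not match source ", source)
    x$token_ids
  } else if (is.numeric(x)) {
    as.integer(x)                    # raw 0-based ids
  } else {
    stop("unsupported input type for source ", source)
  }
  if (length(ids0) != cfg$d_seq[[source]])
    stop(sprintf("source %s expects length %d, got %d", source,
                 cfg$d_seq[[source]], length(ids0)))
  ids0
}

#' Run a source's encoder stack
#'
#' @param model A [deductive_model()].
#' @param source Source name.
#' @param x A `token_sequence` (for `"R"`), a `discretized_spectrum`, or a
#'   raw 0-based id vector of the source's configured length.
#' @return An `encoder_memory`: the `[d_seq, d_emb]` encoder output with the
#'   key-usability mask as an attribute.
#' @export
encoder_forward <- function(model, source, x) {
  stopifnot(inherits(model, "deductive_model"))
  i <- source_index(model, source)
  res <- sn_encode(model$ptr, i - 1L, input_ids0(model, source, x))
  structure(res$memory, key_ok = res$key_ok, source = source,
            class = c("encoder_memory", "matrix", "array"))
}

#' Per-source next-token distribution for a decoded prefix
#'
#' Runs the source's decoder stack (causally masked self-attention over the
#' shared target embedding of the prefix, cross-attention into the encoder
#' memory) and returns the softmax distribution at the last position.
#'
#' @param model A [deductive_model()].
#' @param source Source name.
#' @param memory An [encoder_forward()] result for that source.
#' @param prefix Integer vector of 1-based target token ids beginning with
#'   the start token.
#' @return Numeric probability vector of length `out_vocab`.
#' @export
decoder_next_probs <- function(model, source, memory, prefix) {
  stopifnot(inherits(model, "deductive_model"))
  i <- source_index(model, source)
  cfg <- model$config
  if (length(prefix) < 1 || prefix[1] != cfg$start_id)
    stop("prefix must begin with the start token")
  if (length(prefix) > cfg$max_decode + 1L)
    stop("prefix longer than max_decode")
  P <- sn_decoder_probs(model$ptr, i - 1L, unclass(memory),
                        attr(memory, "key_ok"), as.integer(prefix) - 1L)
  P[nrow(P), ]
}

#' Fuse per-source distributions through the deduction layer
#'
#' Concatenates the per-source probability vectors, applies the trained
#' linear deduction map and a softmax. Weights are static at inference.
#'
#' @param model A [deductive_model()].
#' @param per_source Matrix with one row per source (in the model's source
#'   order) and `out_vocab` columns, or a list of such vectors.
#' @param zero Optional character vector of sources whose probability rows
#'   are zeroed before fusion (for decisiveness probing). Zeroing all
#'   sources at once is rejected.
#' @return Fused probability vector of length `out_vocab`.
#' @export
deduce <- function(model, per_source, zero = NULL) {
  stopifnot(inherits(model, "deductive_model"))
  if (is.list(per_source)) per_source <- do.call(rbind, per_source)
  if (nrow(per_source) != length(model$config$sources))
    stop("per_source must have one row per configured source")
  if (!is.null(zero)) {
    if (length(setdiff(zero, model$config$sources)))
      stop("unknown source in zero: ", paste(setdiff(zero, model$config$sources),
                                             collapse = ", "))
    if (setequal(zero, model$config$sources))
      stop("zeroing all sources simultaneously leaves no prediction to compare")
    per_source[match(zero, model$config$sources), ] <- 0
  }
  sn_deduce(model$ptr, per_source)
}

# -- record encoding ---------------------------------------------------------

#' Encode a reaction record for the model
#'
#' Tokenizes the composed reactant/reagent input string, pads it to the
#' reactant `d_seq`, and normalizes + discretizes each required spectrum.
#'
#' @param record A reaction record.
#' @param vocab A [vocabulary()].
#' @param config A [deductive_model_config()].
#' @param with_separator Logical; reagent-separator variant of the input
#'   string.
#' @return List with `inputs` (named 0-based id vectors per source), `tin`
#'   and `tout` (teacher-forced target in/out ids) and `target`.
#' @export
encode_record <- function(record, vocab, config, with_separator = TRUE) {
  inputs <- list()
  for (s in config$sources) {
    if (s == "R") {
      toks <- tokenize_structure(reaction_input_string(record, with_separator),
                                 vocab)
      inputs[[s]] <- pad_encode(toks, vocab, config$d_seq[["R"]])$ids - 1L
    } else {
      sp <- record$spectra[[s]]
      if (is.null(sp)) stop("record lacks a ", s, " spectrum")
      ids <- discretize(normalize_spectrum(sp))$token_ids
      if (length(ids) != config$d_seq[[s]])
        stop(sprintf("%s spectrum has %d points but the model expects %d",
                     s, length(ids), config$d_seq[[s]]))
      inputs[[s]] <- ids
    }
  }
  tgt <- tokenize_structure(record$target, vocab)
  ids0 <- match(tgt, vocab$tokens) - 1L
  if (length(ids0) > config$max_decode)
    stop("target longer than max_decode")
  list(inputs = inputs,
       tin = c(config$start_id - 1L, ids0),
       tout = c(ids0, config$end_id - 1L),
       target = record$target)
}

#' Encode a record set into training matrices
#'
#' @inheritParams encode_record
#' @param records List of reaction records.
#' @return An `encoded_reactions` object: per-source input id matrices, the
#'   target id matrix (`start, tokens..., end, pad...`), per-record output
#'   lengths, target strings and null flags.
#' @export
encode_dataset <- function(records, vocab, config, with_separator = TRUE) {
  n <- length(records)
  if (!n) stop("no records to encode")
  width <- config$max_decode + 2L
  tgt <- matrix(config$pad_id - 1L, n, width)
  tgtlen <- integer(n)
  inputs <- lapply(config$sources, function(s)
    matrix(0L, n, config$d_seq[[s]]))
  names(inputs) <- config$sources
  for (i in seq_len(n)) {
    e <- encode_record(records[[i]], vocab, config, with_separator)
    for (s in config$sources) inputs[[s]][i, ] <- e$inputs[[s]]
    row <- c(e$tin, config$end_id - 1L)
    tgt[i, seq_along(row)] <- row
    tgtlen[i] <- length(e$tout)
  }
  structure(
    list(inputs = inputs, tgt = tgt, tgtlen = tgtlen, n = n,
         targets = vapply(records, `[[`, character(1), "target"),
         is_null = vapply(records, function(r) isTRUE(r$is_null), logical(1)),
         sources = config$sources),
    class = "encoded_reactions"
  )
}
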