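# Tokenization of structure strings and discretization of spectra.

#' Build a token vocabulary for structure strings
#'
#' A vocabulary consists of an ordered inventory of structure tokens plus four
#' special tokens: the reagent separator `">"`, a padding token, the start
#' token `"<"` and the end token `"$"` (start/end appear only in decoded
#' target strings). The total size is therefore `length(structure_tokens) + 4`.
#'
#' @param structure_tokens Character vector of distinct structure tokens
#'   (single- or multi-character; must not contain the special tokens).
#' @return An object of class `vocabulary` with the full ordered token list
#'   and the indices of the special tokens.
#' @examples
#' v <- vocabulary(c("C", "Cl", "Br", "O", "."))
#' v$size
#' @export
vocabulary <- function(structure_tokens) {
  structure_tokens <- as.character(structure_tokens)
  specials <- c(">", "<pad>", "<", "$")
  if (anyDuplicated(structure_tokens))
    stop("structure tokens must be distinct")
  if (any(structure_tokens %in% specials))
    stop("structure tokens must not include the special tokens >, <pad>, <, $")
  tokens <- c(structure_tokens, specials)
  n <- length(structure_tokens)
  structure(
    list(
      tokens = tokens,
      n_structure = n,
      size = n + 4L,
      sep_id = n + 1L,
      pad_id = n + 2L,
      start_id = n + 3L,
      end_id = n + 4L
    ),
    class = "vocabulary"
  )
}

#' @export
print.vocabulary <- function(x, ...) {
  cat("<vocabulary> ", x$size, " tokens (", x$n_structure,
      " structure + 4 special)\n", sep = "")
  invisible(x)
}

#' A standard-size SMILES token inventory
#'
#' Builds a representative inventory of 284 SMILES structure tokens (organic
#' and aromatic atoms, two-character elements, bracket atoms with charge /
#' hydrogen-count / chirality modifiers, ring-closure digits and `%nn` labels,
#' bond and branch symbols), yielding a 288-token vocabulary once the four
#' special tokens are appended. Only the inventory size matters for
#' architecture sizing; the token set itself is configurable via
#' [vocabulary()].
#'
#' @return A `vocabulary` of total size 288.
#' @export
smiles_vocabulary <- function() {
  singles <- c("B", "C", "N", "O", "P", "S", "F", "I",
               "b", "c", "n", "o", "p", "s")
  doubles <- c("Cl", "Br", "Si", "Se")
  syms <- c("(", ")", "[", "]", "=", "#", "-", "+", "/", "\\",
            ".", ":", "@", "@@", "H")
  digits <- as.character(0:9)
  rings <- paste0("%", 10:99)
  els <- c("C", "N", "O", "S", "P", "B", "Si", "Se", "F", "Cl", "Br", "I")
  forms <- c("%s", "%s+", "%s-", "%s@", "%s@@", "%sH", "%sH+", "%sH-",
             "%sH2", "%sH2+", "%sH3", "%s@H", "%s@@H")
  brackets <- as.vector(outer(els, forms,
                              function(e, f) sprintf(paste0("[", f, "]"), e)))
  toks <- unique(c(singles, doubles, syms, digits, rings, brackets))
  vocabulary(toks[seq_len(284L)])
}

#' Tokenize a structure string
#'
#' Greedy longest-match tokenization over the vocabulary's structure tokens
#' and the `">"` reagent separator. Padding/start/end tokens are never
#' matched from input text.
#'
#' @param s Non-empty character scalar.
#' @param vocab A [vocabulary()].
#' @return Character vector of tokens.
#' @examples
#' v <- vocabulary(c("C", "Cl", "Br", "O"))
#' tokenize_structure("CClBr", v)
#' @export
tokenize_structure <- function(s, vocab) {
  stopifnot(inherits(vocab, "vocabulary"))
  if (!is.character(s) || length(s) != 1L || !nzchar(s))
    stop("input string must be a non-empty character scalar")
  matchable <- c(vocab$tokens[seq_len(vocab$n_structure)], ">")
  matchable <- matchable[order(nchar(matchable), decreasing = TRUE)]
  out <- character(0)
  i <- 1L
  n <- nchar(s)
  while (i <= n) {
    hit <- NA_character_
    for (tok in matchable) {
      k <- nchar(tok)
      if (i + k - 1L <= n && substr(s, i, i + k - 1L) == tok) {
        hit <- tok
        break
      }
    }
    if (is.na(hit))
      stop(sprintf("no vocabulary token matches input at offset %d (\"%s\")",
                   i, substr(s, i, min(n, i + 4L))))
    out <- c(out, hit)
    i <- i + nchar(hit)
  }
  out
}

#' Pad-encode a token list to a fixed-length id sequence
#'
#' @param tokens Character vector of tokens (may be empty).
#' @param vocab A [vocabulary()].
#' @param d_seq Fixed output length.
#' @return A `token_sequence`: integer ids of length `d_seq` (1-based indices
#'   into the vocabulary, padded with the pad token) plus the content count.
#' @export
pad_encode <- function(tokens, vocab, d_seq) {
  stopifnot(inherits(vocab, "vocabulary"), d_seq >= 1)
  if (length(tokens) > d_seq)
    stop(sprintf("sequence of %d tokens exceeds d_seq = %d; the record should have been filtered upstream",
                 length(tokens), d_seq))
  ids <- match(tokens, vocab$tokens)
  if (anyNA(ids))
    stop("unknown token(s): ", paste(tokens[is.na(ids)], collapse = ", "))
  structure(
    list(ids = c(ids, rep(vocab$pad_id, d_seq - length(ids))),
         n_content = length(ids),
         d_seq = as.integer(d_seq)),
    class = "token_sequence"
  )
}

# -- spectra -----------------------------------------------------------------

#' Standard spectral grids
#'
#' IR: 400-4000 cm^-1 at 4 cm^-1 (900 points); 1H-NMR: -2 to 10 ppm at
#' ~0.0121 ppm (993 points); EI-MS: 1-999 m/z at 1 m/z (999 points).
#'
#' @param modality One of `"IR"`, `"NMR"`, `"MS"`.
#' @return Named numeric `c(start, stop, step)` with implied length.
#' @export
spectrum_grid <- function(modality) {
  switch(modality,
    IR  = c(start = 400, stop = 4000, step = 4),
    NMR = c(start = -2, stop = 10, step = 12 / 993),
    MS  = c(start = 1, stop = 999, step = 1),
    stop("unknown modality: ", modality)
  )
}

grid_length <- function(modality) {
  switch(modality, IR = 900L, NMR = 993L, MS = 999L)
}

#' Construct a spectrum
#'
#' @param intensities Non-negative finite numeric vector on a fixed grid.
#' @param modality One of `"IR"`, `"NMR"`, `"MS"`.
#' @param grid Optional `c(start, stop, step)`; defaults to the modality's
#'   standard grid when the length matches, otherwise an index grid.
#' @return An object of class `spectrum`.
#' @export
spectrum <- function(intensities, modality = c("IR", "NMR", "MS"), grid = NULL) {
  modality <- match.arg(modality)
  intensities <- as.numeric(intensities)
  if (any(!is.finite(intensities)))
    stop("spectrum intensities must be finite")
  if (any(intensities < 0))
    stop("spectrum intensities must be non-negative")
  if (is.null(grid)) {
    grid <- if (length(intensities) == grid_length(modality))
      spectrum_grid(modality)
    else c(start = 1, stop = length(intensities), step = 1)
  }
  structure(list(modality = modality, intensities = intensities, grid = grid),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat("<spectrum> ", x$modality, ", ", length(x$intensities), " points, ",
      sum(x$intensities > 0), " non-zero\n", sep = "")
  invisible(x)
}

#' Normalize a spectrum to the unit intensity range
#'
#' Divides by the maximum intensity; an all-zero spectrum is returned
#' unchanged (the missing-spectrum placeholder).
#'
#' @param sp A [spectrum()].
#' @return A `spectrum` with max intensity 1 (or all zero).
#' @export
normalize_spectrum <- function(sp) {
  stopifnot(inherits(sp, "spectrum"))
  m <- max(sp$intensities)
  if (m > 0) sp$intensities <- sp$intensities / m
  sp
}

#' Discretize a normalized spectrum into intensity tokens
#'
#' Intensities in `[0, 1]` are mapped to fixed 1%-wide bins, lower-exclusive
#' and upper-inclusive, with a dedicated token 0 for zero intensity. NMR and
#' MS use 101 tokens (`0` plus bins 1..100); for IR, intensities below 1% are
#' zeroed to suppress background, so the zero token absorbs the first bin and
#' the inventory has 100 tokens total.
#'
#' @param sp A normalized [spectrum()] (all intensities in `[0, 1]`).
#' @return A `discretized_spectrum` with 0-based `token_ids` and the modality
#'   vocabulary size (100 for IR, 101 for NMR/MS).
#' @export
discretize <- function(sp) {
  stopifnot(inherits(sp, "spectrum"))
  v <- sp$intensities
  if (any(v < 0 | v > 1))
    stop("spectrum must be normalized to [0, 1] before discretization")
  bin <- pmin(pmax(ceiling(100 * v), 0L), 100L)   # 0 for v == 0
  if (sp$modality == "IR") {
    bin[v < 0.01] <- 0L
    ids <- ifelse(bin == 0L, 0L, bin - 1L)        # zero token absorbs bin 1
    vocab_size <- 100L
  } else {
    ids <- bin
    vocab_size <- 101L
  }
  structure(list(modality = sp$modality, token_ids = as.integer(ids),
                 vocab_size = vocab_size),
            class = "discretized_spectrum")
}

#' Midpoint de-binning of a discretized spectrum
#'
#' Inverse of [discretize()] up to half a bin width; used for round-trip
#' checks.
#'
#' @param dsp A `discretized_spectrum`.
#' @return Numeric vector of bin-midpoint intensities.
#' @export
debin <- function(dsp) {
  stopifnot(inherits(dsp, "discretized_spectrum"))
  ids <- dsp$token_ids
  if (dsp$modality == "IR") {
    ifelse(ids == 0L, 0, (ids + 1 - 0.5) / 100)
  } else {
    ifelse(ids == 0L, 0, (ids - 0.5) / 100)
  }
}
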