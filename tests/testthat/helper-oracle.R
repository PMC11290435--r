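# A hand-specified two-step probability table over the vocabulary {a, b} +
# specials, and its exhaustive-enumeration oracle for beam-search checks.

oracle_vocab <- vocabulary(c("a", "b"))

table_model <- function(prefix) {
  v <- oracle_vocab
  body <- paste(v$tokens[prefix[-1]], collapse = "")
  p <- numeric(v$size)
  if (body == "") {
    p[match(c("a", "b"), v$tokens)] <- c(0.5, 0.3); p[v$end_id] <- 0.2
  } else if (body == "a") {
    p[match(c("a", "b"), v$tokens)] <- c(0.1, 0.2); p[v$end_id] <- 0.7
  } else if (body == "b") {
    p[match(c("a", "b"), v$tokens)] <- c(0.4, 0.45); p[v$end_id] <- 0.15
  } else {
    p[v$end_id] <- 1
  }
  p
}

# Complete strings scored as the product of token probabilities times the end
# probability -- the independent oracle beam search must reproduce.
enumerate_strings <- function(max_len) {
  v <- oracle_vocab
  out <- list()
  recurse <- function(prefix, lp) {
    p <- table_model(prefix)
    out[[length(out) + 1L]] <<- list(
      string = paste(v$tokens[prefix[-1]], collapse = ""),
      lp = lp + log(p[v$end_id]))
    if (length(prefix) - 1L < max_len) {
      for (tok in match(c("a", "b"), v$tokens)) {
        if (p[tok] > 0) recurse(c(prefix, tok), lp + log(p[tok]))
      }
    }
  }
  recurse(v$start_id, 0)
  ord <- order(-vapply(out, `[[`, numeric(1), "lp"))
  list(strings = vapply(out, `[[`, character(1), "string")[ord],
       lp = vapply(out, `[[`, numeric(1), "lp")[ord])
}
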