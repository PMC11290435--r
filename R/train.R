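# Teacher-forced training: warm-up/decay learning rate, Adam, per-spectrum
# input dropping, early stopping on validation loss.

#' Training configuration
#'
#' @param batch_size Samples per gradient step (default 20).
#' @param beta1,beta2,adam_eps Adam moment decays and epsilon
#'   (0.9 / 0.98 / 1e-9).
#' @param s_warm Warm-up steps; `NULL` uses ~4% of the planned steps
#'   (`max_epochs` times steps per epoch), the convention the full-scale
#'   37 500-step setting follows.
#' @param patience Early-stopping patience in epochs (default 30): training
#'   stops when validation loss fails to improve for this many consecutive
#'   epochs.
#' @param spectral_drop_p Per-spectrum probability of replacing an input
#'   spectrum with the all-zero-token placeholder at each training
#'   presentation (0 disables; 0.1 is the missing-spectra training variant).
#'   The reactant input is never dropped.
#' @param max_epochs Hard epoch cap.
#' @param seed Integer seed driving shuffling, dropout and spectral dropping.
#' @param lr_scale Multiplier on the schedule (default 1).
#' @param clip_norm Global gradient-norm clip applied before each update
#'   (0 disables; the default 1 guards against the occasional unstable step
#'   that small-batch training produces).
#' @param verbose Print per-epoch losses.
#' @return A `train_config`.
#' @export
train_config <- function(batch_size = 20, beta1 = 0.9, beta2 = 0.98,
                         adam_eps = 1e-9, s_warm = NULL, patience = 30,
                         spectral_drop_p = 0, max_epochs = 100, seed = 1,
                         lr_scale = 1, clip_norm = 1, verbose = FALSE) {
  stopifnot(batch_size >= 1, patience >= 1, clip_norm >= 0,
            spectral_drop_p >= 0, spectral_drop_p <= 1)
  structure(
    list(batch_size = as.integer(batch_size), beta1 = beta1, beta2 = beta2,
         adam_eps = adam_eps, s_warm = s_warm, patience = as.integer(patience),
         spectral_drop_p = spectral_drop_p, max_epochs = as.integer(max_epochs),
         seed = as.integer(seed), lr_scale = lr_scale, clip_norm = clip_norm,
         verbose = verbose),
    class = "train_config"
  )
}

#' Warm-up / inverse-square-root learning-rate schedule
#'
#' `eta(s) = d_emb^(-1/2) * min(s^(-1/2), s * s_warm^(-3/2))`: a linear ramp
#' to the peak at `s = s_warm`, then inverse-square-root decay.
#'
#' @param s Update step (>= 1; vectorized).
#' @param d_emb Embedding width.
#' @param s_warm Warm-up step count.
#' @return Learning rate(s).
#' @examples
#' lr_schedule(37500, 256, 37500)   # peak, ~3.23e-4
#' @export
lr_schedule <- function(s, d_emb, s_warm) {
  if (any(s < 1)) stop("step s must be >= 1")
  d_emb^(-0.5) * pmin(s^(-0.5), s * s_warm^(-1.5))
}

#' Randomly drop input spectra from a record
#'
#' Each present spectrum is independently replaced, with probability `p`, by
#' the missing-spectrum placeholder (an all-zero spectrum, which discretizes
#' to all zero-intensity tokens). Uses the session RNG; the reactant input is
#' untouched.
#'
#' @param record A reaction record.
#' @param p Drop probability in `[0, 1]`.
#' @return The record with spectra possibly zeroed.
#' @export
spectral_dropout <- function(record, p) {
  stopifnot(p >= 0, p <= 1)
  if (p == 0 || is.null(record$spectra)) return(record)
  for (m in names(record$spectra)) {
    if (runif(1) < p) {
      sp <- record$spectra[[m]]
      record$spectra[[m]] <- spectrum(numeric(length(sp$intensities)),
                                      sp$modality, sp$grid)
    }
  }
  record
}

#' Train a deductive model
#'
#' Minimizes token-level cross-entropy of the fused deduction distribution
#' against the target sequence under teacher forcing. Loss is computed over
#' content and end-token positions only (padding never enters the loss).
#' Early stopping restores the best-validation weights.
#'
#' @param model A [deductive_model()]; its weights are updated in place.
#' @param splits A `dataset_splits` (train/validation used), or a list with
#'   `train` and `validation` record lists, or pre-encoded
#'   `encoded_reactions` in those slots.
#' @param vocab The [vocabulary()] used for encoding (ignored for
#'   pre-encoded splits).
#' @param config A [train_config()].
#' @param with_separator Reagent-separator variant for input strings.
#' @return A `specdeduce_fit`: the model, a history data frame
#'   (epoch, train/validation token-mean loss, learning rate), the best
#'   validation loss and epoch.
#' @export
train_model <- function(model, splits, vocab = NULL, config = train_config(),
                        with_separator = TRUE) {
  stopifnot(inherits(model, "deductive_model"),
            inherits(config, "train_config"))
  enc <- function(x) {
    if (inherits(x, "encoded_reactions")) return(x)
    if (!length(x)) stop("empty training split")
    encode_dataset(x, vocab, model$config, with_separator)
  }
  tr <- enc(splits$train)
  va <- enc(splits$validation)
  steps_per_epoch <- ceiling(tr$n / config$batch_size)
  s_warm <- config$s_warm
  if (is.null(s_warm))
    s_warm <- max(1, round(0.04 * config$max_epochs * steps_per_epoch))
  tcfg <- list(batch_size = config$batch_size, max_epochs = config$max_epochs,
               patience = config$patience, s_warm = as.numeric(s_warm),
               beta1 = config$beta1, beta2 = config$beta2,
               adam_eps = config$adam_eps,
               spectral_drop_p = config$spectral_drop_p,
               lr_scale = config$lr_scale, clip_norm = config$clip_norm,
               seed = config$seed, verbose = isTRUE(config$verbose))
  res <- sn_train(model$ptr, unname(tr$inputs), tr$tgt, tr$tgtlen,
                  unname(va$inputs), va$tgt, va$tgtlen, tcfg)
  history <- data.frame(epoch = seq_along(res$train_loss),
                        train_loss = res$train_loss,
                        val_loss = res$val_loss,
                        lr = res$lr)
  structure(list(model = model, history = history, best_val = res$best_val,
                 best_epoch = res$best_epoch, steps = res$steps,
                 s_warm = s_warm),
            class = "specdeduce_fit")
}

#' @export
print.specdeduce_fit <- function(x, ...) {
  cat("<specdeduce_fit> ", nrow(x$history), " epochs, best validation loss ",
      signif(x$best_val, 4), " at epoch ", x$best_epoch, "\n", sep = "")
  invisible(x)
}
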