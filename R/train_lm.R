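# Stage 1: language-model pretraining.
#
# Sequences are framed [BOS] s [EOS] and trained with teacher forcing:
# the model input is [BOS] + s, the target is s + [EOS], and the loss is
# the mean next-token cross-entropy. No padding enters the loss: the
# backward pass weights each real token 1/n_tokens and nothing else.

frame_sequence <- function(ids, vocab) {
  list(input = c(vocab$bos_id, ids), target = c(ids, vocab$eos_id))
}

encode_corpus <- function(corpus, vocab, max_len) {
  enc <- lapply(corpus, function(s) encode(s, vocab)$ids)
  keep <- lengths(enc) <= max_len
  if (!all(keep)) {
    warning(sprintf("dropping %d/%d sequences longer than max_len = %d",
                    sum(!keep), length(enc), max_len))
    enc <- enc[keep]
  }
  if (length(enc) == 0L) stop("no trainable sequences after length filtering")
  enc
}

batch_loss_grad <- function(framed, params, config, dropout = 0,
                            forbid = integer(0)) {
  n_tokens <- sum(lengths(lapply(framed, `[[`, "target")))
  weights <- lapply(framed, function(f) rep(1 / n_tokens, length(f$target)))
  res <- cpp_batch_loss_grad(
    lapply(framed, `[[`, "input"), lapply(framed, `[[`, "target"),
    weights, unclass(params), config$n_heads, dropout, as.integer(forbid))
  res
}

#' Train the SMILES language model
#'
#' Minimises mean next-token cross-entropy with teacher forcing over
#' `[BOS]`-prefixed, `[EOS]`-terminated sequences, using Adam on
#' mini-batches reshuffled every epoch. Fully seeded: two runs with the
#' same arguments produce bit-identical loss logs and weights.
#'
#' @param corpus Character vector of SMILES strings, or a path to a `.smi`
#'   file (one molecule per line).
#' @param config A [decoder_config()]; its `vocab_size` is overridden by
#'   the actual vocabulary size.
#' @param epochs Number of passes over the corpus (reference setting: 3).
#' @param seed Integer seed for initialisation, shuffling and dropout.
#' @param vocab A `smirl_vocab`; built from the corpus with
#'   [build_char_vocab()] when `NULL`.
#' @param batch_size Sequences per optimiser step.
#' @param lr Adam learning rate. The optimiser and rate are this package's
#'   defaults for desk-scale corpora, not part of the reference recipe.
#' @param params Optional warm-start weights.
#' @param verbose Print per-epoch loss.
#' @return A `smirl_lm` object: `params`, `vocab`, `config` and a tibble
#'   `log` with per-epoch mean training loss.
#' @export
train_lm <- function(corpus, config = NULL, epochs = 3L, seed = 1L,
                     vocab = NULL, batch_size = 64L, lr = 1e-4,
                     params = NULL, verbose = FALSE) {
  if (length(corpus) == 1L && file.exists(corpus)) {
    corpus <- read_smi(corpus)
  }
  corpus <- as.character(corpus)
  if (length(corpus) == 0L) stop("corpus is empty")
  stopifnot(epochs >= 1L)

  if (is.null(vocab)) vocab <- build_char_vocab(corpus)
  if (is.null(config)) config <- decoder_config(vocab_size = length(vocab))
  config$vocab_size <- length(vocab)

  enc <- encode_corpus(corpus, vocab, config$max_len)
  framed <- lapply(enc, frame_sequence, vocab = vocab)

  if (is.null(params)) {
    params <- init_params(config, seed = seed)
  }
  set.seed(seed + 1L)

  flat <- flatten_params(params)
  opt <- adam_state(length(flat))
  epoch_loss <- numeric(epochs)

  for (ep in seq_len(epochs)) {
    ord <- sample.int(length(framed))
    batches <- split(ord, ceiling(seq_along(ord) / batch_size))
    losses <- numeric(length(batches))
    sizes <- numeric(length(batches))
    for (bi in seq_along(batches)) {
      fb <- framed[batches[[bi]]]
      res <- batch_loss_grad(fb, params, config, dropout = config$dropout)
      losses[bi] <- res$loss
      sizes[bi] <- sum(lengths(lapply(fb, `[[`, "target")))
      step <- adam_step(opt, flatten_params(res$grads), lr)
      opt <- step$state
      flat <- flat - step$delta
      params <- unflatten_params(flat, params)
    }
    epoch_loss[ep] <- sum(losses * sizes) / sum(sizes)
    if (verbose) {
      message(sprintf("epoch %d/%d  loss %.4f", ep, epochs, epoch_loss[ep]))
    }
  }

  structure(
    list(params = params, vocab = vocab, config = config,
         log = tibble::tibble(epoch = seq_len(epochs), loss = epoch_loss),
         seed = seed),
    class = "smirl_lm"
  )
}

#' @export
print.smirl_lm <- function(x, ...) {
  cat(sprintf(
    "<smirl_lm> %d layers, d_model=%d, vocab=%d; final loss %.4f after %d epoch(s)\n",
    x$config$n_layers, x$config$d_model, x$config$vocab_size,
    tail(x$log$loss, 1), nrow(x$log)))
  invisible(x)
}

#' Mean next-token cross-entropy of a model on a corpus
#'
#' Teacher-forced evaluation loss (no dropout, no updates), in nats per
#' predicted token. A uniform model scores `log(vocab_size)`.
#'
#' @param model A `smirl_lm`, or a `smirl_params` (then `vocab` is
#'   required).
#' @param corpus Character vector of SMILES strings.
#' @param vocab Vocabulary when raw params are supplied.
#' @return A single number (nats/token).
#' @export
lm_cross_entropy <- function(model, corpus, vocab = NULL) {
  if (inherits(model, "smirl_lm")) {
    params <- model$params; vocab <- model$vocab
  } else {
    params <- model
    if (is.null(vocab)) stop("vocab is required with raw parameters")
  }
  config <- params_config(params)
  enc <- encode_corpus(corpus, vocab, config$max_len)
  framed <- lapply(enc, frame_sequence, vocab = vocab)
  batch_loss_grad(framed, params, config, dropout = 0)$loss
}

#' Read / write `.smi` corpora
#'
#' Plain text, one SMILES per line, no header.
#'
#' @param path File path.
#' @export
read_smi <- function(path) {
  x <- readLines(path, warn = FALSE)
  x[nzchar(x)]
}

#' @rdname read_smi
#' @param smiles Character vector to write.
#' @export
write_smi <- function(smiles, path) {
  writeLines(smiles, path)
  invisible(path)
}
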