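#' Decoder architecture configuration
#'
#' Hyperparameters of the causal (decoder-only) transformer that serves
#' both as the SMILES language model and as the RL policy. Defaults follow
#' the reference configuration: 4 layers, 8 heads, model width 512,
#' feed-forward width 1024, maximum sequence length 150.
#'
#' @param vocab_size Number of tokens (specials included).
#' @param n_layers Number of decoder blocks.
#' @param n_heads Attention heads per block; must divide `d_model`.
#' @param d_model Embedding / residual-stream width.
#' @param d_ff Hidden width of the position-wise MLP.
#' @param max_len Maximum SMILES length in tokens (positions; one extra
#'   slot is reserved internally for the `[BOS]` prefix).
#' @param dropout Dropout fraction used during training only.
#' @return A `smirl_config` list.
#' @export
decoder_config <- function(vocab_size, n_layers = 4L, n_heads = 8L,
                           d_model = 512L, d_ff = 1024L, max_len = 150L,
                           dropout = 0.1) {
  stopifnot(vocab_size >= 4L, n_layers >= 1L, n_heads >= 1L,
            d_model %% n_heads == 0L, max_len >= 2L,
            dropout >= 0, dropout < 1)
  structure(
    list(vocab_size = as.integer(vocab_size), n_layers = as.integer(n_layers),
         n_heads = as.integer(n_heads), d_model = as.integer(d_model),
         d_ff = as.integer(d_ff), max_len = as.integer(max_len),
         dropout = dropout),
    class = "smirl_config"
  )
}

#' @export
print.smirl_config <- function(x, ...) {
  cat(sprintf(
    "<smirl_config> %d layers x %d heads, d_model=%d, d_ff=%d, max_len=%d, vocab=%d\n",
    x$n_layers, x$n_heads, x$d_model, x$d_ff, x$max_len, x$vocab_size))
  invisible(x)
}

#' Initialise decoder parameters
#'
#' Weights are drawn from a truncated normal (sd 0.02, clipped at two sd);
#' biases and layer-norm shifts start at zero, layer-norm gains at one.
#'
#' @param config A `smirl_config`.
#' @param seed Integer seed; initialisation is fully reproducible.
#' @return A nested parameter list (class `smirl_params`).
#' @export
init_params <- function(config, seed = 1L) {
  set.seed(seed)
  D <- config$d_model; Fw <- config$d_ff; V <- config$vocab_size
  P <- config$max_len + 1L  # + [BOS] slot
  tn <- function(r, c, sd = 0.02) {
    x <- rnorm(r * c, sd = sd)
    x <- pmin(pmax(x, -2 * sd), 2 * sd)
    matrix(x, r, c)
  }
  layer <- function() {
    list(ln1_g = rep(1, D), ln1_b = rep(0, D),
         Wq = tn(D, D), bq = rep(0, D), Wk = tn(D, D), bk = rep(0, D),
         Wv = tn(D, D), bv = rep(0, D), Wo = tn(D, D), bo = rep(0, D),
         ln2_g = rep(1, D), ln2_b = rep(0, D),
         W1 = tn(D, Fw), b1 = rep(0, Fw), W2 = tn(Fw, D), b2 = rep(0, D))
  }
  params <- list(
    tok_emb = tn(V, D), pos_emb = tn(P, D),
    layers = lapply(seq_len(config$n_layers), function(i) layer()),
    lnf_g = rep(1, D), lnf_b = rep(0, D),
    head_W = tn(D, V), head_b = rep(0, V)
  )
  structure(params, class = "smirl_params", config = config)
}

params_config <- function(params) attr(params, "config")

#' Forward pass: per-position next-token distributions
#'
#' Runs the decoder on one id sequence and returns, for every position t,
#' the model's categorical distribution over the next token given the
#' prefix up to t — i.e. the policy \eqn{\pi_\theta(a \mid s_t)}. Future
#' tokens are masked out of attention, so row t depends on positions
#' \eqn{\le t} only.
#'
#' @param ids `smirl_tokens` or 0-based integer id vector (typically
#'   `[BOS]`-prefixed).
#' @param params A `smirl_params`.
#' @param probs If `FALSE`, return raw logits instead of softmax rows.
#' @return Matrix, one row per input position, one column per vocabulary id.
#' @export
decoder_forward <- function(ids, params, probs = TRUE) {
  if (inherits(ids, "smirl_tokens")) ids <- ids$ids
  cfg <- params_config(params)
  if (length(ids) > cfg$max_len + 1L) {
    stop(sprintf("input length %d exceeds max_len + 1 = %d",
                 length(ids), cfg$max_len + 1L))
  }
  cpp_forward(as.integer(ids), unclass(params), cfg$n_heads, probs)
}

# ---- parameter vector utilities (Adam works on a flat vector) ----

flatten_params <- function(params) {
  unlist(params, use.names = FALSE)
}

unflatten_params <- function(flat, template) {
  pos <- 0L
  take <- function(tmpl) {
    if (is.list(tmpl)) {
      out <- lapply(tmpl, take)
      names(out) <- names(tmpl)
      return(out)
    }
    n <- length(tmpl)
    chunk <- flat[(pos + 1L):(pos + n)]
    pos <<- pos + n
    if (is.matrix(tmpl)) matrix(chunk, nrow(tmpl), ncol(tmpl)) else chunk
  }
  res <- take(unclass(template))
  stopifnot(pos == length(flat))
  structure(res, class = "smirl_params", config = params_config(template))
}

# ---- Adam optimiser ----

adam_state <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(state, grad, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(state = state, delta = lr * mhat / (sqrt(vhat) + eps))
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a versioned container holding the architecture
#' configuration, the vocabulary and the weights; reloading restores them
#' bit-for-bit, so `decoder_forward()` after a save/load round trip equals
#' the original exactly.
#'
#' @param params A `smirl_params`.
#' @param vocab The `smirl_vocab` the model was trained with.
#' @param path File path (`.rds`).
#' @param extra Optional named list stored alongside (e.g. training logs).
#' @export
save_checkpoint <- function(params, vocab, path, extra = list()) {
  obj <- list(format = "smirl-checkpoint", version = 1L,
              config = params_config(params), vocab = vocab,
              params = params, extra = extra)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint()` returns a list with `params`, `vocab`,
#'   `config` and `extra`.
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "smirl-checkpoint")) {
    stop("not a smirl checkpoint: ", path)
  }
  obj
}
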