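# Shared test utilities: tiny model builders, an independent reference
# implementation of the decoder forward pass (naive loops, written against
# the layer equations, never calling the package's C++ path), scripted
# deterministic policies, and a memoised fixture corpus.

.helper_cache <- new.env(parent = emptyenv())

tiny_config <- function(vocab_size, n_layers = 2L, n_heads = 2L,
                        d_model = 16L, d_ff = 24L, max_len = 12L,
                        dropout = 0) {
  decoder_config(vocab_size, n_layers = n_layers, n_heads = n_heads,
                 d_model = d_model, d_ff = d_ff, max_len = max_len,
                 dropout = dropout)
}

random_params <- function(config, seed = 1L, jitter = 0.1) {
  p <- init_params(config, seed = seed)
  set.seed(seed + 1000L)
  fl <- smirl:::flatten_params(p)
  smirl:::unflatten_params(fl + rnorm(length(fl), sd = jitter), p)
}

shared_fixture_corpus <- function(n = 1000L, seed = 7L) {
  key <- paste0("fix", n, "_", seed)
  if (!exists(key, envir = .helper_cache)) {
    assign(key, generate_fixture_corpus(fixture_spec(n, seed = seed)),
           envir = .helper_cache)
  }
  get(key, envir = .helper_cache)
}

# ---- independent reference forward pass (naive loops) ----

ref_layernorm <- function(x, g, b, eps = 1e-5) {
  t(apply(x, 1, function(r) {
    mu <- mean(r); v <- mean((r - mu)^2)
    g * (r - mu) / sqrt(v + eps) + b
  }))
}

ref_softmax <- function(v) { e <- exp(v - max(v)); e / sum(e) }

ref_gelu <- function(x) x * pnorm(x)

# Single-head attention by explicit per-row weighted sums.
ref_attention <- function(Q, K, V) {
  L <- nrow(Q); d <- ncol(Q)
  out <- matrix(0, L, ncol(V))
  for (i in seq_len(L)) {
    scores <- vapply(seq_len(i), function(j) sum(Q[i, ] * K[j, ]) / sqrt(d),
                     numeric(1))
    w <- ref_softmax(scores)
    for (j in seq_len(i)) out[i, ] <- out[i, ] + w[j] * V[j, ]
  }
  out
}

ref_forward <- function(ids, params, config, probs = TRUE) {
  D <- config$d_model; H <- config$n_heads; dh <- D / H
  L <- length(ids)
  x <- matrix(0, L, D)
  for (i in seq_len(L)) {
    x[i, ] <- params$tok_emb[ids[i] + 1L, ] + params$pos_emb[i, ]
  }
  for (lw in params$layers) {
    A <- ref_layernorm(x, lw$ln1_g, lw$ln1_b)
    Q <- sweep(A %*% lw$Wq, 2, lw$bq, "+")
    K <- sweep(A %*% lw$Wk, 2, lw$bk, "+")
    V <- sweep(A %*% lw$Wv, 2, lw$bv, "+")
    O <- matrix(0, L, D)
    for (h in seq_len(H)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      O[, cols] <- ref_attention(Q[, cols, drop = FALSE],
                                 K[, cols, drop = FALSE],
                                 V[, cols, drop = FALSE])
    }
    x <- x + sweep(O %*% lw$Wo, 2, lw$bo, "+")
    B <- ref_layernorm(x, lw$ln2_g, lw$ln2_b)
    Hh <- ref_gelu(sweep(B %*% lw$W1, 2, lw$b1, "+"))
    x <- x + sweep(Hh %*% lw$W2, 2, lw$b2, "+")
  }
  Y <- ref_layernorm(x, params$lnf_g, params$lnf_b)
  logits <- sweep(Y %*% params$head_W, 2, params$head_b, "+")
  if (!probs) return(logits)
  t(apply(logits, 1, ref_softmax))
}

# ---- scripted policies ----

# Params whose sampled actions follow `actions` (0-based ids, usually
# ending in [EOS]) with probability ~1: all blocks are identity (zero
# sublayer weights), position embeddings are one-hot, and the output head
# wires position t to action t+1 with a huge logit margin.
scripted_policy <- function(vocab, actions, margin = 30) {
  V <- length(vocab$tokens)
  n <- length(actions)
  cfg <- decoder_config(V, n_layers = 1L, n_heads = 1L,
                        d_model = max(8L, n + 2L), d_ff = 4L,
                        max_len = max(4L, n + 1L), dropout = 0)
  p <- init_params(cfg, seed = 1L)
  fl <- smirl:::flatten_params(p)
  p <- smirl:::unflatten_params(0 * fl, p)
  p$lnf_g <- rep(1, cfg$d_model)
  for (t in seq_len(n)) {
    p$pos_emb[t, t] <- 1
    p$head_W[t, actions[t] + 1L] <- margin
  }
  structure(p, class = "smirl_params", config = cfg)
}

toy_vocab <- function(tokens = "A") {
  smirl:::new_vocabulary(c("[PAD]", "[BOS]", "[EOS]", tokens), "char")
}

# ---- toy-MDP utilities shared by policy-gradient and acceptance tests ----

# Enumerate every trajectory of the single-token MDP (vocabulary {A},
# actions {A, [EOS]}, length cap `max_len`): probabilities are computed
# purely from forward passes, independent of the backward machinery.
enumerate_toy_mdp <- function(params, vocab, max_len) {
  a_id <- match("A", vocab$tokens) - 1L
  eos <- vocab$eos_id
  trajs <- list()
  recurse <- function(actions, state, logp) {
    step <- length(actions) + 1L
    pr <- next_token_probs(params, vocab, state)
    for (a in c(a_id, eos)) {
      lp <- logp + log(unname(pr[a + 1L]))
      acts <- c(actions, a)
      if (a == eos) {
        trajs[[length(trajs) + 1L]] <<- list(actions = acts, logp = lp)
      } else if (length(state) + 1L >= max_len) {
        trajs[[length(trajs) + 1L]] <<- list(actions = acts, logp = lp)
      } else {
        recurse(acts, c(state, a), lp)
      }
    }
  }
  recurse(integer(0), integer(0), 0)
  trajs
}

toy_terminal_string <- function(actions, vocab) {
  chars <- actions[actions != vocab$eos_id]
  paste(vocab$tokens[chars + 1L], collapse = "")
}

grad_of_trajs <- function(trajs, weights_per_traj, params, vocab) {
  cfg <- smirl:::params_config(params)
  inputs <- lapply(trajs, function(tr) {
    a <- tr$actions; n <- length(a)
    c(vocab$bos_id, if (n > 1L) a[seq_len(n - 1L)])
  })
  targets <- lapply(trajs, `[[`, "actions")
  res <- smirl:::cpp_batch_loss_grad(
    inputs, targets, weights_per_traj, unclass(params), cfg$n_heads, 0,
    as.integer(c(vocab$pad_id, vocab$bos_id)))
  smirl:::flatten_params(res$grads)
}


random_garbage_strings <- function(n, seed) {
  set.seed(seed)
  pool <- c(strsplit("()[]=#%+-.0123456789abcXYZ$!?", "")[[1]], "((", "))")
  vapply(seq_len(n), function(i) {
    paste0("(", paste(sample(pool, sample(2:8, 1), replace = TRUE),
                      collapse = ""), "(")
  }, character(1))
}

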