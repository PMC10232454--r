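# Autoregressive sampling: each episode starts from the empty string,
# draws a_t ~ pi_theta(. | s_t), appends the token (transitions are
# deterministic), and stops when [EOS] is drawn (not appended) or the
# string reaches max_len tokens, which is also a terminal state. [PAD]
# and [BOS] are not actions of the MDP and are masked out of the sampling
# distribution; the same mask is applied when policy gradients are
# computed, so sampled log-probabilities and gradient are consistent.

action_forbid <- function(vocab) c(vocab$pad_id, vocab$bos_id)

#' Next-token (policy) distribution for a state
#'
#' The distribution \eqn{\pi_\theta(\cdot \mid s)} the sampler actually
#' draws from: the decoder's next-token softmax with the non-action
#' specials (`[PAD]`, `[BOS]`) removed and the rest renormalised.
#'
#' @param params A `smirl_params`.
#' @param vocab The matching `smirl_vocab`.
#' @param state_ids 0-based ids of the tokens generated so far (without
#'   `[BOS]`); `integer(0)` is the initial state.
#' @param temperature Softmax temperature (1 = the model's distribution).
#' @return Named numeric vector of probabilities over the vocabulary.
#' @export
next_token_probs <- function(params, vocab, state_ids = integer(0),
                             temperature = 1) {
  cfg <- params_config(params)
  p <- cpp_lastpos_probs(list(c(vocab$bos_id, as.integer(state_ids))),
                         unclass(params), cfg$n_heads,
                         as.integer(action_forbid(vocab)))[1, ]
  if (temperature != 1) {
    p <- p^(1 / temperature)
    p <- p / sum(p)
  }
  setNames(p, vocab$tokens)
}

#' Sampling configuration
#'
#' @param n_samples Number of molecules to draw.
#' @param max_len Maximum molecule length in tokens (default 150).
#' @param temperature Positive softmax temperature; 1.0 samples the
#'   model's own distribution and is the reference behaviour.
#' @param seed Integer seed.
#' @return A `smirl_genconfig` list.
#' @export
generation_config <- function(n_samples = 25000L, max_len = 150L,
                              temperature = 1.0, seed = 1L) {
  stopifnot(n_samples >= 0L, temperature > 0, max_len >= 1L)
  structure(list(n_samples = as.integer(n_samples),
                 max_len = as.integer(max_len),
                 temperature = temperature, seed = as.integer(seed)),
            class = "smirl_genconfig")
}

#' Sample a batch of SMILES strings from the policy
#'
#' Draws `n_samples` independent episodes. Strings that hit `max_len`
#' without `[EOS]` are returned as-is (truncation is a terminal state;
#' downstream validity decides their reward). Deterministic given the
#' seed.
#'
#' @param params A `smirl_params` (or a `smirl_lm` / `smirl_rl` object).
#' @param vocab The matching vocabulary (ignored when a fitted object
#'   carries one).
#' @param n_samples Number of episodes.
#' @param max_len Maximum tokens per molecule.
#' @param temperature Softmax temperature.
#' @param seed Seed; `NULL` continues the current RNG stream.
#' @param trajectories If `TRUE`, attach per-episode trajectories (0-based
#'   `actions` including the terminating `[EOS]` where drawn, matching
#'   `log_probs`, and `truncated` flag) as attribute `"trajectories"`.
#' @return Character vector of SMILES strings.
#' @export
sample_batch <- function(params, vocab = NULL, n_samples = 100L,
                         max_len = NULL, temperature = 1.0, seed = NULL,
                         trajectories = FALSE) {
  if (inherits(params, c("smirl_lm", "smirl_rl"))) {
    vocab <- params$vocab
    params <- params$params
  }
  stopifnot(inherits(params, "smirl_params"), inherits(vocab, "smirl_vocab"))
  cfg <- params_config(params)
  if (is.null(max_len)) max_len <- cfg$max_len
  max_len <- min(max_len, cfg$max_len)
  if (!is.null(seed)) set.seed(seed)
  n_samples <- as.integer(n_samples)
  if (n_samples == 0L) {
    out <- character(0)
    if (trajectories) attr(out, "trajectories") <- list()
    return(out)
  }

  forbid <- as.integer(action_forbid(vocab))
  prefixes <- rep(list(integer(0)), n_samples)
  actions <- rep(list(integer(0)), n_samples)
  logps <- rep(list(numeric(0)), n_samples)
  done <- rep(FALSE, n_samples)
  truncated <- rep(FALSE, n_samples)

  for (step in seq_len(max_len)) {
    active <- which(!done)
    if (length(active) == 0L) break
    inputs <- lapply(prefixes[active], function(ids) c(vocab$bos_id, ids))
    p <- cpp_lastpos_probs(inputs, unclass(params), cfg$n_heads, forbid)
    if (temperature != 1) {
      p <- p^(1 / temperature)
      p <- p / rowSums(p)
    }
    for (j in seq_along(active)) {
      b <- active[j]
      a <- sample.int(ncol(p), 1L, prob = p[j, ]) - 1L
      actions[[b]] <- c(actions[[b]], a)
      logps[[b]] <- c(logps[[b]], log(p[j, a + 1L]))
      if (a == vocab$eos_id) {
        done[b] <- TRUE
      } else {
        prefixes[[b]] <- c(prefixes[[b]], a)
        if (length(prefixes[[b]]) >= max_len) {
          done[b] <- TRUE
          truncated[b] <- TRUE
        }
      }
    }
  }

  out <- vapply(prefixes, decode, character(1), vocab = vocab)
  if (trajectories) {
    attr(out, "trajectories") <- lapply(seq_len(n_samples), function(b) {
      list(actions = actions[[b]], log_probs = logps[[b]],
           terminal_smiles = out[b], truncated = truncated[b])
    })
  }
  out
}

#' Sample a single molecule with its trajectory
#'
#' One episode of the generation MDP; returns the terminal SMILES string
#' together with the action/log-probability record needed by REINFORCE.
#'
#' @inheritParams sample_batch
#' @return A list with `smiles` and `trajectory`.
#' @export
sample_one <- function(params, vocab = NULL, max_len = NULL,
                       temperature = 1.0, seed = NULL) {
  out <- sample_batch(params, vocab, n_samples = 1L, max_len = max_len,
                      temperature = temperature, seed = seed,
                      trajectories = TRUE)
  list(smiles = out[1], trajectory = attr(out, "trajectories")[[1]])
}
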