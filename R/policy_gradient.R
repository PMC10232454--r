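# Stage 2: REINFORCE fine-tuning.
#
# The decoder is the policy; an episode's gradient contribution is
# sum_t G_t * grad log pi(a_t | s_t), averaged over episodes (summed over
# time). With terminal-only rewards the returns are G_t = gamma^(T-t) R_T.
# Implementation detail: the same backward pass as the language model is
# reused with per-position weights G_t / n_episodes on the negative
# log-likelihood, so gradient descent on that weighted cross-entropy is
# gradient *ascent* on the REINFORCE objective. The terminating [EOS] draw is an action whose log-probability
# enters the gradient; truncated episodes are terminal states scored like
# any other.

#' Discounted returns of a reward sequence
#'
#' `G_t = rewards[t] + gamma * G_[t+1]`, computed by backward recursion
#' (exact, no approximation). For the terminal-only rewards of molecule
#' generation this reduces to `G_t = gamma^(T-t) * R_T`.
#'
#' @param rewards Numeric vector of per-step rewards.
#' @param gamma Discount factor in (0, 1].
#' @return Numeric vector of the same length (empty in, empty out).
#' @examples
#' compute_returns(c(0, 0, 10), gamma = 0.99)  # 9.801 9.90 10.00
#' @export
compute_returns <- function(rewards, gamma = 0.99) {
  stopifnot(gamma > 0, gamma <= 1, all(is.finite(rewards)))
  n <- length(rewards)
  if (n == 0L) return(numeric(0))
  G <- numeric(n)
  G[n] <- rewards[n]
  if (n > 1L) {
    for (t in (n - 1L):1L) G[t] <- rewards[t] + gamma * G[t + 1L]
  }
  G
}

#' RL stage configuration
#'
#' Defaults mirror the reference protocol: 100 REINFORCE steps of 500
#' episodes each with discount factor 0.99. The optimiser (Adam, lr 1e-5 —
#' deliberately smaller than the LM stage to avoid policy collapse) is
#' this package's choice. A moving-average reward baseline is available
#' behind `baseline = TRUE` but is off by default: plain REINFORCE is the
#' reference algorithm.
#'
#' @param gamma Discount factor in (0, 1].
#' @param n_steps Number of policy-gradient steps.
#' @param episodes_per_step Episodes sampled per step.
#' @param lr Learning rate.
#' @param optimizer `"adam"` (default) or plain `"sgd"`.
#' @param max_len Maximum molecule length; model default when `NULL`.
#' @param baseline Subtract a moving-average reward baseline (non-default
#'   variance reduction).
#' @param seed Integer seed.
#' @return A `smirl_rlconfig` list.
#' @export
rl_config <- function(gamma = 0.99, n_steps = 100L, episodes_per_step = 500L,
                      lr = 1e-5, optimizer = c("adam", "sgd"),
                      max_len = NULL, baseline = FALSE, seed = 1L) {
  optimizer <- match.arg(optimizer)
  stopifnot(gamma > 0, gamma <= 1, n_steps >= 0L, episodes_per_step >= 1L,
            lr > 0)
  structure(list(gamma = gamma, n_steps = as.integer(n_steps),
                 episodes_per_step = as.integer(episodes_per_step),
                 lr = lr, optimizer = optimizer, max_len = max_len,
                 baseline = isTRUE(baseline), seed = as.integer(seed)),
            class = "smirl_rlconfig")
}

# Build (input, target, weight) triples for the shared backward pass.
# For an episode with actions a_1..a_n the conditioning prefixes are
# s_0..s_{n-1}, i.e. model input [BOS] + chars(a_1..a_{n-1}), targets the
# actions themselves.
episode_grad_frames <- function(traj_list, returns_list, scale) {
  inputs <- vector("list", length(traj_list))
  targets <- vector("list", length(traj_list))
  weights <- vector("list", length(traj_list))
  for (i in seq_along(traj_list)) {
    a <- traj_list[[i]]$actions
    n <- length(a)
    inputs[[i]] <- c(1L, if (n > 1L) a[seq_len(n - 1L)])  # 1L = [BOS]
    targets[[i]] <- a
    # positive G weights on the negative log-likelihood: the resulting
    # gradient is -grad(J), so the Adam *descent* step ascends J
    weights[[i]] <- returns_list[[i]] * scale
  }
  list(inputs = inputs, targets = targets, weights = weights)
}

#' One REINFORCE step
#'
#' Samples `episodes_per_step` episodes from the current policy, scores
#' the terminal strings with `reward_fn`, computes discounted returns and
#' ascends the Monte-Carlo policy-gradient estimate
#' `(1/N) sum_episodes sum_t G_t grad log pi(a_t | s_t)` with Adam.
#'
#' @param params Current policy weights (`smirl_params`).
#' @param vocab Vocabulary.
#' @param reward_fn Vectorised terminal reward, e.g. from [reward_spec()].
#' @param config An [rl_config()].
#' @param opt Optimiser state from the previous step (`NULL` to start).
#' @param baseline_value Running baseline from the previous step.
#' @return List with updated `params`, `opt`, `baseline_value` and a
#'   one-row `diagnostics` tibble (mean terminal reward, validity
#'   fraction, diversity, mean episode length).
#' @export
reinforce_step <- function(params, vocab, reward_fn, config = rl_config(),
                           opt = NULL, baseline_value = 0) {
  cfg <- params_config(params)
  N <- config$episodes_per_step
  max_len <- if (is.null(config$max_len)) cfg$max_len else config$max_len

  smiles <- sample_batch(params, vocab, n_samples = N, max_len = max_len,
                         trajectories = TRUE)
  trajs <- attr(smiles, "trajectories")
  term_reward <- reward_fn(as.character(smiles))
  if (any(!is.finite(term_reward)) || any(term_reward < 0)) {
    stop("reward function returned a negative or non-finite value")
  }

  shifted <- term_reward
  if (config$baseline) shifted <- term_reward - baseline_value
  returns <- lapply(seq_len(N), function(i) {
    n <- length(trajs[[i]]$actions)
    compute_returns(c(rep(0, n - 1L), shifted[i]), config$gamma)
  })

  frames <- episode_grad_frames(trajs, returns, scale = 1 / N)
  res <- cpp_batch_loss_grad(frames$inputs, frames$targets, frames$weights,
                             unclass(params), cfg$n_heads, 0.0,
                             as.integer(action_forbid(vocab)))
  grad <- flatten_params(res$grads)
  if (any(!is.finite(grad))) {
    stop("non-finite policy gradient; mean reward was ",
         mean(term_reward))
  }

  flat <- flatten_params(params)
  if (identical(config$optimizer, "sgd")) {
    params <- unflatten_params(flat - config$lr * grad, params)
    opt <- list(sgd = TRUE)
  } else {
    if (is.null(opt) || is.null(opt$m)) opt <- adam_state(length(flat))
    step <- adam_step(opt, grad, config$lr)
    opt <- step$state
    params <- unflatten_params(flat - step$delta, params)
  }

  props <- mol_properties(as.character(smiles))
  n_valid <- sum(props$valid)
  diag <- tibble::tibble(
    mean_reward = mean(term_reward),
    validity = n_valid / N,
    diversity = if (n_valid > 0) {
      length(unique(props$canonical[props$valid])) / n_valid
    } else NA_real_,
    mean_len = mean(nchar(as.character(smiles)))
  )
  new_baseline <- 0.9 * baseline_value + 0.1 * mean(term_reward)
  list(params = params, opt = opt, baseline_value = new_baseline,
       diagnostics = diag)
}

#' REINFORCE fine-tuning of a pretrained policy
#'
#' Runs `n_steps` policy-gradient steps (see [reinforce_step()]) starting
#' from language-model weights. The two-stage order is the supported path:
#' pass `allow_untrained = TRUE` only to reproduce the known-degenerate
#' direct-RL-from-scratch setting.
#'
#' @param model A `smirl_lm` (or list with `params` and `vocab`).
#' @param reward_fn Vectorised terminal reward, e.g. [reward_spec()].
#' @param config An [rl_config()].
#' @param allow_untrained Permit raw/untrained starting weights.
#' @param verbose Print per-step diagnostics.
#' @return A `smirl_rl` object: final `params`, `vocab`, the starting
#'   params as `params_pre`, and a per-step `log` tibble (step,
#'   mean_reward, validity, diversity, mean_len).
#' @export
rl_finetune <- function(model, reward_fn, config = rl_config(),
                        allow_untrained = FALSE, verbose = FALSE) {
  if (inherits(model, "smirl_lm")) {
    params <- model$params; vocab <- model$vocab
  } else if (is.list(model) && !is.null(model$params)) {
    if (!inherits(model, "smirl_rl") && !allow_untrained &&
        is.null(model$log)) {
      stop("starting weights do not look language-model pretrained; ",
           "pass allow_untrained = TRUE to run direct RL anyway")
    }
    params <- model$params; vocab <- model$vocab
  } else {
    stop("model must be a smirl_lm or a list with params and vocab")
  }

  set.seed(config$seed)
  opt <- NULL
  baseline_value <- 0
  logs <- vector("list", config$n_steps)
  params_pre <- params
  for (s in seq_len(config$n_steps)) {
    st <- reinforce_step(params, vocab, reward_fn, config, opt,
                         baseline_value)
    params <- st$params
    opt <- st$opt
    baseline_value <- st$baseline_value
    logs[[s]] <- st$diagnostics
    if (verbose) {
      message(sprintf(
        "step %3d  reward %.4f  validity %.2f  diversity %.2f  len %.1f",
        s, st$diagnostics$mean_reward, st$diagnostics$validity,
        st$diagnostics$diversity, st$diagnostics$mean_len))
    }
  }
  log <- if (config$n_steps > 0) {
    dplyr::bind_rows(logs)
  } else {
    tibble::tibble(mean_reward = numeric(0), validity = numeric(0),
                   diversity = numeric(0), mean_len = numeric(0))
  }
  log <- tibble::add_column(log, step = seq_len(nrow(log)), .before = 1)

  structure(
    list(params = params, vocab = vocab, params_pre = params_pre,
         config = config, log = log),
    class = "smirl_rl"
  )
}

#' @export
print.smirl_rl <- function(x, ...) {
  if (nrow(x$log) > 0) {
    cat(sprintf(
      "<smirl_rl> %d steps x %d episodes; mean reward %.4f -> %.4f\n",
      nrow(x$log), x$config$episodes_per_step,
      x$log$mean_reward[1], tail(x$log$mean_reward, 1)))
  } else {
    cat("<smirl_rl> 0 steps (policy unchanged)\n")
  }
  invisible(x)
}
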