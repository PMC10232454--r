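# REINFORCE: return arithmetic, gradient correctness against enumeration
# and finite differences, estimator unbiasedness, and policy improvement.

test_that("returns follow the discounted backward recursion exactly", {
  expect_equal(compute_returns(c(0, 0, 10), gamma = 0.99),
               c(9.801, 9.9, 10), tolerance = 1e-12)
  expect_identical(compute_returns(c(0, 0, 7), gamma = 1), c(7, 7, 7))
  expect_identical(compute_returns(numeric(0)), numeric(0))

  # brute-force double-sum oracle on random reward vectors
  set.seed(41)
  for (rep in 1:200) {
    n <- sample(1:8, 1)
    r <- rnorm(n)
    g <- runif(1, 0.05, 1)
    want <- vapply(seq_len(n), function(t) {
      sum(g^(seq(t, n) - t) * r[seq(t, n)])
    }, numeric(1))
    expect_equal(compute_returns(r, g), want, tolerance = 1e-10)
  }
})

test_that("expected REINFORCE gradient equals enumeration and finite differences", {
  v <- toy_vocab("A")
  cfg <- tiny_config(length(v$tokens), n_layers = 1L, n_heads = 2L,
                     d_model = 8L, d_ff = 8L, max_len = 4L)
  params <- random_params(cfg, seed = 17)
  max_len <- 2L
  reward <- function(s) as.numeric(s == "A")
  gamma <- 1  # the undiscounted objective; equality is exact here

  trajs <- enumerate_toy_mdp(params, v, max_len)
  expect_length(trajs, 3L)  # [EOS], [A,EOS], [A,A] (truncated)
  p_traj <- vapply(trajs, function(t) exp(t$logp), numeric(1))
  expect_equal(sum(p_traj), 1, tolerance = 1e-9)
  R <- vapply(trajs, function(t) reward(toy_terminal_string(t$actions, v)),
              numeric(1))

  # route 1: E[ sum_t G_t grad log pi ], expectation taken exactly over the
  # enumerated trajectories, one backward call per trajectory
  grad1 <- Reduce(`+`, lapply(seq_along(trajs), function(i) {
    n <- length(trajs[[i]]$actions)
    G <- compute_returns(c(rep(0, n - 1L), R[i]), gamma)
    -grad_of_trajs(trajs[i], list(G), params, v) * p_traj[i]
  }))

  # route 2: grad of sum_s p(s) R(s) via the likelihood-ratio identity,
  # aggregated in a single weighted batch
  grad2 <- -grad_of_trajs(
    trajs, lapply(seq_along(trajs), function(i) {
      rep(p_traj[i] * R[i], length(trajs[[i]]$actions))
    }), params, v)
  expect_lt(max(abs(grad1 - grad2)), 1e-8)

  # route 3: central finite differences of J(theta) = sum_s p_theta(s) R(s),
  # J evaluated from forward passes only
  fl <- smirl:::flatten_params(params)
  J_at <- function(flat) {
    pp <- smirl:::unflatten_params(flat, params)
    tj <- enumerate_toy_mdp(pp, v, max_len)
    sum(vapply(tj, function(t) {
      exp(t$logp) * reward(toy_terminal_string(t$actions, v))
    }, numeric(1)))
  }
  set.seed(18)
  idx <- sample(length(fl), 40)
  h <- 1e-5
  fd <- vapply(idx, function(i) {
    e1 <- fl; e1[i] <- e1[i] + h
    e2 <- fl; e2[i] <- e2[i] - h
    (J_at(e1) - J_at(e2)) / (2 * h)
  }, numeric(1))
  expect_equal(grad1[idx], fd, tolerance = 1e-4)
})

test_that("the sampled-gradient estimator is unbiased on the toy MDP", {
  v <- toy_vocab("A")
  cfg <- tiny_config(length(v$tokens), n_layers = 1L, n_heads = 2L,
                     d_model = 8L, d_ff = 8L, max_len = 4L)
  params <- random_params(cfg, seed = 23)
  max_len <- 2L
  reward <- function(s) as.numeric(s == "A")

  trajs <- enumerate_toy_mdp(params, v, max_len)
  p_traj <- vapply(trajs, function(t) exp(t$logp), numeric(1))
  R <- vapply(trajs, function(t) reward(toy_terminal_string(t$actions, v)),
              numeric(1))
  exact <- Reduce(`+`, lapply(seq_along(trajs), function(i) {
    n <- length(trajs[[i]]$actions)
    G <- compute_returns(c(rep(0, n - 1L), R[i]), 1)
    -grad_of_trajs(trajs[i], list(G), params, v) * p_traj[i]
  }))

  # 20 batches of 500 sampled episodes; batch means estimate the gradient
  set.seed(71)
  n_batches <- 20L
  per_batch <- 500L
  sel <- order(abs(exact), decreasing = TRUE)[1:5]
  batch_means <- matrix(0, n_batches, length(sel))
  for (b in seq_len(n_batches)) {
    s <- sample_batch(params, v, n_samples = per_batch, max_len = max_len,
                      trajectories = TRUE)
    trl <- attr(s, "trajectories")
    Gs <- lapply(trl, function(tr) {
      n <- length(tr$actions)
      compute_returns(c(rep(0, n - 1L), reward(tr$terminal_smiles)), 1)
    })
    g <- -grad_of_trajs(lapply(trl, function(t) list(actions = t$actions)),
                        lapply(Gs, function(G) G / per_batch), params, v)
    batch_means[b, ] <- g[sel]
  }
  est <- colMeans(batch_means)
  se <- apply(batch_means, 2, sd) / sqrt(n_batches)
  expect_true(all(abs(est - exact[sel]) <= 3 * se + 1e-12))
})

test_that("uniformly zero rewards leave the parameters exactly unchanged", {
  v <- toy_vocab(c("C", "O"))
  params <- random_params(tiny_config(length(v$tokens), max_len = 5L),
                          seed = 31)
  set.seed(5)
  st <- reinforce_step(params, v, function(s) rep(0, length(s)),
                       rl_config(n_steps = 1L, episodes_per_step = 20L,
                                 max_len = 4L))
  expect_identical(st$params, params)
  expect_identical(st$diagnostics$mean_reward, 0)
})

test_that("rewarding a first token makes it strictly more probable", {
  v <- toy_vocab(c("C", "N"))
  c_id <- match("C", v$tokens) - 1L
  params <- random_params(tiny_config(length(v$tokens), n_layers = 1L,
                                      d_model = 8L, d_ff = 8L,
                                      max_len = 4L), seed = 37)
  reward <- function(s) as.numeric(substr(s, 1, 1) == "C")
  cfg <- rl_config(gamma = 1, n_steps = 20L, episodes_per_step = 64L,
                   lr = 5e-3, max_len = 3L, seed = 99)
  p_before <- next_token_probs(params, v)[c_id + 1L]
  set.seed(cfg$seed)
  opt <- NULL
  for (i in seq_len(cfg$n_steps)) {
    st <- reinforce_step(params, v, reward, cfg, opt)
    params <- st$params; opt <- st$opt
  }
  p_after <- next_token_probs(params, v)[c_id + 1L]
  expect_gt(p_after, p_before)
  expect_gt(p_after, 0.5)
})

test_that("rl_finetune logs one row per step and n_steps = 0 is a no-op", {
  corpus <- c("CCO", "CNC", "OCC", "CC")
  lm <- train_lm(corpus, tiny_config(7L, max_len = 6L), epochs = 1, seed = 3)
  rl0 <- rl_finetune(lm, reward_spec("qed"), rl_config(n_steps = 0L))
  expect_identical(rl0$params, lm$params)
  expect_identical(nrow(rl0$log), 0L)

  len_reward <- function(s) pmin(nchar(s), 4)
  rl <- rl_finetune(lm, len_reward,
                    rl_config(n_steps = 3L, episodes_per_step = 16L,
                              max_len = 5L, seed = 12))
  expect_identical(nrow(rl$log), 3L)
  expect_identical(tidy(rl), rl$log)
  expect_true(all(is.finite(rl$log$mean_reward)))
  # rerun reproduces the log exactly
  rl2 <- rl_finetune(lm, len_reward,
                     rl_config(n_steps = 3L, episodes_per_step = 16L,
                               max_len = 5L, seed = 12))
  expect_identical(rl$log, rl2$log)
  expect_identical(rl$params, rl2$params)
})

test_that("direct RL from scratch requires the explicit override", {
  v <- toy_vocab("C")
  params <- random_params(tiny_config(length(v$tokens), max_len = 4L),
                          seed = 2)
  raw <- list(params = params, vocab = v)
  expect_error(rl_finetune(raw, reward_spec("qed"), rl_config(n_steps = 0L)),
               "allow_untrained")
  ok <- rl_finetune(raw, reward_spec("qed"), rl_config(n_steps = 0L),
                    allow_untrained = TRUE)
  expect_identical(ok$params, params)
})
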