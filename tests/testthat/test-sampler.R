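# Episode dynamics: scripted policies, termination, truncation,
# determinism, and sampling-distribution consistency.

test_that("a policy committed to [EOS] at step 0 yields the empty string", {
  v <- toy_vocab("C")
  p <- scripted_policy(v, actions = v$eos_id)
  out <- sample_one(p, v, seed = 1)
  expect_identical(out$smiles, "")
  expect_length(out$trajectory$actions, 1L)
  expect_identical(out$trajectory$actions[1], v$eos_id)
  expect_false(out$trajectory$truncated)
  # log-probability of the forced action is ~0 (probability ~1)
  expect_gt(out$trajectory$log_probs[1], -1e-6)
})

test_that("a scripted token sequence is reproduced verbatim", {
  v <- toy_vocab(c("C", "O"))
  c_id <- match("C", v$tokens) - 1L
  o_id <- match("O", v$tokens) - 1L
  p <- scripted_policy(v, actions = c(c_id, v$eos_id))
  expect_identical(sample_one(p, v, seed = 3)$smiles, "C")

  p2 <- scripted_policy(v, actions = c(c_id, o_id, c_id, v$eos_id))
  expect_identical(sample_one(p2, v, seed = 3)$smiles, "COC")
})

test_that("episodes truncate at max_len and are flagged terminal", {
  v <- toy_vocab("C")
  c_id <- match("C", v$tokens) - 1L
  p <- scripted_policy(v, actions = rep(c_id, 6L))
  out <- sample_batch(p, v, n_samples = 3, max_len = 4, seed = 5,
                      trajectories = TRUE)
  expect_identical(as.character(out), rep("CCCC", 3))
  trj <- attr(out, "trajectories")
  expect_true(all(vapply(trj, `[[`, logical(1), "truncated")))
  expect_identical(lengths(lapply(trj, `[[`, "actions")), rep(4L, 3))
})

test_that("sampling is deterministic given a seed and n_samples = 0 works", {
  corpus <- c("CCO", "CNC", "OCC", "CCCC")
  lm <- train_lm(corpus, tiny_config(7L, max_len = 8L), epochs = 1, seed = 2)
  s1 <- sample_batch(lm, n_samples = 25, seed = 11)
  s2 <- sample_batch(lm, n_samples = 25, seed = 11)
  expect_identical(s1, s2)
  expect_identical(sample_batch(lm, n_samples = 0, seed = 1), character(0))
  expect_true(all(nchar(s1) <= lm$config$max_len))
})

test_that("no emitted string carries special-token surface forms", {
  v <- toy_vocab(c("C", "N", "O", "(", ")", "1"))
  p <- random_params(tiny_config(length(v$tokens), max_len = 10L), seed = 6)
  s <- sample_batch(p, v, n_samples = 60, seed = 7)
  expect_false(any(grepl("[PAD]", s, fixed = TRUE)))
  expect_false(any(grepl("[BOS]", s, fixed = TRUE)))
  expect_false(any(grepl("[EOS]", s, fixed = TRUE)))
})

test_that("trajectory log-probabilities agree with the policy distribution", {
  v <- toy_vocab(c("C", "O"))
  p <- random_params(tiny_config(length(v$tokens), max_len = 6L), seed = 9)
  out <- sample_one(p, v, seed = 13)
  tr <- out$trajectory
  state <- integer(0)
  for (k in seq_along(tr$actions)) {
    pr <- next_token_probs(p, v, state)
    expect_equal(tr$log_probs[k], log(unname(pr[tr$actions[k] + 1L])),
                 tolerance = 1e-12)
    if (tr$actions[k] != v$eos_id) state <- c(state, tr$actions[k])
  }
  # [PAD]/[BOS] are excluded from the action space
  pr0 <- next_token_probs(p, v)
  expect_identical(unname(pr0[c(v$pad_id, v$bos_id) + 1L]), c(0, 0))
  expect_equal(sum(pr0), 1, tolerance = 1e-9)
})

test_that("first-token frequencies match the policy's first-step distribution", {
  v <- toy_vocab(c("C", "N", "O"))
  p <- random_params(tiny_config(length(v$tokens), max_len = 4L), seed = 30)
  n <- 10000L
  s <- sample_batch(p, v, n_samples = n, max_len = 1, seed = 31,
                    trajectories = TRUE)
  first <- vapply(attr(s, "trajectories"), function(t) t$actions[1],
                  integer(1))
  pr <- next_token_probs(p, v)
  keep <- which(pr > 0)
  obs <- tabulate(match(first + 1L, keep), nbins = length(keep))
  chi <- suppressWarnings(chisq.test(obs, p = pr[keep] / sum(pr[keep])))
  expect_gt(chi$p.value, 0.01)
})
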