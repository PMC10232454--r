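# Decoder architecture contracts: agreement with a naive reference
# implementation, causality, normalization, residual behaviour, exact
# gradients, serialization, and language-model training.

test_that("forward pass matches the naive loop reference implementation", {
  cfg <- tiny_config(vocab_size = 9L, n_layers = 2L, n_heads = 4L,
                     d_model = 16L, d_ff = 20L)
  p <- random_params(cfg, seed = 11)
  ids <- c(1L, 4L, 7L, 3L, 8L)
  got <- decoder_forward(ids, p)
  want <- ref_forward(ids, p, cfg)
  expect_equal(got, want, tolerance = 1e-10, ignore_attr = TRUE)

  # single-head model agrees too (multi-head reduces to plain attention)
  cfg1 <- tiny_config(vocab_size = 9L, n_layers = 1L, n_heads = 1L)
  p1 <- random_params(cfg1, seed = 12)
  expect_equal(decoder_forward(ids, p1), ref_forward(ids, p1, cfg1),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("every output row is a distribution and causality holds", {
  cfg <- tiny_config(vocab_size = 8L)
  p <- random_params(cfg, seed = 2)
  ids <- c(1L, 3L, 5L, 4L, 6L, 7L)
  pr <- decoder_forward(ids, p)
  expect_equal(rowSums(pr), rep(1, length(ids)), tolerance = 1e-6)
  expect_true(all(pr >= 0))

  # perturb the future: rows <= t must not move at all
  for (t in 1:(length(ids) - 1L)) {
    ids2 <- ids
    ids2[(t + 1L):length(ids)] <- rev(ids2[(t + 1L):length(ids)])
    ids2[t + 1L] <- (ids2[t + 1L] %% 5L) + 3L
    pr2 <- decoder_forward(ids2, p)
    expect_identical(pr[seq_len(t), , drop = FALSE],
                     pr2[seq_len(t), , drop = FALSE])
  }
})

test_that("zeroed sublayers reduce the network to embeddings + head", {
  cfg <- tiny_config(vocab_size = 6L, n_layers = 3L)
  p <- init_params(cfg, seed = 1)
  fl <- smirl:::flatten_params(p)
  p0 <- smirl:::unflatten_params(0 * fl, p)
  p0$tok_emb <- p$tok_emb
  p0$pos_emb <- p$pos_emb
  p0$lnf_g <- rep(1, cfg$d_model)
  p0$head_W <- p$head_W

  ids <- c(1L, 3L, 4L)
  got <- decoder_forward(ids, p0, probs = FALSE)
  # residual-only blocks are the identity, so logits = LN(emb) %*% W
  emb <- p$tok_emb[ids + 1L, ] + p$pos_emb[seq_along(ids), ]
  want <- ref_layernorm(emb, p0$lnf_g, p0$lnf_b) %*% p$head_W
  expect_equal(got, want, tolerance = 1e-10, ignore_attr = TRUE)

  # zeroed head emits the uniform distribution
  pu <- smirl:::unflatten_params(0 * fl, p)
  pu$tok_emb <- p$tok_emb; pu$lnf_g <- rep(1, cfg$d_model)
  pr <- decoder_forward(ids, pu)
  expect_equal(pr, matrix(1 / cfg$vocab_size, length(ids), cfg$vocab_size),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("analytic gradients match central finite differences", {
  cfg <- tiny_config(vocab_size = 7L, n_layers = 2L, n_heads = 2L,
                     d_model = 8L, d_ff = 12L)
  p <- random_params(cfg, seed = 3)
  fl <- smirl:::flatten_params(p)
  inputs <- list(c(1L, 3L, 4L, 5L), c(1L, 6L, 3L))
  targets <- list(c(3L, 4L, 5L, 2L), c(6L, 3L, 2L))
  weights <- list(c(0.3, 0.2, -0.4, 0.25), c(1, -0.5, 0.7))
  loss_at <- function(flat) {
    pp <- smirl:::unflatten_params(flat, p)
    smirl:::cpp_batch_loss_grad(inputs, targets, weights, unclass(pp),
                                cfg$n_heads, 0)$loss
  }
  g <- smirl:::flatten_params(
    smirl:::cpp_batch_loss_grad(inputs, targets, weights, unclass(p),
                                cfg$n_heads, 0)$grads)
  set.seed(99)
  idx <- sample(length(fl), 50)
  h <- 1e-5
  num <- vapply(idx, function(i) {
    e1 <- fl; e1[i] <- e1[i] + h
    e2 <- fl; e2[i] <- e2[i] - h
    (loss_at(e1) - loss_at(e2)) / (2 * h)
  }, numeric(1))
  expect_equal(g[idx], num, tolerance = 1e-6)
})

test_that("checkpoints reload bit-for-bit", {
  cfg <- tiny_config(vocab_size = 6L)
  p <- random_params(cfg, seed = 8)
  v <- toy_vocab(c("C", "N", "O"))
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(p, v, f, extra = list(note = "test"))
  ck <- load_checkpoint(f)
  expect_identical(ck$params, p)
  ids <- c(1L, 3L, 4L)
  expect_identical(decoder_forward(ids, ck$params), decoder_forward(ids, p))
  f2 <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(a = 1), f2)
  expect_error(load_checkpoint(f2), "checkpoint")
})

test_that("language-model training learns, and a zero head scores ln(V)", {
  corpus <- rep("CCOCN", 64)
  vocab <- build_char_vocab(corpus)
  cfg <- tiny_config(vocab_size = length(vocab), d_model = 32L, d_ff = 48L,
                     max_len = 10L)

  # untrained model with zeroed output head: exactly the uniform loss
  p0 <- init_params(cfg, seed = 1)
  p0$head_W[] <- 0; p0$head_b[] <- 0
  fl <- smirl:::flatten_params(p0)
  p0 <- smirl:::unflatten_params(fl, p0)
  for (l in seq_along(p0$layers)) {  # silence the body so logits are exactly 0
    p0$layers[[l]]$Wo[] <- 0; p0$layers[[l]]$W2[] <- 0
  }
  expect_equal(lm_cross_entropy(p0, corpus, vocab), log(length(vocab)),
               tolerance = 1e-12)

  lm <- train_lm(corpus, cfg, epochs = 30, seed = 4, lr = 3e-3)
  expect_s3_class(tidy(lm), "tbl_df")
  expect_identical(nrow(tidy(lm)), 30L)
  # monotone decrease while overfitting a single repeated string
  expect_true(all(diff(lm$log$loss) < 0))
  # approaching perplexity 1
  expect_lt(tail(lm$log$loss, 1), 0.35)
  expect_lt(tail(lm$log$loss, 1), log(length(vocab)))
})

test_that("training is deterministic under a fixed seed", {
  corpus <- c("CCO", "CNC", "OCCO", "CCC")
  cfg <- tiny_config(vocab_size = 7L, max_len = 8L, dropout = 0.1)
  lm1 <- train_lm(corpus, cfg, epochs = 2, seed = 21)
  lm2 <- train_lm(corpus, cfg, epochs = 2, seed = 21)
  expect_identical(lm1$log, lm2$log)
  expect_identical(lm1$params, lm2$params)
})

test_that("overlength inputs are rejected", {
  cfg <- tiny_config(vocab_size = 6L, max_len = 4L)
  p <- init_params(cfg, seed = 1)
  expect_error(decoder_forward(rep(3L, 7L), p), "exceeds")
  expect_warning(train_lm(c("CCO", "CCCCCCCC"), cfg, epochs = 1, seed = 1),
                 "dropping")
})
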