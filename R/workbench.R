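# Orchestration: a RunConfig bundles every stage's settings, a run
# directory captures everything needed to reproduce a run (resolved
# config, vocabulary, checkpoints, logs, samples, reports), and one
# global seed fans out to per-stage derived seeds so a single knob
# controls reproducibility.

derive_seed <- function(seed, stage) {
  offsets <- c(lm = 101L, rl = 211L, generate = 307L, fixtures = 401L)
  (as.integer(seed) * 1000L + offsets[[stage]]) %% .Machine$integer.max
}

#' Pipeline run configuration
#'
#' Everything a two-stage run needs, serialisable to YAML/JSON. A run is
#' reproducible from its persisted configuration alone.
#'
#' @param corpus Character vector of SMILES or path to a `.smi` file.
#' @param out_dir Run directory for checkpoints, logs and reports.
#' @param decoder A [decoder_config()] (vocab size filled in later).
#' @param rl An [rl_config()].
#' @param generation A [generation_config()].
#' @param reward_kind One of `"qed"`, `"pic50"`, `"predictor"`.
#' @param scorer Optional scorer function for the non-QED rewards.
#' @param tokenizer `"char"` or `"bpe"`.
#' @param bpe_size BPE target vocabulary size (non-special tokens).
#' @param epochs LM training epochs.
#' @param seed Global seed; per-stage seeds are derived from it.
#' @return A `smirl_runconfig` list.
#' @export
run_config <- function(corpus, out_dir = tempfile("smirl-run-"),
                       decoder = NULL, rl = rl_config(),
                       generation = generation_config(),
                       reward_kind = "qed", scorer = NULL,
                       tokenizer = c("char", "bpe"), bpe_size = 500L,
                       epochs = 3L, seed = 1L) {
  tokenizer <- match.arg(tokenizer)
  structure(list(corpus = corpus, out_dir = out_dir, decoder = decoder,
                 rl = rl, generation = generation,
                 reward_kind = reward_kind, scorer = scorer,
                 tokenizer = tokenizer, bpe_size = as.integer(bpe_size),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "smirl_runconfig")
}

config_for_yaml <- function(cfg) {
  keep <- cfg[setdiff(names(cfg), c("scorer"))]
  keep$corpus <- if (is.character(keep$corpus) && length(keep$corpus) == 1L) {
    keep$corpus
  } else {
    sprintf("<in-memory corpus of %d molecules>", length(keep$corpus))
  }
  lapply(keep, function(x) if (is.list(x)) unclass(x) else x)
}

#' Run the two-stage pipeline
#'
#' Stage 1 trains the language model; stage 2 fine-tunes it with
#' REINFORCE; finally `generation$n_samples` molecules are drawn from the
#' post-RL policy and evaluated against the training corpus. All
#' artifacts land in `out_dir`: `config.yaml`, `vocab.json`,
#' `lm_checkpoint.rds`, `rl_checkpoint.rds`, `lm_loss.csv`, `rl_log.csv`,
#' `samples.smi`, `metrics.json`, `metrics.csv`.
#'
#' @param cfg A [run_config()].
#' @param verbose Print stage progress.
#' @return A list with `lm`, `rl`, `samples`, `report` and `out_dir`.
#' @export
run_pipeline <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "smirl_runconfig"))
  corpus <- cfg$corpus
  if (length(corpus) == 1L && file.exists(corpus)) corpus <- read_smi(corpus)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(config_for_yaml(cfg), file.path(cfg$out_dir, "config.yaml"))

  vocab <- if (cfg$tokenizer == "bpe") {
    build_bpe_vocab(corpus, cfg$bpe_size)
  } else {
    build_char_vocab(corpus)
  }
  write_vocab(vocab, file.path(cfg$out_dir, "vocab.json"))

  if (verbose) message("stage 1: language model (", cfg$epochs, " epochs)")
  lm <- train_lm(corpus, config = cfg$decoder, epochs = cfg$epochs,
                 seed = derive_seed(cfg$seed, "lm"), vocab = vocab,
                 verbose = verbose)
  save_checkpoint(lm$params, vocab, file.path(cfg$out_dir, "lm_checkpoint.rds"),
                  extra = list(log = lm$log))
  utils::write.csv(lm$log, file.path(cfg$out_dir, "lm_loss.csv"),
                   row.names = FALSE)

  reward_fn <- reward_spec(cfg$reward_kind, cfg$scorer)
  rlc <- cfg$rl
  rlc$seed <- derive_seed(cfg$seed, "rl")
  if (verbose) {
    message("stage 2: REINFORCE (", rlc$n_steps, " steps x ",
            rlc$episodes_per_step, " episodes, ", cfg$reward_kind,
            " reward)")
  }
  rl <- rl_finetune(lm, reward_fn, rlc, verbose = verbose)
  save_checkpoint(rl$params, vocab, file.path(cfg$out_dir, "rl_checkpoint.rds"),
                  extra = list(log = rl$log))
  utils::write.csv(rl$log, file.path(cfg$out_dir, "rl_log.csv"),
                   row.names = FALSE)

  gen <- cfg$generation
  samples <- sample_batch(rl$params, vocab, n_samples = gen$n_samples,
                          max_len = gen$max_len,
                          temperature = gen$temperature,
                          seed = derive_seed(cfg$seed, "generate"))
  write_smi(samples, file.path(cfg$out_dir, "samples.smi"))

  report <- evaluate(samples, corpus, n_expected = gen$n_samples)
  write_metrics_report(report, json = file.path(cfg$out_dir, "metrics.json"),
                       csv = file.path(cfg$out_dir, "metrics.csv"))

  list(lm = lm, rl = rl, samples = samples, report = report,
       out_dir = cfg$out_dir)
}

#' Paired pre/post-RL evaluation
#'
#' Samples the same number of molecules from the policy before and after
#' the RL stage and evaluates both — the with/without-RL comparison
#' protocol.
#'
#' @param rl A `smirl_rl` object (carries pre- and post-RL weights).
#' @param training Training corpus for novelty.
#' @param n_samples Molecules per arm.
#' @param seed Seed (each arm draws with its own derived stream).
#' @return A tibble with one row per arm (`stage` = "pre_rl"/"post_rl")
#'   holding the report columns.
#' @export
ablation_table <- function(rl, training, n_samples = 1000L, seed = 1L) {
  stopifnot(inherits(rl, "smirl_rl"))
  pre <- sample_batch(rl$params_pre, rl$vocab, n_samples = n_samples,
                      seed = seed)
  post <- sample_batch(rl$params, rl$vocab, n_samples = n_samples,
                       seed = seed + 1L)
  rows <- lapply(list(pre_rl = pre, post_rl = post), function(s) {
    r <- evaluate(s, training, n_expected = n_samples)
    tibble::as_tibble(unclass(r)[c("validity_pct", "diversity_pct",
                                   "novelty_pct", "qed_mean", "qed_sd",
                                   "sas_mean", "sas_sd", "n_valid")])
  })
  dplyr::bind_rows(rows, .id = "stage")
}
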