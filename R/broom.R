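# Tidiers: tabular views of fitted objects in the broom convention.

#' Tidy the training log of a language model
#'
#' @param x A `smirl_lm`.
#' @param ... Unused.
#' @return Tibble with `epoch` and `loss` (mean next-token cross-entropy,
#'   nats/token).
#' @method tidy smirl_lm
#' @export
tidy.smirl_lm <- function(x, ...) x$log

#' @rdname tidy.smirl_lm
#' @method glance smirl_lm
#' @export
glance.smirl_lm <- function(x, ...) {
  tibble::tibble(
    epochs = nrow(x$log), final_loss = tail(x$log$loss, 1),
    n_layers = x$config$n_layers, d_model = x$config$d_model,
    vocab_size = x$config$vocab_size
  )
}

#' Tidy the step log of an RL fine-tuning run
#'
#' @param x A `smirl_rl`.
#' @param ... Unused.
#' @return Tibble with `step`, `mean_reward`, `validity`, `diversity`,
#'   `mean_len`.
#' @method tidy smirl_rl
#' @export
tidy.smirl_rl <- function(x, ...) x$log

#' @rdname tidy.smirl_rl
#' @method glance smirl_rl
#' @export
glance.smirl_rl <- function(x, ...) {
  n <- nrow(x$log)
  tibble::tibble(
    n_steps = n,
    episodes_per_step = x$config$episodes_per_step,
    gamma = x$config$gamma,
    first_reward = if (n > 0) x$log$mean_reward[1] else NA_real_,
    final_reward = if (n > 0) x$log$mean_reward[n] else NA_real_,
    final_validity = if (n > 0) x$log$validity[n] else NA_real_
  )
}

#' Tidy an evaluation report
#'
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @return One-row tibble with every report field.
#' @method tidy metrics_report
#' @export
tidy.metrics_report <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("validity_pct", "novelty_pct",
                                 "diversity_pct", "qed_mean", "qed_sd",
                                 "sas_mean", "sas_sd", "n_generated",
                                 "n_valid", "n_expected")])
}
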