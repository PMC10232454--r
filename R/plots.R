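# ggplot2 views of training progress and evaluation results.

#' @importFrom rlang .data
NULL

#' Plot the language-model loss curve
#'
#' @param object A `smirl_lm`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot smirl_lm
#' @export
autoplot.smirl_lm <- function(object, ...) {
  ggplot2::ggplot(object$log, ggplot2::aes(.data$epoch, .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "epoch", y = "cross-entropy (nats/token)",
                  title = "Language-model training loss") +
    ggplot2::theme_minimal()
}

#' Plot RL fine-tuning diagnostics
#'
#' Mean terminal reward, validity and diversity per REINFORCE step.
#'
#' @param object A `smirl_rl`.
#' @param ... Unused.
#' @return A ggplot (facetted by diagnostic).
#' @method autoplot smirl_rl
#' @export
autoplot.smirl_rl <- function(object, ...) {
  long <- tidyr_pivot(object$log)
  ggplot2::ggplot(long, ggplot2::aes(.data$step, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "REINFORCE step", y = NULL,
                  title = "Policy-gradient fine-tuning") +
    ggplot2::theme_minimal()
}

# minimal long-format reshape (avoids importing tidyr for one call)
tidyr_pivot <- function(log) {
  metrics <- c("mean_reward", "validity", "diversity")
  dplyr::bind_rows(lapply(metrics, function(m) {
    tibble::tibble(step = log$step, metric = m, value = log[[m]])
  }))
}

#' Compare QED distributions before and after RL
#'
#' @param pre,post Character vectors of SMILES sampled from the pre- and
#'   post-RL policies.
#' @return A ggplot of the two QED densities (valid molecules only).
#' @export
plot_qed_shift <- function(pre, post) {
  d <- dplyr::bind_rows(
    tibble::tibble(stage = "pre-RL", qed = mol_properties(pre)$qed),
    tibble::tibble(stage = "post-RL", qed = mol_properties(post)$qed)
  )
  d <- d[is.finite(d$qed), ]
  ggplot2::ggplot(d, ggplot2::aes(.data$qed, fill = .data$stage)) +
    ggplot2::geom_density(alpha = 0.4) +
    ggplot2::labs(x = "QED", y = "density",
                  title = "Drug-likeness shift from RL fine-tuning") +
    ggplot2::theme_minimal()
}
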