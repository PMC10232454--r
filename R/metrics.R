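# Evaluation suite for generated molecule sets: validity, novelty,
# diversity, and QED/SAS statistics. Identity comparisons (novelty,
# diversity) use canonical SMILES, so trivially rewritten duplicates
# ("OCC" vs "CCO") count as the same molecule. Novelty and diversity are
# computed over valid molecules only — the invalid-exclusion rule stated
# for QED/SAS is applied uniformly, and the report records that choice.

round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Validity of a generated set
#'
#' Percentage of strings RDKit parses into molecules. An empty input is
#' reported as 0 with a warning.
#'
#' @param generated Character vector of SMILES strings.
#' @return Percentage in \[0, 100\], rounded half-up to 2 decimals.
#' @examples \dontrun{validity(c("CCO", "C1CC1", "C("))  # 66.67}
#' @export
validity <- function(generated) {
  if (length(generated) == 0L) {
    warning("empty generated set; validity reported as 0")
    return(0)
  }
  round_half_up(100 * mean(is_valid(generated)))
}

#' Novelty of a generated set against a training corpus
#'
#' Percentage of valid generated molecules whose canonical form does not
#' occur in the (canonicalised) training corpus.
#'
#' @param generated Character vector of generated SMILES.
#' @param training Character vector of training SMILES.
#' @return Percentage in \[0, 100\], rounded half-up to 2 decimals.
#' @export
novelty <- function(generated, training) {
  can_gen <- canonical_smiles(generated)
  can_gen <- can_gen[!is.na(can_gen)]
  if (length(can_gen) == 0L) {
    warning("no valid generated molecules; novelty reported as 0")
    return(0)
  }
  can_train <- canonical_smiles(training)
  can_train <- can_train[!is.na(can_train)]
  round_half_up(100 * mean(!(can_gen %in% can_train)))
}

#' Diversity (uniqueness) of a generated set
#'
#' Percentage of distinct canonical molecules among the valid generated
#' ones.
#'
#' @param generated Character vector of generated SMILES.
#' @return Percentage in \[0, 100\], rounded half-up to 2 decimals.
#' @examples \dontrun{diversity(c("CCO", "CCO", "CCN"))  # 66.67}
#' @export
diversity <- function(generated) {
  can <- canonical_smiles(generated)
  can <- can[!is.na(can)]
  if (length(can) == 0L) {
    warning("no valid generated molecules; diversity reported as 0")
    return(0)
  }
  round_half_up(100 * length(unique(can)) / length(can))
}

sd0 <- function(x) if (length(x) < 2L) 0 else sd(x)

#' QED and SAS statistics of a generated set
#'
#' Mean and standard deviation of QED (drug-likeness, \[0, 1\]) and SAS
#' (synthetic accessibility, \[1, 10\], lower = easier) over the *valid*
#' molecules, duplicates included. Errors when no molecule is valid.
#'
#' @param generated Character vector of SMILES.
#' @return A one-row tibble: `qed_mean`, `qed_sd`, `sas_mean`, `sas_sd`,
#'   `n_valid`.
#' @export
property_stats <- function(generated) {
  props <- mol_properties(generated)
  props <- props[props$valid & is.finite(props$qed) & is.finite(props$sas), ]
  if (nrow(props) == 0L) stop("no valid molecules to score")
  tibble::tibble(
    qed_mean = mean(props$qed), qed_sd = sd0(props$qed),
    sas_mean = mean(props$sas), sas_sd = sd0(props$sas),
    n_valid = nrow(props)
  )
}

#' Novelty of one generated set against several corpora
#'
#' [novelty()] of the same generated set against each named corpus — the
#' cross-dataset novelty panel.
#'
#' @param generated Character vector of generated SMILES.
#' @param corpora Named list of character vectors.
#' @return A tibble with columns `corpus` and `novelty_pct`.
#' @export
cross_dataset_novelty <- function(generated, corpora) {
  stopifnot(is.list(corpora), !is.null(names(corpora)),
            all(nzchar(names(corpora))))
  tibble::tibble(
    corpus = names(corpora),
    novelty_pct = vapply(corpora, function(tr) novelty(generated, tr),
                         numeric(1), USE.NAMES = FALSE)
  )
}

#' Full evaluation report for a generated set
#'
#' Assembles validity, novelty, diversity and QED/SAS statistics into a
#' `metrics_report`. The reference protocol draws 25,000 molecules for
#' this report; `n_expected` records the intended size next to the actual
#' one.
#'
#' @param generated Character vector of generated SMILES.
#' @param training Character vector of training SMILES (novelty
#'   reference).
#' @param n_expected Intended sample size of the evaluation protocol.
#' @return A `metrics_report` object.
#' @export
evaluate <- function(generated, training, n_expected = 25000L) {
  props <- mol_properties(generated)
  n_valid <- sum(props$valid)
  ps <- if (n_valid > 0) property_stats(generated) else NULL
  rep <- list(
    validity_pct = validity(generated),
    novelty_pct = if (n_valid > 0) novelty(generated, training) else 0,
    diversity_pct = if (n_valid > 0) diversity(generated) else 0,
    qed_mean = if (is.null(ps)) NA_real_ else ps$qed_mean,
    qed_sd = if (is.null(ps)) NA_real_ else ps$qed_sd,
    sas_mean = if (is.null(ps)) NA_real_ else ps$sas_mean,
    sas_sd = if (is.null(ps)) NA_real_ else ps$sas_sd,
    n_generated = length(generated),
    n_valid = n_valid,
    n_expected = as.integer(n_expected),
    denominators = "valid molecules only (novelty, diversity, QED, SAS)"
  )
  structure(rep, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  cat(sprintf("  generated %d (expected %d), valid %d\n",
              x$n_generated, x$n_expected, x$n_valid))
  cat(sprintf("  validity %.2f%%  diversity %.2f%%  novelty %.2f%%\n",
              x$validity_pct, x$diversity_pct, x$novelty_pct))
  cat(sprintf("  QED %.3f +/- %.3f   SAS %.2f +/- %.2f\n",
              x$qed_mean, x$qed_sd, x$sas_mean, x$sas_sd))
  invisible(x)
}

#' Write an evaluation report to JSON and/or CSV
#'
#' The CSV is one row in the conventional column order of generative-
#' chemistry comparison tables: QED, SAS, Validity, Diversity, Novelty.
#'
#' @param report A `metrics_report`.
#' @param json,csv Output paths (`NULL` to skip either).
#' @export
write_metrics_report <- function(report, json = NULL, csv = NULL) {
  stopifnot(inherits(report, "metrics_report"))
  if (!is.null(json)) {
    jsonlite::write_json(unclass(report), json, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  if (!is.null(csv)) {
    row <- data.frame(
      QED = sprintf("%.3f+/-%.3f", report$qed_mean, report$qed_sd),
      SAS = sprintf("%.2f+/-%.2f", report$sas_mean, report$sas_sd),
      Validity = report$validity_pct, Diversity = report$diversity_pct,
      Novelty = report$novelty_pct
    )
    utils::write.csv(row, csv, row.names = FALSE)
  }
  invisible(report)
}
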