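#' @title Terminal reward functions
#' @name rewards
#' @description
#' Episodes in the SMILES-building MDP earn reward only at the terminal
#' state. All three rewards are gated on chemical validity: an invalid
#' terminal string scores exactly 0, which is what teaches the policy to
#' respect SMILES grammar. The three kinds are:
#' \itemize{
#'   \item `qed`: 10 x QED of the molecule (range \[0, 10\]);
#'   \item `pic50`: exp(pIC50 / 3), with pIC50 supplied by a property
#'     scorer (unbounded above, >= 0);
#'   \item `predictor`: the raw probability in \[0, 1\] emitted by an
#'     external classifier-type predictor.
#' }
NULL

#' QED-based reward
#'
#' `10 * QED(s)` for valid molecules, 0 otherwise. Vectorised.
#'
#' @param smiles Character vector of terminal SMILES strings.
#' @return Numeric vector in \[0, 10\].
#' @export
qed_reward <- function(smiles) {
  props <- mol_properties(smiles)
  ifelse(props$valid & is.finite(props$qed), 10 * props$qed, 0)
}

#' pIC50-based reward
#'
#' `exp(scorer(s) / 3)` for valid molecules, 0 otherwise. The scorer must
#' return pIC50-scale values; a scorer failure (non-finite value) on a
#' *valid* molecule is an error, distinct from the invalid-molecule zero.
#'
#' @param smiles Character vector.
#' @param scorer A property scorer: `function(character) -> numeric`, e.g.
#'   from [surrogate_scorer()] or [command_scorer()].
#' @return Numeric vector, 0 or positive.
#' @export
pic50_reward <- function(smiles, scorer) {
  stopifnot(is.function(scorer))
  valid <- is_valid(smiles)
  out <- numeric(length(smiles))
  if (any(valid)) {
    sc <- scorer(smiles[valid])
    if (any(!is.finite(sc))) {
      stop("property scorer returned a non-finite value for a valid molecule")
    }
    out[valid] <- exp(sc / 3)
  }
  out
}

#' External-predictor reward
#'
#' The scorer's raw output probability for valid molecules, 0 otherwise.
#' Scorer outputs outside \[0, 1\] are an error (the contract of a
#' classifier-type predictor), as is a non-finite value on a valid
#' molecule.
#'
#' @inheritParams pic50_reward
#' @return Numeric vector in \[0, 1\].
#' @export
predictor_reward <- function(smiles, scorer) {
  stopifnot(is.function(scorer))
  valid <- is_valid(smiles)
  out <- numeric(length(smiles))
  if (any(valid)) {
    sc <- scorer(smiles[valid])
    if (any(!is.finite(sc))) {
      stop("property scorer returned a non-finite value for a valid molecule")
    }
    if (any(sc < 0 | sc > 1)) {
      stop("predictor scorer output outside [0, 1]")
    }
    out[valid] <- sc
  }
  out
}

#' Convert IC50 (nM) to pIC50
#'
#' `pIC50 = 9 - log10(IC50)` with IC50 in nanomolar, so 1 nM gives 9 and
#' 1000 nM (1 uM) gives 6.
#'
#' @param ic50 Positive numeric vector, nanomolar.
#' @return Numeric vector of pIC50 values.
#' @examples
#' pic50_from_ic50(c(1, 1000))  # 9 6
#' @export
pic50_from_ic50 <- function(ic50) {
  if (any(!is.finite(ic50)) || any(ic50 <= 0)) {
    stop("IC50 values must be positive and finite")
  }
  9 - log10(ic50)
}

#' Reward specification
#'
#' Bundles a reward kind with its scorer (where one is required) into a
#' single vectorised reward function for the RL stage.
#'
#' @param kind One of `"qed"`, `"pic50"`, `"predictor"`.
#' @param scorer Required for `"pic50"` and `"predictor"`.
#' @return A function `character -> numeric` with attribute `kind`.
#' @export
reward_spec <- function(kind = c("qed", "pic50", "predictor"), scorer = NULL) {
  kind <- match.arg(kind)
  if (kind != "qed" && !is.function(scorer)) {
    stop(sprintf("reward kind '%s' requires a scorer function", kind))
  }
  fn <- switch(kind,
    qed = function(smiles) qed_reward(smiles),
    pic50 = function(smiles) pic50_reward(smiles, scorer),
    predictor = function(smiles) predictor_reward(smiles, scorer)
  )
  structure(fn, kind = kind)
}

#' Lightweight surrogate property scorer
#'
#' Fits a deterministic ridge regression of a numeric property on simple
#' string-level molecular descriptors (heavy-atom count, heteroatom and
#' ring-digit counts, branching). It stands in for an externally trained
#' graph-neural-network property predictor during offline development and
#' testing; it is *not* a serious activity model and is clearly labelled
#' as a surrogate.
#'
#' @param training A data frame with columns `smiles` and `value`, or a
#'   path to a CSV file with those columns.
#' @param clamp Optional `c(lo, hi)` to clamp predictions (e.g. `c(0, 1)`
#'   for classifier-type targets).
#' @return A scorer `function(character) -> numeric`.
#' @export
surrogate_scorer <- function(training, clamp = NULL) {
  if (is.character(training)) {
    training <- utils::read.csv(training, stringsAsFactors = FALSE)
  }
  if (!all(c("smiles", "value") %in% names(training))) {
    stop("training data needs 'smiles' and 'value' columns")
  }
  feats <- function(smiles) {
    cbind(
      1,
      nchar(smiles),
      vapply(gregexpr("[NnOo]", smiles), function(m) sum(m > 0), numeric(1)),
      vapply(gregexpr("[0-9]", smiles), function(m) sum(m > 0), numeric(1)),
      vapply(gregexpr("\\(", smiles), function(m) sum(m > 0), numeric(1)),
      vapply(gregexpr("[Cc]", smiles), function(m) sum(m > 0), numeric(1))
    )
  }
  X <- feats(training$smiles)
  y <- as.numeric(training$value)
  if (any(!is.finite(y))) stop("non-finite property values in training data")
  lambda <- 1e-6
  beta <- solve(crossprod(X) + lambda * diag(ncol(X)), crossprod(X, y))
  function(smiles) {
    p <- drop(feats(smiles) %*% beta)
    if (!is.null(clamp)) p <- pmin(pmax(p, clamp[1]), clamp[2])
    p
  }
}

#' Scorer backed by an external command
#'
#' Adapter for an externally trained property predictor: the command is
#' run once per batch with a file of SMILES (one per line) as its single
#' argument and must print one numeric score per line to stdout.
#'
#' @param command Path or name of the executable.
#' @param args Extra arguments placed before the input-file argument.
#' @return A scorer `function(character) -> numeric`.
#' @export
command_scorer <- function(command, args = character()) {
  force(command); force(args)
  function(smiles) {
    f <- tempfile(fileext = ".smi")
    on.exit(unlink(f), add = TRUE)
    writeLines(smiles, f)
    out <- system2(command, c(args, shQuote(f)), stdout = TRUE)
    vals <- suppressWarnings(as.numeric(out))
    if (length(vals) != length(smiles) || any(is.na(vals))) {
      stop("external scorer did not return one numeric score per molecule")
    }
    vals
  }
}
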