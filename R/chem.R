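# Bridge to RDKit for parsing, canonicalisation, QED and SAS.
#
# Validity follows the convention of the field's benchmarks: a string is a
# valid molecule iff RDKit can parse *and sanitise* it. Scoring runs in a
# batched python subprocess (one call per batch of unseen strings) and
# results are cached for the session, so fuzz loops and RL steps cost one
# subprocess launch each.

.mol_cache <- new.env(parent = emptyenv())

python_bin <- function() {
  getOption("smirl.python", Sys.getenv("SMIRL_PYTHON", "python"))
}

mol_props_script <- function() {
  p <- system.file("python", "mol_props.py", package = "smirl")
  if (!nzchar(p)) stop("bundled mol_props.py not found; is smirl installed?")
  p
}

cache_key <- function(s) paste0("k", s)

# Strings RDKit could never parse and that would corrupt the line protocol.
locally_invalid <- function(s) {
  !nzchar(s) | grepl("[[:space:]]", s) | vapply(s, function(x) {
    any(utf8ToInt(x) > 127L)
  }, logical(1), USE.NAMES = FALSE)
}

score_batch <- function(smiles) {
  inp <- tempfile(fileext = ".smi")
  out <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(inp, out)), add = TRUE)
  writeLines(smiles, inp)
  status <- suppressWarnings(
    system2(python_bin(), c(shQuote(mol_props_script()), shQuote(inp),
                            shQuote(out)),
            stdout = FALSE, stderr = FALSE)
  )
  if (!identical(status, 0L) || !file.exists(out)) {
    stop("the RDKit helper process failed; check that '", python_bin(),
         "' is on PATH and has rdkit installed")
  }
  lines <- readLines(out)
  if (length(lines) != length(smiles)) {
    stop("RDKit helper returned ", length(lines), " rows for ",
         length(smiles), " inputs")
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  list(
    valid = vapply(parts, function(p) p[2] == "1", logical(1)),
    canonical = vapply(parts, function(p) if (p[2] == "1") p[3] else NA_character_,
                       character(1)),
    qed = vapply(parts, function(p) suppressWarnings(as.numeric(p[4])),
                 numeric(1)),
    sas = vapply(parts, function(p) suppressWarnings(as.numeric(p[5])),
                 numeric(1)),
    n_heavy = vapply(parts, function(p) suppressWarnings(as.integer(p[6])),
                     integer(1))
  )
}

#' Molecular properties of SMILES strings
#'
#' Parses each string with RDKit and returns validity, the canonical
#' SMILES, QED (drug-likeness, in \[0, 1\]), SAS (synthetic accessibility,
#' roughly \[1, 10\], higher = harder) and the heavy-atom count. Invalid
#' strings get `valid = FALSE` and `NA` properties — parse failure is a
#' value, never an error. Results are memoised for the session.
#'
#' @param smiles Character vector.
#' @return A tibble with columns `smiles`, `valid`, `canonical`, `qed`,
#'   `sas`, `n_heavy`, one row per input in input order.
#' @export
mol_properties <- function(smiles) {
  smiles <- as.character(smiles)
  n <- length(smiles)
  empty_row <- list(valid = FALSE, canonical = NA_character_,
                    qed = NA_real_, sas = NA_real_, n_heavy = NA_integer_)

  uniq <- unique(smiles)
  known <- vapply(uniq, function(s) exists(cache_key(s), envir = .mol_cache),
                  logical(1), USE.NAMES = FALSE)
  todo <- uniq[!known]
  if (length(todo) > 0L) {
    bad <- locally_invalid(todo)
    for (s in todo[bad]) assign(cache_key(s), empty_row, envir = .mol_cache)
    send <- todo[!bad]
    if (length(send) > 0L) {
      res <- score_batch(send)
      for (i in seq_along(send)) {
        assign(cache_key(send[i]),
               list(valid = res$valid[i], canonical = res$canonical[i],
                    qed = res$qed[i], sas = res$sas[i],
                    n_heavy = res$n_heavy[i]),
               envir = .mol_cache)
      }
    }
  }

  rows <- lapply(smiles, function(s) get(cache_key(s), envir = .mol_cache))
  tibble::tibble(
    smiles = smiles,
    valid = vapply(rows, `[[`, logical(1), "valid"),
    canonical = vapply(rows, `[[`, character(1), "canonical"),
    qed = vapply(rows, `[[`, numeric(1), "qed"),
    sas = vapply(rows, `[[`, numeric(1), "sas"),
    n_heavy = vapply(rows, `[[`, integer(1), "n_heavy")
  )
}

#' Is a SMILES string a valid molecule?
#'
#' `TRUE` iff RDKit parses and sanitises the string into a molecule object;
#' the empty string is invalid. Vectorised.
#'
#' @param smiles Character vector.
#' @return Logical vector.
#' @examples \dontrun{is_valid(c("CCO", "C("))  # TRUE FALSE}
#' @export
is_valid <- function(smiles) {
  mol_properties(smiles)$valid
}

#' Canonical SMILES form
#'
#' RDKit's canonicalisation; `NA` for invalid strings. Used for all
#' molecule-identity comparisons (novelty, diversity).
#'
#' @param smiles Character vector.
#' @return Character vector of canonical SMILES (`NA` where invalid).
#' @export
canonical_smiles <- function(smiles) {
  mol_properties(smiles)$canonical
}
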