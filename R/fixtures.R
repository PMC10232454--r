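# Deterministic synthetic SMILES corpora.
#
# Every training and testing stage must run offline, so the package can
# manufacture its own corpus: a combinatorial enumeration of small,
# chemistry-trivial molecules — alkane chains, single branches, 3-6
# membered carbocycles with tails, and O/N heteroatom substitutions
# (single and double). Candidates are canonicalised with RDKit and
# deduplicated, so every emitted molecule is valid and unique, and the
# whole generation is a pure function of the spec. The chemistry is
# deliberately simple (no stereochemistry, charges or fused rings) so a
# small decoder can learn it on a CPU in minutes.

#' Synthetic corpus specification
#'
#' @param n_molecules Number of molecules to emit.
#' @param max_heavy_atoms Heavy-atom budget per molecule (default 11).
#' @param seed Seed for the final shuffle.
#' @param motifs Subset of `c("chains", "branches", "rings",
#'   "heteroatoms")` to enumerate.
#' @return A `smirl_fixturespec` list.
#' @export
fixture_spec <- function(n_molecules, max_heavy_atoms = 11L, seed = 1L,
                         motifs = c("chains", "branches", "rings",
                                    "heteroatoms")) {
  motifs <- match.arg(motifs, several.ok = TRUE)
  stopifnot(n_molecules >= 1L, max_heavy_atoms >= 1L)
  structure(list(n_molecules = as.integer(n_molecules),
                 max_heavy_atoms = as.integer(max_heavy_atoms),
                 seed = as.integer(seed), motifs = motifs),
            class = "smirl_fixturespec")
}

enumerate_skeletons <- function(M, motifs) {
  out <- character(0)
  if ("chains" %in% motifs) {
    out <- c(out, vapply(seq_len(M), function(n) strrep("C", n), ""))
  }
  if ("branches" %in% motifs) {
    for (n in 3:max(3L, M)) {
      for (i in 2:(n - 1L)) {
        for (b in c("C", "CC", "CCC")) {
          if (n + nchar(b) <= M && i < n) {
            out <- c(out, paste0(strrep("C", i), "(", b, ")",
                                 strrep("C", n - i)))
          }
        }
      }
    }
  }
  if ("rings" %in% motifs) {
    for (k in 3:6) {
      if (k > M) next
      ring <- paste0("C1", strrep("C", k - 2L), "C1")
      for (m in 0:(M - k)) {
        out <- c(out, paste0(ring, strrep("C", m)))
      }
    }
  }
  unique(out)
}

substitute_heteroatoms <- function(skeletons) {
  out <- character(0)
  for (s in skeletons) {
    pos <- which(strsplit(s, "")[[1]] == "C")
    for (p in pos) {
      for (x in c("O", "N")) {
        t <- s
        substr(t, p, p) <- x
        out <- c(out, t)
      }
    }
    if (length(pos) >= 2L) {
      prs <- utils::combn(pos, 2L)
      for (j in seq_len(ncol(prs))) {
        for (x1 in c("O", "N")) {
          for (x2 in c("O", "N")) {
            t <- s
            substr(t, prs[1, j], prs[1, j]) <- x1
            substr(t, prs[2, j], prs[2, j]) <- x2
            out <- c(out, t)
          }
        }
      }
    }
  }
  unique(out)
}

#' Generate a deterministic synthetic SMILES corpus
#'
#' Enumerates the motif space of the spec, canonicalises with RDKit,
#' keeps the valid unique molecules, shuffles them with the spec's seed
#' and truncates to `n_molecules`. Identical specs give identical corpora;
#' every output passes [is_valid()].
#'
#' @param spec A [fixture_spec()], or an integer shorthand for
#'   `fixture_spec(n_molecules = spec)`.
#' @return Character vector of canonical SMILES.
#' @export
generate_fixture_corpus <- function(spec) {
  if (is.numeric(spec)) spec <- fixture_spec(spec)
  stopifnot(inherits(spec, "smirl_fixturespec"))
  skel <- enumerate_skeletons(spec$max_heavy_atoms, spec$motifs)
  cand <- skel
  if ("heteroatoms" %in% spec$motifs) {
    cand <- c(cand, substitute_heteroatoms(skel))
  }
  can <- canonical_smiles(cand)
  pool <- sort(unique(can[!is.na(can)]))
  if (spec$n_molecules > length(pool)) {
    stop(sprintf(
      "requested %d molecules but this motif space holds only %d; reduce n_molecules or raise max_heavy_atoms",
      spec$n_molecules, length(pool)))
  }
  set.seed(spec$seed)
  sample(pool)[seq_len(spec$n_molecules)]
}

#' Summary statistics of a corpus
#'
#' The training-set statistics panel: molecule count, mean QED, mean SAS
#' and the largest heavy-atom count. Works for synthetic corpora and for
#' any external `.smi` collection alike.
#'
#' @param corpus Character vector of SMILES, or a path to a `.smi` file.
#' @return A one-row tibble: `n`, `qed_mean`, `sas_mean`, `max_atoms`.
#' @export
corpus_stats <- function(corpus) {
  if (length(corpus) == 1L && file.exists(corpus)) corpus <- read_smi(corpus)
  props <- mol_properties(corpus)
  valid <- props[props$valid, ]
  tibble::tibble(
    n = length(corpus),
    qed_mean = mean(valid$qed, na.rm = TRUE),
    sas_mean = mean(valid$sas, na.rm = TRUE),
    max_atoms = if (nrow(valid) > 0) max(valid$n_heavy, na.rm = TRUE)
                else NA_integer_
  )
}
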