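#' @title SMILES token vocabularies
#' @name vocabulary
#' @description
#' A vocabulary maps SMILES surface tokens to contiguous 0-based integer
#' ids. Three reserved specials occupy fixed slots: `[PAD]` = 0, `[BOS]` = 1,
#' `[EOS]` = 2; corpus-derived tokens follow, sorted for reproducibility.
#' Two schemes are supported: `"char"` (one token per character — the
#' default used throughout; two-letter atoms such as Cl are deliberately
#' split, and concatenation on decode restores them) and `"bpe"`
#' (byte-pair encoding: greedy frequency-ranked merges of adjacent token
#' pairs, each corpus line treated as an independent word).
NULL

SPECIALS <- c("[PAD]", "[BOS]", "[EOS]")

new_vocabulary <- function(tokens, scheme, merges = list()) {
  stopifnot(is.character(tokens), scheme %in% c("char", "bpe"))
  if (!identical(tokens[1:3], SPECIALS)) {
    stop("first three tokens must be the reserved specials [PAD], [BOS], [EOS]")
  }
  if (anyDuplicated(tokens)) stop("vocabulary tokens must be unique")
  if (scheme == "char") {
    nonspecial <- tokens[-(1:3)]
    if (any(nchar(nonspecial) != 1L)) {
      stop("char-scheme vocabulary contains a multi-character token")
    }
  }
  structure(
    list(tokens = tokens, scheme = scheme, merges = merges,
         pad_id = 0L, bos_id = 1L, eos_id = 2L),
    class = "smirl_vocab"
  )
}

#' @export
print.smirl_vocab <- function(x, ...) {
  cat(sprintf("<smirl_vocab> scheme=%s, %d tokens (%d non-special)\n",
              x$scheme, length(x$tokens), length(x$tokens) - 3L))
  invisible(x)
}

#' @export
length.smirl_vocab <- function(x) length(x$tokens)

check_corpus <- function(corpus) {
  corpus <- as.character(corpus)
  if (length(corpus) == 0L) stop("corpus is empty")
  bad <- which(vapply(corpus, function(s) {
    any(utf8ToInt(s) > 127L)
  }, logical(1)))
  if (length(bad) > 0L) {
    stop(sprintf("non-ASCII character in corpus line %d: %s",
                 bad[1], corpus[bad[1]]))
  }
  corpus
}

#' Build a character-level vocabulary from a SMILES corpus
#'
#' One token per distinct character observed in the corpus, ordered by
#' codepoint after the three reserved specials, so two builds from the same
#' corpus are identical.
#'
#' @param corpus Character vector of SMILES strings (ASCII).
#' @return A `smirl_vocab` with `scheme = "char"`.
#' @examples
#' v <- build_char_vocab(c("CCO", "CCN"))
#' length(v)  # 3 specials + C, N, O
#' @export
build_char_vocab <- function(corpus) {
  corpus <- check_corpus(corpus)
  chars <- sort(unique(unlist(strsplit(corpus, "", fixed = TRUE))))
  new_vocabulary(c(SPECIALS, chars), "char")
}

pair_key <- function(a, b) paste(a, b, sep = "\x1f")

count_pairs <- function(words, counts) {
  keys <- unlist(lapply(seq_along(words), function(i) {
    w <- words[[i]]
    n <- length(w)
    if (n < 2L) return(character(0))
    rep(pair_key(w[-n], w[-1L]), counts[i])
  }))
  if (length(keys) == 0L) return(integer(0))
  tab <- table(keys)
  setNames(as.integer(tab), names(tab))
}

apply_merge <- function(w, a, b, ab) {
  n <- length(w)
  if (n < 2L) return(w)
  out <- character(n)
  k <- 0L
  i <- 1L
  while (i <= n) {
    if (i < n && w[i] == a && w[i + 1L] == b) {
      k <- k + 1L
      out[k] <- ab
      i <- i + 2L
    } else {
      k <- k + 1L
      out[k] <- w[i]
      i <- i + 1L
    }
  }
  out[seq_len(k)]
}

#' Build a byte-pair-encoding vocabulary from a SMILES corpus
#'
#' Standard BPE: the vocabulary is seeded with the corpus's distinct
#' characters; adjacent-pair merges are then learned greedily by frequency
#' (ties broken lexicographically) until `target_size` non-special tokens
#' exist or no pair occurs at least twice. Each corpus line is an
#' independent word; merges never cross lines. The learned merge list is
#' stored on the vocabulary for deterministic re-encoding.
#'
#' @param corpus Character vector of SMILES strings.
#' @param target_size Desired number of non-special tokens (default 500).
#' @return A `smirl_vocab` with `scheme = "bpe"`.
#' @export
build_bpe_vocab <- function(corpus, target_size = 500L) {
  corpus <- check_corpus(corpus)
  base <- build_char_vocab(corpus)
  alphabet <- base$tokens[-(1:3)]
  if (target_size < length(alphabet)) {
    stop(sprintf("target_size (%d) is below the base alphabet size (%d)",
                 target_size, length(alphabet)))
  }
  tab <- table(corpus)
  words <- strsplit(names(tab), "", fixed = TRUE)
  counts <- as.integer(tab)

  tokens <- alphabet
  merges <- list()
  while (length(tokens) < target_size) {
    pc <- count_pairs(words, counts)
    pc <- pc[pc >= 2L]
    if (length(pc) == 0L) break
    best <- sort(names(pc)[pc == max(pc)])[1]
    ab <- strsplit(best, "\x1f", fixed = TRUE)[[1]]
    merged <- paste0(ab[1], ab[2])
    if (merged %in% c(tokens, SPECIALS)) {
      # degenerate: the concatenation already exists as a token surface form
      words <- lapply(words, apply_merge, a = ab[1], b = ab[2], ab = merged)
      merges <- c(merges, list(ab))
      next
    }
    tokens <- c(tokens, merged)
    merges <- c(merges, list(ab))
    words <- lapply(words, apply_merge, a = ab[1], b = ab[2], ab = merged)
  }
  new_vocabulary(c(SPECIALS, tokens), "bpe", merges)
}

tokenize_string <- function(s, vocab) {
  w <- strsplit(s, "", fixed = TRUE)[[1]]
  if (vocab$scheme == "bpe") {
    for (m in vocab$merges) {
      w <- apply_merge(w, m[1], m[2], paste0(m[1], m[2]))
    }
  }
  w
}

#' Encode a SMILES string to token ids
#'
#' Character scheme: one id per character. BPE scheme: the stored merge
#' list is replayed greedily, then tokens are mapped to ids. No framing
#' tokens are added; callers that need `[BOS]`/`[EOS]` add them.
#'
#' @param s A single SMILES string (may be empty: the initial state).
#' @param vocab A `smirl_vocab`.
#' @return A `smirl_tokens` object: list with 0-based integer `ids` and the
#'   source `text`.
#' @export
encode <- function(s, vocab) {
  stopifnot(is.character(s), length(s) == 1L, inherits(vocab, "smirl_vocab"))
  if (nchar(s) == 0L) {
    return(structure(list(ids = integer(0), text = s), class = "smirl_tokens"))
  }
  w <- tokenize_string(s, vocab)
  ids <- match(w, vocab$tokens) - 1L
  if (anyNA(ids)) {
    i <- which(is.na(ids))[1]
    stop(sprintf("character/token '%s' at token position %d of '%s' is not in the vocabulary",
                 w[i], i, s))
  }
  structure(list(ids = ids, text = s), class = "smirl_tokens")
}

#' Decode token ids back to a SMILES string
#'
#' Concatenates the surface forms of non-special ids; `[PAD]`, `[BOS]` and
#' `[EOS]` are stripped.
#'
#' @param ids A `smirl_tokens` object or 0-based integer id vector.
#' @param vocab A `smirl_vocab`.
#' @return A single string.
#' @export
decode <- function(ids, vocab) {
  if (inherits(ids, "smirl_tokens")) ids <- ids$ids
  stopifnot(inherits(vocab, "smirl_vocab"))
  ids <- as.integer(ids)
  if (length(ids) == 0L) return("")
  if (any(ids < 0L | ids >= length(vocab$tokens))) {
    stop("token id out of range for this vocabulary")
  }
  toks <- vocab$tokens[ids + 1L]
  paste0(toks[!(toks %in% SPECIALS)], collapse = "")
}

#' Serialize a vocabulary to JSON
#'
#' The file holds `{scheme, tokens, merges}`; [read_vocab()] restores an
#' identical object.
#'
#' @param vocab A `smirl_vocab`.
#' @param path Output file path.
#' @export
write_vocab <- function(vocab, path) {
  obj <- list(scheme = vocab$scheme, tokens = vocab$tokens,
              merges = lapply(vocab$merges, identity))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_vocab
#' @export
read_vocab <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  merges <- lapply(obj$merges, function(m) c(m[[1]], m[[2]]))
  new_vocabulary(vapply(obj$tokens, identity, character(1)),
                 obj$scheme, merges)
}
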