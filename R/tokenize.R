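#' SMILES tokenization
#'
#' Splits a SMILES string into grammar-level tokens: bracket atoms
#' (`[...]`) and the two-letter organic-subset halogens (`Cl`, `Br`) are
#' kept as single tokens, `%nn` ring closures are one token, and every
#' other character (organic-subset atoms, bonds, branches, ring digits,
#' the dot disconnect) is a token of its own.  This guarantees that
#' `paste0(tokens)` reproduces the input exactly, which is the property
#' the encoder/decoder round trip rests on.
#'
#' @param smiles A single SMILES string.
#' @return Character vector of tokens, or an error if the string
#'   contains characters outside the SMILES alphabet.
#' @examples
#' smiles_tokenize("c1ccc(Cl)cc1")
#' @export
smiles_tokenize <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, !is.na(smiles))
  if (!nzchar(smiles)) stop("empty SMILES string")
  m <- gregexpr(.token_regex, smiles, perl = TRUE)[[1]]
  if (m[1] == -1L) stop("no SMILES tokens found in: ", smiles)
  toks <- regmatches(smiles, gregexpr(.token_regex, smiles, perl = TRUE))[[1]]
  if (paste(toks, collapse = "") != smiles) {
    stop("untokenizable characters in SMILES: ", smiles)
  }
  toks
}

.token_regex <- paste0(
  "\\[[^\\[\\]]*\\]",   # bracket atom, one token
  "|Br|Cl",             # two-letter organic subset elements
  "|%[0-9]{2}",         # two-digit ring closure
  "|[0-9]",             # ring closure digit
  "|[BCNOPSFI]|[bcnosp]",
  "|[-=#:/\\\\().]"
)

#' Quietly tokenize, returning NULL on failure
#' @noRd
.try_tokenize <- function(smiles) {
  tryCatch(smiles_tokenize(smiles), error = function(e) NULL)
}

#' Build a token vocabulary from a corpus
#'
#' The vocabulary holds the three special tokens (PAD, BOS, EOS) followed
#' by every chemical token occurring in the corpus, in sorted order, so
#' the same corpus always yields the same vocabulary.  Specials can never
#' be produced by the tokenizer from input text (they are not in the
#' SMILES alphabet).
#'
#' @param smiles Character vector of SMILES strings (typically a curated
#'   corpus in canonical form).
#' @return An object of class `smiles_vocabulary`: a list with `tokens`
#'   (full ordered token set), and the integer indices `pad`, `bos`,
#'   `eos`.
#' @examples
#' v <- smiles_vocabulary(c("CCO", "c1ccccc1"))
#' v$tokens
#' @export
smiles_vocabulary <- function(smiles) {
  stopifnot(length(smiles) >= 1L)
  toks <- unlist(lapply(smiles, smiles_tokenize), use.names = FALSE)
  if (length(toks) == 0L) stop("empty corpus: no tokens")
  chem <- sort(unique(toks), method = "radix")
  v <- list(
    tokens = c("<pad>", "<bos>", "<eos>", chem),
    pad = 1L, bos = 2L, eos = 3L
  )
  class(v) <- "smiles_vocabulary"
  v
}

#' @export
print.smiles_vocabulary <- function(x, ...) {
  cat("SMILES vocabulary:", length(x$tokens), "tokens",
      "(3 specials +", length(x$tokens) - 3L, "chemical)\n")
  cat("  ", paste(x$tokens[-(1:3)], collapse = " "), "\n")
  invisible(x)
}

#' Encode a SMILES string as a token index sequence
#'
#' The encoded sequence starts with BOS and ends with EOS; chemical
#' tokens are mapped through the vocabulary.  Out-of-vocabulary tokens
#' raise an error that names them.
#'
#' @param smiles A single SMILES string.
#' @param vocab A [smiles_vocabulary()].
#' @return Integer vector of 1-based token indices.
#' @export
smiles_encode <- function(smiles, vocab) {
  stopifnot(inherits(vocab, "smiles_vocabulary"))
  toks <- smiles_tokenize(smiles)
  idx <- match(toks, vocab$tokens)
  if (anyNA(idx)) {
    bad <- unique(toks[is.na(idx)])
    stop("out-of-vocabulary token(s): ", paste(bad, collapse = " "),
         " in: ", smiles)
  }
  c(vocab$bos, idx, vocab$eos)
}

#' Decode a token index sequence back to a SMILES string
#'
#' Special tokens (PAD/BOS/EOS) are dropped; the remaining indices are
#' mapped back through the vocabulary and concatenated, so
#' `smiles_decode(smiles_encode(s, v), v)` is exactly `s`.
#'
#' @param indices Integer vector of token indices.
#' @param vocab A [smiles_vocabulary()].
#' @return A single string.
#' @export
smiles_decode <- function(indices, vocab) {
  stopifnot(inherits(vocab, "smiles_vocabulary"))
  if (any(indices < 1L | indices > length(vocab$tokens))) {
    stop("token index out of range")
  }
  keep <- !(indices %in% c(vocab$pad, vocab$bos, vocab$eos))
  paste(vocab$tokens[indices[keep]], collapse = "")
}

#' Encode a whole corpus
#' @param smiles Character vector.
#' @param vocab A [smiles_vocabulary()].
#' @return List of integer vectors.
#' @export
smiles_encode_all <- function(smiles, vocab) {
  lapply(smiles, smiles_encode, vocab = vocab)
}
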