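# Tokenization of compound SMILES strings and protein residue sequences,
# vocabulary construction, and fixed-length padding/truncation.

PAD_TOKEN <- "<PAD>"
MASK_TOKEN <- "<MASK>"

# Two-letter element symbols recognised by the atom-level tokenizer (greedy
# longest match; one- letter symbols and all other characters fall through to
# single-character tokens).
TWO_LETTER_ELEMENTS <- c(
  "He", "Li", "Be", "Ne", "Na", "Mg", "Al", "Si", "Cl", "Ar", "Ca", "Sc",
  "Ti", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se",
  "Br", "Kr", "Rb", "Sr", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag",
  "Cd", "In", "Sn", "Sb", "Te", "Xe", "Cs", "Ba", "Hf", "Ta", "Re", "Os",
  "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po", "At", "Rn"
)

PROTEIN_ALPHABET <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P", "Q",
  "R", "S", "T", "V", "W", "Y", "X", "B", "Z", "U", "O"
)

new_token_seq <- function(tokens, kind, source_id = NA_character_, ids = NULL) {
  structure(
    list(source_id = source_id, kind = kind,
         tokens = as.character(tokens), ids = ids),
    class = "token_seq"
  )
}

#' @export
print.token_seq <- function(x, ...) {
  cat(sprintf("<token_seq %s '%s': %d tokens>\n", x$kind,
              ifelse(is.na(x$source_id), "?", x$source_id), length(x$tokens)))
  if (length(x$tokens)) {
    shown <- utils::head(x$tokens, 20L)
    cat(" ", paste(shown, collapse = " "),
        if (length(x$tokens) > 20L) "..." else "", "\n")
  }
  invisible(x)
}

#' @export
length.token_seq <- function(x) length(x$tokens)

#' Tokenize a SMILES string
#'
#' Splits a SMILES string into tokens.  In `"char"` mode every character is a
#' token (the convention used when the training corpus treats each atom and
#' bond symbol as a word).  In `"atom"` mode two-letter element symbols
#' (`Cl`, `Br`, `Si`, ...) and bracket atoms (`[nH]`, `[O-]`, ...) are emitted
#' as single tokens by greedy longest match; every other character remains a
#' single-character token.  In both modes the concatenation of the tokens
#' reproduces the input string exactly, so tokenization is lossless.
#'
#' No chemical validity checking is performed; the tokenizer is purely
#' lexical.
#'
#' @param smiles A single SMILES string (may be empty).
#' @param mode `"char"` or `"atom"`.
#' @param source_id Optional identifier carried along with the sequence.
#' @param vocab Optional [vocabulary][build_vocabulary]; when given, integer
#'   ids are attached to the result.
#' @return A `token_seq` object with fields `tokens`, `kind`, `source_id`
#'   and (if `vocab` was supplied) `ids`.
#' @examples
#' tokenize_smiles("CC(=)OC1=C", mode = "char")$tokens
#' tokenize_smiles("ClCBr", mode = "atom")$tokens
#' @export
tokenize_smiles <- function(smiles, mode = c("char", "atom"),
                            source_id = NA_character_, vocab = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.character(smiles), length(smiles) == 1L, !is.na(smiles))
  if (nchar(smiles) == 0L) {
    out <- new_token_seq(character(0), "compound", source_id)
    if (!is.null(vocab)) out$ids <- integer(0)
    return(out)
  }
  chars <- strsplit(smiles, "", fixed = TRUE)[[1L]]
  if (mode == "char") {
    tokens <- chars
  } else {
    n <- length(chars)
    tokens <- character(0)
    i <- 1L
    while (i <= n) {
      ch <- chars[i]
      if (ch == "[") {
        j <- i
        while (j <= n && chars[j] != "]") j <- j + 1L
        if (j > n) {
          stop(sprintf(
            "unbalanced bracket atom: '[' at offset %d has no matching ']'",
            i), call. = FALSE)
        }
        tokens <- c(tokens, paste(chars[i:j], collapse = ""))
        i <- j + 1L
      } else if (i < n &&
                 paste0(ch, chars[i + 1L]) %in% TWO_LETTER_ELEMENTS) {
        tokens <- c(tokens, paste0(ch, chars[i + 1L]))
        i <- i + 2L
      } else {
        tokens <- c(tokens, ch)
        i <- i + 1L
      }
    }
  }
  out <- new_token_seq(tokens, "compound", source_id)
  if (!is.null(vocab)) out$ids <- encode_tokens(vocab, out$tokens)
  out
}

#' Tokenize a protein sequence
#'
#' Splits an amino-acid sequence into 1-mer tokens (one token per residue),
#' upper-casing the input.  The 20 canonical residues plus the ambiguity and
#' rare-residue codes X, B, Z, U and O are accepted; anything else is an
#' error naming the offending character and its position.
#'
#' @param sequence A single residue string (may be empty).
#' @inheritParams tokenize_smiles
#' @return A `token_seq` object of kind `"protein"`.
#' @examples
#' tokenize_protein("MKV")$tokens
#' @export
tokenize_protein <- function(sequence, source_id = NA_character_,
                             vocab = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L, !is.na(sequence))
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) {
    out <- new_token_seq(character(0), "protein", source_id)
    if (!is.null(vocab)) out$ids <- integer(0)
    return(out)
  }
  tokens <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- which(!(tokens %in% PROTEIN_ALPHABET))
  if (length(bad)) {
    stop(sprintf("invalid residue character '%s' at position %d",
                 tokens[bad[1L]], bad[1L]), call. = FALSE)
  }
  out <- new_token_seq(tokens, "protein", source_id)
  if (!is.null(vocab)) out$ids <- encode_tokens(vocab, out$tokens)
  out
}

#' Build a vocabulary from a token corpus
#'
#' Collects every distinct token in a corpus and assigns deterministic
#' integer ids: the padding token `<PAD>` always has id 0, the mask token
#' `<MASK>` id 1, and the remaining tokens follow in lexicographic order.
#' Rebuilding from the same corpus (in any order) yields the identical
#' vocabulary.
#'
#' @param corpus A list of `token_seq` objects (or character vectors of
#'   tokens).
#' @param kind `"compound"` or `"protein"`.
#' @return A `dta_vocabulary` object: fields `kind`, `tokens` (specials
#'   first), `size`.
#' @export
build_vocabulary <- function(corpus, kind = c("compound", "protein")) {
  kind <- match.arg(kind)
  if (length(corpus) == 0L) stop("corpus is empty", call. = FALSE)
  toks <- unlist(lapply(corpus, function(s) {
    if (inherits(s, "token_seq")) s$tokens else as.character(s)
  }), use.names = FALSE)
  uniq <- sort(unique(toks), method = "radix")
  uniq <- setdiff(uniq, c(PAD_TOKEN, MASK_TOKEN))
  structure(
    list(kind = kind, tokens = c(PAD_TOKEN, MASK_TOKEN, uniq),
         size = length(uniq) + 2L),
    class = "dta_vocabulary"
  )
}

#' @export
print.dta_vocabulary <- function(x, ...) {
  cat(sprintf("<dta_vocabulary %s: %d tokens (incl. <PAD>, <MASK>)>\n",
              x$kind, x$size))
  invisible(x)
}

#' Map tokens to integer ids under a vocabulary
#'
#' Ids are zero-based: `<PAD>` is 0 and `<MASK>` is 1 by construction.
#'
#' @param vocab A `dta_vocabulary`.
#' @param tokens Character vector of tokens.
#' @return Integer vector of the same length.
#' @export
encode_tokens <- function(vocab, tokens) {
  stopifnot(inherits(vocab, "dta_vocabulary"))
  ids <- match(tokens, vocab$tokens)
  if (anyNA(ids)) {
    missing <- unique(tokens[is.na(ids)])
    stop(sprintf("token(s) not in vocabulary: %s",
                 paste(sQuote(missing), collapse = ", ")), call. = FALSE)
  }
  ids - 1L
}

#' Pad or truncate a token sequence to a fixed length
#'
#' Sequences longer than `max_len` keep their first `max_len` tokens;
#' shorter ones are right-padded with `<PAD>` (id 0).  The operation is
#' idempotent at a fixed `max_len`.
#'
#' @param seq A `token_seq`.
#' @param max_len Target length (>= 1).
#' @return A `token_seq` of length exactly `max_len`.
#' @export
pad_or_truncate <- function(seq, max_len) {
  stopifnot(inherits(seq, "token_seq"), max_len >= 1L)
  n <- length(seq$tokens)
  if (n >= max_len) {
    seq$tokens <- seq$tokens[seq_len(max_len)]
    if (!is.null(seq$ids)) seq$ids <- seq$ids[seq_len(max_len)]
  } else {
    seq$tokens <- c(seq$tokens, rep(PAD_TOKEN, max_len - n))
    if (!is.null(seq$ids)) seq$ids <- c(seq$ids, rep(0L, max_len - n))
  }
  seq
}

#' Summary statistics of a token corpus
#'
#' @param corpus A non-empty list of `token_seq` objects.
#' @return A list with `n_sequences`, `mean_length`, `min_length` and
#'   `vocab_size` (distinct tokens, excluding the `<PAD>`/`<MASK>` specials).
#' @export
corpus_stats <- function(corpus) {
  if (length(corpus) == 0L) stop("corpus is empty", call. = FALSE)
  lens <- vapply(corpus, function(s) length(s$tokens), integer(1))
  toks <- unique(unlist(lapply(corpus, function(s) s$tokens),
                        use.names = FALSE))
  toks <- setdiff(toks, c(PAD_TOKEN, MASK_TOKEN))
  list(n_sequences = length(corpus), mean_length = mean(lens),
       min_length = min(lens), vocab_size = length(toks))
}
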