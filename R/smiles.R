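# SMILES tokenizer used by the DCW optimal-descriptor engine.
#
# A token is one of:
#   * a bracket atom  "[...]"        (kept verbatim, e.g. "[NH3+]")
#   * a two-letter organic-subset element  "Cl" or "Br"
#   * a one-letter atom   B C N O P S F I  or aromatic  b c n o s p
#   * a ring-bond label   digit or "%nn"
#   * a bond symbol       - = # : / \
# Branch parentheses and the dot separator are structural punctuation and are
# not emitted as tokens; adjacency for order-2 attributes is taken over the
# retained token sequence.

#' Tokenize a SMILES string
#'
#' @param smiles a single SMILES string.
#' @return character vector of tokens.
#' @examples
#' smiles_tokens("ClCCO")   # "Cl" "C" "C" "O"
#' @export
smiles_tokens <- function(smiles) {
  fd_assert(is.character(smiles) && length(smiles) == 1L && nzchar(smiles),
            "parse", "cannot tokenize an empty SMILES")
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  tokens <- character(0)
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      fd_assert(j <= n, "parse", "unterminated bracket atom in '%s'", smiles)
      tokens <- c(tokens, paste(chars[i:j], collapse = ""))
      i <- j + 1L
    } else if (ch == "%") {
      fd_assert(i + 2L <= n, "parse", "truncated %% ring label in '%s'", smiles)
      tokens <- c(tokens, paste(chars[i:(i + 2L)], collapse = ""))
      i <- i + 3L
    } else if (ch %in% c("C", "B") && i < n && chars[i + 1L] %in% c("l", "r") &&
               paste0(ch, chars[i + 1L]) %in% c("Cl", "Br")) {
      tokens <- c(tokens, paste0(ch, chars[i + 1L]))
      i <- i + 2L
    } else if (ch %in% c("(", ")", ".")) {
      i <- i + 1L
    } else if (grepl("[A-Za-z0-9@=#:/\\\\+-]", ch)) {
      tokens <- c(tokens, ch)
      i <- i + 1L
    } else {
      fd_stop("parse", "unexpected character '%s' in SMILES '%s'", ch, smiles)
    }
  }
  fd_assert(length(tokens) > 0, "parse", "SMILES '%s' yields no tokens", smiles)
  tokens
}

ORGANIC_ATOMS <- c("B", "C", "N", "O", "P", "S", "F", "I", "Cl", "Br",
                   "b", "c", "n", "o", "p", "s")

is_atom_token <- function(tokens) {
  startsWith(tokens, "[") | tokens %in% ORGANIC_ATOMS
}

atom_tokens <- function(smiles) {
  tk <- smiles_tokens(smiles)
  tk[is_atom_token(tk)]
}

# Element symbol of one atom token: "[NH3+]" -> "N", "c" -> "C".
token_element <- function(token) {
  if (startsWith(token, "[")) {
    m <- regmatches(token, regexpr("[A-Z][a-z]?|[cnosp]", token))
    fd_assert(length(m) == 1L, "parse", "cannot read element from '%s'", token)
    token <- m
  }
  el <- sub("^([A-Za-z][a-z]?).*$", "\\1", token)
  if (el %in% c("b", "c", "n", "o", "p", "s")) el <- toupper(el)
  el
}
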