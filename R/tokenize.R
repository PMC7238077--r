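#' Deterministic word/punctuation tokenizer
#'
#' Splits text into word tokens and single-character punctuation tokens.
#' Runs of letters/digits are kept together, and hyphens or periods that are
#' *internal* to an alphanumeric run stay inside the token (so phone-number
#' tails like `123-4567` and decimals like `1.5` survive as single tokens),
#' while leading/trailing punctuation is split off. Whitespace only
#' separates; no non-whitespace character is ever dropped.
#'
#' @param text a character scalar (may be empty).
#' @return character vector of tokens; `character(0)` for empty/blank input.
#' @examples
#' tokenize("Dr. Smith called.")
#' tokenize("(555) 123-4567")
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) return(character(0))
  pat <- "[\\p{L}\\p{N}]+(?:[-.][\\p{L}\\p{N}]+)*|\\S"
  m <- gregexpr(pat, text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(character(0))
  regmatches(text, list(m))[[1]]
}
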