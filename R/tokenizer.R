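# Character classes shared by the tokenizer and the char-feature model.
# Greek letters count as letters: they occur inside biomedical names
# (alpha-helix, IFN-γ) and must not become split points.
.greek_class <- "\\x{0370}-\\x{03FF}\\x{1F00}-\\x{1FFF}"
.letter_class <- paste0("A-Za-z", .greek_class)
.alnum_class <- paste0(.letter_class, "0-9")

# A token is a maximal alphanumeric run in which runs of '-', '/', '.',
# '(' and ')' are kept internal when flanked by alphanumerics on both
# sides (IL-2, p53/p21, Ca(2)-ATPase); a separator with whitespace or
# other symbols next to it starts/ends the token instead.
# "(*UTF)" puts PCRE in UTF mode so the Greek \x{...} ranges compile.
.token_regex <- paste0(
  "[", .alnum_class, "]+(?:[-/.()]+[", .alnum_class, "]+)*"
)

#' Split raw text into sentences of tokens
#'
#' Splits `text` into sentences and each sentence into tokens, keeping
#' complex biological names (hyphenated, slashed, dotted or parenthesised
#' alphanumeric runs such as `IL-2` or `p53/p21`) as single tokens.
#' Sentence boundaries are `.`, `!` or `?` followed by whitespace and an
#' uppercase letter or digit, except when the period closes an
#' abbreviation-like token that contains an internal dot (`e.g.`).
#' Terminal punctuation is emitted as its own token, as is every other
#' symbol character, so the token stream loses no non-whitespace character.
#'
#' @param text A character scalar (may be empty).
#' @return A list of sentences, each a character vector of token texts.
#'   Empty input yields an empty list.
#' @examples
#' tokenize("IL-2 binds.")
#' tokenize("We used 10-20 mg. It worked.")
#' @seealso [classify_pattern()], [token_info()]
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(trimws(text))) return(list())
  sentences <- .split_sentences(text)
  out <- lapply(sentences, .tokenize_sentence)
  out[lengths(out) > 0L]
}

# Sentence boundary: [.!?] + whitespace + [A-Z0-9]; a '.' boundary is
# suppressed when the non-space run it ends contains letters and an
# internal dot (abbreviation heuristic).
.split_sentences <- function(text) {
  m <- gregexpr("[.!?](?=[[:space:]]+[A-Z0-9])", text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(text)
  cut_after <- integer(0)
  for (pos in as.integer(m)) {
    ch <- substr(text, pos, pos)
    if (ch == ".") {
      # the maximal non-space run ending at pos, without its final '.'
      head <- substr(text, 1L, pos - 1L)
      run <- sub("^.*[[:space:]]", "", head)
      if (grepl("\\.", run) && grepl(paste0("(*UTF)[", .letter_class, "]"), run, perl = TRUE)) {
        next
      }
    }
    cut_after <- c(cut_after, pos)
  }
  if (length(cut_after) == 0L) return(text)
  starts <- c(1L, cut_after + 1L)
  ends <- c(cut_after, nchar(text))
  substring(text, starts, ends)
}

.tokenize_sentence <- function(sentence) {
  m <- gregexpr(paste0("(*UTF)", .token_regex, "|\\S"), sentence, perl = TRUE)[[1]]
  if (m[1] == -1L) return(character(0))
  regmatches(sentence, list(m))[[1]]
}

#' Classify a token against the known surface patterns
#'
#' Tests a token against the closed set of surface patterns that the tagger
#' resolves without a lexicon: plain numbers (optionally signed, with
#' optional thousands separators and a decimal part), number ranges
#' (digit-dash-digit, e.g. `10-20`), and ordinals (`1st`, `22nd`, `3rd`,
#' `11th`, case-insensitive). Every token matches exactly one kind;
#' anything else is `"none"`.
#'
#' @param token A character vector of token texts (non-empty, no whitespace).
#' @return A character vector of the same length with values in
#'   `c("number", "number_range", "ordinal", "none")`.
#' @examples
#' classify_pattern(c("3.14", "10-20", "21st", "tubulointerstitial"))
#' @export
classify_pattern <- function(token) {
  stopifnot(is.character(token), all(nzchar(token)))
  number <- "^[+-]?([0-9]{1,3}(,[0-9]{3})+|[0-9]+)(\\.[0-9]+)?$"
  range <- "^[0-9]+(\\.[0-9]+)?-[0-9]+(\\.[0-9]+)?$"
  ordinal <- "^([0-9]*(1st|2nd|3rd)|[0-9]+th)$"
  out <- rep("none", length(token))
  out[grepl(number, token)] <- "number"
  out[grepl(range, token)] <- "number_range"
  out[grepl(ordinal, token, ignore.case = TRUE)] <- "ordinal"
  out
}

#' Is a token entirely lowercase letters?
#'
#' All-lowercase alphabetic tokens are the ones routed to suffix analysis
#' when unknown; anything containing capitals, digits, Greek letters or
#' symbols is scored from its character-feature string instead.
#'
#' @param token A character vector of token texts.
#' @return A logical vector.
#' @export
is_all_lower <- function(token) {
  grepl("^[a-z]+$", token)
}

#' Token metadata table
#'
#' Convenience wrapper bundling each token's text, surface-pattern kind and
#' all-lowercase flag into one data frame.
#'
#' @param tokens A character vector of token texts.
#' @return A data frame with columns `text`, `pattern`, `is_all_lower`.
#' @export
token_info <- function(tokens) {
  data.frame(
    text = tokens,
    pattern = classify_pattern(tokens),
    is_all_lower = is_all_lower(tokens),
    stringsAsFactors = FALSE
  )
}
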