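#' Read a tag-set definition file
#'
#' One tag label per line; blank lines and leading/trailing whitespace are
#' ignored. The MedPost-style 60-tag set used for biomedical corpora ships
#' with the package (see the example).
#'
#' @param path Path to the tag-set file.
#' @return A character vector of unique tag labels, in file order.
#' @examples
#' tags <- read_tagset(system.file("extdata", "tagset_medpost.txt", package = "tritag"))
#' length(tags)
#' @export
read_tagset <- function(path) {
  tags <- trimws(readLines(path, warn = FALSE))
  tags <- tags[nzchar(tags)]
  validate_tagset(tags)
  tags
}

validate_tagset <- function(tags) {
  if (length(tags) < 1L) stop("tag set must contain at least one tag")
  if (anyDuplicated(tags)) stop("tag set contains duplicated labels: ",
                                paste(unique(tags[duplicated(tags)]), collapse = ", "))
  if (any(!nzchar(tags)) || any(grepl("[[:space:]]", tags)))
    stop("tag labels must be non-empty and contain no whitespace")
  invisible(tags)
}

#' Construct a tagged sentence
#'
#' @param words,tags Equal-length character vectors of token texts and tag labels.
#' @return A list with elements `words` and `tags`.
#' @export
tagged_sentence <- function(words, tags) {
  stopifnot(length(words) == length(tags), length(words) >= 1L)
  list(words = as.character(words), tags = as.character(tags))
}

#' Read a tagged corpus in `word_TAG` / `word/TAG` format
#'
#' One sentence per line; each whitespace-separated token is a word and its
#' tag joined by the dialect separator. The separator is taken at its last
#' occurrence in the token, so words containing the separator character
#' survive (e.g. `p53/p21/NN` in the slash dialect).
#'
#' @param path Path to the corpus file.
#' @param dialect `"underscore"` (`word_TAG`) or `"slash"` (`word/TAG`).
#' @param tagset Optional character vector of admissible tags; when given,
#'   any unknown tag aborts with an error naming it.
#' @return A list of tagged sentences (see [tagged_sentence()]).
#' @export
read_tagged_corpus <- function(path, dialect = c("underscore", "slash"), tagset = NULL) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "underscore") "_" else "/"
  lines <- readLines(path, warn = FALSE)
  out <- vector("list", length(lines))
  kept <- logical(length(lines))
  rx <- paste0("^(.*)\\", sep, "([^\\", sep, "]+)$")
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line)) next
    toks <- strsplit(line, "[[:space:]]+")[[1]]
    bad <- !grepl(rx, toks)
    if (any(bad)) {
      stop(sprintf("line %d: token '%s' has no '%s' separator", i, toks[bad][1], sep))
    }
    words <- sub(rx, "\\1", toks)
    tags <- sub(rx, "\\2", toks)
    if (any(!nzchar(words))) {
      stop(sprintf("line %d: token '%s' has an empty word part", i, toks[!nzchar(words)][1]))
    }
    if (!is.null(tagset)) {
      unknown <- setdiff(tags, tagset)
      if (length(unknown) > 0L) {
        stop(sprintf("line %d: unknown tag '%s'", i, unknown[1]))
      }
    }
    out[[i]] <- tagged_sentence(words, tags)
    kept[i] <- TRUE
  }
  out[kept]
}

#' Write a tagged corpus
#'
#' Inverse of [read_tagged_corpus()]: one sentence per line, tokens
#' space-separated, each token `word<sep>TAG`.
#'
#' @inheritParams read_tagged_corpus
#' @param corpus A list of tagged sentences.
#' @export
write_tagged_corpus <- function(corpus, path, dialect = c("underscore", "slash")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "underscore") "_" else "/"
  lines <- vapply(corpus, function(s) paste(paste0(s$words, sep, s$tags), collapse = " "),
                  character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Build the lexicon table from a tagged corpus
#'
#' Counts how often each surface form occurs with each tag and derives the
#' per-tag totals that feed the word-given-tag maximum-likelihood
#' estimates. Surface case is preserved; case-independent lookup is a view
#' ([lookup_case_independent()]), not a transformation of the table.
#'
#' @param corpus A list of tagged sentences.
#' @param tags The tag set (character vector); every corpus tag must belong to it.
#' @return A `lexicon_table` object.
#' @export
build_lexicon <- function(corpus, tags) {
  if (length(corpus) == 0L) stop("cannot build a lexicon from an empty corpus")
  validate_tagset(tags)
  word <- unlist(lapply(corpus, `[[`, "words"), use.names = FALSE)
  tag <- unlist(lapply(corpus, `[[`, "tags"), use.names = FALSE)
  unknown <- setdiff(tag, tags)
  if (length(unknown) > 0L) stop("corpus contains tags outside the tag set: ",
                                 paste(unknown, collapse = ", "))
  dt <- data.table::data.table(word = word, tag = tag)
  dt <- dt[, list(freq = .N), by = c("word", "tag")]
  lexicon_from_counts(dt, tags)
}

#' Build a lexicon table directly from (word, tag, freq) counts
#'
#' @param counts A data frame with columns `word`, `tag`, `freq`
#'   (positive integers; one row per word-tag pair).
#' @param tags The tag set.
#' @return A `lexicon_table` object.
#' @export
lexicon_from_counts <- function(counts, tags) {
  validate_tagset(tags)
  dt <- data.table::as.data.table(counts)[, c("word", "tag", "freq"), with = FALSE]
  if (nrow(dt) == 0L) stop("empty lexicon counts")
  if (any(dt$freq < 1)) stop("lexicon frequencies must be >= 1")
  if (anyDuplicated(dt, by = c("word", "tag")))
    stop("duplicated (word, tag) rows in lexicon counts")
  unknown <- setdiff(dt$tag, tags)
  if (length(unknown) > 0L) stop("counts contain tags outside the tag set: ",
                                 paste(unknown, collapse = ", "))
  data.table::setkeyv(dt, c("word", "tag"))
  env <- new.env(parent = emptyenv(), size = length(unique(dt$word)))
  for (grp in split(dt, by = "word")) {
    assign(grp$word[1], stats::setNames(as.numeric(grp$freq), grp$tag), envir = env)
  }
  wf <- dt[, list(total = sum(freq)), by = "word"]
  word_freq <- new.env(parent = emptyenv(), size = nrow(wf))
  for (i in seq_len(nrow(wf))) assign(wf$word[i], wf$total[i], envir = word_freq)
  lower <- new.env(parent = emptyenv())
  for (w in sort(unique(dt$word))) {
    lw <- tolower(w)
    assign(lw, c(get0(lw, envir = lower, ifnotfound = character(0)), w), envir = lower)
  }
  tt <- dt[, list(total = sum(freq)), by = "tag"]
  tag_totals <- stats::setNames(rep(0, length(tags)), tags)
  tag_totals[tt$tag] <- tt$total
  structure(
    list(dt = dt, env = env, word_freq = word_freq, lower = lower,
         tag_totals = tag_totals, tags = tags,
         smoothed = new.env(parent = emptyenv())),
    class = "lexicon_table"
  )
}

#' @export
print.lexicon_table <- function(x, ...) {
  cat(sprintf("<lexicon_table> %d word-tag pairs, %d distinct words, %d tags\n",
              nrow(x$dt), length(ls(x$env)), length(x$tags)))
  invisible(x)
}

#' Word-given-tag maximum-likelihood estimate from the lexicon
#'
#' `P(word | tag) = freq(word, tag) / sum_w freq(w, tag)`. Unseen pairs
#' (and tags with zero total) return 0.
#'
#' @param lex A `lexicon_table`.
#' @param word Token text (exact surface form).
#' @param tag A tag label from the lexicon's tag set.
#' @return A probability in `[0, 1]`.
#' @export
lexicon_mle <- function(lex, word, tag) {
  stopifnot(inherits(lex, "lexicon_table"))
  if (!tag %in% lex$tags) stop("tag '", tag, "' is not in the tag set")
  total <- lex$tag_totals[[tag]]
  if (total == 0) return(0)
  cnt <- get0(word, envir = lex$env, ifnotfound = NULL)
  if (is.null(cnt) || is.na(cnt[tag])) return(0)
  unname(cnt[tag]) / total
}

#' Case-independent lexicon lookup
#'
#' Returns the stored surface form whose lowercasing equals that of the
#' query. An exact-case match wins when several forms coexist; otherwise
#' the alphabetically first stored form is returned (deterministic).
#'
#' @param lex A `lexicon_table`.
#' @param word Query token text.
#' @return The matching stored word, or `NA_character_` when absent.
#' @export
lookup_case_independent <- function(lex, word) {
  stopifnot(inherits(lex, "lexicon_table"))
  forms <- get0(tolower(word), envir = lex$lower, ifnotfound = NULL)
  if (is.null(forms)) return(NA_character_)
  if (word %in% forms) word else forms[1]
}

#' Smoothed word-given-tag probabilities for a lexicon word
#'
#' Returns the full per-tag probability vector for a stored word: the
#' suffix-smoothed values when [smooth_known_word_unseen_tags()] has been
#' applied, otherwise the raw maximum-likelihood estimates.
#'
#' @param lex A `lexicon_table`.
#' @param word A stored surface form.
#' @return A named numeric vector over the tag set.
#' @export
lexicon_probs <- function(lex, word) {
  stopifnot(inherits(lex, "lexicon_table"))
  sm <- get0(word, envir = lex$smoothed, ifnotfound = NULL)
  if (!is.null(sm)) return(sm)
  out <- stats::setNames(rep(0, length(lex$tags)), lex$tags)
  cnt <- get0(word, envir = lex$env, ifnotfound = NULL)
  if (!is.null(cnt)) {
    tot <- lex$tag_totals[names(cnt)]
    out[names(cnt)] <- ifelse(tot > 0, cnt / tot, 0)
  }
  out
}
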