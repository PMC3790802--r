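# Character-feature strings summarise the type and order of characters in
# a word: "IL-2" -> "A-0". They carry the signal for unknown tokens with
# capitals, digits or symbols (gene symbols, identifiers, units), where
# suffix analysis is uninformative.

.is_greek_char <- function(code) {
  (code >= 0x0370 & code <= 0x03FF) | (code >= 0x1F00 & code <= 0x1FFF)
}

#' Map a word to its character-feature string
#'
#' Each character maps to a class symbol — uppercase ASCII letter to `A`,
#' lowercase to `a`, digit to `0`, Greek letter (U+0370–U+03FF,
#' U+1F00–U+1FFF) to `g`; the biologically salient separators `-`, `.`,
#' `/`, `(`, `)` are kept literally; any other symbol becomes `S`. Maximal
#' runs of the same symbol then collapse to one occurrence (so `p53` and
#' `p5321` share the feature `a0`), while adjacent distinct literals stay
#' distinct.
#'
#' @param word A non-empty character vector of token texts.
#' @return A character vector of feature strings.
#' @examples
#' feature_string(c("IL-2", "p53", "Abc", "kappaB"))
#' @export
feature_string <- function(word) {
  stopifnot(is.character(word))
  if (any(is.na(word)) || any(!nzchar(word))) stop("words must be non-empty")
  vapply(word, function(w) {
    chars <- strsplit(w, "", fixed = TRUE)[[1]]
    code <- utf8ToInt(w)
    sym <- character(length(chars))
    sym[code >= utf8ToInt("A") & code <= utf8ToInt("Z")] <- "A"
    sym[code >= utf8ToInt("a") & code <= utf8ToInt("z")] <- "a"
    sym[code >= utf8ToInt("0") & code <= utf8ToInt("9")] <- "0"
    sym[.is_greek_char(code)] <- "g"
    literal <- chars %in% c("-", ".", "/", "(", ")")
    sym[literal] <- chars[literal]
    sym[sym == ""] <- "S"
    paste(rle(sym)$values, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Build the character-feature table from a lexicon
#'
#' Each (word, tag) lexicon pair adds its corpus frequency to the row
#' `(feature_string(word), tag)`.
#'
#' @param lex A `lexicon_table`.
#' @return A `char_feature_table` object.
#' @export
build_char_table <- function(lex) {
  stopifnot(inherits(lex, "lexicon_table"))
  dt <- data.table::copy(lex$dt)
  dt[, "feature" := feature_string(word)]
  rows <- dt[, list(count = as.integer(sum(freq))), by = c("feature", "tag")]
  char_table_from_rows(rows, tags = lex$tags)
}

#' Assemble a character-feature table from explicit rows
#'
#' @param rows A data frame with columns `feature`, `tag`, `count`.
#' @param tags The tag set.
#' @return A `char_feature_table` object.
#' @export
char_table_from_rows <- function(rows, tags) {
  validate_tagset(tags)
  dt <- data.table::as.data.table(rows)[, c("feature", "tag", "count"), with = FALSE]
  if (nrow(dt) == 0L) stop("empty character-feature rows")
  if (any(dt$count < 1L)) stop("counts must be >= 1")
  unknown <- setdiff(dt$tag, tags)
  if (length(unknown) > 0L) stop("rows contain tags outside the tag set: ",
                                 paste(unknown, collapse = ", "))
  data.table::setkeyv(dt, c("feature", "tag"))
  env <- new.env(parent = emptyenv(), size = length(unique(dt$feature)))
  for (grp in split(dt, by = "feature")) {
    assign(grp$feature[1], stats::setNames(as.numeric(grp$count), grp$tag), envir = env)
  }
  tt <- dt[, list(total = sum(count)), by = "tag"]
  tag_totals <- stats::setNames(rep(0, length(tags)), tags)
  tag_totals[tt$tag] <- tt$total
  structure(list(dt = dt, env = env, tag_totals = tag_totals, tags = tags),
            class = "char_feature_table")
}

#' @export
print.char_feature_table <- function(x, ...) {
  cat(sprintf("<char_feature_table> %d feature-tag pairs, %d distinct features\n",
              nrow(x$dt), length(ls(x$env))))
  invisible(x)
}

#' Feature-conditional word probability
#'
#' `P(word's feature | tag) = count(feature_string(word), tag) /
#' total(tag)`; 0 when the feature or tag is unrepresented.
#'
#' @param table A `char_feature_table`.
#' @param word A token text.
#' @param tag A tag label.
#' @return A probability in `[0, 1]`.
#' @export
char_mle <- function(table, word, tag) {
  stopifnot(inherits(table, "char_feature_table"))
  if (!tag %in% table$tags) stop("tag '", tag, "' is not in the tag set")
  char_probs(table, word)[[tag]]
}

#' @rdname char_mle
#' @description `char_probs()` returns the estimate for every tag at once.
#' @export
char_probs <- function(table, word) {
  stopifnot(inherits(table, "char_feature_table"), nzchar(word))
  tags <- table$tags
  out <- stats::setNames(rep(0, length(tags)), tags)
  cnt <- get0(feature_string(word), envir = table$env, ifnotfound = NULL)
  if (!is.null(cnt)) {
    tot <- table$tag_totals[names(cnt)]
    out[names(cnt)] <- ifelse(tot > 0, cnt / tot, 0)
  }
  out
}

#' Export a character-feature table as TSV
#'
#' @param table A `char_feature_table`.
#' @param path File path.
#' @export
write_char_table <- function(table, path) {
  stopifnot(inherits(table, "char_feature_table"))
  utils::write.table(table$dt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
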