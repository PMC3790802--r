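# The suffix table is the backbone of unknown-word prediction: for every
# proper suffix (length 1..L_max) of every all-alphabetic lexicon word it
# stores two counts. freq_1 counts word types (each lexicon word-tag row
# contributes 1), freq_n counts word tokens (each row contributes its
# corpus frequency). Because every word that ends in "ing" also ends in
# "ng" and "g", counts are cumulative in suffix length.

.norm_counting <- function(counting) {
  if (length(counting) != 1L) stop("counting method must be a scalar")
  key <- as.character(counting)
  out <- c("1" = "freq_1", "2" = "freq_n",
           "freq_1" = "freq_1", "freq_n" = "freq_n")[key]
  if (is.na(out)) stop("unknown counting method: ", key,
                       " (use 1/'freq_1' or 2/'freq_n')")
  unname(out)
}

.is_alphabetic <- function(word) {
  grepl(paste0("(*UTF)^[", .letter_class, "]+$"), word, perl = TRUE)
}

#' Build the suffix frequency table from a lexicon
#'
#' For every all-alphabetic lexicon word (pattern-like and symbol-bearing
#' tokens are handled by the pattern and character-feature branches
#' downstream) and every proper suffix length `i` in `1..min(L_max,
#' nchar(word) - 1)`, the row `(suffix, tag)` gains 1 under `freq_1` and
#' the word's lexicon frequency under `freq_n`. Words are lowercased
#' before suffix extraction, since suffix analysis serves all-lowercase
#' unknowns.
#'
#' @param lex A `lexicon_table`.
#' @param L_max Maximum suffix length (default 5).
#' @return A `suffix_table` object.
#' @export
build_suffix_table <- function(lex, L_max = 5L) {
  stopifnot(inherits(lex, "lexicon_table"), L_max >= 1L)
  dt <- lex$dt[.is_alphabetic(word) & classify_pattern(word) == "none"]
  if (nrow(dt) == 0L) stop("no alphabetic words in lexicon; cannot build suffix table")
  pieces <- vector("list", L_max)
  wl <- tolower(dt$word)
  nc <- nchar(wl)
  for (i in seq_len(L_max)) {
    keep <- nc - 1L >= i
    if (!any(keep)) break
    pieces[[i]] <- data.table::data.table(
      suffix = substring(wl[keep], nc[keep] - i + 1L, nc[keep]),
      tag = dt$tag[keep],
      f1 = 1L,
      fn = dt$freq[keep]
    )
  }
  rows <- data.table::rbindlist(pieces[!vapply(pieces, is.null, logical(1))])
  rows <- rows[, list(freq_1 = sum(f1), freq_n = as.integer(sum(fn))),
               by = c("suffix", "tag")]
  suffix_table_from_rows(rows, tags = lex$tags, L_max = L_max)
}

#' Assemble a suffix table from explicit (suffix, tag, freq_1, freq_n) rows
#'
#' Low-level constructor used by [build_suffix_table()], by the TSV reader
#' and by tests that need hand-specified tables.
#'
#' @param rows A data frame with columns `suffix`, `tag`, `freq_1`, `freq_n`.
#' @param tags The tag set.
#' @param L_max Maximum suffix length.
#' @return A `suffix_table` object.
#' @export
suffix_table_from_rows <- function(rows, tags, L_max = 5L) {
  validate_tagset(tags)
  dt <- data.table::as.data.table(rows)[, c("suffix", "tag", "freq_1", "freq_n"), with = FALSE]
  if (any(nchar(dt$suffix) < 1L) || any(nchar(dt$suffix) > L_max))
    stop("suffix lengths must lie in [1, L_max]")
  if (any(dt$freq_1 < 1L) || any(dt$freq_n < dt$freq_1))
    stop("rows must satisfy freq_n >= freq_1 >= 1")
  unknown <- setdiff(dt$tag, tags)
  if (length(unknown) > 0L) stop("rows contain tags outside the tag set: ",
                                 paste(unknown, collapse = ", "))
  data.table::setkeyv(dt, c("suffix", "tag"))
  env <- new.env(parent = emptyenv(), size = length(unique(dt$suffix)))
  for (grp in split(dt, by = "suffix")) {
    assign(grp$suffix[1], list(
      freq_1 = stats::setNames(as.numeric(grp$freq_1), grp$tag),
      freq_n = stats::setNames(as.numeric(grp$freq_n), grp$tag),
      total_1 = sum(grp$freq_1),
      total_n = sum(grp$freq_n)
    ), envir = env)
  }
  zero <- stats::setNames(rep(0, length(tags)), tags)
  agg <- function(values) {
    s <- tapply(values, dt$tag, sum)
    out <- zero
    out[names(s)] <- s
    out
  }
  len1 <- nchar(dt$suffix) == 1L
  len1_tag <- function(values) {
    if (!any(len1)) return(zero)
    s <- tapply(values[len1], dt$tag[len1], sum)
    out <- zero
    out[names(s)] <- s
    out
  }
  tag_totals_1 <- agg(dt$freq_1); tag_totals_n <- agg(dt$freq_n)
  len1_tag_1 <- len1_tag(dt$freq_1); len1_tag_n <- len1_tag(dt$freq_n)
  p_tag <- function(v) if (sum(v) > 0) v / sum(v) else v
  structure(
    list(dt = dt, env = env, L_max = as.integer(L_max), tags = tags,
         tag_totals = list(freq_1 = tag_totals_1, freq_n = tag_totals_n),
         len1_tag = list(freq_1 = len1_tag_1, freq_n = len1_tag_n),
         len1_total = list(freq_1 = sum(len1_tag_1), freq_n = sum(len1_tag_n)),
         grand_total = list(freq_1 = sum(tag_totals_1), freq_n = sum(tag_totals_n)),
         p_tag = list(freq_1 = p_tag(len1_tag_1), freq_n = p_tag(len1_tag_n))),
    class = "suffix_table"
  )
}

#' @export
print.suffix_table <- function(x, ...) {
  cat(sprintf("<suffix_table> %d suffix-tag pairs, %d distinct suffixes, L_max = %d\n",
              nrow(x$dt), length(ls(x$env)), x$L_max))
  invisible(x)
}

#' Export / import a suffix table as TSV
#'
#' Columns `suffix`, `tag`, `freq_1`, `freq_n`, tab-separated, for
#' inspection or for shipping small hand-built tables.
#'
#' @param table A `suffix_table`.
#' @param path File path.
#' @export
write_suffix_table <- function(table, path) {
  stopifnot(inherits(table, "suffix_table"))
  utils::write.table(table$dt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_suffix_table
#' @param tags Tag set for the imported table; defaults to the tags present.
#' @param L_max Maximum suffix length of the imported table.
#' @export
read_suffix_table <- function(path, tags = NULL, L_max = 5L) {
  rows <- utils::read.table(path, sep = "\t", header = TRUE,
                            colClasses = c("character", "character", "integer", "integer"))
  if (is.null(tags)) tags <- unique(rows$tag)
  suffix_table_from_rows(rows, tags = tags, L_max = L_max)
}

#' Tag-given-suffix maximum-likelihood estimate
#'
#' `P(tag | suffix) = freq(suffix, tag) / sum_t freq(suffix, t)` under the
#' chosen counting method — the proportion of (type- or token-counted)
#' words carrying `suffix` that bear `tag`. A suffix with no rows at all
#' returns 0.
#'
#' @param table A `suffix_table`.
#' @param tag A tag label.
#' @param suffix A suffix string of length in `[1, L_max]`.
#' @param counting `"freq_1"`/1 (word types) or `"freq_n"`/2 (word tokens).
#' @return A probability in `[0, 1]`.
#' @export
suffix_mle <- function(table, tag, suffix, counting = "freq_1") {
  stopifnot(inherits(table, "suffix_table"))
  counting <- .norm_counting(counting)
  if (nchar(suffix) < 1L || nchar(suffix) > table$L_max)
    stop("suffix length must lie in [1, L_max]")
  row <- get0(suffix, envir = table$env, ifnotfound = NULL)
  if (is.null(row)) return(0)
  num <- row[[counting]][tag]
  if (is.na(num)) return(0)
  den <- if (counting == "freq_1") row$total_1 else row$total_n
  unname(num) / den
}

#' Unconditional tag distribution of a suffix table
#'
#' `P(tag)` estimated from the length-1 rows (the maximal, cumulative
#' suffix mass per tag).
#'
#' @inheritParams suffix_mle
#' @return A named probability vector over the tag set.
#' @export
suffix_p_tag <- function(table, counting = "freq_1") {
  stopifnot(inherits(table, "suffix_table"))
  table$p_tag[[.norm_counting(counting)]]
}

#' Estimate the interpolation weight theta
#'
#' The recursion weight is the sample standard deviation (divisor `k - 1`,
#' mean `1/k`) of the unconditional tag probabilities `P(tag)` over the
#' `k` tags of the tag set. Theta is context-free: one value serves all
#' suffixes and tags. The derived convex weights are
#' `lambda1 = 1/(1 + theta)` for the current-level estimate's complement
#' structure and `lambda2 = theta/(1 + theta)` for the shorter-suffix
#' carry-over.
#'
#' @inheritParams suffix_mle
#' @param depth_method Interpolation depth method (1, 2 or 3), stored for
#'   downstream use; see [interpolate_tag_given_suffix()].
#' @param L_max Maximum suffix length recorded in the parameters.
#' @return An `interpolation_params` object with fields `theta`, `lambda1`,
#'   `lambda2`, `counting`, `depth_method`, `L_max`.
#' @export
estimate_theta <- function(table, counting = "freq_1", depth_method = 3L,
                           L_max = table$L_max) {
  stopifnot(inherits(table, "suffix_table"))
  counting <- .norm_counting(counting)
  k <- length(table$tags)
  theta <- if (k <= 1L) 0 else {
    p <- table$p_tag[[counting]]
    sqrt(sum((p - 1 / k)^2) / (k - 1))
  }
  interpolation_params(theta, counting = counting, depth_method = depth_method,
                       L_max = L_max)
}

#' @rdname estimate_theta
#' @param theta A non-negative interpolation weight.
#' @export
interpolation_params <- function(theta, counting = "freq_1", depth_method = 3L,
                                 L_max = 5L) {
  stopifnot(theta >= 0, depth_method %in% 1:3)
  structure(
    list(theta = theta, lambda1 = 1 / (1 + theta), lambda2 = theta / (1 + theta),
         counting = .norm_counting(counting), depth_method = as.integer(depth_method),
         L_max = as.integer(L_max)),
    class = "interpolation_params"
  )
}

#' Mark the suffix-versus-tag grid for one word
#'
#' For suffix lengths `i = 1..min(L_max, nchar(word) - 1)` and every tag,
#' records whether the row `(last i characters of word, tag)` exists in the
#' table, plus the per-tag maximal marked length (0 when no length is
#' marked). Matching is done on the lowercased word. For tables built by
#' [build_suffix_table()] the marks are downward-closed per tag.
#'
#' @param table A `suffix_table`.
#' @param word A non-empty token text.
#' @return A `suffix_grid` object: logical matrix `grid` (lengths x tags),
#'   integer vector `max_len` per tag, `n_lengths`, `word`.
#' @export
mark_suffix_grid <- function(table, word) {
  stopifnot(inherits(table, "suffix_table"), nzchar(word))
  wl <- tolower(word)
  n <- min(table$L_max, nchar(wl) - 1L)
  tags <- table$tags
  grid <- matrix(FALSE, nrow = max(n, 0L), ncol = length(tags),
                 dimnames = list(NULL, tags))
  if (n >= 1L) {
    for (i in seq_len(n)) {
      row <- get0(substring(wl, nchar(wl) - i + 1L), envir = table$env, ifnotfound = NULL)
      if (!is.null(row)) grid[i, names(row$freq_1)] <- row$freq_1 > 0
    }
  }
  max_len <- apply(grid, 2L, function(col) if (any(col)) max(which(col)) else 0L)
  if (n == 0L) max_len <- stats::setNames(rep(0L, length(tags)), tags)
  structure(list(grid = grid, max_len = as.integer(max_len) |> stats::setNames(tags),
                 n_lengths = n, word = word),
            class = "suffix_grid")
}

# Interpolation depth for one word under the three depth methods:
# 1 — deepest word-suffix length with any table row (any tag);
# 2 — min(L_max, nchar - 1) always, rows or not;
# 3 — the per-tag maximal marked grid length (0 allowed).
.interp_depth <- function(table, word, tag, depth_method) {
  wl <- tolower(word)
  n <- min(table$L_max, nchar(wl) - 1L)
  if (n < 1L) return(0L)
  if (depth_method == 2L) return(n)
  if (depth_method == 1L) {
    for (i in rev(seq_len(n))) {
      if (!is.null(get0(substring(wl, nchar(wl) - i + 1L), envir = table$env,
                        ifnotfound = NULL))) return(i)
    }
    return(0L)
  }
  # method 3: deepest length marked for this tag
  for (i in rev(seq_len(n))) {
    row <- get0(substring(wl, nchar(wl) - i + 1L), envir = table$env, ifnotfound = NULL)
    if (!is.null(row) && !is.na(row$freq_1[tag])) return(i)
  }
  0L
}

#' Interpolation depth used for a word (and tag)
#'
#' Exposes the recursion depth that [interpolate_tag_given_suffix()] will
#' use: the deepest suffix level with any table entry (method 1), the full
#' `min(L_max, nchar - 1)` (method 2), or the deepest level with an entry
#' for `tag` (method 3; 0 when none).
#'
#' @inheritParams interpolate_tag_given_suffix
#' @return An integer depth `>= 0`.
#' @export
interpolation_depth <- function(table, word, tag = NULL, params) {
  stopifnot(inherits(table, "suffix_table"), inherits(params, "interpolation_params"))
  if (params$depth_method == 3L && is.null(tag))
    stop("depth method 3 requires a tag")
  .interp_depth(table, word, tag, params$depth_method)
}

#' Recursive tag-given-suffix probability interpolation
#'
#' The TnT-style recursion blends tag-given-suffix estimates from short to
#' long suffixes: starting from `P_0 = P(tag)` (the unconditional tag
#' probability), each level applies
#' `P_i = (p_mle(tag | s_i) + theta * P_{i-1}) / (1 + theta)`, where `s_i`
#' is the last `i` characters of the (lowercased) word. The final level is
#' chosen by the depth method in `params` (see [interpolation_depth()]);
#' levels whose suffix has no table row contribute `p_mle = 0`. With
#' `theta = 0` the recursion collapses to the deepest-level estimate; a
#' depth of 0 returns `P(tag)` itself.
#'
#' @param table A `suffix_table`.
#' @param word A non-empty token text.
#' @param tag A tag label.
#' @param params An `interpolation_params` object.
#' @return A probability `P(tag | suffix evidence of word)`.
#' @export
interpolate_tag_given_suffix <- function(table, word, tag, params) {
  stopifnot(inherits(table, "suffix_table"), inherits(params, "interpolation_params"),
            nzchar(word))
  counting <- params$counting
  wl <- tolower(word)
  depth <- .interp_depth(table, word, tag, params$depth_method)
  p <- table$p_tag[[counting]][tag]
  if (is.na(p)) stop("tag '", tag, "' is not in the tag set")
  p <- unname(p)
  if (depth < 1L) return(p)
  theta <- params$theta
  for (i in seq_len(depth)) {
    s <- substring(wl, nchar(wl) - i + 1L)
    row <- get0(s, envir = table$env, ifnotfound = NULL)
    pm <- 0
    if (!is.null(row)) {
      num <- row[[counting]][tag]
      if (!is.na(num)) {
        den <- if (counting == "freq_1") row$total_1 else row$total_n
        pm <- unname(num) / den
      }
    }
    p <- (pm + theta * p) / (1 + theta)
  }
  p
}

#' Invert a tag-given-suffix probability to a word-given-tag score
#'
#' Bayesian inversion `P(suffix | tag) = P(tag | suffix) * P(suffix) /
#' P(tag)`, with `P(tag)` the tag's share of all suffix-table rows and
#' `P(suffix)` the share held by the length-1 rows — a per-word constant,
#' so only the per-tag relative values matter in the decoder's argmax.
#'
#' @param p_tag_given_suffix The interpolated `P(tag | suffix)`.
#' @param table A `suffix_table`.
#' @param tag A tag label.
#' @param counting Counting method (see [suffix_mle()]).
#' @return A non-negative emission score (0 when the tag has no suffix mass).
#' @export
invert_to_word_given_tag <- function(p_tag_given_suffix, table, tag,
                                     counting = "freq_1") {
  stopifnot(inherits(table, "suffix_table"))
  counting <- .norm_counting(counting)
  tt <- table$tag_totals[[counting]][tag]
  if (is.na(tt)) stop("tag '", tag, "' is not in the tag set")
  if (tt == 0) return(0)
  p_tag_given_suffix * table$len1_total[[counting]] / unname(tt)
}

#' Maximum-suffix-length (MSL) word-given-tag estimate
#'
#' For each tag, uses only the longest suffix of the word that has a table
#' row for that tag: `P(word | tag) = freq(s_t, tag) / N(tag)` where `s_t`
#' is that suffix and `N(tag)` is the tag's length-1 suffix mass (its
#' maximal, cumulative word mass). Returns 0 when no suffix of the word
#' has a row for the tag.
#'
#' @inheritParams interpolate_tag_given_suffix
#' @param counting Counting method (see [suffix_mle()]).
#' @return A probability in `[0, 1]`.
#' @export
msl_word_given_tag <- function(table, word, tag, counting = "freq_1") {
  stopifnot(inherits(table, "suffix_table"), nzchar(word))
  counting <- .norm_counting(counting)
  if (!tag %in% table$tags) stop("tag '", tag, "' is not in the tag set")
  msl_vector(table, word, counting)[[tag]]
}

#' @rdname msl_word_given_tag
#' @description `msl_vector()` returns the MSL estimate for every tag at once.
#' @export
msl_vector <- function(table, word, counting = "freq_1") {
  stopifnot(inherits(table, "suffix_table"), nzchar(word))
  counting <- .norm_counting(counting)
  tags <- table$tags
  out <- stats::setNames(rep(0, length(tags)), tags)
  wl <- tolower(word)
  n <- min(table$L_max, nchar(wl) - 1L)
  if (n < 1L) return(out)
  N1 <- table$len1_tag[[counting]]
  todo <- stats::setNames(rep(TRUE, length(tags)), tags)
  for (i in rev(seq_len(n))) {
    row <- get0(substring(wl, nchar(wl) - i + 1L), envir = table$env, ifnotfound = NULL)
    if (is.null(row)) next
    hit <- names(row[[counting]])
    hit <- hit[todo[hit]]
    if (length(hit) > 0L) {
      out[hit] <- ifelse(N1[hit] > 0, row[[counting]][hit] / N1[hit], 0)
      todo[hit] <- FALSE
    }
    if (!any(todo)) break
  }
  out
}

#' Smooth known words' unseen tags with suffix evidence
#'
#' A small training corpus leaves many plausible (word, tag) pairs unseen:
#' a word recorded only as a noun may well occur as an adjective. For every
#' lexicon word and every tag with zero lexicon count but positive MSL
#' suffix support, the smoothed probability is set to
#' `beta * msl_word_given_tag(word, tag)`; seen tags keep their
#' maximum-likelihood values. Original counts are untouched; the result is
#' a new lexicon whose [lexicon_probs()] return the smoothed vectors.
#'
#' @param lex A `lexicon_table`.
#' @param table A `suffix_table` built from the same corpus.
#' @param params An `interpolation_params` object (its counting method is
#'   used for the MSL estimates).
#' @param beta Unseen-tag discount in `[0, 1]` (default 0.1); `beta = 0`
#'   leaves the probabilities identical to the MLE.
#' @return A new `lexicon_table` with a populated `smoothed` slot.
#' @export
smooth_known_word_unseen_tags <- function(lex, table, params, beta = 0.1) {
  stopifnot(inherits(lex, "lexicon_table"), inherits(table, "suffix_table"),
            inherits(params, "interpolation_params"), beta >= 0, beta <= 1)
  counting <- params$counting
  tags <- lex$tags
  smoothed <- new.env(parent = emptyenv(), size = length(ls(lex$env)))
  for (w in ls(lex$env)) {
    cnt <- get(w, envir = lex$env)
    probs <- stats::setNames(rep(0, length(tags)), tags)
    tot <- lex$tag_totals[names(cnt)]
    probs[names(cnt)] <- ifelse(tot > 0, cnt / tot, 0)
    if (beta > 0) {
      ms <- msl_vector(table, w, counting)
      unseen <- setdiff(tags[ms > 0], names(cnt))
      probs[unseen] <- beta * ms[unseen]
    }
    assign(w, probs, envir = smoothed)
  }
  out <- lex
  out$smoothed <- smoothed
  out
}
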