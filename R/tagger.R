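#' Tagger configuration
#'
#' Bundles the tunable parameters of the tagger. `suffix_method` selects
#' the unknown-word suffix predictor: `"msl"` (maximum suffix length, the
#' default) or `"interpolation"` (recursive interpolation followed by
#' Bayesian inversion). `counting` picks the suffix counting method
#' (`"freq_1"`/1 word types, `"freq_n"`/2 word tokens),
#' `interpolation_method` the interpolation depth method (1, 2 or 3).
#' `beta_unseen` is the discount applied when suffix evidence adds a tag a
#' known word was never seen with. `pattern_tags` maps the surface-pattern
#' kinds (`number`, `number_range`, `ordinal`) to tags; when `NULL`, all
#' three map to the tag `"MC"` if the tag set has it (the MedPost cardinal
#' number tag), otherwise pattern tokens fall through to the
#' character-feature branch.
#'
#' @param max_suffix_len Maximum suffix length (default 5).
#' @param counting Suffix counting method (default `"freq_n"`).
#' @param interpolation_method Interpolation depth method in `1:3` (default 3).
#' @param suffix_method `"msl"` or `"interpolation"`.
#' @param beta_unseen Unseen-tag discount in `[0, 1]` (default 0.1).
#' @param pattern_tags Named character vector or `NULL`.
#' @return A `tagger_config` list.
#' @export
tagger_config <- function(max_suffix_len = 5L, counting = "freq_n",
                          interpolation_method = 3L,
                          suffix_method = c("msl", "interpolation"),
                          beta_unseen = 0.1, pattern_tags = NULL) {
  suffix_method <- match.arg(suffix_method)
  stopifnot(interpolation_method %in% 1:3, beta_unseen >= 0, beta_unseen <= 1,
            max_suffix_len >= 1L)
  structure(
    list(max_suffix_len = as.integer(max_suffix_len),
         counting = .norm_counting(counting),
         interpolation_method = as.integer(interpolation_method),
         suffix_method = suffix_method,
         beta_unseen = beta_unseen,
         pattern_tags = pattern_tags),
    class = "tagger_config"
  )
}

.resolve_pattern_tags <- function(tags, config) {
  pt <- config$pattern_tags
  if (is.null(pt)) {
    if ("MC" %in% tags) {
      pt <- c(number = "MC", number_range = "MC", ordinal = "MC")
    } else {
      pt <- character(0)
    }
  }
  bad <- setdiff(pt, tags)
  if (length(bad) > 0L) stop("pattern tags outside the tag set: ",
                             paste(bad, collapse = ", "))
  pt
}

#' Train a trigram HMM part-of-speech tagger
#'
#' Builds every table the tagger needs from one tagged corpus: the lexicon
#' (word-given-tag MLE), the suffix table and its interpolation weight
#' theta, the character-feature table, and the deleted-interpolation
#' trigram transition model; then smooths known words' unseen tags with
#' suffix evidence.
#'
#' @param corpus A list of tagged sentences (see [read_tagged_corpus()]).
#' @param tags The tag set.
#' @param config A [tagger_config()].
#' @return A `pos_tagger` model object.
#' @export
train_pos_tagger <- function(corpus, tags, config = tagger_config()) {
  stopifnot(inherits(config, "tagger_config"))
  validate_tagset(tags)
  lex <- build_lexicon(corpus, tags)
  suffix <- build_suffix_table(lex, L_max = config$max_suffix_len)
  params <- estimate_theta(suffix, counting = config$counting,
                           depth_method = config$interpolation_method)
  lex <- smooth_known_word_unseen_tags(lex, suffix, params, beta = config$beta_unseen)
  char <- build_char_table(lex)
  trans <- build_transition_model(corpus, tags)
  structure(
    list(tags = tags, lexicon = lex, suffix = suffix, char = char,
         transitions = trans, params = params, config = config,
         pattern_tags = .resolve_pattern_tags(tags, config)),
    class = "pos_tagger"
  )
}

#' @export
print.pos_tagger <- function(x, ...) {
  cat(sprintf(paste0(
    "<pos_tagger> %d tags; %d word-tag pairs; %d suffix-tag pairs; ",
    "%d feature-tag pairs\n  suffix method: %s (counting %s, depth method %d), ",
    "theta = %.4f\n"),
    length(x$tags), nrow(x$lexicon$dt), nrow(x$suffix$dt), nrow(x$char$dt),
    x$config$suffix_method, x$config$counting, x$config$interpolation_method,
    x$params$theta))
  invisible(x)
}

#' Emission probabilities for one token
#'
#' Resolves `P(word | tag)` for every tag through the emission cascade;
#' exactly one branch fires per token:
#' \enumerate{
#'   \item case-independent lexicon hit: the smoothed lexicon probabilities;
#'   \item known surface pattern (number, range, ordinal) with a configured
#'     pattern tag: an indicator on that tag;
#'   \item token with capitals, digits, Greek letters or symbols: the
#'     character-feature estimate;
#'   \item all-lowercase unknown word: the configured suffix predictor
#'     (MSL, or interpolation plus Bayesian inversion).
#' }
#' An all-zero result falls back to the uniform distribution over tags so
#' a single exotic token cannot annihilate every path (reported via
#' `message()` when `options(tritag.verbose = TRUE)`).
#'
#' @param model A `pos_tagger`.
#' @param word A token text.
#' @param suffix_method,counting,interpolation_method Optional overrides of
#'   the model's configuration (used by the comparison harness).
#' @return A named probability vector over the tag set, with attributes
#'   `"branch"` (`"lexicon"`, `"pattern"`, `"char_feature"` or `"suffix"`)
#'   and `"uniform_fallback"`.
#' @export
emission_probs <- function(model, word, suffix_method = NULL, counting = NULL,
                           interpolation_method = NULL) {
  stopifnot(inherits(model, "pos_tagger"), nzchar(word))
  tags <- model$tags
  k <- length(tags)
  suffix_method <- suffix_method %||% model$config$suffix_method
  counting <- .norm_counting(counting %||% model$config$counting)
  interpolation_method <- interpolation_method %||% model$config$interpolation_method

  hit <- lookup_case_independent(model$lexicon, word)
  if (!is.na(hit)) {
    v <- lexicon_probs(model$lexicon, hit)
    branch <- "lexicon"
  } else {
    pat <- classify_pattern(word)
    pt <- model$pattern_tags
    if (pat != "none" && pat %in% names(pt)) {
      v <- stats::setNames(rep(0, k), tags)
      v[pt[[pat]]] <- 1
      branch <- "pattern"
    } else if (!is_all_lower(word)) {
      v <- char_probs(model$char, word)
      branch <- "char_feature"
    } else {
      v <- .suffix_emission(model, word, suffix_method, counting, interpolation_method)
      branch <- "suffix"
    }
  }
  fallback <- FALSE
  if (all(v == 0)) {
    v <- stats::setNames(rep(1 / k, k), tags)
    fallback <- TRUE
    if (isTRUE(getOption("tritag.verbose", FALSE)))
      message("uniform emission fallback for token '", word, "' (branch ", branch, ")")
  }
  structure(v, branch = branch, uniform_fallback = fallback)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.suffix_emission <- function(model, word, suffix_method, counting,
                             interpolation_method) {
  tbl <- model$suffix
  if (suffix_method == "msl") return(msl_vector(tbl, word, counting))
  params <- interpolation_params(model$params$theta, counting = counting,
                                 depth_method = interpolation_method,
                                 L_max = tbl$L_max)
  tags <- model$tags
  p <- vapply(tags, function(t) interpolate_tag_given_suffix(tbl, word, t, params),
              numeric(1))
  tt <- tbl$tag_totals[[counting]]
  out <- ifelse(tt > 0, p * tbl$len1_total[[counting]] / tt, 0)
  stats::setNames(out, tags)
}

#' Viterbi-decode one tokenized sentence
#'
#' Computes the emission matrix through the cascade of [emission_probs()]
#' and returns the maximum-probability tag sequence under the trigram
#' transition model (see [viterbi_path()] for the decoding core).
#'
#' @param model A `pos_tagger`.
#' @param sentence A non-empty character vector of token texts.
#' @return A character vector of tags with attribute `"logscore"`.
#' @export
viterbi <- function(model, sentence) {
  stopifnot(inherits(model, "pos_tagger"))
  if (length(sentence) < 1L) stop("cannot decode an empty sentence")
  em <- vapply(sentence, function(w) as.numeric(emission_probs(model, w)),
               numeric(length(model$tags)))
  em <- matrix(em, nrow = length(model$tags))
  viterbi_path(model$transitions, em)
}

#' Tag tokenized sentences
#'
#' @param model A `pos_tagger`.
#' @param sentences A list of character vectors of token texts.
#' @return A list of tagged sentences.
#' @export
tag_sentences <- function(model, sentences) {
  lapply(sentences, function(s) tagged_sentence(s, as.character(viterbi(model, s))))
}

#' Tokenize and tag raw text
#'
#' @param model A `pos_tagger`.
#' @param text A character scalar of raw text.
#' @return A list of tagged sentences (empty for empty input).
#' @export
tag_text <- function(model, text) {
  tag_sentences(model, tokenize(text))
}

#' Serialize / restore a trained tagger
#'
#' Writes the model as one versioned JSON archive: tag set, configuration,
#' lexicon counts, smoothed probabilities, suffix and character-feature
#' rows, and the boundary-padded n-gram counts. Integer counts round-trip
#' exactly; the derived structures (environments, interpolation weights,
#' transition mixture) are rebuilt on load.
#'
#' @param model A `pos_tagger`.
#' @param path File path for the JSON archive.
#' @export
save_tagger <- function(model, path) {
  stopifnot(inherits(model, "pos_tagger"))
  sm <- as.list(model$lexicon$smoothed)
  smoothed <- if (length(sm) > 0) {
    data.frame(
      word = rep(names(sm), each = length(model$tags)),
      tag = rep(model$tags, times = length(sm)),
      prob = as.numeric(unlist(sm, use.names = FALSE)),
      stringsAsFactors = FALSE
    )
  } else NULL
  obj <- list(
    format = "tritag-model", version = 1L,
    tags = model$tags,
    config = unclass(model$config),
    theta = model$params$theta,
    lexicon = as.data.frame(model$lexicon$dt),
    smoothed = smoothed,
    suffix = as.data.frame(model$suffix$dt),
    char = as.data.frame(model$char$dt),
    corpus_ngrams = list(
      symbols = model$transitions$symbols,
      tri = {
        nz <- which(model$transitions$tri > 0, arr.ind = TRUE)
        data.frame(dim1 = nz[, 1], dim2 = nz[, 2], dim3 = nz[, 3],
                   count = model$transitions$tri[nz])
      }
    )
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_tagger
#' @return `load_tagger()` returns the restored `pos_tagger`.
#' @export
load_tagger <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "tritag-model"))
    stop("not a tritag model archive: ", path)
  tags <- obj$tags
  cfg <- obj$config
  config <- tagger_config(
    max_suffix_len = cfg$max_suffix_len, counting = cfg$counting,
    interpolation_method = cfg$interpolation_method,
    suffix_method = cfg$suffix_method, beta_unseen = cfg$beta_unseen,
    pattern_tags = if (length(cfg$pattern_tags) > 0) unlist(cfg$pattern_tags) else NULL
  )
  lex <- lexicon_from_counts(obj$lexicon, tags)
  if (!is.null(obj$smoothed) && NROW(obj$smoothed) > 0) {
    sm <- obj$smoothed
    for (w in unique(sm$word)) {
      rows <- sm[sm$word == w, ]
      v <- stats::setNames(rep(0, length(tags)), tags)
      v[rows$tag] <- rows$prob
      assign(w, v, envir = lex$smoothed)
    }
  }
  suffix <- suffix_table_from_rows(obj$suffix, tags = tags, L_max = config$max_suffix_len)
  char <- char_table_from_rows(obj$char, tags = tags)
  params <- interpolation_params(obj$theta, counting = config$counting,
                                 depth_method = config$interpolation_method,
                                 L_max = config$max_suffix_len)
  trans <- .transition_model_from_trigrams(tags, obj$corpus_ngrams)
  structure(
    list(tags = tags, lexicon = lex, suffix = suffix, char = char,
         transitions = trans, params = params, config = config,
         pattern_tags = .resolve_pattern_tags(tags, config)),
    class = "pos_tagger"
  )
}

# Rebuild the full transition model from serialized trigram counts by
# expanding them into an equivalent padded corpus of tag index triples.
.transition_model_from_trigrams <- function(tags, ngrams) {
  m <- length(tags) + 2L
  tri <- array(0, dim = c(m, m, m))
  tr <- ngrams$tri
  tri[cbind(tr$dim1, tr$dim2, tr$dim3)] <- tr$count
  # reconstruct bi / uni from predicted positions of the trigram counts
  bi <- apply(tri, c(2, 3), sum)
  uni <- colSums(bi)
  .assemble_transition_model(tags, tri, bi, uni)
}

.assemble_transition_model <- function(tags, tri, bi, uni) {
  k <- length(tags)
  symbols <- c(tags, .BOS, .EOS)
  m <- k + 2L
  dimnames(tri) <- list(symbols, symbols, symbols)
  dimnames(bi) <- list(symbols, symbols)
  names(uni) <- symbols
  ctx3 <- rowSums(tri, dims = 2L)
  ctx2 <- rowSums(bi)
  N <- sum(uni)
  nz <- which(tri > 0, arr.ind = TRUE)
  cnt <- tri[nz]
  safe_ratio <- function(num, den) ifelse(den > 0, num / den, 0)
  d3 <- safe_ratio(cnt - 1, ctx3[nz[, 1:2, drop = FALSE]] - 1)
  d2 <- safe_ratio(bi[nz[, 2:3, drop = FALSE]] - 1, ctx2[nz[, 2]] - 1)
  d1 <- safe_ratio(uni[nz[, 3]] - 1, N - 1)
  # ties (common for singleton counts, where every leave-one-out ratio is 0)
  # go to the highest order, so tiny corpora keep their trigram evidence
  vote <- 4L - max.col(cbind(d3, d2, d1), ties.method = "first")
  w <- vapply(1:3, function(o) sum(cnt[vote == o]), numeric(1))
  w <- if (sum(w) > 0) w / sum(w) else rep(1 / 3, 3)
  f1 <- uni / N
  f2 <- bi / ctx2
  f2[!is.finite(f2)] <- 0
  f3 <- tri / as.vector(ctx3)
  f3[!is.finite(f3)] <- 0
  A <- w[3] * f3
  for (t in seq_len(m)) {
    A[, , t] <- A[, , t] + w[2] * rep(f2[, t], each = m) + w[1] * f1[t]
  }
  structure(
    list(tags = tags, symbols = symbols, k = k, m = m,
         uni = uni, bi = bi, tri = tri, ctx3 = ctx3, ctx2 = ctx2,
         weights = stats::setNames(w, c("w1", "w2", "w3")),
         A = A, logA = log(A)),
    class = "transition_model"
  )
}
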