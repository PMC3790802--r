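# Synthetic tagged corpora with tag-coupled morphology. Each tag owns an
# inventory of characteristic word endings; words are random stems plus an
# inventory suffix, so suffix-based tag prediction is learnable by
# construction. Unknown words are injected by vocabulary partitioning: a
# slice of every tag's vocabulary is reserved for held-out sentences and
# never appears in training.

.default_tag_weights <- c(
  NN = 0.26, VVG = 0.08, VVN = 0.08, JJ = 0.14,
  RR = 0.07, VVB = 0.10, DD = 0.22, II = 0.05
)

# Inventory endings are chosen so that no two tags share a word-final
# letter: every suffix row then belongs to exactly one tag, which makes
# the suffix signal identifiable at desk scale for both predictors (see
# the methods vignette for why colliding endings are deliberately absent
# from the defaults).
.default_inventory <- list(
  NN = c("tion", "sion", "ation"),
  VVG = "ing",
  VVN = "ed",
  JJ = c("ous", "ious", "less"),
  RR = c("ly", "ally"),
  VVB = c("ate", "ise", "ize"),
  DD = c("th", "ch"),
  II = c("of", "om")
)

.default_vocab_sizes <- c(
  NN = 450, VVG = 150, VVN = 150, JJ = 250,
  RR = 120, VVB = 180, DD = 15, II = 10
)

#' Specification of a synthetic tagged corpus
#'
#' Defines the study conditions the generator emulates: a tag set with
#' base weights (open classes frequent, closed classes small), a per-tag
#' suffix inventory, vocabulary sizes, a trigram tag chain whose rows are
#' drawn from `Dirichlet(concentration * base_weights)` (large
#' concentration = mild second-order structure around the base
#' distribution), geometric sentence lengths, Zipf word use within each
#' tag, and an unknown-word injection rate for the held-out sentences.
#'
#' @param tags Tag labels.
#' @param tag_weights Named base probabilities of the tags (normalised).
#' @param suffix_inventory Named list: per tag, its characteristic endings
#'   (non-empty for every tag with positive weight).
#' @param vocab_sizes Named integer vector: words generated per tag.
#' @param concentration Dirichlet concentration of the trigram rows.
#' @param n_train,n_test Numbers of training and held-out sentences.
#' @param mean_sentence_length Mean of the geometric sentence-length law
#'   (minimum length 1).
#' @param unknown_rate Probability that a held-out token is drawn from the
#'   reserved unknown slice of its tag's vocabulary.
#' @param unknown_fraction Fraction of each tag's vocabulary reserved for
#'   the unknown slice.
#' @param zipf_exponent Zipf exponent of within-tag word use.
#' @param seed Integer seed; a fixed seed makes the corpus byte-identical.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(tags = names(.default_tag_weights),
                           tag_weights = .default_tag_weights,
                           suffix_inventory = .default_inventory,
                           vocab_sizes = .default_vocab_sizes,
                           concentration = 20000,
                           n_train = 5000L, n_test = 500L,
                           mean_sentence_length = 22,
                           unknown_rate = 0.3,
                           unknown_fraction = 0.25,
                           zipf_exponent = 1,
                           seed = 42L) {
  validate_tagset(tags)
  stopifnot(all(tags %in% names(tag_weights)), all(tags %in% names(vocab_sizes)),
            concentration > 0, n_train >= 1L, n_test >= 0L,
            mean_sentence_length > 1, unknown_rate >= 0, unknown_rate <= 1,
            unknown_fraction > 0, unknown_fraction < 1)
  tag_weights <- tag_weights[tags] / sum(tag_weights[tags])
  used <- tags[tag_weights > 0]
  empty <- used[!vapply(used, function(t) length(suffix_inventory[[t]]) > 0, logical(1))]
  if (length(empty) > 0L)
    stop("suffix inventory is empty for used tag(s): ", paste(empty, collapse = ", "))
  structure(
    list(tags = tags, tag_weights = tag_weights,
         suffix_inventory = suffix_inventory,
         vocab_sizes = vocab_sizes[tags],
         concentration = concentration,
         n_train = as.integer(n_train), n_test = as.integer(n_test),
         mean_sentence_length = mean_sentence_length,
         unknown_rate = unknown_rate, unknown_fraction = unknown_fraction,
         zipf_exponent = zipf_exponent, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

.random_stems <- function(n, min_len = 3L, max_len = 6L) {
  len <- sample(min_len:max_len, n, replace = TRUE)
  vapply(len, function(l) paste(sample(letters, l, replace = TRUE), collapse = ""),
         character(1))
}

#' Generate a synthetic tagged corpus with a held-out set
#'
#' Samples tag sequences from the spec's trigram chain (boundary-started,
#' geometric lengths) and words per tag from its stem-plus-inventory
#' vocabulary with Zipf weights. Held-out tokens are drawn, with
#' probability `unknown_rate`, from the reserved unknown slice of the
#' tag's vocabulary (words absent from training by construction) and
#' otherwise from the words actually observed in the training corpus.
#'
#' @param spec A [synthetic_spec()].
#' @return A `synthetic_corpus` list: `train` and `test` (tagged
#'   sentences), `truth` (the generator's boundary-augmented trigram
#'   probability array, symbols, vocabulary slices) and `spec`.
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  tags <- spec$tags
  k <- length(tags)
  rho <- 1 / spec$mean_sentence_length

  # vocabulary: unique stem+ending words per tag, then an unknown slice
  vocab <- list(); all_words <- character(0)
  for (t in tags) {
    n <- spec$vocab_sizes[[t]]
    if (n < 2L) stop("vocab size for tag ", t, " must be at least 2")
    words <- character(0)
    while (length(words) < n) {
      need <- n - length(words)
      cand <- paste0(.random_stems(need),
                     sample(spec$suffix_inventory[[t]], need, replace = TRUE))
      cand <- setdiff(unique(cand), all_words)
      words <- c(words, cand)
      all_words <- c(all_words, cand)
    }
    vocab[[t]] <- words[seq_len(n)]
  }
  unknown_pool <- lapply(tags, function(t) {
    n <- length(vocab[[t]])
    vocab[[t]][seq_len(max(1L, floor(spec$unknown_fraction * n)))]
  })
  names(unknown_pool) <- tags
  train_pool <- lapply(tags, function(t) setdiff(vocab[[t]], unknown_pool[[t]]))
  names(train_pool) <- tags
  zipf <- lapply(tags, function(t) {
    r <- seq_along(train_pool[[t]])
    w <- r^(-spec$zipf_exponent)
    w / sum(w)
  })
  names(zipf) <- tags

  # trigram chain over contexts (tags + start symbol); rows Dirichlet(conc * base)
  syms <- c(tags, .BOS)
  P <- array(0, dim = c(k + 1L, k + 1L, k), dimnames = list(syms, syms, tags))
  for (i in seq_len(k + 1L)) {
    for (j in seq_len(k + 1L)) {
      g <- stats::rgamma(k, shape = spec$concentration * spec$tag_weights)
      P[i, j, ] <- g / sum(g)
    }
  }
  cum <- array(0, dim = dim(P))
  for (i in seq_len(k + 1L)) for (j in seq_len(k + 1L)) cum[i, j, ] <- cumsum(P[i, j, ])

  sample_tag_chain <- function(len) {
    out <- integer(len)
    p2 <- k + 1L; p1 <- k + 1L
    u <- stats::runif(len)
    for (pos in seq_len(len)) {
      t <- findInterval(u[pos], cum[p2, p1, ], left.open = TRUE) + 1L
      out[pos] <- t
      p2 <- p1; p1 <- t
    }
    out
  }

  gen_sentences <- function(n_sent, draw_word) {
    lens <- stats::rgeom(n_sent, rho) + 1L
    lapply(seq_len(n_sent), function(si) {
      ti <- sample_tag_chain(lens[si])
      tagged_sentence(draw_word(ti), tags[ti])
    })
  }

  draw_train <- function(ti) {
    vapply(ti, function(t) {
      pool <- train_pool[[t]]
      pool[sample.int(length(pool), 1L, prob = zipf[[t]])]
    }, character(1))
  }
  train <- gen_sentences(spec$n_train, draw_train)

  # words actually observed in training, with their observed-rank weights
  observed <- lapply(tags, function(t) character(0))
  names(observed) <- tags
  tw <- table(paste(unlist(lapply(train, `[[`, "tags"), use.names = FALSE),
                    unlist(lapply(train, `[[`, "words"), use.names = FALSE),
                    sep = "\r"))
  key <- strsplit(names(tw), "\r", fixed = TRUE)
  obs_words <- vapply(key, `[[`, character(1), 2L)
  obs_tags <- vapply(key, `[[`, character(1), 1L)
  obs_weight <- as.numeric(tw)
  observed <- split(data.frame(word = obs_words, w = obs_weight,
                               stringsAsFactors = FALSE), obs_tags)

  draw_test <- function(ti) {
    vapply(ti, function(t) {
      tag <- tags[t]
      if (stats::runif(1) < spec$unknown_rate) {
        pool <- unknown_pool[[tag]]
        pool[sample.int(length(pool), 1L)]
      } else {
        obs <- observed[[tag]]
        if (is.null(obs) || nrow(obs) == 0L) {
          pool <- train_pool[[tag]]
          pool[sample.int(length(pool), 1L, prob = zipf[[tag]])]
        } else {
          obs$word[sample.int(nrow(obs), 1L, prob = obs$w)]
        }
      }
    }, character(1))
  }
  test <- if (spec$n_test > 0L) gen_sentences(spec$n_test, draw_test) else list()

  # boundary-augmented truth: P(t | ctx) * (1 - rho) for tags, rho for the end
  symbols <- c(tags, .BOS, .EOS)
  A_true <- array(0, dim = c(k + 2L, k + 2L, k + 2L),
                  dimnames = list(symbols, symbols, symbols))
  for (i in seq_len(k + 1L)) {
    for (j in seq_len(k + 1L)) {
      ii <- if (i == k + 1L) k + 1L else i
      jj <- if (j == k + 1L) k + 1L else j
      A_true[ii, jj, seq_len(k)] <- (1 - rho) * P[i, j, ]
      A_true[ii, jj, k + 2L] <- rho
    }
  }

  structure(
    list(train = train, test = test,
         truth = list(transitions = A_true, symbols = symbols, chain = P,
                      vocab = vocab, unknown_pool = unknown_pool,
                      train_pool = train_pool),
         spec = spec),
    class = "synthetic_corpus"
  )
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat(sprintf("<synthetic_corpus> %d training / %d held-out sentences, %d tags\n",
              length(x$train), length(x$test), length(x$spec$tags)))
  invisible(x)
}

#' Tagging accuracy
#'
#' Fraction of positions where predicted and gold tags agree. Accepts
#' plain vectors or lists of per-sentence vectors.
#'
#' @param pred,gold Equal-length character vectors, or lists of vectors
#'   with matching lengths.
#' @return A fraction in `[0, 1]`.
#' @export
accuracy <- function(pred, gold) {
  p <- unlist(pred, use.names = FALSE)
  g <- unlist(gold, use.names = FALSE)
  if (length(p) != length(g)) stop("prediction and gold lengths differ")
  if (length(p) == 0L) stop("cannot score empty sequences")
  mean(p == g)
}

# The eight parameter sets of the suffix-method comparison:
# MSL x {freq_1, freq_n} plus interpolation x {freq_1, freq_n} x depth {1,2,3}.
.parameter_grid <- function() {
  data.frame(
    main_method = c("msl", "msl", rep("interpolation", 6)),
    counting_method = c("freq_1", "freq_n", rep(c("freq_1", "freq_n"), each = 3)),
    interpolation_method = c(NA, NA, 1:3, 1:3),
    stringsAsFactors = FALSE
  )
}

#' Compare the suffix predictors over the eight parameter sets
#'
#' Trains the tagger tables once on `train`, finds the held-out tokens
#' that qualify for suffix analysis (all-lowercase, no case-independent
#' lexicon match, no known surface pattern), and tags each such word type
#' through the suffix pathway alone — `argmax_tag P(word | tag)` — under
#' all eight parameter sets: MSL with either counting method, and
#' interpolation (with Bayesian inversion) for every counting x depth
#' combination. Words on which all eight sets agree are concordant; the
#' summary scores every set against the gold tags, over all suffix-analysed
#' tokens and over the discordant words alone.
#'
#' @param train Training corpus (list of tagged sentences).
#' @param test Held-out corpus with gold tags.
#' @param tags The tag set.
#' @param config A [tagger_config()] for the shared tables.
#' @return A `discordance_report`: `words` (one row per analysed word
#'   type: predicted tag and correct count per set, occurrence total,
#'   concordance flag) and `summary` (one row per parameter set with
#'   overall and discordant-only accuracy).
#' @export
run_parameter_grid <- function(train, test, tags, config = tagger_config()) {
  model <- train_pos_tagger(train, tags, config)
  grid <- .parameter_grid()
  set_ids <- sprintf("%s_%s%s", grid$main_method, grid$counting_method,
                     ifelse(is.na(grid$interpolation_method), "",
                            paste0("_m", grid$interpolation_method)))

  words <- unlist(lapply(test, `[[`, "words"), use.names = FALSE)
  golds <- unlist(lapply(test, `[[`, "tags"), use.names = FALSE)
  eligible <- is_all_lower(words) &
    classify_pattern(words) == "none" &
    is.na(vapply(words, function(w) lookup_case_independent(model$lexicon, w),
                 character(1)))
  words <- words[eligible]; golds <- golds[eligible]
  if (length(words) == 0L) stop("no held-out tokens qualify for suffix analysis")

  types <- sort(unique(words))
  pred <- matrix(NA_character_, nrow = length(types), ncol = nrow(grid),
                 dimnames = list(types, set_ids))
  for (ti in seq_along(types)) {
    w <- types[ti]
    for (si in seq_len(nrow(grid))) {
      scores <- .suffix_emission(
        model, w,
        suffix_method = if (grid$main_method[si] == "msl") "msl" else "interpolation",
        counting = grid$counting_method[si],
        interpolation_method = if (is.na(grid$interpolation_method[si])) 3L
                               else grid$interpolation_method[si]
      )
      pred[ti, si] <- tags[which.max(scores)]
    }
  }
  concordant <- apply(pred, 1L, function(r) length(unique(r)) == 1L)

  total <- as.integer(table(factor(words, levels = types)))
  correct <- matrix(0L, nrow = length(types), ncol = nrow(grid),
                    dimnames = list(types, set_ids))
  for (si in seq_len(nrow(grid))) {
    hit <- pred[match(words, types), si] == golds
    tab <- tapply(hit, factor(words, levels = types), sum)
    correct[, si] <- as.integer(tab)
  }

  disc <- !concordant
  summary <- cbind(grid, data.frame(
    set = set_ids,
    correct = colSums(correct),
    total = sum(total),
    accuracy = colSums(correct) / sum(total),
    discordant_correct = colSums(correct[disc, , drop = FALSE]),
    discordant_total = sum(total[disc]),
    discordant_accuracy = if (sum(total[disc]) > 0)
      colSums(correct[disc, , drop = FALSE]) / sum(total[disc]) else NA_real_,
    row.names = NULL, stringsAsFactors = FALSE
  ))
  words_df <- data.frame(word = types, total = total, concordant = concordant,
                         stringsAsFactors = FALSE, row.names = NULL)
  words_df <- cbind(words_df,
                    stats::setNames(as.data.frame(pred, stringsAsFactors = FALSE),
                                    paste0("tag_", set_ids)),
                    stats::setNames(as.data.frame(correct),
                                    paste0("correct_", set_ids)))
  rownames(words_df) <- NULL
  structure(list(words = words_df, summary = summary, set_ids = set_ids),
            class = "discordance_report")
}

#' @export
print.discordance_report <- function(x, ...) {
  cat(sprintf("<discordance_report> %d suffix-analysed word types (%d discordant)\n",
              nrow(x$words), sum(!x$words$concordant)))
  print(x$summary[, c("main_method", "counting_method", "interpolation_method",
                      "correct", "total", "accuracy", "discordant_accuracy")],
        digits = 4)
  invisible(x)
}
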