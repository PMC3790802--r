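# Shared fixtures, all built in code.

# Three-word lexicon used throughout the suffix-model examples:
# running/VVG x3, ring/NN x1, sing/VVB x2.
fix3_tags <- c("NN", "VVB", "VVG")
fix3_lexicon <- function() {
  lexicon_from_counts(
    data.frame(word = c("running", "ring", "sing"),
               tag = c("VVG", "NN", "VVB"),
               freq = c(3L, 1L, 2L)),
    tags = fix3_tags
  )
}

medpost_tags <- function() {
  read_tagset(system.file("extdata", "tagset_medpost.txt", package = "tritag"))
}

# The hand-built "-tial" suffix table shipped as a TSV fixture
# (length-1 rows for 12 tags, "al" for 5, "ial"/"tial" for NN and JJ).
tial_table <- function() {
  read_suffix_table(
    system.file("extdata", "suffix_table_tial.tsv", package = "tritag"),
    tags = medpost_tags()
  )
}

# A random word: lowercase letters, length 2..10.
random_words <- function(n, min_len = 2L, max_len = 10L) {
  len <- sample(min_len:max_len, n, replace = TRUE)
  vapply(len, function(l) paste(sample(letters, l, replace = TRUE), collapse = ""),
         character(1))
}

# A random lexicon of distinct words over a given tag set.
random_lexicon_counts <- function(n_words, tags, max_freq = 30L) {
  words <- unique(random_words(3L * n_words))[seq_len(n_words)]
  data.frame(word = words,
             tag = sample(tags, n_words, replace = TRUE),
             freq = sample.int(max_freq, n_words, replace = TRUE))
}

# A small random tagged corpus (uniform tags, random words).
random_corpus <- function(n_sentences, tags, vocab = random_words(60),
                          min_len = 1L, max_len = 8L) {
  lapply(seq_len(n_sentences), function(i) {
    n <- sample(min_len:max_len, 1L)
    tagged_sentence(sample(vocab, n, replace = TRUE),
                    sample(tags, n, replace = TRUE))
  })
}

# A random decoding instance: transition array with Dirichlet rows over
# (tags + end symbol) for every context, and positive random emissions.
random_instance <- function(k = sample(2:4, 1L), N = sample(1:5, 1L)) {
  tags <- paste0("T", seq_len(k))
  m <- k + 2L
  A <- array(0, dim = c(m, m, m))
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      g <- stats::rgamma(k + 1L, shape = 1)
      p <- g / sum(g)
      A[i, j, seq_len(k)] <- p[seq_len(k)]
      A[i, j, k + 2L] <- p[k + 1L]
    }
  }
  trans <- tritag:::transition_model_from_array(tags, A)
  em <- matrix(stats::runif(k * N, min = 0.01, max = 1), nrow = k)
  list(trans = trans, em = em, k = k, N = N, tags = tags)
}
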