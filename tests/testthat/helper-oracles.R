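# Independent brute-force oracles. Each recomputes a quantity by direct
# scanning / enumeration, never reusing the package's tables.

# Words of a lexicon data frame that qualify for suffix analysis.
oracle_suffix_words <- function(counts) {
  ok <- grepl("^[[:alpha:]]+$", counts$word) & classify_pattern(counts$word) == "none"
  counts[ok, , drop = FALSE]
}

# Raw suffix frequency by scanning the word list.
oracle_suffix_freq <- function(counts, suffix, tag, counting, L_max = 5L) {
  sw <- oracle_suffix_words(counts)
  i <- nchar(suffix)
  if (i < 1L || i > L_max) return(0)
  wl <- tolower(sw$word)
  hit <- nchar(wl) - 1L >= i & endsWith(wl, suffix) & sw$tag == tag
  if (counting == "freq_1") sum(hit) else sum(sw$freq[hit])
}

oracle_suffix_mle <- function(counts, tags, suffix, tag, counting, L_max = 5L) {
  num <- oracle_suffix_freq(counts, suffix, tag, counting, L_max)
  den <- sum(vapply(tags, function(t)
    oracle_suffix_freq(counts, suffix, t, counting, L_max), numeric(1)))
  if (den == 0) 0 else num / den
}

oracle_len1_mass <- function(counts, tag, counting, L_max = 5L) {
  sw <- oracle_suffix_words(counts)
  wl <- tolower(sw$word)
  hit <- nchar(wl) >= 2L & sw$tag == tag
  if (counting == "freq_1") sum(hit) else sum(sw$freq[hit])
}

oracle_p_tag <- function(counts, tags, counting, L_max = 5L) {
  mass <- vapply(tags, function(t) oracle_len1_mass(counts, t, counting, L_max),
                 numeric(1))
  if (sum(mass) == 0) mass else mass / sum(mass)
}

oracle_msl <- function(counts, tags, word, tag, counting, L_max = 5L) {
  wl <- tolower(word)
  n <- min(L_max, nchar(wl) - 1L)
  if (n < 1L) return(0)
  N1 <- oracle_len1_mass(counts, tag, counting, L_max)
  if (N1 == 0) return(0)
  for (i in rev(seq_len(n))) {
    s <- substring(wl, nchar(wl) - i + 1L)
    f <- oracle_suffix_freq(counts, s, tag, counting, L_max)
    if (f > 0) return(f / N1)
  }
  0
}

# Independent recursion for the interpolated tag-given-suffix probability
# (depth methods 1-3), built on the scan-based estimates above.
oracle_interpolate <- function(counts, tags, word, tag, theta, counting,
                               depth_method, L_max = 5L) {
  wl <- tolower(word)
  n <- min(L_max, nchar(wl) - 1L)
  any_row <- function(s) any(vapply(tags, function(t)
    oracle_suffix_freq(counts, s, t, counting, L_max) > 0, logical(1)))
  depth <- if (n < 1L) 0L else switch(
    depth_method,
    `1` = { d <- 0L
            for (i in rev(seq_len(n)))
              if (any_row(substring(wl, nchar(wl) - i + 1L))) { d <- i; break }
            d },
    `2` = n,
    `3` = { d <- 0L
            for (i in rev(seq_len(n)))
              if (oracle_suffix_freq(counts, substring(wl, nchar(wl) - i + 1L),
                                     tag, counting, L_max) > 0) { d <- i; break }
            d }
  )
  p <- oracle_p_tag(counts, tags, counting, L_max)[[tag]]
  if (depth < 1L) return(p)
  for (i in seq_len(depth)) {
    s <- substring(wl, nchar(wl) - i + 1L)
    pm <- oracle_suffix_mle(counts, tags, s, tag, counting, L_max)
    p <- (pm + theta * p) / (1 + theta)
  }
  p
}

oracle_char_mle <- function(counts, word, tag) {
  fs <- feature_string(counts$word)
  den <- sum(counts$freq[counts$tag == tag])
  if (den == 0) return(0)
  num <- sum(counts$freq[fs == feature_string(word) & counts$tag == tag])
  num / den
}

# Exhaustive decoding: scores every tag sequence and returns the best
# (first in row-major enumeration order on ties).
enumerate_viterbi <- function(trans, em) {
  k <- trans$k
  N <- ncol(em)
  la <- log(trans$A)
  le <- log(em)
  iB <- k + 1L; iE <- k + 2L
  seqs <- as.matrix(expand.grid(rep(list(seq_len(k)), N)))
  score_one <- function(s) {
    p <- c(iB, iB, s, iE)
    tot <- 0
    for (i in 3:length(p)) tot <- tot + la[p[i - 2L], p[i - 1L], p[i]]
    tot + sum(le[cbind(s, seq_len(N))])
  }
  scores <- apply(seqs, 1L, score_one)
  best <- which.max(scores)
  list(path = trans$tags[seqs[best, ]], score = scores[best], all_scores = scores)
}

# Independent n-gram relative frequencies by direct looping over the
# boundary-padded corpus (no tabulate tricks).
oracle_ngram_freqs <- function(corpus, tags) {
  symbols <- c(tags, "<s>", "</s>")
  m <- length(symbols)
  tri <- array(0, dim = c(m, m, m), dimnames = list(symbols, symbols, symbols))
  bi <- matrix(0, m, m, dimnames = list(symbols, symbols))
  uni <- stats::setNames(rep(0, m), symbols)
  for (s in corpus) {
    p <- c("<s>", "<s>", s$tags, "</s>")
    for (i in 3:length(p)) {
      tri[p[i - 2L], p[i - 1L], p[i]] <- tri[p[i - 2L], p[i - 1L], p[i]] + 1
      bi[p[i - 1L], p[i]] <- bi[p[i - 1L], p[i]] + 1
      uni[p[i]] <- uni[p[i]] + 1
    }
  }
  list(tri = tri, bi = bi, uni = uni)
}
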