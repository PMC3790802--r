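test_that("suffix table construction counts types and tokens cumulatively", {
  tbl <- build_suffix_table(fix3_lexicon())
  expect_identical(unname(tbl$env[["ing"]]$freq_1["VVG"]), 1)
  expect_identical(unname(tbl$env[["ing"]]$freq_n["VVG"]), 3)
  expect_identical(tbl$env[["ing"]]$total_1, 3L)   # running, ring, sing
  expect_identical(tbl$env[["ing"]]$total_n, 6L)
  # running (7 letters) contributes lengths 1..5, ring/sing 1..3
  expect_identical(sort(tbl$dt[tag == "VVG", suffix]),
                   sort(c("g", "ng", "ing", "ning", "nning")))

  # all word frequencies 1 makes the two counting methods identical
  tags <- c("A", "B")
  lex1 <- lexicon_from_counts(
    data.frame(word = c("walking", "talking", "breathes"),
               tag = c("A", "B", "A"), freq = 1L), tags)
  t1 <- build_suffix_table(lex1)
  expect_identical(t1$dt$freq_1, t1$dt$freq_n)
})

test_that("suffix_mle matches the worked example and normalizes per suffix", {
  tbl <- build_suffix_table(fix3_lexicon())
  expect_equal(suffix_mle(tbl, "VVG", "ing", "freq_1"), 1 / 3)
  expect_equal(suffix_mle(tbl, "VVG", "ing", "freq_n"), 0.5)
  expect_equal(suffix_mle(tbl, "VVG", "ing", 1), 1 / 3)   # numeric alias
  expect_identical(suffix_mle(tbl, "VVG", "zzz", "freq_1"), 0)
  expect_error(suffix_mle(tbl, "VVG", "toolong", "freq_1"), "length")

  for (counting in c("freq_1", "freq_n")) {
    for (s in unique(tbl$dt$suffix)) {
      total <- sum(vapply(tbl$tags, function(t) suffix_mle(tbl, t, s, counting),
                          numeric(1)))
      expect_equal(total, 1, tolerance = 1e-9)
    }
  }
})

test_that("cumulativity holds on a built table", {
  set.seed(31)
  tags <- c("A", "B", "C")
  lex <- lexicon_from_counts(random_lexicon_counts(400, tags), tags)
  tbl <- build_suffix_table(lex)
  long <- tbl$dt[nchar(suffix) >= 2L]
  tail_of <- substring(long$suffix, 2L)
  for (counting in c("freq_1", "freq_n")) {
    f_long <- long[[counting]]
    f_tail <- mapply(function(s, t) {
      row <- tbl$env[[s]]
      unname(row[[counting]][t])
    }, tail_of, long$tag)
    expect_true(all(!is.na(f_tail)))
    expect_true(all(f_tail >= f_long))
  }
})

test_that("theta is the sample sd of the tag distribution around 1/k", {
  # two equally weighted tags -> zero deviation
  rows <- data.frame(suffix = c("a", "b"), tag = c("T1", "T2"),
                     freq_1 = c(5L, 5L), freq_n = c(5L, 5L))
  tbl <- suffix_table_from_rows(rows, tags = c("T1", "T2"))
  p <- estimate_theta(tbl, "freq_1")
  expect_identical(p$theta, 0)
  expect_identical(p$lambda1, 1)
  expect_identical(p$lambda2, 0)

  # degenerate distribution (1, 0) -> sqrt(2 * 0.25 / 1)
  rows2 <- data.frame(suffix = "a", tag = "T1", freq_1 = 7L, freq_n = 7L)
  tbl2 <- suffix_table_from_rows(rows2, tags = c("T1", "T2"))
  p2 <- estimate_theta(tbl2, "freq_1")
  expect_equal(p2$theta, sqrt(0.5), tolerance = 1e-12)

  tbl3 <- build_suffix_table(fix3_lexicon())
  for (counting in c("freq_1", "freq_n")) {
    p3 <- estimate_theta(tbl3, counting)
    expect_gte(p3$theta, 0)
    expect_equal(p3$lambda1 + p3$lambda2, 1, tolerance = 1e-12)
  }
})

test_that("the -tial fixture grid reproduces the per-tag maximal lengths", {
  tbl <- tial_table()
  g <- mark_suffix_grid(tbl, "tubulointerstitial")
  expect_identical(g$n_lengths, 5L)
  expected <- c(JJ = 4L, NN = 4L, VVI = 2L, RR = 2L, VVB = 2L,
                DB = 1L, CS = 1L, VM = 1L, NNP = 1L, PND = 1L, DD = 1L, II = 1L)
  expect_identical(g$max_len[names(expected)], expected)
  expect_true(all(g$max_len[setdiff(names(g$max_len), names(expected))] == 0L))
  expect_false(any(g$grid[5L, ]))   # no tag reaches "itial"

  # per-tag marks are downward closed
  for (t in names(expected)) {
    col <- g$grid[, t]
    expect_true(all(col[seq_len(expected[[t]])]))
  }

  # a word matching no row gives an all-unmarked grid
  g0 <- mark_suffix_grid(tbl, "qqqqqq")
  expect_true(all(!g0$grid))
  expect_true(all(g0$max_len == 0L))
})

test_that("interpolation depth follows the three methods", {
  tbl <- tial_table()
  word <- "tubulointerstitial"
  p1 <- interpolation_params(0.05, depth_method = 1)
  p2 <- interpolation_params(0.05, depth_method = 2)
  p3 <- interpolation_params(0.05, depth_method = 3)
  expect_identical(interpolation_depth(tbl, word, params = p1), 4L)
  expect_identical(interpolation_depth(tbl, word, params = p2), 5L)
  expect_identical(interpolation_depth(tbl, word, "VVI", p3), 2L)
  expect_identical(interpolation_depth(tbl, word, "JJ", p3), 4L)
  expect_identical(interpolation_depth(tbl, word, "TO", p3), 0L)
})

test_that("interpolation collapses to the deepest MLE at theta = 0 and to the
           prior at depth 0", {
  tbl <- tial_table()
  word <- "tubulointerstitial"
  p0 <- interpolation_params(0, counting = "freq_1", depth_method = 3)
  expect_equal(interpolate_tag_given_suffix(tbl, word, "JJ", p0),
               suffix_mle(tbl, "JJ", "tial", "freq_1"), tolerance = 1e-12)
  expect_equal(interpolate_tag_given_suffix(tbl, word, "VVI", p0),
               suffix_mle(tbl, "VVI", "al", "freq_1"), tolerance = 1e-12)
  # a tag with no marked cell returns the unconditional tag probability
  expect_equal(interpolate_tag_given_suffix(tbl, word, "TO", p0),
               suffix_p_tag(tbl, "freq_1")[["TO"]], tolerance = 1e-12)
})

test_that("Bayesian inversion scales by the per-tag suffix mass", {
  tbl <- tial_table()
  expect_identical(invert_to_word_given_tag(0, tbl, "JJ", "freq_1"), 0)
  # two tags with equal totals and equal conditionals give equal outputs
  rows <- data.frame(suffix = c("a", "a", "b", "b"), tag = c("T1", "T2", "T1", "T2"),
                     freq_1 = c(4L, 4L, 2L, 2L), freq_n = c(4L, 4L, 2L, 2L))
  t2 <- suffix_table_from_rows(rows, tags = c("T1", "T2"))
  expect_equal(invert_to_word_given_tag(0.5, t2, "T1"),
               invert_to_word_given_tag(0.5, t2, "T2"))
  # two-row fixture: p * len1_mass / tag_total by direct arithmetic
  rows3 <- data.frame(suffix = c("g", "ng"), tag = c("T1", "T1"),
                      freq_1 = c(6L, 4L), freq_n = c(6L, 4L))
  t3 <- suffix_table_from_rows(rows3, tags = c("T1", "T2"))
  expect_equal(invert_to_word_given_tag(0.3, t3, "T1"), 0.3 * 6 / 10)
  expect_identical(invert_to_word_given_tag(0.3, t3, "T2"), 0)
})

test_that("MSL uses the longest per-tag suffix with the length-1 mass
           denominator", {
  tbl <- tial_table()
  # JJ resolves at "tial": 25 / 400 under freq_1
  expect_equal(msl_word_given_tag(tbl, "tubulointerstitial", "JJ", "freq_1"),
               25 / 400)
  expect_equal(msl_word_given_tag(tbl, "tubulointerstitial", "VVI", "freq_1"),
               20 / 60)   # "al" row over VVI's length-1 mass
  expect_identical(msl_word_given_tag(tbl, "tubulointerstitial", "TO"), 0)

  t3 <- build_suffix_table(fix3_lexicon())
  expect_equal(msl_word_given_tag(t3, "bling", "VVG", "freq_1"), 1)
  expect_equal(msl_word_given_tag(t3, "bling", "VVG", "freq_n"), 1)

  # monotone support: if the suffix evidence of word A extends that of B,
  # the suffix used for A is at least as long
  gA <- mark_suffix_grid(t3, "brunning")   # shares "nning" with running
  gB <- mark_suffix_grid(t3, "braning")    # shares only "ning"
  expect_gte(gA$max_len[["VVG"]], gB$max_len[["VVG"]])
})

test_that("suffix smoothing adds suffix-supported unseen tags only", {
  tags <- c("NN", "JJ")
  lex <- lexicon_from_counts(
    data.frame(word = c("walked", "talked"), tag = c("NN", "JJ"),
               freq = c(2L, 3L)), tags)
  tbl <- build_suffix_table(lex)
  params <- estimate_theta(tbl, "freq_1")

  sm <- smooth_known_word_unseen_tags(lex, tbl, params, beta = 0.1)
  pr <- lexicon_probs(sm, "walked")
  expect_identical(unname(pr["NN"]), 1)               # seen tag keeps its MLE
  expect_gt(unname(pr["JJ"]), 0)                      # suffix-supported new tag
  expect_equal(unname(pr["JJ"]), 0.1 * msl_word_given_tag(tbl, "walked", "JJ", "freq_1"))
  # original counts untouched
  expect_identical(sm$dt, lex$dt)

  # beta = 0 is the identity on probabilities
  sm0 <- smooth_known_word_unseen_tags(lex, tbl, params, beta = 0)
  expect_identical(unname(lexicon_probs(sm0, "walked")["JJ"]), 0)
  expect_identical(unname(lexicon_probs(sm0, "walked")["NN"]), 1)

  # a word whose suffixes support no new tag keeps its MLE distribution
  tags2 <- c("NN", "VVG")
  lex2 <- lexicon_from_counts(
    data.frame(word = c("nation", "walking"), tag = c("NN", "VVG"),
               freq = c(2L, 2L)), tags2)
  tbl2 <- build_suffix_table(lex2)
  sm2 <- smooth_known_word_unseen_tags(lex2, tbl2, estimate_theta(tbl2, "freq_1"))
  expect_identical(unname(lexicon_probs(sm2, "nation")["VVG"]), 0)
})

test_that("suffix TSV export/import round-trips", {
  tbl <- build_suffix_table(fix3_lexicon())
  f <- withr::local_tempfile(fileext = ".tsv")
  write_suffix_table(tbl, f)
  tbl2 <- read_suffix_table(f, tags = fix3_tags)
  expect_equal(as.data.frame(tbl2$dt), as.data.frame(tbl$dt))
})

test_that("suffix and char estimates match brute-force scans on small lexicons", {
  set.seed(33)
  tags <- c("NN", "JJ", "VVG", "RR")
  for (rep in 1:6) {
    counts <- random_lexicon_counts(sample(5:20, 1L), tags, max_freq = 6L)
    lex <- lexicon_from_counts(counts, tags)
    tbl <- build_suffix_table(lex)
    cht <- build_char_table(lex)
    probe_words <- c(sample(counts$word, 3L), random_words(3, 3L, 8L))
    probe_suffixes <- unique(c(sample(tbl$dt$suffix, 4L), "zz", "q"))
    for (counting in c("freq_1", "freq_n")) {
      expect_equal(unname(suffix_p_tag(tbl, counting)),
                   unname(oracle_p_tag(counts, tags, counting)),
                   tolerance = 1e-12)
      for (s in probe_suffixes) {
        for (t in tags) {
          expect_equal(suffix_mle(tbl, t, s, counting),
                       oracle_suffix_mle(counts, tags, s, t, counting),
                       tolerance = 1e-12)
        }
      }
      for (w in probe_words) {
        for (t in tags) {
          expect_equal(msl_word_given_tag(tbl, w, t, counting),
                       oracle_msl(counts, tags, w, t, counting),
                       tolerance = 1e-12)
          for (dm in 1:3) {
            params <- interpolation_params(0.07, counting = counting,
                                           depth_method = dm)
            expect_equal(
              interpolate_tag_given_suffix(tbl, w, t, params),
              oracle_interpolate(counts, tags, w, t, 0.07, counting, dm),
              tolerance = 1e-12
            )
          }
        }
      }
    }
    for (w in c(sample(counts$word, 3L))) {
      for (t in tags) {
        expect_equal(char_mle(cht, w, t), oracle_char_mle(counts, w, t),
                     tolerance = 1e-12)
      }
    }
  }
})
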