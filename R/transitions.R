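# Trigram transition model. Every sentence is padded with two opening
# boundary pseudo-tags and one closing one; counts are collected only for
# the predicted positions (real tags and the end symbol), so the start
# symbol never appears in a predicted slot. Zero-frequency trigrams are
# smoothed by deleted linear interpolation over orders 1-3.

.BOS <- "<s>"
.EOS <- "</s>"

#' Build a trigram transition model from a tagged corpus
#'
#' Collects unigram, bigram and trigram tag counts over boundary-padded
#' sentences and estimates the interpolation weights `(w1, w2, w3)` by
#' deleted interpolation: each trigram votes, with its count, for the
#' order whose leave-one-out relative frequency is largest (ties favour
#' the lower order); votes are normalised into weights.
#'
#' @param corpus A list of tagged sentences.
#' @param tags The tag set (boundary symbols are added internally and are
#'   not part of it).
#' @return A `transition_model` object.
#' @export
build_transition_model <- function(corpus, tags) {
  if (length(corpus) == 0L) stop("cannot build a transition model from an empty corpus")
  validate_tagset(tags)
  k <- length(tags)
  symbols <- c(tags, .BOS, .EOS)
  m <- k + 2L
  iB <- k + 1L; iE <- k + 2L
  trip <- lapply(corpus, function(s) {
    ti <- match(s$tags, tags)
    if (anyNA(ti)) stop("sentence contains tags outside the tag set: ",
                        paste(unique(s$tags[is.na(ti)]), collapse = ", "))
    p <- c(iB, iB, ti, iE)
    n <- length(p)
    list(a = p[1:(n - 2L)], b = p[2:(n - 1L)], c = p[3:n])
  })
  a <- unlist(lapply(trip, `[[`, "a"), use.names = FALSE)
  b <- unlist(lapply(trip, `[[`, "b"), use.names = FALSE)
  cc <- unlist(lapply(trip, `[[`, "c"), use.names = FALSE)
  tri <- array(tabulate(a + (b - 1L) * m + (cc - 1L) * m * m, nbins = m^3),
               dim = c(m, m, m))
  bi <- matrix(tabulate(b + (cc - 1L) * m, nbins = m^2), nrow = m)
  uni <- tabulate(cc, nbins = m)
  .assemble_transition_model(tags, tri, bi, uni)
}

# Constructor from a fully specified transition array (contexts over
# symbols, rows normalised over tags + end symbol); used for synthetic
# decoding problems where no corpus exists.
transition_model_from_array <- function(tags, A) {
  k <- length(tags)
  m <- k + 2L
  stopifnot(all(dim(A) == m))
  symbols <- c(tags, .BOS, .EOS)
  dimnames(A) <- list(symbols, symbols, symbols)
  structure(
    list(tags = tags, symbols = symbols, k = k, m = m,
         uni = NULL, bi = NULL, tri = NULL, ctx3 = NULL, ctx2 = NULL,
         weights = NULL, A = A, logA = log(A)),
    class = "transition_model"
  )
}

#' @export
print.transition_model <- function(x, ...) {
  cat(sprintf("<transition_model> %d tags (+2 boundary symbols)", x$k))
  if (!is.null(x$weights))
    cat(sprintf("; weights w1=%.3f w2=%.3f w3=%.3f",
                x$weights[1], x$weights[2], x$weights[3]))
  cat("\n")
  invisible(x)
}

#' Smoothed trigram transition probability
#'
#' `P(tag | prev2, prev) = w3 f(tag | prev2, prev) + w2 f(tag | prev) +
#' w1 f(tag)` with `f` the relative frequencies (0 for unseen contexts).
#' Boundary symbols `"<s>"` and `"</s>"` are admissible arguments.
#'
#' @param model A `transition_model`.
#' @param tag The next tag.
#' @param prev,prev2 The previous and the one-before-previous tag.
#' @return A probability.
#' @export
transition_prob <- function(model, tag, prev, prev2) {
  stopifnot(inherits(model, "transition_model"))
  i <- match(c(prev2, prev, tag), model$symbols)
  if (anyNA(i)) stop("unknown tag label among: ",
                     paste(c(prev2, prev, tag), collapse = ", "))
  model$A[i[1], i[2], i[3]]
}

#' Viterbi decoding over an explicit emission matrix
#'
#' The dynamic-programming core: given a transition model and a `k x N`
#' matrix of emission probabilities (rows = tags in tag-set order, columns
#' = sentence positions), returns the tag sequence maximising the joint
#' probability of the boundary-padded path. Computed in log-space; every
#' backpointer tie is broken toward the lower tag-set index.
#'
#' @param trans A `transition_model`.
#' @param emissions A numeric matrix, `length(trans$tags)` rows, `N >= 1` columns.
#' @return A character vector of tags with attribute `"logscore"`, the
#'   joint log-probability of the returned path (including both boundary
#'   transitions).
#' @export
viterbi_path <- function(trans, emissions) {
  stopifnot(inherits(trans, "transition_model"), is.matrix(emissions))
  k <- trans$k
  if (nrow(emissions) != k) stop("emission matrix must have one row per tag")
  N <- ncol(emissions)
  if (N < 1L) stop("cannot decode an empty sentence")
  la <- trans$logA
  iB <- k + 1L; iE <- k + 2L
  logem <- log(emissions)
  tg <- seq_len(k)
  if (N == 1L) {
    sc <- la[iB, iB, tg] + logem[, 1] + la[iB, tg, iE]
    best <- which.max(sc)
    return(structure(trans$tags[best], logscore = unname(sc[best])))
  }
  D1 <- la[iB, iB, tg] + logem[, 1]
  # D[v, w], v = t1, w = t2; matrix() keeps dimensions when k = 1
  D <- matrix(la[iB, tg, tg], k, k) + D1 + rep(logem[, 2], each = k)
  bp <- if (N >= 3L) array(0L, dim = c(k, k, N)) else NULL
  if (N >= 3L) {
    for (i in 3:N) {
      Dn <- matrix(-Inf, k, k)
      for (w in tg) {
        C <- D + matrix(la[tg, tg, w], k, k)   # C[u, v]
        mc <- max.col(t(C), ties.method = "first")
        Dn[, w] <- C[cbind(mc, tg)] + logem[w, i]
        bp[, w, i] <- mc
      }
      D <- Dn
    }
  }
  D <- D + matrix(la[tg, tg, iE], k, k)
  best <- arrayInd(which.max(D), dim(D))
  v <- best[1]; w <- best[2]
  path <- integer(N)
  path[N] <- w; path[N - 1L] <- v
  if (N >= 3L) {
    for (i in N:3) {
      u <- bp[path[i - 1L], path[i], i]
      path[i - 2L] <- u
    }
  }
  structure(trans$tags[path], logscore = unname(D[v, w]))
}
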