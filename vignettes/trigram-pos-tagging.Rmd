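---
title: "Trigram HMM part-of-speech tagging with suffix-based unknown-word prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trigram HMM part-of-speech tagging with suffix-based unknown-word prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tritag)
```

## The model

`tritag` implements a second-order (trigram) hidden Markov model tagger:
the joint probability of a sentence `w_1..w_N` with tags `t_1..t_N` is

    P(w, t) = prod_i  p(t_i | t_{i-1}, t_{i-2}) * p(w_i | t_i),

decoded exactly by Viterbi dynamic programming over tag pairs. Two
boundary pseudo-tags open every sentence and one closes it, so the
trigram term is defined at positions 1 and 2 and sentence termination is
scored like any other event; the boundary symbols are not part of the
user's tag set.

**Transitions.** Trigram maximum-likelihood estimates are sparse, so the
transition term is a deleted linear interpolation
`w3*f(t|t2,t1) + w2*f(t|t1) + w1*f(t)` of relative frequencies. The
weights are estimated by the classic leave-one-out vote: each observed
trigram compares its discounted trigram, bigram and unigram relative
frequencies and adds its count to the winning order; votes are
normalised. Ties — ubiquitous for singleton counts, where all three
ratios are zero — go to the highest order, which keeps the trigram
evidence of very small corpora. Unseen contexts contribute zero at their
order, so the mixture never divides by zero; probabilities over each
observed context sum to one across tags plus the end symbol.

**Emissions.** `p(w|t)` is resolved by a cascade in which exactly one
branch fires per token:

1. *Lexicon.* Case-independent lookup (exact case preferred) of the
   training counts; the value is the smoothed word-given-tag probability
   (below).
2. *Known patterns.* Numbers (`3.14`, `1,234`), number ranges (`10-20`)
   and ordinals (`21st`) receive the cardinal-number tag from
   configuration — `MC` when the tag set has it.
3. *Character features.* Unknown tokens that are not all-lowercase are
   scored by `P(feature string | t)`: each character maps to a class
   symbol (uppercase `A`, lowercase `a`, digit `0`, Greek `g`, the
   biologically salient separators `-./()` kept literally, anything else
   `S`) and runs of the same symbol collapse, so `IL-2` and `IL-10`
   share the feature `A-0`. Collapsing bounds the feature space so rare
   long tokens still share statistics; whether to collapse was an open
   choice and the collapsed variant is implemented.
4. *Suffix prediction.* All-lowercase unknown words go to the suffix
   model described next.

An all-zero emission row falls back to the uniform distribution over
tags (optionally reported via `options(tritag.verbose = TRUE)`), so one
exotic token cannot annihilate every decoding path.

## The suffix model

For every all-alphabetic lexicon word, every proper suffix of length 1
to `L_max = 5` is counted per tag, under two counting methods stored side
by side: `freq_1` counts word types, `freq_n` weights each word by its
corpus frequency. Five is a reasonable maximum for English, where
productive suffixes rarely exceed four letters; a suffix is a *proper*
ending, so one-letter words contribute nothing, and words are lowercased
because suffix analysis serves all-lowercase unknowns. Counts are
cumulative in length by construction: every word ending in `ing` also
ends in `ng` and `g`.

Two predictors turn the table into an emission score:

* **Probability interpolation** (the TnT approach). The recursion
  `P_i = (p_mle(t|s_i) + theta*P_{i-1}) / (1+theta)` starts from the
  unconditional tag probability `P_0 = p(t)` (estimated from the
  length-1 rows) and walks from the shortest to the deepest suffix.
  `theta` is the sample standard deviation (divisor `k-1`) of `p(t)`
  around its mean `1/k` over the `k` tags — a single context-free value;
  on the default synthetic conditions it lands around 0.08–0.11,
  bracketing the 0.03–0.10 range typical of natural tag sets. The
  equivalent convex weights are `lambda1 = 1/(1+theta)` and
  `lambda2 = theta/(1+theta)`. Three *depth methods* choose the final
  level: (1) the deepest suffix of the word with any table entry, (2)
  always `min(5, nchar-1)` whether entries exist or not, (3) per tag,
  the deepest entry for that tag (possibly 0, returning `p(t)`).
  Because the recursion yields `P(t|suffix)`, Bayesian inversion
  `P(s|t) = P(t|s) * P(s) / P(t)` converts it into an emission score;
  `P(s)` is taken as the total length-1 row mass — a per-word constant,
  deliberately so, since only per-tag relative values enter the argmax —
  and `P(t)` as the tag's share of all suffix rows.
* **Maximum Suffix Length (MSL).** Per tag, only the longest suffix of
  the word with an entry for that tag is used:
  `P(w|t) ~ freq(s_t, t) / N(t)`, with `N(t)` the tag's length-1 mass —
  the maximal cumulative word mass, making the value a within-tag share
  `p(s_t|t)` usable directly as an emission without inversion.

**Smoothing known words' unseen tags.** With a small training corpus,
plausible word-tag pairs are missing: a word seen only as a noun may
well occur as an adjective. For every lexicon word and every tag with
zero count but positive MSL support, the smoothed probability is
`beta * msl(w, t)` with `beta = 0.1`; seen tags keep their MLE and the
raw counts are untouched. The value is used as stored, without
renormalisation over words. A caveat documented rather than hidden: the
MSL value is a suffix-class share, which can exceed the word-level MLE
of rare seen words by orders of magnitude, so on natural corpora a large
`beta` can pull known words toward suffix-supported tags; `beta` is the
dial that controls this, and `beta = 0` disables smoothing exactly.

## Tokenization

The biomedicine-aware tokenizer keeps complex biological names whole: runs of
`-`, `/`, `.`, `(`, `)` flanked by alphanumerics stay inside the token
(`IL-2`, `p53/p21`, `Ca(2)-ATPase`), Greek letters count as letters, and
every other symbol is its own token, so the stream loses no non-space
character and re-tokenizing its space-joined form is a fixed point.
Sentences split at `.!?` followed by whitespace and an uppercase letter
or digit, except after abbreviation-like tokens with internal dots
(`e.g.`). These rules are a minimal reconstruction — the level of
sentence-boundary sophistication of a dedicated splitter is out of
scope.

## Synthetic study conditions

The generator (`synthetic_spec()`, `generate_corpus()`) emulates what
makes suffix prediction work, without any external corpus: each of 8
MedPost-style tags owns an inventory of characteristic endings, words
are random stems plus an inventory ending, sentences follow a trigram
tag chain with geometric lengths (mean 22 tokens, biomedical-article
scale; the geometric law makes the padded tag process a homogeneous
Markov chain, so the generator's trigram probabilities — including
sentence termination — are exactly defined for recovery checks), word
use within a tag is Zipf-distributed, and *unknown words are injected by
vocabulary partitioning*: a reserved slice of every tag's vocabulary
never appears in training and supplies held-out tokens at the configured
rate (default 0.3).

Two default choices deserve justification:

* **Mild transition structure.** Trigram rows are drawn from
  `Dirichlet(kappa * base)` with a large concentration
  (`kappa = 20000`), i.e. contexts modulate the base tag distribution
  only gently. The generator's purpose is to carry the lexical and
  morphological signal; near-homogeneous transitions keep the trigram
  recovery well-conditioned at the documented problem size (5,000
  training sentences) and prevent transitions from masking emission
  behaviour in the evaluation of the suffix predictors.
* **Disjoint final letters across tags.** No two default inventories
  share a word-final letter, so every suffix row belongs to exactly one
  tag. This makes the suffix signal identifiable by construction — both
  predictors recover it essentially perfectly, and the eight parameter
  sets agree. It is a deliberate idealisation: on natural corpora,
  colliding endings (an adverb class concentrated on `-ly` versus nouns
  in `-ity`) differentiate the predictors, and the two react
  differently — MSL compares within-tag shares of each tag's own longest
  match, while interpolation-plus-inversion additionally divides by the
  matched suffix's overall mass, which rescues deep rare matches but
  amplifies rare tags. Passing tests on the separable defaults
  demonstrates correctness of both implementations, not the real-data
  margin between them; users can create colliding inventories through
  `synthetic_spec()` to study those regimes.

## Numerical and degenerate-input choices

Decoding is in log-space with `-Inf` for structural zeros; backpointer
ties break toward the lower tag-set index, making output reproducible
across platforms. Empty input yields zero sentences; empty corpora,
empty sentences and malformed corpus lines raise errors naming the line.
The problem sizes used by the test suite — 200 random decoding instances
against exhaustive enumeration, a 5,000-word random lexicon for table
properties, 5,000 training sentences for recovery — are the package's
documented desk-scale conditions.

## Known limitations

* The tokenizer's sentence splitting is heuristic (no abbreviation
  dictionary); `Fig. 3` splits.
* The unseen-tag smoothing scale is class-level (see above); on natural
  corpora prefer small `beta`.
* The synthetic generator does not emulate ambiguous words (one surface
  form, several tags), strong syntactic constraints, or colliding suffix
  classes by default, so synthetic accuracies overstate what any tagger
  achieves on real biomedical text.
* Tag sets are closed: tokens can only receive tags seen in training
  material or configuration.
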