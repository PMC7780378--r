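#' Train a bigram language model
#'
#' Counts unigram and bigram occurrences over a corpus of token sequences.
#' Counts are literal; add-k smoothing is applied at query time, so the
#' conditional distribution over the vocabulary for any fixed history sums
#' to one.
#'
#' @param corpus A list of character vectors (one token sequence per
#'   dialogue), or a `pd_corpus`.
#' @param smoothing_k Positive additive smoothing constant (default 1,
#'   add-one).
#' @return An object of class `bigram_lm` with elements `unigram_counts`,
#'   `bigram_counts` (named numeric vectors; bigram names are
#'   "token1 token2"), `vocabulary` and `smoothing_k`.
#' @export
train_bigram_lm <- function(corpus, smoothing_k = 1) {
  if (inherits(corpus, "pd_corpus")) corpus <- corpus$dialogues$tokens
  if (!length(corpus)) {
    abort("Cannot train a bigram model on an empty corpus.",
          class = "pdvoice_validation_error")
  }
  if (smoothing_k <= 0) {
    abort("`smoothing_k` must be > 0.", class = "pdvoice_validation_error")
  }
  corpus <- lapply(corpus, tolower)
  toks <- unlist(corpus, use.names = FALSE)
  uni <- table(toks)
  big_keys <- unlist(lapply(corpus, function(x) {
    if (length(x) < 2) return(character(0))
    paste(x[-length(x)], x[-1])
  }), use.names = FALSE)
  big <- if (length(big_keys)) table(big_keys) else
    table(factor(character(0)))
  structure(list(
    unigram_counts = setNames(as.numeric(uni), names(uni)),
    bigram_counts = setNames(as.numeric(big), names(big)),
    vocabulary = names(uni),
    smoothing_k = smoothing_k),
    class = "bigram_lm")
}

#' Smoothed bigram probability P(token | history)
#'
#' Add-k estimate (count(history, token) + k) / (count(history) + k * V)
#' with V the vocabulary size. Histories or tokens outside the training
#' vocabulary fall back to the uniform smoothed mass.
#'
#' @param lm A `bigram_lm`.
#' @param history,token Single tokens.
#' @return Probability in (0, 1).
#' @export
bigram_prob <- function(lm, history, token) {
  k <- lm$smoothing_k
  V <- length(lm$vocabulary)
  ch <- lm$unigram_counts[history]
  if (is.na(ch)) ch <- 0
  cb <- lm$bigram_counts[paste(history, token)]
  if (is.na(cb)) cb <- 0
  unname((cb + k) / (ch + k * V))
}

#' Correct out-of-vocabulary tokens with a noisy-channel bigram model
#'
#' Each token outside the known vocabulary (the symptom/sentiment lexicon
#' tokens plus corpus tokens seen at least `min_count` times in the
#' language model) is replaced by the known token within edit distance
#' `max_edit` that maximizes the smoothed bigram likelihood of its local
#' window, P(candidate | left) * P(right | candidate); missing context
#' sides fall back to the smoothed unigram probability. Ties are broken
#' lexicographically. Tokens with no candidate pass through unchanged, so
#' the operation is idempotent.
#'
#' @param tokens Character vector of tokens.
#' @param lexicon_vocab Character vector of tokens always considered
#'   in-vocabulary and always available as candidates.
#' @param lm A `bigram_lm` trained on the (noisy) corpus.
#' @param max_edit Maximum edit distance for candidates (default 1).
#' @param min_count Corpus tokens with unigram count at or above this are
#'   treated as in-vocabulary (default 5).
#' @return A list with `tokens` (corrected sequence) and `ledger` (tibble:
#'   position (0-based), original, replacement).
#' @export
correct_typos <- function(tokens, lexicon_vocab, lm, max_edit = 1L,
                          min_count = 5L) {
  stopifnot(inherits(lm, "bigram_lm"))
  if (max_edit < 1) {
    abort("`max_edit` must be >= 1.", class = "pdvoice_validation_error")
  }
  tokens <- tolower(tokens)
  lexicon_vocab <- tolower(lexicon_vocab)
  frequent <- lm$vocabulary[lm$unigram_counts >= min_count]
  known <- unique(c(lexicon_vocab, frequent))
  oov <- which(!tokens %in% known)
  ledger <- list()
  for (i in oov) {
    d <- adist(tokens[i], known)
    cand <- known[d <= max_edit]
    if (!length(cand)) next
    left <- if (i > 1) tokens[i - 1] else NA
    right <- if (i < length(tokens)) tokens[i + 1] else NA
    scores <- vapply(cand, function(w) window_loglik(lm, left, w, right),
                     numeric(1))
    best <- cand[order(-scores, cand)][1]
    if (!identical(best, tokens[i])) {
      ledger[[length(ledger) + 1L]] <-
        tibble(position = i - 1L, original = tokens[i], replacement = best)
      tokens[i] <- best
    }
  }
  list(tokens = tokens,
       ledger = if (length(ledger)) bind_rows(ledger) else
         tibble(position = integer(), original = character(),
                replacement = character()))
}

# Smoothed log-likelihood of `w` in its trigram window.
window_loglik <- function(lm, left, w, right) {
  ll <- 0
  used <- FALSE
  if (!is.na(left)) { ll <- ll + log(bigram_prob(lm, left, w)); used <- TRUE }
  if (!is.na(right)) { ll <- ll + log(bigram_prob(lm, w, right)); used <- TRUE }
  if (!used) {
    k <- lm$smoothing_k
    cu <- lm$unigram_counts[w]
    if (is.na(cu)) cu <- 0
    ll <- log((cu + k) / (sum(lm$unigram_counts) + k * length(lm$vocabulary)))
  }
  unname(ll)
}

#' Cancel double negations in a token sequence
#'
#' Scans left to right; whenever two negation tokens occur within `window`
#' tokens of each other they cancel (double negation reads as affirmation)
#' and both are removed. Pairing is non-overlapping: after a pair is
#' cancelled scanning resumes beyond it. Single (unpaired) negations are
#' preserved; downstream tagging marks the following mention as negated.
#'
#' @param tokens Character vector of tokens.
#' @param negation_vocab Character vector of negation tokens.
#' @param window Maximum token distance between paired negations
#'   (default 3).
#' @return The token sequence with cancelled negation pairs removed.
#' @export
resolve_double_negation <- function(tokens, negation_vocab = negation_tokens(),
                                    window = 3L) {
  if (window < 1) {
    abort("`window` must be >= 1.", class = "pdvoice_validation_error")
  }
  neg_idx <- which(tolower(tokens) %in% tolower(negation_vocab))
  if (length(neg_idx) < 2) return(tokens)
  drop <- integer(0)
  i <- 1L
  while (i < length(neg_idx)) {
    a <- neg_idx[i]
    b <- neg_idx[i + 1L]
    if (b - a <= window) {
      drop <- c(drop, a, b)
      i <- i + 2L
    } else {
      i <- i + 1L
    }
  }
  if (length(drop)) tokens[-drop] else tokens
}
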