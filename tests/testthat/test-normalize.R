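test_that("bigram counts are literal and smoothed conditionals normalize", {
  lm <- train_bigram_lm(list(c("a", "b"), c("a", "b")))
  expect_equal(unname(lm$bigram_counts["a b"]), 2)
  expect_equal(unname(lm$unigram_counts["a"]), 2)
  # P(. | a) sums to 1 over the vocabulary after add-k smoothing
  total <- sum(vapply(lm$vocabulary, function(w) bigram_prob(lm, "a", w),
                      numeric(1)))
  expect_equal(total, 1, tolerance = 1e-12)
  # and for an unseen history as well
  total2 <- sum(vapply(lm$vocabulary, function(w) bigram_prob(lm, "zzz", w),
                       numeric(1)))
  expect_equal(total2, 1, tolerance = 1e-12)

  solo <- train_bigram_lm(list("alone"))
  expect_length(solo$bigram_counts, 0)
  expect_equal(unname(solo$unigram_counts["alone"]), 1)

  expect_error(train_bigram_lm(list()), class = "pdvoice_validation_error")
  expect_error(train_bigram_lm(list(c("a", "b")), smoothing_k = 0),
               class = "pdvoice_validation_error")
})

test_that("in-vocabulary sequences pass through typo correction unchanged", {
  lm <- train_bigram_lm(list(c("the", "tremor", "returned"),
                             c("the", "pain", "returned")))
  vocab <- c("tremor", "pain")
  res <- correct_typos(c("the", "tremor", "returned"), vocab, lm,
                       min_count = 1)
  expect_identical(res$tokens, c("the", "tremor", "returned"))
  expect_equal(nrow(res$ledger), 0)
})

test_that("a unique edit-distance-1 candidate is restored", {
  lm <- train_bigram_lm(list(c("bad", "tremor", "today")))
  res <- correct_typos(c("bad", "tremr", "today"), c("tremor", "pain"), lm,
                       min_count = 1)
  expect_identical(res$tokens, c("bad", "tremor", "today"))
  expect_equal(res$ledger$position, 1L)
  expect_equal(res$ledger$original, "tremr")
  expect_equal(res$ledger$replacement, "tremor")
})

test_that("competing candidates are ranked by bigram likelihood with a lexicographic tie-break", {
  # "cat" and "car" are both edit distance 1 from "cax"; the corpus makes
  # "the cat sat" much more likely than "the car sat".
  corpus <- c(replicate(5, c("the", "cat", "sat"), simplify = FALSE),
              list(c("the", "car", "drove")))
  lm <- train_bigram_lm(corpus)
  res <- correct_typos(c("the", "cax", "sat"), c("cat", "car"), lm,
                       min_count = 1)
  expect_identical(res$tokens[2], "cat")

  # independent brute-force scorer over all candidates
  known <- unique(c("cat", "car", lm$vocabulary))
  cands <- known[drop(utils::adist("cax", known)) <= 1]
  k <- lm$smoothing_k; V <- length(lm$vocabulary)
  cnt <- function(x) { v <- lm$unigram_counts[x]; ifelse(is.na(v), 0, v) }
  bcnt <- function(a, b) { v <- lm$bigram_counts[paste(a, b)]
                           ifelse(is.na(v), 0, v) }
  score <- vapply(cands, function(w) {
    log((bcnt("the", w) + k) / (cnt("the") + k * V)) +
      log((bcnt(w, "sat") + k) / (cnt(w) + k * V))
  }, numeric(1))
  best <- cands[order(-score, cands)][1]
  expect_identical(res$tokens[2], best)

  # exact tie: symmetric corpus, lexicographically smaller candidate wins
  lm2 <- train_bigram_lm(list(c("x", "cat", "y"), c("x", "car", "y")))
  res2 <- correct_typos(c("x", "cax", "y"), c("cat", "car"), lm2,
                        min_count = 1)
  expect_identical(res2$tokens[2], "car")
})

test_that("typo correction is idempotent", {
  co <- generate_corpus(small_config(n = 150, seed = 21, typo_rate = 0.08))
  lm <- train_bigram_lm(co$dialogues$tokens)
  vocab <- pdvoice:::lexicon_token_set(load_symptom_lexicon(),
                                       load_sentiment_lexicon())
  for (i in c(1, 20, 77, 150)) {
    once <- correct_typos(co$dialogues$tokens[[i]], vocab, lm)
    twice <- correct_typos(once$tokens, vocab, lm)
    expect_identical(twice$tokens, once$tokens)
    expect_equal(nrow(twice$ledger), 0)
  }
})

test_that("double negation cancels in pairs, left to right", {
  negs <- c("not", "no")
  expect_identical(resolve_double_negation(c("a", "b", "c"), negs),
                   c("a", "b", "c"))
  expect_identical(resolve_double_negation(c("not", "no", "tremor"), negs),
                   "tremor")
  # two pairs with a filler inside the first
  expect_identical(
    resolve_double_negation(
      c("not", "x", "no", "tremor", "not", "no", "pain"), negs, window = 3),
    c("x", "tremor", "pain"))
  # distant negations stay
  expect_identical(
    resolve_double_negation(c("not", "a", "b", "c", "d", "no", "pain"),
                            negs, window = 3),
    c("not", "a", "b", "c", "d", "no", "pain"))
})

test_that("double-negation cancellation matches the recursive pairing oracle", {
  # declarative oracle: walk the sorted negation positions; the earliest
  # remaining negation pairs with the next one iff within the window
  oracle_pairs <- function(pos, window) {
    if (length(pos) < 2) return(integer(0))
    if (pos[2] - pos[1] <= window) {
      c(pos[1], pos[2], oracle_pairs(pos[-(1:2)], window))
    } else {
      oracle_pairs(pos[-1], window)
    }
  }
  negs <- c("neg1", "neg2")
  set.seed(404)
  for (rep in 1:200) {
    n <- sample(3:14, 1)
    toks <- sample(c("neg1", "neg2", "w1", "w2", "w3"), n, replace = TRUE)
    window <- sample(1:4, 1)
    got <- resolve_double_negation(toks, negs, window)
    drop_idx <- oracle_pairs(which(toks %in% negs), window)
    want <- if (length(drop_idx)) toks[-drop_idx] else toks
    expect_identical(got, want)
    # properties: never longer, even number of negations removed
    expect_lte(length(got), length(toks))
    expect_equal((sum(toks %in% negs) - sum(got %in% negs)) %% 2, 0)
  }
})
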