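#' Tag symptom mentions in a token sequence
#'
#' Greedy longest-match scan, left to right, over the (possibly
#' multi-token) terms of the symptom lexicon. Matches never overlap: at
#' each position the longest matching term wins and scanning resumes after
#' it. Each mention carries the lexicon taxonomy (canonical symptom,
#' category, subcategory) and a `negated` flag, set when an unresolved
#' negation token occurs within two tokens immediately before the span.
#' Matching is case-insensitive.
#'
#' @param tokens Character vector of (normalized) tokens.
#' @param lexicon Symptom lexicon tibble from [load_symptom_lexicon()].
#' @param negation_vocab Tokens that negate the following mention.
#' @return A tibble of mentions with 0-based half-open spans: columns
#'   `canonical_symptom`, `category`, `subcategory`, `start`, `end`,
#'   `nocturnal` (initialized to the lexicon's `nocturnal_only` flag),
#'   `negated`.
#' @export
tag_symptoms <- function(tokens, lexicon = load_symptom_lexicon(),
                         negation_vocab = negation_tokens()) {
  tokens <- tolower(tokens)
  term_len <- lengths(strsplit(lexicon$term, " ", fixed = TRUE))
  term_map <- setNames(seq_len(nrow(lexicon)), lexicon$term)
  max_len <- max(term_len)
  n <- length(tokens)
  hit_j <- hit_start <- hit_len <- integer(0)
  hit_neg <- logical(0)
  # fast path: only attempt multi-token joins where a single token could
  # start a known term
  i <- 1L
  while (i <= n) {
    matched <- 0L
    for (len in seq(min(max_len, n - i + 1L), 1L)) {
      key <- if (len == 1L) tokens[i] else
        paste(tokens[i:(i + len - 1L)], collapse = " ")
      j <- term_map[key]
      if (!is.na(j)) {
        hit_j <- c(hit_j, j)
        hit_start <- c(hit_start, i - 1L)
        hit_len <- c(hit_len, len)
        hit_neg <- c(hit_neg, i > 1L &&
          any(tokens[max(1L, i - 2L):(i - 1L)] %in% negation_vocab))
        matched <- len
        break
      }
    }
    i <- i + max(matched, 1L)
  }
  tibble(canonical_symptom = lexicon$canonical_symptom[hit_j],
         category = lexicon$category[hit_j],
         subcategory = lexicon$subcategory[hit_j],
         start = hit_start, end = hit_start + hit_len,
         nocturnal = lexicon$nocturnal_only[hit_j],
         negated = hit_neg)
}

#' Is a symptom mention in nocturnal context?
#'
#' TRUE iff a nocturnal marker token occurs within `window` tokens of the
#' mention span (on either side), or the symptom is nocturnal-only
#' (insomnia, RBD, ...), which is nocturnal by definition.
#'
#' @param tokens Token sequence containing the mention.
#' @param start,end 0-based half-open span of the mention.
#' @param nocturnal_only Logical: is the symptom nocturnal by definition?
#' @param markers Nocturnal marker tokens.
#' @param window Context window in tokens (default 5).
#' @return Logical scalar.
#' @export
detect_nocturnal_context <- function(tokens, start, end,
                                     nocturnal_only = FALSE,
                                     markers = nocturnal_markers(),
                                     window = 5L) {
  if (window < 1) {
    abort("`window` must be >= 1.", class = "pdvoice_validation_error")
  }
  if (isTRUE(nocturnal_only)) return(TRUE)
  tokens <- tolower(tokens)
  n <- length(tokens)
  before <- seq(max(1L, start - window + 1L), length.out = min(window, start))
  after <- if (end < n) seq(end + 1L, min(n, end + window)) else integer(0)
  any(tokens[c(before, after)] %in% markers)
}

#' Tag the negative-sentiment grades present in a token sequence
#'
#' Returns the set of severity grades (1-6) whose lexicon terms occur at
#' least once; a dialogue may carry several grades (multi-label) and
#' repeats do not change the set.
#'
#' @param tokens Character vector of tokens.
#' @param sentiment_lexicon Tibble from [load_sentiment_lexicon()].
#' @return Sorted integer vector of grades present.
#' @export
tag_sentiment <- function(tokens, sentiment_lexicon = load_sentiment_lexicon()) {
  tokens <- tolower(tokens)
  sort(unique(sentiment_lexicon$grade[sentiment_lexicon$term %in% tokens]))
}

#' Annotate a single dialogue
#'
#' Applies the full deterministic tagging cascade in order: normalization
#' (lowercasing, optional bigram typo correction, double-negation
#' cancellation), symptom tagging, nocturnal-context flagging, sentiment
#' tagging.
#'
#' @param tokens Token sequence of the dialogue.
#' @param symptom_lexicon,sentiment_lexicon Lexicons.
#' @param markers,negation_vocab Context token sets.
#' @param lm Optional `bigram_lm`; when supplied, typo correction runs
#'   before tagging.
#' @param nocturnal_window Context window for nocturnal markers (default 5).
#' @param negation_window Pairing window for double-negation cancellation
#'   (default 3).
#' @param max_edit,min_count Passed to [correct_typos()].
#' @return A list with `tokens` (normalized sequence), `mentions` (tibble
#'   as in [tag_symptoms()] with final `nocturnal` flags) and `grades`
#'   (integer vector).
#' @export
annotate_dialogue <- function(tokens,
                              symptom_lexicon = load_symptom_lexicon(),
                              sentiment_lexicon = load_sentiment_lexicon(),
                              markers = nocturnal_markers(),
                              negation_vocab = negation_tokens(),
                              lm = NULL, nocturnal_window = 5L,
                              negation_window = 3L, max_edit = 1L,
                              min_count = 5L) {
  tokens <- tolower(tokens)
  if (!is.null(lm)) {
    tokens <- correct_typos(tokens,
                            lexicon_vocab = lexicon_token_set(symptom_lexicon,
                                                              sentiment_lexicon),
                            lm = lm, max_edit = max_edit,
                            min_count = min_count)$tokens
  }
  tokens <- resolve_double_negation(tokens, negation_vocab, negation_window)
  mentions <- tag_symptoms(tokens, symptom_lexicon, negation_vocab)
  if (nrow(mentions)) {
    mentions$nocturnal <- vapply(seq_len(nrow(mentions)), function(i) {
      detect_nocturnal_context(tokens, mentions$start[i], mentions$end[i],
                               nocturnal_only = mentions$nocturnal[i],
                               markers = markers, window = nocturnal_window)
    }, logical(1))
  }
  grades <- tag_sentiment(tokens, sentiment_lexicon)
  list(tokens = tokens, mentions = mentions, grades = grades)
}

#' Annotate a corpus
#'
#' Runs [annotate_dialogue()] over every dialogue. When `correct = TRUE`
#' (default) a bigram language model is trained on the corpus itself and
#' used for typo correction.
#'
#' @param corpus A `pd_corpus` (or the tibble from its `dialogues` field).
#' @param correct Train a bigram model on the corpus and correct typos?
#' @param lm Optional pre-trained `bigram_lm` (overrides `correct`).
#' @inheritParams annotate_dialogue
#' @param smoothing_k Add-k constant for the internally trained model.
#' @return An object of class `pd_annotated`: list with `dialogues`
#'   (tibble: id, year, platform, age, n_tokens), `mentions` (tibble with
#'   an `id` column), `grades` (tibble: id, grade).
#' @export
annotate_corpus <- function(corpus,
                            symptom_lexicon = load_symptom_lexicon(),
                            sentiment_lexicon = load_sentiment_lexicon(),
                            markers = nocturnal_markers(),
                            negation_vocab = negation_tokens(),
                            correct = TRUE, lm = NULL,
                            nocturnal_window = 5L, negation_window = 3L,
                            max_edit = 1L, min_count = 5L, smoothing_k = 1) {
  dia <- if (inherits(corpus, "pd_corpus")) corpus$dialogues else corpus
  if (is.null(lm) && correct && nrow(dia)) {
    lm <- train_bigram_lm(dia$tokens, smoothing_k = smoothing_k)
  }
  mention_rows <- vector("list", nrow(dia))
  grade_rows <- vector("list", nrow(dia))
  for (i in seq_len(nrow(dia))) {
    ann <- annotate_dialogue(dia$tokens[[i]], symptom_lexicon,
                             sentiment_lexicon, markers, negation_vocab,
                             lm = lm, nocturnal_window = nocturnal_window,
                             negation_window = negation_window,
                             max_edit = max_edit, min_count = min_count)
    if (nrow(ann$mentions)) {
      ann$mentions$id <- dia$id[i]
      mention_rows[[i]] <- ann$mentions
    }
    if (length(ann$grades)) {
      grade_rows[[i]] <- tibble(id = dia$id[i], grade = ann$grades)
    }
  }
  mentions <- bind_rows(mention_rows)
  if (!nrow(mentions)) {
    mentions <- tibble(canonical_symptom = character(), category = character(),
                       subcategory = character(), start = integer(),
                       end = integer(), nocturnal = logical(),
                       negated = logical(), id = character())
  }
  grades <- bind_rows(grade_rows)
  if (!nrow(grades)) grades <- tibble(id = character(), grade = integer())
  structure(list(
    dialogues = tibble(id = dia$id, year = dia$year, platform = dia$platform,
                       age = dia$age,
                       n_tokens = lengths(dia$tokens)),
    mentions = mentions[, c("id", "canonical_symptom", "category",
                            "subcategory", "start", "end", "nocturnal",
                            "negated")],
    grades = grades),
    class = "pd_annotated")
}

#' @export
print.pd_annotated <- function(x, ...) {
  cat(sprintf("<pd_annotated> %d dialogues, %d mentions, %d grade records\n",
              nrow(x$dialogues), nrow(x$mentions), nrow(x$grades)))
  invisible(x)
}

#' Apply the study inclusion filter
#'
#' Retains exactly the dialogues with at least one non-negated symptom
#' mention, preserving order. Idempotent and monotone.
#'
#' @param annotated A `pd_annotated`.
#' @return A filtered `pd_annotated`.
#' @export
filter_inclusion <- function(annotated) {
  stopifnot(inherits(annotated, "pd_annotated"))
  keep_ids <- unique(annotated$mentions$id[!annotated$mentions$negated])
  keep <- annotated$dialogues$id %in% keep_ids
  structure(list(
    dialogues = annotated$dialogues[keep, ],
    mentions = annotated$mentions[annotated$mentions$id %in%
                                    annotated$dialogues$id[keep], ],
    grades = annotated$grades[annotated$grades$id %in%
                                annotated$dialogues$id[keep], ]),
    class = "pd_annotated")
}
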