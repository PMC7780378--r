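#' Load a symptom lexicon
#'
#' Reads a tab-delimited symptom lexicon with columns `term`,
#' `canonical_symptom`, `category`, `subcategory` and `nocturnal_only`.
#' A term is one token or several space-separated tokens; matching is
#' case-insensitive after normalization. `category` must be one of
#' `motor`, `non_motor` or `motor_complication`; `nocturnal_only` marks
#' symptoms that by definition occur at night (insomnia, RBD, nocturia, ...),
#' whose mentions are always counted as nocturnal.
#'
#' @param path Path to a tab-delimited file with a header row. Defaults to
#'   the lexicon shipped with the package.
#' @return A tibble with one row per term, validated: duplicate terms and
#'   categories outside the closed set are rejected with an informative error.
#' @export
#' @examples
#' lex <- load_symptom_lexicon()
#' head(lex)
load_symptom_lexicon <- function(path = pdvoice_file("symptom_lexicon.tsv")) {
  lex <- read_lexicon_file(path,
    required = c("term", "canonical_symptom", "category", "subcategory",
                 "nocturnal_only"))
  lex$term <- tolower(trimws(lex$term))
  lex$nocturnal_only <- as.logical(lex$nocturnal_only)
  bad_cat <- !lex$category %in% c("motor", "non_motor", "motor_complication")
  if (any(bad_cat)) {
    abort(sprintf(
      "Invalid category %s at line %s: must be motor, non_motor or motor_complication.",
      lex$category[which(bad_cat)[1]], which(bad_cat)[1] + 1L),
      class = "pdvoice_lexicon_error")
  }
  if (anyNA(lex$nocturnal_only)) {
    abort("`nocturnal_only` must be TRUE or FALSE.", class = "pdvoice_lexicon_error")
  }
  dup <- duplicated(lex$term)
  if (any(dup)) {
    abort(sprintf("Duplicate lexicon term '%s'.", lex$term[which(dup)[1]]),
          class = "pdvoice_lexicon_error")
  }
  if (any(!nzchar(lex$canonical_symptom))) {
    abort("`canonical_symptom` must be non-empty.", class = "pdvoice_lexicon_error")
  }
  as_tibble(lex)
}

#' Load a graded negative-sentiment lexicon
#'
#' Reads a tab-delimited sentiment lexicon with columns `term`, `grade`
#' (integer 1-6) and `label`. The grade-to-label mapping is fixed:
#' suspicion = 1, anxiety = 2, fear = 3, agony = 4, anger = 5, sorrow = 6;
#' rows that contradict it are rejected.
#'
#' @param path Path to a tab-delimited file with a header row. Defaults to
#'   the lexicon shipped with the package.
#' @return A tibble with one row per sentiment term.
#' @export
load_sentiment_lexicon <- function(path = pdvoice_file("sentiment_lexicon.tsv")) {
  lex <- read_lexicon_file(path, required = c("term", "grade", "label"))
  lex$term <- tolower(trimws(lex$term))
  lex$grade <- as.integer(lex$grade)
  if (anyNA(lex$grade) || any(!lex$grade %in% 1:6)) {
    abort("Sentiment `grade` must be an integer in 1..6.",
          class = "pdvoice_lexicon_error")
  }
  expected <- sentiment_grade_labels()
  bad <- lex$label != expected[lex$grade]
  if (any(bad)) {
    i <- which(bad)[1]
    abort(sprintf(
      "Sentiment label '%s' does not match grade %d (expected '%s').",
      lex$label[i], lex$grade[i], expected[lex$grade[i]]),
      class = "pdvoice_lexicon_error")
  }
  dup <- duplicated(lex$term)
  if (any(dup)) {
    abort(sprintf("Duplicate sentiment term '%s'.", lex$term[which(dup)[1]]),
          class = "pdvoice_lexicon_error")
  }
  as_tibble(lex)
}

#' Severity grades of the six negative-sentiment categories
#'
#' The fixed weighting used by the negative-sentiment score: suspicion (1),
#' anxiety (2), fear (3), agony (4), anger (5), sorrow (6).
#'
#' @return A named character vector: names are grades "1".."6", values the
#'   category labels.
#' @export
sentiment_grade_labels <- function() {
  setNames(c("suspicion", "anxiety", "fear", "agony", "anger", "sorrow"),
           as.character(1:6))
}

#' Default nocturnal context markers
#'
#' Tokens indicating that a symptom occurred at night or in the early
#' morning (night, midnight, bedtime, morning, ...).
#'
#' @param path Optional path to a one-token-per-line file.
#' @return Character vector of marker tokens.
#' @export
nocturnal_markers <- function(path = pdvoice_file("nocturnal_markers.txt")) {
  tolower(readLines(path, warn = FALSE))
}

#' Default negation tokens
#'
#' @param path Optional path to a one-token-per-line file.
#' @return Character vector of negation tokens.
#' @export
negation_tokens <- function(path = pdvoice_file("negation_tokens.txt")) {
  tolower(readLines(path, warn = FALSE))
}

# Background (non-lexicon) vocabulary used by the synthetic generator.
filler_vocab <- function(path = pdvoice_file("filler_vocab.txt")) {
  tolower(readLines(path, warn = FALSE))
}

pdvoice_file <- function(...) {
  path <- system.file("extdata", ..., package = "pdvoice", mustWork = FALSE)
  if (!nzchar(path)) {
    abort(sprintf("Packaged file not found: %s", file.path(...)),
          class = "pdvoice_io_error")
  }
  path
}

# Shared reader for delimited lexicon files with per-line error reporting.
read_lexicon_file <- function(path, required) {
  if (!file.exists(path)) {
    abort(sprintf("Lexicon file not found: %s", path), class = "pdvoice_io_error")
  }
  df <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character"),
    error = function(e) abort(sprintf("Cannot parse %s: %s", path, conditionMessage(e)),
                              class = "pdvoice_lexicon_error"))
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(sprintf("Lexicon %s is missing column(s): %s", path,
                  paste(missing, collapse = ", ")),
          class = "pdvoice_lexicon_error")
  }
  incomplete <- which(!stats::complete.cases(df[required]) |
                        rowSums(df[required] == "") > 0)
  if (length(incomplete)) {
    abort(sprintf("Malformed lexicon row at line %d of %s.",
                  incomplete[1] + 1L, path),
          class = "pdvoice_lexicon_error")
  }
  df
}

# All single tokens that belong to any lexicon term (components of
# multi-token terms included). The generator keeps filler text disjoint
# from this set so every tagged mention is intentional.
lexicon_token_set <- function(symptom_lexicon, sentiment_lexicon = NULL) {
  toks <- unlist(strsplit(symptom_lexicon$term, " ", fixed = TRUE))
  if (!is.null(sentiment_lexicon)) toks <- c(toks, sentiment_lexicon$term)
  unique(toks)
}
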