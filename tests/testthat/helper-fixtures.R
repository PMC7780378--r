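# Shared fixtures: tiny lexicons and hand-built annotated corpora.

tiny_symptom_lexicon <- function() {
  tibble::tribble(
    ~term, ~canonical_symptom, ~category, ~subcategory, ~nocturnal_only,
    "tremor", "tremor", "motor", "tremor", FALSE,
    "stiffness", "stiffness", "motor", "rigidity", FALSE,
    "insomnia", "insomnia", "non_motor", "sleep_sensory", TRUE,
    "sleep", "poor_sleep_quality", "non_motor", "sleep_sensory", TRUE,
    "poor sleep quality", "poor_sleep_quality", "non_motor", "sleep_sensory", TRUE,
    "pain", "pain", "non_motor", "sleep_sensory", FALSE,
    "dyskinesia", "dyskinesia", "motor_complication", "dyskinesia", FALSE)
}

tiny_sentiment_lexicon <- function() {
  tibble::tibble(
    term = c("doubt", "worried", "afraid", "suffering", "angry", "sad"),
    grade = 1:6,
    label = c("suspicion", "anxiety", "fear", "agony", "anger", "sorrow"))
}

# Write a data frame as a TSV lexicon file; returns the path.
write_tsv_lexicon <- function(df, path = withr::local_tempfile(
                                fileext = ".tsv", .local_envir = parent.frame())) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

# Build a pd_annotated object directly from a compact description:
# a list of dialogues, each list(id, year, mentions = data.frame(
# canonical_symptom, category, subcategory, nocturnal, negated), grades).
make_annotated <- function(dialogues) {
  dia <- tibble::tibble(
    id = vapply(dialogues, `[[`, character(1), "id"),
    year = vapply(dialogues, function(d) as.integer(d$year), integer(1)),
    platform = "test", age = NA_real_, n_tokens = 10L)
  mention_list <- lapply(dialogues, function(d) {
    m <- d$mentions
    if (is.null(m) || !nrow(m)) return(NULL)
    m$id <- d$id
    if (is.null(m$start)) {
      m$start <- seq_len(nrow(m)) * 3L
      m$end <- m$start + 1L
    }
    if (is.null(m$negated)) m$negated <- FALSE
    if (is.null(m$nocturnal)) m$nocturnal <- FALSE
    if (is.null(m$category)) m$category <- "motor"
    if (is.null(m$subcategory)) m$subcategory <- "tremor"
    m
  })
  mentions <- dplyr::bind_rows(mention_list)
  if (is.null(mentions) || !nrow(mentions)) {
    mentions <- tibble::tibble(id = character(), canonical_symptom = character(),
                               category = character(), subcategory = character(),
                               start = integer(), end = integer(),
                               nocturnal = logical(), negated = logical())
  }
  grade_list <- lapply(dialogues, function(d) {
    if (is.null(d$grades) || !length(d$grades)) return(NULL)
    tibble::tibble(id = d$id, grade = as.integer(d$grades))
  })
  grades <- dplyr::bind_rows(grade_list)
  if (is.null(grades) || !nrow(grades)) {
    grades <- tibble::tibble(id = character(), grade = integer())
  }
  structure(list(dialogues = dia,
                 mentions = mentions[, c("id", "canonical_symptom", "category",
                                         "subcategory", "start", "end",
                                         "nocturnal", "negated")],
                 grades = grades),
            class = "pd_annotated")
}

# A small multi-symptom generator configuration whose prevalences sum
# past 1 (so inclusion calibration is exact).
small_config <- function(n = 300, year = 2018, seed = 1,
                         typo_rate = 0, double_negation_rate = 0, ...) {
  generator_config(
    per_year_counts = stats::setNames(n, year),
    symptom_prevalence = data.frame(
      symptom = c("tremor", "insomnia", "pain", "dyskinesia"),
      year = year, prevalence = c(0.6, 0.35, 0.3, 0.1)),
    nocturnal_given_mention = c(tremor = 0.2, pain = 0.25),
    typo_rate = typo_rate, double_negation_rate = double_negation_rate,
    seed = seed, ...)
}

# Independent brute-force symptom tagger: collect every matching span,
# then resolve by leftmost-longest non-overlapping selection.
brute_force_tag <- function(tokens, lexicon) {
  tokens <- tolower(tokens)
  n <- length(tokens)
  cand <- list()
  for (r in seq_len(nrow(lexicon))) {
    tt <- strsplit(lexicon$term[r], " ", fixed = TRUE)[[1]]
    L <- length(tt)
    if (L > n) next
    for (i in seq_len(n - L + 1)) {
      if (all(tokens[i:(i + L - 1)] == tt)) {
        cand[[length(cand) + 1]] <- list(row = r, start = i - 1L,
                                         end = i - 1L + L)
      }
    }
  }
  if (!length(cand)) {
    return(tibble::tibble(canonical_symptom = character(), start = integer(),
                          end = integer()))
  }
  cd <- data.frame(row = sapply(cand, `[[`, "row"),
                   start = sapply(cand, `[[`, "start"),
                   end = sapply(cand, `[[`, "end"))
  picked <- list()
  covered_until <- -1L
  repeat {
    avail <- cd[cd$start > covered_until, ]
    if (!nrow(avail)) break
    s0 <- min(avail$start)
    at <- avail[avail$start == s0, ]
    best <- at[which.max(at$end - at$start), ]
    picked[[length(picked) + 1]] <- best
    covered_until <- best$end - 1L
  }
  pk <- do.call(rbind, picked)
  tibble::tibble(canonical_symptom = lexicon$canonical_symptom[pk$row],
                 start = as.integer(pk$start), end = as.integer(pk$end))
}

# Independent recomputation of the weighted sentiment score from raw
# per-dialogue grade sets.
brute_force_score <- function(eligible_grade_sets) {
  n <- length(eligible_grade_sets)
  if (!n) return(NA_real_)
  total <- 0
  for (g in eligible_grade_sets) total <- total + sum(unique(g))
  # (sum_k k * 100 * count_k / n) / 100 simplifies to total / n
  total / n
}
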