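#' Share-of-voice table
#'
#' Share of voice (SOV) of a unit in a year is the proportion of included
#' dialogues that year with at least one qualifying mention of the unit.
#' A dialogue counts at most once per unit however often it mentions it;
#' negated mentions never qualify; with `nocturnal = TRUE` only mentions
#' flagged nocturnal qualify. Units are canonical symptoms, subcategories,
#' categories, or the overall aggregate (`by = "overall"`), whose SOV is
#' the dialogue-level union over all symptoms — with `nocturnal = TRUE`
#' this is the overall nocturnal aggregate.
#'
#' @param annotated A `pd_annotated`, normally after [filter_inclusion()].
#' @param by One of "symptom", "subcategory", "category", "overall".
#' @param nocturnal Restrict qualifying mentions to nocturnal ones?
#' @param units Optional character vector of units to report (zero rows
#'   are filled in for units with no mentions).
#' @return A tibble with columns `unit`, `year`, `numerator`,
#'   `denominator`, `sov` (proportion in \[0, 1\]).
#' @export
sov_table <- function(annotated, by = c("symptom", "subcategory", "category",
                                        "overall"),
                      nocturnal = FALSE, units = NULL) {
  stopifnot(inherits(annotated, "pd_annotated"))
  by <- match.arg(by)
  denom <- annotated$dialogues %>% count(.data$year, name = "denominator")
  m <- annotated$mentions %>% filter(!.data$negated)
  if (nocturnal) m <- m %>% filter(.data$nocturnal)
  key <- switch(by, symptom = "canonical_symptom", subcategory = "subcategory",
                category = "category", overall = NULL)
  m <- m %>%
    left_join(annotated$dialogues[, c("id", "year")], by = "id")
  if (is.null(key)) {
    m$unit <- if (nocturnal) "overall_nocturnal" else "overall"
  } else {
    m$unit <- m[[key]]
    if (nocturnal) m$unit <- paste0(m$unit, "_nocturnal")
  }
  num <- m %>%
    distinct(.data$unit, .data$year, .data$id) %>%
    count(.data$unit, .data$year, name = "numerator")
  grid <- tidyr::crossing(
    unit = if (!is.null(units)) units else unique(num$unit),
    year = denom$year)
  grid %>%
    left_join(num, by = c("unit", "year")) %>%
    left_join(denom, by = "year") %>%
    mutate(numerator = ifelse(is.na(.data$numerator), 0L, .data$numerator),
           sov = .data$numerator / .data$denominator) %>%
    arrange(.data$unit, .data$year)
}

#' Share of voice of one unit in one year
#'
#' @inheritParams sov_table
#' @param unit Unit name (a canonical symptom for `by = "symptom"`, etc.;
#'   ignored for `by = "overall"`). For `nocturnal = TRUE` the unit may be
#'   given with or without the `_nocturnal` suffix.
#' @param year Calendar year.
#' @return A one-row tibble as in [sov_table()].
#' @export
compute_sov <- function(annotated, unit, year,
                        by = c("symptom", "subcategory", "category",
                               "overall"),
                        nocturnal = FALSE) {
  by <- match.arg(by)
  tab <- sov_table(annotated, by = by, nocturnal = nocturnal)
  if (!year %in% annotated$dialogues$year) {
    abort(sprintf("No included dialogues in year %s: SOV denominator undefined.",
                  year), class = "pdvoice_validation_error")
  }
  target <- if (by == "overall") {
    if (nocturnal) "overall_nocturnal" else "overall"
  } else if (nocturnal && !grepl("_nocturnal$", unit)) {
    paste0(unit, "_nocturnal")
  } else unit
  row <- tab[tab$unit == target & tab$year == year, ]
  if (!nrow(row)) {
    denom <- sum(annotated$dialogues$year == year)
    row <- tibble(unit = target, year = year, numerator = 0L,
                  denominator = denom, sov = 0)
  }
  row
}

#' Compounded annual growth rate
#'
#' The constant per-period growth rate connecting a start and end value:
#' (v_end / v_start)^(1/n_years) - 1. Scale-invariant, so percentages and
#' proportions give the same result.
#'
#' @param v_start Starting value, strictly positive.
#' @param v_end Ending value, non-negative.
#' @param n_years Number of compounding periods (>= 1).
#' @return Growth rate as a proportion per year.
#' @export
#' @examples
#' compute_cagr(25.3, 29.5, 2)  # ~ +0.080
compute_cagr <- function(v_start, v_end, n_years) {
  if (any(n_years < 1)) {
    abort("`n_years` must be >= 1.", class = "pdvoice_validation_error")
  }
  if (any(v_start <= 0)) {
    abort("CAGR is undefined for a non-positive starting value.",
          class = "pdvoice_undefined_growth_error")
  }
  (v_end / v_start)^(1 / n_years) - 1
}

#' Weighted negative-sentiment score for a symptom
#'
#' Eligible dialogues are those with at least one qualifying (non-negated;
#' nocturnal if requested) mention of the symptom AND at least one
#' sentiment grade. For each grade k, p_k is the percentage of eligible
#' dialogues carrying grade k (multi-label: percentages may sum past 100).
#' The score is (p_1*1 + p_2*2 + ... + p_6*6) / 100, bounded in \[1, 21\]
#' when any dialogue is eligible.
#'
#' @param annotated A `pd_annotated`.
#' @param unit Canonical symptom name.
#' @param nocturnal_only_mentions Restrict qualifying mentions to nocturnal
#'   ones?
#' @return A one-row tibble: `unit`, `nocturnal`, `n_eligible`, `p_1` ...
#'   `p_6`, `score` (NA when no dialogue is eligible).
#' @export
compute_sentiment_score <- function(annotated, unit,
                                    nocturnal_only_mentions = FALSE) {
  stopifnot(inherits(annotated, "pd_annotated"))
  m <- annotated$mentions %>%
    filter(!.data$negated, .data$canonical_symptom == unit)
  if (nocturnal_only_mentions) m <- m %>% filter(.data$nocturnal)
  with_symptom <- unique(m$id)
  with_sentiment <- unique(annotated$grades$id)
  eligible <- intersect(with_symptom, with_sentiment)
  n_eligible <- length(eligible)
  if (!n_eligible) {
    return(tibble(unit = unit, nocturnal = nocturnal_only_mentions,
                  n_eligible = 0L,
                  !!!setNames(as.list(rep(NA_real_, 6)), paste0("p_", 1:6)),
                  score = NA_real_))
  }
  g <- annotated$grades[annotated$grades$id %in% eligible, ]
  p <- vapply(1:6, function(k) {
    100 * length(unique(g$id[g$grade == k])) / n_eligible
  }, numeric(1))
  tibble(unit = unit, nocturnal = nocturnal_only_mentions,
         n_eligible = n_eligible,
         !!!setNames(as.list(p), paste0("p_", 1:6)),
         score = sum(p * (1:6)) / 100)
}

#' Sentiment scores for every symptom with eligible dialogues
#'
#' @inheritParams compute_sentiment_score
#' @param nocturnal Score nocturnal mentions only?
#' @return A tibble of [compute_sentiment_score()] rows, one per symptom
#'   with `n_eligible > 0`.
#' @export
sentiment_table <- function(annotated, nocturnal = FALSE) {
  units <- sort(unique(annotated$mentions$canonical_symptom))
  rows <- lapply(units, function(u) {
    compute_sentiment_score(annotated, u, nocturnal_only_mentions = nocturnal)
  })
  bind_rows(rows) %>% filter(.data$n_eligible > 0)
}

#' Compare any-time and nocturnal sentiment scores per symptom
#'
#' Pairs each symptom's any-time score with its nocturnal score. Symptoms
#' that occur exclusively at night are excluded (their two scores would be
#' identical by construction); symptoms present in only one table are
#' skipped with a message. No significance test is attached.
#'
#' @param any_time_scores,nocturnal_scores Tibbles from
#'   [sentiment_table()] (any-time and nocturnal-only runs).
#' @param symptom_lexicon Lexicon used to identify nocturnal-only symptoms.
#' @return A tibble: `unit`, `score_any`, `score_nocturnal`, `difference`
#'   (nocturnal minus any-time).
#' @export
compare_day_night <- function(any_time_scores, nocturnal_scores,
                              symptom_lexicon = load_symptom_lexicon()) {
  lex <- symptom_lexicon[!duplicated(symptom_lexicon$canonical_symptom), ]
  noct_only <- lex$canonical_symptom[lex$nocturnal_only]
  a <- any_time_scores %>%
    filter(!.data$unit %in% noct_only) %>%
    select("unit", score_any = "score")
  b <- nocturnal_scores %>%
    filter(!.data$unit %in% noct_only) %>%
    select("unit", score_nocturnal = "score")
  skipped <- union(setdiff(a$unit, b$unit), setdiff(b$unit, a$unit))
  if (length(skipped)) {
    message("Skipping unmatched unit(s): ", paste(skipped, collapse = ", "))
  }
  inner_join(a, b, by = "unit") %>%
    mutate(difference = .data$score_nocturnal - .data$score_any)
}
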