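#' Demographic summary of a dialogue corpus
#'
#' Bins patient ages into groups at the given cutpoints (default 50/60/70,
#' giving <50, 50-60, 60-70, >70; intervals are left-closed) and reports
#' counts and percentages over dialogues that carry an age. Percentages
#' are kept at full precision; rounding happens only when tables are
#' written.
#'
#' @param corpus A `pd_corpus` or a tibble with an `age` column.
#' @param bin_edges Increasing age cutpoints.
#' @return A list of class `pd_demographics`: `table` (tibble: age_group,
#'   n, pct), `n_total` (dialogues with age), `mean_age`, `sd_age`.
#' @export
demographics_summary <- function(corpus, bin_edges = c(50, 60, 70)) {
  d <- if (inherits(corpus, "pd_corpus")) corpus$dialogues else corpus
  ages <- d$age[!is.na(d$age)]
  labels <- c(paste0("<", bin_edges[1]),
              if (length(bin_edges) > 1)
                paste0(head(bin_edges, -1), "-", tail(bin_edges, -1)),
              paste0(">", tail(bin_edges, 1)))
  if (!length(ages)) {
    return(structure(list(
      table = tibble(age_group = labels, n = 0L, pct = NA_real_),
      n_total = 0L, mean_age = NA_real_, sd_age = NA_real_),
      class = "pd_demographics"))
  }
  bins <- cut(ages, breaks = c(-Inf, bin_edges, Inf), labels = labels,
              right = FALSE)
  tab <- as.data.frame(table(bins), stringsAsFactors = FALSE)
  out <- tibble(age_group = labels,
                n = as.integer(tab$Freq[match(labels, tab$bins)]),
                pct = 100 * .data$n / length(ages))
  structure(list(table = out, n_total = length(ages),
                 mean_age = mean(ages), sd_age = stats::sd(ages)),
            class = "pd_demographics")
}

#' @export
print.pd_demographics <- function(x, ...) {
  cat(sprintf("<pd_demographics> n = %d, mean age %.1f (SD %.1f)\n",
              x$n_total, x$mean_age, x$sd_age))
  tab <- x$table
  tab$pct <- round(tab$pct, 1)
  print(as.data.frame(tab), row.names = FALSE)
  invisible(x)
}

#' Read a pipeline configuration file
#'
#' YAML with either a `generator` section (fields of [generator_config()];
#' `symptom_prevalence` and `sentiment_mixture` as lists of records) or a
#' `corpus_path` (line-delimited records as written by [write_corpus()]),
#' plus optional `lexicons` (symptom/sentiment/markers/negations paths)
#' and `windows` (nocturnal/negation) sections.
#'
#' @param path Path to a YAML file.
#' @return The parsed configuration list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Config file not found: %s", path),
          class = "pdvoice_io_error")
  }
  yaml::read_yaml(path)
}

#' Run the full analysis pipeline
#'
#' Generate (or ingest) a corpus, normalize and annotate it, apply the
#' inclusion filter, and assemble every output table: demographics,
#' per-unit SOV for symptoms, subcategories, categories and the nocturnal
#' aggregate, trend rows (first-to-last-year SOV with CAGR and p-value),
#' between-group comparisons per year, any-time and nocturnal sentiment
#' scores, and the day-night contrast. Reproducible: the same
#' configuration and seed give identical outputs.
#'
#' @param config A configuration list (see [read_pipeline_config()]) or a
#'   path to a YAML file.
#' @param seed Optional integer overriding the configured generator seed.
#' @param out_dir Optional directory; when given, all tables are written
#'   as CSV plus a `run_metadata.json` via [write_report_bundle()].
#' @param quiet Suppress per-stage log messages?
#' @return A list of class `pd_report`: `demographics`, `sov_symptom`,
#'   `sov_subcategory`, `sov_category`, `sov_nocturnal`,
#'   `sov_nocturnal_overall`, `trend`, `comparisons`, `sentiment_any`,
#'   `sentiment_nocturnal`, `day_night`, `meta`.
#' @export
run_pipeline <- function(config, seed = NULL, out_dir = NULL, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  say <- function(...) if (!quiet) message(sprintf(...))

  lex_paths <- config$lexicons %||% list()
  symptom_lexicon <- load_symptom_lexicon(
    lex_paths$symptom %||% pdvoice_file("symptom_lexicon.tsv"))
  sentiment_lexicon <- load_sentiment_lexicon(
    lex_paths$sentiment %||% pdvoice_file("sentiment_lexicon.tsv"))
  markers <- if (!is.null(lex_paths$markers))
    nocturnal_markers(lex_paths$markers) else nocturnal_markers()
  negations <- if (!is.null(lex_paths$negations))
    negation_tokens(lex_paths$negations) else negation_tokens()

  if (!is.null(config$generator)) {
    g <- config$generator
    if (!is.null(seed)) g$seed <- seed
    gc <- generator_config(
      per_year_counts = unlist(g$per_year_counts),
      symptom_prevalence = bind_rows(lapply(g$symptom_prevalence, as_tibble)),
      nocturnal_given_mention = if (!is.null(g$nocturnal_given_mention))
        unlist(g$nocturnal_given_mention),
      sentiment_mixture = if (!is.null(g$sentiment_mixture))
        bind_rows(lapply(g$sentiment_mixture, as_tibble)),
      typo_rate = g$typo_rate %||% 0.02,
      double_negation_rate = g$double_negation_rate %||% 0.02,
      demographic_rate = g$demographic_rate %||% 0.19,
      age_mean = g$age_mean %||% 63, age_sd = g$age_sd %||% 13.4,
      background_symptomless_rate = g$background_symptomless_rate %||% 0,
      seed = g$seed %||% 1L,
      symptom_lexicon = symptom_lexicon)
    corpus <- generate_corpus(gc, symptom_lexicon, sentiment_lexicon)
    say("generated %d dialogues", nrow(corpus$dialogues))
  } else if (!is.null(config$corpus_path)) {
    corpus <- read_corpus(config$corpus_path)
    say("ingested %d dialogues from %s", nrow(corpus$dialogues),
        config$corpus_path)
  } else {
    abort("Config needs either a `generator` section or a `corpus_path`.",
          class = "pdvoice_config_error")
  }

  win <- config$windows %||% list()
  annotated <- annotate_corpus(
    corpus, symptom_lexicon, sentiment_lexicon, markers, negations,
    nocturnal_window = win$nocturnal %||% 5L,
    negation_window = win$negation %||% 3L)
  included <- filter_inclusion(annotated)
  say("annotated %d dialogues; %d included after filtering",
      nrow(annotated$dialogues), nrow(included$dialogues))
  if (!nrow(included$dialogues)) {
    abort(sprintf(
      "No dialogue passed the inclusion filter (raw: %d, annotated: %d).",
      nrow(corpus$dialogues), nrow(annotated$dialogues)),
      class = "pdvoice_pipeline_error")
  }

  demographics <- demographics_summary(corpus)
  sov_symptom <- sov_table(included, by = "symptom")
  sov_subcategory <- sov_table(included, by = "subcategory")
  sov_category <- sov_table(included, by = "category")
  sov_nocturnal <- sov_table(included, by = "symptom", nocturnal = TRUE)
  sov_noct_overall <- sov_table(included, by = "overall", nocturnal = TRUE)

  years <- sort(unique(included$dialogues$year))
  trend <- NULL
  if (length(years) >= 2) {
    y0 <- years[1]
    y1 <- years[length(years)]
    all_units <- bind_rows(sov_symptom, sov_category, sov_noct_overall)
    trend <- bind_rows(lapply(unique(all_units$unit), function(u) {
      r0 <- all_units[all_units$unit == u & all_units$year == y0, ]
      r1 <- all_units[all_units$unit == u & all_units$year == y1, ]
      if (!nrow(r0) || !nrow(r1)) return(NULL)
      tt <- trend_test(r0, r1)
      tibble(unit = u, sov_start = r0$sov, sov_end = r1$sov,
             n_years = y1 - y0,
             cagr = if (r0$sov > 0) compute_cagr(r0$sov, r1$sov, y1 - y0)
                    else NA_real_,
             statistic = tt$statistic, p_value = tt$p_value)
    }))
  }

  comparisons <- bind_rows(lapply(years, function(y) {
    pairs <- list(c("motor", "non_motor"),
                  c("non_motor", "motor_complication"),
                  c("motor", "motor_complication"))
    bind_rows(lapply(pairs, function(pr) {
      ra <- compute_sov(included, pr[1], y, by = "category")
      rb <- compute_sov(included, pr[2], y, by = "category")
      between_group_test(ra, rb)
    }))
  }))

  sentiment_any <- sentiment_table(included, nocturnal = FALSE)
  sentiment_noct <- sentiment_table(included, nocturnal = TRUE)
  day_night <- compare_day_night(sentiment_any, sentiment_noct,
                                 symptom_lexicon)

  meta <- list(
    package_version = as.character(utils::packageVersion("pdvoice")),
    config_hash = rlang::hash(config),
    seed = if (!is.null(config$generator))
      (if (!is.null(seed)) seed else config$generator$seed %||% 1L),
    n_raw = nrow(corpus$dialogues),
    n_annotated = nrow(annotated$dialogues),
    n_included = nrow(included$dialogues),
    n_tests = (if (is.null(trend)) 0L else nrow(trend)) + nrow(comparisons))

  bundle <- structure(list(
    demographics = demographics,
    sov_symptom = sov_symptom, sov_subcategory = sov_subcategory,
    sov_category = sov_category, sov_nocturnal = sov_nocturnal,
    sov_nocturnal_overall = sov_noct_overall,
    trend = trend, comparisons = comparisons,
    sentiment_any = sentiment_any, sentiment_nocturnal = sentiment_noct,
    day_night = day_night, meta = meta),
    class = "pd_report")
  if (!is.null(out_dir)) write_report_bundle(bundle, out_dir)
  bundle
}

#' @export
print.pd_report <- function(x, ...) {
  cat(sprintf("<pd_report> %d included dialogues, %d SOV units, %d tests\n",
              x$meta$n_included, length(unique(x$sov_symptom$unit)),
              x$meta$n_tests))
  invisible(x)
}

#' Write a report bundle to CSV
#'
#' Writes every table of a `pd_report` as CSV plus `run_metadata.json`.
#' Display rounding follows the study conventions: SOV and percentage
#' columns to one decimal (percent scale), sentiment scores to one
#' decimal, p-values below 0.01 shown as "<0.01". Full-precision columns
#' are kept alongside the display columns.
#'
#' @param bundle A `pd_report`.
#' @param out_dir Output directory, created if needed.
#' @return `out_dir`, invisibly.
#' @export
write_report_bundle <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "pd_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    utils::write.csv(df, file.path(out_dir, paste0(name, ".csv")),
                     row.names = FALSE)
  }
  dem <- bundle$demographics$table
  dem$pct_display <- round(dem$pct, 1)
  w(dem, "demographics")
  for (nm in c("sov_symptom", "sov_subcategory", "sov_category",
               "sov_nocturnal", "sov_nocturnal_overall")) {
    df <- bundle[[nm]]
    df$sov_pct_display <- round(100 * df$sov, 1)
    w(df, nm)
  }
  if (!is.null(bundle$trend)) {
    tr <- bundle$trend
    tr$cagr_pct_display <- round(100 * tr$cagr, 1)
    tr$p_display <- format_p(tr$p_value)
    w(tr, "trend")
  }
  cmp <- bundle$comparisons
  cmp$p_display <- format_p(cmp$p_value)
  w(cmp, "comparisons")
  for (nm in c("sentiment_any", "sentiment_nocturnal")) {
    df <- bundle[[nm]]
    df$score_display <- round(df$score, 1)
    w(df, nm)
  }
  w(bundle$day_night, "day_night")
  jsonlite::write_json(bundle$meta,
                       file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

# Study display convention for p-values.
format_p <- function(p) {
  ifelse(p < 0.01, "<0.01", sprintf("%.2f", p))
}
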