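#' Build and validate a synthetic-corpus generator configuration
#'
#' The configuration fixes every statistical property of a generated
#' dialogue corpus: per-year dialogue counts, per-symptom per-year mention
#' prevalences, nocturnal-context probabilities, graded sentiment-word
#' mixtures, noise rates, and the demographic model. All probabilities are
#' validated to lie in \[0, 1\] and all symptom names must resolve in the
#' symptom lexicon.
#'
#' Prevalences are interpreted as the probability that an *included*
#' (symptom-bearing) dialogue mentions the symptom, matching how share of
#' voice is defined downstream. When `background_symptomless_rate` is 0 the
#' generator guarantees every dialogue carries at least one symptom and
#' calibrates the sampling so the per-symptom rate equals the configured
#' prevalence exactly in expectation (see [generate_corpus()]).
#'
#' @param per_year_counts Named non-negative integer vector, names are
#'   calendar years, values the number of dialogues to generate per year.
#' @param symptom_prevalence Data frame with columns `symptom`, `year`,
#'   `prevalence`: probability in \[0, 1\] that a dialogue in that year
#'   mentions the symptom. Symptom/year pairs not listed have prevalence 0.
#' @param nocturnal_given_mention Named numeric vector: probability that a
#'   mention of the named symptom carries nocturnal context. Symptoms
#'   flagged `nocturnal_only` in the lexicon are always nocturnal.
#' @param sentiment_mixture Data frame with columns `symptom`, `grade`
#'   (1-6), `prob`: probability that a dialogue bearing the symptom
#'   contains a sentiment word of that grade; grades fire independently
#'   (multi-label). Defaults to [default_sentiment_mixture()] over the
#'   configured symptoms.
#' @param typo_rate Per-lexicon-token corruption probability.
#' @param double_negation_rate Per-mention probability that a symptom
#'   mention is wrapped in two negation tokens.
#' @param demographic_rate Probability a dialogue carries a patient age.
#' @param age_mean,age_sd Normal age model (years), truncated at `age_min`.
#' @param age_min Minimum age; draws below it are resampled.
#' @param background_symptomless_rate Probability that a raw dialogue
#'   carries no symptom at all (emulating crawled dialogues that the
#'   inclusion filter later drops).
#' @param seed Integer seed; the corpus is fully reproducible from it.
#' @param platform Free-form platform label stamped on every dialogue.
#' @param filler_range Length-2 integer vector: range of background filler
#'   tokens per dialogue.
#' @param symptom_lexicon Symptom lexicon used to validate symptom names.
#' @return A validated list of class `pdvoice_config`.
#' @export
#' @examples
#' cfg <- generator_config(
#'   per_year_counts = c("2018" = 50),
#'   symptom_prevalence = data.frame(
#'     symptom = c("tremor", "insomnia"), year = 2018,
#'     prevalence = c(0.6, 0.5)))
generator_config <- function(per_year_counts,
                             symptom_prevalence,
                             nocturnal_given_mention = NULL,
                             sentiment_mixture = NULL,
                             typo_rate = 0.02,
                             double_negation_rate = 0.02,
                             demographic_rate = 0.19,
                             age_mean = 63,
                             age_sd = 13.4,
                             age_min = 18,
                             background_symptomless_rate = 0,
                             seed = 1L,
                             platform = "e-consult",
                             filler_range = c(8L, 14L),
                             symptom_lexicon = load_symptom_lexicon()) {
  if (is.null(names(per_year_counts)) || anyNA(suppressWarnings(
        as.integer(names(per_year_counts))))) {
    abort("`per_year_counts` must be named by calendar year.",
          class = "pdvoice_validation_error")
  }
  if (any(per_year_counts < 0) || anyNA(per_year_counts)) {
    abort("`per_year_counts` must be non-negative.",
          class = "pdvoice_validation_error")
  }
  sp <- as_tibble(symptom_prevalence)
  if (!all(c("symptom", "year", "prevalence") %in% names(sp))) {
    abort("`symptom_prevalence` needs columns symptom, year, prevalence.",
          class = "pdvoice_validation_error")
  }
  check_prob(sp$prevalence, "symptom_prevalence$prevalence")
  unknown <- setdiff(sp$symptom, symptom_lexicon$canonical_symptom)
  if (length(unknown)) {
    abort(sprintf("Unknown symptom name(s) in config: %s",
                  paste(unknown, collapse = ", ")),
          class = "pdvoice_config_error")
  }
  symptoms <- unique(sp$symptom)
  if (is.null(nocturnal_given_mention)) {
    nocturnal_given_mention <- setNames(numeric(length(symptoms)), symptoms)
  }
  check_prob(nocturnal_given_mention, "nocturnal_given_mention")
  unknown <- setdiff(names(nocturnal_given_mention), symptom_lexicon$canonical_symptom)
  if (length(unknown)) {
    abort(sprintf("Unknown symptom name(s) in `nocturnal_given_mention`: %s",
                  paste(unknown, collapse = ", ")),
          class = "pdvoice_config_error")
  }
  if (is.null(sentiment_mixture)) {
    sentiment_mixture <- default_sentiment_mixture(symptoms)
  }
  sm <- as_tibble(sentiment_mixture)
  if (!all(c("symptom", "grade", "prob") %in% names(sm))) {
    abort("`sentiment_mixture` needs columns symptom, grade, prob.",
          class = "pdvoice_validation_error")
  }
  if (any(!sm$grade %in% 1:6)) {
    abort("Sentiment mixture grades must be in 1..6.",
          class = "pdvoice_validation_error")
  }
  check_prob(sm$prob, "sentiment_mixture$prob")
  unknown <- setdiff(sm$symptom, symptom_lexicon$canonical_symptom)
  if (length(unknown)) {
    abort(sprintf("Unknown symptom name(s) in `sentiment_mixture`: %s",
                  paste(unknown, collapse = ", ")),
          class = "pdvoice_config_error")
  }
  check_prob(typo_rate, "typo_rate")
  check_prob(double_negation_rate, "double_negation_rate")
  check_prob(demographic_rate, "demographic_rate")
  check_prob(background_symptomless_rate, "background_symptomless_rate")
  structure(list(
    per_year_counts = setNames(as.integer(per_year_counts),
                               names(per_year_counts)),
    symptom_prevalence = sp,
    nocturnal_given_mention = nocturnal_given_mention,
    sentiment_mixture = sm,
    typo_rate = typo_rate,
    double_negation_rate = double_negation_rate,
    demographic_rate = demographic_rate,
    age_mean = age_mean, age_sd = age_sd, age_min = age_min,
    background_symptomless_rate = background_symptomless_rate,
    seed = as.integer(seed),
    platform = platform,
    filler_range = as.integer(filler_range)),
    class = "pdvoice_config")
}

#' Default graded sentiment mixture for a set of symptoms
#'
#' Builds per-symptom grade probabilities whose conditional weighted score
#' (the negative-sentiment score among dialogues carrying at least one
#' grade) equals a target, by default the symptom's reported any-time
#' score (3.0 for symptoms without one). Targets up to 6 put mass 0.45 on
#' the two grades bracketing the target, with the split solved so the
#' conditional score is exact; targets above 6 - which require several
#' grades co-occurring in one dialogue - put equal mass on grades 4-6,
#' again solved exactly (reachable up to 15).
#'
#' @param symptoms Character vector of canonical symptom names.
#' @param scores Optional named numeric vector of target scores in \[1, 15\].
#' @return A tibble with columns `symptom`, `grade`, `prob`.
#' @export
default_sentiment_mixture <- function(symptoms, scores = NULL) {
  ref <- sentiment_reference()
  target <- setNames(rep(3.0, length(symptoms)), symptoms)
  hit <- intersect(symptoms, ref$unit[!is.na(ref$score_any)])
  target[hit] <- ref$score_any[match(hit, ref$unit)]
  if (!is.null(scores)) target[names(scores)] <- scores
  bind_rows(lapply(symptoms, function(s) {
    tibble(symptom = s, grade = 1:6,
           prob = grade_mixture_for_score(target[[s]]))
  }))
}

# Grade probabilities (length 6) whose conditional score equals `score`.
grade_mixture_for_score <- function(score, intensity = 0.45) {
  stopifnot(score >= 1, score <= 15)
  p <- numeric(6)
  if (score <= 6) {
    k0 <- min(floor(score), 5)
    cond <- function(f) {
      pa <- intensity * (1 - f)
      pb <- intensity * f
      num <- k0 * pa + (k0 + 1) * pb
      num / (1 - (1 - pa) * (1 - pb)) - score
    }
    f <- if (cond(0) >= 0) 0 else if (cond(1) <= 0) 1 else
      stats::uniroot(cond, c(0, 1), tol = 1e-10)$root
    p[k0] <- intensity * (1 - f)
    if (k0 < 6) p[k0 + 1] <- intensity * f
  } else {
    cond <- function(s) 15 * s / (1 - (1 - s)^3) - score
    s <- stats::uniroot(cond, c(1e-9, 1), tol = 1e-10)$root
    p[4:6] <- s
  }
  p
}

#' Study-scale generator configuration
#'
#' The default emulation of the reference corpus: included-dialogue counts
#' 7524/5198/2397 for 2016-2018, per-symptom prevalences from the reported
#' overall SOV tables, nocturnal-context probabilities derived from the
#' nocturnal SOV table (nocturnal SOV / overall SOV per symptom and year,
#' averaged over years), ~19% demographic availability with ages
#' N(63, 13.4^2) truncated at 18, and mild noise.
#'
#' @param years Years to include (subset of 2016:2018).
#' @param scale Multiplier on per-year counts (use < 1 for quick demos).
#' @param seed Integer seed.
#' @param ... Overrides passed on to [generator_config()].
#' @return A `pdvoice_config`.
#' @export
study_config <- function(years = 2016:2018, scale = 1, seed = 1L, ...) {
  ref <- sov_reference()
  dem <- demographics_reference()
  counts <- round(dem$per_year_counts[as.character(years)] * scale)
  overall <- ref[ref$block != "nocturnal" & !is.na(ref$unit), ]
  prev <- tidyr::pivot_longer(
    overall, cols = c("sov_2016", "sov_2017", "sov_2018"),
    names_to = "year", names_prefix = "sov_", values_to = "prevalence") %>%
    mutate(year = as.integer(.data$year),
           prevalence = .data$prevalence / 100) %>%
    filter(.data$year %in% years) %>%
    select(symptom = "unit", "year", "prevalence")
  noct <- ref[ref$block == "nocturnal" & !is.na(ref$unit) &
                ref$unit != "overall_nocturnal", ]
  ratio <- vapply(seq_len(nrow(noct)), function(i) {
    u <- noct$unit[i]
    ov <- overall[overall$unit == u, ]
    if (!nrow(ov)) return(1)
    r <- c(noct$sov_2016[i] / ov$sov_2016, noct$sov_2017[i] / ov$sov_2017,
           noct$sov_2018[i] / ov$sov_2018)
    min(1, mean(r))
  }, numeric(1))
  noct_given <- setNames(ratio, noct$unit)
  # frequent_nocturia has no overall counterpart; it is nocturnal_only.
  generator_config(
    per_year_counts = counts,
    symptom_prevalence = prev,
    nocturnal_given_mention = noct_given,
    demographic_rate = dem$n_with_age / sum(dem$per_year_counts),
    age_mean = dem$age_mean, age_sd = dem$age_sd,
    seed = seed, ...)
}

# Deflate-and-reject calibration. Returns Bernoulli probabilities q such
# that, conditional on at least one success, the marginal success rate of
# each symptom equals p exactly: q = c * p with c the positive fixed point
# of c = 1 - prod(1 - c p). A positive fixed point exists when sum(p) > 1
# (or some p = 1); otherwise plain sampling is used and the conditional
# rates exceed p (documented fallback).
calibrate_inclusion <- function(p) {
  if (!length(p) || any(p >= 1) || sum(p) <= 1) {
    return(list(q = p, calibrated = any(p >= 1) || !length(p)))
  }
  c_old <- 1
  for (i in 1:200) {
    c_new <- 1 - prod(1 - c_old * p)
    if (abs(c_new - c_old) < 1e-14) break
    c_old <- c_new
  }
  list(q = c_old * p, calibrated = TRUE)
}

#' Generate a synthetic dialogue corpus with ground truth
#'
#' Generates exactly `per_year_counts[y]` dialogues for each configured
#' year. Each dialogue is an ordered token sequence of background filler
#' words with symptom terms, nocturnal context markers, graded sentiment
#' words, injected typos and double negations interleaved per the
#' configuration. Ground-truth annotations (symptom mentions with spans and
#' nocturnal flags, sentiment grades, corruption ledger) are returned
#' alongside so downstream stages can be tested for exact recovery.
#'
#' Each dialogue draws from its own pseudo-random stream keyed by
#' (seed, year, index), so regeneration is order-independent and two runs
#' with the same configuration are identical.
#'
#' Mention spans in the ground truth refer to the clean (pre-noise) token
#' sequence; when `typo_rate` and `double_negation_rate` are both zero the
#' stored tokens are that clean sequence and the annotate stage recovers
#' the truth exactly.
#'
#' @param config A `pdvoice_config` from [generator_config()].
#' @param symptom_lexicon,sentiment_lexicon Lexicons used to realize
#'   mentions as tokens (defaults: packaged lexicons).
#' @return An object of class `pd_corpus`: a list with `dialogues` (tibble:
#'   id, year, platform, age, tokens list-column), `truth` (list of tibbles
#'   `mentions`, `grades`, `corruptions`) and `config`.
#' @export
generate_corpus <- function(config,
                            symptom_lexicon = load_symptom_lexicon(),
                            sentiment_lexicon = load_sentiment_lexicon()) {
  stopifnot(inherits(config, "pdvoice_config"))
  unknown <- setdiff(config$symptom_prevalence$symptom,
                     symptom_lexicon$canonical_symptom)
  if (length(unknown)) {
    abort(sprintf("Unknown symptom name(s) in config: %s",
                  paste(unknown, collapse = ", ")),
          class = "pdvoice_config_error")
  }
  fillers <- filler_vocab()
  lex_toks <- lexicon_token_set(symptom_lexicon, sentiment_lexicon)
  protected <- unique(c(lex_toks, nocturnal_markers(), negation_tokens(),
                        fillers))
  overlap <- intersect(fillers, lex_toks)
  if (length(overlap)) {
    abort(sprintf("Filler vocabulary overlaps lexicon tokens: %s",
                  paste(overlap, collapse = ", ")),
          class = "pdvoice_config_error")
  }
  terms_by_symptom <- split(symptom_lexicon$term,
                            symptom_lexicon$canonical_symptom)
  lex_info <- symptom_lexicon[!duplicated(symptom_lexicon$canonical_symptom), ]
  noct_only <- setNames(lex_info$nocturnal_only, lex_info$canonical_symptom)
  category <- setNames(lex_info$category, lex_info$canonical_symptom)
  subcategory <- setNames(lex_info$subcategory, lex_info$canonical_symptom)
  sent_terms <- split(sentiment_lexicon$term, sentiment_lexicon$grade)
  markers <- nocturnal_markers()
  negs <- negation_tokens()

  mix <- config$sentiment_mixture
  mix_mat <- matrix(0, nrow = length(unique(mix$symptom)), ncol = 6,
                    dimnames = list(unique(mix$symptom), NULL))
  mix_mat[cbind(match(mix$symptom, rownames(mix_mat)), mix$grade)] <- mix$prob

  years <- as.integer(names(config$per_year_counts))
  dialogues <- vector("list", sum(config$per_year_counts))
  mention_rows <- vector("list", sum(config$per_year_counts))
  grade_rows <- vector("list", sum(config$per_year_counts))
  corr_rows <- vector("list", sum(config$per_year_counts))
  k <- 0L

  for (yi in seq_along(years)) {
    year <- years[yi]
    n_y <- config$per_year_counts[yi]
    if (n_y == 0L) next
    sp_y <- config$symptom_prevalence[config$symptom_prevalence$year == year, ]
    p <- setNames(sp_y$prevalence, sp_y$symptom)
    cal <- calibrate_inclusion(p)
    q <- cal$q
    for (i in seq_len(n_y)) {
      k <- k + 1L
      id <- sprintf("d%d-%05d", year, i)
      res <- with_seed(dialogue_seed(config$seed, year, i), {
        build_dialogue(id, q, config, noct_only, category, subcategory,
                       terms_by_symptom, sent_terms, mix_mat, fillers,
                       markers, negs, protected, lex_toks)
      })
      dialogues[[k]] <- list(id = id, year = year, age = res$age,
                             tokens = res$tokens)
      mention_rows[[k]] <- res[c("m_symptom", "m_start", "m_end", "m_noct")]
      grade_rows[[k]] <- res$grades
      corr_rows[[k]] <- res[c("corr_pos", "corr_orig", "corr_new")]
    }
  }

  ids <- vapply(dialogues, `[[`, character(1), "id")
  dia <- tibble(
    id = ids,
    year = vapply(dialogues, `[[`, integer(1), "year"),
    platform = config$platform,
    age = vapply(dialogues, `[[`, double(1), "age"),
    tokens = lapply(dialogues, `[[`, "tokens"))
  n_m <- vapply(mention_rows, function(r) length(r$m_symptom), integer(1))
  sym <- unlist(lapply(mention_rows, `[[`, "m_symptom"), use.names = FALSE)
  mentions <- tibble(
    id = rep(ids, n_m),
    canonical_symptom = sym %||% character(0),
    category = unname(category[sym]),
    subcategory = unname(subcategory[sym]),
    start = unlist(lapply(mention_rows, `[[`, "m_start")) %||% integer(0),
    end = unlist(lapply(mention_rows, `[[`, "m_end")) %||% integer(0),
    nocturnal = unlist(lapply(mention_rows, `[[`, "m_noct")) %||% logical(0),
    negated = FALSE)
  grades <- tibble(
    id = rep(ids, lengths(grade_rows)),
    grade = unlist(grade_rows) %||% integer(0))
  n_c <- vapply(corr_rows, function(r) length(r$corr_pos), integer(1))
  corruptions <- tibble(
    id = rep(ids, n_c),
    position = unlist(lapply(corr_rows, `[[`, "corr_pos")) %||% integer(0),
    original = unlist(lapply(corr_rows, `[[`, "corr_orig")) %||% character(0),
    corrupted = unlist(lapply(corr_rows, `[[`, "corr_new")) %||% character(0))
  structure(list(dialogues = dia,
                 truth = list(mentions = mentions, grades = grades,
                              corruptions = corruptions),
                 config = config),
            class = "pd_corpus")
}

# One dialogue, drawn from the current RNG stream.
build_dialogue <- function(id, q, config, noct_only, category, subcategory,
                           terms_by_symptom, sent_terms, mix_mat, fillers,
                           markers, negs, protected, lex_toks) {
  age <- NA_real_
  if (runif(1) < config$demographic_rate) {
    repeat {
      age <- round(rnorm(1, config$age_mean, config$age_sd))
      if (age >= config$age_min) break
    }
  }
  symptomless <- config$background_symptomless_rate > 0 &&
    runif(1) < config$background_symptomless_rate
  present <- character(0)
  if (!symptomless && length(q)) {
    repeat {
      hit <- runif(length(q)) < q
      if (any(hit)) { present <- names(q)[hit]; break }
      # calibrated rejection loop; cannot spin when some q = 1
      if (all(q == 0)) break
    }
  }
  n_fill <- sample(seq(config$filler_range[1], config$filler_range[2]), 1)
  units <- as.list(sample(fillers, n_fill, replace = TRUE))
  unit_symptom <- rep(NA_character_, n_fill)
  unit_noct <- rep(FALSE, n_fill)
  unit_termlen <- rep(0L, n_fill)        # length of the symptom term itself
  unit_offset <- rep(0L, n_fill)         # tokens preceding the term in unit
  for (s in present) {
    term <- sample(terms_by_symptom[[s]], 1)
    term_toks <- strsplit(term, " ", fixed = TRUE)[[1]]
    p_noct <- config$nocturnal_given_mention[s]
    if (is.na(p_noct) || is.null(p_noct)) p_noct <- 0
    nocturnal <- isTRUE(noct_only[[s]]) || runif(1) < p_noct
    off <- 0L
    toks <- term_toks
    if (nocturnal && !isTRUE(noct_only[[s]])) {
      marker <- sample(markers, 1)
      if (runif(1) < 0.5) { toks <- c(marker, toks); off <- 1L }
      else toks <- c(toks, marker)
    }
    units <- c(units, list(toks))
    unit_symptom <- c(unit_symptom, s)
    unit_noct <- c(unit_noct, nocturnal)
    unit_termlen <- c(unit_termlen, length(term_toks))
    unit_offset <- c(unit_offset, off)
  }
  grades <- integer(0)
  mixed <- intersect(present, rownames(mix_mat))
  if (length(mixed)) {
    pk <- 1 - apply(1 - mix_mat[mixed, , drop = FALSE], 2, prod)
    grades <- which(runif(6) < pk)
    for (g in grades) {
      units <- c(units, list(sample(sent_terms[[as.character(g)]], 1)))
      unit_symptom <- c(unit_symptom, NA_character_)
      unit_noct <- c(unit_noct, FALSE)
      unit_termlen <- c(unit_termlen, 0L)
      unit_offset <- c(unit_offset, 0L)
    }
  }
  ord <- sample(length(units))
  lens <- lengths(units)[ord]
  starts0 <- cumsum(c(0L, lens[-length(lens)]))  # 0-based unit starts
  tokens <- unlist(units[ord], use.names = FALSE)
  sym_idx <- which(!is.na(unit_symptom[ord]))
  m_symptom <- character(0); m_start <- m_end <- integer(0)
  m_noct <- logical(0)
  if (length(sym_idx)) {
    oi <- ord[sym_idx]
    st <- as.integer(starts0[sym_idx] + unit_offset[oi])
    o <- order(st)
    m_symptom <- unit_symptom[oi][o]
    m_start <- st[o]
    m_end <- as.integer(st + unit_termlen[oi])[o]
    m_noct <- unit_noct[oi][o]
    # Ground truth reflects the realized sequence: a marker placed for one
    # mention can fall inside another mention's context window, so the
    # nocturnal flag is recomputed with the tagger's own rule (window 5).
    marker0 <- which(tokens %in% markers) - 1L
    if (length(marker0)) {
      m_noct <- m_noct | vapply(seq_along(m_start), function(i) {
        any(marker0 >= m_start[i] - 5L & marker0 <= m_start[i] - 1L) ||
          any(marker0 >= m_end[i] & marker0 <= m_end[i] + 4L)
      }, logical(1))
    }
  }
  noisy <- inject_noise_impl(tokens, m_start, config$typo_rate,
                             config$double_negation_rate, protected, negs,
                             lexicon_tokens = which(tokens %in% lex_toks) - 1L)
  list(tokens = noisy$tokens, age = age,
       m_symptom = m_symptom, m_start = m_start, m_end = m_end,
       m_noct = m_noct, grades = as.integer(grades),
       corr_pos = noisy$corr_pos, corr_orig = noisy$corr_orig,
       corr_new = noisy$corr_new)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Injects typos and double negations. `mention_starts` are 0-based on
# `tokens`; corruption positions are reported 0-based on the clean
# sequence. Double negations are inserted immediately before mention
# spans, after typo injection, so recorded corruption positions stay valid
# for the clean sequence.
inject_noise_impl <- function(tokens, mention_starts, typo_rate, dn_rate,
                              protected, negs, lexicon_tokens) {
  corr_pos <- integer(0); corr_orig <- corr_new <- character(0)
  if (typo_rate > 0 && length(lexicon_tokens)) {
    hit <- lexicon_tokens[runif(length(lexicon_tokens)) < typo_rate]
    for (pos in hit) {
      orig <- tokens[pos + 1L]
      corr <- corrupt_token(orig, protected)
      if (is.na(corr)) next
      tokens[pos + 1L] <- corr
      corr_pos <- c(corr_pos, as.integer(pos))
      corr_orig <- c(corr_orig, orig)
      corr_new <- c(corr_new, corr)
    }
  }
  if (dn_rate > 0 && length(mention_starts)) {
    wrap <- which(runif(length(mention_starts)) < dn_rate)
    # insert right-to-left so earlier spans stay valid during insertion
    for (m in rev(wrap)) {
      at <- mention_starts[m]            # 0-based insertion point
      pair <- sample(negs, 2, replace = TRUE)
      tokens <- append(tokens, pair, after = at)
    }
  }
  list(tokens = tokens, corr_pos = corr_pos, corr_orig = corr_orig,
       corr_new = corr_new)
}

# Single-edit corruption of `tok` that is not a protected-vocabulary word
# and has no protected word other than `tok` within edit distance 1, so
# noisy-channel correction is unambiguous. Returns NA if no such
# corruption is found after 20 tries.
corrupt_token <- function(tok, protected, n_try = 20L) {
  others <- protected[protected != tok]
  nc <- nchar(tok)
  for (i in seq_len(n_try)) {
    op <- sample(c("sub", "ins", if (nc > 1) "del"), 1)
    pos <- sample(nc, 1)
    cand <- switch(op,
      sub = {
        ch <- sample(letters, 1)
        if (substr(tok, pos, pos) == ch) next
        paste0(substr(tok, 1, pos - 1), ch, substr(tok, pos + 1, nc))
      },
      ins = {
        at <- sample(0:nc, 1)
        paste0(substr(tok, 1, at), sample(letters, 1), substr(tok, at + 1, nc))
      },
      del = paste0(substr(tok, 1, pos - 1), substr(tok, pos + 1, nc)))
    if (cand == tok || !nzchar(cand)) next
    if (cand %in% protected) next
    if (any(adist(cand, others) <= 1)) next
    return(cand)
  }
  NA_character_
}

#' Inject typos and double negations into a token sequence
#'
#' Standalone noise injector mirroring what [generate_corpus()] applies
#' internally: each token belonging to a symptom- or sentiment-lexicon term
#' is replaced, with probability `typo_rate`, by a single-edit corruption
#' that collides with no other lexicon/background word; with probability
#' `double_negation_rate` each symptom mention is wrapped in two negation
#' tokens. Corruptions are recorded in a ledger.
#'
#' @param tokens Character vector of tokens.
#' @param typo_rate,double_negation_rate Probabilities in \[0, 1\].
#' @param seed Integer seed for the private RNG stream.
#' @param symptom_lexicon,sentiment_lexicon Lexicons defining which tokens
#'   are corruptible and where mentions lie.
#' @return A list with `tokens` (noisy sequence) and `corruptions` (tibble:
#'   position (0-based), original, corrupted).
#' @export
inject_noise <- function(tokens, typo_rate = 0, double_negation_rate = 0,
                         seed = 1L,
                         symptom_lexicon = load_symptom_lexicon(),
                         sentiment_lexicon = load_sentiment_lexicon()) {
  check_prob(typo_rate, "typo_rate")
  check_prob(double_negation_rate, "double_negation_rate")
  if (typo_rate == 0 && double_negation_rate == 0) {
    return(list(tokens = tokens,
                corruptions = tibble(position = integer(),
                                     original = character(),
                                     corrupted = character())))
  }
  lex_toks <- lexicon_token_set(symptom_lexicon, sentiment_lexicon)
  protected <- unique(c(lex_toks, nocturnal_markers(), negation_tokens(),
                        filler_vocab()))
  mentions <- tag_symptoms(tokens, symptom_lexicon)
  lexicon_positions <- which(tolower(tokens) %in% lex_toks) - 1L
  res <- with_seed(seed, {
    inject_noise_impl(tokens, mentions$start, typo_rate,
                      double_negation_rate, protected, negation_tokens(),
                      lexicon_tokens = lexicon_positions)
  })
  list(tokens = res$tokens,
       corruptions = tibble(position = res$corr_pos,
                            original = res$corr_orig,
                            corrupted = res$corr_new))
}

#' @export
print.pd_corpus <- function(x, ...) {
  cat(sprintf("<pd_corpus> %d dialogues over %s\n", nrow(x$dialogues),
              paste(sort(unique(x$dialogues$year)), collapse = ", ")))
  cat(sprintf("  ground truth: %d mentions, %d grade records, %d corruptions\n",
              nrow(x$truth$mentions), nrow(x$truth$grades),
              nrow(x$truth$corruptions)))
  invisible(x)
}

#' Write / read a corpus as line-delimited JSON
#'
#' One JSON object per line with fields id, year, platform, tokens and age
#' (null when absent). Ground truth, when present, is written to a sibling
#' file as one JSON object per dialogue keyed by id.
#'
#' @param corpus A `pd_corpus`.
#' @param path Output path for the dialogue records.
#' @param truth_path Optional output path for ground-truth annotations.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, truth_path = NULL) {
  stopifnot(inherits(corpus, "pd_corpus"))
  d <- corpus$dialogues
  lines <- vapply(seq_len(nrow(d)), function(i) {
    jsonlite::toJSON(list(id = d$id[i], year = d$year[i],
                          platform = d$platform[i],
                          tokens = d$tokens[[i]],
                          age = if (is.na(d$age[i])) NULL else d$age[i]),
                     auto_unbox = TRUE, null = "null")
  }, character(1))
  writeLines(lines, path)
  if (!is.null(truth_path)) {
    tr <- corpus$truth
    ids <- d$id
    lines <- vapply(ids, function(dd) {
      m <- tr$mentions[tr$mentions$id == dd, ]
      g <- tr$grades$grade[tr$grades$id == dd]
      jsonlite::toJSON(list(id = dd,
                            mentions = m[setdiff(names(m), "id")],
                            grades = g),
                       auto_unbox = TRUE, dataframe = "rows")
    }, character(1))
    writeLines(lines, truth_path)
  }
  invisible(path)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(path, truth_path = NULL) {
  lines <- readLines(path, warn = FALSE)
  recs <- lapply(lines, jsonlite::fromJSON)
  dia <- tibble(
    id = vapply(recs, function(r) as.character(r$id), character(1)),
    year = vapply(recs, function(r) as.integer(r$year), integer(1)),
    platform = vapply(recs, function(r) as.character(r$platform), character(1)),
    age = vapply(recs, function(r) if (is.null(r$age)) NA_real_ else as.double(r$age),
                 double(1)),
    tokens = lapply(recs, function(r) as.character(r$tokens)))
  if (anyDuplicated(dia$id)) {
    abort("Corpus ids must be unique.", class = "pdvoice_validation_error")
  }
  truth <- NULL
  if (!is.null(truth_path)) {
    trecs <- lapply(readLines(truth_path, warn = FALSE), jsonlite::fromJSON)
    mention_list <- lapply(trecs, function(r) {
      m <- as_tibble(r$mentions)
      if (nrow(m)) m$id <- as.character(r$id)
      m
    })
    grade_list <- lapply(trecs, function(r) {
      if (length(r$grades)) tibble(id = as.character(r$id),
                                   grade = as.integer(r$grades))
    })
    truth <- list(mentions = bind_rows(mention_list),
                  grades = bind_rows(grade_list),
                  corruptions = tibble(id = character(), position = integer(),
                                       original = character(),
                                       corrupted = character()))
  }
  structure(list(dialogues = dia, truth = truth, config = NULL),
            class = "pd_corpus")
}
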