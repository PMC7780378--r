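#' Reported share-of-voice values from the reference study
#'
#' Per-symptom SOV percentages for 2016-2018, together with the reported
#' two-year CAGR and p-value, as printed in the reference social-listening
#' study of Parkinson's disease dialogues that this package operationalizes.
#' Three blocks are available: overall motor symptoms, overall non-motor
#' symptoms, and nocturnal symptoms (which include the overall nocturnal
#' aggregate). These values serve as generator targets and as inputs to
#' worked CAGR examples; they are not recomputable from raw data, which was
#' never deposited.
#'
#' @param block One of "motor", "non_motor", "nocturnal" or "all".
#' @return A tibble with columns `block`, `subcategory`, `symptom` (display
#'   label), `unit` (canonical symptom id aligned with the packaged lexicon,
#'   or NA where the row has no single lexicon counterpart), `sov_2016`,
#'   `sov_2017`, `sov_2018` (percent), `cagr_reported` (percent) and
#'   `p_reported` (display string).
#' @export
sov_reference <- function(block = c("all", "motor", "non_motor", "nocturnal")) {
  block <- match.arg(block)
  motor <- tibble(
    block = "motor",
    subcategory = c("tremor", "rigidity", "rigidity", "bradykinesia",
                    "bradykinesia", "bradykinesia", "bradykinesia",
                    "postural_instability", "postural_instability"),
    symptom = c("Tremor", "Stiffness", "Problems turning over",
                "Difficulty walking/slow movement", "Reduced facial expression",
                "Unclear enunciation", "Speech disorder", "Falling",
                "Gait postural instabilities"),
    unit = c("tremor", "stiffness", "difficulty_turning_over",
             "difficulty_walking", "reduced_facial_expression",
             "unclear_enunciation", "speech_disorder", "falling",
             "gait_postural_instability"),
    sov_2016 = c(55.6, 25.3, 10.5, 20.7, 4.5, 3.0, 0.8, 7.3, 1.6),
    sov_2017 = c(51.9, 24.6, 11.6, 19.2, 3.0, 2.2, 0.7, 7.8, 2.7),
    sov_2018 = c(52.7, 29.5, 13.9, 24.5, 3.0, 2.8, 1.0, 9.9, 5.1),
    cagr_reported = c(-2.6, 8.0, 15.0, 8.9, -18.2, -2.0, 14.4, 16.6, 79.3),
    p_reported = c("0.03", "<0.01", "<0.01", "<0.01", "<0.01", "0.35",
                   "0.25", "<0.01", "<0.01"))
  non_motor <- tibble(
    block = "non_motor",
    subcategory = c(rep("sleep_sensory", 9), rep("cognitive_psychiatric", 6),
                    rep("autonomic", 3)),
    symptom = c("Pain", "Frequent urination", "Insomnia", "RBD",
                "Poor sleep quality", "Excessive daytime sleepiness",
                "Numbness", "Spasm", "Olfactory disorder", "Depression",
                "Hallucinations", "Dementia", "Anxiety", "Slow reaction",
                "Other psychiatric issues", "Constipation",
                "Other gastrointestinal dysfunctions", "Drooling"),
    unit = c("pain", "frequent_urination", "insomnia", "rbd",
             "poor_sleep_quality", "excessive_daytime_sleepiness",
             "numbness", "spasm", "olfactory_disorder", "depression",
             "hallucinations", "dementia", "anxiety", "slow_reaction",
             "other_psychiatric", "constipation",
             "gastrointestinal_dysfunction", "drooling"),
    sov_2016 = c(24.4, 7.5, 6.2, 3.9, 5.4, 3.8, 4.9, 3.7, 0.9, 6.1, 7.2,
                 5.7, 2.4, 2.0, 1.2, 7.9, 6.8, 4.9),
    sov_2017 = c(25.2, 8.6, 6.3, 5.1, 5.6, 4.1, 4.2, 3.8, 1.0, 7.0, 9.1,
                 6.3, 3.3, 2.0, 1.1, 8.4, 8.3, 4.8),
    sov_2018 = c(25.8, 11.8, 8.9, 7.4, 5.7, 5.6, 5.0, 3.6, 2.5, 11.4, 10.0,
                 9.1, 6.9, 3.4, 1.3, 12.1, 8.1, 5.9),
    cagr_reported = c(2.9, 25.8, 20.0, 37.3, 2.4, 20.9, 1.4, -1.6, 64.5,
                      36.2, 18.1, 26.6, 70.6, 31.4, 4.7, 23.9, 9.5, 9.6),
    p_reported = c("0.15", "<0.01", "<0.01", "<0.01", "0.34", "<0.01",
                   "0.44", "0.43", "<0.01", "<0.01", "<0.01", "<0.01",
                   "<0.01", "<0.01", "0.39", "<0.01", "0.06", "0.08"))
  nocturnal <- tibble(
    block = "nocturnal",
    subcategory = NA_character_,
    symptom = c("Overall nocturnal symptoms", "Rigidity/difficulty turning over",
                "Insomnia", "Night tremor", "RBD", "Nocturnal pain",
                "Poor sleep quality", "Excessive daytime sleepiness",
                "Frequent nocturia", "Hallucinations", "Morning pain",
                "Nocturnal spasm", "Difficulty breathing"),
    unit = c("overall_nocturnal", "difficulty_turning_over", "insomnia",
             "tremor", "rbd", "pain", "poor_sleep_quality",
             "excessive_daytime_sleepiness", "frequent_nocturia",
             "hallucinations", NA, "spasm", "difficulty_breathing"),
    sov_2016 = c(39, 11.9, 6.2, 7.0, 3.9, 5.3, 5.4, 3.8, 2.9, 1.6, 0.6,
                 1.1, 0.3),
    sov_2017 = c(41, 12.8, 6.3, 6.8, 5.1, 5.9, 5.6, 4.1, 3.6, 2.1, 1.0,
                 1.0, 0.5),
    sov_2018 = c(45, 16.0, 8.9, 8.7, 7.4, 7.3, 5.7, 5.6, 5.3, 2.5, 1.4,
                 1.2, 0.8),
    cagr_reported = c(6.0, 16.0, 20.0, 11.2, 37.3, 17.3, 2.4, 20.9, 35.6,
                      26.9, 51.0, 8.2, 52.2),
    p_reported = c("<0.01", "<0.01", "<0.01", "0.02", "<0.01", "<0.01",
                   "0.34", "<0.01", "<0.01", "0.03", "<0.01", "0.38",
                   "0.02"))
  out <- bind_rows(motor, non_motor, nocturnal)
  if (block != "all") out <- out[out$block == block, ]
  out
}

#' Reported per-year symptom-group SOV comparisons
#'
#' The per-year share of voice of the three symptom groups (motor,
#' non-motor, motor complication) as reported in the reference study,
#' with the included-dialogue count per year.
#'
#' @return A tibble with columns `year`, `n_included`, `motor`,
#'   `non_motor`, `motor_complication` (percent).
#' @export
category_sov_reference <- function() {
  tibble(
    year = c(2016L, 2017L, 2018L),
    n_included = c(7524L, 5198L, 2397L),
    motor = c(79, 76, 79),
    non_motor = c(62, 66, 69),
    motor_complication = c(3, 6, 9))
}

#' Reported corpus demographics
#'
#' Demographic summary of the reference corpus: per-year included dialogue
#' counts, age-group counts among the 2895 dialogues with demographic
#' information, and the reported age mean and standard deviation.
#'
#' @return A list with `per_year_counts` (named integer vector),
#'   `age_groups` (tibble: group, n, pct), `n_with_age`, `age_mean`,
#'   `age_sd`.
#' @export
demographics_reference <- function() {
  list(
    per_year_counts = c("2016" = 7524L, "2017" = 5198L, "2018" = 2397L),
    age_groups = tibble(
      group = c("<50", "50-60", "60-70", ">70"),
      n = c(405L, 586L, 957L, 947L),
      pct = c(14.0, 20.2, 33.1, 32.7)),
    n_with_age = 2895L,
    age_mean = 63,
    age_sd = 13.4)
}

#' Reported negative-sentiment scores
#'
#' Weighted negative-sentiment scores for selected symptoms, any-time and
#' nocturnal, as reported in the reference study. Used to calibrate the
#' synthetic generator's default sentiment mixtures.
#'
#' @return A tibble with columns `unit`, `score_any`, `score_nocturnal`
#'   (NA where a value was not reported).
#' @export
sentiment_reference <- function() {
  tibble(
    unit = c("depression", "anxiety", "apathy", "olfactory_disorder",
             "restless_legs_syndrome", "pain", "difficulty_breathing",
             "immobility", "hallucinations", "excessive_daytime_sleepiness",
             "difficulty_turning_over", "frequent_urination", "spasm",
             "falling", "stiffness", "tremor", "morning_pain",
             "fragmented_sleep", "insomnia", "poor_sleep_quality",
             "frequent_nocturia", "rbd"),
    score_any = c(8.5, 7.4, 5.0, 3.9, 3.6, 3.5, 3.4, 2.8, 2.7, 2.7, 2.6,
                  2.6, 2.6, 2.3, 2.2, 1.6, NA, NA, NA, NA, NA, NA),
    score_nocturnal = c(NA, NA, NA, NA, 4.4, 4.4, 4.4, 2.8, 3.5, 2.7, 2.8,
                        NA, 3.4, NA, 2.8, 2.8, 5.3, 4.8, 3.5, 3.5, 3.2,
                        3.1))
}
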