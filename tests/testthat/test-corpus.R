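test_that("generate_corpus honors per-year counts, including zero years", {
  cfg <- generator_config(
    per_year_counts = c("2016" = 40, "2017" = 25, "2018" = 0),
    symptom_prevalence = data.frame(
      symptom = rep(c("tremor", "pain"), each = 3),
      year = rep(2016:2018, 2), prevalence = 0.6),
    typo_rate = 0, double_negation_rate = 0, seed = 5)
  co <- generate_corpus(cfg)
  counts <- table(co$dialogues$year)
  expect_equal(unname(counts[c("2016", "2017")]), c(40L, 25L),
               ignore_attr = TRUE)
  expect_false("2018" %in% names(counts))
  expect_false(anyDuplicated(co$dialogues$id) > 0)
  expect_true(all(lengths(co$dialogues$tokens) > 0))
})

test_that("probability-1 prevalence puts the symptom in every dialogue", {
  cfg <- generator_config(
    per_year_counts = c("2018" = 50),
    symptom_prevalence = data.frame(symptom = "tremor", year = 2018,
                                    prevalence = 1),
    typo_rate = 0, double_negation_rate = 0, seed = 2)
  co <- generate_corpus(cfg)
  lex <- load_symptom_lexicon()
  tremor_terms <- lex$term[lex$canonical_symptom == "tremor"]
  hits <- vapply(co$dialogues$tokens,
                 function(tk) any(tk %in% tremor_terms), logical(1))
  expect_length(hits, 50)
  expect_true(all(hits))
})

test_that("identical config and seed give byte-identical corpora", {
  co1 <- generate_corpus(small_config(n = 60, seed = 9, typo_rate = 0.1,
                                      double_negation_rate = 0.1))
  co2 <- generate_corpus(small_config(n = 60, seed = 9, typo_rate = 0.1,
                                      double_negation_rate = 0.1))
  expect_identical(co1$dialogues, co2$dialogues)
  expect_identical(co1$truth, co2$truth)
  co3 <- generate_corpus(small_config(n = 60, seed = 10))
  expect_false(identical(co1$dialogues$tokens, co3$dialogues$tokens))
})

test_that("empirical mention rates converge to configured prevalences", {
  cfg <- small_config(n = 1200, seed = 31)
  co <- generate_corpus(cfg)
  truth <- co$truth$mentions
  n <- nrow(co$dialogues)
  for (s in c("tremor", "insomnia", "pain", "dyskinesia")) {
    p <- cfg$symptom_prevalence$prevalence[cfg$symptom_prevalence$symptom == s]
    est <- length(unique(truth$id[truth$canonical_symptom == s])) / n
    expect_lt(abs(est - p), 3 * sqrt(p * (1 - p) / n))
  }
})

test_that("configuration validation names the offending input", {
  expect_error(
    generator_config(per_year_counts = c("2018" = 10),
                     symptom_prevalence = data.frame(
                       symptom = "levitation", year = 2018, prevalence = 0.5)),
    regexp = "levitation", class = "pdvoice_config_error")
  expect_error(
    generator_config(per_year_counts = c("2018" = -3),
                     symptom_prevalence = data.frame(
                       symptom = "tremor", year = 2018, prevalence = 0.5)),
    class = "pdvoice_validation_error")
  expect_error(
    generator_config(per_year_counts = c("2018" = 10),
                     symptom_prevalence = data.frame(
                       symptom = "tremor", year = 2018, prevalence = 1.4)),
    class = "pdvoice_validation_error")
})

test_that("inject_noise is the identity at zero rates and logs every corruption", {
  tokens <- c("doctor", "tremor", "today", "insomnia")
  clean <- inject_noise(tokens, 0, 0, seed = 4)
  expect_identical(clean$tokens, tokens)
  expect_equal(nrow(clean$corruptions), 0)

  one <- c("doctor", "tremor", "today")
  noisy <- inject_noise(one, typo_rate = 1, double_negation_rate = 0, seed = 4)
  expect_equal(nrow(noisy$corruptions), 1)
  expect_equal(noisy$corruptions$original, "tremor")
  corrupted <- noisy$tokens[noisy$corruptions$position + 1]
  expect_equal(corrupted, noisy$corruptions$corrupted)
  expect_equal(drop(utils::adist("tremor", corrupted)), 1)
  expect_equal(sum(noisy$tokens != c("doctor", "tremor", "today")), 1)
})

test_that("double-negation injection wraps mentions in two negation tokens", {
  tokens <- c("doctor", "tremor", "today")
  noisy <- inject_noise(tokens, typo_rate = 0, double_negation_rate = 1,
                        seed = 8)
  expect_length(noisy$tokens, 5)
  negs <- negation_tokens()
  pos <- which(noisy$tokens == "tremor")
  expect_true(all(noisy$tokens[c(pos - 2, pos - 1)] %in% negs))
})

test_that("corpus JSONL round-trips with ages and ground truth", {
  co <- generate_corpus(small_config(n = 40, seed = 12,
                                     demographic_rate = 0.5))
  path <- withr::local_tempfile(fileext = ".jsonl")
  tpath <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(co, path, tpath)
  back <- read_corpus(path, tpath)
  expect_identical(back$dialogues$id, co$dialogues$id)
  expect_identical(back$dialogues$tokens, co$dialogues$tokens)
  expect_identical(back$dialogues$age, co$dialogues$age)
  m1 <- dplyr::arrange(co$truth$mentions, id, start)
  m2 <- dplyr::arrange(back$truth$mentions, id, start)[, names(m1)]
  expect_equal(as.data.frame(m2), as.data.frame(m1))
})

test_that("the study-scale configuration builds and generates at reduced scale", {
  cfg <- study_config(years = 2018, scale = 0.05, seed = 14)
  expect_s3_class(cfg, "pdvoice_config")
  expect_equal(unname(cfg$per_year_counts), round(2397 * 0.05))
  expect_true(all(cfg$symptom_prevalence$prevalence > 0 &
                    cfg$symptom_prevalence$prevalence < 1))
  expect_true(all(cfg$nocturnal_given_mention >= 0 &
                    cfg$nocturnal_given_mention <= 1))
  co <- generate_corpus(cfg)
  expect_equal(nrow(co$dialogues), round(2397 * 0.05))
  ann <- filter_inclusion(annotate_corpus(co))
  # every generated dialogue is symptom-bearing at this prevalence mass
  expect_equal(nrow(ann$dialogues), nrow(co$dialogues))
  expect_gt(nrow(sentiment_table(ann)), 5)
})
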