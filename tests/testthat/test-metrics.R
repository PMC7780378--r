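test_that("SOV counts each dialogue once per unit", {
  ann <- make_annotated(list(
    list(id = "a", year = 2018,
         mentions = data.frame(canonical_symptom = c("tremor", "tremor"))),
    list(id = "b", year = 2018,
         mentions = data.frame(canonical_symptom = "tremor")),
    list(id = "c", year = 2018,
         mentions = data.frame(canonical_symptom = "tremor")),
    list(id = "d", year = 2018,
         mentions = data.frame(canonical_symptom = "pain",
                               category = "non_motor",
                               subcategory = "sleep_sensory"))))
  row <- compute_sov(ann, "tremor", 2018)
  expect_equal(row$numerator, 3L)
  expect_equal(row$denominator, 4L)
  expect_equal(row$sov, 0.75)

  zero <- compute_sov(ann, "insomnia", 2018)
  expect_equal(zero$sov, 0)

  expect_error(compute_sov(ann, "tremor", 2016),
               class = "pdvoice_validation_error")
})

test_that("category SOV is the dialogue-level union of member symptoms", {
  # one dialogue with two motor symptoms: union = 1 dialogue, not 2
  ann <- make_annotated(list(
    list(id = "a", year = 2018,
         mentions = data.frame(canonical_symptom = c("tremor", "stiffness"),
                               category = "motor",
                               subcategory = c("tremor", "rigidity"))),
    list(id = "b", year = 2018,
         mentions = data.frame(canonical_symptom = "pain",
                               category = "non_motor",
                               subcategory = "sleep_sensory"))))
  cat_row <- compute_sov(ann, "motor", 2018, by = "category")
  expect_equal(cat_row$numerator, 1L)
  sym <- sov_table(ann, by = "symptom")
  expect_true(all(cat_row$sov >= sym$sov[sym$unit %in% c("tremor", "stiffness")]))
})

test_that("negated and non-nocturnal mentions are excluded where required", {
  ann <- make_annotated(list(
    list(id = "a", year = 2018,
         mentions = data.frame(canonical_symptom = "tremor", negated = TRUE)),
    list(id = "b", year = 2018,
         mentions = data.frame(canonical_symptom = "tremor",
                               nocturnal = TRUE)),
    list(id = "c", year = 2018,
         mentions = data.frame(canonical_symptom = "tremor"))))
  expect_equal(compute_sov(ann, "tremor", 2018)$numerator, 2L)
  noct <- compute_sov(ann, "tremor", 2018, nocturnal = TRUE)
  expect_equal(noct$numerator, 1L)
  agg <- compute_sov(ann, NULL, 2018, by = "overall", nocturnal = TRUE)
  expect_equal(agg$unit, "overall_nocturnal")
  expect_equal(agg$numerator, 1L)
})

test_that("CAGR reproduces compounding and rejects a zero start", {
  expect_equal(round(100 * compute_cagr(25.3, 29.5, 2), 1), 8.0)
  expect_equal(round(100 * compute_cagr(55.6, 52.7, 2), 1), -2.6)
  expect_equal(compute_cagr(7, 7, 5), 0)
  # inversion: v_start * (1 + cagr)^n = v_end
  set.seed(5)
  for (i in 1:50) {
    v0 <- runif(1, 0.01, 1); v1 <- runif(1, 0, 1); n <- sample(1:10, 1)
    g <- compute_cagr(v0, v1, n)
    expect_gt(g, -1)
    expect_equal(v0 * (1 + g)^n, v1, tolerance = 1e-12)
  }
  expect_error(compute_cagr(0, 5, 2), class = "pdvoice_undefined_growth_error")
})

test_that("sentiment score matches the hand-enumerated example", {
  # 10 eligible dialogues: 5 with grade 2 only, 3 with grade 3 only,
  # 2 with grades {2, 6} -> p = (0, 70, 30, 0, 0, 20), score 3.5
  dialogues <- c(
    lapply(1:5, function(i) list(id = paste0("a", i), year = 2018,
      mentions = data.frame(canonical_symptom = "tremor"), grades = 2L)),
    lapply(1:3, function(i) list(id = paste0("b", i), year = 2018,
      mentions = data.frame(canonical_symptom = "tremor"), grades = 3L)),
    lapply(1:2, function(i) list(id = paste0("c", i), year = 2018,
      mentions = data.frame(canonical_symptom = "tremor"),
      grades = c(2L, 6L))))
  ann <- make_annotated(dialogues)
  row <- compute_sentiment_score(ann, "tremor")
  expect_equal(row$n_eligible, 10L)
  expect_equal(c(row$p_1, row$p_2, row$p_3, row$p_4, row$p_5, row$p_6),
               c(0, 70, 30, 0, 0, 20))
  expect_equal(row$score, 3.5)
})

test_that("sentiment score hits its bounds and is absent with no eligible dialogue", {
  only6 <- make_annotated(lapply(1:4, function(i)
    list(id = paste0("d", i), year = 2018,
         mentions = data.frame(canonical_symptom = "pain"), grades = 6L)))
  expect_equal(compute_sentiment_score(only6, "pain")$score, 6)

  all6 <- make_annotated(lapply(1:4, function(i)
    list(id = paste0("e", i), year = 2018,
         mentions = data.frame(canonical_symptom = "pain"), grades = 1:6)))
  expect_equal(compute_sentiment_score(all6, "pain")$score, 21)

  mute <- make_annotated(list(list(id = "f", year = 2018,
    mentions = data.frame(canonical_symptom = "pain"))))
  row <- compute_sentiment_score(mute, "pain")
  expect_equal(row$n_eligible, 0L)
  expect_true(is.na(row$score))
})

test_that("scores equal brute-force recomputation on generated corpora", {
  co <- generate_corpus(small_config(n = 250, seed = 77))
  ann <- filter_inclusion(annotate_corpus(co, correct = FALSE))
  for (u in c("tremor", "insomnia", "pain")) {
    row <- compute_sentiment_score(ann, u)
    with_u <- unique(ann$mentions$id[ann$mentions$canonical_symptom == u &
                                       !ann$mentions$negated])
    sets <- lapply(intersect(with_u, unique(ann$grades$id)), function(d) {
      ann$grades$grade[ann$grades$id == d]
    })
    expect_equal(row$score, brute_force_score(sets))
    if (row$n_eligible > 0) {
      expect_gte(row$score, 1)
      expect_lte(row$score, 21)
    }
  }
})

test_that("day-night contrast pairs, skips, and orders as configured", {
  any_t <- tibble::tibble(unit = c("tremor", "pain", "stiffness"),
                          score = c(1.6, 3.5, 2.2))
  noct <- tibble::tibble(unit = c("tremor", "pain", "insomnia"),
                         score = c(2.8, 4.4, 3.5))
  expect_message(out <- compare_day_night(any_t, noct), "stiffness")
  expect_setequal(out$unit, c("tremor", "pain"))  # insomnia nocturnal-only
  expect_equal(out$difference, out$score_nocturnal - out$score_any)

  same <- compare_day_night(any_t[1:2, ], any_t[1:2, ])
  expect_true(all(same$difference == 0))

  # nocturnal mentions co-occurring with heavier grades score higher
  dialogues <- c(
    lapply(1:30, function(i) list(id = paste0("n", i), year = 2018,
      mentions = data.frame(canonical_symptom = "tremor", nocturnal = TRUE),
      grades = c(5L, 6L))),
    lapply(1:30, function(i) list(id = paste0("d", i), year = 2018,
      mentions = data.frame(canonical_symptom = "tremor"),
      grades = c(1L, 2L))))
  ann <- make_annotated(dialogues)
  cmp <- compare_day_night(sentiment_table(ann),
                           sentiment_table(ann, nocturnal = TRUE))
  expect_true(all(cmp$difference > 0))
  expect_gte(min(compute_sentiment_score(ann, "tremor",
                                         nocturnal_only_mentions = TRUE)$n_eligible),
             30)
})
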