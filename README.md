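# pdvoice

Social-listening analysis of Parkinson's disease (PD) symptom dialogues:
a tested R implementation of the pipeline behind share-of-voice studies of
patient-generated text, built for researchers in digital epidemiology /
infodemiology who want the full chain — noisy dialogue normalization,
dictionary-based symptom and sentiment tagging, and trend statistics —
reproducible without access to any crawled corpus.

## What it computes

A *dialogue* (one patient–doctor or patient–patient conversation, as a
token sequence) is the unit of counting throughout.

- **Share of voice (SOV).** For a symptom, subcategory, category (motor /
  non-motor / motor complication) or the overall nocturnal aggregate *u*
  in year *y*:

  SOV(u, y) = #{included dialogues in y with ≥ 1 qualifying mention of u} / #{included dialogues in y}

  A dialogue counts once per unit; negated mentions never qualify; a
  dialogue enters the analysis only if it has at least one non-negated
  symptom mention (the inclusion filter).

- **Compounded annual growth rate (CAGR).**
  `(v_end / v_start)^(1/n) − 1` between two SOV values n years apart.

- **Weighted negative-sentiment score.** Sentiment words carry severity
  grades 1–6 (suspicion = 1, anxiety = 2, fear = 3, agony = 4, anger = 5,
  sorrow = 6). Among dialogues that mention the symptom *and* carry at
  least one sentiment word, with p_k the percentage carrying grade k
  (multi-label, so Σp_k may exceed 100):

  score = (p₁·1 + p₂·2 + … + p₆·6) / 100,  bounded in [1, 21].

- **Trend and between-group tests.** Welch two-sample t on the
  dialogue-level 0/1 indicators (numerically the unpooled two-proportion
  z at these sample sizes), across years for one unit or between symptom
  groups within a year.

- **Normalization.** A bigram noisy-channel corrector restores
  out-of-vocabulary tokens from edit-distance-1 candidates scored by
  add-k bigram likelihood of the flanking window, and paired
  double negations cancel (double negation reads as affirmation; a
  single negation negates the following mention).

Because raw dialogue corpora of this kind are not redistributable, the
package ships a synthetic corpus generator (`generate_corpus()`) whose
configuration fixes per-year dialogue counts, per-symptom prevalences,
nocturnal-context rates, graded sentiment mixtures, typo/double-negation
noise and a demographic model — with ground-truth annotations returned
alongside, so every downstream stage is testable for exact recovery.

## Worked example

```r
library(pdvoice)

cfg <- system.file("extdata", "demo_config.yaml", package = "pdvoice")
bundle <- run_pipeline(cfg, quiet = TRUE)

dplyr::filter(bundle$sov_symptom, unit == "tremor")
#    unit year numerator denominator        sov
#  tremor 2016        68         120 0.56666667
#  tremor 2017        52         100 0.52000000
#  tremor 2018        50          80 0.62500000

bundle$trend[bundle$trend$unit == "tremor", ]
#    unit sov_start sov_end n_years  cagr statistic p_value
#  tremor     0.567   0.625       2 0.050    -0.822   0.412
```

The demo config generates 300 dialogues (120/100/80 over 2016–2018) with
tremor prevalence 0.56/0.52/0.53; the estimated SOV column recovers those
values up to binomial noise, and the trend row reports the two-point CAGR
(+5.0%/year here) with the indicator t-test p-value (0.41: no evidence of
change at this sample size).

Between-group comparisons from the same run (2018, N = 80):

```r
dplyr::filter(bundle$comparisons, year == 2018)[, c("unit_a", "unit_b", "statistic", "p_value")]
#     unit_a             unit_b statistic      p_value
#      motor          non_motor  6.293900 3.270573e-09
#  non_motor motor_complication  7.069625 5.497954e-10
#      motor motor_complication 19.298409 1.237081e-31
```

A worked CAGR check against a published SOV pair (stiffness, 25.3% in
2016 to 29.5% in 2018):

```r
round(100 * compute_cagr(25.3, 29.5, 2), 1)
# [1] 8
```

A thin CLI wrapper with `generate` / `annotate` / `metrics` / `report` /
`run-all` subcommands is installed at
`system.file("scripts", "pdvoice", package = "pdvoice")`.

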