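# Small demonstration configuration: three years, four symptoms.
generator:
  per_year_counts:
    "2016": 120
    "2017": 100
    "2018": 80
  symptom_prevalence:
    - {symptom: tremor, year: 2016, prevalence: 0.56}
    - {symptom: tremor, year: 2017, prevalence: 0.52}
    - {symptom: tremor, year: 2018, prevalence: 0.53}
    - {symptom: stiffness, year: 2016, prevalence: 0.25}
    - {symptom: stiffness, year: 2017, prevalence: 0.25}
    - {symptom: stiffness, year: 2018, prevalence: 0.30}
    - {symptom: insomnia, year: 2016, prevalence: 0.06}
    - {symptom: insomnia, year: 2017, prevalence: 0.06}
    - {symptom: insomnia, year: 2018, prevalence: 0.09}
    - {symptom: depression, year: 2016, prevalence: 0.06}
    - {symptom: depression, year: 2017, prevalence: 0.07}
    - {symptom: depression, year: 2018, prevalence: 0.11}
    - {symptom: pain, year: 2016, prevalence: 0.24}
    - {symptom: pain, year: 2017, prevalence: 0.25}
    - {symptom: pain, year: 2018, prevalence: 0.26}
    - {symptom: constipation, year: 2016, prevalence: 0.08}
    - {symptom: constipation, year: 2017, prevalence: 0.08}
    - {symptom: constipation, year: 2018, prevalence: 0.12}
  nocturnal_given_mention:
    tremor: 0.13
    stiffness: 0.3
  typo_rate: 0.02
  double_negation_rate: 0.02
  demographic_rate: 0.19
  age_mean: 63
  age_sd: 13.4
  seed: 1
windows:
  nocturnal: 5
  negation: 3
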