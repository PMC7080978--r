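# Bundled plain-text fixtures

- `smq_demo.csv` — SYNTHETIC, illustrative term dictionary: two standardized
  query groupings ("Parkinson-like events", "Dementia") with plausible member
  preferred terms. This is NOT licensed MedDRA content and the membership
  lists are not the ones any real SMQ defines; they exist so the mapping,
  counting and screening machinery can be exercised end to end.
- `study_counts.csv` — printed summary counts of the published intravitreal
  anti-VEGF screen (numerator/denominator pairs); inputs to the report
  module's percentage arithmetic.
- `demo_generator.yaml` — tutorial generator config: a 20,000-report
  synthetic database with one planted drug–event reporting-rate ratio.
- `demo_study.yaml` — tutorial screening config matching the generator.
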