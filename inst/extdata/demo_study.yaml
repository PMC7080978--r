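# Tutorial screening config matching demo_generator.yaml. `input` and
# `dictionary` are resolved relative to the working directory; the CLI and
# the vignette fill them in with system.file() paths.
input: reports.jsonl
dialect: jsonl
dictionary: smq_demo.csv
drugs: [ranibizumab, aflibercept]
route: intravitreal
events:
  smqs: [Parkinson-like events, Dementia]
  scope: narrow
  pt_level: true
period:
  start: "2010-01-01"
  end: "2016-12-31"
strata:
  all_ages: {}
  ge65:
    min_age: 65
min_cases: 3
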