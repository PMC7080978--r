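# Tutorial synthetic database: 20,000 spontaneous reports, 2010-2016, with
# two intravitreal drugs used mainly in the elderly and one planted
# reporting-rate ratio (ranibizumab -> Parkinson's disease, RRR = 4).
n_reports: 20000
seed: 42
dialect: jsonl
drugs:
  - name: ranibizumab
    p_report: 0.004
    route: intravitreal
    p_route_unreported: 0.1
    elderly_multiplier: 8
    indication: age-related macular degeneration
  - name: aflibercept
    p_report: 0.002
    route: intravitreal
    p_route_unreported: 0.1
    elderly_multiplier: 8
    indication: age-related macular degeneration
events:
  - pt_name: Parkinson's disease
    baseline_p: 0.012
    age_mult_per_decade: 1.3
  - pt_name: Dementia
    baseline_p: 0.015
    age_mult_per_decade: 1.5
  - pt_name: Dementia Alzheimer's type
    baseline_p: 0.004
    age_mult_per_decade: 1.5
  - pt_name: Senile dementia
    baseline_p: 0.002
    age_mult_per_decade: 1.5
  - pt_name: Mixed dementia
    baseline_p: 0.001
    age_mult_per_decade: 1.5
  - pt_name: Hypertonia
    baseline_p: 0.004
    age_mult_per_decade: 1.1
  - pt_name: Akinesia
    baseline_p: 0.003
    age_mult_per_decade: 1.1
planted:
  - drug_name: ranibizumab
    pt_name: Parkinson's disease
    rrr: 4
age:
  prop_ge65: 0.2
  young: [18, 64]
  old: [65, 90]
sex_ratio: 0.45
period: ["2010-01-01", "2016-12-31"]
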