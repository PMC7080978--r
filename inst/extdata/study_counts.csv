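quantity,numerator,denominator,description
dementia_share_of_two_smq_cases,17,27,dementia-SMQ reports among the 27 reports matching either query (all ages)
elderly_share_of_exposed,4758,7945,reports aged 65+ among all intravitreal anti-VEGF reports
two_smq_share_of_exposed,27,7945,reports matching either query among all intravitreal anti-VEGF reports
possible_causality_share,5,6,cases classified possible among the six flagged signal cases
elderly_dementia_share,8,4758,dementia-SMQ reports among the 65+ intravitreal anti-VEGF reports
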