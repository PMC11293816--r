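scenario,sex,outcome,reduction_pct
social_contact_quality,female,prevalence,18.2
social_contact_quality,male,prevalence,18.6
social_contact_quality,female,onset,17.2
social_contact_quality,male,onset,19.4
social_contact_quality,female,duration,26.7
social_contact_quality,male,duration,30.4
joint,female,prevalence,37.7
joint,male,prevalence,39.0
joint,female,onset,48.7
joint,male,onset,38.1
joint,female,duration,50.8
joint,male,duration,48.0
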