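sex,education,life_course_prevalence,mean_age_onset,mean_duration
female,low,35.3,35.5,5.8
female,high,14.5,36.3,4.9
male,low,28.6,35.7,6.6
male,high,11.3,36.6,5.1
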