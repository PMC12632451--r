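sample_id	donor_id	age_years	sex	tissue	cohort
S1	D1	62	F	cancer	toy
S2	D2	55	M	cancer	toy
S3	D3	NA	F	cancer	toy
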