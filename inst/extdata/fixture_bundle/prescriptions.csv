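patient_id,rx_date,drug_concept,n_issues
F004,2010-05-12,gabapentin,1
F004,2010-08-01,gabapentin,2
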