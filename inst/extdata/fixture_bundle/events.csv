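patient_id,event_date,concept,setting
F001,2008-04-10,ms,outpatient
F001,2008-09-22,ms,outpatient
F001,2007-12-01,paresthesia,outpatient
F002,2009-02-14,ms,outpatient
F004,2010-05-05,epilepsy,outpatient
F005,2006-03-03,stroke,outpatient
F005,2006-05-20,ms,outpatient
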