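patient_id,start_date,end_date
F001,2002-01-01,2015-12-31
F002,2005-06-01,2012-03-31
F003,2000-01-01,2016-12-31
F004,2008-01-01,2014-06-30
F005,2001-09-01,2010-12-31
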