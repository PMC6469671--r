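patient_id,sex,birth_date,geography,dialect
F001,F,1975-03-02,practice_01,EMR_CPRD
F002,M,1980-07-15,practice_01,EMR_CPRD
F003,F,1962-11-30,practice_02,EMR_CPRD
F004,F,1990-01-20,practice_02,EMR_CPRD
F005,M,1955-06-05,practice_03,EMR_CPRD
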