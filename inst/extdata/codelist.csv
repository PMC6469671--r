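concept,label,category,dod_codes,cprd_codes
ms,Multiple sclerosis,ms_diagnosis,340;G35,F20..
demyelinating_disease,Other demyelinating disease of CNS,demyelinating_disease,341.9;G37.9,F21z.
interferon_beta,Interferon beta,dmt_or_dalfampridine,NDC68546-0170,
glatiramer,Glatiramer acetate,dmt_or_dalfampridine,NDC68546-0317,
natalizumab,Natalizumab,dmt_or_dalfampridine,J2323,du23.
fingolimod,Fingolimod,dmt_or_dalfampridine,NDC0078-0607,dv12.
dimethyl_fumarate,Dimethyl fumarate,dmt_or_dalfampridine,NDC64406-0007,
dalfampridine,Dalfampridine,dmt_or_dalfampridine,NDC10144-0427,
optic_neuritis,Optic neuritis,ms_symptom,377.30;H46,F4023
paresthesia,Disturbance of skin sensation / paraesthesia,ms_symptom,782.0;R20.2,R0140
paresis,"Paresis, plegia, muscle weakness",ms_symptom,344.9;G83.9,F22z.
spasticity_ataxia,Spasticity or ataxia / abnormality of gait,ms_symptom,781.2;R26,F131.
dizziness,Dizziness and giddiness,ms_symptom,780.4;R42,R0040
fatigue,Malaise and fatigue,ms_symptom,780.79;R53,R0073
vision_symptoms,Vision symptoms,ms_symptom,368.8;H53,F42y.
bladder_symptoms,Bladder symptoms,ms_symptom,788.3;R32,R083.
oxybutynin,Oxybutynin (bladder symptom treatment),symptomatic_treatment,NDC0378-2052,bi21.
depression,Depression diagnosis,comorbidity:depression,311;F32,E2B..
epilepsy,Epilepsy,comorbidity:epilepsy,345;G40,F25..
asthma_copd,Asthma or COPD,comorbidity:asthma_copd,493;J44,H33..
hypertension,Essential hypertension,comorbidity:hypertension,401;I10,G20..
diabetes_t2,Type II diabetes mellitus,comorbidity:diabetes,250.00;E11,C10F.
dyslipidemia,Dyslipidemia,comorbidity:dyslipidemia,272.4;E78.5,C324.
fracture,Fracture,comorbidity:fracture,829;T14.8,S350.
cancer_primary,Primary malignant neoplasm,comorbidity:cancer,199.1;C80,B....
cancer_history,History of cancer or secondary cancer,comorbidity:cancer_history,V10;Z85,ZV10.
uti,Urinary tract or kidney infection,infection:urinary_kidney,599.0;N39.0,K190.
respiratory_infection,Respiratory or throat infection,infection:respiratory_throat,465.9;J06.9,H05z.
skin_infection,Skin infection,infection:skin,686.9;L08.9,M03z.
eye_ear_infection,Eye or ear infection,infection:eye_ear,372.30;H10.9,F4C..
viral_infection,Viral infection,infection:viral,079.99;B34.9,A794.
meningitis,Meningitis or encephalitis,infection:meningitis,322.9;G03.9,F00z.
sepsis,Severe systemic infection,infection:other,038.9;A41.9,A3By.
baclofen,Baclofen,medication:spasticity,NDC0172-4096,di41.
tizanidine,Tizanidine,medication:spasticity,NDC0185-0111,di63.
gabapentin,Gabapentin,medication:anticonvulsants,NDC0071-0803,dn71.
carbamazepine,Carbamazepine,medication:anticonvulsants,NDC0083-0027,dn21.
prednisone,Oral corticosteroid,medication:steroids,NDC0054-4728,fe62.
duloxetine,Neuropathic pain treatment,medication:neuropathic_pain,NDC0002-3235,da95.
amantadine,Amantadine (fatigue),medication:fatigue,NDC0093-2118,dw32.
oxycodone,Oxycodone,medication:opioids,NDC0406-0552,dj53.
codeine,Codeine,medication:opioids,NDC0093-0350,dj21.
fluoxetine,Fluoxetine,medication:antidepressants,NDC0777-3105,d71z.
sertraline,Sertraline,medication:antidepressants,NDC0049-4900,d717.
lisinopril,Lisinopril,medication:antihypertensives,NDC0310-0130,bd13.
metformin,Metformin,medication:antidiabetics,NDC0093-1048,f411.
amoxicillin,Amoxicillin,medication:antibiotics,NDC0093-4150,e211.
nitrofurantoin,Nitrofurantoin,medication:antibiotics,NDC0149-0007,e511.
als,Amyotrophic lateral sclerosis,exclusion:als,335.20;G12.21,F152.
stroke,Stroke,exclusion:stroke,434.91;I63.9,G66..
tia,Transient ischemic attack,exclusion:tia,435.9;G45.9,G65z.
other_neuro_alternate,Alternate neurological diagnosis,exclusion:alternate,343.9;G80.9,F23z.
hospital_admission,Hospital admission marker,hospitalization_marker,,8H2..
suicidal_ideation,Suicidal ideation,suicidal_behavior,V62.84;R45.851,1BD4.
self_harm,Intentional self-harm or suicide attempt,suicidal_behavior,E958.9;X84,U2...
overdose,Overdose,suicidal_behavior,,TJz..
smoking_current,Current smoker,covariate:smoking,305.1;Z72.0,1374.
smoking_former,Former smoker,covariate:smoking,V15.82;Z87.891,137S.
smoking_never,Never smoked,covariate:smoking,NOSMOKE;Z71.6,1371.
bmi_measurement,Body mass index measurement,covariate:bmi,VITBMI,22K..
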