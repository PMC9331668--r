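# Regional PM2.5 deposition fractions per cohort (nasal breathing, spherical
# particles, density 1.0 g/cm3), standing in for an external multiple-path
# dosimetry run. Pulmonary values decrease with age within each life stage,
# male >= female, children 0.15-0.26, adults 0.12-0.14; totals (head + TB +
# pulmonary) span 0.64-0.79 for children and 0.72-0.80 for adults.
age_group,sex,df_head,df_tb,df_pulmonary
2-5,male,0.345,0.060,0.2550
2-5,female,0.329,0.060,0.2510
5-7,male,0.395,0.055,0.2300
5-7,female,0.385,0.055,0.2200
7-11,male,0.460,0.050,0.2000
7-11,female,0.455,0.050,0.1900
11-23,male,0.580,0.045,0.1650
11-23,female,0.575,0.045,0.1550
23-30,male,0.5513,0.040,0.1387
23-30,female,0.547,0.040,0.1330
30-40,male,0.565,0.040,0.1350
30-40,female,0.562,0.040,0.1280
40-65,male,0.590,0.040,0.1300
40-65,female,0.586,0.040,0.1240
65-96,male,0.638,0.040,0.1220
65-96,female,0.630,0.040,0.1200
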