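# Default cohort registry: eight age groups x two sexes.
# body_weight_kg and inhr_m3_day are long-term exposure-factor defaults in
# USEPA exposure-handbook-plausible ranges, calibrated (see package vignette)
# so that the shipped deposition-fraction table reproduces the study's
# published dose table. ed_years is exposure duration (6 child / 26 adult).
# height/age/tidal volume/breath frequency/upper-airway volume drive the
# closed-form deposition model and FRC reference equations.
age_group,sex,life_stage,age_years,height_cm,body_weight_kg,inhr_m3_day,ed_years,tidal_volume_ml,breath_freq_per_min,uaw_volume_ml
2-5,male,child,3.5,99,16.2,8.083,6,110,22,28
2-5,female,child,3.5,98,15.8,7.877,6,105,22,27
5-7,male,child,6,115,21.8,9.517,6,170,20,32
5-7,female,child,6,114,21.2,9.245,6,160,20,31
7-11,male,child,9,133,29.5,10.328,6,250,18,37
7-11,female,child,9,132,29.0,10.051,6,240,18,36
11-23,male,child,17,172,52.0,13.804,6,500,14,47
11-23,female,child,17,160,48.5,12.773,6,440,14,43
23-30,male,adult,26.5,175,65.0,16.058,26,625,12,50
23-30,female,adult,26.5,162,56.5,13.291,26,465,12,44
30-40,male,adult,35,175,67.5,15.941,26,625,12,50
30-40,female,adult,35,162,58.0,12.961,26,465,12,44
40-65,male,adult,52.5,172,69.0,15.657,26,615,12,49
40-65,female,adult,52.5,160,60.5,12.212,26,455,12,43
65-96,male,adult,80,167,66.0,11.928,26,580,12,47
65-96,female,adult,80,155,57.0,9.624,26,430,12,41
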