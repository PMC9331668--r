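# Annual mean +/- sd of PM2.5 mass (ug/m3) and PM2.5-bound metal
# concentrations (ng/m3) for the Huludao smelting-district study area:
# Xinqu Park (XP), Dongcheng District (DD), and both sites pooled (ALL).
# total_* is the acid-digest concentration; alf_* and gs_* are the
# fractions extracted by artificial lysosomal fluid and Gamble's solution.
site,pm25_mean,pm25_sd,metal,total_mean,total_sd,alf_mean,alf_sd,gs_mean,gs_sd
XP,74.7,49.2,Cd,9.99,3.46,3.48,0.97,1.21,0.78
XP,74.7,49.2,Pb,264,109,69.5,30.8,32.8,26.2
DD,88.8,55.4,Cd,11.4,3.30,3.51,1.80,3.04,2.01
DD,88.8,55.4,Pb,452,337,164,99.9,83.1,108
ALL,81.7,52.9,Cd,10.7,3.46,3.50,1.45,2.13,1.78
ALL,81.7,52.9,Pb,358,268,117,87.7,58.0,82.2
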