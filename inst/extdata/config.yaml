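# Example pipeline configuration. Every key shown here is optional; omitted
# keys fall back to the package defaults (which this file restates).
exposure:
  ef_day_per_year: 350        # exposure frequency
  ed_child_years: 6           # exposure duration, all child cohorts
  ed_adult_years: 26          # exposure duration, all adult cohorts
  at_c_days: 25550            # carcinogen averaging time, 70 x 365 days
monte_carlo:
  iterations: 5000
  inhr_cv: 0.3                # coefficient of variation of inhalation rate
particle:
  diameter_um: 2.5
  density_gcm3: 1.0
toxicity:
  Cd:
    rfd: 1.0e-3               # inhalation reference dose, mg/kg/day
    csf: 6.3                  # cancer slope factor, (mg/kg/day)^-1
  Pb:
    rfd: 3.5e-3               # no slope factor: Pb is not assessed as a carcinogen
frc:
  child:
    a: 0.00357                # FRC_mL = a * height_cm ^ b
    b: 2.67
  adult_male:
    intercept_ml: -1090       # FRC_mL = intercept + b_height*height_cm + b_age*age
    b_height: 23.4
    b_age: 10.0
  adult_female:
    intercept_ml: -1000
    b_height: 22.4
    b_age: 1.0
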