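# Shared fixtures, built in code.

# Two pseudo-samples carrying the study's per-site annual mean
# concentrations (XP and DD); pooling them reproduces the all-area means.
pseudo_site_samples <- function() {
  validate_samples(tibble::tibble(
    sample_id = rep(c("XP-mean", "DD-mean"), each = 2),
    site = rep(c("XP", "DD"), each = 2),
    date = NA_character_,
    pm25_ugm3 = rep(c(74.7, 88.8), each = 2),
    metal = rep(c("Cd", "Pb"), 2),
    total_ngm3 = c(9.99, 264, 11.4, 452),
    alf_ngm3 = c(3.48, 69.5, 3.51, 164),
    gs_ngm3 = c(1.21, 32.8, 3.04, 83.1)
  ))
}

write_sample_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  path
}

# Published per-cohort daily-dose summary (1e-6 mg/kg/day) for the
# bioaccessibility + deposition adjusted variants; the two fluids'
# columns correspond to the pipeline's ALF+DF and GS+DF variants.
published_doses <- function() {
  tibble::tribble(
    ~age_group, ~sex, ~add_cd_alf, ~add_cd_gs, ~add_pb_alf, ~add_pb_gs,
      ~ladd_cd_alf, ~ladd_cd_gs,
    "2-5",   "male",   0.427, 0.260, 14.2, 7.07, 0.037, 0.022,
    "2-5",   "female", 0.420, 0.255, 14.0, 6.95, 0.036, 0.022,
    "5-7",   "male",   0.337, 0.205, 11.3, 5.59, 0.029, 0.018,
    "5-7",   "female", 0.322, 0.196, 10.7, 5.33, 0.028, 0.017,
    "7-11",  "male",   0.235, 0.143, 7.82, 3.89, 0.020, 0.012,
    "7-11",  "female", 0.221, 0.135, 7.38, 3.67, 0.019, 0.012,
    "11-23", "male",   0.147, 0.090, 4.91, 2.44, 0.013, 0.008,
    "11-23", "female", 0.137, 0.083, 4.58, 2.27, 0.012, 0.007,
    "23-30", "male",   0.115, 0.070, 3.83, 1.90, 0.043, 0.026,
    "23-30", "female", 0.105, 0.064, 3.52, 1.75, 0.039, 0.024,
    "30-40", "male",   0.107, 0.065, 3.57, 1.77, 0.040, 0.024,
    "30-40", "female", 0.096, 0.058, 3.19, 1.59, 0.036, 0.022,
    "40-65", "male",   0.099, 0.060, 3.29, 1.64, 0.037, 0.022,
    "40-65", "female", 0.084, 0.051, 2.82, 1.40, 0.031, 0.019,
    "65-96", "male",   0.074, 0.045, 2.48, 1.23, 0.028, 0.017,
    "65-96", "female", 0.068, 0.041, 2.27, 1.13, 0.025, 0.015
  )
}

# Dose table for the study-area means under the shipped defaults, in
# display units, joined wide for comparison against published_doses().
pipeline_dose_wide <- function() {
  d <- dose_display(dose_table(study_conc_summary()))
  d$fluid <- ifelse(d$variant == "ALF+DF", "alf",
                    ifelse(d$variant == "GS+DF", "gs", NA))
  d <- d[!is.na(d$fluid), ]
  add <- tidyr::pivot_wider(
    d[c("age_group", "sex", "metal", "fluid", "add_1e6")],
    names_from = c("metal", "fluid"), values_from = "add_1e6",
    names_glue = "add_{tolower(metal)}_{fluid}"
  )
  ladd <- tidyr::pivot_wider(
    d[d$metal == "Cd", c("age_group", "sex", "fluid", "ladd_1e6")],
    names_from = "fluid", values_from = "ladd_1e6",
    names_glue = "ladd_cd_{fluid}"
  )
  out <- dplyr::left_join(add, ladd, by = c("age_group", "sex"))
  out$age_group <- as.character(out$age_group)
  out
}
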