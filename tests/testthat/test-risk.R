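test_that("hazard quotient, hazard index and ILCR primitives", {
  expect_equal(hazard_quotient(3.5e-3, 3.5e-3), 1)
  expect_equal(hazard_quotient(0, 1e-3), 0)
  expect_equal(hazard_quotient(14.2e-6, 3.5e-3), 14.2e-6 / 3.5e-3)
  expect_error(hazard_quotient(1, 0), "positive")

  expect_equal(hazard_index(c(Cd = 4.27e-4, Pb = 4.057e-3)),
               4.484e-3)
  expect_equal(hazard_index(c(Pb = 4.057e-3, Cd = 4.27e-4)),
               hazard_index(c(Cd = 4.27e-4, Pb = 4.057e-3)))
  expect_equal(hazard_index(0.5), 0.5)
  expect_error(hazard_index(numeric(0)), "at least one")

  expect_equal(ilcr(4.271e-8, 6.3), 2.691e-7, tolerance = 1e-4)
  expect_equal(ilcr(0, 6.3), 0)
  expect_equal(ilcr(1e-8, 12.6), 2 * ilcr(1e-8, 6.3))
  expect_error(ilcr(1e-8, NA_real_), "not assessed as a")
})

test_that("risk categories follow the strict-exceedance convention", {
  both <- categorize(hi = 0.004, ilcr_value = 2.69e-7)
  expect_equal(both$hi_category, "no_risk")
  expect_equal(both$ilcr_category, "none")

  expect_equal(categorize(ilcr_value = 1.94e-6)$ilcr_category, "potential")
  expect_equal(categorize(ilcr_value = 2e-4)$ilcr_category, "carcinogenic")
  # boundaries fall in the lower category
  expect_equal(categorize(ilcr_value = 1e-6)$ilcr_category, "none")
  expect_equal(categorize(ilcr_value = 1e-4)$ilcr_category, "potential")
  expect_equal(categorize(hi = 1)$hi_category, "no_risk")
  expect_equal(categorize(hi = 1 + 1e-12)$hi_category, "risk")
  expect_error(categorize(hi = -1), ">= 0")

  # monotone step functions
  hi_seq <- vapply(c(0, 0.5, 1, 2, 10),
                   function(h) categorize(hi = h)$hi_category,
                   character(1))
  expect_equal(hi_seq, c("no_risk", "no_risk", "no_risk", "risk", "risk"))
})

test_that("Pb carries no slope factor: ILCR for Pb is an explicit error", {
  tox <- default_toxicity()
  expect_true(is.na(tox$csf[tox$metal == "Pb"]))
  expect_error(ilcr(1e-8, tox$csf[tox$metal == "Pb"]),
               "not assessed as a")
  # and the risk table's ILCR is fed by Cd only
  doses <- dose_table(study_conc_summary())
  risks <- risk_table(doses)
  cd_only <- dose_table(study_conc_summary())
  cd_only <- cd_only[cd_only$metal == "Cd", ]
  expect_equal(risk_table(cd_only)$ilcr, risks$ilcr)
})

test_that("risk table reproduces the study's headline HI and ILCR", {
  risks <- risk_table(dose_table(study_conc_summary()))

  pick <- function(age, sex, variant, col) {
    risks[[col]][risks$age_group == age & risks$sex == sex &
                 risks$variant == variant]
  }
  # highest non-carcinogenic risk: youngest male children
  expect_equal(round(pick("2-5", "male", "ALF", "hi"), 3), 0.018)
  expect_equal(round(pick("2-5", "male", "GS", "hi"), 3), 0.009)
  expect_equal(round(pick("2-5", "male", "DF", "hi"), 3), 0.014)
  expect_equal(round(pick("2-5", "male", "GS+DF", "hi"), 3), 0.002)
  # the fully adjusted ALF dose: recomputed from the published dose cells
  # (0.427 and 14.2, in 1e-6 mg/kg/day) via the same HQ/HI primitives
  hi_from_published <- hazard_index(c(
    hazard_quotient(0.427e-6, 1e-3), hazard_quotient(14.2e-6, 3.5e-3)
  ))
  expect_equal(round(hi_from_published, 3), 0.004)
  expect_equal(pick("2-5", "male", "ALF+DF", "hi"), hi_from_published,
               tolerance = 0.006)

  # highest carcinogenic risk: 23-30-year-old males (longest remaining
  # exposure duration), within 1% of the published values
  expect_equal(pick("23-30", "male", "ALF", "ilcr"), 1.94e-6,
               tolerance = 0.005)
  expect_equal(pick("23-30", "male", "GS", "ilcr"), 1.18e-6,
               tolerance = 0.005)
  expect_equal(pick("23-30", "male", "DF", "ilcr"), 8.21e-7,
               tolerance = 0.01)
  expect_equal(pick("23-30", "male", "ALF+DF", "ilcr"), 2.69e-7,
               tolerance = 0.005)
  expect_equal(pick("23-30", "male", "GS+DF", "ilcr"), 1.63e-7,
               tolerance = 0.01)

  # category conclusions: no non-carcinogenic risk anywhere; fully
  # adjusted doses carry no carcinogenic risk, fluid-only doses at most
  # a potential one
  expect_true(all(risks$hi < 1))
  expect_true(all(risks$hi_category == "no_risk"))
  adj <- risks$variant %in% c("ALF+DF", "GS+DF")
  expect_true(all(risks$ilcr_category[adj] == "none"))
  expect_true(all(risks$ilcr_category %in% c("none", "potential")))
})

test_that("HI ordering across variants and cohorts matches the study", {
  risks <- risk_table(dose_table(study_conc_summary()))
  wide <- tidyr::pivot_wider(
    risks[c("age_group", "sex", "life_stage", "variant", "hi")],
    names_from = "variant", values_from = "hi"
  )
  # ALF > DF > ALF+DF > GS+DF and GS > GS+DF in every cohort
  expect_true(all(wide$ALF > wide$DF))
  expect_true(all(wide$DF > wide$`ALF+DF`))
  expect_true(all(wide$`ALF+DF` > wide$`GS+DF`))
  expect_true(all(wide$GS >= wide$`GS+DF`))

  # HI decreases with age within each life stage; male > female
  for (stage in c("child", "adult")) {
    for (s in c("male", "female")) {
      hi <- wide$ALF[wide$life_stage == stage & wide$sex == s]
      expect_true(all(diff(hi) < 0))
    }
  }
  m <- wide[wide$sex == "male", ]
  f <- wide[wide$sex == "female", ]
  expect_true(all(m$ALF > f$ALF))
})
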