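dose_variants <- c("Total", "ALF", "GS", "DF", "ALF+DF", "GS+DF")

#' Deposition- and bioaccessibility-adjusted concentration set
#'
#' From a metal's total concentration, its two simulated-lung-fluid
#' extract concentrations, and the cohort's pulmonary deposition fraction
#' (DF), builds the six assessment concentrations:
#' `C_DF = C_Total * DF`, `C_ALF+DF = C_ALF * DF`, `C_GS+DF = C_GS * DF`,
#' alongside the unadjusted Total/ALF/GS values.
#'
#' @param total,alf,gs Concentrations in mg/m3 (>= 0).
#' @param df_pulmonary Pulmonary deposition fraction in `[0, 1]`.
#' @return A named list of the six variants (mg/m3) plus `df_pulmonary`.
#' @export
adjusted_concentrations <- function(total, alf, gs, df_pulmonary) {
  if (df_pulmonary < 0 || df_pulmonary > 1) {
    stop("df_pulmonary must lie in [0, 1]", call. = FALSE)
  }
  if (any(c(total, alf, gs) < 0, na.rm = TRUE)) {
    stop("concentrations must be >= 0", call. = FALSE)
  }
  list(
    "Total" = total,
    "ALF" = alf,
    "GS" = gs,
    "DF" = total * df_pulmonary,
    "ALF+DF" = alf * df_pulmonary,
    "GS+DF" = gs * df_pulmonary,
    df_pulmonary = df_pulmonary
  )
}

#' Exposure parameters for one cohort
#'
#' Bundles the symbols of the daily-dose equation for one cohort:
#' inhalation rate InhR (m3/day), exposure frequency EF (day/year),
#' exposure duration ED (years), body weight BW (kg), and the two
#' averaging times: AT_n = ED x 365 days (non-carcinogens) and
#' AT_c = 70 x 365 days (carcinogens).
#'
#' @param inhr,bw,ed Cohort inhalation rate, body weight and exposure
#'   duration.
#' @param ef Exposure frequency, day/year (default 350).
#' @param at_c_days Carcinogen averaging time in days (default 70 x 365).
#' @return A validated named list.
#' @export
exposure_parameters <- function(inhr, bw, ed, ef = 350,
                                at_c_days = 70 * 365) {
  p <- list(inhr = inhr, ef = ef, ed = ed, bw = bw,
            at_n = ed * 365, at_c = at_c_days)
  if (any(unlist(p) <= 0)) {
    stop("all exposure parameters must be > 0", call. = FALSE)
  }
  p
}

#' Average daily inhaled dose (non-carcinogens)
#'
#' `ADD_inh = C * InhR * EF * ED / (BW * AT_n)` in mg/kg/day. Because
#' AT_n = ED x 365, ADD is independent of ED and equals
#' `C * InhR * (EF/365) / BW`.
#'
#' @param C Assessment concentration, mg/m3.
#' @param params An [exposure_parameters()] list.
#' @return Dose in mg/kg/day.
#' @export
add_inh <- function(C, params) {
  C * params$inhr * params$ef * params$ed / (params$bw * params$at_n)
}

#' Lifetime-averaged daily inhaled dose (carcinogens)
#'
#' `LADD_inh = C * InhR * EF * ED / (BW * AT_c)` in mg/kg/day with
#' AT_c = 70 x 365 days, so `LADD = ADD * ED / 70` exactly.
#'
#' @inheritParams add_inh
#' @return Dose in mg/kg/day.
#' @export
ladd_inh <- function(C, params) {
  C * params$inhr * params$ef * params$ed / (params$bw * params$at_c)
}

#' Per-cohort dose table over all concentration variants
#'
#' Computes ADD (and, for carcinogens, LADD) for every cohort x sex x
#' metal x concentration variant. Metal concentrations enter in ng/m3 and
#' are converted to mg/m3 once, on ingest, via [ngm3_to_mgm3()].
#'
#' @param conc A tibble with columns `metal`, `total_ngm3`, `alf_ngm3`,
#'   `gs_ngm3` of mean concentrations (e.g. [study_conc_summary()] or
#'   [conc_summary()]).
#' @param registry Cohort registry (see [default_cohort_registry()]).
#' @param df_table Per-cohort deposition table (see
#'   [default_df_table()]); its pulmonary column is the DF of the
#'   adjusted concentrations.
#' @param config Configuration list (exposure constants, toxicity).
#' @param carcinogens Metals for which LADD is computed (default `"Cd"`).
#' @param variants Concentration variants to emit (default all six).
#' @return A tibble with columns `age_group`, `sex`, `life_stage`,
#'   `metal`, `variant`, `add_mgkgday`, `ladd_mgkgday` (NA for
#'   non-carcinogens).
#' @export
dose_table <- function(conc, registry = default_cohort_registry(),
                       df_table = default_df_table(),
                       config = default_config(),
                       carcinogens = "Cd",
                       variants = dose_variants) {
  variants <- match.arg(variants, dose_variants, several.ok = TRUE)
  rows <- list()
  for (i in seq_len(nrow(registry))) {
    r <- registry[i, ]
    df_row <- df_lookup(df_table, r$age_group, r$sex)
    params <- exposure_parameters(
      inhr = r$inhr_m3_day, bw = r$body_weight_kg, ed = r$ed_years,
      ef = config$exposure$ef_day_per_year,
      at_c_days = config$exposure$at_c_days
    )
    for (j in seq_len(nrow(conc))) {
      m <- conc[j, ]
      cs <- adjusted_concentrations(
        total = ngm3_to_mgm3(m$total_ngm3),
        alf = ngm3_to_mgm3(m$alf_ngm3),
        gs = ngm3_to_mgm3(m$gs_ngm3),
        df_pulmonary = df_row$df_pulmonary
      )
      for (v in variants) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          age_group = r$age_group, sex = r$sex, life_stage = r$life_stage,
          metal = m$metal, variant = v,
          add_mgkgday = add_inh(cs[[v]], params),
          ladd_mgkgday = if (m$metal %in% carcinogens) {
            ladd_inh(cs[[v]], params)
          } else NA_real_
        )
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  out$variant <- factor(out$variant, levels = dose_variants)
  out
}

#' Display-scale a dose table
#'
#' Doses are held internally in mg/kg/day; published summaries print them
#' in units of 1e-6 mg/kg/day. This helper rescales for display.
#'
#' @param doses A [dose_table()] tibble.
#' @return The same tibble with `add_1e6` and `ladd_1e6` columns added.
#' @export
dose_display <- function(doses) {
  doses$add_1e6 <- doses$add_mgkgday * 1e6
  doses$ladd_1e6 <- doses$ladd_mgkgday * 1e6
  doses
}
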