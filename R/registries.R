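extdata <- function(file) {
  system.file("extdata", file, package = "inhalrisk", mustWork = TRUE)
}

age_group_levels <- c("2-5", "5-7", "7-11", "11-23",
                      "23-30", "30-40", "40-65", "65-96")

#' Cohort definitions
#'
#' The eight age groups of the assessment, each split by sex. Children are
#' 2-23 years old (four groups), adults 23-96 (four groups).
#'
#' @return A tibble with `age_group` (ordered factor), `age_lo`, `age_hi`
#'   and `life_stage` (child/adult).
#' @export
default_cohorts <- function() {
  lo <- c(2, 5, 7, 11, 23, 30, 40, 65)
  hi <- c(5, 7, 11, 23, 30, 40, 65, 96)
  tibble::tibble(
    age_group = factor(age_group_levels, levels = age_group_levels,
                       ordered = TRUE),
    age_lo = lo,
    age_hi = hi,
    life_stage = ifelse(hi <= 23, "child", "adult")
  )
}

#' Default cohort exposure/physiology registry
#'
#' The shipped per-cohort registry: body weight, long-term inhalation rate,
#' exposure duration, and the physiological quantities (height, tidal
#' volume, breathing frequency, upper-airway volume) that drive the
#' deposition model. Values are exposure-handbook-plausible defaults
#' calibrated against the study's published dose table (see the methods
#' vignette); every value can be overridden by supplying your own table
#' in the same column layout.
#'
#' @param path Optional path to a replacement registry CSV.
#' @return A tibble, one row per age group x sex.
#' @export
default_cohort_registry <- function(path = NULL) {
  path <- if (is.null(path)) extdata("cohort_registry.csv") else path
  reg <- tibble::as_tibble(
    utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  )
  required <- c("age_group", "sex", "life_stage", "age_years", "height_cm",
                "body_weight_kg", "inhr_m3_day", "ed_years")
  missing_cols <- setdiff(required, names(reg))
  if (length(missing_cols) > 0) {
    stop("cohort registry is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  num <- vapply(reg, is.numeric, logical(1))
  if (any(vapply(reg[num], function(x) any(x <= 0), logical(1)))) {
    stop("cohort registry values must all be positive", call. = FALSE)
  }
  reg$age_group <- factor(reg$age_group, levels = age_group_levels,
                          ordered = TRUE)
  reg
}

#' Default toxicity registry
#'
#' Inhalation reference doses and cancer slope factors: Cd RfD
#' 1.0e-3 mg/kg/day with CSF 6.3 (mg/kg/day)^-1; Pb RfD 3.5e-3 mg/kg/day
#' and no CSF (Pb is not assessed as an inhalation carcinogen here).
#'
#' @param config A configuration list (see [default_config()]); the
#'   registry is built from its `toxicity` block so overrides flow through.
#' @return A tibble with columns `metal`, `rfd`, `csf` (NA when absent).
#' @export
default_toxicity <- function(config = default_config()) {
  tox <- config$toxicity
  tibble::tibble(
    metal = names(tox),
    rfd = unname(vapply(tox, function(t) t$rfd %||% NA_real_, numeric(1))),
    csf = unname(vapply(tox, function(t) t$csf %||% NA_real_, numeric(1)))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Study-area annual mean concentration profiles
#'
#' The shipped annual mean +/- sd summary of PM2.5 mass and Cd/Pb
#' concentrations (total and per simulated lung fluid) for the two
#' monitoring sites (XP, DD) and their pooled average (ALL).
#'
#' @return A tibble, one row per site x metal.
#' @export
study_profiles <- function() {
  tibble::as_tibble(
    utils::read.csv(extdata("study_annual_means.csv"), comment.char = "#",
                    stringsAsFactors = FALSE)
  )
}

#' Study-area concentration summary for dose work
#'
#' Extracts the pooled (or per-site) mean concentrations from the shipped
#' annual-means fixture in the shape `dose_table()` expects.
#'
#' @param site `"ALL"` (default), `"XP"` or `"DD"`.
#' @return A tibble with columns `metal`, `total_ngm3`, `alf_ngm3`,
#'   `gs_ngm3` (annual means, ng/m3).
#' @export
study_conc_summary <- function(site = "ALL") {
  prof <- study_profiles()
  prof <- prof[prof$site == site, ]
  if (nrow(prof) == 0) {
    stop("unknown site: ", site, call. = FALSE)
  }
  tibble::tibble(
    metal = prof$metal,
    total_ngm3 = prof$total_mean,
    alf_ngm3 = prof$alf_mean,
    gs_ngm3 = prof$gs_mean
  )
}

#' Summarize a sample table into mean concentrations
#'
#' Collapses a long sample table to per-metal mean concentrations, either
#' pooled over all samples or per site. Each record carries equal weight.
#'
#' @param samples A sample tibble (see [read_samples()]).
#' @param grouping `"all"` (default) or `"site"`.
#' @return A tibble with columns (`site`,) `metal`, `n`, `total_ngm3`,
#'   `alf_ngm3`, `gs_ngm3`.
#' @export
conc_summary <- function(samples, grouping = c("all", "site")) {
  grouping <- match.arg(grouping)
  groups <- if (grouping == "site") c("site", "metal") else "metal"
  samples |>
    dplyr::group_by(dplyr::across(dplyr::all_of(groups))) |>
    dplyr::summarise(
      n = dplyr::n(),
      total_ngm3 = mean(.data$total_ngm3, na.rm = TRUE),
      alf_ngm3 = mean(.data$alf_ngm3, na.rm = TRUE),
      gs_ngm3 = mean(.data$gs_ngm3, na.rm = TRUE),
      .groups = "drop"
    )
}

#' PM2.5 exceedance ratio against an air-quality standard
#'
#' Ratio of a mean PM2.5 mass concentration to a regulatory standard
#' (default: the 35 ug/m3 annual standard).
#'
#' @param pm25_mean Mean PM2.5 mass concentration(s), ug/m3.
#' @param standard The standard, ug/m3.
#' @return `pm25_mean / standard`.
#' @export
pm25_exceedance_ratio <- function(pm25_mean, standard = 35) {
  stopifnot(standard > 0, all(pm25_mean >= 0))
  pm25_mean / standard
}
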