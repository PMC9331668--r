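#' Hazard quotient
#'
#' `HQ = ADD / RfD`: the non-carcinogenic dose scaled by the metal's
#' inhalation reference dose.
#'
#' @param add Average daily dose, mg/kg/day.
#' @param rfd Reference dose, mg/kg/day; must be > 0.
#' @return Dimensionless HQ.
#' @export
hazard_quotient <- function(add, rfd) {
  if (any(!is.finite(rfd)) || any(rfd <= 0)) {
    stop("RfD must be a positive number", call. = FALSE)
  }
  add / rfd
}

#' Hazard index
#'
#' `HI = sum_i HQ_i`: hazard quotients are summed across metals without
#' modelling interactions between them.
#'
#' @param hqs Numeric vector (optionally named by metal) of HQ values.
#' @return Dimensionless HI.
#' @export
hazard_index <- function(hqs) {
  if (length(hqs) == 0) {
    stop("at least one hazard quotient is required", call. = FALSE)
  }
  sum(hqs)
}

#' Incremental lifetime cancer risk
#'
#' `ILCR = LADD * CSF`. Only metals with a cancer slope factor are
#' assessable; requesting ILCR without a CSF is an explicit error, never
#' a silent zero.
#'
#' @param ladd Lifetime-averaged daily dose, mg/kg/day.
#' @param csf Cancer slope factor, (mg/kg/day)^-1.
#' @return Dimensionless ILCR.
#' @export
ilcr <- function(ladd, csf) {
  if (any(is.na(csf)) || any(!is.finite(csf)) || any(csf <= 0)) {
    stop("no cancer slope factor: this metal is not assessed as a ",
         "carcinogen", call. = FALSE)
  }
  ladd * csf
}

#' Categorize HI and ILCR values
#'
#' HI above 1 flags a non-carcinogenic risk. ILCR above 1e-4 flags a
#' carcinogenic risk; between 1e-6 and 1e-4 a potential risk; at or below
#' 1e-6 none. Boundary values fall in the lower category ("exceeds" read
#' strictly).
#'
#' @param hi Hazard index (>= 0), or NA.
#' @param ilcr_value ILCR (>= 0), or NA.
#' @return A list with `hi_category` (`"risk"`/`"no_risk"`) and
#'   `ilcr_category` (`"carcinogenic"`/`"potential"`/`"none"`); NA inputs
#'   give NA categories.
#' @export
categorize <- function(hi = NA_real_, ilcr_value = NA_real_) {
  if (any(c(hi, ilcr_value) < 0, na.rm = TRUE)) {
    stop("hi and ilcr_value must be >= 0", call. = FALSE)
  }
  hi_cat <- ifelse(is.na(hi), NA_character_,
                   ifelse(hi > 1, "risk", "no_risk"))
  ilcr_cat <- ifelse(is.na(ilcr_value), NA_character_,
                     ifelse(ilcr_value > 1e-4, "carcinogenic",
                            ifelse(ilcr_value > 1e-6, "potential", "none")))
  list(hi_category = hi_cat, ilcr_category = ilcr_cat)
}

#' Risk characterization table
#'
#' Collapses a dose table to one row per cohort x sex x variant: the
#' per-metal hazard quotients (wide `hq_<metal>` columns), their sum HI
#' with its category, and the ILCR summed over carcinogens with its
#' category. Full precision is retained; display rounding is left to the
#' caller.
#'
#' @param doses A [dose_table()] tibble.
#' @param toxicity Toxicity registry (see [default_toxicity()]).
#' @return A tibble with columns `age_group`, `sex`, `life_stage`,
#'   `variant`, `hq_<metal>`..., `hi`, `hi_category`, `ilcr`,
#'   `ilcr_category` (`ilcr` is NA when no carcinogen dose is present).
#' @export
risk_table <- function(doses, toxicity = default_toxicity()) {
  missing_metals <- setdiff(unique(doses$metal), toxicity$metal)
  if (length(missing_metals) > 0) {
    stop("no toxicity entry for metal(s): ",
         paste(missing_metals, collapse = ", "), call. = FALSE)
  }
  d <- dplyr::left_join(doses, toxicity, by = "metal")
  d$hq <- hazard_quotient(d$add_mgkgday, d$rfd)
  d$ilcr_i <- ifelse(is.na(d$ladd_mgkgday) | is.na(d$csf),
                     NA_real_, d$ladd_mgkgday * d$csf)

  wide_hq <- d |>
    dplyr::select(dplyr::all_of(c("age_group", "sex", "life_stage",
                                  "variant", "metal", "hq"))) |>
    tidyr::pivot_wider(names_from = "metal", values_from = "hq",
                       names_prefix = "hq_")

  agg <- d |>
    dplyr::group_by(.data$age_group, .data$sex, .data$life_stage,
                    .data$variant) |>
    dplyr::summarise(
      hi = hazard_index(.data$hq),
      ilcr = if (all(is.na(.data$ilcr_i))) NA_real_ else
        sum(.data$ilcr_i, na.rm = TRUE),
      .groups = "drop"
    )

  out <- dplyr::left_join(wide_hq, agg,
                          by = c("age_group", "sex", "life_stage",
                                 "variant"))
  cats <- categorize(out$hi, out$ilcr)
  out$hi_category <- cats$hi_category
  out$ilcr_category <- cats$ilcr_category
  out
}
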