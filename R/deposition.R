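#' Regional deposition fractions from the ICRP-66 semi-empirical fits
#'
#' Evaluates the published ICRP-66 closed-form regional deposition
#' expressions for a nose-breathing reference adult at light activity:
#' head airways (above the pharynx), tracheobronchial (TB) region, and
#' pulmonary (alveolar) region, as functions of the particle's
#' aerodynamic diameter. For a spherical particle of density rho (g/cm3),
#' the aerodynamic diameter is `d * sqrt(rho)`.
#'
#' This closed-form engine characterizes the reference adult; the
#' per-cohort deposition fractions used in dose work come from an
#' override table (see [default_df_table()]), mirroring how an external
#' multiple-path dosimetry run would be consumed.
#'
#' @param diameter_um Geometric particle diameter(s), um, in
#'   `[0.001, 100]`.
#' @param density_gcm3 Particle density, g/cm3 (default 1.0, so the
#'   geometric and aerodynamic diameters coincide).
#' @return A tibble with columns `diameter_um`, `head`, `tracheobronchial`,
#'   `pulmonary`, `total`, `source = "model"`. Components are fractions
#'   in `[0, 1]` with `total <= 1`.
#' @export
#' @examples
#' icrp_regional_df(2.5)
icrp_regional_df <- function(diameter_um, density_gcm3 = 1.0) {
  if (any(diameter_um < 0.001 | diameter_um > 100)) {
    stop("diameter_um must lie in [0.001, 100] um", call. = FALSE)
  }
  if (density_gcm3 <= 0) stop("density_gcm3 must be > 0", call. = FALSE)
  d <- diameter_um * sqrt(density_gcm3) # aerodynamic diameter
  ln <- log(d)
  inhalable <- 1 - 0.5 * (1 - 1 / (1 + 0.00076 * d^2.8))
  head <- inhalable * (1 / (1 + exp(6.84 + 1.183 * ln)) +
                       1 / (1 + exp(0.924 - 1.885 * ln)))
  tb <- (0.00352 / d) * (exp(-0.234 * (ln + 3.40)^2) +
                         63.9 * exp(-0.819 * (ln - 1.61)^2))
  pul <- (0.0155 / d) * (exp(-0.416 * (ln + 2.84)^2) +
                         19.11 * exp(-0.482 * (ln - 1.362)^2))
  out <- tibble::tibble(
    diameter_um = diameter_um,
    head = head,
    tracheobronchial = tb,
    pulmonary = pul,
    total = head + tb + pul,
    source = "model"
  )
  stopifnot(all(out$head >= 0 & out$head <= 1),
            all(out$tracheobronchial >= 0 & out$tracheobronchial <= 1),
            all(out$pulmonary >= 0 & out$pulmonary <= 1),
            all(out$total <= 1 + 1e-12))
  out
}

#' Reference adult physiology for deposition scaling
#'
#' @return A named list: height (cm), FRC (mL), tidal volume (mL),
#'   breathing frequency (breaths/min), upper-airway volume (mL), nasal
#'   breathing mode.
#' @export
reference_physiology <- function() {
  list(height_cm = 175, frc_ml = 3300, tidal_volume_ml = 625,
       breath_freq_per_min = 12, uaw_volume_ml = 50,
       breathing_mode = "nasal")
}

validate_physiology <- function(p) {
  vols <- c(p$frc_ml, p$tidal_volume_ml, p$breath_freq_per_min,
            p$uaw_volume_ml)
  if (any(!is.finite(vols)) || any(vols <= 0)) {
    stop("physiology volumes and frequencies must all be > 0",
         call. = FALSE)
  }
  invisible(p)
}

#' Rescale regional deposition for a non-reference physiology
#'
#' Applies a documented ventilation/FRC scaling rule to adapt the
#' reference-adult regional fractions to another cohort: pulmonary
#' deposition scales with the tidal-volume-to-FRC ratio (deeper breaths
#' relative to lung volume carry more aerosol into the alveolar region),
#' and TB deposition scales with the square root of the minute-ventilation
#' ratio; head deposition is left unchanged. If scaling pushes the
#' regional sum above 1, all three components are renormalized onto the
#' simplex with a warning.
#'
#' @param base A one-row regional-deposition tibble (e.g. from
#'   [icrp_regional_df()]).
#' @param physiology,reference Named lists as from
#'   [reference_physiology()].
#' @return The rescaled tibble (same shape as `base`).
#' @export
scale_df <- function(base, physiology, reference = reference_physiology()) {
  validate_physiology(physiology)
  validate_physiology(reference)
  s_pul <- (physiology$tidal_volume_ml / physiology$frc_ml) /
           (reference$tidal_volume_ml / reference$frc_ml)
  vent <- (physiology$tidal_volume_ml * physiology$breath_freq_per_min) /
          (reference$tidal_volume_ml * reference$breath_freq_per_min)
  out <- base
  out$pulmonary <- base$pulmonary * s_pul
  out$tracheobronchial <- base$tracheobronchial * sqrt(vent)
  out$pulmonary <- pmin(out$pulmonary, 1)
  out$tracheobronchial <- pmin(out$tracheobronchial, 1)
  out$total <- out$head + out$tracheobronchial + out$pulmonary
  over <- out$total > 1
  if (any(over)) {
    warning("scaled deposition exceeded 1; renormalized onto the simplex",
            call. = FALSE)
    for (col in c("head", "tracheobronchial", "pulmonary")) {
      out[[col]][over] <- out[[col]][over] / out$total[over]
    }
    out$total[over] <- 1
  }
  out
}

#' Read and validate a per-cohort deposition-fraction table
#'
#' @param path CSV with columns `age_group, sex, df_head, df_tb,
#'   df_pulmonary`. Each component must lie in `[0, 1]` and each row must
#'   sum to at most 1; violations are load errors.
#' @return A tibble with an added `df_total` column and `source =
#'   "override"`.
#' @export
read_df_table <- function(path) {
  df <- tibble::as_tibble(
    utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  )
  required <- c("age_group", "sex", "df_head", "df_tb", "df_pulmonary")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("deposition table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  comp <- df[c("df_head", "df_tb", "df_pulmonary")]
  if (any(comp < 0 | comp > 1)) {
    stop("deposition fractions must lie in [0, 1]", call. = FALSE)
  }
  df$df_total <- df$df_head + df$df_tb + df$df_pulmonary
  if (any(df$df_total > 1 + 1e-9)) {
    stop("regional deposition fractions must sum to at most 1 per cohort",
         call. = FALSE)
  }
  df$source <- "override"
  df$age_group <- factor(df$age_group, levels = age_group_levels,
                         ordered = TRUE)
  df
}

#' Shipped per-cohort deposition-fraction table
#'
#' The default regional deposition fractions per age group and sex for
#' 2.5 um spherical particles of unit density under nasal breathing,
#' standing in for an external multiple-path dosimetry run. Pulmonary
#' fractions decrease with age within each life stage, males exceed
#' females, children span 0.15-0.26 and adults 0.12-0.14; totals span
#' 0.64-0.79 (children) and 0.72-0.80 (adults).
#'
#' @return A validated deposition tibble (see [read_df_table()]).
#' @export
default_df_table <- function() {
  read_df_table(extdata("df_table.csv"))
}

#' Look up a cohort's regional deposition fractions
#'
#' @param table A deposition tibble (see [read_df_table()]).
#' @param age_group One of the eight age-group labels.
#' @param sex `"male"` or `"female"`.
#' @return The matching one-row tibble.
#' @export
df_lookup <- function(table, age_group, sex) {
  hit <- table[as.character(table$age_group) == as.character(age_group) &
               table$sex == sex, ]
  if (nrow(hit) != 1) {
    stop("no deposition entry for cohort ", age_group, " ", sex,
         call. = FALSE)
  }
  hit
}

#' Functional residual capacity from reference equations
#'
#' FRC (mL) from height for children, and from age and height for adults,
#' using the coefficient registry in the configuration: children use a
#' power law `a * height^b`; adults use a linear reference equation
#' `intercept + b_height * height + b_age * age`, sex-specific. The
#' package ships standard reference-equation defaults; no coefficients
#' are invented silently — a missing registry entry is an error.
#'
#' @param age_years Age in years (children < 23, adults >= 23).
#' @param height_cm Height in cm; must be > 0.
#' @param sex `"male"` or `"female"`.
#' @param coefficients The `frc` block of a configuration list.
#' @return FRC in mL (> 0).
#' @export
frc_estimate <- function(age_years, height_cm, sex = c("male", "female"),
                         coefficients = default_config()$frc) {
  sex <- match.arg(sex)
  if (any(height_cm <= 0)) stop("height_cm must be > 0", call. = FALSE)
  if (any(age_years <= 0)) stop("age_years must be > 0", call. = FALSE)
  if (is.null(coefficients)) {
    stop("FRC coefficient registry is required", call. = FALSE)
  }
  child <- age_years < 23
  out <- numeric(length(age_years))
  if (any(child)) {
    cc <- coefficients$child
    if (is.null(cc$a) || is.null(cc$b)) {
      stop("missing child FRC coefficients (a, b)", call. = FALSE)
    }
    out[child] <- cc$a * height_cm[child]^cc$b
  }
  if (any(!child)) {
    ca <- coefficients[[paste0("adult_", sex)]]
    if (is.null(ca$intercept_ml) || is.null(ca$b_height) ||
        is.null(ca$b_age)) {
      stop("missing adult FRC coefficients for sex ", sex, call. = FALSE)
    }
    out[!child] <- ca$intercept_ml + ca$b_height * height_cm[!child] +
      ca$b_age * age_years[!child]
  }
  if (any(out <= 0)) {
    stop("FRC estimate is non-positive; check heights and coefficients",
         call. = FALSE)
  }
  out
}

#' Model-based per-cohort deposition report
#'
#' Convenience wrapper chaining the closed-form reference deposition
#' ([icrp_regional_df()]) and the physiology scaling rule ([scale_df()])
#' over every cohort in a registry. This is the self-contained alternative
#' to the shipped override table and is reported alongside it.
#'
#' @param registry A cohort registry (see [default_cohort_registry()]).
#' @param diameter_um,density_gcm3 Particle specification.
#' @param config Configuration list supplying FRC coefficients.
#' @return A tibble, one row per cohort, with the scaled regional
#'   fractions and `source = "model"`.
#' @export
model_df_table <- function(registry = default_cohort_registry(),
                           diameter_um = 2.5, density_gcm3 = 1.0,
                           config = default_config()) {
  base <- icrp_regional_df(diameter_um, density_gcm3)
  ref <- reference_physiology()
  rows <- lapply(seq_len(nrow(registry)), function(i) {
    r <- registry[i, ]
    phys <- list(
      height_cm = r$height_cm,
      frc_ml = frc_estimate(r$age_years, r$height_cm, r$sex,
                            config$frc),
      tidal_volume_ml = r$tidal_volume_ml,
      breath_freq_per_min = r$breath_freq_per_min,
      uaw_volume_ml = r$uaw_volume_ml,
      breathing_mode = "nasal"
    )
    scaled <- scale_df(base, phys, ref)
    tibble::tibble(
      age_group = r$age_group, sex = r$sex,
      df_head = scaled$head, df_tb = scaled$tracheobronchial,
      df_pulmonary = scaled$pulmonary, df_total = scaled$total,
      source = "model"
    )
  })
  dplyr::bind_rows(rows)
}
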