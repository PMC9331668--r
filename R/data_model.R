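#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
NULL

sample_columns <- c("sample_id", "site", "date", "pm25_ugm3", "metal",
                    "total_ngm3", "alf_ngm3", "gs_ngm3")

#' Read a filter-sample table
#'
#' Reads a long-format delimited table of PM2.5 filter samples: one row per
#' sample x metal, with the PM2.5 mass concentration (ug/m3), the total
#' (acid-digest) metal concentration, and the concentrations extracted by
#' the two simulated lung fluids, artificial lysosomal fluid (ALF) and
#' Gamble's solution (GS), all in ng/m3. Extract columns may be missing
#' (NA) for samples without a bioaccessibility measurement.
#'
#' @param path Path to a CSV (default) or TSV file with columns
#'   `sample_id, site, date, pm25_ugm3, metal, total_ngm3, alf_ngm3,
#'   gs_ngm3`. Lines starting with `#` are treated as comments.
#' @param sep Field separator; `","` by default, `"\t"` accepted.
#' @return A tibble of validated sample records with a `units` attribute
#'   recording the input conventions (PM: ug/m3, metals: ng/m3). A file
#'   with no data rows yields an empty tibble.
#' @details An extract concentration exceeding the total concentration is
#'   physically impossible and indicates analytical error; such rows are
#'   kept as-is but flagged with a warning (never silently clamped).
#' @export
read_samples <- function(path, sep = ",") {
  if (!file.exists(path)) {
    stop("sample file not found: ", path, call. = FALSE)
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          stringsAsFactors = FALSE)
  missing_cols <- setdiff(sample_columns, names(df))
  if (length(missing_cols) > 0) {
    stop("sample table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- as_tibble(df[sample_columns])
  validate_samples(df)
}

#' Validate a sample table
#'
#' Checks the invariants of the sample data model: non-negative
#' concentrations, unique sample_id x metal rows, and extract <= total.
#' Violations of the last are flagged with a warning rather than an error.
#'
#' @param df A tibble in the `read_samples()` column layout.
#' @return The validated tibble, with a `units` attribute attached.
#' @export
validate_samples <- function(df) {
  if (nrow(df) > 0) {
    for (col in c("pm25_ugm3", "total_ngm3", "alf_ngm3", "gs_ngm3")) {
      bad <- which(!is.na(df[[col]]) & df[[col]] < 0)
      if (length(bad) > 0) {
        stop("negative ", col, " in row(s): ", paste(bad, collapse = ", "),
             call. = FALSE)
      }
    }
    key <- paste(df$sample_id, df$metal)
    if (anyDuplicated(key)) {
      stop("duplicated sample_id x metal row(s): ",
           paste(unique(key[duplicated(key)]), collapse = ", "),
           call. = FALSE)
    }
    over <- which((!is.na(df$alf_ngm3) & df$alf_ngm3 > df$total_ngm3) |
                  (!is.na(df$gs_ngm3) & df$gs_ngm3 > df$total_ngm3))
    if (length(over) > 0) {
      warning("extract concentration exceeds total in row(s): ",
              paste(over, collapse = ", "),
              " (kept as measured, not clamped)", call. = FALSE)
    }
  }
  attr(df, "units") <- c(pm25 = "ug/m3", metals = "ng/m3")
  df
}

#' Write a result table to delimited text
#'
#' Writes any stage's result table as CSV with a commented metadata header
#' (units line) and a deterministic column order (the order of the input
#' tibble). Full numeric precision is preserved so that write/read
#' round-trips are lossless.
#'
#' @param results A data frame; must be non-null.
#' @param path Output file path.
#' @param units Optional named character vector describing column units,
#'   written as a `#` comment line.
#' @return Invisibly, `path`.
#' @export
write_results <- function(results, path, units = NULL) {
  if (is.null(results) || !is.data.frame(results)) {
    stop("`results` must be a data frame", call. = FALSE)
  }
  con <- tryCatch(file(path, open = "w"),
                  error = function(e) stop("cannot write to ", path,
                                           call. = FALSE))
  on.exit(close(con))
  if (!is.null(units)) {
    writeLines(paste0("# units: ",
                      paste(names(units), units, sep = "=", collapse = "; ")),
               con)
  }
  df <- as.data.frame(results)
  # full precision: serialize numerics with 17 significant digits
  for (col in names(df)) {
    if (is.numeric(df[[col]])) df[[col]] <- sprintf("%.17g", df[[col]])
  }
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read back a result table written by `write_results()`
#'
#' @param path Path to the CSV file.
#' @return A tibble with the original column order and full-precision
#'   numeric payload.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("result file not found: ", path, call. = FALSE)
  as_tibble(utils::read.csv(path, comment.char = "#",
                            stringsAsFactors = FALSE))
}

#' Default pipeline configuration
#'
#' Returns the complete default configuration used across the pipeline:
#' exposure constants (EF = 350 day/year, ED = 6 years for children and 26
#' for adults, carcinogen averaging time 70 x 365 days), Monte Carlo
#' settings (5000 iterations, inhalation-rate CV 0.3), the particle
#' specification (2.5 um, density 1.0 g/cm3, spherical, nasal breathing),
#' the toxicity registry (Cd: RfD 1.0e-3 mg/kg/day, CSF 6.3 (mg/kg/day)^-1;
#' Pb: RfD 3.5e-3, no CSF), and the FRC reference-equation coefficients.
#'
#' @return A nested named list.
#' @export
default_config <- function() {
  list(
    exposure = list(
      ef_day_per_year = 350,
      ed_child_years = 6,
      ed_adult_years = 26,
      at_c_days = 70 * 365
    ),
    monte_carlo = list(
      iterations = 5000,
      inhr_cv = 0.3
    ),
    particle = list(
      diameter_um = 2.5,
      density_gcm3 = 1.0
    ),
    toxicity = list(
      Cd = list(rfd = 1.0e-3, csf = 6.3),
      Pb = list(rfd = 3.5e-3)
    ),
    frc = list(
      child = list(a = 0.00357, b = 2.67),
      adult_male = list(intercept_ml = -1090, b_height = 23.4, b_age = 10.0),
      adult_female = list(intercept_ml = -1000, b_height = 22.4, b_age = 1.0)
    )
  )
}

merge_config <- function(base, override, path = character()) {
  for (key in names(override)) {
    here <- c(path, key)
    if (!key %in% names(base)) {
      stop("unknown configuration key: ", paste(here, collapse = "$"),
           call. = FALSE)
    }
    if (is.list(base[[key]]) && is.list(override[[key]])) {
      base[[key]] <- merge_config(base[[key]], override[[key]], here)
    } else {
      base[[key]] <- override[[key]]
    }
  }
  base
}

#' Read a pipeline configuration file
#'
#' Parses a YAML configuration file and merges it over the package
#' defaults (`default_config()`). Unknown keys are rejected rather than
#' silently ignored, so typos surface immediately. An empty or missing
#' override yields the defaults.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return The merged, validated configuration list.
#' @export
read_config <- function(path = NULL) {
  config <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) {
      stop("config file not found: ", path, call. = FALSE)
    }
    override <- yaml::read_yaml(path)
    if (!is.null(override)) {
      if (!is.list(override)) {
        stop("config file must parse to a key-value mapping", call. = FALSE)
      }
      config <- merge_config(config, override)
    }
  }
  validate_config(config)
}

validate_config <- function(config) {
  mc <- config$monte_carlo
  if (mc$iterations < 1) {
    stop("monte_carlo$iterations must be >= 1", call. = FALSE)
  }
  if (mc$inhr_cv < 0) {
    stop("monte_carlo$inhr_cv must be >= 0", call. = FALSE)
  }
  for (metal in names(config$toxicity)) {
    tox <- config$toxicity[[metal]]
    if (!is.null(tox$rfd) && tox$rfd <= 0) {
      stop("toxicity$", metal, "$rfd must be > 0", call. = FALSE)
    }
    if (!is.null(tox$csf) && tox$csf <= 0) {
      stop("toxicity$", metal, "$csf must be > 0", call. = FALSE)
    }
  }
  if (config$exposure$ef_day_per_year <= 0 ||
      config$exposure$ef_day_per_year > 365) {
    stop("exposure$ef_day_per_year must be in (0, 365]", call. = FALSE)
  }
  config
}
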