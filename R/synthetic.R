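lnorm_params <- function(mean, sd) {
  if (any(mean <= 0)) {
    stop("log-normal moment matching requires a positive mean",
         call. = FALSE)
  }
  sdlog2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

rlnorm_matched <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  p <- lnorm_params(mean, sd)
  stats::rlnorm(n, p$meanlog, p$sdlog)
}

rbeta_matched <- function(n, mean, sd) {
  if (mean <= 0 || mean >= 1) {
    stop("fraction mean must lie in (0, 1)", call. = FALSE)
  }
  if (sd == 0) return(rep(mean, n))
  if (sd^2 >= mean * (1 - mean)) {
    stop("fraction sd too large for a beta distribution with this mean",
         call. = FALSE)
  }
  t <- mean * (1 - mean) / sd^2 - 1
  out <- stats::rbeta(n, mean * t, (1 - mean) * t)
  # truncate to (0, 1]: resample exact zeros (a measure-zero guard)
  bad <- which(out <= 0)
  while (length(bad) > 0) {
    out[bad] <- stats::rbeta(length(bad), mean * t, (1 - mean) * t)
    bad <- bad[out[bad] <= 0]
  }
  out
}

#' Build a generator site profile from an annual-means summary
#'
#' Converts one site's rows of the annual-means table into the profile
#' consumed by [generate_samples()]. Extractable-fraction means are the
#' ratios of the extract and total means; the fraction sd defaults to
#' `fraction_cv` times the mean (the summary reports concentration sds,
#' not fraction sds).
#'
#' @param summary_rows Rows of [study_profiles()] for a single site.
#' @param fraction_cv Relative sd assumed for extractable fractions
#'   (default 0.2).
#' @return A site-profile list.
#' @export
site_profile <- function(summary_rows, fraction_cv = 0.2) {
  stopifnot(length(unique(summary_rows$site)) == 1)
  metals <- lapply(seq_len(nrow(summary_rows)), function(i) {
    r <- summary_rows[i, ]
    f_alf <- r$alf_mean / r$total_mean
    f_gs <- r$gs_mean / r$total_mean
    list(metal = r$metal,
         total_mean = r$total_mean, total_sd = r$total_sd,
         alf_fraction_mean = f_alf, alf_fraction_sd = fraction_cv * f_alf,
         gs_fraction_mean = f_gs, gs_fraction_sd = fraction_cv * f_gs)
  })
  names(metals) <- summary_rows$metal
  list(site = summary_rows$site[1],
       pm25_mean = summary_rows$pm25_mean[1],
       pm25_sd = summary_rows$pm25_sd[1],
       metals = metals)
}

#' Generate synthetic filter samples for one site
#'
#' Draws per-sample PM2.5 mass and total metal concentrations from
#' log-normal distributions moment-matched to the profile's mean and sd
#' (the right-skewed, strictly positive shape typical of environmental
#' concentration data), and per-sample extractable fractions from
#' moment-matched beta distributions on (0, 1]. Extract concentrations
#' are built as `fraction * total`, never drawn independently, so
#' `extract <= total` holds by construction. Deterministic under `seed`.
#'
#' @param profile A site profile from [site_profile()].
#' @param n Number of samples (>= 1).
#' @param seed Integer seed (required).
#' @return A sample tibble in the [read_samples()] layout.
#' @export
generate_samples <- function(profile, n, seed) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (missing(seed) || is.null(seed)) {
    stop("a seed is required", call. = FALSE)
  }
  set.seed(seed)
  pm <- rlnorm_matched(n, profile$pm25_mean, profile$pm25_sd)
  rows <- lapply(profile$metals, function(m) {
    total <- rlnorm_matched(n, m$total_mean, m$total_sd)
    f_alf <- rbeta_matched(n, m$alf_fraction_mean, m$alf_fraction_sd)
    f_gs <- rbeta_matched(n, m$gs_fraction_mean, m$gs_fraction_sd)
    tibble::tibble(
      sample_id = sprintf("%s-%03d", profile$site, seq_len(n)),
      site = profile$site,
      date = NA_character_,
      pm25_ugm3 = pm,
      metal = m$metal,
      total_ngm3 = total,
      alf_ngm3 = f_alf * total,
      gs_ngm3 = f_gs * total
    )
  })
  validate_samples(dplyr::bind_rows(rows))
}

#' Generate jittered cohort registries
#'
#' Emits a complete cohort registry (8 age groups x 2 sexes) by applying
#' multiplicative log-normal jitter with coefficient of variation
#' `perturbation` to the numeric columns of the shipped defaults. Zero
#' perturbation returns the defaults unchanged. Useful for robustness
#' sweeps of the downstream pipeline.
#'
#' @param seed Integer seed (required).
#' @param perturbation Coefficient of variation of the jitter (>= 0).
#' @return A cohort registry tibble.
#' @export
generate_registries <- function(seed, perturbation = 0) {
  if (missing(seed) || is.null(seed)) {
    stop("a seed is required", call. = FALSE)
  }
  if (perturbation < 0) stop("perturbation must be >= 0", call. = FALSE)
  reg <- default_cohort_registry()
  if (perturbation == 0) return(reg)
  set.seed(seed)
  jitter_cols <- c("height_cm", "body_weight_kg", "inhr_m3_day",
                   "tidal_volume_ml", "breath_freq_per_min",
                   "uaw_volume_ml")
  for (col in jitter_cols) {
    reg[[col]] <- reg[[col]] * rlnorm_matched(nrow(reg), 1, perturbation)
  }
  reg
}
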