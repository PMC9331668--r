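draw_truncated_normal <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sd <- cv * mean
  out <- stats::rnorm(n, mean, sd)
  # respiration rate cannot be negative: resample non-positive draws
  bad <- which(out <= 0)
  while (length(bad) > 0) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] <= 0]
  }
  out
}

#' Monte Carlo uncertainty propagation for HI and ILCR
#'
#' Propagates inhalation-rate uncertainty through the dose and risk
#' equations for each cohort x concentration variant: the respiration
#' rate is drawn from a normal distribution (mean from the registry,
#' standard deviation `cv * mean`, truncated at zero by resampling) while
#' concentrations and body weight are held at their means. Each draw is
#' pushed through ADD/LADD, HQ/HI and ILCR. Fully reproducible: the same
#' seed yields bit-identical draws.
#'
#' @param conc Mean-concentration tibble (`metal`, `total_ngm3`,
#'   `alf_ngm3`, `gs_ngm3`).
#' @param registry Cohort registry (see [default_cohort_registry()]).
#' @param df_table Per-cohort deposition table.
#' @param toxicity Toxicity registry.
#' @param config Configuration list.
#' @param n_iter Number of iterations (default from config: 5000).
#' @param seed Integer seed; required, never taken from the clock.
#' @param inhr_cv Coefficient of variation of the respiration rate
#'   (default from config: 0.3). `0` degenerates to the deterministic
#'   pipeline.
#' @param variants Concentration variants to simulate.
#' @param carcinogens Metals contributing to ILCR (default `"Cd"`).
#' @return A tibble of class `mc_result`, one row per cohort x sex x
#'   variant, with list-columns `hi_draws` and `ilcr_draws` (the latter
#'   NULL-free only for carcinogen-bearing runs) plus `n_iter` and `seed`.
#' @export
run_mc <- function(conc, registry = default_cohort_registry(),
                   df_table = default_df_table(),
                   toxicity = default_toxicity(),
                   config = default_config(),
                   n_iter = config$monte_carlo$iterations,
                   seed,
                   inhr_cv = config$monte_carlo$inhr_cv,
                   variants = dose_variants,
                   carcinogens = "Cd") {
  if (missing(seed) || is.null(seed)) {
    stop("a seed is required for reproducible Monte Carlo runs",
         call. = FALSE)
  }
  if (n_iter < 1) stop("n_iter must be >= 1", call. = FALSE)
  if (inhr_cv < 0) stop("inhr_cv must be >= 0", call. = FALSE)
  variants <- match.arg(variants, dose_variants, several.ok = TRUE)
  set.seed(seed)

  rfd <- stats::setNames(toxicity$rfd, toxicity$metal)
  csf <- stats::setNames(toxicity$csf, toxicity$metal)
  ef <- config$exposure$ef_day_per_year
  at_c <- config$exposure$at_c_days

  rows <- list()
  for (i in seq_len(nrow(registry))) {
    r <- registry[i, ]
    df_row <- df_lookup(df_table, r$age_group, r$sex)
    # one inhalation-rate vector per cohort, shared across variants so
    # the variants stay comparable within a draw
    inhr <- draw_truncated_normal(n_iter, r$inhr_m3_day, inhr_cv)
    for (v in variants) {
      hi_draws <- rep(0, n_iter)
      ilcr_draws <- rep(0, n_iter)
      any_carc <- FALSE
      for (j in seq_len(nrow(conc))) {
        m <- conc[j, ]
        cs <- adjusted_concentrations(
          total = ngm3_to_mgm3(m$total_ngm3),
          alf = ngm3_to_mgm3(m$alf_ngm3),
          gs = ngm3_to_mgm3(m$gs_ngm3),
          df_pulmonary = df_row$df_pulmonary
        )
        add <- cs[[v]] * inhr * ef / 365 / r$body_weight_kg
        hi_draws <- hi_draws + hazard_quotient(add, rfd[[m$metal]])
        if (m$metal %in% carcinogens) {
          ladd <- cs[[v]] * inhr * ef * r$ed_years /
            (r$body_weight_kg * at_c)
          ilcr_draws <- ilcr_draws + ilcr(ladd, csf[[m$metal]])
          any_carc <- TRUE
        }
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        age_group = r$age_group, sex = r$sex, life_stage = r$life_stage,
        variant = v, n_iter = n_iter, seed = seed,
        hi_draws = list(hi_draws),
        ilcr_draws = list(if (any_carc) ilcr_draws else NULL)
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  out$variant <- factor(out$variant, levels = dose_variants)
  class(out) <- c("mc_result", class(out))
  out
}

#' Empirical cumulative distribution of Monte Carlo draws
#'
#' @param draws Numeric vector of draws (non-empty).
#' @return A tibble with `value` (sorted draws) and `cum_prob`
#'   (non-decreasing from 1/n to 1).
#' @export
cumulative_curve <- function(draws) {
  if (length(draws) == 0) stop("draws must be non-empty", call. = FALSE)
  n <- length(draws)
  tibble::tibble(value = sort(draws), cum_prob = seq_len(n) / n)
}

#' Exceedance probability of a threshold
#'
#' Fraction of draws strictly above `threshold`; the complement of the
#' empirical CDF away from ties.
#'
#' @param draws Numeric vector of draws.
#' @param threshold Threshold (>= 0).
#' @return A probability in `[0, 1]`.
#' @export
exceedance_probability <- function(draws, threshold) {
  if (threshold < 0) stop("threshold must be >= 0", call. = FALSE)
  mean(draws > threshold)
}

#' Summarize a Monte Carlo result
#'
#' Per cohort x variant: mean, sd, percentiles 5/50/95 of the HI and ILCR
#' draws, plus exceedance probabilities at the category thresholds
#' (HI > 1; ILCR > 1e-6 and > 1e-4).
#'
#' @param mc An `mc_result` tibble from [run_mc()].
#' @return A plain tibble of summaries.
#' @export
mc_summary <- function(mc) {
  summarize_one <- function(x, prefix) {
    if (is.null(x)) {
      stats::setNames(rep(NA_real_, 5),
                      paste0(prefix, c("_mean", "_sd", "_p05", "_p50",
                                       "_p95")))
    } else {
      q <- stats::quantile(x, c(0.05, 0.5, 0.95), names = FALSE)
      stats::setNames(c(mean(x), stats::sd(x), q),
                      paste0(prefix, c("_mean", "_sd", "_p05", "_p50",
                                       "_p95")))
    }
  }
  rows <- lapply(seq_len(nrow(mc)), function(i) {
    hi <- mc$hi_draws[[i]]
    il <- mc$ilcr_draws[[i]]
    tibble::as_tibble(c(
      list(age_group = mc$age_group[i], sex = mc$sex[i],
           life_stage = mc$life_stage[i],
           variant = as.character(mc$variant[i]),
           n_iter = mc$n_iter[i]),
      as.list(summarize_one(hi, "hi")),
      as.list(summarize_one(il, "ilcr")),
      list(
        p_hi_gt_1 = exceedance_probability(hi, 1),
        p_ilcr_gt_1e6 = if (is.null(il)) NA_real_ else
          exceedance_probability(il, 1e-6),
        p_ilcr_gt_1e4 = if (is.null(il)) NA_real_ else
          exceedance_probability(il, 1e-4)
      )
    ))
  })
  dplyr::bind_rows(rows)
}

#' Plot cumulative-probability curves from a Monte Carlo result
#'
#' Draws the empirical CDF of HI or ILCR per variant, faceted by age
#' group, with solid/dashed linetype for sex — the usual layout for
#' cumulative risk curves. Requires ggplot2.
#'
#' @param mc An `mc_result` tibble.
#' @param measure `"hi"` or `"ilcr"`.
#' @return A ggplot object.
#' @export
plot_mc_cdf <- function(mc, measure = c("hi", "ilcr")) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  measure <- match.arg(measure)
  col <- if (measure == "hi") "hi_draws" else "ilcr_draws"
  keep <- !vapply(mc[[col]], is.null, logical(1))
  pieces <- lapply(which(keep), function(i) {
    curve <- cumulative_curve(mc[[col]][[i]])
    curve$age_group <- mc$age_group[i]
    curve$sex <- mc$sex[i]
    curve$variant <- mc$variant[i]
    curve
  })
  df <- dplyr::bind_rows(pieces)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, y = .data$cum_prob,
                                   colour = .data$variant,
                                   linetype = .data$sex)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$age_group), scales = "free_x") +
    ggplot2::labs(x = toupper(measure), y = "cumulative probability")
}
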