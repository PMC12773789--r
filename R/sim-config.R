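#' Configuration for the synthetic hardship cohort generator
#'
#' Bundles every tunable of the cohort simulator into one validated list.
#' The defaults emulate the study conditions of the survey the package was
#' designed around: 321 families reporting monthly subjective economic
#' hardship (six binary "hard to pay for" items, summed 0-6 then +1
#' transformed to a 1-7 scale) over up to 36 calendar months, with between
#' 15 and 36 observed months per family, piecewise mean/variance structure,
#' an annual seasonal component, 1/f colored noise, SES- and race-correlated
#' exposure, and a one-time child self-regulation outcome observed on a
#' subsample of 125 families.
#'
#' @param n_families Number of families in the cohort.
#' @param months_total Length of the monthly sampling window (36 = the
#'   study's Apr 2020 - Aug 2023 span collapsed to months).
#' @param min_months Eligibility floor: minimum observed months for a family
#'   to enter the analysis (15, the recommended lower bound for reliable
#'   unpredictability statistics).
#' @param missing_rate Mean per-family-month probability that a month goes
#'   unobserved. Per-family rates are drawn Uniform(0, 2 * missing_rate) so
#'   observed-month counts spread over the 15-36 range rather than
#'   clustering at one value.
#' @param extra_response_rate Probability that an observed family-month
#'   carries a second survey response (the instrument allows more than one
#'   response per month; monthly scores average them).
#' @param group_probs Named list of probability vectors for the categorical
#'   confounders: `education` (6 levels), `income_fpl` (3 levels),
#'   `race_ethnicity` (5 levels), `disability` (3 levels). Each must sum
#'   to 1.
#' @param segment_rate Expected number of mean-level changepoints per series.
#' @param var_segment_rate Expected number of variance changepoints per
#'   series.
#' @param seasonal_amplitude Amplitude (hardship units, 0-6 scale) of the
#'   planted annual harmonic.
#' @param noise_beta_range Interval from which each family's spectral
#'   exponent beta is drawn (0 = white, 2 = red/slow).
#' @param noise_sd Baseline standard deviation of the colored-noise
#'   component before the per-family and per-segment variance multipliers.
#' @param jump_sd Standard deviation of mean-level jumps at planted
#'   changepoints (hardship units).
#' @param var_jump_sd Log-scale standard deviation of segment variance
#'   multipliers at planted variance changepoints.
#' @param ses_exposure_strength Coupling between the latent SES scalar and
#'   the family's hardship level; the severity-confounder correlation is
#'   monotone in this value.
#' @param instability_link Loading of the (standardized) severity driver on
#'   the latent instability scalar; with the default 0.5 the planted
#'   severity-unpredictability correlation echoes the moderate association
#'   such cohorts show.
#' @param effect_severity Planted outcome slope per unit hardship severity.
#' @param effect_unpredictability Planted outcome slope per unit latent
#'   instability.
#' @param confounder_effects Numeric vector of length 15: outcome effects of
#'   the dummy-coded confounder columns (see [confounder_design()] for the
#'   column order).
#' @param outcome_noise_sd Residual standard deviation of the child outcome.
#' @param n_outcome Size of the outcome (self-regulation) subsample.
#' @param eligible_fraction Fraction of families the generator guarantees to
#'   meet `min_months` (the remainder are free to fall below, emulating
#'   attrition).
#' @param seed Integer seed; identical configs + seed give identical cohorts.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_families = 321,
                       months_total = 36,
                       min_months = 15,
                       missing_rate = 0.25,
                       extra_response_rate = 0.1,
                       group_probs = default_group_probs(),
                       segment_rate = 1.2,
                       var_segment_rate = 0.8,
                       seasonal_amplitude = 0.25,
                       noise_beta_range = c(0, 2),
                       noise_sd = 0.6,
                       jump_sd = 1.4,
                       var_jump_sd = 0.6,
                       ses_exposure_strength = 0.6,
                       instability_link = 0.5,
                       effect_severity = 0.36,
                       effect_unpredictability = 0.21,
                       confounder_effects = default_confounder_effects(),
                       outcome_noise_sd = 0.7,
                       n_outcome = min(125L, n_families),
                       eligible_fraction = 1,
                       seed = 1L) {
  cfg <- list(
    n_families = as.integer(n_families),
    months_total = as.integer(months_total),
    min_months = as.integer(min_months),
    missing_rate = missing_rate,
    extra_response_rate = extra_response_rate,
    group_probs = group_probs,
    segment_rate = segment_rate,
    var_segment_rate = var_segment_rate,
    seasonal_amplitude = seasonal_amplitude,
    noise_beta_range = noise_beta_range,
    noise_sd = noise_sd,
    jump_sd = jump_sd,
    var_jump_sd = var_jump_sd,
    ses_exposure_strength = ses_exposure_strength,
    instability_link = instability_link,
    effect_severity = effect_severity,
    effect_unpredictability = effect_unpredictability,
    confounder_effects = confounder_effects,
    outcome_noise_sd = outcome_noise_sd,
    n_outcome = as.integer(n_outcome),
    eligible_fraction = eligible_fraction,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Default category probabilities for the simulated confounders
#'
#' Rough marginal frequencies for a socioeconomically diverse U.S. cohort of
#' caregivers with children under six.
#'
#' @return Named list of named probability vectors.
#' @export
default_group_probs <- function() {
  list(
    education = c(less_hs = 0.05, hs_ged = 0.20, some_college = 0.20,
                  associate = 0.10, bachelor = 0.25, postgraduate = 0.20),
    income_fpl = c(fpl_le_200 = 0.35, fpl_200_400 = 0.30, fpl_ge_400 = 0.35),
    race_ethnicity = c(black = 0.15, latinx = 0.20, white = 0.50,
                       asian = 0.08, other = 0.07),
    disability = c(none = 0.80, one = 0.15, multiple = 0.05)
  )
}

#' Default planted outcome effects of the 15 dummy-coded confounders
#'
#' Order matches [confounder_design()]: education (5 dummies, reference
#' "less_hs"), income band (2, reference at/below 200% FPL), race/ethnicity
#' (4, reference "black"), child age (continuous, years), disability (2,
#' reference "none"), child health (continuous, 1-5 higher = better).
#' Signs emulate the usual gradients (more education/income and better
#' health predict fewer regulation challenges) so that SES confounds the
#' hardship-outcome association.
#'
#' @return Numeric vector of length 15.
#' @export
default_confounder_effects <- function() {
  c(educ_hs_ged = -0.10, educ_some_college = -0.15, educ_associate = -0.20,
    educ_bachelor = -0.30, educ_postgraduate = -0.40,
    income_200_400 = -0.20, income_ge_400 = -0.40,
    race_latinx = 0.00, race_white = -0.15, race_asian = -0.15,
    race_other = -0.05,
    child_age = -0.05,
    disability_one = 0.20, disability_multiple = 0.35,
    child_health = -0.10)
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_families > 0, cfg$months_total > 0)
  if (cfg$min_months > cfg$months_total) {
    stop("`min_months` (", cfg$min_months, ") exceeds `months_total` (",
         cfg$months_total, ")", call. = FALSE)
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate > 0.5) {
    stop("`missing_rate` must lie in [0, 0.5] (per-family rates are drawn ",
         "Uniform(0, 2 * missing_rate))", call. = FALSE)
  }
  stopifnot(
    cfg$extra_response_rate >= 0, cfg$extra_response_rate <= 1,
    cfg$outcome_noise_sd > 0,
    length(cfg$noise_beta_range) == 2,
    cfg$noise_beta_range[1] <= cfg$noise_beta_range[2],
    cfg$segment_rate >= 0, cfg$var_segment_rate >= 0,
    cfg$seasonal_amplitude >= 0, cfg$noise_sd >= 0,
    length(cfg$confounder_effects) == 15,
    all(is.finite(cfg$confounder_effects)),
    cfg$n_outcome <= cfg$n_families,
    cfg$eligible_fraction >= 0, cfg$eligible_fraction <= 1
  )
  for (nm in c("education", "income_fpl", "race_ethnicity", "disability")) {
    p <- cfg$group_probs[[nm]]
    if (is.null(p) || any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      stop("group_probs$", nm, " must be non-negative and sum to 1",
           call. = FALSE)
    }
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  families:", x$n_families,
      " window:", x$months_total, "months",
      " eligibility >=", x$min_months, "months\n")
  cat("  planted effects: severity =", x$effect_severity,
      " unpredictability =", x$effect_unpredictability, "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}
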