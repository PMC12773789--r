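#' Synthesize colored (1/f^beta) noise by spectral shaping
#'
#' Builds a zero-mean real series whose spectral amplitudes are proportional
#' to f^(-beta/2) with uniform random phases, then rescales to the requested
#' standard deviation. beta = 0 gives white noise, beta = 2 red (slow,
#' predictable) noise, negative beta blue (fast but regular) noise.
#'
#' @param n Series length (>= 4).
#' @param beta Spectral exponent.
#' @param sd Target sample standard deviation (0 returns a zero vector).
#' @return Numeric vector of length `n`.
#' @export
colored_noise <- function(n, beta, sd = 1) {
  stopifnot(n >= 4, is.finite(beta), sd >= 0)
  if (sd == 0) return(numeric(n))
  m_half <- floor((n - 1) / 2)            # frequencies with free phase
  j <- seq_len(m_half)
  amp <- (j / n)^(-beta / 2)
  phase <- runif(m_half, 0, 2 * pi)
  spec <- complex(real = numeric(n), imaginary = numeric(n))
  spec[1 + j] <- amp * exp(1i * phase)
  spec[n + 1 - j] <- Conj(spec[1 + j])
  if (n %% 2 == 0) {                      # Nyquist ordinate must be real
    spec[n / 2 + 1] <- 0.5^(-beta / 2) * sample(c(-1, 1), 1)
  }
  x <- Re(fft(spec, inverse = TRUE)) / n
  x <- x - mean(x)
  x * sd / stats::sd(x)
}

.month_cache <- new.env(parent = emptyenv())

month_seq <- function(start = "2020-09", n) {
  key <- paste0(start, "#", n)
  hit <- .month_cache[[key]]
  if (!is.null(hit)) return(hit)
  first <- as.Date(paste0(start, "-01"))
  out <- format(seq(first, by = "month", length.out = n), "%Y-%m")
  .month_cache[[key]] <- out
  out
}

# Sample k changepoint positions (last index of a segment) in 1..(n-1),
# keeping every segment at least `min_gap` long. Returns a sorted vector,
# possibly shorter than k when the spacing constraint bites.
sample_boundaries <- function(n, k, min_gap = 3) {
  if (k <= 0 || n < 2 * min_gap) return(integer(0))
  cand <- seq(min_gap, n - min_gap)
  if (length(cand) == 0) return(integer(0))
  pos <- sort(sample(cand, min(k, length(cand))))
  keep <- c(TRUE, diff(pos) >= min_gap)
  pos[keep]
}

step_path <- function(n, boundaries, values) {
  seg <- findInterval(seq_len(n) - 1, boundaries) + 1
  values[seg]
}

#' Simulate one family's monthly hardship series with planted structure
#'
#' Generates a latent continuous path = piecewise-constant mean +
#' piecewise-scaled colored noise + an annual harmonic, then discretizes it
#' the way the instrument would observe it: round, clip to the 0-6 sum-score
#' range, add 1 (final scale 1-7). Months are then dropped at the family's
#' missingness rate; when `eligible` is TRUE the missingness mask is redrawn
#' (up to `max_retry` times) until at least `config$min_months` months
#' survive.
#'
#' Draws from the current RNG stream; seed at the cohort level for
#' reproducibility.
#'
#' @param config A [sim_config()].
#' @param level Family latent hardship level on the 0-6 pre-transform scale.
#' @param instability Latent instability scalar (scales changepoint rates
#'   and noise amplitude).
#' @param beta Spectral exponent of the family's noise (default drawn from
#'   `config$noise_beta_range`).
#' @param p_miss Per-month missingness probability (default
#'   `config$missing_rate`).
#' @param eligible Guarantee at least `min_months` observed months.
#' @param max_retry Missingness redraw budget before failing.
#' @return List with `series` (tibble: `month_index`, `month`, `value`,
#'   `observed`) and `truth` (planted boundaries, levels, scales, beta,
#'   `sev_true` = full-window mean of the discretized 1-7 values).
#' @export
simulate_hardship_series <- function(config, level, instability = 0,
                                     beta = NULL, p_miss = NULL,
                                     eligible = TRUE, max_retry = 100L) {
  core <- sim_series_core(config, level, instability, beta, p_miss,
                          eligible, max_retry)
  n <- config$months_total
  list(
    series = tibble(
      month_index = seq_len(n),
      month = month_seq(n = n),
      value = core$value,
      observed = core$observed
    ),
    truth = core$truth
  )
}

# numeric core shared by the public wrapper and the cohort loop
sim_series_core <- function(config, level, instability = 0, beta = NULL,
                            p_miss = NULL, eligible = TRUE, max_retry = 100L) {
  stopifnot(is.finite(level), is.finite(instability))
  n <- config$months_total
  if (is.null(beta)) beta <- runif(1, config$noise_beta_range[1],
                                   config$noise_beta_range[2])
  if (is.null(p_miss)) p_miss <- config$missing_rate

  rate_scale <- exp(0.7 * instability)
  k_mean <- rpois(1, config$segment_rate * rate_scale)
  mean_bnd <- sample_boundaries(n, k_mean)
  mean_levels <- level + c(0, cumsum(rnorm(length(mean_bnd), 0, config$jump_sd)))
  mean_path <- step_path(n, mean_bnd, mean_levels)

  k_var <- rpois(1, config$var_segment_rate * rate_scale)
  var_bnd <- sample_boundaries(n, k_var)
  var_mult <- exp(rnorm(length(var_bnd) + 1, 0, config$var_jump_sd))
  family_sd <- config$noise_sd * exp(0.5 * instability)
  sd_path <- family_sd * step_path(n, var_bnd, var_mult)

  phase <- runif(1, 0, 2 * pi)
  month_of_year <- as.integer(substr(month_seq(n = n), 6, 7))
  seasonal <- config$seasonal_amplitude * sin(2 * pi * month_of_year / 12 + phase)

  noise <- if (family_sd > 0 && n >= 4) colored_noise(n, beta, 1) * sd_path else numeric(n)
  latent <- mean_path + seasonal + noise
  value <- pmin(pmax(round(latent), 0), 6) + 1

  observed <- runif(n) < 1 - p_miss
  if (eligible) {
    tries <- 0L
    while (sum(observed) < config$min_months) {
      tries <- tries + 1L
      if (tries > max_retry) {
        stop("could not retain ", config$min_months,
             " observed months after ", max_retry, " missingness redraws",
             call. = FALSE)
      }
      observed <- runif(n) < 1 - p_miss
    }
  }

  list(
    value = value,
    observed = observed,
    truth = list(
      level = level, instability = instability, beta = beta, p_miss = p_miss,
      mean_boundaries = mean_bnd, mean_levels = mean_levels,
      var_boundaries = var_bnd, var_multipliers = var_mult,
      seasonal_phase = phase,
      sev_true = mean(value),
      n_obs = sum(observed)
    )
  )
}

# Categorical confounder draws, all tilted by the latent SES scalar so the
# hardship exposure is confounded through group membership.
draw_confounders <- function(n, ses, group_probs) {
  cut_by_quantile <- function(latent, probs) {
    br <- c(-Inf, quantile(latent, cumsum(probs)[-length(probs)]), Inf)
    factor(names(probs)[findInterval(latent, br, rightmost.closed = TRUE)],
           levels = names(probs))
  }
  education <- cut_by_quantile(ses + rnorm(n), group_probs$education)
  income_fpl <- cut_by_quantile(ses + rnorm(n, 0, 0.8), group_probs$income_fpl)
  disability <- cut_by_quantile(-0.3 * ses + rnorm(n), group_probs$disability)
  # race/ethnicity: multinomial with SES-tilted logits (emulates structural
  # correlation between group membership and economic position)
  p0 <- group_probs$race_ethnicity
  tilt <- c(black = -0.35, latinx = -0.25, white = 0.30, asian = 0.25,
            other = 0)[names(p0)]
  race <- vapply(seq_len(n), function(i) {
    lp <- log(p0) + tilt * ses[i]
    pr <- exp(lp) / sum(exp(lp))
    sample(names(p0), 1, prob = pr)
  }, character(1))
  race_ethnicity <- factor(race, levels = names(p0))

  child_age <- pmin(pmax(rnorm(n, 3.32, 1.40), 0.25), 5.99)
  child_health <- pmin(pmax(3.5 + 0.3 * ses + rnorm(n, 0, 0.8), 1), 5)

  tibble(
    family_id = sprintf("F%04d", seq_len(n)),
    education = education, income_fpl = income_fpl,
    race_ethnicity = race_ethnicity, child_age = child_age,
    disability = disability, child_health = child_health
  )
}

#' Dummy-code the confounder table into the 15-column design matrix
#'
#' Categorical confounders are expanded to treatment dummies with the first
#' declared factor level (the lowest SES category) as reference: education
#' contributes 5 columns, income band 2, race/ethnicity 4, disability 2;
#' child age and child health enter as-is. Exactly 15 columns.
#'
#' @param confounders Tibble as produced by [simulate_cohort()] (columns
#'   `education`, `income_fpl`, `race_ethnicity`, `child_age`, `disability`,
#'   `child_health`).
#' @return Numeric matrix (n x 15) with rownames = `family_id`.
#' @export
confounder_design <- function(confounders) {
  dummies <- function(f, prefix) {
    lv <- levels(f)[-1]
    m <- vapply(lv, function(l) as.numeric(f == l), numeric(length(f)))
    colnames(m) <- paste0(prefix, lv)
    m
  }
  cf <- confounders
  for (col in c("education", "income_fpl", "race_ethnicity", "disability")) {
    if (!is.factor(cf[[col]])) cf[[col]] <- factor(cf[[col]])
  }
  X <- cbind(
    dummies(cf$education, "educ_"),
    dummies(cf$income_fpl, "income_"),
    dummies(cf$race_ethnicity, "race_"),
    child_age = cf$child_age,
    dummies(cf$disability, "disability_"),
    child_health = cf$child_health
  )
  stopifnot(ncol(X) == 15)
  rownames(X) <- cf$family_id
  X
}

items_from_score <- function(score) {
  item_names <- c("item_food", "item_housing", "item_utilities",
                  "item_healthcare", "item_childcare", "item_wellbeing")
  v <- setNames(numeric(6), item_names)
  if (score > 0) v[sample(6, score)] <- 1
  v
}

#' Simulate a full synthetic cohort with planted ground truth
#'
#' Produces every table the analysis pipeline consumes: item-level survey
#' responses, the per-family monthly series, raw confounders, the child
#' outcome on a subsample, questionnaire scales (family routines and an
#' 18-item home-unpredictability inventory), and a ground-truth record of
#' every planted parameter. Identical `config` (including seed) gives an
#' identical cohort.
#'
#' The outcome is linear in the planted severity (full-window mean hardship
#' on the 1-7 scale) and the latent instability scalar, plus the 15
#' dummy-coded confounder effects and Gaussian noise; its intercept is set
#' so the cohort mean outcome is about 0.14 (the scale the factor-score
#' outcome is reported on).
#'
#' @param config A [sim_config()].
#' @return List of class `hardship_cohort`: `responses`, `series`,
#'   `confounders`, `outcome`, `routines`, `quic`, `ground_truth`, `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_families
  ids <- sprintf("F%04d", seq_len(n))

  ses <- rnorm(n)
  # latent level: unit variance split between the SES coupling and an
  # idiosyncratic part, so exposure-confounder correlations land in the
  # minimal-to-moderate range such cohorts show
  s <- config$ses_exposure_strength
  sev_driver <- 0.25 - s * ses + rnorm(n, 0, sqrt(max(0.1, 1 - s^2)))
  level <- pmax(0, sev_driver)
  z_sev <- as.numeric(scale(sev_driver))
  rho <- config$instability_link
  instability <- rho * z_sev + sqrt(1 - rho^2) * rnorm(n)
  # noise color: unstable families drift toward white (beta near 0), the
  # maximally random end, while stable families show slower red noise
  u_beta <- stats::plogis(stats::qlogis(runif(n)) - 0.8 * instability)
  beta_f <- config$noise_beta_range[1] +
    (config$noise_beta_range[2] - config$noise_beta_range[1]) * u_beta
  p_miss <- pmin(runif(n, 0, 2 * config$missing_rate), 0.95)
  n_elig_target <- round(config$eligible_fraction * n)
  eligible_flag <- seq_len(n) <= n_elig_target
  # families guaranteed eligible need a missingness rate the retry loop can
  # actually satisfy: expected observed months strictly above the floor
  cap <- max(0, 1 - (config$min_months + 2) / config$months_total)
  p_miss[eligible_flag] <- pmin(p_miss[eligible_flag], cap)

  sims <- vector("list", n)
  for (i in seq_len(n)) {
    sims[[i]] <- sim_series_core(
      config, level = level[i], instability = instability[i],
      beta = beta_f[i], p_miss = p_miss[i], eligible = eligible_flag[i]
    )
  }

  mt <- config$months_total
  series <- tibble(
    family_id = rep(ids, each = mt),
    month_index = rep(seq_len(mt), times = n),
    month = rep(month_seq(n = mt), times = n),
    value = unlist(lapply(sims, `[[`, "value"), use.names = FALSE),
    observed = unlist(lapply(sims, `[[`, "observed"), use.names = FALSE)
  )

  # item-level responses: one (sometimes two) responses per observed month;
  # each response carries items summing exactly to the planted monthly score
  obs <- dplyr::filter(series, .data$observed)
  n_resp <- 1L + rbinom(nrow(obs), 1L, config$extra_response_rate)
  obs_rep <- obs[rep(seq_len(nrow(obs)), n_resp), ]
  day <- sample(1:28, nrow(obs_rep), replace = TRUE)
  items <- t(vapply(obs_rep$value - 1, items_from_score, numeric(6)))
  responses <- dplyr::bind_cols(
    tibble(
      family_id = obs_rep$family_id,
      date = sprintf("%s-%02d", obs_rep$month, day)
    ),
    as_tibble(items)
  )
  responses <- dplyr::arrange(responses, .data$family_id, .data$date)

  confounders <- draw_confounders(n, ses, config$group_probs)
  X <- confounder_design(confounders)

  truth_per_family <- tibble(
    family_id = ids,
    ses = ses,
    level = level,
    instability = instability,
    beta = beta_f,
    p_miss = p_miss,
    eligible_flag = eligible_flag,
    n_obs = vapply(sims, function(s) s$truth$n_obs, numeric(1)),
    sev_true = vapply(sims, function(s) s$truth$sev_true, numeric(1)),
    n_cpt_mean_true = vapply(sims, function(s) length(s$truth$mean_boundaries), numeric(1)),
    n_cpt_var_true = vapply(sims, function(s) length(s$truth$var_boundaries), numeric(1)),
    mean_boundaries = purrr::map(sims, ~ .x$truth$mean_boundaries),
    mean_levels = purrr::map(sims, ~ .x$truth$mean_levels),
    var_boundaries = purrr::map(sims, ~ .x$truth$var_boundaries),
    var_multipliers = purrr::map(sims, ~ .x$truth$var_multipliers)
  )

  # one-time outcome on a subsample of families meeting the eligibility bar
  elig_ids <- ids[truth_per_family$n_obs >= config$min_months]
  n_out <- min(config$n_outcome, length(elig_ids))
  out_ids <- sort(sample(elig_ids, n_out))
  idx <- match(out_ids, ids)
  lin <- config$effect_severity * truth_per_family$sev_true[idx] +
    config$effect_unpredictability * instability[idx] +
    as.numeric(X[idx, , drop = FALSE] %*% config$confounder_effects)
  intercept <- 0.14 - mean(lin)
  outcome <- tibble(
    family_id = out_ids,
    self_regulation = intercept + lin + rnorm(n_out, 0, config$outcome_noise_sd)
  )

  # questionnaire scales, weakly loaded on the latent instability
  routines <- purrr::map_dfr(1:3, function(adm) {
    base <- pmin(pmax(3.26 - 0.25 * instability + rnorm(n, 0, 0.35), 1), 4)
    it <- vapply(1:5, function(j) pmin(pmax(round(base + rnorm(n, 0, 0.55)), 1), 4),
                 numeric(n))
    colnames(it) <- paste0("routine_", 1:5)
    dplyr::bind_cols(tibble(family_id = ids, administration = adm), as_tibble(it))
  })
  quic_p <- stats::plogis(-2.3 + 0.55 * instability)
  quic_items <- vapply(1:18, function(j) rbinom(n, 1, quic_p), numeric(n))
  colnames(quic_items) <- sprintf("quic_%02d", 1:18)
  quic <- dplyr::bind_cols(tibble(family_id = ids), as_tibble(quic_items))

  structure(list(
    responses = responses,
    series = series,
    confounders = confounders,
    outcome = outcome,
    routines = routines,
    quic = quic,
    ground_truth = list(
      per_family = truth_per_family,
      n_eligible_true = sum(truth_per_family$n_obs >= config$min_months),
      effect_severity = config$effect_severity,
      effect_unpredictability = config$effect_unpredictability,
      confounder_effects = config$confounder_effects,
      outcome_intercept = intercept,
      seed = config$seed
    ),
    config = config
  ), class = "hardship_cohort")
}

#' @export
print.hardship_cohort <- function(x, ...) {
  cat("<hardship_cohort>", x$config$n_families, "families,",
      x$config$months_total, "month window,",
      nrow(x$responses), "survey responses\n")
  cat("  eligible (>=", x$config$min_months, "months):",
      x$ground_truth$n_eligible_true, "; outcome subsample:",
      nrow(x$outcome), "\n")
  invisible(x)
}

#' Simulate a confounded continuous exposure for balance testing
#'
#' Draws the 15-column confounder design as in [simulate_cohort()] and a
#' standardized exposure whose population R-squared on the confounders is
#' `r2` (linear confounding).
#'
#' @param n Sample size.
#' @param r2 Fraction of exposure variance explained by the confounders.
#' @param seed Optional integer seed.
#' @return List: `exposure` (length-n vector), `confounders` (tibble),
#'   `X` (n x 15 matrix).
#' @export
simulate_balance_scenario <- function(n, r2 = 0.3, seed = NULL) {
  stopifnot(n > 20, r2 >= 0, r2 < 1)
  if (!is.null(seed)) set.seed(seed)
  ses <- rnorm(n)
  confounders <- draw_confounders(n, ses, default_group_probs())
  X <- confounder_design(confounders)
  b <- c(1, 2, 3, 4, 5,            # education gradient
         1.5, 3,                   # income
         -0.5, -2, -2, -1,         # race/ethnicity
         0.3,                      # age
         1, 2,                     # disability
         -0.5)                     # health
  eta <- as.numeric(scale(X %*% b))
  exposure <- sqrt(r2) * eta + sqrt(1 - r2) * rnorm(n)
  list(exposure = exposure, confounders = confounders, X = X)
}

#' Write a synthetic cohort to plain-text artifacts
#'
#' Emits `responses.csv`, `monthly_series.csv`, `confounders.csv`,
#' `outcome.csv`, `routines.csv`, `quic.csv` and `ground_truth.json` into
#' `dir`.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "hardship_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    responses = file.path(dir, "responses.csv"),
    series = file.path(dir, "monthly_series.csv"),
    confounders = file.path(dir, "confounders.csv"),
    outcome = file.path(dir, "outcome.csv"),
    routines = file.path(dir, "routines.csv"),
    quic = file.path(dir, "quic.csv")
  )
  write.csv(cohort$responses, paths["responses"], row.names = FALSE)
  write.csv(cohort$series, paths["series"], row.names = FALSE)
  write.csv(cohort$confounders, paths["confounders"], row.names = FALSE)
  write.csv(cohort$outcome, paths["outcome"], row.names = FALSE)
  write.csv(cohort$routines, paths["routines"], row.names = FALSE)
  write.csv(cohort$quic, paths["quic"], row.names = FALSE)
  gt <- cohort$ground_truth
  gt$per_family <- lapply(
    split(gt$per_family, seq_len(nrow(gt$per_family))),
    function(r) lapply(as.list(r), function(x) if (is.list(x)) x[[1]] else x)
  )
  gt_path <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(gt, gt_path, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, ground_truth = gt_path))
}
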