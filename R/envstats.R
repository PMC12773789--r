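#' Coefficient of variation of a hardship series
#'
#' Sample standard deviation (n-1 denominator) divided by the arithmetic
#' mean. The +1 transform applied at ingest guarantees a strictly positive
#' mean, so the ratio is always defined for eligible series.
#'
#' @param x Numeric values over observed months.
#' @return Non-negative scalar.
#' @export
coefficient_of_variation <- function(x) {
  if (length(x) < 2) stop("coefficient of variation needs >= 2 points",
                          call. = FALSE)
  m <- mean(x)
  if (!is.finite(m) || m <= 0) stop("coefficient of variation needs a positive mean",
                                    call. = FALSE)
  sd(x) / m
}

#' Per-family unpredictability statistics
#'
#' Computes the four unpredictability indices for every family in a monthly
#' series table: coefficient of variation, penalized changepoint counts in
#' mean and in variance (PELT, [detect_changepoints()]), and the spectral
#' noise color with its unpredictability transform ([noise_color()]).
#' Severity (time-mean hardship) and the observed-month count ride along.
#'
#' CV and the changepoint counts use the observed months as an ordered
#' sequence (no interpolation); the noise stage works on the regular
#' monthly grid with internal gaps linearly interpolated, and records
#' `interp_flag` when more than 20% of the grid had to be interpolated.
#'
#' @param series Monthly series tibble from [monthly_series()] /
#'   [filter_eligible()] (columns `family_id`, `month`, `value`, `is_gap`).
#' @param penalty_rule `"mbic"` (default) or `"bic"` changepoint penalty.
#' @param noise_transform Passed to [noise_color()].
#' @return Tibble: `family_id`, `cv`, `n_cpt_mean`, `n_cpt_var`,
#'   `noise_beta`, `noise_unpred`, `n_months`, `severity`, `interp_flag`.
#' @export
env_stats <- function(series, penalty_rule = c("mbic", "bic"),
                      noise_transform = c("negabs", "neg", "shift")) {
  penalty_rule <- match.arg(penalty_rule)
  noise_transform <- match.arg(noise_transform)
  if ("observed" %in% names(series) && !"is_gap" %in% names(series)) {
    series <- series %>%
      dplyr::filter(.data$observed) %>%
      dplyr::mutate(is_gap = FALSE)
  }
  series %>%
    dplyr::arrange(.data$family_id, .data$month) %>%
    dplyr::group_by(.data$family_id) %>%
    dplyr::group_modify(function(d, key) {
      obs <- d$value[!d$is_gap]
      n_obs <- length(obs)
      cpt_m <- detect_changepoints(obs, "mean", penalty_rule = penalty_rule)
      cpt_v <- detect_changepoints(obs, "variance", penalty_rule = penalty_rule)
      # regular grid between first and last observation for the noise stage
      first <- which(!d$is_gap)[1]
      last <- max(which(!d$is_gap))
      grid_val <- ifelse(d$is_gap, NA_real_, d$value)[first:last]
      moy <- as.integer(substr(d$month, 6, 7))[first:last]
      det <- detrend_for_noise(grid_val, moy)
      if (sd(det$residuals) < 1e-10) {
        # a flat series is the limit of slow, fully predictable change:
        # score it at the red (beta = 2) end rather than failing
        nc <- list(beta = 2)
        nc$unpred <- switch(noise_transform, negabs = -2, neg = -2, shift = 0)
      } else {
        nc <- noise_color(det$residuals, transform = noise_transform)
      }
      tibble(
        cv = coefficient_of_variation(obs),
        n_cpt_mean = cpt_m$n_changepoints,
        n_cpt_var = cpt_v$n_changepoints,
        noise_beta = nc$beta,
        noise_unpred = nc$unpred,
        n_months = n_obs,
        severity = mean(obs),
        interp_flag = det$flagged
      )
    }) %>%
    dplyr::ungroup()
}
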