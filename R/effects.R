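#' Weighted regression of the child outcome on one exposure
#'
#' Weighted least squares with an intercept, heteroskedasticity-robust
#' (HC3) sandwich standard errors — weighted estimation with estimated
#' weights needs a variance estimator robust to the weight-induced
#' heteroskedasticity — and normal-approximation 95% confidence intervals.
#' The standardized slope rescales the raw slope by the unweighted sample
#' standard deviations of exposure and outcome (the common convention), so
#' exposures on different scales can be compared.
#'
#' @param data Tibble containing outcome and exposure columns.
#' @param outcome,exposure Column names (strings).
#' @param weights Positive weights: a numeric vector, a `balance_result`,
#'   or NULL for uniform weights (plain OLS).
#' @return Object of class `effect_fit`: raw slope `B`, `se`, `ci_lo`,
#'   `ci_hi`, `beta_std`, `p_value`, `n`, `ess`, `weights_source`.
#' @export
weighted_effect <- function(data, outcome, exposure, weights = NULL) {
  stopifnot(outcome %in% names(data), exposure %in% names(data))
  y <- data[[outcome]]
  x <- data[[exposure]]
  src <- "uniform"
  if (inherits(weights, "balance_result")) {
    src <- weights$method
    weights <- weights$weights
  } else if (!is.null(weights)) {
    src <- "user"
  }
  if (is.null(weights)) weights <- rep(1, length(y))
  stopifnot(length(weights) == length(y), all(weights > 0))
  if (var(x) <= 0) stop("exposure has zero variance", call. = FALSE)

  df <- data.frame(.y = y, .x = x)
  fit <- lm(.y ~ .x, data = df, weights = weights)
  if (any(!is.finite(coef(fit)))) stop("degenerate design", call. = FALSE)
  vc <- sandwich::vcovHC(fit, type = "HC3")
  B <- unname(coef(fit)[".x"])
  se <- sqrt(vc[".x", ".x"])
  z <- qnorm(0.975)
  structure(list(
    exposure = exposure,
    outcome = outcome,
    B = B,
    se = se,
    ci_lo = B - z * se,
    ci_hi = B + z * se,
    beta_std = B * sd(x) / sd(y),
    p_value = 2 * pnorm(-abs(B / se)),
    n = length(y),
    ess = ess(weights),
    weights_source = src,
    fit = fit
  ), class = "effect_fit")
}

#' @export
print.effect_fit <- function(x, ...) {
  cat("<effect_fit> ", x$outcome, " ~ ", x$exposure,
      "  (weights: ", x$weights_source, ")\n", sep = "")
  cat(sprintf("  B = %.3f, 95%% CI [%.3f, %.3f], beta = %.3f, p = %.4g, n = %d, ESS = %.1f\n",
              x$B, x$ci_lo, x$ci_hi, x$beta_std, x$p_value, x$n, x$ess))
  invisible(x)
}

#' @rdname weighted_effect
#' @param x An `effect_fit`.
#' @param ... Unused.
#' @export
tidy.effect_fit <- function(x, ...) {
  tibble(
    exposure = x$exposure,
    B = x$B,
    se = x$se,
    ci_lo = x$ci_lo,
    ci_hi = x$ci_hi,
    beta_std = x$beta_std,
    p_value = x$p_value
  )
}

#' @rdname weighted_effect
#' @export
glance.effect_fit <- function(x, ...) {
  tibble(n = x$n, ess = x$ess, weights_source = x$weights_source)
}

#' Fit the full suite of per-exposure weighted effect models
#'
#' One balanced, weighted model per exposure (severity, the composite, and
#' each individual unpredictability index), each with its own weights
#' constructed and selected by [balance_weights()]. Exposures missing from
#' the data are flagged (NA row) while the rest proceed. Rows are ordered
#' by descending |standardized slope|.
#'
#' @param data Analysis tibble: outcome column plus one column per
#'   exposure, rows aligned with `X`.
#' @param X Confounder design matrix (n x 15).
#' @param outcome Outcome column name.
#' @param exposures Character vector of exposure columns.
#' @param methods Balancing methods to search over.
#' @return Tibble: `exposure`, `B`, `se`, `ci_lo`, `ci_hi`, `beta_std`,
#'   `p_value`, `n`, `ess`, `method`.
#' @export
effect_suite <- function(data, X, outcome = "self_regulation",
                         exposures = c("severity", "composite", "cv",
                                       "n_cpt_mean", "n_cpt_var",
                                       "noise_unpred"),
                         methods = c("gps", "ebal")) {
  rows <- purrr::map_dfr(exposures, function(ex) {
    if (!ex %in% names(data) || all(is.na(data[[ex]]))) {
      warning("exposure `", ex, "` missing; row flagged", call. = FALSE)
      return(tibble(exposure = ex, B = NA_real_, se = NA_real_,
                    ci_lo = NA_real_, ci_hi = NA_real_, beta_std = NA_real_,
                    p_value = NA_real_, n = NA_integer_, ess = NA_real_,
                    method = NA_character_))
    }
    bal <- balance_weights(data, ex, X, methods = methods)
    eff <- weighted_effect(data, outcome, ex, weights = bal)
    dplyr::bind_cols(tidy(eff),
                     tibble(n = eff$n, ess = eff$ess, method = bal$method))
  })
  dplyr::arrange(rows, dplyr::desc(abs(.data$beta_std)))
}
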