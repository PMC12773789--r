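#' Cronbach's alpha internal-consistency coefficient
#'
#' alpha = k/(k-1) * (1 - sum of item variances / variance of the total
#' score), on complete rows.
#'
#' @param items Matrix or data frame of item responses (columns = items).
#' @return Scalar alpha.
#' @export
cronbach_alpha <- function(items) {
  M <- as.matrix(items)
  M <- M[stats::complete.cases(M), , drop = FALSE]
  k <- ncol(M)
  if (k < 2) stop("alpha needs at least 2 items", call. = FALSE)
  if (nrow(M) < 3) stop("alpha needs at least 3 complete respondents",
                        call. = FALSE)
  total_var <- var(rowSums(M))
  if (total_var <= 0) stop("total-score variance is zero; alpha undefined",
                           call. = FALSE)
  (k / (k - 1)) * (1 - sum(apply(M, 2, var)) / total_var)
}

#' Score the questionnaire measures
#'
#' Family routines (five 1-4 frequency items) are averaged within
#' administration, then within family across administrations, so repeated
#' assessments index overall routine stability. The 18 binary
#' home-unpredictability items are summed (0-18, single administration).
#'
#' @param routines Tibble: `family_id`, `administration`, `routine_1..5`.
#' @param quic Tibble: `family_id`, `quic_01..18`.
#' @return Tibble: `family_id`, `routines_mean`, `quic_sum` (NA where a
#'   family is missing from a measure).
#' @export
score_scales <- function(routines, quic) {
  r <- routines %>%
    dplyr::mutate(adm_mean = rowMeans(dplyr::pick(dplyr::starts_with("routine_")))) %>%
    dplyr::group_by(.data$family_id) %>%
    dplyr::summarise(routines_mean = mean(.data$adm_mean), .groups = "drop")
  q <- tibble(
    family_id = quic$family_id,
    quic_sum = rowSums(as.matrix(quic[grep("^quic_", names(quic))]))
  )
  dplyr::full_join(r, q, by = "family_id")
}

#' Pairwise Pearson correlations with pairwise-complete observations
#'
#' @param data Tibble; all numeric columns are used unless `vars` is given.
#' @param vars Optional character vector of columns.
#' @return Long tibble `var1`, `var2`, `r`, `n` (upper triangle), with the
#'   full symmetric matrix attached as attribute `"matrix"`. Constant
#'   columns yield `NA` cells.
#' @export
pairwise_correlations <- function(data, vars = NULL) {
  if (is.null(vars)) {
    vars <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  M <- as.matrix(data[vars])
  p <- length(vars)
  R <- matrix(NA_real_, p, p, dimnames = list(vars, vars))
  N <- matrix(0L, p, p, dimnames = list(vars, vars))
  for (i in seq_len(p)) {
    for (j in i:p) {
      ok <- stats::complete.cases(M[, c(i, j)])
      N[i, j] <- N[j, i] <- sum(ok)
      if (sum(ok) >= 3 && sd(M[ok, i]) > 0 && sd(M[ok, j]) > 0) {
        R[i, j] <- R[j, i] <- cor(M[ok, i], M[ok, j])
      }
    }
    R[i, i] <- 1
  }
  idx <- which(upper.tri(R), arr.ind = TRUE)
  out <- tibble(
    var1 = vars[idx[, 1]],
    var2 = vars[idx[, 2]],
    r = R[idx],
    n = N[idx]
  )
  attr(out, "matrix") <- R
  out
}

#' Descriptive group summaries of indices and composite
#'
#' Per-group mean, standard deviation, n and a normal-approximation 95%
#' confidence interval (mean +/- 1.96 sd/sqrt(n)) for each statistic.
#' Deliberately non-inferential: no tests are run.
#'
#' @param data Tibble holding the statistics and the grouping column.
#' @param group Name of the grouping column (string).
#' @param vars Character vector of statistic columns to summarize.
#' @return Tibble: `group_var`, `group`, `statistic`, `mean`, `sd`, `n`,
#'   `ci_lo`, `ci_hi`, `flagged` (TRUE when n < 2 and sd is omitted).
#' @export
group_summaries <- function(data, group, vars) {
  stopifnot(group %in% names(data), all(vars %in% names(data)))
  data %>%
    tidyr::pivot_longer(dplyr::all_of(vars), names_to = "statistic",
                        values_to = "value") %>%
    dplyr::group_by(group = .data[[group]], .data$statistic) %>%
    dplyr::summarise(
      mean = mean(.data$value, na.rm = TRUE),
      sd = if (sum(!is.na(.data$value)) >= 2) sd(.data$value, na.rm = TRUE) else NA_real_,
      n = sum(!is.na(.data$value)),
      .groups = "drop"
    ) %>%
    dplyr::mutate(
      group_var = group,
      ci_lo = .data$mean - 1.96 * .data$sd / sqrt(.data$n),
      ci_hi = .data$mean + 1.96 * .data$sd / sqrt(.data$n),
      flagged = .data$n < 2
    ) %>%
    dplyr::relocate("group_var")
}
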