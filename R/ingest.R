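#' Score item-level survey responses into 0-6 hardship sums
#'
#' Each response carries six binary "hard to pay for" indicators (food,
#' housing, utilities, healthcare, childcare, socioemotional well-being);
#' the hardship score is their sum. Responses with any missing item are
#' dropped (not prorated; a partial sum would deflate severity) and the
#' dropped count is attached as the `"n_dropped"` attribute.
#'
#' @param responses Tibble with columns `family_id`, `date` (ISO-8601), and
#'   the six `item_*` columns coded 0/1.
#' @return The response tibble with a `score` column (integer 0-6), invalid
#'   rows removed.
#' @export
score_responses <- function(responses) {
  item_cols <- grep("^item_", names(responses), value = TRUE)
  if (length(item_cols) != 6) {
    stop("expected six `item_*` columns, found ", length(item_cols),
         call. = FALSE)
  }
  items <- as.matrix(responses[item_cols])
  if (!all(items %in% c(0, 1, NA))) {
    stop("item indicators must be 0/1 or missing", call. = FALSE)
  }
  complete <- rowSums(is.na(items)) == 0
  out <- responses[complete, , drop = FALSE]
  out$score <- as.integer(rowSums(items[complete, , drop = FALSE]))
  attr(out, "n_dropped") <- sum(!complete)
  out
}

month_to_index <- function(month) {
  12L * as.integer(substr(month, 1, 4)) + as.integer(substr(month, 6, 7))
}

index_to_month <- function(idx) {
  y <- (idx - 1L) %/% 12L
  m <- idx - 12L * y
  sprintf("%04d-%02d", y, m)
}

#' Aggregate scored responses into per-family monthly hardship series
#'
#' Responses are bucketed by the calendar month of their date; multiple
#' responses within a month are averaged; 1 is added to every monthly mean
#' (shifting the 0-6 sum-score range to 1-7 so ratio statistics such as the
#' coefficient of variation are defined). Months between a family's first
#' and last observation with no response are retained as explicit gap rows
#' (`is_gap = TRUE`, `value = NA`); nothing is imputed here.
#'
#' @param responses Tibble of scored responses ([score_responses()] is
#'   applied first if no `score` column is present).
#' @return Tibble: `family_id`, `month` ("YYYY-MM"), `value` (1-7 scale),
#'   `is_gap`.
#' @export
monthly_series <- function(responses) {
  if (!"score" %in% names(responses)) responses <- score_responses(responses)
  monthly <- responses %>%
    dplyr::mutate(month = substr(.data$date, 1, 7)) %>%
    dplyr::group_by(.data$family_id, .data$month) %>%
    dplyr::summarise(value = mean(.data$score) + 1, .groups = "drop")

  monthly %>%
    dplyr::group_by(.data$family_id) %>%
    dplyr::group_modify(function(d, key) {
      idx <- month_to_index(d$month)
      grid <- seq(min(idx), max(idx))
      tibble(
        month = index_to_month(grid),
        value = d$value[match(grid, idx)],
        is_gap = !(grid %in% idx)
      )
    }) %>%
    dplyr::ungroup() %>%
    dplyr::arrange(.data$family_id, .data$month)
}

#' Keep families with enough observed months for reliable statistics
#'
#' Eligibility counts observed months (gap rows do not count), not the span
#' length. The default floor of 15 monthly responses is the recommended
#' lower bound for stable unpredictability statistics on series of this
#' kind.
#'
#' @param series Monthly series tibble from [monthly_series()].
#' @param min_months Minimum observed months (>= 2).
#' @return The eligible subset, with an `"eligibility"` attribute holding a
#'   one-row report (`n_total`, `n_eligible`, `n_excluded`).
#' @export
filter_eligible <- function(series, min_months = 15) {
  stopifnot(min_months >= 2)
  counts <- series %>%
    dplyr::group_by(.data$family_id) %>%
    dplyr::summarise(n_months = sum(!.data$is_gap), .groups = "drop")
  keep <- counts$family_id[counts$n_months >= min_months]
  out <- dplyr::filter(series, .data$family_id %in% keep)
  attr(out, "eligibility") <- tibble(
    n_total = nrow(counts),
    n_eligible = length(keep),
    n_excluded = nrow(counts) - length(keep),
    min_months = min_months
  )
  out
}

#' Eligibility report of a filtered series table
#'
#' @param series Result of [filter_eligible()].
#' @return One-row tibble with counts in/out.
#' @export
eligibility_report <- function(series) {
  rep <- attr(series, "eligibility")
  if (is.null(rep)) stop("no eligibility attribute; run filter_eligible() first",
                         call. = FALSE)
  rep
}

#' Hardship severity: each family's time-mean monthly hardship
#'
#' The arithmetic mean of the monthly 1-7 values over observed months only
#' (gaps are ignored) — the cumulative exposure score the unpredictability
#' indices are contrasted with.
#'
#' @param series Monthly series tibble (gap rows allowed).
#' @return Tibble: `family_id`, `severity`, `n_months`.
#' @export
severity_scores <- function(series) {
  series %>%
    dplyr::filter(!.data$is_gap) %>%
    dplyr::group_by(.data$family_id) %>%
    dplyr::summarise(
      severity = mean(.data$value),
      n_months = dplyr::n(),
      .groups = "drop"
    )
}
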