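make_response <- function(items, family_id = "F1", date = "2020-04-10") {
  names(items) <- c("item_food", "item_housing", "item_utilities",
                    "item_healthcare", "item_childcare", "item_wellbeing")
  tibble::as_tibble(c(list(family_id = family_id, date = date),
                      as.list(items)))
}

test_that("response scoring sums the six binary items", {
  expect_equal(score_responses(make_response(rep(0, 6)))$score, 0L)
  expect_equal(score_responses(make_response(c(1, 1, 0, 0, 1, 0)))$score, 3L)
  expect_equal(score_responses(make_response(rep(1, 6)))$score, 6L)
})

test_that("responses with any missing item are dropped and counted", {
  r <- dplyr::bind_rows(make_response(rep(1, 6)),
                        make_response(c(1, NA, 0, 0, 0, 0)))
  scored <- score_responses(r)
  expect_equal(nrow(scored), 1)
  expect_equal(attr(scored, "n_dropped"), 1)
  expect_error(score_responses(make_response(c(2, 0, 0, 0, 0, 0))), "0/1")
})

test_that("monthly aggregation averages within month and adds one", {
  r <- dplyr::bind_rows(
    make_response(c(1, 1, 0, 0, 0, 0), date = "2020-04-05"),
    make_response(c(1, 1, 1, 0, 0, 0), date = "2020-04-20")
  )
  ms <- monthly_series(r)
  expect_equal(ms$value, 3.5)           # mean(2, 3) + 1
  expect_equal(ms$month, "2020-04")

  single <- monthly_series(make_response(rep(0, 6)))
  expect_equal(single$value, 1.0)
})

test_that("unobserved months between observations become gap rows", {
  r <- dplyr::bind_rows(
    make_response(rep(0, 6), date = "2020-04-10"),
    make_response(rep(1, 6), date = "2020-06-10")
  )
  ms <- monthly_series(r)
  expect_equal(ms$month, c("2020-04", "2020-05", "2020-06"))
  expect_equal(ms$is_gap, c(FALSE, TRUE, FALSE))
  expect_true(is.na(ms$value[2]))
  # year boundary
  r2 <- dplyr::bind_rows(
    make_response(rep(0, 6), date = "2020-11-10"),
    make_response(rep(0, 6), date = "2021-02-10")
  )
  expect_equal(monthly_series(r2)$month,
               c("2020-11", "2020-12", "2021-01", "2021-02"))
})

test_that("aggregation is permutation-invariant within and across months", {
  r <- dplyr::bind_rows(
    make_response(c(1, 0, 0, 0, 0, 0), date = "2020-04-05"),
    make_response(c(1, 1, 1, 1, 0, 0), date = "2020-04-25"),
    make_response(c(1, 1, 0, 0, 0, 0), date = "2020-05-07")
  )
  expect_equal(monthly_series(r), monthly_series(r[c(3, 1, 2), ]))
})

test_that("eligibility keeps exactly the series with enough observed months", {
  vals14 <- series_tbl(rep(2, 14), family_id = "A")
  vals15 <- series_tbl(rep(2, 15), family_id = "B")
  both <- dplyr::bind_rows(vals14, vals15)
  kept <- filter_eligible(both, min_months = 15)
  expect_equal(unique(kept$family_id), "B")
  rep <- eligibility_report(kept)
  expect_equal(rep$n_eligible, 1)
  expect_equal(rep$n_excluded, 1)
  # gap rows do not count as observed months
  gappy <- series_tbl(rep(2, 14), family_id = "C", gap_at = 5)
  expect_equal(nrow(filter_eligible(gappy, 15)), 0)
})

test_that("synthetic cohort eligibility matches the planted count", {
  co <- simulate_cohort(sim_config(n_families = 80, missing_rate = 0.45,
                                   eligible_fraction = 0.6, seed = 21))
  ms <- monthly_series(co$responses)
  kept <- filter_eligible(ms, min_months = 15)
  expect_equal(eligibility_report(kept)$n_eligible,
               co$ground_truth$n_eligible_true)
})

test_that("severity is the mean over observed months only", {
  expect_equal(severity_scores(series_tbl(rep(3, 10)))$severity, 3)
  expect_equal(severity_scores(series_tbl(rep(c(1, 7), 8)))$severity, 4)
  s <- series_tbl(c(2, 4, 6), gap_at = 2)
  expect_equal(severity_scores(s)$severity, 4)
  x <- runif(20, 1, 7)
  sev <- severity_scores(series_tbl(x))$severity
  expect_gte(sev, min(x)); expect_lte(sev, max(x))
})

test_that("simulator items round-trip exactly through scoring and aggregation", {
  co <- simulate_cohort(sim_config(n_families = 25, extra_response_rate = 0,
                                   seed = 13))
  ms <- monthly_series(co$responses)
  obs <- dplyr::filter(ms, !is_gap)
  truth <- dplyr::filter(co$series, observed)
  joined <- dplyr::inner_join(obs, truth, by = c("family_id", "month"))
  expect_equal(nrow(joined), nrow(truth))
  expect_equal(joined$value.x, joined$value.y)
  # multiple responses per month carry the same planted sum, so the
  # monthly mean is unchanged
  co2 <- simulate_cohort(sim_config(n_families = 10, extra_response_rate = 1,
                                    seed = 13))
  ms2 <- monthly_series(co2$responses)
  obs2 <- dplyr::filter(ms2, !is_gap)
  truth2 <- dplyr::filter(co2$series, observed)
  j2 <- dplyr::inner_join(obs2, truth2, by = c("family_id", "month"))
  expect_equal(j2$value.x, j2$value.y)
})
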