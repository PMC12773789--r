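test_that("effective sample size follows its formula", {
  expect_equal(ess(c(1, 1, 2)), 16 / 6, tolerance = 1e-12)
  expect_equal(ess(rep(2, 50)), 50)
  set.seed(4)
  w <- rexp(100) + 0.1
  expect_equal(ess(w), sum(w)^2 / sum(w^2), tolerance = 1e-12)
  expect_lte(ess(w), 100)
  expect_error(ess(c(1, -1)))
})

test_that("weighted correlation agrees with the regression-slope route", {
  set.seed(15)
  x <- rnorm(200); y <- 0.4 * x + rnorm(200); w <- rexp(200) + 0.2
  expect_equal(weighted_cor(x, y, w), weighted_cor_regression(x, y, w),
               tolerance = 1e-10)
  expect_equal(weighted_cor(x, y, rep(1, 200)), cor(x, y), tolerance = 1e-12)
})

test_that("GPS weights are near-uniform when exposure is independent of X", {
  set.seed(26)
  sc <- simulate_balance_scenario(2000, r2 = 0)
  g <- gps_weights(sc$exposure, sc$X)
  # the 15 estimated coefficients leave O(sqrt(p/n)) wobble, largest in the
  # exposure tails; the bulk of the weights sits tight around 1
  expect_lt(mean(abs(g$weights - 1)), 0.1)
  expect_lt(unname(quantile(abs(g$weights - 1), 0.9)), 0.2)
  expect_lt(max(abs(g$weights - 1)), 1)
  expect_gt(g$ess, 0.95 * 2000)
  # confounding, by contrast, forces strongly non-uniform weights
  sc3 <- simulate_balance_scenario(2000, r2 = 0.3)
  g3 <- gps_weights(sc3$exposure, sc3$X)
  expect_gt(mean(abs(g3$weights - 1)), 2 * mean(abs(g$weights - 1)))
  # null guarantee: weighting does not move the correlations
  expect_lt(max(abs(g$post_corr - g$pre_corr)), 0.05)
})

test_that("GPS weighting removes most planted linear confounding", {
  set.seed(30)
  sc <- simulate_balance_scenario(500, r2 = 0.3)
  g <- gps_weights(sc$exposure, sc$X)
  expect_lt(max(abs(g$pre_corr)), 1)
  expect_gt(max(abs(g$pre_corr)), 0.15)     # confounding really planted
  expect_lt(g$max_abs_post_corr, max(abs(g$pre_corr)))
  expect_lt(mean(abs(g$post_corr)), mean(abs(g$pre_corr)) / 2)
  expect_lt(g$ess, g$n)
})

test_that("GPS detects overlap violations", {
  set.seed(2)
  sc <- simulate_balance_scenario(100, r2 = 0)
  a_det <- as.numeric(sc$X %*% rnorm(15))   # exposure deterministic in X
  expect_error(gps_weights(a_det, sc$X), "overlap")
})

test_that("entropy balancing returns uniform weights on in-sample-balanced data", {
  set.seed(44)
  sc <- simulate_balance_scenario(300, r2 = 0)
  # make the sample exactly balanced: residualize the exposure on the
  # standardized confounders, so uniform weights satisfy every constraint
  a <- unname(resid(lm(sc$exposure ~ scale(sc$X))))
  e <- entropy_balance_weights(a, sc$X)
  wn <- e$weights / sum(e$weights)
  kl <- sum(wn * log(wn * length(wn)))
  expect_lt(kl, 1e-6)
  expect_gt(e$ess, 0.999 * 300)
  # merely balanced-in-expectation data still gives near-uniform weights
  e2 <- entropy_balance_weights(sc$exposure, sc$X)
  expect_gt(e2$ess, 0.9 * 300)
})

test_that("entropy balancing drives every post-correlation to zero", {
  set.seed(52)
  sc <- simulate_balance_scenario(300, r2 = 0.3)
  e <- entropy_balance_weights(sc$exposure, sc$X)
  expect_true(e$converged)
  expect_lt(e$max_abs_post_corr, 0.01)
  expect_equal(e$n_balanced, 15)
  # weighted moments reproduce the unweighted confounder means
  w <- e$weights
  expect_equal(colSums(sc$X * w) / sum(w), colMeans(sc$X), tolerance = 1e-6)
})

test_that("the dual solution matches a primal augmented-Lagrangian oracle", {
  set.seed(61)
  for (rep in 1:3) {
    sc <- simulate_balance_scenario(50, r2 = 0.25, seed = 100 + rep)
    e <- entropy_balance_weights(sc$exposure, sc$X[, c(1, 6, 12)])
    ora <- primal_entropy_balance(sc$exposure, sc$X[, c(1, 6, 12)])
    expect_lt(ora$max_violation, 1e-6)
    expect_equal(sum(e$weights * log(e$weights)), ora$objective,
                 tolerance = 1e-6)
  }
})

test_that("ESS falls as planted confounding strengthens", {
  set.seed(70)
  ess_at <- vapply(c(0.1, 0.3, 0.5), function(r2) {
    mean(replicate(5, {
      sc <- simulate_balance_scenario(400, r2 = r2)
      gps_weights(sc$exposure, sc$X)$ess
    }))
  }, numeric(1))
  expect_true(all(diff(ess_at) < 0))
})

test_that("method selection follows balance-first tie-breaking", {
  mk <- function(n_balanced, max_abs, ess_val, method = "x") {
    structure(list(n_balanced = n_balanced, max_abs_post_corr = max_abs,
                   ess = ess_val, method = method),
              class = "balance_result")
  }
  a <- mk(15, 0.05, 90, "a"); b <- mk(14, 0.01, 120, "b")
  expect_equal(select_method(list(a, b))$method, "a")
  c1 <- mk(15, 0.05, 90, "c1"); c2 <- mk(15, 0.09, 120, "c2")
  expect_equal(select_method(list(c1, c2))$method, "c1")
  d1 <- mk(15, 0.05, 90, "d1"); d2 <- mk(15, 0.05, 120, "d2")
  expect_equal(select_method(list(d1, d2))$method, "d2")
  expect_equal(select_method(list(a))$method, "a")
})

test_that("balance_weights searches methods and survives one failing", {
  set.seed(83)
  sc <- simulate_balance_scenario(200, r2 = 0.2)
  d <- tibble::tibble(expo = sc$exposure)
  best <- balance_weights(d, "expo", sc$X)
  expect_s3_class(best, "balance_result")
  expect_equal(best$method, "ebal")       # exact constraints always win
  cands <- attr(best, "candidates")
  expect_named(cands, c("gps", "ebal"))
  td <- tidy(best)
  expect_equal(nrow(td), 15)
  expect_s3_class(autoplot(best), "ggplot")
})
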