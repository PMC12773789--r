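test_that("Cronbach's alpha matches the covariance-matrix identity", {
  # small hand-checkable matrix, alpha from tr(S)/sum(S) independently
  M <- matrix(c(1, 2, 3, 4,
                2, 3, 4, 5,
                1, 3, 3, 5,
                2, 2, 4, 4), nrow = 4)
  S <- cov(M)
  k <- ncol(M)
  oracle <- (k / (k - 1)) * (1 - sum(diag(S)) / sum(S))
  expect_equal(cronbach_alpha(M), oracle, tolerance = 1e-12)
})

test_that("alpha hits its boundary cases", {
  x <- rnorm(30)
  expect_equal(cronbach_alpha(cbind(x, x, x)), 1, tolerance = 1e-12)
  set.seed(19)
  indep <- matrix(rnorm(5000 * 4), ncol = 4)
  expect_lt(abs(cronbach_alpha(indep)), 0.05)
  # invariant to adding a constant per item
  M <- matrix(rnorm(60), ncol = 3)
  expect_equal(cronbach_alpha(M), cronbach_alpha(M + 7), tolerance = 1e-12)
  expect_error(cronbach_alpha(matrix(1, 10, 3)), "zero")
  expect_error(cronbach_alpha(matrix(rnorm(4), 4, 1)), "2 items")
})

test_that("pairwise correlations behave on identities and constants", {
  set.seed(8)
  d <- tibble::tibble(x = rnorm(40))
  d$same <- d$x
  d$neg <- -d$x
  d$const <- 1
  pc <- pairwise_correlations(d)
  M <- attr(pc, "matrix")
  expect_equal(M["x", "same"], 1)
  expect_equal(M["x", "neg"], -1)
  expect_true(is.na(M["x", "const"]))
  expect_equal(M, t(M))
  expect_true(all(diag(M) == 1))
})

test_that("complete-case correlation matrices are positive semidefinite", {
  co <- simulate_cohort(sim_config(n_families = 80, seed = 23))
  es <- env_stats(co$series)
  pc <- pairwise_correlations(es, vars = c("severity", "cv", "n_cpt_mean",
                                           "n_cpt_var", "noise_unpred"))
  ev <- eigen(attr(pc, "matrix"), symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-8))
})

test_that("measured severity tracks the planted instability correlation", {
  co <- simulate_cohort(sim_config(n_families = 800, seed = 37))
  gt <- co$ground_truth$per_family
  sev <- severity_scores(dplyr::mutate(
    dplyr::filter(co$series, observed), is_gap = FALSE))
  d <- dplyr::inner_join(sev, gt, by = "family_id")
  # planted latent correlation is 0.5 (instability_link default)
  expect_lt(abs(cor(d$severity, d$instability) - 0.5), 0.1)
})

test_that("scale scoring respects ranges and the averaging order", {
  r <- tibble::tibble(
    family_id = c("A", "A", "B"),
    administration = c(1, 2, 1),
    routine_1 = c(1, 3, 4), routine_2 = c(2, 3, 4), routine_3 = c(1, 3, 4),
    routine_4 = c(2, 3, 4), routine_5 = c(4, 3, 4)
  )
  q <- tibble::tibble(family_id = c("A", "B"))
  for (j in 1:18) q[[sprintf("quic_%02d", j)]] <- c(1, 0)
  sc <- score_scales(r, q)
  # family A: administration means 2 and 3 -> 2.5
  expect_equal(sc$routines_mean[sc$family_id == "A"], 2.5)
  expect_equal(sc$routines_mean[sc$family_id == "B"], 4)
  expect_equal(sc$quic_sum, c(18, 0))
  co <- simulate_cohort(sim_config(n_families = 50, seed = 31))
  sc2 <- score_scales(co$routines, co$quic)
  expect_true(all(sc2$routines_mean >= 1 & sc2$routines_mean <= 4))
  expect_true(all(sc2$quic_sum == round(sc2$quic_sum) &
                    sc2$quic_sum >= 0 & sc2$quic_sum <= 18))
})

test_that("group summaries reduce to the cohort mean for one group", {
  d <- tibble::tibble(g = "all", v = rnorm(30))
  gs <- group_summaries(d, "g", "v")
  expect_equal(gs$mean, mean(d$v))
  expect_equal(gs$n, 30)
  expect_equal(gs$ci_hi - gs$ci_lo, 2 * 1.96 * sd(d$v) / sqrt(30))
})

test_that("confidence interval width halves when n is quadrupled", {
  base <- rep(c(-2, -1, 1, 2), 5)          # fixed sd regardless of copies
  d <- tibble::tibble(
    g = c(rep("small", 20), rep("big", 80)),
    v = c(base, rep(base, 4))
  )
  gs <- group_summaries(d, "g", "v")
  w_small <- with(gs[gs$group == "small", ], ci_hi - ci_lo)
  w_big <- with(gs[gs$group == "big", ], ci_hi - ci_lo)
  # sample-sd denominators (n-1) perturb the exact 1/2 slightly
  expect_equal(w_big / w_small, 0.5, tolerance = 0.02)
})

test_that("singleton groups omit the sd and are flagged", {
  d <- tibble::tibble(g = c("a", "a", "b"), v = c(1, 2, 3))
  gs <- group_summaries(d, "g", "v")
  expect_true(is.na(gs$sd[gs$group == "b"]))
  expect_true(gs$flagged[gs$group == "b"])
  expect_false(gs$flagged[gs$group == "a"])
})

test_that("lower-SES groups show higher composite unpredictability", {
  agree <- vapply(1:3, function(seed) {
    co <- simulate_cohort(sim_config(n_families = 400, seed = seed))
    es <- env_stats(co$series)
    comp <- composite_index(fit_pca(es))
    d <- dplyr::inner_join(comp, co$confounders, by = "family_id")
    lo <- mean(d$composite[d$income_fpl == "fpl_le_200"])
    hi <- mean(d$composite[d$income_fpl == "fpl_ge_400"])
    lo > hi
  }, logical(1))
  expect_gte(mean(agree), 2 / 3)
})
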