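fake_stats <- function(n, seed = 1, rho = NULL) {
  set.seed(seed)
  if (is.null(rho)) {
    M <- matrix(rnorm(n * 4), n, 4)
  } else {
    f <- rnorm(n)
    M <- sqrt(rho) * f + sqrt(1 - rho) * matrix(rnorm(n * 4), n, 4)
  }
  tibble::tibble(family_id = sprintf("F%04d", 1:n),
                 cv = M[, 1], n_cpt_mean = M[, 2],
                 n_cpt_var = M[, 3], noise_unpred = M[, 4])
}

test_that("four identical features collapse onto a single component", {
  set.seed(2)
  x <- rnorm(50)
  d <- tibble::tibble(family_id = as.character(1:50), cv = x,
                      n_cpt_mean = x, n_cpt_var = x, noise_unpred = x)
  m <- fit_pca(d)
  expect_equal(m$variance_explained[1], 1, tolerance = 1e-10)
  expect_equal(sum(m$variance_explained), 1, tolerance = 1e-10)
})

test_that("PCA contracts hold: proportions, orthonormality, decorrelation", {
  m <- fit_pca(fake_stats(400, seed = 8, rho = 0.5))
  expect_equal(sum(m$variance_explained), 1, tolerance = 1e-10)
  expect_equal(crossprod(m$loadings), diag(4), tolerance = 1e-10,
               ignore_attr = TRUE)
  S <- as.matrix(m$scores[paste0("PC", 1:4)])
  cors <- cor(S)
  expect_lt(max(abs(cors[upper.tri(cors)])), 1e-8)
  expect_true(all(diff(m$eigenvalues) <= 1e-12))   # descending order
  # sign convention: a material variance-changepoint loading is never
  # negative (near-zero anchors fall back to the dominant loading)
  l <- m$loadings["n_cpt_var", ]
  expect_true(all(l[abs(l) > 0.1] >= 0))
  dom <- apply(m$loadings, 2, function(v) v[which.max(abs(v))])
  expect_true(all(l >= 0 | dom > 0))
})

test_that("loadings agree with an independent power-iteration eigensolver", {
  d <- fake_stats(200, seed = 5, rho = 0.4)
  m <- fit_pca(d)
  S <- cor(as.matrix(d[m$features]))
  ora <- power_eigen(S)
  expect_equal(m$eigenvalues, ora$values, tolerance = 1e-8)
  for (j in 1:4) {
    v <- ora$vectors[, j]
    expect_lt(min(sum((m$loadings[, j] - v)^2),
                  sum((m$loadings[, j] + v)^2)), 1e-8)
  }
})

test_that("zero-variance features are rejected by name", {
  d <- fake_stats(30, seed = 3)
  d$n_cpt_var <- 2
  expect_error(fit_pca(d), "n_cpt_var")
  expect_error(fit_pca(fake_stats(4)), "5 families")
})

test_that("row permutation leaves loadings fixed and permutes scores", {
  d <- fake_stats(60, seed = 10, rho = 0.3)
  m1 <- fit_pca(d)
  perm <- sample(nrow(d))
  m2 <- fit_pca(d[perm, ])
  expect_equal(m1$loadings, m2$loadings)
  reord <- m2$scores[match(m1$scores$family_id, m2$scores$family_id), ]
  expect_equal(m1$scores$PC1, reord$PC1)
})

test_that("the composite is the normalized variance-weighted score average", {
  # fabricated two-component model reproducing the documented arithmetic:
  # weights (0.6394, 0.1998), scores (1, -1)
  m <- structure(list(
    features = c("a", "b", "c", "d"),
    variance_explained = c(0.6394, 0.1998, 0.1, 0.0608),
    k = 2L,
    scores = tibble::tibble(family_id = "F1", PC1 = 1, PC2 = -1,
                            PC3 = 5, PC4 = -5)
  ), class = "unpred_pca")
  comp <- composite_index(m)
  expect_equal(comp$composite, (0.6394 - 0.1998) / (0.6394 + 0.1998),
               tolerance = 1e-12)
  # unaffected by non-retained components; zero scores give zero
  m$scores$PC3 <- 99
  expect_equal(composite_index(m)$composite, comp$composite)
  m$scores$PC1 <- 0; m$scores$PC2 <- 0
  expect_equal(composite_index(m)$composite, 0)
  # k = 1 reduces to the first component score
  m$k <- 1L; m$scores$PC1 <- 2.5
  expect_equal(composite_index(m)$composite, 2.5)
})

test_that("the composite is invariant to feature ordering", {
  d <- fake_stats(80, seed = 12, rho = 0.5)
  m1 <- fit_pca(d)
  m2 <- fit_pca(d, features = c("noise_unpred", "n_cpt_var", "n_cpt_mean", "cv"))
  c1 <- composite_index(m1)
  c2 <- composite_index(m2)
  expect_equal(c1$composite, c2$composite, tolerance = 1e-10)
})

test_that("a stronger common factor raises the first component share", {
  shares <- vapply(c(0.2, 0.5, 0.8), function(rho) {
    mean(replicate(20, {
      m <- fit_pca(fake_stats(150, seed = sample.int(1e6, 1), rho = rho))
      m$variance_explained[1]
    }))
  }, numeric(1))
  expect_true(all(diff(shares) > 0))
})

test_that("tidy, glance and autoplot expose the fitted model", {
  m <- fit_pca(fake_stats(50, seed = 20, rho = 0.4))
  td <- tidy(m)
  expect_equal(nrow(td), 16)
  expect_true(all(c("component", "feature", "loading") %in% names(td)))
  gl <- glance(m)
  expect_equal(gl$k, 2L)
  p <- autoplot(m)
  expect_s3_class(p, "ggplot")
})
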