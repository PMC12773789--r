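# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths for the quantity they check.

# build a monthly-series tibble from a plain numeric vector
series_tbl <- function(values, family_id = "F1", start = "2020-01",
                       gap_at = integer(0)) {
  n <- length(values) + length(gap_at)
  first <- as.Date(paste0(start, "-01"))
  months <- format(seq(first, by = "month", length.out = n), "%Y-%m")
  is_gap <- seq_len(n) %in% gap_at
  value <- rep(NA_real_, n)
  value[!is_gap] <- values
  tibble::tibble(family_id = family_id, month = months,
                 value = value, is_gap = is_gap)
}

# brute-force symmetric eigensolver: power iteration with deflation
power_eigen <- function(S, tol = 1e-13, max_iter = 20000) {
  p <- ncol(S)
  vals <- numeric(p)
  vecs <- matrix(0, p, p)
  A <- S + diag(p)          # shift to make dominant eigenvalue positive
  for (j in seq_len(p)) {
    v <- rep(1 / sqrt(p), p)
    for (it in seq_len(max_iter)) {
      w <- A %*% v
      w <- w / sqrt(sum(w^2))
      if (sum((w - v)^2) < tol^2) break
      v <- w
    }
    vals[j] <- as.numeric(t(v) %*% S %*% v)
    vecs[, j] <- v
    A <- A - as.numeric(t(v) %*% A %*% v) * tcrossprod(v)
  }
  ord <- order(vals, decreasing = TRUE)
  list(values = vals[ord], vectors = vecs[, ord, drop = FALSE])
}

# exhaustive single-split scan for the penalized mean-change objective,
# written from the cost definition directly (robust global variance from
# first differences, RSS per segment)
best_single_split_mean <- function(y, penalty) {
  n <- length(y)
  sigma2 <- (stats::mad(diff(y)) / sqrt(2))^2
  if (!is.finite(sigma2) || sigma2 < 1e-8) sigma2 <- stats::var(diff(y)) / 2
  rss <- function(v) sum((v - mean(v))^2)
  cost0 <- n * log(sigma2) + rss(y) / sigma2
  costs <- vapply(1:(n - 1), function(s) {
    (s * log(sigma2) + rss(y[1:s]) / sigma2) +
      ((n - s) * log(sigma2) + rss(y[(s + 1):n]) / sigma2) + penalty
  }, numeric(1))
  if (min(costs) < cost0) which.min(costs) else integer(0)
}

# primal entropy-balancing solver: augmented Lagrangian over log-weights,
# generic optimizer, no use of the package's dual formulation
primal_entropy_balance <- function(exposure, X, outer_iter = 40) {
  n <- length(exposure)
  Xs <- scale(X)
  a <- as.numeric(scale(exposure))
  C <- cbind(Xs, a, Xs * a)
  constraints <- function(w) c(sum(w) - n, as.numeric(crossprod(C, w / n)))
  obj <- function(w) sum(w * log(w))
  v <- rep(0, n)                      # w = n * softmax-free exp(v) scaling
  lambda <- numeric(1 + ncol(C))
  mu <- 1
  for (k in seq_len(outer_iter)) {
    fn <- function(v) {
      w <- exp(v)
      g <- constraints(w)
      obj(w) + sum(lambda * g) + (mu / 2) * sum(g^2)
    }
    gr <- function(v) {
      w <- exp(v)
      g <- constraints(w)
      J <- cbind(1, C / n)            # d g / d w
      as.numeric((log(w) + 1 + J %*% (lambda + mu * g)) * w)
    }
    opt <- stats::optim(v, fn, gr, method = "BFGS",
                        control = list(maxit = 400, reltol = 1e-14))
    v <- opt$par
    g <- constraints(exp(v))
    if (max(abs(g)) < 1e-9) break
    lambda <- lambda + mu * g
    mu <- min(mu * 3, 1e8)
  }
  w <- exp(v)
  list(weights = w, objective = obj(w),
       max_violation = max(abs(constraints(w))))
}

# weighted correlation via the regression-slope route: slope of weighted
# regression of standardized y on standardized x (weighted moments)
weighted_cor_regression <- function(x, y, w) {
  w <- w / sum(w)
  zx <- (x - sum(w * x)) / sqrt(sum(w * (x - sum(w * x))^2))
  zy <- (y - sum(w * y)) / sqrt(sum(w * (y - sum(w * y))^2))
  sum(w * zx * zy) / sum(w * zx^2)
}
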