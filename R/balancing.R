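# Balancing weights for continuous exposures against the 15 dummy-coded
# confounders. Two families of methods are provided: stabilized
# generalized-propensity-score density ratios (normal linear model) and
# entropy balancing (exact moment constraints via the convex dual). The
# selection rule across methods mirrors balance-first practice: most
# confounders with |weighted r| <= .10, then smallest max |r|, then
# largest effective sample size.

#' Effective sample size of a weight vector
#'
#' (sum w)^2 / sum(w^2): the number of equally-weighted observations
#' carrying the same information.
#'
#' @param w Positive weights.
#' @return Scalar <= length(w).
#' @export
ess <- function(w) {
  stopifnot(all(w > 0))
  sum(w)^2 / sum(w^2)
}

#' Weighted Pearson correlation
#'
#' Weighted covariance over the product of weighted standard deviations
#' (all moments weighted).
#'
#' @param x,y Numeric vectors.
#' @param w Positive weights.
#' @return Scalar correlation.
#' @export
weighted_cor <- function(x, y, w) {
  w <- w / sum(w)
  mx <- sum(w * x); my <- sum(w * y)
  vx <- sum(w * (x - mx)^2); vy <- sum(w * (y - my)^2)
  sum(w * (x - mx) * (y - my)) / sqrt(vx * vy)
}

balance_result <- function(exposure, X, w, method, converged = TRUE,
                           threshold = 0.10) {
  pre <- apply(X, 2, cor, y = exposure)
  post <- apply(X, 2, weighted_cor, y = exposure, w = w)
  structure(list(
    weights = w,
    method = method,
    pre_corr = pre,
    post_corr = post,
    n_balanced = sum(abs(post) <= threshold),
    max_abs_post_corr = max(abs(post)),
    ess = ess(w),
    n = length(w),
    threshold = threshold,
    converged = converged
  ), class = "balance_result")
}

#' @export
print.balance_result <- function(x, ...) {
  cat("<balance_result:", x$method, "> n =", x$n,
      " ESS =", round(x$ess, 1), "\n")
  cat("  balanced", x$n_balanced, "of", length(x$post_corr),
      "confounders (|r| <=", x$threshold, "); max |r| =",
      signif(x$max_abs_post_corr, 3), "\n")
  invisible(x)
}

#' Stabilized generalized-propensity-score weights (density ratio)
#'
#' Models the continuous exposure given the confounders as a normal linear
#' regression; the weight is the ratio of the exposure's marginal normal
#' density to its conditional density at the observed value, normalized to
#' mean 1. Under correct specification the weighted exposure-confounder
#' association vanishes in expectation.
#'
#' @param exposure Numeric exposure vector.
#' @param X Confounder design matrix (n x 15; see [confounder_design()]).
#' @param truncate_at Optional upper weight quantile (e.g. 0.99) at which
#'   weights are capped; default no trimming.
#' @return A `balance_result` (weights, pre/post correlations, ESS, counts).
#' @export
gps_weights <- function(exposure, X, truncate_at = NULL) {
  n <- length(exposure)
  stopifnot(nrow(X) == n, n > ncol(X) + 2)
  if (var(exposure) <= 0) stop("exposure has zero variance", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, X), exposure)
  p <- sum(!is.na(fit$coefficients))
  sig2 <- sum(fit$residuals^2) / (n - p)
  if (sig2 < 1e-10 * var(exposure)) {
    stop("near-zero conditional exposure variance: overlap violated",
         call. = FALSE)
  }
  num <- dnorm(exposure, mean(exposure), sd(exposure))
  den <- dnorm(exposure, fit$fitted.values, sqrt(sig2))
  w <- num / den
  if (!is.null(truncate_at)) w <- pmin(w, quantile(w, truncate_at))
  w <- w / mean(w)
  balance_result(exposure, X, w, "gps")
}

#' Entropy-balancing weights with exact decorrelation constraints
#'
#' Finds the weights closest to uniform in Kullback-Leibler divergence
#' (minimum sum w log w) subject to: sum w = n, the weighted mean of every
#' confounder and of the exposure equals its unweighted mean, and the
#' weighted exposure-confounder covariance is exactly zero for every
#' confounder. Solved through the convex dual (weights are log-linear in
#' the constraint functions) with BFGS plus Newton polishing; convergence
#' requires every standardized moment violation below `tol`.
#'
#' @inheritParams gps_weights
#' @param tol Maximum absolute constraint violation (default 1e-8).
#' @param max_iter Iteration cap for the dual optimization.
#' @return A `balance_result`.
#' @export
entropy_balance_weights <- function(exposure, X, tol = 1e-8, max_iter = 500) {
  n <- length(exposure)
  stopifnot(nrow(X) == n, n > ncol(X) + 2)
  if (var(exposure) <= 0) stop("exposure has zero variance", call. = FALSE)
  Xs <- scale(X)
  ok <- is.finite(colSums(Xs))
  if (!all(ok)) stop("constant confounder column(s): ",
                     paste(colnames(X)[!ok], collapse = ", "), call. = FALSE)
  a <- as.numeric(scale(exposure))
  C <- cbind(Xs, exposure = a, Xs * a)   # targets are all zero
  cn <- c(colnames(X), "exposure", paste0(colnames(X), ":exposure"))
  colnames(C) <- cn

  nw <- function(lambda) {               # normalized weights given dual vars
    u <- -as.numeric(C %*% lambda)
    u <- u - max(u)
    e <- exp(u)
    e / sum(e)
  }
  fn <- function(lambda) {
    u <- -as.numeric(C %*% lambda)
    m <- max(u)
    m + log(sum(exp(u - m)))
  }

  # damped Newton with backtracking on the smooth convex dual
  lambda <- numeric(ncol(C))
  fval <- fn(lambda)
  for (it in seq_len(max_iter)) {
    w <- nw(lambda)
    g <- as.numeric(crossprod(C, w))    # = -gradient of fn
    if (max(abs(g)) < tol) break
    H <- crossprod(C * w, C) - tcrossprod(g)
    step <- tryCatch(solve(H + diag(1e-10, ncol(C)), g),
                     error = function(e) g)
    alpha <- 1
    repeat {
      cand <- lambda + alpha * step
      fc <- fn(cand)
      if (is.finite(fc) && fc <= fval + 1e-12) break
      alpha <- alpha / 2
      if (alpha < 1e-12) break
    }
    if (alpha < 1e-12) break            # no descent possible: stop
    lambda <- lambda + alpha * step
    fval <- fn(lambda)
  }
  w <- nw(lambda)
  viol <- abs(as.numeric(crossprod(C, w)))
  if (max(viol) >= max(tol, 1e-6)) {
    stop("entropy balancing failed to converge; worst constraint: ",
         cn[which.max(viol)], " (violation ", signif(max(viol), 3), ")",
         call. = FALSE)
  }
  balance_result(exposure, X, n * w, "ebal",
                 converged = max(viol) < tol)
}

#' Balance a continuous exposure in a data frame against confounders
#'
#' Tidy front-end: takes the analysis table, the exposure column, and the
#' confounder design matrix; runs the requested methods and returns the one
#' chosen by [select_method()].
#'
#' @param data Tibble containing the exposure column.
#' @param exposure Name of the exposure column (string).
#' @param X Confounder design matrix with rows aligned to `data`.
#' @param methods Subset of `c("gps", "ebal")`.
#' @return The selected `balance_result`, with all candidates in attribute
#'   `"candidates"`.
#' @export
balance_weights <- function(data, exposure, X, methods = c("gps", "ebal")) {
  stopifnot(exposure %in% names(data))
  a <- data[[exposure]]
  fits <- list()
  for (m in methods) {
    res <- tryCatch(
      switch(m,
             gps = gps_weights(a, X),
             ebal = entropy_balance_weights(a, X),
             stop("unknown balancing method: ", m, call. = FALSE)),
      error = function(e) {
        warning("balancing method `", m, "` failed for `", exposure,
                "`: ", conditionMessage(e), call. = FALSE)
        NULL
      })
    if (!is.null(res)) fits[[m]] <- res
  }
  if (length(fits) == 0) {
    stop("no balancing method succeeded for `", exposure, "`", call. = FALSE)
  }
  best <- select_method(fits)
  attr(best, "candidates") <- fits
  best
}

#' Choose the best-balancing weight set
#'
#' Most confounders balanced (|weighted r| below the threshold), ties
#' broken by smaller maximum absolute post-weighting correlation, then by
#' larger effective sample size.
#'
#' @param results List of `balance_result` objects.
#' @return The chosen `balance_result`.
#' @export
select_method <- function(results) {
  stopifnot(length(results) >= 1)
  if (length(results) == 1) return(results[[1]])
  score <- vapply(results, function(r) {
    c(r$n_balanced, -r$max_abs_post_corr, r$ess)
  }, numeric(3))
  ord <- order(score[1, ], score[2, ], score[3, ], decreasing = TRUE)
  results[[ord[1]]]
}

#' @rdname gps_weights
#' @param x A `balance_result`.
#' @param ... Unused.
#' @export
tidy.balance_result <- function(x, ...) {
  tibble(
    confounder = names(x$pre_corr),
    pre_corr = as.numeric(x$pre_corr),
    post_corr = as.numeric(x$post_corr),
    balanced = abs(as.numeric(x$post_corr)) <= x$threshold
  )
}

#' @rdname gps_weights
#' @export
glance.balance_result <- function(x, ...) {
  tibble(
    method = x$method,
    n = x$n,
    n_balanced = x$n_balanced,
    max_abs_post_corr = x$max_abs_post_corr,
    ess = x$ess,
    converged = x$converged
  )
}

#' @rdname gps_weights
#' @param object A `balance_result`.
#' @export
autoplot.balance_result <- function(object, ...) {
  d <- tidy(object) %>%
    tidyr::pivot_longer(c("pre_corr", "post_corr"), names_to = "stage",
                        values_to = "r") %>%
    dplyr::mutate(stage = factor(.data$stage, c("pre_corr", "post_corr"),
                                 c("unweighted", "weighted")))
  ggplot2::ggplot(d, ggplot2::aes(x = abs(.data$r), y = .data$confounder,
                                  colour = .data$stage)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = 2) +
    ggplot2::labs(x = "|exposure-confounder correlation|", y = NULL,
                  colour = NULL,
                  title = paste0("Covariate balance (", object$method, ")")) +
    ggplot2::theme_minimal()
}
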