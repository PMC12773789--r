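# Penalized changepoint detection in mean and in variance.
#
# Two search strategies over the same penalized segment-cost objective:
# an O(n^2) optimal-partitioning dynamic program (`segment_optimal`, the
# exhaustive reference) and PELT (`detect_changepoints`), which prunes
# candidate segment starts and returns the same global optimum.
#
# Segment costs:
#   mean kind:     n_s * log(sigma2_g) + RSS_s / sigma2_g, with sigma2_g a
#                  robust global noise variance (squared MAD of first
#                  differences / 2) so the changepoints themselves do not
#                  inflate it;
#   variance kind: n_s * (log(sigma2_s) + 1), deviations taken about the
#                  global series mean.
# A penalty is added once per changepoint.

#' Per-changepoint penalty for a series of length n
#'
#' `"mbic"` (default) uses 3 log n, the conventional stricter default for
#' short noisy series; `"bic"` uses 2 log n (one level/scale parameter plus
#' one location per changepoint).
#'
#' @param rule `"mbic"` or `"bic"`.
#' @param n Series length.
#' @return Scalar penalty.
#' @export
changepoint_penalty <- function(rule = c("mbic", "bic"), n) {
  rule <- match.arg(rule)
  switch(rule, mbic = 3 * log(n), bic = 2 * log(n))
}

# Vectorized segment cost C(s+1, t) for all candidate starts s (0-based
# segment end bookkeeping: cost of y[(s+1):t]).
make_cost_fun <- function(y, kind) {
  n <- length(y)
  if (kind == "mean") {
    s1 <- c(0, cumsum(y))
    s2 <- c(0, cumsum(y^2))
    # robust noise scale from first differences (level shifts barely move
    # it); discrete series often have >50% zero differences, which zeroes
    # the MAD, so fall back to the difference variance, then to a floor
    sigma2 <- (stats::mad(diff(y)) / sqrt(2))^2
    if (!is.finite(sigma2) || sigma2 < 1e-8) sigma2 <- var(diff(y)) / 2
    if (!is.finite(sigma2) || sigma2 < 1e-8) sigma2 <- 1e-8
    function(s, t) {
      len <- t - s
      rss <- (s2[t + 1] - s2[s + 1]) - (s1[t + 1] - s1[s + 1])^2 / len
      len * log(sigma2) + pmax(rss, 0) / sigma2
    }
  } else {
    mu <- mean(y)
    d2 <- c(0, cumsum((y - mu)^2))
    function(s, t) {
      len <- t - s
      sig2 <- pmax((d2[t + 1] - d2[s + 1]) / len, 1e-8)
      len * (log(sig2) + 1)
    }
  }
}

segment_params_from <- function(y, kind, bounds) {
  n <- length(y)
  starts <- c(1, bounds + 1)
  ends <- c(bounds, n)
  if (kind == "mean") {
    mapply(function(a, b) mean(y[a:b]), starts, ends)
  } else {
    mu <- mean(y)
    mapply(function(a, b) mean((y[a:b] - mu)^2), starts, ends)
  }
}

finalize_segmentation <- function(y, kind, penalty, min_seglen, bounds, total_cost) {
  structure(list(
    changepoints = as.integer(bounds),
    n_changepoints = length(bounds),
    segment_params = segment_params_from(y, kind, bounds),
    total_cost = total_cost,
    penalty = penalty,
    kind = kind,
    min_seglen = min_seglen,
    n = length(y)
  ), class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat("<segmentation:", x$kind, "> n =", x$n,
      " changepoints:", if (x$n_changepoints) paste(x$changepoints, collapse = ", ") else "none",
      " cost =", signif(x$total_cost, 6), "\n")
  invisible(x)
}

check_cpt_input <- function(y, min_seglen) {
  if (!all(is.finite(y))) stop("series contains non-finite values", call. = FALSE)
  stopifnot(length(y) >= min_seglen, min_seglen >= 1)
}

# Shared tie-break: among candidate previous endpoints with (near-)equal
# cost, prefer the path with fewer changepoints, then the earliest boundary.
pick_candidate <- function(vals, segs, cand, tol = 1e-9) {
  best <- min(vals)
  tied <- which(vals <= best + tol)
  tied <- tied[order(segs[tied], cand[tied])]
  tied[1]
}

#' Exhaustive optimal-partitioning changepoint search (quadratic reference)
#'
#' Dynamic program over all admissible segmentations; globally minimizes
#' total segment cost + penalty per changepoint. This is the reference
#' implementation that [detect_changepoints()] (PELT) must agree with.
#'
#' @param y Numeric series (finite).
#' @param kind `"mean"` or `"variance"`.
#' @param penalty Scalar penalty per changepoint (see
#'   [changepoint_penalty()]).
#' @param min_seglen Minimum segment length (1 for mean, 2 for variance —
#'   a variance needs at least two points).
#' @return A `segmentation` object: `changepoints` (last index of each
#'   segment but the final), `segment_params`, `total_cost`, `penalty`,
#'   `kind`.
#' @export
segment_optimal <- function(y, kind = c("mean", "variance"), penalty,
                            min_seglen = if (kind[1] == "variance") 2L else 1L) {
  kind <- match.arg(kind)
  check_cpt_input(y, min_seglen)
  n <- length(y)
  cost <- make_cost_fun(y, kind)

  f <- rep(Inf, n + 1)   # f[t+1] = optimal cost of y[1:t] (+ penalty bookkeeping)
  f[1] <- -penalty
  segs <- rep(NA_integer_, n + 1)
  segs[1] <- 0L
  prev <- rep(NA_integer_, n + 1)
  for (t in min_seglen:n) {
    cand <- 0:(t - min_seglen)
    cand <- cand[is.finite(f[cand + 1])]
    vals <- f[cand + 1] + cost(cand, t) + penalty
    j <- pick_candidate(vals, segs[cand + 1], cand)
    f[t + 1] <- vals[j]
    prev[t + 1] <- cand[j]
    segs[t + 1] <- segs[cand[j] + 1] + 1L
  }

  bounds <- integer(0)
  t <- n
  while (t > 0) {
    s <- prev[t + 1]
    if (s > 0) bounds <- c(s, bounds)
    t <- s
  }
  finalize_segmentation(y, kind, penalty, min_seglen, bounds, f[n + 1])
}

#' PELT: pruned exact changepoint detection
#'
#' Same objective and tie-breaks as [segment_optimal()], with the PELT
#' pruning rule (a candidate start is discarded once it can no longer be
#' optimal for any future endpoint), giving near-linear scaling while
#' preserving the exact global optimum.
#'
#' @inheritParams segment_optimal
#' @param penalty_rule Convenience: `"mbic"`/`"bic"` to derive the penalty
#'   from the series length when `penalty` is not given.
#' @return A `segmentation` object (see [segment_optimal()]).
#' @export
detect_changepoints <- function(y, kind = c("mean", "variance"),
                                penalty = NULL,
                                penalty_rule = c("mbic", "bic"),
                                min_seglen = if (kind[1] == "variance") 2L else 1L) {
  kind <- match.arg(kind)
  check_cpt_input(y, min_seglen)
  n <- length(y)
  if (is.null(penalty)) penalty <- changepoint_penalty(match.arg(penalty_rule), n)
  cost <- make_cost_fun(y, kind)

  f <- rep(Inf, n + 1)
  f[1] <- -penalty
  segs <- rep(NA_integer_, n + 1)
  segs[1] <- 0L
  prev <- rep(NA_integer_, n + 1)
  active <- 0L                     # candidate segment starts (0-based)
  for (t in min_seglen:n) {
    cand <- active[active <= t - min_seglen]
    if (length(cand) == 0) next
    cvals <- cost(cand, t)
    vals <- f[cand + 1] + cvals + penalty
    j <- pick_candidate(vals, segs[cand + 1], cand)
    f[t + 1] <- vals[j]
    prev[t + 1] <- cand[j]
    segs[t + 1] <- segs[cand[j] + 1] + 1L
    # prune: keep s only while f[s] + C(s+1,t) <= f[t]
    keep <- f[cand + 1] + cvals <= f[t + 1] + 1e-9
    active <- c(cand[keep], setdiff(active, cand), t)
  }

  bounds <- integer(0)
  t <- n
  while (t > 0) {
    s <- prev[t + 1]
    if (s > 0) bounds <- c(s, bounds)
    t <- s
  }
  finalize_segmentation(y, kind, penalty, min_seglen, bounds, f[n + 1])
}
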