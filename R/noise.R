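# Noise color: the 1/f^beta spectral exponent of what remains in a series
# after systematic structure (trend, seasonality, drifting variance) is
# removed. beta near 0 = white/maximally random; near 2 = slow, predictable
# ("red") change; negative = fast but regular ("blue") change.

#' Remove systematic structure before spectral noise estimation
#'
#' Three steps on a regular monthly grid: (a) internal gaps are filled by
#' linear interpolation (spectral estimation needs equal spacing; the other
#' indices never interpolate); (b) OLS removal of intercept, linear time
#' trend and one annual harmonic pair (sine + cosine of calendar month —
#' series as short as 15 points cannot support month dummies); (c) variance
#' detrending: |residual| is regressed on time and each residual is divided
#' by max(fitted, 0.1 * median |residual|).
#'
#' @param x Numeric series on a regular monthly grid; `NA` marks gaps.
#' @param month_of_year Integer 1-12 per point (defaults to a cyclic count
#'   from 1).
#' @return List: `residuals`, `interpolated_fraction`, `flagged` (TRUE when
#'   more than 20% of the grid was interpolated).
#' @export
detrend_for_noise <- function(x, month_of_year = NULL) {
  n <- length(x)
  stopifnot(n >= 8)
  if (is.null(month_of_year)) month_of_year <- (seq_len(n) - 1) %% 12 + 1
  gaps <- is.na(x)
  if (gaps[1] || gaps[n]) {
    stop("leading/trailing gaps are not interpolable; trim the grid first",
         call. = FALSE)
  }
  if (any(gaps)) {
    x <- approx(which(!gaps), x[!gaps], xout = seq_len(n))$y
  }
  tt <- seq_len(n)
  X <- cbind(1, tt, sin(2 * pi * month_of_year / 12),
             cos(2 * pi * month_of_year / 12))
  res <- stats::lm.fit(X, x)$residuals

  med <- median(abs(res))
  if (med > 1e-10) {
    vf <- stats::lm.fit(cbind(1, tt), abs(res))
    scale <- pmax(vf$fitted.values, 0.1 * med)
    res <- res / scale
  }
  list(
    residuals = res,
    interpolated_fraction = mean(gaps),
    flagged = mean(gaps) > 0.2
  )
}

#' Estimate the spectral exponent (noise color) of a residual series
#'
#' Periodogram ordinates at the Fourier frequencies f_j = j/n,
#' j = 1..floor((n-1)/2); the slope of log power on log frequency gives
#' -beta. The unpredictability transform maps beta to a scale where higher
#' means more unpredictable: the default `"negabs"` (-|beta|) treats white
#' noise (beta = 0) as maximally unpredictable and both predictable
#' extremes (red beta ~ 2, blue beta < 0) as low; `"neg"` is plain -beta;
#' `"shift"` is 2 - beta (distance below the red end).
#'
#' @param residuals Detrended series (>= 8 points).
#' @param transform `"negabs"` (default), `"neg"` or `"shift"`.
#' @return List: `beta`, `unpred`, `n_ordinates`.
#' @export
noise_color <- function(residuals, transform = c("negabs", "neg", "shift")) {
  transform <- match.arg(transform)
  x <- residuals
  n <- length(x)
  stopifnot(n >= 8)
  x <- x - mean(x)
  m <- floor((n - 1) / 2)
  pgram <- Mod(fft(x))^2 / n
  power <- pgram[1 + seq_len(m)]
  freq <- seq_len(m) / n
  usable <- power > 0
  if (sum(usable) < 3) stop("fewer than 3 usable periodogram ordinates",
                            call. = FALSE)
  slope <- coef(stats::lm.fit(cbind(1, log(freq[usable])),
                              log(power[usable])))[2]
  beta <- -as.numeric(slope)
  unpred <- switch(transform,
                   negabs = -abs(beta),
                   neg = -beta,
                   shift = 2 - beta)
  list(beta = beta, unpred = unpred, n_ordinates = sum(usable))
}
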