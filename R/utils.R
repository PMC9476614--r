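# Low-level numerical helpers shared by the simulators and the envelope
# pipeline.

#' Derive a stage seed from a global seed and a stage name
#'
#' Every random stage of the pipeline draws its seed deterministically from
#' the global seed plus the stage name, so stages can be re-run in
#' isolation without disturbing each other.
#'
#' @param seed Global integer seed.
#' @param stage Stage name.
#' @return Integer seed below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  code <- utf8ToInt(stage)
  h <- sum(code * seq_along(code))
  as.integer((as.numeric(seed) * 1009 + h) %% 2147483647)
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher rejection sampler. `kappa = 0` reduces to the circular
#' uniform, `kappa = Inf` to a point mass at `mu`.
#'
#' @param n Number of draws.
#' @param mu Mean direction (radians).
#' @param kappa Concentration, `>= 0` (may be `Inf`).
#' @return Angles in `(-pi, pi]`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 0) stop("`kappa` must be >= 0")
  if (!is.finite(kappa)) return(wrap_angle(rep(mu, n)))
  if (kappa < 1e-8) return(runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0L
  while (i < n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (u[2] < cc * (2 - cc) || log(cc) - log(u[2]) + 1 - cc >= 0) {
      i <- i + 1L
      out[i] <- sign(u[3] - 0.5) * acos(pmin(pmax(f, -1), 1)) + mu
    }
  }
  wrap_angle(out)
}

#' Wrap angles into (-pi, pi]
#' @param x Angles in radians.
#' @return Wrapped angles.
#' @export
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

# Column-wise Gaussian noise shaped in the frequency domain. `h_of_f`
# receives the (two-sided, folded) frequency axis and returns the desired
# amplitude response; columns are standardized to zero mean, unit SD.
.shaped_noise <- function(n_samples, n_series, sfreq, h_of_f) {
  w <- matrix(rnorm(n_samples * n_series), n_samples, n_series)
  f <- (seq_len(n_samples) - 1) * sfreq / n_samples
  f <- pmin(f, sfreq - f)
  h <- h_of_f(f)
  x <- Re(mvfft(mvfft(w) * h, inverse = TRUE)) / n_samples
  mu <- colMeans(x)
  sdv <- sqrt(pmax(colMeans(x^2) - mu^2, 1e-24))
  sweep(sweep(x, 2, mu), 2, sdv, "/")
}

#' Smooth unit-variance Gaussian processes
#'
#' Gaussian low-pass shaped white noise, used for the slow envelope phase
#' wander of the synthetic generator.
#'
#' @param n_samples,n_series Matrix size (samples x series).
#' @param sfreq Sampling frequency (Hz).
#' @param fc Low-pass corner frequency (Hz).
#' @return `n_samples x n_series` matrix, columns standardized.
#' @export
smooth_gp <- function(n_samples, n_series, sfreq, fc) {
  .shaped_noise(n_samples, n_series, sfreq,
                function(f) exp(-0.5 * (f / fc)^2))
}

#' Band-limited unit-variance Gaussian noise
#'
#' Brick-wall band-limited white noise, the carrier model of the synthetic
#' EEG generator.
#'
#' @inheritParams smooth_gp
#' @param band Two-element band edges (Hz).
#' @return `n_samples x n_series` matrix, columns standardized.
#' @export
band_noise <- function(n_samples, n_series, sfreq, band) {
  .shaped_noise(n_samples, n_series, sfreq,
                function(f) as.numeric(f >= band[1] & f <= band[2]))
}

#' 1/f background noise
#'
#' @inheritParams smooth_gp
#' @param exponent Spectral slope: power falls as `1/f^exponent`.
#' @return `n_samples x n_series` matrix, columns standardized.
#' @export
pink_noise <- function(n_samples, n_series, sfreq, exponent = 1) {
  .shaped_noise(n_samples, n_series, sfreq,
                function(f) ifelse(f > 0, f^(-exponent / 2), 0))
}

#' Analytic signal via the frequency domain
#'
#' Standard FFT construction of the analytic signal: negative frequencies
#' are zeroed, positive doubled. `Mod()` of the result is the amplitude
#' envelope, `Arg()` the instantaneous phase.
#'
#' @param x Real numeric vector.
#' @return Complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / n
}

# zero-phase Butterworth applied along the last (time) dimension of a
# trials x channels x samples array (or a matrix / vector)
.filt_array <- function(x, filt) {
  if (is.null(dim(x))) return(signal::filtfilt(filt, x))
  d <- dim(x)
  if (length(d) == 2) {
    out <- t(apply(x, 1, function(v) signal::filtfilt(filt, v)))
    dim(out) <- d
    return(out)
  }
  out <- x
  for (i in seq_len(d[1]))
    for (j in seq_len(d[2]))
      out[i, j, ] <- signal::filtfilt(filt, x[i, j, ])
  out
}
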