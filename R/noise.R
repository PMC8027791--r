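#' Colored (1/f^chi) noise
#'
#' Generates zero-mean, unit-variance noise whose expected power spectral
#' density is proportional to `f^(-chi)` over the analyzable band, by
#' spectral shaping of Gaussian white noise: independent complex Fourier
#' coefficients are scaled by `f^(-chi/2)` and inverse-transformed.
#' `chi = 0` gives white noise; `chi = 1` pink; `chi = 2` Brownian-like.
#' The DC component is set to zero.
#'
#' @param n_samples Number of samples (>= 2).
#' @param fs Sampling rate, Hz (sets the frequency axis only; the shape is
#'   scale-free).
#' @param chi Spectral exponent, >= 0.
#'
#' @return Numeric vector of length `n_samples`, mean 0, variance 1.
#' @examples
#' set.seed(1)
#' x <- colored_noise(4096, fs = 500, chi = 1)
#' c(mean(x), var(x))
#' @export
colored_noise <- function(n_samples, fs, chi) {
  if (chi < 0) stop("chi must be >= 0")
  if (n_samples < 2) stop("n_samples must be >= 2")
  n <- as.integer(n_samples)
  n2 <- stats::nextn(n, 2)     # pad to a fast FFT length, truncate afterwards
  freqs <- seq(0, n2 - 1) / n2 * fs
  # two-sided frequency axis folded at Nyquist
  f_fold <- pmin(freqs, fs - freqs)
  amp <- c(0, f_fold[-1]^(-chi / 2))          # kill DC
  z <- stats::fft(stats::rnorm(n2))           # Hermitian-symmetric by construction
  x <- Re(stats::fft(z * amp, inverse = TRUE))[seq_len(n)] / n2
  x <- x - mean(x)
  x / stats::sd(x)
}

#' Band-limited unit-variance Gaussian noise
#'
#' White noise restricted to `[low, high]` Hz by Fourier masking, then
#' renormalized to zero mean and unit variance.
#'
#' @param n_samples Number of samples.
#' @param fs Sampling rate, Hz.
#' @param low,high Band edges, Hz.
#' @return Numeric vector of length `n_samples`.
#' @export
band_noise <- function(n_samples, fs, low, high) {
  n <- as.integer(n_samples)
  n2 <- stats::nextn(n, 2)
  freqs <- seq(0, n2 - 1) / n2 * fs
  f_fold <- pmin(freqs, fs - freqs)
  mask <- as.numeric(f_fold >= low & f_fold <= high)
  z <- stats::fft(stats::rnorm(n2))
  x <- Re(stats::fft(z * mask, inverse = TRUE))[seq_len(n)] / n2
  x <- x - mean(x)
  x / stats::sd(x)
}

#' Sample from the von Mises distribution
#'
#' Best–Fisher (1979) rejection sampler for circular data with mean
#' direction `mu` and concentration `kappa`. `kappa = 0` reduces to the
#' uniform distribution on the circle; large `kappa` concentrates mass at
#' `mu` (circular SD ~ `1/sqrt(kappa)`).
#'
#' @param n Number of draws.
#' @param mu Mean direction, radians.
#' @param kappa Concentration parameter, >= 0.
#'
#' @return Numeric vector of angles in (-pi, pi].
#' @examples
#' set.seed(1)
#' mean(cos(rvonmises(1000, 0, 5)))  # ~ I1(5)/I0(5) = 0.894
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 0) stop("kappa must be >= 0")
  if (kappa == 0) {
    return(stats::runif(n, -pi, pi))
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- stats::runif(1); u2 <- stats::runif(1); u3 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (c_ * (2 - c_) - u2 > 0 || log(c_ / u2) + 1 - c_ >= 0) {
      theta <- sign(u3 - 0.5) * acos(f)
      out[i] <- atan2(sin(theta + mu), cos(theta + mu))
      i <- i + 1L
    }
  }
  out
}
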