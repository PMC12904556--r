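## Small FFT helpers shared by the simulator, calibration and reconstruction.
## Signals live along the FIRST dimension of a matrix (one column per
## lateral position); stats::mvfft transforms columns in one call.

#' Analytic signal along the first dimension
#'
#' Builds the complex analytic signal (signal + i * Hilbert transform) of a
#' real matrix column-by-column via the one-sided FFT construction, giving
#' access to instantaneous phase and envelope of the fringe.
#'
#' @param x real matrix (n x m), signal along rows.
#' @return complex matrix of the same shape.
#' @keywords internal
.analytic <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    if (n > 2) h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    if (n > 1) h[2:((n + 1) / 2)] <- 2
  }
  X <- stats::mvfft(x) * h
  stats::mvfft(X, inverse = TRUE) / n
}

## Signed FFT sample frequencies (cycles per sample), numpy fftfreq layout.
.fftfreq <- function(n) {
  f <- c(0:(ceiling(n / 2) - 1), -(floor(n / 2):1))
  f / n
}

#' Fractional circular shift along the first dimension
#'
#' y[j] = x[j - shift] evaluated by the Fourier shift theorem (band-limited
#' sinc interpolation for non-integer shifts).
#' @keywords internal
.fourier_shift <- function(x, shift) {
  x <- as.matrix(x)
  n <- nrow(x)
  ## signed frequencies (Nyquist assigned to -n/2); a pure phase ramp, so
  ## shift(h) followed by shift(-h) is exactly the identity
  ph <- exp(-2i * pi * .fftfreq(n) * shift)
  X <- stats::mvfft(x) * ph
  stats::mvfft(X, inverse = TRUE) / n
}

#' Band-limited upsampling along the first dimension by an integer factor
#' (zero-padding in the conjugate domain; exact for band-limited content).
#' @keywords internal
.fft_upsample <- function(x, factor) {
  stopifnot(factor >= 1, factor == round(factor))
  x <- as.matrix(x)
  n <- nrow(x); m <- ncol(x)
  if (factor == 1) return(x)
  N <- n * factor
  X <- stats::mvfft(x)
  Y <- matrix(0 + 0i, N, m)
  if (n %% 2 == 0) {
    h <- n / 2
    Y[1:h, ] <- X[1:h, , drop = FALSE]
    ## split the Nyquist coefficient between +/- Nyquist
    Y[h + 1, ] <- X[h + 1, ] / 2
    Y[N - h + 1, ] <- X[h + 1, ] / 2
    if (h > 1) Y[(N - h + 2):N, ] <- X[(h + 2):n, , drop = FALSE]
  } else {
    h <- (n + 1) / 2
    Y[1:h, ] <- X[1:h, , drop = FALSE]
    if (h < n) Y[(N - (n - h) + 1):N, ] <- X[(h + 1):n, , drop = FALSE]
  }
  stats::mvfft(Y, inverse = TRUE) * (factor / N)
}

## Phase unwrapping (delegates to signal::unwrap).
.unwrap <- function(p) signal::unwrap(p)

#' Tukey (tapered cosine) window
#'
#' @param n window length.
#' @param ratio fraction of the window inside the cosine tapers (0 =
#'   rectangular, 1 = Hann).
#' @return numeric vector of length \code{n} in [0, 1].
#' @export
tukeyWindow <- function(n, ratio = 0.5) {
  stopifnot(n >= 1, ratio >= 0, ratio <= 1)
  if (ratio == 0 || n == 1) return(rep(1, n))
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  a <- ratio / 2
  lo <- t < a
  hi <- t > 1 - a
  w[lo] <- 0.5 * (1 + cos(pi * (t[lo] / a - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * ((t[hi] - 1 + a) / a)))
  w
}

## Parabolic (quadratic) refinement of a discrete argmax: given the values at
## (i-1, i, i+1) returns the sub-sample offset of the vertex in [-0.5, 0.5].
.quad_refine <- function(ym1, y0, yp1) {
  denom <- ym1 - 2 * y0 + yp1
  if (denom == 0) return(0)
  off <- 0.5 * (ym1 - yp1) / denom
  max(-0.5, min(0.5, off))
}

## Flatten (nx, ny, n) array -> (n, nx*ny) matrix with signal along rows.
.cube_to_mat <- function(a) {
  d <- dim(a)
  stopifnot(length(d) == 3)
  t(matrix(a, d[1] * d[2], d[3]))
}

## Inverse of .cube_to_mat.
.mat_to_cube <- function(m, nx, ny) {
  array(t(m), dim = c(nx, ny, nrow(m)))
}

## Wavelength (nm) <-> wavenumber (rad/um). k = 2*pi/lambda with lambda in um.
.lambda_to_k <- function(lambda_nm) 2 * pi * 1e3 / lambda_nm
.k_to_lambda <- function(k) 2 * pi * 1e3 / k
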