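## Subpixel overlap determination between adjacent lasers by summed
## normalized cross-correlation of padded, k-linearized mirror spectra.

#' Construct an AnalyticSpectrum directly
#'
#' @param data complex (nx, ny, N) array or a complex vector (treated as
#'   1 x 1 lateral).
#' @param k_start wavenumber of the first pixel (rad/um).
#' @param dk pixel size (rad/um).
#' @param laser_id identifier.
#' @export
analyticSpectrum <- function(data, k_start, dk, laser_id = "spec") {
  if (is.null(dim(data))) data <- array(data, dim = c(1L, 1L, length(data)))
  new("AnalyticSpectrum", data = data, k_start = k_start, dk = dk,
      laser_id = laser_id)
}

#' Ideal k-linear mirror spectrum
#'
#' Synthesizes the already-k-linearized complex spectrum
#' S(k) * sum_l A_l exp(i (2 k z_l + phase)) on a uniform grid; the
#' closed-form counterpart of simulating, trimming and regridding a mirror
#' sweep.  Used for oracles and for replicating idealized overlap
#' simulations.
#'
#' @param k_start,dk,n grid definition (rad/um).
#' @param depths,amplitudes mirror depths (um) and amplitudes.
#' @param envelope optional numeric S(k) of length n.
#' @param phase constant phase added to every layer (rad).
#' @param laser_id identifier.
#' @export
mirrorSpectrum <- function(k_start, dk, n, depths, amplitudes = 1,
                           envelope = NULL, phase = 0, laser_id = "spec") {
  amplitudes <- rep(amplitudes, length.out = length(depths))
  k <- k_start + (seq_len(n) - 1) * dk
  v <- rep(0 + 0i, n)
  for (l in seq_along(depths))
    v <- v + amplitudes[l] * exp(1i * (2 * k * depths[l] + phase))
  if (!is.null(envelope)) v <- v * envelope
  analyticSpectrum(v, k_start, dk, laser_id)
}

## Laterally averaged complex spectrum vector.
.avg_spectrum <- function(spec) {
  m <- .cube_to_mat(spec@data)
  rowMeans(m)
}

#' Zero-pad two spectra to a common correlation frame
#'
#' Places spectrum a on pixels [0, N_a) and spectrum b on pixels
#' [N_a, N_a + N_b) of a common length-(N_a + N_b) frame, zero elsewhere.
#' The padding prevents wrap-around in the circular cross-correlation.
#' Zero-padding conserves the energy of each input.
#'
#' @param a,b \linkS4class{AnalyticSpectrum} objects on the same dk
#'   (a = lower-k laser).
#' @return list with complex vectors \code{a}, \code{b} (laterally
#'   averaged) of length N_a + N_b, plus \code{n_a}, \code{n_b}.
#' @export
padSpectra <- function(a, b) {
  stopifnot(is(a, "AnalyticSpectrum"), is(b, "AnalyticSpectrum"))
  if (abs(a@dk - b@dk) > 1e-12 * a@dk)
    stop("dk mismatch between the two spectra")
  va <- .avg_spectrum(a); vb <- .avg_spectrum(b)
  n_a <- length(va); n_b <- length(vb)
  if (n_a == 0L || n_b == 0L) stop("degenerate: empty spectrum")
  list(a = c(va, rep(0 + 0i, n_b)), b = c(rep(0 + 0i, n_a), vb),
       n_a = n_a, n_b = n_b)
}

#' Normalized cross-correlation of two padded mirror spectra
#'
#' Computes the cross-correlation of the padded spectra via the convolution
#' theorem, zero-padding the transform-domain product by \code{pad_factor}
#' (default 100, i.e. padded 99 times its own length) so the correlation is
#' sampled every 1/pad_factor = 0.01 pixels.  Normalizing by the magnitude
#' and taking the real part yields, for a mirror at depth z_n,
#' rho(l) = cos(2 (l - kappa) dk z_n): periodic in lag l, so a single depth
#' cannot identify the overlap by itself.  The magnitude is regularized at
#' 1e-3 of its maximum before division, since it vanishes outside the
#' support of the envelope cross-correlation.
#'
#' @param padded the list returned by \code{\link{padSpectra}}.
#' @param pad_factor fine-grid factor (grid spacing 1/pad_factor px).
#' @return list: \code{rho} (normalized correlation), \code{R} (complex
#'   correlation), \code{lag} (pixels, 0 .. L - 1/pad_factor, circular).
#' @export
depthCrossCorrelation <- function(padded, pad_factor = 100L) {
  pa <- padded$a; pb <- padded$b
  L <- length(pa)
  P <- stats::fft(pb) * Conj(stats::fft(pa))
  if (max(abs(P)) == 0) stop("no common fringe content between the spectra")
  Lf <- L * pad_factor
  Y <- rep(0 + 0i, Lf)
  if (pad_factor == 1L) {
    Y <- P
  } else if (L %% 2 == 0) {
    h <- L / 2
    Y[1:h] <- P[1:h]
    Y[h + 1] <- P[h + 1] / 2
    Y[Lf - h + 1] <- P[h + 1] / 2
    if (h > 1) Y[(Lf - h + 2):Lf] <- P[(h + 2):L]
  } else {
    h <- (L + 1) / 2
    Y[1:h] <- P[1:h]
    Y[(Lf - (L - h) + 1):Lf] <- P[(h + 1):L]
  }
  R <- stats::fft(Y, inverse = TRUE) / L
  mag <- Mod(R)
  rho <- Re(R) / pmax(mag, 1e-3 * max(mag))
  list(rho = rho, R = R, lag = (seq_len(Lf) - 1) / pad_factor)
}

#' Determine the subpixel overlap from multiple mirror depths
#'
#' Sums the individual normalized cross-correlations of k-linearized mirror
#' spectrum pairs recorded at several distinct depths z_n; the sum
#' rho0(l) = sum_n cos(2 (l - kappa) dk z_n) adds up constructively only at
#' the true overlap, whose position is taken as the argmax of rho0 inside a
#' physical search window derived from the nominal laser ranges
#' ([0.25, 4] x kappa_nom), preventing lock-on to periodic aliases.
#'
#' @param pairs list over depths; each element a list/pair of
#'   \linkS4class{AnalyticSpectrum} (lower-k laser first).
#' @param depths the mirror depths z_n in um (used for reporting and the
#'   harmonic-depth warning).
#' @param kappa_nom nominal overlap in pixels; default derived from the
#'   spectra's own k grids.
#' @param search_window numeric c(lo, hi) in pixels; default
#'   [0.25, 4] * kappa_nom.
#' @param pad_factor fine-grid factor (0.01 px at the default 100).
#' @return an \linkS4class{OverlapEstimate}.
#' @export
determineOverlap <- function(pairs, depths = NULL, kappa_nom = NULL,
                             search_window = NULL, pad_factor = 100L) {
  if (length(pairs) < 2L)
    stop("at least 2 mirror depths are required: a single normalized cross-correlation is periodic and ambiguous")
  if (is.null(depths)) depths <- rep(NA_real_, length(pairs))
  zd <- depths[!is.na(depths)]
  if (length(zd) >= 2) {
    rat <- outer(zd, zd, function(x, y) pmax(x, y) / pmin(x, y))
    rat <- rat[upper.tri(rat)]
    if (any(abs(rat - round(rat)) < 0.02 & round(rat) > 1))
      warning("some calibration depths are close to integer multiples of each other; the summed cross-correlation may be ambiguous")
  }
  a1 <- pairs[[1]][[1]]; b1 <- pairs[[1]][[2]]
  dkv <- a1@dk
  if (is.null(kappa_nom)) {
    k_end_a <- a1@k_start + (dim(a1@data)[3] - 1) * dkv
    kappa_nom <- (k_end_a - b1@k_start) / dkv + 1
  }
  if (kappa_nom <= 0)
    stop("nominal laser ranges do not overlap; cannot search for kappa")
  if (is.null(search_window))
    search_window <- c(0.25 * kappa_nom, 4 * kappa_nom)
  rho0 <- NULL; lag <- NULL
  for (p in pairs) {
    pp <- padSpectra(p[[1]], p[[2]])
    cc <- depthCrossCorrelation(pp, pad_factor = pad_factor)
    if (is.null(rho0)) { rho0 <- cc$rho; lag <- cc$lag }
    else {
      if (length(cc$rho) != length(rho0))
        stop("all depth pairs must share the same grid lengths")
      rho0 <- rho0 + cc$rho
    }
  }
  L <- length(lag) / pad_factor
  search_window[2] <- min(search_window[2], L / 2)
  sel <- which(lag >= search_window[1] & lag <= search_window[2])
  if (!length(sel)) stop("empty search window")
  rs <- rho0[sel]
  best <- which(rs == max(rs))
  if (length(best) > 1)                       # tie-break toward kappa_nom
    best <- best[which.min(abs(lag[sel][best] - kappa_nom))]
  kap <- lag[sel][best]
  boundary <- best == 1L || best == length(sel)
  if (boundary)
    warning("overlap argmax on the search-window boundary; estimate unreliable")
  new("OverlapEstimate", kappa = kap, rho0 = rs, lag_grid = lag[sel],
      depths_used = depths, n_depths = length(pairs),
      search_window = search_window, boundary = boundary)
}
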