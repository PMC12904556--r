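## Per-measurement reconstruction: background subtraction, motion-phase
## correction, inter-volume registration, fractional-pixel spectral shifts,
## phase-correct stitching, apodization and depth reconstruction.

#' Subtract background and DC from a raw sweep
#'
#' Removes the per-pixel temporal mean (or a supplied reference sweep, e.g.
#' a sample-free acquisition capturing the ASE background b(k)); optionally
#' also removes the per-frame lateral mean, which suppresses laterally
#' uniform stray light but must not be used for laterally uniform samples
#' such as calibration mirrors.
#'
#' @param raw a \linkS4class{RawSweep}.
#' @param reference optional \linkS4class{RawSweep} holding the background
#'   (same shape), subtracted frame-by-frame before the mean removal.
#' @param frame_dc also remove each frame's lateral mean (default FALSE).
#' @return the background-subtracted \linkS4class{RawSweep}.
#' @export
subtractBackground <- function(raw, reference = NULL, frame_dc = FALSE) {
  stopifnot(is(raw, "RawSweep"))
  f <- raw@frames
  if (!is.null(reference)) {
    stopifnot(all(dim(reference@frames) == dim(f)))
    f <- f - reference@frames
  }
  m <- .cube_to_mat(f)                       # t x nlat
  m <- base::sweep(m, 2, colMeans(m))        # per-pixel temporal mean
  if (frame_dc) m <- m - rowMeans(m)         # per-frame lateral DC
  raw@frames <- .mat_to_cube(m, dim(f)[1], dim(f)[2])
  raw
}

## Sharpness metric S = sum |U|^gamma, energy-normalized so it measures
## concentration rather than scale; smaller = sharper (gamma < 2).
.sharpness <- function(U, gamma) {
  e <- sum(Mod(U)^2)
  if (e == 0) return(Inf)
  sum(Mod(U)^gamma) / e^(gamma / 2)
}

#' Estimate and remove the in-volume motion/dispersion phase
#'
#' The spectral phase of orders >= 2 (in-volume sample motion plus
#' dispersion mismatch) is modelled as a polynomial in the normalized
#' wavenumber offset u = (k - k0)/k_half and estimated by minimizing the
#' sharpness metric S = sum |U|^gamma of the reconstructed volume; orders 0
#' and 1 are deliberately untouched (they are handled by registration and
#' the phase-offset search).
#'
#' @param spec a k-linearized \linkS4class{AnalyticSpectrum}.
#' @param order_max highest polynomial order (>= 2) to correct.
#' @param gamma sharpness exponent (default 1.4).
#' @param pad_factor depth zero-padding during optimization (>= 2 so
#'   sidelobes are visible to the metric).
#' @return list with the corrected spectrum (\code{spectrum}) and a
#'   \linkS4class{MotionPhase} (\code{phase}); non-convergence returns the
#'   best phase found with \code{converged = FALSE}.
#' @export
correctMotionPhase <- function(spec, order_max = 3L, gamma = 1.4,
                               pad_factor = 2L) {
  stopifnot(is(spec, "AnalyticSpectrum"), order_max >= 2L)
  m <- .cube_to_mat(spec@data)
  n <- nrow(m)
  kg <- kGrid(spec)
  k0 <- mean(range(kg))
  k_half <- (max(kg) - min(kg)) / 2
  u <- (kg - k0) / k_half
  npad <- n * pad_factor
  orders <- 2:order_max
  basis <- vapply(orders, function(j) u^j, numeric(n))
  obj <- function(cf) {
    ph <- exp(-1i * (basis %*% cf)[, 1])
    corr <- m * ph
    U <- stats::mvfft(rbind(corr, matrix(0 + 0i, npad - n, ncol(m)))) /
      sqrt(npad)
    .sharpness(U, gamma)
  }
  if (length(orders) == 1L) {
    ## 1-d: coarse grid to escape local minima, then golden-section refine
    grid <- seq(-60, 60, length.out = 61)
    vals <- vapply(grid, obj, 0)
    g0 <- grid[which.min(vals)]
    o1 <- stats::optimize(obj, interval = g0 + c(-3, 3), tol = 1e-8)
    res <- list(par = o1$minimum, value = o1$objective, convergence = 0L)
  } else {
    ## coarse scan over the quadratic term for a good simplex start
    grid <- seq(-60, 60, length.out = 31)
    vals <- vapply(grid, function(g)
      obj(c(g, rep(0, length(orders) - 1L))), 0)
    init <- c(grid[which.min(vals)], rep(0, length(orders) - 1L))
    res <- stats::optim(init, obj, method = "Nelder-Mead",
                        control = list(maxit = 600, reltol = 1e-10))
  }
  conv <- identical(res$convergence, 0L) || res$convergence == 0
  if (!conv) warning("motion-phase optimizer did not fully converge; returning best found")
  ph <- exp(-1i * (basis %*% res$par)[, 1])
  spec@data <- .mat_to_cube(m * ph, dim(spec@data)[1], dim(spec@data)[2])
  mp <- new("MotionPhase", volume_index = NA_integer_,
            laser_id = spec@laser_id,
            coefficients = c(0, 0, res$par), k0 = k0, k_half = k_half,
            converged = conv)
  list(spectrum = spec, phase = mp)
}

#' @describeIn correctMotionPhase Polynomial coefficients of the estimated
#'   phase in physical units (rad per (rad/um)^j, orders 0..order_max).
#' @param mp a \linkS4class{MotionPhase}.
#' @export
motionCoefficients <- function(mp) {
  j <- seq_along(mp@coefficients) - 1
  mp@coefficients / mp@k_half^j
}

## Magnitude depth profile of a laterally averaged spectrum embedded in a
## common length L and padded pad-fold (bin position depends only on the
## fringe frequency, not on k_start).
.depth_profile <- function(v, L, pad) {
  x <- c(v, rep(0 + 0i, L - length(v)))
  Mod(stats::fft(c(x, rep(0 + 0i, L * (pad - 1))))) / L
}

#' Register volumes axially and remove their phase ramps
#'
#' Estimates each volume's bulk axial displacement against a reference
#' volume and removes the corresponding linear spectral phase ramp
#' exp(i 2 k dz).  Spectra sharing the reference's k grid use the
#' cross-spectrum phase-slope estimator (the mean per-pixel phase increment
#' of ref * conj(x), magnitude-weighted, equivalent to subpixel A-scan
#' cross-correlation); spectra from other lasers fall back to subpixel
#' cross-correlation of zero-padded magnitude A-scans, which is insensitive
#' to the disjoint k supports.
#'
#' @param spectra list of \linkS4class{AnalyticSpectrum} on the common dk
#'   grid (all volumes of all lasers).
#' @param reference index of the reference volume (default 1).
#' @param pad magnitude-profile zero-padding for the cross-laser estimator.
#' @param min_corr normalized peak correlation below which a volume is
#'   declared decorrelated and excluded (shift NA, warning).
#' @return list: \code{shifts} (um, one per input; 0 for the reference) and
#'   \code{spectra} (deramped).
#' @export
registerVolumes <- function(spectra, reference = 1L, pad = 16L,
                            min_corr = 0.2) {
  stopifnot(length(spectra) >= 1)
  dkv <- spectra[[reference]]@dk
  for (s in spectra) if (abs(s@dk - dkv) > 1e-12 * dkv)
    stop("all spectra must share the common dk grid")
  avg <- lapply(spectra, .avg_spectrum)
  L <- max(vapply(avg, length, 0L))
  ref <- spectra[[reference]]
  pr <- .depth_profile(avg[[reference]], L, pad)
  z_fine <- pi / (L * pad * dkv)             # um per fine depth pixel
  shifts <- numeric(length(spectra))
  for (i in seq_along(spectra)) {
    if (i == reference) next
    s <- spectra[[i]]
    same_grid <- length(avg[[i]]) == length(avg[[reference]]) &&
      abs(s@k_start - ref@k_start) < 1e-9
    if (same_grid) {
      ## cross-spectrum c(k) = ref * conj(x) is (near) a pure tone
      ## exp(-i 2 k dz): coarse peak of its transform, then the exact mean
      ## phase increment of the derotated tone
      c_ij <- avg[[reference]] * Conj(avg[[i]])
      nk <- length(c_ij)
      D <- Mod(stats::fft(c(c_ij, rep(0 + 0i, nk * (pad - 1)))))
      npd <- nk * pad
      pk <- which.max(D)
      lag <- pk - 1
      if (lag > npd / 2) lag <- lag - npd
      dz0 <- -lag * 2 * pi / (npd * 2 * dkv)
      kg <- kGrid(spectra[[i]])
      c2 <- c_ij * exp(1i * 2 * kg * dz0)
      ## weighted LS fit of the residual phase slope over the interior
      ## (regridding leaves ringing at the spectrum edges)
      drop <- max(4L, ceiling(0.02 * nk))
      idx <- (drop + 1L):(nk - drop)
      phr <- .unwrap(Arg(c2[idx]))
      w <- Mod(c2[idx])^2
      x <- seq_along(idx)
      xm <- sum(w * x) / sum(w); ym <- sum(w * phr) / sum(w)
      slope <- sum(w * (x - xm) * (phr - ym)) / sum(w * (x - xm)^2)
      shifts[i] <- dz0 - slope / (2 * dkv)
    } else {
      pi_ <- .depth_profile(avg[[i]], L, pad)
      ## center the magnitude profiles: their non-negative means would
      ## otherwise dominate the normalized correlation
      prc <- pr - mean(pr)
      pic <- pi_ - mean(pi_)
      X <- stats::fft(stats::fft(prc) * Conj(stats::fft(pic)),
                      inverse = TRUE)
      X <- Re(X) / length(X)
      peak <- which.max(X)
      denom <- sqrt(sum(prc^2) * sum(pic^2))
      if (X[peak] / denom < min_corr) {
        warning(sprintf("volume %d decorrelated from the reference; excluded", i))
        shifts[i] <- NA_real_
        next
      }
      lagpx <- peak - 1
      nfft <- length(X)
      ym1 <- X[(peak - 2) %% nfft + 1]; yp1 <- X[peak %% nfft + 1]
      lagpx <- lagpx + .quad_refine(ym1, X[peak], yp1)
      if (lagpx > nfft / 2) lagpx <- lagpx - nfft
      shifts[i] <- -lagpx * z_fine
    }
    if (!is.na(shifts[i]) && shifts[i] != 0) {
      kg <- kGrid(spectra[[i]])
      ramp <- exp(-1i * 2 * kg * shifts[i])
      spectra[[i]]@data <- spectra[[i]]@data *
        rep(ramp, each = prod(dim(spectra[[i]]@data)[1:2]))
    }
  }
  list(shifts = shifts, spectra = spectra)
}

#' Shift a spectrum by a fractional number of pixels
#'
#' Exact fractional-pixel spectral shift via a linear phase ramp in the
#' conjugate (depth) domain; \code{shiftSpectrum(x, kappa)} followed by
#' \code{shiftSpectrum(., -kappa)} is the identity to numerical precision.
#' Content moves toward higher k by \code{shift} pixels (circularly).
#'
#' @param spec an \linkS4class{AnalyticSpectrum} on a uniform grid.
#' @param shift pixels (fractional allowed).
#' @export
shiftSpectrum <- function(spec, shift) {
  stopifnot(is(spec, "AnalyticSpectrum"))
  d <- dim(spec@data)
  m <- .cube_to_mat(spec@data)
  spec@data <- .mat_to_cube(.fourier_shift(m, shift), d[1], d[2])
  spec
}

#' Linear blend weight of the stitch overlap
#'
#' w(k) = (k - (N_m - kappa))/kappa: 0 at the blend start, 1 at the first
#' pixel owned solely by the second laser.
#'
#' @param k global pixel coordinate (may be a vector).
#' @param n_m length of the first (lower-k) spectrum in pixels.
#' @param kappa fractional overlap in pixels.
#' @export
blendWeight <- function(k, n_m, kappa) {
  pmin(1, pmax(0, (k - (n_m - kappa)) / kappa))
}

#' Stitch two adjacent spectra phase-correctly
#'
#' Composes the combined spectrum: the lower-k spectrum alone below the
#' overlap, a linear amplitude blend with the phase-offset-corrected upper
#' spectrum across the overlap, and the upper spectrum alone beyond it.
#' The fractional part of the overlap is applied by the Fourier shift
#' theorem (never rounded during estimation); the blend spans the rounded
#' overlap in integer pixels with the weight evaluated at pixel centers.
#'
#' @param spec_m lower-k \linkS4class{AnalyticSpectrum} (length N_m).
#' @param spec_m1 upper-k \linkS4class{AnalyticSpectrum}, registered and
#'   motion-corrected.
#' @param phase either a single phase offset (rad), or a
#'   \linkS4class{PhaseOffsetField} from \code{\link{searchPhaseOffsets}}.
#' @param plan a \linkS4class{StitchPlan} carrying kappa for this pair.
#' @return the stitched \linkS4class{AnalyticSpectrum} of length
#'   N_m + N_m1 - round(kappa), starting at spec_m's first pixel.
#' @export
stitchSpectra <- function(spec_m, spec_m1, phase = 0, plan) {
  stopifnot(is(spec_m, "AnalyticSpectrum"), is(spec_m1, "AnalyticSpectrum"),
            is(plan, "StitchPlan"))
  if (abs(spec_m@dk - spec_m1@dk) > 1e-12 * spec_m@dk)
    stop("dk mismatch; regrid to the common dk first")
  da <- dim(spec_m@data); db <- dim(spec_m1@data)
  if (!all(da[1:2] == db[1:2])) stop("lateral dimensions differ")
  kap <- plan@kappa[1]
  n_m <- da[3]; n_b <- db[3]
  r <- n_m - kap                       # fractional start of b on a's grid
  gi0 <- floor(r + 1e-9)               # blend spans ceil(kappa) pixels;
  h <- r - gi0                         # grid stays inside the measured span
  if (gi0 < 0 || gi0 > n_m) stop("overlap outside the valid range")
  mb <- .cube_to_mat(spec_m1@data)
  if (h != 0) mb <- .fourier_shift(mb, h)

  ## per-pixel phase offset
  nlat <- da[1] * da[2]
  if (is(phase, "PhaseOffsetField")) {
    phmap <- .expand_bins(phase, da[1], da[2])
    ph <- exp(1i * as.vector(phmap))
  } else ph <- rep(exp(1i * phase), nlat)
  mb <- base::sweep(mb, 2, ph, "*")

  ma <- .cube_to_mat(spec_m@data)
  n_tot <- gi0 + n_b
  out <- matrix(0 + 0i, n_tot, nlat)
  kap_i <- n_m - gi0                   # integer blend length = round(kappa)
  if (gi0 > 0) out[1:gi0, ] <- ma[1:gi0, , drop = FALSE]
  if (kap_i > 0) {
    g <- gi0:(n_m - 1)                 # global pixel coords of the blend
    w <- blendWeight(g, n_m, kap)
    out[g + 1, ] <- (1 - w) * ma[g + 1, , drop = FALSE] +
      w * mb[seq_len(kap_i), , drop = FALSE]
  }
  if (n_b > kap_i)
    out[(n_m + 1):n_tot, ] <- mb[(kap_i + 1):n_b, , drop = FALSE]
  new("AnalyticSpectrum", data = .mat_to_cube(out, da[1], da[2]),
      k_start = spec_m@k_start, dk = spec_m@dk, laser_id = "stitched")
}

#' Apodize a spectrum
#'
#' Pointwise multiplication along k with a Tukey window (ratio 0 =
#' rectangular = identity on amplitudes) to trade main-lobe width for
#' sidelobe suppression; \code{kind = "none"} is the identity.
#'
#' @param spec an \linkS4class{AnalyticSpectrum}.
#' @param kind "none" or "tukey".
#' @param ratio Tukey taper ratio (default 0.5).
#' @export
apodize <- function(spec, kind = c("none", "tukey"), ratio = 0.5) {
  kind <- match.arg(kind)
  if (kind == "none") return(spec)
  n <- dim(spec@data)[3]
  w <- tukeyWindow(n, ratio)
  spec@data <- spec@data * rep(w, each = prod(dim(spec@data)[1:2]))
  spec
}

#' Reconstruct the complex depth volume
#'
#' Inverse Fourier transform along k (orthonormal scaling, so the unapodized
#' transform conserves energy exactly); the depth pixel is pi/(N dk) um in
#' air under the cos(2 k z) fringe convention.
#'
#' @param spec an \linkS4class{AnalyticSpectrum} on a uniform k grid.
#' @param pad_factor zero-pad the spectrum to pad_factor times its length
#'   before transforming (sub-pixel depth sampling).
#' @return a \linkS4class{ReconVolume}.
#' @export
reconstructVolume <- function(spec, pad_factor = 1L) {
  stopifnot(is(spec, "AnalyticSpectrum"), pad_factor >= 1L)
  m <- .cube_to_mat(spec@data)
  n <- nrow(m)
  npad <- n * pad_factor
  if (pad_factor > 1L) m <- rbind(m, matrix(0 + 0i, npad - n, ncol(m)))
  U <- stats::mvfft(m) / sqrt(npad)
  d <- dim(spec@data)
  new("ReconVolume", data = .mat_to_cube(U, d[1], d[2]),
      z_pixel = pi / (npad * spec@dk),
      meta = list(laser_id = spec@laser_id, pad_factor = pad_factor,
                  dk = spec@dk, n_k = n))
}
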