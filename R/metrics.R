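## Axial PSF and resolution diagnostics: theoretical resolution, -6 dB
## FWHM / sidelobe measurement, and stitching error-sensitivity sweeps.

#' Theoretical axial resolution of a rectangular spectrum
#'
#' The -6 dB (intensity) full width at half maximum of the axial PSF of an
#' ideal flat spectrum of width dk0 = k_max - k_min is 1.21 * pi / dk0 in
#' air (under the cos(2 k z) fringe convention used throughout).
#'
#' @param k_min,k_max sweep limits in rad/um.
#' @return FWHM in um.
#' @examples
#' theoreticalResolution(0, 1.21 * pi)  # 1 um
#' @export
theoreticalResolution <- function(k_min, k_max) {
  stopifnot(k_max > k_min)
  1.21 * pi / (k_max - k_min)
}

## Circular index helper (1-based).
.cidx <- function(i, n) ((i - 1) %% n) + 1

## Linear interpolation of the half-maximum crossing between circular
## samples i (above) and i+dir (below); returns fractional offset from i.
.cross_frac <- function(p, i, dir, half, n) {
  j <- .cidx(i + dir, n)
  (p[i] - half) / (p[i] - p[j])
}

#' Measure the axial PSF: -6 dB FWHM and sidelobe levels
#'
#' Locates the strongest peak of the magnitude depth profile (inside
#' \code{depth_window} if given), measures its full width at half maximum
#' of the magnitude (the -6 dB intensity width) by linear interpolation of
#' the crossings, and reports the highest local maximum on each side of the
#' main lobe -- excluding the lobe down to its first nulls -- within
#' +/- 15 FWHM, in dB intensity relative to the peak.  The depth axis is
#' treated as circular.
#'
#' @param x an \linkS4class{AnalyticSpectrum} (zero-padded by
#'   \code{pad_factor} and transformed internally), a
#'   \linkS4class{ReconVolume}, or a numeric/complex depth profile.
#' @param depth_window optional c(lo, hi) in um restricting the peak
#'   search.
#' @param pad_factor zero-padding applied when \code{x} is a spectrum
#'   (>= 16 for sub-pixel FWHM interpolation).
#' @param z_pixel depth pixel in um; required when \code{x} is a bare
#'   profile.
#' @return a \linkS4class{PSFReport}.
#' @export
psfReport <- function(x, depth_window = NULL, pad_factor = 16L,
                      z_pixel = NULL) {
  if (is(x, "AnalyticSpectrum")) {
    if (pad_factor < 16L)
      warning("pad_factor below 16 limits sub-pixel FWHM interpolation")
    vol <- reconstructVolume(x, pad_factor = pad_factor)
    p <- rowMeans(Mod(.cube_to_mat(vol@data)))
    zp <- vol@z_pixel
  } else if (is(x, "ReconVolume")) {
    p <- rowMeans(Mod(.cube_to_mat(x@data)))
    zp <- x@z_pixel
    pad_factor <- as.integer(x@meta$pad_factor %||% pad_factor)
  } else {
    stopifnot(!is.null(z_pixel))
    p <- Mod(as.vector(x))
    zp <- z_pixel
  }
  n <- length(p)
  z <- (seq_len(n) - 1) * zp
  zc <- ifelse(z > n * zp / 2, z - n * zp, z)  # circular depth coordinate
  sel <- seq_len(n)
  if (!is.null(depth_window))
    sel <- which(zc >= depth_window[1] & zc <= depth_window[2])
  if (!length(sel) || max(p[sel]) <= 0)
    stop("no peak found in the requested depth window")
  pk <- sel[which.max(p[sel])]
  pkv <- p[pk]
  ## a window that only sees tails of a distant response holds no peak
  if (!is.null(depth_window) && pkv < 0.05 * max(p))
    stop("no resolved peak in the requested depth window (in-window maximum below 5% of the global peak)")
  half <- pkv / 2

  ## FWHM: walk out from the peak to the half-max crossings
  walk <- function(dir) {
    i <- pk
    for (s in seq_len(n - 1)) {
      j <- .cidx(pk + dir * s, n)
      if (p[j] < half) {
        prev <- .cidx(pk + dir * (s - 1), n)
        return((s - 1) + (p[prev] - half) / (p[prev] - p[j]))
      }
      i <- j
    }
    stop("no half-maximum crossing found; profile has no resolved peak")
  }
  wl <- walk(-1); wr <- walk(+1)
  fw <- (wl + wr) * zp

  ## first null each side, then highest sidelobe within +/- 15 FWHM
  first_null <- function(dir) {
    for (s in seq_len(n - 2)) {
      a <- p[.cidx(pk + dir * s, n)]
      b <- p[.cidx(pk + dir * (s + 1), n)]
      if (b >= a) return(s)
    }
    n - 2
  }
  side_db <- function(dir) {
    s0 <- first_null(dir)
    smax <- min(floor(15 * fw / zp), floor((n - 1) / 2))
    if (s0 >= smax) return(-Inf)
    vals <- p[.cidx(pk + dir * (s0:smax), n)]
    20 * log10(max(vals) / pkv)
  }
  new("PSFReport", depth = zc[pk], fwhm = fw,
      sidelobe_left_db = min(side_db(-1), 0),
      sidelobe_right_db = min(side_db(+1), 0),
      pad_factor = as.integer(pad_factor))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Idealized dual-laser stitching scenario
#'
#' Builds the two k-linearized mirror spectra of a dual-laser system on
#' their calibrated common-dk grids (closed form, no simulation noise)
#' together with the matching \linkS4class{StitchPlan}; the starting point
#' of the stitching error-sensitivity analyses.
#'
#' @param depth mirror depth in um.
#' @param lasers list of two \linkS4class{LaserSpec} (default: the
#'   dual-laser system, 805-882 nm / 879-950 nm).
#' @param trim head/tail frame discards defining the common grid.
#' @return list: \code{a}, \code{b} (\linkS4class{AnalyticSpectrum}, lower-k
#'   laser first), \code{plan}, \code{kappa}, \code{dk}.
#' @export
stitchScenario <- function(depth, lasers = dualLaserSpecs(),
                           trim = c(8L, 8L)) {
  cg <- .common_grids(lasers, trim = trim)
  ord <- cg$order
  glo <- cg$grids[[ord[1]]]; ghi <- cg$grids[[ord[2]]]
  a <- mirrorSpectrum(glo$k_start, cg$dk, glo$N, depth,
                      laser_id = glo$laser_id)
  b <- mirrorSpectrum(ghi$k_start, cg$dk, ghi$N, depth,
                      laser_id = ghi$laser_id)
  plan <- stitchPlan(c(glo$laser_id, ghi$laser_id), cg$kappa)
  list(a = a, b = b, plan = plan, kappa = cg$kappa, dk = cg$dk)
}

#' The dual-laser system specification
#'
#' Nominal sweep ranges 805-882 nm (515 frames) and 879-950 nm (478
#' frames), both sweeping in the same direction.
#' @export
dualLaserSpecs <- function() {
  list(laserSpec("laser840", 805, 882, 515L, "decreasing_k"),
       laserSpec("laser950", 879, 950, 478L, "decreasing_k"))
}

#' Sweep the stitched PSF over injected stitching errors
#'
#' Re-stitches a dual-laser scenario with a controlled error injected --
#' a constant phase offset on the second laser, an overlap mis-set by a
#' fractional pixel, or an amplitude scale step at the seam -- and reports
#' the PSF degradation per magnitude relative to the error-free stitch.
#'
#' @param scenario list from \code{\link{stitchScenario}} (fields a, b,
#'   plan).
#' @param kind which error to inject.
#' @param magnitudes error magnitudes: rad for "phase_offset", pixels for
#'   "overlap"; for "amplitude", the factor of a hard amplitude step
#'   applied at the seam (1 = no error; the error-free blended stitch is
#'   the baseline).
#' @param pad_factor PSF zero-padding.
#' @return data.frame with one row per magnitude (the error-free baseline
#'   first): fwhm (um), left/right sidelobe (dB), the worst one-sided
#'   sidelobe and its rise over baseline (dB).
#' @export
errorSensitivitySweep <- function(scenario,
                                  kind = c("phase_offset", "overlap",
                                           "amplitude"),
                                  magnitudes, pad_factor = 16L) {
  kind <- match.arg(kind)
  base_mag <- if (kind == "amplitude") 1 else 0
  stitch_with <- function(mag) {
    a <- scenario$a; b <- scenario$b; plan <- scenario$plan
    ph <- 0
    if (kind == "phase_offset") ph <- mag
    if (kind == "overlap") plan@kappa <- plan@kappa + mag
    st <- stitchSpectra(a, b, phase = ph, plan = plan)
    if (kind == "amplitude" && mag != 1) {
      ## uncorrected amplitude mismatch: a hard step at the seam (the
      ## blended baseline is the corrected reference)
      n_m <- dim(specData(a))[3]
      n_tot <- dim(st@data)[3]
      seam <- round(n_m - plan@kappa[1] / 2)
      step <- c(rep(1, seam), rep(mag, n_tot - seam))
      st@data <- st@data * rep(step, each = prod(dim(st@data)[1:2]))
    }
    st
  }
  mags <- c(base_mag, magnitudes)
  rows <- lapply(mags, function(mg) {
    rep <- psfReport(stitch_with(mg), pad_factor = pad_factor)
    sl <- sidelobes(rep)
    data.frame(magnitude = mg, fwhm = fwhm(rep),
               sidelobe_left_db = sl[["left"]],
               sidelobe_right_db = sl[["right"]],
               worst_sidelobe_db = max(sl))
  })
  out <- do.call(rbind, rows)
  out$rise_db <- out$worst_sidelobe_db - out$worst_sidelobe_db[1]
  out$baseline <- seq_len(nrow(out)) == 1L
  out
}
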