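## S4 classes for the dual-laser FF-FD-OCT stitching framework.
##
## Unit conventions, used everywhere in the package:
##   wavelengths nm; wavenumbers k = 2*pi/lambda in rad/um; depths z are
##   optical path in air, um.  A mirror at depth z produces the fringe
##   cos(2 k z); spectra sampled at spacing dk over N pixels therefore
##   reconstruct onto depth pixels of size pi/(N*dk) and the Nyquist depth
##   is pi/(2*dk).

setClassUnion("numericOrArray", c("numeric", "array"))

#' Laser sweep specification
#'
#' Nominal sweep endpoints and frame count of one swept-source laser.
#'
#' @slot laser_id short identifier, e.g. "laser840".
#' @slot lambda_min,lambda_max nominal sweep endpoints in nm.
#' @slot n_frames camera frames recorded during the sweep.
#' @slot sweep_direction "increasing_k" or "decreasing_k" (in time).
#' @export
setClass("LaserSpec",
  representation(laser_id = "character", lambda_min = "numeric",
                 lambda_max = "numeric", n_frames = "integer",
                 sweep_direction = "character"),
  validity = function(object) {
    if (object@lambda_min >= object@lambda_max)
      return("lambda_min must be < lambda_max")
    if (object@n_frames < 16L) return("n_frames must be >= 16")
    if (!object@sweep_direction %in% c("increasing_k", "decreasing_k"))
      return("sweep_direction must be 'increasing_k' or 'decreasing_k'")
    TRUE
  })

#' @param laser_id,lambda_min,lambda_max,n_frames,sweep_direction see slots.
#' @rdname LaserSpec-class
#' @export
laserSpec <- function(laser_id, lambda_min, lambda_max, n_frames,
                      sweep_direction = "decreasing_k") {
  new("LaserSpec", laser_id = laser_id, lambda_min = lambda_min,
      lambda_max = lambda_max, n_frames = as.integer(n_frames),
      sweep_direction = sweep_direction)
}

#' Parametric model of the laser chirp k(t)
#'
#' Describes the (generally non-linear) mapping from frame index to
#' instantaneous wavenumber over the nominal span.  All kinds anchor the
#' endpoints to the nominal sweep wavenumbers exactly; coefficients shape
#' the interior.  For \code{kind="polynomial"} the normalized sweep is
#' g(u) = u + sum_j c_j (u^j - u), j = 2, 3, ...; for
#' \code{kind="sinusoidal"} it is g(u) = u + a * sin(2*pi*f*u) with
#' coefficients (a, f), f a positive integer.
#' @export
setClass("ChirpModel",
  representation(kind = "character", coefficients = "numeric"),
  validity = function(object) {
    if (!object@kind %in% c("linear", "polynomial", "sinusoidal"))
      return("kind must be linear, polynomial or sinusoidal")
    TRUE
  })

#' @param kind,coefficients see class description.
#' @rdname ChirpModel-class
#' @export
chirpModel <- function(kind = c("linear", "polynomial", "sinusoidal"),
                       coefficients = numeric(0)) {
  new("ChirpModel", kind = match.arg(kind), coefficients = coefficients)
}

#' Source envelope and ASE contrast model
#'
#' The source power envelope S(k) and the interference-contrast curve
#' alpha(k) in (0, 1].  Towards the sweep ends the laser emits incoherent
#' amplified spontaneous emission (ASE): a background b(k) is added to the
#' DC level and the fringe amplitude is multiplied by
#' alpha(k) = 1 - (1 - ase_contrast_floor) * edge_ramp(k), so alpha is the
#' literal ground truth the contrast estimator must recover.
#'
#' @slot shape "rectangular" or "rounded" (raised-cosine edges).
#' @slot ase_edge_fraction fraction of the sweep at each end over which the
#'   ASE ramp rises (0 disables ASE).
#' @slot ase_contrast_floor contrast remaining at the extreme sweep ends.
#' @slot ase_background_level DC background added at full ramp, relative to
#'   unit fringe amplitude.
#' @export
setClass("EnvelopeModel",
  representation(shape = "character", ase_edge_fraction = "numeric",
                 ase_contrast_floor = "numeric",
                 ase_background_level = "numeric"),
  validity = function(object) {
    if (!object@shape %in% c("rectangular", "rounded"))
      return("shape must be 'rectangular' or 'rounded'")
    if (object@ase_edge_fraction < 0 || object@ase_edge_fraction > 0.3)
      return("ase_edge_fraction must be in [0, 0.3]")
    if (object@ase_contrast_floor <= 0 || object@ase_contrast_floor > 1)
      return("ase_contrast_floor must be in (0, 1]")
    TRUE
  })

#' @param shape,ase_edge_fraction,ase_contrast_floor,ase_background_level
#'   see slots.
#' @rdname EnvelopeModel-class
#' @export
envelopeModel <- function(shape = c("rectangular", "rounded"),
                          ase_edge_fraction = 0,
                          ase_contrast_floor = 1,
                          ase_background_level = 0.5) {
  new("EnvelopeModel", shape = match.arg(shape),
      ase_edge_fraction = ase_edge_fraction,
      ase_contrast_floor = ase_contrast_floor,
      ase_background_level = ase_background_level)
}

#' Scattering phantom
#'
#' Discrete-layer scattering potential eta(z) = sum_l A_l delta(z - z_l).
#' Amplitudes are either one number per layer (laterally uniform) or an
#' (nx, ny, n_layers) array.
#'
#' @slot kind "mirror" (single layer), "layered" or "volumetric".
#' @slot depths optical depths in um (air): one per layer, or an
#'   (nx, ny, n_layers) array giving each lateral position its own layer
#'   depths (a distributed scatterer).
#' @slot amplitudes non-negative layer amplitudes: one per layer or an
#'   (nx, ny, n_layers) array.
#' @slot lateral_size c(nx, ny).
#' @export
setClass("ScatteringPhantom",
  representation(kind = "character", depths = "numericOrArray",
                 amplitudes = "numericOrArray", lateral_size = "integer"),
  validity = function(object) {
    if (any(object@depths < 0)) return("depths must be non-negative")
    if (any(object@amplitudes < 0)) return("amplitudes must be non-negative")
    nl <- .n_layers(object)
    for (slot in c("depths", "amplitudes")) {
      v <- slot(object, slot)
      if (is.array(v) && length(dim(v)) == 3) {
        d <- dim(v)
        if (!all(d[1:2] == object@lateral_size))
          return(sprintf("%s array lateral dims must match lateral_size", slot))
        if (d[3] != nl) return("depths/amplitudes layer counts differ")
      } else if (length(v) != nl) {
        return("one amplitude per depth required")
      }
    }
    TRUE
  })

## layer count of a phantom (third dim of whichever field is an array)
.n_layers <- function(ph) {
  if (is.array(ph@depths) && length(dim(ph@depths)) == 3)
    dim(ph@depths)[3]
  else length(ph@depths)
}

#' @param depths,amplitudes,lateral_size see slots.
#' @rdname ScatteringPhantom-class
#' @export
mirrorPhantom <- function(depths, amplitudes = rep(1, length(depths)),
                          lateral_size = c(1L, 1L)) {
  kind <- if (length(depths) == 1L) "mirror" else "layered"
  new("ScatteringPhantom", kind = kind, depths = depths,
      amplitudes = amplitudes, lateral_size = as.integer(lateral_size))
}

#' @describeIn ScatteringPhantom-class Seeded random distributed scatterer:
#'   every lateral position gets \code{n_layers} layers at independent
#'   uniform depths in \code{z_range} with independent uniform amplitudes,
#'   so neighbouring A-lines decorrelate as in tissue speckle.
#' @param n_layers layers per lateral position.
#' @param z_range c(lo, hi) depth range in um.
#' @param seed RNG seed.
#' @export
randomScatteringPhantom <- function(lateral_size, n_layers, z_range,
                                    seed = 1L) {
  set.seed(seed)
  nx <- lateral_size[1]; ny <- lateral_size[2]
  zs <- array(stats::runif(nx * ny * n_layers, z_range[1], z_range[2]),
              dim = c(nx, ny, n_layers))
  am <- array(stats::runif(nx * ny * n_layers, 0.1, 1),
              dim = c(nx, ny, n_layers))
  new("ScatteringPhantom", kind = "volumetric", depths = zs,
      amplitudes = am, lateral_size = as.integer(lateral_size))
}

#' Per-session disturbances
#'
#' Spectral-phase and noise disturbances applied by the simulator.  With
#' all fields zero the generated sweep is the pure mirror fringe
#' S(k(t)) * cos(2 k(t) z0).
#'
#' @slot dispersion_coeffs coefficients c_j (j >= 2) of the polynomial
#'   spectral phase sum_j c_j (k - k0)^j in rad/(rad/um)^j.
#' @slot bulk_motion per-volume axial displacement in um (adds phase 2 k dz).
#' @slot phase_offset per-volume constant phase in rad applied to every
#'   laser after the first (the inter-sweep phase jump the stitcher must
#'   recover); recycled over volumes.
#' @slot noise_sigma additive white Gaussian noise sd relative to the summed
#'   fringe amplitude.
#' @slot seed integer RNG seed.
#' @export
setClass("DisturbanceModel",
  representation(dispersion_coeffs = "numeric", bulk_motion = "numeric",
                 phase_offset = "numeric", noise_sigma = "numeric",
                 seed = "integer"),
  validity = function(object) {
    if (object@noise_sigma < 0) return("noise_sigma must be >= 0")
    TRUE
  })

#' @param dispersion_coeffs,bulk_motion,phase_offset,noise_sigma,seed see
#'   slots.
#' @rdname DisturbanceModel-class
#' @export
disturbanceModel <- function(dispersion_coeffs = numeric(0),
                             bulk_motion = 0, phase_offset = 0,
                             noise_sigma = 0, seed = 1L) {
  new("DisturbanceModel", dispersion_coeffs = dispersion_coeffs,
      bulk_motion = bulk_motion, phase_offset = phase_offset,
      noise_sigma = noise_sigma, seed = as.integer(seed))
}

#' Raw spectral frame stack for one laser sweep
#'
#' @slot frames real (nx, ny, n_frames) array I(x, y, t).
#' @slot laser the \linkS4class{LaserSpec}.
#' @slot discard_head,discard_tail frames already dropped at sweep start/stop.
#' @slot volume_index acquisition volume this sweep belongs to.
#' @export
setClass("RawSweep",
  representation(frames = "array", laser = "LaserSpec",
                 discard_head = "integer", discard_tail = "integer",
                 volume_index = "integer"),
  validity = function(object) {
    if (length(dim(object@frames)) != 3L)
      return("frames must be a 3-d array (nx, ny, t)")
    if (dim(object@frames)[3] < 16L)
      return("fewer than 16 retained frames")
    TRUE
  })

#' Sampled chirp curve k_m(t)
#'
#' @slot laser_id laser this curve calibrates.
#' @slot k_of_t wavenumber at each retained frame, rad/um, strictly
#'   monotonic.
#' @slot anchoring endpoint convention (nominal sweep endpoints).
#' @export
setClass("ChirpCurve",
  representation(laser_id = "character", k_of_t = "numeric",
                 anchoring = "character"),
  validity = function(object) {
    d <- diff(object@k_of_t)
    if (!(all(d > 0) || all(d < 0))) {
      bad <- which(sign(d) != sign(d[1]) | d == 0)[1]
      return(sprintf("k(t) not strictly monotonic (first violation at frame %d)",
                     bad + 1L))
    }
    TRUE
  })

#' Complex spectrum on a uniform wavenumber grid
#'
#' @slot data complex (nx, ny, N) array, k ascending along the third axis.
#' @slot k_start wavenumber of the first pixel, rad/um.
#' @slot dk pixel size, rad/um (identical across lasers after calibration).
#' @slot laser_id originating laser ("stitched" for combined spectra).
#' @export
setClass("AnalyticSpectrum",
  representation(data = "array", k_start = "numeric", dk = "numeric",
                 laser_id = "character"),
  validity = function(object) {
    if (length(dim(object@data)) != 3L)
      return("data must be a 3-d complex array (nx, ny, N)")
    if (object@dk <= 0) return("dk must be > 0")
    TRUE
  })

#' Envelope / interference-contrast correction for one laser
#'
#' Gamma(k) is the envelope estimate (sum over lateral positions of the
#' analytic-signal magnitude), alpha(k) = Gamma/Gamma_max the interference
#' contrast, floored at a small epsilon so division is always safe.
#' @export
setClass("EnvelopeCorrection",
  representation(laser_id = "character", gamma = "numeric",
                 alpha = "numeric", gamma_max = "numeric",
                 mode = "character", floor_eps = "numeric"),
  validity = function(object) {
    if (abs(max(object@alpha) - 1) > 1e-12) return("max(alpha) must be 1")
    if (any(object@alpha < object@floor_eps - 1e-12))
      return("alpha fell below its floor")
    if (!object@mode %in% c("scattering", "reflecting"))
      return("mode must be 'scattering' or 'reflecting'")
    TRUE
  })

#' Subpixel overlap estimate between two adjacent lasers
#'
#' @slot kappa fractional-pixel overlap (argmax of the summed normalized
#'   cross-correlation within the physical search window).
#' @slot rho0 summed normalized cross-correlation on the 0.01-px grid.
#' @slot lag_grid lag (px) for each rho0 sample.
#' @slot depths_used calibration mirror depths z_n (um).
#' @slot n_depths number of depths summed.
#' @slot search_window pixel interval searched.
#' @slot boundary logical, TRUE when the argmax hit the window boundary
#'   (estimate unreliable).
#' @export
setClass("OverlapEstimate",
  representation(kappa = "numeric", rho0 = "numeric", lag_grid = "numeric",
                 depths_used = "numeric", n_depths = "integer",
                 search_window = "numeric", boundary = "logical"),
  validity = function(object) {
    if (object@kappa < object@search_window[1] - 1e-9 ||
        object@kappa > object@search_window[2] + 1e-9)
      return("kappa outside its search window")
    TRUE
  })

#' One-time system calibration
#'
#' Per-laser chirp curves and envelope corrections, the common wavenumber
#' pixel size dk, and the subpixel overlap for every adjacent laser pair,
#' ordered along ascending wavenumber.
#' @export
setClass("SystemCalibration",
  representation(lasers = "list", chirps = "list", envelopes = "list",
                 dk = "numeric", kappa = "numeric", meta = "list"),
  validity = function(object) {
    nl <- length(object@lasers)
    if (length(object@chirps) != nl)
      return("one chirp curve per laser required")
    if (nl >= 2 && length(object@kappa) != nl - 1)
      return("one overlap per adjacent laser pair required")
    TRUE
  })

#' Simulated acquisition session with ground truth
#'
#' @slot lasers list of \linkS4class{LaserSpec}.
#' @slot raw list: one entry per laser, each a list of
#'   \linkS4class{RawSweep} (one per volume / calibration depth).
#' @slot truth list of ground-truth fields (chirp curves, alpha curves,
#'   kappa, depths, per-volume motion and phase offsets, phantom, seed);
#'   sufficient to predict every pipeline estimate in the noiseless case.
#' @export
setClass("SimulatedSession",
  representation(lasers = "list", raw = "list", truth = "list"))

#' Motion/dispersion spectral phase for one volume and laser
#'
#' Coefficients of the polynomial spectral phase over the normalized
#' wavenumber offset u = (k - k0)/k_half in [-1, 1]; orders 0..1 are left to
#' registration and the phase-offset search, orders >= 2 are the in-volume
#' motion + dispersion terms removed by \code{correctMotionPhase}.
#' @export
setClass("MotionPhase",
  representation(volume_index = "integer", laser_id = "character",
                 coefficients = "numeric", k0 = "numeric",
                 k_half = "numeric", converged = "logical"))

#' Per-bin phase offsets found by the sharpness-metric grid search
#' @export
setClass("PhaseOffsetField",
  representation(offsets = "matrix", bin_size = "integer",
                 metric_gamma = "numeric", pad_factor = "integer",
                 flagged = "matrix"),
  validity = function(object) {
    if (any(object@offsets < 0 | object@offsets >= 2 * pi))
      return("offsets must be wrapped to [0, 2*pi)")
    TRUE
  })

#' Stitching plan for an ordered laser chain
#' @export
setClass("StitchPlan",
  representation(laser_order = "character", kappa = "numeric",
                 weight_kind = "character", apod_kind = "character",
                 apod_ratio = "numeric"),
  validity = function(object) {
    if (!object@weight_kind %in% "linear")
      return("only linear blend weights are implemented")
    if (!object@apod_kind %in% c("none", "tukey"))
      return("apod_kind must be 'none' or 'tukey'")
    TRUE
  })

#' @param laser_order,kappa,weight_kind,apod_kind,apod_ratio see slots.
#' @rdname StitchPlan-class
#' @export
stitchPlan <- function(laser_order, kappa, weight_kind = "linear",
                       apod_kind = "none", apod_ratio = 0.5) {
  new("StitchPlan", laser_order = laser_order, kappa = kappa,
      weight_kind = weight_kind, apod_kind = apod_kind,
      apod_ratio = apod_ratio)
}

#' Reconstructed complex depth volume
#'
#' @slot data complex (nx, ny, nz) array U(x, y, z).
#' @slot z_pixel depth pixel size in um (air).
#' @slot meta provenance (plan, calibration ids, padding).
#' @export
setClass("ReconVolume",
  representation(data = "array", z_pixel = "numeric", meta = "list"))

#' Axial PSF diagnostics for one point response
#'
#' @slot depth peak depth in um.
#' @slot fwhm -6 dB (intensity) full width at half maximum of the
#'   magnitude, um.
#' @slot sidelobe_left_db,sidelobe_right_db highest sidelobe each side, dB
#'   intensity relative to the main-lobe peak (<= 0).
#' @slot pad_factor zero-padding used for sub-pixel interpolation.
#' @export
setClass("PSFReport",
  representation(depth = "numeric", fwhm = "numeric",
                 sidelobe_left_db = "numeric", sidelobe_right_db = "numeric",
                 pad_factor = "integer"),
  validity = function(object) {
    if (object@fwhm <= 0) return("fwhm must be > 0")
    if (object@sidelobe_left_db > 1e-9 || object@sidelobe_right_db > 1e-9)
      return("sidelobe levels must be <= 0 dB")
    TRUE
  })
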