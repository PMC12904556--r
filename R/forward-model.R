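## Forward simulator: chirped spectral interferograms with known ground
## truth for every quantity the calibration and reconstruction estimate.

## Nominal sweep endpoints in rad/um, ordered along time per the sweep
## direction.
.sweep_endpoints <- function(spec) {
  k_lo <- .lambda_to_k(spec@lambda_max)
  k_hi <- .lambda_to_k(spec@lambda_min)
  if (spec@sweep_direction == "increasing_k") c(k_lo, k_hi) else c(k_hi, k_lo)
}

## Normalized sweep profile g(u), g(0) = 0, g(1) = 1.
.chirp_profile <- function(model, u) {
  switch(model@kind,
    linear = u,
    polynomial = {
      g <- u
      cf <- model@coefficients
      for (j in seq_along(cf)) g <- g + cf[j] * (u^(j + 1) - u)
      g
    },
    sinusoidal = {
      a <- model@coefficients[1]
      f <- if (length(model@coefficients) >= 2) model@coefficients[2] else 1
      u + a * sin(2 * pi * f * u)
    })
}

#' Sample a chirp model at every frame of a sweep
#'
#' Evaluates the (possibly non-linear) frame-to-wavenumber mapping k(t) of a
#' laser sweep at each frame index, with the endpoints anchored exactly to
#' the nominal sweep wavenumbers 2*pi/lambda_max and 2*pi/lambda_min.
#'
#' @param spec a \linkS4class{LaserSpec}.
#' @param model a \linkS4class{ChirpModel}.
#' @param margin head/tail frame counts lying OUTSIDE the nominal sweep
#'   range (default none).  The nominal range is interpreted as the usable
#'   sweep: frames discarded for start/stop uncertainty sit beyond the
#'   nominal endpoints, so after trimming \code{margin} frames the retained
#'   sweep spans the nominal wavelengths exactly.
#' @return a \linkS4class{ChirpCurve}; non-monotonic models are rejected
#'   with a diagnostic naming the first violating frame.
#' @examples
#' sp <- laserSpec("laser840", 805, 882, 515)
#' cc <- buildChirpCurve(sp, chirpModel("linear"))
#' range(kGrid(cc)) * 1e-3 / (2 * pi)  # 1/882, 1/805 in nm^-1
#' @export
buildChirpCurve <- function(spec, model, margin = c(0L, 0L)) {
  n <- spec@n_frames
  denom <- n - 1L - margin[1] - margin[2]
  stopifnot(denom >= 15L)
  u <- (seq_len(n) - 1L - margin[1]) / denom
  g <- .chirp_profile(model, u)
  ends <- .sweep_endpoints(spec)
  k <- ends[1] + (ends[2] - ends[1]) * g
  new("ChirpCurve", laser_id = spec@laser_id, k_of_t = k,
      anchoring = "nominal-endpoints")
}

## Envelope/ASE curves over the sweep (u = frame fraction in [0, 1]):
## source power S, interference contrast alpha, additive ASE background b.
.envelope_curves <- function(env, n) {
  u <- seq(0, 1, length.out = n)
  S <- switch(env@shape,
    rectangular = rep(1, n),
    rounded = tukeyWindow(n, 0.2))
  a <- env@ase_edge_fraction
  ramp <- numeric(n)
  if (a > 0) {
    lo <- u < a
    hi <- u > 1 - a
    ramp[lo] <- 0.5 * (1 + cos(pi * u[lo] / a))
    ramp[hi] <- 0.5 * (1 + cos(pi * (1 - u[hi]) / a))
  }
  alpha <- 1 - (1 - env@ase_contrast_floor) * ramp
  list(S = S, alpha = alpha, b = env@ase_background_level * ramp)
}

## Largest local k step of a chirp curve -> most restrictive Nyquist depth.
.nyquist_depth <- function(k_of_t) pi / (2 * max(abs(diff(k_of_t))))

## Per-pixel map of a phantom field (amplitudes or depths) for layer l.
.layer_field <- function(v, l, nlat) {
  if (is.array(v) && length(dim(v)) == 3) as.vector(v[, , l])
  else rep(v[l], nlat)
}

#' Simulate one raw laser sweep
#'
#' Generates the real-valued frame stack I(x, y, t) recorded by the camera
#' while the laser sweeps: each frame holds
#' DC + b(k) + alpha(k) S(k) sum_l A_l(x, y) cos(2 k(t) z_l + phi(k(t)))
#' plus optional white detector noise, where phi collects dispersion, bulk
#' axial motion (2 k dz) and a constant inter-sweep phase offset.  With all
#' disturbances zero the sweep is the pure mirror interferogram.
#'
#' @param spec a \linkS4class{LaserSpec}.
#' @param chirp a \linkS4class{ChirpCurve} matching \code{spec}.
#' @param envelope an \linkS4class{EnvelopeModel}.
#' @param phantom a \linkS4class{ScatteringPhantom}; depths must stay below
#'   the Nyquist depth implied by the largest local k step.
#' @param disturb a \linkS4class{DisturbanceModel}.
#' @param volume_index volume label stored in the sweep.
#' @param include_dc add the DC level (sum of layer amplitudes); disable for
#'   idealized pre-subtracted signals.
#' @param rng_seed seed for the noise draw (default derived from
#'   \code{disturb@seed} and \code{volume_index}).
#' @return a \linkS4class{RawSweep}.
#' @export
simulateSweep <- function(spec, chirp, envelope, phantom,
                          disturb = disturbanceModel(),
                          volume_index = 1L, include_dc = TRUE,
                          rng_seed = NULL) {
  stopifnot(is(spec, "LaserSpec"), is(chirp, "ChirpCurve"),
            is(phantom, "ScatteringPhantom"))
  k <- chirp@k_of_t
  nt <- length(k)
  if (nt != spec@n_frames)
    stop("chirp curve length does not match spec n_frames")
  zmax <- .nyquist_depth(k)
  if (any(phantom@depths >= zmax))
    stop(sprintf(
      "phantom depth %.1f um at or above the Nyquist depth %.1f um; aliasing would invalidate calibration",
      max(phantom@depths), zmax))
  nx <- phantom@lateral_size[1]; ny <- phantom@lateral_size[2]
  env <- .envelope_curves(envelope, nt)

  ## disturbance phase over the sweep
  k0 <- mean(range(k))
  phi <- rep(disturb@phase_offset[1], nt)
  dz <- disturb@bulk_motion[1]
  phi <- phi + 2 * k * dz
  cf <- disturb@dispersion_coeffs
  for (j in seq_along(cf)) phi <- phi + cf[j] * (k - k0)^(j + 1)

  amp_scale <- env$alpha * env$S                   # nt vector
  nlat <- nx * ny
  sig <- matrix(0, nt, nlat)
  uniform_z <- !is.array(phantom@depths) || length(dim(phantom@depths)) != 3
  for (l in seq_len(.n_layers(phantom))) {
    amps <- .layer_field(phantom@amplitudes, l, nlat)
    if (uniform_z) {
      co <- amp_scale * cos(2 * k * phantom@depths[l] + phi)
      sig <- sig + outer(co, amps)
    } else {
      zl <- .layer_field(phantom@depths, l, nlat)
      sig <- sig + amp_scale *
        cos(outer(2 * k, zl) + phi) * rep(amps, each = nt)
    }
  }
  a_tot <- sum(abs(if (is.array(phantom@amplitudes))
    apply(phantom@amplitudes, 3, max) else phantom@amplitudes))
  if (include_dc) sig <- sig + (a_tot + env$b)
  if (disturb@noise_sigma > 0) {
    if (is.null(rng_seed))
      rng_seed <- (disturb@seed + 7919L * as.integer(volume_index)) %% .Machine$integer.max
    set.seed(rng_seed)
    sig <- sig + matrix(stats::rnorm(nt * nx * ny, sd = disturb@noise_sigma * a_tot),
                        nt, nx * ny)
  }
  new("RawSweep", frames = .mat_to_cube(sig, nx, ny), laser = spec,
      discard_head = 0L, discard_tail = 0L,
      volume_index = as.integer(volume_index))
}

## Per-laser uniform-k grids at a common dk (reference = first laser in the
## user-supplied list, after trimming), plus the ground-truth fractional
## overlap for each adjacent pair along ascending k.  Returns grids in the
## user-supplied laser order; kappa follows ascending-k adjacency.
.common_grids <- function(lasers, trim = c(8L, 8L)) {
  spans <- lapply(lasers, function(sp) {
    k_lo <- .lambda_to_k(sp@lambda_max); k_hi <- .lambda_to_k(sp@lambda_min)
    c(k_lo, k_hi)
  })
  n_ret <- vapply(lasers, function(sp)
    as.integer(sp@n_frames - sum(trim)), 0L)
  ref_span <- spans[[1]][2] - spans[[1]][1]
  dk <- ref_span / (n_ret[1] - 1)
  grids <- vector("list", length(lasers))
  for (i in seq_along(lasers)) {
    if (i == 1L) N <- n_ret[1]
    else N <- floor((spans[[i]][2] - spans[[i]][1]) / dk + 1e-9) + 1L
    grids[[i]] <- list(k_start = spans[[i]][1], N = as.integer(N), dk = dk,
                       laser_id = lasers[[i]]@laser_id)
  }
  ord <- order(vapply(grids, function(g) g$k_start, 0))
  kappa <- numeric(0)
  if (length(lasers) >= 2) {
    kappa <- vapply(seq_len(length(lasers) - 1), function(j) {
      lo <- grids[[ord[j]]]; hi <- grids[[ord[j + 1]]]
      k_end_lo <- lo$k_start + (lo$N - 1) * dk
      (k_end_lo - hi$k_start) / dk + 1
    }, 0)
  }
  list(grids = grids, dk = dk, order = ord, kappa = kappa)
}

#' Simulate a full calibration session
#'
#' Emulates the one-time calibration acquisition: for every laser and every
#' mirror depth z_n one sweep is recorded from a stable single-mirror
#' interferometer.  The ground-truth chirp curves, contrast curves and the
#' fractional pixel overlap kappa on the common dk grid (the number of
#' uniform-grid pixels shared by adjacent lasers' k ranges) are stored in
#' the session truth.
#'
#' @param lasers list of \linkS4class{LaserSpec} (first laser defines the
#'   common dk after trimming).
#' @param chirp_models one \linkS4class{ChirpModel} per laser (recycled if
#'   length 1).
#' @param envelopes one \linkS4class{EnvelopeModel} per laser (recycled).
#' @param depths mirror depths z_n in um; at least 2 for later overlap
#'   calibration.
#' @param noise_sigma detector noise level (0 = noiseless).
#' @param seed RNG seed for noise.
#' @param lateral_size lateral frame size (kept small; calibration averages
#'   all A-lines anyway).
#' @param trim head/tail discard counts assumed by the truth-kappa grid.
#' @param include_background also record one sample-free sweep per laser
#'   (DC + ASE background), stored in the session truth and used as the
#'   background reference downstream.
#' @return a \linkS4class{SimulatedSession}.
#' @export
simulateCalibrationSet <- function(lasers, chirp_models, envelopes, depths,
                                   noise_sigma = 0, seed = 1L,
                                   lateral_size = c(2L, 2L),
                                   trim = c(8L, 8L),
                                   include_background = TRUE) {
  if (length(depths) < 2L)
    stop("at least 2 mirror depths are required for overlap calibration")
  if (anyDuplicated(depths)) stop("depths must be pairwise distinct")
  nl <- length(lasers)
  chirp_models <- rep(chirp_models, length.out = nl)
  envelopes <- rep(envelopes, length.out = nl)
  chirps <- mapply(buildChirpCurve, lasers, chirp_models,
                   MoreArgs = list(margin = trim), SIMPLIFY = FALSE)
  cg <- .common_grids(lasers, trim = trim)
  raw <- vector("list", nl)
  names(raw) <- vapply(lasers, function(l) l@laser_id, "")
  for (i in seq_len(nl)) {
    raw[[i]] <- lapply(seq_along(depths), function(n) {
      ph <- mirrorPhantom(depths[n], lateral_size = lateral_size)
      db <- disturbanceModel(noise_sigma = noise_sigma,
                             seed = seed + 131L * i)
      simulateSweep(lasers[[i]], chirps[[i]], envelopes[[i]], ph,
                    disturb = db, volume_index = n)
    })
  }
  alpha <- lapply(seq_len(nl), function(i)
    .envelope_curves(envelopes[[i]], lasers[[i]]@n_frames)$alpha)
  names(alpha) <- names(raw)
  bg <- NULL
  if (include_background) {
    ## sample-free acquisition per laser: captures DC + ASE background
    bg <- lapply(seq_len(nl), function(i) {
      ph <- mirrorPhantom(depths[1], amplitudes = 0,
                          lateral_size = lateral_size)
      db <- disturbanceModel(noise_sigma = noise_sigma,
                             seed = seed + 977L * i)
      simulateSweep(lasers[[i]], chirps[[i]], envelopes[[i]], ph,
                    disturb = db, volume_index = 0L)
    })
    names(bg) <- names(raw)
  }
  new("SimulatedSession", lasers = lasers, raw = raw,
      truth = list(kind = "calibration", chirps = chirps, alpha = alpha,
                   depths = depths, kappa = cg$kappa, dk = cg$dk,
                   grids = cg$grids, k_order = cg$order, trim = trim,
                   noise_sigma = noise_sigma, seed = seed,
                   background = bg))
}

#' Default calibration mirror depths
#'
#' Log-spaced over [10%, 80%] of the most restrictive Nyquist depth of the
#' laser set, with a small seeded jitter so no depth is an integer multiple
#' of another (harmonic depths make the summed cross-correlation ambiguous).
#'
#' @param lasers list of \linkS4class{LaserSpec}.
#' @param chirp_models matching chirp models (default linear).
#' @param n number of depths.
#' @param seed jitter seed.
#' @export
defaultCalibrationDepths <- function(lasers, chirp_models = NULL, n = 6L,
                                     seed = 1L) {
  if (is.null(chirp_models))
    chirp_models <- rep(list(chirpModel("linear")), length(lasers))
  chirp_models <- rep(chirp_models, length.out = length(lasers))
  zn <- min(vapply(seq_along(lasers), function(i)
    .nyquist_depth(buildChirpCurve(lasers[[i]], chirp_models[[i]])@k_of_t), 0))
  set.seed(seed)
  z <- exp(seq(log(0.1 * zn), log(0.8 * zn), length.out = n))
  z <- z * stats::runif(n, 0.97, 1.03)
  ## nudge any pair whose ratio is within 2.5% of an integer: harmonic
  ## depths make the summed cross-correlation ambiguous
  for (iter in 1:20) {
    rat <- outer(z, z, function(x, y) pmax(x, y) / pmin(x, y))
    bad <- abs(rat - round(rat)) < 0.025 & round(rat) > 1
    if (!any(bad)) break
    i <- which(bad, arr.ind = TRUE)[1, ]
    z[max(i)] <- z[max(i)] * 1.045
  }
  sort(z)
}

#' Simulate a sample measurement session
#'
#' Generates \code{n_volumes} volumes, each with one sweep per laser,
#' carrying per-volume disturbances: bulk axial motion (recycled from
#' \code{disturb@bulk_motion}), a constant inter-sweep phase offset applied
#' to every laser after the first (recycled from \code{disturb@phase_offset})
#' and independent detector noise.  Truth records every per-volume draw.
#'
#' @inheritParams simulateCalibrationSet
#' @param phantom the \linkS4class{ScatteringPhantom} imaged in every volume.
#' @param n_volumes number of volumes (>= 1).
#' @param disturb a \linkS4class{DisturbanceModel}.
#' @return a \linkS4class{SimulatedSession}.
#' @export
simulateSampleSession <- function(lasers, chirp_models, envelopes, phantom,
                                  n_volumes = 1L,
                                  disturb = disturbanceModel(),
                                  seed = NULL, trim = c(8L, 8L),
                                  include_background = TRUE) {
  stopifnot(n_volumes >= 1L)
  nl <- length(lasers)
  chirp_models <- rep(chirp_models, length.out = nl)
  envelopes <- rep(envelopes, length.out = nl)
  chirps <- mapply(buildChirpCurve, lasers, chirp_models,
                   MoreArgs = list(margin = trim), SIMPLIFY = FALSE)
  if (is.null(seed)) seed <- disturb@seed
  dzs <- rep(disturb@bulk_motion, length.out = n_volumes)
  phis <- rep(disturb@phase_offset, length.out = n_volumes)
  cg <- .common_grids(lasers, trim = trim)
  raw <- vector("list", nl)
  names(raw) <- vapply(lasers, function(l) l@laser_id, "")
  for (i in seq_len(nl)) {
    raw[[i]] <- lapply(seq_len(n_volumes), function(v) {
      db <- new("DisturbanceModel",
                dispersion_coeffs = disturb@dispersion_coeffs,
                bulk_motion = dzs[v],
                phase_offset = if (i == 1L) 0 else phis[v],
                noise_sigma = disturb@noise_sigma,
                seed = as.integer(seed))
      simulateSweep(lasers[[i]], chirps[[i]], envelopes[[i]], phantom,
                    disturb = db, volume_index = v,
                    rng_seed = (seed + 7919L * v + 104729L * i) %%
                      .Machine$integer.max)
    })
  }
  alpha <- lapply(seq_len(nl), function(i)
    .envelope_curves(envelopes[[i]], lasers[[i]]@n_frames)$alpha)
  names(alpha) <- names(raw)
  bg <- NULL
  if (include_background) {
    bg <- lapply(seq_len(nl), function(i) {
      ph0 <- mirrorPhantom(1, amplitudes = 0,
                           lateral_size = phantom@lateral_size)
      db <- disturbanceModel(noise_sigma = disturb@noise_sigma,
                             seed = as.integer(seed) + 977L * i)
      simulateSweep(lasers[[i]], chirps[[i]], envelopes[[i]], ph0,
                    disturb = db, volume_index = 0L)
    })
    names(bg) <- names(raw)
  }
  new("SimulatedSession", lasers = lasers, raw = raw,
      truth = list(kind = "sample", chirps = chirps, alpha = alpha,
                   background = bg,
                   bulk_motion = dzs, phase_offsets = phis,
                   dispersion_coeffs = disturb@dispersion_coeffs,
                   phantom = phantom, kappa = cg$kappa, dk = cg$dk,
                   grids = cg$grids, k_order = cg$order, trim = trim,
                   noise_sigma = disturb@noise_sigma, seed = seed))
}
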