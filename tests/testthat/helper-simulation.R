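## Shared fixtures: everything is generated in code at test time.

## the dual-laser system used throughout (805-882 nm / 879-950 nm)
dual_lasers <- dualLaserSpecs()

## mildly non-linear chirps: a few percent, different per laser
dual_chirps <- list(chirpModel("polynomial", 0.05),
                    chirpModel("polynomial", c(0.04, 0.02)))

flat_envs <- list(envelopeModel(), envelopeModel())

## one calibration session + calibration, reused across test files via a
## per-session cache (simulation and calibration are deterministic)
.cache <- new.env(parent = emptyenv())

cached_calibration <- function() {
  if (is.null(.cache$cal)) {
    depths <- defaultCalibrationDepths(dual_lasers, dual_chirps,
                                       n = 6L, seed = 3L)
    ses <- simulateCalibrationSet(dual_lasers, dual_chirps, flat_envs,
                                  depths, lateral_size = c(2L, 2L))
    .cache$ses <- ses
    .cache$cal <- calibrateSession(ses)
  }
  list(session = .cache$ses, result = .cache$cal)
}

## ideal k-linear spectrum pair with an exactly known overlap
ideal_pair <- function(depth, kappa = 24, n_a = 515L, n_b = 478L,
                       dk = 1.3257e-3, k_a0 = 6.61) {
  k_b0 <- k_a0 + (n_a - kappa) * dk
  list(a = mirrorSpectrum(k_a0, dk, n_a, depth, laser_id = "a"),
       b = mirrorSpectrum(k_b0, dk, n_b, depth, laser_id = "b"),
       kappa = kappa, dk = dk)
}

## brute-force circular cross-correlation oracle (direct sum)
direct_xcorr <- function(a, b) {
  n <- length(a)
  vapply(0:(n - 1), function(l)
    sum(b * Conj(a[((seq_len(n) - 1 - l) %% n) + 1])), complex(1))
}

expect_phase_close <- function(hat, truth, tol) {
  d <- (hat - truth) %% (2 * pi)
  expect_lt(min(d, 2 * pi - d), tol)
}
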