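test_that("linear chirp is an arithmetic progression between the nominal endpoints", {
  sp <- laserSpec("laser840", 805, 882, 515L, "increasing_k")
  cc <- buildChirpCurve(sp, chirpModel("linear"))
  k <- kGrid(cc)
  expect_equal(k[1], 2 * pi * 1e3 / 882)
  expect_equal(k[515], 2 * pi * 1e3 / 805)
  expect_equal(diff(k), rep(diff(k)[1], 514))

  ## decreasing sweep runs the other way
  cc2 <- buildChirpCurve(laserSpec("l", 805, 882, 515L, "decreasing_k"),
                         chirpModel("linear"))
  expect_equal(kGrid(cc2), rev(k))
})

test_that("a polynomial model with zero coefficients reduces to the linear chirp", {
  sp <- laserSpec("l", 805, 882, 515L)
  expect_equal(kGrid(buildChirpCurve(sp, chirpModel("polynomial", c(0, 0)))),
               kGrid(buildChirpCurve(sp, chirpModel("linear"))))
})

test_that("sinusoidal perturbation attains its closed-form extremum", {
  sp <- laserSpec("l", 805, 882, 515L, "increasing_k")
  a <- 0.01
  klin <- kGrid(buildChirpCurve(sp, chirpModel("linear")))
  kper <- kGrid(buildChirpCurve(sp, chirpModel("sinusoidal", c(a, 1))))
  span <- abs(klin[515] - klin[1])
  dev <- max(abs(kper - klin))
  ## perturbation a*sin(2*pi*u) peaks at u = 1/4; the frame grid contains
  ## u = 128.5/514, so evaluate the model there
  u <- (which.max(abs(kper - klin)) - 1) / 514
  expect_equal(dev, span * a * abs(sin(2 * pi * u)), tolerance = 1e-12)
  expect_equal(dev, span * a, tolerance = 1e-4)
})

test_that("non-monotonic chirp models are rejected with the violating frame", {
  sp <- laserSpec("l", 805, 882, 64L)
  err <- tryCatch(buildChirpCurve(sp, chirpModel("sinusoidal", c(0.4, 2))),
                  error = conditionMessage)
  expect_match(err, "monotonic")
  expect_match(err, "frame")
})

test_that("a disturbance-free mirror sweep is a pure cosine with affine analytic phase", {
  sp <- laserSpec("l", 805, 882, 256L, "increasing_k")
  cc <- buildChirpCurve(sp, chirpModel("linear"))
  sw <- simulateSweep(sp, cc, envelopeModel(), mirrorPhantom(300),
                      include_dc = FALSE)
  tr <- as.vector(frames(sw))
  expect_equal(tr, cos(2 * kGrid(cc) * 300), tolerance = 1e-12)
  ph <- signal::unwrap(Arg(octstitch:::.analytic(matrix(tr, ncol = 1))[, 1]))
  resid <- stats::lm(ph[20:237] ~ seq_along(ph[20:237]))$residuals
  ## finite-support analytic signal leaves a slowly decaying interior
  ## ripple of a few hundredths of a radian
  expect_lt(max(abs(resid)), 0.05)
})

test_that("the simulator is linear in phantom amplitudes (superposition)", {
  sp <- laserSpec("l", 805, 882, 200L)
  cc <- buildChirpCurve(sp, chirpModel("polynomial", 0.05))
  one <- function(z, a) frames(simulateSweep(sp, cc, envelopeModel(),
    mirrorPhantom(z, a), include_dc = FALSE))
  both <- frames(simulateSweep(sp, cc, envelopeModel(),
    mirrorPhantom(c(210, 333.3), c(1, 0.6)), include_dc = FALSE))
  expect_equal(both, one(210, 1) + one(333.3, 0.6), tolerance = 1e-12)
})

test_that("injected quadratic spectral phase appears exactly in the analytic phase", {
  sp <- laserSpec("l", 805, 882, 400L, "increasing_k")
  cc <- buildChirpCurve(sp, chirpModel("linear"))
  k <- kGrid(cc)
  c2 <- 15
  sw <- simulateSweep(sp, cc, envelopeModel(), mirrorPhantom(350),
                      disturb = disturbanceModel(dispersion_coeffs = c2),
                      include_dc = FALSE)
  ph <- signal::unwrap(Arg(octstitch:::.analytic(
    matrix(as.vector(frames(sw)), ncol = 1))[, 1]))
  k0 <- mean(range(k))
  expected <- 2 * k * 350 + c2 * (k - k0)^2
  idx <- 30:370                              # away from Hilbert edges
  resid <- (ph[idx] - expected[idx]) - mean(ph[idx] - expected[idx])
  expect_lt(max(abs(resid)), 0.02)
})

test_that("phantoms above the Nyquist depth are rejected", {
  sp <- laserSpec("l", 805, 882, 128L)
  cc <- buildChirpCurve(sp, chirpModel("linear"))
  zmax <- pi / (2 * max(abs(diff(kGrid(cc)))))
  expect_error(simulateSweep(sp, cc, envelopeModel(),
                             mirrorPhantom(zmax * 1.01)), "Nyquist")
})

test_that("a mirror at half the Nyquist depth gives an N/4-cycle fringe after regridding", {
  sp <- laserSpec("l", 805, 882, 256L, "increasing_k")
  cc <- buildChirpCurve(sp, chirpModel("polynomial", 0.04))
  dk_u <- abs(diff(range(kGrid(cc)))) / 255
  z <- pi / (2 * dk_u) / 2
  sw <- simulateSweep(sp, cc, envelopeModel(),
                      mirrorPhantom(z, lateral_size = c(1L, 1L)),
                      include_dc = FALSE)
  as <- regridKLinear(sw, cc, dk_u)
  v <- specData(as)[1, 1, ]
  cyc <- sum(diff(signal::unwrap(Arg(v)))) / (2 * pi)
  expect_equal(cyc, length(v) / 4, tolerance = 0.01)
})

test_that("calibration-set truth records the exact grid overlap", {
  ## two lasers whose ranges share exactly 24 common-grid pixels: the
  ## second laser's span is an exact grid multiple ending 23 px above the
  ## first laser's start
  la <- laserSpec("a", 805, 882, 515L)
  dk <- (2 * pi * 1e3 / 805 - 2 * pi * 1e3 / 882) / 498
  k_b_hi <- 2 * pi * 1e3 / 882 + 23 * dk
  k_b_lo <- k_b_hi - 461 * dk               # 462 retained -> 462-px grid
  lb <- laserSpec("b", 2 * pi * 1e3 / k_b_hi, 2 * pi * 1e3 / k_b_lo, 478L)
  ses <- simulateCalibrationSet(list(la, lb), list(chirpModel("linear")),
                                flat_envs, c(150, 420),
                                include_background = FALSE)
  expect_equal(truth(ses)$kappa, 24, tolerance = 1e-9)

  ## identical ranges: full overlap, kappa = N (degenerate)
  ses2 <- simulateCalibrationSet(list(la, laserSpec("b", 805, 882, 515L)),
                                 list(chirpModel("linear")), flat_envs,
                                 c(150, 420), include_background = FALSE)
  expect_equal(truth(ses2)$kappa, 499)

  ## nominal dual-laser system: kappa equals the independent
  ## interval-intersection count on the common grid
  ses3 <- simulateCalibrationSet(dual_lasers, dual_chirps, flat_envs,
                                 c(150, 420), include_background = FALSE)
  k_lo_840 <- 2 * pi * 1e3 / 882
  k_lo_950 <- 2 * pi * 1e3 / 950
  k_hi_950 <- 2 * pi * 1e3 / 879
  dk3 <- truth(ses3)$dk
  n_950 <- floor((k_hi_950 - k_lo_950) / dk3) + 1   # 950-laser grid length
  k_end_950 <- k_lo_950 + (n_950 - 1) * dk3
  expect_equal(truth(ses3)$kappa, (k_end_950 - k_lo_840) / dk3 + 1,
               tolerance = 1e-9)
})

test_that("calibration sets need at least two distinct depths", {
  expect_error(simulateCalibrationSet(dual_lasers, dual_chirps, flat_envs,
                                      depths = 300), "2 mirror depths")
  expect_error(simulateCalibrationSet(dual_lasers, dual_chirps, flat_envs,
                                      depths = c(300, 300)), "distinct")
})

test_that("sample sessions record per-volume truth and reproduce bit-identically", {
  ph <- mirrorPhantom(300, lateral_size = c(2L, 2L))
  db <- disturbanceModel(bulk_motion = c(0, 1.0, -0.5), phase_offset = 1.5,
                         noise_sigma = 0.02, seed = 11L)
  s1 <- simulateSampleSession(dual_lasers, dual_chirps, flat_envs, ph,
                              n_volumes = 3L, disturb = db)
  s2 <- simulateSampleSession(dual_lasers, dual_chirps, flat_envs, ph,
                              n_volumes = 3L, disturb = db)
  expect_identical(frames(rawSweeps(s1, "laser840")[[3]]),
                   frames(rawSweeps(s2, "laser840")[[3]]))
  expect_equal(truth(s1)$bulk_motion, c(0, 1.0, -0.5))

  ## the truth phase ramp between volumes equals 2 k dz on the sweep grid
  db0 <- disturbanceModel(bulk_motion = c(0, 1.0))
  s3 <- simulateSampleSession(dual_lasers, dual_chirps, flat_envs, ph,
                              n_volumes = 2L, disturb = db0)
  k <- kGrid(truth(s3)$chirps[[1]])
  f1 <- frames(rawSweeps(s3, "laser840")[[1]])[1, 1, ]
  f2 <- frames(rawSweeps(s3, "laser840")[[2]])[1, 1, ]
  ## DC level is the summed layer amplitude (flat envelope, no ASE)
  expect_equal(f2 - 1, cos(2 * k * (300 + 1.0)),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(f1 - 1, cos(2 * k * 300), tolerance = 1e-10,
               ignore_attr = TRUE)

  ## one noiseless volume equals a direct simulateSweep
  s4 <- simulateSampleSession(dual_lasers, dual_chirps, flat_envs, ph,
                              n_volumes = 1L)
  direct <- simulateSweep(dual_lasers[[1]],
                          buildChirpCurve(dual_lasers[[1]], dual_chirps[[1]],
                                          margin = c(8L, 8L)),
                          flat_envs[[1]], ph)
  expect_equal(frames(rawSweeps(s4, "laser840")[[1]]), frames(direct))
})
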