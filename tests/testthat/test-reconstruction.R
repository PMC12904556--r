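test_that("background subtraction removes constant offsets and recovers fringes", {
  sp <- laserSpec("l", 805, 882, 128L)
  cc <- buildChirpCurve(sp, chirpModel("linear"))
  const <- new("RawSweep", frames = array(3.7, dim = c(2, 2, 128)),
               laser = sp, discard_head = 0L, discard_tail = 0L,
               volume_index = 1L)
  expect_equal(max(abs(frames(subtractBackground(const)))), 0)

  sw <- simulateSweep(sp, cc, envelopeModel(), mirrorPhantom(60, lateral_size = c(2, 2)))
  fringe <- frames(simulateSweep(sp, cc, envelopeModel(),
                                 mirrorPhantom(60, lateral_size = c(2, 2)),
                                 include_dc = FALSE))
  rec <- frames(subtractBackground(sw))
  ## the temporal mean of the fringe itself is the only residual
  expect_lt(max(abs(rec - (fringe - mean(fringe[1, 1, ])))), 1e-9)

  ## a reference sweep removes a simulated ASE background near-exactly
  env <- envelopeModel(ase_edge_fraction = 0.15, ase_contrast_floor = 0.6)
  swa <- simulateSweep(sp, cc, env, mirrorPhantom(60, lateral_size = c(2, 2)))
  bg <- simulateSweep(sp, cc, env, mirrorPhantom(60, 0, lateral_size = c(2, 2)))
  reca <- frames(subtractBackground(swa, reference = bg))
  fra <- frames(simulateSweep(sp, cc, env, mirrorPhantom(60, lateral_size = c(2, 2)),
                              include_dc = FALSE))
  resid <- reca - (fra - mean(fra[1, 1, ]))
  expect_lt(max(abs(resid)), 0.02)
})

test_that("fractional spectral shifts are exact and invertible", {
  sp <- mirrorSpectrum(7.0, 1.4e-3, 256L, 300)
  expect_equal(specData(shiftSpectrum(sp, 0)), specData(sp),
               tolerance = 1e-12)
  rt <- shiftSpectrum(shiftSpectrum(sp, 17.58), -17.58)
  expect_lt(max(Mod(specData(rt) - specData(sp))), 1e-10)

  ## integer shift equals an index roll away from the edges
  sh <- shiftSpectrum(sp, 3)
  v0 <- specData(sp)[1, 1, ]; v3 <- specData(sh)[1, 1, ]
  expect_equal(v3[10:250], v0[7:247], tolerance = 1e-9)
})

test_that("stitching reassembles a split continuous spectrum", {
  ## one known continuous mirror spectrum cut into two overlapping halves
  dk <- 1.3e-3; n_tot <- 600L; kap <- 20
  full <- mirrorSpectrum(6.6, dk, n_tot, 421.3)
  n_a <- 320L; n_b <- n_tot - n_a + kap
  va <- specData(full)[1, 1, 1:n_a]
  vb <- specData(full)[1, 1, (n_a - kap + 1):n_tot]
  a <- analyticSpectrum(va, 6.6, dk, "a")
  b <- analyticSpectrum(vb, 6.6 + (n_a - kap) * dk, dk, "b")
  st <- stitchSpectra(a, b, phase = 0,
                      plan = stitchPlan(c("a", "b"), kap))
  out <- specData(st)[1, 1, ]
  expect_length(out, n_tot)
  blend <- (n_a - kap + 1):n_a
  rms <- sqrt(mean(Mod(out[blend] - specData(full)[1, 1, blend])^2))
  expect_lt(rms, 0.01)
  expect_lt(max(Mod(out - specData(full)[1, 1, ])), 0.01)

  ## kappa = 0: pure concatenation (with the phase applied to b)
  b0 <- analyticSpectrum(vb, 6.6 + n_a * dk, dk, "b")
  st0 <- stitchSpectra(a, b0, phase = pi / 3,
                       plan = stitchPlan(c("a", "b"), 0))
  out0 <- specData(st0)[1, 1, ]
  expect_length(out0, n_a + n_b)
  expect_equal(out0[1:n_a], va)
  expect_equal(out0[(n_a + 1):(n_a + n_b)], vb * exp(1i * pi / 3))
})

test_that("the blend weight runs from 0 at the seam start to 1 at the seam end", {
  expect_equal(blendWeight(515 - 17.58, 515, 17.58), 0)
  expect_equal(blendWeight(515, 515, 17.58), 1)
  w <- blendWeight(seq(515 - 17.58, 515, length.out = 50), 515, 17.58)
  expect_true(all(diff(w) >= 0))
})

test_that("no amplitude step is left at the stitch seam", {
  sc <- stitchScenario(400)
  st <- stitchSpectra(sc$a, sc$b, 0, sc$plan)
  v <- Mod(octstitch:::.avg_spectrum(st))
  seam <- dim(specData(sc$a))[3] - 25:0
  steps <- abs(diff(v[seam])) / stats::median(v)
  expect_lt(max(steps), 0.05)
})

test_that("apodization windows behave at their limits and suppress sidelobes", {
  sp <- mirrorSpectrum(7.0, 1.4e-3, 400L, 350)
  expect_identical(specData(apodize(sp, "none")), specData(sp))
  expect_equal(specData(apodize(sp, "tukey", ratio = 0)), specData(sp))
  r_rect <- psfReport(sp, pad_factor = 32L)
  r_tuk <- psfReport(apodize(sp, "tukey", ratio = 0.5), pad_factor = 32L)
  expect_lt(max(sidelobes(r_tuk)), -13.26)
  expect_lt(max(sidelobes(r_rect)), -13.2)
  expect_gt(max(sidelobes(r_rect)), -13.4)
})

test_that("reconstruction conserves energy and places peaks at their depth", {
  set.seed(5)
  v <- complex(real = rnorm(300), imaginary = rnorm(300))
  sp <- analyticSpectrum(v, 7.0, 1.4e-3)
  vol <- reconstructVolume(sp)
  expect_equal(sum(Mod(specData(vol))^2), sum(Mod(v)^2), tolerance = 1e-9)

  z0 <- 350
  m <- mirrorSpectrum(7.0, 1.4e-3, 300L, z0)
  volm <- reconstructVolume(m, pad_factor = 2L)
  pk <- which.max(Mod(specData(volm)[1, 1, ]))
  expect_lt(abs((pk - 1) * zPixel(volm) - z0), pi / (300 * 1.4e-3))

  ## the same mirror reconstructs to the same depth for both lasers
  cal <- cached_calibration()
  r1 <- psfReport(cal$result$spectra[[1]][[4]], pad_factor = 16L)
  r2 <- psfReport(cal$result$spectra[[2]][[4]], pad_factor = 16L)
  expect_lt(abs(r1@depth - r2@depth), pi / (391 * dk(cal$result$calibration)))
})

test_that("zero-dispersion spectra pass through motion correction unchanged", {
  sp <- mirrorSpectrum(7.0, 1.4e-3, 300L, 350)
  mc <- correctMotionPhase(sp, order_max = 2L)
  expect_true(mc$phase@converged)
  dphi <- Arg(specData(mc$spectrum)[1, 1, ] * Conj(specData(sp)[1, 1, ]))
  expect_lt(max(abs(dphi)), 1e-3)
})

test_that("injected quadratic phase is recovered within 2%", {
  sp <- laserSpec("l", 805, 882, 515L)
  cc <- buildChirpCurve(sp, chirpModel("linear"), margin = c(8L, 8L))
  c2 <- 40
  sw <- simulateSweep(sp, cc, envelopeModel(),
                      mirrorPhantom(400, lateral_size = c(2L, 2L)),
                      disturb = disturbanceModel(dispersion_coeffs = c2))
  swt <- subtractBackground(trimSweep(sw))
  dk_n <- 2 * pi * 1e3 * (1 / 805 - 1 / 882) / 498
  as <- regridKLinear(swt, cc, dk_n)
  mc <- correctMotionPhase(as, order_max = 2L)
  expect_equal(motionCoefficients(mc$phase)[3], c2, tolerance = 0.02)
})

test_that("cubic + quadratic dispersion: corrected PSF width within 5% of clean", {
  sp <- laserSpec("l", 805, 882, 515L)
  cc <- buildChirpCurve(sp, chirpModel("linear"), margin = c(8L, 8L))
  dk_n <- 2 * pi * 1e3 * (1 / 805 - 1 / 882) / 498
  mk <- function(disturb) {
    sw <- simulateSweep(sp, cc, envelopeModel(),
                        mirrorPhantom(400, lateral_size = c(2L, 2L)),
                        disturb = disturb)
    regridKLinear(subtractBackground(trimSweep(sw)), cc, dk_n)
  }
  clean <- mk(disturbanceModel())
  dirty <- mk(disturbanceModel(dispersion_coeffs = c(25, 60)))
  r_clean <- psfReport(clean, pad_factor = 16L)
  r_dirty <- psfReport(dirty, pad_factor = 16L)
  expect_gt(fwhm(r_dirty), 1.5 * fwhm(r_clean))    # visibly blurred
  mc <- correctMotionPhase(dirty, order_max = 3L)
  r_fix <- psfReport(mc$spectrum, pad_factor = 16L)
  expect_lt(abs(fwhm(r_fix) - fwhm(r_clean)) / fwhm(r_clean), 0.05)
})

test_that("registration recovers injected ramps and is transitive", {
  base <- mirrorSpectrum(7.0, 1.4e-3, 480L, 420)
  shifted <- function(dz) {
    s <- base
    s@data <- s@data * rep(exp(1i * 2 * kGrid(s) * dz), each = 1)
    s
  }
  reg <- registerVolumes(list(base, shifted(1.0), shifted(2.0),
                              shifted(-1.0)))
  expect_equal(reg$shifts, c(0, 1, 2, -1), tolerance = 0.01)
  ## deramped spectra all equal the reference
  for (i in 2:4)
    expect_lt(max(Mod(specData(reg$spectra[[i]]) - specData(base))), 1e-6)

  ## transitivity: registering to a different reference shifts consistently
  reg2 <- registerVolumes(list(base, shifted(2.0), shifted(-1.0)),
                          reference = 2L)
  expect_equal(reg2$shifts[3] - reg2$shifts[1],
               reg$shifts[4] - reg$shifts[1], tolerance = 0.02)

  ## cross-laser (disjoint k support): magnitude-correlation path
  other <- mirrorSpectrum(7.8, 1.4e-3, 400L, 420 + 1.5)
  regx <- registerVolumes(list(base, other))
  expect_equal(regx$shifts[2], 1.5, tolerance = 0.05)
})

test_that("a decorrelated volume is excluded with a warning", {
  ## unrelated random content on a different laser grid: the normalized
  ## magnitude correlation finds no common structure
  set.seed(23)
  base <- analyticSpectrum(complex(real = rnorm(400), imaginary = rnorm(400)),
                           7.0, 1.4e-3)
  junk <- analyticSpectrum(complex(real = rnorm(320), imaginary = rnorm(320)),
                           7.8, 1.4e-3)
  expect_warning(reg <- registerVolumes(list(base, junk)), "decorrelated")
  expect_true(is.na(reg$shifts[2]))
})
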