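make_sweep <- function(depth = 400, env = envelopeModel(), n = 515L,
                       model = chirpModel("polynomial", 0.05),
                       lateral = c(2L, 2L), margin = c(0L, 0L),
                       spec = laserSpec("l", 805, 882, n)) {
  cc <- buildChirpCurve(spec, model, margin = margin)
  simulateSweep(spec, cc, env, mirrorPhantom(depth, lateral_size = lateral))
}

test_that("trimming drops the configured frames and refuses to over-trim", {
  sw <- make_sweep(n = 515L)
  tr <- trimSweep(sw, 8L, 8L)
  expect_equal(dim(frames(tr))[3], 499L)
  expect_equal(tr@discard_head, 8L)
  expect_identical(frames(trimSweep(sw, 0L, 0L)), frames(sw))
  expect_error(trimSweep(make_sweep(n = 32L, depth = 30), 10L, 10L),
               "over-trim")
})

test_that("auto-trim keeps the region whose simulated contrast is above threshold", {
  env <- envelopeModel(ase_edge_fraction = 0.15, ase_contrast_floor = 0.3)
  sw <- subtractBackground(make_sweep(depth = 400, env = env,
                                      margin = c(8L, 8L)))
  tr <- trimSweep(sw, "auto", "auto", contrast_threshold = 0.8)
  a_true <- octstitch:::.envelope_curves(env, 515L)$alpha
  kept <- (tr@discard_head + 1L):(515L - tr@discard_tail)
  ## every retained frame has true contrast near/above threshold (the
  ## envelope estimate blurs the cut by a few frames)
  expect_gt(min(a_true[kept]), 0.6)
  ## and the cut is tight: 15 frames below the head cut the contrast is low
  expect_lt(a_true[max(1L, tr@discard_head - 15L)], 0.8)
})

test_that("scattering-mode contrast of an ideal flat spectrum is exactly one", {
  sp <- mirrorSpectrum(7.0, 1.4e-3, 400L, 350)
  ec <- estimateEnvelope(sp, mode = "scattering")
  expect_lt(max(abs(alphaCurve(ec) - 1)), 1e-6)
})

test_that("scattering-mode contrast tracks the true ASE ramp on a distributed phantom", {
  sp <- laserSpec("l", 805, 882, 515L)
  cc <- buildChirpCurve(sp, chirpModel("linear"), margin = c(8L, 8L))
  env <- envelopeModel(ase_edge_fraction = 0.1, ase_contrast_floor = 0.7)
  sweeps <- lapply(1:3, function(s) subtractBackground(trimSweep(
    simulateSweep(sp, cc, env,
                  randomScatteringPhantom(c(40L, 40L), 25L, c(80, 900),
                                          seed = s)))))
  ec <- estimateEnvelope(sweeps, mode = "scattering")
  a_true <- octstitch:::.envelope_curves(env, 515L)$alpha[9:507]
  ratio <- alphaCurve(ec) / (a_true / max(a_true))
  core <- ratio[40:460]
  expect_lt(max(abs(core / mean(core) - 1)), 0.025)

  ## raw-|I| variant agrees with the analytic-signal variant in shape
  ec_raw <- estimateEnvelope(sweeps, mode = "scattering", raw_abs = TRUE)
  r2 <- alphaCurve(ec_raw)[40:460] / alphaCurve(ec)[40:460]
  expect_lt(stats::sd(r2) / mean(r2), 0.05)
})

test_that("reflecting-mode contrast is free of the coverslip two-surface beat", {
  sp <- laserSpec("l", 805, 882, 515L)
  cc <- buildChirpCurve(sp, chirpModel("linear"), margin = c(8L, 8L))
  env <- envelopeModel(ase_edge_fraction = 0.1, ase_contrast_floor = 0.7)
  ## coverslip: 170 um glass at n = 1.51 -> 257 um optical separation
  sw <- subtractBackground(trimSweep(simulateSweep(sp, cc, env,
    mirrorPhantom(c(400, 657), c(1, 0.8), lateral_size = c(2L, 2L)))))
  ec <- estimateEnvelope(sw, mode = "reflecting")
  a_true <- octstitch:::.envelope_curves(env, 515L)$alpha[9:507]
  err <- abs(alphaCurve(ec) - a_true / max(a_true))
  expect_lt(max(err[30:470]), 0.03)          # interior ripple

  ## the beat is present if the two-surface spectrum is used directly
  ec_beat <- estimateEnvelope(sw, mode = "scattering")
  expect_gt(max(abs(alphaCurve(ec_beat)[30:470] -
                      (a_true / max(a_true))[30:470])), 0.2)
})

test_that("reflecting mode rejects two unresolved surfaces in one window", {
  sp <- laserSpec("l", 805, 882, 515L)
  cc <- buildChirpCurve(sp, chirpModel("linear"), margin = c(8L, 8L))
  sw <- subtractBackground(trimSweep(simulateSweep(sp, cc, envelopeModel(),
    mirrorPhantom(c(400, 430), c(1, 1), lateral_size = c(2L, 2L)))))
  expect_error(estimateEnvelope(sw, mode = "reflecting",
                                depth_window = c(75, 105)),
               "unresolved surfaces")
})

test_that("amplitude correction divides by alpha and restores flat fringes", {
  sp <- mirrorSpectrum(7.0, 1.4e-3, 300L, 350)
  ec1 <- new("EnvelopeCorrection", laser_id = "spec",
             gamma = rep(1, 300), alpha = rep(1, 300), gamma_max = 1,
             mode = "scattering", floor_eps = 0.05)
  expect_identical(specData(correctAmplitude(sp, ec1)), specData(sp))
  ec2 <- ec1; ec2@alpha <- rep(0.5, 300); ec2@alpha[1] <- 1  # max = 1
  out <- specData(correctAmplitude(sp, ec2))
  expect_equal(out[1, 1, 2:300], 2 * specData(sp)[1, 1, 2:300])

  ## simulated ASE edges: corrected fringe flat over the retained frames
  spc <- laserSpec("l", 805, 882, 515L)
  cc <- buildChirpCurve(spc, chirpModel("linear"), margin = c(8L, 8L))
  env <- envelopeModel(ase_edge_fraction = 0.1, ase_contrast_floor = 0.7)
  sw <- simulateSweep(spc, cc, env, mirrorPhantom(400, lateral_size = c(2L, 2L)))
  bg <- simulateSweep(spc, cc, env,
                      mirrorPhantom(400, amplitudes = 0,
                                    lateral_size = c(2L, 2L)))
  swt <- subtractBackground(trimSweep(sw), reference = trimSweep(bg))
  ecr <- estimateEnvelope(swt, mode = "reflecting")
  corr <- correctAmplitude(swt, ecr)
  am <- Mod(octstitch:::.analytic(matrix(
    rowMeans(octstitch:::.cube_to_mat(frames(corr))), ncol = 1))[, 1])
  core <- am[30:470]
  expect_lt((max(core) - min(core)) / mean(core), 0.02)
})

test_that("chirp recovery is accurate, shape-invariant to mirror depth, and robust", {
  sp <- laserSpec("l", 805, 882, 515L)
  span <- 2 * pi * 1e3 * (1 / 805 - 1 / 882)
  for (model in list(chirpModel("linear"),
                     chirpModel("polynomial", 0.05),
                     chirpModel("polynomial", c(0.08, 0.02)),
                     chirpModel("sinusoidal", c(0.012, 2)))) {
    cc <- buildChirpCurve(sp, model, margin = c(8L, 8L))
    sw <- subtractBackground(trimSweep(simulateSweep(sp, cc, envelopeModel(),
      mirrorPhantom(500, lateral_size = c(2L, 2L)))))
    est <- estimateChirp(sw, sp)
    expect_lt(max(abs(kGrid(est) - kGrid(cc)[9:507])) / span, 1e-3)
  }

  ## doubling the mirror depth leaves the recovered curve unchanged
  cc <- buildChirpCurve(sp, chirpModel("polynomial", 0.05), margin = c(8L, 8L))
  est1 <- estimateChirp(subtractBackground(trimSweep(simulateSweep(
    sp, cc, envelopeModel(), mirrorPhantom(300, lateral_size = c(2L, 2L))))), sp)
  est2 <- estimateChirp(subtractBackground(trimSweep(simulateSweep(
    sp, cc, envelopeModel(), mirrorPhantom(600, lateral_size = c(2L, 2L))))), sp)
  expect_lt(max(abs(kGrid(est1) - kGrid(est2))) / span, 1e-3)
})

test_that("degenerate chirp input is rejected with guidance", {
  sp <- laserSpec("l", 805, 882, 64L)
  ## mirror at depth ~0: no fringe, no usable phase
  cc <- buildChirpCurve(sp, chirpModel("linear"))
  sw <- simulateSweep(sp, cc, envelopeModel(),
                      mirrorPhantom(0.2, lateral_size = c(2L, 2L)),
                      include_dc = FALSE)
  expect_error(estimateChirp(sw, sp, smooth = "none"), "z0")
})

test_that("regridding an already-linear sweep at native spacing is the identity", {
  sp <- laserSpec("l", 805, 882, 256L, "increasing_k")
  cc <- buildChirpCurve(sp, chirpModel("linear"))
  sw <- simulateSweep(sp, cc, envelopeModel(),
                      mirrorPhantom(300, lateral_size = c(1L, 1L)),
                      include_dc = FALSE)
  native_dk <- diff(range(kGrid(cc))) / 255
  as <- regridKLinear(sw, cc, native_dk)
  ## regridding removes residual DC first; reference the same way
  tr <- as.vector(frames(sw))
  a_ref <- octstitch:::.analytic(matrix(tr - mean(tr), ncol = 1))[, 1]
  err <- Mod(specData(as)[1, 1, ] - a_ref) / max(Mod(a_ref))
  expect_lt(max(err), 1e-6)
})

test_that("regridding flattens the instantaneous frequency of chirped fringes", {
  cal <- cached_calibration()
  sp <- cal$result$spectra[[1]][[4]]
  v <- octstitch:::.avg_spectrum(sp)
  instf <- diff(signal::unwrap(Arg(v)))
  core <- instf[20:(length(instf) - 20)]
  expect_lt(stats::sd(core) / abs(mean(core)), 0.01)

  ## both lasers see the same fringe frequency at a common depth
  sp2 <- cal$result$spectra[[2]][[4]]
  f2 <- diff(signal::unwrap(Arg(octstitch:::.avg_spectrum(sp2))))
  f2 <- f2[20:(length(f2) - 20)]
  expect_lt(abs(mean(core) - mean(f2)) / abs(mean(core)), 0.005)
})

test_that("excessive upsampling and out-of-range grids are rejected", {
  sp <- laserSpec("l", 805, 882, 256L)
  cc <- buildChirpCurve(sp, chirpModel("linear"))
  sw <- simulateSweep(sp, cc, envelopeModel(),
                      mirrorPhantom(300, lateral_size = c(1L, 1L)))
  native_dk <- diff(range(kGrid(cc))) / 255
  expect_error(regridKLinear(sw, cc, native_dk / 5), "4x upsampling")
  expect_error(regridKLinear(sw, cc, native_dk,
                             k_start = min(kGrid(cc)) - 10 * native_dk),
               "beyond the measured sweep")
})

test_that("system calibration builds, serializes and round-trips losslessly", {
  cal <- cached_calibration()$result$calibration
  f <- tempfile(fileext = ".json")
  saveCalibration(cal, f)
  cal2 <- readCalibration(f)
  expect_identical(kappa_px(cal2), kappa_px(cal))
  expect_identical(dk(cal2), dk(cal))
  for (i in seq_along(cal@chirps))
    expect_identical(cal2@chirps[[i]]@k_of_t, cal@chirps[[i]]@k_of_t)
  for (i in seq_along(cal@envelopes))
    expect_identical(cal2@envelopes[[i]]@alpha, cal@envelopes[[i]]@alpha)

  ## a missing overlap is rejected
  expect_error(buildSystemCalibration(dual_lasers, cal@chirps,
                                      overlaps = list(), dk = dk(cal)),
               "overlap")
})
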