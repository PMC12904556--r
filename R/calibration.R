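## One-time system calibration: sweep trimming, envelope/ASE contrast
## estimation and correction, chirp determination from single-mirror
## sweeps, and k-linearization onto a common uniform wavenumber grid.

#' Discard frames near the sweep start and stop
#'
#' A few camera frames around the laser sweep start/stop are unreliable
#' (trigger uncertainty of about 1/16 frame, ASE-dominated edges) and are
#' dropped before any estimation.
#'
#' @param raw a \linkS4class{RawSweep}.
#' @param head,tail frames to drop at each end (default 8/8), or "auto" to
#'   derive the counts from the fringe contrast: the smoothed analytic-
#'   signal envelope of the averaged A-line is normalized to its interior
#'   level and leading/trailing frames below \code{contrast_threshold} are
#'   discarded (ASE-dominated sweep ends lose interference contrast).
#' @param contrast_threshold relative contrast cut for auto-trim.
#' @return the trimmed \linkS4class{RawSweep} with updated discard counts.
#' @export
trimSweep <- function(raw, head = 8L, tail = 8L,
                      contrast_threshold = 0.8) {
  stopifnot(is(raw, "RawSweep"))
  if (identical(head, "auto") || identical(tail, "auto")) {
    aline <- rowMeans(.cube_to_mat(raw@frames))
    env <- Mod(.analytic(matrix(aline - mean(aline), ncol = 1))[, 1])
    env <- stats::runmed(env, 15)
    n <- length(env)
    core <- stats::median(env[floor(n / 4):ceiling(3 * n / 4)])
    ok <- env >= contrast_threshold * core
    if (identical(head, "auto"))
      head <- if (all(ok)) 0L else which(ok)[1] - 1L
    if (identical(tail, "auto"))
      tail <- if (all(ok)) 0L else n - which(ok)[sum(ok)]
  }
  stopifnot(head >= 0, tail >= 0)
  nt <- dim(raw@frames)[3]
  if (nt - head - tail < 16L)
    stop("over-trimming: fewer than 16 frames would remain")
  if (head == 0L && tail == 0L) return(raw)
  idx <- (head + 1L):(nt - tail)
  new("RawSweep", frames = raw@frames[, , idx, drop = FALSE],
      laser = raw@laser,
      discard_head = raw@discard_head + as.integer(head),
      discard_tail = raw@discard_tail + as.integer(tail),
      volume_index = raw@volume_index)
}

## Chirp curve restricted to the retained frames of a trimmed sweep.
.chirp_for_sweep <- function(chirp, raw) {
  nt_full <- length(chirp@k_of_t)
  idx <- (raw@discard_head + 1L):(nt_full - raw@discard_tail)
  if (length(idx) != dim(raw@frames)[3])
    stop("chirp curve does not cover the sweep's retained frames")
  new("ChirpCurve", laser_id = chirp@laser_id, k_of_t = chirp@k_of_t[idx],
      anchoring = chirp@anchoring)
}

## Extract the signal matrix (n x nlat) along the spectral axis from either
## a RawSweep (real frames along t) or an AnalyticSpectrum (complex, along k).
.spectral_mat <- function(x) {
  if (is(x, "RawSweep")) .cube_to_mat(x@frames)
  else if (is(x, "AnalyticSpectrum")) .cube_to_mat(x@data)
  else stop("expected a RawSweep or AnalyticSpectrum")
}

.laser_id_of <- function(x) {
  if (is(x, "RawSweep")) x@laser@laser_id else x@laser_id
}

#' Estimate the source envelope and interference contrast
#'
#' For distributed (scattering) samples the envelope Gamma(k) is the sum
#' over lateral positions of the analytic-signal magnitude of each A-line;
#' normalizing by its maximum gives the interference contrast alpha(k)
#' in (0, 1].  For localized reflectors (mirror, coverslip) the spectrum is
#' first transformed to depth and a window isolating a single surface is
#' applied before the magnitude is taken, which removes the spectral beat
#' that two or more reflecting depths would imprint on Gamma.
#'
#' @param x a \linkS4class{RawSweep} (DC must already be subtracted) or
#'   \linkS4class{AnalyticSpectrum}, or a list of them (repeated
#'   measurements are averaged).
#' @param mode "scattering" or "reflecting".
#' @param depth_window for reflecting mode, c(lo, hi) in depth pixels of
#'   the un-padded reconstruction; \code{NULL} auto-detects a window of
#'   half-width \code{window_halfwidth} around the strongest peak.
#' @param window_halfwidth half-width (depth px) of the auto-detected
#'   single-surface window.
#' @param floor_eps lower floor for alpha so later division is safe.
#' @param raw_abs scattering mode only: use |I| of the raw real frames
#'   instead of the analytic-signal magnitude.
#' @return an \linkS4class{EnvelopeCorrection}.
#' @export
estimateEnvelope <- function(x, mode = c("scattering", "reflecting"),
                             depth_window = NULL, window_halfwidth = 12L,
                             floor_eps = 0.05, raw_abs = FALSE) {
  mode <- match.arg(mode)
  xs <- if (is.list(x)) x else list(x)
  user_window <- depth_window
  gam <- NULL
  for (xi in xs) {
    m <- .spectral_mat(xi)
    if (is.complex(m)) a <- m else a <- .analytic(m)
    g <- switch(mode,
      scattering = {
        if (raw_abs && !is.complex(m)) rowSums(abs(m))
        else rowSums(abs(a))
      },
      reflecting = {
        n <- nrow(a)
        U <- stats::mvfft(a)
        prof <- rowSums(abs(U)^2)
        dw <- user_window
        if (is.null(dw)) {
          ## auto-window per measurement: repeated acquisitions may sit at
          ## different depths
          pk <- which.max(prof[1:max(2L, floor(n / 2))])
          dw <- c(max(1L, pk - window_halfwidth),
                  min(n, pk + window_halfwidth))
        }
        win <- dw[1]:dw[2]
        ## reject two unresolved surfaces inside the window: their beat
        ## would modulate Gamma
        pw <- prof[win]
        locmax <- which(diff(sign(diff(pw))) == -2) + 1L
        strong <- locmax[pw[locmax] > 0.25 * max(pw)]
        if (length(strong) >= 2L)
          stop("two or more unresolved surfaces in the depth window; choose a window isolating one surface")
        mask <- rep(0, n)
        ## tapered pass-band: a hard mask would ring across the spectrum
        mask[win] <- tukeyWindow(length(win), 0.5)
        filt <- stats::mvfft(U * mask, inverse = TRUE) / n
        rowMeans(abs(filt))
      })
    gam <- if (is.null(gam)) g else gam + g
  }
  gam <- gam / length(xs)
  gmax <- max(gam)
  alpha <- pmax(gam / gmax, floor_eps)
  alpha <- alpha / max(alpha)
  new("EnvelopeCorrection", laser_id = .laser_id_of(xs[[1]]), gamma = gam,
      alpha = alpha, gamma_max = gmax, mode = mode, floor_eps = floor_eps)
}

#' Divide out the interference-contrast curve
#'
#' Pointwise division of the spectral data by alpha(k); with alpha identical
#' to 1 this is the identity.  DC must already be subtracted.
#'
#' @param x a \linkS4class{RawSweep} or \linkS4class{AnalyticSpectrum}.
#' @param env the matching \linkS4class{EnvelopeCorrection}.
#' @return object of the same class with corrected amplitudes.
#' @export
correctAmplitude <- function(x, env) {
  stopifnot(is(env, "EnvelopeCorrection"))
  n <- if (is(x, "RawSweep")) dim(x@frames)[3] else dim(x@data)[3]
  if (length(env@alpha) != n)
    stop("alpha length does not match the spectral axis")
  w <- 1 / env@alpha
  if (is(x, "RawSweep")) {
    x@frames <- x@frames * rep(w, each = prod(dim(x@frames)[1:2]))
  } else {
    x@data <- x@data * rep(w, each = prod(dim(x@data)[1:2]))
  }
  x
}

#' Determine the chirp k(t) from a single-mirror sweep
#'
#' All A-lines of the (trimmed, DC-subtracted) calibration volume are
#' averaged, the analytic signal is formed along time and its unwrapped
#' phase -- which for a motion- and dispersion-free mirror at z0 equals
#' 2 k(t) z0 + const -- is rescaled affinely so the endpoints match the
#' laser's nominal sweep wavenumbers.  The unknown z0 and phase constant
#' drop out in the anchoring.
#'
#' @param mirror_sweep a trimmed \linkS4class{RawSweep} of a single mirror.
#' @param anchor the \linkS4class{LaserSpec} providing nominal endpoints.
#' @param smooth "poly" fits the unwrapped phase with a degree-
#'   \code{smooth_degree} polynomial to suppress unwrap/edge noise (the
#'   chirp of a sweeping laser is smooth); "none" uses the raw phase.
#' @param smooth_degree polynomial degree for \code{smooth = "poly"}.
#' @param edge_ignore frames at each end excluded from the polynomial fit
#'   (the analytic signal rings there); the fit is extrapolated across
#'   them.
#' @return a \linkS4class{ChirpCurve} over the retained frames.
#' @export
estimateChirp <- function(mirror_sweep, anchor, smooth = c("poly", "none"),
                          smooth_degree = 9L, edge_ignore = 12L) {
  smooth <- match.arg(smooth)
  stopifnot(is(mirror_sweep, "RawSweep"), is(anchor, "LaserSpec"))
  m <- .cube_to_mat(mirror_sweep@frames)
  aline <- rowMeans(m)
  aline <- aline - mean(aline)
  a <- .analytic(matrix(aline, ncol = 1))[, 1]
  psi <- .unwrap(Arg(a))
  t <- seq_along(psi)
  if (smooth == "poly") {
    ## fit the smooth sweep phase over the interior only -- the analytic
    ## signal rings over the first/last few frames -- and extrapolate the
    ## polynomial to the edges
    ei <- min(edge_ignore, (length(psi) - 32L) %/% 2L)
    idx <- if (ei > 0) (ei + 1L):(length(psi) - ei) else t
    deg <- min(smooth_degree, length(idx) - 2L)
    tc <- (t - mean(t)) / (length(t) / 2)
    X <- stats::poly(tc[idx], deg, raw = TRUE)
    fit <- stats::lm.fit(cbind(1, X), psi[idx])
    Xall <- cbind(1, stats::poly(tc, deg, raw = TRUE))
    psi <- as.vector(Xall %*% fit$coefficients)
  }
  if (psi[length(psi)] == psi[1])
    stop("degenerate phase: mirror too shallow or SNR too low; raise z0")
  ends <- .sweep_endpoints(anchor)
  k <- ends[1] + (ends[2] - ends[1]) *
    (psi - psi[1]) / (psi[length(psi)] - psi[1])
  d <- diff(k)
  if (!(all(d > 0) || all(d < 0))) {
    bad <- which(sign(d) != sign(d[length(d) %/% 2]) | d == 0)[1]
    stop(sprintf(
      "unwrapped phase not monotonic at frame %d; SNR too low or z0 too shallow - raise z0",
      bad + 1L))
  }
  new("ChirpCurve", laser_id = anchor@laser_id, k_of_t = k,
      anchoring = "nominal-endpoints")
}

#' Resample a sweep onto a uniform wavenumber grid
#'
#' The computational k-clock: the analytic signal recorded along time is
#' resampled at the frame positions where the chirp curve crosses each
#' uniform k-grid point, so that a fixed depth z0 produces a constant-
#' frequency fringe.  The signal is band-limited upsampled (FFT
#' zero-padding, factor \code{upsample}) before cubic-spline evaluation at
#' the fractional frame positions, which keeps the interpolation error of
#' tone-like fringes negligible.
#'
#' @param sweep a trimmed, background-subtracted \linkS4class{RawSweep}
#'   (real frames) whose retained frames the chirp curve covers.
#' @param chirp the laser's \linkS4class{ChirpCurve} (full sweep or already
#'   restricted to the retained frames).
#' @param dk target pixel size in rad/um, shared across lasers.
#' @param k_start,n_out target grid start and length; default: the laser's
#'   nominal k range tiled from its lower endpoint with as many pixels as
#'   fit.
#' @param upsample band-limited upsampling factor before interpolation.
#' @return an \linkS4class{AnalyticSpectrum} with ascending k.
#' @export
regridKLinear <- function(sweep, chirp, dk, k_start = NULL, n_out = NULL,
                          upsample = 16L) {
  stopifnot(is(sweep, "RawSweep"), is(chirp, "ChirpCurve"))
  k_t <- if (length(chirp@k_of_t) == dim(sweep@frames)[3]) chirp@k_of_t
         else .chirp_for_sweep(chirp, sweep)@k_of_t
  nt <- length(k_t)
  native <- abs(k_t[nt] - k_t[1]) / (nt - 1)
  if (dk < native / 4)
    stop("requested dk implies more than 4x upsampling of the native sweep; extrapolation risk")
  if (is.null(k_start)) k_start <- min(k_t)
  if (is.null(n_out)) n_out <- floor((max(k_t) - k_start) / dk + 1e-6) + 1L
  k_out <- k_start + (seq_len(n_out) - 1) * dk
  if (k_out[1] < min(k_t) - 1e-9 || k_out[n_out] > max(k_t) + 1e-9)
    stop("target k grid extends beyond the measured sweep range")

  ## fractional frame position of each target wavenumber
  ka <- if (k_t[1] < k_t[nt]) k_t else rev(k_t)
  ta <- if (k_t[1] < k_t[nt]) seq_len(nt) else rev(seq_len(nt))
  t_of_k <- stats::splinefun(ka, ta, method = "hyman")
  tq <- t_of_k(pmin(pmax(k_out, ka[1]), ka[length(ka)]))

  m <- .cube_to_mat(sweep@frames)
  m <- sweep(m, 2, colMeans(m))              # remove any residual DC
  a <- .analytic(m)
  up <- .fft_upsample(a, upsample)
  tu <- seq_len(nrow(up))                      # position in upsampled samples
  tq_u <- (tq - 1) * upsample + 1
  out <- matrix(0 + 0i, n_out, ncol(m))
  for (j in seq_len(ncol(m))) {
    fre <- stats::splinefun(tu, Re(up[, j]), method = "natural")
    fim <- stats::splinefun(tu, Im(up[, j]), method = "natural")
    out[, j] <- fre(tq_u) + 1i * fim(tq_u)
  }
  ## the analytic signal carries positive frequency along t; for a sweep
  ## with decreasing k this is exp(-i 2 k z) -- conjugate so every laser
  ## lands on the exp(+i 2 k z) convention on the ascending k grid
  if (k_t[1] > k_t[nt]) out <- Conj(out)
  d <- dim(sweep@frames)
  new("AnalyticSpectrum", data = .mat_to_cube(out, d[1], d[2]),
      k_start = k_out[1], dk = dk, laser_id = sweep@laser@laser_id)
}

#' Assemble and serialize the one-time system calibration
#'
#' @param lasers list of \linkS4class{LaserSpec} (any order; stored sorted
#'   along ascending wavenumber).
#' @param chirps matching list of estimated \linkS4class{ChirpCurve}.
#' @param envelopes matching list of \linkS4class{EnvelopeCorrection}
#'   (may be empty).
#' @param overlaps list of \linkS4class{OverlapEstimate}, one per adjacent
#'   pair along ascending k.
#' @param dk the common pixel size (rad/um).
#' @param meta free-form provenance (seeds, session ids).
#' @return a \linkS4class{SystemCalibration}.
#' @export
buildSystemCalibration <- function(lasers, chirps, envelopes = list(),
                                   overlaps, dk, meta = list()) {
  k_lo <- vapply(lasers, function(l) .lambda_to_k(l@lambda_max), 0)
  ord <- order(k_lo)
  lasers <- lasers[ord]; chirps <- chirps[ord]
  if (length(envelopes)) envelopes <- envelopes[ord]
  if (!is.list(overlaps)) overlaps <- list(overlaps)
  if (length(lasers) >= 2 && length(overlaps) != length(lasers) - 1)
    stop("one overlap estimate per adjacent laser pair is required")
  kap <- vapply(overlaps, function(o)
    if (is(o, "OverlapEstimate")) o@kappa else as.numeric(o), 0)
  new("SystemCalibration", lasers = lasers, chirps = chirps,
      envelopes = envelopes, dk = dk, kappa = kap,
      meta = c(meta, list(k_convention = "ascending",
                          created = as.character(Sys.time()))))
}

#' @describeIn buildSystemCalibration Serialize a calibration to a JSON
#'   file (full-precision doubles; round-trips losslessly).
#' @param cal a \linkS4class{SystemCalibration}.
#' @param path output file.
#' @export
saveCalibration <- function(cal, path) {
  obj <- list(
    version = as.character(utils::packageVersion("octstitch")),
    dk = cal@dk, kappa = cal@kappa,
    meta = cal@meta[setdiff(names(cal@meta), "created")],
    lasers = lapply(cal@lasers, function(l) list(
      laser_id = l@laser_id, lambda_min = l@lambda_min,
      lambda_max = l@lambda_max, n_frames = l@n_frames,
      sweep_direction = l@sweep_direction)),
    chirps = lapply(cal@chirps, function(cc) list(
      laser_id = cc@laser_id, anchoring = cc@anchoring,
      k_of_t = cc@k_of_t)),
    envelopes = lapply(cal@envelopes, function(e) list(
      laser_id = e@laser_id, gamma = e@gamma, alpha = e@alpha,
      gamma_max = e@gamma_max, mode = e@mode, floor_eps = e@floor_eps)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @describeIn buildSystemCalibration Read a calibration back from JSON.
#' @export
readCalibration <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  lasers <- lapply(seq_len(nrow(o$lasers)), function(i)
    laserSpec(o$lasers$laser_id[i], o$lasers$lambda_min[i],
              o$lasers$lambda_max[i], o$lasers$n_frames[i],
              o$lasers$sweep_direction[i]))
  chirps <- lapply(seq_len(nrow(o$chirps)), function(i)
    new("ChirpCurve", laser_id = o$chirps$laser_id[i],
        k_of_t = o$chirps$k_of_t[[i]], anchoring = o$chirps$anchoring[i]))
  envelopes <- list()
  if (!is.null(o$envelopes) && length(o$envelopes) &&
      NROW(o$envelopes) > 0) {
    envelopes <- lapply(seq_len(nrow(o$envelopes)), function(i)
      new("EnvelopeCorrection", laser_id = o$envelopes$laser_id[i],
          gamma = o$envelopes$gamma[[i]], alpha = o$envelopes$alpha[[i]],
          gamma_max = o$envelopes$gamma_max[i], mode = o$envelopes$mode[i],
          floor_eps = o$envelopes$floor_eps[i]))
  }
  meta <- if (is.null(o$meta)) list() else as.list(o$meta)
  new("SystemCalibration", lasers = lasers, chirps = chirps,
      envelopes = envelopes, dk = o$dk, kappa = as.numeric(o$kappa),
      meta = meta)
}
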