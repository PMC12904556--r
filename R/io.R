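## Session file formats: a directory with a JSON manifest plus one raw
## little-endian float64 file per sweep (exact round-trip), or float32
## multi-page TIFF with affine normalization recorded in the manifest
## (interchange).  The manifest schema is documented in the package README.

.sweep_filename <- function(laser_id, volume, ext) {
  sprintf("%s_vol%03d.%s", laser_id, volume, ext)
}

#' Write a session to disk
#'
#' @param session a \linkS4class{SimulatedSession} (or any session built
#'   from RawSweep lists).
#' @param dir output directory (created if missing).
#' @param format "bin" (raw float64, exact) or "tiff" (float32 multi-page
#'   TIFF, values affinely mapped to [0, 1] with scale/offset stored in the
#'   manifest).
#' @return the manifest path, invisibly.
#' @export
writeSession <- function(session, dir, format = c("bin", "tiff")) {
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ext <- if (format == "bin") "f64" else "tif"
  lasers <- lapply(session@lasers, function(l) list(
    laser_id = l@laser_id, lambda_min = l@lambda_min,
    lambda_max = l@lambda_max, n_frames = l@n_frames,
    sweep_direction = l@sweep_direction))
  sweeps <- list()
  bg <- session@truth$background
  for (li in seq_along(session@raw)) {
    lid <- session@lasers[[li]]@laser_id
    vols <- session@raw[[li]]
    if (!is.null(bg) && !is.null(bg[[lid]]))
      vols <- c(vols, list(bg[[lid]]))
    for (vi in seq_along(vols)) {
      sw <- vols[[vi]]
      role <- if (vi > length(session@raw[[li]])) "background" else "sweep"
      d <- dim(sw@frames)
      fn <- .sweep_filename(lid, if (role == "background") 0L else vi, ext)
      entry <- list(laser_id = lid, volume = vi, role = role, path = fn,
                    dim = d, discard_head = sw@discard_head,
                    discard_tail = sw@discard_tail)
      if (format == "bin") {
        con <- file(file.path(dir, fn), "wb")
        writeBin(as.vector(sw@frames), con, size = 8, endian = "little")
        close(con)
      } else {
        lo <- min(sw@frames); hi <- max(sw@frames)
        scale <- if (hi > lo) hi - lo else 1
        norm <- (sw@frames - lo) / scale
        pages <- lapply(seq_len(d[3]), function(t) norm[, , t])
        tiff::writeTIFF(pages, file.path(dir, fn),
                        bits.per.sample = 32L, compression = "none")
        entry$offset <- lo
        entry$scale <- scale
      }
      sweeps[[length(sweeps) + 1L]] <- entry
    }
  }
  truth <- session@truth
  truth_json <- NULL
  if (length(truth)) {
    truth_json <- truth[intersect(names(truth),
      c("kind", "depths", "kappa", "dk", "trim", "noise_sigma", "seed",
        "bulk_motion", "phase_offsets", "dispersion_coeffs"))]
    if (!is.null(truth$chirps))
      truth_json$chirp_k_of_t <- lapply(truth$chirps, function(cc) cc@k_of_t)
    if (!is.null(truth$alpha)) truth_json$alpha <- truth$alpha
  }
  manifest <- list(schema = "octstitch-session-v1", format = format,
                   lasers = lasers, sweeps = sweeps, truth = truth_json)
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = I(17))
  invisible(mp)
}

#' Read a session from disk
#'
#' Validates the manifest schema (every referenced file must exist and
#' match its declared shape) and loads the sweeps; the truth group is
#' optional.
#'
#' @param dir session directory containing \code{manifest.json}.
#' @return a \linkS4class{SimulatedSession}.
#' @export
readSession <- function(dir) {
  mp <- file.path(dir, "manifest.json")
  if (!file.exists(mp)) stop("no manifest.json in ", dir)
  man <- jsonlite::read_json(mp, simplifyVector = FALSE)
  if (!identical(man$schema, "octstitch-session-v1"))
    stop("unrecognized session schema: ", man$schema %||% "<missing>")
  lasers <- lapply(man$lasers, function(l)
    laserSpec(l$laser_id, l$lambda_min, l$lambda_max, l$n_frames,
              l$sweep_direction))
  names(lasers) <- vapply(lasers, function(l) l@laser_id, "")
  raw <- stats::setNames(vector("list", length(lasers)), names(lasers))
  backgrounds <- NULL
  for (e in man$sweeps) {
    fp <- file.path(dir, e$path)
    d <- as.integer(unlist(e$dim))
    if (!file.exists(fp))
      stop("schema violation: dataset ", e$path, " referenced but missing")
    if (man$format == "bin") {
      expected <- prod(d)
      sz <- file.info(fp)$size
      if (sz != expected * 8)
        stop("schema violation: ", e$path, " has ", sz,
             " bytes, expected ", expected * 8)
      con <- file(fp, "rb")
      v <- readBin(con, "double", n = expected, size = 8, endian = "little")
      close(con)
      arr <- array(v, dim = d)
    } else {
      pages <- tiff::readTIFF(fp, all = TRUE)
      if (length(pages) != d[3] || !all(dim(pages[[1]]) == d[1:2]))
        stop("schema violation: ", e$path, " shape does not match manifest")
      arr <- array(0, dim = d)
      for (t in seq_len(d[3])) arr[, , t] <- pages[[t]]
      arr <- arr * e$scale + e$offset
    }
    sw <- new("RawSweep", frames = arr, laser = lasers[[e$laser_id]],
              discard_head = as.integer(e$discard_head),
              discard_tail = as.integer(e$discard_tail),
              volume_index = as.integer(e$volume))
    if (identical(e$role, "background")) {
      if (is.null(backgrounds)) backgrounds <- list()
      backgrounds[[e$laser_id]] <- sw
    } else raw[[e$laser_id]][[e$volume]] <- sw
  }
  truth <- list()
  if (!is.null(man$truth))
    truth <- as.list(jsonlite::read_json(mp, simplifyVector = TRUE)$truth)
  if (!is.null(backgrounds)) truth$background <- backgrounds
  new("SimulatedSession", lasers = unname(lasers), raw = raw, truth = truth)
}
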