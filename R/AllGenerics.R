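## Generics, accessors and show methods.

#' @name octstitch-accessors
#' @title Accessors for octstitch classes
#' @description Slot access for the package's S4 classes goes through these
#'   accessors; slots are an implementation detail.
#' @param x an octstitch object.
#' @param ... unused.
NULL

#' @rdname octstitch-accessors
#' @export
setGeneric("kGrid", function(x, ...) standardGeneric("kGrid"))

#' @rdname octstitch-accessors
#' @export
setGeneric("dk", function(x) standardGeneric("dk"))

#' @rdname octstitch-accessors
#' @export
setGeneric("kappa_px", function(x) standardGeneric("kappa_px"))

#' @rdname octstitch-accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname octstitch-accessors
#' @export
setGeneric("specData", function(x) standardGeneric("specData"))

#' @rdname octstitch-accessors
#' @export
setGeneric("alphaCurve", function(x) standardGeneric("alphaCurve"))

#' @rdname octstitch-accessors
#' @export
setGeneric("zPixel", function(x) standardGeneric("zPixel"))

#' @rdname octstitch-accessors
#' @export
setGeneric("truth", function(x) standardGeneric("truth"))

#' @rdname octstitch-accessors
#' @export
setGeneric("rawSweeps", function(x, ...) standardGeneric("rawSweeps"))

#' @rdname octstitch-accessors
#' @export
setGeneric("offsets", function(x) standardGeneric("offsets"))

#' @rdname octstitch-accessors
#' @export
setGeneric("fwhm", function(x) standardGeneric("fwhm"))

#' @rdname octstitch-accessors
#' @export
setGeneric("sidelobes", function(x) standardGeneric("sidelobes"))

#' @rdname octstitch-accessors
#' @export
setMethod("kGrid", "AnalyticSpectrum", function(x, ...)
  x@k_start + (seq_len(dim(x@data)[3]) - 1) * x@dk)

#' @rdname octstitch-accessors
#' @export
setMethod("kGrid", "ChirpCurve", function(x, ...) x@k_of_t)

#' @rdname octstitch-accessors
#' @export
setMethod("dk", "AnalyticSpectrum", function(x) x@dk)

#' @rdname octstitch-accessors
#' @export
setMethod("dk", "SystemCalibration", function(x) x@dk)

#' @rdname octstitch-accessors
#' @export
setMethod("kappa_px", "OverlapEstimate", function(x) x@kappa)

#' @rdname octstitch-accessors
#' @export
setMethod("kappa_px", "SystemCalibration", function(x) x@kappa)

#' @rdname octstitch-accessors
#' @export
setMethod("kappa_px", "StitchPlan", function(x) x@kappa)

#' @rdname octstitch-accessors
#' @export
setMethod("frames", "RawSweep", function(x) x@frames)

#' @rdname octstitch-accessors
#' @export
setMethod("specData", "AnalyticSpectrum", function(x) x@data)

#' @rdname octstitch-accessors
#' @export
setMethod("specData", "ReconVolume", function(x) x@data)

#' @rdname octstitch-accessors
#' @export
setMethod("alphaCurve", "EnvelopeCorrection", function(x) x@alpha)

#' @rdname octstitch-accessors
#' @export
setMethod("zPixel", "ReconVolume", function(x) x@z_pixel)

#' @rdname octstitch-accessors
#' @export
setMethod("truth", "SimulatedSession", function(x) x@truth)

#' @rdname octstitch-accessors
#' @param laser_id which laser's sweeps to return (default: all).
#' @export
setMethod("rawSweeps", "SimulatedSession", function(x, laser_id = NULL, ...) {
  if (is.null(laser_id)) return(x@raw)
  x@raw[[laser_id]]
})

#' @rdname octstitch-accessors
#' @export
setMethod("offsets", "PhaseOffsetField", function(x) x@offsets)

#' @rdname octstitch-accessors
#' @export
setMethod("fwhm", "PSFReport", function(x) x@fwhm)

#' @rdname octstitch-accessors
#' @export
setMethod("sidelobes", "PSFReport", function(x)
  c(left = x@sidelobe_left_db, right = x@sidelobe_right_db))

setMethod("show", "LaserSpec", function(object) {
  cat(sprintf("LaserSpec '%s': %g-%g nm, %d frames, %s\n",
              object@laser_id, object@lambda_min, object@lambda_max,
              object@n_frames, object@sweep_direction))
})

setMethod("show", "RawSweep", function(object) {
  d <- dim(object@frames)
  cat(sprintf("RawSweep [%s] %d x %d x %d frames (trim %d/%d, volume %d)\n",
              object@laser@laser_id, d[1], d[2], d[3],
              object@discard_head, object@discard_tail,
              object@volume_index))
})

setMethod("show", "AnalyticSpectrum", function(object) {
  d <- dim(object@data)
  kg <- kGrid(object)
  cat(sprintf(
    "AnalyticSpectrum [%s] %d x %d lateral, %d k-pixels, k = %.4f..%.4f rad/um (dk = %.3e)\n",
    object@laser_id, d[1], d[2], d[3], kg[1], kg[d[3]], object@dk))
})

setMethod("show", "OverlapEstimate", function(object) {
  cat(sprintf(
    "OverlapEstimate: kappa = %.2f px from %d depths (window [%.2f, %.2f]%s)\n",
    object@kappa, object@n_depths, object@search_window[1],
    object@search_window[2],
    if (object@boundary) ", BOUNDARY - unreliable" else ""))
})

setMethod("show", "SystemCalibration", function(object) {
  ids <- vapply(object@lasers, function(l) l@laser_id, "")
  cat(sprintf("SystemCalibration: %s | dk = %.4e rad/um | kappa = %s px\n",
              paste(ids, collapse = " -> "), object@dk,
              paste(sprintf("%.2f", object@kappa), collapse = ", ")))
})

setMethod("show", "SimulatedSession", function(object) {
  ids <- vapply(object@lasers, function(l) l@laser_id, "")
  nv <- vapply(object@raw, length, 1L)
  cat(sprintf("SimulatedSession: lasers %s; %s sweeps each\n",
              paste(ids, collapse = ", "), paste(nv, collapse = "/")))
})

setMethod("show", "ReconVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("ReconVolume %d x %d x %d, z pixel %.3f um\n",
              d[1], d[2], d[3], object@z_pixel))
})

setMethod("show", "PSFReport", function(object) {
  cat(sprintf(
    "PSFReport: depth %.1f um, -6 dB FWHM %.3f um, sidelobes L %.2f / R %.2f dB\n",
    object@depth, object@fwhm, object@sidelobe_left_db,
    object@sidelobe_right_db))
})
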