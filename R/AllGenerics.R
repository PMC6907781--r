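#' Ground-truth per-tissue metabolite ratios
#'
#' @param object a [Phantom-class]
#' @return list with elements `tumor` and `normal`, each a named vector
#'   of realized ratios (lacPyr, bicPyr, lacBic) computed as ratios of
#'   per-tissue amplitude sums.
#' @export
setGeneric("truthRatios", function(object) standardGeneric("truthRatios"))

#' Peak (argmax) times of dynamic metabolite curves
#'
#' Returns the time of the global maximum of each metabolite curve; ties
#' are broken toward the earliest time. An all-zero curve yields NA with
#' the `undefined` attribute flagging the metabolite (no error raised).
#'
#' @param object a [TimeCurves-class]
#' @return named numeric (pyr, lac, bic) of peak times in seconds, with
#'   attribute `undefined` (named logical).
#' @export
setGeneric("peakTimes", function(object) standardGeneric("peakTimes"))

#' Total scan time (s) and native resolution (mm) of an acquisition
#' @param object an [AcqParams-class]
#' @export
setGeneric("scanTimeS", function(object) standardGeneric("scanTimeS"))

#' @rdname scanTimeS
#' @export
setGeneric("nativeResMm", function(object) standardGeneric("nativeResMm"))

# --- show methods ---------------------------------------------------------

#' @noRd
#' @export
setMethod("show", "KineticParams", function(object) {
  cat("KineticParams: kPL =", object@kPL, "kPB =", object@kPB, "1/s\n",
      " decay r1 (P/L/B):", object@r1P, object@r1L, object@r1B, "1/s\n",
      " input: gamma(shape =", object@inputShape, ", scale =",
      object@inputScale, "s) delay", object@inputDelay, "s, amp",
      object@inputAmp, "\n  flip", object@flipDeg, "deg, TR",
      object@trDyn, "s\n")
})

#' @noRd
#' @export
setMethod("show", "TimeCurves", function(object) {
  cat(sprintf("TimeCurves: %d points, t in [%g, %g] s\n",
              length(object@t), min(object@t), max(object@t)))
})

#' @noRd
#' @export
setMethod("show", "AcqParams", function(object) {
  cat(sprintf(paste0("AcqParams: %dx%d encodes, TR %g ms (scan %.1f s), ",
                     "FOV %g mm (%g mm native)\n  BW %g Hz, %d samples, ",
                     "flip %g deg, slice %g mm, carrier %g ppm @ %g MHz\n"),
              object@matrixSize, object@matrixSize, object@trMs,
              scanTimeS(object), object@fovMm, nativeResMm(object),
              object@bwHz, object@nSamples, object@flipDeg,
              object@sliceMm, object@carrierPpm, object@f0Mhz))
})

#' @noRd
#' @export
setMethod("show", "Phantom", function(object) {
  tr <- truthRatios(object)
  cat(sprintf(paste0("Phantom: %dx%d grid, %d tumor / %d normal voxels\n",
                     "  truth Lac/Bic: tumor %.2f, normal %.2f\n"),
              nrow(object@labels), ncol(object@labels),
              sum(object@labels == 2L), sum(object@labels == 1L),
              tr$tumor["lacBic"], tr$normal["lacBic"]))
})

#' @noRd
#' @export
setMethod("show", "CsiDataset", function(object) {
  d <- dim(object@kspace)
  cat(sprintf("CsiDataset '%s' (%s): %dx%dx%d k-space, noise sd %g\n",
              object@animalId, object@timepoint, d[1], d[2], d[3],
              object@noiseSd))
})

#' @noRd
#' @export
setMethod("show", "Spectrum", function(object) {
  cat(sprintf("Spectrum: %d bins, %.1f to %.1f ppm\n",
              length(object@values), min(object@ppm), max(object@ppm)))
})

#' @noRd
#' @export
setMethod("show", "MetaboliteMapSet", function(object) {
  d <- dim(object@maps)
  cat(sprintf("MetaboliteMapSet: %dx%d maps (%g mm), peaks: %s\n",
              d[1], d[2], object@resMm,
              paste(object@peaks$name, collapse = ", ")))
})

#' @noRd
#' @export
setMethod("show", "RatioSet", function(object) {
  cat(sprintf(paste0("RatioSet (%s over %d voxels, %d masked): Lac/Pyr %.3f,",
                     " Bic/Pyr %.3f, Lac/Bic %.2f\n"),
              object@mode, object@nVoxels, object@nMasked, object@lacPyr,
              object@bicPyr, object@lacBic))
})

#' @noRd
#' @export
setMethod("show", "CohortSpec", function(object) {
  cat(sprintf("CohortSpec: %d deceased / %d survivors / %d controls, censor day %g\n",
              object@nDeceased, object@nSurvivors, object@nControls,
              object@censorDay))
})

#' @noRd
#' @export
setMethod("show", "DynamicSeries", function(object) {
  cat(sprintf("DynamicSeries: %d FIDs (%d samples) at t = %g..%g s\n",
              ncol(object@fids), nrow(object@fids), min(object@tAcq),
              max(object@tAcq)))
})

# --- simple accessors -----------------------------------------------------

#' Coerce TimeCurves to a data.frame
#'
#' @param x a [TimeCurves-class]
#' @param ... ignored
#' @return data.frame with columns t_s, pyr, lac, bic
#' @export
as.data.frame.TimeCurves <- function(x, ...) {
  data.frame(t_s = x@t, pyr = x@pyr, lac = x@lac, bic = x@bic)
}

#' @rdname scanTimeS
#' @export
setMethod("scanTimeS", "AcqParams", function(object)
  object@matrixSize^2 * object@trMs / 1000)

#' @rdname scanTimeS
#' @export
setMethod("nativeResMm", "AcqParams", function(object)
  object@fovMm / object@matrixSize)

#' Extract one metabolite map
#'
#' @param x a [MetaboliteMapSet-class]
#' @param name peak name (e.g. "pyr", "lac", "bic")
#' @return numeric matrix
#' @export
getMap <- function(x, name) {
  stopifnot(is(x, "MetaboliteMapSet"))
  i <- match(name, x@peaks$name)
  if (is.na(i)) stop("unknown peak: ", name)
  x@maps[, , i]
}

#' Peak names available in a map set
#' @param x a [MetaboliteMapSet-class]
#' @export
mapNames <- function(x) x@peaks$name
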