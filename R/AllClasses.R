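#' @import methods
NULL

#' Kinetic model parameters for hyperpolarized pyruvate dynamics
#'
#' Parameters of the unidirectional precursor-product exchange model
#' driven by a gamma-variate arterial input. Rates are apparent in-vivo
#' signal decay rates: they lump longitudinal relaxation, vascular
#' washout and (for pyruvate) metabolic consumption, which is why the
#' default pyruvate rate is much faster than 1/T1 of the nucleus.
#'
#' @slot kPL pyruvate-to-lactate exchange rate (1/s)
#' @slot kPB pyruvate-to-bicarbonate exchange rate (1/s)
#' @slot r1P,r1L,r1B effective signal decay rates of the three pools (1/s)
#' @slot inputAmp arterial input scale (arbitrary units)
#' @slot inputDelay bolus arrival time (s)
#' @slot inputShape gamma-variate shape parameter (dimensionless)
#' @slot inputScale gamma-variate time constant (s)
#' @slot flipDeg excitation flip angle (degrees); 0 disables the
#'   RF-sampling loss term
#' @slot trDyn dynamic sampling interval (s)
#' @exportClass KineticParams
setClass("KineticParams",
  representation(
    kPL = "numeric", kPB = "numeric",
    r1P = "numeric", r1L = "numeric", r1B = "numeric",
    inputAmp = "numeric", inputDelay = "numeric",
    inputShape = "numeric", inputScale = "numeric",
    flipDeg = "numeric", trDyn = "numeric"))

setValidity("KineticParams", function(object) {
  v <- c(kPL = object@kPL, kPB = object@kPB, r1P = object@r1P,
         r1L = object@r1L, r1B = object@r1B, inputAmp = object@inputAmp,
         inputDelay = object@inputDelay, inputShape = object@inputShape,
         inputScale = object@inputScale, flipDeg = object@flipDeg,
         trDyn = object@trDyn)
  if (any(lengths(list(object@kPL, object@kPB, object@r1P, object@r1L,
                       object@r1B, object@inputAmp, object@inputDelay,
                       object@inputShape, object@inputScale,
                       object@flipDeg, object@trDyn)) != 1L))
    return("all kinetic parameters must be length-1 numerics")
  if (any(!is.finite(v))) return("invalid-parameter: non-finite value")
  if (any(v[c("kPL", "kPB", "r1P", "r1L", "r1B", "inputAmp",
              "inputDelay")] < 0))
    return("invalid-parameter: rates, input amplitude and delay must be >= 0")
  if (object@inputShape <= 0 || object@inputScale <= 0)
    return("invalid-parameter: gamma-variate shape and scale must be > 0")
  if (object@flipDeg < 0 || object@flipDeg >= 90)
    return("invalid-parameter: flip angle must be in [0, 90) degrees")
  if (object@trDyn <= 0) return("invalid-parameter: trDyn must be > 0")
  TRUE
})

#' Dynamic metabolite signal curves
#'
#' Pyruvate, lactate and bicarbonate signal amplitudes on a common
#' uniform time grid, as produced by [simulateDynamics()] or by
#' integrating a reconstructed dynamic FID series.
#'
#' @slot t time grid (s), strictly increasing
#' @slot pyr,lac,bic non-negative signal amplitudes (arbitrary units)
#' @exportClass TimeCurves
setClass("TimeCurves",
  representation(t = "numeric", pyr = "numeric", lac = "numeric",
                 bic = "numeric"))

setValidity("TimeCurves", function(object) {
  n <- length(object@t)
  if (length(object@pyr) != n || length(object@lac) != n ||
      length(object@bic) != n)
    return("time grid and signal vectors must have equal length")
  if (n > 1 && any(diff(object@t) <= 0))
    return("time grid must be strictly increasing")
  if (any(!is.finite(c(object@t, object@pyr, object@lac, object@bic))))
    return("non-finite values in curves")
  if (any(c(object@pyr, object@lac, object@bic) < 0))
    return("signal amplitudes must be >= 0")
  TRUE
})

#' CSI acquisition parameters
#'
#' Geometry and sampling of the phase-encoded FID chemical-shift-imaging
#' acquisition: 16 x 16 encodes over a 64 mm field of view, TR 75 ms
#' (19.2 s scan), 5000 Hz spectral bandwidth with 256 complex samples,
#' 10 degree flip, 5 mm slice.
#'
#' @slot matrixSize phase encodes per side
#' @slot trMs repetition time between encodes (ms)
#' @slot flipDeg excitation flip angle (degrees)
#' @slot bwHz spectral (readout) bandwidth (Hz)
#' @slot nSamples complex FID samples per encode
#' @slot fovMm field of view (mm)
#' @slot sliceMm slice thickness (mm)
#' @slot carrierPpm transmit centre frequency (ppm); pyruvate on-resonance
#' @slot f0Mhz 13C Larmor frequency (MHz), so 1 ppm = f0Mhz Hz
#' @slot trDynS repetition time of the dynamic (non-imaging) series (s)
#' @exportClass AcqParams
setClass("AcqParams",
  representation(
    matrixSize = "integer", trMs = "numeric", flipDeg = "numeric",
    bwHz = "numeric", nSamples = "integer", fovMm = "numeric",
    sliceMm = "numeric", carrierPpm = "numeric", f0Mhz = "numeric",
    trDynS = "numeric"))

setValidity("AcqParams", function(object) {
  if (object@matrixSize < 4L) return("matrixSize must be >= 4")
  if (object@bwHz <= 0) return("bwHz must be > 0")
  if (object@nSamples < 2L) return("nSamples must be >= 2")
  if (object@fovMm <= 0 || object@sliceMm <= 0)
    return("fovMm and sliceMm must be > 0")
  if (object@f0Mhz <= 0) return("f0Mhz must be > 0")
  if (object@trMs <= 0 || object@trDynS <= 0)
    return("trMs and trDynS must be > 0")
  TRUE
})

#' Digital phantom specification
#'
#' Geometry and signal statistics of the two-compartment (normal brain
#' vs tumour) digital phantom. Both compartments are ellipses in the
#' axial plane; per-voxel metabolite amplitudes are drawn independently
#' around per-tissue means with a common coefficient of variation.
#'
#' @slot gridN acquisition matrix per side
#' @slot fovMm field of view (mm)
#' @slot sliceMm slice thickness (mm)
#' @slot brainCenter,brainSemi brain ellipse centre and semi-axes (mm)
#' @slot tumorCenter,tumorSemi tumour ellipse centre and semi-axes (mm)
#' @slot tumorAmp,normalAmp named per-metabolite mean amplitudes
#' @slot ampCV coefficient of variation of per-voxel amplitude draws
#' @slot linewidthHz named per-metabolite Lorentzian FWHM (Hz)
#' @slot phaseRangeDeg half-range of the uniform per-dataset global
#'   zero-order phase offset (degrees)
#' @slot noiseSd default complex k-space noise sd (per real component)
#' @slot includeMinor include low-amplitude pyruvate-hydrate and alanine
#' @slot seed RNG seed for amplitude draws
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(
    gridN = "integer", fovMm = "numeric", sliceMm = "numeric",
    brainCenter = "numeric", brainSemi = "numeric",
    tumorCenter = "numeric", tumorSemi = "numeric",
    tumorAmp = "numeric", normalAmp = "numeric", ampCV = "numeric",
    linewidthHz = "numeric", phaseRangeDeg = "numeric",
    noiseSd = "numeric", includeMinor = "logical", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  if (object@gridN < 4L) return("gridN must be >= 4")
  if (object@fovMm <= 0) return("fovMm must be > 0")
  if (any(object@brainSemi <= 0) || any(object@tumorSemi <= 0))
    return("ellipse semi-axes must be > 0")
  if (any(object@tumorAmp < 0) || any(object@normalAmp < 0))
    return("amplitudes must be >= 0")
  if (object@ampCV < 0) return("ampCV must be >= 0")
  if (any(object@linewidthHz <= 0)) return("linewidths must be > 0")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  # tumour ellipse must sit inside the brain ellipse: test boundary points
  th <- seq(0, 2 * pi, length.out = 181)
  px <- object@tumorCenter[1] + object@tumorSemi[1] * cos(th)
  py <- object@tumorCenter[2] + object@tumorSemi[2] * sin(th)
  inb <- ((px - object@brainCenter[1]) / object@brainSemi[1])^2 +
         ((py - object@brainCenter[2]) / object@brainSemi[2])^2
  if (any(inb > 1)) return("geometry error: tumor ellipse not inside brain")
  TRUE
})

#' Digital phantom (ground truth)
#'
#' Realized per-voxel metabolite amplitudes, tissue labels
#' (0 background, 1 normal brain, 2 tumour), a global zero-order phase,
#' and the spec the phantom was drawn from. Truth ratios are available
#' via [truthRatios()].
#'
#' @slot labels integer matrix of tissue labels
#' @slot amplitudes 3-D array (x, y, metabolite) of amplitudes
#' @slot phaseRad global zero-order phase offset (rad)
#' @slot linewidthHz named per-metabolite FWHM (Hz)
#' @slot spec the generating [PhantomSpec-class]
#' @exportClass Phantom
setClass("Phantom",
  representation(labels = "matrix", amplitudes = "array",
                 phaseRad = "numeric", linewidthHz = "numeric",
                 spec = "PhantomSpec"))

setValidity("Phantom", function(object) {
  if (!all(object@labels %in% 0:2)) return("labels must be in {0,1,2}")
  d <- dim(object@amplitudes)
  if (length(d) != 3 || any(d[1:2] != dim(object@labels)))
    return("amplitude array must be gridN x gridN x metabolites")
  if (any(object@amplitudes < 0)) return("amplitudes must be >= 0")
  out <- object@labels == 0L
  if (any(apply(object@amplitudes, 3, function(m) any(m[out] != 0))))
    return("amplitudes must be 0 outside the brain")
  TRUE
})

#' Synthetic CSI dataset
#'
#' One imaging session: the complex k-space FID grid
#' (kx, ky, time sample) plus acquisition parameters and session
#' metadata. Optionally carries the generating phantom's truth ratios.
#'
#' @slot kspace complex array, matrixSize x matrixSize x nSamples
#' @slot params [AcqParams-class]
#' @slot animalId,timepoint session metadata; timepoint is "baseline"
#'   or "48h"
#' @slot seed RNG seed used for the noise draw
#' @slot noiseSd complex noise sd per real component
#' @slot truth list of ground-truth references (may be empty)
#' @exportClass CsiDataset
setClass("CsiDataset",
  representation(kspace = "array", params = "AcqParams",
                 animalId = "character", timepoint = "character",
                 seed = "integer", noiseSd = "numeric", truth = "list"))

setValidity("CsiDataset", function(object) {
  d <- dim(object@kspace)
  p <- object@params
  if (length(d) != 3) return("kspace must be a 3-D array")
  if (d[1] != p@matrixSize || d[2] != p@matrixSize || d[3] != p@nSamples)
    return(sprintf("kspace dims %s inconsistent with params (%d x %d x %d)",
                   paste(d, collapse = "x"), p@matrixSize, p@matrixSize,
                   p@nSamples))
  if (!is.complex(object@kspace)) return("kspace must be complex")
  if (any(!is.finite(Re(object@kspace))) ||
      any(!is.finite(Im(object@kspace))))
    return("kspace must be finite")
  TRUE
})

#' Single-voxel complex spectrum
#'
#' @slot values complex spectral values, DC-centred
#' @slot hz frequency axis relative to the carrier (Hz), increasing
#' @slot ppm chemical-shift axis (ppm), increasing (displayed decreasing
#'   by NMR convention)
#' @slot voxel source voxel index (row, col) on the interpolated grid,
#'   or integer(0)
#' @exportClass Spectrum
setClass("Spectrum",
  representation(values = "complex", hz = "numeric", ppm = "numeric",
                 voxel = "integer"))

setValidity("Spectrum", function(object) {
  n <- length(object@values)
  if (length(object@hz) != n || length(object@ppm) != n)
    return("axis length must equal value length")
  if (n > 1 && (any(diff(object@hz) <= 0) || any(diff(object@ppm) <= 0)))
    return("frequency axes must be strictly monotone increasing")
  TRUE
})

#' Reconstructed per-metabolite amplitude maps
#'
#' Output of [reconstructMaps()]: one non-negative amplitude map per
#' peak on the Fourier-interpolated grid, with the phases applied,
#' quality flags and provenance.
#'
#' @slot maps 3-D array (x, y, peak) of non-negative amplitudes
#' @slot peaks the peak definition table used
#' @slot factor spatial/spectral interpolation factor
#' @slot resMm interpolated in-plane resolution (mm)
#' @slot datasetPhase named per-peak dataset-level fallback phase (rad)
#' @slot nClamped,nLowSignal named per-peak counts of clamped-negative
#'   and low-signal-fallback voxels
#' @slot provenance list: dataset id, timepoint, parameter hash
#' @exportClass MetaboliteMapSet
setClass("MetaboliteMapSet",
  representation(maps = "array", peaks = "data.frame", factor = "integer",
                 resMm = "numeric", datasetPhase = "numeric",
                 nClamped = "numeric", nLowSignal = "numeric",
                 provenance = "list"))

setValidity("MetaboliteMapSet", function(object) {
  d <- dim(object@maps)
  if (length(d) != 3) return("maps must be a 3-D array")
  if (d[3] != nrow(object@peaks))
    return("one map per peak definition required")
  if (any(!is.finite(object@maps))) return("map amplitudes must be finite")
  if (any(object@maps < 0)) return("map amplitudes must be >= 0")
  TRUE
})

#' ROI metabolite ratio set
#'
#' Ratios of metabolite amplitudes over a region of interest. Undefined
#' ratios (denominator below floor) are NA with `nMasked` counting
#' affected voxels in mean-of-ratios mode.
#'
#' @slot lacPyr,bicPyr,lacBic,lacTotal,bicTotal dimensionless ratios
#' @slot nVoxels ROI voxels used
#' @slot nMasked voxels masked by the denominator floor
#' @slot mode "sum" (ratio of ROI sums) or "mean" (mean of voxel ratios)
#' @exportClass RatioSet
setClass("RatioSet",
  representation(lacPyr = "numeric", bicPyr = "numeric",
                 lacBic = "numeric", lacTotal = "numeric",
                 bicTotal = "numeric", nVoxels = "integer",
                 nMasked = "integer", mode = "character"))

setValidity("RatioSet", function(object) {
  r <- c(object@lacPyr, object@bicPyr, object@lacBic, object@lacTotal,
         object@bicTotal)
  if (any(r[!is.na(r)] < 0)) return("ratios must be >= 0 or NA")
  if (object@nVoxels < 1L) return("empty-roi: nVoxels must be >= 1")
  TRUE
})

#' Synthetic cohort specification
#'
#' Group sizes and distributional parameters of the synthetic animal
#' cohort: per-group baseline tumour Lac/Bic means and SDs, per-group
#' multiplicative 48-hour effects with lognormal jitter, survival
#' distribution of non-surviving animals, censoring day, tumour volume
#' statistics, and the latent coupling between the 48-hour Lac/Bic level
#' and tumour growth rate.
#'
#' @slot nDeceased,nSurvivors,nControls group sizes
#' @slot tumorBaseline,tumorBaselineSd named (deceased, survivor,
#'   control) baseline tumour Lac/Bic mean and SD
#' @slot normalBaseline,normalBaselineSd normal-brain Lac/Bic mean, SD
#' @slot tumorEffect named per-group multiplicative 48-h tumour Lac/Bic
#'   change
#' @slot normalEffect multiplicative 48-h change in normal brain
#' @slot effectSdLog lognormal jitter sd of the 48-h effects
#' @slot survivalMeanD,survivalSdD survival of non-survivors (days)
#' @slot censorDay observation cutoff (days)
#' @slot volBaseline,volBaselineSd named baseline tumour volume mean and
#'   SD (mm^3)
#' @slot volEffect named per-group 48-h volume growth factor
#' @slot volEffectSdLog lognormal jitter sd of the growth factor
#' @slot couplingRho latent correlation between Lac/Bic jitter and
#'   growth jitter
#' @slot responseRate probability a treated animal is a responder (used
#'   when groups are randomized)
#' @slot seed RNG seed
#' @exportClass CohortSpec
setClass("CohortSpec",
  representation(
    nDeceased = "integer", nSurvivors = "integer", nControls = "integer",
    tumorBaseline = "numeric", tumorBaselineSd = "numeric",
    normalBaseline = "numeric", normalBaselineSd = "numeric",
    tumorEffect = "numeric", normalEffect = "numeric",
    effectSdLog = "numeric", survivalMeanD = "numeric",
    survivalSdD = "numeric", censorDay = "numeric",
    volBaseline = "numeric", volBaselineSd = "numeric",
    volEffect = "numeric", volEffectSdLog = "numeric",
    couplingRho = "numeric", responseRate = "numeric", seed = "integer"))

setValidity("CohortSpec", function(object) {
  if (object@nDeceased < 0L || object@nSurvivors < 0L ||
      object@nControls < 0L) return("group sizes must be >= 0")
  if (object@censorDay <= 0) return("censorDay must be > 0")
  if (object@responseRate < 0 || object@responseRate > 1)
    return("responseRate must be in [0, 1]")
  grp <- c("deceased", "survivor", "control")
  for (nm in c("tumorBaseline", "tumorBaselineSd", "tumorEffect",
               "volBaseline", "volBaselineSd", "volEffect")) {
    v <- slot(object, nm)
    if (!all(grp %in% names(v)))
      return(sprintf("%s must be named with %s", nm,
                     paste(grp, collapse = ", ")))
  }
  if (abs(object@couplingRho) > 1) return("couplingRho must be in [-1, 1]")
  TRUE
})

#' Dynamic slice-FID series
#'
#' Sequence of whole-slice FIDs acquired every `trDynS` seconds with a
#' single-shot pulse-and-acquire readout (2048 samples at 5000 Hz by
#' default), used to time the imaging window.
#'
#' @slot fids complex matrix, nSamples x nAcquisitions
#' @slot tAcq acquisition times (s)
#' @slot params [AcqParams-class] (nSamples refers to this readout)
#' @slot linewidthHz named per-metabolite FWHM (Hz)
#' @exportClass DynamicSeries
setClass("DynamicSeries",
  representation(fids = "matrix", tAcq = "numeric", params = "AcqParams",
                 linewidthHz = "numeric"))

setValidity("DynamicSeries", function(object) {
  if (ncol(object@fids) != length(object@tAcq))
    return("one FID column per acquisition time required")
  if (!is.complex(object@fids)) return("fids must be complex")
  TRUE
})
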