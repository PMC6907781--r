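# 13C chemical shifts (ppm) used to place peaks in the 5000 Hz window;
# pyruvate is the transmit carrier
METAB_PPM <- c(pyr = 171.0, lac = 183.2, hyd = 179.5, ala = 176.6,
               bic = 161.0)

#' Construct CSI acquisition parameters
#'
#' Defaults reproduce the small-animal phase-encoded FID CSI protocol:
#' 16 x 16 encodes, TR 75 ms (19.2 s scan), 64 mm FOV (4 mm native
#' resolution), 5000 Hz bandwidth, 256 samples, 10 degree flip, 5 mm
#' slice, carrier on pyruvate at 32.13 MHz (3 T).
#'
#' @param matrixSize,trMs,flipDeg,bwHz,nSamples,fovMm,sliceMm,carrierPpm,f0Mhz,trDynS
#'   see [AcqParams-class]
#' @return an [AcqParams-class]
#' @export
acqParams <- function(matrixSize = 16, trMs = 75, flipDeg = 10,
                      bwHz = 5000, nSamples = 256, fovMm = 64,
                      sliceMm = 5, carrierPpm = 171.0, f0Mhz = 32.13,
                      trDynS = 3) {
  new("AcqParams", matrixSize = as.integer(matrixSize), trMs = trMs,
      flipDeg = flipDeg, bwHz = bwHz, nSamples = as.integer(nSamples),
      fovMm = fovMm, sliceMm = sliceMm, carrierPpm = carrierPpm,
      f0Mhz = f0Mhz, trDynS = trDynS)
}

#' Construct a digital phantom specification
#'
#' The default phantom is a rat-brain-scale ellipse (28 x 20 mm) holding
#' an offset tumour ellipse (12 x 10 mm) on a 16 x 16 grid over a 64 mm
#' FOV. Amplitude means put the tumour Lac/Bic at 11.1 and normal brain
#' at 6.2 -- the baseline scale of treated-cohort tumours and
#' contralateral brain.
#'
#' @param gridN,fovMm,sliceMm grid and geometry, see [PhantomSpec-class]
#' @param brainCenter,brainSemi,tumorCenter,tumorSemi ellipse geometry (mm)
#' @param tumorLacBic,normalLacBic target per-tissue Lac/Bic ratios;
#'   bicarbonate means are derived from these and the lactate means
#' @param tumorLacPyr,normalLacPyr per-tissue Lac/Pyr amplitude ratios
#' @param ampCV per-voxel amplitude coefficient of variation
#' @param linewidthHz named per-metabolite Lorentzian FWHM (Hz)
#' @param phaseRangeDeg half-range of the uniform global phase offset
#' @param noiseSd default k-space complex noise sd (per component)
#' @param includeMinor add small pyruvate-hydrate and alanine peaks
#' @param seed RNG seed for per-voxel amplitude draws
#' @return a [PhantomSpec-class]
#' @export
phantomSpec <- function(gridN = 16, fovMm = 64, sliceMm = 5,
                        brainCenter = c(0, 0), brainSemi = c(14, 10),
                        tumorCenter = c(5, 3), tumorSemi = c(6, 5),
                        tumorLacBic = 11.1, normalLacBic = 6.2,
                        tumorLacPyr = 0.46, normalLacPyr = 0.52,
                        ampCV = 0.10,
                        linewidthHz = c(pyr = 5, lac = 5, bic = 5,
                                        hyd = 5, ala = 5),
                        phaseRangeDeg = 45, noiseSd = 0,
                        includeMinor = FALSE, seed = 1L) {
  tumorAmp <- c(pyr = 1, lac = tumorLacPyr,
                bic = tumorLacPyr / tumorLacBic,
                hyd = 0.05, ala = 0.03)
  normalAmp <- c(pyr = 1, lac = normalLacPyr,
                 bic = normalLacPyr / normalLacBic,
                 hyd = 0.05, ala = 0.03)
  if (!includeMinor) {
    tumorAmp <- tumorAmp[c("pyr", "lac", "bic")]
    normalAmp <- normalAmp[c("pyr", "lac", "bic")]
  }
  new("PhantomSpec", gridN = as.integer(gridN), fovMm = fovMm,
      sliceMm = sliceMm, brainCenter = brainCenter, brainSemi = brainSemi,
      tumorCenter = tumorCenter, tumorSemi = tumorSemi,
      tumorAmp = tumorAmp, normalAmp = normalAmp, ampCV = ampCV,
      linewidthHz = linewidthHz[names(tumorAmp)],
      phaseRangeDeg = phaseRangeDeg, noiseSd = noiseSd,
      includeMinor = includeMinor, seed = as.integer(seed))
}

# voxel-centre coordinates (mm) of an n-point axis over fov, centred so
# that index n/2 + 1 (0-based n/2) sits at 0 -- the DC/grid centre
gridCoords <- function(n, fovMm) {
  (seq_len(n) - 1 - floor(n / 2)) * (fovMm / n)
}

insideEllipse <- function(x, y, center, semi) {
  outer(x - center[1], rep(1, length(y)))^2 / semi[1]^2 +
    outer(rep(1, length(x)), y - center[2])^2 / semi[2]^2 <= 1
}

#' Generate a ground-truth digital phantom
#'
#' Labels each voxel background / normal brain / tumour from the spec's
#' ellipse geometry and draws per-voxel metabolite amplitudes as
#' truncated normals around the per-tissue means with CV `spec@ampCV`.
#' A single global zero-order phase offset is drawn uniformly in
#' +/- `spec@phaseRangeDeg`. Deterministic given `spec@seed`.
#'
#' @param spec a [PhantomSpec-class]
#' @return a [Phantom-class]
#' @export
makePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  n <- spec@gridN
  xy <- gridCoords(n, spec@fovMm)
  brain <- insideEllipse(xy, xy, spec@brainCenter, spec@brainSemi)
  tumor <- insideEllipse(xy, xy, spec@tumorCenter, spec@tumorSemi)
  labels <- matrix(0L, n, n)
  labels[brain] <- 1L
  labels[tumor & brain] <- 2L
  if (!any(labels == 2L)) stop("geometry error: tumor contains no voxel")
  mets <- names(spec@tumorAmp)
  amps <- array(0, dim = c(n, n, length(mets)),
                dimnames = list(NULL, NULL, mets))
  phase <- withSeed(spec@seed, {
    for (m in mets) {
      a <- matrix(0, n, n)
      for (lab in 1:2) {
        mu <- if (lab == 2L) spec@tumorAmp[m] else spec@normalAmp[m]
        idx <- which(labels == lab)
        a[idx] <- pmax(stats::rnorm(length(idx), mu, spec@ampCV * mu), 0)
      }
      amps[, , m] <- a
    }
    stats::runif(1, -spec@phaseRangeDeg, spec@phaseRangeDeg) * pi / 180
  })
  new("Phantom", labels = labels, amplitudes = amps, phaseRad = phase,
      linewidthHz = spec@linewidthHz, spec = spec)
}

#' @rdname truthRatios
#' @export
setMethod("truthRatios", "Phantom", function(object) {
  one <- function(lab) {
    idx <- object@labels == lab
    s <- apply(object@amplitudes, 3, function(m) sum(m[idx]))
    c(lacPyr = unname(s["lac"] / s["pyr"]),
      bicPyr = unname(s["bic"] / s["pyr"]),
      lacBic = unname(s["lac"] / s["bic"]))
  }
  list(tumor = one(2L), normal = one(1L))
})

#' Synthesize one complex FID from metabolite amplitudes
#'
#' FID(t_j) = sum_m A_m exp(i 2 pi f_m t_j) exp(-pi LW_m t_j) exp(i phi),
#' with t_j = j / bwHz (j = 0, ..., nSamples - 1) and f_m the offset of
#' metabolite m from the carrier (ppm difference times f0Mhz).
#'
#' @param amplitudes named per-metabolite amplitudes (names must be a
#'   subset of pyr, lac, bic, hyd, ala)
#' @param phases single global phase (rad) or named per-metabolite phases
#' @param linewidths named per-metabolite Lorentzian FWHM (Hz)
#' @param params an [AcqParams-class] (bwHz, nSamples, carrierPpm, f0Mhz)
#' @return complex vector of length `params@nSamples`
#' @export
synthesizeFid <- function(amplitudes, phases = 0, linewidths, params) {
  stopifnot(is(params, "AcqParams"))
  mets <- names(amplitudes)
  if (is.null(mets) || !all(mets %in% names(METAB_PPM)))
    stop("amplitudes must be named with known metabolites")
  if (any(linewidths[mets] < 0))
    stop("invalid-parameter: negative linewidth")
  if (length(phases) == 1 && is.null(names(phases)))
    phases <- stats::setNames(rep(phases, length(mets)), mets)
  tj <- (seq_len(params@nSamples) - 1) / params@bwHz
  fid <- complex(real = numeric(params@nSamples))
  for (m in mets) {
    fm <- (METAB_PPM[m] - params@carrierPpm) * params@f0Mhz
    fid <- fid + amplitudes[m] *
      exp((2i * pi * fm - pi * linewidths[m]) * tj + 1i * phases[m])
  }
  unname(fid)
}

# voxel FID array (n x n x nSamples) for a phantom: each metabolite adds
# its complex exponential weighted by the voxel amplitude map
voxelFids <- function(phantom, params) {
  n <- dim(phantom@labels)[1]
  ns <- params@nSamples
  tj <- (seq_len(ns) - 1) / params@bwHz
  out <- array(0i, dim = c(n, n, ns))
  for (m in dimnames(phantom@amplitudes)[[3]]) {
    fm <- (METAB_PPM[m] - params@carrierPpm) * params@f0Mhz
    prof <- exp((2i * pi * fm - pi * phantom@linewidthHz[m]) * tj)
    amp <- phantom@amplitudes[, , m]
    out <- out + outer(amp, prof)
  }
  out * exp(1i * phantom@phaseRad)
}

#' Synthesize a phase-encoded CSI k-space dataset from a phantom
#'
#' For each time sample, the k-space grid is the unitary 2-D DFT of the
#' voxel FID grid (DC encode at the grid centre), matching the inverse
#' used by [spatialRecon()]. i.i.d. circular complex Gaussian noise of
#' per-component sd `noiseSd` is added to every sample; the draw is
#' deterministic given `seed`.
#'
#' @param phantom a [Phantom-class]
#' @param params an [AcqParams-class]; matrix must match the phantom grid
#' @param noiseSd complex noise sd per real component
#' @param seed RNG seed for the noise draw
#' @param animalId,timepoint session metadata stored on the dataset
#' @return a [CsiDataset-class]
#' @export
synthesizeCsi <- function(phantom, params = acqParams(), noiseSd = 0,
                          seed = 1L, animalId = "phantom",
                          timepoint = "baseline") {
  stopifnot(is(phantom, "Phantom"), is(params, "AcqParams"))
  n <- dim(phantom@labels)[1]
  if (n != params@matrixSize)
    stop("shape error: phantom grid does not match acquisition matrix")
  fids <- voxelFids(phantom, params)
  ks <- array(0i, dim = dim(fids))
  for (j in seq_len(params@nSamples))
    ks[, , j] <- fftshift2(fft2u(ifftshift2(fids[, , j])))
  if (noiseSd > 0) {
    ks <- ks + withSeed(seed, {
      ntot <- length(ks)
      complex(real = stats::rnorm(ntot, 0, noiseSd),
              imaginary = stats::rnorm(ntot, 0, noiseSd))
    })
  }
  tr <- truthRatios(phantom)
  new("CsiDataset", kspace = ks, params = params, animalId = animalId,
      timepoint = timepoint, seed = as.integer(seed), noiseSd = noiseSd,
      truth = list(ratios = tr, phaseRad = phantom@phaseRad))
}

#' Synthesize a dynamic slice-FID series from metabolite time curves
#'
#' Emulates the single-slice pulse-and-acquire timing experiment: one
#' whole-slice FID (default 2048 samples at 5000 Hz) every `trDynS`
#' seconds, with metabolite amplitudes following `curves` sampled at the
#' acquisition times, plus circular complex Gaussian noise.
#'
#' @param curves a [TimeCurves-class] covering the acquisition span
#' @param params an [AcqParams-class]; `nSamples` is the readout length
#'   (2048 for the timing experiment) and `trDynS` the spacing
#' @param noiseSd complex noise sd per real component
#' @param seed RNG seed
#' @param linewidthHz named per-metabolite FWHM (Hz)
#' @return a [DynamicSeries-class]
#' @export
synthesizeDynamicSeries <- function(curves,
                                    params = acqParams(nSamples = 2048),
                                    noiseSd = 0, seed = 1L,
                                    linewidthHz = c(pyr = 8, lac = 8,
                                                    bic = 8)) {
  stopifnot(is(curves, "TimeCurves"), is(params, "AcqParams"))
  tAcq <- seq(0, max(curves@t), by = params@trDynS)
  if (length(tAcq) < 2)
    stop("invalid-window: curves do not cover one dynamic TR")
  samp <- function(s) stats::approx(curves@t, s, xout = tAcq)$y
  amp <- cbind(pyr = samp(curves@pyr), lac = samp(curves@lac),
               bic = samp(curves@bic))
  fids <- vapply(seq_along(tAcq), function(k) {
    synthesizeFid(amp[k, ], phases = 0, linewidths = linewidthHz, params)
  }, complex(params@nSamples))
  if (noiseSd > 0) {
    fids <- fids + withSeed(seed, {
      complex(real = stats::rnorm(length(fids), 0, noiseSd),
              imaginary = stats::rnorm(length(fids), 0, noiseSd))
    })
  }
  new("DynamicSeries", fids = fids, tAcq = tAcq, params = params,
      linewidthHz = linewidthHz)
}

#' Tissue masks on the interpolated map grid
#'
#' Builds tumour and normal-brain logical masks aligned to the
#' `factor`-interpolated reconstruction grid from the phantom's ellipse
#' geometry. The tumour mask can be eroded (semi-axes reduced by
#' `erodeMm`) and the normal mask additionally excludes a `guardMm` ring
#' around the tumour, keeping ROI statistics away from partial-volume
#' edges.
#'
#' @param phantom a [Phantom-class]
#' @param factor interpolation factor of the map grid
#' @param erodeMm erosion of each region's boundary (mm)
#' @param guardMm exclusion margin around the tumour in the normal mask
#' @return list of logical matrices `tumor` and `normal`
#' @export
tissueMasks <- function(phantom, factor = 4, erodeMm = 2, guardMm = 2) {
  spec <- phantom@spec
  n <- spec@gridN * factor
  xy <- gridCoords(n, spec@fovMm)
  shrink <- function(semi, d) pmax(semi - d, spec@fovMm / n)
  tum <- insideEllipse(xy, xy, spec@tumorCenter,
                       shrink(spec@tumorSemi, erodeMm))
  brain <- insideEllipse(xy, xy, spec@brainCenter,
                         shrink(spec@brainSemi, erodeMm))
  tumGuard <- insideEllipse(xy, xy, spec@tumorCenter,
                            spec@tumorSemi + guardMm)
  list(tumor = tum & brain, normal = brain & !tumGuard)
}

#' Calibrate the k-space noise sd for a target reconstructed SNR
#'
#' SNR is defined as the noiseless tumour-voxel pyruvate peak height
#' (real part, after phasing) in the reconstructed spectrum divided by
#' the spectral noise sd after reconstruction. The noise propagation
#' factor is measured empirically by reconstructing a noise-only dataset
#' with unit k-space sd.
#'
#' @param phantom a [Phantom-class]
#' @param params an [AcqParams-class]
#' @param snr target SNR
#' @param lbHz,zerofill reconstruction settings the SNR refers to
#' @return k-space complex noise sd (per real component)
#' @export
calibrateNoiseSd <- function(phantom, params = acqParams(), snr = 20,
                             lbHz = 15, zerofill = 4) {
  ds0 <- synthesizeCsi(phantom, params, noiseSd = 0)
  spec0 <- reconSpectra(ds0@kspace, params, lbHz, zerofill)
  # tumour-centre voxel on the interpolated grid
  sp <- phantom@spec
  n4 <- sp@gridN * zerofill
  cx <- round(sp@tumorCenter / (sp@fovMm / n4)) + floor(n4 / 2) + 1
  vox <- (cx[2] - 1) * n4 + cx[1]
  pk <- defaultPeaks()
  win <- peakWindowBins(spec0$ppm, pk[pk$name == "pyr", ])
  S <- sum(spec0$values[win, vox])
  peakHeight <- max(Re(exp(-1i * Arg(S)) * spec0$values[win, vox]))
  # unit-noise propagation through the same pipeline
  ksn <- withSeed(271828L, array(
    complex(real = stats::rnorm(length(ds0@kspace), 0, 1),
            imaginary = stats::rnorm(length(ds0@kspace), 0, 1)),
    dim = dim(ds0@kspace)))
  specn <- reconSpectra(ksn, params, lbHz, zerofill)
  g <- stats::sd(c(Re(specn$values), Im(specn$values)))
  peakHeight / (snr * g)
}
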