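p16 <- acqParams()

test_that("apodization follows the stated exponential and adds linewidth", {
  dwell <- 1 / p16@bwHz
  fid <- rep(1 + 0i, 64)
  expect_identical(apodize(fid, 0, dwell), fid)
  out <- apodize(fid, 15, dwell)
  expect_equal(out, complex(real =
    exp(-pi * 15 * (0:63) * dwell)), tolerance = 1e-12)
  expect_error(apodize(complex(0), 15, dwell), "empty-input")

  # 20 Hz line + 15 Hz broadening -> 35 Hz measured FWHM
  fid <- synthesizeFid(c(pyr = 1), 0, c(pyr = 20), p16)
  sp <- fidToSpectrum(apodize(fid, 15, dwell), p16, 4)
  expect_equal(measureFwhm(sp), 35, tolerance = 1 / 35)
})

test_that("fidToSpectrum places tones correctly and interpolates 4x", {
  tj <- (seq_len(p16@nSamples) - 1) / p16@bwHz
  tone <- exp(2i * pi * 500 * tj)
  sp <- fidToSpectrum(tone, p16, 4)
  expect_length(sp@values, 1024)
  expect_equal(sp@hz[which.max(Mod(sp@values))], 500,
               tolerance = (p16@bwHz / 1024) / 500)
  # ppm axis maps the carrier to the centre bin
  expect_equal(sp@ppm[513], p16@carrierPpm)
})

test_that("spatial reconstruction inverts the phase-encode model", {
  # one-voxel phantom: forward then inverse localizes at the source
  sp <- phantomSpec(ampCV = 0)
  ph <- makePhantom(sp)
  src <- which(ph@labels == 2L, arr.ind = TRUE)[1, ]
  one <- ph
  for (m in seq_len(dim(one@amplitudes)[3])) {
    a <- matrix(0, 16, 16); a[src[1], src[2]] <- 1
    one@amplitudes[, , m] <- a
  }
  one@labels[] <- 0L; one@labels[src[1], src[2]] <- 2L
  ds <- synthesizeCsi(one, p16, 0)

  # zerofill 1 inverts the forward model exactly: all energy in the
  # source voxel, off-peak magnitude at numerical zero
  img1 <- spatialRecon(ds@kspace[, , 1], zerofill = 1)
  expect_equal(dim(img1), c(16L, 16L, 1L))
  m1 <- Mod(img1[, , 1])
  expect_equal(which.max(m1), unname((src[2] - 1) * 16 + src[1]))
  expect_lt(sort(m1, decreasing = TRUE)[2] / max(m1), 1e-9)

  # zerofill 4: dominant peak at the interpolated source location;
  # the sinc (Dirichlet) interpolation kernel has ~11% sidelobes along
  # the axes, so off-peak magnitude is bounded, not negligible
  img4 <- spatialRecon(ds@kspace[, , 1], zerofill = 4)[, , 1]
  pk <- which(Mod(img4) == max(Mod(img4)), arr.ind = TRUE)[1, ]
  expect_equal(unname(pk), unname(src * 4 - 3))
  dist <- sqrt(outer((seq_len(64) - pk[1])^2,
                     (seq_len(64) - pk[2])^2, "+"))
  expect_lt(max(Mod(img4)[dist >= 4]) / max(Mod(img4)), 0.25)

  expect_error(spatialRecon(matrix(0i, 8, 4)), "shape error")
})

test_that("zero-order phase estimation recovers constructed phases", {
  pk <- defaultPeaks()
  fid <- synthesizeFid(c(pyr = 1), 0, c(pyr = 25), p16)
  sp0 <- fidToSpectrum(apodize(fid, 15, 1 / p16@bwHz), p16, 4)

  # already phased
  phi0 <- estimateZeroOrderPhase(sp0, pk[pk$name == "pyr", ])
  expect_lt(abs(phi0) * 180 / pi, 0.5)

  # premultiplied by 30 degrees
  sp30 <- sp0
  sp30@values <- sp0@values * exp(1i * 30 * pi / 180)
  phi30 <- estimateZeroOrderPhase(sp30, pk[pk$name == "pyr", ])
  expect_equal(as.numeric(phi30) * 180 / pi, 30, tolerance = 0.5 / 30)

  # Monte-Carlo at spectral SNR 10: |error| < 5 degrees in >= 95/100
  peakH <- max(Re(sp0@values))
  set.seed(123)
  errs <- replicate(100, {
    spn <- sp0
    nn <- length(spn@values)
    spn@values <- spn@values * exp(1i * 0.3) +
      complex(real = rnorm(nn, 0, peakH / 10 / sqrt(2)),
              imaginary = rnorm(nn, 0, peakH / 10 / sqrt(2)))
    est <- estimateZeroOrderPhase(spn, pk[pk$name == "pyr", ])
    abs(as.numeric(est) - 0.3) * 180 / pi
  })
  expect_gte(mean(errs < 5), 0.95)

  # all-zero window falls back with the low-signal flag
  spz <- sp0; spz@values[] <- 0i
  phiz <- estimateZeroOrderPhase(spz, pk[pk$name == "pyr", ])
  expect_equal(as.numeric(phiz), 0)
  expect_true(attr(phiz, "lowSignal"))
})

test_that("absorption-mode integration matches the analytic Lorentzian tail fraction", {
  pk <- data.frame(name = "pyr", center_ppm = 171,
                   halfwidth_ppm = 4 * 15 / 32.13)  # halfwidth = 4 x FWHM
  n <- p16@nSamples
  # a causal FID's absorption spectrum integrates to x0/2, so amplitude
  # 2*sqrt(Npad)/bw gives unit continuous area under the peak
  A <- 2 * sqrt(4 * n) / p16@bwHz
  fid <- A * exp(-pi * 15 * (seq_len(n) - 1) / p16@bwHz)
  sp <- fidToSpectrum(fid, p16, 4)
  got <- integratePeakAbsorption(sp, pk, phase = 0)
  # fraction of a Lorentzian within +/- 4 FWHM of centre
  expect_equal(as.numeric(got), (2 / pi) * atan(8), tolerance = 0.02)

  expect_equal(as.numeric(integratePeakAbsorption(
    new("Spectrum", values = complex(real = numeric(1024)), hz = sp@hz,
        ppm = sp@ppm, voxel = integer(0)),
    pk, phase = 0)), 0)

  # two equal peaks in disjoint windows integrate equally
  pks <- defaultPeaks()
  fid2 <- synthesizeFid(c(lac = 1, bic = 1), 0, c(lac = 6, bic = 6), p16)
  sp2 <- fidToSpectrum(apodize(fid2, 15, 1 / p16@bwHz), p16, 4)
  iL <- integratePeakAbsorption(sp2, pks[pks$name == "lac", ], phase = 0)
  iB <- integratePeakAbsorption(sp2, pks[pks$name == "bic", ], phase = 0)
  expect_equal(as.numeric(iL), as.numeric(iB), tolerance = 0.01)
})

test_that("full reconstruction is linear and absorbs global phase rotations", {
  ph <- makePhantom(phantomSpec())
  ds <- synthesizeCsi(ph, p16, 0)
  maps <- reconstructMaps(ds)
  expect_equal(maps@resMm, 1)
  expect_equal(dim(maps@maps)[1:2], c(64L, 64L))

  ds3 <- ds; ds3@kspace <- ds@kspace * 3
  maps3 <- reconstructMaps(ds3)
  expect_equal(maps3@maps, 3 * maps@maps, tolerance = 1e-9)

  msk <- tissueMasks(ph)
  base <- roiRatios(maps, msk$tumor)@lacBic
  for (deg in c(10, 45, 170)) {
    dsr <- ds; dsr@kspace <- ds@kspace * exp(1i * deg * pi / 180)
    mr <- reconstructMaps(dsr)
    for (nm in mapNames(maps))
      expect_lt(max(abs(getMap(mr, nm) - getMap(maps, nm))) /
                  max(getMap(maps, nm)), 0.01)
    expect_equal(roiRatios(mr, msk$tumor)@lacBic, base,
                 tolerance = 1e-6)
  }
})

test_that("uniform-signal brain reconstructs with low interior variability", {
  sp <- phantomSpec(tumorLacBic = 6.2, normalLacBic = 6.2,
                    tumorLacPyr = 0.52, normalLacPyr = 0.52, ampCV = 0)
  ph <- makePhantom(sp)
  maps <- reconstructMaps(synthesizeCsi(ph, p16, 0))
  interior <- tissueMasks(ph, erodeMm = 4)$normal |
    tissueMasks(ph, erodeMm = 4)$tumor
  for (nm in c("pyr", "lac", "bic")) {
    v <- getMap(maps, nm)[interior]
    expect_lt(sd(v) / mean(v), 0.05)
  }
})

test_that("line broadening lowers map noise without moving the ratio estimate", {
  ph <- makePhantom(phantomSpec())
  nsd <- calibrateNoiseSd(ph, p16, snr = 500)
  ds0 <- synthesizeCsi(ph, p16, 0)
  dsn <- synthesizeCsi(ph, p16, noiseSd = nsd, seed = 21L)
  msk <- tissueMasks(ph)
  tr <- truthRatios(ph)

  noiseSdOf <- function(lb) {
    m0 <- reconstructMaps(ds0, lbHz = lb)
    mn <- reconstructMaps(dsn, lbHz = lb)
    # noise measured against the noiseless reconstruction, scale-matched
    d <- (getMap(mn, "lac") - getMap(m0, "lac"))[msk$normal]
    sd(d) / mean(getMap(m0, "lac")[msk$normal])
  }
  expect_lt(noiseSdOf(15), noiseSdOf(0))

  # the SNR gain costs no additional ratio bias on noiseless truth
  # (without apodization the barely-decayed FID's truncation ringing
  # itself moves the tumour Lac/Bic by several percent)
  biasOf <- function(lb) {
    m0 <- reconstructMaps(ds0, lbHz = lb)
    roiRatios(m0, msk$tumor)@lacBic / tr$tumor["lacBic"] - 1
  }
  expect_lte(abs(biasOf(15)), abs(biasOf(0)) + 0.03)
})
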