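test_that("phantom amplitudes honour tissue means, CV and determinism", {
  # zero CV: every voxel carries exactly the target ratios
  sp0 <- phantomSpec(ampCV = 0)
  ph0 <- makePhantom(sp0)
  tum <- ph0@labels == 2L
  expect_true(all(abs(ph0@amplitudes[, , "lac"][tum] /
                        ph0@amplitudes[, , "bic"][tum] - 11.1) < 1e-9))
  tr0 <- truthRatios(ph0)
  expect_equal(unname(tr0$tumor["lacBic"]), 11.1)
  expect_equal(unname(tr0$normal["lacBic"]), 6.2)

  # default CV: realized per-tissue means within 10% of targets
  tr <- truthRatios(makePhantom(phantomSpec()))
  expect_equal(unname(tr$tumor["lacBic"]), 11.1, tolerance = 0.1)
  expect_equal(unname(tr$normal["lacBic"]), 6.2, tolerance = 0.1)

  # determinism: same seed identical, different seed different
  a <- makePhantom(phantomSpec(seed = 5))
  b <- makePhantom(phantomSpec(seed = 5))
  c <- makePhantom(phantomSpec(seed = 6))
  expect_identical(a@amplitudes, b@amplitudes)
  expect_false(identical(a@amplitudes, c@amplitudes))
})

test_that("tumor geometry outside the brain is rejected", {
  expect_error(phantomSpec(tumorCenter = c(12, 8)), "geometry")
})

test_that("synthesizeFid produces the stated complex model", {
  p <- acqParams()
  # single metabolite, no decay, no phase: pure complex exponential
  fid <- synthesizeFid(c(lac = 2), phases = 0,
                       linewidths = c(lac = 1e-12), p)
  tj <- (seq_len(p@nSamples) - 1) / p@bwHz
  fl <- (183.2 - 171.0) * 32.13
  expect_equal(fid, 2 * exp(2i * pi * fl * tj), tolerance = 1e-9)

  expect_true(all(synthesizeFid(c(pyr = 0, lac = 0, bic = 0), 0,
                                c(pyr = 5, lac = 5, bic = 5), p) == 0))
  expect_error(synthesizeFid(c(pyr = 1), 0, c(pyr = -2), p),
               "invalid-parameter")
})

test_that("a 20 Hz Lorentzian line shows a 20 Hz FWHM in the spectrum", {
  # long readout so that truncation broadening is negligible (the 19 Hz
  # sinc convolution of a 51 ms readout would widen the line by ~8%)
  p <- acqParams(nSamples = 2048)
  fid <- synthesizeFid(c(pyr = 1), phases = 0, linewidths = c(pyr = 20), p)
  sp <- fidToSpectrum(fid, p, zerofill = 4)
  expect_equal(measureFwhm(sp, centerHz = 0), 20, tolerance = 1 / 20)
})

test_that("k-space synthesis: point source, determinism and linearity", {
  sp <- phantomSpec(ampCV = 0)
  ph <- makePhantom(sp)
  # single nonzero voxel: |k| constant across encodes at fixed t
  one <- ph
  keep <- which(ph@labels == 2L)[1]
  for (m in seq_len(dim(one@amplitudes)[3])) {
    a <- matrix(0, 16, 16)
    a[keep] <- 1
    one@amplitudes[, , m] <- a
  }
  one@labels[] <- 0L; one@labels[keep] <- 2L
  ds1 <- synthesizeCsi(one, acqParams(), 0)
  mags <- Mod(ds1@kspace[, , 3])
  expect_lt(diff(range(mags)) / mean(mags), 1e-9)

  # identical seed, bit-identical noise draw
  dsa <- synthesizeCsi(ph, acqParams(), noiseSd = 0.1, seed = 9L)
  dsb <- synthesizeCsi(ph, acqParams(), noiseSd = 0.1, seed = 9L)
  expect_identical(dsa@kspace, dsb@kspace)

  # linearity: scaling amplitudes scales k-space (noise off)
  ph3 <- ph
  ph3@amplitudes <- ph3@amplitudes * 3
  ds <- synthesizeCsi(ph, acqParams(), 0)
  ds3 <- synthesizeCsi(ph3, acqParams(), 0)
  expect_equal(ds3@kspace, 3 * ds@kspace, tolerance = 1e-12)
})

test_that("voxel FID energy equals spectrum energy (unitary transform)", {
  p <- acqParams()
  fid <- synthesizeFid(c(pyr = 1, lac = 0.5, bic = 0.05),
                       phases = 0.4,
                       linewidths = c(pyr = 8, lac = 8, bic = 8), p)
  sp <- fidToSpectrum(fid, p, zerofill = 1, firstPointHalf = FALSE)
  expect_equal(sum(Mod(fid)^2), sum(Mod(sp@values)^2), tolerance = 1e-9)
})

test_that("dynamic series round-trips metabolite time courses", {
  cv <- simulateDynamics(kineticParams(), tEnd = 90, dt = 0.1)
  ser <- synthesizeDynamicSeries(cv, acqParams(nSamples = 2048),
                                 noiseSd = 0)
  expect_equal(ncol(ser@fids), length(seq(0, 90, by = 3)))

  rec <- reconstructDynamics(ser)
  at <- match(ser@tAcq, cv@t)
  expect_gt(cor(rec@pyr, cv@pyr[at]), 0.999)
  expect_gt(cor(rec@lac, cv@lac[at]), 0.999)
  # bicarbonate carries ~0.5% of the pyruvate area as Lorentzian-tail
  # cross-talk, which caps its correlation slightly below the others
  expect_gt(cor(rec@bic, cv@bic[at]), 0.99)

  pk <- peakTimes(rec)
  expect_equal(unname(pk["pyr"]), 20, tolerance = 2.9 / 20)
  expect_equal(unname(pk["lac"]), 28, tolerance = 2.9 / 28)
  expect_equal(unname(pk["bic"]), 33, tolerance = 2.9 / 33)

  zero <- new("TimeCurves", t = cv@t, pyr = 0 * cv@t, lac = 0 * cv@t,
              bic = 0 * cv@t)
  serz <- synthesizeDynamicSeries(zero, acqParams(nSamples = 2048), 0)
  expect_true(all(serz@fids == 0))
})

test_that("cohort generator reproduces group structure and effects", {
  co <- makeCohort(cohortSpec())
  expect_equal(nrow(co), 25)
  expect_equal(as.vector(table(co$group)[c("deceased", "survivor",
                                           "control")]), c(6L, 7L, 12L))
  # survivors censored at day 70 without event
  expect_true(all(co$survival_day[co$group == "survivor"] == 70))
  expect_true(all(co$event[co$group == "survivor"] == 0))
  expect_true(all(co$survival_day > 0))

  # zero jitter: survivor post/pre ratio is exactly the group effect
  co0 <- makeCohort(cohortSpec(effectSdLog = 0))
  sv <- co0$group == "survivor"
  expect_equal(co0$post_lacbic_tumor[sv] / co0$pre_lacbic_tumor[sv],
               rep(0.823, 7))

  expect_error(makeCohort(cohortSpec(nDeceased = 0, nSurvivors = 0,
                                     nControls = 0)), "empty-cohort")
})

test_that("deceased survival sampling is consistent with its target mean", {
  co <- makeCohort(cohortSpec(nDeceased = 1000, nSurvivors = 0,
                              nControls = 0, seed = 3))
  expect_equal(mean(co$survival_day), 13.5, tolerance = 0.2 / 13.5)
})

test_that("same cohort seed yields byte-identical CSV output", {
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  writeCohort(makeCohort(cohortSpec(seed = 11)), f1)
  writeCohort(makeCohort(cohortSpec(seed = 11)), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("most survivors decrease and most deceased increase Lac/Bic at 48 h", {
  co <- makeCohort(cohortSpec(nDeceased = 300, nSurvivors = 300,
                              nControls = 0, seed = 7))
  dec <- co$group == "deceased"; sur <- co$group == "survivor"
  expect_gte(mean(co$post_lacbic_tumor[dec] > co$pre_lacbic_tumor[dec]),
             0.9)
  expect_gte(mean(co$post_lacbic_tumor[sur] < co$pre_lacbic_tumor[sur]),
             0.9)
})
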