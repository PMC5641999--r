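test_that("apodization applies the exponential window exactly", {
  fid <- nmrFid(rep(1 + 0i, 2048), dwellTime = 1e-3)
  ## lb = 0 is the identity
  expect_identical(apodize(fid, 0)@points, fid@points)
  a <- apodize(fid, 1)
  ## first point always unchanged
  expect_equal(Mod(a@points[1]), 1)
  ## closed form of the window: t = 1 s after 1000 dwell periods of 1 ms
  expect_equal(Re(a@points[1001]), exp(-pi), tolerance = 1e-12)
  expect_error(apodize(fid, -1), "lbHz")
})

test_that("zero-filling appends exact zeros and preserves content", {
  set.seed(2)
  pts <- complex(real = rnorm(1024), imaginary = rnorm(1024))
  fid <- nmrFid(pts, dwellTime = 1e-4)
  expect_identical(zeroFill(fid, 1024)@points, fid@points)
  z <- zeroFill(fid, 4096)
  expect_length(z@points, 4096)
  expect_true(all(z@points[1025:4096] == 0))
  expect_equal(sum(Mod(z@points)), sum(Mod(pts)))
  expect_error(zeroFill(fid, 512), "cannot zero-fill")
})

test_that("Fourier transform places a damped exponential at the right ppm", {
  ## FID of a single resonance 300 Hz above the carrier
  sw <- 2400
  n <- 4096
  dt <- 1 / sw
  t <- (0:(n - 1)) * dt
  f0 <- 300
  fid <- nmrFid(exp(2i * pi * f0 * t - t / 0.3), dwellTime = dt,
                frequencyMHz = 600, carrierPpm = 4.7)
  sp <- fourierTransform(fid)
  expect_true(all(diff(sp@ppm) < 0))
  apex <- sp@ppm[which.max(sp@intensity)]
  expect_equal(apex, 4.7 + f0 / 600, tolerance = sw / n / 600 + 1e-9)
  ## Parseval: energy preserved by the transform
  expect_equal(sum(Mod(sp@complexIntensity)^2) / n, sum(Mod(fid@points)^2),
               tolerance = 1e-9)
  ## zero FID -> zero spectrum
  z <- fourierTransform(nmrFid(rep(0 + 0i, 64), dwellTime = dt))
  expect_equal(max(abs(z@intensity)), 0)
})

test_that("zero-order phasing behaves as a rotation group and finds 0 when phased", {
  sw <- 2400
  n <- 2048
  dt <- 1 / sw
  t <- (0:(n - 1)) * dt
  fid <- nmrFid(exp(2i * pi * 200 * t - t / 0.2), dwellTime = dt,
                frequencyMHz = 600, carrierPpm = 4.7)
  sp <- fourierTransform(fid)
  ## explicit zero phase is the identity
  expect_equal(phaseCorrect(sp, 0)@intensity, sp@intensity, tolerance = 1e-12)
  ## +90 then -90 degrees is the identity
  back <- phaseCorrect(phaseCorrect(sp, 90), -90)
  expect_equal(back@intensity, sp@intensity, tolerance = 1e-12)
  ## an already-phased absorption spectrum needs (close to) no phase
  auto <- phaseCorrect(sp, "auto")
  expect_lt(min(abs(c(auto@processing$phi0, auto@processing$phi0 - 360,
                      auto@processing$phi0 + 360))), 1)
  ## a deliberately rotated spectrum is recovered
  rot <- phaseCorrect(sp, 135)
  fixed <- phaseCorrect(rot, "auto")
  expect_gt(cor(fixed@intensity, sp@intensity), 0.9999)
})

test_that("baseline correction removes smooth offsets without touching peaks", {
  ppm <- seq(9, 1, by = -1e-3)
  h <- 0.002
  peaks <- 1 / (1 + ((ppm - 5) / h)^2) + 0.6 / (1 + ((ppm - 2.2) / h)^2)
  cOff <- 0.35
  sp <- nmrSpectrum(ppm, peaks + cOff)
  corr <- baselineCorrect(sp, lambda = 1e7, p = 0.001)
  ## constant offset removed to within 5%
  est <- sp@intensity - corr@intensity
  expect_lt(abs(median(est) - cOff), 0.05 * cOff)
  ## peak apexes unchanged
  expect_equal(which.max(corr@intensity), which.max(sp@intensity))
  ## the subtracted baseline is smooth: tiny second differences
  expect_lt(max(abs(diff(est, differences = 2))), 1e-4)
  ## an already-flat spectrum is barely altered
  flat <- nmrSpectrum(ppm, peaks)
  corr2 <- baselineCorrect(flat, lambda = 1e7, p = 0.001)
  expect_lt(max(abs(flat@intensity - corr2@intensity)), 0.05)
})

test_that("glucose referencing shifts, is idempotent, and fails on flat input", {
  ppm <- seq(6, 4.5, by = -1e-3)
  h <- 0.0015
  ## peak deliberately misplaced at 5.240 ppm
  sp <- nmrSpectrum(ppm, 1 / (1 + ((ppm - 5.240) / h)^2))
  ref <- referenceToGlucose(sp)
  expect_equal(ref@processing$referenceShift, -0.004, tolerance = 1e-9)
  expect_equal(ref@ppm[which.max(ref@intensity)], 5.236, tolerance = 1e-9)
  ## idempotent: a second application changes nothing
  ref2 <- referenceToGlucose(ref)
  expect_equal(ref2@ppm, ref@ppm, tolerance = 1e-12)
  ## already-referenced spectrum: identity
  sp0 <- nmrSpectrum(ppm, 1 / (1 + ((ppm - 5.236) / h)^2))
  expect_equal(referenceToGlucose(sp0)@ppm, sp0@ppm, tolerance = 1e-12)
  ## flat spectrum cannot be referenced
  expect_error(referenceToGlucose(nmrSpectrum(ppm, rep(1, length(ppm)))),
               "no local maximum")
  ## ties broken towards higher ppm: two spikes of identical height
  y <- rep(0, length(ppm))
  y[which.min(abs(ppm - 5.22))] <- 1
  y[which.min(abs(ppm - 5.26))] <- 1
  reft <- referenceToGlucose(nmrSpectrum(ppm, y),
                             processingConfig(referenceWindow = c(5.18, 5.30)))
  ## the higher-ppm spike (5.26) is the one moved onto 5.236
  expect_equal(reft@processing$referenceShift, 5.236 - 5.26, tolerance = 1e-9)
})

test_that("binning yields the exact grid, constant integrals and additivity", {
  cfg <- processingConfig()
  ppm <- seq(9.3, 0.3, by = -1e-3)
  ## constant intensity 1: every bin integrates to the bin width
  flat <- nmrSpectrum(ppm, rep(1, length(ppm)))
  b <- binSpectrum(flat, cfg)
  expect_equal(nrow(b), 2125)
  expect_equal(b$value, rep(0.004, 2125), tolerance = 1e-12)
  ## additivity: bin total equals the integral over the full range
  set.seed(4)
  y <- abs(rnorm(length(ppm))) + 0.1
  sp <- nmrSpectrum(ppm, y)
  b2 <- binSpectrum(sp, cfg)
  x <- rev(ppm)
  yy <- rev(y)
  totalRange <- serumNMR:::.cumTrapzAt(x, yy, 9.0) -
    serumNMR:::.cumTrapzAt(x, yy, 0.5)
  expect_equal(sum(b2$value), totalRange, tolerance = 1e-9 * abs(totalRange))
  ## bins ordered by descending ppm, constant width
  expect_true(all(diff(b2$ppmCenter) < 0))
  expect_equal(unique(round(b2$ppmUpper - b2$ppmLower, 12)), 0.004)
  ## a spectrum narrower than the bin range is rejected
  expect_error(binSpectrum(nmrSpectrum(seq(5, 1, by = -1e-3),
                                       rep(1, 4001)), cfg),
               "does not cover")
})

test_that("water-region exclusion drops exactly the intersecting bins", {
  cfg <- processingConfig()
  d <- noiselessDesign(groups = c(a = 2))
  co <- simulateCohort(d)
  b <- binSpectra(co, cfg)
  expect_equal(nrow(b), 2125)
  ## empty region list: identity
  expect_equal(nrow(excludeRegions(b, list())), 2125)
  ex <- excludeRegions(b, list(cfg@waterRegion))
  expect_equal(2125 - nrow(ex), 238)
  ## no surviving bin intersects the excluded region
  rd <- rowData(ex)
  expect_false(any(rd$ppmUpper > 4.23 + 1e-9 & rd$ppmLower < 5.18 - 1e-9))
  expect_equal(nrow(metadata(ex)$excludedRegions), 1)
})

test_that("segment alignment recovers synthetic displacements and logs shifts", {
  d <- noiselessDesign(groups = c(a = 4), intensityCv = 0.1, seed = 8)
  co <- simulateCohort(d)
  b <- excludeRegions(binSpectra(co))
  ## zero jitter: all shifts are zero
  al <- alignSegments(b)
  for (s in metadata(al)$alignmentShifts) expect_true(all(s == 0))
  ## displace one sample's alanine segment by +2 bins; alignment undoes it
  mat <- assay(b, "binned")
  ctr <- rowData(b)$ppmCenter
  idx <- which(ctr >= 1.43 & ctr <= 1.50)
  idx <- idx[order(ctr[idx], decreasing = TRUE)]
  seg <- mat[idx, 2]
  mat[idx, 2] <- serumNMR:::.shiftSegment(seg, 2L)
  assay(b, "binned") <- mat
  al2 <- alignSegments(b)
  expect_equal(unname(metadata(al2)$alignmentShifts[["1.43-1.5"]][2]), -2L)
  ## aligned segment is a shift-with-edge-padding of the displaced input
  expect_equal(assay(al2, "binned")[idx, 2],
               serumNMR:::.shiftSegment(mat[idx, 2], -2L), tolerance = 1e-12)
})

test_that("total-sum normalisation is exact, scale-invariant and guarded", {
  d <- noiselessDesign(groups = c(a = 3), intensityCv = 0.2, seed = 9)
  co <- simulateCohort(d)
  b <- excludeRegions(binSpectra(co))
  nb <- totalSumNormalize(b)
  expect_true(isNormalized(nb))
  expect_equal(unname(colSums(assay(nb, "binned"))), rep(1, 3),
               tolerance = 1e-9)
  ## scaling one sample by 7 pre-normalisation changes nothing
  b2 <- b
  assay(b2, "binned")[, 1] <- 7 * assay(b2, "binned")[, 1]
  nb2 <- totalSumNormalize(b2)
  expect_equal(assay(nb2, "binned"), assay(nb, "binned"), tolerance = 1e-12)
  ## an all-zero sample is rejected
  b3 <- b
  assay(b3, "binned")[, 1] <- 0
  expect_error(totalSumNormalize(b3), "positive sample sums")
})

test_that("the full chain is invariant to overall spectrum scale", {
  d <- cohortDesign(c(a = 2), noiseSd = 0.005, seed = 12,
                    ppmAxis = seq(9.5, 0.2, by = -0.001))
  co <- simulateCohort(d)
  scaled <- co
  scaled@spectra <- lapply(co@spectra, function(s) {
    s@intensity <- 7 * s@intensity
    s
  })
  b1 <- processCohort(co)
  b2 <- processCohort(scaled)
  expect_equal(assay(b1, "binned"), assay(b2, "binned"), tolerance = 1e-9)
})

test_that("fidToSpectrum runs the FID chain in order and survives a round trip", {
  ## build a synthetic spectrum, convert to FID, process back
  ppm <- seq(6.5, 4.0, by = -5e-4)
  h <- 0.003
  truth <- 1 / (1 + ((ppm - 5.236) / h)^2) + 0.5 / (1 + ((ppm - 4.4) / h)^2)
  sp <- nmrSpectrum(ppm, truth)
  fid <- spectrumToFid(sp, spectralWidthHz = 2000, nPoints = 16384)
  cfg <- processingConfig(lbHz = 0, zeroFillTo = 16384L,
                          binRange = c(4.1, 6.2), waterRegion = c(4.6, 4.8),
                          alignRegions = list(), baselineLambda = 1e8)
  out <- fidToSpectrum(fid, cfg)
  ## the glucose line ends up referenced at 5.236
  expect_equal(out@ppm[which.max(out@intensity)], 5.236, tolerance = 1e-6)
  expect_s4_class(out, "NMRSpectrum")
})
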