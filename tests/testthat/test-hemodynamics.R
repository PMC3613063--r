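test_that("automatic AIF selection finds the arterial voxels", {
  ph <- defaultPhantom()
  conc <- signalToConcentration(ph@series)
  bm <- computeBrainMask(ph@series)
  aif <- selectAif(conc, bm, k = 10)
  expect_identical(aif@method, "AUTO")

  # every selected voxel is a true vessel voxel
  sel <- aifSourceVoxels(aif)
  expect_true(all(ph@truthMasks$VESSEL[sel]))

  # shape matches the true AIF: after area normalization, peak error < 5%
  got <- aifCurve(aif) * sum(ph@aifTrue) / sum(aifCurve(aif))
  expect_equal(which.max(got), which.max(ph@aifTrue))
  expect_lt(abs(max(got) - max(ph@aifTrue)) / max(ph@aifTrue), 0.05)
})

test_that("manual AIF selection returns the mean of the given voxels", {
  ph <- defaultPhantom()
  conc <- signalToConcentration(ph@series)
  vox <- which(ph@truthMasks$GM, arr.ind = TRUE)[1:3, ]
  aif <- selectAif(conc, computeBrainMask(ph@series), voxels = vox)
  expect_identical(aif@method, "MANUAL")
  flat <- matrix(voxelData(conc), ncol = nDynamics(ph@series))
  idx <- vox[, 1] + (vox[, 2] - 1) * dim(voxelData(conc))[1]
  expect_equal(aifCurve(aif), colMeans(flat[idx, ]))
})

test_that("oversized k falls back to all candidates with a warning", {
  ph <- defaultPhantom()
  conc <- signalToConcentration(ph@series)
  bm <- computeBrainMask(ph@series)
  expect_warning(aif <- selectAif(conc, bm, k = 1e6), "candidate")
  expect_s4_class(aif, "ArterialInputFunction")
})

test_that("rCBV is the windowed concentration ratio times k_H/rho", {
  aif <- defaultAifCurve()
  aifObj <- new("ArterialInputFunction", curve = aif,
                sourceVoxels = matrix(1L, 1, 3), method = "MANUAL")

  # C = AIF -> rCBV = k_H/rho = 0.705; linear in the tissue curve
  rcbv <- computeRcbv(curveAsConc(aif), aifObj)
  expect_equal(voxelData(rcbv)[1, 1, 1], 0.705)
  expect_identical(mapUnits(rcbv), "relative")
  expect_equal(voxelData(computeRcbv(curveAsConc(2 * aif), aifObj))[1, 1, 1],
               1.410)
  expect_equal(voxelData(computeRcbv(curveAsConc(numeric(70)), aifObj))[1, 1, 1], 0)

  # scale invariance: C and AIF scaled by the same constant
  aifScaled <- new("ArterialInputFunction", curve = 3 * aif,
                   sourceVoxels = matrix(1L, 1, 3), method = "MANUAL")
  expect_equal(voxelData(computeRcbv(curveAsConc(3 * aif), aifScaled)),
               voxelData(rcbv), tolerance = 1e-12)

  # AIF with no mass inside the integration window (peak before dynamic 11)
  preBolusAif <- new("ArterialInputFunction", curve = c(1, numeric(69)),
                     sourceVoxels = matrix(1L, 1, 3), method = "MANUAL")
  expect_error(computeRcbv(curveAsConc(aif), preBolusAif), "integral")
})

test_that("convolution operators implement the discrete forward model", {
  # impulse AIF, tr = 1: Toeplitz operator is (rho/k_H) * identity
  impulse <- c(1, numeric(9))
  cfg <- deconvolutionConfig("sSVD", tr = 1)
  A <- buildConvolutionOperator(impulse, cfg)
  expect_equal(A@matrix, diag(10) / 0.705)

  # operator x residue reproduces the forward synthesis exactly (zero delay)
  aif <- defaultAifCurve()
  As <- buildConvolutionOperator(aif, deconvolutionConfig("sSVD", tr = 1))
  f <- discreteResidue(4, 50, 70)
  expect_equal(as.vector(As@matrix %*% f),
               synthesizeTissueCurve(aif, 4, 50, tr = 1), tolerance = 1e-12)

  # independent convolution oracle: direct double loop
  g <- exp(-(0:69) / 7)
  direct <- vapply(1:70, function(i)
    sum(aif[i - seq_len(i) + 1] * g[seq_len(i)]) / 0.705, numeric(1))
  expect_equal(as.vector(As@matrix %*% g), direct, tolerance = 1e-12)

  # circulant operator applied to a delta reproduces the padded AIF cyclically
  Ac <- buildConvolutionOperator(aif, deconvolutionConfig("cSVD", tr = 1))
  expect_equal(dim(Ac@matrix), c(140L, 140L))
  delta <- c(1, numeric(139))
  expect_equal(as.vector(Ac@matrix %*% delta), c(aif, numeric(70)) / 0.705,
               tolerance = 1e-12)
})

test_that("truncated SVD recovers the residue on noise-free curves", {
  aif <- defaultAifCurve()

  # AIF deconvolved by itself -> scaled delta with max k_H/rho = 0.705;
  # recovery sharpens as the truncation is lowered
  errAt <- function(frac) {
    op <- buildConvolutionOperator(aif, deconvolutionConfig(
      "sSVD", truncationFraction = frac, tr = 1))
    abs(max(deconvolveCurves(aif, op)) - 0.705) / 0.705
  }
  errs <- vapply(c(0.2, 0.05, 0.01), errAt, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.05)

  # GM-like voxel: max f recovers the generating discrete residue within 10%
  f <- discreteResidue(4, 50, 70)
  ct <- synthesizeTissueCurve(aif, 4, 50, tr = 1)
  op <- buildConvolutionOperator(aif, deconvolutionConfig(
    "sSVD", truncationFraction = 0.05, tr = 1))
  fRec <- deconvolveCurves(ct, op)
  expect_equal(max(fRec), max(f), tolerance = 0.10)

  expect_identical(deconvolveCurves(numeric(70), op), numeric(70))
})

test_that("forward-convolving the recovered residue reproduces the curve", {
  aif <- defaultAifCurve()
  for (m in c("sSVD", "cSVD")) {
    op <- buildConvolutionOperator(aif, deconvolutionConfig(
      m, truncationFraction = 0.02, tr = 1))
    ct <- synthesizeTissueCurve(aif, 4, 50, tr = 1)
    fRec <- deconvolveCurves(ct, op)
    back <- if (m == "sSVD") as.vector(op@matrix %*% fRec)
            else as.vector(op@matrix %*% c(fRec, numeric(70)))[1:70]
    relL2 <- sqrt(sum((back - ct)^2) / sum(ct^2))
    expect_lt(relL2, 0.05)
  }
})

test_that("rCBF maps are linear and delay-sensitive in the expected direction", {
  ph <- defaultPhantom()
  conc <- signalToConcentration(ph@series)
  bm <- computeBrainMask(ph@series)
  aifObj <- new("ArterialInputFunction", curve = ph@aifTrue,
                sourceVoxels = matrix(1L, 1, 3), method = "MANUAL")

  cfg <- deconvolutionConfig("sSVD", tr = 1)
  r1 <- computeRcbf(conc, aifObj, cfg, mask = bm)
  conc2 <- conc; conc2@conc <- conc@conc * 2
  r2 <- computeRcbf(conc2, aifObj, cfg, mask = bm)
  expect_equal(voxelData(r2), 2 * voxelData(r1), tolerance = 1e-8)

  # a zero concentration curve gives exactly zero rCBF
  rZero <- computeRcbf(curveAsConc(numeric(70)), aifObj, cfg)
  expect_equal(voxelData(rZero)[1, 1, 1], 0)

  # delayed bolus: circulant deconvolution is delay-insensitive, Toeplitz not
  phd <- delayedPhantom(4)
  concD <- signalToConcentration(phd@series)
  bmD <- computeBrainMask(phd@series)
  aifD <- new("ArterialInputFunction", curve = phd@aifTrue,
              sourceVoxels = matrix(1L, 1, 3), method = "MANUAL")
  rS <- computeRcbf(concD, aifD, deconvolutionConfig("sSVD", tr = 1), mask = bmD)
  rC <- computeRcbf(concD, aifD, deconvolutionConfig("cSVD", tr = 1), mask = bmD)
  nx <- dim(voxelData(rS))[1]
  delayed <- phd@truthMasks$GM | phd@truthMasks$WM
  delayed[seq_len(nx / 2), , ] <- FALSE
  expect_true(all(voxelData(rC)[delayed] >= voxelData(rS)[delayed]))
})

test_that("recovered rCBF preserves the tissue-class rank order", {
  ph <- defaultPhantom()
  conc <- signalToConcentration(ph@series)
  bm <- computeBrainMask(ph@series)
  aifObj <- new("ArterialInputFunction", curve = ph@aifTrue,
                sourceVoxels = matrix(1L, 1, 3), method = "MANUAL")
  for (m in c("sSVD", "cSVD")) {
    r <- voxelData(computeRcbf(conc, aifObj,
                               deconvolutionConfig(m, tr = 1), mask = bm))
    expect_gt(min(r[ph@truthMasks$VESSEL]), max(r[ph@truthMasks$GM]))
    expect_gt(min(r[ph@truthMasks$GM]), max(r[ph@truthMasks$WM]))
  }
})

test_that("TTP is the integration-window argmax in seconds", {
  # peak at dynamic 25 (1-based), TR = 1 s -> 24 s
  curve <- numeric(70); curve[25] <- 1
  ttp <- computeTtp(curveAsConc(curve))
  expect_equal(voxelData(ttp)[1, 1, 1], 24)

  # a uniform delay d shifts TTP by d
  aif <- defaultAifCurve()
  ct <- synthesizeTissueCurve(aif, 4, 50, tr = 1)
  t0 <- voxelData(computeTtp(curveAsConc(ct)))[1, 1, 1]
  ctd <- synthesizeTissueCurve(aif, 4, 50, delay = 3, tr = 1)
  expect_equal(voxelData(computeTtp(curveAsConc(ctd)))[1, 1, 1], t0 + 3)

  # flat curve: window start, flagged
  flat <- computeTtp(curveAsConc(numeric(70)))
  expect_equal(voxelData(flat)[1, 1, 1], 10)
  expect_true(flat@metadata$flat[1, 1, 1])
})

test_that("MTT follows the central-volume ratio with a CBF floor", {
  cbv <- ParametricMap(array(3.2, c(2, 2, 1)), "CBV", "mL/100 g")
  cbf <- ParametricMap(array(40, c(2, 2, 1)), "CBF", "mL/100 g/min",
                       method = "sSVD")
  mtt <- computeMtt(cbv, cbf)
  expect_equal(voxelData(mtt), array(4.8, c(2, 2, 1)))
  expect_identical(mapMethod(mtt), "sSVD")

  zero <- ParametricMap(array(0, c(2, 2, 1)), "CBV", "mL/100 g")
  expect_equal(voxelData(computeMtt(zero, cbf)), array(0, c(2, 2, 1)))

  # voxels under the CBF floor are zeroed and flagged
  lowf <- ParametricMap(array(1e-4, c(2, 2, 1)), "CBF", "mL/100 g/min")
  m2 <- computeMtt(cbv, lowf)
  expect_equal(voxelData(m2), array(0, c(2, 2, 1)))
  expect_equal(m2@metadata$nFloored, 4)
})
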