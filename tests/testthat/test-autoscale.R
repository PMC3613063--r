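test_that("composite reference mixes GM and WM by the configured fraction", {
  ref <- referenceConstants()
  expect_equal(compositeReference(ref, "CBV"), 3.2)
  expect_equal(compositeReference(ref, "CBF"), 40)
  expect_equal(compositeReference(referenceConstants(gmFraction = 0.5), "CBV"), 3)
  expect_error(referenceConstants(gmFraction = 1.2), "gmFraction")
  expect_error(referenceConstants(cbvGm = -1), "> 0")
})

test_that("preliminary vessel mask applies the twice-the-median rule", {
  asMap <- function(v, q = "rCBV") ParametricMap(array(v, c(5, 1, 1)), q, "relative")
  el <- VoxelMask(array(TRUE, c(5, 1, 1)), "BRAIN")

  # {1,1,1,1,10}: median 1, only the 10 exceeds 2 x median
  pm <- preliminaryVesselMask(asMap(c(1, 1, 1, 1, 10)), asMap(c(1, 1, 1, 1, 1), "rCBF"), el)
  expect_equal(as.vector(voxelData(pm)), c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(unname(attr(pm, "thresholds")["rcbv"]), 2)

  # either criterion flags: the rCBF outlier is caught too
  pm2 <- preliminaryVesselMask(asMap(rep(1, 5)), asMap(c(1, 1, 9, 1, 1), "rCBF"), el)
  expect_equal(as.vector(voxelData(pm2)), c(FALSE, FALSE, TRUE, FALSE, FALSE))

  # all-equal maps: nothing exceeds twice the median
  pm3 <- preliminaryVesselMask(asMap(rep(2, 5)), asMap(rep(3, 5), "rCBF"), el)
  expect_equal(sum(voxelData(pm3)), 0)

  empty <- VoxelMask(array(FALSE, c(5, 1, 1)), "BRAIN")
  expect_error(preliminaryVesselMask(asMap(rep(1, 5)), asMap(rep(1, 5)), empty),
               "empty")
})

test_that("preliminary vessel mask captures the phantom vessels", {
  run <- defaultRun()
  ph <- defaultPhantom()
  flagged <- voxelData(run@masks$prelimVessel)
  expect_gte(mean(flagged[ph@truthMasks$VESSEL]), 0.95)
})

test_that("normal-parenchyma mask keeps the inclusive TTP window", {
  ttpVals <- c(20, 21, 22, 23, 24, 25, 26)
  ttp <- ParametricMap(array(ttpVals, c(7, 1, 1)), "TTP", "s")
  el <- VoxelMask(array(TRUE, c(7, 1, 1)), "BRAIN")
  nb <- normalBrainMask(ttp, el, window = 3)
  expect_equal(as.vector(voxelData(nb)), ttpVals <= 23)  # median 23, [20, 23]
  expect_equal(attr(nb, "ttpMedian"), 23)

  # degenerate: a single shared TTP keeps every voxel
  ttp1 <- ParametricMap(array(15, c(7, 1, 1)), "TTP", "s")
  expect_equal(sum(voxelData(normalBrainMask(ttp1, el))), 7)

  empty <- VoxelMask(array(FALSE, c(7, 1, 1)), "BRAIN")
  expect_error(normalBrainMask(ttp, empty), "eligible")
})

test_that("flat-TTP voxels are excluded from the median and the mask", {
  ttp <- ParametricMap(array(c(10, 10, 10, 20, 20, 20, 20), c(7, 1, 1)),
                       "TTP", "s",
                       metadata = list(flat = array(c(rep(TRUE, 3), rep(FALSE, 4)),
                                                    c(7, 1, 1))))
  el <- VoxelMask(array(TRUE, c(7, 1, 1)), "BRAIN")
  nb <- normalBrainMask(ttp, el, window = 3)
  expect_equal(attr(nb, "ttpMedian"), 20)  # median over non-flat voxels only
  expect_equal(as.vector(voxelData(nb)), c(rep(FALSE, 3), rep(TRUE, 4)))
})

test_that("delayed-hemisphere voxels are excluded from the normal mask", {
  run <- delayedRun(4)
  ph <- delayedPhantom(4)
  nx <- dim(voxelData(run@masks$normalBrain))[1]
  delayedPerfused <- ph@truthMasks$GM | ph@truthMasks$WM
  delayedPerfused[seq_len(nx / 2), , ] <- FALSE
  normal <- voxelData(run@masks$normalBrain)
  expect_gte(mean(!normal[delayedPerfused]), 0.95)
  # and the kept voxels concentrate on the normal hemisphere
  kept <- which(normal, arr.ind = TRUE)
  expect_gte(mean(kept[, 1] <= nx / 2), 0.95)
})

test_that("normal-mask count on the impaired side shrinks with the delay", {
  nx <- 32L
  counts <- vapply(c(0, 2, 4), function(d) {
    run <- if (d == 0) defaultRun() else delayedRun(d)
    nm <- voxelData(run@masks$normalBrain)
    sum(nm[(nx / 2 + 1):nx, , ])
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_lt(counts[3], counts[1])
})

test_that("scaling factors normalize the normal-mask means exactly", {
  rcbv <- ParametricMap(array(16, c(4, 1, 1)), "rCBV", "relative")
  rcbf <- list(sSVD = ParametricMap(array(200, c(4, 1, 1)), "rCBF", "relative",
                                    method = "sSVD"))
  nm <- VoxelMask(array(TRUE, c(4, 1, 1)), "NORMAL_BRAIN")
  sf <- computeScalingFactors(rcbv, rcbf, nm)
  expect_equal(sfCbv(sf), 0.2)     # 3.2 / 16
  expect_equal(unname(sfCbf(sf, "sSVD")), 0.2)  # 40 / 200

  # algebraic identity on heterogeneous maps
  set.seed(5)
  vals <- array(stats::runif(64, 1, 30), c(4, 4, 4))
  rcbv2 <- ParametricMap(vals, "rCBV", "relative")
  rcbf2 <- list(cSVD = ParametricMap(vals * 2.3, "rCBF", "relative",
                                     method = "cSVD"))
  nm2 <- VoxelMask(array(c(TRUE, FALSE), c(4, 4, 4)), "NORMAL_BRAIN")
  sf2 <- computeScalingFactors(rcbv2, rcbf2, nm2)
  scaled <- applyScaling(rcbv2, rcbf2, sf2)
  sel <- voxelData(nm2)
  expect_equal(mean(voxelData(scaled$cbv)[sel]), 3.2, tolerance = 1e-12)
  expect_equal(mean(voxelData(scaled$cbf$cSVD)[sel]), 40, tolerance = 1e-12)

  zero <- ParametricMap(array(0, c(4, 1, 1)), "rCBV", "relative")
  expect_error(computeScalingFactors(zero, rcbf, nm), "> 0")
})

test_that("scaling is monotone and recomputes MTT from the scaled maps", {
  rcbv <- ParametricMap(array(c(16, 8, 24, 4), c(4, 1, 1)), "rCBV", "relative")
  rcbf <- list(sSVD = ParametricMap(array(c(100, 300, 200, 50), c(4, 1, 1)),
                                    "rCBF", "relative", method = "sSVD"))
  nm <- VoxelMask(array(TRUE, c(4, 1, 1)), "NORMAL_BRAIN")
  sf <- computeScalingFactors(rcbv, rcbf, nm)
  scaled <- applyScaling(rcbv, rcbf, sf)
  expect_equal(order(voxelData(scaled$cbv)), order(voxelData(rcbv)))
  # MTT equals scaled CBV / scaled CBF * 60 voxelwise
  expect_equal(voxelData(scaled$mtt$sSVD),
               voxelData(scaled$cbv) / voxelData(scaled$cbf$sSVD) * 60)
  expect_equal(voxelData(scaled$cbv)[1, 1, 1], sfCbv(sf) * 16)
})

test_that("pipeline masks are mutually exclusive subsets of the brain", {
  run <- defaultRun()
  brain <- voxelData(run@masks$brain)
  csf <- voxelData(run@masks$csf)
  prelim <- voxelData(run@masks$prelimVessel)
  normal <- voxelData(run@masks$normalBrain)
  expect_true(all(csf <= brain))
  expect_true(all(prelim <= brain))
  expect_true(all(normal <= brain))
  expect_equal(sum(normal & csf), 0)
  expect_equal(sum(normal & prelim), 0)
})
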