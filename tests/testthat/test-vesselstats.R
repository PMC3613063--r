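test_that("final vessel mask categorizes by the dual strict thresholds", {
  cbvVals <- c(9, 5, 9, 5, 8, 12)
  cbfVals <- c(50, 120, 120, 50, 100, 30)
  cbv <- ParametricMap(array(cbvVals, c(6, 1, 1)), "CBV", "mL/100 g")
  cbf <- ParametricMap(array(cbfVals, c(6, 1, 1)), "CBF", "mL/100 g/min",
                       method = "sSVD")
  brain <- VoxelMask(array(TRUE, c(6, 1, 1)), "BRAIN")
  vm <- finalVesselMask(cbv, cbf, brain)
  # (9,50)->CBV only; (5,120)->CBF only; (9,120)->both; (5,50)->none;
  # exact threshold values (8, 100) are NOT flagged (strict inequalities);
  # choroid-plexus-like (high CBV, low CBF) -> CBV-only
  expect_equal(as.vector(voxelData(vm)), c(1L, 2L, 3L, 0L, 0L, 1L))
  expect_identical(mapMethod(vm), "sSVD")

  bool <- asVesselVoxelMask(vm)
  expect_identical(maskLabel(bool), "FINAL_VESSEL")
  expect_equal(as.vector(voxelData(bool)), as.vector(voxelData(vm)) > 0)

  # restricted to the brain mask
  brain2 <- VoxelMask(array(c(rep(TRUE, 3), rep(FALSE, 3)), c(6, 1, 1)), "BRAIN")
  expect_equal(as.vector(voxelData(finalVesselMask(cbv, cbf, brain2))),
               c(1L, 2L, 3L, 0L, 0L, 0L))
})

test_that("threshold comparison reproduces the percent-difference arithmetic", {
  cmp <- thresholdComparison(7.24, c(sSVD = 83.2, cSVD = 85.0))
  expect_equal(cmp$pctBelowFinal[cmp$quantity == "CBV"], 9.5)
  expect_equal(round(cmp$pctBelowFinal[cmp$method == "sSVD"], 1), 16.8)
  expect_equal(cmp$pctBelowFinal[cmp$method == "cSVD"], 15.0)

  # equal thresholds give zero difference
  expect_equal(thresholdComparison(8, c(sSVD = 100))$pctBelowFinal, c(0, 0))

  # relative inputs are converted through the scaling factors
  sf <- new("ScalingFactors", sfCbv = 2, sfCbf = c(sSVD = 10),
            nNormalVoxels = 100L, references = referenceConstants())
  cmp2 <- thresholdComparison(3.62, c(sSVD = 8.32), factors = sf)
  expect_equal(cmp2$prelimAbs, c(7.24, 83.2))
})

test_that("hemispheric ROI statistics honour symmetry and set algebra", {
  run <- defaultRun()
  roi <- run@roiReport
  expect_true(all(c("condition", "hemisphere", "quantity", "method",
                    "mean", "sd", "n") %in% names(roi)))

  # mirror-symmetric noise-free phantom: left and right means agree
  for (q in c("CBV", "CBF", "MTT")) {
    sub <- roi[roi$quantity == q & roi$method == "sSVD", ]
    left <- sub[sub$hemisphere == "left", ]
    right <- sub[sub$hemisphere == "right", ]
    expect_equal(left$mean, right$mean, tolerance = 1e-6)
    expect_equal(left$n, right$n)
  }

  # voxel counts: both-removed <= each single removal <= all
  for (h in c("left", "right")) {
    sub <- roi[roi$quantity == "CBV" & roi$method == "sSVD" &
                 roi$hemisphere == h, ]
    n <- setNames(sub$n, sub$condition)
    expect_lte(n[["both-removed"]], n[["csf-removed"]])
    expect_lte(n[["both-removed"]], n[["vessel-removed"]])
    expect_lte(n[["csf-removed"]], n[["all"]])
    expect_lte(n[["vessel-removed"]], n[["all"]])
  }

  # every removed vessel voxel exceeds the pre-removal mean, so removal
  # lowers the mean CBV (the trimming property)
  sub <- roi[roi$quantity == "CBV" & roi$method == "sSVD" &
               roi$hemisphere == "left", ]
  m <- setNames(sub$mean, sub$condition)
  expect_lt(m[["vessel-removed"]], m[["all"]])

  # empty ROI reported as missing, not an error
  roi0 <- hemisphericRoiStats(run@maps$cbv, run@maps$cbf, run@maps$mtt,
                              run@masks$brain, run@masks$csf,
                              run@vesselMasks, midline = 0)
  leftRows <- roi0[roi0$hemisphere == "left", ]
  expect_true(all(leftRows$n == 0))
  expect_true(all(is.na(leftRows$mean)))
})

test_that("vessel-category balance shifts with impaired perfusion", {
  run <- delayedRun(4)
  codes <- voxelData(run@vesselMasks$sSVD)
  nx <- dim(codes)[1]
  left <- codes[seq_len(nx / 2), , ]    # normal side
  right <- codes[(nx / 2 + 1):nx, , ]   # impaired side
  # CBV-based detection (codes 1 or 3) must not be weaker on the impaired
  # side, and CBF-based detection (codes 2 or 3) not weaker on the normal side
  expect_gte(sum(right %in% c(1L, 3L)), sum(right %in% c(2L, 3L)))
  expect_gte(sum(left %in% c(2L, 3L)), sum(left %in% c(1L, 3L)))
})

test_that("Mann-Whitney U matches exhaustive enumeration and identities", {
  # pairwise-count oracle for U (independent of the rank-sum formula)
  uOracle <- function(a, b)
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  # exact two-sided p by enumerating every label assignment
  pOracle <- function(a, b) {
    pooled <- c(a, b); na <- length(a)
    mu <- na * length(b) / 2
    sets <- utils::combn(length(pooled), na)
    Us <- apply(sets, 2, function(ix)
      uOracle(pooled[ix], pooled[-ix]))
    uObs <- uOracle(a, b)
    mean(abs(Us - mu) >= abs(uObs - mu) - 1e-12)
  }

  expect_equal(mannWhitneyU(c(1, 2, 3), c(10, 11, 12))$U, 0)

  x <- c(5, 5, 5); res <- mannWhitneyU(x, x)
  expect_equal(res$U, 4.5)   # n_a n_b / 2 under complete ties
  expect_equal(res$p, 1)

  set.seed(9)
  for (na in c(2, 4, 6)) for (nb in c(2, 5, 6)) {
    a <- sample(1:8, na, replace = TRUE)   # ties likely
    b <- sample(3:10, nb, replace = TRUE)
    res <- mannWhitneyU(a, b)
    expect_true(res$exact)
    expect_equal(res$U, uOracle(a, b))
    expect_equal(res$p, pOracle(a, b))
    # complement identity: U_a + U_b = n_a n_b
    expect_equal(res$U + mannWhitneyU(b, a)$U, na * nb)
  }

  # exact path agrees with wilcox.test when there are no ties
  a <- c(1.2, 3.4, 2.2, 5.1); b <- c(4.3, 6.6, 7.1, 0.5, 2.9)
  res <- mannWhitneyU(a, b)
  ref <- stats::wilcox.test(a, b, exact = TRUE)
  expect_equal(res$U, unname(ref$statistic))
  expect_equal(res$p, ref$p.value)

  # large-sample normal path tracks wilcox.test's corrected approximation
  set.seed(10)
  a <- stats::rnorm(30); b <- stats::rnorm(25, mean = 0.5)
  res <- mannWhitneyU(a, b)
  expect_false(res$exact)
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(res$p, ref$p.value, tolerance = 1e-10)

  expect_error(mannWhitneyU(numeric(0), 1), "non-empty")
})
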