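## Relative CBV/CBF/TTP/MTT maps from concentration curves and an AIF.
##
## The tissue curve is modelled as C(t) = (rho/k_H) AIF(t) (x) [CBF R(t)];
## truncated-SVD inversion of the discrete convolution recovers the
## flow-scaled residue f(t) = CBF R(t), whose maximum is the relative CBF.

#' Select an arterial input function
#'
#' With `voxels` given, returns the mean concentration curve of exactly those
#' voxels (`MANUAL`). Otherwise ranks brain voxels by a composite score of
#' early time-to-peak, high peak concentration and a narrow first-moment
#' width (each z-scored over the candidates, equal weights) and averages the
#' top `k` curves (`AUTO`). Deterministic given the input; ties broken by
#' voxel order.
#'
#' @param conc a [ConcentrationSeries-class].
#' @param brainMask a [VoxelMask-class] restricting the candidates.
#' @param k number of voxels to average (default 10).
#' @param voxels optional integer matrix (n x 3) of voxel coordinates for
#'   manual selection.
#' @return An [ArterialInputFunction-class].
#' @export
selectAif <- function(conc, brainMask, k = 10L, voxels = NULL) {
  d <- dim(conc@conc)
  flat <- matrix(conc@conc, nrow = prod(d[1:3]), ncol = d[4])
  if (!is.null(voxels)) {
    voxels <- as.matrix(voxels)
    idx <- voxels[, 1] + (voxels[, 2] - 1L) * d[1] +
      (voxels[, 3] - 1L) * d[1] * d[2]
    curve <- colMeans(flat[idx, , drop = FALSE])
    return(new("ArterialInputFunction", curve = curve,
               sourceVoxels = voxels, method = "MANUAL"))
  }
  inBrain <- which(as.vector(voxelData(brainMask)))
  curves <- flat[inBrain, , drop = FALSE]
  win <- integrationWindow(d[4])
  sub <- curves[, win, drop = FALSE]
  peak <- apply(sub, 1, max)
  cand <- which(peak > 0)
  if (length(cand) == 0L)
    stop("no candidate AIF voxel with a positive concentration peak")
  if (k > length(cand)) {
    warning("k = ", k, " exceeds the ", length(cand),
            " candidate voxels; using all candidates")
    k <- length(cand)
  }
  sub <- sub[cand, , drop = FALSE]
  tsec <- (win - 1) * conc@tr
  ttp <- tsec[apply(sub, 1, which.max)]
  pos <- pmax(sub, 0)
  fm <- as.vector(pos %*% tsec) / rowSums(pos)   # first moment, seconds
  z <- function(x) if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x) else x * 0
  score <- (z(peak[cand]) - z(ttp) - z(fm)) / 3
  top <- cand[order(-score, cand)[seq_len(k)]]
  sel <- inBrain[top]
  coords <- arrayInd(sel, d[1:3])
  curve <- colMeans(flat[sel, , drop = FALSE])
  new("ArterialInputFunction", curve = curve,
      sourceVoxels = coords, method = "AUTO")
}

#' Relative cerebral blood volume map
#'
#' Ratio of the voxel concentration sum to the AIF sum over the bolus
#' integration window (dynamics 11 to 70, clamped to the series length),
#' scaled by the hematocrit/density constant:
#' \deqn{rCBV = (k_H/\rho) \sum C(t) / \sum AIF(t).}
#' Negative values (noise) are clamped to 0 and counted in
#' `metadata$nClamped`.
#'
#' @param conc a [ConcentrationSeries-class].
#' @param aif an [ArterialInputFunction-class].
#' @param kHOverRho k_H/rho in cc/g (default 0.705).
#' @return A [ParametricMap-class] with quantity `"rCBV"`.
#' @export
computeRcbv <- function(conc, aif, kHOverRho = .KH_OVER_RHO) {
  d <- dim(conc@conc)
  win <- integrationWindow(d[4])
  aifSum <- sum(aifCurve(aif)[win])
  if (aifSum <= 0) stop("AIF integral over the integration window must be > 0")
  flat <- matrix(conc@conc, nrow = prod(d[1:3]), ncol = d[4])
  rcbv <- kHOverRho * rowSums(flat[, win, drop = FALSE]) / aifSum
  nClamped <- sum(rcbv < 0)
  rcbv <- pmax(rcbv, 0)
  ParametricMap(array(rcbv, d[1:3]), "rCBV", "relative",
                metadata = list(nClamped = nClamped))
}

#' Build the discrete AIF convolution operator
#'
#' For `sSVD`, the lower-triangular Toeplitz matrix
#' `A[i, j] = (rho/k_H) * tr * AIF(i - j + 1)`; for `cSVD`, the circulant
#' matrix of the AIF zero-padded to `padFactor * nDynamics`, which makes the
#' inversion insensitive to bolus arrival delays. The SVD is precomputed and
#' reused for every voxel.
#'
#' @param aif an [ArterialInputFunction-class] or a numeric curve.
#' @param config a [DeconvolutionConfig-class].
#' @param kHOverRho k_H/rho in cc/g.
#' @return A [ConvolutionOperator-class].
#' @export
buildConvolutionOperator <- function(aif, config, kHOverRho = .KH_OVER_RHO) {
  validObject(config)
  curve <- if (is(aif, "ArterialInputFunction")) aifCurve(aif) else aif
  n <- length(curve)
  scale <- (1 / kHOverRho) * config@tr
  if (config@method == "sSVD") {
    i <- matrix(seq_len(n), n, n)
    lag <- i - t(i) + 1L
    A <- matrix(0, n, n)
    pos <- lag >= 1L
    A[pos] <- scale * curve[lag[pos]]
  } else {
    L <- config@padFactor * n
    pad <- c(curve, numeric(L - n))
    i <- matrix(seq_len(L), L, L)
    lag <- ((i - t(i)) %% L) + 1L
    A <- matrix(scale * pad[lag], L, L)
  }
  s <- svd(A)
  new("ConvolutionOperator", matrix = A, d = s$d, u = s$u, v = s$v,
      config = config, nDynamics = as.integer(n))
}

#' Truncated-SVD deconvolution
#'
#' Applies the truncated pseudoinverse `V diag(w) U' c` where singular values
#' below `truncationFraction * max(d)` get inverse weight 0. For circulant
#' operators, curves are zero-padded before inversion and the result is cut
#' back to the original length.
#'
#' @param curves numeric vector (one curve) or matrix (dynamics x voxels).
#' @param operator a [ConvolutionOperator-class].
#' @return Residue-scaled curve(s) `f(t) = rCBF * R(t)`, same shape as the
#'   input (vector in, vector out).
#' @export
deconvolveCurves <- function(curves, operator) {
  vec <- is.null(dim(curves))
  c0 <- if (vec) matrix(curves, ncol = 1) else curves
  n <- operator@nDynamics
  if (nrow(c0) != n)
    stop("curves must have ", n, " dynamics to match the operator")
  L <- length(operator@d)
  if (L > n) c0 <- rbind(c0, matrix(0, L - n, ncol(c0)))
  keep <- operator@d >= operator@config@truncationFraction * max(operator@d)
  if (!any(keep))
    stop("all singular values truncated; lower truncationFraction")
  w <- ifelse(keep, 1 / operator@d, 0)
  f <- operator@v %*% (w * crossprod(operator@u, c0))
  f <- f[seq_len(n), , drop = FALSE]
  if (vec) as.vector(f) else f
}

#' Relative cerebral blood flow map
#'
#' Voxelwise maximum of the deconvolved residue-scaled curve f(t). The
#' maximum is taken over the signed curve; truncation-induced negative map
#' values (possible only in degenerate voxels) are clamped to 0 and counted
#' in `metadata$nClamped`. Units are "relative" per second of `tr`.
#'
#' @param conc a [ConcentrationSeries-class].
#' @param aif an [ArterialInputFunction-class].
#' @param config a [DeconvolutionConfig-class].
#' @param mask optional [VoxelMask-class]; outside voxels are 0.
#' @param operator optional prebuilt [ConvolutionOperator-class].
#' @return A [ParametricMap-class] with quantity `"rCBF"`, method-tagged.
#' @export
computeRcbf <- function(conc, aif, config = deconvolutionConfig(tr = conc@tr),
                        mask = NULL, operator = NULL) {
  if (is.null(operator)) operator <- buildConvolutionOperator(aif, config)
  d <- dim(conc@conc)
  m <- if (is.null(mask)) array(TRUE, d[1:3]) else voxelData(mask)
  curves <- curvesMatrix(conc@conc, m)
  f <- deconvolveCurves(curves, operator)
  rcbf <- apply(f, 2, max)
  out <- array(0, d[1:3])
  out[m] <- rcbf
  nClamped <- sum(out < 0)
  out <- pmax(out, 0)
  ParametricMap(out, "rCBF", "relative", method = config@method,
                metadata = list(nClamped = nClamped,
                                truncationFraction = config@truncationFraction))
}

#' Time-to-peak map
#'
#' Per-voxel time (seconds from the series start, `(dynamic - 1) * tr`) of
#' the maximum concentration over the bolus integration window; the first
#' occurrence wins ties. Voxels whose window maximum is not positive (flat
#' curves) are assigned the window start and flagged in `metadata$flat`.
#'
#' @param conc a [ConcentrationSeries-class].
#' @return A [ParametricMap-class] with quantity `"TTP"` (seconds).
#' @export
computeTtp <- function(conc) {
  d <- dim(conc@conc)
  win <- integrationWindow(d[4])
  flat <- matrix(conc@conc, nrow = prod(d[1:3]), ncol = d[4])[, win, drop = FALSE]
  idx <- max.col(flat, ties.method = "first")
  peak <- flat[cbind(seq_len(nrow(flat)), idx)]
  ttp <- (win[idx] - 1) * conc@tr
  flatMask <- peak <= 0
  ttp[flatMask] <- (win[1] - 1) * conc@tr
  ParametricMap(array(ttp, d[1:3]), "TTP", "s",
                metadata = list(flat = array(flatMask, d[1:3])))
}

#' Mean transit time map
#'
#' Central-volume relation `MTT = CBV / CBF * 60` seconds, computed
#' voxelwise. Voxels with CBF at or below `cbfFloor` are set to 0 and
#' counted in `metadata$nFloored`.
#'
#' @param cbvMap,cbfMap [ParametricMap-class] objects on the same grid (both
#'   relative or both absolute).
#' @param cbfFloor minimum CBF (map units) for a defined MTT (default 0.01).
#' @return A [ParametricMap-class] with quantity `"MTT"` (seconds), tagged
#'   with the CBF map's method.
#' @export
computeMtt <- function(cbvMap, cbfMap, cbfFloor = .MTT_CBF_FLOOR) {
  stopifnot(identical(dim(voxelData(cbvMap)), dim(voxelData(cbfMap))))
  cbv <- voxelData(cbvMap); cbf <- voxelData(cbfMap)
  ok <- cbf > cbfFloor
  mtt <- array(0, dim(cbv))
  mtt[ok] <- cbv[ok] / cbf[ok] * 60
  ParametricMap(mtt, "MTT", "s", method = mapMethod(cbfMap),
                metadata = list(nFloored = sum(!ok & cbv > 0)))
}
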