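## Final dual-threshold vessel removal, hemispheric ROI statistics and the
## rank-sum significance test.

#' Final categorized vessel mask
#'
#' Applies the dual absolute thresholds (strict inequalities) to the scaled
#' maps inside the brain mask: code 1 = CBV > `cbvThreshold` only, code 2 =
#' CBF > `cbfThreshold` only, code 3 = both, 0 = neither. Choroid-plexus-like
#' tissue (high CBV, low CBF) appears as code 1; on an impaired hemisphere,
#' vessels with raised CBV but reduced CBF also fall into code 1 while
#' normally perfused vessels are caught by the CBF threshold.
#'
#' @param cbvMap absolute CBV map (mL/100 g).
#' @param cbfMap absolute CBF map (mL/100 g/min), method-tagged.
#' @param brainMask a [VoxelMask-class].
#' @param cbvThreshold,cbfThreshold thresholds (defaults 8 and 100).
#' @return A [CategorizedVesselMask-class].
#' @export
finalVesselMask <- function(cbvMap, cbfMap, brainMask,
                            cbvThreshold = .FINAL_CBV_THRESHOLD,
                            cbfThreshold = .FINAL_CBF_THRESHOLD) {
  bm <- voxelData(brainMask)
  hitV <- bm & (voxelData(cbvMap) > cbvThreshold)
  hitF <- bm & (voxelData(cbfMap) > cbfThreshold)
  codes <- array(0L, dim(bm))
  codes[hitV & !hitF] <- 1L
  codes[!hitV & hitF] <- 2L
  codes[hitV & hitF] <- 3L
  new("CategorizedVesselMask", codes = codes, cbvThreshold = cbvThreshold,
      cbfThreshold = cbfThreshold, method = mapMethod(cbfMap))
}

#' Coerce a categorized vessel mask to a boolean VoxelMask
#'
#' @param x a [CategorizedVesselMask-class].
#' @return A [VoxelMask-class] with label `"FINAL_VESSEL"` (any code > 0).
#' @export
asVesselVoxelMask <- function(x) {
  VoxelMask(voxelData(x) > 0L, "FINAL_VESSEL",
            sprintf("CBV > %g or CBF > %g (%s)", x@cbvThreshold,
                    x@cbfThreshold, x@method))
}

#' Compare preliminary and final vessel thresholds
#'
#' Converts the relative preliminary thresholds (twice the median) to
#' absolute units with the scaling factors, then reports the percent
#' difference versus the final thresholds:
#' `(final - prelim_abs) / final * 100` (positive = preliminary threshold is
#' lower). Absolute preliminary thresholds may also be supplied directly by
#' omitting `factors`.
#'
#' @param prelimCbv preliminary rCBV threshold (relative if `factors` is
#'   given, otherwise absolute mL/100 g).
#' @param prelimCbf named numeric of preliminary rCBF thresholds per method
#'   (relative or absolute mL/100 g/min, as above).
#' @param factors optional [ScalingFactors-class] used for the conversion.
#' @param finalCbv,finalCbf final thresholds (defaults 8 and 100).
#' @return A `data.frame` with columns `quantity`, `method`, `prelimAbs`,
#'   `final`, `pctBelowFinal`.
#' @examples
#' thresholdComparison(7.24, c(cSVD = 85))$pctBelowFinal  # 9.5, 15.0
#' @export
thresholdComparison <- function(prelimCbv, prelimCbf, factors = NULL,
                                finalCbv = .FINAL_CBV_THRESHOLD,
                                finalCbf = .FINAL_CBF_THRESHOLD) {
  if (!is.null(factors)) {
    prelimCbv <- sfCbv(factors) * prelimCbv
    prelimCbf <- sfCbf(factors)[names(prelimCbf)] * prelimCbf
  }
  if (is.null(names(prelimCbf)))
    names(prelimCbf) <- rep("", length(prelimCbf))
  out <- data.frame(
    quantity = c("CBV", rep("CBF", length(prelimCbf))),
    method = c("none", names(prelimCbf)),
    prelimAbs = c(prelimCbv, unname(prelimCbf)),
    final = c(finalCbv, rep(finalCbf, length(prelimCbf))),
    stringsAsFactors = FALSE)
  out$pctBelowFinal <- (out$final - out$prelimAbs) / out$final * 100
  out
}

#' Hemispheric ROI statistics under the four masking conditions
#'
#' For each hemisphere (split at the in-plane x midline of the brain-mask
#' bounding box, configurable) and each cumulative masking condition --
#' `all`, `csf-removed`, `vessel-removed`, `both-removed` -- reports mean, SD
#' and voxel count of the scaled CBV, CBF and MTT maps. CBF/MTT (and the
#' vessel mask) are per deconvolution method; CBV rows are repeated per
#' method because the vessel condition depends on the method's CBF map.
#'
#' @param cbvMap absolute CBV map.
#' @param cbfMaps,mttMaps named lists of absolute CBF/MTT maps per method.
#' @param brainMask,csfMask [VoxelMask-class] objects.
#' @param vesselMasks named list of [CategorizedVesselMask-class] per method.
#' @param midline x index of the last column of the left hemisphere
#'   (default: midpoint of the brain bounding box).
#' @param slices slice indices to include (default: all).
#' @return A `data.frame` with columns `condition`, `hemisphere`, `quantity`,
#'   `method`, `mean`, `sd`, `n`. Empty ROIs yield `NA` means with `n = 0`.
#' @export
hemisphericRoiStats <- function(cbvMap, cbfMaps, mttMaps, brainMask, csfMask,
                                vesselMasks, midline = NULL, slices = NULL) {
  bm <- voxelData(brainMask); csf <- voxelData(csfMask)
  d <- dim(bm)
  if (is.null(slices)) slices <- seq_len(d[3])
  if (is.null(midline)) {
    xs <- which(apply(bm, 1, any))
    midline <- floor((min(xs) + max(xs)) / 2)
  }
  inSlice <- array(FALSE, d); inSlice[, , slices] <- TRUE
  left <- array(FALSE, d); left[seq_len(midline), , ] <- TRUE
  hemis <- list(left = left & inSlice, right = (!left) & inSlice)
  rows <- list()
  for (method in names(cbfMaps)) {
    vessel <- voxelData(vesselMasks[[method]]) > 0L
    conds <- list("all" = bm,
                  "csf-removed" = bm & !csf,
                  "vessel-removed" = bm & !vessel,
                  "both-removed" = bm & !csf & !vessel)
    maps <- list(CBV = cbvMap, CBF = cbfMaps[[method]], MTT = mttMaps[[method]])
    for (cn in names(conds)) for (hn in names(hemis)) {
      sel <- conds[[cn]] & hemis[[hn]]
      n <- sum(sel)
      for (qn in names(maps)) {
        v <- voxelData(maps[[qn]])[sel]
        rows[[length(rows) + 1L]] <- data.frame(
          condition = cn, hemisphere = hn, quantity = qn, method = method,
          mean = if (n) mean(v) else NA_real_,
          sd = if (n > 1) stats::sd(v) else NA_real_,
          n = n, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Mann-Whitney U rank-sum test
#'
#' Computed from rank definitions: `U_a = R_a - n_a (n_a + 1) / 2` with
#' `R_a` the pooled rank sum of the first sample (midranks under ties).
#' The two-sided p-value uses the exact permutation null (all
#' `choose(n_a + n_b, n_a)` label assignments, valid under ties) when both
#' groups have at most `exactLimit` observations, and otherwise the
#' tie-corrected normal approximation with continuity correction.
#'
#' @param a,b numeric samples (non-empty).
#' @param exactLimit exact enumeration when `max(n_a, n_b) <= exactLimit`
#'   (default 8).
#' @return A list with `U` (for sample `a`), `p` (two-sided) and `exact`.
#' @examples
#' mannWhitneyU(c(1, 2, 3), c(10, 11, 12))$U  # 0
#' @export
mannWhitneyU <- function(a, b, exactLimit = 8L) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  if (max(na, nb) <= exactLimit) {
    sets <- combn(na + nb, na)
    rsum <- colSums(matrix(r[sets], nrow = na))
    Uperm <- rsum - na * (na + 1) / 2
    p <- mean(abs(Uperm - mu) >= abs(U - mu) - 1e-12)
    return(list(U = U, p = p, exact = TRUE))
  }
  N <- na + nb
  ties <- table(pooled)
  sigma2 <- na * nb / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) return(list(U = U, p = 1, exact = FALSE))
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
  list(U = U, p = min(1, 2 * pnorm(-abs(z))), exact = FALSE)
}
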