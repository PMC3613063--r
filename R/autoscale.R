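## Normal-parenchyma segmentation and relative-to-absolute scaling.

#' Composite literature reference value
#'
#' Gray/white mixture of the reference constants:
#' `gmFraction * value_GM + (1 - gmFraction) * value_WM`. With the defaults
#' this gives the standard composite CBV of 3.2 mL/100 g and CBF of
#' 40 mL/100 g/min for normal parenchyma (60% GM / 40% WM).
#'
#' @param ref a [ReferenceConstants-class].
#' @param quantity `"CBV"` or `"CBF"`.
#' @return A single numeric reference value.
#' @examples
#' compositeReference(referenceConstants(), "CBV")  # 3.2
#' compositeReference(referenceConstants(), "CBF")  # 40
#' @export
compositeReference <- function(ref, quantity = c("CBV", "CBF")) {
  quantity <- match.arg(quantity)
  g <- ref@gmFraction
  if (quantity == "CBV") g * ref@cbvGm + (1 - g) * ref@cbvWm
  else g * ref@cbfGm + (1 - g) * ref@cbfWm
}

#' Preliminary vessel mask (twice-the-median rule)
#'
#' Medians of rCBV and rCBF are computed over the eligible voxels (brain
#' minus CSF); voxels exceeding twice either median are preliminarily
#' classified as vessels. Both medians are recorded in the provenance and in
#' the returned mask's attributes.
#'
#' @param rcbvMap,rcbfMap relative [ParametricMap-class] objects.
#' @param eligibleMask a [VoxelMask-class] (brain minus CSF), non-empty.
#' @return A [VoxelMask-class] with label `"PRELIM_VESSEL"`; the 2x-median
#'   thresholds are in `attr(, "thresholds")`.
#' @export
preliminaryVesselMask <- function(rcbvMap, rcbfMap, eligibleMask) {
  el <- voxelData(eligibleMask)
  if (!any(el)) stop("eligible mask is empty")
  rcbv <- voxelData(rcbvMap); rcbf <- voxelData(rcbfMap)
  medCbv <- median(rcbv[el]); medCbf <- median(rcbf[el])
  mask <- el & (rcbv > 2 * medCbv | rcbf > 2 * medCbf)
  out <- VoxelMask(mask, "PRELIM_VESSEL",
                   sprintf("rCBV > 2 x median (%.4g) or rCBF > 2 x median (%.4g)",
                           medCbv, medCbf))
  attr(out, "thresholds") <- c(rcbv = 2 * medCbv, rcbf = 2 * medCbf)
  attr(out, "medians") <- c(rcbv = medCbv, rcbf = medCbf)
  out
}

#' Normal-parenchyma mask from the TTP window
#'
#' The median TTP is computed over the eligible voxels (brain minus CSF minus
#' preliminary vessels, excluding flat-curve voxels flagged by
#' [computeTtp()]); voxels with TTP in the inclusive window
#' `[TTP_median - window, TTP_median]` form the normally perfused parenchyma.
#' Voxels with delayed bolus arrival (stenosis territory) fall above the
#' median and are excluded.
#'
#' @param ttpMap a TTP [ParametricMap-class] (seconds).
#' @param eligibleMask a [VoxelMask-class], non-empty.
#' @param window window width below the median, seconds (default 3).
#' @return A [VoxelMask-class] with label `"NORMAL_BRAIN"`; the median TTP is
#'   in `attr(, "ttpMedian")`.
#' @export
normalBrainMask <- function(ttpMap, eligibleMask, window = .TTP_WINDOW) {
  el <- voxelData(eligibleMask)
  flat <- ttpMap@metadata$flat
  if (!is.null(flat)) el <- el & !flat
  if (!any(el))
    stop("no eligible voxels with a defined TTP; inspect the input masks")
  ttp <- voxelData(ttpMap)
  med <- median(ttp[el])
  mask <- el & ttp >= med - window & ttp <= med
  if (!any(mask))
    stop("normal-parenchyma mask is empty; inspect the TTP map and masks")
  out <- VoxelMask(mask, "NORMAL_BRAIN",
                   sprintf("TTP in [%.4g, %.4g] s (median %.4g, window %g s)",
                           med - window, med, med, window))
  attr(out, "ttpMedian") <- med
  out
}

#' Compute the dual scaling factors
#'
#' `SF_CBV = composite CBV reference / mean(rCBV over the normal mask)` and,
#' per deconvolution method, `SF_CBF[m] = composite CBF reference /
#' mean(rCBF_m over the normal mask)`. By construction the scaled maps
#' average exactly to the composite references over the normal mask.
#'
#' @param rcbvMap relative CBV [ParametricMap-class].
#' @param rcbfMaps named list of relative CBF maps, one per method.
#' @param normalMask the `"NORMAL_BRAIN"` [VoxelMask-class].
#' @param ref a [ReferenceConstants-class].
#' @return A [ScalingFactors-class].
#' @export
computeScalingFactors <- function(rcbvMap, rcbfMaps, normalMask,
                                  ref = referenceConstants()) {
  nm <- voxelData(normalMask)
  if (!any(nm)) stop("normal mask is empty")
  meanCbv <- mean(voxelData(rcbvMap)[nm])
  if (meanCbv <= 0) stop("mean rCBV over the normal mask must be > 0")
  if (is(rcbfMaps, "ParametricMap")) {
    rcbfMaps <- setNames(list(rcbfMaps), mapMethod(rcbfMaps))
  }
  sfC <- vapply(rcbfMaps, function(m) {
    mu <- mean(voxelData(m)[nm])
    if (mu <= 0) stop("mean rCBF over the normal mask must be > 0")
    compositeReference(ref, "CBF") / mu
  }, numeric(1))
  new("ScalingFactors", sfCbv = compositeReference(ref, "CBV") / meanCbv,
      sfCbf = sfC, nNormalVoxels = as.integer(sum(nm)), references = ref)
}

#' Convert relative maps to absolute CBV/CBF/MTT
#'
#' `CBV = SF_CBV * rCBV` (mL/100 g); per method `CBF_m = SF_CBF[m] * rCBF_m`
#' (mL/100 g/min); MTT is then recomputed from the scaled maps via
#' [computeMtt()] (it changes relative to the unscaled ratio because SF_CBV
#' and SF_CBF differ in general).
#'
#' @param rcbvMap relative CBV map.
#' @param rcbfMaps named list of relative CBF maps per method (a single map
#'   is accepted).
#' @param factors a [ScalingFactors-class] computed from the same run.
#' @param cbfFloor forwarded to [computeMtt()].
#' @return A list with elements `cbv` ([ParametricMap-class]), `cbf` and
#'   `mtt` (named lists per method).
#' @export
applyScaling <- function(rcbvMap, rcbfMaps, factors, cbfFloor = .MTT_CBF_FLOOR) {
  if (is(rcbfMaps, "ParametricMap"))
    rcbfMaps <- setNames(list(rcbfMaps), mapMethod(rcbfMaps))
  cbv <- ParametricMap(sfCbv(factors) * voxelData(rcbvMap), "CBV", "mL/100 g")
  cbf <- lapply(setNames(nm = names(rcbfMaps)), function(m) {
    ParametricMap(sfCbf(factors, m) * voxelData(rcbfMaps[[m]]),
                  "CBF", "mL/100 g/min", method = mapMethod(rcbfMaps[[m]]))
  })
  mtt <- lapply(cbf, function(cm) computeMtt(cbv, cm, cbfFloor = cbfFloor))
  list(cbv = cbv, cbf = cbf, mtt = mtt)
}
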