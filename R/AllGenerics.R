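## Accessor generics. Slot access from user code should go through these.

#' Extract the voxel data array of a container
#'
#' Returns the underlying numeric/logical array: the 4-D signal of a
#' [PerfusionSeries-class], the 4-D concentration of a
#' [ConcentrationSeries-class], the 3-D map of a [ParametricMap-class], the
#' logical mask of a [VoxelMask-class], or the integer codes of a
#' [CategorizedVesselMask-class].
#'
#' @param x a dscquant container object.
#' @return An array.
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' @rdname voxelData
setMethod("voxelData", "PerfusionSeries", function(x) x@signal)
#' @rdname voxelData
setMethod("voxelData", "ConcentrationSeries", function(x) x@conc)
#' @rdname voxelData
setMethod("voxelData", "ParametricMap", function(x) x@map)
#' @rdname voxelData
setMethod("voxelData", "VoxelMask", function(x) x@mask)
#' @rdname voxelData
setMethod("voxelData", "CategorizedVesselMask", function(x) x@codes)

#' Acquisition timing accessors
#'
#' `trTime` and `teTime` return the repetition and echo time in seconds;
#' `nDynamics` the number of dynamics.
#'
#' @param x a [PerfusionSeries-class] or [ConcentrationSeries-class].
#' @return A single number (or integer count).
#' @export
setGeneric("trTime", function(x) standardGeneric("trTime"))
#' @rdname trTime
setMethod("trTime", "PerfusionSeries", function(x) x@tr)
#' @rdname trTime
setMethod("trTime", "ConcentrationSeries", function(x) x@tr)

#' @rdname trTime
#' @export
setGeneric("teTime", function(x) standardGeneric("teTime"))
#' @rdname trTime
setMethod("teTime", "PerfusionSeries", function(x) x@te)
#' @rdname trTime
setMethod("teTime", "ConcentrationSeries", function(x) x@te)

#' @rdname trTime
#' @export
setGeneric("nDynamics", function(x) standardGeneric("nDynamics"))
#' @rdname trTime
setMethod("nDynamics", "PerfusionSeries", function(x) dim(x@signal)[4])
#' @rdname trTime
setMethod("nDynamics", "ConcentrationSeries", function(x) dim(x@conc)[4])

#' Map and mask descriptors
#'
#' `quantityName`, `mapUnits` and `mapMethod` describe a
#' [ParametricMap-class]; `maskLabel` returns the label of a
#' [VoxelMask-class].
#'
#' @param x the object.
#' @return A character scalar.
#' @export
setGeneric("quantityName", function(x) standardGeneric("quantityName"))
#' @rdname quantityName
setMethod("quantityName", "ParametricMap", function(x) x@quantity)

#' @rdname quantityName
#' @export
setGeneric("mapUnits", function(x) standardGeneric("mapUnits"))
#' @rdname quantityName
setMethod("mapUnits", "ParametricMap", function(x) x@units)

#' @rdname quantityName
#' @export
setGeneric("mapMethod", function(x) standardGeneric("mapMethod"))
#' @rdname quantityName
setMethod("mapMethod", "ParametricMap", function(x) x@method)
#' @rdname quantityName
setMethod("mapMethod", "CategorizedVesselMask", function(x) x@method)

#' @rdname quantityName
#' @export
setGeneric("maskLabel", function(x) standardGeneric("maskLabel"))
#' @rdname quantityName
setMethod("maskLabel", "VoxelMask", function(x) x@label)

#' AIF accessors
#'
#' @param x an [ArterialInputFunction-class].
#' @return `aifCurve`: numeric concentration curve; `aifSourceVoxels`:
#'   integer matrix of voxel coordinates.
#' @export
setGeneric("aifCurve", function(x) standardGeneric("aifCurve"))
#' @rdname aifCurve
setMethod("aifCurve", "ArterialInputFunction", function(x) x@curve)

#' @rdname aifCurve
#' @export
setGeneric("aifSourceVoxels", function(x) standardGeneric("aifSourceVoxels"))
#' @rdname aifCurve
setMethod("aifSourceVoxels", "ArterialInputFunction", function(x) x@sourceVoxels)

#' Scaling-factor accessors
#'
#' @param x a [ScalingFactors-class].
#' @param method deconvolution method name for `sfCbf` (default: all, named).
#' @return Numeric scaling factor(s).
#' @export
setGeneric("sfCbv", function(x) standardGeneric("sfCbv"))
#' @rdname sfCbv
setMethod("sfCbv", "ScalingFactors", function(x) x@sfCbv)

#' @rdname sfCbv
#' @export
setGeneric("sfCbf", function(x, method = NULL) standardGeneric("sfCbf"))
#' @rdname sfCbv
setMethod("sfCbf", "ScalingFactors", function(x, method = NULL) {
  if (is.null(method)) x@sfCbf else x@sfCbf[[method]]
})

## show methods -----------------------------------------------------------

setMethod("show", "PerfusionSeries", function(object) {
  d <- dim(object@signal)
  cat(sprintf("PerfusionSeries: %d x %d x %d voxels, %d dynamics\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  TR = %g s, TE = %g s\n", object@tr, object@te))
})

setMethod("show", "ConcentrationSeries", function(object) {
  d <- dim(object@conc)
  cat(sprintf("ConcentrationSeries: %d x %d x %d voxels, %d dynamics (k1 = %g)\n",
              d[1], d[2], d[3], d[4], object@k1))
})

setMethod("show", "ParametricMap", function(object) {
  d <- dim(object@map)
  cat(sprintf("ParametricMap <%s%s> [%s]: %d x %d x %d\n", object@quantity,
              if (object@method != "none") paste0(", ", object@method) else "",
              object@units, d[1], d[2], d[3]))
  v <- object@map[is.finite(object@map)]
  cat(sprintf("  range %.4g .. %.4g, mean %.4g\n", min(v), max(v), mean(v)))
})

setMethod("show", "VoxelMask", function(object) {
  cat(sprintf("VoxelMask <%s>: %d of %d voxels\n  %s\n", object@label,
              sum(object@mask), length(object@mask), object@provenance))
})

setMethod("show", "CategorizedVesselMask", function(object) {
  tab <- tabulate(object@codes + 1L, nbins = 4L)
  cat(sprintf("CategorizedVesselMask [%s]: CBV > %g, CBF > %g\n",
              object@method, object@cbvThreshold, object@cbfThreshold))
  cat(sprintf("  CBV-only %d, CBF-only %d, both %d\n", tab[2], tab[3], tab[4]))
})

setMethod("show", "ArterialInputFunction", function(object) {
  cat(sprintf("ArterialInputFunction (%s): %d dynamics, peak %.4g from %d voxels\n",
              object@method, length(object@curve), max(object@curve),
              nrow(object@sourceVoxels)))
})

setMethod("show", "ScalingFactors", function(object) {
  cat(sprintf("ScalingFactors over %d normal-parenchyma voxels\n",
              object@nNormalVoxels))
  cat(sprintf("  SF_CBV = %.4g (mL/100 g)/rel\n", object@sfCbv))
  for (m in names(object@sfCbf))
    cat(sprintf("  SF_CBF[%s] = %.4g (mL/100 g/min)/rel\n", m, object@sfCbf[[m]]))
})

setMethod("show", "PhantomDataset", function(object) {
  d <- dim(object@series@signal)
  cat(sprintf("PhantomDataset: %d x %d x %d x %d (seed %d, noise sd %g)\n",
              d[1], d[2], d[3], d[4], object@config@seed,
              object@config@noiseSigma))
  counts <- vapply(object@truthMasks, sum, numeric(1))
  cat("  voxels:", paste(sprintf("%s=%d", names(counts), counts), collapse = ", "),
      "\n")
})

setMethod("show", "DscRun", function(object) {
  cat("DscRun\n")
  cat(sprintf("  AIF: %s (%d voxels)\n", object@aif@method,
              nrow(object@aif@sourceVoxels)))
  show(object@scaling)
  cat(sprintf("  ROI report: %d rows; manifest scalars: %d\n",
              nrow(object@roiReport), length(object@manifest$scalars)))
})
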