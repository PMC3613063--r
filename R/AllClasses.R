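## Central S4 containers. All voxel containers store plain numeric/logical
## arrays indexed (x, y, slice[, dynamic]); geometry metadata beyond the grid
## is carried by the NIfTI reader/writer, not by these classes.

.MASK_LABELS <- c("BRAIN", "CSF", "PRELIM_VESSEL", "NORMAL_BRAIN", "FINAL_VESSEL")
.MAP_QUANTITIES <- c("rCBV", "rCBF", "TTP", "CBV", "CBF", "MTT")
.DECONV_METHODS <- c("sSVD", "cSVD")
.TISSUE_LABELS <- c("GM", "WM", "CSF", "VESSEL", "BACKGROUND")

#' PerfusionSeries: a 4-D DSC-MRI signal series
#'
#' Raw dynamic signal intensities on an (x, y, slice, dynamic) grid together
#' with the repetition time `tr` and echo time `te` (both seconds).
#'
#' @slot signal 4-D numeric array of non-negative signal intensities.
#' @slot tr repetition time in seconds (temporal spacing of dynamics).
#' @slot te echo time in seconds.
#' @export
setClass("PerfusionSeries",
  representation(signal = "array", tr = "numeric", te = "numeric"))

setValidity("PerfusionSeries", function(object) {
  msg <- character()
  if (length(dim(object@signal)) != 4L)
    msg <- c(msg, "signal must be a 4-D array (x, y, slice, dynamic)")
  if (any(!is.finite(object@signal)) || any(object@signal < 0))
    msg <- c(msg, "signal intensities must be finite and >= 0")
  if (length(object@tr) != 1L || object@tr <= 0)
    msg <- c(msg, "tr must be a single positive number (seconds)")
  if (length(object@te) != 1L || object@te <= 0)
    msg <- c(msg, "te must be a single positive number (seconds)")
  if (length(msg)) msg else TRUE
})

#' Construct a PerfusionSeries
#'
#' @param signal 4-D numeric array (x, y, slice, dynamic).
#' @param tr repetition time, seconds.
#' @param te echo time, seconds.
#' @return A [PerfusionSeries-class] object.
#' @examples
#' s <- PerfusionSeries(array(100, c(4, 4, 1, 12)), tr = 1, te = 0.04)
#' nDynamics(s)
#' @export
PerfusionSeries <- function(signal, tr, te) {
  new("PerfusionSeries", signal = signal, tr = as.numeric(tr), te = as.numeric(te))
}

#' ConcentrationSeries: voxelwise contrast-concentration curves
#'
#' Concentration C(t) derived from a [PerfusionSeries-class] by the
#' log-ratio relation C(t) = -(k1/TE) log(S(t)/S0) (arbitrary units).
#'
#' @slot conc 4-D numeric concentration array.
#' @slot baseline 3-D baseline signal S0 (mean of the baseline dynamics).
#' @slot k1 proportionality constant (dimensionless, default 1).
#' @slot tr,te acquisition timing carried over from the series (seconds).
#' @export
setClass("ConcentrationSeries",
  representation(conc = "array", baseline = "array", k1 = "numeric",
                 tr = "numeric", te = "numeric"))

setValidity("ConcentrationSeries", function(object) {
  msg <- character()
  if (length(dim(object@conc)) != 4L)
    msg <- c(msg, "conc must be a 4-D array")
  if (!identical(dim(object@conc)[1:3], dim(object@baseline)))
    msg <- c(msg, "baseline grid must match the concentration grid")
  if (length(object@k1) != 1L || object@k1 <= 0)
    msg <- c(msg, "k1 must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' ParametricMap: a 3-D scalar perfusion map
#'
#' @slot map 3-D numeric array.
#' @slot quantity one of `"rCBV"`, `"rCBF"`, `"TTP"`, `"CBV"`, `"CBF"`, `"MTT"`.
#' @slot units unit string (e.g. `"mL/100 g"`, `"s"`, `"relative"`).
#' @slot method deconvolution method tag: `"none"`, `"sSVD"` or `"cSVD"`.
#' @slot metadata free-form list (QC flag masks, provenance scalars).
#' @export
setClass("ParametricMap",
  representation(map = "array", quantity = "character", units = "character",
                 method = "character", metadata = "list"),
  prototype(method = "none", metadata = list()))

setValidity("ParametricMap", function(object) {
  msg <- character()
  if (length(dim(object@map)) != 3L)
    msg <- c(msg, "map must be a 3-D array")
  if (!object@quantity %in% .MAP_QUANTITIES)
    msg <- c(msg, paste("quantity must be one of:",
                        paste(.MAP_QUANTITIES, collapse = ", ")))
  if (!object@method %in% c("none", .DECONV_METHODS))
    msg <- c(msg, "method must be 'none', 'sSVD' or 'cSVD'")
  if (length(msg)) msg else TRUE
})

#' Construct a ParametricMap
#'
#' @param map 3-D numeric array.
#' @param quantity,units,method,metadata see [ParametricMap-class].
#' @return A [ParametricMap-class] object.
#' @export
ParametricMap <- function(map, quantity, units, method = "none",
                          metadata = list()) {
  new("ParametricMap", map = map, quantity = quantity, units = units,
      method = method, metadata = metadata)
}

#' VoxelMask: a labelled boolean 3-D mask
#'
#' @slot mask 3-D logical array.
#' @slot label one of `"BRAIN"`, `"CSF"`, `"PRELIM_VESSEL"`, `"NORMAL_BRAIN"`,
#'   `"FINAL_VESSEL"`.
#' @slot provenance human-readable description of the rule that produced it.
#' @export
setClass("VoxelMask",
  representation(mask = "array", label = "character", provenance = "character"),
  prototype(provenance = ""))

setValidity("VoxelMask", function(object) {
  msg <- character()
  if (length(dim(object@mask)) != 3L || !is.logical(object@mask))
    msg <- c(msg, "mask must be a 3-D logical array")
  if (!object@label %in% .MASK_LABELS)
    msg <- c(msg, paste("label must be one of:", paste(.MASK_LABELS, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a VoxelMask
#'
#' @param mask 3-D logical array.
#' @param label,provenance see [VoxelMask-class].
#' @return A [VoxelMask-class] object.
#' @export
VoxelMask <- function(mask, label, provenance = "") {
  storage.mode(mask) <- "logical"
  new("VoxelMask", mask = mask, label = label, provenance = provenance)
}

#' CategorizedVesselMask: final dual-threshold vessel map
#'
#' Integer codes: 0 none, 1 flagged by the CBV threshold only, 2 by the CBF
#' threshold only, 3 by both.
#'
#' @slot codes 3-D integer array with values in 0..3.
#' @slot cbvThreshold,cbfThreshold thresholds used (mL/100 g; mL/100 g/min).
#' @slot method deconvolution method of the CBF map used.
#' @export
setClass("CategorizedVesselMask",
  representation(codes = "array", cbvThreshold = "numeric",
                 cbfThreshold = "numeric", method = "character"))

setValidity("CategorizedVesselMask", function(object) {
  msg <- character()
  if (length(dim(object@codes)) != 3L)
    msg <- c(msg, "codes must be a 3-D array")
  if (!all(object@codes %in% 0:3))
    msg <- c(msg, "codes must be integers in 0..3")
  if (!object@method %in% .DECONV_METHODS)
    msg <- c(msg, "method must be 'sSVD' or 'cSVD'")
  if (length(msg)) msg else TRUE
})

#' ArterialInputFunction: the deconvolution kernel curve
#'
#' @slot curve concentration per dynamic (length = number of dynamics).
#' @slot sourceVoxels integer matrix (n x 3) of contributing voxel coordinates.
#' @slot method `"MANUAL"` or `"AUTO"`.
#' @export
setClass("ArterialInputFunction",
  representation(curve = "numeric", sourceVoxels = "matrix", method = "character"))

setValidity("ArterialInputFunction", function(object) {
  msg <- character()
  if (max(object@curve) <= 0)
    msg <- c(msg, "AIF peak must be positive")
  if (!object@method %in% c("MANUAL", "AUTO"))
    msg <- c(msg, "method must be 'MANUAL' or 'AUTO'")
  if (length(msg)) msg else TRUE
})

#' ReferenceConstants: literature CBV/CBF values for normal parenchyma
#'
#' Defaults follow the composite of PET/CT literature: GM approximately
#' 4 mL/100 g and 50 mL/100 g/min, WM approximately 2 and 25, with normal
#' parenchyma modelled as 60% GM / 40% WM.
#'
#' @slot cbvGm,cbvWm gray/white-matter CBV references, mL/100 g.
#' @slot cbfGm,cbfWm gray/white-matter CBF references, mL/100 g/min.
#' @slot gmFraction gray-matter fraction of normal parenchyma, in \[0, 1\].
#' @export
setClass("ReferenceConstants",
  representation(cbvGm = "numeric", cbvWm = "numeric", cbfGm = "numeric",
                 cbfWm = "numeric", gmFraction = "numeric"))

setValidity("ReferenceConstants", function(object) {
  msg <- character()
  vals <- c(object@cbvGm, object@cbvWm, object@cbfGm, object@cbfWm)
  if (any(vals <= 0)) msg <- c(msg, "all reference values must be > 0")
  if (object@gmFraction < 0 || object@gmFraction > 1)
    msg <- c(msg, "gmFraction must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct ReferenceConstants
#'
#' @param cbvGm,cbvWm,cbfGm,cbfWm,gmFraction see [ReferenceConstants-class].
#' @return A [ReferenceConstants-class] object.
#' @examples
#' compositeReference(referenceConstants(), "CBV")  # 3.2 mL/100 g
#' @export
referenceConstants <- function(cbvGm = .REF_CBV_GM, cbvWm = .REF_CBV_WM,
                               cbfGm = .REF_CBF_GM, cbfWm = .REF_CBF_WM,
                               gmFraction = .GM_FRACTION) {
  new("ReferenceConstants", cbvGm = cbvGm, cbvWm = cbvWm, cbfGm = cbfGm,
      cbfWm = cbfWm, gmFraction = gmFraction)
}

#' ScalingFactors: relative-to-absolute conversion factors
#'
#' @slot sfCbv scalar SF_CBV, (mL/100 g) per relative unit.
#' @slot sfCbf named numeric, SF_CBF per deconvolution method,
#'   (mL/100 g/min) per relative unit.
#' @slot nNormalVoxels number of voxels in the normal-parenchyma mask.
#' @slot references the [ReferenceConstants-class] used.
#' @export
setClass("ScalingFactors",
  representation(sfCbv = "numeric", sfCbf = "numeric",
                 nNormalVoxels = "integer", references = "ReferenceConstants"))

setValidity("ScalingFactors", function(object) {
  msg <- character()
  if (object@sfCbv <= 0 || any(object@sfCbf <= 0))
    msg <- c(msg, "scaling factors must be > 0")
  if (is.null(names(object@sfCbf)) || any(!nzchar(names(object@sfCbf))))
    msg <- c(msg, "sfCbf must be named by deconvolution method")
  if (object@nNormalVoxels <= 0L)
    msg <- c(msg, "nNormalVoxels must be > 0")
  if (length(msg)) msg else TRUE
})

#' DeconvolutionConfig: truncated-SVD settings
#'
#' @slot method `"sSVD"` (lower-triangular Toeplitz) or `"cSVD"`
#'   (zero-padded block circulant, delay-insensitive).
#' @slot truncationFraction singular values below this fraction of the largest
#'   are zeroed; strictly in (0, 1).
#' @slot padFactor integer >= 2; circulant padding multiple (cSVD only).
#' @slot tr temporal resolution, seconds.
#' @export
setClass("DeconvolutionConfig",
  representation(method = "character", truncationFraction = "numeric",
                 padFactor = "integer", tr = "numeric"))

setValidity("DeconvolutionConfig", function(object) {
  msg <- character()
  if (!object@method %in% .DECONV_METHODS)
    msg <- c(msg, "method must be 'sSVD' or 'cSVD'")
  if (object@truncationFraction <= 0 || object@truncationFraction >= 1)
    msg <- c(msg, "truncationFraction must be strictly between 0 and 1")
  if (object@padFactor < 2L)
    msg <- c(msg, "padFactor must be an integer >= 2")
  if (object@tr <= 0)
    msg <- c(msg, "tr must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a DeconvolutionConfig
#'
#' @param method `"sSVD"` or `"cSVD"`.
#' @param truncationFraction truncation threshold as a fraction of the largest
#'   singular value; defaults to 0.20 (sSVD) or 0.10 (cSVD).
#' @param padFactor circulant padding multiple (cSVD), integer >= 2.
#' @param tr temporal resolution, seconds.
#' @return A [DeconvolutionConfig-class] object.
#' @export
deconvolutionConfig <- function(method = c("sSVD", "cSVD"),
                                truncationFraction = NULL,
                                padFactor = .PAD_FACTOR, tr = 1) {
  method <- match.arg(method)
  if (is.null(truncationFraction))
    truncationFraction <- if (method == "sSVD") .TRUNCATION_SSVD else .TRUNCATION_CSVD
  new("DeconvolutionConfig", method = method,
      truncationFraction = truncationFraction,
      padFactor = as.integer(padFactor), tr = as.numeric(tr))
}

#' ConvolutionOperator: discrete AIF convolution matrix with precomputed SVD
#'
#' Built once per AIF and reused across all voxels; see
#' [buildConvolutionOperator()].
#'
#' @slot matrix the convolution matrix (Toeplitz or circulant).
#' @slot d,u,v singular value decomposition of `matrix`.
#' @slot config the [DeconvolutionConfig-class] used.
#' @slot nDynamics original curve length before any padding.
#' @export
setClass("ConvolutionOperator",
  representation(matrix = "matrix", d = "numeric", u = "matrix", v = "matrix",
                 config = "DeconvolutionConfig", nDynamics = "integer"))

#' TissueClassSpec: ground-truth description of one phantom tissue class
#'
#' @slot label one of `"GM"`, `"WM"`, `"CSF"`, `"VESSEL"`, `"BACKGROUND"`.
#' @slot cbvTrue true CBV, mL/100 g (0 for CSF/background).
#' @slot cbfTrue true CBF, mL/100 g/min.
#' @slot delay bolus arrival offset versus the AIF, seconds.
#' @slot s0 baseline signal, arbitrary units.
#' @slot firstImageRatio first-dynamic/baseline signal ratio (T1-saturation
#'   surrogate; CSF must have the largest value in the phantom).
#' @export
setClass("TissueClassSpec",
  representation(label = "character", cbvTrue = "numeric", cbfTrue = "numeric",
                 delay = "numeric", s0 = "numeric", firstImageRatio = "numeric"))

setValidity("TissueClassSpec", function(object) {
  msg <- character()
  if (!object@label %in% .TISSUE_LABELS)
    msg <- c(msg, paste("label must be one of:", paste(.TISSUE_LABELS, collapse = ", ")))
  if (object@cbvTrue < 0 || object@cbfTrue < 0)
    msg <- c(msg, "cbvTrue and cbfTrue must be >= 0")
  if (object@label == "CSF" && (object@cbvTrue != 0 || object@cbfTrue != 0))
    msg <- c(msg, "CSF must have zero CBV and CBF")
  if (object@cbvTrue > 0 && object@cbfTrue == 0)
    msg <- c(msg, "perfused classes need cbfTrue > 0 for a finite MTT")
  if (object@s0 < 0) msg <- c(msg, "s0 must be >= 0")
  if (object@firstImageRatio <= 0) msg <- c(msg, "firstImageRatio must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a TissueClassSpec
#'
#' @param label,cbvTrue,cbfTrue,delay,s0,firstImageRatio see
#'   [TissueClassSpec-class].
#' @return A [TissueClassSpec-class] object.
#' @export
tissueClassSpec <- function(label, cbvTrue, cbfTrue, delay = 0, s0 = 800,
                            firstImageRatio = 1) {
  new("TissueClassSpec", label = label, cbvTrue = cbvTrue, cbfTrue = cbfTrue,
      delay = delay, s0 = s0, firstImageRatio = firstImageRatio)
}

#' PhantomConfig: full description of a synthetic DSC dataset
#'
#' @slot dim integer grid shape (nx, ny, nslices).
#' @slot nDynamics number of dynamics (>= 12).
#' @slot tr,te acquisition timing, seconds.
#' @slot aif gamma-variate AIF parameters: `amplitude`, `t0`, `alpha`, `beta`.
#' @slot noiseSigma additive Gaussian signal noise SD.
#' @slot seed integer RNG seed; fully determines the dataset.
#' @slot classes named list of [TissueClassSpec-class] (GM, WM, CSF, VESSEL,
#'   BACKGROUND).
#' @slot impairedDelay extra bolus delay (s) applied to the right hemisphere.
#' @slot impairedCbfFactor multiplicative CBF reduction on the right hemisphere.
#' @slot vesselCarriesAif if `TRUE` (default) vessel voxels carry the
#'   amplitude-scaled, undispersed AIF itself (delta-like residue).
#' @export
setClass("PhantomConfig",
  representation(dim = "integer", nDynamics = "integer", tr = "numeric",
                 te = "numeric", aif = "list", noiseSigma = "numeric",
                 seed = "integer", classes = "list", impairedDelay = "numeric",
                 impairedCbfFactor = "numeric", vesselCarriesAif = "logical"))

setValidity("PhantomConfig", function(object) {
  msg <- character()
  if (length(object@dim) != 3L || any(object@dim < 1L))
    msg <- c(msg, "dim must be three positive integers (nx, ny, nslices)")
  if (object@dim[1] < 16L || object@dim[2] < 16L)
    msg <- c(msg, "in-plane grid must be at least 16 x 16 to hold the layout")
  if (object@nDynamics < 12L)
    msg <- c(msg, "nDynamics must be >= 12 (baseline window 6-10 plus bolus)")
  if (!all(c("amplitude", "t0", "alpha", "beta") %in% names(object@aif)))
    msg <- c(msg, "aif must name amplitude, t0, alpha, beta")
  if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
  req <- c("GM", "WM", "CSF", "VESSEL", "BACKGROUND")
  if (!all(req %in% names(object@classes)))
    msg <- c(msg, paste("classes must include", paste(req, collapse = ", ")))
  if (object@impairedCbfFactor <= 0 || object@impairedCbfFactor > 1)
    msg <- c(msg, "impairedCbfFactor must be in (0, 1]")
  ok <- vapply(object@classes, function(x) is(x, "TissueClassSpec"), logical(1))
  if (!all(ok)) msg <- c(msg, "classes must be TissueClassSpec objects")
  if (length(msg) == 0) {
    ratios <- vapply(object@classes, function(x) x@firstImageRatio, numeric(1))
    if (ratios[["CSF"]] <= max(ratios[setdiff(names(ratios), "CSF")]))
      msg <- c(msg, "CSF firstImageRatio must exceed that of all other classes")
  }
  if (length(msg)) msg else TRUE
})

#' PhantomDataset: synthetic series plus ground truth
#'
#' @slot series the rendered [PerfusionSeries-class].
#' @slot truthMaps named list of [ParametricMap-class]: CBV, CBF, MTT, TTP.
#' @slot truthMasks named list of logical 3-D arrays, one per tissue class,
#'   plus `BRAIN` (all non-background voxels).
#' @slot aifTrue the noise-free arterial concentration curve.
#' @slot config the generating [PhantomConfig-class].
#' @export
setClass("PhantomDataset",
  representation(series = "PerfusionSeries", truthMaps = "list",
                 truthMasks = "list", aifTrue = "numeric",
                 config = "PhantomConfig"))

setValidity("PhantomDataset", function(object) {
  msg <- character()
  grid <- dim(object@series@signal)[1:3]
  for (m in object@truthMaps)
    if (!identical(dim(m@map), grid))
      msg <- c(msg, "truth maps must share the series grid")
  if (!all(c("CBV", "CBF", "MTT", "TTP") %in% names(object@truthMaps)))
    msg <- c(msg, "truthMaps must include CBV, CBF, MTT, TTP")
  if (length(msg)) msg else TRUE
})

#' DscRun: result container for a full pipeline run
#'
#' @slot maps named list of relative and absolute [ParametricMap-class]
#'   objects (`rcbv`, `rcbf$<method>`, `ttp`, `cbv`, `cbf$<method>`,
#'   `mtt$<method>`).
#' @slot masks named list of [VoxelMask-class] objects (`brain`, `csf`,
#'   `prelimVessel`, `normalBrain`).
#' @slot vesselMasks named list of [CategorizedVesselMask-class] per method.
#' @slot aif the [ArterialInputFunction-class] used.
#' @slot scaling the [ScalingFactors-class].
#' @slot roiReport hemispheric ROI statistics `data.frame`.
#' @slot manifest list of run parameters, derived scalars and output files.
#' @export
setClass("DscRun",
  representation(maps = "list", masks = "list", vesselMasks = "list",
                 aif = "ArterialInputFunction", scaling = "ScalingFactors",
                 roiReport = "data.frame", manifest = "list"))
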