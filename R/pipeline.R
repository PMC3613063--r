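## End-to-end orchestration: brain mask -> baseline -> concentration -> AIF
## -> rCBV/rCBF/TTP -> CSF mask -> preliminary vessel mask -> normal mask ->
## scaling -> absolute maps -> final vessel masks -> ROI report.

#' Run the full quantification pipeline
#'
#' Executes every stage on a [PerfusionSeries-class] (or a
#' [PhantomConfig-class], which is built first) and returns a
#' [DscRun-class] holding the relative and absolute maps, all masks, the
#' scaling factors, the hemispheric ROI report and a manifest of every
#' derived scalar. If `outputDir` is given, all volumes, the ROI CSV and the
#' manifest JSON are written there.
#'
#' A stage failure aborts with the stage name; the partial manifest is
#' attached to the error condition as `condition$manifest`.
#'
#' @param input a [PerfusionSeries-class], [PhantomConfig-class], or a NIfTI
#'   path accepted by [readPerfusionSeries()].
#' @param outputDir optional output directory (created if missing).
#' @param methods deconvolution methods to run (`"sSVD"`, `"cSVD"` or both).
#' @param truncation named truncation fractions per method (defaults 0.20
#'   sSVD, 0.10 cSVD).
#' @param padFactor circulant padding multiple for cSVD.
#' @param ref a [ReferenceConstants-class].
#' @param ttpWindow TTP window width in seconds (default 3).
#' @param finalCbv,finalCbf final vessel thresholds (defaults 8, 100).
#' @param aifVoxels optional manual AIF voxel coordinates (n x 3 matrix).
#' @param aifK number of auto-selected AIF voxels (default 10).
#' @param primaryMethod method whose rCBF feeds the preliminary vessel mask.
#' @param midline,slices forwarded to [hemisphericRoiStats()].
#' @param kHOverRho hematocrit/density constant, cc/g.
#' @param verbose print stage progress and derived scalars.
#' @return A [DscRun-class].
#' @examples
#' \donttest{
#' run <- runPipeline(phantomConfig(dim = c(32, 32, 1), noiseSigma = 0))
#' run@manifest$scalars$sf_cbv
#' }
#' @export
runPipeline <- function(input, outputDir = NULL,
                        methods = c("sSVD", "cSVD"),
                        truncation = c(sSVD = .TRUNCATION_SSVD,
                                       cSVD = .TRUNCATION_CSVD),
                        padFactor = .PAD_FACTOR,
                        ref = referenceConstants(), ttpWindow = .TTP_WINDOW,
                        finalCbv = .FINAL_CBV_THRESHOLD,
                        finalCbf = .FINAL_CBF_THRESHOLD,
                        aifVoxels = NULL, aifK = 10L,
                        primaryMethod = methods[1], midline = NULL,
                        slices = NULL, kHOverRho = .KH_OVER_RHO,
                        verbose = FALSE) {
  methods <- match.arg(methods, c("sSVD", "cSVD"), several.ok = TRUE)
  stopifnot(primaryMethod %in% methods)
  manifest <- list(parameters = list(
    methods = methods, truncation = as.list(truncation[methods]),
    padFactor = padFactor, ttpWindow = ttpWindow,
    finalThresholds = list(cbv = finalCbv, cbf = finalCbf),
    references = list(cbvGm = ref@cbvGm, cbvWm = ref@cbvWm, cbfGm = ref@cbfGm,
                      cbfWm = ref@cbfWm, gmFraction = ref@gmFraction),
    primaryMethod = primaryMethod, kHOverRho = kHOverRho),
    scalars = list(), outputs = character())
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      cond <- simpleError(sprintf("pipeline stage '%s' failed: %s", name,
                                  conditionMessage(e)))
      cond$manifest <- manifest
      stop(cond)
    })
  }

  series <- stage("input", {
    if (is(input, "PhantomConfig")) {
      manifest$parameters$phantomSeed <- input@seed
      buildPhantom(input)@series
    } else if (is.character(input)) readPerfusionSeries(input)
    else if (is(input, "PerfusionSeries")) input
    else stop("unsupported input type: ", class(input))
  })

  brain <- stage("brain-mask", computeBrainMask(series))
  say("brain mask: %d voxels", sum(voxelData(brain)))
  s0 <- stage("baseline", computeBaseline(series))
  conc <- stage("concentration", signalToConcentration(series, s0))
  aif <- stage("aif", selectAif(conc, brain, k = aifK, voxels = aifVoxels))
  say("AIF (%s): peak %.4g", aif@method, max(aifCurve(aif)))

  rcbv <- stage("rcbv", computeRcbv(conc, aif, kHOverRho = kHOverRho))
  rcbf <- stage("rcbf", {
    lapply(setNames(nm = methods), function(m) {
      cfg <- deconvolutionConfig(m, truncationFraction = truncation[[m]],
                                 padFactor = padFactor, tr = series@tr)
      computeRcbf(conc, aif, cfg, mask = brain)
    })
  })
  ttp <- stage("ttp", computeTtp(conc))

  csf <- stage("csf-mask", {
    ratio <- computeRatioImage(series, s0, brain)
    computeCsfMask(ratio, brain)
  })
  say("CSF mask: %d voxels", sum(voxelData(csf)))

  eligible <- VoxelMask(voxelData(brain) & !voxelData(csf), "BRAIN",
                        "brain minus CSF")
  prelim <- stage("prelim-vessel",
                  preliminaryVesselMask(rcbv, rcbf[[primaryMethod]], eligible))
  medians <- attr(prelim, "medians")
  ## per-method rCBF medians over the eligible voxels, for threshold reporting
  rcbfMedians <- vapply(rcbf, function(m)
    median(voxelData(m)[voxelData(eligible)]), numeric(1))
  say("preliminary vessel mask: %d voxels", sum(voxelData(prelim)))

  normalEligible <- VoxelMask(voxelData(eligible) & !voxelData(prelim),
                              "BRAIN", "brain minus CSF minus prelim vessels")
  normal <- stage("normal-brain",
                  normalBrainMask(ttp, normalEligible, window = ttpWindow))
  say("normal-parenchyma mask: %d voxels (TTP median %.4g s)",
      sum(voxelData(normal)), attr(normal, "ttpMedian"))

  scaling <- stage("scaling", computeScalingFactors(rcbv, rcbf, normal, ref))
  absMaps <- stage("apply-scaling", applyScaling(rcbv, rcbf, scaling))
  say("SF_CBV = %.4g; %s", sfCbv(scaling),
      paste(sprintf("SF_CBF[%s] = %.4g", names(sfCbf(scaling)),
                    sfCbf(scaling)), collapse = "; "))

  vessel <- stage("final-vessel", {
    lapply(setNames(nm = methods), function(m)
      finalVesselMask(absMaps$cbv, absMaps$cbf[[m]], brain,
                      cbvThreshold = finalCbv, cbfThreshold = finalCbf))
  })

  prelimAbsCbf <- sfCbf(scaling)[methods] * (2 * rcbfMedians[methods])
  cmp <- thresholdComparison(sfCbv(scaling) * medians[["rcbv"]] * 2,
                             prelimAbsCbf, finalCbv = finalCbv,
                             finalCbf = finalCbf)

  roi <- stage("roi-stats",
               hemisphericRoiStats(absMaps$cbv, absMaps$cbf, absMaps$mtt,
                                   brain, csf, vessel, midline = midline,
                                   slices = slices))

  manifest$scalars <- list(
    brain_voxels = sum(voxelData(brain)),
    csf_voxels = sum(voxelData(csf)),
    prelim_vessel_voxels = sum(voxelData(prelim)),
    normal_voxels = scaling@nNormalVoxels,
    rcbv_median = unname(medians[["rcbv"]]),
    rcbf_median = as.list(rcbfMedians),
    prelim_threshold_rcbv = unname(2 * medians[["rcbv"]]),
    prelim_threshold_rcbf = as.list(2 * rcbfMedians),
    ttp_median = attr(normal, "ttpMedian"),
    sf_cbv = sfCbv(scaling),
    sf_cbf = as.list(sfCbf(scaling)),
    prelim_threshold_cbv_abs = cmp$prelimAbs[cmp$quantity == "CBV"],
    prelim_threshold_cbf_abs = as.list(setNames(
      cmp$prelimAbs[cmp$quantity == "CBF"], cmp$method[cmp$quantity == "CBF"])),
    prelim_vs_final_pct = as.list(setNames(
      cmp$pctBelowFinal, paste0(cmp$quantity, "_", cmp$method))),
    vessel_voxels = lapply(vessel, function(v) sum(voxelData(v) > 0L)))

  run <- new("DscRun",
             maps = list(rcbv = rcbv, rcbf = rcbf, ttp = ttp,
                         cbv = absMaps$cbv, cbf = absMaps$cbf,
                         mtt = absMaps$mtt),
             masks = list(brain = brain, csf = csf, prelimVessel = prelim,
                          normalBrain = normal),
             vesselMasks = vessel, aif = aif, scaling = scaling,
             roiReport = roi, manifest = manifest)
  if (!is.null(outputDir)) run <- writeRunOutputs(run, outputDir)
  run
}

#' Write all pipeline outputs of a run
#'
#' Writes every map and mask as NIfTI + sidecar, the ROI report as CSV and
#' the manifest (with the output file list) as JSON.
#'
#' @param run a [DscRun-class].
#' @param outputDir target directory (created if missing).
#' @return The run with `manifest$outputs` filled in, invisibly.
#' @export
writeRunOutputs <- function(run, outputDir) {
  dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
  out <- character()
  wv <- function(x, stem) {
    p <- file.path(outputDir, paste0(stem, ".nii.gz"))
    writeVolume(x, p)
    out <<- c(out, p)
  }
  wv(run@maps$rcbv, "rcbv")
  wv(run@maps$ttp, "ttp")
  wv(run@maps$cbv, "cbv")
  for (m in names(run@maps$rcbf)) {
    wv(run@maps$rcbf[[m]], paste0("rcbf_", tolower(m)))
    wv(run@maps$cbf[[m]], paste0("cbf_", tolower(m)))
    wv(run@maps$mtt[[m]], paste0("mtt_", tolower(m)))
    wv(run@vesselMasks[[m]], paste0("vessel_mask_", tolower(m)))
  }
  for (nm in names(run@masks)) wv(run@masks[[nm]], paste0("mask_", nm))
  roiPath <- file.path(outputDir, "roi_report.csv")
  utils::write.csv(run@roiReport, roiPath, row.names = FALSE)
  out <- c(out, roiPath)
  run@manifest$outputs <- out
  manifestPath <- file.path(outputDir, "manifest.json")
  jsonlite::write_json(run@manifest, manifestPath, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(run)
}
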