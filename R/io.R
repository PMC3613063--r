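## NIfTI-1 I/O with JSON sidecars for acquisition metadata.
##
## Every volume is written as NIfTI; TR/TE and map descriptors travel in a
## sidecar `<stem>.json` next to the image so a series round-trips losslessly
## together with its timing.

## read a NIfTI volume as a bare numeric array (drop the niftiImage class)
readNiftiArray <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  array(as.numeric(arr), dim(arr))
}

sidecarPath <- function(path) {
  paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
}

readSidecar <- function(path) {
  sp <- sidecarPath(path)
  if (file.exists(sp)) jsonlite::read_json(sp, simplifyVector = TRUE) else NULL
}

#' Read a 4-D perfusion series from NIfTI
#'
#' TR/TE are taken from the JSON sidecar when present (sidecar precedence),
#' falling back to the `tr`/`te` arguments; a missing value is an error
#' naming the argument to set. A sidecar `n_dynamics` inconsistent with the
#' data is an error.
#'
#' @param path NIfTI file (`.nii` or `.nii.gz`).
#' @param tr,te fallback timing in seconds when no sidecar is present.
#' @return A [PerfusionSeries-class].
#' @export
readPerfusionSeries <- function(path, tr = NULL, te = NULL) {
  arr <- readNiftiArray(path)
  if (length(dim(arr)) == 3L)
    stop("expected a 4-D series (x, y, slice, dynamic); got a 3-D volume")
  if (length(dim(arr)) != 4L)
    stop("expected a 4-D series (x, y, slice, dynamic); got ",
         length(dim(arr)), "-D data")
  side <- readSidecar(path)
  if (!is.null(side$tr)) tr <- side$tr
  if (!is.null(side$te)) te <- side$te
  if (is.null(tr)) stop("TR not found in sidecar; pass tr= (seconds)")
  if (is.null(te)) stop("TE not found in sidecar; pass te= (seconds)")
  if (!is.null(side$n_dynamics) && side$n_dynamics != dim(arr)[4])
    stop("sidecar n_dynamics (", side$n_dynamics,
         ") does not match the data (", dim(arr)[4], ")")
  PerfusionSeries(arr, tr = tr, te = te)
}

#' Write a perfusion series to NIfTI with a JSON sidecar
#'
#' @param series a [PerfusionSeries-class].
#' @param path output NIfTI path.
#' @param extra named list merged into the sidecar (e.g. phantom seed).
#' @return `path`, invisibly.
#' @export
writePerfusionSeries <- function(series, path, extra = list()) {
  RNifti::writeNifti(RNifti::asNifti(series@signal, pixdim = c(1, 1, 1, series@tr)),
                     path)
  side <- c(list(tr = series@tr, te = series@te,
                 n_dynamics = nDynamics(series)), extra)
  jsonlite::write_json(side, sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a parametric map or mask volume to NIfTI
#'
#' Maps carry `quantity`, `units` and `method` in the sidecar; masks are
#' written as integer volumes with their label (and, for categorized vessel
#' masks, the code legend) recorded.
#'
#' @param x a [ParametricMap-class], [VoxelMask-class] or
#'   [CategorizedVesselMask-class].
#' @param path output NIfTI path.
#' @return `path`, invisibly.
#' @export
writeVolume <- function(x, path) {
  if (is(x, "ParametricMap")) {
    RNifti::writeNifti(RNifti::asNifti(x@map), path)
    side <- list(quantity = x@quantity, units = x@units, method = x@method)
  } else if (is(x, "VoxelMask")) {
    arr <- x@mask; storage.mode(arr) <- "integer"
    RNifti::writeNifti(RNifti::asNifti(arr), path)
    side <- list(label = x@label, provenance = x@provenance)
  } else if (is(x, "CategorizedVesselMask")) {
    RNifti::writeNifti(RNifti::asNifti(x@codes), path)
    side <- list(label = "FINAL_VESSEL_CATEGORIZED", method = x@method,
                 cbv_threshold = x@cbvThreshold, cbf_threshold = x@cbfThreshold,
                 legend = "0=none 1=CBV-only 2=CBF-only 3=both")
  } else stop("unsupported volume type: ", class(x))
  jsonlite::write_json(side, sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a parametric map written by [writeVolume()]
#'
#' @param path NIfTI path with its JSON sidecar.
#' @return A [ParametricMap-class].
#' @export
readParametricMap <- function(path) {
  arr <- readNiftiArray(path)
  if (length(dim(arr)) == 2L)           # single-slice volume: NIfTI drops the
    dim(arr) <- c(dim(arr), 1L)         # trailing singleton dimension
  side <- readSidecar(path)
  if (is.null(side$quantity))
    stop("no map sidecar found for ", path)
  ParametricMap(arr, side$quantity, side$units, method = side$method)
}
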