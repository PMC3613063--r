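## Signal-to-concentration conversion, brain masking and CSF removal.

#' Otsu histogram threshold
#'
#' Returns the threshold that maximizes the between-class variance of the
#' binned value distribution (the classical two-class histogram criterion).
#' The returned threshold is a bin edge; classification is `value > threshold`.
#' Deterministic for a fixed `nBins` (first maximum wins ties).
#'
#' @param values numeric vector with at least two distinct values.
#' @param nBins number of histogram bins (default 256).
#' @return A single numeric threshold, strictly inside the value range.
#' @examples
#' otsuThreshold(c(rep(0, 50), rep(10, 50)))  # between 0 and 10
#' @export
otsuThreshold <- function(values, nBins = 256L) {
  values <- values[is.finite(values)]
  if (length(unique(values)) < 2L)
    stop("Otsu threshold undefined: need at least two distinct values")
  nBins <- max(2L, as.integer(nBins))
  rng <- range(values)
  breaks <- seq(rng[1], rng[2], length.out = nBins + 1L)
  h <- hist(values, breaks = breaks, plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  muT <- mu0[nBins]
  ## between-class variance for a split after bin k (k = 1..nBins-1)
  k <- seq_len(nBins - 1L)
  w0k <- w0[k]; mu0k <- mu0[k]
  valid <- w0k > 0 & w0k < 1
  sigmaB <- rep(-Inf, nBins - 1L)
  sigmaB[valid] <- (muT * w0k[valid] - mu0k[valid])^2 /
    (w0k[valid] * (1 - w0k[valid]))
  kBest <- which.max(sigmaB)
  breaks[kBest + 1L]
}

## Otsu separability measure eta = sigma_between^2 / sigma_total^2 in [0, 1];
## used to decide whether a two-class structure is present at all.
otsuSeparability <- function(values, threshold) {
  values <- values[is.finite(values)]
  tot <- stats::var(values) * (length(values) - 1) / length(values)
  if (tot <= 0) return(0)
  lo <- values <= threshold
  w0 <- mean(lo)
  if (w0 == 0 || w0 == 1) return(0)
  sb <- w0 * (1 - w0) * (mean(values[!lo]) - mean(values[lo]))^2
  sb / tot
}

#' Compute the brain mask
#'
#' Applies the Otsu threshold to the first perfusion image; voxels above the
#' threshold constitute the brain mask (air/background falls below).
#'
#' @param series a [PerfusionSeries-class].
#' @param nBins histogram bins for the Otsu search.
#' @return A [VoxelMask-class] with label `"BRAIN"`.
#' @export
computeBrainMask <- function(series, nBins = 256L) {
  first <- series@signal[, , , 1, drop = FALSE]
  dim(first) <- dim(series@signal)[1:3]
  if (all(first == 0))
    stop("cannot build a brain mask from an all-zero first image")
  thr <- otsuThreshold(as.vector(first), nBins = nBins)
  mask <- first > thr
  if (!any(mask))
    stop("brain mask is empty: Otsu threshold excluded every voxel")
  VoxelMask(mask, "BRAIN",
            sprintf("first image > Otsu threshold %.6g", thr))
}

#' Compute the baseline image S0
#'
#' Voxelwise mean of the pre-bolus baseline dynamics (dynamics 6-10,
#' 1-based, the convention used throughout this package).
#'
#' @param series a [PerfusionSeries-class] with at least 10 dynamics.
#' @param window 1-based dynamic indices to average (default `6:10`).
#' @return 3-D numeric array S0.
#' @export
computeBaseline <- function(series, window = .BASELINE_WINDOW) {
  nT <- nDynamics(series)
  if (nT < max(window))
    stop("need at least ", max(window), " dynamics for the baseline window")
  sub <- series@signal[, , , window, drop = FALSE]
  d <- dim(sub)
  out <- rowMeans(matrix(sub, nrow = prod(d[1:3]), ncol = d[4]))
  array(out, d[1:3])
}

#' Convert signal to concentration
#'
#' The susceptibility-contrast relation, with the sign arranged so that the
#' bolus passage yields positive concentrations:
#' \deqn{C(t) = -(k_1/TE)\,\log(S(t)/S_0).}
#' Signals are floored at `epsilon * S0` before the log to avoid infinities
#' in noisy voxels; voxels with non-positive baseline (outside the brain)
#' yield zero concentration.
#'
#' @param series a [PerfusionSeries-class].
#' @param s0 3-D baseline array from [computeBaseline()] (computed if `NULL`).
#' @param k1 proportionality constant (default 1; it cancels in the CBV ratio
#'   and is absorbed by the scaling step).
#' @param epsilon relative signal floor (default `1e-3`).
#' @return A [ConcentrationSeries-class].
#' @examples
#' s <- PerfusionSeries(array(100 * exp(-1), c(1, 1, 1, 12)), tr = 1, te = 0.04)
#' s@signal[, , , 1:10] <- 100
#' cs <- signalToConcentration(s)
#' voxelData(cs)[1, 1, 1, 12]  # 25 = -(1/0.04) * log(exp(-1))
#' @export
signalToConcentration <- function(series, s0 = NULL, k1 = 1,
                                  epsilon = .SIGNAL_FLOOR_EPS) {
  if (series@te <= 0) stop("te must be > 0")
  if (is.null(s0)) s0 <- computeBaseline(series)
  d <- dim(series@signal)
  s0v <- as.vector(s0)
  sig <- matrix(series@signal, nrow = prod(d[1:3]), ncol = d[4])
  conc <- matrix(0, nrow = nrow(sig), ncol = ncol(sig))
  ok <- s0v > 0
  floorv <- epsilon * s0v[ok]
  conc[ok, ] <- -(k1 / series@te) *
    log(pmax(sig[ok, , drop = FALSE], floorv) / s0v[ok])
  new("ConcentrationSeries", conc = array(conc, d), baseline = s0,
      k1 = k1, tr = series@tr, te = series@te)
}

#' First-image/baseline ratio image
#'
#' Voxelwise first dynamic divided by the baseline S0, evaluated inside the
#' brain mask (0 outside). CSF, whose long T1 keeps the first unsaturated
#' image disproportionately bright, shows the highest ratios.
#'
#' @param series a [PerfusionSeries-class].
#' @param s0 3-D baseline array (computed if `NULL`).
#' @param brainMask optional [VoxelMask-class]; outside voxels are set to 0.
#' @return 3-D numeric ratio array.
#' @export
computeRatioImage <- function(series, s0 = NULL, brainMask = NULL) {
  if (is.null(s0)) s0 <- computeBaseline(series)
  first <- series@signal[, , , 1, drop = FALSE]
  dim(first) <- dim(series@signal)[1:3]
  ratio <- array(0, dim(first))
  inside <- s0 > 0
  if (!is.null(brainMask)) inside <- inside & voxelData(brainMask)
  ratio[inside] <- first[inside] / s0[inside]
  ratio
}

#' Segment CSF voxels from the ratio image
#'
#' CSF is the high-ratio class of the within-brain first-image/baseline
#' distribution; the cut is placed by the Otsu criterion. A separability
#' guard (between-class/total variance, Otsu's eta) decides whether a CSF
#' class is present at all: a unimodal ratio distribution (no CSF) yields an
#' empty mask with a warning rather than an arbitrary split.
#'
#' @param ratio 3-D ratio array from [computeRatioImage()].
#' @param brainMask a [VoxelMask-class] with label `"BRAIN"`.
#' @param nBins histogram bins for the Otsu search.
#' @param minSeparability minimum Otsu eta in (0, 1) required to accept the
#'   split (default 0.75).
#' @param polarity `"high"` (default): CSF is the high-ratio class;
#'   `"low"` flips the comparison.
#' @return A [VoxelMask-class] with label `"CSF"` (subset of the brain mask).
#' @export
computeCsfMask <- function(ratio, brainMask, nBins = 256L,
                           minSeparability = 0.75,
                           polarity = c("high", "low")) {
  polarity <- match.arg(polarity)
  bm <- voxelData(brainMask)
  if (!any(bm)) stop("brain mask is empty")
  vals <- ratio[bm]
  empty <- function(reason) {
    warning("CSF mask empty: ", reason)
    VoxelMask(array(FALSE, dim(bm)), "CSF", paste("empty:", reason))
  }
  if (length(unique(vals)) < 2L)
    return(empty("degenerate (constant) ratio distribution"))
  thr <- otsuThreshold(vals, nBins = nBins)
  eta <- otsuSeparability(vals, thr)
  if (eta < minSeparability)
    return(empty(sprintf("ratio distribution not bimodal (eta = %.2f)", eta)))
  mask <- if (polarity == "high") bm & (ratio > thr) else bm & (ratio <= thr)
  VoxelMask(mask, "CSF",
            sprintf("ratio %s Otsu threshold %.4g (eta = %.2f)",
                    if (polarity == "high") ">" else "<=", thr, eta))
}
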