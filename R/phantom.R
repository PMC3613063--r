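## Synthetic DSC-MRI phantom with known ground-truth perfusion.
##
## The phantom emulates the bolus-tracking experiment end to end: a
## gamma-variate arterial bolus, tissue curves generated by the tracer-kinetic
## forward model (AIF convolved with a flow-scaled mono-exponential residue),
## vessel voxels carrying the undispersed arterial curve, CSF voxels with zero
## perfusion but an elevated first-image/baseline ratio, and additive Gaussian
## signal noise. Every downstream stage can therefore be validated against
## exact truth maps and masks.

#' Gamma-variate arterial input function
#'
#' The standard parametric bolus model
#' \deqn{AIF(t) = A (t - t_0)^{\alpha} e^{-(t - t_0)/\beta}} for `t > t0` and 0
#' otherwise. The curve is single-peaked with its analytic mode at
#' `t0 + alpha * beta`.
#'
#' @param t sample times, seconds (the dynamic grid).
#' @param amplitude scale factor `A` (arbitrary concentration units).
#' @param t0 bolus arrival time, seconds.
#' @param alpha shape exponent, > 0.
#' @param beta decay time constant, seconds, > 0.
#' @return Numeric concentration curve, same length as `t`.
#' @examples
#' aif <- gammaVariateAif(0:69, amplitude = 1, t0 = 14, alpha = 3, beta = 1.5)
#' which.max(aif)  # near t0 + alpha*beta = 18.5 s
#' @export
gammaVariateAif <- function(t, amplitude = 1, t0 = 14, alpha = 3, beta = 1.5) {
  if (alpha <= 0 || beta <= 0)
    stop("alpha and beta must be positive")
  out <- numeric(length(t))
  up <- t > t0
  out[up] <- amplitude * (t[up] - t0)^alpha * exp(-(t[up] - t0) / beta)
  out
}

#' Forward-model a tissue concentration curve
#'
#' Implements the tracer-kinetic convolution
#' \deqn{C_{tissue}(t) = (\rho/k_H)\, TR \sum_j AIF(t - t_j - delay)\, f(t_j)}
#' with `f(t) = (CBF/60) R(t)` and a mono-exponential residue
#' `R(t) = exp(-t/MTT)`, `MTT = CBV/CBF * 60` seconds. The discrete residue is
#' cell-averaged over each sample interval so that the discrete curve area
#' satisfies the central-volume theorem exactly:
#' `sum(C) / sum(AIF) * (k_H/rho) = CBV` up to the window truncation error.
#' The bolus `delay` is applied as a shift of `round(delay/tr)` samples.
#'
#' @param aif arterial concentration curve on the dynamic grid.
#' @param cbvTrue true CBV, mL/100 g (0 gives an identically zero curve).
#' @param cbfTrue true CBF, mL/100 g/min (> 0 when `cbvTrue > 0`).
#' @param delay bolus arrival offset versus the AIF, seconds.
#' @param tr temporal resolution, seconds.
#' @param kHOverRho hematocrit/density constant k_H/rho, cc/g.
#' @return Numeric tissue concentration curve, same length as `aif`.
#' @export
synthesizeTissueCurve <- function(aif, cbvTrue, cbfTrue, delay = 0, tr = 1,
                                  kHOverRho = .KH_OVER_RHO) {
  if (cbvTrue < 0 || cbfTrue < 0)
    stop("cbvTrue and cbfTrue must be >= 0")
  n <- length(aif)
  if (cbvTrue == 0) return(numeric(n))
  if (cbfTrue == 0)
    stop("perfused voxels (cbvTrue > 0) need cbfTrue > 0")
  mtt <- cbvTrue / cbfTrue * 60            # seconds
  cbfPerSec <- cbfTrue / 60
  j <- 0:(n - 1)
  ## cell-averaged exp(-t/MTT): (1/tr) * integral over [j*tr, (j+1)*tr]
  f <- cbfPerSec * (mtt / tr) * (1 - exp(-tr / mtt)) * exp(-j * tr / mtt)
  shift <- as.integer(round(delay / tr))
  aifS <- shiftCurve(aif, shift)
  conv <- convolve(aifS, rev(f), type = "open")[seq_len(n)]
  (1 / kHOverRho) * tr * conv
}

## shift a curve later in time by `shift` samples (zero fill at the front)
shiftCurve <- function(x, shift) {
  n <- length(x)
  if (shift == 0) return(x)
  if (shift > 0) c(numeric(shift), x)[seq_len(n)]
  else c(x[-seq_len(-shift)], numeric(-shift))
}

#' Render an MR signal curve from a concentration curve
#'
#' The susceptibility signal model `S(t) = s0 * exp(-TE * C(t))` (the
#' proportionality constant is fixed at 1 so that concentration conversion
#' with `k1 = 1` round-trips exactly). The first dynamic is multiplied by
#' `firstImageRatio` to emulate the T1-saturation excess of unsaturated spins
#' (largest in CSF), and Gaussian noise of SD `noiseSigma` is added; negative
#' intensities are clipped at 0.
#'
#' @param conc concentration curve (arbitrary units).
#' @param s0 baseline signal, > 0.
#' @param te echo time, seconds.
#' @param firstImageRatio multiplicative factor for dynamic 1.
#' @param noiseSigma additive Gaussian noise SD (signal units).
#' @param seed RNG seed used when `noiseSigma > 0`.
#' @return Numeric signal curve, same length as `conc`.
#' @export
renderSignal <- function(conc, s0, te, firstImageRatio = 1, noiseSigma = 0,
                         seed = 1L) {
  if (s0 <= 0) stop("s0 must be > 0")
  s <- s0 * exp(-te * conc)
  s[1] <- s[1] * firstImageRatio
  if (noiseSigma > 0)
    s <- withSeed(seed, s + rnorm(length(s), sd = noiseSigma))
  pmax(s, 0)
}

#' Default phantom tissue classes
#'
#' Literature-composite perfusion values: GM 4 mL/100 g and 50 mL/100 g/min,
#' WM 2 and 25 (both give MTT = 4.8 s), CSF zero perfusion with a
#' first-image/baseline ratio of 3, and vessels with several-fold higher
#' CBV/CBF. When the phantom is built with `vesselCarriesAif = TRUE`
#' (the default) the vessel CBF truth is re-derived as `cbvTrue * 60 / tr`
#' (delta-like residue, MTT = TR).
#'
#' @return Named list of [TissueClassSpec-class] objects.
#' @export
defaultTissueClasses <- function() {
  list(
    GM = tissueClassSpec("GM", cbvTrue = 4, cbfTrue = 50, s0 = 800,
                         firstImageRatio = 1),
    WM = tissueClassSpec("WM", cbvTrue = 2, cbfTrue = 25, s0 = 700,
                         firstImageRatio = 1),
    CSF = tissueClassSpec("CSF", cbvTrue = 0, cbfTrue = 0, s0 = 1000,
                          firstImageRatio = 2),
    VESSEL = tissueClassSpec("VESSEL", cbvTrue = 20, cbfTrue = 1200, s0 = 900,
                             firstImageRatio = 1),
    BACKGROUND = tissueClassSpec("BACKGROUND", cbvTrue = 0, cbfTrue = 0,
                                 s0 = 1e-6, firstImageRatio = 1)
  )
}

#' Construct a PhantomConfig
#'
#' Defaults mirror a routine 1.5 T gradient-echo EPI perfusion protocol:
#' TR = 1 s, TE = 40 ms, 70 dynamics.
#'
#' @param dim grid shape (nx, ny, nslices).
#' @param nDynamics number of dynamics (>= 12).
#' @param tr,te timing, seconds.
#' @param aif gamma-variate parameters (`amplitude`, `t0`, `alpha`, `beta`).
#' @param noiseSigma Gaussian signal-noise SD (default 10; baseline signals
#'   are 700-1000, i.e. baseline SNR of order 10^2 as in EPI perfusion).
#' @param seed integer seed; the dataset is bit-reproducible given the seed.
#' @param classes named list of [TissueClassSpec-class].
#' @param impairedDelay extra bolus delay (s) on the right hemisphere
#'   (emulates carotid stenosis with delayed collateral supply).
#' @param impairedCbfFactor CBF multiplier (0, 1] on the right hemisphere.
#' @param vesselCarriesAif vessel voxels carry the scaled undispersed AIF.
#' @return A [PhantomConfig-class] object.
#' @export
phantomConfig <- function(dim = c(48L, 48L, 3L), nDynamics = 70L, tr = 1,
                          te = 0.040,
                          aif = list(amplitude = 1, t0 = 14, alpha = 3, beta = 1.5),
                          noiseSigma = 10, seed = 20130318L,
                          classes = defaultTissueClasses(),
                          impairedDelay = 0, impairedCbfFactor = 1,
                          vesselCarriesAif = TRUE) {
  new("PhantomConfig", dim = as.integer(dim), nDynamics = as.integer(nDynamics),
      tr = as.numeric(tr), te = as.numeric(te), aif = aif,
      noiseSigma = noiseSigma, seed = as.integer(seed), classes = classes,
      impairedDelay = impairedDelay, impairedCbfFactor = impairedCbfFactor,
      vesselCarriesAif = vesselCarriesAif)
}

## Deterministic two-hemisphere layout, mirror-symmetric about the in-plane
## x midline. Per slice: a rectangular brain region inside a background
## margin; a central CSF block (ventricle surrogate); four small vessel
## blocks; remaining parenchyma split WM (central, 40%) / GM (peripheral,
## 60%) by distance-to-centre rank, quota applied per hemisphere so the
## GM:WM voxel ratio matches the 60/40 reference mixture exactly.
phantomLayout <- function(nx, ny, nz) {
  lab <- array("BACKGROUND", c(nx, ny, nz))
  m <- max(2L, round(nx * 0.08))
  bx <- (m + 1L):(nx - m); by <- (max(2L, round(ny * 0.08)) + 1L):(ny - max(2L, round(ny * 0.08)))
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  half <- seq_len(ceiling(nx / 2))
  sliceLab <- matrix("BACKGROUND", nx, ny)
  sliceLab[bx, by] <- "PARENCHYMA"
  ## central CSF block
  wx <- max(2L, round(nx / 8)); wy <- max(1L, round(ny / 12))
  csfX <- (round(cx) - wx + 1L):(round(cx) + wx)
  csfY <- (round(cy) - wy + 1L):(round(cy) + wy)
  csfX <- intersect(csfX, bx); csfY <- intersect(csfY, by)
  sliceLab[csfX, csfY] <- "CSF"
  ## four symmetric 2x2 vessel blocks
  dx <- round(nx / 4); dy <- round(ny / 4)
  for (sx in c(-1, 1)) for (sy in c(-1, 1)) {
    vx <- round(cx + sx * dx) + 0:1; vy <- round(cy + sy * dy) + 0:1
    vx <- intersect(vx, bx); vy <- intersect(vy, by)
    sliceLab[vx, vy] <- "VESSEL"
  }
  ## WM quota per left hemisphere, mirrored to the right
  cand <- which(sliceLab == "PARENCHYMA", arr.ind = TRUE)
  cand <- cand[cand[, 1] <= max(half), , drop = FALSE]
  d2 <- (cand[, 1] - cx)^2 + (cand[, 2] - cy)^2
  ord <- order(d2, cand[, 1], cand[, 2])
  nw <- round(0.4 * nrow(cand))
  wmIdx <- cand[ord[seq_len(nw)], , drop = FALSE]
  sliceLab[cbind(wmIdx)] <- "WM"
  sliceLab[sliceLab == "PARENCHYMA"] <- "GM"
  ## mirror left onto right so hemispheres are exactly symmetric
  for (x in seq_len(floor(nx / 2)))
    sliceLab[nx + 1L - x, ] <- sliceLab[x, ]
  for (z in seq_len(nz)) lab[, , z] <- sliceLab
  lab
}

#' Build a synthetic DSC-MRI phantom
#'
#' Generates the layered two-hemisphere phantom described by `config`:
#' noise-free concentration curves per tissue class (vessel voxels carry the
#' amplitude-scaled undispersed AIF when `vesselCarriesAif`), an optionally
#' impaired right hemisphere with delayed/reduced perfusion, signal rendering
#' with the T1-saturation first-image factor and seeded Gaussian noise, plus
#' exact ground-truth maps (CBV, CBF, MTT, TTP) and class masks.
#'
#' @param config a [PhantomConfig-class].
#' @return A [PhantomDataset-class].
#' @examples
#' ph <- buildPhantom(phantomConfig(dim = c(24, 24, 1), noiseSigma = 0))
#' range(voxelData(ph@truthMaps$CBV)[ph@truthMasks$GM])  # 4, 4
#' @export
buildPhantom <- function(config) {
  validObject(config)
  nx <- config@dim[1]; ny <- config@dim[2]; nz <- config@dim[3]
  nT <- config@nDynamics; tr <- config@tr
  t <- (0:(nT - 1)) * tr
  aif <- do.call(gammaVariateAif, c(list(t = t), config@aif))
  lab <- phantomLayout(nx, ny, nz)
  missing <- setdiff(.TISSUE_LABELS, unique(as.vector(lab)))
  if (length(missing))
    stop("grid too small: layout cannot place class(es) ",
         paste(missing, collapse = ", "))

  classes <- config@classes
  if (config@vesselCarriesAif) {
    v <- classes$VESSEL
    classes$VESSEL <- tissueClassSpec("VESSEL", cbvTrue = v@cbvTrue,
                                      cbfTrue = v@cbvTrue * 60 / tr,
                                      delay = v@delay, s0 = v@s0,
                                      firstImageRatio = v@firstImageRatio)
  }

  rightHemi <- array(FALSE, c(nx, ny, nz))
  rightHemi[(floor(nx / 2) + 1L):nx, , ] <- TRUE
  impaired <- config@impairedDelay > 0 || config@impairedCbfFactor < 1

  conc <- array(0, c(nx, ny, nz, nT))
  truthCbv <- array(0, c(nx, ny, nz))
  truthCbf <- array(0, c(nx, ny, nz))

  classCurve <- function(spec, delay, cbfFactor) {
    if (spec@label == "VESSEL" && config@vesselCarriesAif) {
      kappa <- spec@cbvTrue / .KH_OVER_RHO
      kappa * shiftCurve(aif, as.integer(round((spec@delay + delay) / tr)))
    } else {
      synthesizeTissueCurve(aif, spec@cbvTrue, spec@cbfTrue * cbfFactor,
                            delay = spec@delay + delay, tr = tr)
    }
  }

  flat <- matrix(0, nrow = nx * ny * nz, ncol = nT)
  for (cl in setdiff(names(classes), "BACKGROUND")) {
    spec <- classes[[cl]]
    sides <- if (impaired) list(left = !rightHemi, right = rightHemi)
             else list(all = array(TRUE, c(nx, ny, nz)))
    for (side in names(sides)) {
      sel <- (lab == cl) & sides[[side]]
      if (!any(sel)) next
      dly <- if (side == "right") config@impairedDelay else 0
      fac <- if (side == "right") config@impairedCbfFactor else 1
      curve <- classCurve(spec, dly, fac)
      flat[as.vector(sel), ] <- matrix(curve, nrow = sum(sel), ncol = nT,
                                       byrow = TRUE)
      truthCbv[sel] <- spec@cbvTrue
      truthCbf[sel] <- spec@cbfTrue * fac
    }
  }
  conc <- array(flat, c(nx, ny, nz, nT))

  ## render signal: S = s0 exp(-TE C); first dynamic scaled; seeded noise
  s0map <- array(0, c(nx, ny, nz))
  ratioMap <- array(1, c(nx, ny, nz))
  for (cl in names(classes)) {
    sel <- lab == cl
    s0map[sel] <- classes[[cl]]@s0
    ratioMap[sel] <- classes[[cl]]@firstImageRatio
  }
  sig <- array(as.vector(s0map) * exp(-config@te * flat), c(nx, ny, nz, nT))
  sig[, , , 1] <- as.vector(sig[, , , 1, drop = FALSE]) * as.vector(ratioMap)
  if (config@noiseSigma > 0)
    sig <- withSeed(config@seed,
                    sig + array(rnorm(length(sig), sd = config@noiseSigma),
                                dim(sig)))
  sig <- pmax(sig, 0)

  series <- PerfusionSeries(sig, tr = tr, te = config@te)

  ## truth maps; TTP from the noise-free concentration with the same
  ## integration-window argmax convention the pipeline uses
  mtt <- ifelse(truthCbf > 0, truthCbv / truthCbf * 60, 0)
  win <- integrationWindow(nT)
  ttp <- apply(conc[, , , win, drop = FALSE], 1:3,
               function(v) (win[which.max(v)] - 1) * tr)
  ttp[truthCbv == 0] <- 0

  truthMasks <- lapply(setNames(nm = .TISSUE_LABELS), function(cl) lab == cl)
  truthMasks$BRAIN <- lab != "BACKGROUND"

  truthMaps <- list(
    CBV = ParametricMap(truthCbv, "CBV", "mL/100 g"),
    CBF = ParametricMap(truthCbf, "CBF", "mL/100 g/min"),
    MTT = ParametricMap(mtt, "MTT", "s"),
    TTP = ParametricMap(ttp, "TTP", "s"))

  new("PhantomDataset", series = series, truthMaps = truthMaps,
      truthMasks = truthMasks, aifTrue = aif, config = config)
}
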