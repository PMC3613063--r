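# Shared fixtures, generated in code. Small grids keep the suite fast while
# preserving the layout (two hemispheres, central CSF, four vessel blocks,
# exact 60/40 GM/WM parenchyma split).

quickConfig <- function(dim = c(32, 32, 1), noiseSigma = 0, seed = 42L, ...) {
  phantomConfig(dim = dim, noiseSigma = noiseSigma, seed = seed, ...)
}

# default gamma-variate AIF on the 70-dynamic grid (TR = 1 s)
defaultAifCurve <- function(n = 70, tr = 1) {
  gammaVariateAif((0:(n - 1)) * tr, amplitude = 1, t0 = 14, alpha = 3,
                  beta = 1.5)
}

# Wrap a single concentration curve as a 1-voxel ConcentrationSeries.
curveAsConc <- function(curve, tr = 1, te = 0.04) {
  new("ConcentrationSeries", conc = array(curve, c(1, 1, 1, length(curve))),
      baseline = array(1, c(1, 1, 1)), k1 = 1, tr = tr, te = te)
}

# The discrete (cell-averaged) flow-scaled residue the phantom convolves
# with; its maximum is the recoverable discrete rCBF.
discreteResidue <- function(cbv, cbf, n, tr = 1) {
  mtt <- cbv / cbf * 60
  (cbf / 60) * (mtt / tr) * (1 - exp(-tr / mtt)) * exp(-(0:(n - 1)) * tr / mtt)
}

# Cache one noise-free default pipeline run + phantom per test session.
.fixtures <- new.env(parent = emptyenv())

defaultPhantom <- function() {
  if (is.null(.fixtures$phantom))
    .fixtures$phantom <- buildPhantom(quickConfig())
  .fixtures$phantom
}

defaultRun <- function() {
  if (is.null(.fixtures$run))
    .fixtures$run <- runPipeline(quickConfig())
  .fixtures$run
}

delayedRun <- function(delay = 4) {
  key <- paste0("delayed", delay)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- runPipeline(quickConfig(impairedDelay = delay))
  .fixtures[[key]]
}

delayedPhantom <- function(delay = 4) {
  key <- paste0("delayedPh", delay)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- buildPhantom(quickConfig(impairedDelay = delay))
  .fixtures[[key]]
}
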