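## internal helpers

## Evaluate expr with a locally seeded RNG, restoring any prior state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## 1-based integration window (bolus-passage summation window), clamped.
integrationWindow <- function(nDyn, start = .INTEGRATION_START) {
  if (nDyn < start) stop("series too short for the integration window")
  seq.int(start, nDyn)
}

## Collapse a 4-D array to a (dynamics x voxels) matrix for masked voxels.
curvesMatrix <- function(arr4d, mask) {
  d <- dim(arr4d)
  flat <- matrix(arr4d, nrow = prod(d[1:3]), ncol = d[4])
  t(flat[as.vector(mask), , drop = FALSE])
}

## Jaccard overlap of two logical arrays.
jaccard <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}
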