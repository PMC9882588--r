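#' Empirical synchrotron SAXS error model
#'
#' Standard error of a simulated measurement at momentum transfer q and
#' (normalized) intensity I:
#' \deqn{\sigma(q) = s \sqrt{(I(q) + c) / (k\,q)},}
#' with k = 5e6 and c = 0.05 Angstrom chosen to imitate the noise of typical
#' synchrotron SAXS data. The scale s lets the user adjust the relative
#' noise level; doubling s doubles sigma everywhere. sigma diverges at
#' q = 0, so the noise grid must be strictly positive.
#'
#' @param q numeric grid in 1/Angstrom, strictly positive.
#' @param I numeric, calculated intensity (>= 0) on the same grid.
#' @param noiseScale scale factor s (default 1).
#' @return numeric, sigma(q) > 0.
#' @examples
#' errorModel(0.01, 1)  # sqrt(1.05 / 5e4) ~ 4.583e-3
#' @export
errorModel <- function(q, I, noiseScale = 1) {
  if (any(q <= 0))
    .stopf("error model undefined at q <= 0 (sigma diverges); drop q = 0")
  if (length(I) != length(q)) .stopf("q and I must have equal length")
  # multi-contrast Monte-Carlo curves can dip marginally below zero; sigma
  # stays defined as long as I + 0.05 > 0
  if (any(I <= -0.05))
    .stopf("error model undefined: intensity at or below -0.05")
  noiseScale * sqrt((I + 0.05) / (5e6 * q))
}

#' Simulate experimental SAXS data
#'
#' Draws \eqn{I_{sim}(q) \sim N(I(q), \sigma(q))} independently per grid
#' point, with sigma from [errorModel()]. Any q = 0 point is dropped from
#' the noise grid. Negative simulated intensities are kept, as in real
#' background-subtracted SAXS data. Reproducible under the seed; the
#' caller's RNG state is left untouched.
#'
#' @param curve a [ScatteringCurve-class].
#' @param noiseScale noise scale s (default 1).
#' @param seed integer seed for the Gaussian draws.
#' @return a [SimulatedData-class].
#' @examples
#' cloud <- buildModel(modelSpec(subunit("sphere", 50), seed = 1))
#' crv <- scatteringIntensity(pairDistribution(cloud),
#'                            seq(0.005, 0.3, length.out = 200))
#' sim <- simulateData(crv, seed = 42)
#' @export
simulateData <- function(curve, noiseScale = 1, seed = 1L) {
  keep <- curve@q > 0
  q <- curve@q[keep]
  I <- curve@I[keep]
  if (!length(q)) .stopf("no q > 0 points to simulate")
  sigma <- errorModel(q, I, noiseScale)
  Isim <- .withSeed(seed, stats::rnorm(length(q), mean = I, sd = sigma))
  new("SimulatedData", q = q, Isim = Isim, sigma = sigma,
      noiseScale = as.numeric(noiseScale), seed = as.integer(seed))
}

#' @rdname SimulatedData-class
#' @param object a [SimulatedData-class].
#' @export
setMethod("show", "SimulatedData", function(object) {
  cat(sprintf(
    "SimulatedData: %d points in q [%.4g, %.4g] 1/A, noise scale %g, seed %d\n",
    length(object@q), min(object@q), max(object@q), object@noiseScale,
    object@seed))
})
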