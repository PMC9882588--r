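#' @useDynLib saxsim, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# default bin count: sqrt-rule on the number of pairs, floored at 50 and
# capped at 1000 to keep the q-transform cheap
.defaultBins <- function(nPoints) {
  nPairs <- nPoints * (nPoints - 1) / 2
  max(50L, min(1000L, as.integer(ceiling(sqrt(nPairs)))))
}

# midpoint-rule nodes/weights for the Gaussian size-scale distribution:
# s on [1-3*sigma, 1+3*sigma], weight exp(-((s-1)/sigma)^2/2) * s^6
# (the s^6 factor is the squared relative volume v = s^3 entering the
# intensity). The constant node spacing cancels in normalization.
.polyNodes <- function(sigmaPoly, nNodes = 15L) {
  h <- 6 * sigmaPoly / nNodes
  s <- 1 - 3 * sigmaPoly + (seq_len(nNodes) - 0.5) * h
  w <- exp(-0.5 * ((s - 1) / sigmaPoly)^2) * s^6
  list(s = s, w = w / sum(w))
}

#' Contrast-weighted pair distance distribution
#'
#' Bins all j < k pair distances of a point cloud, each pair weighted by the
#' product \eqn{\Delta b_j \Delta b_k} of the two excess scattering lengths;
#' self-pairs are excluded. With \code{sigmaPoly > 0} a polydisperse
#' distribution is computed instead: a Gaussian distribution of a global
#' size-scale factor s (truncated to \eqn{1 \pm 3\sigma_{poly}}) scales all
#' pair distances, each scale weighted by the Gaussian density times
#' \eqn{s^6} (squared relative volume), accumulated on a common grid; Rg and
#' Dmax are then those of the polydisperse histogram.
#'
#' @param cloud a [PointCloud-class] with at least 2 points.
#' @param nBins number of bins; default
#'   \code{min(ceiling(sqrt(Npairs)), 1000)}, floored at 50.
#' @param sigmaPoly relative polydispersity in (0, 0.33), or 0 for a
#'   monodisperse sample.
#' @param nNodes number of size-scale quadrature nodes for the polydisperse
#'   path (midpoint rule; default 15).
#' @return a [PairDistribution-class].
#' @examples
#' cloud <- buildModel(modelSpec(subunit("sphere", 50), seed = 1))
#' pd <- pairDistribution(cloud)
#' radiusOfGyration(pd)  # close to sqrt(3/5) * 50
#' dMax(pd)              # close to 100
#' @export
pairDistribution <- function(cloud, nBins = NULL, sigmaPoly = 0,
                             nNodes = 15L) {
  n <- nrow(cloud@positions)
  if (n < 2L) .stopf("pair distribution needs at least two points")
  if (is.null(nBins)) nBins <- .defaultBins(n)
  nBins <- as.integer(nBins)
  if (sigmaPoly < 0 || sigmaPoly >= 0.33)
    .stopf("sigmaPoly must be in [0, 0.33) so that 1 - 3*sigmaPoly > 0")
  if (sigmaPoly == 0) {
    h <- pair_hist_cpp(cloud@positions, cloud@weights, nBins)
  } else {
    nd <- .polyNodes(sigmaPoly, as.integer(nNodes))
    h <- pair_hist_poly_cpp(cloud@positions, cloud@weights, nBins,
                            nd$s, nd$w)
  }
  r <- (seq_len(nBins) - 0.5) * h$dr
  p <- as.numeric(h$p)
  sp <- sum(p)
  rg <- if (sp > 0) sqrt(0.5 * sum(r^2 * p) / sp) else NA_real_
  new("PairDistribution", r = r, p = p, dr = h$dr, dmax = h$dmax,
      rg = rg, nBins = nBins, totalContrast = sum(cloud@weights))
}

#' Exported p(r) table
#'
#' The distribution in its exported form: a leading (0, 0) row is added and
#' p is scaled so its maximum absolute value is 1.
#'
#' @param pd a [PairDistribution-class].
#' @return data.frame with columns \code{r} (Angstrom) and \code{p}.
#' @export
prTable <- function(pd) {
  pk <- max(abs(pd@p))
  if (pk == 0) pk <- 1
  data.frame(r = c(0, pd@r), p = c(0, pd@p / pk))
}

#' @describeIn pairDistribution radius of gyration accessor.
#' @param x a [PairDistribution-class].
#' @export
setMethod("radiusOfGyration", "PairDistribution", function(x) x@rg)

#' @describeIn pairDistribution maximum distance accessor.
#' @export
setMethod("dMax", "PairDistribution", function(x) x@dmax)

#' @rdname PairDistribution-class
#' @param object a [PairDistribution-class].
#' @export
setMethod("show", "PairDistribution", function(object) {
  cat(sprintf(
    "PairDistribution: %d bins, dr = %.4g A, Dmax = %.4g A, Rg = %.4g A\n",
    object@nBins, object@dr, object@dmax, object@rg))
})

#' Scattering intensity from a binned pair distribution
#'
#' The Debye double sum reduced to a single sum over histogram bins:
#' \deqn{P(q) = \sum_i p_i \,\mathrm{sinc}(q r_i) / \sum_i p_i,}
#' so sin(x)/x is evaluated once per (q, bin), never per pair. The
#' normalization by the forward scattering makes P(0) = 1 and removes the
#' number density and effective scatterer volumes from the result.
#'
#' @param pd a [PairDistribution-class] (mono- or polydisperse).
#' @param q numeric grid in 1/Angstrom, non-negative.
#' @return a [ScatteringCurve-class] with \code{Seff = 1} and \code{I = P}.
#' @examples
#' cloud <- buildModel(modelSpec(subunit("sphere", 50), seed = 1))
#' crv <- scatteringIntensity(pairDistribution(cloud), seq(0, 0.2, len = 100))
#' intensity(crv)[1]  # 1 at q = 0
#' @export
scatteringIntensity <- function(pd, q) {
  q <- as.numeric(q)
  if (any(q < 0) || any(!is.finite(q)))
    .stopf("invalid q grid: values must be finite and non-negative")
  if (abs(pd@totalContrast) < 1e-12 * max(abs(pd@p), 1e-300))
    .stopf(paste("zero forward scattering: the net excess scattering length",
                 "of the model is zero, so P(q) is undefined"))
  sp <- sum(pd@p)
  if (sp == 0) .stopf("zero forward scattering: sum of p(r) is zero")
  P <- as.numeric(.sinc(outer(q, pd@r)) %*% pd@p) / sp
  new("ScatteringCurve", q = q, P = P, Seff = rep(1, length(q)), I = P)
}

#' @rdname ScatteringCurve-class
#' @param x a [ScatteringCurve-class].
#' @export
qGrid <- function(x) x@q

#' @rdname ScatteringCurve-class
#' @export
formFactor <- function(x) x@P

#' @rdname ScatteringCurve-class
#' @export
effectiveSF <- function(x) x@Seff

#' @rdname ScatteringCurve-class
#' @export
intensity <- function(x) x@I

#' @rdname ScatteringCurve-class
#' @param object a [ScatteringCurve-class].
#' @export
setMethod("show", "ScatteringCurve", function(object) {
  cat(sprintf("ScatteringCurve: %d q points in [%.4g, %.4g] 1/A%s\n",
              length(object@q), min(object@q), max(object@q),
              if (any(object@Seff != 1)) ", structure factor applied" else ""))
})

#' Direct Debye sum (reference implementation)
#'
#' Evaluates the Debye double sum pairwise without binning:
#' \deqn{I(q) \propto \sum_{j \ne k} \Delta b_j \Delta b_k
#'   \,\mathrm{sinc}(q r_{jk}),}
#' normalized to 1 at q = 0. Exact but O(N^2) per q point; intended for
#' small clouds and for validating the histogram transform.
#'
#' @param cloud a [PointCloud-class].
#' @param q numeric grid in 1/Angstrom.
#' @return numeric, normalized P(q).
#' @export
debyeIntensity <- function(cloud, q) {
  pos <- cloud@positions
  w <- cloud@weights
  d <- as.numeric(stats::dist(pos))
  wp <- tcrossprod(w)[lower.tri(matrix(0, nrow(pos), nrow(pos)))]
  sp <- sum(wp)
  if (sp == 0) .stopf("zero forward scattering in Debye sum")
  vapply(q, function(qi) sum(wp * .sinc(qi * d)) / sp, numeric(1))
}
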