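#' @import methods
NULL

#' Subunit: one geometric body of a bead model
#'
#' A \code{Subunit} describes a single geometric body: its kind, its
#' dimensions in Angstrom, its excess scattering length density (contrast,
#' relative units, may be negative) and a center-of-mass displacement.
#' Supported kinds and the meaning of \code{dims}:
#' \describe{
#'   \item{sphere}{radius R}
#'   \item{ellipsoid_triaxial}{semi-axes a, b, c}
#'   \item{cylinder, disc}{radius R, length L (axis along z)}
#'   \item{cube}{side a}
#'   \item{cuboid}{sides a, b, c}
#'   \item{sphere_hollow}{outer radius R, inner radius r}
#'   \item{cube_hollow}{outer side a, inner side b}
#'   \item{ring_cylindrical, ring_discoidal}{outer radius R, inner radius r,
#'     length L}
#' }
#'
#' @slot kind character(1), one of the kinds above.
#' @slot dims numeric, ordered positive lengths in Angstrom.
#' @slot contrast numeric(1), excess scattering length density.
#' @slot com numeric(3), center-of-mass displacement in Angstrom.
#'
#' @seealso [subunit()], [volume()], [isInside()], [samplePoints()]
#' @export
setClass("Subunit",
  representation(kind = "character", dims = "numeric",
                 contrast = "numeric", com = "numeric"))

setValidity("Subunit", function(object) {
  msg <- character()
  if (length(object@kind) != 1L || !object@kind %in% names(.kindRegistry))
    msg <- c(msg, paste0("unsupported subunit kind: ",
                         paste(object@kind, collapse = ", ")))
  else {
    reg <- .kindRegistry[[object@kind]]
    if (length(object@dims) != length(reg$dims))
      msg <- c(msg, sprintf("kind '%s' needs %d dims (%s)", object@kind,
                            length(reg$dims), paste(reg$dims, collapse = ", ")))
    else {
      if (any(!is.finite(object@dims)) || any(object@dims <= 0))
        msg <- c(msg, "all dims must be strictly positive and finite")
      else {
        if (!is.null(reg$inner) &&
            object@dims[reg$inner] >= object@dims[reg$outer])
          msg <- c(msg, sprintf("kind '%s': inner dimension must be < outer",
                                object@kind))
        if (length(msg) == 0L && reg$volume(object@dims) < 1e-6)
          msg <- c(msg, "degenerate subunit: volume below 1e-6 Angstrom^3")
      }
    }
  }
  if (length(object@contrast) != 1L || !is.finite(object@contrast))
    msg <- c(msg, "contrast must be a single finite number")
  if (length(object@com) != 3L || any(!is.finite(object@com)))
    msg <- c(msg, "com must be a finite 3-vector")
  if (length(msg)) msg else TRUE
})

#' ModelSpec: a particle model made of subunits
#'
#' Defines a particle as an ordered list of [Subunit-class] bodies, how many
#' points to sample in total, whether to remove points in overlap regions
#' (later-listed subunits take precedence) and the seed used when the model
#' is realized as a point cloud.
#'
#' @slot subunits list of [Subunit-class].
#' @slot excludeOverlap logical(1); if TRUE, points of earlier subunits that
#'   fall inside later subunits are removed. If FALSE all points are kept, so
#'   the effective contrast in an overlap region is the sum of the
#'   overlapping subunits' contrasts.
#' @slot nPoints integer(1), total points allocated across subunits
#'   proportional to their volumes (default 5000).
#' @slot seed integer(1), RNG seed for [buildModel()].
#'
#' @seealso [modelSpec()], [buildModel()]
#' @export
setClass("ModelSpec",
  representation(subunits = "list", excludeOverlap = "logical",
                 nPoints = "integer", seed = "integer"))

setValidity("ModelSpec", function(object) {
  msg <- character()
  if (length(object@subunits) < 1L)
    msg <- c(msg, "need at least one subunit")
  ok <- vapply(object@subunits, function(s) is(s, "Subunit"), logical(1))
  if (!all(ok)) msg <- c(msg, "subunits must all be Subunit objects")
  if (length(object@nPoints) != 1L || is.na(object@nPoints) ||
      object@nPoints < 100L)
    msg <- c(msg, "nPoints must be a single integer >= 100")
  if (length(object@excludeOverlap) != 1L || is.na(object@excludeOverlap))
    msg <- c(msg, "excludeOverlap must be TRUE or FALSE")
  if (length(object@seed) != 1L)
    msg <- c(msg, "seed must be a single integer")
  if (length(msg)) msg else TRUE
})

#' PointCloud: sampled scatterer positions
#'
#' The Monte-Carlo realization of a [ModelSpec-class]: uniform-density point
#' scatterers with per-point excess scattering lengths
#' \eqn{\Delta b = \Delta\rho \cdot V_{point}}, where the effective per-point
#' volume \eqn{V_{point}} is constant across the whole model.
#'
#' @slot positions N x 3 numeric matrix of coordinates in Angstrom.
#' @slot weights numeric(N), per-point excess scattering length.
#' @slot subunitIndex integer(N), which subunit each point came from.
#' @slot pointDensity numeric(1), points per cubic Angstrom.
#'
#' @seealso [buildModel()], [pairDistribution()], [writePDB()]
#' @export
setClass("PointCloud",
  representation(positions = "matrix", weights = "numeric",
                 subunitIndex = "integer", pointDensity = "numeric"))

setValidity("PointCloud", function(object) {
  msg <- character()
  if (ncol(object@positions) != 3L)
    msg <- c(msg, "positions must have 3 columns")
  n <- nrow(object@positions)
  if (length(object@weights) != n || length(object@subunitIndex) != n)
    msg <- c(msg, "weights and subunitIndex must match number of positions")
  if (length(msg)) msg else TRUE
})

#' PairDistribution: contrast-weighted pair-distance histogram
#'
#' Binned distribution of intra-particle pair distances, each pair weighted
#' by the product of the two scatterers' excess scattering lengths; the
#' discrete estimate of p(r). Self-pairs are excluded. Bin centers are
#' \eqn{r_i = (i - 1/2)\,dr}.
#'
#' @slot r numeric, bin centers in Angstrom.
#' @slot p numeric, weighted pair counts per bin (unnormalized; use
#'   [prTable()] for the exported, max-normalized form with the leading
#'   (0, 0) row).
#' @slot dr numeric(1), bin width in Angstrom.
#' @slot dmax numeric(1), largest pair distance in Angstrom.
#' @slot rg numeric(1), radius of gyration in Angstrom, from
#'   \eqn{R_g^2 = \frac{1}{2}\sum r_i^2 p_i / \sum p_i}.
#' @slot nBins integer(1), number of bins.
#' @slot totalContrast numeric(1), sum of point weights \eqn{\sum \Delta b}
#'   of the source cloud (needed to detect zero forward scattering).
#'
#' @seealso [pairDistribution()], [scatteringIntensity()], [prTable()]
#' @export
setClass("PairDistribution",
  representation(r = "numeric", p = "numeric", dr = "numeric",
                 dmax = "numeric", rg = "numeric", nBins = "integer",
                 totalContrast = "numeric"))

setValidity("PairDistribution", function(object) {
  msg <- character()
  if (length(object@r) != length(object@p))
    msg <- c(msg, "r and p must have equal length")
  if (length(object@r) && abs(object@r[1] - object@dr / 2) > 1e-9 * object@dr)
    msg <- c(msg, "bin centers must start at dr/2")
  if (length(msg)) msg else TRUE
})

#' ScatteringCurve: normalized scattering intensity on a q grid
#'
#' Holds the normalized form factor \eqn{P(q)} (with \eqn{P(0) = 1}), the
#' effective structure factor \eqn{S_{eff}(q)} (1 everywhere when no
#' structure factor is applied) and the total intensity I(q), which carries
#' any roughness smearing.
#'
#' @slot q numeric, momentum transfer grid in 1/Angstrom.
#' @slot P numeric, normalized form factor.
#' @slot Seff numeric, effective structure factor.
#' @slot I numeric, total intensity.
#'
#' @seealso [scatteringIntensity()], [applyStructureFactor()],
#'   [applyRoughness()], [simulateData()]
#' @export
setClass("ScatteringCurve",
  representation(q = "numeric", P = "numeric", Seff = "numeric",
                 I = "numeric"))

setValidity("ScatteringCurve", function(object) {
  n <- length(object@q)
  if (length(object@P) != n || length(object@Seff) != n ||
      length(object@I) != n)
    return("q, P, Seff and I must have equal length")
  if (any(object@q < 0)) return("q must be non-negative")
  TRUE
})

#' SimulatedData: noisy simulated SAXS data
#'
#' A calculated intensity turned into simulated experimental data:
#' \eqn{I_{sim}(q) \sim N(I(q), \sigma(q))} with the empirical synchrotron
#' error model of [errorModel()]. Negative simulated intensities are kept,
#' as in real background-subtracted SAXS data.
#'
#' @slot q numeric, grid in 1/Angstrom (strictly positive).
#' @slot Isim numeric, simulated noisy intensity.
#' @slot sigma numeric, standard error estimate.
#' @slot noiseScale numeric(1), the noise scale s used.
#' @slot seed integer(1), seed used for the Gaussian draws.
#'
#' @seealso [simulateData()], [writeSimulatedData()], [fitModel()]
#' @export
setClass("SimulatedData",
  representation(q = "numeric", Isim = "numeric", sigma = "numeric",
                 noiseScale = "numeric", seed = "integer"))

setValidity("SimulatedData", function(object) {
  n <- length(object@q)
  if (length(object@Isim) != n || length(object@sigma) != n)
    return("q, Isim and sigma must have equal length")
  if (any(object@q <= 0)) return("q must be strictly positive")
  if (any(object@sigma <= 0)) return("sigma must be strictly positive")
  TRUE
})

#' StructureFactorParams: interparticle interaction settings
#'
#' @slot kind character(1): "none", "hard_sphere" (Percus-Yevick repulsion)
#'   or "fractal_aggregate" (2-D mass-fractal aggregation).
#' @slot rHS numeric(1), hard-sphere radius in Angstrom.
#' @slot eta numeric(1), hard-sphere volume fraction in (0, 0.5].
#' @slot fracR0 numeric(1), aggregate building-block radius in Angstrom.
#' @slot fracN numeric(1), aggregation number (>= 2).
#' @slot fracFraction numeric(1), fraction of particles in aggregates [0, 1].
#'
#' @seealso [structureFactorParams()], [hardSphereSF()], [fractalSF()]
#' @export
setClass("StructureFactorParams",
  representation(kind = "character", rHS = "numeric", eta = "numeric",
                 fracR0 = "numeric", fracN = "numeric",
                 fracFraction = "numeric"))

setValidity("StructureFactorParams", function(object) {
  msg <- character()
  if (!object@kind %in% c("none", "hard_sphere", "fractal_aggregate"))
    msg <- c(msg, "kind must be none, hard_sphere or fractal_aggregate")
  if (object@kind == "hard_sphere") {
    if (!(object@eta > 0 && object@eta <= 0.5))
      msg <- c(msg, "eta must be in (0, 0.5]")
    if (!(object@rHS > 0)) msg <- c(msg, "rHS must be positive")
  }
  if (object@kind == "fractal_aggregate") {
    if (!(object@fracN >= 2)) msg <- c(msg, "fracN must be >= 2")
    if (!(object@fracR0 > 0)) msg <- c(msg, "fracR0 must be positive")
    if (object@fracFraction < 0 || object@fracFraction > 1)
      msg <- c(msg, "fracFraction must be in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' AnalyticModel: closed-form scattering model for fitting
#'
#' @slot kind character(1): "sphere", "cylinder", "ellipsoid_rev" or
#'   "core_shell_cylinder".
#' @slot params named numeric: model parameters (lengths in Angstrom,
#'   contrasts in relative units) plus "scale".
#' @slot freeMask named logical: which parameters are refined by
#'   [fitModel()].
#'
#' @seealso [analyticModel()], [evaluateModel()], [fitModel()]
#' @export
setClass("AnalyticModel",
  representation(kind = "character", params = "numeric",
                 freeMask = "logical"))

setValidity("AnalyticModel", function(object) {
  msg <- character()
  if (!object@kind %in% names(.analyticRegistry))
    msg <- c(msg, paste0("unknown analytic model kind: ", object@kind))
  else {
    need <- c(.analyticRegistry[[object@kind]]$params, "scale")
    if (!setequal(names(object@params), need))
      msg <- c(msg, paste0("params must be exactly: ",
                           paste(need, collapse = ", ")))
    if (!setequal(names(object@freeMask), need))
      msg <- c(msg, "freeMask must name the same parameters as params")
  }
  if (length(msg)) msg else TRUE
})

#' FitResult: refined parameters from a least-squares fit
#'
#' @slot parHat named numeric, refined parameter values.
#' @slot parSD named numeric, standard deviations from the covariance of the
#'   least-squares solution at the optimum (NA for fixed parameters).
#' @slot chi2Red numeric(1), reduced chi-square.
#' @slot model the fitted [AnalyticModel-class] with refined parameters.
#' @slot fitted numeric, fitted model intensity on the data grid.
#' @slot converged logical(1).
#'
#' @seealso [fitModel()]
#' @export
setClass("FitResult",
  representation(parHat = "numeric", parSD = "numeric", chi2Red = "numeric",
                 model = "AnalyticModel", fitted = "numeric",
                 converged = "logical"))

#' RunConfig: a full simulation run
#'
#' Bundles one or two particle models with the scattering options of a run:
#' q grid, polydispersity, roughness, structure factor, noise scale, seed and
#' output directory.
#'
#' @slot models list of one or two [ModelSpec-class].
#' @slot qMin,qMax numeric(1), q-grid limits in 1/Angstrom
#'   (defaults 0.001 and 0.5).
#' @slot nQ integer(1), number of (linearly spaced) grid points (default 400).
#' @slot sigmaPoly numeric(1), relative polydispersity (0 = monodisperse).
#' @slot sigmaR numeric(1), interface roughness in Angstrom.
#' @slot sf [StructureFactorParams-class].
#' @slot noiseScale numeric(1), noise scale s.
#' @slot seed integer(1).
#' @slot outDir character(1), output directory.
#' @slot offset numeric(1), plot offset applied to model 2 (default 100).
#'
#' @seealso [runConfig()], [runSimulation()]
#' @export
setClass("RunConfig",
  representation(models = "list", qMin = "numeric", qMax = "numeric",
                 nQ = "integer", sigmaPoly = "numeric", sigmaR = "numeric",
                 sf = "StructureFactorParams", noiseScale = "numeric",
                 seed = "integer", outDir = "character", offset = "numeric"))

setValidity("RunConfig", function(object) {
  msg <- character()
  nm <- length(object@models)
  if (nm < 1L || nm > 2L) msg <- c(msg, "need one or two models")
  if (!(object@qMin > 0 && object@qMin < object@qMax))
    msg <- c(msg, "need 0 < qMin < qMax")
  if (object@nQ < 2L) msg <- c(msg, "nQ must be >= 2")
  if (object@sigmaPoly < 0 || object@sigmaPoly >= 0.33)
    msg <- c(msg, "sigmaPoly must be in [0, 0.33)")
  if (object@sigmaR < 0) msg <- c(msg, "sigmaR must be >= 0")
  if (length(msg)) msg else TRUE
})
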