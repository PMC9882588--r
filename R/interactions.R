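#' Structure factor parameter container
#'
#' @param kind "none", "hard_sphere" or "fractal_aggregate".
#' @param rHS hard-sphere radius in Angstrom.
#' @param eta hard-sphere volume fraction in (0, 0.5].
#' @param fracR0 aggregate building-block radius in Angstrom.
#' @param fracN aggregation number (>= 2).
#' @param fracFraction fraction of particles in aggregates, in [0, 1].
#' @return a [StructureFactorParams-class].
#' @export
structureFactorParams <- function(kind = "none", rHS = 50, eta = 0.1,
                                  fracR0 = 50, fracN = 50,
                                  fracFraction = 1) {
  new("StructureFactorParams", kind = kind, rHS = as.numeric(rHS),
      eta = as.numeric(eta), fracR0 = as.numeric(fracR0),
      fracN = as.numeric(fracN), fracFraction = as.numeric(fracFraction))
}

#' Percus-Yevick hard-sphere structure factor
#'
#' Closed-form structure factor of hard spheres of radius \code{rHS} at
#' volume fraction \code{eta} in the Percus-Yevick approximation:
#' \deqn{S(q) = 1 / (1 + 24\,\eta\, G(A)/A), \quad A = 2 q R_{HS},}
#' with the standard auxiliary function G built from the coefficients
#' \eqn{\alpha = (1+2\eta)^2/(1-\eta)^4},
#' \eqn{\beta = -6\eta(1+\eta/2)^2/(1-\eta)^4} and
#' \eqn{\gamma = \eta\alpha/2}. For small A the trigonometric terms suffer
#' catastrophic cancellation, so their Taylor series are used; at q = 0 this
#' reproduces the compressibility limit \eqn{S(0) = (1-\eta)^4/(1+2\eta)^2}
#' exactly.
#'
#' @param q numeric grid in 1/Angstrom.
#' @param rHS hard-sphere radius, Angstrom (> 0).
#' @param eta volume fraction, in (0, 0.5].
#' @return numeric, S(q) > 0, tending to 1 at large q.
#' @examples
#' hardSphereSF(0, 70, 0.2)  # (1 - 0.2)^4 / (1 + 0.4)^2
#' @export
hardSphereSF <- function(q, rHS, eta) {
  if (!(eta > 0 && eta <= 0.5))
    .stopf("eta must be in (0, 0.5], got %g", eta)
  if (!(rHS > 0)) .stopf("rHS must be positive")
  A <- 2 * q * rHS
  al <- (1 + 2 * eta)^2 / (1 - eta)^4
  be <- -6 * eta * (1 + eta / 2)^2 / (1 - eta)^4
  ga <- eta * al / 2
  # G(A)/A split into three terms c1, c2, c3; series below A = 0.1
  c1 <- c2 <- c3 <- numeric(length(A))
  small <- A < 0.1
  if (any(small)) {
    As <- A[small]
    A2 <- As^2
    c1[small] <- 1 / 3 - A2 / 30 + A2^2 / 840 - A2^3 / 45360
    c2[small] <- 1 / 4 - A2 / 36 + A2^2 / 960 - A2^3 / 50400
    c3[small] <- 1 / 6 - A2 / 48 + A2^2 / 1200 - A2^3 / 60480
  }
  if (any(!small)) {
    Ab <- A[!small]
    sA <- sin(Ab); cA <- cos(Ab)
    c1[!small] <- (sA - Ab * cA) / Ab^3
    c2[!small] <- (2 * Ab * sA + (2 - Ab^2) * cA - 2) / Ab^4
    c3[!small] <- (-Ab^4 * cA +
                     4 * ((3 * Ab^2 - 6) * cA + (Ab^3 - 6 * Ab) * sA + 6)) /
                  Ab^6
  }
  1 / (1 + 24 * eta * (al * c1 + be * c2 + ga * c3))
}

#' 2-D mass-fractal aggregate structure factor
#'
#' Mass-fractal structure factor with the fractal dimension fixed at D = 2,
#' describing flat (sheet-like) aggregates of spherical building blocks of
#' radius \code{r0}. At D = 2 the Teixeira-type closed form collapses to
#' \deqn{S_{agg}(q) = 1 + \frac{2}{(q r_0)^2}\,
#'   \frac{(q\xi)^2}{1 + (q\xi)^2},}
#' with the cutoff length \eqn{\xi = r_0 \sqrt{(N_{agg}-1)/2}} chosen so the
#' forward limit is exactly the aggregation number,
#' \eqn{S_{agg}(0) = N_{agg}}. A mixed sample is modelled by blending:
#' \code{S(q) = 1 + fracFraction * (S_agg(q) - 1)}.
#'
#' @param q numeric grid in 1/Angstrom.
#' @param fracR0 building-block radius, Angstrom (> 0).
#' @param fracN aggregation number (>= 2).
#' @param fracFraction fraction of particles in aggregates, in [0, 1].
#' @return numeric, S(q) >= 1, tending to 1 at large q.
#' @examples
#' fractalSF(0, 50, 80, 1)  # 80
#' @export
fractalSF <- function(q, fracR0, fracN, fracFraction = 1) {
  if (!(fracR0 > 0)) .stopf("fracR0 must be positive")
  if (!(fracN >= 2)) .stopf("fracN must be >= 2")
  if (fracFraction < 0 || fracFraction > 1)
    .stopf("fracFraction must be in [0, 1]")
  xi <- fracR0 * sqrt((fracN - 1) / 2)
  sagg <- ifelse(q == 0, fracN,
                 1 + 2 / (q * fracR0)^2 * (q * xi)^2 / (1 + (q * xi)^2))
  1 + fracFraction * (sagg - 1)
}

# S(q) on a grid from a StructureFactorParams object; 1 when kind == "none"
.evalSF <- function(sf, q) {
  switch(sf@kind,
         none = rep(1, length(q)),
         hard_sphere = hardSphereSF(q, sf@rHS, sf@eta),
         fractal_aggregate = fractalSF(q, sf@fracR0, sf@fracN,
                                       sf@fracFraction))
}

#' Decoupling factor beta(q) for anisotropic particles
#'
#' The decoupling approximation corrects a structure factor for particle
#' anisotropy via \eqn{\beta(q) = \langle A(q)\rangle^2 / P(q)}, where the
#' spherically averaged amplitude about the contrast-weighted center of mass
#' is \deqn{\langle A(q)\rangle = \sum_j \Delta b_j\,
#'   \mathrm{sinc}(q\,|r_j - r_{com}|) \big/ \sum_j \Delta b_j} and P(q) is
#' the form factor of the same cloud. This amplitude is exact for
#' centrosymmetric bodies, for which \eqn{\beta = 1} up to the first
#' form-factor zero in the spherical case. beta is clipped to [0, 1].
#'
#' @param cloud a [PointCloud-class] with non-zero net contrast.
#' @param q numeric grid in 1/Angstrom.
#' @param pd optional precomputed [PairDistribution-class] of the same cloud
#'   (monodisperse); computed if missing.
#' @return numeric, beta(q) in [0, 1] with beta(0) = 1.
#' @export
decouplingBeta <- function(cloud, q, pd = NULL) {
  w <- cloud@weights
  sw <- sum(w)
  if (abs(sw) < 1e-12 * sum(abs(w)))
    .stopf("undefined amplitude: net excess scattering length is zero")
  com <- colSums(cloud@positions * w) / sw
  d <- sqrt(rowSums(sweep(cloud@positions, 2L, com)^2))
  Aq <- as.numeric(.sinc(outer(q, d)) %*% w) / sw
  if (is.null(pd)) pd <- pairDistribution(cloud)
  P <- formFactor(scatteringIntensity(pd, q))
  beta <- Aq^2 / P
  beta[q == 0] <- 1
  pmin(pmax(beta, 0), 1)
}

#' Apply a structure factor to a scattering curve
#'
#' Combines a raw structure factor with the decoupling factor as
#' \eqn{S_{eff}(q) = 1 + \beta(q)(S(q) - 1)} and sets
#' \eqn{I(q) = P(q) S_{eff}(q)}. The pair distribution is untouched by
#' design: real-space output always describes the non-interacting particle,
#' while I(q) describes the interacting sample.
#'
#' @param curve a [ScatteringCurve-class].
#' @param S numeric, raw structure factor on the same grid.
#' @param beta numeric, decoupling factor on the same grid (default 1,
#'   i.e. the monodisperse-sphere limit).
#' @return a new [ScatteringCurve-class] with updated \code{Seff} and
#'   \code{I}.
#' @export
applyStructureFactor <- function(curve, S, beta = 1) {
  n <- length(curve@q)
  if (length(S) != n)
    .stopf("grid mismatch: S has %d values for %d q points", length(S), n)
  if (length(beta) == 1L) beta <- rep(beta, n)
  if (length(beta) != n)
    .stopf("grid mismatch: beta has %d values for %d q points",
           length(beta), n)
  Seff <- 1 + beta * (S - 1)
  new("ScatteringCurve", q = curve@q, P = curve@P, Seff = Seff,
      I = curve@P * Seff)
}

#' Apply interface roughness smearing
#'
#' Multiplies the intensity by \eqn{\exp(-\frac{1}{2}(q\sigma_R)^2)},
#' effectively smearing sharp inter-subunit interfaces. Only I(q) is
#' affected; P(q), S_eff(q) and the pair distribution are not.
#'
#' @param curve a [ScatteringCurve-class].
#' @param sigmaR smearing length in Angstrom (>= 0).
#' @return a new [ScatteringCurve-class].
#' @export
applyRoughness <- function(curve, sigmaR) {
  if (length(sigmaR) != 1L || !is.finite(sigmaR) || sigmaR < 0)
    .stopf("sigmaR must be a single non-negative number")
  new("ScatteringCurve", q = curve@q, P = curve@P, Seff = curve@Seff,
      I = curve@I * exp(-0.5 * (curve@q * sigmaR)^2))
}
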