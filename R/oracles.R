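# normalized sphere amplitude 3(sin x - x cos x)/x^3, series below x = 1e-2
.sphereAmp <- function(x) {
  out <- numeric(length(x))
  small <- abs(x) < 1e-2
  xs <- x[small]
  out[small] <- 1 - xs^2 / 10 + xs^4 / 280
  xb <- x[!small]
  out[!small] <- 3 * (sin(xb) - xb * cos(xb)) / xb^3
  out
}

# normalized cross-section amplitude 2 J1(x)/x, series below x = 1e-4
.discAmp <- function(x) {
  out <- numeric(length(x))
  small <- abs(x) < 1e-4
  xs <- x[small]
  out[small] <- 1 - xs^2 / 8
  xb <- x[!small]
  out[!small] <- 2 * besselJ(xb, 1) / xb
  out
}

# orientation-average quadrature: Gauss-Legendre nodes/weights on
# u = cos(alpha) in [0, 1]; the solid-angle average is a plain integral in u
.glCache <- new.env(parent = emptyenv())
.glNodes <- function(n) {
  key <- as.character(n)
  if (is.null(.glCache[[key]]))
    .glCache[[key]] <- pracma::gaussLegendre(n, 0, 1)
  .glCache[[key]]
}

# normalized cylinder amplitude on the (q, u) mesh: matrix length(q) x n
.cylAmpMesh <- function(q, u, R, L) {
  s <- sqrt(pmax(0, 1 - u^2))
  xr <- q %o% (R * s)
  xl <- q %o% (L * u / 2)
  matrix(.discAmp(xr), nrow = length(q)) * .sinc(xl)
}

#' Analytic sphere form factor
#'
#' \eqn{P(q) = [3(\sin x - x\cos x)/x^3]^2} with \eqn{x = qR};
#' \eqn{P(0) = 1}. The first zero sits at \eqn{x \approx 4.4934} (smallest
#' positive root of tan x = x).
#'
#' @param q numeric grid in 1/Angstrom.
#' @param R sphere radius, Angstrom (> 0).
#' @return numeric P(q) in [0, 1].
#' @examples
#' sphereFF(0, 50)  # 1
#' @export
sphereFF <- function(q, R) {
  if (!(R > 0)) .stopf("R must be positive")
  .sphereAmp(q * R)^2
}

#' Analytic cylinder form factor
#'
#' Orientational average of
#' \eqn{[2 J_1(qR\sin\alpha)/(qR\sin\alpha)\cdot
#' \mathrm{sinc}(qL\cos\alpha/2)]^2} over the angle \eqn{\alpha} between the
#' cylinder axis and q, by fixed-order Gauss-Legendre quadrature on
#' \eqn{\cos\alpha \in [0,1]}. The Guinier radius is
#' \eqn{R_g^2 = R^2/2 + L^2/12}.
#'
#' @param q numeric grid in 1/Angstrom.
#' @param R radius, Angstrom (> 0).
#' @param L length, Angstrom (> 0).
#' @param nQuad quadrature order (default 128).
#' @return numeric P(q) in [0, 1].
#' @export
cylinderFF <- function(q, R, L, nQuad = 128L) {
  if (!(R > 0 && L > 0)) .stopf("R and L must be positive")
  gl <- .glNodes(nQuad)
  amp <- .cylAmpMesh(q, gl$x, R, L)
  as.numeric(amp^2 %*% gl$w)
}

#' Analytic ellipsoid-of-revolution form factor
#'
#' Orientational average of the sphere amplitude with the
#' direction-dependent effective radius
#' \eqn{r(u) = \sqrt{a^2(1-u^2) + c^2 u^2}}, where a is the equatorial and
#' c the polar semi-axis.
#'
#' @param q numeric grid in 1/Angstrom.
#' @param a equatorial semi-axis, Angstrom (> 0).
#' @param c polar semi-axis, Angstrom (> 0).
#' @param nQuad quadrature order (default 128).
#' @return numeric P(q) in [0, 1].
#' @export
ellipsoidRevFF <- function(q, a, c, nQuad = 128L) {
  if (!(a > 0 && c > 0)) .stopf("semi-axes must be positive")
  gl <- .glNodes(nQuad)
  re <- sqrt(a^2 * (1 - gl$x^2) + c^2 * gl$x^2)
  amp <- matrix(.sphereAmp(q %o% re), nrow = length(q))
  as.numeric(amp^2 %*% gl$w)
}

#' Analytic core-shell cylinder form factor
#'
#' Orientationally averaged intensity of a cylinder of radius
#' \code{rCore} and length \code{lCore} at contrast \code{rhoCore}, wrapped
#' in a shell of thickness \code{tShell} at contrast \code{rhoShell} (outer
#' body: radius rCore + tShell, length lCore + 2 tShell). The oriented
#' amplitude is
#' \deqn{F = (\rho_c - \rho_s) V_c \psi_c + \rho_s V_o \psi_o,}
#' with \eqn{\psi} the normalized cylinder amplitudes; P is normalized to
#' P(0) = 1 and the squared forward amplitude \eqn{F(0)^2} is recorded in
#' the \code{"forward"} attribute.
#'
#' @param q numeric grid in 1/Angstrom.
#' @param rCore core radius, Angstrom (> 0).
#' @param lCore core length, Angstrom (> 0).
#' @param tShell shell thickness, Angstrom (> 0).
#' @param rhoCore,rhoShell core and shell contrasts (relative units).
#' @param nQuad quadrature order (default 128).
#' @return numeric P(q) with attribute \code{forward}.
#' @examples
#' # homogeneous limit: equal contrasts reduce to the outer cylinder
#' q <- seq(0, 0.3, length.out = 50)
#' all.equal(as.numeric(coreShellCylinderFF(q, 20, 360, 20, 1, 1)),
#'           cylinderFF(q, 40, 400))
#' @export
coreShellCylinderFF <- function(q, rCore, lCore, tShell, rhoCore, rhoShell,
                                nQuad = 128L) {
  if (!(rCore > 0 && lCore > 0 && tShell > 0))
    .stopf("all lengths must be positive")
  vc <- pi * rCore^2 * lCore
  vo <- pi * (rCore + tShell)^2 * (lCore + 2 * tShell)
  f0 <- (rhoCore - rhoShell) * vc + rhoShell * vo
  den <- abs(rhoCore - rhoShell) * vc + abs(rhoShell) * vo
  if (den == 0 || abs(f0) < 1e-12 * den)
    .stopf("undefined normalization: zero net forward amplitude")
  gl <- .glNodes(nQuad)
  Fc <- .cylAmpMesh(q, gl$x, rCore, lCore)
  Fo <- .cylAmpMesh(q, gl$x, rCore + tShell, lCore + 2 * tShell)
  Fq <- (rhoCore - rhoShell) * vc * Fc + rhoShell * vo * Fo
  P <- as.numeric(Fq^2 %*% gl$w) / f0^2
  attr(P, "forward") <- f0^2
  P
}

# analytic model registry: parameter names (without "scale"), evaluator of
# the normalized P(q), and lower bounds for the fit
.analyticRegistry <- list(
  sphere = list(
    params = "R",
    eval = function(q, p) sphereFF(q, p[["R"]]),
    lower = c(R = 1e-3)
  ),
  cylinder = list(
    params = c("R", "L"),
    eval = function(q, p) cylinderFF(q, p[["R"]], p[["L"]]),
    lower = c(R = 1e-3, L = 1e-3)
  ),
  ellipsoid_rev = list(
    params = c("a", "c"),
    eval = function(q, p) ellipsoidRevFF(q, p[["a"]], p[["c"]]),
    lower = c(a = 1e-3, c = 1e-3)
  ),
  core_shell_cylinder = list(
    params = c("r_core", "l_core", "t_shell", "rho_core", "rho_shell"),
    eval = function(q, p)
      as.numeric(coreShellCylinderFF(q, p[["r_core"]], p[["l_core"]],
                                     p[["t_shell"]], p[["rho_core"]],
                                     p[["rho_shell"]])),
    lower = c(r_core = 1e-3, l_core = 1e-3, t_shell = 1e-3,
              rho_core = -Inf, rho_shell = -Inf)
  )
)

#' Construct an analytic scattering model
#'
#' @param kind "sphere", "cylinder", "ellipsoid_rev" or
#'   "core_shell_cylinder".
#' @param params named numeric of model parameters (see
#'   [AnalyticModel-class]); a "scale" entry is added with default 1 if
#'   absent.
#' @param fixed character vector of parameter names held fixed by
#'   [fitModel()] (e.g. \code{"rho_core"}).
#' @return an [AnalyticModel-class].
#' @examples
#' analyticModel("core_shell_cylinder",
#'               c(r_core = 20, l_core = 360, t_shell = 20,
#'                 rho_core = -1, rho_shell = 1),
#'               fixed = "rho_core")
#' @export
analyticModel <- function(kind, params, fixed = character()) {
  if (!kind %in% names(.analyticRegistry))
    .stopf("unknown analytic model kind: '%s'", kind)
  if (!"scale" %in% names(params)) params <- c(params, scale = 1)
  free <- setNames(!names(params) %in% fixed, names(params))
  new("AnalyticModel", kind = kind, params = params, freeMask = free)
}

#' @describeIn analyticModel evaluate scale * P(q) on a grid.
#' @param model an [AnalyticModel-class].
#' @param q numeric grid in 1/Angstrom.
#' @export
setMethod("evaluateModel", "AnalyticModel", function(model, q, params = NULL) {
  p <- model@params
  if (!is.null(params)) p[names(params)] <- params
  p[["scale"]] * .analyticRegistry[[model@kind]]$eval(q, p)
})

# central-difference Jacobian of a residual function at a point
.numJacobian <- function(fn, par, rel = 1e-6) {
  r0 <- fn(par)
  J <- matrix(0, length(r0), length(par))
  for (i in seq_along(par)) {
    h <- rel * max(abs(par[i]), 1e-4)
    up <- par; up[i] <- up[i] + h
    dn <- par; dn[i] <- dn[i] - h
    J[, i] <- (fn(up) - fn(dn)) / (2 * h)
  }
  J
}

#' Least-squares fit of an analytic model to simulated data
#'
#' Minimizes \eqn{\chi^2 = \sum ((I_{sim} - s P_{model}) / \sigma)^2} over
#' the model's free parameters (which include the overall scale) with
#' bounded Levenberg-Marquardt least squares. To guard against parameter
#' correlation (e.g. between shell contrast and scale), the optimization is
#' restarted from jittered initial values and the best optimum kept.
#' Standard deviations come from the covariance of the least-squares
#' solution at the optimum, \eqn{\hat\sigma^2 (J^T J)^{-1}} with
#' \eqn{\hat\sigma^2} the reduced chi-square and J the sigma-weighted
#' Jacobian.
#'
#' @param data a [SimulatedData-class] (or anything with q, Isim, sigma).
#' @param model an [AnalyticModel-class]; parameters flagged in \code{fixed}
#'   at construction stay at their initial values.
#' @param init optional named numeric overriding the model's parameter
#'   values as starting point.
#' @param nStarts number of starts (first from init, the rest jittered by
#'   fixed factors; default 3).
#' @return a [FitResult-class].
#' @export
fitModel <- function(data, model, init = NULL, nStarts = 3L) {
  p0 <- model@params
  if (!is.null(init)) p0[names(init)] <- init
  free <- names(p0)[model@freeMask]
  if (!length(free)) .stopf("no free parameters to fit")
  reg <- .analyticRegistry[[model@kind]]
  lowerAll <- c(reg$lower, scale = 1e-12)
  lower <- lowerAll[free]
  q <- data@q; y <- data@Isim; sig <- data@sigma
  resid <- function(th) {
    p <- p0; p[free] <- th
    (y - evaluateModel(model, q, p)) / sig
  }
  jitter <- c(1, 0.85, 1.15, 0.7, 1.3)
  best <- NULL
  for (k in seq_len(max(1L, as.integer(nStarts)))) {
    start <- pmax(p0[free] * jitter[(k - 1) %% length(jitter) + 1], lower)
    fit <- try(minpack.lm::nls.lm(
      par = start, fn = resid, lower = lower,
      control = minpack.lm::nls.lm.control(maxiter = 300)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    .stopf("fit failure: no start converged (model '%s')", model@kind)
  th <- setNames(coef(best), free)
  pHat <- p0; pHat[free] <- th
  nres <- length(q); k <- length(free)
  chi2red <- best$deviance / max(1L, nres - k)
  J <- .numJacobian(resid, th)
  covm <- try(chi2red * solve(crossprod(J)), silent = TRUE)
  sdFree <- if (inherits(covm, "try-error")) rep(NA_real_, k)
            else sqrt(pmax(0, diag(covm)))
  parSD <- setNames(rep(NA_real_, length(p0)), names(p0))
  parSD[free] <- sdFree
  fittedModel <- model
  fittedModel@params <- pHat
  new("FitResult", parHat = pHat, parSD = parSD, chi2Red = chi2red,
      model = fittedModel, fitted = evaluateModel(model, q, pHat),
      converged = best$info %in% 1:4)
}

#' @rdname FitResult-class
#' @param object a [FitResult-class].
#' @export
setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult (%s): reduced chi^2 = %.4g, converged = %s\n",
              object@model@kind, object@chi2Red, object@converged))
  for (nm in names(object@parHat)) {
    if (is.na(object@parSD[nm]))
      cat(sprintf("  %-10s %10.4g  (fixed)\n", nm, object@parHat[nm]))
    else
      cat(sprintf("  %-10s %10.4g +/- %.2g\n", nm, object@parHat[nm],
                  object@parSD[nm]))
  }
})
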