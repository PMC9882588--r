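#' Analytic volume of a subunit
#'
#' Closed-form volume of the body in cubic Angstrom; for hollow and ring
#' kinds, outer volume minus inner volume.
#'
#' @param x a [Subunit-class] (or a [ModelSpec-class], which returns the sum
#'   over its subunits).
#' @return numeric(1), volume in Angstrom^3.
#' @examples
#' volume(subunit("sphere", 50))        # (4/3) pi 50^3
#' volume(subunit("cylinder", c(50, 400)))
#' @export
setGeneric("volume", function(x) standardGeneric("volume"))

#' Test whether points lie inside a subunit
#'
#' Boundary points count as inside. Points are given in the model frame;
#' the subunit's center-of-mass shift is subtracted before the test.
#'
#' @param x a [Subunit-class].
#' @param points numeric 3-vector or N x 3 matrix of coordinates (Angstrom).
#' @return logical vector, one element per point.
#' @examples
#' s <- subunit("sphere", 50)
#' isInside(s, c(0, 0, 49))  # TRUE
#' isInside(s, c(0, 0, 51))  # FALSE
#' @export
setGeneric("isInside", function(x, points) standardGeneric("isInside"))

#' Radius of gyration
#' @param x a [PairDistribution-class].
#' @return numeric(1), Rg in Angstrom.
#' @export
setGeneric("radiusOfGyration", function(x) standardGeneric("radiusOfGyration"))

#' Maximum intra-particle distance
#' @param x a [PairDistribution-class].
#' @return numeric(1), Dmax in Angstrom.
#' @export
setGeneric("dMax", function(x) standardGeneric("dMax"))

#' Evaluate an analytic model on a q grid
#'
#' @param model an [AnalyticModel-class].
#' @param q numeric, momentum transfer grid in 1/Angstrom.
#' @param params optional named numeric overriding the model's parameters.
#' @return numeric, scale * P(q).
#' @export
setGeneric("evaluateModel",
           function(model, q, params = NULL) standardGeneric("evaluateModel"))
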