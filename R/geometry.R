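# Subunit catalogue. Each entry gives the dimension names, the closed-form
# volume, the axis-aligned bounding box (3 x 2 matrix, subunit frame) and a
# vectorized inside test on an N x 3 matrix in the subunit frame. Bodies are
# axis-aligned; cylinders, discs and rings have their axis along z.
# For hollow/ring kinds `outer`/`inner` index the dims checked as inner < outer.
.kindRegistry <- list(
  sphere = list(
    dims = "R",
    volume = function(d) 4 / 3 * pi * d[1]^3,
    bbox = function(d) cbind(-rep(d[1], 3), rep(d[1], 3)),
    inside = function(d, X) rowSums(X^2) <= d[1]^2
  ),
  ellipsoid_triaxial = list(
    dims = c("a", "b", "c"),
    volume = function(d) 4 / 3 * pi * d[1] * d[2] * d[3],
    bbox = function(d) cbind(-d, d),
    inside = function(d, X)
      (X[, 1] / d[1])^2 + (X[, 2] / d[2])^2 + (X[, 3] / d[3])^2 <= 1
  ),
  cylinder = list(
    dims = c("R", "L"),
    volume = function(d) pi * d[1]^2 * d[2],
    bbox = function(d) cbind(c(-d[1], -d[1], -d[2] / 2),
                             c(d[1], d[1], d[2] / 2)),
    inside = function(d, X)
      X[, 1]^2 + X[, 2]^2 <= d[1]^2 & abs(X[, 3]) <= d[2] / 2
  ),
  disc = list(
    dims = c("R", "L"),
    volume = function(d) pi * d[1]^2 * d[2],
    bbox = function(d) cbind(c(-d[1], -d[1], -d[2] / 2),
                             c(d[1], d[1], d[2] / 2)),
    inside = function(d, X)
      X[, 1]^2 + X[, 2]^2 <= d[1]^2 & abs(X[, 3]) <= d[2] / 2
  ),
  cube = list(
    dims = "a",
    volume = function(d) d[1]^3,
    bbox = function(d) cbind(-rep(d[1] / 2, 3), rep(d[1] / 2, 3)),
    inside = function(d, X)
      pmax(abs(X[, 1]), abs(X[, 2]), abs(X[, 3])) <= d[1] / 2
  ),
  cuboid = list(
    dims = c("a", "b", "c"),
    volume = function(d) d[1] * d[2] * d[3],
    bbox = function(d) cbind(-d / 2, d / 2),
    inside = function(d, X)
      abs(X[, 1]) <= d[1] / 2 & abs(X[, 2]) <= d[2] / 2 &
        abs(X[, 3]) <= d[3] / 2
  ),
  sphere_hollow = list(
    dims = c("R", "r"), outer = 1L, inner = 2L,
    volume = function(d) 4 / 3 * pi * (d[1]^3 - d[2]^3),
    bbox = function(d) cbind(-rep(d[1], 3), rep(d[1], 3)),
    inside = function(d, X) {
      s <- rowSums(X^2)
      s <= d[1]^2 & s >= d[2]^2
    }
  ),
  cube_hollow = list(
    dims = c("a", "b"), outer = 1L, inner = 2L,
    volume = function(d) d[1]^3 - d[2]^3,
    bbox = function(d) cbind(-rep(d[1] / 2, 3), rep(d[1] / 2, 3)),
    inside = function(d, X) {
      m <- pmax(abs(X[, 1]), abs(X[, 2]), abs(X[, 3]))
      m <= d[1] / 2 & m >= d[2] / 2
    }
  ),
  ring_cylindrical = list(
    dims = c("R", "r", "L"), outer = 1L, inner = 2L,
    volume = function(d) pi * (d[1]^2 - d[2]^2) * d[3],
    bbox = function(d) cbind(c(-d[1], -d[1], -d[3] / 2),
                             c(d[1], d[1], d[3] / 2)),
    inside = function(d, X) {
      s <- X[, 1]^2 + X[, 2]^2
      s <= d[1]^2 & s >= d[2]^2 & abs(X[, 3]) <= d[3] / 2
    }
  ),
  ring_discoidal = list(
    dims = c("R", "r", "L"), outer = 1L, inner = 2L,
    volume = function(d) pi * (d[1]^2 - d[2]^2) * d[3],
    bbox = function(d) cbind(c(-d[1], -d[1], -d[3] / 2),
                             c(d[1], d[1], d[3] / 2)),
    inside = function(d, X) {
      s <- X[, 1]^2 + X[, 2]^2
      s <= d[1]^2 & s >= d[2]^2 & abs(X[, 3]) <= d[3] / 2
    }
  )
)

#' Supported subunit kinds
#' @return character vector of valid subunit kinds.
#' @export
subunitKinds <- function() names(.kindRegistry)

#' Construct a geometric subunit
#'
#' @param kind one of [subunitKinds()].
#' @param dims numeric vector of dimensions in Angstrom; see
#'   [Subunit-class] for the meaning per kind.
#' @param contrast excess scattering length density (relative units; may be
#'   negative for, e.g., a solvent-matched or deuterated component).
#' @param com center-of-mass displacement, 3-vector in Angstrom.
#' @return a [Subunit-class].
#' @examples
#' subunit("sphere", 50)
#' subunit("cylinder", c(20, 360), contrast = -1)
#' @export
subunit <- function(kind, dims, contrast = 1, com = c(0, 0, 0)) {
  if (!is.character(kind) || length(kind) != 1L ||
      !kind %in% names(.kindRegistry))
    .stopf("unsupported subunit kind: '%s'", paste(kind, collapse = ","))
  new("Subunit", kind = kind, dims = as.numeric(dims),
      contrast = as.numeric(contrast), com = as.numeric(com))
}

#' Construct a model specification
#'
#' @param subunits a [Subunit-class] or list of them (order matters for
#'   overlap precedence: later subunits win).
#' @param excludeOverlap remove points of earlier subunits that fall inside
#'   later subunits (default TRUE).
#' @param nPoints total number of points across all subunits (default 5000).
#' @param seed RNG seed used by [buildModel()].
#' @return a [ModelSpec-class].
#' @examples
#' modelSpec(subunit("sphere", 50), seed = 1)
#' @export
modelSpec <- function(subunits, excludeOverlap = TRUE, nPoints = 5000L,
                      seed = 1L) {
  if (is(subunits, "Subunit")) subunits <- list(subunits)
  new("ModelSpec", subunits = subunits,
      excludeOverlap = as.logical(excludeOverlap),
      nPoints = as.integer(nPoints), seed = as.integer(seed))
}

#' @describeIn volume closed-form volume of one subunit.
#' @export
setMethod("volume", "Subunit", function(x) {
  .kindRegistry[[x@kind]]$volume(x@dims)
})

#' @describeIn volume total volume of all subunits in a model spec.
#' @export
setMethod("volume", "ModelSpec", function(x) {
  sum(vapply(x@subunits, volume, numeric(1)))
})

#' @describeIn isInside vectorized point-in-body test.
#' @export
setMethod("isInside", "Subunit", function(x, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L, byrow = TRUE)
  X <- sweep(points, 2L, x@com)
  .kindRegistry[[x@kind]]$inside(x@dims, X)
})

#' Sample uniform points inside a subunit
#'
#' Rejection sampling from the axis-aligned bounding box of the body, which
#' is uniform in the volume by construction; the accepted points are then
#' shifted by the subunit's center of mass. Uses the current RNG state.
#'
#' @param x a [Subunit-class].
#' @param n number of points (>= 1).
#' @return n x 3 numeric matrix of coordinates in Angstrom.
#' @examples
#' set.seed(1)
#' pts <- samplePoints(subunit("sphere", 50), 1000)
#' @export
samplePoints <- function(x, n) {
  n <- as.integer(n)
  if (n < 1L) .stopf("n must be >= 1")
  reg <- .kindRegistry[[x@kind]]
  bb <- reg$bbox(x@dims)
  vbox <- prod(bb[, 2] - bb[, 1])
  eff <- reg$volume(x@dims) / vbox
  out <- matrix(numeric(0), ncol = 3L)
  while (nrow(out) < n) {
    m <- max(1000L, as.integer(ceiling((n - nrow(out)) / eff * 1.2)))
    cand <- cbind(stats::runif(m, bb[1, 1], bb[1, 2]),
                  stats::runif(m, bb[2, 1], bb[2, 2]),
                  stats::runif(m, bb[3, 1], bb[3, 2]))
    keep <- reg$inside(x@dims, cand)
    out <- rbind(out, cand[keep, , drop = FALSE])
  }
  out <- out[seq_len(n), , drop = FALSE]
  sweep(out, 2L, x@com, "+")
}

# Largest-remainder allocation of n points proportional to volumes;
# ties broken by subunit order.
.allocatePoints <- function(volumes, n) {
  quota <- n * volumes / sum(volumes)
  base <- floor(quota)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- quota - base
    ord <- order(-frac, seq_along(frac))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Realize a model specification as a point cloud
#'
#' Allocates the total point budget across subunits proportional to their
#' volumes (largest-remainder rounding, ties by subunit order), samples each
#' subunit uniformly, and optionally removes overlap: with
#' \code{excludeOverlap} on, every point of subunit i that lies inside a
#' later-listed subunit j > i is deleted, so later subunits can "carve"
#' regions out of earlier ones. The total point count is not topped back up
#' after exclusion, keeping the point density constant. Each surviving point
#' gets weight \eqn{\Delta b = \Delta\rho \cdot V_{point}} with
#' \eqn{V_{point} = \sum_k V_k / N_{total}}.
#'
#' @param spec a [ModelSpec-class].
#' @param seed optional seed overriding \code{spec@seed}.
#' @return a [PointCloud-class].
#' @examples
#' cloud <- buildModel(modelSpec(subunit("sphere", 50), seed = 7))
#' nrow(positions(cloud))  # 5000
#' @export
buildModel <- function(spec, seed = NULL) {
  validObject(spec)
  if (is.null(seed)) seed <- spec@seed
  subs <- spec@subunits
  vols <- vapply(subs, volume, numeric(1))
  counts <- .allocatePoints(vols, spec@nPoints)
  pts <- .withSeed(seed, {
    lapply(seq_along(subs), function(k) {
      if (counts[k] == 0L) matrix(numeric(0), ncol = 3L)
      else samplePoints(subs[[k]], counts[k])
    })
  })
  if (spec@excludeOverlap && length(subs) > 1L) {
    for (i in seq_along(subs)) {
      if (nrow(pts[[i]]) == 0L) next
      drop <- rep(FALSE, nrow(pts[[i]]))
      for (j in seq_along(subs)) {
        if (j <= i) next
        drop <- drop | isInside(subs[[j]], pts[[i]])
      }
      pts[[i]] <- pts[[i]][!drop, , drop = FALSE]
    }
  }
  kept <- vapply(pts, nrow, integer(1))
  if (sum(kept) == 0L)
    .stopf("empty model: all points were removed by overlap exclusion")
  vPoint <- sum(vols) / spec@nPoints
  w <- rep(vapply(subs, function(s) s@contrast, numeric(1)) * vPoint, kept)
  new("PointCloud",
      positions = do.call(rbind, pts),
      weights = w,
      subunitIndex = rep(seq_along(subs), kept),
      pointDensity = spec@nPoints / sum(vols))
}

#' @rdname PointCloud-class
#' @param x,object a [PointCloud-class].
#' @export
positions <- function(x) x@positions

#' @rdname PointCloud-class
#' @export
pointWeights <- function(x) x@weights

#' @rdname PointCloud-class
#' @export
subunitIndex <- function(x) x@subunitIndex

#' @rdname PointCloud-class
#' @export
setMethod("show", "PointCloud", function(object) {
  cat(sprintf("PointCloud: %d points, %d subunit(s), density %.4g pts/A^3\n",
              nrow(object@positions), length(unique(object@subunitIndex)),
              object@pointDensity))
  tab <- table(object@subunitIndex)
  cat("  points per subunit:", paste(tab, collapse = ", "), "\n")
})

#' @rdname Subunit-class
#' @param object a [Subunit-class].
#' @export
setMethod("show", "Subunit", function(object) {
  reg <- .kindRegistry[[object@kind]]
  cat(sprintf("Subunit '%s': %s; contrast %g; com (%g, %g, %g); V = %.6g A^3\n",
              object@kind,
              paste(sprintf("%s=%g", reg$dims, object@dims), collapse = ", "),
              object@contrast, object@com[1], object@com[2], object@com[3],
              volume(object)))
})

#' @rdname ModelSpec-class
#' @param object a [ModelSpec-class].
#' @export
setMethod("show", "ModelSpec", function(object) {
  cat(sprintf("ModelSpec: %d subunit(s), N = %d, excludeOverlap = %s, seed = %d\n",
              length(object@subunits), object@nPoints,
              object@excludeOverlap, object@seed))
  for (s in object@subunits) show(s)
})
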