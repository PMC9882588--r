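test_that("closed-form volumes match the analytic bodies", {
  cases <- list(
    list(subunit("sphere", 50), 4 / 3 * pi * 50^3),
    list(subunit("ellipsoid_triaxial", c(50, 50, 100)),
         4 / 3 * pi * 50 * 50 * 100),
    list(subunit("cylinder", c(50, 400)), pi * 50^2 * 400),
    list(subunit("disc", c(50, 10)), pi * 50^2 * 10),
    list(subunit("cube", 10), 1000),
    list(subunit("cuboid", c(10, 20, 30)), 6000),
    list(subunit("sphere_hollow", c(50, 30)), 4 / 3 * pi * (50^3 - 30^3)),
    list(subunit("cube_hollow", c(20, 10)), 20^3 - 10^3),
    list(subunit("ring_cylindrical", c(40, 20, 100)),
         pi * (40^2 - 20^2) * 100),
    list(subunit("ring_discoidal", c(40, 20, 10)), pi * (40^2 - 20^2) * 10))
  for (cs in cases)
    expect_equal(volume(cs[[1]]), cs[[2]], tolerance = 1e-12)
})

test_that("degenerate and malformed subunits are rejected", {
  expect_error(subunit("dodecahedron", 10), "unsupported")
  expect_error(subunit("sphere_hollow", c(50, 50)), "inner")
  expect_error(subunit("ring_cylindrical", c(20, 40, 100)), "inner")
  expect_error(subunit("sphere", -5), "positive")
  expect_error(subunit("cylinder", 50), "dims")
  expect_error(subunit("sphere", 1e-3), "degenerate")
})

test_that("point-in-body tests honor boundaries and com shifts", {
  s <- subunit("sphere", 50)
  expect_true(isInside(s, c(0, 0, 49)))
  expect_true(isInside(s, c(0, 0, 50)))   # boundary counts as inside
  expect_false(isInside(s, c(0, 0, 51)))
  ring <- subunit("ring_cylindrical", c(40, 20, 100))
  expect_true(isInside(ring, c(30, 0, 0)))    # 20 <= 30 <= 40, |z| <= 50
  expect_false(isInside(ring, c(10, 0, 0)))   # inside the hole
  expect_false(isInside(ring, c(30, 0, 51)))  # beyond the end cap
  shifted <- subunit("cube", 10, com = c(100, 0, 0))
  expect_true(isInside(shifted, c(104, 0, 0)))
  expect_false(isInside(shifted, c(4, 0, 0)))
  hollow <- subunit("sphere_hollow", c(50, 30))
  expect_false(isInside(hollow, c(0, 0, 0)))
  expect_true(isInside(hollow, c(0, 0, 40)))
})

test_that("Monte-Carlo hit fractions reproduce every kind's volume", {
  subs <- list(subunit("sphere", 50),
               subunit("ellipsoid_triaxial", c(30, 50, 80)),
               subunit("cylinder", c(50, 400)),
               subunit("disc", c(80, 20)),
               subunit("cube", 40),
               subunit("cuboid", c(20, 40, 80)),
               subunit("sphere_hollow", c(50, 30)),
               subunit("cube_hollow", c(40, 25)),
               subunit("ring_cylindrical", c(40, 20, 100)),
               subunit("ring_discoidal", c(60, 30, 15)))
  set.seed(101)
  n <- 1e5
  for (s in subs) {
    # enclosing box from the kind's own extents (dims are axis-aligned caps)
    ext <- switch(s@kind,
      sphere = rep(s@dims[1], 3),
      ellipsoid_triaxial = s@dims,
      cylinder = ,
      disc = c(s@dims[1], s@dims[1], s@dims[2] / 2),
      cube = rep(s@dims[1] / 2, 3),
      cuboid = s@dims / 2,
      sphere_hollow = rep(s@dims[1], 3),
      cube_hollow = rep(s@dims[1] / 2, 3),
      ring_cylindrical = ,
      ring_discoidal = c(s@dims[1], s@dims[1], s@dims[3] / 2))
    ext <- ext * 1.25  # strictly larger than the body so 0 < p < 1
    pts <- cbind(runif(n, -ext[1], ext[1]), runif(n, -ext[2], ext[2]),
                 runif(n, -ext[3], ext[3]))
    phat <- mean(isInside(s, pts))
    p <- volume(s) / prod(2 * ext)
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(phat - p), 5 * se, label = s@kind)
  }
})

test_that("uniform sampling has the right moments and support", {
  set.seed(7)
  pts <- samplePoints(subunit("sphere", 50), 1e5)
  expect_lt(max(abs(colMeans(pts))), 1)
  rgHat <- sqrt(mean(rowSums(pts^2)))
  expect_lt(abs(rgHat / (sqrt(3 / 5) * 50) - 1), 0.01)

  cube <- samplePoints(subunit("cube", 10, com = c(100, 0, 0)), 1e4)
  expect_true(all(cube[, 1] >= 95 & cube[, 1] <= 105))
  expect_true(all(abs(cube[, 2]) <= 5 & abs(cube[, 3]) <= 5))

  cyl <- samplePoints(subunit("cylinder", c(50, 400)), 1e5)
  frac <- mean(abs(cyl[, 3]) < 100)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 1e5))
})

test_that("points are allocated proportional to volume by largest remainder", {
  # second sphere has exactly twice the volume of the first
  spec <- modelSpec(list(
    subunit("sphere", 50),
    subunit("sphere", 50 * 2^(1 / 3), com = c(500, 0, 0))),
    nPoints = 3000, seed = 1)
  cloud <- buildModel(spec)
  counts <- tabulate(subunitIndex(cloud), 2)
  expect_equal(counts, c(1000, 2000))
  # all weights equal within a subunit, proportional to contrast overall
  expect_length(unique(pointWeights(cloud)[subunitIndex(cloud) == 1]), 1)
})

test_that("single-subunit model yields exactly N equal-weight points", {
  cloud <- buildModel(modelSpec(subunit("sphere", 50), seed = 3))
  expect_equal(nrow(positions(cloud)), 5000)
  expect_length(unique(pointWeights(cloud)), 1)
  # weight = contrast * V_total / N
  expect_equal(unique(pointWeights(cloud)), volume(subunit("sphere", 50)) / 5000)
})

test_that("later subunits carve overlap regions out of earlier ones", {
  spec <- coreShellSpec(seed = 11)
  cloud <- buildModel(spec)
  core <- spec@subunits[[2]]
  shellPts <- positions(cloud)[subunitIndex(cloud) == 1, ]
  expect_false(any(isInside(core, shellPts)))
  # without exclusion every sampled point is kept, and the last-listed core
  # keeps the same points either way (it never loses a contest)
  spec2 <- modelSpec(spec@subunits, excludeOverlap = FALSE, nPoints = 5000,
                     seed = 11)
  cloud2 <- buildModel(spec2)
  expect_equal(nrow(positions(cloud2)), 5000)
  expect_identical(positions(cloud)[subunitIndex(cloud) == 2, ],
                   positions(cloud2)[subunitIndex(cloud2) == 2, ])
})

test_that("identical spec and seed give bit-identical clouds", {
  spec <- coreShellSpec(seed = 42)
  c1 <- buildModel(spec)
  c2 <- buildModel(spec)
  expect_identical(positions(c1), positions(c2))
  expect_identical(pointWeights(c1), pointWeights(c2))
  # and the build does not disturb the caller's RNG
  set.seed(5); before <- runif(1)
  set.seed(5); invisible(buildModel(spec)); after <- runif(1)
  expect_identical(before, after)
})
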