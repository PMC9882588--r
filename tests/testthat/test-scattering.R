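test_that("two-point and collinear systems are binned exactly", {
  cloud <- makeCloud(rbind(c(0, 0, 0), c(0, 0, 10)))
  pd <- pairDistribution(cloud, nBins = 100)
  expect_equal(sum(pd@p), 1)
  expect_equal(pd@r[pd@p == 1], 10, tolerance = pd@dr)
  expect_equal(dMax(pd), 10)
  expect_equal(radiusOfGyration(pd), sqrt(10^2 / 2), tolerance = 1e-2)

  tri <- makeCloud(rbind(c(0, 0, 0), c(0, 0, 10), c(0, 0, 20)))
  pd3 <- pairDistribution(tri, nBins = 50)
  expect_equal(sum(pd3@p), 3)  # pairs at 10, 10, 20
  ref <- oracleHist(positions(tri), pointWeights(tri),
                    seq(0, pd3@dr * 50, by = pd3@dr))
  expect_equal(pd3@p, ref)
  expect_equal(pd3@p[findInterval(10, seq(0, pd3@dr * 50, by = pd3@dr))], 2)
})

test_that("a uniform sphere cloud reproduces the ball's Rg and Dmax", {
  cloud <- buildModel(modelSpec(subunit("sphere", 50), seed = 1))
  pd <- pairDistribution(cloud)
  expect_lt(abs(radiusOfGyration(pd) / (sqrt(3 / 5) * 50) - 1), 0.01)
  expect_gt(dMax(pd), 98)
  expect_lte(dMax(pd), 100)
})

test_that("exported p(r) carries the (0,0) row and unit maximum", {
  cloud <- buildModel(modelSpec(subunit("sphere", 30), seed = 2))
  tab <- prTable(pairDistribution(cloud))
  expect_equal(tab$r[1], 0)
  expect_equal(tab$p[1], 0)
  expect_equal(max(abs(tab$p)), 1)
})

test_that("intensity normalization gives P(0) = 1 and rejects bad grids", {
  cloud <- buildModel(modelSpec(subunit("cube", 40), seed = 3))
  crv <- scatteringIntensity(pairDistribution(cloud), c(0, 0.01, 0.1))
  expect_equal(formFactor(crv)[1], 1)
  expect_error(scatteringIntensity(pairDistribution(cloud), c(-0.1, 0.1)),
               "invalid q")
  # single bin at r = 10: P(pi/10) = sinc(pi) = 0
  pd1 <- new("PairDistribution", r = 10, p = 1, dr = 20, dmax = 10,
             rg = sqrt(50), nBins = 1L, totalContrast = 2)
  expect_equal(formFactor(scatteringIntensity(pd1, pi / 10))[1], 0,
               tolerance = 1e-15)
})

test_that("binned transform matches the direct Debye sum on random clouds", {
  q <- seq(0, 0.3, length.out = 31)
  for (seed in 1:5) {
    cloud <- randomCloud(n = 150, seed = seed)
    pd <- pairDistribution(cloud, nBins = 1e5)
    P <- formFactor(scatteringIntensity(pd, q))
    ref <- oracleDebye(positions(cloud), pointWeights(cloud), q)
    # relative agreement where the curve is resolvable; near its
    # zero-crossings a pure ratio is ill-defined, so bound the absolute
    # error there (P(0) = 1 sets the scale)
    strong <- abs(ref) >= 1e-2
    expect_lt(max(abs(P - ref)[strong] / abs(ref)[strong]), 1e-3)
    expect_lt(max(abs(P - ref)[!strong]), 1e-5)
  }
})

test_that("the histogram is invariant under translation and permutation", {
  cloud <- randomCloud(n = 100, seed = 9)
  pd <- pairDistribution(cloud, nBins = 200)
  shifted <- makeCloud(sweep(positions(cloud), 2, c(123, -45, 6), "+"),
                       pointWeights(cloud))
  expect_equal(pairDistribution(shifted, nBins = 200)@p, pd@p)
  set.seed(1)
  perm <- sample(100)
  permuted <- makeCloud(positions(cloud)[perm, ], pointWeights(cloud)[perm])
  expect_equal(pairDistribution(permuted, nBins = 200)@p, pd@p)
})

test_that("contrast-matched clouds raise the zero-forward-scattering error", {
  cloud <- makeCloud(rbind(c(0, 0, 0), c(0, 0, 10)), w = c(1, -1))
  pd <- pairDistribution(cloud, nBins = 10)
  expect_error(scatteringIntensity(pd, c(0, 0.1)), "forward scattering")
})

test_that("polydispersity reduces to the monodisperse limit at one node", {
  cloud <- buildModel(modelSpec(subunit("sphere", 50), seed = 4))
  mono <- pairDistribution(cloud, nBins = 300)
  # a single midpoint node sits exactly at s = 1
  poly <- pairDistribution(cloud, nBins = 300, sigmaPoly = 0.05, nNodes = 1)
  expect_equal(poly@p, mono@p)
  expect_equal(poly@dmax, mono@dmax)
})

test_that("polydisperse support and Rg behave as scaled mixtures", {
  two <- makeCloud(rbind(c(0, 0, 0), c(0, 0, 10)))
  pd <- pairDistribution(two, nBins = 130, sigmaPoly = 0.1)
  nz <- pd@r[pd@p > 0]
  expect_gte(min(nz), 7 - pd@dr)   # s in [0.7, 1.3]
  expect_lte(max(nz), 13 + pd@dr)

  cloud <- buildModel(modelSpec(subunit("sphere", 50), seed = 5))
  rgMono <- radiusOfGyration(pairDistribution(cloud))
  rgPoly <- radiusOfGyration(pairDistribution(cloud, sigmaPoly = 0.1))
  expect_gt(rgPoly, rgMono)  # s^6 weighting favors the larger sizes
})

test_that("15 size-scale nodes reproduce a dense quadrature to 0.1%", {
  cloud <- buildModel(modelSpec(subunit("cylinder", c(50, 400)),
                                nPoints = 1000, seed = 6))
  q <- seq(0, 0.2, length.out = 60)
  P15 <- formFactor(scatteringIntensity(
    pairDistribution(cloud, sigmaPoly = 0.1, nNodes = 15), q))
  P201 <- formFactor(scatteringIntensity(
    pairDistribution(cloud, sigmaPoly = 0.1, nNodes = 201), q))
  # 0.1% agreement over the resolvable three decades of the curve, and a
  # tight absolute bound in the weak tail
  strong <- P201 >= 1e-3
  expect_lt(max(abs(P15 - P201)[strong] / P201[strong]), 1e-3)
  expect_lt(max(abs(P15 - P201)[!strong]), 1e-5)
})

test_that("out-of-range polydispersity is rejected", {
  cloud <- makeCloud(rbind(c(0, 0, 0), c(0, 0, 10)))
  expect_error(pairDistribution(cloud, sigmaPoly = 0.4), "sigmaPoly")
  expect_error(pairDistribution(makeCloud(matrix(0, 1, 3))), "two points")
})
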