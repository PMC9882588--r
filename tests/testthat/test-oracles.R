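test_that("the sphere form factor has its known limits and first zero", {
  expect_equal(sphereFF(0, 50), 1)
  # first zero at x = qR ~ 4.4934 (smallest positive root of tan x = x)
  q <- seq(0.085, 0.095, length.out = 2000)
  expect_equal(q[which.min(sphereFF(q, 50))], 4.4934 / 50, tolerance = 1e-3)
  # Guinier regime: P ~ exp(-q^2 Rg^2 / 3) with Rg^2 = (3/5) R^2
  qg <- seq(0.001, 0.02, length.out = 20)  # qR < 1
  expect_lt(max(abs(sphereFF(qg, 50) / exp(-qg^2 * (3 / 5) * 50^2 / 3) - 1)),
            0.01)
})

test_that("the cylinder form factor recovers the Guinier radius", {
  rg2 <- 50^2 / 2 + 400^2 / 12
  qg <- seq(0.0005, 0.004, length.out = 15)  # q Rg < 0.5
  P <- cylinderFF(qg, 50, 400)
  slope <- unname(coef(lm(log(P) ~ I(qg^2)))[2])
  expect_equal(sqrt(-3 * slope), sqrt(rg2), tolerance = 0.01)
  expect_equal(cylinderFF(0, 50, 400), 1)
})

test_that("a vanishing length reduces the cylinder to a thin disc", {
  q <- seq(0.05, 0.3, length.out = 30)
  x <- q * 50
  thinDisc <- 2 / x^2 * (1 - besselJ(2 * x, 1) / x)
  expect_lt(max(abs(cylinderFF(q, 50, 1e-3) / thinDisc - 1)), 0.01)
})

test_that("core-shell cylinder collapses to its homogeneous limits", {
  q <- seq(0, 0.3, length.out = 80)
  # equal contrasts: outer cylinder
  expect_equal(as.numeric(coreShellCylinderFF(q, 20, 360, 20, 1, 1)),
               cylinderFF(q, 40, 400), tolerance = 1e-10)
  # vanishing shell: core cylinder regardless of shell contrast
  expect_equal(as.numeric(coreShellCylinderFF(q, 20, 360, 1e-7, 1, 5)),
               cylinderFF(q, 20, 360), tolerance = 1e-4)
  expect_error(coreShellCylinderFF(q, 20, 360, 20, 0, 0), "normalization")
})

test_that("all analytic form factors stay normalized within [0, 1]", {
  q <- seq(0, 0.5, length.out = 200)
  curves <- list(sphereFF(q, 50), cylinderFF(q, 50, 400),
                 ellipsoidRevFF(q, 50, 100),
                 as.numeric(coreShellCylinderFF(q, 20, 360, 20, -1, 1)))
  for (P in curves) {
    expect_equal(P[1], 1)
    expect_true(all(P >= 0 & P <= 1 + 1e-12))
  }
})

test_that("128-point orientational quadrature is converged", {
  q <- seq(0, 0.5, length.out = 100)
  P128 <- as.numeric(coreShellCylinderFF(q, 20, 360, 20, -1, 1, nQuad = 128))
  P1024 <- as.numeric(coreShellCylinderFF(q, 20, 360, 20, -1, 1,
                                          nQuad = 1024))
  expect_lt(max(abs(P128 - P1024)), 1e-8)
})

test_that("Monte-Carlo form factors match the closed forms at low q", {
  # Guinier-region agreement of the N = 5000 bead models with the analytic
  # sphere and cylinder to better than 0.5%
  qs <- seq(0.004, 0.02, length.out = 10)
  sphere <- buildModel(modelSpec(subunit("sphere", 50), seed = 21))
  Ps <- formFactor(scatteringIntensity(pairDistribution(sphere), qs))
  expect_lt(max(abs(Ps / sphereFF(qs, 50) - 1)), 0.005)
  qc <- seq(0.002, 0.01, length.out = 10)
  cyl <- buildModel(modelSpec(subunit("cylinder", c(50, 400)), seed = 22))
  Pc <- formFactor(scatteringIntensity(pairDistribution(cyl), qc))
  expect_lt(max(abs(Pc / cylinderFF(qc, 50, 400) - 1)), 0.005)
})

test_that("fitting noise-free self-generated data recovers the truth", {
  q <- seq(0.005, 0.4, length.out = 150)
  m <- analyticModel("sphere", c(R = 50, scale = 1.3))
  I <- evaluateModel(m, q)
  d <- new("SimulatedData", q = q, Isim = I,
           sigma = errorModel(q, I), noiseScale = 1, seed = 1L)
  f <- fitModel(d, m, init = c(R = 50, scale = 1.3))
  expect_equal(unname(f@parHat["R"]), 50, tolerance = 1e-6)
  expect_equal(unname(f@parHat["scale"]), 1.3, tolerance = 1e-6)
  expect_lt(f@chi2Red, 1e-10)
})

test_that("sphere radius is recovered from simulated noisy bead data", {
  cloud <- buildModel(modelSpec(subunit("sphere", 50), seed = 23))
  q <- seq(0.001, 0.3, length.out = 300)
  crv <- scatteringIntensity(pairDistribution(cloud), q)
  sim <- simulateData(crv, noiseScale = 1, seed = 24)
  f <- fitModel(sim, analyticModel("sphere", c(R = 45, scale = 1)))
  expect_gt(unname(f@parSD["R"]), 0)
  expect_lt(abs(unname(f@parHat["R"]) - 50),
            3 * unname(f@parSD["R"]) + 0.25)
  expect_true(f@converged)
})
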