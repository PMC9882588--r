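# Independent reference implementations used as oracles, plus small fixture
# builders. Deliberately naive: plain R loops, no binning shortcuts.

# build a PointCloud directly from coordinates and weights
makeCloud <- function(pos, w = rep(1, nrow(pos)), idx = rep(1L, nrow(pos))) {
  new("PointCloud", positions = pos, weights = as.numeric(w),
      subunitIndex = as.integer(idx), pointDensity = 1)
}

# random multi-contrast test cloud
randomCloud <- function(n, seed, contrasts = c(1, -0.5)) {
  set.seed(seed)
  pos <- matrix(runif(3 * n, -60, 60), ncol = 3)
  w <- sample(contrasts, n, replace = TRUE)
  makeCloud(pos, w)
}

# direct Debye double sum over explicit pairs, no histogram
oracleDebye <- function(pos, w, q) {
  n <- nrow(pos)
  num <- numeric(length(q))
  den <- 0
  for (j in seq_len(n - 1)) {
    for (k in (j + 1):n) {
      d <- sqrt(sum((pos[j, ] - pos[k, ])^2))
      wp <- w[j] * w[k]
      den <- den + wp
      x <- q * d
      num <- num + wp * ifelse(x == 0, 1, sin(x) / x)
    }
  }
  num / den
}

# brute-force weighted pair-distance histogram on given breaks
oracleHist <- function(pos, w, breaks) {
  p <- numeric(length(breaks) - 1)
  n <- nrow(pos)
  for (j in seq_len(n - 1)) {
    for (k in (j + 1):n) {
      d <- sqrt(sum((pos[j, ] - pos[k, ])^2))
      i <- findInterval(d, breaks, rightmost.closed = TRUE)
      p[i] <- p[i] + w[j] * w[k]
    }
  }
  p
}

# the Example-3 core-shell cylinder built by carving: shell cylinder first,
# core cylinder (negative contrast) last so the overlap region is removed
# from the shell
coreShellSpec <- function(seed, nPoints = 5000) {
  modelSpec(list(subunit("cylinder", c(40, 400), contrast = 1),
                 subunit("cylinder", c(20, 360), contrast = -1)),
            excludeOverlap = TRUE, nPoints = nPoints, seed = seed)
}

# simulate + fit the Example-3 pipeline once; returns the FitResult
coreShellFit <- function(seed) {
  cloud <- buildModel(coreShellSpec(seed))
  q <- seq(0.001, 0.5, length.out = 400)
  crv <- scatteringIntensity(pairDistribution(cloud), q)
  sim <- simulateData(crv, noiseScale = 1, seed = seed + 100L)
  m <- analyticModel("core_shell_cylinder",
                     c(r_core = 20, l_core = 360, t_shell = 20,
                       rho_core = -1, rho_shell = 1),
                     fixed = "rho_core")
  fitModel(sim, m)
}
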