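#' @importFrom stats setNames coef
#' @importFrom utils read.table
NULL

.writeLines2 <- function(lines, path) {
  con <- file(path, open = "wb")  # fixed LF endings keep round-trips exact
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
}

#' Write the exported p(r) as 2-column ASCII
#'
#' Columns r (Angstrom) and p (max-normalized), with the leading (0, 0) row.
#'
#' @param pd a [PairDistribution-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writePr <- function(pd, path) {
  tab <- prTable(pd)
  .writeLines2(c("# r [A]  p(r) (normalized, p(0) = 0 added)",
                 paste(.fmt(tab$r), .fmt(tab$p))), path)
  invisible(path)
}

#' Write a calculated intensity as 2-column ASCII
#' @param curve a [ScatteringCurve-class].
#' @param path output file.
#' @param what "I" (total intensity, default), "P" (form factor) or "Seff"
#'   (effective structure factor).
#' @return the path, invisibly.
#' @export
writeIq <- function(curve, path, what = c("I", "P", "Seff")) {
  what <- match.arg(what)
  y <- slot(curve, what)
  lab <- c(I = "I(q)", P = "P(q)", Seff = "S_eff(q)")[[what]]
  .writeLines2(c(sprintf("# q [1/A]  %s", lab),
                 paste(.fmt(curve@q), .fmt(y))), path)
  invisible(path)
}

#' Read a 2-column ASCII curve
#' @param path file written by [writeIq()] or [writePr()].
#' @return data.frame with columns x and y.
#' @export
readCurve <- function(path) {
  tab <- read.table(path, comment.char = "#", col.names = c("x", "y"))
  tab
}

#' Write simulated data in SasView-compatible 3-column format
#'
#' Columns q (1/Angstrom), I_sim and sigma, with a comment header: the
#' de-facto .dat format read by SAXS fitting tools.
#'
#' @param sd a [SimulatedData-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeSimulatedData <- function(sd, path) {
  .writeLines2(c("# Simulated small-angle scattering data",
                 sprintf("# noise scale: %s", .fmt(sd@noiseScale)),
                 "# q [1/A]  I_sim(q)  sigma(q)",
                 paste(.fmt(sd@q), .fmt(sd@Isim), .fmt(sd@sigma))), path)
  invisible(path)
}

#' Read simulated data from a 3-column .dat file
#' @param path file in the format of [writeSimulatedData()] (comment lines
#'   starting with # are skipped).
#' @return a [SimulatedData-class] (noiseScale and seed are not recovered
#'   and are set to NA).
#' @export
readSimulatedData <- function(path) {
  tab <- read.table(path, comment.char = "#",
                    col.names = c("q", "Isim", "sigma"))
  new("SimulatedData", q = tab$q, Isim = tab$Isim, sigma = tab$sigma,
      noiseScale = NA_real_, seed = NA_integer_)
}

#' Export a point cloud in PDB format
#'
#' One fixed-column ATOM record per point (dummy residue DUM, chain A,
#' residue number = subunit index). The element encodes the contrast sign —
#' C for positive, O for negative, N for zero — and the occupancy column
#' carries the normalized absolute contrast, so multi-contrast models render
#' with distinct colors in standard viewers.
#'
#' @param cloud a non-empty [PointCloud-class] with all |coordinates| below
#'   1e4 Angstrom (the PDB fixed-column limit).
#' @param path output file.
#' @return the path, invisibly.
#' @export
writePDB <- function(cloud, path) {
  n <- nrow(cloud@positions)
  if (n == 0L) .stopf("cannot export an empty point cloud")
  if (any(abs(cloud@positions) >= 1e4))
    .stopf(paste("coordinate overflow: |coordinates| must be < 1e4 A to fit",
                 "PDB fixed columns; rescale the model units"))
  elem <- ifelse(cloud@weights > 0, "C", ifelse(cloud@weights < 0, "O", "N"))
  wmax <- max(abs(cloud@weights))
  occ <- if (wmax > 0) abs(cloud@weights) / wmax else rep(0, n)
  rec <- sprintf(
    "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(n), paste0(" ", elem), "DUM", "A",
    cloud@subunitIndex %% 10000L,
    cloud@positions[, 1], cloud@positions[, 2], cloud@positions[, 3],
    occ, 0, elem)
  .writeLines2(c(rec, "END"), path)
  invisible(path)
}

#' Serialize a model specification to a flat key-value config
#'
#' One header block (n_points, seed, exclude_overlap) followed by one
#' \code{[subunit]} block per subunit with kind, dims, contrast and com.
#' All numbers use fixed 8-significant-digit formatting, so
#' write -> read -> write is byte-identical.
#'
#' @param spec a [ModelSpec-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeModelConfig <- function(spec, path) {
  lines <- c(sprintf("n_points: %d", spec@nPoints),
             sprintf("seed: %d", spec@seed),
             sprintf("exclude_overlap: %s",
                     tolower(as.character(spec@excludeOverlap))))
  for (s in spec@subunits) {
    lines <- c(lines, "[subunit]",
               sprintf("kind: %s", s@kind),
               sprintf("dims: %s", paste(.fmt(s@dims), collapse = " ")),
               sprintf("contrast: %s", .fmt(s@contrast)),
               sprintf("com: %s", paste(.fmt(s@com), collapse = " ")))
  }
  .writeLines2(lines, path)
  invisible(path)
}

#' @rdname writeModelConfig
#' @return \code{readModelConfig}: the deserialized [ModelSpec-class].
#' @export
readModelConfig <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  blocks <- cumsum(lines == "[subunit]")
  kv <- function(ls) {
    ls <- ls[ls != "[subunit]"]
    parts <- regmatches(ls, regexpr(":", ls), invert = TRUE)
    setNames(trimws(vapply(parts, `[`, character(1), 2)),
             trimws(vapply(parts, `[`, character(1), 1)))
  }
  head <- kv(lines[blocks == 0])
  subs <- lapply(split(lines[blocks > 0], blocks[blocks > 0]), function(ls) {
    f <- kv(ls)
    subunit(f[["kind"]],
            as.numeric(strsplit(f[["dims"]], "\\s+")[[1]]),
            contrast = as.numeric(f[["contrast"]]),
            com = as.numeric(strsplit(f[["com"]], "\\s+")[[1]]))
  })
  modelSpec(unname(subs),
            excludeOverlap = toupper(head[["exclude_overlap"]]) %in%
              c("TRUE", "YES", "1"),
            nPoints = as.integer(head[["n_points"]]),
            seed = as.integer(head[["seed"]]))
}

#' Assemble a run configuration
#'
#' @param models a [ModelSpec-class] or list of one or two.
#' @param qMin,qMax q-grid limits in 1/Angstrom (defaults 0.001, 0.5).
#' @param nQ number of linearly spaced grid points (default 400).
#' @param sigmaPoly relative polydispersity (default 0).
#' @param sigmaR interface roughness, Angstrom (default 0).
#' @param sf a [StructureFactorParams-class] (default none).
#' @param noiseScale noise scale s (default 1).
#' @param seed run seed (default 1).
#' @param outDir output directory.
#' @param offset plot offset for model 2 (default 100).
#' @return a [RunConfig-class].
#' @export
runConfig <- function(models, qMin = 0.001, qMax = 0.5, nQ = 400L,
                      sigmaPoly = 0, sigmaR = 0,
                      sf = structureFactorParams(), noiseScale = 1,
                      seed = 1L, outDir = ".", offset = 100) {
  if (is(models, "ModelSpec")) models <- list(models)
  new("RunConfig", models = models, qMin = qMin, qMax = qMax,
      nQ = as.integer(nQ), sigmaPoly = sigmaPoly, sigmaR = sigmaR, sf = sf,
      noiseScale = noiseScale, seed = as.integer(seed), outDir = outDir,
      offset = offset)
}

#' Run the full simulation pipeline
#'
#' For each model: builds the point cloud, computes the pair distribution
#' (polydisperse if requested), transforms to P(q), applies the structure
#' factor (with the decoupling factor computed from the monodisperse cloud)
#' and roughness, simulates noisy data, and writes
#' \code{model<k>_pr.dat}, \code{model<k>_Iq.dat}, \code{model<k>_Isim.dat},
#' \code{model<k>.pdb} (plus \code{model<k>_Seff.dat} when a structure
#' factor is active) and projection/comparison plots to the output
#' directory. Rg, Dmax and per-subunit point counts are logged to
#' \code{run.log}. Model k uses build seed \code{seed + k - 1} and noise
#' seed \code{seed + 100 + k}, so a config is fully reproducible from its
#' seed.
#'
#' @param config a [RunConfig-class].
#' @param plots also write PDF plots (default TRUE).
#' @return invisibly, a list with one entry per model (cloud, pd, curve,
#'   sim, rg, dmax, files) plus the log path.
#' @export
runSimulation <- function(config, plots = TRUE) {
  validObject(config)
  dir.create(config@outDir, showWarnings = FALSE, recursive = TRUE)
  q <- seq(config@qMin, config@qMax, length.out = config@nQ)
  log <- c("saxsim run",
           sprintf("seed: %d", config@seed),
           sprintf("q grid: %s to %s 1/A, %d points", .fmt(config@qMin),
                   .fmt(config@qMax), config@nQ),
           sprintf("sigma_poly: %s  sigma_R: %s A  noise scale: %s",
                   .fmt(config@sigmaPoly), .fmt(config@sigmaR),
                   .fmt(config@noiseScale)),
           sprintf("structure factor: %s", config@sf@kind))
  out <- list()
  for (k in seq_along(config@models)) {
    spec <- config@models[[k]]
    pre <- file.path(config@outDir, sprintf("model%d", k))
    res <- tryCatch({
      cloud <- buildModel(spec, seed = config@seed + k - 1L)
      pdMono <- pairDistribution(cloud)
      pd <- if (config@sigmaPoly > 0)
        pairDistribution(cloud, sigmaPoly = config@sigmaPoly) else pdMono
      curve <- scatteringIntensity(pd, q)
      if (config@sf@kind != "none") {
        S <- .evalSF(config@sf, q)
        beta <- decouplingBeta(cloud, q, pd = pdMono)
        curve <- applyStructureFactor(curve, S, beta)
      }
      curve <- applyRoughness(curve, config@sigmaR)
      sim <- simulateData(curve, noiseScale = config@noiseScale,
                          seed = config@seed + 100L + k)
      files <- c(pr = writePr(pd, paste0(pre, "_pr.dat")),
                 Iq = writeIq(curve, paste0(pre, "_Iq.dat")),
                 Isim = writeSimulatedData(sim, paste0(pre, "_Isim.dat")),
                 pdb = writePDB(cloud, paste0(pre, ".pdb")))
      if (config@sf@kind != "none")
        files <- c(files,
                   Seff = writeIq(curve, paste0(pre, "_Seff.dat"), "Seff"))
      if (plots) {
        grDevices::pdf(paste0(pre, "_projections.pdf"), width = 9,
                       height = 3.2)
        plotProjections(cloud,
                        main = sprintf("model %d point projections", k))
        grDevices::dev.off()
      }
      list(cloud = cloud, pd = pd, curve = curve, sim = sim,
           rg = radiusOfGyration(pd), dmax = dMax(pd), files = files)
    }, error = function(e)
      .stopf("model %d: %s", k, conditionMessage(e)))
    counts <- table(factor(res$cloud@subunitIndex,
                           levels = seq_along(spec@subunits)))
    log <- c(log,
             sprintf("model %d: %d points (per subunit: %s)", k,
                     nrow(res$cloud@positions),
                     paste(as.integer(counts), collapse = ", ")),
             sprintf("model %d: Rg = %s A, Dmax = %s A", k, .fmt(res$rg),
                     .fmt(res$dmax)))
    out[[k]] <- res
  }
  if (plots) {
    grDevices::pdf(file.path(config@outDir, "comparison.pdf"), width = 9,
                   height = 4)
    plotComparison(out, offset = config@offset)
    grDevices::dev.off()
  }
  logPath <- file.path(config@outDir, "run.log")
  .writeLines2(log, logPath)
  invisible(c(out, list(log = logPath)))
}

#' 2-D projections of a point cloud
#'
#' Three scatter panels (xy, xz, yz) colored by contrast sign (red:
#' positive, green: negative, grey: zero).
#'
#' @param cloud a [PointCloud-class].
#' @param main overall title.
#' @param cex point size (default 0.2).
#' @return invisibly, NULL.
#' @export
plotProjections <- function(cloud, main = "point projections", cex = 0.2) {
  pos <- cloud@positions
  col <- ifelse(cloud@weights > 0, "red3",
                ifelse(cloud@weights < 0, "green4", "grey50"))
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 3, 1))
  on.exit(graphics::par(op))
  panes <- list(c(1, 2, "x", "y"), c(1, 3, "x", "z"), c(2, 3, "y", "z"))
  for (p in panes)
    graphics::plot(pos[, as.integer(p[1])], pos[, as.integer(p[2])],
                   col = col, pch = 16, cex = cex, asp = 1,
                   xlab = paste0(p[3], " [A]"), ylab = paste0(p[4], " [A]"),
                   main = main)
  invisible(NULL)
}

#' Overlay plot of p(r) and simulated intensities for one or two models
#'
#' Model 2's intensity is multiplied by \code{offset} (default 100) so the
#' two curves separate on the log scale.
#'
#' @param results list of per-model results as returned by
#'   [runSimulation()].
#' @param offset multiplicative plot offset for model 2.
#' @return invisibly, NULL.
#' @export
plotComparison <- function(results, offset = 100) {
  results <- Filter(function(r) is.list(r) && !is.null(r$pd), results)
  cols <- c("red3", "blue3")
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 3, 1))
  on.exit(graphics::par(op))
  graphics::plot(NA, xlim = c(0, max(vapply(results, function(r)
    dMax(r$pd), numeric(1)))), ylim = c(0, 1), xlab = "r [A]",
    ylab = "p(r)", main = "pair distance distributions")
  for (k in seq_along(results)) {
    tab <- prTable(results[[k]]$pd)
    graphics::lines(tab$r, tab$p, col = cols[k])
  }
  sims <- lapply(results, `[[`, "sim")
  fac <- c(1, offset)
  ypos <- unlist(lapply(seq_along(sims), function(k)
    sims[[k]]@Isim[sims[[k]]@Isim > 0] * fac[k]))
  graphics::plot(NA, xlim = range(sims[[1]]@q), log = "xy",
                 ylim = range(ypos), xlab = "q [1/A]", ylab = "I(q)",
                 main = "simulated intensities")
  for (k in seq_along(sims)) {
    keep <- sims[[k]]@Isim > 0
    graphics::points(sims[[k]]@q[keep], sims[[k]]@Isim[keep] * fac[k],
                     col = cols[k], pch = 16, cex = 0.3)
  }
  invisible(NULL)
}
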