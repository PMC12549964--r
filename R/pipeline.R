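## Orchestration: deterministic seed splitting, footprint-set simulation,
## run configuration and the end-to-end pipeline.

#' Derive a child seed from a master seed and counters
#'
#' Counter-based affine splitting: starting from the master seed, each
#' counter index k folds in as s <- (s * 48271 + k + 1) mod 2147483629.
#' Deterministic and collision-sparse for the counter ranges used here;
#' every stochastic stage of the pipeline obtains its seed this way, so
#' runs are reproducible stage by stage.
#'
#' @param master integer master seed.
#' @param ... integer counters identifying the stage (any number).
#' @return integer child seed in [0, 2147483628].
#' @export
deriveSeed <- function(master, ...) {
  s <- as.numeric(master) %% 2147483629
  for (k in c(...)) {
    s <- (s * 48271 + as.numeric(k) + 1) %% 2147483629
  }
  as.integer(s)
}

#' Simulate a set of oriented explosion footprints
#'
#' The reference sampling scheme: \code{nSimulations} independent
#' explosion realizations of one structure (each with fresh Gaussian
#' coordinate jitter emulating structural heterogeneity and a fresh
#' stochastic charge assignment), and \code{patternsPerSimulation}
#' Haar-uniform orientations per realization, each yielding one footprint
#' (total patterns = nSimulations x patternsPerSimulation). Additionally
#' one identity-orientation footprint per realization is returned for
#' reproducibility-variance analysis.
#'
#' @param cloud an \linkS4class{AtomCloud} (uncharged template).
#' @param nSimulations explosion realizations (default 100).
#' @param patternsPerSimulation orientations per realization (default 100).
#' @param meanIonization mean charges per atom (default 1.2).
#' @param pulse a \linkS4class{PulseModel}.
#' @param geom a \linkS4class{DetectorGeometry}.
#' @param jitterSigma per-realization coordinate jitter, Angstrom
#'   (default 0.3; 0 disables).
#' @param dt,maxTime,softening integrator settings, see
#'   \code{\link{simulateExplosion}}.
#' @param seed master seed; child seeds are derived per stage via
#'   \code{\link{deriveSeed}}.
#' @return list with \code{footprints} (length nSimulations x
#'   patternsPerSimulation), \code{fixedOrientation} (one
#'   identity-orientation footprint per realization) and \code{ejecta}
#'   (the per-realization \linkS4class{IonEjecta}).
#' @export
simulateFootprints <- function(cloud, nSimulations = 100L,
                               patternsPerSimulation = 100L,
                               meanIonization = 1.2,
                               pulse = pulseModel(),
                               geom = detectorGeometry(),
                               jitterSigma = 0.3,
                               dt = 0.5, maxTime = 250, softening = 0.1,
                               seed = 1L) {
  stopifnot(nSimulations >= 1L, patternsPerSimulation >= 1L)
  footprints <- vector("list", nSimulations * patternsPerSimulation)
  fixed <- vector("list", nSimulations)
  ejectas <- vector("list", nSimulations)
  for (s in seq_len(nSimulations)) {
    jSeed <- deriveSeed(seed, 1L, s)
    cSeed <- deriveSeed(seed, 2L, s)
    oSeed <- deriveSeed(seed, 3L, s)
    cl <- if (jitterSigma > 0) jitterCloud(cloud, jitterSigma, seed = jSeed)
          else cloud
    cl <- assignCharges(cl, pulse = pulse, meanIonization = meanIonization,
                        seed = cSeed)
    ej <- simulateExplosion(cl, dt = dt, maxTime = maxTime,
                            softening = softening, realizationSeed = cSeed)
    ejectas[[s]] <- ej
    fixed[[s]] <- projectToDetectors(ej, geom)
    qs <- sampleUniformRotations(patternsPerSimulation, seed = oSeed)
    for (p in seq_len(patternsPerSimulation)) {
      footprints[[(s - 1L) * patternsPerSimulation + p]] <-
        projectToDetectors(ej, geom, orientation = qs[p, ])
    }
  }
  list(footprints = footprints, fixedOrientation = fixed, ejecta = ejectas)
}

#' Thin a footprint set by detector efficiency
#'
#' Applies independent binomial thinning to every footprint with child
#' seeds derived from \code{seed}.
#'
#' @param footprints list of \linkS4class{Footprint}s.
#' @param eff efficiency in [0, 1].
#' @param seed master seed.
#' @return list of thinned footprints.
#' @export
thinFootprints <- function(footprints, eff, seed = 1L) {
  lapply(seq_along(footprints), function(k)
    applyEfficiency(footprints[[k]], eff,
                    seed = deriveSeed(seed, 4L, k)))
}

#' Construct a pipeline run configuration
#'
#' Defaults follow the reference workflow: 100 simulations x 100 patterns,
#' mean ionization 1.2, efficiencies 0.3/0.6/1.0, blur sigma 0.5 px,
#' 100 envelope bins. Either a PDB path or a synthetic-cloud atom count
#' defines the structure source.
#'
#' @param pdbPath PDB file, or NA to synthesize.
#' @param nAtoms synthetic-cloud size (used when pdbPath is NA).
#' @param nSimulations explosion realizations.
#' @param patternsPerSimulation orientations per realization.
#' @param meanIonization mean charges per atom.
#' @param efficiencies detector efficiency levels.
#' @param blurSigma blur before distances, pixels.
#' @param envelopeBins envelope bin count.
#' @param jitterSigma structural-heterogeneity jitter, Angstrom.
#' @param masterSeed master seed.
#' @param outputDir artifact directory.
#' @return named list of class "runConfig".
#' @export
runConfig <- function(pdbPath = NA_character_, nAtoms = 800L,
                      nSimulations = 100L, patternsPerSimulation = 100L,
                      meanIonization = 1.2,
                      efficiencies = c(0.3, 0.6, 1.0),
                      blurSigma = 0.5, envelopeBins = 100L,
                      jitterSigma = 0.3, masterSeed = 1L,
                      outputDir = "ionfootprint-run") {
  cfg <- list(pdbPath = pdbPath, nAtoms = as.integer(nAtoms),
              nSimulations = as.integer(nSimulations),
              patternsPerSimulation = as.integer(patternsPerSimulation),
              meanIonization = meanIonization,
              efficiencies = efficiencies, blurSigma = blurSigma,
              envelopeBins = as.integer(envelopeBins),
              jitterSigma = jitterSigma,
              masterSeed = as.integer(masterSeed), outputDir = outputDir)
  class(cfg) <- c("runConfig", "list")
  cfg
}

#' Write a run configuration as YAML
#' @param config a \code{\link{runConfig}}.
#' @param path output file.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a run configuration from YAML
#' @param path YAML file; missing keys take the \code{\link{runConfig}}
#'   defaults.
#' @return a \code{\link{runConfig}}.
#' @export
readRunConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(runConfig, vals[names(vals) %in% names(formals(runConfig))])
}

#' Run the end-to-end orientation-retrieval pipeline
#'
#' Loads or synthesizes the structure, simulates the footprint set, runs
#' the cutoff analysis at each configured detector efficiency, computes
#' the fixed-orientation reproducibility variance, and writes JSON
#' reports, the footprint container and a manifest (config, seeds,
#' package version, config hash) under the output directory.
#' Deterministic given the master seed.
#'
#' @param config a \code{\link{runConfig}}.
#' @param writeFootprintSets also serialize the full footprint set
#'   (can be large; default FALSE).
#' @return invisibly, a list with \code{cutoffReports} (one per
#'   efficiency), \code{varianceReport} and \code{manifest}.
#' @export
runPipeline <- function(config, writeFootprintSets = FALSE) {
  stopifnot(inherits(config, "runConfig"))
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  cloud <- if (!is.na(config$pdbPath)) readPDB(config$pdbPath)
           else synthesizeCloud(config$nAtoms,
                                seed = deriveSeed(config$masterSeed, 0L),
                                label = sprintf("synthetic-%d",
                                                config$nAtoms))
  sim <- simulateFootprints(
    cloud,
    nSimulations = config$nSimulations,
    patternsPerSimulation = config$patternsPerSimulation,
    meanIonization = config$meanIonization,
    jitterSigma = config$jitterSigma,
    seed = deriveSeed(config$masterSeed, 10L))
  reports <- lapply(seq_along(config$efficiencies), function(k) {
    eff <- config$efficiencies[k]
    fps <- if (eff >= 1) sim$footprints
           else thinFootprints(sim$footprints, eff,
                               seed = deriveSeed(config$masterSeed, 20L, k))
    cutoffAnalysis(fps, nBins = config$envelopeBins,
                   blurSigma = config$blurSigma, efficiency = eff)
  })
  varRep <- if (config$nSimulations >= 2L)
    patternVariance(sim$fixedOrientation) else NULL
  cfgPath <- file.path(config$outputDir, "config.yaml")
  writeRunConfig(config, cfgPath)
  manifest <- list(
    package = "ionFootprint",
    version = as.character(utils::packageVersion("ionFootprint")),
    configHash = unname(tools::md5sum(cfgPath)),
    masterSeed = config$masterSeed,
    stageSeeds = list(
      synthesis = deriveSeed(config$masterSeed, 0L),
      simulation = deriveSeed(config$masterSeed, 10L),
      thinning = vapply(seq_along(config$efficiencies), function(k)
        deriveSeed(config$masterSeed, 20L, k), integer(1))),
    structure = sourceLabel(cloud),
    nAtoms = nAtoms(cloud))
  writeReports(reports, file.path(config$outputDir, "cutoff_reports.json"))
  if (!is.null(varRep))
    jsonlite::write_json(list(
      protein_variance = varRep@proteinVariance,
      K = varRep@K,
      mean_detected_ions = varRep@meanDetectedIons,
      label = varRep@sourceLabel),
      file.path(config$outputDir, "variance_report.json"),
      digits = NA, auto_unbox = TRUE)
  jsonlite::write_json(manifest, file.path(config$outputDir,
                                           "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  if (writeFootprintSets)
    writeFootprints(sim$footprints,
                    file.path(config$outputDir, "footprints.json"))
  invisible(list(cutoffReports = reports, varianceReport = varRep,
                 manifest = manifest))
}
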