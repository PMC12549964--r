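# Shared fixtures, built in code.

# a Footprint object straight from a count matrix (bypasses the detector)
makeFootprint <- function(counts, orientation = c(1, 0, 0, 0),
                          efficiency = 1, label = "fixture") {
  counts <- matrix(as.integer(counts), nrow(counts), ncol(counts))
  new("Footprint", counts = counts, orientation = orientation,
      efficiency = efficiency, nDetected = sum(counts),
      sourceLabel = label)
}

# ejecta with prescribed directions (unit-normalized), unit speeds/masses
makeEjecta <- function(directions, label = "fixture") {
  directions <- as.matrix(directions)
  directions <- directions / sqrt(rowSums(directions^2))
  n <- nrow(directions)
  new("IonEjecta", directions = directions, speeds = rep(1e4, n),
      charges = rep(1L, n), masses = rep(1, n), sourceLabel = label,
      realizationSeed = NA_integer_)
}

# isotropic unit directions
isotropicDirections <- function(n, seed) {
  set.seed(seed)
  v <- matrix(rnorm(3 * n), ncol = 3)
  v / sqrt(rowSums(v^2))
}

# quaternion for a rotation by `angle` about `axis`
axisAngleQuat <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  c(cos(angle / 2), sin(angle / 2) * axis)
}

# minimal valid PDB text for a handful of atoms
writeTinyPDB <- function(path, coords, elements, resid = "ALA") {
  lines <- vapply(seq_len(nrow(coords)), function(i) {
    sprintf("ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            i, elements[i], resid, 1,
            coords[i, 1], coords[i, 2], coords[i, 3], 1, 0,
            elements[i])
  }, character(1))
  writeLines(c(lines, "END"), path)
  path
}

# two-ion cloud for the closed-form explosion oracle
twoIonCloud <- function(d = 2) {
  suppressWarnings(atomCloud(rbind(c(-d / 2, 0, 0), c(d / 2, 0, 0)),
                             c(1L, 1L), charges = c(1L, 1L),
                             label = "two-ion"))
}

kCoulombInternal <- 14.3996 / 103.6426966

# cache for simulation products shared between acceptance blocks
.simCache <- new.env(parent = emptyenv())

cachedEndToEndSim <- function() {
  if (is.null(.simCache$e2e)) {
    cl <- suppressWarnings(
      synthesizeCloud(3000, seed = 101, label = "synth3000"))
    .simCache$e2e <- simulateFootprints(
      cl, nSimulations = 50, patternsPerSimulation = 20, seed = 202)
  }
  .simCache$e2e
}
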