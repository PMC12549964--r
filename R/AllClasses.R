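#' @import methods
NULL

## Central S4 containers. Quaternions are stored as plain numeric vectors
## (w, x, y, z) or n x 4 matrices rather than wrapped objects: rotation
## sampling and pairwise-angle computation are hot paths over 1e5+ draws.

#' AtomCloud: an exploding object
#'
#' Atomic positions (Angstrom), element identities (atomic number Z),
#' masses (amu) and per-atom integer charges (elementary charges; 0 before
#' ionization). The center of mass is translated to the origin on
#' construction; the origin is the explosion and detector origin.
#'
#' @slot positions numeric N x 3 matrix, Angstrom.
#' @slot elements integer vector of atomic numbers.
#' @slot masses numeric vector, atomic mass units.
#' @slot charges integer vector, elementary charges.
#' @slot label character(1) structure identifier.
#'
#' @exportClass AtomCloud
setClass("AtomCloud",
  representation(
    positions = "matrix",
    elements  = "integer",
    masses    = "numeric",
    charges   = "integer",
    label     = "character"
  )
)

setValidity("AtomCloud", function(object) {
  n <- nrow(object@positions)
  msg <- character()
  if (ncol(object@positions) != 3L)
    msg <- c(msg, "positions must be an N x 3 matrix")
  if (length(object@elements) != n || length(object@masses) != n ||
      length(object@charges) != n)
    msg <- c(msg, "elements, masses and charges must match nrow(positions)")
  if (any(object@elements < 1L))
    msg <- c(msg, "atomic numbers must be >= 1")
  if (any(object@charges < 0L))
    msg <- c(msg, "charges must be non-negative")
  if (any(object@charges > object@elements))
    msg <- c(msg, "charge cannot exceed the element's electron count")
  if (n > 0) {
    com <- colSums(object@positions * object@masses) / sum(object@masses)
    if (max(abs(com)) > 1e-6)
      msg <- c(msg, "center of mass must lie at the origin")
  }
  if (length(msg)) msg else TRUE
})

#' PulseModel: XFEL pulse parameters
#'
#' Gaussian temporal envelope of the ionizing pulse. Defaults follow the
#' simulated experiment: fluence 5e6 photons/nm^2, photon energy 2 keV,
#' peak at 20 fs, FWHM 10 fs. In the sudden-ionization stand-in only the
#' fluence enters the computation (it scales the expected ionization);
#' the temporal parameters are retained as experiment metadata.
#'
#' @slot fluence photons per nm^2.
#' @slot photonEnergy keV.
#' @slot peakTime fs.
#' @slot fwhm fs.
#'
#' @exportClass PulseModel
setClass("PulseModel",
  representation(
    fluence = "numeric", photonEnergy = "numeric",
    peakTime = "numeric", fwhm = "numeric"
  ),
  prototype(fluence = 5e6, photonEnergy = 2, peakTime = 20, fwhm = 10)
)

setValidity("PulseModel", function(object) {
  if (object@fluence <= 0) return("fluence must be positive")
  if (object@fwhm <= 0) return("fwhm must be positive")
  TRUE
})

#' IonEjecta: asymptotic ion states after an explosion
#'
#' Unit ejection directions and asymptotic speeds of the ions once Coulomb
#' repulsion has effectively ceased and trajectories are straight lines.
#'
#' @slot directions numeric N x 3 matrix of unit vectors.
#' @slot speeds numeric vector, m/s.
#' @slot charges integer vector, elementary charges.
#' @slot masses numeric vector, amu.
#' @slot sourceLabel character(1) identifier of the exploded structure.
#' @slot realizationSeed integer seed of the charge-assignment realization
#'   (NA when charges were assigned without a seed).
#'
#' @exportClass IonEjecta
setClass("IonEjecta",
  representation(
    directions = "matrix",
    speeds = "numeric",
    charges = "integer",
    masses = "numeric",
    sourceLabel = "character",
    realizationSeed = "integer"
  )
)

setValidity("IonEjecta", function(object) {
  n <- nrow(object@directions)
  msg <- character()
  if (ncol(object@directions) != 3L)
    msg <- c(msg, "directions must be an N x 3 matrix")
  if (n > 0) {
    nrm <- sqrt(rowSums(object@directions^2))
    if (max(abs(nrm - 1)) > 1e-9)
      msg <- c(msg, "directions must be unit vectors")
  }
  if (length(object@speeds) != n || length(object@charges) != n ||
      length(object@masses) != n)
    msg <- c(msg, "speeds, charges and masses must match nrow(directions)")
  if (any(object@speeds < 0))
    msg <- c(msg, "speeds must be non-negative")
  if (length(msg)) msg else TRUE
})

#' DetectorGeometry: two-panel virtual ion detector
#'
#' Two flat square detectors of side \code{sideLength} mm, placed
#' \code{distance} mm from the explosion origin on opposite sides along the
#' normal axis, each binned into an n x n pixel grid. Defaults reproduce the
#' simulated setup: 120 mm side, 30 mm distance, 18 x 18 pixels (pitch
#' 120/18 = 6.67 mm).
#'
#' @slot sideLength mm.
#' @slot distance mm.
#' @slot nPixelsSide integer, pixels per side.
#' @slot normalAxis "x", "y" or "z" (lab frame; default z).
#'
#' @exportClass DetectorGeometry
setClass("DetectorGeometry",
  representation(
    sideLength = "numeric", distance = "numeric",
    nPixelsSide = "integer", normalAxis = "character"
  ),
  prototype(sideLength = 120, distance = 30, nPixelsSide = 18L,
            normalAxis = "z")
)

setValidity("DetectorGeometry", function(object) {
  msg <- character()
  if (object@sideLength <= 0) msg <- c(msg, "sideLength must be positive")
  if (object@distance <= 0) msg <- c(msg, "distance must be positive")
  if (object@nPixelsSide < 1L) msg <- c(msg, "nPixelsSide must be >= 1")
  if (!object@normalAxis %in% c("x", "y", "z"))
    msg <- c(msg, "normalAxis must be one of 'x', 'y', 'z'")
  if (length(msg)) msg else TRUE
})

#' Footprint: stacked two-panel explosion footprint
#'
#' Raw integer ion counts on the two detector panels, stacked front panel on
#' top into a (2n x n) matrix. Carries the ground-truth orientation of the
#' source at exposure (a unit quaternion) and the detector efficiency that
#' produced it. Blurred views are plain float matrices, kept distinct from
#' the raw counts.
#'
#' @slot counts integer (2n x n) matrix of pixel counts.
#' @slot orientation numeric(4) unit quaternion (w, x, y, z).
#' @slot efficiency numeric in [0, 1].
#' @slot nDetected integer, total registered ions (= sum(counts)).
#' @slot sourceLabel character(1).
#'
#' @exportClass Footprint
setClass("Footprint",
  representation(
    counts = "matrix",
    orientation = "numeric",
    efficiency = "numeric",
    nDetected = "integer",
    sourceLabel = "character"
  )
)

setValidity("Footprint", function(object) {
  msg <- character()
  if (nrow(object@counts) != 2L * ncol(object@counts))
    msg <- c(msg, "counts must have shape (2n x n)")
  if (any(object@counts < 0) || any(object@counts != round(object@counts)))
    msg <- c(msg, "counts must be non-negative integers")
  if (sum(object@counts) != object@nDetected)
    msg <- c(msg, "nDetected must equal sum(counts)")
  if (length(object@orientation) != 4L ||
      abs(sqrt(sum(object@orientation^2)) - 1) > 1e-9)
    msg <- c(msg, "orientation must be a unit quaternion (w, x, y, z)")
  if (object@efficiency < 0 || object@efficiency > 1)
    msg <- c(msg, "efficiency must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' OrientationDistanceMap: pairwise footprint distance vs relative angle
#'
#' All N(N-1)/2 pairs (i < j) of a set of oriented footprints, each pair
#' carrying the pixel-space Euclidean distance d between the two footprints
#' and the ground-truth relative orientation angle theta in [0, pi].
#'
#' @slot pairs data.frame with columns i, j, d, theta.
#' @slot N integer, number of footprints.
#' @slot blurSigma numeric, Gaussian blur (pixels) applied before distances
#'   (NA when distances were computed on raw counts).
#' @slot sourceLabel character(1).
#'
#' @exportClass OrientationDistanceMap
setClass("OrientationDistanceMap",
  representation(
    pairs = "data.frame",
    N = "integer",
    blurSigma = "numeric",
    sourceLabel = "character"
  )
)

setValidity("OrientationDistanceMap", function(object) {
  msg <- character()
  if (!all(c("i", "j", "d", "theta") %in% names(object@pairs)))
    msg <- c(msg, "pairs must have columns i, j, d, theta")
  if (nrow(object@pairs) != object@N * (object@N - 1L) / 2L)
    msg <- c(msg, "pairs must contain exactly N(N-1)/2 rows")
  if (nrow(object@pairs)) {
    if (any(object@pairs$d < 0)) msg <- c(msg, "distances must be >= 0")
    if (any(object@pairs$theta < -1e-12 | object@pairs$theta > pi + 1e-12))
      msg <- c(msg, "theta must lie in [0, pi]")
  }
  if (length(msg)) msg else TRUE
})

#' EnvelopeCurve: upper envelope of the orientation-distance scatter
#'
#' The distance axis is split into uniform bins; for each occupied bin the
#' envelope value f is the maximum relative angle among its pairs.
#' Unoccupied bins carry no value.
#'
#' @slot binEdges numeric(nBins + 1).
#' @slot binCenters numeric, centers of the OCCUPIED bins (ascending).
#' @slot fValues numeric, max theta per occupied bin, in [0, pi].
#'
#' @exportClass EnvelopeCurve
setClass("EnvelopeCurve",
  representation(
    binEdges = "numeric",
    binCenters = "numeric",
    fValues = "numeric"
  )
)

setValidity("EnvelopeCurve", function(object) {
  msg <- character()
  if (length(object@binCenters) != length(object@fValues))
    msg <- c(msg, "binCenters and fValues must have equal length")
  if (length(object@fValues) &&
      any(object@fValues < 0 | object@fValues > pi + 1e-12))
    msg <- c(msg, "envelope values must lie in [0, pi]")
  if (is.unsorted(object@binCenters))
    msg <- c(msg, "binCenters must be ascending")
  if (length(msg)) msg else TRUE
})

#' CutoffReport: under-cutoff orientation statistics
#'
#' @slot xCutoff numeric distance cutoff.
#' @slot meanAngleUnder numeric mean relative angle of pairs with
#'   d <= xCutoff (NA when no pair qualifies).
#' @slot nPairsUnder integer count of qualifying pairs.
#' @slot nPairsTotal integer total pairs in the map.
#' @slot efficiency numeric detector efficiency of the underlying set
#'   (NA when not applicable).
#' @slot sourceLabel character(1).
#' @slot valid logical, FALSE for degenerate inputs (e.g. efficiency 0).
#'
#' @exportClass CutoffReport
setClass("CutoffReport",
  representation(
    xCutoff = "numeric",
    meanAngleUnder = "numeric",
    nPairsUnder = "integer",
    nPairsTotal = "integer",
    efficiency = "numeric",
    sourceLabel = "character",
    valid = "logical"
  ),
  prototype(valid = TRUE, efficiency = NA_real_)
)

#' VarianceReport: explosion-reproducibility variance
#'
#' Per-pixel population variance of intensity-normalized fixed-orientation
#' footprints, and their average (the per-protein variance).
#'
#' @slot perPixelVariance numeric matrix matching the footprint shape.
#' @slot proteinVariance numeric(1), mean of the per-pixel variances.
#' @slot K integer, number of footprints used.
#' @slot meanDetectedIons numeric(1).
#' @slot sourceLabel character(1).
#'
#' @exportClass VarianceReport
setClass("VarianceReport",
  representation(
    perPixelVariance = "matrix",
    proteinVariance = "numeric",
    K = "integer",
    meanDetectedIons = "numeric",
    sourceLabel = "character"
  )
)

setValidity("VarianceReport", function(object) {
  msg <- character()
  if (any(object@perPixelVariance < 0))
    msg <- c(msg, "variances must be non-negative")
  if (abs(object@proteinVariance - mean(object@perPixelVariance)) >
      1e-12 * max(1, object@proteinVariance))
    msg <- c(msg, "proteinVariance must equal the mean per-pixel variance")
  if (length(msg)) msg else TRUE
})

## show methods ------------------------------------------------------------

setMethod("show", "AtomCloud", function(object) {
  cat(sprintf("AtomCloud '%s': %d atoms, total charge %+d e\n",
              object@label, nrow(object@positions), sum(object@charges)))
  tb <- table(elementSymbol(object@elements))
  cat("  composition:",
      paste(sprintf("%s=%d", names(tb), as.integer(tb)), collapse = " "),
      "\n")
})

setMethod("show", "IonEjecta", function(object) {
  cat(sprintf("IonEjecta from '%s': %d ions, median speed %.3g m/s\n",
              object@sourceLabel, nrow(object@directions),
              stats::median(object@speeds)))
})

setMethod("show", "Footprint", function(object) {
  n <- ncol(object@counts)
  cat(sprintf(
    "Footprint '%s': (%d x %d) stacked panels, %d ions detected, efficiency %.2f\n",
    object@sourceLabel, 2L * n, n, object@nDetected, object@efficiency))
})

setMethod("show", "OrientationDistanceMap", function(object) {
  cat(sprintf(
    "OrientationDistanceMap '%s': N = %d footprints, %d pairs%s\n",
    object@sourceLabel, object@N, nrow(object@pairs),
    if (is.na(object@blurSigma)) " (raw counts)"
    else sprintf(" (blur sigma = %.2g px)", object@blurSigma)))
})

setMethod("show", "EnvelopeCurve", function(object) {
  cat(sprintf("EnvelopeCurve: %d occupied of %d bins, f in [%.3g, %.3g]\n",
              length(object@fValues), length(object@binEdges) - 1L,
              min(object@fValues), max(object@fValues)))
})

setMethod("show", "CutoffReport", function(object) {
  cat(sprintf(
    "CutoffReport '%s': cutoff %.4g, %d/%d pairs under, mean angle %.4g rad%s\n",
    object@sourceLabel, object@xCutoff, object@nPairsUnder,
    object@nPairsTotal, object@meanAngleUnder,
    if (object@valid) "" else " [INVALID]"))
})

setMethod("show", "VarianceReport", function(object) {
  cat(sprintf(
    "VarianceReport '%s': K = %d footprints, sigma_p^2 = %.4g, mean detected ions %.1f\n",
    object@sourceLabel, object@K, object@proteinVariance,
    object@meanDetectedIons))
})
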