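## Accessor generics. Slot access from user code goes through these.

#' Number of atoms or ions
#' @param x an AtomCloud or IonEjecta.
#' @return integer count.
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @describeIn nAtoms atoms in a cloud
#' @export
setMethod("nAtoms", "AtomCloud", function(x) nrow(x@positions))

#' Atomic positions
#' @param x an AtomCloud.
#' @return N x 3 matrix, Angstrom.
#' @export
setGeneric("atomPositions", function(x) standardGeneric("atomPositions"))

#' @describeIn atomPositions positions of a cloud
#' @export
setMethod("atomPositions", "AtomCloud", function(x) x@positions)

#' Atomic numbers
#' @param x an AtomCloud.
#' @return integer vector of Z.
#' @export
setGeneric("atomElements", function(x) standardGeneric("atomElements"))

#' @describeIn atomElements elements of a cloud
#' @export
setMethod("atomElements", "AtomCloud", function(x) x@elements)

#' Per-particle charges
#' @param x an AtomCloud or IonEjecta.
#' @return integer vector, elementary charges.
#' @export
setGeneric("charges", function(x) standardGeneric("charges"))

#' @describeIn charges charges of a cloud
#' @export
setMethod("charges", "AtomCloud", function(x) x@charges)

#' @describeIn charges charges of the ejected ions
#' @export
setMethod("charges", "IonEjecta", function(x) x@charges)

#' Per-particle masses
#' @param x an AtomCloud or IonEjecta.
#' @return numeric vector, amu.
#' @export
setGeneric("masses", function(x) standardGeneric("masses"))

#' @describeIn masses masses of a cloud
#' @export
setMethod("masses", "AtomCloud", function(x) x@masses)

#' @describeIn masses masses of the ejected ions
#' @export
setMethod("masses", "IonEjecta", function(x) x@masses)

#' Structure label
#' @param x an object carrying a source identifier.
#' @return character(1).
#' @export
setGeneric("sourceLabel", function(x) standardGeneric("sourceLabel"))

#' @describeIn sourceLabel label of a cloud
#' @export
setMethod("sourceLabel", "AtomCloud", function(x) x@label)

#' @describeIn sourceLabel source of the ejecta
#' @export
setMethod("sourceLabel", "IonEjecta", function(x) x@sourceLabel)

#' @describeIn sourceLabel source of a footprint
#' @export
setMethod("sourceLabel", "Footprint", function(x) x@sourceLabel)

#' Ejection directions
#' @param x an IonEjecta.
#' @return N x 3 matrix of unit vectors.
#' @export
setGeneric("ionDirections", function(x) standardGeneric("ionDirections"))

#' @describeIn ionDirections directions of the ejected ions
#' @export
setMethod("ionDirections", "IonEjecta", function(x) x@directions)

#' Asymptotic ion speeds
#' @param x an IonEjecta.
#' @return numeric vector, m/s.
#' @export
setGeneric("ionSpeeds", function(x) standardGeneric("ionSpeeds"))

#' @describeIn ionSpeeds speeds of the ejected ions
#' @export
setMethod("ionSpeeds", "IonEjecta", function(x) x@speeds)

#' Footprint pixel counts
#' @param x a Footprint.
#' @return integer (2n x n) matrix.
#' @export
setGeneric("footprintCounts", function(x) standardGeneric("footprintCounts"))

#' @describeIn footprintCounts raw counts of a footprint
#' @export
setMethod("footprintCounts", "Footprint", function(x) x@counts)

#' Ground-truth orientation of a footprint
#' @param x a Footprint.
#' @return numeric(4) unit quaternion (w, x, y, z).
#' @export
setGeneric("orientation", function(x) standardGeneric("orientation"))

#' @describeIn orientation orientation quaternion of a footprint
#' @export
setMethod("orientation", "Footprint", function(x) x@orientation)

#' Detector efficiency of a footprint or report
#' @param x a Footprint or CutoffReport.
#' @return numeric(1) in [0, 1].
#' @export
setGeneric("efficiency", function(x) standardGeneric("efficiency"))

#' @describeIn efficiency efficiency applied to a footprint
#' @export
setMethod("efficiency", "Footprint", function(x) x@efficiency)

#' @describeIn efficiency efficiency of the set a report summarizes
#' @export
setMethod("efficiency", "CutoffReport", function(x) x@efficiency)

#' Number of detected ions
#' @param x a Footprint.
#' @return integer(1).
#' @export
setGeneric("nDetected", function(x) standardGeneric("nDetected"))

#' @describeIn nDetected detected ions of a footprint
#' @export
setMethod("nDetected", "Footprint", function(x) x@nDetected)

#' Pairwise (distance, angle) table
#' @param x an OrientationDistanceMap.
#' @return data.frame with columns i, j, d, theta.
#' @export
setGeneric("pairTable", function(x) standardGeneric("pairTable"))

#' @describeIn pairTable pairs of a map
#' @export
setMethod("pairTable", "OrientationDistanceMap", function(x) x@pairs)

#' Envelope values
#' @param x an EnvelopeCurve.
#' @return data.frame with occupied bin centers and f values.
#' @export
setGeneric("envelopeTable", function(x) standardGeneric("envelopeTable"))

#' @describeIn envelopeTable occupied-bin envelope of a curve
#' @export
setMethod("envelopeTable", "EnvelopeCurve",
          function(x) data.frame(x = x@binCenters, f = x@fValues))

#' Distance cutoff of a report
#' @param x a CutoffReport.
#' @return numeric(1).
#' @export
setGeneric("xCutoff", function(x) standardGeneric("xCutoff"))

#' @describeIn xCutoff cutoff of a report
#' @export
setMethod("xCutoff", "CutoffReport", function(x) x@xCutoff)

#' Mean relative angle under the cutoff
#' @param x a CutoffReport.
#' @return numeric(1) radians; NA when no pair is under the cutoff.
#' @export
setGeneric("meanAngleUnder", function(x) standardGeneric("meanAngleUnder"))

#' @describeIn meanAngleUnder under-cutoff mean angle of a report
#' @export
setMethod("meanAngleUnder", "CutoffReport", function(x) x@meanAngleUnder)

#' Number of pairs under the cutoff
#' @param x a CutoffReport.
#' @return integer(1).
#' @export
setGeneric("nPairsUnder", function(x) standardGeneric("nPairsUnder"))

#' @describeIn nPairsUnder under-cutoff pair count of a report
#' @export
setMethod("nPairsUnder", "CutoffReport", function(x) x@nPairsUnder)

#' Per-protein variance (mean per-pixel variance)
#' @param x a VarianceReport.
#' @return numeric(1).
#' @export
setGeneric("proteinVariance", function(x) standardGeneric("proteinVariance"))

#' @describeIn proteinVariance scalar variance of a report
#' @export
setMethod("proteinVariance", "VarianceReport", function(x) x@proteinVariance)

#' Per-pixel variance grid
#' @param x a VarianceReport.
#' @return numeric matrix matching the footprint shape.
#' @export
setGeneric("perPixelVariance",
           function(x) standardGeneric("perPixelVariance"))

#' @describeIn perPixelVariance variance grid of a report
#' @export
setMethod("perPixelVariance", "VarianceReport",
          function(x) x@perPixelVariance)
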