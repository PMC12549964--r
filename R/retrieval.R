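## Core analysis: pixel-space footprint distances, orientation-distance
## maps, the upper-envelope distance cutoff and under-cutoff statistics.

## pull a comparable image out of a Footprint or blurred matrix,
## remembering its preprocessing state
.imageState <- function(x) {
  if (is(x, "Footprint"))
    list(img = x@counts, sigma = NA_real_)
  else if (is.matrix(x))
    list(img = x, sigma = attr(x, "blurSigma") %||% NA_real_)
  else stop("expected a Footprint or a blurred image matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Euclidean footprint distance in pixel space
#'
#' d(A, B) = sqrt(sum_i (A_i - B_i)^2) over all pixels of the stacked
#' image. Computed on raw counts, not normalized images. Both inputs must
#' be in the same preprocessing state: both raw footprints, or both
#' blurred with the same sigma.
#'
#' @param A,B \linkS4class{Footprint}s, or blurred image matrices from
#'   \code{\link{gaussianBlur}}.
#' @return numeric(1) distance, >= 0; symmetric; d(A, A) = 0.
#' @export
footprintDistance <- function(A, B) {
  a <- .imageState(A); b <- .imageState(B)
  if (!identical(dim(a$img), dim(b$img)))
    stop("footprints have different shapes")
  if (!identical(is.na(a$sigma), is.na(b$sigma)) ||
      (!is.na(a$sigma) && a$sigma != b$sigma))
    stop("cannot mix raw and blurred footprints (or different blur sigmas)")
  sqrt(sum((as.numeric(a$img) - as.numeric(b$img))^2))
}

#' Build an orientation-distance map from oriented footprints
#'
#' Computes, for every pair i < j of footprints, the pixel-space distance
#' d (optionally after per-panel Gaussian blur) and the ground-truth
#' relative orientation angle theta from the stored quaternions; N
#' footprints yield exactly N(N-1)/2 pairs.
#'
#' @param footprints list of \linkS4class{Footprint}s (>= 2), all from the
#'   same source unless \code{allowMixedSources}.
#' @param blurSigma Gaussian blur in pixels applied before distances
#'   (default 0.5, for robustness against small spatial offsets); NA or
#'   NULL computes distances on raw counts.
#' @param allowMixedSources permit footprints with different source labels.
#' @return an \linkS4class{OrientationDistanceMap}.
#' @export
buildOrientationDistanceMap <- function(footprints, blurSigma = 0.5,
                                        allowMixedSources = FALSE) {
  N <- length(footprints)
  if (N < 2L) stop("need at least 2 footprints")
  labels <- vapply(footprints, sourceLabel, character(1))
  if (!allowMixedSources && length(unique(labels)) > 1L)
    stop("footprints come from mixed sources: ",
         paste(unique(labels), collapse = ", "),
         " (set allowMixedSources = TRUE to override)")
  useBlur <- !is.null(blurSigma) && !is.na(blurSigma) && blurSigma > 0
  imgs <- t(vapply(footprints, function(fp) {
    as.numeric(if (useBlur) gaussianBlur(fp, blurSigma) else fp@counts)
  }, numeric(length(footprints[[1]]@counts))))
  D <- as.matrix(stats::dist(imgs))
  Q <- t(vapply(footprints, orientation, numeric(4)))
  TH <- 2 * acos(pmin(abs(tcrossprod(Q)), 1))
  idx <- which(upper.tri(D), arr.ind = TRUE)
  pairs <- data.frame(i = idx[, 1], j = idx[, 2],
                      d = D[idx], theta = TH[idx])
  new("OrientationDistanceMap", pairs = pairs, N = as.integer(N),
      blurSigma = if (useBlur) blurSigma else NA_real_,
      sourceLabel = labels[1])
}

#' Upper envelope of the orientation-distance scatter
#'
#' The distance axis is split into \code{nBins} uniform bins spanning
#' [min d, max d]; for each occupied bin the envelope value is the maximum
#' relative angle among its pairs. Unoccupied bins carry no value.
#'
#' The population envelope is non-decreasing in distance until it
#' saturates at pi, so by default the estimator enforces that shape
#' constraint: each occupied bin carries the running maximum over all
#' occupied bins up to and including it (one-sided isotonic regression).
#' This suppresses the spurious derivative maxima that single-pair bins
#' in the distance tails otherwise produce at moderate sample sizes;
#' \code{monotone = FALSE} gives the plain per-bin maximum.
#'
#' @param map an \linkS4class{OrientationDistanceMap} (or a data.frame
#'   with columns d, theta).
#' @param nBins number of distance bins (default 100).
#' @param monotone enforce the non-decreasing shape constraint
#'   (default TRUE).
#' @return an \linkS4class{EnvelopeCurve}.
#' @export
upperEnvelope <- function(map, nBins = 100L, monotone = TRUE) {
  if (nBins < 2L) stop("nBins must be >= 2")
  pairs <- if (is(map, "OrientationDistanceMap")) map@pairs else map
  if (nrow(pairs) < 1L) stop("need at least 1 pair")
  d <- pairs$d; theta <- pairs$theta
  lo <- min(d); hi <- max(d)
  if (hi == lo) {
    ## all pairs at one distance: single-point envelope
    return(new("EnvelopeCurve", binEdges = c(lo, hi),
               binCenters = lo, fValues = max(theta)))
  }
  edges <- seq(lo, hi, length.out = nBins + 1L)
  bin <- findInterval(d, edges, rightmost.closed = TRUE)
  fmax <- tapply(theta, bin, max)
  occ <- as.integer(names(fmax))
  centers <- (edges[occ] + edges[occ + 1L]) / 2
  o <- order(centers)
  f <- as.numeric(fmax)[o]
  if (monotone) f <- cummax(f)
  new("EnvelopeCurve", binEdges = edges,
      binCenters = centers[o], fValues = f)
}

#' Distance cutoff from the envelope's steepest rise
#'
#' The derivative of the envelope f is estimated by forward differences
#' between consecutive occupied bin centers (robust to unoccupied gaps);
#' the cutoff is the bin center at which that slope is maximal, ties
#' broken toward the smaller distance.
#'
#' @param env an \linkS4class{EnvelopeCurve} with >= 3 occupied bins.
#' @return numeric(1) distance cutoff.
#' @export
distanceCutoff <- function(env) {
  x <- env@binCenters; f <- env@fValues
  if (length(x) < 3L)
    stop("envelope too sparse: need at least 3 occupied bins")
  slope <- diff(f) / diff(x)
  k <- which.max(slope)  # first maximum: ties go to the smaller distance
  x[k]
}

#' Orientation statistics of the pairs under a distance cutoff
#'
#' @param map an \linkS4class{OrientationDistanceMap}.
#' @param xCutoff distance cutoff; pairs with d <= xCutoff qualify.
#' @param efficiency detector efficiency of the underlying footprint set,
#'   recorded in the report (default NA).
#' @return a \linkS4class{CutoffReport}; when no pair qualifies the count
#'   is 0 and the mean angle is NA.
#' @export
underCutoffStats <- function(map, xCutoff, efficiency = NA_real_) {
  stopifnot(is.numeric(xCutoff), length(xCutoff) == 1L)
  under <- map@pairs$d <= xCutoff
  nUnder <- sum(under)
  new("CutoffReport",
      xCutoff = xCutoff,
      meanAngleUnder = if (nUnder) mean(map@pairs$theta[under])
                       else NA_real_,
      nPairsUnder = as.integer(nUnder),
      nPairsTotal = nrow(map@pairs),
      efficiency = efficiency,
      sourceLabel = map@sourceLabel,
      valid = TRUE)
}

#' Full cutoff analysis of one footprint set
#'
#' Convenience composition: orientation-distance map, upper envelope,
#' distance cutoff, under-cutoff statistics. Degenerate sets (all-zero
#' footprints, or an envelope too sparse for a cutoff) yield a report
#' flagged invalid rather than an error.
#'
#' @param footprints list of oriented \linkS4class{Footprint}s.
#' @param nBins envelope bins (default 100).
#' @param blurSigma blur before distances (default 0.5; NA for raw).
#' @param efficiency efficiency recorded in the report; by default taken
#'   from the footprints.
#' @param monotone shape-constrained envelope (see
#'   \code{\link{upperEnvelope}}; default TRUE).
#' @return a \linkS4class{CutoffReport}.
#' @export
cutoffAnalysis <- function(footprints, nBins = 100L, blurSigma = 0.5,
                           efficiency = NULL, monotone = TRUE) {
  if (is.null(efficiency))
    efficiency <- footprints[[1]]@efficiency
  invalid <- function(msg) {
    rep <- new("CutoffReport", xCutoff = NA_real_,
               meanAngleUnder = NA_real_, nPairsUnder = 0L,
               nPairsTotal = (length(footprints) *
                 (length(footprints) - 1L)) %/% 2L,
               efficiency = efficiency,
               sourceLabel = sourceLabel(footprints[[1]]), valid = FALSE)
    attr(rep, "reason") <- msg
    rep
  }
  if (all(vapply(footprints, function(fp) fp@nDetected == 0L, logical(1))))
    return(invalid("all footprints are empty (zero detected ions)"))
  map <- buildOrientationDistanceMap(footprints, blurSigma = blurSigma)
  tryCatch({
    env <- upperEnvelope(map, nBins, monotone = monotone)
    xc <- distanceCutoff(env)
    underCutoffStats(map, xc, efficiency = efficiency)
  }, error = function(e) invalid(conditionMessage(e)))
}

#' Cutoff analysis across detector efficiencies
#'
#' Runs the full cutoff analysis on one footprint set per efficiency
#' level, enabling the efficiency-trend comparisons (tighter angular
#' restraint and more matched pairs as more ions are registered).
#'
#' @param footprintSets list of footprint lists, one per efficiency; all
#'   from the same source.
#' @param nBins envelope bins (default 100).
#' @param blurSigma blur before distances (default 0.5).
#' @return list of \linkS4class{CutoffReport}s, one per set.
#' @export
efficiencySweep <- function(footprintSets, nBins = 100L, blurSigma = 0.5) {
  stopifnot(length(footprintSets) >= 1L)
  labels <- vapply(footprintSets,
                   function(s) sourceLabel(s[[1]]), character(1))
  if (length(unique(labels)) > 1L)
    stop("footprint sets come from different sources")
  lapply(footprintSets, cutoffAnalysis,
         nBins = nBins, blurSigma = blurSigma)
}
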