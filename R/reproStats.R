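## Explosion-reproducibility variance of fixed-orientation footprints and
## the fluence-robustness difference metric.

#' Normalize a footprint by its total intensity
#'
#' @param fp a \linkS4class{Footprint} or count matrix with positive total.
#' @return float matrix of the same shape summing to 1.
#' @export
normalizeImage <- function(fp) {
  img <- if (is(fp, "Footprint")) fp@counts else as.matrix(fp)
  tot <- sum(img)
  if (tot <= 0) stop("cannot normalize a zero-intensity footprint")
  img / tot
}

#' Explosion-reproducibility variance of fixed-orientation footprints
#'
#' Each footprint is normalized by its total intensity; the per-pixel
#' population variance (divisor K) around the per-pixel mean is computed,
#' then averaged over pixels to a single per-protein variance. Zero
#' intensity footprints are excluded with a warning. All footprints must
#' share one orientation and one source: this is an intra-protein,
#' fixed-orientation statistic.
#'
#' @param footprints list of K >= 2 \linkS4class{Footprint}s at identical
#'   orientation from one source.
#' @return a \linkS4class{VarianceReport}.
#' @export
patternVariance <- function(footprints) {
  if (length(footprints) < 2L) stop("need K >= 2 footprints")
  q0 <- orientation(footprints[[1]])
  sameOri <- vapply(footprints, function(fp) {
    isTRUE(all.equal(orientation(fp), q0, tolerance = 1e-12)) ||
      isTRUE(all.equal(orientation(fp), -q0, tolerance = 1e-12))
  }, logical(1))
  if (!all(sameOri))
    stop("footprints have mixed orientations; pattern variance is a fixed-orientation statistic")
  labels <- vapply(footprints, sourceLabel, character(1))
  if (length(unique(labels)) > 1L)
    stop("footprints come from mixed sources")
  empty <- vapply(footprints, function(fp) fp@nDetected == 0L, logical(1))
  if (any(empty)) {
    warning(sum(empty), " zero-intensity footprint(s) excluded from the variance")
    footprints <- footprints[!empty]
    if (length(footprints) < 2L)
      stop("fewer than 2 non-empty footprints remain")
  }
  K <- length(footprints)
  shape <- dim(footprints[[1]]@counts)
  stack <- vapply(footprints, function(fp) normalizeImage(fp),
                  matrix(0, shape[1], shape[2]))
  mu <- apply(stack, c(1, 2), mean)
  perPixel <- apply(stack, c(1, 2), function(v) mean((v - mean(v))^2))
  new("VarianceReport",
      perPixelVariance = perPixel,
      proteinVariance = mean(perPixel),
      K = as.integer(K),
      meanDetectedIons = mean(vapply(footprints, nDetected, integer(1))),
      sourceLabel = labels[1])
}

#' Fluence-robustness comparison of two footprint sets
#'
#' Compares the per-pixel mean raw-count images of two sets of
#' fixed-orientation footprints (e.g. at two pulse fluences): difference
#' map mean(A) - mean(B), its summed absolute error and the mean absolute
#' error per pixel of the stacked image. Raw counts are used (the metric
#' is in ion counts), not normalized images.
#'
#' @param setA,setB lists of \linkS4class{Footprint}s at one common
#'   orientation and geometry.
#' @return list with \code{meanA}, \code{meanB}, \code{differenceMap},
#'   \code{summedAbsError} and \code{meanAbsErrorPerPixel}.
#' @export
fluenceRobustness <- function(setA, setB) {
  if (!length(setA) || !length(setB)) stop("both sets must be non-empty")
  shape <- dim(setA[[1]]@counts)
  meanOf <- function(set) {
    if (!all(vapply(set, function(fp) identical(dim(fp@counts), shape),
                    logical(1))))
      stop("footprint shapes differ between the sets")
    Reduce(`+`, lapply(set, function(fp) fp@counts)) / length(set)
  }
  mA <- meanOf(setA); mB <- meanOf(setB)
  diffMap <- mA - mB
  sae <- sum(abs(diffMap))
  list(meanA = mA, meanB = mB, differenceMap = diffMap,
       summedAbsError = sae,
       meanAbsErrorPerPixel = sae / length(diffMap))
}
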