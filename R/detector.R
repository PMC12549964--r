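## Two-panel virtual ion detector: ray projection of asymptotic ion
## directions, pixel binning, binomial efficiency thinning and per-panel
## Gaussian blur.

#' Construct a detector geometry
#'
#' @param sideLength panel side, mm (default 120).
#' @param distance origin-to-panel distance, mm (default 30).
#' @param nPixelsSide pixels per side (default 18; pixel pitch 120/18 mm).
#' @param normalAxis lab axis of the panel normals: "x", "y" or "z"
#'   (default "z").
#' @return a \linkS4class{DetectorGeometry}.
#' @export
detectorGeometry <- function(sideLength = 120, distance = 30,
                             nPixelsSide = 18L, normalAxis = "z") {
  new("DetectorGeometry", sideLength = sideLength, distance = distance,
      nPixelsSide = as.integer(nPixelsSide), normalAxis = normalAxis)
}

## in-plane axes (u, v) for each normal axis, right-handed
.planeAxes <- function(normalAxis) {
  switch(normalAxis,
         z = c(1L, 2L, 3L),  # u = x, v = y, normal = z
         x = c(2L, 3L, 1L),  # u = y, v = z, normal = x
         y = c(3L, 1L, 2L))  # u = z, v = x, normal = y
}

#' Project ion ejecta onto the two detector panels
#'
#' Each unit direction is rotated by \code{orientation} (emulating the
#' random orientation of the source at exposure), then ray-cast from the
#' origin. Rays with positive component along the normal intersect the
#' front panel (at +distance), negative the back panel (at -distance);
#' rays parallel to the panels within 1e-12 are discarded. The
#' intersection is binned into the panel's n x n grid with half-open
#' intervals per axis (the single top/right edge belongs to the last
#' cell); hits outside the square are discarded. The two panel images are
#' stacked front-on-top into a (2n x n) matrix; the back panel keeps the
#' in-plane coordinates as seen from the origin (no mirroring). An exactly
#' on-axis ray lands in the cell with 0-based index (n/2, n/2) for even n.
#'
#' @param ejecta an \linkS4class{IonEjecta}.
#' @param geom a \linkS4class{DetectorGeometry}.
#' @param orientation numeric(4) unit quaternion; default identity.
#' @return a \linkS4class{Footprint} with efficiency 1. The number of
#'   discarded ions is available as \code{attr(fp, "nDiscarded")}.
#' @export
projectToDetectors <- function(ejecta, geom = detectorGeometry(),
                               orientation = c(1, 0, 0, 0)) {
  assertUnitQuat(orientation)
  n <- geom@nPixelsSide
  half <- geom@sideLength / 2
  pitch <- geom@sideLength / n
  dirs <- quatRotate(ejecta@directions, orientation)
  ax <- .planeAxes(geom@normalAxis)
  du <- dirs[, ax[1]]; dv <- dirs[, ax[2]]; dn <- dirs[, ax[3]]
  counts <- matrix(0L, 2L * n, n)
  nIons <- nrow(dirs)
  live <- abs(dn) >= 1e-12
  if (any(live)) {
    t <- geom@distance / abs(dn[live])
    u <- du[live] * t
    v <- dv[live] * t
    front <- dn[live] > 0
    inside <- u >= -half & u <= half & v >= -half & v <= half
    iu <- floor((u + half) / pitch)
    iv <- floor((v + half) / pitch)
    iu[iu == n] <- n - 1L  # top/right edge joins the last cell
    iv[iv == n] <- n - 1L
    hit <- inside & iu >= 0 & iu < n & iv >= 0 & iv < n
    row <- iv[hit] + 1L + ifelse(front[hit], 0L, n)
    col <- iu[hit] + 1L
    if (length(row)) {
      counts <- matrix(tabulate(row + 2L * n * (col - 1L),
                                nbins = 2L * n * n), 2L * n, n)
    }
  }
  fp <- new("Footprint", counts = counts,
            orientation = as.numeric(orientation),
            efficiency = 1.0, nDetected = sum(counts),
            sourceLabel = ejecta@sourceLabel)
  attr(fp, "nDiscarded") <- nIons - sum(counts)
  fp
}

#' Thin a footprint by detector efficiency
#'
#' Each recorded count is independently kept with probability
#' \code{efficiency} (binomial thinning per pixel), modelling the
#' probability that an ion hitting the detector is registered.
#'
#' @param fp a raw \linkS4class{Footprint}.
#' @param efficiency keep probability in [0, 1].
#' @param seed integer seed.
#' @return the thinned \linkS4class{Footprint}; its efficiency slot is
#'   multiplied by \code{efficiency}.
#' @export
applyEfficiency <- function(fp, efficiency, seed = NULL) {
  if (!is.numeric(efficiency) || efficiency < 0 || efficiency > 1)
    stop("efficiency must lie in [0, 1]")
  cnt <- fp@counts
  if (efficiency < 1) {
    kept <- withSeed(seed,
      stats::rbinom(length(cnt), as.vector(cnt), efficiency))
    cnt <- matrix(as.integer(kept), nrow(cnt), ncol(cnt))
  }
  out <- fp
  out@counts <- cnt
  out@nDetected <- sum(cnt)
  out@efficiency <- fp@efficiency * efficiency
  out
}

## direct 2D convolution with zero padding (panels are small: n x n)
.convolve2zero <- function(img, kernel) {
  r <- (nrow(kernel) - 1L) %/% 2L
  nr <- nrow(img); nc <- ncol(img)
  pad <- matrix(0, nr + 2L * r, nc + 2L * r)
  pad[r + seq_len(nr), r + seq_len(nc)] <- img
  out <- matrix(0, nr, nc)
  for (i in seq_len(2L * r + 1L)) {
    for (j in seq_len(2L * r + 1L)) {
      k <- kernel[i, j]
      if (k == 0) next
      out <- out + k * pad[(i - 1L) + seq_len(nr), (j - 1L) + seq_len(nc)]
    }
  }
  out
}

#' Gaussian-blur a footprint, per panel
#'
#' Convolution with a 2D Gaussian kernel (truncated at 4 sigma and
#' renormalized to unit sum), applied to each panel separately: the two
#' panels are physically distinct detectors, so blur never leaks across
#' the stack boundary. Boundary mode is constant-zero padding (panels have
#' hard edges); total intensity is preserved for counts away from the
#' panel edges.
#'
#' @param fp a \linkS4class{Footprint}, or a (2n x n) numeric matrix.
#' @param sigma blur width in pixels (default 0.5); 0 returns the image
#'   unchanged.
#' @return float (2n x n) matrix carrying attribute \code{blurSigma}.
#' @export
gaussianBlur <- function(fp, sigma = 0.5) {
  stopifnot(sigma >= 0)
  img <- if (is(fp, "Footprint")) fp@counts else as.matrix(fp)
  img <- matrix(as.numeric(img), nrow(img), ncol(img))
  n <- ncol(img)
  if (nrow(img) != 2L * n)
    stop("expected a stacked (2n x n) footprint image")
  if (sigma > 0) {
    r <- max(1L, as.integer(ceiling(4 * sigma)))
    g <- stats::dnorm(seq(-r, r), sd = sigma)
    kernel <- outer(g, g)
    kernel <- kernel / sum(kernel)
    img <- rbind(
      .convolve2zero(img[seq_len(n), , drop = FALSE], kernel),
      .convolve2zero(img[n + seq_len(n), , drop = FALSE], kernel))
  }
  attr(img, "blurSigma") <- sigma
  img
}
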