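test_that("footprint distance equals the elementwise brute-force norm", {
  set.seed(10)
  A <- makeFootprint(matrix(rpois(648, 2), 36, 18))
  B <- makeFootprint(matrix(rpois(648, 2), 36, 18))
  brute <- sqrt(sum(vapply(seq_len(648), function(i)
    (footprintCounts(A)[i] - footprintCounts(B)[i])^2, numeric(1))))
  expect_equal(footprintDistance(A, B), brute, tolerance = 1e-12)
  expect_equal(footprintDistance(A, A), 0)
  expect_equal(footprintDistance(A, B), footprintDistance(B, A))
  # single-pixel difference of 3 counts
  C <- footprintCounts(A); C[5, 5] <- C[5, 5] + 3L
  expect_equal(footprintDistance(A, makeFootprint(C)), 3)
})

test_that("mixed preprocessing states and shapes are rejected", {
  A <- makeFootprint(matrix(1L, 36, 18))
  B <- makeFootprint(matrix(1L, 20, 10))
  expect_error(footprintDistance(A, B), "shape")
  expect_error(footprintDistance(A, gaussianBlur(A, 0.5)), "mix")
  expect_error(footprintDistance(gaussianBlur(A, 0.5),
                                 gaussianBlur(A, 1.0)), "mix")
  expect_equal(footprintDistance(gaussianBlur(A, 0.5),
                                 gaussianBlur(A, 0.5)), 0)
})

test_that("orientation-distance maps enumerate all N(N-1)/2 pairs", {
  set.seed(20)
  mk <- function(q) makeFootprint(matrix(rpois(648, 1), 36, 18),
                                  orientation = q)
  qs <- sampleUniformRotations(100, seed = 21)
  fps <- lapply(seq_len(100), function(k) mk(qs[k, ]))
  map <- buildOrientationDistanceMap(fps, blurSigma = NA)
  expect_equal(nrow(pairTable(map)), 4950L)
  expect_equal(map@N, 100L)
  two <- buildOrientationDistanceMap(fps[1:2], blurSigma = NA)
  expect_equal(nrow(pairTable(two)), 1L)
  # theta agrees with the pairwise relative angle of the stored rotations
  expect_equal(pairTable(two)$theta, relativeAngle(qs[1, ], qs[2, ]),
               tolerance = 1e-9)
})

test_that("replicated identical footprints give an all-zero map", {
  fp <- makeFootprint(matrix(rpois(648, 1), 36, 18),
                      orientation = quaternion(1, 0, 0, 0))
  map <- buildOrientationDistanceMap(list(fp, fp, fp), blurSigma = NA)
  expect_true(all(pairTable(map)$d == 0))
  expect_true(all(pairTable(map)$theta == 0))
})

test_that("maps refuse footprints from mixed sources unless allowed", {
  a <- makeFootprint(matrix(1L, 36, 18), label = "a")
  b <- makeFootprint(matrix(2L, 36, 18), label = "b")
  expect_error(buildOrientationDistanceMap(list(a, b)), "mixed sources")
  map <- buildOrientationDistanceMap(list(a, b), allowMixedSources = TRUE)
  expect_equal(nrow(pairTable(map)), 1L)
})

test_that("upper envelope recovers hand-placed per-bin maxima", {
  # distances fixed at bin centers of [0, 10] with 5 bins; theta chosen so
  # each occupied bin's max is known
  d <- c(1, 1, 3, 3, 9, 9)
  theta <- c(0.2, 0.7, 1.1, 0.4, 3.0, 2.5)
  map <- data.frame(d = d, theta = theta)
  env <- upperEnvelope(map, nBins = 5, monotone = FALSE)
  expect_equal(envelopeTable(env)$f, c(0.7, 1.1, 3.0))
  # bins 3 and 4 are unoccupied and carry no value
  expect_equal(length(env@fValues), 3L)
  expect_true(all(env@fValues <= pi))
  expect_error(upperEnvelope(map, nBins = 1), ">= 2")
  # default shape constraint: running maximum over occupied bins
  dip <- data.frame(d = c(1, 3, 9), theta = c(2.0, 1.0, 3.0))
  expect_equal(upperEnvelope(dip, nBins = 5, monotone = FALSE)@fValues,
               c(2.0, 1.0, 3.0))
  expect_equal(upperEnvelope(dip, nBins = 5)@fValues, c(2.0, 2.0, 3.0))
})

test_that("degenerate envelopes collapse to a single point", {
  map <- data.frame(d = rep(2, 5), theta = c(0.1, 0.5, 0.3, 0.2, 0.4))
  env <- upperEnvelope(map, nBins = 10)
  expect_equal(env@binCenters, 2)
  expect_equal(env@fValues, 0.5)
})

test_that("distance cutoff sits at the envelope's steepest rise", {
  # step envelope: low plateau then jump -> cutoff at the jump's left bin
  d <- c(0.5, 1.5, 2.5, 3.5, 4.5, 5.5)
  theta <- c(0.2, 0.2, 0.2, 3.0, 3.0, 3.0)
  env <- upperEnvelope(data.frame(d = d, theta = theta), nBins = 6)
  centers <- envelopeTable(env)$x
  expect_equal(distanceCutoff(env), centers[3])
  # strictly linear envelope (exact-arithmetic grid): tie broken toward
  # the smallest distance
  envLin <- upperEnvelope(
    data.frame(d = c(0, 1, 2, 3, 4),
               theta = c(0.25, 0.5, 0.75, 1.0, 1.0)), nBins = 4)
  expect_equal(distanceCutoff(envLin), envelopeTable(envLin)$x[1])
  sparse <- upperEnvelope(data.frame(d = c(1, 2), theta = c(1, 2)),
                          nBins = 2)
  expect_error(distanceCutoff(sparse), "sparse")
})

test_that("under-cutoff statistics filter and average exactly", {
  qs <- sampleUniformRotations(3, seed = 30)
  map <- new("OrientationDistanceMap",
             pairs = data.frame(i = c(1L, 1L, 2L), j = c(2L, 3L, 3L),
                                d = c(1, 2, 3), theta = c(0.1, 0.5, 3.0)),
             N = 3L, blurSigma = NA_real_, sourceLabel = "hand")
  rep2 <- underCutoffStats(map, 2)
  expect_equal(nPairsUnder(rep2), 2L)
  expect_equal(meanAngleUnder(rep2), 0.3)
  repLow <- underCutoffStats(map, 0.5)
  expect_equal(nPairsUnder(repLow), 0L)
  expect_true(is.na(meanAngleUnder(repLow)))
  repAll <- underCutoffStats(map, 10)
  expect_equal(nPairsUnder(repAll), 3L)
  expect_equal(repAll@nPairsTotal, 3L)
})

test_that("under-cutoff mean of random orientations saturates near 2.21 rad", {
  set.seed(40)
  qs <- sampleUniformRotations(500, seed = 41)
  fps <- lapply(seq_len(500), function(k)
    makeFootprint(matrix(rpois(648, 1), 36, 18), orientation = qs[k, ]))
  map <- buildOrientationDistanceMap(fps, blurSigma = NA)
  repAll <- underCutoffStats(map, max(pairTable(map)$d) + 1)
  expect_equal(meanAngleUnder(repAll), pi / 2 + 2 / pi, tolerance = 0.03)
})

test_that("footprint distance is continuous in the orientation difference", {
  cl <- synthesizeCloud(800, seed = 45)
  cl <- assignCharges(cl, seed = 46)
  ej <- simulateExplosion(cl)
  base <- gaussianBlur(projectToDetectors(ej), 0.5)
  dists <- vapply(c(0.05, 0.1), function(ang) {
    fp <- projectToDetectors(ej, orientation = axisAngleQuat(c(0, 0, 1),
                                                             ang))
    footprintDistance(base, gaussianBlur(fp, 0.5))
  }, numeric(1))
  d0 <- footprintDistance(base, gaussianBlur(projectToDetectors(ej), 0.5))
  expect_equal(d0, 0)
  expect_true(dists[1] <= dists[2])
})

test_that("cutoff analysis flags degenerate inputs instead of failing", {
  empty <- lapply(1:4, function(k)
    makeFootprint(matrix(0L, 36, 18),
                  orientation = sampleUniformRotations(1, seed = k)[1, ]))
  rep <- cutoffAnalysis(empty)
  expect_false(rep@valid)
  expect_equal(nPairsUnder(rep), 0L)
})
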