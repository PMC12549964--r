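test_that("on-axis and corner rays bin per the documented conventions", {
  geom <- detectorGeometry()
  # straight up the normal: front panel, cell (n/2, n/2) 0-based
  fp <- projectToDetectors(makeEjecta(rbind(c(0, 0, 1))), geom)
  expect_equal(nDetected(fp), 1L)
  expect_equal(footprintCounts(fp)[10, 10], 1L)
  # straight down: same cell on the back panel (rows n+1..2n)
  fpB <- projectToDetectors(makeEjecta(rbind(c(0, 0, -1))), geom)
  expect_equal(footprintCounts(fpB)[28, 10], 1L)
  # panel-diagonal ray at arctan(60/30) off-normal lands exactly on the
  # corner; the top/right edge belongs to the last cell
  fpC <- projectToDetectors(makeEjecta(rbind(c(60, 60, 30))), geom)
  expect_equal(footprintCounts(fpC)[18, 18], 1L)
  # just beyond the edge is discarded
  fpD <- projectToDetectors(makeEjecta(rbind(c(60.01, 60, 30))), geom)
  expect_equal(nDetected(fpD), 0L)
  # ray parallel to the panels is discarded
  fpE <- projectToDetectors(makeEjecta(rbind(c(1, 0, 0))), geom)
  expect_equal(nDetected(fpE), 0L)
})

test_that("counts are conserved: detected + discarded = ejected", {
  ej <- makeEjecta(isotropicDirections(5000, seed = 1))
  fp <- projectToDetectors(ej)
  expect_equal(nDetected(fp) + attr(fp, "nDiscarded"), 5000L)
  expect_equal(sum(footprintCounts(fp)), nDetected(fp))
})

test_that("detected fraction matches the analytic square solid angle", {
  ej <- makeEjecta(isotropicDirections(1e6, seed = 2))
  fp <- projectToDetectors(ej)
  a <- 60; dd <- 30
  omega <- 4 * atan(a^2 / (dd * sqrt(dd^2 + 2 * a^2)))
  analytic <- 2 * omega / (4 * pi)
  expect_equal(nDetected(fp) / 1e6, analytic, tolerance = 0.005)
})

test_that("projection is rotation-equivariant, bit-exact", {
  ej <- makeEjecta(isotropicDirections(2000, seed = 3))
  q <- sampleUniformRotations(1, seed = 4)[1, ]
  viaOrientation <- projectToDetectors(ej, orientation = q)
  viaRotation <- projectToDetectors(rotateEjecta(ej, q))
  expect_identical(footprintCounts(viaOrientation),
                   footprintCounts(viaRotation))
})

test_that("efficiency thinning is binomial, deterministic and bounded", {
  ej <- makeEjecta(isotropicDirections(2000, seed = 5))
  fp <- projectToDetectors(ej)
  expect_identical(footprintCounts(applyEfficiency(fp, 1.0, seed = 1)),
                   footprintCounts(fp))
  expect_equal(nDetected(applyEfficiency(fp, 0.0, seed = 1)), 0L)
  expect_identical(footprintCounts(applyEfficiency(fp, 0.3, seed = 9)),
                   footprintCounts(applyEfficiency(fp, 0.3, seed = 9)))
  tot <- vapply(1:200, function(s)
    nDetected(applyEfficiency(fp, 0.3, seed = s)), integer(1))
  expect_equal(mean(tot), 0.3 * nDetected(fp),
               tolerance = 10 / (0.3 * nDetected(fp)))
  expect_error(applyEfficiency(fp, 1.2), "0, 1")
})

test_that("gaussian blur preserves interior intensity and panel separation", {
  n <- 18L
  img <- matrix(0L, 2L * n, n)
  img[9, 9] <- 1L  # central count, front panel
  fp <- makeFootprint(img)
  bl <- gaussianBlur(fp, 0.5)
  expect_equal(sum(bl), 1, tolerance = 1e-9)
  # symmetric kernel around the source pixel
  expect_equal(bl[8, 9], bl[10, 9])
  expect_equal(bl[9, 8], bl[9, 10])
  # sigma 0 leaves the image unchanged
  b0 <- gaussianBlur(fp, 0)
  expect_equal(unname(b0[,]), unname(matrix(as.numeric(img), 2L * n, n)))
  # a count on the front panel's last row must not leak onto the back panel
  edge <- matrix(0L, 2L * n, n)
  edge[n, 9] <- 1L
  be <- gaussianBlur(makeFootprint(edge), 0.5)
  expect_true(all(be[(n + 1L):(2L * n), ] == 0))
  expect_lt(sum(be), 1)  # intensity clipped at the hard panel edge
})

test_that("degenerate geometries and empty ejecta are handled", {
  expect_error(detectorGeometry(sideLength = -1), "positive")
  expect_error(detectorGeometry(nPixelsSide = 0), ">= 1")
  ej <- makeEjecta(matrix(numeric(0), 0, 3))
  fp <- projectToDetectors(ej)
  expect_equal(nDetected(fp), 0L)
})
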