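test_that("uniform rotation sampling is reproducible and unit-norm", {
  q1 <- sampleUniformRotations(100, seed = 42)
  q2 <- sampleUniformRotations(100, seed = 42)
  expect_identical(q1, q2)
  expect_equal(rowSums(q1^2), rep(1, 100), tolerance = 1e-12)
  expect_false(identical(q1, sampleUniformRotations(100, seed = 43)))
})

test_that("sampling does not disturb the caller's RNG stream", {
  set.seed(7); before <- rnorm(1)
  set.seed(7); invisible(sampleUniformRotations(10, seed = 99))
  expect_identical(rnorm(1), before)
})

test_that("relative angle matches the rotation-matrix trace oracle", {
  qi <- sampleUniformRotations(1000, seed = 1)
  qj <- sampleUniformRotations(1000, seed = 2)
  theta <- relativeAngle(qi, qj)
  oracle <- vapply(seq_len(1000), function(k) {
    Mi <- quatToMatrix(qi[k, ]); Mj <- quatToMatrix(qj[k, ])
    acos(pmin(1, pmax(-1, (sum(diag(crossprod(Mi, Mj))) - 1) / 2)))
  }, numeric(1))
  expect_equal(theta, oracle, tolerance = 1e-9)
})

test_that("relative angle handles identity, quarter turns and sign flips", {
  I <- quaternion(1, 0, 0, 0)
  expect_equal(relativeAngle(I, I), 0)
  qz <- axisAngleQuat(c(0, 0, 1), pi / 2)
  expect_equal(relativeAngle(I, qz), pi / 2, tolerance = 1e-12)
  # q and -q are the same rotation
  expect_equal(relativeAngle(I, -qz), pi / 2, tolerance = 1e-12)
  # symmetry
  qa <- sampleUniformRotations(1, seed = 5)[1, ]
  qb <- sampleUniformRotations(1, seed = 6)[1, ]
  expect_equal(relativeAngle(qa, qb), relativeAngle(qb, qa))
  expect_error(relativeAngle(c(2, 0, 0, 0), I), "unit")
})

test_that("relative angle is left-invariant and bounded", {
  qi <- sampleUniformRotations(200, seed = 11)
  qj <- sampleUniformRotations(200, seed = 12)
  Q <- sampleUniformRotations(200, seed = 13)
  base <- relativeAngle(qi, qj)
  shifted <- relativeAngle(quatMultiply(Q, qi), quatMultiply(Q, qj))
  expect_equal(shifted, base, tolerance = 1e-9)
  expect_true(all(base >= 0 & base <= pi))
})

test_that("sampled relative angles follow the normalized SO(3) density", {
  qi <- sampleUniformRotations(1e5, seed = 21)
  qj <- sampleUniformRotations(1e5, seed = 22)
  theta <- relativeAngle(qi, qj)
  # closed-form mean pi/2 + 2/pi
  expect_equal(mean(theta), pi / 2 + 2 / pi, tolerance = 0.01)
  # goodness of fit against F(theta) = (theta - sin theta)/pi at alpha 0.01
  ks <- suppressWarnings(stats::ks.test(theta, angleCdf))
  expect_gt(ks$p.value, 0.01)
})

test_that("angle pdf is normalized and correctly shaped", {
  expect_equal(anglePdf(0), 0)
  expect_equal(anglePdf(pi), 2 / pi)
  quad <- stats::integrate(anglePdf, 0, pi, rel.tol = 1e-12)
  expect_equal(quad$value, 1, tolerance = 1e-9)
  expect_error(anglePdf(pi + 0.1), "0, pi")
  expect_error(anglePdf(-0.1), "0, pi")
  # documented constant linking the unnormalized textbook form
  expect_equal(angleUnnormalizedFactor * anglePdf(1), 0.5 * sin(0.5)^2)
})

test_that("distribution stats match closed form, bisection and Monte Carlo", {
  st <- angleDistributionStats()
  expect_equal(st$mean, pi / 2 + 2 / pi, tolerance = 1e-12)
  # independent bisection oracle for theta - sin(theta) = pi/2
  lo <- 0; hi <- pi
  for (k in 1:60) {
    mid <- (lo + hi) / 2
    if (mid - sin(mid) < pi / 2) lo <- mid else hi <- mid
  }
  expect_equal(st$median, (lo + hi) / 2, tolerance = 1e-9)
  # MC median over 1e6 pairs
  qi <- sampleUniformRotations(1e6, seed = 31)
  qj <- sampleUniformRotations(1e6, seed = 32)
  expect_equal(unname(stats::median(relativeAngle(qi, qj))), st$median,
               tolerance = 0.01)
})

test_that("quaternion algebra behaves (product, conjugate, rotation action)", {
  qa <- sampleUniformRotations(1, seed = 41)[1, ]
  qb <- sampleUniformRotations(1, seed = 42)[1, ]
  # composition of rotation matrices equals matrix of quaternion product
  expect_equal(quatToMatrix(quatMultiply(qa, qb)),
               quatToMatrix(qa) %*% quatToMatrix(qb), tolerance = 1e-12)
  # conjugate inverts
  expect_equal(abs(sum(quatMultiply(qa, quatConjugate(qa)) *
                         c(1, 0, 0, 0))), 1, tolerance = 1e-12)
  v <- c(0.3, -1.2, 2.5)
  expect_equal(quatRotate(quatRotate(v, qa), quatConjugate(qa)), v,
               tolerance = 1e-12)
  expect_error(quaternion(0, 0, 0, 0), "zero")
})
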