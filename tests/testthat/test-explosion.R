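test_that("charge assignment hits the target mean and respects caps", {
  cl <- synthesizeCloud(1000, seed = 50)
  means <- vapply(1:200, function(s)
    mean(charges(assignCharges(cl, seed = 1000 + s))), numeric(1))
  expect_equal(mean(means), 1.2, tolerance = 0.05)
  ch <- charges(assignCharges(cl, meanIonization = 5, seed = 1))
  expect_true(all(ch[atomElements(cl) == 1L] <= 1L))  # H capped at +1
  expect_true(all(ch <= atomElements(cl)))
  # vanishing ionization: all charges 0
  expect_true(all(charges(assignCharges(cl, meanIonization = 1e-9,
                                        seed = 2)) == 0L))
  expect_error(assignCharges(cl, meanIonization = 0), "positive")
})

test_that("expected total charge scales linearly with fluence", {
  cl <- synthesizeCloud(1000, seed = 51)
  half <- pulseModel(fluence = 2.5e6)
  means <- vapply(1:100, function(s)
    mean(charges(assignCharges(cl, pulse = half, seed = 2000 + s))),
    numeric(1))
  expect_equal(mean(means), 0.6, tolerance = 0.04)
})

test_that("two-ion explosion matches the closed-form energy and geometry", {
  cl <- twoIonCloud(d = 2)
  ej <- simulateExplosion(cl, dt = 0.05, maxTime = 5000,
                          stopPotentialFrac = 1e-3)
  d <- explosionDiagnostics(ej)
  expected <- kCoulombInternal / sqrt(2^2 + 0.1^2)
  expect_equal(d$kineticEnergy, expected, tolerance = 0.01)
  # back-to-back along +-x
  expect_equal(abs(ionDirections(ej)[, 1]), c(1, 1), tolerance = 1e-9)
  expect_equal(ionDirections(ej)[1, ], -ionDirections(ej)[2, ],
               tolerance = 1e-9)
})

test_that("square of equal charges ejects with the square's symmetry", {
  s <- 2
  pos <- rbind(c(s, s, 0), c(-s, s, 0), c(-s, -s, 0), c(s, -s, 0))
  cl <- suppressWarnings(atomCloud(pos, rep(6L, 4),
                                   charges = rep(1L, 4)))
  ej <- simulateExplosion(cl, dt = 0.1, maxTime = 2000,
                          stopPotentialFrac = 1e-4)
  dirs <- ionDirections(ej)
  # each ion leaves radially along its corner diagonal
  rad <- pos / sqrt(rowSums(pos^2))
  ang <- acos(pmin(1, rowSums(dirs * rad)))
  expect_true(all(ang < 1e-6))
  expect_equal(diff(range(ionSpeeds(ej))) / mean(ionSpeeds(ej)), 0,
               tolerance = 1e-9)
})

test_that("explosions conserve momentum and energy at the default step", {
  cl <- synthesizeCloud(400, seed = 60)
  cl <- assignCharges(cl, seed = 61)
  ej <- simulateExplosion(cl)
  d <- explosionDiagnostics(ej)
  expect_lt(d$maxEnergyDrift, 0.01)
  pScale <- sum(masses(ej) * ionSpeeds(ej)) / 1e5  # amu A/fs
  expect_lt(sqrt(sum(d$momentum^2)) / pScale, 1e-6)
})

test_that("explosion output is deterministic and fails cleanly when neutral", {
  cl <- synthesizeCloud(150, seed = 70)
  cl <- assignCharges(cl, seed = 71)
  e1 <- simulateExplosion(cl)
  e2 <- simulateExplosion(cl)
  expect_identical(ionDirections(e1), ionDirections(e2))
  expect_identical(ionSpeeds(e1), ionSpeeds(e2))
  neutral <- synthesizeCloud(150, seed = 70)
  expect_error(simulateExplosion(neutral), "nothing to explode")
})

test_that("ion speeds land on the expected physical scale", {
  cl <- synthesizeCloud(300, seed = 80)
  cl <- assignCharges(cl, seed = 81)
  med <- stats::median(ionSpeeds(simulateExplosion(cl)))
  expect_gte(med, 1e4)   # at least the lower end of the ejection scale
  expect_lt(med, 1e6)    # within an order of magnitude of the upper end
})

test_that("neutral atoms are excluded by default but can be kept ballistic", {
  cl <- synthesizeCloud(200, seed = 90)
  cl <- assignCharges(cl, meanIonization = 0.3, seed = 91)
  nCharged <- sum(charges(cl) > 0L)
  ej <- simulateExplosion(cl)
  expect_equal(nrow(ionDirections(ej)), nCharged)
  ejAll <- simulateExplosion(cl, includeNeutrals = TRUE)
  expect_equal(nrow(ionDirections(ejAll)), 200L)
  expect_true(all(ionSpeeds(ejAll)[charges(ejAll) == 0L] == 0))
})

test_that("pooled ejection directions over random orientations are isotropic", {
  cl <- synthesizeCloud(300, seed = 95)
  cl <- assignCharges(cl, seed = 96)
  ej <- simulateExplosion(cl)
  qs <- sampleUniformRotations(100, seed = 97)
  pooled <- do.call(rbind, lapply(seq_len(100), function(k)
    ionDirections(rotateEjecta(ej, qs[k, ]))))
  dipole <- sqrt(sum(colMeans(pooled)^2))
  expect_lt(dipole, 0.05)
})
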