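test_that("superposition removes rigid motion exactly and preserves
           chirality", {
  set.seed(2)
  ref <- matrix(runif(30, 0, 10), 10, 3)
  R <- randomRotationMatrix()
  moved <- sweep(ref %*% R, 2, c(3, -2, 7), `+`)
  coords <- array(NA_real_, c(2, 10, 3))
  coords[1, , ] <- ref
  coords[2, , ] <- moved
  ens <- trajectoryEnsemble(coords)
  sup <- superposeFrames(ens)
  expect_lt(sqrt(mean((sup@coords[2, , ] - ref)^2)), 1e-8)

  ## mirror image: proper rotations only, residual must stay positive
  mirror <- ref %*% diag(c(-1, 1, 1))
  coords[2, , ] <- mirror
  rms <- rmsdSeries(trajectoryEnsemble(coords))
  expect_gt(rms[2], 0.5)

  ## collinear selections are rejected
  line <- array(rep(cbind(1:4, 2 * (1:4), 3 * (1:4)), each = 2), c(2, 4, 3))
  expect_error(superposeFrames(trajectoryEnsemble(line)), "collinear")
})

test_that("per-frame RMSD matches the quaternion closed form", {
  set.seed(3)
  ref <- matrix(runif(36, 0, 10), 12, 3)
  nF <- 6
  coords <- array(NA_real_, c(nF, 12, 3))
  coords[1, , ] <- ref
  for (f in 2:nF) {
    jit <- ref + matrix(rnorm(36, 0, 0.4), 12, 3)
    coords[f, , ] <- sweep(jit %*% randomRotationMatrix(), 2,
                           runif(3, -5, 5), `+`)
  }
  ens <- trajectoryEnsemble(coords)
  rms <- rmsdSeries(ens)
  oracle <- vapply(1:nF, function(f) quaternionRmsd(coords[f, , ], ref),
                   numeric(1))
  expect_equal(unclass(rms), oracle, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(rms[1], 0, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("a single displaced atom gives the closed-form RMSD bound and a
           jittered trajectory plateaus near sigma * sqrt(3)", {
  set.seed(4)
  m <- 30
  ref <- matrix(runif(3 * m, 0, 20), m, 3)
  moved <- ref
  d <- 2
  moved[5, ] <- moved[5, ] + c(d, 0, 0)
  coords <- array(NA_real_, c(2, m, 3))
  coords[1, , ] <- ref
  coords[2, , ] <- moved
  rms <- rmsdSeries(trajectoryEnsemble(coords))
  ## translation-only optimum is d * sqrt(m - 1) / m; rotation only helps
  expect_lte(rms[2], d * sqrt(m - 1) / m + 1e-9)
  expect_equal(rms[2], quaternionRmsd(moved, ref), tolerance = 1e-8,
               ignore_attr = TRUE)

  sigma <- 0.2
  nF <- 200
  coords <- array(NA_real_, c(nF, m, 3))
  for (f in 1:nF) coords[f, , ] <- ref + matrix(rnorm(3 * m, 0, sigma), m, 3)
  rms <- rmsdSeries(trajectoryEnsemble(coords), reference = ref)
  expect_equal(mean(rms), sigma * sqrt(3), tolerance = 0.1)
})

test_that("PCA isolates a single moving coordinate and reconstructs the
           data", {
  nF <- 40
  coords <- array(0, c(nF, 4, 3))
  base <- matrix(runif(12, 0, 5), 4, 3)
  shift <- seq(0, 3, length.out = nF)
  for (f in 1:nF) {
    coords[f, , ] <- base
    coords[f, 1, 1] <- base[1, 1] + shift[f]    # only atom 1, x moves
  }
  pm <- pcaFit(trajectoryEnsemble(coords))
  ev <- explainedVariance(pm)
  expect_equal(ev[1], 1, tolerance = 1e-10)
  expect_equal(abs(pm@rotation[1, 1]), 1, tolerance = 1e-10)

  recon <- pcaReconstruct(pm)
  expect_lt(max(abs(recon - matrix(coords, nrow = nF))), 1e-8)
})

test_that("isotropic Gaussian data yields no spuriously dominant component", {
  set.seed(9)
  X <- matrix(rnorm(5000 * 12), 5000, 12)
  ev <- explainedVariance(pcaFit(X))
  expect_lt(max(ev) / min(ev), 1.5)
})

test_that("frame accounting over cases, monomers and crystal frames", {
  ## 8 simulation cases x 4 monomers x 6001 frames + 4 crystal structures
  set.seed(10)
  parts <- list()
  for (case in 1:8) for (mono in 1:4) {
    parts[[length(parts) + 1]] <- trajectoryEnsemble(
      array(rnorm(6001 * 3 * 3), c(6001, 3, 3)),
      labels = paste0("case", case), monomer = paste0("m", mono))
  }
  parts[[length(parts) + 1]] <- trajectoryEnsemble(
    array(rnorm(4 * 3 * 3), c(4, 3, 3)), labels = "crystal",
    monomer = c("A", "B", "C", "D"))
  combined <- bindEnsembles(parts)
  expect_identical(nFrames(combined), 192036L)
  expect_identical(sum(frameLabels(combined) == "crystal"), 4L)
})

test_that("k-means basics: k = 1 mean centroid, determinism, and sieving
           robustness on separated blobs", {
  ## separation 8 sigma: blob overlap is negligible, so sieved and full
  ## training must agree frame-for-frame (up to label permutation)
  gt <- genGateTrajectory(seed = 8, separation = 8,
                          framesPerCondition = c(mono = 150L,
                                                 double = 150L))
  sup <- superposeFrames(gt$ensemble)
  sc <- pcaScores(pcaFit(sup))[, 1:2]

  one <- kmeansSieved(sc, k = 1, sieve = 5)
  train <- sc[seq(1, nrow(sc), by = 5), ]
  expect_equal(drop(clusterCentroids(one)), colMeans(train),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_true(all(clusterAssignments(one) == 1L))

  a <- kmeansSieved(sc, k = 4, sieve = 5, seed = 17)
  b <- kmeansSieved(sc, k = 4, sieve = 5, seed = 17)
  expect_identical(clusterAssignments(a), clusterAssignments(b))

  full <- kmeansSieved(sc, k = 4, sieve = 1, seed = 17)
  expect_equal(mclust::adjustedRandIndex(clusterAssignments(a),
                                         clusterAssignments(full)), 1)

  expect_error(kmeansSieved(sc, k = 10000, sieve = 5), "exceeds")
})

test_that("the synthetic gate trajectory is clustered to its design", {
  gt <- genGateTrajectory(seed = 1, framesPerCondition = c(mono = 400L,
                                                           double = 400L))
  sup <- superposeFrames(gt$ensemble)
  sc <- pcaScores(pcaFit(sup))[, 1:2]
  cm <- kmeansSieved(sc, k = 4, sieve = 5, labels = frameLabels(sup))
  ari <- mclust::adjustedRandIndex(clusterAssignments(cm), gt$blob)
  expect_gte(ari, 0.95)
  ## label-permutation-safe population check: sorted fractions per condition
  for (cond in c("mono", "double")) {
    expect_lt(max(abs(sort(clusterPopulations(cm)[, cond]) -
                      sort(gt$designPopulations[, cond]))), 0.02)
  }
  expect_true(all(colSums(clusterPopulations(cm)) - 1 < 1e-8))
})

test_that("population heat maps normalize per condition and separate
           disjoint supports", {
  set.seed(12)
  scores <- rbind(cbind(rnorm(300, -10), rnorm(300, -10)),
                  cbind(rnorm(300, 10), rnorm(300, 10)))
  labels <- rep(c("mono", "double"), each = 300)
  hm <- populationHeatmap(scores, labels, bins = 30)
  expect_equal(sum(hm$maps$mono), 1)
  expect_equal(sum(hm$maps$double), 1)
  expect_equal(sum(hm$maps$mono > 0 & hm$maps$double > 0), 0)
})

test_that("representatives are the frames closest to their centroid, with
           deterministic tie-breaks", {
  scores <- matrix(c(0, 0, 10, 10.5, 0.2, 9.8), ncol = 1)
  cm <- kmeansSieved(scores, k = 2, sieve = 1, seed = 17)
  reps <- representatives(cm)
  for (j in 1:2) {
    members <- which(clusterAssignments(cm) == j)
    d <- abs(scores[members, 1] - clusterCentroids(cm)[j, 1])
    expect_equal(reps[j], members[which.min(d)])
  }

  ## symmetric pair: both frames equidistant, lowest index wins
  sym <- matrix(c(-1, 1), ncol = 1)
  cm1 <- kmeansSieved(sym, k = 1, sieve = 1)
  expect_identical(representatives(cm1), 1L)

  gt <- genGateTrajectory(seed = 2, framesPerCondition = c(mono = 100L,
                                                           double = 100L))
  sup <- superposeFrames(gt$ensemble)
  pm <- pcaFit(sup)
  cm4 <- kmeansSieved(pcaScores(pm)[, 1:2], k = 4, sieve = 5,
                      labels = frameLabels(sup))
  reps4 <- representativeStructure(cm4, sup)
  expect_s4_class(reps4, "TrajectoryEnsemble")
  expect_equal(nFrames(reps4), 4)
  ## each representative lies within ~1 blob-sigma of its centroid in PC
  ## space (sigma = 0.3 in flattened coordinates)
  d <- sqrt(rowSums((pcaScores(pm)[attr(reps4, "frames"), 1:2] -
                     clusterCentroids(cm4))^2))
  expect_true(all(d < 3 * 0.3))
})

test_that("gate distances track atomic displacements and correlate with the
           matching PC", {
  coords <- array(0, c(5, 3, 3))
  base <- rbind(c(0, 0, 0), c(5, 0, 0), c(0, 4, 0))
  for (f in 1:5) coords[f, , ] <- base
  ens <- trajectoryEnsemble(coords,
                            atomMeta = data.frame(chain = "A",
                                                  resNo = c(76L, 80L, 174L),
                                                  atomName = "CA"))
  d <- gateDistances(ens, list(c("A:76:CA", "A:80:CA")))
  expect_equal(drop(d), rep(5, 5), ignore_attr = TRUE)

  ## moving atom 76 along the 76-80 axis changes the distance one-to-one
  for (f in 1:5) coords[f, 1, 1] <- -(f - 1) * 0.7
  ens2 <- trajectoryEnsemble(coords, atomMeta = ens@atomMeta)
  d2 <- gateDistances(ens2, list(c("A:76:CA", "A:80:CA")))
  expect_equal(drop(d2), 5 + (0:4) * 0.7, ignore_attr = TRUE)
  expect_error(gateDistances(ens2, list(c("A:99:CA", "A:80:CA"))),
               "resolves to 0")

  gt <- genGateTrajectory(seed = 6, framesPerCondition = c(mono = 150L,
                                                           double = 150L))
  sup <- superposeFrames(gt$ensemble)
  sc <- pcaScores(pcaFit(sup))[, 1:2]
  dd <- gateDistances(sup, list(c("A:76:CA", "A:174:CA"),
                                c("A:76:CA", "A:80:CA")), scores = sc)
  corr <- attr(dd, "correlations")
  expect_true(all(apply(abs(corr), 1, max) >= 0.9))
})
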