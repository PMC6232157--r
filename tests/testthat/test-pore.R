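test_that("poreRadiusAt matches the brute-force minimum over atoms", {
  one <- atomSet(matrix(c(4, 0, 0), 1, 3), vdw = 1.5)
  expect_equal(poreRadiusAt(one, c(0, 0, 0)), 2.5)
  expect_equal(poreRadiusAt(one, c(4, 0, 0)), -1.5)

  set.seed(7)
  xyz <- matrix(runif(300, -10, 10), 100, 3)
  vdw <- runif(100, 1, 2)
  atoms <- atomSet(xyz, vdw = vdw)
  for (i in 1:5) {
    p <- runif(3, -10, 10)
    brute <- min(sqrt(rowSums(sweep(xyz, 2, p)^2)) - vdw)
    expect_equal(poreRadiusAt(atoms, p), brute, tolerance = 1e-12)
  }
})

test_that("a 12-atom ring of radius 5 (vdw 1.5) profiles at 3.5 A", {
  ch <- genChannelPdb(ringRadius = 5, spacing = 0.5, zRange = c(-6, 6),
                      vdw = 1.5)
  prof <- profileChannel(ch$atoms, seedPoint = c(0, 0, 0), axis = c(0, 0, 1),
                         step = 0.25)
  atRing <- which.min(abs(axialCoords(prof)))   # seed slice is a ring plane
  expect_equal(poreRadii(prof)[atRing], 3.5, tolerance = 0.02)
  ## cylinder interior: whole profile matches the closed-form ring geometry
  inside <- abs(axialCoords(prof)) <= 5
  expect_lt(max(abs(poreRadii(prof)[inside] -
                    ch$analyticRadius(axialCoords(prof)[inside]))), 0.02)
})

test_that("a linear funnel matches its analytic profile and terminates at
           the stop radius", {
  fu <- genChannelPdb(ringRadius = c(3, 9), spacing = 0.5,
                      zRange = c(-10, 10), vdw = 1.5)
  prof <- profileChannel(fu$atoms, seedPoint = c(0, 0, -5),
                         axis = c(0, 0, 1), step = 0.25)
  z <- axialCoords(prof) - 5                     # seed sits at z = -5
  keep <- poreRadii(prof) <= 5 & z >= -9.5
  expect_lt(max(abs(poreRadii(prof)[keep] - fu$analyticRadius(z[keep]))),
            0.05)
  ## radius grows towards the mouth and the profile stops past 5 A
  expect_true(prof@terminatedHigh)
  expect_false(prof@terminatedLow)
  expect_gt(max(poreRadii(prof)), 5)
})

test_that("profiles are invariant under rigid motion of the whole system", {
  ch <- genChannelPdb(ringRadius = c(4, 6), spacing = 0.5, zRange = c(-5, 5),
                      vdw = 1.5)
  prof <- profileChannel(ch$atoms, seedPoint = c(0, 0, 0),
                         axis = c(0, 0, 1), step = 0.5)
  set.seed(21)
  R <- randomRotationMatrix()
  shift <- runif(3, -20, 20)
  moved <- atomSet(sweep(atomCoords(ch$atoms) %*% R, 2, shift, `+`),
                   vdw = vdwRadii(ch$atoms))
  profM <- profileChannel(moved, seedPoint = drop(c(0, 0, 0) %*% R) + shift,
                          axis = drop(c(0, 0, 1) %*% R), step = 0.5)
  expect_equal(poreRadii(profM), poreRadii(prof), tolerance = 1e-6)
})

test_that("optimized centers of a symmetric channel sit on the axis", {
  ch <- genChannelPdb(ringRadius = 5, spacing = 0.5, zRange = c(-4, 4),
                      vdw = 1.5)
  prof <- profileChannel(ch$atoms, seedPoint = c(0.4, -0.3, 0),
                         axis = c(0, 0, 1), step = 0.5)
  expect_lt(max(abs(poreCenters(prof)[, 1:2])), 0.05)
})

test_that("inflating every vdW radius by delta shrinks interior radii by
           exactly delta", {
  ch <- genChannelPdb(ringRadius = 5, spacing = 0.5, zRange = c(-4, 4),
                      vdw = 1.5)
  prof <- profileChannel(ch$atoms, seedPoint = c(0, 0, 0),
                         axis = c(0, 0, 1), step = 0.5)
  delta <- 0.2
  inflated <- atomSet(atomCoords(ch$atoms), vdw = vdwRadii(ch$atoms) + delta)
  profI <- profileChannel(inflated, seedPoint = c(0, 0, 0),
                          axis = c(0, 0, 1), step = 0.5)
  inside <- abs(axialCoords(prof)) <= 3.5
  expect_equal(poreRadii(profI)[inside], poreRadii(prof)[inside] - delta,
               tolerance = 1e-6)
})

test_that("the slice optimizer agrees with an exhaustive fine-grid search on
           random atom systems", {
  set.seed(33)
  for (i in 1:3) {
    xyz <- matrix(runif(600, -8, 8), 200, 3)
    atoms <- atomSet(xyz, vdw = runif(200, 1.2, 2))
    ## pick an interior seed in open space
    repeat {
      seed <- runif(3, -3, 3)
      if (poreRadiusAt(atoms, seed) > 0.3) break
    }
    opt <- sliceOptimum(atoms, seed, axis = c(0, 0, 1))
    grid <- gridSliceMax(atoms, seed, halfWidth = 1.6, stepGrid = 0.02)
    ## at least as good as the local exhaustive search ...
    expect_gte(opt$radius, grid$radius - 0.05)
    ## ... and matching it when the optimum stayed within the grid window
    if (max(abs(opt$center[1:2] - seed[1:2])) <= 1.55)
      expect_equal(opt$radius, grid$radius, tolerance = 0.05)
  }
})

test_that("a seed inside an atom is rejected", {
  ch <- genChannelPdb(ringRadius = 5, spacing = 0.5, zRange = c(-2, 2),
                      vdw = 1.5)
  expect_error(profileChannel(ch$atoms, seedPoint = c(5, 0, 0),
                              axis = c(0, 0, 1)), "inside")
})

test_that("region minima report the constriction and its position", {
  cyl <- genChannelPdb(ringRadius = 5, spacing = 0.5, zRange = c(-4, 4),
                       vdw = 1.5)
  prof <- profileChannel(cyl$atoms, seedPoint = c(0, 0, 0),
                         axis = c(0, 0, 1), step = 0.5)
  m <- minInRegion(prof, poreRegion("mid", c(-2, 2)))
  expect_equal(m$radius, 3.5, tolerance = 0.02)

  ## hourglass: narrowest ring in the middle
  hour <- genChannelPdb(ringRadius = c(7, 3), spacing = 0.5,
                        zRange = c(-8, 0), vdw = 1.5)
  lower <- genChannelPdb(ringRadius = c(3, 7), spacing = 0.5,
                         zRange = c(0.5, 8.5), vdw = 1.5)
  both <- atomSet(rbind(atomCoords(hour$atoms), atomCoords(lower$atoms)),
                  vdw = 1.5)
  profH <- profileChannel(both, seedPoint = c(0, 0, 0.25),
                          axis = c(0, 0, 1), step = 0.25)
  mh <- minInRegion(profH, poreRegion("gate", c(-3, 3)))
  ## narrowest rings (R = 3) sit at z = 0/0.5; nearest-ring geometry gives
  ## sqrt(0.25^2 + 3^2) - 1.5 at the midplane
  expect_equal(mh$radius, sqrt(0.25^2 + 9) - 1.5, tolerance = 0.05)
  expect_lt(abs(mh$s), 0.51)
  expect_error(minInRegion(profH, poreRegion("far", c(40, 50))), "overlap")
})

test_that("compareProfiles orders structures by minimal radius with stable
           label tie-breaks", {
  mk <- function(r) {
    ch <- genChannelPdb(ringRadius = r + 1.5, spacing = 0.5,
                        zRange = c(-3, 3), vdw = 1.5)
    profileChannel(ch$atoms, seedPoint = c(0, 0, 0), axis = c(0, 0, 1),
                   step = 0.5)
  }
  p1 <- mk(1); p2 <- mk(2)
  tab <- compareProfiles(list(p2, p1), labels = c("wide", "narrow"))
  expect_equal(tab$label, c("narrow", "wide"))
  expect_true(all(diff(tab$minRadius) >= 0))

  tie <- compareProfiles(list(p1, p1), labels = c("b", "a"))
  expect_equal(tie$label, c("a", "b"))

  tabR <- compareProfiles(list(p2, p1), labels = c("wide", "narrow"),
                          regions = list(mid = poreRegion("mid", c(-1, 1))))
  expect_equal(tabR$mid, tabR$minRadius, tolerance = 0.02)
})

test_that("channelAxis and residue helpers locate a tilted channel", {
  ch <- genChannelPdb(ringRadius = 5, spacing = 0.5, zRange = c(-8, 8),
                      vdw = 1.5)
  ## synthetic rings have no CA atoms: principal axis of all coordinates
  ax <- channelAxis(ch$atoms)
  expect_equal(abs(ax[3]), 1, tolerance = 1e-6)
})
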