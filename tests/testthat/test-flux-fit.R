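test_that("an exact exponential is recovered to machine-level accuracy and a
           flat trace is flagged degenerate", {
  t <- seq(0, 2, length.out = 100)
  fit <- fitSingleExponential(osmoticTrace(t, 4 + 1.5 * exp(-2 * t)))
  expect_equal(fit@k, 2, tolerance = 1e-6)
  expect_false(fit@degenerate)

  flat <- fitSingleExponential(osmoticTrace(t, rep(3.3, length(t))))
  expect_true(flat@degenerate)
  expect_identical(flat@k, 0)
  expect_equal(flat@y0, flat@yInf)
})

test_that("the exponential rate survives 2% noise (median over seeds)", {
  t <- seq(0, 1, length.out = 200)
  clean <- 10 + 5 * exp(-5 * t)
  err <- vapply(1:20, function(s) {
    set.seed(s)
    y <- clean + rnorm(length(t), 0, 0.02 * diff(range(clean)))
    abs(fitSingleExponential(osmoticTrace(t, y))@k - 5) / 5
  }, numeric(1))
  expect_lt(median(err), 0.05)
})

test_that("pfFromRate is the plain initial-rate formula", {
  geom <- vesicleGeometry(v0 = 1, area = 1)
  expect_identical(pfFromRate(0, geom, deltaC = 1, vw = 1), 0)
  expect_equal(pfFromRate(3.7, geom, deltaC = 1, vw = 1), 3.7)
  expect_error(pfFromRate(1, geom, deltaC = 0), "> 0")
})

test_that("simulate -> exponential fit -> invert recovers Pf within 10%", {
  geom <- sphereGeometry(1e-12)
  shock <- shockCondition(osmOutImpermeant = 0.33, osmInImpermeant0 = 0.3)
  pf <- 3e-3
  traj <- simulateVolumeTrace(fluxParams(pf, 0), geom, shock,
                              seq(0, 5, 0.005))
  k <- fitSingleExponential(osmoticTrace(times(traj), vRel(traj)))@k
  pfEst <- pfFromRate(k, geom, effectiveOsmoticGradient(shock, geom))
  expect_equal(pfEst, pf, tolerance = 0.1)
})

test_that("pglyFromSwelling is 1/((S/V) tau) and decreases with tau", {
  geom <- vesicleGeometry(v0 = 1, area = 1)    # S/V = 1
  expect_equal(pglyFromSwelling(1, geom), 1)
  taus <- c(1, 5, 50, 500)
  expect_true(all(diff(sapply(taus, pglyFromSwelling, geom = geom)) < 0))
  expect_error(pglyFromSwelling(0, geom), "> 0")
})

test_that("swelling-phase fit inverts to Pgly within 15% (dilute tracer)", {
  geom <- sphereGeometry(1e-12)
  shock <- shockCondition(osmOutImpermeant = 0.3, cGlyOut = 0.015,
                          osmInImpermeant0 = 0.3)
  pg <- 1e-6
  traj <- simulateVolumeTrace(fluxParams(5e-3, pg), geom, shock,
                              seq(0, 150, 0.1))
  v <- vRel(traj)
  i <- which.min(v)
  swell <- osmoticTrace(times(traj)[i:length(v)] - times(traj)[i],
                        v[i:length(v)])
  pgEst <- pglyFromSwelling(1 / fitSingleExponential(swell)@k, geom)
  expect_equal(pgEst, pg, tolerance = 0.15)
})

test_that("calibration anchors at baseline and removes linear bleaching
           drift", {
  t <- seq(0, 10, 0.01)
  ## flat baseline for 2 s, then an osmotic response
  clean <- ifelse(t < 2, 100, 100 * (0.8 + 0.2 * exp(-(t - 2))))
  cal <- calibrationLine(a = 1, b = 0)
  v0 <- vRel(calibrateTrace(osmoticTrace(t, clean), cal,
                            baselineWindow = c(0, 2)))
  expect_equal(v0[1], 1, tolerance = 1e-12)

  drifted <- clean - 0.4 * t                     # bleaching drift
  vd <- vRel(calibrateTrace(osmoticTrace(t, drifted), cal,
                            baselineWindow = c(0, 2)))
  expect_lt(max(abs(vd - v0)), 1e-6)

  ## control-trace subtraction removes the same drift
  ctrl <- osmoticTrace(t, 100 - 0.4 * t)
  vc <- vRel(calibrateTrace(osmoticTrace(t, drifted), cal,
                            baselineWindow = c(0, 2), control = ctrl))
  expect_lt(max(abs(vc - v0)), 1e-6)

  ## vrel = a F/F0 + b is anchored: F = F0 maps to a + b
  cal2 <- calibrationLine(a = -0.5, b = 1.5)
  v2 <- vRel(calibrateTrace(osmoticTrace(t[1:300], rep(50, 300)), cal2,
                            baselineWindow = c(0, 1)))
  expect_equal(v2, rep(1, 300), tolerance = 1e-12)

  expect_error(calibrateTrace(osmoticTrace(t, clean), cal,
                              baselineWindow = c(-2, -1)), "baseline")
})

test_that("fitFluxTrace recovers its own forward model exactly and flags a
           structurally non-identifiable Pgly", {
  d <- yeastShockDefaults()
  tt <- seq(0, 20, length.out = 400)
  clean <- simulateVolumeTrace(d$params, d$geom, d$shock, tt)
  fit <- fitFluxTrace(clean, d$geom, d$shock, init = fluxParams(1e-3, 1e-5))
  expect_true(fit@converged)
  expect_equal(fit@params@pf, d$params@pf, tolerance = 1e-3)
  expect_equal(fit@params@pgly, d$params@pgly, tolerance = 1e-3)
  expect_true(all(is.finite(fit@se)))

  ## sorbitol-only shock: no glycerol gradient
  sorb <- shockCondition(osmOutImpermeant = 1.75, osmInImpermeant0 = 1.4)
  cleanS <- simulateVolumeTrace(fluxParams(5e-3, 0), d$geom, sorb, tt)
  expect_warning(fitS <- fitFluxTrace(cleanS, d$geom, sorb,
                                      init = fluxParams(1e-3, 1e-5)),
                 "not identifiable")
  expect_false(fitS@identifiable[["pgly"]])
  expect_true(fitS@identifiable[["pf"]])
  expect_equal(fitS@params@pf, 5e-3, tolerance = 1e-3)
})

test_that("fitFluxTrace recovers both permeabilities from noisy traces
           (median over seeds)", {
  d <- yeastShockDefaults()
  tt <- seq(0, 20, length.out = 500)
  clean <- simulateVolumeTrace(d$params, d$geom, d$shock, tt)
  errs <- sapply(1:8, function(s) {
    traj <- noisyVrelTrajectory(clean, 0.01, seed = s)
    fit <- fitFluxTrace(traj, d$geom, d$shock, init = fluxParams(1e-3, 1e-5))
    c(pf = abs(fit@params@pf - d$params@pf) / d$params@pf,
      pgly = abs(fit@params@pgly - d$params@pgly) / d$params@pgly)
  })
  expect_lt(median(errs["pf", ]), 0.1)
  expect_lt(median(errs["pgly", ]), 0.1)
})
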