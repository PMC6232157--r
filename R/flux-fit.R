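## Rate-constant and permeability estimation from osmotic-shock traces.

#' Fit a single exponential to a trace
#'
#' Least-squares fit of `y(t) = yInf + (y0 - yInf) * exp(-k * t)` with
#' `k >= 0`. A robust rate-profile search (for fixed k the amplitude and
#' offset are linear and solved exactly) seeds a Levenberg-Marquardt
#' refinement. Flat traces are flagged degenerate (`k = 0`, zero amplitude)
#' rather than returning silent garbage.
#'
#' @param trace an [OsmoticTrace-class] with at least 4 points.
#' @return An [ExpFit-class].
#' @examples
#' t <- seq(0, 2, length.out = 100)
#' fitSingleExponential(osmoticTrace(t, 3 + 2 * exp(-2 * t)))
#' @export
fitSingleExponential <- function(trace) {
  stopifnot(is(trace, "OsmoticTrace"))
  t <- trace@times - trace@times[1L]
  y <- trace@values
  n <- length(y)
  if (n < 4L) stop("single-exponential fit needs at least 4 points")

  scale <- max(abs(y), 1e-12)
  if (diff(range(y)) <= 1e-10 * scale) {
    m <- mean(y)
    return(new("ExpFit", k = 0, y0 = m, yInf = m,
               rss = sum((y - m)^2), converged = TRUE, degenerate = TRUE))
  }

  ## profile rss over k: given k, (yInf, amplitude) solve a linear LS problem
  profile <- function(k) {
    basis <- exp(-k * t)
    fit <- stats::lm.fit(cbind(1, basis), y)
    sum(fit$residuals^2)
  }
  span <- t[n]
  kGrid <- 10^seq(log10(0.01 / span), log10(2000 / span), length.out = 60L)
  rssGrid <- vapply(kGrid, profile, numeric(1L))
  kBest <- kGrid[which.min(rssGrid)]
  opt <- stats::optimize(profile, interval = c(kBest / 10, kBest * 10))
  k0 <- opt$minimum
  cf <- stats::lm.fit(cbind(1, exp(-k0 * t)), y)$coefficients

  start <- list(yInf = cf[[1L]], A = cf[[2L]], k = k0)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ yInf + A * exp(-k * t), start = start,
                      lower = c(-Inf, -Inf, 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    ## fall back to the profile solution, flagged as unrefined
    return(new("ExpFit", k = max(k0, 0), y0 = cf[[1L]] + cf[[2L]],
               yInf = cf[[1L]], rss = profile(k0), converged = FALSE,
               degenerate = FALSE))
  }
  est <- stats::coef(fit)
  new("ExpFit", k = max(est[["k"]], 0), y0 = est[["yInf"]] + est[["A"]],
      yInf = est[["yInf"]], rss = sum(stats::residuals(fit)^2),
      converged = fit$convInfo$isConv, degenerate = FALSE)
}

#' Water permeability from an exponential rate constant
#'
#' The classical initial-rate relation `Pf = k * V0 / (deltaC * Vw * A)`.
#' The formula is pure arithmetic: all quantities must be supplied in
#' mutually consistent units (with V0 in cm^3, A in cm^2, Vw in cm^3/mol and
#' `deltaC` in mol/cm^3, Pf comes out in cm/s). Because the fitted rate of
#' the full nonlinear relaxation approximates the *linearized* kinetics, the
#' appropriate gradient for inverting a fitted rate is
#' [effectiveOsmoticGradient()], not the raw concentration step; see the
#' methods vignette.
#'
#' @param k fitted rate constant, 1/s.
#' @param geom a [VesicleGeometry-class].
#' @param deltaC osmotic gradient (consistent units, > 0).
#' @param vw molar water volume (18 cm^3/mol).
#' @return Pf, in the units implied by the inputs.
#' @export
pfFromRate <- function(k, geom, deltaC, vw = 18) {
  stopifnot(is(geom, "VesicleGeometry"))
  if (deltaC <= 0) stop("deltaC must be > 0")
  if (k < 0) stop("k must be >= 0")
  k * geom@v0 / (deltaC * vw * geom@area)
}

#' Effective osmotic gradient of the linearized shrink kinetics
#'
#' Linearizing the volume equation around its equilibrium gives a relaxation
#' rate `k = Pf * (A/V0) * Vw * osm_out^2 / ((1 - beta) * osm_in_0)` for an
#' impermeant shock. The corresponding driving gradient to use in
#' [pfFromRate()] when `k` comes from a single-exponential fit is therefore
#' `osm_out^2 / osm_in_0 * (1 - beta)^-1`, returned here in mol/cm^3.
#'
#' @param shock a [ShockCondition-class] (impermeant shock).
#' @param geom a [VesicleGeometry-class] (for beta).
#' @return gradient in mol/cm^3, suitable for [pfFromRate()] with cgs
#'   geometry.
#' @export
effectiveOsmoticGradient <- function(shock, geom) {
  stopifnot(is(shock, "ShockCondition"), is(geom, "VesicleGeometry"))
  osmOut <- shock@osmOutImpermeant + shock@cGlyOut
  if (shock@osmInImpermeant0 <= 0)
    stop("requires a positive initial internal osmolarity")
  1e-3 * osmOut^2 / shock@osmInImpermeant0 / (1 - geom@inactiveFraction)
}

#' Glycerol permeability from the swelling time constant
#'
#' `Pgly = 1 / ((S/V) * tau)` with `S/V = A/V0`: in the fast-water limit the
#' swelling phase tracks glycerol equilibration, which relaxes exponentially
#' with time constant `tau = V / (A * Pgly)`.
#'
#' @param tau exponential time constant of the swelling phase, s (> 0).
#' @param geom a [VesicleGeometry-class].
#' @return Pgly in cm/s (for cgs geometry).
#' @export
pglyFromSwelling <- function(tau, geom) {
  stopifnot(is(geom, "VesicleGeometry"))
  if (tau <= 0) stop("tau must be > 0")
  1 / ((geom@area / geom@v0) * tau)
}

#' Calibrate a fluorescence trace to relative volume
#'
#' Converts a fluorescence-quenching trace to relative volume via the linear
#' relation `vRel = a * F/F0 + b`. The bleaching drift is removed first:
#' when an iso-osmotic control trace is supplied its (baseline-anchored)
#' time course is subtracted; otherwise a line fitted to the pre-shock
#' baseline window is extrapolated and its time-dependent part subtracted.
#' `F0` is the mean corrected signal over the baseline window.
#'
#' @param trace an [OsmoticTrace-class].
#' @param cal a [CalibrationLine-class] (slope `a`, intercept `b`).
#' @param baselineFraction fraction of leading points treated as pre-shock
#'   baseline (default 0.05), used when `baselineWindow` is NULL.
#' @param baselineWindow optional explicit time window `c(t0, t1)` for the
#'   baseline.
#' @param control optional iso-osmotic control [OsmoticTrace-class] whose
#'   drift is subtracted instead of the fitted line.
#' @return A [VolumeTrajectory-class] (with `cGlyIn` set to NA).
#' @export
calibrateTrace <- function(trace, cal, baselineFraction = 0.05,
                           baselineWindow = NULL, control = NULL) {
  stopifnot(is(trace, "OsmoticTrace"), is(cal, "CalibrationLine"))
  t <- trace@times
  y <- trace@values
  if (is.null(baselineWindow)) {
    nb <- max(2L, ceiling(baselineFraction * length(t)))
    idx <- seq_len(nb)
  } else {
    idx <- which(t >= baselineWindow[1L] & t <= baselineWindow[2L])
  }
  if (length(idx) < 2L) stop("empty (or single-point) baseline window")

  if (!is.null(control)) {
    stopifnot(is(control, "OsmoticTrace"))
    ctrl <- stats::approx(control@times, control@values, xout = t,
                          rule = 2L)$y
    ## anchor the control at its own baseline level (line intercept over the
    ## window) so only its time-dependent drift is subtracted
    cline <- stats::lm.fit(cbind(1, t[idx]), ctrl[idx])$coefficients
    corrected <- y - (ctrl - cline[[1L]])
  } else {
    line <- stats::lm.fit(cbind(1, t[idx]), y[idx])$coefficients
    corrected <- y - line[[2L]] * t   # remove the drift, keep the level
  }
  f0 <- mean(corrected[idx])
  if (abs(f0) < .Machine$double.eps) stop("baseline signal F0 is zero")
  newVolumeTrajectory(times = t, vRel = cal@a * corrected / f0 + cal@b)
}

#' Fit Pf and Pgly to a calibrated relative-volume trace
#'
#' Nonlinear least squares matching [simulateVolumeTrace()] to an observed
#' relative-volume series. Parameters are optimized on a log scale
#' (positivity for free), with approximate standard errors from the
#' Levenberg-Marquardt Jacobian propagated back to the natural scale.
#' Structurally non-identifiable parameters (Pgly without any glycerol
#' gradient) are detected, frozen at their initial value and flagged.
#'
#' @param traj a [VolumeTrajectory-class] (calibrated data; `times` must
#'   start at 0).
#' @param geom a [VesicleGeometry-class].
#' @param shock the fully specified [ShockCondition-class] of the experiment.
#' @param init starting [FluxParams-class] (both entries > 0).
#' @param rtol forward-model integrator tolerance.
#' @return A [FluxFit-class].
#' @export
fitFluxTrace <- function(traj, geom, shock, init = fluxParams(1e-3, 1e-5),
                         rtol = 1e-8) {
  stopifnot(is(traj, "VolumeTrajectory"), is(geom, "VesicleGeometry"),
            is(shock, "ShockCondition"), is(init, "FluxParams"))
  t <- traj@times
  obs <- traj@vRel
  if (init@pf <= 0 || init@pgly <= 0)
    stop("init must carry strictly positive Pf and Pgly starting values")

  glyGradient <- abs(shock@cGlyOut - shock@cGlyIn0) > 0
  free <- c(pf = TRUE, pgly = glyGradient)
  if (!glyGradient)
    warning("no glycerol gradient in the shock: Pgly is not identifiable ",
            "and is frozen at its initial value")

  toParams <- function(theta) {
    p <- c(pf = init@pf, pgly = init@pgly)
    p[names(theta)] <- p[names(theta)] * exp(theta)
    fluxParams(p[["pf"]], p[["pgly"]], init@vw)
  }
  residFun <- function(theta) {
    names(theta) <- names(which(free))
    sim <- simulateVolumeTrace(toParams(theta), geom, shock, t, rtol = rtol)
    sim@vRel - obs
  }

  theta0 <- rep(0, sum(free))
  fit <- minpack.lm::nls.lm(par = theta0, fn = residFun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-12, ptol = 1e-12))
  theta <- fit$par
  names(theta) <- names(which(free))
  pars <- toParams(theta)
  rss <- sum(fit$fvec^2)
  converged <- fit$info %in% 1:4

  ## delta-method SEs: se(p) = p * se(log p)
  se <- c(pf = NA_real_, pgly = NA_real_)
  covTheta <- tryCatch({
    dof <- length(obs) - sum(free)
    chol2inv(chol(fit$hessian)) * (rss / max(dof, 1L))
  }, error = function(e) NULL)
  if (!is.null(covTheta)) {
    seTheta <- sqrt(pmax(diag(covTheta), 0))
    names(seTheta) <- names(theta)
    if (free[["pf"]]) se[["pf"]] <- pars@pf * seTheta[["pf"]]
    if (free[["pgly"]]) se[["pgly"]] <- pars@pgly * seTheta[["pgly"]]
  }

  sim <- simulateVolumeTrace(pars, geom, shock, t, rtol = rtol)
  new("FluxFit", params = pars, se = se, rss = rss, converged = converged,
      identifiable = free, fitted = sim@vRel)
}
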