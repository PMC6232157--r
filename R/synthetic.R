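## Seeded synthetic generators emulating every input class the analyses
## consume: biphasic shrink/swell traces, Hill titration series, Arrhenius
## series, ring-built channel geometries with closed-form radius profiles,
## and clustered gate trajectories under random rigid-body motion.
##
## RNG protocol: one user seed; each generator draws from its own substream
## (seed + a generator-specific offset) under withr::with_seed, so adding a
## generator never shifts the fixtures of another, and identical
## configurations yield byte-identical outputs.

.genOffsets <- c(trace = 101L, titration = 202L, arrhenius = 303L,
                 channel = 404L, trajectory = 505L)

.genSeed <- function(seed, which) as.integer(seed) + .genOffsets[[which]]

#' Default study conditions for the yeast glycerol-shock assay
#'
#' Cells (5 micron diameter sphere, osmotically inactive fraction 0.55) in
#' 1.4 osmol/L sorbitol, mixed with an equal volume of 2.1 osmol/L glycerol
#' challenge: externally 0.7 osmol/L impermeant plus 1.05 mol/L glycerol,
#' a tonicity of 1.25.
#'
#' @return list with `geom` ([VesicleGeometry-class]), `shock`
#'   ([ShockCondition-class]) and `params` ([FluxParams-class], Pf = 5e-3,
#'   Pgly = 2e-5 cm/s).
#' @export
yeastShockDefaults <- function() {
  v0 <- 4 / 3 * pi * (2.5e-4)^3            # 5 um diameter sphere, cm^3
  list(geom = sphereGeometry(v0, inactiveFraction = 0.55),
       shock = shockCondition(osmOutImpermeant = 0.7, cGlyOut = 1.05,
                              osmInImpermeant0 = 1.4, cGlyIn0 = 0),
       params = fluxParams(pf = 5e-3, pgly = 2e-5))
}

#' Generate a synthetic osmotic-shock trace
#'
#' Forward-simulates the flux model under the given conditions, maps relative
#' volume to a measured signal (affine in `vRel` for fluorescence quenching,
#' affine in `1/vRel` for light scattering) and adds Gaussian noise scaled to
#' the clean signal amplitude.
#'
#' @param seed RNG seed.
#' @param params,geom,shock true conditions; defaults are
#'   [yeastShockDefaults()].
#' @param times sampling times, s.
#' @param mode `"fluorescence"` or `"scattering"` signal mapping.
#' @param noiseSd additive noise SD as a fraction of the clean signal
#'   amplitude (0 gives a deterministic trace).
#' @param f0 baseline signal level.
#' @return list with `trace` ([OsmoticTrace-class]), `truth` (the inputs),
#'   `clean` (noise-free [VolumeTrajectory-class]) and `calibration`
#'   (the [CalibrationLine-class] inverting the fluorescence mapping).
#' @export
genFluxTrace <- function(seed = 17L, params = NULL, geom = NULL,
                         shock = NULL, times = seq(0, 20, by = 0.04),
                         mode = c("fluorescence", "scattering"),
                         noiseSd = 0.01, f0 = 100) {
  mode <- match.arg(mode)
  defs <- yeastShockDefaults()
  if (is.null(params)) params <- defs$params
  if (is.null(geom)) geom <- defs$geom
  if (is.null(shock)) shock <- defs$shock

  clean <- simulateVolumeTrace(params, geom, shock, times)
  signal <- switch(mode,
    fluorescence = f0 * clean@vRel,
    scattering = f0 * (1 / clean@vRel))
  amp <- diff(range(signal))
  values <- if (noiseSd > 0) {
    withr::with_seed(.genSeed(seed, "trace"),
                     signal + stats::rnorm(length(signal), 0, noiseSd * amp))
  } else signal
  trace <- osmoticTrace(times, values,
                        meta = list(mode = mode,
                                    temperature_K = shock@temperature,
                                    tonicity = (shock@osmOutImpermeant +
                                                shock@cGlyOut) /
                                               shock@osmInImpermeant0))
  list(trace = trace,
       truth = list(params = params, geom = geom, shock = shock),
       clean = clean, calibration = calibrationLine(a = 1, b = 0))
}

#' Generate a synthetic pH titration series
#'
#' Hill-structured normalized permeabilities plus additive noise. The
#' `"acid"` preset (n > 0) emulates channels activated by acidification;
#' `"alkaline"` (n < 0) the opposite regulation.
#'
#' @param seed RNG seed.
#' @param pK,n,pMax Hill truth; `n`'s sign is forced by `preset` unless
#'   supplied explicitly.
#' @param ph pH values (>= 4 points).
#' @param noiseSd additive noise SD as a fraction of `pMax`.
#' @param preset `"acid"` or `"alkaline"`.
#' @return list with `ph`, `pNorm` and `truth` (a [HillFit-class]).
#' @export
genTitration <- function(seed = 17L, pK = 6, n = NULL, pMax = 1,
                         ph = seq(4.5, 8, length.out = 8L), noiseSd = 0.05,
                         preset = c("acid", "alkaline")) {
  preset <- match.arg(preset)
  if (is.null(n)) n <- if (preset == "acid") 2 else -2
  if (length(ph) < 4L) stop("need at least 4 pH points")
  clean <- hillCurve(ph, pK, n, pMax)
  pNorm <- if (noiseSd > 0) {
    withr::with_seed(.genSeed(seed, "titration"),
                     clean + stats::rnorm(length(ph), 0, noiseSd * pMax))
  } else clean
  list(ph = ph, pNorm = pNorm,
       truth = new("HillFit", pK = pK, n = n, pMax = pMax, rss = 0,
                   degenerate = FALSE))
}

#' Generate a synthetic Arrhenius series
#'
#' Log-linear permeability versus inverse temperature with multiplicative
#' (lognormal) noise, over the 283-307 K assay range.
#'
#' @param seed RNG seed.
#' @param ea activation energy, kJ/mol.
#' @param lnPrefactor intercept of the Arrhenius line (sets the permeability
#'   scale; the default puts Pgly near 1e-4 cm/s at 296 K).
#' @param temps temperatures, K (>= 3).
#' @param noiseSd SD of the multiplicative log-noise (e.g. 0.03 for 3%).
#' @return list with `temps`, `pgly` and `truth` (`ea`, `lnPrefactor`).
#' @export
genArrhenius <- function(seed = 17L, ea = 20, lnPrefactor = NULL,
                         temps = seq(283, 307, by = 4), noiseSd = 0.03) {
  if (length(temps) < 3L) stop("need at least 3 temperatures")
  R <- 8.314
  if (is.null(lnPrefactor)) lnPrefactor <- log(1e-4) + ea * 1000 / (R * 296)
  clean <- exp(lnPrefactor - ea * 1000 / (R * temps))
  pgly <- if (noiseSd > 0) {
    withr::with_seed(.genSeed(seed, "arrhenius"),
                     clean * exp(stats::rnorm(length(temps), 0, noiseSd)))
  } else clean
  list(temps = temps, pgly = pgly,
       truth = list(ea = ea, lnPrefactor = lnPrefactor))
}

#' Generate a stacked-ring synthetic channel
#'
#' A pseudo-protein channel built from rings of atoms centered on the z axis:
#' a cylinder for constant ring radius, a funnel for a linearly varying one.
#' The closed-form pore radius on the axis,
#' `r(z) = min_j sqrt((z - z_j)^2 + R_j^2) - vdw`, is returned alongside for
#' oracle testing, together with valid PDB text.
#'
#' @param seed unused (the geometry is deterministic); kept for interface
#'   uniformity.
#' @param zRange axial extent `c(zmin, zmax)`, Angstrom.
#' @param spacing ring spacing, Angstrom.
#' @param ringRadius single radius (cylinder) or `c(rAtZmin, rAtZmax)`
#'   (linear funnel), Angstrom.
#' @param nPerRing atoms per ring.
#' @param element ring atom element (sets the table vdW radius).
#' @param vdw explicit vdW radius overriding the table.
#' @return list with `atoms` ([AtomSet-class]), `pdb` (text),
#'   `analyticRadius` (function of z) and `ringRadiusAt` (function of z).
#' @export
genChannelPdb <- function(seed = 17L, zRange = c(-10, 10), spacing = 0.5,
                          ringRadius = 5, nPerRing = 12L, element = "C",
                          vdw = NULL) {
  if (is.null(vdw)) {
    tab <- defaultVdwTable()
    vdw <- tab$radius[match(element, tab$element)]
    if (is.na(vdw)) stop("element not in vdW table; supply vdw explicitly")
  }
  z <- seq(zRange[1L], zRange[2L], by = spacing)
  rr <- if (length(ringRadius) == 1L) rep(ringRadius, length(z))
        else ringRadius[1L] + (ringRadius[2L] - ringRadius[1L]) *
             (z - zRange[1L]) / diff(zRange)
  if (any(rr < vdw)) stop("ring radii must be >= the atom vdW radius")
  ang <- 2 * pi * (seq_len(nPerRing) - 1L) / nPerRing
  coords <- do.call(rbind, lapply(seq_along(z), function(j)
    cbind(rr[j] * cos(ang), rr[j] * sin(ang), z[j])))
  atoms <- atomSet(coords, vdw = vdw, element = element,
                   atomName = paste0(element, 1L),
                   resName = "UNK",
                   resNo = rep(seq_along(z), each = nPerRing))
  ringRadiusAt <- stats::approxfun(z, rr, rule = 2L)
  analyticRadius <- function(zq) {
    vapply(zq, function(q) min(sqrt((q - z)^2 + rr^2)) - vdw, numeric(1L))
  }
  list(atoms = atoms, pdb = writeStructurePdb(atoms),
       analyticRadius = analyticRadius, ringRadiusAt = ringRadiusAt,
       vdw = vdw)
}

## uniform random rotation matrix via a normalized quaternion
.randomRotation <- function() {
  q <- stats::rnorm(4L)
  q <- q / sqrt(sum(q^2))
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3L, 3L, byrow = TRUE)
}

#' Generate a clustered synthetic gate trajectory
#'
#' Frames drawn from k template conformations of an M-atom CA selection,
#' plus isotropic Gaussian jitter and (optionally) a random rigid-body
#' rotation and translation per frame. Template b displaces one designated
#' "gate" atom (residue 76 by default) progressively away from its two
#' pore-width partners (residues 80 and 174), so both pair distances grow
#' with the blob index. Per-condition blob counts follow the mixing weights
#' deterministically (largest-remainder allocation), so designed populations
#' are exact; frame order within a condition is shuffled.
#'
#' @param seed RNG seed.
#' @param nAtoms selection size M (default 28).
#' @param k number of conformational clusters.
#' @param sigma isotropic jitter SD, Angstrom.
#' @param separation spacing of consecutive templates in multiples of
#'   `sigma` (flattened-coordinate distance).
#' @param framesPerCondition named integer vector of frame counts.
#' @param weights k x nCondition matrix of mixing weights (columns sum to
#'   1); the default concentrates the `mono` condition in blob 1 and spreads
#'   `double` over the open blobs.
#' @param rigid apply random rigid-body motion per frame (TRUE).
#' @param translation half-range of the uniform per-frame translation,
#'   Angstrom.
#' @return list with `ensemble` ([TrajectoryEnsemble-class]), `blob` (true
#'   cluster per frame), `templates`, `weights` and `designPopulations`
#'   (k x nCondition, the realized = designed fractions).
#' @export
genGateTrajectory <- function(seed = 17L, nAtoms = 28L, k = 4L, sigma = 0.3,
                              separation = 5,
                              framesPerCondition = c(mono = 400L,
                                                     double = 400L),
                              weights = NULL, rigid = TRUE,
                              translation = 5) {
  if (is.null(weights)) {
    weights <- cbind(mono = c(0.85, rep(0.05, k - 1L)),
                     double = c(0.10, rep(0.90 / (k - 1L), k - 1L)))
    weights <- weights[, names(framesPerCondition), drop = FALSE]
  }
  stopifnot(nrow(weights) == k,
            ncol(weights) == length(framesPerCondition))

  withr::with_seed(.genSeed(seed, "trajectory"), {
    base <- matrix(stats::runif(nAtoms * 3L, 0, 10), nAtoms, 3L)
    ## the moving gate atom and its two partners (indices 1..3 map to
    ## residues 76, 80, 174 in atomMeta below)
    u <- base[1L, ] - (base[2L, ] + base[3L, ]) / 2
    u <- u / sqrt(sum(u^2))
    delta <- separation * sigma
    templates <- lapply(seq_len(k), function(b) {
      tm <- base
      tm[1L, ] <- tm[1L, ] + (b - 1L) * delta * u
      tm
    })

    ## largest-remainder allocation of frames to blobs per condition
    blob <- integer(0)
    labels <- character(0)
    for (cond in names(framesPerCondition)) {
      nC <- framesPerCondition[[cond]]
      raw <- weights[, cond] * nC
      counts <- floor(raw)
      rem <- nC - sum(counts)
      if (rem > 0) {
        extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
        counts[extra] <- counts[extra] + 1L
      }
      b <- sample(rep.int(seq_len(k), counts))
      blob <- c(blob, b)
      labels <- c(labels, rep(cond, nC))
    }

    nF <- length(blob)
    coords <- array(NA_real_, c(nF, nAtoms, 3L))
    for (f in seq_len(nF)) {
      fr <- templates[[blob[f]]] +
        matrix(stats::rnorm(nAtoms * 3L, 0, sigma), nAtoms, 3L)
      if (rigid) {
        fr <- fr %*% .randomRotation()
        fr <- sweep(fr, 2L, stats::runif(3L, -translation, translation), `+`)
      }
      coords[f, , ] <- fr
    }

    resNo <- c(76L, 80L, 174L, 27L, 73L, 74L, 77L, 83L, 84L, 85L, 94L)
    resNo <- c(resNo, setdiff(100L + seq_len(nAtoms), resNo))[seq_len(nAtoms)]
    ens <- trajectoryEnsemble(coords, labels = labels, monomer = "m1",
                              atomMeta = data.frame(chain = "A",
                                                    resNo = resNo,
                                                    atomName = "CA"))
    design <- vapply(names(framesPerCondition), function(cond)
      tabulate(blob[labels == cond], k) / framesPerCondition[[cond]],
      numeric(k))
    list(ensemble = ens, blob = blob,
         templates = templates, weights = weights,
         designPopulations = matrix(design, nrow = k,
                                    dimnames = list(NULL,
                                      names(framesPerCondition))))
  })
}
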