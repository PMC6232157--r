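#' @import methods
NULL

## ---------------------------------------------------------------------------
## Osmotic-kinetics containers
## ---------------------------------------------------------------------------

#' Raw osmotic-shock trace
#'
#' A sampled signal (stopped-flow light scattering or fluorescence quenching)
#' versus time, with free-form metadata (pH, temperature, osmolyte, tonicity).
#'
#' @slot times numeric, seconds, strictly increasing, non-negative.
#' @slot values numeric signal in arbitrary units; same length as `times`.
#' @slot meta list of metadata (e.g. `pH`, `temperature_K`, `osmolyte`,
#'   `tonicity`).
#' @seealso [osmoticTrace()], [readTrace()], [fitSingleExponential()]
#' @export
setClass("OsmoticTrace",
  slots = c(times = "numeric", values = "numeric", meta = "list"),
  prototype = prototype(meta = list()),
  validity = function(object) {
    msg <- character()
    if (length(object@times) != length(object@values))
      msg <- c(msg, "times and values must have equal length")
    if (length(object@times) < 3L)
      msg <- c(msg, "a trace needs at least 3 points")
    if (anyNA(object@times) || anyNA(object@values) ||
        any(!is.finite(object@times)) || any(!is.finite(object@values)))
      msg <- c(msg, "times and values must be finite")
    else {
      if (any(diff(object@times) <= 0))
        msg <- c(msg, "times must be strictly increasing")
      if (object@times[1L] < 0)
        msg <- c(msg, "times must be non-negative")
    }
    if (length(msg)) msg else TRUE
  })

#' Construct an osmotic-shock trace
#'
#' @param times sampling times in seconds, strictly increasing, >= 0.
#' @param values signal values (arbitrary units), one per time point.
#' @param meta optional named list of metadata.
#' @return An [OsmoticTrace-class] object.
#' @examples
#' tr <- osmoticTrace(0:10 / 10, exp(-2 * (0:10 / 10)))
#' @export
osmoticTrace <- function(times, values, meta = list()) {
  new("OsmoticTrace", times = as.numeric(times), values = as.numeric(values),
      meta = meta)
}

#' Vesicle or cell geometry
#'
#' Initial volume, surface area and osmotically inactive volume fraction of
#' the compartment exchanging water and glycerol.
#'
#' @slot v0 initial volume, cm^3.
#' @slot area surface area, cm^2 (held constant during a shock).
#' @slot inactiveFraction osmotically inactive volume fraction beta in [0, 1).
#' @export
setClass("VesicleGeometry",
  slots = c(v0 = "numeric", area = "numeric", inactiveFraction = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@v0) != 1L || !is.finite(object@v0) || object@v0 <= 0)
      msg <- c(msg, "v0 must be a single positive number")
    if (length(object@area) != 1L || !is.finite(object@area) ||
        object@area <= 0)
      msg <- c(msg, "area must be a single positive number")
    b <- object@inactiveFraction
    if (length(b) != 1L || !is.finite(b) || b < 0 || b >= 1)
      msg <- c(msg, "inactiveFraction must lie in [0, 1)")
    if (length(msg)) msg else TRUE
  })

#' @rdname VesicleGeometry-class
#' @param v0 initial volume, cm^3.
#' @param area surface area, cm^2.
#' @param inactiveFraction osmotically inactive fraction in [0, 1).
#' @export
vesicleGeometry <- function(v0, area, inactiveFraction = 0) {
  new("VesicleGeometry", v0 = v0, area = area,
      inactiveFraction = inactiveFraction)
}

#' Spherical geometry from a volume
#'
#' Builds a [VesicleGeometry-class] for a sphere, so that
#' `area = (36 * pi * v0^2)^(1/3)`.
#'
#' @inheritParams vesicleGeometry
#' @export
sphereGeometry <- function(v0, inactiveFraction = 0) {
  vesicleGeometry(v0, (36 * pi * v0^2)^(1 / 3), inactiveFraction)
}

#' Osmotic shock condition
#'
#' External and initial internal solute composition of an osmotic challenge.
#' Concentrations are osmolarities in osmol/L (impermeant species) and molar
#' glycerol concentrations in mol/L.
#'
#' @slot osmOutImpermeant external impermeant osmolarity, osmol/L.
#' @slot cGlyOut external glycerol concentration, mol/L.
#' @slot osmInImpermeant0 initial internal impermeant osmolarity, osmol/L.
#' @slot cGlyIn0 initial internal glycerol concentration, mol/L.
#' @slot temperature temperature, K.
#' @export
setClass("ShockCondition",
  slots = c(osmOutImpermeant = "numeric", cGlyOut = "numeric",
            osmInImpermeant0 = "numeric", cGlyIn0 = "numeric",
            temperature = "numeric"),
  validity = function(object) {
    v <- c(object@osmOutImpermeant, object@cGlyOut,
           object@osmInImpermeant0, object@cGlyIn0)
    msg <- character()
    if (length(v) != 4L || anyNA(v) || any(!is.finite(v)) || any(v < 0))
      msg <- c(msg, "all concentrations must be finite and >= 0")
    if (length(object@temperature) != 1L || object@temperature <= 0)
      msg <- c(msg, "temperature must be a single positive value (K)")
    if (length(msg)) msg else TRUE
  })

#' @rdname ShockCondition-class
#' @param osmOutImpermeant external impermeant osmolarity, osmol/L.
#' @param cGlyOut external glycerol concentration, mol/L.
#' @param osmInImpermeant0 initial internal impermeant osmolarity, osmol/L.
#' @param cGlyIn0 initial internal glycerol concentration, mol/L.
#' @param temperature temperature in K.
#' @export
shockCondition <- function(osmOutImpermeant, cGlyOut = 0,
                           osmInImpermeant0 = osmOutImpermeant, cGlyIn0 = 0,
                           temperature = 296.15) {
  new("ShockCondition", osmOutImpermeant = osmOutImpermeant,
      cGlyOut = cGlyOut, osmInImpermeant0 = osmInImpermeant0,
      cGlyIn0 = cGlyIn0, temperature = temperature)
}

#' Membrane permeability parameters
#'
#' @slot pf osmotic water permeability, cm/s.
#' @slot pgly glycerol permeability, cm/s.
#' @slot vw molar water volume, cm^3/mol (18.0 by default).
#' @export
setClass("FluxParams",
  slots = c(pf = "numeric", pgly = "numeric", vw = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@pf < 0 || object@pgly < 0)
      msg <- c(msg, "pf and pgly must be >= 0")
    if (object@vw <= 0)
      msg <- c(msg, "vw must be > 0")
    if (length(msg)) msg else TRUE
  })

#' @rdname FluxParams-class
#' @param pf water permeability, cm/s.
#' @param pgly glycerol permeability, cm/s.
#' @param vw molar water volume, cm^3/mol.
#' @export
fluxParams <- function(pf, pgly = 0, vw = 18) {
  new("FluxParams", pf = pf, pgly = pgly, vw = vw)
}

#' Simulated relative-volume trajectory
#'
#' Output of the coupled water/glycerol flux model: relative volume and
#' internal glycerol concentration at each time point. `cGlyIn` may be `NA`
#' for calibrated experimental traces, where only the relative volume is
#' observed.
#'
#' @slot times seconds.
#' @slot vRel V(t)/V0, unitless.
#' @slot cGlyIn internal glycerol concentration, mol/L (may be `NA`).
#' @slot inactiveFraction the beta used, for reference.
#' @export
setClass("VolumeTrajectory",
  slots = c(times = "numeric", vRel = "numeric", cGlyIn = "numeric",
            inactiveFraction = "numeric"),
  validity = function(object) {
    msg <- character()
    n <- length(object@times)
    if (length(object@vRel) != n || length(object@cGlyIn) != n)
      msg <- c(msg, "times, vRel and cGlyIn must have equal length")
    if (anyNA(object@vRel) || any(!is.finite(object@vRel)))
      msg <- c(msg, "vRel must be finite")
    else if (any(object@vRel <= object@inactiveFraction))
      msg <- c(msg, "vRel must exceed the osmotically inactive fraction")
    if (length(msg)) msg else TRUE
  })

newVolumeTrajectory <- function(times, vRel, cGlyIn = rep(NA_real_,
                                length(times)), inactiveFraction = 0) {
  new("VolumeTrajectory", times = as.numeric(times), vRel = as.numeric(vRel),
      cGlyIn = as.numeric(cGlyIn), inactiveFraction = inactiveFraction)
}

#' Single-exponential fit result
#'
#' Result of fitting `y(t) = yInf + (y0 - yInf) * exp(-k * t)`.
#'
#' @slot k rate constant, 1/s (>= 0).
#' @slot y0,yInf initial and asymptotic signal.
#' @slot rss residual sum of squares.
#' @slot converged logical, optimizer convergence.
#' @slot degenerate logical, TRUE for flat traces (k fixed at 0).
#' @export
setClass("ExpFit",
  slots = c(k = "numeric", y0 = "numeric", yInf = "numeric", rss = "numeric",
            converged = "logical", degenerate = "logical"),
  validity = function(object) {
    msg <- character()
    if (object@k < 0) msg <- c(msg, "k must be >= 0")
    if (is.finite(object@rss) && object@rss < 0)
      msg <- c(msg, "rss must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' Fluorescence-to-volume calibration line
#'
#' The linear relationship `vRel = a * F/F0 + b` between relative cell volume
#' and baseline-normalized fluorescence.
#'
#' @slot a slope (non-zero).
#' @slot b intercept.
#' @export
setClass("CalibrationLine",
  slots = c(a = "numeric", b = "numeric"),
  validity = function(object) {
    if (object@a == 0) "slope a must be non-zero" else TRUE
  })

#' @rdname CalibrationLine-class
#' @param a slope.
#' @param b intercept.
#' @export
calibrationLine <- function(a, b = 0) new("CalibrationLine", a = a, b = b)

#' Hill titration fit
#'
#' Fit of `p(pH) = pMax / (1 + 10^(n * (pH - pK)))`. The sign of `n` encodes
#' the direction of regulation: `n > 0` means activation by acidification
#' (hAQP10-like), `n < 0` activation by alkalinization (hAQP3-like).
#'
#' @slot pK midpoint pH.
#' @slot n signed Hill coefficient.
#' @slot pMax normalized amplitude.
#' @slot rss residual sum of squares.
#' @slot degenerate logical; TRUE when the data carry no pH dependence.
#' @export
setClass("HillFit",
  slots = c(pK = "numeric", n = "numeric", pMax = "numeric", rss = "numeric",
            degenerate = "logical"))

#' Arrhenius fit
#'
#' Ordinary least squares of `ln Pgly` on `1/T`; the activation energy is
#' `Ea = -slope * R`, reported positive for thermally activated transport,
#' in kJ/mol. R is fixed at 8.314 J/(mol K).
#'
#' @slot ea activation energy, kJ/mol.
#' @slot lnPrefactor intercept of the Arrhenius line.
#' @slot slope raw slope of ln Pgly vs 1/T, K.
#' @slot seEa standard error of ea, kJ/mol (NA with two points).
#' @export
setClass("ArrheniusFit",
  slots = c(ea = "numeric", lnPrefactor = "numeric", slope = "numeric",
            seEa = "numeric"))

#' Flux-model fit result
#'
#' Least-squares estimate of (Pf, Pgly) obtained by matching the forward
#' volume model to a calibrated relative-volume trace.
#'
#' @slot params fitted [FluxParams-class].
#' @slot se approximate standard errors, named (`pf`, `pgly`); NA where not
#'   identifiable.
#' @slot rss residual sum of squares.
#' @slot converged logical.
#' @slot identifiable named logical; FALSE for parameters that the shock
#'   design cannot constrain (e.g. Pgly without a glycerol gradient).
#' @slot fitted fitted relative volume at the data times.
#' @export
setClass("FluxFit",
  slots = c(params = "FluxParams", se = "numeric", rss = "numeric",
            converged = "logical", identifiable = "logical",
            fitted = "numeric"))

## ---------------------------------------------------------------------------
## Pore-profile containers
## ---------------------------------------------------------------------------

#' Set of atoms with van der Waals radii
#'
#' Coordinates plus per-atom annotation parsed from a PDB file, with an
#' assigned van der Waals radius per atom (HOLE "simple" table by default).
#'
#' @slot coords n x 3 matrix, Angstrom.
#' @slot vdw van der Waals radius per atom, Angstrom, > 0.
#' @slot element element symbol per atom.
#' @slot atomName PDB atom name per atom.
#' @slot resName residue name per atom.
#' @slot resNo residue number per atom.
#' @slot chain chain identifier per atom.
#' @slot record PDB record type per atom ("ATOM"/"HETATM").
#' @export
setClass("AtomSet",
  slots = c(coords = "matrix", vdw = "numeric", element = "character",
            atomName = "character", resName = "character", resNo = "integer",
            chain = "character", record = "character"),
  validity = function(object) {
    n <- nrow(object@coords)
    msg <- character()
    if (ncol(object@coords) != 3L)
      msg <- c(msg, "coords must be an n x 3 matrix")
    if (any(!is.finite(object@coords)))
      msg <- c(msg, "coordinates must be finite")
    lens <- c(length(object@vdw), length(object@element),
              length(object@atomName), length(object@resName),
              length(object@resNo), length(object@chain),
              length(object@record))
    if (any(lens != n))
      msg <- c(msg, "all per-atom slots must match nrow(coords)")
    if (any(object@vdw <= 0))
      msg <- c(msg, "all vdw radii must be > 0")
    if (length(msg)) msg else TRUE
  })

#' @rdname AtomSet-class
#' @param coords n x 3 coordinate matrix, Angstrom.
#' @param vdw per-atom van der Waals radii, Angstrom.
#' @param element,atomName,resName,resNo,chain,record per-atom annotation;
#'   recycled defaults are provided for synthetic systems.
#' @export
atomSet <- function(coords, vdw, element = "C", atomName = "C",
                    resName = "UNK", resNo = seq_len(nrow(coords)),
                    chain = "A", record = "ATOM") {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  new("AtomSet", coords = unname(coords), vdw = rep_len(vdw, n),
      element = rep_len(element, n), atomName = rep_len(atomName, n),
      resName = rep_len(resName, n), resNo = as.integer(rep_len(resNo, n)),
      chain = rep_len(chain, n), record = rep_len(record, n))
}

#' Pore radius profile
#'
#' Largest-inscribed-sphere radius along a channel axis: at each axial
#' position `s` (Angstrom, relative to the seed point) the in-plane position
#' maximizing the distance-to-nearest-atom-surface was located; `radii[i]` is
#' that maximal radius. Profiles terminate where the radius first exceeds the
#' stop radius (5 Angstrom by default).
#'
#' @slot s axial coordinate per slice, Angstrom, increasing.
#' @slot centers n x 3 matrix of optimized sphere centers.
#' @slot radii pore radius per slice, Angstrom.
#' @slot flagged logical per slice; TRUE where the optimizer failed to improve
#'   on its starting point.
#' @slot terminatedLow,terminatedHigh logical: TRUE when the corresponding end
#'   stopped because the radius exceeded the stop radius (rather than running
#'   out of atoms).
#' @slot axis unit vector of the channel axis.
#' @slot origin the seed point (s = 0).
#' @slot stopRadius the stop radius used, Angstrom.
#' @export
setClass("PoreProfile",
  slots = c(s = "numeric", centers = "matrix", radii = "numeric",
            flagged = "logical", terminatedLow = "logical",
            terminatedHigh = "logical", axis = "numeric", origin = "numeric",
            stopRadius = "numeric"),
  validity = function(object) {
    msg <- character()
    n <- length(object@s)
    if (nrow(object@centers) != n || length(object@radii) != n ||
        length(object@flagged) != n)
      msg <- c(msg, "s, centers, radii and flagged must be congruent")
    if (n > 1 && any(diff(object@s) <= 0))
      msg <- c(msg, "s must be strictly increasing")
    if (length(msg)) msg else TRUE
  })

#' Named axial region of a pore
#'
#' An axial window (in profile coordinates) derived from annotated residues,
#' e.g. the ar/R selectivity filter or the cytoplasmic gate.
#'
#' @slot name region name.
#' @slot window length-2 numeric, axial window `[lo, hi]` in Angstrom.
#' @slot resNo residue numbers defining the region (may be empty).
#' @slot chain chain the residues belong to ("" if unspecified).
#' @export
setClass("RegionAnnotation",
  slots = c(name = "character", window = "numeric", resNo = "integer",
            chain = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@window) != 2L || object@window[2] < object@window[1])
      msg <- c(msg, "window must be c(lo, hi) with lo <= hi")
    if (length(msg)) msg else TRUE
  })

#' @rdname RegionAnnotation-class
#' @param name region name.
#' @param window axial window `c(lo, hi)`, Angstrom.
#' @param resNo defining residue numbers (optional).
#' @param chain chain id (optional).
#' @export
poreRegion <- function(name, window, resNo = integer(), chain = "") {
  new("RegionAnnotation", name = name, window = as.numeric(window),
      resNo = as.integer(resNo), chain = chain)
}

## ---------------------------------------------------------------------------
## Gate-conformation containers
## ---------------------------------------------------------------------------

#' Trajectory ensemble of a fixed atom selection
#'
#' `F x M x 3` coordinates (Angstrom) of M selected atoms over F frames, with
#' a condition label and source monomer id per frame and per-atom annotation
#' (chain, residue number, atom name).
#'
#' @slot coords numeric array F x M x 3.
#' @slot labels condition tag per frame.
#' @slot monomer source monomer id per frame.
#' @slot atomMeta data.frame with columns `chain`, `resNo`, `atomName`, one
#'   row per atom.
#' @export
setClass("TrajectoryEnsemble",
  slots = c(coords = "array", labels = "character", monomer = "character",
            atomMeta = "data.frame"),
  validity = function(object) {
    d <- dim(object@coords)
    msg <- character()
    if (length(d) != 3L || d[3] != 3L)
      msg <- c(msg, "coords must be an F x M x 3 array")
    else {
      if (length(object@labels) != d[1])
        msg <- c(msg, "labels must have one entry per frame")
      if (length(object@monomer) != d[1])
        msg <- c(msg, "monomer must have one entry per frame")
      if (nrow(object@atomMeta) != d[2])
        msg <- c(msg, "atomMeta must have one row per atom")
    }
    if (any(!is.finite(object@coords)))
      msg <- c(msg, "coordinates must be finite")
    if (length(msg)) msg else TRUE
  })

#' @rdname TrajectoryEnsemble-class
#' @param coords F x M x 3 array of coordinates.
#' @param labels condition label per frame (recycled if length 1).
#' @param monomer monomer id per frame (recycled if length 1).
#' @param atomMeta per-atom data.frame (`chain`, `resNo`, `atomName`); a
#'   default CA selection is generated when omitted.
#' @export
trajectoryEnsemble <- function(coords, labels = "frame", monomer = "m1",
                               atomMeta = NULL) {
  d <- dim(coords)
  if (is.null(atomMeta))
    atomMeta <- data.frame(chain = "A", resNo = seq_len(d[2]),
                           atomName = "CA", stringsAsFactors = FALSE)
  new("TrajectoryEnsemble", coords = coords,
      labels = rep_len(as.character(labels), d[1]),
      monomer = rep_len(as.character(monomer), d[1]), atomMeta = atomMeta)
}

#' Principal component model of gate coordinates
#'
#' Eigendecomposition of the covariance of flattened (3M) superposed
#' coordinates. Components are orthonormal and the component variances sum to
#' the total variance of the centered data.
#'
#' @slot center mean vector (length 3M).
#' @slot rotation orthonormal component matrix (3M x ncomp).
#' @slot sdev standard deviation per component, non-increasing.
#' @slot scores per-frame scores (F x ncomp).
#' @export
setClass("PCAModel",
  slots = c(center = "numeric", rotation = "matrix", sdev = "numeric",
            scores = "matrix"),
  validity = function(object) {
    msg <- character()
    if (ncol(object@rotation) != length(object@sdev))
      msg <- c(msg, "rotation and sdev must agree in component count")
    if (ncol(object@scores) != length(object@sdev))
      msg <- c(msg, "scores and sdev must agree in component count")
    g <- crossprod(object@rotation)
    if (max(abs(g - diag(ncol(g)))) > 1e-6)
      msg <- c(msg, "components must be orthonormal")
    if (is.unsorted(rev(object@sdev)))
      msg <- c(msg, "explained variances must be non-increasing")
    if (length(msg)) msg else TRUE
  })

#' Sieved k-means cluster model
#'
#' k-means trained on every sieve-th frame of the PC scores, with all frames
#' assigned to the nearest centroid afterwards.
#'
#' @slot centroids k x d matrix in PC space.
#' @slot assignment cluster index per frame.
#' @slot populations k x nCondition matrix of population fractions; each
#'   column sums to 1.
#' @slot representatives frame index minimizing the distance to each centroid
#'   (NA for empty clusters).
#' @slot inertia total within-cluster sum of squares on the sieved training
#'   set.
#' @slot seed RNG seed used for the k-means++ initialization.
#' @slot sieve the sieving stride.
#' @export
setClass("ClusterModel",
  slots = c(centroids = "matrix", assignment = "integer",
            populations = "matrix", representatives = "integer",
            inertia = "numeric", seed = "integer", sieve = "integer"),
  validity = function(object) {
    msg <- character()
    k <- nrow(object@centroids)
    if (any(object@assignment < 1L | object@assignment > k))
      msg <- c(msg, "assignments must index the centroids")
    if (nrow(object@populations) != k)
      msg <- c(msg, "populations must have one row per cluster")
    if (ncol(object@populations) > 0) {
      cs <- colSums(object@populations)
      if (max(abs(cs - 1)) > 1e-8)
        msg <- c(msg, "population fractions must sum to 1 per condition")
    }
    if (length(msg)) msg else TRUE
  })
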