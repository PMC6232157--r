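## Largest-inscribed-sphere pore profiling along a channel axis.
##
## At each axial slice the in-plane position maximizing the distance to the
## nearest atom *surface* (Euclidean distance minus vdW radius) is located by
## a deterministic multi-start downhill simplex; marching proceeds in both
## directions from a seed point, each slice initialized from the previous
## optimum, and stops once the radius exceeds the stop radius (5 A) or the
## path leaves the atom bounding box.

#' Pore radius at a point
#'
#' The radius of the largest sphere centered at `point` that touches no atom:
#' `min_i(||point - x_i|| - vdw_i)`. Negative inside an atom.
#'
#' @param atoms an [AtomSet-class] with at least one atom.
#' @param point length-3 coordinate, Angstrom.
#' @return radius in Angstrom.
#' @export
poreRadiusAt <- function(atoms, point) {
  stopifnot(is(atoms, "AtomSet"), nAtoms(atoms) >= 1L)
  dx <- atoms@coords[, 1L] - point[1L]
  dy <- atoms@coords[, 2L] - point[2L]
  dz <- atoms@coords[, 3L] - point[3L]
  min(sqrt(dx * dx + dy * dy + dz * dz) - atoms@vdw)
}

## orthonormal in-plane basis perpendicular to a unit axis
.planeBasis <- function(axis) {
  ref <- if (abs(axis[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * axis) * axis
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2L] * e1[3L] - axis[3L] * e1[2L],
          axis[3L] * e1[1L] - axis[1L] * e1[3L],
          axis[1L] * e1[2L] - axis[2L] * e1[1L])
  list(e1 = e1, e2 = e2)
}

#' Optimize the sphere center within one axial slice
#'
#' Deterministic multi-start Nelder-Mead maximization of [poreRadiusAt()]
#' over the plane through `center` perpendicular to `axis`: 9 starts on a
#' 1 Angstrom grid around `center`, convergence tolerance `tol`.
#'
#' @param atoms an [AtomSet-class].
#' @param center in-plane starting point (defines the slice).
#' @param axis unit channel axis.
#' @param tol convergence tolerance on the radius, Angstrom.
#' @param startGrid half-spacing of the 3 x 3 start grid, Angstrom.
#' @return list with `center` (optimized point), `radius`, and `flagged`
#'   (TRUE when no restart improved on the starting point).
#' @export
sliceOptimum <- function(atoms, center, axis, tol = 0.01, startGrid = 1) {
  axis <- axis / sqrt(sum(axis^2))
  basis <- .planeBasis(axis)
  pointOf <- function(uv)
    center + uv[1L] * basis$e1 + uv[2L] * basis$e2
  negRadius <- function(uv) -poreRadiusAt(atoms, pointOf(uv))
  startRadius <- poreRadiusAt(atoms, center)

  offsets <- as.matrix(expand.grid(u = c(-1, 0, 1) * startGrid,
                                   v = c(-1, 0, 1) * startGrid))
  best <- list(value = Inf, par = c(0, 0))
  for (i in seq_len(nrow(offsets))) {
    opt <- stats::optim(offsets[i, ], negRadius, method = "Nelder-Mead",
                        control = list(maxit = 400, reltol = 1e-10))
    if (opt$value < best$value) best <- opt
  }
  radius <- -best$value
  list(center = pointOf(best$par), radius = radius,
       flagged = radius < startRadius - tol)
}

#' Profile a channel by marching slices along its axis
#'
#' From a seed point inside the channel, slices spaced `step` Angstrom apart
#' are profiled in both directions, each initialized from the previous
#' optimized center. Marching in a direction stops once the slice radius
#' exceeds `stopRadius` (that end is then flagged terminated) or the path
#' leaves the atom bounding box.
#'
#' @param atoms an [AtomSet-class] (already stripped, see
#'   [stripForProfile()]).
#' @param seedPoint length-3 point inside the channel (pore radius > 0).
#' @param axis channel axis (normalized internally); see [channelAxis()].
#' @param step axial slice spacing, Angstrom.
#' @param stopRadius termination radius, Angstrom (5 by default).
#' @param tol slice optimizer tolerance, Angstrom.
#' @return A [PoreProfile-class]; `s` is the axial coordinate relative to the
#'   seed point.
#' @export
profileChannel <- function(atoms, seedPoint, axis = c(0, 0, 1), step = 0.25,
                           stopRadius = 5, tol = 0.01) {
  stopifnot(is(atoms, "AtomSet"), nAtoms(atoms) >= 1L)
  axis <- axis / sqrt(sum(axis^2))
  seedPoint <- as.numeric(seedPoint)
  if (poreRadiusAt(atoms, seedPoint) <= 0)
    stop("seed point lies inside (or on) an atom; pick a point in the pore")

  sAtoms <- drop(atoms@coords %*% axis)
  margin <- max(atoms@vdw) + 1
  sBounds <- range(sAtoms) + c(-margin, margin)
  sSeed <- sum(seedPoint * axis)
  ## atoms further along the axis than this can never define a radius that is
  ## still below stopRadius at the slice, so pruning is exact for kept slices
  pruneDist <- stopRadius + max(atoms@vdw) + 6

  sliceAt <- function(center) {
    s <- sum(center * axis)
    sub <- which(abs(sAtoms - s) <= pruneDist)
    if (!length(sub))
      return(list(center = center, radius = Inf, flagged = FALSE))
    sliceOptimum(atoms[sub], center, axis, tol = tol)
  }

  seedSlice <- sliceAt(seedPoint)
  march <- function(dir) {
    out <- list()
    prev <- seedSlice$center
    terminated <- FALSE
    repeat {
      center0 <- prev + dir * step * axis
      s <- sum(center0 * axis)
      if (s < sBounds[1L] || s > sBounds[2L]) break
      sl <- sliceAt(center0)
      out[[length(out) + 1L]] <- sl
      if (sl$radius > stopRadius) { terminated <- TRUE; break }
      prev <- sl$center
    }
    list(slices = out, terminated = terminated)
  }

  up <- march(1)
  down <- march(-1)
  slices <- c(rev(down$slices), list(seedSlice), up$slices)
  centers <- do.call(rbind, lapply(slices, `[[`, "center"))
  radii <- vapply(slices, `[[`, numeric(1L), "radius")
  flagged <- vapply(slices, `[[`, logical(1L), "flagged")
  s <- drop(centers %*% axis) - sSeed

  ord <- order(s)
  new("PoreProfile", s = s[ord], centers = centers[ord, , drop = FALSE],
      radii = radii[ord], flagged = flagged[ord],
      terminatedLow = down$terminated, terminatedHigh = up$terminated,
      axis = axis, origin = seedPoint, stopRadius = stopRadius)
}

#' Estimate the channel axis as the principal axis of the CA trace
#'
#' The membrane normal of a single transmembrane bundle is approximated by
#' the first principal axis of its C-alpha coordinates.
#'
#' @param atoms an [AtomSet-class].
#' @return unit length-3 vector (oriented with a non-negative z component).
#' @export
channelAxis <- function(atoms) {
  stopifnot(is(atoms, "AtomSet"))
  ca <- atoms@coords[atoms@atomName == "CA", , drop = FALSE]
  if (nrow(ca) < 3L) ca <- atoms@coords
  ax <- stats::prcomp(ca)$rotation[, 1L]
  if (ax[3L] < 0) ax <- -ax
  unname(ax)
}

#' Centroid of the C-alpha atoms of given residues
#'
#' Default seed point for [profileChannel()]: the centroid of the CA atoms of
#' the residues the pore passes through.
#'
#' @param atoms an [AtomSet-class].
#' @param resNo residue numbers.
#' @param chain optional chain restriction.
#' @return length-3 coordinate.
#' @export
residueCentroid <- function(atoms, resNo, chain = NULL) {
  stopifnot(is(atoms, "AtomSet"))
  keep <- atoms@resNo %in% resNo & atoms@atomName == "CA"
  if (!is.null(chain)) keep <- keep & atoms@chain == chain
  if (!any(keep)) stop("no CA atoms found for the requested residues")
  colMeans(atoms@coords[keep, , drop = FALSE])
}

#' Axial region window from annotated residues
#'
#' Maps named residues (e.g. the ar/R filter or the cytoplasmic gate
#' S77/H80/R94) to an axial window: the CA centroid of the residues projected
#' on the channel axis, widened by `halfWidth` on both sides.
#'
#' @param atoms an [AtomSet-class].
#' @param resNo defining residue numbers.
#' @param axis unit channel axis (as used for the profile).
#' @param origin profile origin (the seed point handed to
#'   [profileChannel()]).
#' @param name region name.
#' @param chain optional chain restriction.
#' @param halfWidth half-width of the window, Angstrom (default 3).
#' @return A [RegionAnnotation-class].
#' @export
regionFromResidues <- function(atoms, resNo, axis, origin,
                               name = "region", chain = NULL,
                               halfWidth = 3) {
  centroid <- residueCentroid(atoms, resNo, chain)
  axis <- axis / sqrt(sum(axis^2))
  s0 <- sum((centroid - origin) * axis)
  poreRegion(name, c(s0 - halfWidth, s0 + halfWidth), resNo = resNo,
             chain = if (is.null(chain)) "" else chain)
}

#' Minimal pore radius within a region
#'
#' @param profile a [PoreProfile-class].
#' @param region a [RegionAnnotation-class] whose window overlaps the
#'   profile.
#' @return list with `radius` (Angstrom) and `s` (axial position of the
#'   minimum).
#' @export
minInRegion <- function(profile, region) {
  stopifnot(is(profile, "PoreProfile"), is(region, "RegionAnnotation"))
  idx <- which(profile@s >= region@window[1L] &
               profile@s <= region@window[2L])
  if (!length(idx))
    stop("region '", region@name, "' does not overlap the profile")
  i <- idx[which.min(profile@radii[idx])]
  list(radius = profile@radii[i], s = profile@s[i])
}

#' Compare minimal pore dimensions across structures
#'
#' Tabulates the overall minimal radius (and, when regions are given, the
#' per-region minima) for a set of profiles, sorted by increasing overall
#' minimum with ties broken by label.
#'
#' @param profiles list of [PoreProfile-class] objects (>= 2).
#' @param labels one label per profile.
#' @param regions optional named list of [RegionAnnotation-class] applied to
#'   every profile.
#' @return data.frame with `label`, `minRadius` and one column per region.
#' @export
compareProfiles <- function(profiles, labels, regions = NULL) {
  if (length(profiles) < 2L) stop("need at least 2 profiles")
  if (length(labels) != length(profiles))
    stop("one label per profile required")
  overall <- vapply(profiles, function(p) min(p@radii), numeric(1L))
  out <- data.frame(label = as.character(labels), minRadius = overall,
                    stringsAsFactors = FALSE)
  for (rn in names(regions)) {
    out[[rn]] <- vapply(profiles, function(p)
      minInRegion(p, regions[[rn]])$radius, numeric(1L))
  }
  out <- out[order(out$minRadius, out$label), , drop = FALSE]
  rownames(out) <- NULL
  out
}
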