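## Accessor generics and show methods. Slots are reached through these, never
## directly, so the internal representation can change without breaking users.

#' @name accessors
#' @title Accessors for poregate containers
#' @param x a poregate object.
#' @param ... unused.
#' @description Small accessor generics: `times()`, `signalValues()`,
#'   `traceMeta()`, `vRel()`, `cGlyIn()`, `nAtoms()`, `atomCoords()`,
#'   `vdwRadii()`, `axialCoords()`, `poreRadii()`, `poreCenters()`,
#'   `nFrames()`, `frameLabels()`, `frameCoords()`, `pcaScores()`,
#'   `explainedVariance()`, `clusterAssignments()`, `clusterPopulations()`,
#'   `clusterCentroids()`, `representatives()`.
NULL

#' @rdname accessors
#' @export
setGeneric("times", function(x) standardGeneric("times"))
#' @rdname accessors
#' @export
setGeneric("signalValues", function(x) standardGeneric("signalValues"))
#' @rdname accessors
#' @export
setGeneric("traceMeta", function(x) standardGeneric("traceMeta"))
#' @rdname accessors
#' @export
setGeneric("vRel", function(x) standardGeneric("vRel"))
#' @rdname accessors
#' @export
setGeneric("cGlyIn", function(x) standardGeneric("cGlyIn"))
#' @rdname accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))
#' @rdname accessors
#' @export
setGeneric("atomCoords", function(x) standardGeneric("atomCoords"))
#' @rdname accessors
#' @export
setGeneric("vdwRadii", function(x) standardGeneric("vdwRadii"))
#' @rdname accessors
#' @export
setGeneric("axialCoords", function(x) standardGeneric("axialCoords"))
#' @rdname accessors
#' @export
setGeneric("poreRadii", function(x) standardGeneric("poreRadii"))
#' @rdname accessors
#' @export
setGeneric("poreCenters", function(x) standardGeneric("poreCenters"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("frameLabels", function(x) standardGeneric("frameLabels"))
#' @rdname accessors
#' @param i frame index.
#' @export
setGeneric("frameCoords", function(x, i) standardGeneric("frameCoords"))
#' @rdname accessors
#' @export
setGeneric("pcaScores", function(x) standardGeneric("pcaScores"))
#' @rdname accessors
#' @export
setGeneric("explainedVariance",
           function(x) standardGeneric("explainedVariance"))
#' @rdname accessors
#' @export
setGeneric("clusterAssignments",
           function(x) standardGeneric("clusterAssignments"))
#' @rdname accessors
#' @export
setGeneric("clusterPopulations",
           function(x) standardGeneric("clusterPopulations"))
#' @rdname accessors
#' @export
setGeneric("clusterCentroids",
           function(x) standardGeneric("clusterCentroids"))
#' @rdname accessors
#' @export
setGeneric("representatives", function(x) standardGeneric("representatives"))

#' @rdname accessors
setMethod("times", "OsmoticTrace", function(x) x@times)
#' @rdname accessors
setMethod("signalValues", "OsmoticTrace", function(x) x@values)
#' @rdname accessors
setMethod("traceMeta", "OsmoticTrace", function(x) x@meta)
#' @rdname accessors
setMethod("times", "VolumeTrajectory", function(x) x@times)
#' @rdname accessors
setMethod("vRel", "VolumeTrajectory", function(x) x@vRel)
#' @rdname accessors
setMethod("cGlyIn", "VolumeTrajectory", function(x) x@cGlyIn)

#' @rdname accessors
setMethod("nAtoms", "AtomSet", function(x) nrow(x@coords))
#' @rdname accessors
setMethod("atomCoords", "AtomSet", function(x) x@coords)
#' @rdname accessors
setMethod("vdwRadii", "AtomSet", function(x) x@vdw)

#' @rdname accessors
setMethod("axialCoords", "PoreProfile", function(x) x@s)
#' @rdname accessors
setMethod("poreRadii", "PoreProfile", function(x) x@radii)
#' @rdname accessors
setMethod("poreCenters", "PoreProfile", function(x) x@centers)

#' @rdname accessors
setMethod("nFrames", "TrajectoryEnsemble", function(x) dim(x@coords)[1])
#' @rdname accessors
setMethod("nAtoms", "TrajectoryEnsemble", function(x) dim(x@coords)[2])
#' @rdname accessors
setMethod("frameLabels", "TrajectoryEnsemble", function(x) x@labels)
#' @rdname accessors
setMethod("frameCoords", "TrajectoryEnsemble",
          function(x, i) x@coords[i, , , drop = TRUE])

#' @rdname accessors
setMethod("pcaScores", "PCAModel", function(x) x@scores)
#' @rdname accessors
setMethod("explainedVariance", "PCAModel",
          function(x) x@sdev^2 / sum(x@sdev^2))

#' @rdname accessors
setMethod("clusterAssignments", "ClusterModel", function(x) x@assignment)
#' @rdname accessors
setMethod("clusterPopulations", "ClusterModel", function(x) x@populations)
#' @rdname accessors
setMethod("clusterCentroids", "ClusterModel", function(x) x@centroids)
#' @rdname accessors
setMethod("representatives", "ClusterModel", function(x) x@representatives)

## -- subsetting -------------------------------------------------------------

#' Subset an AtomSet by atom index
#' @param x an [AtomSet-class].
#' @param i integer or logical index.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "AtomSet", function(x, i, j, ..., drop = FALSE) {
  new("AtomSet", coords = x@coords[i, , drop = FALSE], vdw = x@vdw[i],
      element = x@element[i], atomName = x@atomName[i],
      resName = x@resName[i], resNo = x@resNo[i], chain = x@chain[i],
      record = x@record[i])
})

#' Subset a TrajectoryEnsemble by frame index
#' @param x a [TrajectoryEnsemble-class].
#' @param i integer or logical frame index.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "TrajectoryEnsemble", function(x, i, j, ..., drop = FALSE) {
  new("TrajectoryEnsemble", coords = x@coords[i, , , drop = FALSE],
      labels = x@labels[i], monomer = x@monomer[i], atomMeta = x@atomMeta)
})

## -- show methods -----------------------------------------------------------

setMethod("show", "OsmoticTrace", function(object) {
  cat(sprintf("OsmoticTrace: %d points over %.3g s", length(object@times),
              diff(range(object@times))))
  if (length(object@meta))
    cat(" |", paste(names(object@meta), unlist(object@meta), sep = "=",
                    collapse = ", "))
  cat("\n")
})

setMethod("show", "VolumeTrajectory", function(object) {
  cat(sprintf("VolumeTrajectory: %d points, vRel in [%.4f, %.4f]\n",
              length(object@times), min(object@vRel), max(object@vRel)))
})

setMethod("show", "FluxParams", function(object) {
  cat(sprintf("FluxParams: Pf = %.4g cm/s, Pgly = %.4g cm/s, Vw = %g cm3/mol\n",
              object@pf, object@pgly, object@vw))
})

setMethod("show", "ExpFit", function(object) {
  cat(sprintf("ExpFit: k = %.6g 1/s (tau = %.4g s), rss = %.4g%s\n",
              object@k, if (object@k > 0) 1 / object@k else Inf, object@rss,
              if (object@degenerate) " [degenerate]"
              else if (!object@converged) " [not converged]" else ""))
})

setMethod("show", "HillFit", function(object) {
  if (object@degenerate) {
    cat("HillFit: degenerate (no detectable pH dependence)\n")
  } else {
    cat(sprintf(
      "HillFit: pK = %.3f, n = %.3f (%s), pMax = %.3f, rss = %.4g\n",
      object@pK, object@n,
      if (object@n > 0) "activated by acidification"
      else "activated by alkalinization", object@pMax, object@rss))
  }
})

setMethod("show", "ArrheniusFit", function(object) {
  cat(sprintf("ArrheniusFit: Ea = %.3f kJ/mol (se %.3g), ln A = %.3f\n",
              object@ea, object@seEa, object@lnPrefactor))
})

setMethod("show", "FluxFit", function(object) {
  cat(sprintf(
    "FluxFit: Pf = %.4g (se %.2g), Pgly = %.4g (se %.2g) cm/s; rss = %.4g%s\n",
    object@params@pf, object@se[["pf"]], object@params@pgly,
    object@se[["pgly"]], object@rss,
    if (!object@converged) " [not converged]" else ""))
  if (!all(object@identifiable))
    cat("  non-identifiable:",
        paste(names(object@identifiable)[!object@identifiable],
              collapse = ", "), "\n")
})

setMethod("show", "AtomSet", function(object) {
  cat(sprintf("AtomSet: %d atoms, %d chain(s), records: %s\n",
              nAtoms(object), length(unique(object@chain)),
              paste(unique(object@record), collapse = "/")))
})

setMethod("show", "PoreProfile", function(object) {
  cat(sprintf(
    "PoreProfile: %d slices, s in [%.2f, %.2f] A, min radius %.3f A%s%s\n",
    length(object@s), min(object@s), max(object@s), min(object@radii),
    if (object@terminatedLow) " [low end: stop radius reached]" else "",
    if (object@terminatedHigh) " [high end: stop radius reached]" else ""))
})

setMethod("show", "TrajectoryEnsemble", function(object) {
  cat(sprintf("TrajectoryEnsemble: %d frames x %d atoms; conditions: %s\n",
              nFrames(object), nAtoms(object),
              paste(unique(object@labels), collapse = ", ")))
})

setMethod("show", "PCAModel", function(object) {
  ev <- explainedVariance(object)
  cat(sprintf("PCAModel: %d components; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              length(object@sdev), 100 * ev[1],
              if (length(ev) > 1) 100 * ev[2] else 0))
})

setMethod("show", "ClusterModel", function(object) {
  cat(sprintf("ClusterModel: k = %d, sieve = %d, %d frames assigned\n",
              nrow(object@centroids), object@sieve,
              length(object@assignment)))
})
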