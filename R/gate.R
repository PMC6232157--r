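## Gate-conformation analysis: Kabsch superposition, coordinate PCA, sieved
## k-means clustering, per-condition population maps, representative frames
## and pore-width distance descriptors.

## Kabsch rotation taking centered P onto centered Q (rows are atoms);
## proper rotation enforced (det = +1), so chirality is preserved.
.kabschRotation <- function(Pc, Qc) {
  s <- svd(crossprod(Pc, Qc))
  d <- sign(det(s$u) * det(s$v))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

.superposeOne <- function(P, ref, refCenter) {
  pc <- colMeans(P)
  Pc <- sweep(P, 2L, pc)
  R <- .kabschRotation(Pc, ref)
  list(coords = sweep(Pc %*% R, 2L, refCenter, `+`), rotation = R)
}

.checkNotCollinear <- function(M) {
  s <- svd(sweep(M, 2L, colMeans(M)))$d
  if (s[2L] < 1e-8 * max(s[1L], 1e-12))
    stop("degenerate (collinear) atom selection: superposition is not ",
         "defined")
}

#' Rigid-body superposition of all frames onto a reference
#'
#' Least-squares (Kabsch) rotation + translation of every frame onto the
#' reference frame. Only proper rotations are used (determinant +1), so a
#' mirror-image frame keeps a positive residual instead of being reflected.
#'
#' @param ensemble a [TrajectoryEnsemble-class] with M >= 3 non-collinear
#'   atoms.
#' @param reference frame index (default 1) or an M x 3 coordinate matrix.
#' @return The superposed [TrajectoryEnsemble-class].
#' @export
superposeFrames <- function(ensemble, reference = 1L) {
  stopifnot(is(ensemble, "TrajectoryEnsemble"))
  refM <- if (is.matrix(reference)) reference
          else ensemble@coords[reference, , , drop = TRUE]
  if (nrow(refM) < 3L) stop("need at least 3 atoms to superpose")
  .checkNotCollinear(refM)
  refCenter <- colMeans(refM)
  refC <- sweep(refM, 2L, refCenter)

  out <- ensemble@coords
  for (f in seq_len(dim(out)[1L])) {
    out[f, , ] <- .superposeOne(out[f, , , drop = TRUE], refC,
                                refCenter)$coords
  }
  initialize(ensemble, coords = out)
}

#' Per-frame RMSD against a reference
#'
#' Each frame is optimally superposed (Kabsch) onto the reference and the
#' root-mean-square deviation over the selection is reported.
#'
#' @inheritParams superposeFrames
#' @return numeric vector of per-frame RMSD (Angstrom) with attribute
#'   `"max"`.
#' @export
rmsdSeries <- function(ensemble, reference = 1L) {
  stopifnot(is(ensemble, "TrajectoryEnsemble"))
  refM <- if (is.matrix(reference)) reference
          else ensemble@coords[reference, , , drop = TRUE]
  .checkNotCollinear(refM)
  refCenter <- colMeans(refM)
  refC <- sweep(refM, 2L, refCenter)
  rmsd <- vapply(seq_len(nFrames(ensemble)), function(f) {
    al <- .superposeOne(ensemble@coords[f, , , drop = TRUE], refC,
                        refCenter)$coords
    sqrt(mean(rowSums((al - refM)^2)))
  }, numeric(1L))
  attr(rmsd, "max") <- max(rmsd)
  rmsd
}

## flatten F x M x 3 -> F x 3M (column order: all x, all y, all z)
.flattenFrames <- function(coords) {
  d <- dim(coords)
  matrix(coords, nrow = d[1L])
}

#' Principal component analysis of superposed frames
#'
#' Eigendecomposition of the covariance of the flattened (3M) Cartesian
#' coordinates, mean-centered and unscaled (mass-unweighted). Frames should
#' be superposed first ([superposeFrames()]); a plain numeric matrix is also
#' accepted for already-featurized data.
#'
#' @param x a superposed [TrajectoryEnsemble-class] (F >= 2) or an F x p
#'   numeric matrix.
#' @return A [PCAModel-class] with per-frame scores.
#' @export
pcaFit <- function(x) {
  X <- if (is(x, "TrajectoryEnsemble")) {
    if (nFrames(x) < 2L) stop("PCA needs at least 2 frames")
    .flattenFrames(x@coords)
  } else {
    as.matrix(x)
  }
  if (nrow(X) < 2L) stop("PCA needs at least 2 frames")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  new("PCAModel", center = unname(pc$center), rotation = unname(pc$rotation),
      sdev = pc$sdev, scores = unname(pc$x))
}

#' Reconstruct centered coordinates from a PCA model
#'
#' Projects scores back through the components; with all components retained
#' this reproduces the centered input exactly (up to round-off).
#'
#' @param model a [PCAModel-class].
#' @param scores score matrix (defaults to the model's own scores).
#' @return reconstructed (uncentered) data matrix.
#' @export
pcaReconstruct <- function(model, scores = pcaScores(model)) {
  sweep(scores %*% t(model@rotation), 2L, model@center, `+`)
}

## deterministic k-means++ seeding (uses the current RNG stream)
.kmeansppInit <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  centers[1L, ] <- X[sample.int(n, 1L), ]
  d2 <- rowSums(sweep(X, 2L, centers[1L, ])^2)
  for (j in seq_len(k - 1L) + 1L) {
    probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j, ] <- X[sample.int(n, 1L, prob = probs), ]
    d2 <- pmin(d2, rowSums(sweep(X, 2L, centers[j, ])^2))
  }
  centers
}

.nearestCentroid <- function(X, centers) {
  d2 <- sapply(seq_len(nrow(centers)), function(j)
    rowSums(sweep(X, 2L, centers[j, ])^2))
  d2 <- matrix(d2, nrow = nrow(X))
  list(cluster = max.col(-d2, ties.method = "first"), d2 = d2)
}

#' Sieved k-means clustering of PC scores
#'
#' k-means (k-means++ initialization under a fixed seed, then the standard
#' Hartigan-Wong iteration) trained on every `sieve`-th frame; all frames
#' are then assigned to their nearest centroid. Population fractions per
#' cluster are tabulated per condition label, and the frame closest to each
#' centroid is recorded as its representative (ties broken by lowest frame
#' index).
#'
#' @param scores F x d matrix of PC scores (pass the leading columns of
#'   [pcaScores()], e.g. `pcaScores(m)[, 1:2]`).
#' @param k number of clusters (>= 1, at most the number of sieved frames).
#' @param sieve training stride (>= 1; 5 reproduces every-fifth-frame
#'   sieving).
#' @param labels optional condition label per frame for the population
#'   table; defaults to a single condition.
#' @param seed RNG seed for the initialization (default 17).
#' @param nstart number of seeded k-means++ restarts; the run with the
#'   lowest inertia is kept (deterministic for a given seed).
#' @return A [ClusterModel-class].
#' @export
kmeansSieved <- function(scores, k, sieve = 5L, labels = NULL, seed = 17L,
                         nstart = 5L) {
  scores <- as.matrix(scores)
  nF <- nrow(scores)
  if (sieve < 1L) stop("sieve must be >= 1")
  if (k < 1L) stop("k must be >= 1")
  train <- scores[seq(1L, nF, by = sieve), , drop = FALSE]
  if (k > nrow(train))
    stop("k exceeds the number of sieved training frames")
  if (is.null(labels)) labels <- rep("all", nF)
  labels <- rep_len(as.character(labels), nF)

  km <- withr::with_seed(as.integer(seed), {
    if (k == 1L) {
      list(centers = matrix(colMeans(train), 1L),
           tot.withinss = sum(sweep(train, 2L, colMeans(train))^2))
    } else {
      best <- NULL
      for (r in seq_len(nstart)) {
        cand <- stats::kmeans(train, centers = .kmeansppInit(train, k),
                              iter.max = 100L)
        if (is.null(best) || cand$tot.withinss < best$tot.withinss)
          best <- cand
      }
      best
    }
  })

  assign <- .nearestCentroid(scores, km$centers)
  cl <- assign$cluster

  conds <- unique(labels)
  pops <- vapply(conds, function(cond)
    tabulate(cl[labels == cond], nbins = k) / sum(labels == cond),
    numeric(k))
  pops <- matrix(pops, nrow = k, dimnames = list(NULL, conds))

  reps <- vapply(seq_len(k), function(j) {
    members <- which(cl == j)
    if (!length(members)) return(NA_integer_)
    members[which.min(assign$d2[members, j])]
  }, integer(1L))

  new("ClusterModel", centroids = unname(km$centers), assignment = cl,
      populations = pops, representatives = reps,
      inertia = km$tot.withinss, seed = as.integer(seed),
      sieve = as.integer(sieve))
}

#' Per-condition population heat maps in PC space
#'
#' Normalized 2D histograms of the first two score columns, on a common grid
#' across conditions, mirroring the population-distribution heat map used to
#' read off dominant gate arrangements.
#'
#' @param scores F x >=2 score matrix.
#' @param labels condition label per frame.
#' @param bins number of bins per axis (default 50).
#' @return list with `breaksX`, `breaksY` and `maps`, a named list of
#'   bins x bins matrices each summing to 1.
#' @export
populationHeatmap <- function(scores, labels, bins = 50L) {
  scores <- as.matrix(scores)
  stopifnot(ncol(scores) >= 2L)
  labels <- rep_len(as.character(labels), nrow(scores))
  eps <- 1e-9 + 1e-9 * apply(scores[, 1:2, drop = FALSE], 2L,
                             function(v) diff(range(v)))
  bx <- seq(min(scores[, 1L]) - eps[1L], max(scores[, 1L]) + eps[1L],
            length.out = bins + 1L)
  by <- seq(min(scores[, 2L]) - eps[2L], max(scores[, 2L]) + eps[2L],
            length.out = bins + 1L)
  maps <- lapply(split(seq_along(labels), labels), function(idx) {
    cx <- cut(scores[idx, 1L], bx, include.lowest = TRUE)
    cy <- cut(scores[idx, 2L], by, include.lowest = TRUE)
    m <- table(cx, cy)
    unname(as.matrix(m) / sum(m))
  })
  list(breaksX = bx, breaksY = by, maps = maps)
}

#' Representative frame per cluster
#'
#' Extracts, for each cluster, the frame whose PC-space position is closest
#' to the cluster centroid, as a small ensemble labelled by cluster. Empty
#' clusters are dropped with a warning.
#'
#' @param model a [ClusterModel-class].
#' @param ensemble the [TrajectoryEnsemble-class] the model was fitted on.
#' @return A [TrajectoryEnsemble-class] of representative frames; frame
#'   indices in attribute `"frames"`.
#' @export
representativeStructure <- function(model, ensemble) {
  stopifnot(is(model, "ClusterModel"), is(ensemble, "TrajectoryEnsemble"))
  reps <- representatives(model)
  if (anyNA(reps)) {
    warning("empty cluster(s): ", paste(which(is.na(reps)), collapse = ", "),
            " have no representative")
  }
  keep <- which(!is.na(reps))
  out <- ensemble[reps[keep]]
  out@labels <- paste0("cluster", keep)
  attr(out, "frames") <- reps[keep]
  out
}

.resolveAtom <- function(ensemble, spec) {
  if (is.numeric(spec)) return(as.integer(spec))
  parts <- strsplit(spec, ":", fixed = TRUE)[[1L]]
  if (length(parts) == 2L) parts <- c(parts, "CA")
  meta <- ensemble@atomMeta
  hit <- which(meta$chain == parts[1L] & meta$resNo == as.integer(parts[2L]) &
               meta$atomName == parts[3L])
  if (length(hit) != 1L)
    stop("atom spec '", spec, "' resolves to ", length(hit), " atoms")
  hit
}

#' Per-frame pore-width distances
#'
#' Euclidean distances between named atom pairs (e.g. the CA-CA V76-L174 and
#' V76-H80 pore-width distances) for every frame. When PC scores are
#' supplied, the Pearson correlation of each distance with each score column
#' is attached.
#'
#' @param ensemble a [TrajectoryEnsemble-class].
#' @param pairs list of length-2 vectors; each entry is an atom index or a
#'   `"chain:resNo:atomName"` spec (atomName defaults to CA).
#' @param scores optional F x d score matrix for correlation reporting.
#' @return F x nPairs matrix of distances (Angstrom); attribute
#'   `"correlations"` (pairs x PCs) when `scores` is given.
#' @export
gateDistances <- function(ensemble, pairs, scores = NULL) {
  stopifnot(is(ensemble, "TrajectoryEnsemble"))
  d <- vapply(pairs, function(pr) {
    i <- .resolveAtom(ensemble, pr[[1L]])
    j <- .resolveAtom(ensemble, pr[[2L]])
    sqrt(rowSums((ensemble@coords[, i, , drop = TRUE] -
                  ensemble@coords[, j, , drop = TRUE])^2))
  }, numeric(nFrames(ensemble)))
  d <- matrix(d, nrow = nFrames(ensemble))
  colnames(d) <- vapply(pairs, function(pr)
    paste(unlist(pr), collapse = "-"), character(1L))
  if (!is.null(scores))
    attr(d, "correlations") <- stats::cor(d, as.matrix(scores))
  d
}

#' Concatenate trajectory ensembles
#'
#' Binds ensembles over the same atom selection frame-wise, e.g. the four
#' monomers of each simulation case plus crystal-structure frames, keeping
#' labels and monomer ids.
#'
#' @param ... [TrajectoryEnsemble-class] objects with identical atom counts.
#' @return the combined [TrajectoryEnsemble-class].
#' @export
bindEnsembles <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1L]]) &&
      !is(parts[[1L]], "TrajectoryEnsemble"))
    parts <- parts[[1L]]
  m <- unique(vapply(parts, nAtoms, integer(1L)))
  if (length(m) != 1L) stop("all ensembles must share the atom selection")
  total <- sum(vapply(parts, nFrames, integer(1L)))
  coords <- array(NA_real_, c(total, m, 3L))
  at <- 0L
  for (p in parts) {
    coords[at + seq_len(nFrames(p)), , ] <- p@coords
    at <- at + nFrames(p)
  }
  new("TrajectoryEnsemble", coords = coords,
      labels = unlist(lapply(parts, frameLabels)),
      monomer = unlist(lapply(parts, function(p) p@monomer)),
      atomMeta = parts[[1L]]@atomMeta)
}
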