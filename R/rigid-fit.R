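#' @include AllClasses.R constructors.R utils-geometry.R
NULL

#' Apply a rigid-body pose to a model
#'
#' Coordinates are centred on the model's centroid, rotated by the pose
#' quaternion, and translated so the centroid lands on the pose translation.
#'
#' @param model an [AssemblyModel].
#' @param p a [Pose].
#' @return a transformed [AssemblyModel].
#' @export
applyPose <- function(model, p) {
  a <- atoms(model)
  X <- as.matrix(a[, c("x", "y", "z")])
  cen <- colMeans(X)
  Y <- sweep(X, 2, cen) %*% t(quatToMatrix(p@quat))
  Y <- sweep(Y, 2, p@trans, "+")
  a$x <- Y[, 1]; a$y <- Y[, 2]; a$z <- Y[, 3]
  assemblyModel(a, source = model@provenance$source, model = 1L)
}

## Gaussian width from nominal resolution: sigma = res / (2 sqrt(2 ln 2)),
## i.e. the resolution is the FWHM of the point-spread Gaussian.
.resSigma <- function(resolution) resolution / (2 * sqrt(2 * log(2)))

## Add per-atom Gaussians (truncated at 3.5 sigma) into an array of given
## geometry. Separable evaluation: one small outer-product cube per atom.
.addGaussians <- function(dims, origin, voxel, X, sigma, out = NULL) {
  if (is.null(out)) out <- array(0, dim = dims)
  hw <- 3.5 * sigma
  inv <- 1 / (2 * sigma^2)
  for (k in seq_len(nrow(X))) {
    p <- X[k, ]
    lo <- pmax(1L, ceiling((p - hw - origin) / voxel) + 1L)
    hi <- pmin(dims, floor((p + hw - origin) / voxel) + 1L)
    if (any(lo > hi)) next
    ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
    gx <- exp(-((origin[1] + (ix - 1L) * voxel - p[1])^2) * inv)
    gy <- exp(-((origin[2] + (iy - 1L) * voxel - p[2])^2) * inv)
    gz <- exp(-((origin[3] + (iz - 1L) * voxel - p[3])^2) * inv)
    cube <- outer(outer(gx, gy), gz)
    out[ix, iy, iz] <- out[ix, iy, iz] + as.vector(cube)
  }
  out
}

#' Simulate a density map from a model
#'
#' Sum of per-atom Gaussians with `sigma = resolution / (2 sqrt(2 ln 2))`
#' (resolution = FWHM), sampled on a cubic grid covering the model plus
#' padding. Total integrated density is proportional to the atom count.
#'
#' @param model an [AssemblyModel].
#' @param resolution nominal resolution in Angstrom; must be at least twice
#'   the voxel size.
#' @param voxel voxel edge in Angstrom.
#' @param pad padding around the model bounding box, Angstrom (default
#'   equals the resolution).
#' @return a [DensityGrid].
#' @export
simulateDensity <- function(model, resolution, voxel, pad = resolution) {
  if (resolution < 2 * voxel)
    stop("resolution (", resolution, ") must be >= 2 x voxel (", voxel,
         "): the grid cannot sample the Gaussian")
  a <- atoms(model)
  if (nrow(a) == 0L) stop("model has no atoms")
  X <- as.matrix(a[, c("x", "y", "z")])
  lo <- apply(X, 2, min) - pad
  hi <- apply(X, 2, max) + pad
  dims <- pmax(1L, as.integer(ceiling((hi - lo) / voxel)) + 1L)
  g <- .addGaussians(dims, lo, voxel, X, .resSigma(resolution))
  densityGrid(g, voxel, lo)
}

#' Normalised cross-correlation of a posed model with a density map
#'
#' Simulates density for the posed model on the target grid geometry and
#' returns the Pearson correlation with the target over the model's support
#' (voxels where the simulated density is non-negligible). Zero-variance
#' overlap - including a posed model entirely outside the grid - scores 0.
#'
#' @param model an [AssemblyModel].
#' @param p a [Pose].
#' @param grid target [DensityGrid].
#' @param resolution resolution (Angstrom) used to blur the model.
#' @return correlation in `[-1, 1]`.
#' @export
crossCorrelation <- function(model, p, grid, resolution) {
  a <- atoms(model)
  X <- as.matrix(a[, c("x", "y", "z")])
  cen <- colMeans(X)
  Y <- sweep(X, 2, cen) %*% t(quatToMatrix(p@quat))
  Y <- sweep(Y, 2, p@trans, "+")
  .ccCoords(Y, grid, resolution)
}

## correlation of blurred coordinates against the grid; shared fast path
.ccCoords <- function(Y, grid, resolution) {
  dims <- dim(grid@data)
  vox <- grid@voxel
  org <- grid@origin
  sigma <- .resSigma(resolution)
  hw <- 3.5 * sigma
  lo <- pmax(1L, as.integer(ceiling((apply(Y, 2, min) - hw - org) / vox)) + 1L)
  hi <- pmin(dims, as.integer(floor((apply(Y, 2, max) + hw - org) / vox)) + 1L)
  if (any(lo > hi)) return(0)
  subDims <- hi - lo + 1L
  subOrg <- org + (lo - 1L) * vox
  sim <- .addGaussians(subDims, subOrg, vox, Y, sigma)
  tgt <- grid@data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
  sup <- sim > 1e-4 * max(sim)
  if (sum(sup) < 2L) return(0)
  s <- sim[sup]; t <- tgt[sup]
  if (stats::sd(s) == 0 || stats::sd(t) == 0) return(0)
  stats::cor(s, t)
}

#' Build a clustered fit library for one rigid body
#'
#' Samples `nPositions` poses - quasi-uniform rotations over SO(3)
#' (Shoemake mapping of a Halton sequence, so libraries are deterministic)
#' crossed with Halton translations inside the map bounding box restricted
#' to a sphere of `radius` around the map centre - keeps poses placing at
#' least `insideThreshold` of their atoms inside the map support, scores
#' them by [crossCorrelation()], and greedily clusters them: a pose joins
#' the best-scoring existing cluster whose exemplar lies within
#' `clusterAngle` degrees and `clusterShift` Angstrom. Clusters are ranked
#' by their best member's score.
#'
#' @param model the rigid body ([AssemblyModel]).
#' @param grid target [DensityGrid].
#' @param resolution blur resolution, Angstrom.
#' @param nPositions poses to sample (default 80000).
#' @param clusterAngle,clusterShift cluster tolerances (default 4 deg, 3 A).
#' @param radius translation sphere radius around the map centre (default
#'   200 A).
#' @param insideThreshold minimum fraction of atoms inside the map support
#'   (default 0.3).
#' @param supportLevel fraction of the map maximum defining support
#'   (default 0.02).
#' @param maxPoses keep only the best-scoring `maxPoses` poses for
#'   clustering (default 500); greedy clustering is quadratic, and only the
#'   well-scoring part of the library is ever used downstream.
#' @param refine number of top cluster exemplars to polish with
#'   [refinePose()] after clustering (0 = none); clusters are re-ranked by
#'   the refined scores.
#' @param body body identifier stored in the library.
#' @return a [FitLibrary]; empty (with a warning) when no pose passes the
#'   inside filter.
#' @export
buildFitLibrary <- function(model, grid, resolution, nPositions = 80000L,
                            clusterAngle = 4, clusterShift = 3, radius = 200,
                            insideThreshold = 0.3, supportLevel = 0.02,
                            maxPoses = 500L, refine = 0L, body = "body1") {
  stopifnot(nPositions >= 1L)
  a <- atoms(model)
  X0 <- as.matrix(a[, c("x", "y", "z")])
  X0 <- sweep(X0, 2, colMeans(X0))
  dims <- dim(grid@data)
  vox <- grid@voxel
  org <- grid@origin
  ctr <- org + (dims - 1) * vox / 2
  support <- grid@data > supportLevel * max(grid@data)

  n <- as.integer(nPositions)
  u <- cbind(haltonSeq(n, 2L), haltonSeq(n, 3L), haltonSeq(n, 5L))
  tv <- cbind(haltonSeq(n, 7L), haltonSeq(n, 11L), haltonSeq(n, 13L))
  tv <- sweep(sweep(tv, 2, (dims - 1) * vox, "*"), 2, org, "+")
  inSphere <- sqrt(rowSums(sweep(tv, 2, ctr)^2)) <= radius
  ## translations must land the body centroid on map support: placements in
  ## empty space cannot pass the inside filter anyway, so prune them early
  tvIdx <- round(sweep(tv, 2, org) / vox) + 1L
  tvOk <- tvIdx[, 1] >= 1 & tvIdx[, 1] <= dims[1] & tvIdx[, 2] >= 1 &
    tvIdx[, 2] <= dims[2] & tvIdx[, 3] >= 1 & tvIdx[, 3] <= dims[3]
  inSphere <- inSphere & tvOk
  inSphere[tvOk][!support[tvIdx[tvOk, , drop = FALSE]]] <- FALSE

  keepQ <- matrix(NA_real_, n, 4)
  insideFrac <- rep(NA_real_, n)
  score <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    if (!inSphere[k]) next
    q <- shoemakeQuat(u[k, 1], u[k, 2], u[k, 3])
    Y <- X0 %*% t(quatToMatrix(q))
    Y <- sweep(Y, 2, tv[k, ], "+")
    idx <- round(sweep(Y, 2, org) / vox) + 1L
    ok <- idx[, 1] >= 1 & idx[, 1] <= dims[1] & idx[, 2] >= 1 &
      idx[, 2] <= dims[2] & idx[, 3] >= 1 & idx[, 3] <= dims[3]
    frac <- 0
    if (any(ok))
      frac <- sum(support[idx[ok, , drop = FALSE]]) / nrow(Y)
    insideFrac[k] <- frac
    if (frac < insideThreshold) next
    keepQ[k, ] <- q
    score[k] <- .ccCoords(Y, grid, resolution)
  }
  sel <- which(!is.na(score))
  params <- list(nPositions = n, clusterAngle = clusterAngle,
                 clusterShift = clusterShift, radius = radius,
                 insideThreshold = insideThreshold, resolution = resolution)
  if (length(sel) == 0L) {
    warning("no pose passed the inside filter; returning an empty library")
    return(new("FitLibrary", poses = data.frame(), body = body,
               params = params))
  }
  ord <- sel[order(score[sel], decreasing = TRUE)]
  ord <- utils::head(ord, maxPoses)
  poses <- data.frame(qw = keepQ[ord, 1], qx = keepQ[ord, 2],
                      qy = keepQ[ord, 3], qz = keepQ[ord, 4],
                      tx = tv[ord, 1], ty = tv[ord, 2], tz = tv[ord, 3],
                      score = score[ord], inside = insideFrac[ord])
  if (refine > 0L) {
    ## rotation enrichment: paired rotation/translation sampling leaves the
    ## joint basin of a placement badly under-sampled, so candidate centres
    ## are re-scanned with a dense deterministic rotation set. Sites are
    ## local maxima of the map (a voxel at least as dense as its 26
    ## neighbours): blob centres are local maxima while superposition
    ## bridges between blobs are saddles, so every blob gets a site
    d <- grid@data
    isMax <- array(TRUE, dims)
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      xi <- pmin(pmax(seq_len(dims[1]) + dx, 1L), dims[1])
      yi <- pmin(pmax(seq_len(dims[2]) + dy, 1L), dims[2])
      zi <- pmin(pmax(seq_len(dims[3]) + dz, 1L), dims[3])
      isMax <- isMax & d >= d[xi, yi, zi]
    }
    cand <- which(isMax & d > 0.1 * max(d))
    cand <- cand[order(d[cand], decreasing = TRUE)]
    sites <- matrix(numeric(0), 0, 3)
    for (v in cand) {
      ijk <- arrayInd(v, dims)
      t <- org + (as.numeric(ijk) - 1) * vox
      if (nrow(sites) && any(sqrt(rowSums(sweep(sites, 2, t)^2)) < 10)) next
      sites <- rbind(sites, t)
      if (nrow(sites) >= 12L) break
    }
    ## per site: a dense rotation scan with a cheap atom-overlap objective
    ## (mean map density at the rotated atom positions), then full
    ## cross-correlation for the best handful. Cross-correlation is
    ## rotationally selective to ~15 degrees at these resolutions, so the
    ## scan must be dense; the overlap score makes that affordable
    nR <- 4096L
    uR <- cbind(haltonSeq(nR, 2L, offset = 5000L),
                haltonSeq(nR, 3L, offset = 5000L),
                haltonSeq(nR, 5L, offset = 5000L))
    rotList <- lapply(seq_len(nR), function(k)
      quatToMatrix(shoemakeQuat(uR[k, 1], uR[k, 2], uR[k, 3])))
    Yrot <- lapply(rotList, function(R) X0 %*% t(R))
    extra <- list()
    for (si in seq_len(nrow(sites))) {
      off <- sites[si, ] - org
      ov <- vapply(Yrot, function(Y) {
        idx <- round(sweep(Y, 2, off, "+") / vox) + 1L
        ok <- idx[, 1] >= 1 & idx[, 1] <= dims[1] & idx[, 2] >= 1 &
          idx[, 2] <= dims[2] & idx[, 3] >= 1 & idx[, 3] <= dims[3]
        if (!any(ok)) return(0)
        sum(d[idx[ok, , drop = FALSE]]) / nrow(Y)
      }, numeric(1))
      ## the best overlap rotations at the site are refined immediately:
      ## a body's centroid rarely coincides exactly with its blob's
      ## density peak, and at a few Angstrom of offset raw correlation
      ## misranks rotation modes, while refinement absorbs the offset
      for (k in utils::head(order(ov, decreasing = TRUE), 4L)) {
        q <- shoemakeQuat(uR[k, 1], uR[k, 2], uR[k, 3])
        r <- refinePose(model, new("Pose", quat = q, trans = sites[si, ],
                                   body = body),
                        grid, resolution, angle0 = 16, shift0 = 6)
        Y <- sweep(X0 %*% t(quatToMatrix(r$pose@quat)), 2, r$pose@trans, "+")
        idx <- round(sweep(Y, 2, org) / vox) + 1L
        ok <- idx[, 1] >= 1 & idx[, 1] <= dims[1] & idx[, 2] >= 1 &
          idx[, 2] <= dims[2] & idx[, 3] >= 1 & idx[, 3] <= dims[3]
        frac <- if (any(ok)) sum(support[idx[ok, , drop = FALSE]]) / nrow(Y)
                else 0
        if (frac < insideThreshold) next
        extra[[length(extra) + 1L]] <- data.frame(
          qw = r$pose@quat[1], qx = r$pose@quat[2], qy = r$pose@quat[3],
          qz = r$pose@quat[4], tx = r$pose@trans[1], ty = r$pose@trans[2],
          tz = r$pose@trans[3], score = r$score, inside = frac)
      }
    }
    if (length(extra)) {
      extra <- do.call(rbind, extra)
      ## refined site candidates are kept unconditionally: in a crowded map
      ## the correct placement can score below the global cap
      poses <- poses[order(poses$score, decreasing = TRUE), , drop = FALSE]
      poses <- unique(rbind(utils::head(poses, maxPoses), extra))
      poses <- poses[order(poses$score, decreasing = TRUE), , drop = FALSE]
    }
  }
  ## greedy clustering in score order: first pose of each cluster is its
  ## exemplar, so exemplars carry the cluster's best score by construction
  cl <- integer(nrow(poses))
  exQ <- list(); exT <- list()
  for (i in seq_len(nrow(poses))) {
    q <- as.numeric(poses[i, c("qw", "qx", "qy", "qz")])
    t <- as.numeric(poses[i, c("tx", "ty", "tz")])
    assigned <- 0L
    for (e in seq_along(exQ)) {
      if (quatAngle(q, exQ[[e]]) <= clusterAngle &&
          sqrt(sum((t - exT[[e]])^2)) <= clusterShift) {
        assigned <- e
        break
      }
    }
    if (assigned == 0L) {
      exQ[[length(exQ) + 1L]] <- q
      exT[[length(exT) + 1L]] <- t
      assigned <- length(exQ)
    }
    cl[i] <- assigned
  }
  poses$cluster <- cl
  poses$exemplar <- !duplicated(cl)
  if (refine > 0L) {
    ## spread the refinement budget spatially: at most 3 exemplars per
    ## 12 A translation neighbourhood, so every density region gets
    ## polished even when one region's smooth fits crowd the top ranks
    exRows <- which(poses$exemplar)
    refined <- matrix(numeric(0), 0, 3)
    chosen <- integer(0)
    for (e in exRows) {
      if (length(chosen) >= refine) break
      t <- as.numeric(poses[e, c("tx", "ty", "tz")])
      nNear <- if (nrow(refined)) sum(sqrt(rowSums(sweep(refined, 2, t)^2)) < 12)
               else 0L
      if (nNear >= 3L) next
      chosen <- c(chosen, e)
      refined <- rbind(refined, t)
    }
    ## every enrichment site keeps its best exemplar in the refinement set,
    ## so no density region is starved by better-scoring regions elsewhere
    if (exists("sites") && nrow(sites)) {
      exT <- as.matrix(poses[exRows, c("tx", "ty", "tz")])
      for (si in seq_len(nrow(sites))) {
        d <- sqrt(rowSums(sweep(exT, 2, sites[si, ])^2))
        near <- exRows[d < 12]
        if (length(near) && !near[1] %in% chosen)
          chosen <- c(chosen, near[1])
      }
    }
    for (e in chosen) {
      p0 <- pose(as.numeric(poses[e, c("qw", "qx", "qy", "qz")]),
                 as.numeric(poses[e, c("tx", "ty", "tz")]), body)
      r <- refinePose(model, p0, grid, resolution, angle0 = 24, shift0 = 6)
      if (r$score > poses$score[e]) {
        poses[e, c("qw", "qx", "qy", "qz")] <- as.list(r$pose@quat)
        poses[e, c("tx", "ty", "tz")] <- as.list(r$pose@trans)
        poses$score[e] <- r$score
      }
    }
    ## re-rank clusters by their (possibly refined) exemplar score
    exScore <- poses$score[poses$exemplar][order(unique(poses$cluster))]
    newId <- rank(-exScore, ties.method = "first")
    poses$cluster <- newId[poses$cluster]
    poses <- poses[order(poses$cluster, -poses$score), , drop = FALSE]
    poses$exemplar <- !duplicated(poses$cluster)
  }
  new("FitLibrary", poses = poses, body = body, params = params)
}

#' Deterministic local refinement of a pose against a map
#'
#' Pattern search on the cross-correlation: trial moves are +/- rotations
#' about the three axes and +/- axis translations, with step sizes halved
#' whenever no trial improves, from (`angle0`, `shift0`) down to
#' (`angleMin`, `shiftMin`). No randomness, so refinement is reproducible.
#'
#' @param model the rigid body.
#' @param p starting [Pose].
#' @param grid target [DensityGrid].
#' @param resolution blur resolution, Angstrom.
#' @param angle0,shift0 initial step sizes (degrees, Angstrom).
#' @param angleMin,shiftMin terminal step sizes.
#' @return list: `pose` (refined), `score` (its cross-correlation).
#' @export
refinePose <- function(model, p, grid, resolution, angle0 = 8, shift0 = 4,
                       angleMin = 0.5, shiftMin = 0.25) {
  a <- atoms(model)
  X0 <- as.matrix(a[, c("x", "y", "z")])
  X0 <- sweep(X0, 2, colMeans(X0))
  sc <- function(q, t) {
    Y <- sweep(X0 %*% t(quatToMatrix(q)), 2, t, "+")
    .ccCoords(Y, grid, resolution)
  }
  q <- p@quat; t <- p@trans
  best <- sc(q, t)
  ang <- angle0; shf <- shift0
  axes <- rbind(diag(3), -diag(3))
  while (ang >= angleMin || shf >= shiftMin) {
    improved <- FALSE
    for (k in seq_len(nrow(axes))) {
      qq <- quatMultiply(axisAngleQuat(abs(axes[k, ]), ang * sign(sum(axes[k, ]))), q)
      s <- sc(qq, t)
      if (s > best + 1e-9) { q <- qq; best <- s; improved <- TRUE }
      tt <- t + axes[k, ] * shf
      s <- sc(q, tt)
      if (s > best + 1e-9) { t <- tt; best <- s; improved <- TRUE }
    }
    if (!improved) { ang <- ang / 2; shf <- shf / 2 }
  }
  list(pose = pose(q, t, p@body), score = best)
}

#' Exemplar poses of a fit library
#'
#' @param lib a [FitLibrary].
#' @param n return at most the top `n` cluster exemplars.
#' @return list of [Pose] objects in cluster rank order.
#' @export
libraryExemplars <- function(lib, n = Inf) {
  p <- lib@poses
  if (nrow(p) == 0L) return(list())
  p <- p[p$exemplar, , drop = FALSE]
  p <- p[seq_len(min(nrow(p), n)), , drop = FALSE]
  lapply(seq_len(nrow(p)), function(i)
    pose(as.numeric(p[i, c("qw", "qx", "qy", "qz")]),
         as.numeric(p[i, c("tx", "ty", "tz")]), lib@body))
}

#' Default restraint weights
#'
#' Connectivity 1, cross-link 30, discrete 10000, excluded volume 10,
#' EM 1000.
#' @return named numeric(5).
#' @export
defaultWeights <- function() {
  c(connectivity = 1, xlink = 30, discrete = 10000, exvol = 10, em = 1000)
}

#' Score a multi-body configuration under the weighted restraint set
#'
#' Terms (raw values, each multiplied by its weight in the total):
#' \describe{
#'   \item{em}{`1 - mean` cross-correlation of the posed bodies with the map.}
#'   \item{xlink}{sum over mapped cross-links of `max(0, d - threshold)^2`
#'     (flat-bottom quadratic), with `d` the minimum Calpha-Calpha distance
#'     over all copies in the posed configuration.}
#'   \item{connectivity}{sum over declared chain continuations between bodies
#'     of `max(0, gap - maxGap)^2`.}
#'   \item{exvol}{count of inter-body atom pairs closer than the sum of
#'     their sphere radii.}
#'   \item{discrete}{0/1 penalty per declared required contact that is not
#'     made.}
#' }
#'
#' @param bodies list of [AssemblyModel] rigid bodies (chain ids must be
#'   unique across bodies).
#' @param poseList list of [Pose], one per body.
#' @param grid target [DensityGrid] (NULL drops the EM term).
#' @param resolution blur resolution for the EM term.
#' @param xlinks an [XLinkSet] (or NULL).
#' @param maps list of [ChainMap]s, one per body (needed for cross-links).
#' @param policy a [ThresholdPolicy] (threshold feeds the flat bottom).
#' @param weights named weights (see [defaultWeights()]).
#' @param connectivity data.frame `chain1,resno1,chain2,resno2,maxGap` of
#'   declared continuations (or NULL).
#' @param contacts data.frame `chain1,chain2,maxDist` of required contacts
#'   (or NULL).
#' @param beadRadius sphere radius per atom for excluded volume.
#' @return a [ScoreBreakdown].
#' @export
scoreConfiguration <- function(bodies, poseList, grid = NULL,
                               resolution = NULL, xlinks = NULL, maps = NULL,
                               policy = thresholdPolicy(),
                               weights = defaultWeights(),
                               connectivity = NULL, contacts = NULL,
                               beadRadius = 3.0) {
  if (length(bodies) != length(poseList))
    stop("need exactly one pose per rigid body (got ", length(bodies),
         " bodies, ", length(poseList), " poses)")
  posed <- mapply(applyPose, bodies, poseList, SIMPLIFY = FALSE)
  terms <- c(em = 0, xlink = 0, connectivity = 0, exvol = 0, discrete = 0)

  if (!is.null(grid)) {
    cc <- vapply(posed, function(m) {
      Y <- as.matrix(atoms(m)[, c("x", "y", "z")])
      .ccCoords(Y, grid, resolution)
    }, numeric(1))
    terms["em"] <- 1 - mean(cc)
  }

  allAtoms <- do.call(rbind, lapply(posed, atoms))
  combined <- assemblyModel(allAtoms, source = "<configuration>")

  if (!is.null(xlinks) && length(xlinks) > 0) {
    if (is.null(maps)) stop("cross-link scoring needs per-body chain maps")
    combMap <- chainMap(do.call(rbind, lapply(maps, chainMapTable)))
    l <- linkTable(xlinks)
    pen <- 0
    for (i in seq_len(nrow(l))) {
      d <- minCaDistance(combined, combMap, l$protein1[i], l$residue1[i],
                         l$protein2[i], l$residue2[i])
      if (d$mapped) pen <- pen + max(0, d$distance - policy@threshold)^2
    }
    terms["xlink"] <- pen
  }

  if (length(posed) > 1L) {
    ov <- 0
    for (i in seq_along(posed)) for (j in seq_along(posed)) {
      if (j <= i) next
      Xi <- as.matrix(atoms(posed[[i]])[, c("x", "y", "z")])
      Xj <- as.matrix(atoms(posed[[j]])[, c("x", "y", "z")])
      ov <- ov + sum(crossDist2(Xi, Xj) < (2 * beadRadius)^2)
    }
    terms["exvol"] <- ov
  }

  ca <- allAtoms[allAtoms$elety == "CA", , drop = FALSE]
  site <- function(ch, rn) {
    s <- ca[ca$chain == ch & ca$resno == rn, c("x", "y", "z"), drop = FALSE]
    if (nrow(s) == 0L) NULL else as.numeric(s[1, ])
  }
  if (!is.null(connectivity) && nrow(connectivity)) {
    pen <- 0
    for (i in seq_len(nrow(connectivity))) {
      p1 <- site(connectivity$chain1[i], connectivity$resno1[i])
      p2 <- site(connectivity$chain2[i], connectivity$resno2[i])
      if (is.null(p1) || is.null(p2)) next
      gap <- sqrt(sum((p1 - p2)^2))
      pen <- pen + max(0, gap - connectivity$maxGap[i])^2
    }
    terms["connectivity"] <- pen
  }
  if (!is.null(contacts) && nrow(contacts)) {
    pen <- 0
    for (i in seq_len(nrow(contacts))) {
      Xi <- as.matrix(allAtoms[allAtoms$chain == contacts$chain1[i],
                               c("x", "y", "z"), drop = FALSE])
      Xj <- as.matrix(allAtoms[allAtoms$chain == contacts$chain2[i],
                               c("x", "y", "z"), drop = FALSE])
      made <- nrow(Xi) && nrow(Xj) &&
        min(crossDist2(Xi, Xj)) < contacts$maxDist[i]^2
      pen <- pen + as.numeric(!made)
    }
    terms["discrete"] <- pen
  }
  new("ScoreBreakdown", terms = terms, weights = weights[names(terms)],
      total = sum(terms * weights[names(terms)]))
}

#' Monte-Carlo simulated annealing over rigid-body configurations
#'
#' Moves propose either a jump to a random fit-library cluster exemplar or a
#' local perturbation of the current pose (rotation up to `localAngle`
#' degrees about a random axis, translation up to `localShift` Angstrom).
#' Acceptance is Metropolis on the weighted total score with the stage
#' temperature as energy scale. The best configuration ever visited is
#' returned. Fully reproducible for a fixed seed.
#'
#' @param bodies,maps,grid,resolution,xlinks,policy,weights,connectivity,contacts,beadRadius
#'   as in [scoreConfiguration()].
#' @param libraries list of [FitLibrary], one per body; an empty library is
#'   an error.
#' @param schedule an [AnnealSchedule] (default: the six-stage regime).
#' @param seed integer RNG seed.
#' @param nExemplars exemplars per library available as jump targets.
#' @param pExemplar probability of an exemplar jump (vs local move).
#' @param localShift,localAngle local move magnitudes (0 restricts the
#'   search to library exemplars).
#' @param init `"greedy"` (default) seeds each body in turn at the library
#'   exemplar minimising the partial configuration score given the bodies
#'   already placed; `"random"` starts from random exemplars.
#' @param finalRefine polish the best configuration after the last stage
#'   with a deterministic pattern search on the total score (default TRUE;
#'   automatically off when local moves are disabled, so exemplar-only
#'   searches stay on the exemplar grid).
#' @return list: `poses` (best configuration), `score` ([ScoreBreakdown]),
#'   `trace` (current total per step), `acceptance` (per-stage rates).
#' @export
annealFit <- function(bodies, maps, grid, resolution, xlinks = NULL,
                      libraries, schedule = annealSchedule(), seed = 1L,
                      policy = thresholdPolicy(), weights = defaultWeights(),
                      connectivity = NULL, contacts = NULL, beadRadius = 3.0,
                      nExemplars = 25L, pExemplar = 0.5, localShift = 2,
                      localAngle = 5, init = c("greedy", "random"),
                      finalRefine = TRUE) {
  init <- match.arg(init)
  if (localShift == 0 && localAngle == 0) finalRefine <- FALSE
  ex <- lapply(libraries, libraryExemplars, n = nExemplars)
  if (any(vapply(ex, length, 1L) == 0L))
    stop("empty fit library for at least one body")
  set.seed(as.integer(seed))
  nb <- length(bodies)
  if (init == "greedy") {
    cur <- vector("list", nb)
    placed <- integer(0)
    for (b in seq_len(nb)) {
      bestScore <- Inf
      for (e in ex[[b]]) {
        idx <- c(placed, b)
        sb <- scoreConfiguration(bodies[idx], c(cur[placed], list(e)), grid,
                                 resolution, xlinks, maps[idx], policy,
                                 weights, connectivity, contacts, beadRadius)
        if (totalScore(sb) < bestScore) {
          bestScore <- totalScore(sb)
          cur[[b]] <- e
        }
      }
      placed <- c(placed, b)
    }
  } else {
    cur <- lapply(seq_len(nb), function(b) ex[[b]][[sample.int(length(ex[[b]]), 1)]])
  }
  evalCfg <- function(cfg) scoreConfiguration(
    bodies, cfg, grid, resolution, xlinks, maps, policy, weights,
    connectivity, contacts, beadRadius)
  curScore <- evalCfg(cur)
  best <- cur
  bestScore <- curScore
  stages <- scheduleStages(schedule)
  trace <- numeric(0)
  accRate <- numeric(nrow(stages))
  for (s in seq_len(nrow(stages))) {
    temp <- stages$temp[s]
    acc <- 0L
    for (step in seq_len(stages$steps[s])) {
      b <- sample.int(nb, 1)
      prop <- cur
      if (stats::runif(1) < pExemplar || (localShift == 0 && localAngle == 0)) {
        prop[[b]] <- ex[[b]][[sample.int(length(ex[[b]]), 1)]]
      } else {
        p0 <- cur[[b]]
        ax <- stats::rnorm(3)
        dq <- axisAngleQuat(ax, stats::runif(1, 0, localAngle))
        dt <- stats::rnorm(3)
        dt <- dt / sqrt(sum(dt^2)) * stats::runif(1, 0, localShift)
        prop[[b]] <- pose(quatMultiply(dq, p0@quat), p0@trans + dt, p0@body)
      }
      propScore <- evalCfg(prop)
      dE <- totalScore(propScore) - totalScore(curScore)
      if (dE <= 0 || stats::runif(1) < exp(-dE / temp)) {
        cur <- prop
        curScore <- propScore
        acc <- acc + 1L
        if (totalScore(curScore) < totalScore(bestScore)) {
          best <- cur
          bestScore <- curScore
        }
      }
      trace <- c(trace, totalScore(curScore))
    }
    accRate[s] <- acc / stages$steps[s]
  }
  if (finalRefine) {
    ## deterministic pattern search on the total score: cycle over bodies,
    ## trial +/- axis rotations and shifts, halve steps when stuck
    ang <- 16; shf <- 8
    axes <- rbind(diag(3), -diag(3))
    while (ang >= 0.5 || shf >= 0.25) {
      improved <- FALSE
      for (b in seq_len(nb)) {
        for (k in seq_len(nrow(axes))) {
          p0 <- best[[b]]
          qq <- quatMultiply(axisAngleQuat(abs(axes[k, ]),
                                          ang * sign(sum(axes[k, ]))), p0@quat)
          prop <- best
          prop[[b]] <- pose(qq, p0@trans, p0@body)
          sc <- evalCfg(prop)
          if (totalScore(sc) < totalScore(bestScore) - 1e-9) {
            best <- prop; bestScore <- sc; improved <- TRUE
          }
          prop <- best
          p0 <- best[[b]]
          prop[[b]] <- pose(p0@quat, p0@trans + axes[k, ] * shf, p0@body)
          sc <- evalCfg(prop)
          if (totalScore(sc) < totalScore(bestScore) - 1e-9) {
            best <- prop; bestScore <- sc; improved <- TRUE
          }
        }
      }
      if (!improved) { ang <- ang / 2; shf <- shf / 2 }
    }
  }
  list(poses = best, score = bestScore, trace = trace,
       acceptance = data.frame(temp = stages$temp, steps = stages$steps,
                               rate = accRate))
}

#' Score histogram and convergence verdict over independent runs
#'
#' The diagnostic mirrors the score-distribution check used for global
#' optimisation runs: when all runs land in one near-Gaussian mass there is
#' no evidence of a distinct good-scoring solution, while a best-scoring
#' mode separated from the main mass indicates convergence. Operationally,
#' the verdict is `"converged"` iff the best (lowest) 5% of scores lie below
#' the mean of the remaining scores by more than twice their standard
#' deviation *and* are separated from them by a gap larger than half that
#' standard deviation. (The gap condition is required: the lowest 5% of a
#' single Gaussian sits slightly more than two of its truncated SDs below
#' the rest, so the mean condition alone would mislabel a pure Gaussian.)
#' The verdict is invariant under rescaling all scores by a positive
#' constant.
#'
#' @param scores numeric vector of final run scores (>= 30 runs).
#' @param nBins histogram bin count (default 15).
#' @return list: `histogram` (data.frame lower, upper, count), `verdict`,
#'   `gap`, `bestMean`, `mainMean`, `mainSD`.
#' @export
scoreHistogram <- function(scores, nBins = 15L) {
  if (length(scores) < 30L)
    stop("need at least 30 independent run scores, got ", length(scores))
  br <- seq(min(scores), max(scores), length.out = nBins + 1L)
  h <- graphics::hist(scores, breaks = br, plot = FALSE)
  k <- max(1L, ceiling(0.05 * length(scores)))
  srt <- sort(scores)
  best <- srt[seq_len(k)]
  main <- srt[-seq_len(k)]
  gap <- min(main) - max(best)
  sdm <- stats::sd(main)
  converged <- mean(best) < mean(main) - 2 * sdm && gap > 0.5 * sdm
  list(histogram = data.frame(lower = h$breaks[-length(h$breaks)],
                              upper = h$breaks[-1], count = h$counts),
       verdict = if (converged) "converged" else "not converged",
       gap = gap, bestMean = mean(best), mainMean = mean(main), mainSD = sdm)
}
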