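#' @include AllClasses.R constructors.R utils-geometry.R xlink-validation.R
NULL

## ---- building blocks ----------------------------------------------------

## Compact random coil of CA beads: step-3.8 walk confined to a sphere.
## Uses the session RNG (callers seed it); returns centred coordinates.
.randomCoil <- function(n, radius = 2.2 * n^(1/3) + 4, step = 3.8) {
  X <- matrix(0, n, 3)
  for (k in seq_len(n)[-1]) {
    for (try in 1:100) {
      d <- stats::rnorm(3)
      p <- X[k - 1, ] + d / sqrt(sum(d^2)) * step
      if (sum(p^2) <= radius^2) break
      p <- X[k - 1, ] - X[k - 1, ] / sqrt(sum(X[k - 1, ]^2)) * step
    }
    X[k, ] <- p
  }
  sweep(X, 2, colMeans(X))
}

## Compact three-arm star of CA beads with a small random wiggle: rigid-fit
## test bodies need shape asymmetry that survives low-resolution blurring
## (a compact or ellipsoidal coil is rotationally near-degenerate once
## blurred) and a bounded extent (~35 A), so that neighbouring bodies'
## densities stay distinct no matter how many beads a body carries: extra
## beads thicken the arms as parallel strands instead of lengthening them.
## Arm bead counts get a small random jitter so bodies differ in shape,
## not just mass.
.lBody <- function(n, step = 3.5) {
  counts <- c(10L, 7L, 5L) + sample(c(-1L, 0L, 1L), 3L, replace = TRUE)
  if (n < sum(counts)) counts <- pmax(2L, round(counts * n / sum(counts)))
  base <- rbind(cbind(step * seq_len(counts[1]), 0, 0),
                cbind(0, step * seq_len(counts[2]), 0),
                cbind(0, 0, step * seq_len(counts[3])))
  extra <- n - nrow(base)
  if (extra > 0) {
    e1 <- min(extra, counts[1])
    base <- rbind(base, cbind(step * seq_len(e1), 4, 2.5))
    extra <- extra - e1
  }
  if (extra > 0) {
    e2 <- min(extra, counts[2])
    base <- rbind(base, cbind(4, step * seq_len(e2), 2.5))
    extra <- extra - e2
  }
  if (extra > 0)
    base <- rbind(base, cbind(step * seq_len(extra), -4, -2.5))
  base <- base + matrix(stats::rnorm(3L * nrow(base), 0, 1.2), nrow(base))
  sweep(base, 2, colMeans(base))
}

## Elongated IFTA thread in the extended state-B unit frame: runs from the
## unit centre out along +x with a small lateral offset, so the C2 image
## (IFTA2) runs out along -x at the opposite offset and consecutive units'
## antiparallel threads pass within contact distance of each other.
.threadB <- function(n, halfLen = 230) {
  k <- seq_len(n)
  dx <- halfLen / n
  cbind(x = 5 + dx * k, y = 3.5 + 1.2 * sin(k / 4), z = 1.0 * cos(k / 3.7))
}

## Same chain in the compact state-A conformation: perpendicular to the
## polymer axis (vertical), IFTA1/IFTA2 side by side.
.threadA <- function(n, halfLen = 230, ySign = 1) {
  k <- seq_len(n)
  dz <- halfLen / n
  cbind(x = 0.8 * cos(k / 3.7), y = ySign * (3.5 + 1.2 * sin(k / 4)),
        z = 5 + dz * k)
}

.c2z <- function(X) cbind(-X[, 1], -X[, 2], X[, 3])

.beadAtoms <- function(X, chain, startRes = 1L) {
  data.frame(chain = chain, resno = seq_len(nrow(X)) + startRes - 1L,
             resid = "ALA", elety = "CA", element = "C",
             x = X[, 1], y = X[, 2], z = X[, 3], b = 90,
             stringsAsFactors = FALSE)
}

## Independent brute-force minimum CA-CA distance used for truth tables:
## plain loops over every copy pair, deliberately separate from the
## vectorised production path.
.bruteMinDist <- function(atomTab, mapTab, p1, r1, p2, r2) {
  ch1 <- mapTab$chain[tolower(mapTab$protein) == tolower(p1)]
  ch2 <- mapTab$chain[tolower(mapTab$protein) == tolower(p2)]
  s1 <- atomTab[atomTab$chain %in% ch1 & atomTab$resno == r1 &
                  atomTab$elety == "CA", , drop = FALSE]
  s2 <- atomTab[atomTab$chain %in% ch2 & atomTab$resno == r2 &
                  atomTab$elety == "CA", , drop = FALSE]
  if (nrow(s1) == 0L || nrow(s2) == 0L) return(NA_real_)
  same <- tolower(p1) == tolower(p2) && r1 == r2
  best <- Inf
  for (i in seq_len(nrow(s1))) for (j in seq_len(nrow(s2))) {
    if (same && s1$chain[i] == s2$chain[j]) next
    d <- sqrt((s1$x[i] - s2$x[j])^2 + (s1$y[i] - s2$y[j])^2 +
                (s1$z[i] - s2$z[j])^2)
    if (d < best) best <- d
  }
  if (is.finite(best)) best else NA_real_
}

## ---- two-state generator ------------------------------------------------

#' Generate a two-state synthetic polymer with planted ground truth
#'
#' Builds the same set of chains in two conformations: a compact stacked
#' state A with separate IFTA (115 A repeat) and IFTB (65 A repeat)
#' sub-polymers, and an extended state B in which each repeating unit (one
#' IFTA complex, two IFTB complexes) is internally 2-fold symmetric about an
#' axis perpendicular to the polymer axis and units repeat every
#' `visibleRepeatB / unitsPerVisibleRepeat` Angstrom. Cross-links are
#' planted by classifying candidate residue pairs against the threshold in
#' both states (all-copy-pair brute force) and drawing from the four
#' (satisfied-in-A x satisfied-in-B) buckets to hit the requested satisfied
#' fractions; every planted distance is kept at least `margin` Angstrom away
#' from the threshold in both states. A `flexFrac` fraction of residues is
#' marked low-confidence (pLDDT 30) in contiguous segments. Coordinate noise
#' is applied after the truth table is computed; at noise 0 the truth is
#' exact by construction.
#'
#' @param spec a [SyntheticSpec].
#' @return list: `modelA`, `modelB` ([AssemblyModel]s), `map` (shared
#'   [ChainMap]), `xlinks` ([XLinkSet]), `truth` (data.frame id, endpoints,
#'   distA, distB, classA, classB), `spec`.
#' @export
generateTwoState <- function(spec = syntheticSpec()) {
  validObject(spec)
  set.seed(spec@seed)
  nU <- spec@nUnits
  n <- spec@domainsPerSubcomplex * spec@atomsPerDomain
  sB <- spec@visibleRepeatB / spec@unitsPerVisibleRepeat
  sA <- spec@spacingA

  ## unit-frame templates (state B) and their state-A counterparts;
  ## coil shapes are drawn once and reused in both states
  coilB1 <- .randomCoil(n)
  coilB2 <- .randomCoil(n)
  a1B <- .threadB(n)
  a2B <- .c2z(a1B)
  b1iB <- sweep(coilB1, 2, c(60, 28, 14), "+")
  b2iB <- sweep(coilB2, 2, c(60, 28, -14), "+")
  b1oB <- .c2z(b1iB)
  b2oB <- .c2z(b2iB)
  a1A <- .threadA(n, ySign = 1)
  a2A <- .threadA(n, ySign = -1)

  rowsA <- list(); rowsB <- list(); mapRows <- list()
  addChain <- function(ch, prot, copy, sub, unit, XA, XB) {
    rowsA[[length(rowsA) + 1L]] <<- .beadAtoms(XA, ch)
    rowsB[[length(rowsB) + 1L]] <<- .beadAtoms(XB, ch)
    mapRows[[length(mapRows) + 1L]] <<- data.frame(
      chain = ch, protein = prot, copy = copy, subcomplex = sub,
      unit = unit, stringsAsFactors = FALSE)
  }
  for (u in seq_len(nU)) {
    xB <- (u - 1) * sB
    xA <- (u - 1) * sA[["IFTA"]]
    shift <- function(X, dx) sweep(X, 2, c(dx, 0, 0), "+")
    addChain(sprintf("a1u%d", u), "IFTA1", u, "IFTA1", u,
             shift(a1A, xA), shift(a1B, xB))
    addChain(sprintf("a2u%d", u), "IFTA2", u, "IFTA2", u,
             shift(a2A, xA), shift(a2B, xB))
    for (side in c("i", "o")) {
      copy <- if (side == "i") 2L * u - 1L else 2L * u
      xAc <- (copy - 1) * sA[["IFTB"]]
      b1 <- if (side == "i") b1iB else b1oB
      b2 <- if (side == "i") b2iB else b2oB
      b1A <- sweep(coilB1, 2, c(xAc, 45, 200), "+")
      b2A <- sweep(coilB2, 2, c(xAc, 45, 170), "+")
      addChain(sprintf("b1%s%d", side, u), "IFTB1", copy, "IFTB1", u,
               b1A, shift(b1, xB))
      addChain(sprintf("b2%s%d", side, u), "IFTB2", copy, "IFTB2", u,
               b2A, shift(b2, xB))
    }
  }
  atomsA <- do.call(rbind, rowsA)
  atomsB <- do.call(rbind, rowsB)
  mapTab <- do.call(rbind, mapRows)

  ## low-confidence segments, identical in both states
  nFlex <- round(spec@flexFrac * n)
  if (nFlex > 0L) {
    for (ch in unique(mapTab$chain)) {
      start <- sample.int(n - nFlex + 1L, 1)
      sel <- atomsA$chain == ch & atomsA$resno >= start &
        atomsA$resno < start + nFlex
      atomsA$b[sel] <- 30
      atomsB$b[sel] <- 30
    }
  }

  ## plant cross-links from classified candidates
  proteins <- unique(mapTab$protein)
  nCand <- max(60L * spec@nLinks, 1500L)
  cand <- data.frame(
    protein1 = sample(proteins, nCand, replace = TRUE),
    residue1 = sample.int(n, nCand, replace = TRUE),
    protein2 = sample(proteins, nCand, replace = TRUE),
    residue2 = sample.int(n, nCand, replace = TRUE),
    stringsAsFactors = FALSE)
  key <- apply(cand, 1, function(r) {
    e <- sort(c(paste(r[1], r[2]), paste(r[3], r[4])))
    paste(e, collapse = "|")
  })
  cand <- cand[!duplicated(key) &
                 !(cand$protein1 == cand$protein2 &
                     cand$residue1 == cand$residue2), , drop = FALSE]
  cand$dA <- NA_real_; cand$dB <- NA_real_
  for (i in seq_len(nrow(cand))) {
    cand$dA[i] <- .bruteMinDist(atomsA, mapTab, cand$protein1[i],
                                cand$residue1[i], cand$protein2[i],
                                cand$residue2[i])
    cand$dB[i] <- .bruteMinDist(atomsB, mapTab, cand$protein1[i],
                                cand$residue1[i], cand$protein2[i],
                                cand$residue2[i])
  }
  th <- spec@threshold
  ok <- abs(cand$dA - th) >= spec@margin & abs(cand$dB - th) >= spec@margin
  cand <- cand[ok & !is.na(cand$dA) & !is.na(cand$dB), , drop = FALSE]
  cand$satA <- cand$dA < th
  cand$satB <- cand$dB < th

  nL <- spec@nLinks
  nSatA <- round(nL * spec@satFrac[["A"]])
  nSatB <- round(nL * spec@satFrac[["B"]])
  avail <- function(a, b) which(cand$satA == a & cand$satB == b)
  pick <- NULL
  for (x11 in seq(min(nSatA, nSatB), max(0L, nSatA + nSatB - nL))) {
    x10 <- nSatA - x11; x01 <- nSatB - x11
    x00 <- nL - x11 - x10 - x01
    if (x00 < 0L) next
    b11 <- avail(TRUE, TRUE); b10 <- avail(TRUE, FALSE)
    b01 <- avail(FALSE, TRUE); b00 <- avail(FALSE, FALSE)
    if (length(b11) >= x11 && length(b10) >= x10 &&
        length(b01) >= x01 && length(b00) >= x00) {
      pick <- c(utils::head(b11, x11), utils::head(b10, x10),
                utils::head(b01, x01), utils::head(b00, x00))
      break
    }
  }
  if (is.null(pick))
    stop("infeasible spec: requested satisfied fractions (A=",
         spec@satFrac[["A"]], ", B=", spec@satFrac[["B"]], ") unreachable ",
         "with the generated geometry; candidate buckets hold ",
         length(avail(TRUE, TRUE)), "/", length(avail(TRUE, FALSE)), "/",
         length(avail(FALSE, TRUE)), "/", length(avail(FALSE, FALSE)),
         " (satA.satB = 11/10/01/00) pairs")
  sel <- cand[pick, , drop = FALSE]
  xl <- xlinkSet(sel$protein1, sel$residue1, sel$protein2, sel$residue2)
  truth <- data.frame(
    id = seq_len(nrow(sel)), protein1 = sel$protein1,
    residue1 = sel$residue1, protein2 = sel$protein2,
    residue2 = sel$residue2, distA = sel$dA, distB = sel$dB,
    classA = ifelse(sel$satA, "satisfied", "violated"),
    classB = ifelse(sel$satB, "satisfied", "violated"),
    stringsAsFactors = FALSE)

  if (spec@noise > 0) {
    atomsA[, c("x", "y", "z")] <- atomsA[, c("x", "y", "z")] +
      stats::rnorm(3L * nrow(atomsA), sd = spec@noise)
    atomsB[, c("x", "y", "z")] <- atomsB[, c("x", "y", "z")] +
      stats::rnorm(3L * nrow(atomsB), sd = spec@noise)
  }
  src <- sprintf("synthetic two-state polymer (seed %d)", spec@seed)
  list(modelA = assemblyModel(atomsA, source = paste(src, "state A")),
       modelB = assemblyModel(atomsB, source = paste(src, "state B")),
       map = chainMap(mapTab), xlinks = xl, truth = truth, spec = spec)
}

#' Check 2-fold symmetry of an assembly
#'
#' Applies a 180-degree rotation about the given axis through the assembly
#' centroid and reports the nearest-atom RMSD between the rotated and
#' original coordinates. Exactly symmetric assemblies score 0.
#'
#' @param model an [AssemblyModel].
#' @param axis rotation axis (default z, perpendicular to the generator's
#'   polymer axis x).
#' @return nearest-neighbour RMSD in Angstrom.
#' @export
checkC2Symmetry <- function(model, axis = c(0, 0, 1)) {
  X <- as.matrix(atoms(model)[, c("x", "y", "z")])
  op <- c2Operator(axis, colMeans(X))
  Y <- op$apply(X)
  ## nearest original atom for every rotated atom, chunked
  best <- rep(Inf, nrow(Y))
  chunk <- 512L
  for (s in seq(1L, nrow(Y), by = chunk)) {
    e <- min(nrow(Y), s + chunk - 1L)
    D2 <- crossDist2(Y[s:e, , drop = FALSE], X)
    best[s:e] <- apply(D2, 1, min)
  }
  sqrt(mean(pmax(best, 0)))
}

## ---- occlusion planting -------------------------------------------------

#' Plant a blocking domain over an exposed face
#'
#' Docks a dense blocking pseudo-domain onto the +axis face of one protein
#' copy: every open direction of every face bead that points into the
#' occluded half-space receives a cap bead at one bead diameter plus
#' 1 Angstrom - too close for a 1.4 Angstrom probe to slip between face
#' and block, and dense enough (~3 Angstrom cap spacing) to leave no
#' channels. The returned occluded list is computed by a shadowing oracle
#' that recomputes per-residue accessibility with plain loops (independent
#' of the production SASA path): a bead is planted iff its
#' accessible-direction fraction is at least 0.27 and the majority (55%) of
#' its open directions point into the occluded half-space, i.e. essentially
#' all of its exposure is what the block takes away.
#'
#' @param model an [AssemblyModel] of CA beads.
#' @param map its [ChainMap].
#' @param protein,copy select the face-bearing chain.
#' @param axis occlusion direction: `"x"`, `"y"` or `"z"` (default).
#' @param beadRadius bead radius consistent with [calcSASA()].
#' @param probe probe radius consistent with [calcSASA()].
#' @return list: `model` (with wall chain `ZW` appended), `map` (wall added
#'   as `other`), `occluded` (data.frame chain, resno).
#' @export
plantOcclusion <- function(model, map, protein, copy = 1L, axis = "z",
                           beadRadius = 3.0, probe = 1.4) {
  m <- chainMapTable(map)
  hit <- tolower(m$protein) == tolower(protein) & m$copy == copy
  if (!any(hit))
    stop("face selector matches nothing: no chain for protein '", protein,
         "' copy ", copy)
  ch <- m$chain[hit][1]
  a <- atoms(model)
  ax <- match(axis, c("x", "y", "z"))
  if (is.na(ax)) stop("axis must be x, y or z")
  latIdx <- setdiff(1:3, ax)
  A3 <- as.matrix(a[, c("x", "y", "z")])
  faceSel <- a$chain == ch
  face <- a[faceSel, , drop = FALSE]
  X3 <- A3[faceSel, , drop = FALSE]
  R <- beadRadius + probe

  ## shadowing oracle: loop-based accessibility recomputation per face bead
  dirs <- spherePoints(240L)
  upDir <- dirs[, ax] > 0.05
  planted <- logical(nrow(face))
  accFrac <- numeric(nrow(face))
  openList <- vector("list", nrow(face))
  for (i in seq_len(nrow(face))) {
    ctr <- X3[i, ]
    d2 <- rowSums(sweep(A3, 2, ctr)^2)
    nb <- which(d2 > 1e-9 & d2 < (2 * R)^2)
    pt <- sweep(dirs * R, 2, ctr, "+")
    open <- rep(TRUE, nrow(dirs))
    for (j in nb)
      open <- open & rowSums(sweep(pt, 2, A3[j, ])^2) >= R^2
    accFrac[i] <- mean(open)
    openList[[i]] <- open
    planted[i] <- accFrac[i] >= 0.27 && any(open) &&
      mean(upDir[open]) >= 0.55
  }
  if (!any(planted))
    stop("face selector matches nothing: chain ", ch,
         " has no exposed beads facing +", axis)

  ## blocking domain: cap beads along every open up-direction of every
  ## face bead, then thinned to a ~1.5 Angstrom minimum spacing
  capOff <- 2 * beadRadius + 1.0
  caps <- list()
  for (i in seq_len(nrow(face))) {
    sel <- openList[[i]] & upDir
    if (!any(sel)) next
    caps[[length(caps) + 1L]] <-
      sweep(dirs[sel, , drop = FALSE] * capOff, 2, X3[i, ], "+")
  }
  wall <- do.call(rbind, caps)
  keep <- rep(TRUE, nrow(wall))
  for (i in seq_len(nrow(wall))) {
    if (!keep[i]) next
    later <- which(keep & seq_len(nrow(wall)) > i)
    if (!length(later)) break
    d2 <- rowSums(sweep(wall[later, , drop = FALSE], 2, wall[i, ])^2)
    keep[later[d2 < 1.5^2]] <- FALSE
  }
  wall <- wall[keep, , drop = FALSE]
  wallAtoms <- .beadAtoms(wall, "ZW")
  newAtoms <- rbind(a, wallAtoms)
  newMap <- chainMap(rbind(m, data.frame(
    chain = "ZW", protein = "WALL", copy = 1L, subcomplex = "other",
    unit = NA_integer_, stringsAsFactors = FALSE)))
  list(model = assemblyModel(newAtoms, source = model@provenance$source),
       map = newMap,
       occluded = data.frame(chain = ch, resno = face$resno[planted],
                             stringsAsFactors = FALSE))
}

## ---- rigid-fit ground truth ---------------------------------------------

#' Generate a rigid-body fitting test case with known poses
#'
#' Builds `nBodies` compact random-coil bodies, places them at planted poses
#' (random rotations, well-separated translations), simulates a density map
#' from the planted configuration, and returns the bodies unposed (centred
#' at the origin) together with the planted poses, the map and - for
#' multi-body cases - inter-body cross-links that are satisfied in the
#' planted configuration.
#'
#' @param nBodies 1 or more rigid bodies. Bodies differ in size (the
#'   bead count grows by `sizeStep` per body, as real subcomplexes differ),
#'   so their blurred densities are distinguishable.
#' @param atomsPerBody CA beads in the first body.
#' @param sizeStep extra beads per subsequent body (default 8).
#' @param resolution map resolution, Angstrom (default 25).
#' @param voxel voxel size (default 4).
#' @param nLinks inter-body cross-links to plant (multi-body only).
#' @param seed RNG seed.
#' @return list: `bodies`, `maps` (per body), `posesTrue`, `grid`,
#'   `xlinks`, `resolution`.
#' @export
generateFitCase <- function(nBodies = 1L, atomsPerBody = 24L,
                            resolution = 25, voxel = 4, nLinks = 2L,
                            sizeStep = 8L, seed = 1L) {
  set.seed(as.integer(seed))
  centers <- list(c(0, 0, 0), c(72, 0, 0), c(36, 62, 0), c(0, 72, 56),
                  c(72, 72, 56))
  if (nBodies > length(centers)) stop("at most 5 bodies supported")
  bodies <- list(); maps <- list(); posesTrue <- list(); posedAtoms <- list()
  chains <- c("P", "Q", "R", "S", "T")
  for (b in seq_len(nBodies)) {
    X <- .lBody(atomsPerBody + (b - 1L) * sizeStep)
    bodyName <- sprintf("BODY%d", b)
    bodies[[b]] <- assemblyModel(.beadAtoms(X, chains[b]),
                                 source = sprintf("synthetic body %d", b))
    maps[[b]] <- chainMap(data.frame(
      chain = chains[b], protein = bodyName, copy = 1L,
      subcomplex = "other", unit = NA_integer_, stringsAsFactors = FALSE))
    q <- shoemakeQuat(stats::runif(1), stats::runif(1), stats::runif(1))
    posesTrue[[b]] <- pose(q, centers[[b]], bodyName)
    posedAtoms[[b]] <- atoms(applyPose(bodies[[b]], posesTrue[[b]]))
    if (b > 1L) {
      ## keep consecutive bodies within cross-linking range (nearest beads
      ## ~25 A apart) without creating steric overlap
      Xp <- as.matrix(posedAtoms[[b - 1L]][, c("x", "y", "z")])
      Xb <- as.matrix(posedAtoms[[b]][, c("x", "y", "z")])
      dmin <- sqrt(min(crossDist2(Xp, Xb)))
      if (dmin > 30) {
        dir <- centers[[b - 1L]] - centers[[b]]
        dir <- dir / sqrt(sum(dir^2))
        posesTrue[[b]] <- pose(q, centers[[b]] + dir * (dmin - 25), bodyName)
        posedAtoms[[b]] <- atoms(applyPose(bodies[[b]], posesTrue[[b]]))
      }
    }
  }
  planted <- assemblyModel(do.call(rbind, posedAtoms),
                           source = "planted configuration")
  grid <- simulateDensity(planted, resolution, voxel, pad = resolution)
  xl <- NULL
  if (nBodies > 1L && nLinks > 0L) {
    pr1 <- character(0); r1 <- integer(0); pr2 <- character(0); r2 <- integer(0)
    for (k in seq_len(nLinks)) {
      i <- 1L + (k - 1L) %% (nBodies - 1L)
      j <- i + 1L
      Xi <- as.matrix(posedAtoms[[i]][, c("x", "y", "z")])
      Xj <- as.matrix(posedAtoms[[j]][, c("x", "y", "z")])
      D <- crossDist(Xi, Xj)
      ij <- arrayInd(which.min(D), dim(D))
      pr1 <- c(pr1, sprintf("BODY%d", i)); r1 <- c(r1, ij[1])
      pr2 <- c(pr2, sprintf("BODY%d", j)); r2 <- c(r2, ij[2])
    }
    xl <- xlinkSet(pr1, r1, pr2, r2)
  }
  list(bodies = bodies, maps = maps, posesTrue = posesTrue, grid = grid,
       xlinks = xl, resolution = resolution)
}

#' Rotation and translation error between two poses
#'
#' @param est,true [Pose] objects.
#' @return c(angle = degrees, shift = Angstrom).
#' @export
poseError <- function(est, true) {
  c(angle = quatAngle(est@quat, true@quat),
    shift = sqrt(sum((est@trans - true@trans)^2)))
}
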