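#' @include AllClasses.R constructors.R utils-geometry.R
NULL

## van der Waals radii (Angstrom) by element for SASA; single-bead
## pseudo-residues (one CA atom and nothing else) use `beadRadius` instead,
## since one bead stands for a whole residue.
.vdwRadii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20)

## Tien et al. (2013) theoretical maximal SASA (Angstrom^2), used as the
## reference for relative accessibility of full-atom residues.
.maxSASA <- c(
  ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167, GLN = 225,
  GLU = 223, GLY = 104, HIS = 224, ILE = 197, LEU = 201, LYS = 236,
  MET = 224, PHE = 240, PRO = 159, SER = 155, THR = 172, TRP = 285,
  TYR = 263, VAL = 174)

.atomRadii <- function(a, beadRadius) {
  r <- unname(.vdwRadii[a$element])
  r[is.na(r)] <- 1.70
  ## residues represented by a single CA bead
  key <- paste(a$chain, a$resno, sep = "\r")
  perRes <- table(key)
  isBead <- a$elety == "CA" & perRes[key] == 1L
  r[isBead] <- beadRadius
  r
}

#' Solvent-accessible surface area per residue (Shrake-Rupley)
#'
#' Numerical SASA with a deterministic golden-spiral point set, so results
#' are exactly reproducible for a fixed point count. Coarse-grained models
#' whose residues are single CA beads are supported: each bead gets
#' `beadRadius` instead of an element radius.
#'
#' Relative accessibility divides residue SASA by a reference maximal SASA
#' (Tien-style theoretical maxima for full-atom residues; the isolated-bead
#' sphere area for single-bead residues) and is capped at 1.2 for reporting.
#'
#' @param model an [AssemblyModel] (heavy atoms; burial is computed in the
#'   full assembly context present in the model).
#' @param probe probe radius, Angstrom (1.4 = water).
#' @param nPoints sphere points per atom (default 960).
#' @param beadRadius radius assigned to single-bead residues, Angstrom.
#' @return data.frame with `chain`, `resno`, `resid`, `sasa`, `relAcc`.
#' @export
calcSASA <- function(model, probe = 1.4, nPoints = 960L, beadRadius = 3.0) {
  a <- atoms(model)
  if (nrow(a) == 0L) stop("model has no atoms")
  X <- as.matrix(a[, c("x", "y", "z")])
  r <- .atomRadii(a, beadRadius)
  R <- r + probe
  S <- spherePoints(nPoints)
  n <- nrow(X)
  ## neighbour lists from a chunked all-pairs distance scan
  area <- numeric(n)
  chunk <- 512L
  nbr <- vector("list", n)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    D2 <- crossDist2(X[s:e, , drop = FALSE], X)
    lim2 <- outer(R[s:e], R, "+")^2
    for (k in seq_len(e - s + 1L)) {
      j <- which(D2[k, ] < lim2[k, ])
      nbr[[s + k - 1L]] <- j[j != s + k - 1L]
    }
  }
  for (i in seq_len(n)) {
    P <- S * R[i]
    P <- sweep(P, 2, X[i, ], "+")
    j <- nbr[[i]]
    if (length(j)) {
      D2 <- crossDist2(P, X[j, , drop = FALSE])
      buried <- rowSums(sweep(D2, 2, R[j]^2, "<")) > 0
      frac <- mean(!buried)
    } else frac <- 1
    area[i] <- 4 * pi * R[i]^2 * frac
  }
  key <- paste(a$chain, a$resno, sep = "\r")
  first <- !duplicated(key)
  out <- data.frame(chain = a$chain[first], resno = a$resno[first],
                    resid = a$resid[first], stringsAsFactors = FALSE)
  sums <- tapply(area, key, sum)
  out$sasa <- as.numeric(sums[paste(out$chain, out$resno, sep = "\r")])
  isBead <- as.numeric(table(key)[paste(out$chain, out$resno, sep = "\r")]) == 1
  ref <- unname(.maxSASA[out$resid])
  ref[is.na(ref)] <- mean(.maxSASA)
  ref[isBead] <- 4 * pi * (beadRadius + probe)^2
  out$relAcc <- pmin(out$sasa / ref, 1.2)
  rownames(out) <- NULL
  out
}

.attachIdentity <- function(prof, map) {
  m <- chainMapTable(map)
  idx <- match(prof$chain, m$chain)
  if (any(is.na(idx)))
    stop("profile contains chains absent from the chain map: ",
         paste(unique(prof$chain[is.na(idx)]), collapse = ", "))
  prof$protein <- m$protein[idx]
  prof$copy <- m$copy[idx]
  prof
}

#' State-specific burial differential between two conformations
#'
#' Identifies residues that are surface-accessible in one state but buried
#' in the other: a residue joins a set iff its relative accessibility is
#' `>= accCutoff` in one state and `< buriedCutoff` in the other. Residues
#' are matched across states by protein, copy and author residue number, so
#' the two models must share identities via their chain maps. The two sets
#' are disjoint by construction and swap exactly when A and B are swapped.
#'
#' @param profA,profB accessibility profiles from [calcSASA()].
#' @param mapA,mapB the states' [ChainMap]s.
#' @param buriedCutoff relative accessibility below which a residue is
#'   buried (default 0.10).
#' @param accCutoff relative accessibility at/above which a residue is
#'   accessible (default 0.25).
#' @return list with data.frames `accessibleAburiedB` and
#'   `accessibleBburiedA` (protein, copy, resno, relAccA, relAccB) and the
#'   count `nMatched`.
#' @export
burialDifferential <- function(profA, profB, mapA, mapB,
                               buriedCutoff = 0.10, accCutoff = 0.25) {
  if (buriedCutoff > accCutoff)
    stop("buriedCutoff must not exceed accCutoff")
  pa <- .attachIdentity(profA, mapA)
  pb <- .attachIdentity(profB, mapB)
  keyA <- paste(pa$protein, pa$copy, pa$resno, sep = "\r")
  keyB <- paste(pb$protein, pb$copy, pb$resno, sep = "\r")
  idx <- match(keyA, keyB)
  ok <- !is.na(idx)
  if (!any(ok)) stop("no residues matched between the two states")
  pa <- pa[ok, , drop = FALSE]
  relB <- pb$relAcc[idx[ok]]
  base <- data.frame(protein = pa$protein, copy = pa$copy, resno = pa$resno,
                     relAccA = pa$relAcc, relAccB = relB,
                     stringsAsFactors = FALSE)
  selAB <- base$relAccA >= accCutoff & base$relAccB < buriedCutoff
  selBA <- base$relAccB >= accCutoff & base$relAccA < buriedCutoff
  list(accessibleAburiedB = base[selAB, , drop = FALSE],
       accessibleBburiedA = base[selBA, , drop = FALSE],
       nMatched = nrow(base))
}

#' Cluster a residue set into spatial patches
#'
#' Single-linkage clustering by minimal inter-residue heavy-atom distance:
#' two residues belong to the same patch iff they are connected through
#' steps shorter than `cutoff`. Patches are numbered in decreasing size.
#'
#' @param residues data.frame with `chain` and `resno` columns.
#' @param model the [AssemblyModel] providing coordinates.
#' @param cutoff linkage cutoff in Angstrom (default 6).
#' @return `residues` with a `patch` column added.
#' @export
patchCluster <- function(residues, model, cutoff = 6) {
  if (nrow(residues) == 0L) stop("residue set is empty")
  a <- atoms(model)
  n <- nrow(residues)
  coords <- lapply(seq_len(n), function(i) {
    sel <- a$chain == residues$chain[i] & a$resno == residues$resno[i]
    as.matrix(a[sel, c("x", "y", "z"), drop = FALSE])
  })
  if (any(vapply(coords, nrow, 1L) == 0L))
    stop("residue set contains residues absent from the model")
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    adj[i, j] <- adj[j, i] <- min(crossDist(coords[[i]], coords[[j]])) < cutoff
  }
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] != 0L) next
    cur <- cur + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v] != 0L) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & comp == 0L))
    }
  }
  sizes <- table(comp)
  rank <- match(comp, names(sort(sizes, decreasing = TRUE)))
  residues$patch <- rank
  residues[order(residues$patch), , drop = FALSE]
}

#' Contact graph between repeating units of a polymer
#'
#' Two units are adjacent iff any inter-unit heavy-atom pair lies closer
#' than `cutoff`. Units come from the `unit` column of the chain map.
#'
#' @param model an [AssemblyModel].
#' @param map a [ChainMap] with unit labels.
#' @param cutoff contact cutoff in Angstrom (default 8).
#' @return list with `adjacency` (logical unit x unit matrix) and `degrees`
#'   (data.frame unit, degree); both empty with fewer than 2 units.
#' @export
contactGraph <- function(model, map, cutoff = 8) {
  m <- chainMapTable(map)
  if (all(is.na(m$unit))) stop("chain map carries no unit labels")
  a <- atoms(model)
  unit <- m$unit[match(a$chain, m$chain)]
  units <- sort(unique(unit[!is.na(unit)]))
  if (length(units) < 2L)
    return(list(adjacency = matrix(FALSE, 0, 0),
                degrees = data.frame(unit = integer(), degree = integer())))
  adj <- matrix(FALSE, length(units), length(units),
                dimnames = list(units, units))
  coords <- lapply(units, function(u)
    as.matrix(a[!is.na(unit) & unit == u, c("x", "y", "z"), drop = FALSE]))
  for (i in seq_along(units)) for (j in seq_along(units)) {
    if (j <= i) next
    ## cheap bounding-sphere reject before the all-pairs scan
    ci <- colMeans(coords[[i]]); cj <- colMeans(coords[[j]])
    ri <- sqrt(max(rowSums(sweep(coords[[i]], 2, ci)^2)))
    rj <- sqrt(max(rowSums(sweep(coords[[j]], 2, cj)^2)))
    if (sqrt(sum((ci - cj)^2)) - ri - rj > cutoff) next
    adj[i, j] <- adj[j, i] <-
      min(crossDist2(coords[[i]], coords[[j]])) < cutoff^2
  }
  list(adjacency = adj,
       degrees = data.frame(unit = units, degree = rowSums(adj)))
}

#' Polymer train metrics: stoichiometry and axial geometry
#'
#' Counts IFTB and IFTA complexes from the chain map's subcomplex labels
#' (one complex per distinct copy of each lobe) and reports the assembly's
#' extent along the principal polymer axis - the first principal component
#' of the CA coordinates - plus the spacing between consecutive repeating
#' units along that axis.
#'
#' @param model an [AssemblyModel].
#' @param map a [ChainMap] with subcomplex labels.
#' @return list: `stoichiometry` (IFTB complexes per IFTA complex), `nIFTA`,
#'   `nIFTB`, `axialExtent`, `lengthPerUnit`, `unitSpacing` (NA with one
#'   unit), `nUnits`.
#' @export
trainMetrics <- function(model, map) {
  m <- chainMapTable(map)
  if (all(m$subcomplex == "other"))
    stop("chain map carries no subcomplex labels")
  nA <- max(length(unique(m$copy[m$subcomplex == "IFTA1"])),
            length(unique(m$copy[m$subcomplex == "IFTA2"])))
  nB <- max(length(unique(m$copy[m$subcomplex == "IFTB1"])),
            length(unique(m$copy[m$subcomplex == "IFTB2"])))
  if (nA == 0L) stop("no IFTA subcomplex labels in the chain map")
  a <- atoms(model)
  ca <- a[a$elety == "CA", c("x", "y", "z"), drop = FALSE]
  axis <- stats::prcomp(ca, center = TRUE)$rotation[, 1]
  proj <- as.matrix(ca) %*% axis
  extent <- diff(range(proj))
  unit <- m$unit[match(a$chain, m$chain)][a$elety == "CA"]
  nUnits <- length(unique(unit[!is.na(unit)]))
  if (nUnits == 0L) nUnits <- nA
  spacing <- NA_real_
  if (nUnits > 1L && any(!is.na(unit))) {
    cent <- tapply(proj, unit, mean)
    spacing <- stats::median(diff(sort(cent)))
  }
  list(stoichiometry = nB / nA, nIFTA = nA, nIFTB = nB,
       axialExtent = extent, lengthPerUnit = extent / nUnits,
       unitSpacing = abs(spacing), nUnits = nUnits)
}
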