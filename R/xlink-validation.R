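#' @include AllClasses.R constructors.R
NULL

## Internal: CA-atom site table for one (protein, residue) endpoint.
## Protein matching against the chain map is case-insensitive exact match
## after stripping whitespace; no fuzzy matching.
.endpointSites <- function(model, map, protein, residue) {
  m <- chainMapTable(map)
  hit <- tolower(trimws(m$protein)) == tolower(trimws(protein))
  if (!any(hit)) return(NULL)
  a <- atoms(model)
  sel <- a$chain %in% m$chain[hit] & a$resno == residue & a$elety == "CA"
  if (!any(sel)) return(NULL)
  a[sel, c("chain", "resno", "x", "y", "z"), drop = FALSE]
}

#' Resolve the copy-ambiguous endpoints of a cross-link
#'
#' A residue-level cross-link names a protein and residue, not a chain; in a
#' polymeric assembly every copy of that protein is a candidate site. Returns
#' all CA sites per endpoint; an endpoint with no site (protein absent from
#' the chain map, or residue not modelled) marks the link unmapped.
#'
#' @param model an [AssemblyModel].
#' @param map a [ChainMap], validated against the model.
#' @param protein1,residue1,protein2,residue2 the link's endpoints.
#' @return list with `sites1`, `sites2` (data.frames or NULL) and `mapped`.
#' @export
resolveEndpoints <- function(model, map, protein1, residue1,
                             protein2, residue2) {
  s1 <- .endpointSites(model, map, protein1, residue1)
  s2 <- .endpointSites(model, map, protein2, residue2)
  list(sites1 = s1, sites2 = s2, mapped = !is.null(s1) && !is.null(s2))
}

#' Minimum Calpha-Calpha distance of a cross-link over all copy pairs
#'
#' Copy ambiguity is resolved by taking the minimum distance over all pairs
#' of candidate sites - the most permissive structurally consistent
#' assignment. When both endpoints are the same protein and residue, the
#' pairing of a site with itself (same chain) is excluded, so such a link is
#' measured between two different copies.
#'
#' @inheritParams resolveEndpoints
#' @return list with `distance` (Angstrom, NA when unmapped), `chain1`,
#'   `chain2` (the minimising pair) and `mapped`.
#' @export
minCaDistance <- function(model, map, protein1, residue1,
                          protein2, residue2) {
  ep <- resolveEndpoints(model, map, protein1, residue1, protein2, residue2)
  if (!ep$mapped)
    return(list(distance = NA_real_, chain1 = NA_character_,
                chain2 = NA_character_, mapped = FALSE))
  A <- as.matrix(ep$sites1[, c("x", "y", "z")])
  B <- as.matrix(ep$sites2[, c("x", "y", "z")])
  D <- crossDist(A, B)
  samePoint <- tolower(trimws(protein1)) == tolower(trimws(protein2)) &&
    residue1 == residue2
  if (samePoint) {
    excl <- outer(ep$sites1$chain, ep$sites2$chain, "==")
    D[excl] <- Inf
  }
  if (all(!is.finite(D)))
    return(list(distance = NA_real_, chain1 = NA_character_,
                chain2 = NA_character_, mapped = FALSE))
  ij <- arrayInd(which.min(D), dim(D))
  list(distance = D[ij], chain1 = ep$sites1$chain[ij[1]],
       chain2 = ep$sites2$chain[ij[2]], mapped = TRUE)
}

#' Classify a cross-link distance against the linker threshold
#'
#' Strict inequality: satisfied iff `distance < threshold`; a distance
#' exactly at the threshold is a violation.
#'
#' @param distance Calpha-Calpha distance in Angstrom (>= 0).
#' @param policy a [ThresholdPolicy].
#' @return `"satisfied"` or `"violated"`.
#' @export
classifyDistance <- function(distance, policy = thresholdPolicy()) {
  stopifnot(all(distance >= 0))
  ifelse(distance < policy@threshold, "satisfied", "violated")
}

#' Flexibility rescue of a violated cross-link
#'
#' A violated link is rescued when at least one endpoint residue - or any
#' residue within `rescueWindow` of it on the same chain - has confidence
#' below the cutoff (pLDDT < 50 by default), i.e. the violation is
#' attributable to a segment the model cannot place reliably.
#'
#' @param model an [AssemblyModel] carrying confidence.
#' @param chain1,residue1,chain2,residue2 the minimising site pair.
#' @param policy a [ThresholdPolicy].
#' @return list `rescued` (logical) and `reason` (names the flexible
#'   residue, or NA).
#' @export
flexibilityRescue <- function(model, chain1, residue1, chain2, residue2,
                              policy = thresholdPolicy()) {
  conf <- residueConfidence(model)
  w <- policy@rescueWindow
  for (ep in list(c(chain1, residue1), c(chain2, residue2))) {
    ch <- ep[1]; rn <- as.integer(ep[2])
    sel <- conf$chain == ch & conf$resno >= rn - w & conf$resno <= rn + w &
      !is.na(conf$confidence) & conf$confidence < policy@confCutoff
    if (any(sel)) {
      hit <- conf[sel, , drop = FALSE][1, ]
      return(list(rescued = TRUE,
                  reason = sprintf("%s:%d confidence %.1f < %g", hit$chain,
                                   hit$resno, hit$confidence,
                                   policy@confCutoff)))
    }
  }
  list(rescued = FALSE, reason = NA_character_)
}

#' Map, classify and rescue a set of cross-links on one model
#'
#' The full validation stage: every record is resolved over all copies,
#' measured (minimum Calpha-Calpha distance), classified against the
#' threshold (strict `<`), and - when violated - tested for flexibility
#' rescue. Unmapped links are a classification of their own, never an error.
#'
#' @param model an [AssemblyModel].
#' @param map a [ChainMap].
#' @param xlinks an [XLinkSet].
#' @param policy a [ThresholdPolicy].
#' @return data.frame with one row per record: endpoints, link class,
#'   `distance`, minimising `chain1`/`chain2`, `status` (satisfied /
#'   violated / unmapped), `rescued`, `rescueReason`.
#' @export
validateCrossLinks <- function(model, map, xlinks,
                               policy = thresholdPolicy()) {
  validateChainMap(map, model)
  l <- linkTable(xlinks)
  out <- data.frame(
    id = l$id, protein1 = l$protein1, residue1 = l$residue1,
    protein2 = l$protein2, residue2 = l$residue2, class = l$class,
    distance = NA_real_, chain1 = NA_character_, chain2 = NA_character_,
    status = "unmapped", rescued = NA, rescueReason = NA_character_,
    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(l))) {
    d <- minCaDistance(model, map, l$protein1[i], l$residue1[i],
                       l$protein2[i], l$residue2[i])
    if (!d$mapped) next
    out$distance[i] <- d$distance
    out$chain1[i] <- d$chain1
    out$chain2[i] <- d$chain2
    out$status[i] <- classifyDistance(d$distance, policy)
    if (out$status[i] == "violated") {
      r <- flexibilityRescue(model, d$chain1, l$residue1[i], d$chain2,
                             l$residue2[i], policy)
      out$rescued[i] <- r$rescued
      out$rescueReason[i] <- r$reason
    } else {
      out$rescued[i] <- FALSE
    }
  }
  out
}

#' Histogram of mapped cross-link distances
#'
#' Fixed-width bins over `[0, max)`, left-closed; unmapped links are
#' excluded (reported separately by [validateCrossLinks()]), and the bin
#' counts sum to the number of mapped links.
#'
#' @param reports report data.frame from [validateCrossLinks()].
#' @param binWidth bin width in Angstrom.
#' @return data.frame with `lower`, `upper`, `count`.
#' @export
distanceHistogram <- function(reports, binWidth = 5) {
  d <- reports$distance[reports$status != "unmapped"]
  if (length(d) == 0L) stop("no mapped links to histogram")
  nb <- max(1L, ceiling(max(d) / binWidth + 1e-9))
  idx <- pmin(nb, floor(d / binWidth) + 1L)
  counts <- tabulate(idx, nbins = nb)
  data.frame(lower = (seq_len(nb) - 1) * binWidth,
             upper = seq_len(nb) * binWidth, count = counts)
}

#' Compare cross-link distances between two conformational states
#'
#' Maps the same records onto both models (each with its own chain map) and
#' reports both distances, both classifications and the per-link change
#' `delta = dB - dA`. Links unmapped in either state are flagged and get NA
#' delta.
#'
#' @param modelA,modelB the two [AssemblyModel]s.
#' @param mapA,mapB their [ChainMap]s.
#' @param xlinks an [XLinkSet].
#' @param policy a [ThresholdPolicy].
#' @return data.frame with one row per record.
#' @export
compareStates <- function(modelA, modelB, mapA, mapB, xlinks,
                          policy = thresholdPolicy()) {
  ra <- validateCrossLinks(modelA, mapA, xlinks, policy)
  rb <- validateCrossLinks(modelB, mapB, xlinks, policy)
  data.frame(
    id = ra$id, protein1 = ra$protein1, residue1 = ra$residue1,
    protein2 = ra$protein2, residue2 = ra$residue2, class = ra$class,
    distanceA = ra$distance, distanceB = rb$distance,
    statusA = ra$status, statusB = rb$status,
    delta = rb$distance - ra$distance,
    mappedBoth = ra$status != "unmapped" & rb$status != "unmapped",
    stringsAsFactors = FALSE)
}
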