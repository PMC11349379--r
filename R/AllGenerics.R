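#' @include AllClasses.R
NULL

#' Atom table of an assembly
#' @param x an [AssemblyModel].
#' @return data.frame of atoms.
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname atoms
#' @export
setMethod("atoms", "AssemblyModel", function(x) x@atoms)

#' Number of atoms
#' @param x an [AssemblyModel].
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname nAtoms
#' @export
setMethod("nAtoms", "AssemblyModel", function(x) nrow(x@atoms))

#' Chain identifiers of an assembly or chain map
#' @param x an [AssemblyModel] or [ChainMap].
#' @export
setGeneric("chainIds", function(x) standardGeneric("chainIds"))

#' @rdname chainIds
#' @export
setMethod("chainIds", "AssemblyModel", function(x) unique(x@atoms$chain))

#' @rdname chainIds
#' @export
setMethod("chainIds", "ChainMap", function(x) x@map$chain)

#' Chain-map table
#' @param x a [ChainMap].
#' @export
setGeneric("chainMapTable", function(x) standardGeneric("chainMapTable"))

#' @rdname chainMapTable
#' @export
setMethod("chainMapTable", "ChainMap", function(x) x@map)

#' Per-residue confidence scores
#'
#' Mean B-factor per residue, the slot where prediction confidence (pLDDT)
#' is conventionally stored.
#'
#' @param x an [AssemblyModel].
#' @return data.frame with chain, resno, resid, confidence.
#' @export
setGeneric("residueConfidence", function(x) standardGeneric("residueConfidence"))

#' @rdname residueConfidence
#' @export
setMethod("residueConfidence", "AssemblyModel", function(x) {
  a <- x@atoms
  if (nrow(a) == 0L)
    return(data.frame(chain = character(), resno = integer(),
                      resid = character(), confidence = numeric()))
  key <- paste(a$chain, a$resno, sep = "\r")
  first <- !duplicated(key)
  out <- data.frame(chain = a$chain[first], resno = a$resno[first],
                    resid = a$resid[first], stringsAsFactors = FALSE)
  means <- tapply(a$b, key, function(v) mean(v, na.rm = TRUE))
  out$confidence <- as.numeric(means[paste(out$chain, out$resno, sep = "\r")])
  out[order(out$chain, out$resno), , drop = FALSE]
})

#' Cross-link table
#' @param x an [XLinkSet].
#' @export
setGeneric("linkTable", function(x) standardGeneric("linkTable"))

#' @rdname linkTable
#' @export
setMethod("linkTable", "XLinkSet", function(x) x@links)

#' Number of cross-link records
#' @param x an [XLinkSet].
#' @export
setMethod("length", "XLinkSet", function(x) nrow(x@links))

#' Density values, voxel size and origin of a grid
#' @param x a [DensityGrid].
#' @export
setGeneric("gridData", function(x) standardGeneric("gridData"))

#' @rdname gridData
#' @export
setMethod("gridData", "DensityGrid", function(x) x@data)

#' @rdname gridData
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname gridData
#' @export
setMethod("voxelSize", "DensityGrid", function(x) x@voxel)

#' @rdname gridData
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))

#' @rdname gridData
#' @export
setMethod("gridOrigin", "DensityGrid", function(x) x@origin)

#' Pose accessors
#' @param x a [Pose].
#' @export
setGeneric("poseQuat", function(x) standardGeneric("poseQuat"))

#' @rdname poseQuat
#' @export
setMethod("poseQuat", "Pose", function(x) x@quat)

#' @rdname poseQuat
#' @export
setGeneric("poseTrans", function(x) standardGeneric("poseTrans"))

#' @rdname poseQuat
#' @export
setMethod("poseTrans", "Pose", function(x) x@trans)

#' Fit-library pose table
#' @param x a [FitLibrary].
#' @export
setGeneric("libraryPoses", function(x) standardGeneric("libraryPoses"))

#' @rdname libraryPoses
#' @export
setMethod("libraryPoses", "FitLibrary", function(x) x@poses)

#' Score breakdown accessors
#' @param x a [ScoreBreakdown].
#' @export
setGeneric("scoreTerms", function(x) standardGeneric("scoreTerms"))

#' @rdname scoreTerms
#' @export
setMethod("scoreTerms", "ScoreBreakdown", function(x) x@terms)

#' @rdname scoreTerms
#' @export
setGeneric("scoreWeights", function(x) standardGeneric("scoreWeights"))

#' @rdname scoreTerms
#' @export
setMethod("scoreWeights", "ScoreBreakdown", function(x) x@weights)

#' @rdname scoreTerms
#' @export
setGeneric("totalScore", function(x) standardGeneric("totalScore"))

#' @rdname scoreTerms
#' @export
setMethod("totalScore", "ScoreBreakdown", function(x) x@total)

#' Annealing stages table
#' @param x an [AnnealSchedule].
#' @export
setGeneric("scheduleStages", function(x) standardGeneric("scheduleStages"))

#' @rdname scheduleStages
#' @export
setMethod("scheduleStages", "AnnealSchedule", function(x) x@stages)

## ---- show methods -------------------------------------------------------

setMethod("show", "AssemblyModel", function(object) {
  a <- object@atoms
  nres <- if (nrow(a)) length(unique(paste(a$chain, a$resno))) else 0L
  cat("AssemblyModel:", nrow(a), "atoms,", nres, "residues,",
      length(unique(a$chain)), "chains\n")
  cat("  source:", object@provenance$source %||% "<in memory>", "\n")
})

setMethod("show", "ChainMap", function(object) {
  m <- object@map
  cat("ChainMap:", nrow(m), "chains,",
      length(unique(m$protein)), "proteins\n")
  tab <- table(m$subcomplex)
  cat("  subcomplexes:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
})

setMethod("show", "XLinkSet", function(object) {
  l <- object@links
  cat("XLinkSet:", nrow(l), "residue-pair cross-links (",
      sum(l$class == "self"), "self,", sum(l$class == "heteromeric"),
      "heteromeric )\n")
})

setMethod("show", "DensityGrid", function(object) {
  d <- dim(object@data)
  cat("DensityGrid:", paste(d, collapse = " x "), "voxels @",
      object@voxel, "A\n")
  cat("  origin:", paste(signif(object@origin, 5), collapse = ", "),
      " range:", signif(min(object@data), 4), "..",
      signif(max(object@data), 4), "\n")
})

setMethod("show", "Pose", function(object) {
  cat("Pose[", object@body, "] quat=(",
      paste(signif(object@quat, 4), collapse = ", "), ") trans=(",
      paste(signif(object@trans, 4), collapse = ", "), ")\n")
})

setMethod("show", "FitLibrary", function(object) {
  p <- object@poses
  cat("FitLibrary[", object@body, "]:", nrow(p), "poses in",
      length(unique(p$cluster)), "clusters\n")
  if (nrow(p)) {
    best <- p[p$exemplar & p$cluster == 1, , drop = FALSE]
    cat("  top cluster score:", signif(best$score[1], 4), "\n")
  }
})

setMethod("show", "ScoreBreakdown", function(object) {
  nm <- c("em", "xlink", "connectivity", "exvol", "discrete")
  cat("ScoreBreakdown: total =", signif(object@total, 6), "\n")
  for (k in nm)
    cat(sprintf("  %-12s %12.5g  (w = %g)\n", k, object@terms[[k]],
                object@weights[[k]]))
})

setMethod("show", "AnnealSchedule", function(object) {
  s <- object@stages
  cat("AnnealSchedule:", nrow(s), "stages,", sum(s$steps), "steps\n")
  cat(" ", paste(sprintf("%g/%d", s$temp, s$steps), collapse = "; "), "\n")
})

setMethod("show", "SyntheticSpec", function(object) {
  cat("SyntheticSpec:", object@nUnits, "repeating units,",
      object@atomsPerDomain, "beads/domain, ", object@nLinks,
      "planted links (satFrac A =", object@satFrac[["A"]], ", B =",
      object@satFrac[["B"]], "), noise", object@noise, "A, seed",
      object@seed, "\n")
})

`%||%` <- function(a, b) if (is.null(a)) b else a
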