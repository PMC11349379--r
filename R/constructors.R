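#' @include AllClasses.R
NULL

#' Construct an AssemblyModel from an atom table
#'
#' @param atoms data.frame with columns chain, resno, resid, elety, element,
#'   x, y, z, b. Missing `element` is inferred from the atom name; missing
#'   `b` becomes NA.
#' @param source provenance label.
#' @param model model number (for multi-model files).
#' @return an [AssemblyModel].
#' @export
assemblyModel <- function(atoms, source = NA_character_, model = 1L) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (is.null(atoms$element))
    atoms$element <- substr(gsub("[^A-Za-z].*", "", atoms$elety), 1, 1)
  if (is.null(atoms$b)) atoms$b <- NA_real_
  atoms$resno <- as.integer(atoms$resno)
  rownames(atoms) <- NULL
  new("AssemblyModel",
      atoms = atoms[, c("chain", "resno", "resid", "elety", "element",
                        "x", "y", "z", "b")],
      provenance = list(source = source, model = as.integer(model)))
}

#' Construct a ChainMap
#'
#' @param chain,protein,copy,subcomplex,unit parallel vectors (unit optional),
#'   or a single data.frame in `chain`.
#' @return a [ChainMap].
#' @export
chainMap <- function(chain, protein = NULL, copy = NULL,
                     subcomplex = "other", unit = NA_integer_) {
  if (is.data.frame(chain)) {
    m <- chain
  } else {
    m <- data.frame(chain = as.character(chain),
                    protein = as.character(protein),
                    copy = as.integer(copy),
                    subcomplex = as.character(subcomplex),
                    unit = as.integer(unit),
                    stringsAsFactors = FALSE)
  }
  if (is.null(m$unit)) m$unit <- NA_integer_
  rownames(m) <- NULL
  new("ChainMap", map = m)
}

#' Validate a ChainMap against a model
#'
#' Downstream stages refuse to run when the model contains chains the map
#' does not describe; this is where that is enforced.
#'
#' @param map a [ChainMap].
#' @param model an [AssemblyModel].
#' @return invisibly TRUE, or an error naming the unmapped chains.
#' @export
validateChainMap <- function(map, model) {
  missing <- setdiff(chainIds(model), map@map$chain)
  if (length(missing))
    stop("chains present in the model but absent from the chain map: ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Construct an XLinkSet from endpoint vectors
#'
#' @param protein1,residue1,protein2,residue2 endpoint vectors.
#' @param score optional numeric score.
#' @return an [XLinkSet]; link class is derived from the protein names
#'   (case-insensitive, whitespace-stripped comparison).
#' @export
xlinkSet <- function(protein1, residue1, protein2, residue2, score = NA_real_) {
  p1 <- trimws(as.character(protein1))
  p2 <- trimws(as.character(protein2))
  n <- length(p1)
  l <- data.frame(protein1 = p1, residue1 = as.integer(residue1),
                  protein2 = p2, residue2 = as.integer(residue2),
                  class = ifelse(tolower(p1) == tolower(p2),
                                 "self", "heteromeric"),
                  score = rep_len(as.numeric(score), n),
                  id = seq_len(max(n, 0L)),
                  stringsAsFactors = FALSE)
  if (n == 0L) l <- l[0, , drop = FALSE]
  new("XLinkSet", links = l)
}

#' Construct a DensityGrid
#'
#' @param data 3-D numeric array, x index fastest.
#' @param voxel voxel edge (Angstrom).
#' @param origin centre of voxel (1,1,1) in Angstrom.
#' @export
densityGrid <- function(data, voxel, origin = c(0, 0, 0)) {
  new("DensityGrid", data = data, voxel = as.numeric(voxel),
      origin = as.numeric(origin))
}

#' Construct a ThresholdPolicy
#'
#' @param threshold satisfied/violated cutoff in Angstrom (strict `<`).
#' @param confCutoff confidence below which a residue counts as flexible.
#' @param rescueWindow residues around an endpoint inspected for flexibility.
#' @export
thresholdPolicy <- function(threshold = 35, confCutoff = 50, rescueWindow = 0L) {
  new("ThresholdPolicy", threshold = threshold, confCutoff = confCutoff,
      rescueWindow = as.integer(rescueWindow))
}

#' Construct a Pose
#' @param quat unit quaternion (w, x, y, z).
#' @param trans centroid target position (Angstrom).
#' @param body body identifier.
#' @export
pose <- function(quat = c(1, 0, 0, 0), trans = c(0, 0, 0),
                 body = NA_character_) {
  new("Pose", quat = quat / sqrt(sum(quat^2)), trans = as.numeric(trans),
      body = body)
}

#' Construct an AnnealSchedule
#'
#' With no arguments this is the default six-stage regime
#' (75000/1000, 30000/800, 10000/800, 5000/500, 1000/500, 300/300).
#'
#' @param temp strictly decreasing temperatures.
#' @param steps positive step counts, same length.
#' @export
annealSchedule <- function(temp = NULL, steps = NULL) {
  if (is.null(temp)) return(new("AnnealSchedule"))
  new("AnnealSchedule",
      stages = data.frame(temp = as.numeric(temp), steps = as.integer(steps)))
}

#' Construct a SyntheticSpec
#'
#' Defaults describe the polymer system the generator emulates: five
#' repeating units of one IFTA + two IFTB complexes; state-A sub-polymer
#' repeats 115 and 65 Angstrom; state-B visible repeat 450 Angstrom shared
#' by two repeating units, with C2 axes perpendicular to the polymer axis.
#'
#' @param nUnits,domainsPerSubcomplex,atomsPerDomain lattice composition.
#' @param spacingA named numeric(2) (IFTA, IFTB) state-A repeats, Angstrom.
#' @param visibleRepeatB,unitsPerVisibleRepeat state-B geometry.
#' @param nLinks,satFrac,margin,threshold cross-link planting controls.
#' @param flexFrac fraction of residues given confidence < 50.
#' @param noise coordinate noise SD, Angstrom.
#' @param seed RNG seed recorded in provenance.
#' @export
syntheticSpec <- function(nUnits = 5L, domainsPerSubcomplex = 1L,
                          atomsPerDomain = 50L,
                          spacingA = c(IFTA = 115, IFTB = 65),
                          visibleRepeatB = 450, unitsPerVisibleRepeat = 2L,
                          nLinks = 40L, satFrac = c(A = 0.8, B = 0.95),
                          margin = 5, threshold = 35, flexFrac = 0.1,
                          noise = 0, seed = 1L) {
  new("SyntheticSpec", nUnits = as.integer(nUnits),
      domainsPerSubcomplex = as.integer(domainsPerSubcomplex),
      atomsPerDomain = as.integer(atomsPerDomain),
      spacingA = spacingA, visibleRepeatB = visibleRepeatB,
      unitsPerVisibleRepeat = as.integer(unitsPerVisibleRepeat),
      nLinks = as.integer(nLinks), satFrac = satFrac, margin = margin,
      threshold = threshold, flexFrac = flexFrac, noise = noise,
      seed = as.integer(seed))
}
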